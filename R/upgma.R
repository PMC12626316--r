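#' UPGMA (average-linkage) agglomerative clustering
#'
#' Unweighted pair-group agglomeration on a labelled distance matrix.  At
#' each step the two clusters with the smallest average inter-cluster
#' distance are joined; the merge is recorded at *half* that distance, so a
#' pair of leaves separated by genetic distance 0.24 joins at height 0.12
#' and "cutting the tree at genetic distance x" means cutting at height x
#' (see [cut_dendrogram()]).  Ties are broken by the lexicographically
#' smallest pair of cluster labels (a cluster is labelled by its smallest
#' member), which makes the merge sequence invariant to input row order.
#'
#' The result is `hclust`-compatible (plot, [stats::cutree()],
#' [stats::cophenetic()] all work) with class `c("upgma", "hclust")`.
#'
#' @param d symmetric distance matrix with labels, or a `dist` object
#' @param height_scale `"half"` (default, heights = average distance / 2)
#'   or `"distance"` (heights on the raw distance scale, as
#'   `stats::hclust(method = "average")` reports them)
#' @return an object of class `c("upgma", "hclust")`
#' @examples
#' d <- matrix(c(0, .24, .24, 0), 2, dimnames = list(c("A","B"), c("A","B")))
#' t <- upgma(d)
#' t$height  # 0.12
#' @export
upgma <- function(d, height_scale = c("half", "distance")) {
  height_scale <- match.arg(height_scale)
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-12)) stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n < 2L) stop("need at least two leaves")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("L", seq_len(n))
  div <- if (height_scale == "half") 2 else 1

  # active clusters: id (negative leaf index or merge step), members, label
  cl <- lapply(seq_len(n), function(i)
    list(id = -i, members = i, label = labs[i]))
  dm <- d  # dm[i,j] = average distance between active clusters i and j
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(cl)
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      cand <- dm[i, j]
      lab <- sort(c(cl[[i]]$label, cl[[j]]$label))
      if (is.null(best) || cand < best$d - 1e-15 ||
          (abs(cand - best$d) <= 1e-15 &&
           (lab[1] < best$lab[1] || (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
        best <- list(i = i, j = j, d = cand, lab = lab)
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort(c(cl[[i]]$id, cl[[j]]$id))
    height[step] <- best$d / div
    ni <- length(cl[[i]]$members); nj <- length(cl[[j]]$members)
    newd <- (ni * dm[i, ] + nj * dm[j, ]) / (ni + nj)  # size-weighted average
    newcl <- list(id = step,
                  members = c(cl[[i]]$members, cl[[j]]$members),
                  label = min(cl[[i]]$label, cl[[j]]$label))
    keep <- setdiff(seq_len(k), c(i, j))
    dm <- rbind(cbind(dm[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    cl <- c(cl[keep], list(newcl))
  }
  # absorb floating-point ties: average linkage cannot truly invert heights
  for (s in seq_len(max(n - 2L, 0L)))
    if (height[s + 1L] < height[s] && height[s] - height[s + 1L] < 1e-9)
      height[s + 1L] <- height[s]
  out <- structure(list(merge = merge, height = height,
                        order = tree_leaf_order(merge),
                        labels = labs, method = "upgma",
                        call = match.call(), dist.method = "user"),
                   class = c("upgma", "hclust"))
  out
}

# leaf plotting order by in-order traversal of the merge tree
tree_leaf_order <- function(merge) {
  rec <- function(node) {
    if (node < 0L) return(-node)
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  rec(nrow(merge))
}

#' Cut a dendrogram into groups
#'
#' Removes all merges above the threshold and returns the resulting group
#' memberships.  Exactly one of `height` and `k` must be given.  Group
#' numbers are assigned deterministically in order of each group's first
#' leaf (as in [stats::cutree()]).
#'
#' @param tree an `hclust`-like tree (e.g. [upgma()])
#' @param height cut height, on the tree's own height scale
#' @param k desired number of groups
#' @return named integer vector of group memberships
#' @export
cut_dendrogram <- function(tree, height = NULL, k = NULL) {
  if (is.null(height) == is.null(k))
    stop("supply exactly one of `height` and `k`")
  if (!is.null(k) && k > length(tree$labels))
    stop("k exceeds the number of leaves")
  cutree(stats::as.hclust(tree), k = k, h = height)
}

#' Cophenetic distance matrix of an ultrametric tree
#'
#' For each pair of leaves, twice the height of their lowest common merge:
#' the tree's implied distances on the same scale as the input to [upgma()]
#' under its half-distance height convention.
#'
#' @param tree an `hclust`-like tree with half-distance heights
#' @return symmetric labelled distance matrix
#' @export
cophenetic_matrix <- function(tree) {
  2 * as.matrix(cophenetic(stats::as.hclust(tree)))
}
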
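#' Codominant genotype matrix
#'
#' Container for diploid codominant marker calls: for each individual and
#' locus an unordered pair of allele labels (integer fragment sizes in bp),
#' or missing.  Allele identity is exact label equality, as produced by
#' fragment-sizing software.  Calls are stored with the smaller label first
#' so that `(100, 104)` and `(104, 100)` are the same genotype.
#'
#' @param alleles integer array of dimension `n_individuals x n_loci x 2`
#'   (dimnames give individual and locus names), or a matrix with two
#'   adjacent columns per locus.  A missing call has `NA` in both slots.
#' @param pop factor (or character) of population codes, one per individual.
#'   Names, if present, must match the individual names.
#' @param loci optional data.frame of locus metadata with at least a `name`
#'   column (e.g. repeat motif, expected fragment size, annealing
#'   temperature).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `alleles` (the `n x L x 2` array), `pop` (factor) and `loci`
#'   (data.frame).
#' @examples
#' a <- array(c(100L, 100L, 104L, 100L), dim = c(2, 1, 2),
#'            dimnames = list(c("i1", "i2"), "L1", NULL))
#' g <- genotype_matrix(a, pop = c("P1", "P1"))
#' n_alleles(g)
#' @export
genotype_matrix <- function(alleles, pop, loci = NULL) {
  if (is.matrix(alleles)) {
    if (ncol(alleles) %% 2L != 0L)
      stop("allele matrix must have two columns per locus")
    L <- ncol(alleles) / 2L
    nm <- colnames(alleles)[seq(1L, by = 2L, length.out = L)]
    alleles <- array(as.integer(alleles[, c(seq(1L, 2L * L, 2L), seq(2L, 2L * L, 2L))]),
                     dim = c(nrow(alleles), L, 2L),
                     dimnames = list(rownames(alleles), nm, NULL))
  }
  stopifnot(is.array(alleles), length(dim(alleles)) == 3L, dim(alleles)[3] == 2L)
  storage.mode(alleles) <- "integer"
  n <- dim(alleles)[1]; L <- dim(alleles)[2]
  if (is.null(dimnames(alleles)[[1]])) dimnames(alleles)[[1]] <- paste0("I", seq_len(n))
  if (is.null(dimnames(alleles)[[2]])) dimnames(alleles)[[2]] <- paste0("L", seq_len(L))
  if (anyDuplicated(dimnames(alleles)[[2]]))
    stop("locus names must be unique")
  miss1 <- is.na(alleles[, , 1, drop = FALSE]); miss2 <- is.na(alleles[, , 2, drop = FALSE])
  if (any(miss1 != miss2))
    stop("half-missing calls: each call must carry two allele labels or none")
  if (any(alleles <= 0L, na.rm = TRUE))
    stop("allele labels must be positive integers")
  # canonical unordered storage: smaller label first
  a1 <- pmin(alleles[, , 1, drop = FALSE], alleles[, , 2, drop = FALSE])
  a2 <- pmax(alleles[, , 1, drop = FALSE], alleles[, , 2, drop = FALSE])
  alleles[, , 1] <- a1; alleles[, , 2] <- a2

  if (length(pop) != n) stop("`pop` must have one entry per individual")
  if (!is.null(names(pop)) && !identical(names(pop), dimnames(alleles)[[1]]))
    stop("names of `pop` do not match individual names")
  pop <- if (is.factor(pop)) droplevels(pop) else factor(pop, levels = unique(pop))
  if (any(table(pop) == 0L)) stop("every population must be non-empty")

  if (is.null(loci)) loci <- data.frame(name = dimnames(alleles)[[2]])
  if (!all(dimnames(alleles)[[2]] %in% loci$name))
    stop("`loci` metadata does not cover all loci")

  structure(list(alleles = alleles, pop = pop, loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- dim(x$alleles)
  miss <- sum(is.na(x$alleles[, , 1]))
  cat(sprintf("genotype_matrix: %d individuals x %d loci, %d populations\n",
              d[1], d[2], nlevels(x$pop)))
  cat(sprintf("  missing calls: %d (%.1f%%)\n", miss, 100 * miss / (d[1] * d[2])))
  cat("  populations:", paste(sprintf("%s (%d)", levels(x$pop), table(x$pop)),
                              collapse = ", "), "\n")
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g a `genotype_matrix`
#' @export
individuals <- function(g) dimnames(g$alleles)[[1]]

#' @rdname genotype_matrix
#' @export
locus_names <- function(g) dimnames(g$alleles)[[2]]

#' Observed allele counts per locus
#'
#' Number of distinct allele labels seen at each locus (Na).
#'
#' @param g a [genotype_matrix()]
#' @param subset individuals to include (names or indices); default all
#' @return named integer vector, one entry per locus
#' @export
n_alleles <- function(g, subset = NULL) {
  a <- g$alleles
  if (!is.null(subset)) a <- a[subset, , , drop = FALSE]
  vapply(seq_len(dim(a)[2]), function(l) {
    length(unique(stats::na.omit(c(a[, l, ]))))
  }, integer(1)) |> setNames(dimnames(a)[[2]])
}

#' Allele-sharing distance between individuals
#'
#' `1 - shared/(2L)` where `shared` counts allele matches between the two
#' genotypes at each locus (0, 1 or 2, with heterozygote/homozygote overlap
#' handled by multiset intersection) and `L` is the number of loci with
#' non-missing calls in both individuals.
#'
#' @param g a [genotype_matrix()]
#' @return symmetric distance matrix with individual labels
#' @export
allele_sharing_distance <- function(g) {
  a <- g$alleles
  n <- dim(a)[1]; L <- dim(a)[2]
  d <- matrix(0, n, n, dimnames = list(individuals(g), individuals(g)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- 0L; used <- 0L
    for (l in seq_len(L)) {
      x <- a[i, l, ]; y <- a[j, l, ]
      if (anyNA(x) || anyNA(y)) next
      used <- used + 1L
      # multiset intersection size of two unordered pairs
      s <- 0L
      yy <- y
      for (al in x) {
        hit <- match(al, yy)
        if (!is.na(hit)) { s <- s + 1L; yy <- yy[-hit] }
      }
      shared <- shared + s
    }
    d[i, j] <- d[j, i] <- if (used > 0L) 1 - shared / (2 * used) else NA_real_
  }
  d
}
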
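#' Three-level analysis of molecular variance (AMOVA)
#'
#' Excoffier-style AMOVA for codominant diploid data on allele copies, with
#' the 0/1 allele-mismatch distance summed over loci.  Variance is
#' partitioned into among populations (df `k - 1`), among individuals
#' within populations (df `N - k`) and within individuals (df `N`).  Sums
#' of squares use the pairwise-distance identity
#' `SS = sum_{i<j} d_ij / n` within each grouping level, summed over loci
#' with per-locus deletion of missing calls.  Variance components follow
#' the standard unequal-sample-size estimators: `sigma2_c = MS_WI`,
#' `sigma2_b = (MS_AI - MS_WI)/2`, `sigma2_a = (MS_AP - MS_AI)/(2 n0)` with
#' `n0 = (N - sum(n_i^2)/N)/(k - 1)`.  Negative components are reported raw
#' but truncated to zero for the percentage column (flagged via the
#' `truncated` attribute).  `Fst = sigma2_a / sigma2_total`.
#'
#' @param g a [genotype_matrix()]
#' @param pop optional population factor overriding `g$pop`
#' @return object of class `amova_table`: a data.frame with rows for the
#'   three strata plus a total (columns `df`, `ss`, `ms`, `sigma2`, `pct`),
#'   with attributes `fst`, `fis`, `fit`, `n0`, `truncated`
#' @export
amova <- function(g, pop = NULL) {
  if (is.null(pop)) pop <- g$pop
  pop <- droplevels(as.factor(pop))
  a <- g$alleles
  N <- dim(a)[1]; L <- dim(a)[2]; k <- nlevels(pop)
  if (k < 2L) stop("AMOVA needs at least two populations")
  sizes <- as.integer(table(pop))
  if (any(sizes < 2L))
    stop("singleton population(s): ",
         paste(levels(pop)[sizes < 2L], collapse = ", "))

  # SS of a set of allele copies under the 0/1 mismatch metric:
  # sum_{i<j} d_ij / n = (n - sum(c_a^2)/n) / 2
  ss_copies <- function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2L) return(0)
    (n - sum(table(x)^2) / n) / 2
  }

  ss_total <- ss_wp <- ss_wi <- 0
  for (l in seq_len(L)) {
    x <- c(a[, l, 1], a[, l, 2])
    ss_total <- ss_total + ss_copies(x)
    for (p in levels(pop)) {
      sel <- pop == p
      ss_wp <- ss_wp + ss_copies(c(a[sel, l, 1], a[sel, l, 2]))
    }
    het <- a[, l, 1] != a[, l, 2]
    ss_wi <- ss_wi + sum(het, na.rm = TRUE) / 2
  }
  ss_ap <- ss_total - ss_wp       # among populations
  ss_ai <- ss_wp - ss_wi          # among individuals within populations

  df <- c(k - 1L, N - k, N)
  ss <- c(ss_ap, ss_ai, ss_wi)
  ms <- ss / df
  n0 <- (N - sum(sizes^2) / N) / (k - 1)
  sig_c <- ms[3]
  sig_b <- (ms[2] - ms[3]) / 2
  sig_a <- (ms[1] - ms[2]) / (2 * n0)
  sig <- c(sig_a, sig_b, sig_c)
  trunc <- pmax(sig, 0)
  truncated <- any(sig < 0)
  pct <- 100 * trunc / sum(trunc)
  tot <- sum(trunc)

  out <- data.frame(
    stratum = c("Among populations", "Among individuals within populations",
                "Within individuals", "Total"),
    df = c(df, sum(df)), ss = c(ss, sum(ss)), ms = c(ms, NA),
    sigma2 = c(sig, sum(sig)), pct = c(pct, 100))
  structure(out, class = c("amova_table", "data.frame"),
            fst = trunc[1] / tot,
            fis = if (trunc[2] + trunc[3] > 0) trunc[2] / (trunc[2] + trunc[3]) else NA_real_,
            fit = (trunc[1] + trunc[2]) / tot,
            n0 = n0, truncated = truncated)
}

#' @export
print.amova_table <- function(x, ...) {
  cat("Analysis of molecular variance (codominant, allele-mismatch distance)\n")
  df <- as.data.frame(x)
  df$ss <- round(df$ss, 2); df$ms <- round(df$ms, 2)
  df$sigma2 <- round(df$sigma2, 3); df$pct <- round(df$pct, 2)
  print(df, row.names = FALSE)
  cat(sprintf("Fst = %.3f, Fis = %.3f, Fit = %.3f\n",
              attr(x, "fst"), attr(x, "fis"), attr(x, "fit")))
  if (isTRUE(attr(x, "truncated")))
    cat("note: negative variance component(s) truncated to 0 for percentages\n")
  invisible(x)
}

#' Pairwise population differentiation (Fst) and gene flow (Nm)
#'
#' Runs a two-population AMOVA for every population pair and reports
#' `Fst = sigma2_a / sigma2_total` (negative estimates truncated to 0),
#' together with the island-model gene flow [gene_flow()].
#'
#' @param g a [genotype_matrix()]
#' @return list with symmetric matrices `fst` and `nm`
#' @export
pairwise_fst <- function(g) {
  pops <- levels(g$pop)
  k <- length(pops)
  fst <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sel <- g$pop %in% pops[c(i, j)]
    sub <- genotype_matrix(g$alleles[sel, , , drop = FALSE],
                           pop = droplevels(g$pop[sel]))
    f <- attr(amova(sub), "fst")
    fst[i, j] <- fst[j, i] <- max(f, 0)
  }
  nm <- suppressWarnings(apply(fst, c(1, 2), gene_flow))
  diag(nm) <- NA
  list(fst = fst, nm = nm)
}

#' Island-model gene flow from Fst
#'
#' `Nm = (1 - Fst) / (4 Fst)`: effective migrants per generation under
#' Wright's island model.
#'
#' @param fst differentiation coefficient in `[0, 1]`
#' @return Nm (with `Inf` and a warning for `fst <= 0`, 0 for `fst >= 1`)
#' @export
gene_flow <- function(fst) {
  if (is.na(fst)) return(NA_real_)
  if (fst <= 0) {
    warning("Fst <= 0: gene flow effectively unbounded")
    return(Inf)
  }
  if (fst >= 1) return(0)
  (1 - fst) / (4 * fst)
}

#' Nei (1972) standard genetic distance between populations
#'
#' `D = -ln( J_XY / sqrt(J_X * J_Y) )` where `J_XY` is the mean over loci
#' of the probability of allele identity between populations
#' (`sum_a x_a y_a`) and `J_X`, `J_Y` the within-population analogues.
#' Loci missing in either population of a pair are excluded pairwise.
#'
#' @param freqs_by_pop per-population allele frequencies as produced by
#'   `allele_frequencies(g, by_pop = TRUE)`
#' @return symmetric labelled distance matrix (`Inf` where populations
#'   share no alleles at any locus)
#' @export
nei_distance <- function(freqs_by_pop) {
  pops <- names(freqs_by_pop)
  k <- length(pops)
  d <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    fx <- freqs_by_pop[[i]]; fy <- freqs_by_pop[[j]]
    loci <- intersect(names(fx)[!vapply(fx, is.null, logical(1))],
                      names(fy)[!vapply(fy, is.null, logical(1))])
    if (length(loci) == 0L) stop("no shared loci between ", pops[i], " and ", pops[j])
    jxy <- jx <- jy <- numeric(length(loci))
    for (m in seq_along(loci)) {
      x <- fx[[loci[m]]]; y <- fy[[loci[m]]]
      shared <- intersect(names(x), names(y))
      jxy[m] <- sum(x[shared] * y[shared])
      jx[m] <- sum(x^2); jy[m] <- sum(y^2)
    }
    J <- mean(jxy) / sqrt(mean(jx) * mean(jy))
    d[i, j] <- d[j, i] <- if (J > 0) -log(J) else {
      warning("no allele identity between ", pops[i], " and ", pops[j],
              ": distance is infinite")
      Inf
    }
  }
  d
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the strictly-lower-triangle entries, with a
#' one-tailed permutation p-value under simultaneous row/column permutation
#' of the second matrix: `p = (#{r_perm >= r_obs} + 1) / (n_perm + 1)`.
#'
#' @param d1,d2 symmetric labelled distance matrices over the same labels
#'   (d2 is reordered to d1's labels if needed)
#' @param n_perm number of permutations (>= 99; default 9999)
#' @param seed optional RNG seed for reproducibility
#' @return list with `r`, `p`, `n_perm` and the permuted statistics
#'   `perm_r`
#' @export
mantel_test <- function(d1, d2, n_perm = 9999, seed = NULL) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2)))
      stop("matrix labels do not match")
    d2 <- d2[rownames(d1), rownames(d1)]
  } else if (!all(dim(d1) == dim(d2))) stop("matrix dimensions do not match")
  if (n_perm < 99) stop("use at least 99 permutations")
  n <- nrow(d1)
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  if (sd(v1) == 0 || sd(d2[lt]) == 0)
    stop("zero variance in a distance triangle: Mantel r undefined")
  if (!is.null(seed)) set.seed(seed)
  r_obs <- cor(v1, d2[lt])
  perm_r <- vapply(seq_len(n_perm), function(b) {
    o <- sample.int(n)
    cor(v1, d2[o, o][lt])
  }, numeric(1))
  list(r = r_obs,
       p = (sum(perm_r >= r_obs) + 1) / (n_perm + 1),
       n_perm = n_perm, perm_r = perm_r)
}
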
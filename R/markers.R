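#' Allele frequencies per locus
#'
#' Tallies allele copies (two per non-missing call) and normalizes.  With
#' `by_pop = TRUE` the tally is done separately within each population
#' (per-locus deletion of missing calls; a population with no data at a
#' locus gets `NULL` there).
#'
#' @param g a [genotype_matrix()]
#' @param subset individuals to include (names or indices); default all
#' @param by_pop tally within populations instead of overall?
#' @return for `by_pop = FALSE`, a list with one named frequency vector per
#'   locus (attribute `n_copies` = allele copies counted); for
#'   `by_pop = TRUE`, a list of such lists, one per population
#' @export
allele_frequencies <- function(g, subset = NULL, by_pop = FALSE) {
  a <- g$alleles; pop <- g$pop
  if (!is.null(subset)) {
    if (is.character(subset)) subset <- match(subset, individuals(g))
    a <- a[subset, , , drop = FALSE]; pop <- droplevels(pop[subset])
  }
  if (dim(a)[1] == 0L) stop("empty individual subset")
  tally <- function(arr) {
    lapply(setNames(seq_len(dim(arr)[2]), dimnames(arr)[[2]]), function(l) {
      x <- c(arr[, l, ]); x <- x[!is.na(x)]
      if (length(x) == 0L) return(NULL)
      tab <- table(factor(x, levels = sort(unique(x))))
      structure(as.numeric(tab) / length(x),
                names = names(tab), n_copies = length(x))
    })
  }
  if (!by_pop) return(tally(a))
  lapply(setNames(levels(pop), levels(pop)),
         function(p) tally(a[pop == p, , , drop = FALSE]))
}

#' Effective number of alleles
#'
#' `Ne = 1 / sum(p^2)`: the number of equally frequent alleles giving the
#' same expected homozygosity.
#'
#' @param p allele frequency vector
#' @return Ne, between 1 and the allele count
#' @export
effective_alleles <- function(p) 1 / sum(p^2)

#' Shannon information index of an allele frequency vector
#'
#' `I = -sum(p * ln p)`, the same kernel as the phenotypic H'
#' (see [shannon_index()]).
#'
#' @param p allele frequency vector
#' @return I in nats
#' @export
shannon_information <- function(p) shannon_index(p)

#' Observed heterozygosity at a locus
#'
#' Fraction of non-missing calls whose two allele labels differ.
#'
#' @param g a [genotype_matrix()]
#' @param locus locus name or index
#' @param subset individuals to include; default all
#' @return Ho in `[0, 1]`, or `NA` if every call is missing
#' @export
observed_heterozygosity <- function(g, locus, subset = NULL) {
  a <- g$alleles
  if (!is.null(subset)) a <- a[subset, , , drop = FALSE]
  a1 <- a[, locus, 1]; a2 <- a[, locus, 2]
  ok <- !is.na(a1)
  if (!any(ok)) return(NA_real_)
  mean(a1[ok] != a2[ok])
}

#' Expected heterozygosity
#'
#' `He = 1 - sum(p^2)` (the biased form used by GenAlEx by default);
#' `unbiased = TRUE` applies the small-sample correction
#' `2n/(2n - 1) * He` using the allele-copy count carried by the frequency
#' vector (or given as `n_copies`).
#'
#' @param p allele frequency vector
#' @param unbiased apply the 2n/(2n-1) correction?
#' @param n_copies allele copies behind `p` (defaults to its `n_copies`
#'   attribute); only needed when `unbiased = TRUE`
#' @return He in `[0, 1)`
#' @export
expected_heterozygosity <- function(p, unbiased = FALSE, n_copies = attr(p, "n_copies")) {
  he <- 1 - sum(p^2)
  if (unbiased) {
    if (is.null(n_copies)) stop("`n_copies` needed for the unbiased estimator")
    he <- n_copies / (n_copies - 1) * he
  }
  he
}

#' Within-locus fixation index
#'
#' `F = 1 - Ho/He`: positive under heterozygote deficit, negative under
#' excess.  Undefined (`NA`) for monomorphic loci.
#'
#' @param ho observed heterozygosity
#' @param he expected heterozygosity
#' @return F, or `NA` when `he == 0`
#' @export
fixation_index <- function(ho, he) ifelse(he > 0, 1 - ho / he, NA_real_)

#' Polymorphism information content
#'
#' Botstein's PIC: `1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`.
#'
#' @param p allele frequency vector
#' @return PIC in `[0, 1)`
#' @export
pic <- function(p) {
  p2 <- p^2
  1 - sum(p2) - (sum(p2)^2 - sum(p2^2))  # sum_{i<j} 2 p_i^2 p_j^2
}

#' Per-locus diversity summary
#'
#' Na, Ne, I, Ho, He, F and PIC for every locus over all individuals, plus
#' totals (Na, Ne) and means across loci, mirroring a standard SSR panel
#' polymorphism table.
#'
#' @param g a [genotype_matrix()]
#' @param unbiased_he use the small-sample-corrected He?
#' @return data.frame with one row per locus; attributes `totals` and
#'   `means` carry the panel summaries
#' @export
summarize_loci <- function(g, unbiased_he = FALSE) {
  fr <- allele_frequencies(g)
  rows <- lapply(locus_names(g), function(l) {
    p <- fr[[l]]
    if (is.null(p)) stop("locus ", l, " has no non-missing calls")
    ho <- observed_heterozygosity(g, l)
    he <- expected_heterozygosity(p, unbiased = unbiased_he)
    data.frame(locus = l, na = length(p), ne = effective_alleles(p),
               i = shannon_information(p), ho = ho, he = he,
               f = fixation_index(ho, he), pic = pic(p))
  })
  out <- do.call(rbind, rows)
  attr(out, "totals") <- c(na = sum(out$na), ne = sum(out$ne))
  attr(out, "means") <- colMeans(out[, -1])
  out
}

#' Per-population diversity summary
#'
#' Na, Ne, I, Ho and He computed within each population and averaged over
#' loci, plus the percentage of effective alleles `100 * mean(Ne) /
#' mean(Na)`.  Loci with no data in a population are skipped in that
#' population's means (with a message).
#'
#' @param g a [genotype_matrix()]
#' @param unbiased_he use the small-sample-corrected He?
#' @return data.frame with one row per population
#' @export
summarize_populations <- function(g, unbiased_he = FALSE) {
  frp <- allele_frequencies(g, by_pop = TRUE)
  rows <- lapply(levels(g$pop), function(pp) {
    sub <- which(g$pop == pp)
    fr <- frp[[pp]]
    keep <- !vapply(fr, is.null, logical(1))
    if (!all(keep))
      message("population ", pp, ": skipping all-missing loci ",
              paste(names(fr)[!keep], collapse = ", "))
    fr <- fr[keep]
    na <- vapply(fr, length, numeric(1))
    ne <- vapply(fr, effective_alleles, numeric(1))
    ii <- vapply(fr, shannon_information, numeric(1))
    ho <- vapply(names(fr), function(l) observed_heterozygosity(g, l, sub), numeric(1))
    he <- vapply(fr, expected_heterozygosity, numeric(1), unbiased = unbiased_he)
    data.frame(population = pp, mean_na = mean(na), mean_ne = mean(ne),
               pct_effective = 100 * mean(ne) / mean(na),
               mean_i = mean(ii), mean_ho = mean(ho), mean_he = mean(he))
  })
  do.call(rbind, rows)
}
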
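# Shared oracles and small builders used across the suite.

# build a genotype_matrix from a list of per-individual call lists:
# calls[[i]][[l]] = c(a1, a2) or NA
toy_genotypes <- function(calls, pop, loci = NULL) {
  n <- length(calls); L <- length(calls[[1]])
  a <- array(NA_integer_, dim = c(n, L, 2),
             dimnames = list(names(calls) %||% paste0("i", seq_len(n)),
                             loci %||% paste0("L", seq_len(L)), NULL))
  for (i in seq_len(n)) for (l in seq_len(L)) {
    cl <- calls[[i]][[l]]
    if (!anyNA(cl)) a[i, l, ] <- as.integer(cl)
  }
  genotype_matrix(a, pop = pop)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# adjusted Rand index between two labelings
ari <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(n) n * (n - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab))); sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# brute-force total AMOVA SS: per locus, sum over all copy pairs of the
# 0/1 mismatch, divided by the copy count
brute_ss_total <- function(g) {
  a <- g$alleles
  tot <- 0
  for (l in seq_len(dim(a)[2])) {
    x <- unname(c(a[, l, 1], a[, l, 2])); x <- x[!is.na(x)]
    n <- length(x)
    if (n < 2) next
    s <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) s <- s + (x[i] != x[j])
    tot <- tot + s / n
  }
  tot
}

# brute-force allele tally
brute_freqs <- function(g, locus) {
  x <- c(g$alleles[, locus, ]); x <- x[!is.na(x)]
  tab <- table(x)
  setNames(as.numeric(tab) / length(x), names(tab))
}

rdirichlet <- function(n, a) {
  x <- matrix(rgamma(n * length(a), a), n, byrow = TRUE)
  x / rowSums(x)
}

# random symmetric distance matrix with labels (points in R^3)
random_distance <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pts <- matrix(rnorm(n * 3), n)
  rownames(pts) <- paste0("p", seq_len(n))
  as.matrix(dist(pts))
}

# Mantel r without permutation
mantel_r <- function(d1, d2) cor(d1[lower.tri(d1)], d2[lower.tri(d2)])
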
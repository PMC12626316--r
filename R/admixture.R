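#' Gibbs-sampling admixture inference
#'
#' Bayesian admixture model with independent allele frequencies, in the
#' style of STRUCTURE's no-admixture-prior-free default: each allele copy
#' carries a latent cluster of origin `z` sampled from
#' `Pr(z = k) prop. to q_i[k] * p_{k,l,a}`; cluster allele frequencies are
#' Gibbs-updated from `Dirichlet(lambda + counts)` with `lambda = 1`, and
#' each individual's ancestry vector from `Dirichlet(alpha + origin
#' counts)` with `alpha = 1` held fixed (no Metropolis update of alpha).
#' The model evidence is estimated from the retained sweeps as
#' `lnPD = mean(lnL) - var(lnL)/2`, the estimator the Evanno delta-K
#' statistic was designed around.
#'
#' @param g a [genotype_matrix()]
#' @param K number of ancestral clusters (>= 1)
#' @param sweeps total Gibbs sweeps (default 20000)
#' @param burnin sweeps discarded before accumulation (default 5000)
#' @param seed optional RNG seed; identical seed and inputs give identical
#'   results
#' @param alpha,lambda Dirichlet hyperparameters for ancestry and allele
#'   frequencies
#' @return object of class `admixture_fit`: list with `Q` (posterior-mean
#'   ancestry, individuals x K), `P` (final-state cluster allele
#'   frequencies), `lnPD`, `lnl` (per-sweep log-likelihood trace), `K`,
#'   `sweeps`, `burnin`, `seed`
#' @examples
#' \donttest{
#' sim <- simulate_tea_panel(seed = 1)
#' fit <- admixture_gibbs(sim$genotypes, K = 2, sweeps = 2000,
#'                        burnin = 500, seed = 1)
#' summary(fit)
#' }
#' @export
admixture_gibbs <- function(g, K, sweeps = 20000, burnin = 5000, seed = NULL,
                            alpha = 1, lambda = 1) {
  if (K < 1L) stop("K must be >= 1")
  if (burnin >= sweeps) stop("burnin must be smaller than sweeps")
  enc <- encode_genotypes(g)
  if (K >= 2L && all(enc$n_alleles < 2L))
    stop("no polymorphic locus: cannot fit K >= 2")
  if (any(rowSums(enc$geno != 0L) == 0L))
    stop("individual(s) with no non-missing calls")
  if (!is.null(seed)) set.seed(seed)
  res <- .gibbs_admixture_cpp(enc$geno, enc$n_alleles, as.integer(K),
                              as.integer(sweeps), as.integer(burnin),
                              alpha, lambda)
  Q <- res$Q
  dimnames(Q) <- list(individuals(g), paste0("K", seq_len(K)))
  stopifnot(all(abs(rowSums(Q) - 1) < 1e-9))
  lnl <- res$lnl
  structure(list(Q = Q, P = res$P, lnPD = mean(lnl) - var(lnl) / 2,
                 lnl = lnl, K = K, sweeps = sweeps, burnin = burnin,
                 seed = seed),
            class = "admixture_fit")
}

# recode allele labels to 1..A per locus; 0 = missing
encode_genotypes <- function(g) {
  a <- g$alleles
  N <- dim(a)[1]; L <- dim(a)[2]
  geno <- matrix(0L, N, 2L * L)
  n_alleles <- integer(L)
  alleles <- vector("list", L)
  for (l in seq_len(L)) {
    lev <- sort(unique(stats::na.omit(c(a[, l, ]))))
    alleles[[l]] <- lev
    n_alleles[l] <- length(lev)
    for (cp in 1:2) {
      idx <- match(a[, l, cp], lev)
      idx[is.na(idx)] <- 0L
      geno[, l + (cp - 1L) * L] <- idx
    }
  }
  list(geno = geno, n_alleles = n_alleles, alleles = alleles)
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: K = %d, %d individuals, lnPD = %.2f\n",
              x$K, nrow(x$Q), x$lnPD))
  cat(sprintf("  %d sweeps (%d burn-in)\n", x$sweeps, x$burnin))
  invisible(x)
}

#' @export
summary.admixture_fit <- function(object, threshold = 0.6, ...) {
  print(object)
  memb <- classify_membership(object$Q, threshold = threshold)
  cat("cluster sizes:", paste(table(memb$cluster), collapse = ", "), "\n")
  cat(sprintf("admixed individuals (max Q < %.2f): %d\n",
              threshold, sum(memb$admixed)))
  invisible(memb)
}

#' Replicated lnPD scan over K
#'
#' Runs `reps` independently seeded Gibbs fits for each `K = 1..Kmax` and
#' collects the model-evidence estimates, the input to [evanno_delta_k()].
#' Replicate seeds are derived deterministically from `seed`.
#'
#' @param g a [genotype_matrix()]
#' @param Kmax largest cluster number scanned (default 5)
#' @param reps replicates per K (default 10)
#' @param sweeps,burnin MCMC lengths per run (defaults 20000 / 5000)
#' @param seed master seed
#' @param verbose print one line per run?
#' @return `Kmax x reps` matrix of lnPD values (rows named `K1..`)
#' @export
replicate_scan <- function(g, Kmax = 5, reps = 10, sweeps = 20000,
                           burnin = 5000, seed = 1, verbose = FALSE) {
  set.seed(seed)
  run_seeds <- matrix(sample.int(.Machine$integer.max - 1L, Kmax * reps),
                      Kmax, reps)
  out <- matrix(NA_real_, Kmax, reps,
                dimnames = list(paste0("K", seq_len(Kmax)), NULL))
  for (K in seq_len(Kmax)) for (r in seq_len(reps)) {
    fit <- admixture_gibbs(g, K, sweeps = sweeps, burnin = burnin,
                           seed = run_seeds[K, r])
    out[K, r] <- fit$lnPD
    if (verbose) message(sprintf("K=%d rep=%d lnPD=%.2f", K, r, fit$lnPD))
  }
  out
}

#' Evanno delta-K cluster-number selection
#'
#' From a `K x replicate` table of lnPD values: `L(K)` is the replicate
#' mean, `L'(K) = L(K) - L(K-1)`, and for each replicate the second
#' difference `L''(K) = lnPD(K+1) - 2 lnPD(K) + lnPD(K-1)`.
#' `delta K = mean(|L''(K)|) / sd(lnPD(K))`, defined for
#' `2 <= K <= Kmax - 1`; the supported cluster number is its argmax.
#'
#' @param lnpd `Kmax x reps` matrix as from [replicate_scan()]
#' @return object of class `evanno`: list with `table` (per-K summary) and
#'   `K` (argmax of delta K)
#' @export
evanno_delta_k <- function(lnpd) {
  lnpd <- as.matrix(lnpd)
  Kmax <- nrow(lnpd); reps <- ncol(lnpd)
  if (Kmax < 3L) stop("need Kmax >= 3 for delta K")
  if (reps < 2L) stop("need >= 2 replicates for delta K")
  L <- rowMeans(lnpd)
  s <- apply(lnpd, 1, sd)
  Lp <- c(NA, diff(L))
  abs_lpp <- delta <- rep(NA_real_, Kmax)
  for (K in 2:(Kmax - 1)) {
    lpp_r <- lnpd[K + 1, ] - 2 * lnpd[K, ] + lnpd[K - 1, ]
    abs_lpp[K] <- mean(abs(lpp_r))
    delta[K] <- if (s[K] > 0) abs_lpp[K] / s[K] else {
      warning("zero replicate SD at K = ", K, ": delta K is infinite")
      Inf
    }
  }
  tab <- data.frame(K = seq_len(Kmax), mean_lnpd = L, sd_lnpd = s,
                    lprime = Lp, abs_lpp = abs_lpp, delta_k = delta)
  structure(list(table = tab, K = which.max(delta)), class = "evanno")
}

#' @export
print.evanno <- function(x, ...) {
  cat("Evanno delta-K model selection\n")
  print(transform(x$table, mean_lnpd = round(mean_lnpd, 2),
                  sd_lnpd = round(sd_lnpd, 2), lprime = round(lprime, 2),
                  abs_lpp = round(abs_lpp, 2), delta_k = round(delta_k, 2)),
        row.names = FALSE)
  cat("supported number of clusters:", x$K, "\n")
  invisible(x)
}

#' @export
plot.evanno <- function(x, ...) {
  with(x$table, {
    plot(K, delta_k, type = "b", pch = 19, xlab = "K",
         ylab = expression(Delta * K), ...)
    graphics::abline(v = x$K, lty = 2, col = "grey50")
  })
  invisible(x)
}

#' Classify individuals from an ancestry matrix
#'
#' Assigns each individual to its largest-Q cluster and flags individuals
#' whose maximum ancestry falls below the purity threshold as admixed
#' (complex genetic background).
#'
#' @param Q individuals x K ancestry matrix (rows sum to 1)
#' @param threshold purity threshold on max Q (default 0.6)
#' @return data.frame with `individual`, `cluster`, `max_q`, `admixed`
#' @export
classify_membership <- function(Q, threshold = 0.6) {
  Q <- as.matrix(Q)
  cl <- max.col(Q, ties.method = "first")
  mq <- Q[cbind(seq_len(nrow(Q)), cl)]
  data.frame(individual = rownames(Q) %||% seq_len(nrow(Q)),
             cluster = cl, max_q = mq, admixed = mq < threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Align cluster labels between two ancestry matrices
#'
#' Greedy label matching (largest column correlation first) to undo label
#' switching before comparing an estimated Q to a reference or truth.
#'
#' @param Q estimated ancestry matrix
#' @param ref reference matrix with the same dimensions
#' @return `Q` with columns permuted to best match `ref`
#' @export
align_clusters <- function(Q, ref) {
  Q <- as.matrix(Q); ref <- as.matrix(ref)
  stopifnot(all(dim(Q) == dim(ref)))
  K <- ncol(Q)
  sim <- matrix(0, K, K)
  for (i in seq_len(K)) for (j in seq_len(K))
    sim[i, j] <- -sum(abs(Q[, i] - ref[, j]))
  perm <- integer(K)
  for (step in seq_len(K)) {
    idx <- arrayInd(which.max(sim), dim(sim))
    perm[idx[2]] <- idx[1]
    sim[idx[1], ] <- -Inf; sim[, idx[2]] <- -Inf
  }
  Q[, perm, drop = FALSE]
}
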
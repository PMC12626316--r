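test_that("K = 1 gives unit ancestry and matches the closed-form evidence", {
  g <- toy_genotypes(list(i1 = list(c(100, 100)), i2 = list(c(100, 104)),
                          i3 = list(c(104, 104))),
                     pop = rep("P", 3))
  fit <- admixture_gibbs(g, K = 1, sweeps = 20000, burnin = 2000, seed = 1)
  expect_true(all(fit$Q == 1))
  # Dirichlet-multinomial evidence for 6 copies (3+3 over 2 alleles),
  # lambda = 1: lgamma(2) - lgamma(8) + 2*lgamma(4).  The mean - var/2
  # estimator is approximate; its bias on this toy is ~0.23 nats.
  closed <- lgamma(2) - lgamma(8) + 2 * lgamma(4)
  expect_equal(fit$lnPD, closed, tolerance = 0.3 / abs(closed))
})

test_that("the sampler is deterministic under a fixed seed", {
  set.seed(51)
  fr <- simulate_allele_freqs(2, n_loci = 6, fst = 0.3)
  sim <- simulate_genotypes(fr$clusters, sizes = c(6, 6))
  f1 <- admixture_gibbs(sim$genotypes, K = 2, sweeps = 500, burnin = 100, seed = 99)
  f2 <- admixture_gibbs(sim$genotypes, K = 2, sweeps = 500, burnin = 100, seed = 99)
  expect_identical(f1$Q, f2$Q)
  expect_identical(f1$lnl, f2$lnl)
  expect_true(all(abs(rowSums(f1$Q) - 1) < 1e-9))
  expect_error(admixture_gibbs(sim$genotypes, K = 0), "K must be")
})

test_that("two fixed populations are recovered with near-pure ancestry", {
  fr <- list(C1 = setNames(lapply(1:10, function(l) setNames(1, "100")),
                           paste0("L", 1:10)),
             C2 = setNames(lapply(1:10, function(l) setNames(1, "104")),
                           paste0("L", 1:10)))
  sim <- simulate_genotypes(fr, sizes = c(8, 8), seed = 5)
  fit <- admixture_gibbs(sim$genotypes, K = 2, sweeps = 2000, burnin = 500, seed = 9)
  Qa <- align_clusters(fit$Q, sim$true_q)
  expect_lte(mean(abs(Qa - sim$true_q)), 0.05)
})

test_that("replicate scans are reproducibly seeded with the right shape", {
  set.seed(52)
  fr <- simulate_allele_freqs(2, n_loci = 6, fst = 0.3)
  sim <- simulate_genotypes(fr$clusters, sizes = c(8, 8))
  t1 <- replicate_scan(sim$genotypes, Kmax = 3, reps = 2, sweeps = 300,
                       burnin = 60, seed = 7)
  expect_equal(dim(t1), c(3L, 2L))
  expect_true(all(is.finite(t1)))
  t2 <- replicate_scan(sim$genotypes, Kmax = 3, reps = 2, sweeps = 300,
                       burnin = 60, seed = 7)
  expect_identical(t1, t2)
})

test_that("Evanno delta-K evaluates its formula and flags degenerate input", {
  # replicate offsets constant within a replicate: per-K sd exactly 1
  L <- c(-1000, -500, -495, -494)
  tab <- cbind(L - 1 / sqrt(2), L + 1 / sqrt(2))
  ev <- evanno_delta_k(tab)
  expect_equal(ev$table$sd_lnpd, rep(1, 4))
  expect_equal(ev$table$abs_lpp[2], 495)
  expect_equal(ev$table$delta_k[2], 495)
  expect_equal(ev$table$delta_k[3], 4)
  expect_true(all(is.na(ev$table$delta_k[c(1, 4)])))
  expect_equal(ev$K, 2L)

  expect_error(evanno_delta_k(tab[1:2, ]), "Kmax >= 3")
  expect_error(evanno_delta_k(tab[, 1, drop = FALSE]), "replicates")
  expect_warning(expect_warning(ev0 <- evanno_delta_k(cbind(L, L)),
                                "zero replicate SD"), "zero replicate SD")
  expect_identical(ev0$table$delta_k[2], Inf)
})

test_that("membership classification applies the purity threshold", {
  Q <- rbind(a = c(0.95, 0.05), b = c(0.55, 0.45), c = c(0.30, 0.70))
  m <- classify_membership(Q, threshold = 0.6)
  expect_equal(m$cluster, c(1L, 1L, 2L))
  expect_equal(m$admixed, c(FALSE, TRUE, FALSE))

  # a truly admixed individual (q = 0.5/0.5) is flagged in most runs
  fr <- list(C1 = setNames(lapply(1:60, function(l) setNames(1, "100")),
                           paste0("L", 1:60)),
             C2 = setNames(lapply(1:60, function(l) setNames(1, "104")),
                           paste0("L", 1:60)))
  q <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  flagged <- vapply(1:10, function(r) {
    sim <- simulate_genotypes(fr, sizes = c(10, 10, 1), q = q, seed = 60 + r)
    fit <- admixture_gibbs(sim$genotypes, K = 2, sweeps = 1500, burnin = 300,
                           seed = 70 + r)
    classify_membership(fit$Q)$admixed[21]
  }, logical(1))
  expect_gte(mean(flagged), 0.9)
})
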
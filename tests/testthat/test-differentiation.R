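test_that("AMOVA has the right degrees of freedom and SS decomposition", {
  sim <- simulate_tea_panel(seed = 8)
  a <- amova(sim$genotypes)
  expect_equal(a$df, c(6, 33, 40, 79))
  expect_equal(sum(a$pct[1:3]), 100, tolerance = 1e-9)
  expect_equal(a$ms[1:3], a$ss[1:3] / a$df[1:3])
  expect_equal(attr(a, "fst"), a$pct[1] / 100, tolerance = 1e-12)

  # SS identity against the brute-force all-pairs oracle, small instances
  set.seed(41)
  for (i in 1:3) {
    fr <- simulate_allele_freqs(3, n_loci = 4, fst = 0.3)
    s <- simulate_genotypes(fr$clusters, sizes = c(4, 4, 4), missing_rate = 0.1)
    at <- amova(s$genotypes)
    expect_equal(at$ss[4], brute_ss_total(s$genotypes), tolerance = 1e-9)
  }
  expect_error(amova(sim$genotypes, pop = rep("X", 40)), "two populations")
  expect_error(amova(sim$genotypes,
                     pop = c("solo", as.character(sim$pop[-1]))), "solo")
})

test_that("AMOVA hits its boundary cases", {
  # two populations fixed for different alleles, all homozygous
  fixed <- toy_genotypes(
    c(lapply(1:3, function(i) list(c(100, 100), c(200, 200))),
      lapply(1:3, function(i) list(c(104, 104), c(208, 208)))),
    pop = rep(c("A", "B"), each = 3))
  a <- amova(fixed)
  expect_equal(a$pct[1], 100)
  expect_equal(attr(a, "fst"), 1)

  # one panmictic population split arbitrarily in two
  set.seed(42)
  fr <- simulate_allele_freqs(1, n_loci = 10, fst = 0.5)
  s <- simulate_genotypes(list(fr$clusters[[1]], fr$clusters[[1]]),
                          sizes = c(100, 100))
  a0 <- amova(s$genotypes)
  expect_lt(a0$pct[1], 5)
})

test_that("pairwise Fst is consistent with simulated divergence", {
  # fully fixed divergent pair
  fixed <- toy_genotypes(
    c(lapply(1:3, function(i) list(c(100, 100))),
      lapply(1:3, function(i) list(c(104, 104)))),
    pop = rep(c("A", "B"), each = 3))
  expect_equal(pairwise_fst(fixed)$fst["A", "B"], 1)

  # identical frequencies, Hardy-Weinberg, large n: Fst near 0
  set.seed(43)
  fr <- simulate_allele_freqs(1, n_loci = 10, fst = 0.5)
  s0 <- simulate_genotypes(list(fr$clusters[[1]], fr$clusters[[1]]),
                           sizes = c(200, 200))
  expect_lt(pairwise_fst(s0$genotypes)$fst[1, 2], 0.02)
})

test_that("gene flow follows the island-model identity", {
  expect_equal(round(gene_flow(0.38), 2), 0.41)
  expect_equal(gene_flow(0.25), 0.75)
  expect_equal(gene_flow(0.5), 0.25)
  expect_equal(gene_flow(1), 0)
  expect_warning(nm0 <- gene_flow(0), "unbounded")
  expect_identical(nm0, Inf)
})

test_that("Nei distance matches hand evaluation and is a proper distance", {
  mk <- function(p) list(L1 = p)
  expect_equal(nei_distance(list(A = mk(c(`1` = 0.8, `2` = 0.2)),
                                 B = mk(c(`1` = 0.8, `2` = 0.2))))["A", "B"], 0)
  d <- nei_distance(list(X = mk(c(`1` = 0.8, `2` = 0.2)),
                         Y = mk(c(`1` = 0.2, `2` = 0.8))))
  expect_equal(d["X", "Y"], -log(0.32 / 0.68), tolerance = 1e-9)

  set.seed(44)
  fr <- simulate_allele_freqs(4, n_loci = 6, fst = 0.2)
  nd <- nei_distance(fr$clusters)
  expect_true(isSymmetric(unname(nd)))
  expect_equal(unname(diag(nd)), rep(0, 4))
  expect_true(all(nd >= 0))
})

test_that("Mantel statistic is exact on aligned and affine inputs", {
  d1 <- random_distance(6, seed = 45)
  expect_equal(mantel_test(d1, d1, n_perm = 99)$r, 1)
  d2 <- 3 * d1 + 2; diag(d2) <- 0
  expect_equal(mantel_test(d1, d2, n_perm = 99)$r, 1)
  # label alignment: permuted second matrix gives the same r
  o <- c(3, 1, 6, 2, 5, 4)
  expect_equal(mantel_test(d1, d1[o, o], n_perm = 99)$r, 1)
  expect_error(mantel_test(d1, random_distance(5)), "labels")
  expect_error(mantel_test(d1, 0 * d1, n_perm = 99), "zero variance")
})

test_that("Mantel agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  d1 <- random_distance(12, seed = 46)
  d2 <- random_distance(12, seed = 47)
  ours <- mantel_test(d1, d2, n_perm = 999, seed = 1)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  expect_lt(abs(ours$p - ref$signif), 0.05)
})
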
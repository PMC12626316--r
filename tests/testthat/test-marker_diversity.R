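test_that("allele frequencies tally copies and drop missing calls", {
  g <- toy_genotypes(list(i1 = list(c(100, 100)), i2 = list(c(100, 104)),
                          i3 = list(NA)),
                     pop = c("P1", "P1", "P2"))
  p <- allele_frequencies(g)[["L1"]]
  expect_equal(as.numeric(p), c(0.75, 0.25))
  expect_equal(names(p), c("100", "104"))
  expect_equal(attr(p, "n_copies"), 4L)  # the missing call is excluded

  sim <- simulate_tea_panel(seed = 6)
  fr <- allele_frequencies(sim$genotypes)
  for (l in c("L1", "L7", "L14")) {
    expect_equal(as.numeric(fr[[l]]), as.numeric(brute_freqs(sim$genotypes, l)))
    expect_equal(names(fr[[l]]), names(brute_freqs(sim$genotypes, l)))
  }
  expect_error(allele_frequencies(g, subset = integer(0)), "empty")
})

test_that("Ne, I, He and PIC evaluate their closed forms", {
  expect_equal(effective_alleles(c(0.5, 0.5)), 2)
  expect_equal(effective_alleles(1), 1)
  expect_equal(effective_alleles(c(0.7, 0.2, 0.1)), 1 / 0.54)

  expect_equal(shannon_information(c(0.5, 0.5)), log(2))
  expect_equal(shannon_information(1), 0)
  expect_equal(shannon_information(rep(1 / 6, 6)), log(6))

  expect_equal(expected_heterozygosity(c(0.5, 0.5)), 0.5)
  expect_equal(expected_heterozygosity(1), 0)
  expect_equal(expected_heterozygosity(rep(0.25, 4)), 0.75)
  p <- structure(c(0.5, 0.5), n_copies = 10)
  expect_equal(expected_heterozygosity(p, unbiased = TRUE), 10 / 9 * 0.5)

  expect_equal(pic(c(0.5, 0.5)), 0.375)
  expect_equal(pic(1), 0)
  expect_equal(pic(c(0.7, 0.2, 0.1)), 0.4102, tolerance = 1e-4)
})

test_that("observed heterozygosity counts heterozygous non-missing calls", {
  g <- toy_genotypes(list(i1 = list(c(100, 104)), i2 = list(c(100, 100)),
                          i3 = list(c(104, 108))),
                     pop = rep("P1", 3))
  expect_equal(observed_heterozygosity(g, "L1"), 2 / 3)
  hom <- toy_genotypes(list(i1 = list(c(100, 100)), i2 = list(c(104, 104))),
                       pop = rep("P1", 2))
  expect_equal(observed_heterozygosity(hom, "L1"), 0)

  set.seed(31)
  fr <- simulate_allele_freqs(1, n_loci = 5, fst = 0.5)
  sim <- simulate_genotypes(fr$clusters, sizes = 30, missing_rate = 0.2)
  a <- sim$genotypes$alleles
  for (l in 1:5) {
    het <- a[, l, 1] != a[, l, 2]
    expect_equal(observed_heterozygosity(sim$genotypes, l),
                 sum(het, na.rm = TRUE) / sum(!is.na(het)))
  }
})

test_that("fixation index relates Ho and He", {
  expect_equal(fixation_index(0.4, 0.4), 0)
  expect_equal(fixation_index(0, 0.6), 1)
  expect_equal(fixation_index(0.5, 0.8), 0.375)
  expect_true(is.na(fixation_index(0, 0)))
})

test_that("locus summaries respect floors, bounds and panel totals", {
  mono <- toy_genotypes(list(i1 = list(c(100, 100), c(90, 94)),
                             i2 = list(c(100, 100), c(90, 90))),
                        pop = rep("P1", 2))
  s <- summarize_loci(mono)
  expect_equal(s$na[1], 1)
  expect_equal(s$ne[1], 1)
  expect_equal(s$i[1], 0)
  expect_equal(s$he[1], 0)
  expect_equal(s$pic[1], 0)
  expect_true(is.na(s$f[1]))
  expect_equal(attr(s, "totals")[["na"]], sum(s$na))

  # estimator inequalities over random frequency vectors
  set.seed(32)
  for (i in 1:200) {
    k <- sample(2:15, 1)
    p <- rdirichlet(1, rep(0.6, k))[1, ]
    he <- expected_heterozygosity(p)
    expect_lte(pic(p), he + 1e-12)
    expect_lte(he, 1 - 1 / k + 1e-12)
    expect_lte(effective_alleles(p), k + 1e-9)
    # Jensen relation between the Shannon and Simpson kernels
    expect_gte(exp(shannon_information(p)), effective_alleles(p) - 1e-9)
  }
})

test_that("population summaries average loci within populations", {
  set.seed(33)
  fr <- simulate_allele_freqs(2, n_loci = 8, fst = 0.3)
  sim <- simulate_genotypes(fr$clusters, sizes = c(60, 60),
                            pop_names = c("A", "B"))
  ps <- summarize_populations(sim$genotypes)
  expect_equal(ps$population, c("A", "B"))
  expect_equal(ps$pct_effective, 100 * ps$mean_ne / ps$mean_na)
  # panmictic Hardy-Weinberg population: Ho tracks He
  expect_lt(max(abs(ps$mean_ho - ps$mean_he)), 0.06)

  uni <- toy_genotypes(list(i1 = list(c(100, 100)), i2 = list(c(100, 100))),
                       pop = rep("P1", 2))
  pu <- summarize_populations(uni)
  expect_equal(pu$mean_na, 1)
  expect_equal(pu$mean_ho, 0)
  expect_equal(pu$mean_he, 0)
})
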
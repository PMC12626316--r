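test_that("Balding-Nichols draws concentrate and satisfy the moment identity", {
  # near-zero divergence: cluster frequencies collapse onto the ancestral
  fr <- simulate_allele_freqs(3, n_loci = 5, fst = 1e-4, seed = 71)
  dev <- unlist(lapply(seq_along(fr$ancestral), function(l)
    sapply(fr$clusters, function(cl) max(abs(cl[[l]] - fr$ancestral[[l]])))))
  expect_lt(max(dev), 0.02)

  # Var(p_cluster) = p(1-p) F across replicate draws
  F <- 0.2; p <- c(0.3, 0.7)
  set.seed(72)
  draws <- rdirichlet(5000, p * (1 - F) / F)
  expect_equal(var(draws[, 1]), p[1] * (1 - p[1]) * F, tolerance = 0.1)

  f1 <- simulate_allele_freqs(2, n_loci = 4, fst = 0.2, seed = 73)
  f2 <- simulate_allele_freqs(2, n_loci = 4, fst = 0.2, seed = 73)
  expect_identical(f1, f2)
  expect_error(simulate_allele_freqs(2, fst = 1.2), "fst")
})

test_that("simulated genotypes track their generating frequencies", {
  set.seed(74)
  fr <- simulate_allele_freqs(1, n_loci = 3, fst = 0.5)
  sim <- simulate_genotypes(fr$clusters, sizes = 1000)
  expect_true(all(sim$true_q == 1))
  realized <- allele_frequencies(sim$genotypes)
  for (l in names(realized)) {
    truth <- fr$clusters[[1]][[l]]
    got <- realized[[l]][names(truth)]
    got[is.na(got)] <- 0
    expect_lt(max(abs(got - truth)), 0.05)
  }

  # Hardy-Weinberg heterozygosity at a 50/50 biallelic locus
  half <- list(C1 = list(L1 = c(`100` = 0.5, `104` = 0.5)))
  s <- simulate_genotypes(half, sizes = 500, seed = 75)
  expect_lt(abs(observed_heterozygosity(s$genotypes, "L1") - 0.5), 0.05)
})

test_that("phenotype effects scale from independence to full separation", {
  pop <- factor(rep(c("A", "B", "C"), each = 8))

  # zero effects: phenotype distance uncorrelated with cluster structure
  set.seed(76)
  rs <- replicate(100, {
    ph <- simulate_phenotypes(pop, desc_effect = 0, quant_effect = 0)
    z <- suppressWarnings(standardize_phenotypes(ph))  # constant traits drop
    gd <- as.matrix(dist(cbind(as.integer(pop))))  # crude cluster distance
    mantel_r(gd, euclidean_matrix(z))
  })
  expect_lt(abs(mean(rs)), 0.05)

  # strong offsets: clustering the phenotypes recovers the populations
  ph <- simulate_phenotypes(pop, desc_effect = 0.6, quant_effect = 6,
                            seed = 77)
  got <- cut_dendrogram(upgma(euclidean_matrix(standardize_phenotypes(ph))), k = 3)
  expect_gte(ari(got, as.integer(pop)), 0.9)

  # leaf area respects the length x width x 0.7 construction
  q <- ph$quantitative
  expect_equal(q$leaf_area_cm2, q$leaf_length_cm * q$leaf_width_cm * 0.7)
  expect_equal(q$length_width_ratio, q$leaf_length_cm / q$leaf_width_cm)
})

test_that("the study-like panel has the survey's shape and is deterministic", {
  sim <- simulate_tea_panel(seed = 5)
  expect_equal(dim(sim$genotypes$alleles)[1:2], c(40L, 14L))
  expect_equal(nlevels(sim$pop), 7L)
  expect_equal(as.vector(table(sim$pop)), c(5L, 5L, 10L, 5L, 5L, 5L, 5L))
  counts <- vapply(sim$truth$ancestral, length, integer(1))
  expect_true(all(counts >= 4 & counts <= 15))
  expect_equal(sim$truth$cluster_of_pop, c(2L, rep(1L, 6)))

  sim2 <- simulate_tea_panel(seed = 5)
  expect_identical(sim$genotypes$alleles, sim2$genotypes$alleles)
  expect_identical(sim$phenotypes, sim2$phenotypes)
})

test_that("the divergent population separates in the population tree", {
  qs_alone <- vapply(1:10, function(s) {
    sim <- simulate_tea_panel(seed = 100 + s)
    nd <- nei_distance(allele_frequencies(sim$genotypes, by_pop = TRUE))
    cl <- cut_dendrogram(upgma(nd), k = 2)
    sum(cl == cl[["QS"]]) == 1
  }, logical(1))
  expect_gte(mean(qs_alone), 0.9)
})

test_that("bundles round-trip through the plain-text writers", {
  sim <- simulate_tea_panel(seed = 6)
  dir <- withr::local_tempdir()
  write_bundle(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("genotypes.tsv", "phenotypes.tsv",
                                               "truth.txt")))))
  back <- read_genotypes(file.path(dir, "genotypes.tsv"))
  expect_identical(back$genotypes$alleles, sim$genotypes$alleles)
  expect_match(readLines(file.path(dir, "truth.txt"))[1], "seed=6")
})
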
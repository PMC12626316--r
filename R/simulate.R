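#' Balding-Nichols cluster allele frequencies
#'
#' Draws ancestral allele frequencies from a flat Dirichlet per locus, then
#' per-cluster frequencies from `Dirichlet(ancestral * (1 - F)/F)` with
#' `F = fst`.  Under this construction `F` is exactly the expected Fst of
#' the clusters around the ancestral pool
#' (`Var(p_cluster) = p(1 - p) F`), which makes parameter-recovery tests
#' quantitative.  Allele labels are synthetic SSR fragment sizes (a random
#' base size plus motif-length steps).
#'
#' @param n_clusters number of descendant clusters
#' @param n_loci number of loci (default 14)
#' @param allele_range min/max alleles per locus (default `c(4, 15)`)
#' @param fst divergence parameter in (0, 1)
#' @param seed optional RNG seed
#' @return list with `ancestral` (per-locus named frequency vectors) and
#'   `clusters` (list of per-cluster frequency tables of the same shape)
#' @export
simulate_allele_freqs <- function(n_clusters, n_loci = 14, allele_range = c(4, 15),
                                  fst = 0.2, seed = NULL) {
  if (fst <= 0 || fst >= 1) stop("fst must be in (0, 1)")
  if (min(allele_range) < 2) stop("need at least 2 alleles per locus")
  if (!is.null(seed)) set.seed(seed)
  rdirichlet1 <- function(a) { x <- rgamma(length(a), a); x / sum(x) }
  ancestral <- vector("list", n_loci)
  names(ancestral) <- paste0("L", seq_len(n_loci))
  for (l in seq_len(n_loci)) {
    A <- sample(seq(allele_range[1], allele_range[2]), 1)
    base <- sample(80:300, 1); step <- sample(2:6, 1)
    labels <- as.character(base + step * (0:(A - 1)))
    ancestral[[l]] <- setNames(rdirichlet1(rep(1, A)), labels)
  }
  clusters <- lapply(seq_len(n_clusters), function(k)
    lapply(ancestral, function(p)
      setNames(rdirichlet1(p * (1 - fst) / fst), names(p))))
  names(clusters) <- paste0("C", seq_len(n_clusters))
  list(ancestral = ancestral, clusters = clusters)
}

#' Simulate codominant genotypes from group allele frequencies
#'
#' Each individual belongs to a population; each population has an ancestry
#' vector `q` over the frequency groups (default: population g draws only
#' from group g).  The two allele copies of each call are drawn
#' independently: first the copy's group of origin from `q`, then the
#' allele from that group's frequencies (Hardy-Weinberg within group).
#' Uniform random missingness is applied last.
#'
#' @param freqs list of per-group frequency tables (as the `clusters`
#'   element of [simulate_allele_freqs()])
#' @param sizes individuals per population
#' @param pop_names population codes (default `P1..`)
#' @param q optional `length(sizes) x length(freqs)` matrix of
#'   population-level ancestry proportions (rows sum to 1)
#' @param missing_rate per-call missingness probability (default 0)
#' @param seed optional RNG seed
#' @return list with `genotypes` (a [genotype_matrix()]), `pop` (factor)
#'   and `true_q` (individuals x groups expected-ancestry matrix)
#' @export
simulate_genotypes <- function(freqs, sizes, pop_names = NULL, q = NULL,
                               missing_rate = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- length(freqs); P <- length(sizes)
  if (is.null(pop_names)) pop_names <- paste0("P", seq_len(P))
  if (is.null(q)) {
    if (P != G) stop("supply `q` when populations and frequency groups differ")
    q <- diag(G)
  }
  q <- as.matrix(q)
  stopifnot(nrow(q) == P, ncol(q) == G, all(abs(rowSums(q) - 1) < 1e-9))
  loci <- names(freqs[[1]])
  L <- length(loci); N <- sum(sizes)
  pop <- factor(rep(pop_names, sizes), levels = pop_names)
  a <- array(NA_integer_, dim = c(N, L, 2),
             dimnames = list(paste0("I", seq_len(N)), loci, NULL))
  true_q <- q[as.integer(pop), , drop = FALSE]
  rownames(true_q) <- dimnames(a)[[1]]
  colnames(true_q) <- names(freqs)
  for (i in seq_len(N)) {
    qi <- true_q[i, ]
    for (l in seq_len(L)) {
      for (cp in 1:2) {
        gsrc <- sample.int(G, 1, prob = qi)
        p <- freqs[[gsrc]][[loci[l]]]
        a[i, l, cp] <- as.integer(sample(names(p), 1, prob = p))
      }
    }
  }
  if (missing_rate > 0) {
    drop <- matrix(runif(N * L) < missing_rate, N, L)
    for (cp in 1:2) a[, , cp][drop] <- NA_integer_
  }
  g <- genotype_matrix(a, pop = pop)
  list(genotypes = g, pop = g$pop, true_q = true_q)
}

#' Simulate population-correlated phenotypes
#'
#' Generates a phenotype table shaped like a tea-germplasm survey sheet:
#' coded descriptive traits drawn from cluster-specific categorical
#' distributions, and quantitative leaf traits built from cluster-offset
#' leaf length and width, with the ratio and area derived as
#' `length/width` and `length x width x 0.7`.  `desc_effect` is a
#' Balding-Nichols-style divergence parameter for the categorical
#' distributions and `quant_effect` the SD (in noise-SD units) of the
#' per-cluster offsets of leaf length and width; both at 0 give phenotypes
#' independent of the clusters.
#'
#' @param pop factor of population codes, one per accession
#' @param cluster_of_pop integer cluster id per population level (default:
#'   each population is its own cluster)
#' @param n_descriptive number of coded traits (default 18)
#' @param desc_effect categorical divergence in (0, 1); 0 disables
#' @param quant_effect SD of per-cluster quantitative offsets (noise-SD
#'   units); 0 disables
#' @param noise_sd residual SD of leaf length/width (cm)
#' @param seed optional RNG seed
#' @return list with data.frames `descriptive` (integer codes) and
#'   `quantitative` (`leaf_length_cm`, `leaf_width_cm`,
#'   `length_width_ratio`, `leaf_area_cm2`), rownames = accessions
#' @export
simulate_phenotypes <- function(pop, cluster_of_pop = NULL, n_descriptive = 18,
                                desc_effect = 0.3, quant_effect = 2,
                                noise_sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- as.factor(pop)
  if (is.null(cluster_of_pop)) cluster_of_pop <- seq_len(nlevels(pop))
  cl <- cluster_of_pop[as.integer(pop)]
  n <- length(pop); ncl <- max(cluster_of_pop)
  rdirichlet1 <- function(a) { x <- rgamma(length(a), a); x / sum(x) }

  desc <- as.data.frame(lapply(seq_len(n_descriptive), function(tr) {
    k <- sample(2:5, 1)
    base <- rdirichlet1(rep(2, k))
    probs <- lapply(seq_len(ncl), function(cc) {
      if (desc_effect <= 0) base
      else rdirichlet1(base * (1 - desc_effect) / desc_effect)
    })
    vapply(cl, function(cc) sample.int(k, 1, prob = probs[[cc]]), integer(1))
  }))
  names(desc) <- paste0("trait", seq_len(n_descriptive))

  len_off <- rnorm(ncl, 0, quant_effect * noise_sd)
  wid_off <- rnorm(ncl, 0, quant_effect * noise_sd * 0.4)
  len <- pmax(10 + len_off[cl] + rnorm(n, 0, noise_sd), 0.5)
  wid <- pmax(3.5 + wid_off[cl] + rnorm(n, 0, noise_sd * 0.4), 0.2)
  quant <- data.frame(leaf_length_cm = len, leaf_width_cm = wid,
                      length_width_ratio = len / wid,
                      leaf_area_cm2 = len * wid * 0.7)
  acc <- paste0("I", seq_len(n))
  rownames(desc) <- rownames(quant) <- acc
  list(descriptive = desc, quantitative = quant)
}

#' Simulate a study-like tea germplasm panel
#'
#' A full synthetic bundle shaped like the Chongzuo survey: 40 accessions
#' in 7 populations of sizes (5, 5, 10, 5, 5, 5, 5), 14 SSR loci with 4-15
#' alleles, and two underlying ancestral clusters with only the first
#' population (the QS analogue) drawn from the minor cluster.  Population
#' frequencies are drawn hierarchically: cluster frequencies around a
#' common ancestral pool (`fst_between`), then each population around its
#' cluster (`fst_within`).  The defaults are calibrated so the realized
#' among-population AMOVA variance share is about 20%.  Phenotypes are
#' population-correlated through the same two clusters.
#'
#' @param seed master seed; the whole bundle is reproducible from it
#' @param sizes population sizes
#' @param n_loci,allele_range SSR panel shape
#' @param fst_between,fst_within Balding-Nichols divergence of clusters
#'   around the ancestral pool and of populations around their cluster
#' @param missing_rate per-call missingness (default 0.02)
#' @return list with `genotypes`, `pop`, `phenotypes`, and `truth`
#'   (seed, cluster of each population, population frequency tables,
#'   per-individual cluster ancestry)
#' @export
simulate_tea_panel <- function(seed = 1,
                               sizes = c(QS = 5, RX = 5, CQ = 10, XL = 5,
                                         LT = 5, NN = 5, JB = 5),
                               n_loci = 14, allele_range = c(4, 15),
                               fst_between = 0.28, fst_within = 0.10,
                               missing_rate = 0.02) {
  set.seed(seed)
  P <- length(sizes)
  cluster_of_pop <- c(2L, rep(1L, P - 1L))
  fr <- simulate_allele_freqs(2, n_loci = n_loci, allele_range = allele_range,
                              fst = fst_between)
  rdirichlet1 <- function(a) { x <- rgamma(length(a), a); x / sum(x) }
  pop_freqs <- lapply(cluster_of_pop, function(cc)
    lapply(fr$clusters[[cc]], function(p)
      setNames(rdirichlet1(p * (1 - fst_within) / fst_within), names(p))))
  names(pop_freqs) <- names(sizes)
  sim <- simulate_genotypes(pop_freqs, sizes, pop_names = names(sizes),
                            missing_rate = missing_rate)
  phen <- simulate_phenotypes(sim$pop, cluster_of_pop,
                              desc_effect = 0.25, quant_effect = 3,
                              noise_sd = 1.2)
  rownames(phen$descriptive) <- rownames(phen$quantitative) <- individuals(sim$genotypes)
  cluster_q <- cbind(C1 = as.numeric(cluster_of_pop[as.integer(sim$pop)] == 1L),
                     C2 = as.numeric(cluster_of_pop[as.integer(sim$pop)] == 2L))
  rownames(cluster_q) <- individuals(sim$genotypes)
  list(genotypes = sim$genotypes, pop = sim$pop, phenotypes = phen,
       truth = list(seed = seed, cluster_of_pop = cluster_of_pop,
                    ancestral = fr$ancestral, cluster_freqs = fr$clusters,
                    pop_freqs = pop_freqs, cluster_q = cluster_q))
}

#' Write a simulated bundle to disk
#'
#' Genotypes in the delimited two-columns-per-locus layout
#' (see [write_genotypes()]), phenotypes as TSV, and a key-value truth
#' sidecar recording the seed and the population-to-cluster map.
#'
#' @param bundle a [simulate_tea_panel()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(bundle$genotypes, file.path(dir, "genotypes.tsv"))
  phen <- cbind(accession = rownames(bundle$phenotypes$descriptive),
                bundle$phenotypes$descriptive, bundle$phenotypes$quantitative)
  write.table(phen, file.path(dir, "phenotypes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tr <- bundle$truth
  lines <- c(paste0("seed=", tr$seed),
             paste0("cluster_of_pop=", paste(tr$cluster_of_pop, collapse = ",")),
             paste0("populations=", paste(levels(bundle$pop), collapse = ",")))
  writeLines(lines, file.path(dir, "truth.txt"))
  invisible(dir)
}
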
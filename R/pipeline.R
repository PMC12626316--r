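#' Run the full phenotype + SSR diversity analysis
#'
#' One-command orchestration of the whole workflow on a genotype matrix and
#' phenotype table: descriptive-trait summary, quantitative-trait summary,
#' phenotype clustering, per-locus and per-population marker diversity,
#' admixture scan with Evanno delta-K, Nei population distances with UPGMA,
#' pairwise Fst/Nm, AMOVA, and the Mantel concordance test between
#' individual genetic and phenotypic distances.  Every artifact is written
#' as delimited text (dendrograms as Newick) plus a run manifest; all
#' randomness flows from `seed`, so a rerun with identical inputs and
#' configuration reproduces the artifacts byte for byte.
#'
#' @param g a [genotype_matrix()]
#' @param phenotypes list with `descriptive` and `quantitative`
#'   data.frames (as from [simulate_phenotypes()]), rownames matching the
#'   individuals of `g`; `NULL` skips the phenotype stages
#' @param out_dir output directory (created if needed)
#' @param Kmax,reps,sweeps,burnin admixture scan settings (desk-scale
#'   defaults; `Kmax = 0` skips the admixture stage)
#' @param mantel_perms Mantel permutation count (default 9999)
#' @param grading_classes classes for quantitative-trait grading
#' @param q_threshold purity threshold for membership classification
#' @param seed master seed recorded in the manifest
#' @param verbose log one message per stage?
#' @return invisibly, a list with every stage result and the artifact paths
#' @export
run_full_analysis <- function(g, phenotypes = NULL, out_dir,
                              Kmax = 5, reps = 10, sweeps = 20000,
                              burnin = 5000, mantel_perms = 9999,
                              grading_classes = 10, q_threshold = 0.6,
                              seed = 1, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[teadiv] ", sprintf(...))
  res <- list(); paths <- character(0)
  emit <- function(df, name, digits = 2) {
    paths[[name]] <<- report_table(df, file.path(out_dir, name), digits = digits)
  }
  stage <- function(name, expr) {
    say("stage: %s", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  phen_dist <- NULL
  if (!is.null(phenotypes)) {
    stage("trait summary", {
      res$trait_summary <- summarize_traits(phenotypes$descriptive)
      emit(res$trait_summary, "trait_summary.tsv")
    })
    stage("quantitative summary", {
      res$quantitative_summary <-
        summarize_quantitative(phenotypes$quantitative, grading_classes)
      emit(res$quantitative_summary, "quantitative_summary.tsv")
    })
    stage("phenotype clustering", {
      z <- standardize_phenotypes(phenotypes)
      phen_dist <- euclidean_matrix(z)
      res$phenotype_tree <- upgma(phen_dist)
      write_newick(res$phenotype_tree, file.path(out_dir, "phenotype_upgma.nwk"))
      res$phenotype_groups <- cut_dendrogram(res$phenotype_tree, k = 3)
      emit(data.frame(individual = names(res$phenotype_groups),
                      group = res$phenotype_groups), "phenotype_groups.tsv")
    })
  }

  stage("locus summary", {
    res$locus_summary <- summarize_loci(g)
    emit(res$locus_summary, "locus_summary.tsv")
  })
  stage("population summary", {
    res$population_summary <- summarize_populations(g)
    emit(res$population_summary, "population_summary.tsv")
  })

  if (Kmax >= 3) {
    stage("admixture scan", {
      res$lnpd <- replicate_scan(g, Kmax = Kmax, reps = reps, sweeps = sweeps,
                                 burnin = burnin, seed = seed)
      res$evanno <- evanno_delta_k(res$lnpd)
      emit(res$evanno$table, "delta_k.tsv")
      set.seed(seed + 1L)
      res$admixture <- admixture_gibbs(g, K = res$evanno$K, sweeps = sweeps,
                                       burnin = burnin,
                                       seed = sample.int(.Machine$integer.max - 1L, 1))
      memb <- classify_membership(res$admixture$Q, threshold = q_threshold)
      emit(cbind(data.frame(individual = rownames(res$admixture$Q)),
                 as.data.frame(round(res$admixture$Q, 4)),
                 memb[, c("cluster", "admixed")]), "q_matrix.tsv", digits = 4)
    })
  }

  stage("population distances", {
    res$nei <- nei_distance(allele_frequencies(g, by_pop = TRUE))
    emit(dist_df(res$nei), "population_distance.tsv")
    res$population_tree <- upgma(res$nei)
    write_newick(res$population_tree, file.path(out_dir, "population_upgma.nwk"))
  })
  stage("pairwise Fst / Nm", {
    res$fst_nm <- pairwise_fst(g)
    emit(dist_df(combine_fst_nm(res$fst_nm$fst, res$fst_nm$nm)), "fst_nm.tsv")
  })
  stage("AMOVA", {
    res$amova <- amova(g)
    emit(as.data.frame(res$amova), "amova.tsv")
  })

  if (!is.null(phen_dist)) {
    stage("Mantel test", {
      gen_dist <- allele_sharing_distance(g)
      res$mantel <- mantel_test(gen_dist, phen_dist, n_perm = mantel_perms,
                                seed = seed)
      emit(data.frame(r = res$mantel$r, p = res$mantel$p,
                      n_perm = res$mantel$n_perm), "mantel.tsv", digits = 4)
    })
  }

  manifest <- c(
    paste0("package=teadiv ", as.character(utils::packageVersion("teadiv"))),
    paste0("seed=", seed),
    paste0("Kmax=", Kmax), paste0("reps=", reps),
    paste0("sweeps=", sweeps), paste0("burnin=", burnin),
    paste0("mantel_perms=", mantel_perms),
    paste0("grading_classes=", grading_classes),
    paste0("q_threshold=", q_threshold),
    paste0("individuals=", dim(g$alleles)[1]),
    paste0("loci=", dim(g$alleles)[2]),
    paste0("populations=", paste(levels(g$pop), collapse = ",")),
    paste0("artifacts=", paste(basename(unlist(paths)), collapse = ",")))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  say("done: %d artifacts in %s", length(paths), out_dir)
  invisible(c(res, list(paths = paths, out_dir = out_dir)))
}

#' Combine Fst and Nm into one matrix
#'
#' Differentiation below the diagonal and gene flow above it, the
#' conventional joint presentation.
#'
#' @param fst,nm symmetric matrices with matching labels
#' @return combined matrix (`NA` diagonal)
#' @export
combine_fst_nm <- function(fst, nm) {
  out <- fst
  out[upper.tri(out)] <- nm[upper.tri(nm)]
  diag(out) <- NA
  out
}

# labelled matrix -> data.frame with a leading label column
dist_df <- function(m) data.frame(label = rownames(m), m, check.names = FALSE)

#' Write a report table with a full-precision sidecar
#'
#' The main file renders numeric columns at a fixed number of decimals (2
#' by default, matching the published tables); an adjacent
#' `<name>.full.tsv` keeps full precision.
#'
#' @param df data.frame to write
#' @param path output path for the rounded table
#' @param digits decimals in the main file
#' @return `path`, invisibly
#' @export
report_table <- function(df, path, digits = 2) {
  full <- sub("\\.tsv$", ".full.tsv", path)
  write.table(df, full, sep = "\t", quote = FALSE, row.names = FALSE)
  rounded <- as.data.frame(lapply(df, function(col)
    if (is.numeric(col)) format(round(col, digits), nsmall = digits, trim = TRUE)
    else col), check.names = FALSE, stringsAsFactors = FALSE)
  names(rounded) <- names(df)
  write.table(rounded, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
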
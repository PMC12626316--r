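#' Read a codominant genotype table
#'
#' Reads the delimited two-columns-per-locus layout used by GenAlEx-style
#' workflows: a header row declaring locus names (each locus name on the
#' first of its two allele columns), then one row per individual with its
#' identifier, population code, and two allele labels per locus.  An allele
#' equal to the missing code (default 0) or a blank cell marks the whole
#' call as missing.
#'
#' @param path file to read
#' @param sep field delimiter; `NULL` (default) auto-detects tab vs comma
#'   from the header line
#' @param missing integer allele code to treat as missing (default 0)
#' @return list with elements `genotypes` (a [genotype_matrix()]) and
#'   `pop` (factor of population codes, named by individual)
#' @seealso [write_genotypes()], [write_structure()]
#' @export
read_genotypes <- function(path, sep = NULL, missing = 0L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("genotype file needs a header and at least one data row")
  if (is.null(sep))
    sep <- if (grepl("\t", lines[1])) "\t" else ","
  header <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  ncols <- length(header)
  if ((ncols - 2L) %% 2L != 0L || ncols < 4L)
    stop("format error: header must have an individual column, a population column and two columns per locus")
  L <- (ncols - 2L) / 2L
  loci <- trimws(header[seq(3L, by = 2L, length.out = L)])
  if (any(!nzchar(loci))) stop("format error: locus names missing from header")

  # sentinel keeps trailing blank fields that strsplit would drop
  rows <- lapply(strsplit(paste0(lines[-1], sep, "\x01"), sep, fixed = TRUE),
                 function(f) f[-length(f)])
  n <- length(rows)
  a <- array(NA_integer_, dim = c(n, L, 2L))
  ind <- character(n); pop <- character(n)
  for (r in seq_len(n)) {
    f <- trimws(rows[[r]])
    if (length(f) != ncols)
      stop(sprintf("parse error at data row %d: expected %d fields, found %d",
                   r, ncols, length(f)))
    ind[r] <- f[1]; pop[r] <- f[2]
    v <- f[-(1:2)]
    v[!nzchar(v)] <- NA
    v <- suppressWarnings(as.integer(v))
    v[!is.na(v) & v == missing] <- NA_integer_
    m <- matrix(v, ncol = 2L, byrow = TRUE)
    # a blank/missing half invalidates the whole call
    m[is.na(m[, 1]) | is.na(m[, 2]), ] <- NA_integer_
    a[r, , ] <- m
  }
  dimnames(a) <- list(ind, loci, NULL)
  g <- genotype_matrix(a, pop = pop)
  list(genotypes = g, pop = g$pop)
}

#' Write a codominant genotype table
#'
#' Inverse of [read_genotypes()]: two allele columns per locus, the locus
#' name repeated on both, missing calls written as the missing code.
#'
#' @param g a [genotype_matrix()]
#' @param path output file
#' @param sep field delimiter (default tab)
#' @param missing integer code written for missing alleles (default 0)
#' @return `path`, invisibly
#' @export
write_genotypes <- function(g, path, sep = "\t", missing = 0L) {
  a <- g$alleles
  n <- dim(a)[1]; L <- dim(a)[2]
  header <- c("individual", "population", rep(locus_names(g), each = 2L))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(header, collapse = sep), con)
  for (i in seq_len(n)) {
    v <- as.integer(t(a[i, , ]))
    v[is.na(v)] <- missing
    writeLines(paste(c(individuals(g)[i], as.character(g$pop[i]), v),
                     collapse = sep), con)
  }
  invisible(path)
}

#' Read a phenotype table
#'
#' Reads a delimited sheet with one row per accession (first column =
#' accession id) and splits it into coded descriptive traits and
#' quantitative traits: integer-valued columns are treated as category
#' codes, the remaining numeric columns as quantitative measurements.
#'
#' @param path file to read
#' @param sep field delimiter (default tab)
#' @return list with data.frames `descriptive` and `quantitative`,
#'   rownames = accession ids (the shape produced by
#'   [simulate_phenotypes()])
#' @export
read_phenotypes <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  acc <- as.character(df[[1]])
  df <- df[, -1, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  if (!all(num)) stop("non-numeric trait columns: ",
                      paste(names(df)[!num], collapse = ", "))
  is_coded <- vapply(df, function(v) all(is.na(v) | v == round(v)), logical(1))
  out <- list(descriptive = df[, is_coded, drop = FALSE],
              quantitative = df[, !is_coded, drop = FALSE])
  rownames(out$descriptive) <- rownames(out$quantitative) <- acc
  out
}

#' Export genotypes in STRUCTURE two-row format
#'
#' One line per allele copy set: each individual contributes two rows, each
#' carrying its identifier, integer population index, and one allele label
#' per locus.  Missing alleles are encoded as -9.
#'
#' @param g a [genotype_matrix()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_structure <- function(g, path) {
  a <- g$alleles
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(dim(a)[1])) {
    for (cp in 1:2) {
      v <- a[i, , cp]
      v[is.na(v)] <- -9L
      writeLines(paste(c(individuals(g)[i], as.integer(g$pop[i]), v),
                       collapse = " "), con)
    }
  }
  invisible(path)
}

#' Write a dendrogram as Newick
#'
#' Branch lengths are chosen so that every leaf's root-to-tip distance
#' equals the final merge height of the (ultrametric) tree.
#'
#' @param tree an `hclust`-like tree, e.g. from [upgma()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_newick <- function(tree, path) {
  writeLines(newick_string(tree), path)
  invisible(path)
}

#' @rdname write_newick
#' @export
newick_string <- function(tree) {
  if (!is.null(tree$labels) && length(tree$labels) == 1L && is.null(tree$merge))
    return(paste0(tree$labels, ";"))
  h <- stats::as.hclust(tree)
  # ape halves hclust heights (it reads them as inter-cluster distances);
  # double them so root-to-tip depth equals the final merge height
  h$height <- 2 * h$height
  ape::write.tree(ape::as.phylo(h))
}

#' Write a labelled distance matrix as delimited text
#'
#' @param d symmetric matrix with dimnames
#' @param path output file
#' @param sep delimiter
#' @param digits significant digits kept (`NULL` = full precision)
#' @return `path`, invisibly
#' @export
write_distance <- function(d, path, sep = "\t", digits = NULL) {
  if (!is.null(digits)) d <- round(d, digits)
  df <- data.frame(label = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled summary tables of the Chongzuo wild-tea survey
#'
#' Loads the published summary tables of a field survey of 40 wild tea
#' accessions from seven populations in Chongzuo, Guangxi, shipped with the
#' package as plain-text fixtures:
#'
#' * `accessions` — accession-to-population map with site metadata.  The
#'   published membership list assigns S35 to two populations; the fixture
#'   keeps S35 in NN and S36-S40 in JB so both populations have the stated
#'   size of five.
#' * `loci` — the 14-locus SSR panel (repeat motif, annealing temperature,
#'   expected fragment size).
#' * `trait_summary` — per-trait category frequencies (percent), CV and
#'   Shannon-Weaver H' for the 18 coded descriptive traits, plus
#'   `h_consistent`/`cv_consistent` flags marking rows whose printed H'/CV
#'   agree (to 2 decimals) with recomputation from the printed frequencies;
#'   several published rows are internally inconsistent and are flagged
#'   `FALSE`.  The leaf-blade-texture first frequency is repaired from
#'   12.20 to 12.50 so the row sums to 100.
#' * `leaf_traits` — per-accession quantitative leaf traits (cm, cm2), with
#'   two typographic repairs and one suspect value noted in the `note`
#'   column (the S34 leaf width is retained as published but flagged; any
#'   computation relying on leaf width should exclude it).
#' * `quantitative_summary` — published min/max/mean/SD/CV/H' of the four
#'   quantitative traits.
#' * `locus_stats` — per-locus Na, Ne, I, Ho, He, F, PIC.
#' * `population_diversity` — per-population means of the marker statistics.
#' * `population_distance` — 7x7 Nei genetic distance matrix.
#' * `fst` / `nm` — pairwise differentiation and island-model gene flow,
#'   split out of the published combined matrix (Fst below, Nm above the
#'   diagonal).
#' * `amova` — the published three-stratum molecular variance table.
#'
#' @return named list of data.frames / matrices as described above
#' @examples
#' tabs <- survey_tables()
#' tabs$population_distance["JB", "RX"]
#' @export
survey_tables <- function() {
  p <- function(f) system.file("extdata", f, package = "teadiv", mustWork = TRUE)
  rd <- function(f) read.delim(p(f), check.names = FALSE, stringsAsFactors = FALSE)
  mat <- function(df) {
    m <- as.matrix(df[, -1]); rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    m
  }
  fstnm <- mat(rd("fst_nm.tsv"))
  fst <- fstnm; fst[upper.tri(fstnm)] <- t(fstnm)[upper.tri(fstnm)]; diag(fst) <- 0
  nm <- fstnm; nm[lower.tri(fstnm)] <- t(fstnm)[lower.tri(fstnm)]; diag(nm) <- NA
  list(
    accessions = rd("accessions.tsv"),
    loci = rd("loci.tsv"),
    trait_summary = rd("trait_summary.tsv"),
    leaf_traits = rd("leaf_traits.tsv"),
    quantitative_summary = rd("quantitative_summary.tsv"),
    locus_stats = rd("locus_stats.tsv"),
    population_diversity = rd("population_diversity.tsv"),
    population_distance = mat(rd("population_distance.tsv")),
    fst = fst,
    nm = nm,
    amova = rd("amova.tsv")
  )
}
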
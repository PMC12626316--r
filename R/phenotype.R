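#' Category frequencies of a coded trait
#'
#' Proportions of each observed category code, ordered by ascending code.
#'
#' @param codes integer vector of category codes
#' @return named numeric vector of proportions summing to 1
#' @export
category_frequencies <- function(codes) {
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0L) stop("no codes supplied")
  tab <- table(factor(codes, levels = sort(unique(codes))))
  p <- as.numeric(tab) / length(codes)
  setNames(p, names(tab))
}

#' Shannon-Weaver diversity index
#'
#' `H' = -sum(Pi * ln(Pi))` over the non-zero proportions `Pi` (natural
#' log; `0 * ln 0` taken as 0).  Applied to trait category frequencies it
#' is the phenotypic diversity index H'; applied to allele frequencies it
#' is the marker information index I.
#'
#' @param p numeric vector of proportions (must sum to 1 within 1e-6
#'   after dropping zeros)
#' @return H' in nats
#' @examples
#' shannon_index(c(0.875, 0.125))  # 0.3768
#' @export
shannon_index <- function(p) {
  p <- p[!is.na(p) & p > 0]
  if (abs(sum(p) - 1) > 1e-6) stop("proportions must sum to 1")
  -sum(p * log(p))
}

#' Coefficient of variation (percent)
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation.  For
#' coded descriptive traits the integer category codes are treated as
#' ordinal scores.
#'
#' @param x numeric vector, at least two values, non-zero mean
#' @return CV in percent
#' @export
coefficient_of_variation <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("need at least two values")
  m <- mean(x)
  if (m == 0) stop("coefficient of variation undefined for zero mean")
  100 * sd(x) / m
}

#' Grade a quantitative trait into diversity classes
#'
#' Converts continuous measurements into ordered classes for Shannon-Weaver
#' diversity computation: class 1 holds values below `mean - 2 sd`, the top
#' class holds values at or above `mean + 2 sd`, and the interior classes
#' each span half a standard deviation.
#'
#' @param x numeric vector (>= 2 values)
#' @param n_classes number of classes (default 10)
#' @return integer class codes, one per value
#' @export
grade_quantitative <- function(x, n_classes = 10L) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least two values")
  m <- mean(x, na.rm = TRUE); s <- sd(x, na.rm = TRUE)
  if (s == 0) {
    warning("zero standard deviation: all values fall in the middle class")
    return(rep(as.integer(ceiling(n_classes / 2)), length(x)))
  }
  breaks <- m + s * seq(-2, -2 + 0.5 * (n_classes - 2), by = 0.5)
  cls <- findInterval(x, breaks) + 1L
  cls[cls > n_classes] <- n_classes
  as.integer(cls)
}

#' Standardize a phenotype table to per-trait z-scores
#'
#' Descriptive traits enter via their integer category codes; every trait is
#' centred and scaled to sample SD 1.  Traits with zero SD are dropped with
#' a warning.
#'
#' @param x numeric matrix or data.frame, accessions in rows, traits in
#'   columns (a [simulate_phenotypes()] result is accepted and flattened)
#' @return numeric matrix of z-scores with the same rownames
#' @export
standardize_phenotypes <- function(x) {
  if (is.list(x) && !is.data.frame(x) && all(c("descriptive", "quantitative") %in% names(x)))
    x <- cbind(x$descriptive, x$quantitative)
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  sds <- apply(x, 2, sd, na.rm = TRUE)
  if (any(sds == 0)) {
    warning("dropping zero-variance traits: ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  scale(x)[, , drop = FALSE]
}

#' Pairwise Euclidean distance over standardized traits
#'
#' @param z numeric matrix without missing values (rows = accessions)
#' @return symmetric labelled distance matrix
#' @export
euclidean_matrix <- function(z) {
  z <- as.matrix(z)
  if (anyNA(z))
    stop("missing values in the trait matrix: impute or drop incomplete traits first")
  as.matrix(dist(z))
}

#' Summarize coded descriptive traits
#'
#' Per-trait category frequencies (percent), coefficient of variation of the
#' ordinal codes, and Shannon-Weaver H'.
#'
#' @param codes data.frame/matrix of integer category codes, accessions in
#'   rows, traits in columns
#' @return data.frame with one row per trait: frequency columns `f1..fk`
#'   (percent), `cv_pct`, `shannon`
#' @export
summarize_traits <- function(codes) {
  codes <- as.data.frame(codes)
  kmax <- max(vapply(codes, function(v) max(v, na.rm = TRUE), numeric(1)))
  rows <- lapply(names(codes), function(tr) {
    v <- codes[[tr]]
    f <- rep(0, kmax)
    tab <- table(factor(v[!is.na(v)], levels = seq_len(kmax)))
    f[seq_len(kmax)] <- 100 * as.numeric(tab) / sum(tab)
    data.frame(trait = tr, t(setNames(f, paste0("f", seq_len(kmax)))),
               cv_pct = coefficient_of_variation(v),
               shannon = shannon_index(category_frequencies(v)))
  })
  do.call(rbind, rows)
}

#' Summarize quantitative traits
#'
#' Min, max, mean, SD, CV and graded Shannon-Weaver H' per trait
#' (see [grade_quantitative()]).
#'
#' @param x data.frame/matrix of quantitative trait values
#' @param n_classes classes used for the diversity grading
#' @return data.frame with one row per trait
#' @export
summarize_quantitative <- function(x, n_classes = 10L) {
  x <- as.data.frame(x)
  do.call(rbind, lapply(names(x), function(tr) {
    v <- x[[tr]][!is.na(x[[tr]])]
    data.frame(trait = tr, min = min(v), max = max(v), mean = mean(v),
               sd = sd(v), cv_pct = coefficient_of_variation(v),
               shannon = shannon_index(category_frequencies(grade_quantitative(v, n_classes))))
  }))
}
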
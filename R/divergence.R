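# Per-locus divergence summaries over TR representatives.

expand_weights <- function(x, w) {
  if (is.null(w)) w <- rep(1L, length(x))
  if (length(w) != length(x)) stop("lengths and weights differ")
  if (any(w < 1)) stop("weights must be >= 1")
  rep(x, times = w)
}

#' Length of a TR locus
#'
#' The median length of all TRs observed at the locus; each representative
#' contributes one observation per member allele.
#'
#' @param lengths Representative lengths.
#' @param weights Allele counts per representative (default all 1).
#' @return Weighted median length.
#' @export
locus_length <- function(lengths, weights = NULL) {
  if (!length(lengths)) stop("no length observations")
  median(expand_weights(lengths, weights))
}

#' Interquartile-range ratio of a TR locus
#'
#' `(Q3 - Q1) / median` over all TR observations at the locus - a robust
#' divergence measure for length distributions that are often bimodal or
#' multimodal.  Quartiles use linear interpolation between order statistics
#' (`type = 7`) by default.
#'
#' @inheritParams locus_length
#' @param type Quantile rule passed to [stats::quantile()].
#' @return Non-negative ratio, invariant under positive scaling of lengths.
#' @export
iqr_ratio <- function(lengths, weights = NULL, type = 7) {
  x <- expand_weights(lengths, weights)
  med <- median(x)
  if (med == 0) stop("median length is zero")
  q <- quantile(x, c(0.25, 0.75), names = FALSE, type = type)
  (q[2] - q[1]) / med
}

#' Mutation rate of a TR locus
#'
#' The average of the representatives' mutation rates weighted by their
#' allele counts.
#'
#' @param rates Per-representative mutation rates.
#' @param weights Allele counts (default all 1).
#' @return Weighted mean rate.
#' @export
locus_mutation_rate <- function(rates, weights = NULL) {
  if (is.null(weights)) weights <- rep(1L, length(rates))
  weighted.mean(rates, weights)
}

#' Complexity class of a TR locus
#'
#' Under the default `"any"` rule a locus is complex as soon as one of its
#' representatives is complex (k >= 2 key units).  The alternative
#' `"union"` rule pools the key units of all representatives and calls the
#' locus complex when the pooled set has two or more distinct units.
#'
#' @param key_reports List of [key_units()] reports, one per representative.
#' @param method `"any"` (default) or `"union"`.
#' @return `"complex"` or `"single-unit"`.
#' @export
classify_locus <- function(key_reports, method = c("any", "union")) {
  method <- match.arg(method)
  if (!length(key_reports)) stop("no representatives")
  complex <- switch(method,
    any = any(vapply(key_reports, function(r) isTRUE(r$is_complex),
                     logical(1))),
    union = length(unique(unlist(lapply(key_reports, `[[`, "key_units")))) >= 2L
  )
  if (complex) "complex" else "single-unit"
}

#' Extension flag of a TR locus
#'
#' The excess of the longest representative over the locus (median) length;
#' loci whose longest TR exceeds the median by more than `threshold` bases
#' (default 100) are flagged as extended - candidates for
#' disease-associated expansion.
#'
#' @inheritParams locus_length
#' @param threshold Extension threshold in bases (strict `>`).
#' @return List with `extension_delta` and `extended`.
#' @export
extension_flag <- function(lengths, weights = NULL, threshold = 100) {
  if (!length(lengths)) stop("no representatives")
  delta <- max(lengths) - locus_length(lengths, weights)
  list(extension_delta = delta, extended = delta > threshold)
}

#' Divergence summary of one TR locus
#'
#' @param reps data.frame with one row per representative: `length`,
#'   `n_alleles`, `mutation_rate`.
#' @param key_reports Optional list of [key_units()] reports (enables the
#'   complexity class).
#' @param locus Locus id.
#' @param extension_threshold Passed to [extension_flag()].
#' @param complexity_method Passed to [classify_locus()].
#' @return One-row data.frame: `locus`, `n_representatives`,
#'   `locus_length`, `iqr_ratio`, `mutation_rate`, `complexity`,
#'   `extension_delta`, `extended`.
#' @export
tr_locus_summary <- function(reps, key_reports = NULL, locus = "locus",
                             extension_threshold = 100,
                             complexity_method = c("any", "union")) {
  stopifnot(all(c("length", "n_alleles", "mutation_rate") %in% names(reps)))
  ext <- extension_flag(reps$length, reps$n_alleles,
                        threshold = extension_threshold)
  data.frame(
    locus = locus,
    n_representatives = nrow(reps),
    locus_length = locus_length(reps$length, reps$n_alleles),
    iqr_ratio = iqr_ratio(reps$length, reps$n_alleles),
    mutation_rate = locus_mutation_rate(reps$mutation_rate, reps$n_alleles),
    complexity = if (is.null(key_reports)) NA_character_ else
      classify_locus(key_reports, complexity_method),
    extension_delta = ext$extension_delta,
    extended = ext$extended,
    stringsAsFactors = FALSE
  )
}
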
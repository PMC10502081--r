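# Reliable flanking substitutions under an exact binomial error model, and
# nearest-SNV grouping of TR representatives.

#' Significance threshold for a flanking substitution count
#'
#' With read depth `n` and a per-read substitution-error probability `p`,
#' returns the minimum count `k` at which a substitution is treated as a
#' real SNV rather than sequencing error at significance level `alpha`
#' (substitutions with count >= `k` are significant).
#'
#' Tail convention: the default `"greater"` returns the smallest `k` with
#' exact-binomial `P(X > k) < alpha`, which reproduces the reference worked
#' value k = 4 at n = 3000, p = 0.05%.  The literal "k or more" reading -
#' smallest `k` with `P(X >= k) < alpha` - is available as `tail = "geq"`
#' (it gives k = 5 for the same inputs; the two conventions differ by one).
#'
#' @param n Read depth (>= 1).
#' @param p Per-read substitution probability (default 0.0005, i.e. 0.05%,
#'   half of the ~0.1% average HiFi error rate).
#' @param alpha Significance level (default 0.05).
#' @param tail `"greater"` (default) or `"geq"`, see above.
#' @return Integer threshold count `k` (vectorised over `n`).
#' @examples
#' significant_substitution_threshold(3000, 0.0005)  # 4
#' @export
significant_substitution_threshold <- function(n, p = 0.0005, alpha = 0.05,
                                               tail = c("greater", "geq")) {
  tail <- match.arg(tail)
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (any(n < 1)) stop("n must be >= 1")
  k <- vapply(n, function(ni) {
    kk <- max(0L, as.integer(qbinom(alpha, ni, p, lower.tail = FALSE)) - 2L)
    while (pbinom(kk, ni, p, lower.tail = FALSE) >= alpha) kk <- kk + 1L
    kk
  }, integer(1))
  if (tail == "geq") k <- k + 1L
  k
}

#' Call significant substitutions from a flank pileup
#'
#' Evaluates every non-reference base count against the exact binomial
#' threshold at that position's depth.  Indels are excluded by construction
#' of the pileup (only A/C/G/T counts enter).
#'
#' @param pileup data.frame with columns `chrom`, `pos` (0-based reference
#'   position), `ref` (reference base), `depth`, and counts `A`, `C`, `G`,
#'   `T`.  Per-position counts must not exceed `depth`.
#' @inheritParams significant_substitution_threshold
#' @return data.frame of substitution observations: `chrom`, `pos`, `ref`,
#'   `alt`, `count`, `depth`, `significant`.  Zero counts are never
#'   reported; a significant call always has `count >= max(k, 1)`.
#' @export
call_flank_snvs <- function(pileup, p = 0.0005, alpha = 0.05,
                            tail = c("greater", "geq")) {
  tail <- match.arg(tail)
  need <- c("chrom", "pos", "ref", "depth", "A", "C", "G", "T")
  if (!all(need %in% names(pileup))) {
    stop("pileup must have columns: ", paste(need, collapse = ", "))
  }
  if (any(pileup$depth < 1)) stop("pileup depths must be >= 1")
  bases <- c("A", "C", "G", "T")
  cnt <- as.matrix(pileup[, bases])
  if (any(rowSums(cnt) > pileup$depth)) stop("counts exceed depth")
  k <- significant_substitution_threshold(pileup$depth, p, alpha, tail)
  out <- lapply(seq_len(nrow(pileup)), function(i) {
    alt <- setdiff(bases, pileup$ref[i])
    cc <- cnt[i, alt]
    keep <- cc > 0
    if (!any(keep)) return(NULL)
    data.frame(chrom = pileup$chrom[i], pos = pileup$pos[i],
               ref = pileup$ref[i], alt = alt[keep],
               count = as.integer(cc[keep]), depth = pileup$depth[i],
               significant = cc[keep] >= max(k[i], 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      count = integer(0), depth = integer(0),
                      significant = logical(0))
  }
  rownames(out) <- NULL
  out
}

#' Nearest flanking SNVs of a TR interval
#'
#' The significant SNVs closest to the TR, searched strictly upstream of the
#' TR start and strictly downstream of the TR end within a peripheral
#' window.
#'
#' @param tr_start,tr_end TR interval, 0-based half-open.
#' @param snvs data.frame of significant substitutions with columns `pos`
#'   and `alt` (e.g. the significant rows of [call_flank_snvs()]).
#' @param window Search window in bases on each side (default 1000).
#' @return List with `upstream` and `downstream`, each either `NULL` or a
#'   list `(pos, alt)`.
#' @export
nearest_snv_pair <- function(tr_start, tr_end, snvs, window = 1000) {
  stopifnot(tr_start <= tr_end)
  up <- snvs[snvs$pos < tr_start & tr_start - snvs$pos <= window, ,
             drop = FALSE]
  down <- snvs[snvs$pos >= tr_end & snvs$pos - tr_end < window, ,
               drop = FALSE]
  pick <- function(df, decreasing) {
    if (!nrow(df)) return(NULL)
    i <- order(df$pos, decreasing = decreasing)[1]
    list(pos = df$pos[i], alt = df$alt[i])
  }
  list(upstream = pick(up, decreasing = TRUE),
       downstream = pick(down, decreasing = FALSE))
}

snv_pair_key <- function(pair) {
  fmt <- function(x) if (is.null(x)) "NONE" else paste0(x$pos, x$alt)
  paste(fmt(pair$upstream), fmt(pair$downstream), sep = "|")
}

#' Group TR representatives by identical nearest-SNV pairs
#'
#' Representatives sharing the exact same (upstream, downstream) nearest-SNV
#' pair form a TR group; the group's length spread (longest minus shortest
#' member) measures how poorly the surrounding SNVs impute the TR.
#'
#' @param reps data.frame with one row per representative: a `length`
#'   column plus either a `pair` list-column of [nearest_snv_pair()] results
#'   or precomputed key columns.
#' @param pairs Optional list of [nearest_snv_pair()] results, parallel to
#'   the rows of `reps` (used when `reps` has no `pair` column).
#' @return List with `groups` (data.frame `key`, `n_members`, `spread`) and
#'   `membership` (list of row indices of `reps`).
#' @export
group_by_snv_pair <- function(reps, pairs = reps$pair) {
  if (is.null(pairs)) stop("no SNV pairs supplied")
  keys <- vapply(pairs, snv_pair_key, character(1))
  idx <- split(seq_len(nrow(reps)), keys)
  idx <- idx[order(names(idx))]
  groups <- data.frame(
    key = names(idx),
    n_members = vapply(idx, length, integer(1)),
    spread = vapply(idx, function(i) {
      max(reps$length[i]) - min(reps$length[i])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(groups) <- NULL
  list(groups = groups, membership = unname(idx))
}
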
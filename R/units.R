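# Repeat-unit selection and TR decomposition.

#' Canonical rotation of a repeat unit
#'
#' Returns the lexicographically smallest rotation of a unit, used to
#' identify rotation-equivalent units ((e.g. `"GAC"`, `"ACG"` and `"CGA"`
#' describe the same repeat when tiled).
#'
#' @param u Character vector of units (non-empty strings).
#' @return Character vector of canonical rotations, same length as `u`.
#' @examples
#' canonical_unit(c("GAC", "AAAG"))
#' @export
canonical_unit <- function(u) {
  stopifnot(is.character(u))
  if (any(nchar(u) < 1)) stop("unit must have length >= 1")
  vapply(u, function(x) {
    n <- nchar(x)
    if (n == 1L) return(x)
    rot <- vapply(seq_len(n), function(i) {
      paste0(substr(x, i, n), substr(x, 1, i - 1L))
    }, character(1))
    min(rot)
  }, character(1), USE.NAMES = FALSE)
}

is_primitive_unit <- function(u) {
  n <- nchar(u)
  for (d in seq_len(n %/% 2)) {
    if (n %% d == 0L && strrep(substr(u, 1, d), n %/% d) == u) return(FALSE)
  }
  TRUE
}

check_units <- function(units) {
  if (length(units) == 0L) stop("unit set is empty")
  if (any(nchar(units) < 1L)) stop("empty unit")
  if (any(grepl("[^ACGT]", units))) stop("invalid unit alphabet")
  invisible(units)
}

#' Enumerate candidate repeat units of a TR sequence
#'
#' Candidates are substrings of length `2..max_unit` that occur at least
#' twice in tandem adjacency (the substring is immediately followed by an
#' identical copy).  Non-primitive substrings (exact powers of a shorter
#' string) are dropped, rotation-equivalent candidates are collapsed to the
#' earliest-occurring phase, and a longer candidate that a shorter kept
#' candidate already explains (decomposing it by the shorter unit leaves at
#' most `explain_tol` of its bases as edits or uncovered) is discarded.
#' The last rule matters because the selection penalty, taken literally,
#' prefers a k-copy composite `u^k` over the base unit `u` for long
#' expansions (`km + n/km < m + n/m`), and a single sequencing error makes
#' such a composite technically primitive; pruning explained candidates
#' keeps the pool at true generating units.
#'
#' @param seq TR sequence (single string over `ACGTN`).
#' @param max_unit Maximum candidate unit length.
#' @param explain_tol Discrepancy fraction below which a longer candidate
#'   counts as explained by a shorter one (default 0.1, above the HiFi
#'   error rate and below typical inter-unit divergence).
#' @return Character vector of candidate units, ordered by length then by
#'   first tandem occurrence.
#' @export
tandem_candidate_units <- function(seq, max_unit = 100, explain_tol = 0.1) {
  stopifnot(is.character(seq), length(seq) == 1L)
  n <- nchar(seq)
  out_unit <- character(0)
  out_len <- integer(0)
  out_pos <- integer(0)
  for (L in 2:max(2, min(max_unit, n %/% 2))) {
    if (2L * L > n) break
    starts <- seq_len(n - 2L * L + 1L)
    x <- substring(seq, starts, starts + L - 1L)
    y <- substring(seq, starts + L, starts + 2L * L - 1L)
    hit <- which(x == y)
    if (length(hit)) {
      out_unit <- c(out_unit, x[hit])
      out_len <- c(out_len, rep(L, length(hit)))
      out_pos <- c(out_pos, starts[hit])
    }
  }
  if (!length(out_unit)) return(character(0))
  # longest run of consecutive exact copies of u in seq
  max_tandem_run <- function(u) {
    m <- nchar(u)
    n2 <- nchar(seq)
    starts <- seq_len(n2 - m + 1L)
    hit <- substring(seq, starts, starts + m - 1L) == u
    run <- integer(n2 + 1L)
    best <- 0L
    for (s in starts[hit]) {
      run[s + m] <- if (s > m && hit[s - m]) run[s] + 1L else 1L
      if (run[s + m] > best) best <- run[s + m]
    }
    best
  }
  ord <- order(out_len, out_pos)
  out_unit <- out_unit[ord]
  prim <- vapply(out_unit, is_primitive_unit, logical(1), USE.NAMES = FALSE)
  out_unit <- out_unit[prim]
  # among rotation-equivalent candidates keep the phase whose tandem run is
  # longest (the true block phase); inside a periodic block every rotation
  # ties within one copy, so ties prefer the canonical rotation, then the
  # earliest occurrence
  runs <- vapply(out_unit, max_tandem_run, integer(1), USE.NAMES = FALSE)
  can <- canonical_unit(out_unit)
  keep_idx <- unlist(lapply(split(seq_along(out_unit), can), function(ix) {
    ix[order(-runs[ix], out_unit[ix] != can[ix], ix)[1]]
  }), use.names = FALSE)
  out_unit <- out_unit[sort(keep_idx)]
  # drop candidates explained by a shorter kept candidate: a true composite
  # is (near) a power of a single rotation of the shorter unit, so each
  # rotation is tried alone - offering all rotations at once would also
  # "explain" genuine units that merely share rotated fragments
  rotations <- function(u) {
    n <- nchar(u)
    unique(vapply(seq_len(n), function(i) {
      paste0(substr(u, i, n), substr(u, 1, i - 1L))
    }, character(1)))
  }
  kept <- character(0)
  for (cand in out_unit) {
    shorter <- kept[2L * nchar(kept) <= nchar(cand)]
    explained <- FALSE
    for (u in shorter) {
      for (r in rotations(u)) {
        raw <- cpp_decompose(cand, r, 1L, 1L, 0L, 1L)
        if (raw$combined <= explain_tol * nchar(cand)) {
          explained <- TRUE
          break
        }
      }
      if (explained) break
    }
    if (!explained) kept <- c(kept, cand)
  }
  kept
}

new_tr_decomposition <- function(seq, units, raw) {
  seg_unit <- ifelse(is.na(raw$unit), NA_character_, units[raw$unit])
  segments <- data.frame(
    start = raw$start, end = raw$end,
    unit = seg_unit, edits = raw$edits,
    stringsAsFactors = FALSE
  )
  occ <- vapply(units, function(u) sum(segments$unit %in% u), integer(1))
  names(occ) <- units
  covered <- sum((segments$end - segments$start)[!is.na(segments$unit)])
  uncovered <- nchar(seq) - covered
  structure(
    list(
      seq = seq, units = units, segments = segments, occ = occ,
      distance = raw$distance, covered_bases = covered,
      uncovered_bases = uncovered,
      penalty = sum(nchar(units)) + sum(occ) + uncovered
    ),
    class = "tr_decomposition"
  )
}

#' Decompose a TR into copies of a fixed unit set
#'
#' Computes an optimal parse of `seq` into consecutive (possibly edited)
#' copies of the given units plus uncovered literal segments.  The dynamic
#' program minimises the combined parsimony cost
#' `edit distance + copy_cost * (number of copies) + unc_cost * (uncovered
#' bases)`; among cost-ties the parse with the smaller edit distance is
#' kept.  The copy and uncovered terms mirror the `occ(u)` and uncovered
#' terms of the unit-selection penalty (see [tr_penalty()]), so the same
#' parse supports the reported Levenshtein distance, the penalty, and the
#' per-TR mutation rate.
#'
#' @param seq TR sequence (single string).
#' @param units Character vector of repeat units over `ACGT`.
#' @param mismatch,indel Unit costs of a substitution and of an
#'   insertion/deletion inside a copy (Levenshtein distance uses 1/1).
#' @param copy_cost,unc_cost Parsimony weights of opening a unit copy and of
#'   leaving a base uncovered.
#' @return A `tr_decomposition`: list with `seq`, `units`, `segments`
#'   (0-based half-open `start`/`end`, `unit` (`NA` = uncovered), `edits`),
#'   `occ`, `distance`, `covered_bases`, `uncovered_bases`, `penalty`.
#' @examples
#' d <- decompose_with_units("AGAGAGAGAG", "AG")
#' d$occ
#' @export
decompose_with_units <- function(seq, units, mismatch = 1, indel = 1,
                                 copy_cost = 1, unc_cost = 1) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty sequence")
  check_units(units)
  raw <- cpp_decompose(seq, units, as.integer(mismatch), as.integer(indel),
                       as.integer(copy_cost), as.integer(unc_cost))
  new_tr_decomposition(seq, units, raw)
}

#' Penalty of a decomposition by a unit set
#'
#' The parsimony penalty `sum over units of (|u| + occ(u)) + uncovered
#' bases`: fewer copies of fewer, shorter units and less uncovered sequence
#' are preferred.
#'
#' @param decomposition A [decompose_with_units()] result.
#' @param units Unit set to score against; defaults to the decomposition's
#'   own units.  Units absent from the parse still contribute `|u|`.
#' @return Numeric penalty value.
#' @export
tr_penalty <- function(decomposition, units = decomposition$units) {
  stopifnot(inherits(decomposition, "tr_decomposition"))
  used <- unique(decomposition$segments$unit)
  used <- used[!is.na(used)]
  if (!all(used %in% units)) stop("inconsistent decomposition")
  occ <- vapply(units, function(u) sum(decomposition$segments$unit %in% u),
                integer(1))
  sum(nchar(units)) + sum(occ) + decomposition$uncovered_bases
}

#' Greedy repeat-unit selection for a complex TR
#'
#' Starting from the empty unit set (penalty = TR length, everything
#' uncovered), repeatedly adds the candidate unit whose inclusion gives the
#' lowest penalty, stopping when no candidate lowers it.  Ties are broken
#' toward the lower penalty, then the shorter unit, then the
#' lexicographically smaller canonical rotation.
#'
#' Candidate penalties are evaluated on exact-copy parses - `occ(u)` counts
#' exact occurrences of `u` in `S`, so a region of a foreign unit stays
#' uncovered (expensive) until its own unit joins the set, rather than
#' being absorbed as edited copies.  This is what lets a
#' `(AAAG)i(AG)j(AGGG)k` repeat select all three units instead of being
#' flattened to a single edited (AAAG)-repeat.  Copies further count only
#' inside tandem runs of at least `min_run` adjacent exact copies: true
#' generating units are laid down in runs by slippage, whereas chance
#' matches of a short unit inside error-broken stretches are scattered and
#' would otherwise be selected as spurious units.  The returned
#' decomposition of the final unit set allows edits anywhere, yielding the
#' Levenshtein distance and mutation rate.
#'
#' @inheritParams decompose_with_units
#' @param max_unit Maximum candidate unit length considered.
#' @param min_run Minimum tandem-run length for a copy to count during
#'   selection; selection-time only, the final parse is unrestricted.  The
#'   default `NULL` scales the requirement with unit length as
#'   `max(3, 1 + ceiling(6 / m))` (runs of 4 for dinucleotides, 3
#'   otherwise).  This keeps the chance of a spurious qualifying run low
#'   and, because a single sequencing indel inside a block creates a
#'   genuine tandem pair - but never a triple - of a one-edit variant
#'   unit, the floor of 3 stops such variants from being selected.
#' @return A `tr_decomposition` for the selected unit set (empty unit set
#'   allowed: a sequence with no tandem substring stays fully uncovered),
#'   with the greedy trace in attribute `"selection"`.
#' @examples
#' d <- select_units(strrep("ACAGG", 20))
#' d$units
#' @export
select_units <- function(seq, max_unit = 100, mismatch = 1, indel = 1,
                         copy_cost = 1, unc_cost = 1, min_run = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("empty sequence")
  cands <- tandem_candidate_units(seq, max_unit = max_unit)
  run_req <- function(units) {
    if (is.null(min_run)) {
      # floor of 3: a single indel inside a block creates a genuine tandem
      # pair of a one-edit variant unit, but never a triple
      pmax(3L, 1L + as.integer(ceiling(6 / nchar(units))))
    } else rep_len(as.integer(min_run), length(units))
  }
  exact_penalty <- function(units) {
    # penalty on the optimal exact-copy parse, copies restricted to tandem
    # runs (scattered chance matches cannot absorb uncovered bases)
    raw <- cpp_decompose(seq, units, 1L, 1L, 1L, 1L, exact = 2L,
                         min_run = run_req(units))
    sum(nchar(units)) + raw$combined
  }
  chosen <- character(0)
  best_pen <- nchar(seq)
  trace <- list()
  repeat {
    pool <- setdiff(cands, chosen)
    if (!length(pool)) break
    round_pen <- vapply(pool, function(cand) exact_penalty(c(chosen, cand)),
                        numeric(1))
    ord <- order(round_pen, nchar(pool), canonical_unit(pool))
    if (round_pen[ord[1]] >= best_pen) break
    pick <- ord[1]
    chosen <- c(chosen, pool[pick])
    best_pen <- round_pen[pick]
    trace[[length(trace) + 1L]] <- data.frame(
      round = length(trace) + 1L, unit = pool[pick], penalty = best_pen,
      stringsAsFactors = FALSE
    )
  }
  best_dec <- if (length(chosen)) {
    decompose_with_units(seq, chosen, mismatch = mismatch, indel = indel,
                         copy_cost = copy_cost, unc_cost = unc_cost)
  } else NULL
  if (is.null(best_dec)) {
    best_dec <- structure(
      list(
        seq = seq, units = character(0),
        segments = data.frame(start = 0L, end = nchar(seq),
                              unit = NA_character_, edits = 0L,
                              stringsAsFactors = FALSE),
        occ = integer(0), distance = 0, covered_bases = 0L,
        uncovered_bases = nchar(seq), penalty = nchar(seq)
      ),
      class = "tr_decomposition"
    )
  }
  attr(best_dec, "selection") <-
    if (length(trace)) do.call(rbind, trace) else
      data.frame(round = integer(0), unit = character(0), penalty = numeric(0))
  best_dec
}

#' Mutation rate of a TR
#'
#' The ratio of the Levenshtein distance between the TR and its optimal
#' concatenation of units to the TR length.
#'
#' @param decomposition A `tr_decomposition`.
#' @return Numeric fraction in `[0, 1]`.
#' @export
tr_mutation_rate <- function(decomposition) {
  stopifnot(inherits(decomposition, "tr_decomposition"))
  n <- nchar(decomposition$seq)
  if (n == 0L) stop("empty sequence")
  decomposition$distance / n
}

#' Key units of a decomposition
#'
#' Units are ranked by the number of bases they cover; the key units are the
#' smallest prefix covering at least `threshold` of the TR length.  A TR
#' whose key-unit count `k` is 2 or more is complex; with `k = 1` it is a
#' single-unit TR.
#'
#' @param decomposition A `tr_decomposition` with at least one unit-labeled
#'   segment.
#' @param threshold Base fraction the key units must reach (default 0.9).
#' @return List with `k`, `key_units`, `base_fraction`, `is_complex`.
#' @export
key_units <- function(decomposition, threshold = 0.9) {
  stopifnot(inherits(decomposition, "tr_decomposition"))
  seg <- decomposition$segments
  seg <- seg[!is.na(seg$unit), , drop = FALSE]
  if (!nrow(seg)) stop("no units to rank")
  bases <- tapply(seg$end - seg$start, seg$unit, sum)
  units <- names(bases)
  ord <- order(-as.numeric(bases), nchar(units), units)
  bases <- as.numeric(bases)[ord]
  units <- units[ord]
  total <- nchar(decomposition$seq)
  cum <- cumsum(bases) / total
  k <- which(cum >= threshold)
  k <- if (length(k)) k[1] else length(units)
  list(k = k, key_units = units[seq_len(k)], base_fraction = cum[k],
       is_complex = k >= 2L)
}

#' Pattern-string notation of a decomposition
#'
#' Collapses consecutive copies of the same unit into `(UNIT)count` blocks;
#' uncovered literal segments are emitted verbatim in lowercase.
#'
#' @param decomposition A `tr_decomposition`.
#' @return Single string, e.g. `"(GT)12(CCG)56(AGCC)5(CCG)9"`.
#' @export
pattern_string <- function(decomposition) {
  stopifnot(inherits(decomposition, "tr_decomposition"))
  seg <- decomposition$segments
  if (!nrow(seg)) return("")
  lab <- ifelse(is.na(seg$unit), "", seg$unit)
  r <- rle(lab)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  parts <- character(length(r$values))
  for (i in seq_along(r$values)) {
    if (r$values[i] == "") {
      lit <- substr(decomposition$seq, seg$start[idx_start[i]] + 1L,
                    seg$end[idx_end[i]])
      parts[i] <- tolower(lit)
    } else {
      parts[i] <- sprintf("(%s)%d", r$values[i], r$lengths[i])
    }
  }
  paste0(parts, collapse = "")
}

#' @export
print.tr_decomposition <- function(x, ...) {
  n <- nchar(x$seq)
  cat(sprintf("TR decomposition: %d bp, %d unit(s), distance %g, penalty %g\n",
              n, length(x$units), x$distance, x$penalty))
  if (length(x$units)) {
    cat("  units:", paste(sprintf("%s (occ %d)", x$units, x$occ),
                          collapse = ", "), "\n")
    cat(sprintf("  mutation rate: %.4g\n", tr_mutation_rate(x)))
  }
  pat <- pattern_string(x)
  if (nchar(pat) > 70) pat <- paste0(substr(pat, 1, 67), "...")
  cat("  pattern:", pat, "\n")
  invisible(x)
}

#' Decompose a set of TR sequences into a summary table
#'
#' Runs [select_units()] on each sequence and reports one row per TR with
#' the field layout used by the command-line `decompose` subcommand.
#'
#' @param seqs Named character vector of TR sequences.
#' @param ... Passed to [select_units()].
#' @return data.frame with columns `id`, `length`, `pattern`, `distance`,
#'   `mutation_rate`, `k`, `is_complex`.
#' @export
decompose_table <- function(seqs, ...) {
  stopifnot(is.character(seqs))
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("tr", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    d <- select_units(seqs[[i]], ...)
    ku <- if (length(d$units)) key_units(d) else
      list(k = 0L, is_complex = FALSE)
    data.frame(
      id = ids[i], length = nchar(seqs[[i]]), pattern = pattern_string(d),
      distance = d$distance, mutation_rate = tr_mutation_rate(d),
      k = ku$k, is_complex = ku$is_complex, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
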
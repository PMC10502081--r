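# Seeded generators for synthetic complex TR haplotypes, slippage-driven
# populations, and HiFi-like reads.  Every stage of the package can be
# exercised against these generators' truth records; no external data is
# required.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

# point edits applied i.i.d. per base; returns the edited string + log
apply_point_errors <- function(seq, rate, p_sub = 0.5, p_ins = 0.25,
                               p_del = 0.25) {
  n <- nchar(seq)
  if (rate <= 0 || n == 0L) {
    return(list(seq = seq,
                edits = data.frame(pos = integer(0), type = character(0))))
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(n) < rate)
  if (!length(hit)) {
    return(list(seq = seq,
                edits = data.frame(pos = integer(0), type = character(0))))
  }
  type <- sample(c("sub", "ins", "del"), length(hit), replace = TRUE,
                 prob = c(p_sub, p_ins, p_del))
  for (k in seq_along(hit)) {
    i <- hit[k]
    ch[i] <- switch(type[k],
      sub = sample(setdiff(DNA_BASES, substr(ch[i], 1, 1)), 1),
      ins = paste0(ch[i], sample(DNA_BASES, 1)),
      del = ""
    )
  }
  list(seq = paste0(ch, collapse = ""),
       edits = data.frame(pos = hit, type = type, stringsAsFactors = FALSE))
}

normalize_blocks <- function(blocks) {
  if (is.list(blocks) && !is.data.frame(blocks)) {
    blocks <- data.frame(
      unit = vapply(blocks, `[[`, character(1), 1),
      copies = as.integer(vapply(blocks, `[[`, character(1), 2)),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(c("unit", "copies") %in% names(blocks)))
  if (any(blocks$copies < 1)) stop("copy numbers must be >= 1")
  check_units(blocks$unit)
  blocks
}

#' Simulate a complex TR from a block pattern
#'
#' Concatenates ordered blocks of `(unit, copies)` and applies seeded
#' i.i.d. point edits (substitution : insertion : deletion = 2 : 1 : 1 by
#' default).  The truth record keeps the planted blocks, the canonical unit
#' set, and every edit.
#'
#' @param blocks data.frame with columns `unit` and `copies` (or a list of
#'   `(unit, copies)` pairs), e.g. the pattern `(GT)12 (CCG)56 (AGCC)5
#'   (CCG)9`.
#' @param mut_rate Per-base point-edit probability in `[0, 1)`.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @return List with `seq` and `truth` (`blocks`, `units` = planted
#'   canonical units, `edits`).
#' @export
sim_tr <- function(blocks, mut_rate = 0, seed = NULL) {
  blocks <- normalize_blocks(blocks)
  if (mut_rate < 0 || mut_rate >= 1) stop("mut_rate must be in [0, 1)")
  with_seed(seed, {
    clean <- paste0(strrep(blocks$unit, blocks$copies), collapse = "")
    mut <- apply_point_errors(clean, mut_rate)
    list(seq = mut$seq,
         truth = list(blocks = blocks,
                      units = sort(unique(canonical_unit(blocks$unit))),
                      clean_seq = clean, edits = mut$edits))
  })
}

tandem_event_sites <- function(seq, units, min_pure_copies = 2L) {
  n <- nchar(seq)
  span <- max(2L, as.integer(min_pure_copies))
  out <- NULL
  for (u in units) {
    m <- nchar(u)
    if (span * m > n) next
    starts <- seq_len(n - span * m + 1L)
    ok <- substring(seq, starts, starts + span * m - 1L) == strrep(u, span)
    if (any(ok)) {
      out <- rbind(out, data.frame(pos = starts[ok], unit = u,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) data.frame(pos = integer(0), unit = character(0)) else out
}

#' Simulate a TR population by replication slippage
#'
#' Evolves `2 * n_individuals` haplotypes independently from a founder TR.
#' Each generation, slippage events (unit duplication or contraction,
#' equally likely) occur at sites where two exact adjacent copies of a
#' planted unit remain - slippage requires local unit purity, so point
#' mutations progressively suppress it, halting expansion.  Point mutations
#' are substitutions applied i.i.d. per base per generation.
#'
#' @param blocks Founder pattern as in [sim_tr()].
#' @param n_individuals Number of diploid individuals.
#' @param generations Generations of independent evolution per haplotype.
#' @param slippage Per-eligible-site, per-generation event probability.
#' @param point_mut Per-base, per-generation substitution probability
#'   (private to each haplotype).
#' @param founder_mut_rate Per-base substitution probability applied once to
#'   the founder before the population diverges.  This models the shared
#'   mutation load of an old TR: ancestral substitutions are inherited by
#'   every haplotype, erode the pure adjacent copies that slippage needs,
#'   and so halt further expansion - without inflating apparent allele
#'   diversity the way private mutations would.
#' @param min_pure_copies Number of consecutive exact unit copies a site
#'   must carry before a slippage event can occur there (default 2, the
#'   minimal adjacent pair).  Larger spans model stronger mutation halting:
#'   a modest ancestral mutation load then removes most eligible tracts.
#' @param seed Optional integer seed.
#' @return List with `founder` (after ancestral mutations), `haplotypes`
#'   (data.frame `individual`, `hap`, `seq`), `events` (full event log),
#'   and `units`.
#' @export
sim_population <- function(blocks, n_individuals, generations = 8,
                           slippage = 0.002, point_mut = 1e-4,
                           founder_mut_rate = 0, min_pure_copies = 2L,
                           seed = NULL) {
  blocks <- normalize_blocks(blocks)
  stopifnot(n_individuals >= 1, generations >= 0)
  if (slippage < 0 || slippage >= 1) stop("slippage must be in [0, 1)")
  if (point_mut < 0 || point_mut >= 1) stop("point_mut must be in [0, 1)")
  if (founder_mut_rate < 0 || founder_mut_rate >= 1) {
    stop("founder_mut_rate must be in [0, 1)")
  }
  units <- unique(blocks$unit)
  with_seed(seed, {
    founder <- paste0(strrep(blocks$unit, blocks$copies), collapse = "")
    if (founder_mut_rate > 0) {
      founder <- apply_point_errors(founder, founder_mut_rate, p_sub = 1,
                                    p_ins = 0, p_del = 0)$seq
    }
    haps <- expand.grid(hap = 1:2, individual = seq_len(n_individuals))
    events <- list()
    seqs <- character(nrow(haps))
    for (h in seq_len(nrow(haps))) {
      s <- founder
      for (g in seq_len(generations)) {
        sites <- tandem_event_sites(s, units, min_pure_copies)
        if (nrow(sites)) {
          n_ev <- rbinom(1, nrow(sites), slippage)
          for (e in seq_len(n_ev)) {
            sites <- tandem_event_sites(s, units, min_pure_copies)
            if (!nrow(sites)) break
            pick <- sites[sample.int(nrow(sites), 1), ]
            m <- nchar(pick$unit)
            dup <- runif(1) < 0.5
            s <- if (dup) {
              paste0(substr(s, 1, pick$pos - 1L), pick$unit,
                     substr(s, pick$pos, nchar(s)))
            } else {
              paste0(substr(s, 1, pick$pos - 1L),
                     substr(s, pick$pos + m, nchar(s)))
            }
            events[[length(events) + 1L]] <- data.frame(
              individual = haps$individual[h], hap = haps$hap[h], gen = g,
              type = if (dup) "duplication" else "contraction",
              unit = pick$unit, pos = pick$pos, stringsAsFactors = FALSE
            )
          }
        }
        if (point_mut > 0) {
          mut <- apply_point_errors(s, point_mut, p_sub = 1, p_ins = 0,
                                    p_del = 0)
          s <- mut$seq
          if (nrow(mut$edits)) {
            events[[length(events) + 1L]] <- data.frame(
              individual = haps$individual[h], hap = haps$hap[h], gen = g,
              type = "substitution", unit = NA_character_,
              pos = mut$edits$pos, stringsAsFactors = FALSE
            )
          }
        }
      }
      seqs[h] <- s
    }
    list(
      founder = founder,
      haplotypes = data.frame(individual = haps$individual, hap = haps$hap,
                              seq = seqs, stringsAsFactors = FALSE),
      events = if (length(events)) do.call(rbind, events) else
        data.frame(individual = integer(0), hap = integer(0),
                   gen = integer(0), type = character(0),
                   unit = character(0), pos = integer(0)),
      units = units
    )
  })
}

#' Simulate HiFi-like reads over haplotypes
#'
#' Per haplotype, the read count is Poisson with mean `coverage` (matching
#' the stochastic yield of a sequencing cell); each read spans the whole
#' haplotype segment and receives i.i.d. per-base errors with the given
#' substitution fraction (the remainder split equally between insertions
#' and deletions - indels dominate HiFi errors).
#'
#' @param haplotypes Character vector of haplotype segment sequences.
#' @param coverage Mean reads per haplotype.
#' @param error_rate Per-base error probability (default 0.001, HiFi-like
#'   ~99.9% accuracy).
#' @param sub_frac Fraction of errors that are substitutions (default 0.2).
#' @param seed Optional integer seed.
#' @return List with `reads` (named character vector) and `truth`
#'   (data.frame `read_id`, `hap` index).
#' @export
sim_reads <- function(haplotypes, coverage = 10, error_rate = 0.001,
                      sub_frac = 0.2, seed = NULL) {
  stopifnot(coverage > 0)
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  with_seed(seed, {
    reads <- character(0)
    hap_of <- integer(0)
    for (h in seq_along(haplotypes)) {
      nr <- rpois(1, coverage)
      for (r in seq_len(nr)) {
        mut <- apply_point_errors(haplotypes[[h]], error_rate,
                                  p_sub = sub_frac,
                                  p_ins = (1 - sub_frac) / 2,
                                  p_del = (1 - sub_frac) / 2)
        reads <- c(reads, mut$seq)
        hap_of <- c(hap_of, h)
      }
    }
    ids <- sprintf("read%03d_h%d", seq_along(reads), hap_of)
    names(reads) <- ids
    list(reads = reads,
         truth = data.frame(read_id = ids, hap = hap_of,
                            stringsAsFactors = FALSE))
  })
}
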
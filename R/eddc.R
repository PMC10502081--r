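# Edit distance with unit duplication and contraction (EDDC) and
# neighbor-joining phylogenies of TR representatives.

#' EDDC cost model
#'
#' Six parameters: match, mismatch, insertion, deletion, and per-unit
#' duplication and contraction costs.  The defaults are match 0, mismatch
#' +1, insertion +1, deletion +1, and +m/2 for duplicating or contracting a
#' unit of length m - a longer unit is less likely to gain or lose a copy,
#' but a whole-unit event is still cheaper than the m single-base edits it
#' would otherwise take.
#'
#' @param match Cost of an aligned match (must be 0).
#' @param mismatch,insertion,deletion Single-character edit costs.
#' @param duplication,contraction Functions of the unit length m returning
#'   the event cost.
#' @return List of class `eddc_costs`.
#' @export
eddc_costs <- function(match = 0, mismatch = 1, insertion = 1, deletion = 1,
                       duplication = function(m) m / 2,
                       contraction = function(m) m / 2) {
  if (match != 0) stop("match cost must be 0")
  if (any(c(mismatch, insertion, deletion) < 0)) stop("costs must be >= 0")
  structure(list(match = match, mismatch = mismatch, insertion = insertion,
                 deletion = deletion, duplication = duplication,
                 contraction = contraction),
            class = "eddc_costs")
}

#' Edit distance with duplication and contraction of repeat units
#'
#' Minimum total cost of transforming `s` into `t` using single-character
#' substitutions, insertions and deletions plus whole-unit duplications
#' (`u -> uu`) and contractions (`uu -> u`) of the units in `units`.  With
#' symmetric costs the distance is symmetric, and it never exceeds the
#' plain Levenshtein distance.
#'
#' @param s,t Sequences over `ACGT`.
#' @param units Character vector of repeat units.
#' @param costs An [eddc_costs()] model.
#' @param max_len Input length cap (default 2000); the dynamic program is
#'   quadratic per pair with cubic-like constants, so longer inputs are
#'   rejected with an error rather than silently attempted.
#' @return Numeric distance (0 if and only if `s == t` under positive
#'   costs).
#' @examples
#' eddc_distance("ACACAC", "ACACACAC", "AC")  # one duplication: 1
#' @export
eddc_distance <- function(s, t, units, costs = eddc_costs(),
                          max_len = 2000) {
  stopifnot(is.character(s), is.character(t), length(s) == 1L,
            length(t) == 1L)
  check_units(units)
  if (max(nchar(s), nchar(t)) > max_len) {
    stop("input longer than max_len (", max_len, " bp)")
  }
  m <- nchar(units)
  cpp_eddc(s, t, units, costs$mismatch, costs$insertion, costs$deletion,
           vapply(m, costs$duplication, numeric(1)),
           vapply(m, costs$contraction, numeric(1)))
}

#' Pairwise EDDC distance matrix
#'
#' @param seqs Named character vector of sequences.
#' @inheritParams eddc_distance
#' @return Symmetric matrix (computed on unordered pairs; use symmetric
#'   costs).
#' @export
eddc_matrix <- function(seqs, units, costs = eddc_costs(), max_len = 2000) {
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <-
          eddc_distance(seqs[[i]], seqs[[j]], units, costs, max_len)
      }
    }
  }
  d
}

#' EDDC phylogeny of TR representatives
#'
#' Computes the pairwise EDDC matrix of the representatives and builds a
#' neighbor-joining tree whose leaves are labeled
#' `(length,allele_count,discrepancy_rate)` - the representative length,
#' the number of TR alleles it covers, and the discrepancy (mutation) rate
#' of its unit decomposition, printed to two decimals.
#'
#' @param reps data.frame with columns `seq`, `length`, `n_alleles`,
#'   `mutation_rate` (at least 2 rows).
#' @inheritParams eddc_distance
#' @return List of class `eddc_phylogeny` with `tree` (ape `phylo`, leaf
#'   labels as above), `matrix`, and `labels`.
#' @export
eddc_nj_tree <- function(reps, units, costs = eddc_costs(), max_len = 2000) {
  stopifnot(all(c("seq", "length", "n_alleles", "mutation_rate") %in%
                  names(reps)))
  if (nrow(reps) < 2) stop("need at least 2 representatives")
  labels <- sprintf("(%d,%d,%.2f)", reps$length, reps$n_alleles,
                    reps$mutation_rate)
  seqs <- reps$seq
  names(seqs) <- make.unique(labels)
  d <- eddc_matrix(seqs, units, costs, max_len)
  tree <- if (nrow(reps) == 2) {
    structure(list(merge = matrix(c(-1L, -2L), 1), labels = names(seqs),
                   edge_length = matrix(rep(d[1, 2] / 2, 2), 1)),
              class = "nj_tree")
  } else {
    nj_rooted(d)
  }
  structure(list(tree = as_phylo_nj(tree), nj = tree, matrix = d,
                 labels = names(seqs)),
            class = "eddc_phylogeny")
}

#' Newick serialisation of an EDDC phylogeny
#'
#' Leaf labels are single-quoted so the `(length,count,rate)` form survives
#' Newick parsing.
#'
#' @param phylogeny An [eddc_nj_tree()] result.
#' @param file Optional path; when omitted the Newick string is returned.
#' @return Newick string (invisibly when writing to a file).
#' @export
write_eddc_newick <- function(phylogeny, file = "") {
  stopifnot(inherits(phylogeny, "eddc_phylogeny"))
  nwk <- nj_newick(phylogeny$nj)
  if (nzchar(file)) {
    writeLines(nwk, file)
    return(invisible(nwk))
  }
  nwk
}

#' @export
print.eddc_phylogeny <- function(x, ...) {
  cat(sprintf("EDDC phylogeny: %d representatives\n", length(x$labels)))
  cat(" ", paste(head(x$labels, 8), collapse = " "),
      if (length(x$labels) > 8) "..." else "", "\n")
  invisible(x)
}
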
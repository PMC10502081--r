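# Clustering TR sequences into per-individual alleles and population
# representatives: neighbor-joining with a diameter-validity criterion.

#' Pairwise global-alignment edit distance matrix
#'
#' Unit-cost Levenshtein distance from an optimal global alignment of every
#' pair (never a local alignment: two TRs from the same haplotype must match
#' end to end).
#'
#' @param seqs Character vector of sequences (names become matrix labels).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
edit_distance_matrix <- function(seqs) {
  if (length(seqs) < 1L) stop("empty sequence list")
  d <- utils::adist(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("s", seq_along(seqs))
  dimnames(d) <- list(ids, ids)
  storage.mode(d) <- "double"
  d
}

#' Rooted neighbor-joining clustering tree
#'
#' Standard Saitou-Nei agglomeration over a distance matrix.  The unrooted
#' NJ result is rooted at the last join, giving a binary merge structure
#' (hclust-style) whose internal nodes carry nested leaf sets - the form
#' needed for diameter-validity analysis.  Negative branch-length estimates
#' are clamped to zero.  Ties in the Q-criterion (always present at the
#' three-cluster stage, where Q is constant) break toward the closest pair,
#' then the earliest pair in current cluster order.
#'
#' @param d Symmetric distance matrix (labels in dimnames).
#' @return Object of class `nj_tree`: list with `merge` ((n-1) x 2 matrix,
#'   negative entries are leaves, positive entries earlier merges),
#'   `labels`, and `edge_length` (branch lengths per merge row, children in
#'   column order).
#' @export
nj_rooted <- function(d) {
  n <- nrow(d)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("s", seq_len(n))
  if (n < 2L) stop("need at least 2 sequences to build a tree")
  D <- as.matrix(d)
  active <- -seq_len(n)          # negative = leaf, positive = merge row
  merge <- matrix(0L, n - 1L, 2L)
  elen <- matrix(0, n - 1L, 2L)
  row <- 0L
  while (length(active) > 2L) {
    r <- length(active)
    rs <- rowSums(D)
    Q <- (r - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    # Q-ties (always at r = 3) break toward the closest pair, then order
    dd <- D[idx]
    idx <- idx[order(dd, idx[, 1], idx[, 2])[1], ]
    i <- idx[1]; j <- idx[2]
    li <- 0.5 * D[i, j] + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- D[i, j] - li
    row <- row + 1L
    merge[row, ] <- c(active[i], active[j])
    elen[row, ] <- pmax(c(li, lj), 0)
    dn <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dn[keep]),
               c(dn[keep], 0))
    active <- c(active[keep], row)
  }
  row <- row + 1L
  merge[row, ] <- c(active[1], active[2])
  elen[row, ] <- rep(D[1, 2] / 2, 2)
  structure(list(merge = merge, labels = labels, edge_length = elen),
            class = "nj_tree")
}

#' @export
print.nj_tree <- function(x, ...) {
  cat(sprintf("Rooted neighbor-joining tree: %d leaves\n", length(x$labels)))
  invisible(x)
}

# leaf sets (integer leaf indices) of every merge row
nj_leafsets <- function(tree) {
  m <- tree$merge
  sets <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    kids <- m[i, ]
    sets[[i]] <- unlist(lapply(kids, function(k) {
      if (k < 0) -k else sets[[k]]
    }))
  }
  sets
}

# parent merge row of every node; nodes coded as in `merge` (neg leaf / pos row)
nj_parents <- function(tree) {
  m <- tree$merge
  n <- length(tree$labels)
  parent_leaf <- integer(n)
  parent_merge <- integer(nrow(m))
  for (i in seq_len(nrow(m))) {
    for (k in m[i, ]) {
      if (k < 0) parent_leaf[-k] <- i else parent_merge[k] <- i
    }
  }
  list(leaf = parent_leaf, merge = parent_merge)  # 0 = root has no parent
}

#' Convert a rooted NJ clustering tree to an ape phylo object
#'
#' @param tree An [nj_rooted()] result.
#' @return An object of class `phylo`.
#' @export
as_phylo_nj <- function(tree) {
  m <- tree$merge
  n <- length(tree$labels)
  nm <- nrow(m)
  node_id <- function(k) if (k < 0) -k else n + (nm - k + 1L)
  edges <- matrix(0L, 2L * nm, 2L)
  elen <- numeric(2L * nm)
  e <- 0L
  for (i in seq_len(nm)) {
    for (col in 1:2) {
      e <- e + 1L
      edges[e, ] <- c(n + (nm - i + 1L), node_id(m[i, col]))
      elen[e] <- tree$edge_length[i, col]
    }
  }
  phy <- list(edge = edges, edge.length = elen, tip.label = tree$labels,
              Nnode = nm)
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Newick serialisation of a rooted NJ clustering tree
#'
#' Labels are single-quoted, so labels containing parentheses or commas
#' (e.g. `(54,210,0.00)`) survive round trips.
#'
#' @param tree An [nj_rooted()] result.
#' @return Newick string.
#' @export
nj_newick <- function(tree) {
  stopifnot(inherits(tree, "nj_tree"))
  q <- function(x) paste0("'", gsub("'", "''", x), "'")
  node <- function(k) {
    if (k < 0) return(q(tree$labels[-k]))
    kids <- vapply(1:2, function(col) {
      paste0(node(tree$merge[k, col]), ":",
             format(tree$edge_length[k, col], trim = TRUE))
    }, character(1))
    paste0("(", paste(kids, collapse = ","), ")")
  }
  paste0(node(nrow(tree$merge)), ";")
}

group_diameter <- function(members, d) {
  if (length(members) < 2L) return(0)
  max(d[members, members])
}

group_valid <- function(members, d, lens, threshold_fraction) {
  group_diameter(members, d) <= threshold_fraction * max(lens[members])
}

#' Centroid of a group of sequences
#'
#' The member minimising the sum of distances to all members.  Ties break
#' toward the shorter sequence, then the lexicographically smaller sequence,
#' then the smaller label.
#'
#' @param members Labels (or indices) of the group members.
#' @param d Distance matrix covering the members.
#' @param seqs Named character vector of the sequences.
#' @return Label of the centroid member.
#' @export
centroid <- function(members, d, seqs) {
  if (!length(members)) stop("empty group")
  if (is.character(members) && !all(members %in% rownames(d)))
    stop("member not in distance matrix")
  sums <- rowSums(d[members, members, drop = FALSE])
  ids <- if (is.character(members)) members else rownames(d)[members]
  sq <- seqs[ids]
  ord <- order(sums, nchar(sq), sq, ids)
  ids[ord[1]]
}

# nodes (neg leaf / pos merge row) below `root_node` whose filtered leaf set
# is valid while the parent's is not; returns list of leaf-index vectors
maximally_valid_groups <- function(tree, d, lens, threshold_fraction,
                                   remaining, root_node = NULL) {
  sets <- nj_leafsets(tree)
  fset <- function(k) {
    s <- if (k < 0) -k else sets[[k]]
    intersect(s, remaining)
  }
  valid <- function(k) {
    s <- fset(k)
    length(s) > 0L && group_valid(s, d, lens, threshold_fraction)
  }
  nodes <- list()
  walk <- function(k) {
    if (valid(k)) {
      nodes[[length(nodes) + 1L]] <<- fset(k)
    } else if (k > 0) {
      for (child in tree$merge[k, ]) walk(child)
    }
  }
  if (is.null(root_node)) root_node <- nrow(tree$merge)
  if (valid(root_node)) return(list(fset(root_node)))
  walk(root_node)
  nodes
}

# iteratively extract maximally valid NJ nodes until every sequence is
# assigned; returns a list of index groups (a partition of seq_along(seqs))
extract_valid_groups <- function(d, lens, threshold_fraction, ids) {
  n <- nrow(d)
  if (n == 1L) return(list(1L))
  tree <- nj_rooted(d)
  remaining <- seq_len(n)
  groups <- list()
  while (length(remaining)) {
    if (group_valid(remaining, d, lens, threshold_fraction)) {
      groups[[length(groups) + 1L]] <- remaining
      break
    }
    cand <- maximally_valid_groups(tree, d, lens, threshold_fraction,
                                   remaining = remaining)
    g <- pick_group(cand, d, ids)
    groups[[length(groups) + 1L]] <- g
    remaining <- setdiff(remaining, g)
  }
  groups
}

pick_group <- function(groups, d, labels) {
  diams <- vapply(groups, group_diameter, numeric(1), d = d)
  sizes <- vapply(groups, length, integer(1))
  minlab <- vapply(groups, function(g) min(labels[g]), character(1))
  groups[[order(-sizes, diams, minlab)[1]]]
}

#' Call TR alleles for one individual
#'
#' Clusters the reads observed at one TR locus in one individual into one or
#' two groups (homozygous or heterozygous).  A group is valid when its
#' diameter (maximum pairwise edit distance) is at most
#' `threshold_fraction` of its longest member.  If all reads form a valid
#' group one allele is called; otherwise maximally valid nodes of the NJ
#' tree are extracted until every read is grouped, the two largest groups
#' become the alleles, and reads in any further group are reported as
#' unassigned.  The centroid of each group is the allele sequence.
#'
#' @param reads Named character vector of read segments at the locus.
#' @param threshold_fraction Diameter validity threshold (default 0.01, the
#'   1% rule: two alleles are assumed to differ by more than 1%).
#' @return Object of class `tr_alleles`: list with `alleles` (data.frame
#'   `allele`, `centroid`, `seq`, `members`), `membership` (list of read
#'   ids), `unassigned` (read ids).
#' @export
call_alleles <- function(reads, threshold_fraction = 0.01) {
  if (length(reads) < 1L) stop("no reads")
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("r", seq_along(reads))
  names(reads) <- ids
  lens <- nchar(reads)
  finish <- function(groups, unassigned) {
    d <- attr(groups, "d")
    rows <- lapply(seq_along(groups), function(i) {
      g <- groups[[i]]
      cid <- centroid(ids[g], d, reads)
      data.frame(allele = i, centroid = cid, seq = unname(reads[cid]),
                 members = length(g), stringsAsFactors = FALSE)
    })
    structure(list(
      alleles = do.call(rbind, rows),
      membership = lapply(groups, function(g) ids[g]),
      unassigned = ids[unassigned]
    ), class = "tr_alleles")
  }
  if (length(reads) == 1L) {
    d <- matrix(0, 1, 1, dimnames = list(ids, ids))
    groups <- list(1L); attr(groups, "d") <- d
    return(finish(groups, integer(0)))
  }
  d <- edit_distance_matrix(reads)
  all_idx <- seq_along(reads)
  if (group_valid(all_idx, d, lens, threshold_fraction)) {
    groups <- list(all_idx); attr(groups, "d") <- d
    return(finish(groups, integer(0)))
  }
  parts <- extract_valid_groups(d, lens, threshold_fraction, ids)
  sizes <- vapply(parts, length, integer(1))
  diams <- vapply(parts, group_diameter, numeric(1), d = d)
  minlab <- vapply(parts, function(g) min(ids[g]), character(1))
  ord <- order(-sizes, diams, minlab)
  keep <- ord[seq_len(min(2L, length(parts)))]
  groups <- parts[keep]
  unassigned <- unlist(parts[setdiff(seq_along(parts), keep)])
  if (is.null(unassigned)) unassigned <- integer(0)
  attr(groups, "d") <- d
  finish(groups, unassigned)
}

#' @export
print.tr_alleles <- function(x, ...) {
  cat(sprintf("TR alleles: %d called, %d unassigned read(s)\n",
              nrow(x$alleles), length(x$unassigned)))
  print(x$alleles[, c("allele", "centroid", "members")], row.names = FALSE)
  invisible(x)
}

#' Population TR representatives
#'
#' Pools TR alleles (across individuals) and partitions them into valid
#' groups by repeatedly extracting a maximally valid node of the
#' neighbor-joining tree - a valid node none of whose ancestors is valid -
#' until the remaining root is itself valid.  After each extraction the
#' subtree is removed and node diameters are refreshed.  The centroid of
#' each group is the TR representative.  Extraction order: largest leaf
#' count, then smaller diameter, then smallest leaf label.
#'
#' @param alleles Named character vector of TR allele sequences.
#' @param threshold_fraction Diameter validity threshold (default 0.01).
#' @return Object of class `tr_representatives`: list with
#'   `representatives` (data.frame `rep`, `centroid`, `seq`, `n_alleles`,
#'   `length`) and `membership` (list of allele ids).  Groups partition the
#'   input.
#' @export
population_representatives <- function(alleles, threshold_fraction = 0.01) {
  if (length(alleles) < 1L) stop("no alleles")
  ids <- names(alleles)
  if (is.null(ids)) ids <- paste0("a", seq_along(alleles))
  names(alleles) <- ids
  lens <- nchar(alleles)
  if (length(alleles) == 1L) {
    d <- matrix(0, 1, 1, dimnames = list(ids, ids))
    groups <- list(1L)
  } else {
    d <- edit_distance_matrix(alleles)
    groups <- extract_valid_groups(d, lens, threshold_fraction, ids)
  }
  rows <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    cid <- centroid(ids[g], d, alleles)
    data.frame(rep = i, centroid = cid, seq = unname(alleles[cid]),
               n_alleles = length(g), length = nchar(alleles[cid]),
               stringsAsFactors = FALSE)
  })
  structure(list(
    representatives = do.call(rbind, rows),
    membership = lapply(groups, function(g) ids[g])
  ), class = "tr_representatives")
}

#' @export
print.tr_representatives <- function(x, ...) {
  cat(sprintf("TR representatives: %d group(s) from %d allele(s)\n",
              nrow(x$representatives), sum(x$representatives$n_alleles)))
  print(x$representatives[, c("rep", "centroid", "n_alleles", "length")],
        row.names = FALSE)
  invisible(x)
}
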
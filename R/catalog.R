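# TR locus catalog: merging detector interval lists, masking, and
# extraction of per-read TR segments from anchoring alignments.
# Coordinates are 0-based half-open throughout (BED convention).

catalog_to_granges <- function(df) {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) stop("intervals need chrom, start, end")
  if (any(df$start >= df$end)) stop("invalid interval")
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

granges_to_catalog <- function(gr) {
  gr <- GenomicRanges::sort(gr)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Merge two TR detector interval lists into a locus catalog
#'
#' Concatenates both lists, merges overlapping intervals, then merges
#' intervals separated by at most `merge_gap` bases, repeating to a fixed
#' point.  The result is the sorted, non-overlapping locus list whose
#' consecutive intervals are all separated by more than `merge_gap`.
#'
#' @param listA,listB data.frames with `chrom`, `start`, `end` (0-based
#'   half-open).  `listB` may be `NULL`.
#' @param merge_gap Maximum gap closed between intervals (default 10).
#' @return Sorted non-overlapping data.frame `chrom`, `start`, `end`.
#' @export
merge_catalogs <- function(listA, listB = NULL, merge_gap = 10) {
  grs <- catalog_to_granges(listA)
  if (!is.null(listB) && nrow(listB)) {
    grs <- c(grs, catalog_to_granges(listB))
  }
  merged <- GenomicRanges::reduce(grs, min.gapwidth = merge_gap + 1L)
  granges_to_catalog(merged)
}

#' Drop catalog loci overlapping a mask
#'
#' Removes every locus overlapping any mask interval by at least one base
#' (used to exclude segmental duplications, where read anchoring is
#' unreliable).  Half-open intervals that merely touch do not overlap.
#'
#' @param catalog,mask data.frames with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return Filtered catalog data.frame.
#' @export
exclude_by_overlap <- function(catalog, mask) {
  if (is.null(mask) || !nrow(mask)) return(catalog)
  gc <- catalog_to_granges(catalog)
  gm <- catalog_to_granges(mask)
  hit <- IRanges::overlapsAny(gc, gm)
  out <- catalog[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# project reference position x (0-based) to a 0-based read offset through a
# CIGAR string laid out in reference-forward order
project_through_cigar <- function(x, ref_start, read_start, cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (!length(ops) || nchar(paste0(ops, collapse = "")) != nchar(cigar)) {
    stop("malformed CIGAR: ", cigar)
  }
  lens <- as.integer(sub("[MIDNSHP=X]", "", ops))
  type <- sub("\\d+", "", ops)
  r <- ref_start; q <- read_start
  for (i in seq_along(ops)) {
    consumes_ref <- type[i] %in% c("M", "=", "X", "D", "N")
    consumes_read <- type[i] %in% c("M", "=", "X", "I")
    if (consumes_ref && x < r + lens[i]) {
      return(if (consumes_read) q + (x - r) else q)
    }
    if (consumes_ref) r <- r + lens[i]
    if (consumes_read) q <- q + lens[i]
  }
  if (x == r) return(q)
  stop("position ", x, " outside aligned span")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract per-read TR segments at catalog loci
#'
#' For every locus whose reference span is entirely covered by a read's
#' alignment, returns the read subsequence projected onto the locus.
#' Minus-strand reads are reverse-complemented first, so the emitted
#' segment is always in locus-forward orientation.  Reads that only
#' partially overlap a locus emit nothing.  Projection uses the record's
#' CIGAR blocks; records without a CIGAR are rejected rather than
#' approximated.  Read bases inserted relative to the reference attach to
#' the segment holding the reference base on their left, so an insertion at
#' the locus end is included and one at the locus start is not.
#'
#' @param alignments data.frame of anchoring records with columns
#'   `read_id`, `chrom`, `ref_start`, `ref_end` (0-based half-open span on
#'   the reference), `strand` (`"+"`/`"-"`), `read_start` (0-based offset of
#'   the alignment on the oriented read), and `cigar` (reference-forward
#'   order over the oriented read).
#' @param catalog Locus data.frame `chrom`, `start`, `end` (a `locus` id
#'   column is used if present).
#' @param reads Named character vector of read sequences (as sequenced).
#' @return data.frame `locus`, `read_id`, `seq`.
#' @export
extract_tr_segments <- function(alignments, catalog, reads) {
  need <- c("read_id", "chrom", "ref_start", "ref_end", "strand",
            "read_start", "cigar")
  if (!all(need %in% names(alignments))) {
    stop("alignment records need columns: ", paste(need, collapse = ", "))
  }
  locus_ids <- if ("locus" %in% names(catalog)) catalog$locus else
    sprintf("%s:%d-%d", catalog$chrom, catalog$start, catalog$end)
  out <- list()
  for (ai in seq_len(nrow(alignments))) {
    rec <- alignments[ai, ]
    if (is.na(rec$cigar) || rec$cigar == "" || rec$cigar == "*") {
      stop("record ", ai, ": missing CIGAR; refusing to approximate")
    }
    if (!rec$read_id %in% names(reads)) {
      stop("record ", ai, ": unknown read ", rec$read_id)
    }
    if (rec$ref_start >= rec$ref_end) stop("record ", ai, ": invalid span")
    oriented <- reads[[rec$read_id]]
    if (rec$strand == "-") oriented <- revcomp(oriented)
    cover <- which(catalog$chrom == rec$chrom &
                     catalog$start >= rec$ref_start &
                     catalog$end <= rec$ref_end)
    for (li in cover) {
      qs <- project_through_cigar(catalog$start[li], rec$ref_start,
                                  rec$read_start, rec$cigar)
      qe <- project_through_cigar(catalog$end[li], rec$ref_start,
                                  rec$read_start, rec$cigar)
      out[[length(out) + 1L]] <- data.frame(
        locus = locus_ids[li], read_id = rec$read_id,
        seq = substr(oriented, qs + 1L, qe),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(locus = character(0), read_id = character(0),
                      seq = character(0)))
  }
  do.call(rbind, out)
}

#' Observed-allele ratio of a TR locus
#'
#' The fraction of possible alleles actually observed across individuals
#' (each autosomal individual contributes up to `ploidy` alleles).  Loci
#' with a ratio below 0.5 are flagged for exclusion: at low coverage one
#' allele of a heterozygote is easily overlooked, and such loci would bias
#' population summaries.
#'
#' @param observed Integer vector of observed allele counts per individual
#'   (each in `0..ploidy`).
#' @param ploidy Alleles per individual (default 2).
#' @param min_ratio Retention threshold (default 0.5; a locus is retained
#'   when `ratio >= min_ratio`).
#' @return List with `ratio` and `retained`.
#' @export
allele_observation_ratio <- function(observed, ploidy = 2, min_ratio = 0.5) {
  if (any(observed < 0 | observed > ploidy)) {
    stop("observed allele counts must be in 0..ploidy")
  }
  ratio <- sum(observed) / (ploidy * length(observed))
  list(ratio = ratio, retained = ratio >= min_ratio)
}
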
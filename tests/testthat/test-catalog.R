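iv <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end,
             stringsAsFactors = FALSE)
}

test_that("catalog merge closes overlaps and small gaps only", {
  m1 <- merge_catalogs(iv("chr1", 100, 200), iv("chr1", 150, 250))
  expect_equal(m1, iv("chr1", 100, 250))
  m2 <- merge_catalogs(iv("chr1", 100, 200), iv("chr1", 205, 300))
  expect_equal(m2, iv("chr1", 100, 300))       # gap 5 <= 10 closed
  m3 <- merge_catalogs(iv("chr1", 100, 200), iv("chr1", 215, 300))
  expect_equal(nrow(m3), 2L)                   # gap 15 kept
  expect_error(merge_catalogs(iv("chr1", 200, 100)), "invalid interval")
})

test_that("catalog merge is idempotent, commutative, and reaches a fixed point", {
  set.seed(601)
  for (i in 1:8) {
    a <- iv("chr1", s <- sort(sample(0:5000, 12)), s + sample(5:60, 12,
                                                              replace = TRUE))
    b <- iv("chr1", s2 <- sort(sample(0:5000, 9)), s2 + sample(5:60, 9,
                                                               replace = TRUE))
    ab <- merge_catalogs(a, b)
    expect_equal(merge_catalogs(ab), ab)                    # idempotent
    expect_equal(merge_catalogs(b, a), ab)                  # commutative
    if (nrow(ab) > 1) {                                     # fixed point
      gaps <- ab$start[-1] - ab$end[-nrow(ab)]
      expect_true(all(gaps > 10))
    }
    expect_true(all(ab$start < ab$end))
  }
})

test_that("mask exclusion removes overlaps but keeps touching intervals", {
  cat3 <- iv("chr1", c(100, 300, 500), c(200, 400, 600))
  expect_equal(exclude_by_overlap(cat3, cat3[0, ]), cat3)   # empty mask
  left <- exclude_by_overlap(cat3, iv("chr1", 320, 330))    # inside mask
  expect_equal(left$start, c(100, 500))
  kept <- exclude_by_overlap(cat3, iv("chr1", 200, 300))    # end-to-start
  expect_equal(nrow(kept), 3L)
})

test_that("TR segments are extracted only from fully covering reads", {
  locus <- iv("chr1", 10, 22)
  locus$locus <- "L1"
  hap <- "ACGTACGTACGT"            # 12 bp TR at the locus
  read_plus <- paste0(rand_dna_fixed <- "TTTTTTTTTT", hap, "GGGGG")
  aln <- data.frame(read_id = "rp", chrom = "chr1", ref_start = 0L,
                    ref_end = 27L, strand = "+", read_start = 0L,
                    cigar = "27M", stringsAsFactors = FALSE)
  seg <- extract_tr_segments(aln, locus, c(rp = read_plus))
  expect_equal(seg$seq, hap)

  # minus strand: stored read is the reverse complement of the + projection
  read_minus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(read_plus)))
  aln_m <- transform(aln, read_id = "rm", strand = "-")
  seg_m <- extract_tr_segments(aln_m, locus, c(rm = read_minus))
  expect_equal(seg_m$seq, hap)

  # read ends inside the locus: no emission
  aln_part <- transform(aln, ref_end = 20L, cigar = "20M")
  seg_p <- extract_tr_segments(aln_part, locus,
                               c(rp = substr(read_plus, 1, 20)))
  expect_equal(nrow(seg_p), 0L)

  expect_error(extract_tr_segments(transform(aln, cigar = "*"), locus,
                                   c(rp = read_plus)), "record 1")
})

test_that("projection walks CIGAR blocks through indels", {
  # ref:  0-4 match, 5-6 deleted from read, 7-12 match; read has 2 bp insert
  # read: 5M [2D] 3M 2I 4M  -> read length 14
  read <- "AAAAACCCGGTTTT"
  aln <- data.frame(read_id = "r1", chrom = "chr1", ref_start = 0L,
                    ref_end = 14L, strand = "+", read_start = 0L,
                    cigar = "5M2D3M2I4M", stringsAsFactors = FALSE)
  # locus [7, 10): ref bases map to read offsets 5..7; the insertion at the
  # right boundary attaches to the segment on its left, so [5, 10) = "CCCGG"
  locus <- iv("chr1", 7, 10); locus$locus <- "L"
  seg <- extract_tr_segments(aln, locus, c(r1 = read))
  expect_equal(seg$seq, "CCCGG")
  # the same insertion is excluded when it sits at the locus start
  locus2 <- iv("chr1", 10, 14); locus2$locus <- "L2"
  seg2 <- extract_tr_segments(aln, locus2, c(r1 = read))
  expect_equal(seg2$seq, "TTTT")
  # a position inside the deletion projects to the deletion's read offset
  expect_equal(ctrkit:::project_through_cigar(6, 0, 0, "5M2D3M2I4M"), 5)
})

test_that("round trip: error-free reads return the exact locus substring", {
  set.seed(602)
  for (i in 1:5) {
    flank_l <- rand_dna(50); flank_r <- rand_dna(40)
    tr <- sim_tr(data.frame(unit = "ACGGT", copies = 30))
    genome <- paste0(flank_l, tr$seq, flank_r)
    locus <- iv("chr1", 50, 50 + nchar(tr$seq)); locus$locus <- "L"
    aln <- data.frame(read_id = "r", chrom = "chr1", ref_start = 0L,
                      ref_end = nchar(genome), strand = "+", read_start = 0L,
                      cigar = sprintf("%dM", nchar(genome)),
                      stringsAsFactors = FALSE)
    seg <- extract_tr_segments(aln, locus, c(r = genome))
    expect_equal(seg$seq, tr$seq)
  }
})

test_that("allele observation ratio applies the 0.5 retention rule", {
  full <- allele_observation_ratio(rep(2L, 10))
  expect_equal(full$ratio, 1)
  expect_true(full$retained)
  half <- allele_observation_ratio(rep(1L, 270))     # 270 of 540 alleles
  expect_equal(half$ratio, 0.5)
  expect_true(half$retained)
  below <- allele_observation_ratio(c(rep(1L, 269), 0L))
  expect_false(below$retained)
  expect_error(allele_observation_ratio(c(1L, 3L)), "0..ploidy")
})
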
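test_that("canonical rotation is minimal and idempotent", {
  expect_equal(canonical_unit("GAC"), "ACG")
  expect_equal(canonical_unit("AAAG"), "AAAG")
  set.seed(101)
  for (i in 1:20) {
    u <- rand_dna(sample(1:8, 1))
    can <- canonical_unit(u)
    expect_equal(canonical_unit(can), can)
    # canonical form is a rotation of the input
    expect_true(can %in% vapply(seq_len(nchar(u)), function(k) {
      paste0(substr(u, k, nchar(u)), substr(u, 1, k - 1))
    }, character(1)))
  }
})

test_that("perfect repeats decompose without edits", {
  d <- decompose_with_units("AGAGAGAGAG", "AG")
  expect_equal(unname(d$occ["AG"]), 5L)
  expect_equal(d$distance, 0)
  expect_equal(d$covered_bases, 10L)
  expect_equal(tr_mutation_rate(d), 0)
})

test_that("a four-unit compound repeat is parsed into its exact blocks", {
  s <- paste0(strrep("GT", 12), strrep("CCG", 56), strrep("AGCC", 5),
              strrep("CCG", 9))
  expect_equal(nchar(s), 239L)
  d <- decompose_with_units(s, c("GT", "CCG", "AGCC"))
  expect_equal(d$distance, 0)
  expect_equal(pattern_string(d), "(GT)12(CCG)56(AGCC)5(CCG)9")
  expect_equal(unname(d$occ[c("GT", "CCG", "AGCC")]), c(12L, 65L, 5L))
  # segments tile [0, |S|) without gaps or overlaps
  seg <- d$segments
  expect_equal(seg$start, c(0L, head(seg$end, -1)))
  expect_equal(tail(seg$end, 1), nchar(s))
})

test_that("an interior edited copy is absorbed with one edit", {
  d <- decompose_with_units("AAAGAATGAAAG", "AAAG")
  expect_equal(unname(d$occ["AAAG"]), 3L)
  expect_equal(d$distance, 1)
  expect_equal(tr_mutation_rate(d), 1 / 12)
})

test_that("degenerate inputs are rejected", {
  expect_error(decompose_with_units("", "AG"), "empty sequence")
  expect_error(decompose_with_units("ACGT", "AXG"), "invalid unit alphabet")
  expect_error(decompose_with_units("ACGT", character(0)), "empty")
})

test_that("decomposition matches the brute-force parse oracle", {
  set.seed(202)
  for (i in 1:40) {
    nu <- sample(1:2, 1)
    units <- unique(vapply(seq_len(nu), function(k) rand_dna(sample(2:4, 1)),
                           character(1)))
    units <- units[!duplicated(canonical_unit(units))]
    # strings biased toward repeat structure so unit copies matter
    S <- paste0(
      paste0(strrep(sample(units, 1), sample(0:5, 1)), rand_dna(sample(1:6, 1)),
             strrep(sample(units, 1), sample(0:5, 1))),
      collapse = ""
    )
    S <- substr(S, 1, 30)
    if (nchar(S) < 1) next
    d <- decompose_with_units(S, units)
    orc <- oracle_decompose(S, units)
    expect_equal(d$distance, orc$distance,
                 info = sprintf("S=%s units=%s", S, paste(units, collapse = ",")))
  }
})

test_that("penalty follows the unit-set formula and is additive in uncovered bases", {
  d <- decompose_with_units("AGAGAGAGAG", "AG")
  expect_equal(tr_penalty(d), 7)           # |AG| + occ 5
  d2 <- decompose_with_units(paste0("AGAGAGAGAG", "TTC"), "AG")
  expect_equal(tr_penalty(d2), 10)         # previous + 3 uncovered bases
  s <- paste0(strrep("GT", 12), strrep("CCG", 56), strrep("AGCC", 5),
              strrep("CCG", 9))
  d3 <- decompose_with_units(s, c("GT", "CCG", "AGCC"))
  expect_equal(tr_penalty(d3), (2 + 12) + (3 + 65) + (4 + 5))
  expect_error(tr_penalty(d3, units = c("GT", "CCG")),
               "inconsistent decomposition")
})

test_that("greedy selection handles expanded, compound, and repeat-free input", {
  d <- select_units(strrep("ACAGG", 586))
  expect_equal(d$units, "ACAGG")
  expect_equal(unname(d$occ["ACAGG"]), 586L)
  expect_equal(d$distance, 0)

  s <- paste0(strrep("AAAG", 6), strrep("AG", 4), strrep("AGGG", 5))
  d2 <- select_units(s)
  expect_setequal(canonical_unit(d2$units),
                  canonical_unit(c("AAAG", "AG", "AGGG")))
  expect_equal(d2$distance, 0)

  # no substring occurs twice in tandem: nothing is selected
  s3 <- "ACGTAGCTTGACCATGGTTACGCATGAACTGTCCGATAAGCCTTAGGCAT"
  d3 <- select_units(s3)
  expect_length(d3$units, 0)
  expect_equal(d3$penalty, 50)
})

test_that("greedy penalties strictly decrease and added units never raise distance", {
  set.seed(303)
  for (i in 1:10) {
    tr <- sim_tr(data.frame(unit = c("ACGG", "TG"), copies = c(20, 15)),
                 mut_rate = 0.005)
    d <- select_units(tr$seq)
    pen <- attr(d, "selection")$penalty
    expect_true(all(diff(c(nchar(tr$seq), pen)) < 0))
    if (length(d$units)) {
      d_less <- decompose_with_units(tr$seq, d$units[1])
      expect_lte(d$distance, d_less$distance)
    }
  }
})

test_that("key units rank by covered bases and set the complexity class", {
  d <- decompose_with_units("AGAGAGAGAG", "AG")
  ku <- key_units(d)
  expect_equal(ku$k, 1L)
  expect_false(ku$is_complex)

  s <- paste0(strrep("GT", 12), strrep("CCG", 56), strrep("AGCC", 5),
              strrep("CCG", 9))
  d2 <- decompose_with_units(s, c("GT", "CCG", "AGCC"))
  ku2 <- key_units(d2)
  # CCG alone covers 195/239 ~ 81.6% < 90%; adding GT reaches 219/239
  expect_equal(ku2$k, 2L)
  expect_setequal(ku2$key_units, c("CCG", "GT"))
  expect_true(ku2$is_complex)
  expect_equal(ku2$base_fraction, 219 / 239)

  # three units covering 50/30/20 percent of the bases
  u <- c("AAAAATTTTT", "CCCCCGGGGG", "ACACAGTGTG")
  s3 <- paste0(strrep(u[1], 5), strrep(u[2], 3), strrep(u[3], 2))
  d3 <- decompose_with_units(s3, u)
  expect_equal(key_units(d3, threshold = 0.8)$k, 2L)
  expect_equal(key_units(d3, threshold = 0.95)$k, 3L)

  d4 <- decompose_with_units("ACGTACGAACCGGTTACAT", "TTTT")
  d4$segments$unit <- NA_character_   # fully uncovered parse
  expect_error(key_units(d4), "no units to rank")
})

test_that("uncovered literals appear lowercase in pattern strings", {
  d <- decompose_with_units(paste0(strrep("AG", 5), "TTC"), "AG")
  expect_equal(pattern_string(d), "(AG)5ttc")
})

test_that("decomposition runtime grows about linearly with sequence length", {
  u <- "ACAGG"
  small <- strrep(u, 200)
  big <- strrep(u, 2000)
  t1 <- system.time(for (r in 1:5) decompose_with_units(small, u))[["elapsed"]]
  t2 <- system.time(for (r in 1:5) decompose_with_units(big, u))[["elapsed"]]
  # 10x the length; allow wide slack over the linear ratio for timer noise
  expect_lt(t2, max(t1, 0.02) * 60)
})
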
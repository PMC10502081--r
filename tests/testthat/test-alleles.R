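test_that("edit distance matrix is a global-alignment Levenshtein matrix", {
  expect_equal(edit_distance_matrix(c(a = "ACGT", b = "ACGT"))["a", "b"], 0)
  expect_equal(edit_distance_matrix(c(a = "ACGT", b = "ACG"))["a", "b"], 1)
  set.seed(401)
  seqs <- vapply(1:6, function(i) rand_dna(100), character(1))
  d <- edit_distance_matrix(seqs)
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 6), ignore_attr = TRUE)
  expect_error(edit_distance_matrix(character(0)), "empty")
})

test_that("rooted NJ matches ape's unrooted NJ topology", {
  skip_if_not_installed("phangorn")
  set.seed(402)
  for (i in 1:5) {
    n <- sample(5:8, 1)
    pts <- matrix(rnorm(2 * n), n)
    d <- as.matrix(dist(pts)) + 0.01
    diag(d) <- 0
    dimnames(d) <- list(letters[1:n], letters[1:n])
    mine <- ape::unroot(as_phylo_nj(nj_rooted(d)))
    ref <- ape::unroot(ape::nj(as.dist(d)))
    expect_equal(phangorn::RF.dist(mine, ref), 0)
  }
})

test_that("validity is monotone along the NJ tree", {
  set.seed(403)
  for (i in 1:5) {
    seqs <- vapply(1:8, function(k) {
      paste0(strrep("ACGT", 20), rand_dna(sample(0:10, 1)))
    }, character(1))
    names(seqs) <- paste0("s", 1:8)
    d <- edit_distance_matrix(seqs)
    tree <- nj_rooted(d)
    sets <- ctrkit:::nj_leafsets(tree)
    parents <- ctrkit:::nj_parents(tree)$merge
    lens <- nchar(seqs)
    for (nd in seq_along(sets)) {
      p <- parents[nd]
      if (p > 0) {
        # diameters never shrink toward the root
        expect_lte(ctrkit:::group_diameter(sets[[nd]], d),
                   ctrkit:::group_diameter(sets[[p]], d))
      }
    }
  }
})

test_that("centroid minimises the within-group distance sum", {
  seqs <- c(x1 = "AAAA", x2 = "AAAA", y = "TTTT")
  d <- edit_distance_matrix(seqs)
  expect_equal(centroid("x1", d, seqs), "x1")
  expect_equal(centroid(c("x1", "x2", "y"), d, seqs), "x1")
  expect_error(centroid("zz", d, seqs), "not in distance matrix")
  set.seed(404)
  for (i in 1:5) {
    seqs <- vapply(1:5, function(k) rand_dna(sample(20:40, 1)), character(1))
    names(seqs) <- paste0("s", 1:5)
    d <- edit_distance_matrix(seqs)
    got <- centroid(names(seqs), d, seqs)
    sums <- rowSums(d)
    expect_equal(sums[[got]], min(sums))
  }
})

test_that("allele calling distinguishes homozygous and heterozygous loci", {
  reads <- setNames(rep(strrep("ACGT", 50), 10), paste0("r", 1:10))
  hom <- call_alleles(reads)
  expect_equal(nrow(hom$alleles), 1L)
  expect_equal(hom$alleles$members, 10L)
  expect_length(hom$unassigned, 0)

  one <- call_alleles(c(solo = "ACGTACGT"))
  expect_equal(nrow(one$alleles), 1L)
  expect_equal(one$alleles$members, 1L)

  # 1000 bp alleles 50 edits apart: 5% >> the 1% diameter rule forces a split
  set.seed(405)
  A <- rand_dna(1000)
  B <- A
  for (p in sample(1000, 50)) substr(B, p, p) <- rand_dna(1)
  het <- call_alleles(c(a1 = A, a2 = A, a3 = A, a4 = A, a5 = A,
                        b1 = B, b2 = B, b3 = B, b4 = B, b5 = B))
  expect_equal(nrow(het$alleles), 2L)
  expect_setequal(het$alleles$seq, c(A, B))
  expect_equal(sort(het$alleles$members), c(5L, 5L))
})

test_that("allele calling never returns more than two alleles", {
  set.seed(406)
  for (i in 1:8) {
    base <- rand_dna(200)
    reads <- vapply(1:7, function(k) {
      x <- base
      for (p in sample(200, sample(0:20, 1))) substr(x, p, p) <- rand_dna(1)
      x
    }, character(1))
    names(reads) <- paste0("r", 1:7)
    res <- call_alleles(reads)
    expect_lte(nrow(res$alleles), 2L)
    # groups and unassigned reads partition the input
    expect_setequal(c(unlist(res$membership), res$unassigned), names(reads))
  }
})

test_that("diploid centroid recovery works on seeded read simulations", {
  set.seed(407)
  hits <- 0
  for (trial in 1:10) {
    pop <- sim_tr(data.frame(unit = c("ACAGG", "AAAGG"), copies = c(40, 20)))
    hapA <- pop$seq
    hapB <- paste0(strrep("ACAGG", 48), strrep("AAAGG", 20))
    rd <- sim_reads(c(hapA, hapB), coverage = 10, error_rate = 0.001)
    if (length(rd$reads) < 2) next
    res <- call_alleles(rd$reads)
    if (nrow(res$alleles) == 2 && setequal(res$alleles$seq, c(hapA, hapB))) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)
})

test_that("population representatives partition alleles into valid groups", {
  hapA <- strrep("ACGT", 100)
  hapB <- paste0(strrep("ACGT", 90), strrep("TTGA", 10))
  res <- population_representatives(
    c(a1 = hapA, a2 = hapA, a3 = hapB, a4 = hapB, a5 = hapA))
  expect_equal(nrow(res$representatives), 2L)
  expect_setequal(res$representatives$n_alleles, c(3L, 2L))

  # identical alleles collapse to a single representative
  same <- population_representatives(setNames(rep(hapA, 6), paste0("a", 1:6)))
  expect_equal(nrow(same$representatives), 1L)
  expect_equal(same$representatives$n_alleles, 6L)

  # three well-separated clusters with zero within-cluster distance
  set.seed(408)
  centers <- vapply(1:3, function(k) rand_dna(400), character(1))
  alleles <- setNames(rep(centers, times = c(4, 3, 2)), paste0("a", 1:9))
  res3 <- population_representatives(alleles)
  expect_equal(nrow(res3$representatives), 3L)
  expect_setequal(res3$representatives$n_alleles, c(4L, 3L, 2L))
  expect_setequal(res3$representatives$seq, centers)

  # postconditions on arbitrary input: partition + per-group validity
  set.seed(409)
  base <- rand_dna(300)
  alleles <- vapply(1:12, function(k) {
    x <- base
    for (p in sample(300, sample(0:12, 1))) substr(x, p, p) <- rand_dna(1)
    x
  }, character(1))
  names(alleles) <- paste0("a", 1:12)
  res4 <- population_representatives(alleles)
  expect_setequal(unlist(res4$membership), names(alleles))
  d <- edit_distance_matrix(alleles)
  for (g in res4$membership) {
    expect_lte(max(d[g, g]), 0.01 * max(nchar(alleles[g])))
  }
})

test_that("representative count recovers the planted haplotype structure", {
  set.seed(410)
  hits <- 0
  for (trial in 1:6) {
    founders <- vapply(1:5, function(k) {
      paste0(strrep("ACTGG", 30 + 8 * k), rand_dna(20))
    }, character(1))
    # 50 individuals draw two haplotypes each from the founder pool
    alleles <- sample(founders, 100, replace = TRUE)
    names(alleles) <- paste0("a", seq_along(alleles))
    res <- population_representatives(alleles)
    if (nrow(res$representatives) == length(unique(alleles))) hits <- hits + 1
  }
  expect_gte(hits, 6 * 0.95 - 1)
})
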
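# Per-residue exceptionality score over physicochemical categories

test_that("the six categories partition the 20 standard residues", {
  cats <- amino_acid_categories()
  all_res <- unlist(cats)
  expect_length(all_res, 20)
  expect_false(anyDuplicated(all_res) > 0)
  expect_equal(residue_category("C"), "aliphatic")
  expect_equal(residue_category("H"), "aromatic")
  expect_true(is.na(residue_category("X")))
  expect_true(is.na(residue_category("-")))
  expect_error(residue_category("AB"), "single")
})

test_that("category entropy matches analytic values", {
  expect_equal(category_entropy(c(0.5, 0.5)), log(2))
  expect_equal(category_entropy(rep(1 / 3, 3)), log(3))
  expect_equal(category_entropy(1), 0)
  expect_equal(category_entropy(c(0.5, 0.5), base = 2), 1)
})

test_that("column profiles count homologs only and apply the gap rule", {
  aln <- one_column_alignment(c("K", "R", "D", "E"), "A")
  prof <- column_profile(aln, "query", 1)
  expect_equal(unname(prof$proportions[c("positive", "negative")]),
               c(0.5, 0.5))
  expect_equal(prof$entropy, log(2))
  expect_false(prof$masked)

  # 4 gaps of 6 homolog rows: gap fraction 0.667 > 0.5 -> masked, entropy 0
  masked <- one_column_alignment(c("A", "V", "-", "-", "-", "-"), "A")
  prof2 <- column_profile(masked, "query", 1)
  expect_true(prof2$masked)
  expect_equal(prof2$entropy, 0)
  expect_equal(column_entropy(prof2), 0)

  # single category: p_max 1, entropy 0
  uni <- one_column_alignment(c("A", "V", "L"), "F")
  prof3 <- column_profile(uni, "query", 1)
  expect_equal(prof3$p_max, 1)
  expect_equal(prof3$entropy, 0)
})

test_that("worked 23-homolog example reproduces the closed-form score", {
  # 20 aliphatic + 3 aromatic homologs, aromatic query:
  # P_max = 20/23, P_i = 3/23, s = -(20/23 log 20/23 + 3/23 log 3/23)
  aln <- one_column_alignment(c(rep("A", 20), rep("F", 3)), "W")
  sc <- exceptionality_score(aln, "query", 1)
  p1 <- 20 / 23; p2 <- 3 / 23
  s <- -(p1 * log(p1) + p2 * log(p2))
  expect_equal(sc$value, (p1 - p2) / s, tolerance = 1e-12)
  expect_equal(sc$value, 1.9089, tolerance = 1e-4)
  expect_equal(sc$status, "finite")
})

test_that("score statuses cover modal, deviant-conserved and masked cases", {
  modal <- one_column_alignment(c("A", "V", "L", "F"), "I")
  expect_equal(exceptionality_score(modal, "query", 1),
               list(value = 0, status = "zero"))

  conserved <- one_column_alignment(rep("A", 23), "W")
  sc <- exceptionality_score(conserved, "query", 1)
  expect_equal(sc$status, "infinite")
  expect_true(is.infinite(sc$value))

  gappy <- one_column_alignment(c("A", "-", "-", "-"), "W")
  sc2 <- exceptionality_score(gappy, "query", 1)
  expect_equal(sc2$status, "masked")
  expect_true(is.na(sc2$value))
})

test_that("random small columns agree with the exhaustive-counting oracle", {
  set.seed(101)
  pool <- c(unlist(oracle_categories), "X", "-", "-")
  for (i in 1:300) {
    n <- sample(2:8, 1)
    hom <- sample(pool, n, replace = TRUE)
    qres <- sample(unlist(oracle_categories), 1)
    aln <- one_column_alignment(hom, qres)
    want <- oracle_column(hom, qres)
    prof <- suppressWarnings(column_profile(aln, "query", 1))
    sc <- suppressWarnings(exceptionality_score(aln, "query", 1))
    expect_equal(unname(prof$proportions), unname(want$proportions),
                 tolerance = 1e-12)
    expect_equal(prof$entropy, want$entropy, tolerance = 1e-12)
    expect_equal(prof$masked, want$status == "masked")
    expect_equal(sc$status, want$status)
    if (want$status == "finite")
      expect_equal(sc$value, want$score, tolerance = 1e-12)
  }
})

test_that("scores are invariant under same-category residue replacement", {
  set.seed(11)
  cats <- oracle_categories
  hom <- sample(unlist(cats), 23, replace = TRUE)
  aln <- one_column_alignment(hom, "W")
  base_sc <- exceptionality_score(aln, "query", 1)
  for (i in 1:10) {
    hom2 <- vapply(hom, function(ch) {
      set <- cats[[oracle_cat_lookup(ch)]]
      sample(set, 1)
    }, character(1))
    sc2 <- exceptionality_score(one_column_alignment(hom2, "W"), "query", 1)
    expect_identical(sc2, base_sc)
  }
})

test_that("profiles span the ungapped query with 1-based positions", {
  aln <- alignment(c("query", "h1", "h2"),
                   c("AW-KD", "AFAKE", "VYVRE"))
  prof <- exceptionality_profile(aln, "query")
  expect_equal(nrow(prof), 4)            # query gap column dropped
  expect_equal(prof$position, 1:4)
  expect_equal(prof$column, c(1L, 2L, 4L, 5L))
  expect_equal(prof$residue, c("A", "W", "K", "D"))

  nogap <- alignment(c("query", "h"), c("AVLIM", "AVLIM"))
  expect_equal(nrow(exceptionality_profile(nogap, "query")), 5)
})

test_that("changing the log base rescales scores but never the ranking", {
  g <- gen_alignment(make_planted_recipe(3, length = 25, n_planted = 3))
  nats <- exceptionality_profile(g$alignment, "query")
  bits <- exceptionality_profile(g$alignment, "query", base = 2)
  fin <- nats$status == "finite"
  expect_true(any(fin))
  expect_equal(bits$score[fin] / nats$score[fin],
               rep(log(2), sum(fin)), tolerance = 1e-12)
  expect_identical(rank_exceptional(nats, nrow(nats))$position,
                   rank_exceptional(bits, nrow(bits))$position)
})

test_that("ranking puts infinite scores first and breaks ties by position", {
  # all-zero profile: tie-break returns the first k positions in order
  flat <- alignment(c("query", "h1", "h2"), c("AAA", "VVV", "LLL"))
  prof <- exceptionality_profile(flat, "query")
  expect_equal(rank_exceptional(prof, 2)$position, 1:2)

  # a fully conserved deviant column (infinite) ranks above finite scores
  hom <- c(rep("AA", 20), rep("AF", 3))
  mixed <- alignment(c("query", sprintf("h%d", 1:23)), c("WW", hom))
  prof2 <- exceptionality_profile(mixed, "query")
  expect_equal(prof2$status, c("infinite", "finite"))
  top <- rank_exceptional(prof2, 2)
  expect_equal(top$position, 1:2)
  expect_equal(top$status[1], "infinite")

  expect_message(rank_exceptional(prof2, 10), "only 2 positions")
})

test_that("planted deviants are recovered in planted order", {
  for (seed in 1:5) {
    g <- gen_alignment(make_planted_recipe(seed, length = 30,
                                           n_planted = 2))
    prof <- exceptionality_profile(g$alignment, "query")
    planted <- g$truth$position[g$truth$planted]
    top <- rank_exceptional(prof, length(planted))
    expect_setequal(top$position, planted)
    # module scores agree with the generator's independent closed form
    expect_equal(prof$score[planted], g$truth$score[planted],
                 tolerance = 1e-12)
  }
})
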
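test_that("frozen local-alignment examples are reproduced", {
  s <- scoring_scheme()

  aln <- smith_waterman("ACDE", "ACDE", s)
  expect_equal(aln$score, 24)  # BLOSUM62 diagonal A+C+D+E = 4+9+6+5
  expect_equal(aln$identities, 4)
  expect_equal(aln$columns, 4)
  expect_equal(percent_identity(aln), 100)

  empty <- smith_waterman("AAAA", "GGGG", s)
  expect_equal(empty$score, 0)
  expect_equal(empty$columns, 0)
  expect_error(percent_identity(empty), "undefined")

  self <- smith_waterman("MKWVTFISLLFLFSSAYS", "MKWVTFISLLFLFSSAYS", s)
  expect_equal(self$identities, self$columns)
  expect_equal(self$columns, 18)
})

test_that("frozen global-alignment examples are reproduced", {
  s <- scoring_scheme()
  aln <- needleman_wunsch("ACD", "AD", s)
  expect_equal(aln$aligned_a, "ACD")
  expect_equal(aln$aligned_b, "A-D")
  expect_equal(aln$identities, 2)
  expect_equal(aln$score, 4 + 6 - 12)  # A:A + D:D - (open 11 + ext 1)

  x <- "WQNMHEY"
  self <- needleman_wunsch(x, x, s)
  expect_false(grepl("-", self$aligned_a, fixed = TRUE))
  expect_equal(percent_identity(self), 100)

  gap75 <- needleman_wunsch("ACD", "ACED", s)
  expect_equal(gap75$aligned_a, "AC-D")
  expect_equal(percent_identity(gap75), 75)
})

test_that("invalid sequences are rejected and X is scored neutrally", {
  expect_error(smith_waterman("", "ACD"), "empty")
  expect_error(needleman_wunsch("A", ""), "empty")
  expect_error(smith_waterman("ACB", "ACD"), "B")
  expect_error(smith_waterman("ACU", "ACD"), "U")
  expect_error(smith_waterman("ACZ", "ACD"), "Z")

  # X contributes 0 to any column
  m <- blosum62_x0()
  expect_true(all(m["X", ] == 0))
  withX <- needleman_wunsch("AXD", "AWD")
  noX <- needleman_wunsch("AD", "AD")
  expect_equal(withX$score, noX$score + 0)
})

test_that("alignment scores match the independent DP oracle on random pairs", {
  s <- scoring_scheme()
  mat <- s$matrix
  set.seed(42)
  for (i in 1:40) {
    a <- random_peptide(sample(1:8, 1))
    b <- random_peptide(sample(1:8, 1))
    expect_equal(smith_waterman(a, b, s)$score,
                 oracle_align_score(a, b, mat, mode = "local"),
                 info = paste(a, b, "local"))
    expect_equal(needleman_wunsch(a, b, s)$score,
                 oracle_align_score(a, b, mat, mode = "global"),
                 info = paste(a, b, "global"))
    # local score is symmetric in its arguments
    expect_equal(smith_waterman(a, b, s)$score, smith_waterman(b, a, s)$score)
  }
})

test_that("the DP oracle agrees with exhaustive alignment enumeration", {
  mat <- scoring_scheme()$matrix
  set.seed(7)
  for (i in 1:8) {
    a <- random_peptide(sample(1:4, 1))
    b <- random_peptide(sample(1:4, 1))
    expect_equal(oracle_align_score(a, b, mat, mode = "global"),
                 oracle_enumerate_global(a, b, mat),
                 info = paste(a, b))
  }
})

test_that("E-values follow the Karlin-Altschul relation", {
  s <- scoring_scheme()
  expect_equal(evalue(0, 100, 100, s), 0.041 * 1e4)
  expect_equal(evalue(40, 100, 100, s), 0.041 * 1e4 * exp(-0.267 * 40))
  expect_lt(abs(evalue(40, 100, 100, s) - 9.4e-3), 2e-4)

  # ratio identity and monotonicity / linearity
  expect_equal(evalue(50, 80, 900, s) / evalue(40, 80, 900, s),
               exp(-10 * s$lambda))
  sc <- 0:60
  expect_true(all(diff(evalue(sc, 100, 1000, s)) < 0))
  expect_equal(evalue(10, 200, 500, s), 2 * evalue(10, 100, 500, s))
  expect_equal(evalue(10, 200, 1500, s), 3 * evalue(10, 200, 500, s))
  expect_error(evalue(-1, 10, 10, s), ">= 0")
})

test_that("scoring scheme validates its invariants", {
  expect_error(scoring_scheme(gap_open = 1, gap_extend = 2), "gap_open")
  expect_error(scoring_scheme(gap_extend = 0), "gap_open")
  expect_error(scoring_scheme(lambda = -1), "lambda")
  expect_error(scoring_scheme(k = 0), "k")
  m <- blosum62_x0()
  expect_true(isTRUE(all.equal(m, t(m))))
})

test_that("align_hits reports BLAST-tabular-style best hits", {
  subjects <- c(s1 = "MKWVTFISLLFLFSSAYS", s2 = "GGGGGGGGGG")
  queries <- c(q1 = "MKWVTFISLLFLFSSAYS")
  hits <- align_hits(subjects, queries)
  expect_s3_class(hits, "tbl_df")
  expect_equal(nrow(hits), 2)
  h1 <- hits[hits$subject_id == "s1", ]
  expect_equal(h1$identity_pct, 100)
  expect_lt(h1$evalue, 1e-5)
  expect_equal(unname(unlist(h1[, c("q_start", "q_end")])), c(1L, 18L))
})
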
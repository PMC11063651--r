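test_that("single-residue alignment returns the single match column", {
  p <- protein_sequence("p", "A")
  q <- protein_sequence("q", "A")
  s <- matrix(7, 1, 1, dimnames = list("A", "A"))
  res <- align_pair(p, q, matrix_model(s, p, q), "global")
  expect_equal(res$alignment$p_row, "A")
  expect_equal(res$alignment$q_row, "A")
  expect_equal(res$score, 7)
})

test_that("semiglobal alignment embeds a short sequence gap-free", {
  p <- protein_sequence("p", "AAA")
  q <- protein_sequence("q", "GGAAAGG")
  model <- identity_model(p, q, match = 1, mismatch = -1,
                          gap_open = -2, gap_extend = -0.5)
  res <- align_pair(p, q, model, "semiglobal")
  expect_equal(res$score, 3)
  expect_equal(res$alignment$p_row, "--AAA--")
  expect_equal(res$alignment$q_row, "GGAAAGG")
  # the brute-force oracle agrees
  expect_equal(brute_force_align(p, q, model, "semiglobal")$score, 3)
})

test_that("DP equals the enumeration oracle on random instances, both modes", {
  set.seed(31)
  alphabet <- c("A", "R", "N", "D", "C")
  n_checked <- 0L
  for (k in 1:60) {
    p <- random_protein(sample(1:6, 1), alphabet, "p")
    q <- random_protein(sample(1:6, 1), alphabet, "q")
    if (length(p) + length(q) > 11) next
    model <- if (k %% 2 == 0) {
      matrix_model(random_score_matrix(alphabet), p, q,
                   gap_open = -round(runif(1, 1, 8)),
                   gap_extend = -round(runif(1, 0, 2), 1))
    } else {
      prov <- synthetic_embedder(8, sample(0:2, 1), seed = k)
      escore_model(prov$embed(p), prov$embed(q), p, q)
    }
    for (mode in c("global", "semiglobal")) {
      res <- align_pair(p, q, model, mode)
      oracle <- brute_force_align(p, q, model, mode)
      expect_equal(res$score, oracle$score,
                   info = paste(mode, p$residues, q$residues))
      # round trip: re-scoring the returned alignment reproduces the score
      expect_equal(score_alignment(res$alignment, model, mode), res$score,
                   info = paste(mode, p$residues, q$residues))
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 80L)
})

test_that("affine gap accounting follows open + k * extend", {
  p <- protein_sequence("p", "AAAA")
  q <- protein_sequence("q", "AA")
  model <- identity_model(p, q, gap_open = -3, gap_extend = -0.5)
  # internal gap of length 2 contributes open + 2 * extend
  a <- pairwise_alignment("AAAA", "A--A")
  expect_equal(score_alignment(a, model, "global"), 2 - 3 - 2 * 0.5)
  # both runs terminal: no gap cost in semiglobal
  p2 <- protein_sequence("p", "AA")
  q2 <- protein_sequence("q", "AA")
  m2 <- identity_model(p2, q2, gap_open = -3, gap_extend = -0.5)
  b <- pairwise_alignment("AA--", "--AA")
  expect_equal(score_alignment(b, m2, "semiglobal"), 0)
  expect_equal(score_alignment(b, m2, "global"), -2 * (3 + 2 * 0.5))
})

test_that("score symmetry under swapping P and Q with the transposed model", {
  set.seed(41)
  for (k in 1:10) {
    p <- random_protein(sample(2:8, 1), id = "p")
    q <- random_protein(sample(2:8, 1), id = "q")
    s <- random_score_matrix()
    for (mode in c("global", "semiglobal")) {
      f <- align_pair(p, q, matrix_model(s, p, q, -5, -1), mode)
      r <- align_pair(q, p, matrix_model(s, q, p, -5, -1), mode)
      expect_equal(f$score, r$score)
    }
  }
})

test_that("relaxing end-gap costs never lowers the optimum", {
  set.seed(51)
  for (k in 1:15) {
    p <- random_protein(sample(2:10, 1), id = "p")
    q <- random_protein(sample(2:10, 1), id = "q")
    model <- matrix_model(random_score_matrix(), p, q, -6, -1)
    expect_lte(align_pair(p, q, model, "global")$score,
               align_pair(p, q, model, "semiglobal")$score)
  }
})

test_that("the enumeration covers the worked-example alignments", {
  p <- protein_sequence("p", "RKD")
  q <- protein_sequence("q", "DNN")
  paths <- escore:::enumerate_ops(3L, 3L)
  rows <- vapply(paths, function(ops) {
    a <- escore:::ops_to_alignment(ops, p, q)
    paste(a$p_row, a$q_row)
  }, character(1L))
  expect_true("-RKD DN-N" %in% rows)
  expect_true("RKD- D-NN" %in% rows)
  # no duplicates: each monotone gap placement appears once
  expect_false(anyDuplicated(rows) > 0)
})

test_that("brute force enforces its size bound; mode only changes end costs", {
  p <- random_protein(7, id = "p")
  q <- random_protein(7, id = "q")
  model <- matrix_model(random_score_matrix(), p, q)
  expect_error(brute_force_align(p, q, model), "<= 12")

  # fixed-matrix scorer from a context-free embedder equals the escore path
  set.seed(61)
  prov <- synthetic_embedder(8, 0, seed = 17)
  cf <- context_free_matrix(prov)
  for (k in 1:5) {
    pp <- random_protein(4, id = "p"); qq <- random_protein(5, id = "q")
    em <- escore_model(prov$embed(pp), prov$embed(qq), pp, qq)
    mm <- matrix_model(cf, pp, qq, -0.25, -0.01)
    for (mode in c("global", "semiglobal"))
      expect_equal(align_pair(pp, qq, em, mode)$score,
                   align_pair(pp, qq, mm, mode)$score)
  }
})

test_that("aligner validates model and sequence agreement", {
  p <- protein_sequence("p", "ARN")
  q <- protein_sequence("q", "AR")
  model <- identity_model(p, q)
  expect_error(align_pair(q, p, model), "lengths")
  wrong <- pairwise_alignment("AR-", "ARN")
  expect_error(score_alignment(wrong, model, "global"), "match")
})
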
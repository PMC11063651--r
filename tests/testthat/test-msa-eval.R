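toy_msa <- function() {
  # deletions are separated by match columns, so each induced reference
  # alignment is the unique optimum of the reference-rewarding oracle below
  msa(c("a", "b", "c", "d", "e"),
      c("ARND-CQEG", "ARNDKCQEG", "AR-DKCQEG", "ARNDKCQ-G", "TRNDKCQEG"))
}

test_that("sample_pairs returns all pairs when few, samples when many", {
  m <- toy_msa()
  pairs <- sample_pairs(m, max_pairs = 1000, seed = 1)
  expect_equal(nrow(pairs), choose(5, 2))
  expect_equal(pairs, t(combn(5, 2)))

  big <- msa(sprintf("s%02d", 1:20),
             rep(c("ARNDCQEG", "ARND-QEG"), 10))
  s1 <- sample_pairs(big, max_pairs = 50, seed = 9)
  s2 <- sample_pairs(big, max_pairs = 50, seed = 9)
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 50L)
  expect_false(anyDuplicated(paste(s1[, 1], s1[, 2])) > 0)
  s3 <- sample_pairs(big, max_pairs = 50, seed = 10)
  expect_false(identical(s1, s3))
})

test_that("a scorer reproducing the induced alignment gets zero distances", {
  m <- toy_msa()
  # an oracle scorer: huge reward exactly on the reference pairing
  oracle_factory <- function(ref_msa) {
    function(p, q) {
      i <- match(p$id, ref_msa$ids); j <- match(q$id, ref_msa$ids)
      ref <- induced_pairwise(ref_msa, i, j)
      s <- matrix(-100, length(p), length(q))
      pc <- cumsum(escore:::seq_chars(ref$p_row) != "-")
      qc <- cumsum(escore:::seq_chars(ref$q_row) != "-")
      cols <- which(escore:::seq_chars(ref$p_row) != "-" &
                      escore:::seq_chars(ref$q_row) != "-")
      s[cbind(pc[cols], qc[cols])] <- 10
      escore:::new_scoring_model(s, -15, -1, "ref-oracle", p, q)
    }
  }
  res <- evaluate_msa(m, list(oracle = oracle_factory(m)),
                      evaluation_config(seed = 1))
  expect_true(all(res$per_pair[, c("cc", "d", "pos", "seq", "ssp")] == 0))
})

test_that("identical scorers tie on every pair with degenerate p-values", {
  m <- toy_msa()
  b62 <- read_substitution_matrix(blosum_file("BLOSUM62"))
  f <- function(p, q) blosum_model(b62, p, q)
  res <- evaluate_msa(m, list(one = f, two = f),
                      evaluation_config(seed = 2, metrics = c("cc", "d")))
  expect_true(all(is.na(res$wilcoxon$p_value)))
  expect_true(all(res$tallies$equal == choose(5, 2)))
  expect_true(all(res$tallies$better == 0))
  # paired design: every pair appears for every scorer
  expect_equal(unname(table(res$per_pair$scorer)),
               rep(choose(5, 2), 2), ignore_attr = TRUE)
})

test_that("evaluation results are deterministic given the seed", {
  m <- simulate_benchmark_msa(n_rows = 5, seed = 3)
  scorers <- benchmark_scorers(dimension = 16)
  cfg <- evaluation_config(max_pairs = 6, seed = 5, metrics = c("cc", "d"))
  r1 <- evaluate_msa(m, scorers, cfg)
  r2 <- evaluate_msa(m, scorers, cfg)
  expect_identical(r1$per_pair, r2$per_pair)
  expect_identical(r1$means, r2$means)
})

test_that("wilcox p-values agree with an exact-enumeration oracle", {
  set.seed(81)
  for (k in 1:8) {
    n <- sample(6:12, 1)
    x <- rnorm(n)
    y <- x + rnorm(n, mean = 0.4)
    p_r <- wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
    expect_equal(p_r, wilcoxon_exact_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("average score matrices: context-free provider gives equal views", {
  m <- simulate_benchmark_msa(n_rows = 6, length = 40, sub_rate = 0.2,
                              seed = 11)
  prov0 <- synthetic_embedder(12, 0, seed = 4)
  res <- average_score_matrices(m, prov0, n_samples = 4000, seed = 6)
  # context-free: a pair (a, b) scores identically wherever sampled, so
  # shared cells of the two matrices agree exactly and diagonals are 1
  shared <- !is.na(res$aligned) & !is.na(res$unaligned)
  expect_gt(sum(shared), 10)
  expect_equal(res$aligned[shared], res$unaligned[shared])
  diag_known <- !is.na(diag(res$aligned))
  expect_equal(unname(diag(res$aligned)[diag_known]),
               rep(1, sum(diag_known)))
  # symmetry by pooled sampling
  expect_equal(res$aligned, t(res$aligned))
  expect_equal(attr(res$unaligned, "n_samples"), 4000L)
})

test_that("aligned scores exceed unaligned under a context-aware provider", {
  m <- simulate_benchmark_msa(n_rows = 8, length = 60, sub_rate = 0.3,
                              seed = 21)
  prov <- synthetic_embedder(24, 2, seed = 4)
  res <- average_score_matrices(m, prov, n_samples = 6000, seed = 7)
  expect_gt(mean(res$aligned, na.rm = TRUE),
            mean(res$unaligned, na.rm = TRUE))
})

test_that("matrix correlation is Pearson over the upper triangle", {
  set.seed(91)
  m <- matrix(rnorm(400), 20, 20)
  m <- (m + t(m)) / 2
  expect_equal(matrix_correlation(m, m), 1)
  expect_equal(matrix_correlation(m, -m), -1)

  # direct-formula oracle on a 3x3 toy block
  a <- matrix(c(1, 2, 3, 2, 4, 5, 3, 5, 6), 3, 3)
  b <- matrix(c(2, 1, 4, 1, 3, 3, 4, 3, 8), 3, 3)
  va <- a[upper.tri(a, diag = TRUE)]; vb <- b[upper.tri(b, diag = TRUE)]
  oracle <- sum((va - mean(va)) * (vb - mean(vb))) /
    sqrt(sum((va - mean(va))^2) * sum((vb - mean(vb))^2))
  expect_equal(matrix_correlation(a, b), oracle)

  m2 <- m; m2[2, 19] <- NA
  expect_error(matrix_correlation(m, m2), "missing cells")
  expect_error(matrix_correlation(m, m[1:10, 1:10]), "shapes")
})

test_that("BLOSUM rescaling maps into the cosine range by max-abs", {
  b45 <- read_substitution_matrix(blosum_file("BLOSUM45"))
  s <- scale_substitution_matrix(b45)
  expect_equal(dim(s), c(20L, 20L))
  expect_equal(max(abs(s)), 1)
  expect_equal(s, t(s))
  # correlation with itself unchanged by scaling
  raw <- b45$scores[rownames(s), colnames(s)]
  expect_equal(matrix_correlation(s, raw), 1)
})
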
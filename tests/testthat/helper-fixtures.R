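# Shared fixtures and independent oracles, all built in code.

# The worked example pair: P = RKD, Q = DNN with two alignments.
example_alignments <- function() {
  list(a1 = pairwise_alignment("-RKD", "DN-N"),
       a2 = pairwise_alignment("RKD-", "D-NN"))
}

blosum_file <- function(name) {
  system.file("extdata", paste0(name, ".txt"), package = "escore")
}

random_protein <- function(len, alphabet = c("A", "R", "N", "D", "C"),
                           id = "s") {
  protein_sequence(id, paste(sample(alphabet, len, replace = TRUE),
                             collapse = ""))
}

# Random symmetric integer-ish score matrix over a small alphabet.
random_score_matrix <- function(alphabet = c("A", "R", "N", "D", "C")) {
  k <- length(alphabet)
  s <- matrix(round(runif(k * k, -4, 6)), k, k,
              dimnames = list(alphabet, alphabet))
  (s + t(s)) / 2
}

# Random alignment of p and q: a uniformly grown monotone op path.
random_alignment <- function(p, q) {
  i <- length(p); j <- length(q)
  ops <- integer(0)
  while (i > 0 || j > 0) {
    moves <- c(if (i > 0 && j > 0) 0L, if (i > 0) 1L, if (j > 0) 2L)
    mv <- if (length(moves) == 1L) moves else sample(moves, 1L)
    ops <- c(mv, ops)
    if (mv != 2L) i <- i - 1L
    if (mv != 1L) j <- j - 1L
  }
  escore:::ops_to_alignment(ops, p, q)
}

# Exhaustive-enumeration oracle for the two-sided paired Wilcoxon
# signed-rank p-value (no zeros, no tied magnitudes; n <= 12).
wilcoxon_exact_oracle <- function(x, y) {
  d <- x - y
  stopifnot(all(d != 0), !anyDuplicated(abs(d)), length(d) <= 12L)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  p_low <- mean(v_all <= v_obs)
  p_high <- mean(v_all >= v_obs)
  min(1, 2 * min(p_low, p_high))
}
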
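#' Simulate a conserved-motif reference MSA
#'
#' Generates a synthetic protein family for benchmarking scoring schemes
#' where the true alignment is known exactly by construction.  An ancestral
#' sequence is drawn uniformly over the 20 standard amino acids; a central
#' motif block is perfectly conserved; every other position mutates
#' independently in each descendant row (substitution to a different
#' residue), and each row may lose one contiguous block outside the motif
#' (a deletion).  Because the rows are deletions-of-the-ancestor, ancestor
#' positions serve as MSA columns and the reference alignment is exact --
#' no alignment heuristic touches the truth.
#'
#' The substitutions are context-dependent noise in the sense that they
#' change residue identities while leaving each residue's neighbourhood
#' largely ancestral, which is precisely the signal a context-sensitive
#' embedder can exploit and a fixed identity/mismatch matrix cannot.
#'
#' What this emulates -- and what it does not: it reproduces the divergence
#' structure (many substitutions, few indels, a conserved core) of a
#' curated reference family, but not insertion events, rate heterogeneity
#' beyond the motif, or biochemically structured substitution preferences.
#'
#' @param n_rows Number of sequences (>= 2).
#' @param length Ancestor length (MSA alignment length).
#' @param motif_length Length of the central conserved block.
#' @param sub_rate Per-position substitution probability outside the motif.
#' @param del_prob Probability that a row carries a deletion block.
#' @param del_max Maximum deletion block length.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return An [msa()] whose induced pairwise alignments are the ground
#'   truth.
#' @examples
#' simulate_benchmark_msa(n_rows = 4, length = 30, seed = 1)
#' @export
simulate_benchmark_msa <- function(n_rows = 8L, length = 80L,
                                   motif_length = 12L, sub_rate = 0.4,
                                   del_prob = 0.9, del_max = 6L, seed = 1L) {
  stopifnot(n_rows >= 2L, length >= motif_length + 2L * del_max + 2L,
            sub_rate >= 0, sub_rate < 1, del_prob >= 0, del_prob <= 1)
  with_local_seed(seed, {
    ancestor <- sample(AA_STANDARD, length, replace = TRUE)
    motif_start <- (length - motif_length) %/% 2L + 1L
    motif <- motif_start:(motif_start + motif_length - 1L)
    rows <- character(n_rows)
    for (r in seq_len(n_rows)) {
      chars <- ancestor
      mutable <- setdiff(seq_len(length), motif)
      hit <- mutable[runif(base::length(mutable)) < sub_rate]
      for (pos in hit)
        chars[pos] <- sample(setdiff(AA_STANDARD, chars[pos]), 1L)
      if (runif(1L) < del_prob) {
        del_len <- sample.int(del_max, 1L)
        # candidate starts whose block stays off the motif and in range
        starts <- setdiff(seq_len(length - del_len + 1L),
                          (motif_start - del_len + 1L):max(motif))
        starts <- starts[starts >= 1L]
        if (base::length(starts) > 0L) {
          del_start <- sample(starts, 1L)
          chars[del_start:(del_start + del_len - 1L)] <- GAP
        }
      }
      rows[r] <- paste(chars, collapse = "")
    }
    msa(sprintf("seq%02d", seq_len(n_rows)), rows)
  })
}

#' Scorer factories for the synthetic benchmark
#'
#' The two scoring schemes the benchmark compares, packaged as factories
#' for [evaluate_msa()]: a context-aware E-score scorer built on a
#' [synthetic_embedder()] (cosine-scale gap penalties -0.25 / -0.01) and a
#' context-free identity/mismatch matrix scorer (+1 match, -1 mismatch,
#' unit-scale gaps -2 / -0.5).
#'
#' @param dimension,context_window,decay Synthetic embedder settings.
#' @param embedder_seed Seed of the embedder's base-vector draw.
#' @return Named list of two factories, `escore` and `identity`.
#' @export
benchmark_scorers <- function(dimension = 48L, context_window = 2L,
                              decay = 0.5, embedder_seed = 1L) {
  provider <- synthetic_embedder(dimension, context_window,
                                 seed = embedder_seed, decay = decay)
  list(
    escore = function(p, q)
      escore_model(provider$embed(p), provider$embed(q), p, q),
    identity = function(p, q) identity_model(p, q)
  )
}
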
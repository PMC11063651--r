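#' Cosine similarity of two vectors
#'
#' The cosine of the angle between two vectors:
#' `sum(a * b) / (||a|| * ||b||)`, in `[-1, 1]` -- 1 for vectors pointing
#' the same way, 0 for orthogonal vectors, -1 for opposite vectors.  The
#' result is clamped to `[-1, 1]` against floating-point overshoot so
#' downstream range invariants hold exactly.
#'
#' @param a,b Numeric vectors of equal length; neither may be all-zero
#'   (the angle is undefined for the zero vector).
#' @return A number in `[-1, 1]`.
#' @examples
#' cosine_similarity(c(1, 0), c(0, 1))
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) != length(b))
    stop("vectors have different lengths: ", length(a), " vs ", length(b),
         call. = FALSE)
  if (length(a) < 1L)
    stop("vectors must have length >= 1", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("cosine similarity is undefined for the zero vector", call. = FALSE)
  min(1, max(-1, sum(a * b) / (na * nb)))
}

#' E-score between two embedded residues
#'
#' The E-score of positions `i` of P and `j` of Q is the cosine similarity
#' of row `i` of P's embedding matrix and row `j` of Q's.  With a
#' contextual embedder the score depends on the residues' surrounding
#' sequence, not just their amino-acid identities.
#'
#' @param p_emb,q_emb Embedding matrices (one row per residue) of equal
#'   column dimension.
#' @param i,j 1-based residue positions into `p_emb` and `q_emb`.
#' @return A number in `[-1, 1]`.
#' @export
escore <- function(p_emb, q_emb, i, j) {
  stopifnot(is.matrix(p_emb), is.matrix(q_emb))
  if (ncol(p_emb) != ncol(q_emb))
    stop("embedding dimensions differ: ", ncol(p_emb), " vs ", ncol(q_emb),
         call. = FALSE)
  stopifnot(i >= 1L, i <= nrow(p_emb), j >= 1L, j <= nrow(q_emb))
  cosine_similarity(p_emb[i, ], q_emb[j, ])
}

#' All-against-all E-score matrix
#'
#' Entry `(i, j)` is `escore(p_emb, q_emb, i, j)`; computed by
#' row-normalizing both embedding matrices and taking their cross product.
#'
#' @inheritParams escore
#' @return An `nrow(p_emb) x nrow(q_emb)` matrix with entries in `[-1, 1]`.
#' @export
escore_matrix <- function(p_emb, q_emb) {
  stopifnot(is.matrix(p_emb), is.matrix(q_emb))
  if (ncol(p_emb) != ncol(q_emb))
    stop("embedding dimensions differ: ", ncol(p_emb), " vs ", ncol(q_emb),
         call. = FALSE)
  np <- sqrt(rowSums(p_emb^2)); nq <- sqrt(rowSums(q_emb^2))
  if (any(np == 0) || any(nq == 0))
    stop("cosine similarity is undefined for the zero vector", call. = FALSE)
  s <- tcrossprod(p_emb / np, q_emb / nq)
  s[s > 1] <- 1; s[s < -1] <- -1
  s
}

# Internal scoring-model constructor.  A model carries the full positional
# score matrix S (score of aligning P[i] with Q[j]), affine gap parameters
# (a gap run of length k costs gap_open + k * gap_extend), and a label for
# provenance.
new_scoring_model <- function(scores, gap_open, gap_extend, label, p, q) {
  stopifnot(is.matrix(scores), is.numeric(gap_open), is.numeric(gap_extend))
  structure(list(scores = scores, gap_open = gap_open,
                 gap_extend = gap_extend, label = label,
                 p = p, q = q),
            class = "scoring_model")
}

#' @export
print.scoring_model <- function(x, ...) {
  cat("<scoring_model> ", x$label, "\n", sep = "")
  cat("  ", nrow(x$scores), " x ", ncol(x$scores),
      " positions; gap open ", x$gap_open, ", extend ", x$gap_extend,
      "\n", sep = "")
  invisible(x)
}

#' Positional score lookup
#'
#' @param model A scoring model from [blosum_model()], [escore_model()] or
#'   [matrix_model()].
#' @param i,j 1-based positions in the model's P and Q.
#' @return The substitution score for aligning `P[i]` with `Q[j]`.
#' @export
score_at <- function(model, i, j) {
  stopifnot(inherits(model, "scoring_model"))
  model$scores[i, j]
}

#' Substitution-matrix scoring model
#'
#' Builds a positional scoring model for P and Q from a fixed substitution
#' matrix: `score_at(i, j)` depends only on the amino acids `P[i]` and
#' `Q[j]`.  Default gap penalties are the NCBI BLAST defaults for protein
#' matrices: open -11, extend -1.  Ambiguity codes are scored with the
#' matrix's own rows when present, otherwise they are an error (no invented
#' substitution values).
#'
#' @param matrix A [read_substitution_matrix()] result.
#' @param p,q [protein_sequence()] objects.
#' @param gap_open,gap_extend Affine gap penalties (negative); a gap run of
#'   length k costs `gap_open + k * gap_extend`.
#' @return A `scoring_model`.
#' @export
blosum_model <- function(matrix, p, q, gap_open = -11, gap_extend = -1) {
  stopifnot(inherits(matrix, "substitution_matrix"),
            inherits(p, "protein_sequence"), inherits(q, "protein_sequence"))
  pc <- seq_chars(p); qc <- seq_chars(q)
  miss <- setdiff(unique(c(pc, qc)), rownames(matrix$scores))
  if (length(miss) > 0L)
    stop("residue(s) not covered by matrix ", matrix$name, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  s <- matrix$scores[pc, qc, drop = FALSE]
  dimnames(s) <- NULL
  new_scoring_model(s, gap_open, gap_extend, matrix$name, p, q)
}

#' Generic fixed-matrix scoring model
#'
#' Like [blosum_model()] but takes any symmetric letter-by-letter score
#' matrix (e.g. an identity/mismatch matrix, or the 20x20 cosine matrix
#' induced by a context-free embedder).
#'
#' @param scores Numeric matrix with residue-letter dimnames.
#' @param label Provenance label.
#' @inheritParams blosum_model
#' @return A `scoring_model`.
#' @export
matrix_model <- function(scores, p, q, gap_open = -11, gap_extend = -1,
                         label = "matrix") {
  stopifnot(is.matrix(scores), !is.null(rownames(scores)),
            inherits(p, "protein_sequence"), inherits(q, "protein_sequence"))
  pc <- seq_chars(p); qc <- seq_chars(q)
  miss <- setdiff(unique(c(pc, qc)),
                  intersect(rownames(scores), colnames(scores)))
  if (length(miss) > 0L)
    stop("residue(s) not covered by score matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  s <- scores[pc, qc, drop = FALSE]
  dimnames(s) <- NULL
  new_scoring_model(s, gap_open, gap_extend, label, p, q)
}

#' Identity/mismatch scoring model
#'
#' A context-free baseline: `match` for identical residues, `mismatch`
#' otherwise.  Gap defaults are unit-scale analogues of matrix-scorer
#' conventions (the score range here is `[-1, 1]`, an order of magnitude
#' below BLOSUM entries, so the BLAST protein defaults would forbid gaps
#' outright).
#'
#' @inheritParams blosum_model
#' @param match,mismatch Scores for identical / differing residues.
#' @return A `scoring_model`.
#' @export
identity_model <- function(p, q, match = 1, mismatch = -1,
                           gap_open = -2, gap_extend = -0.5) {
  s <- matrix(mismatch, length(AA_ALPHABET), length(AA_ALPHABET),
              dimnames = list(AA_ALPHABET, AA_ALPHABET))
  diag(s) <- match
  matrix_model(s, p, q, gap_open, gap_extend, label = "identity")
}

#' E-score scoring model
#'
#' Builds a positional scoring model whose `score_at(i, j)` is the E-score
#' (embedding cosine similarity) of `P[i]` and `Q[j]`.  Default gap
#' penalties are the experimentally set values for cosine-scale scores:
#' open -0.25, extend -0.01.
#'
#' @param p_emb,q_emb Embedding matrices for P and Q (equal dimensions).
#' @param p,q The underlying [protein_sequence()] objects (optional but
#'   required by [score_alignment()]'s consistency checks).
#' @inheritParams blosum_model
#' @param label Provenance label; defaults to the embedding's model name.
#' @return A `scoring_model`.
#' @export
escore_model <- function(p_emb, q_emb, p = NULL, q = NULL,
                         gap_open = -0.25, gap_extend = -0.01,
                         label = NULL) {
  s <- escore_matrix(p_emb, q_emb)
  if (is.null(label)) {
    label <- attr(p_emb, "model_name")
    if (is.null(label)) label <- "escore"
    else label <- paste0("escore:", label)
  }
  new_scoring_model(s, gap_open, gap_extend, label, p, q)
}

#' Context-free cosine substitution matrix of a provider
#'
#' For an embedding provider with `context_window = 0`, the E-score depends
#' only on amino-acid identities; this returns the induced fixed
#' letter-by-letter cosine matrix (base vectors against each other), usable
#' with [matrix_model()].
#'
#' @param provider A [synthetic_embedder()] with `context_window = 0`.
#' @return Symmetric numeric matrix over the residue alphabet.
#' @export
context_free_matrix <- function(provider) {
  stopifnot(inherits(provider, "embedding_provider"))
  if (!identical(provider$context_window, 0L) && provider$context_window != 0)
    stop("context_free_matrix() requires a provider with context_window = 0",
         call. = FALSE)
  base <- provider$base_vectors
  m <- escore_matrix(base, base)
  dimnames(m) <- list(rownames(base), rownames(base))
  m
}
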
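# Build alignment row strings from a 0/1/2 op vector
# (0 = match column, 1 = gap in Q row, 2 = gap in P row).
ops_to_alignment <- function(ops, p, q) {
  pc <- seq_chars(p); qc <- seq_chars(q)
  pa <- character(length(ops)); qa <- character(length(ops))
  i <- 0L; j <- 0L
  for (k in seq_along(ops)) {
    if (ops[k] == 0L) {
      i <- i + 1L; j <- j + 1L
      pa[k] <- pc[i]; qa[k] <- qc[j]
    } else if (ops[k] == 1L) {
      i <- i + 1L
      pa[k] <- pc[i]; qa[k] <- GAP
    } else {
      j <- j + 1L
      pa[k] <- GAP; qa[k] <- qc[j]
    }
  }
  stopifnot(i == length(pc), j == length(qc))
  pairwise_alignment(paste(pa, collapse = ""), paste(qa, collapse = ""))
}

#' Align two protein sequences
#'
#' Optimal pairwise alignment under affine gap costs by the
#' Needleman-Wunsch/Gotoh dynamic program, over any positional scoring
#' model (fixed substitution matrix or E-score).  A gap run of length k
#' costs `gap_open + k * gap_extend`.  In `"semiglobal"` mode, leading and
#' trailing gap runs in either row cost nothing -- the variant of choice
#' when two sequences are expected to align end to end but end-gap
#' penalties would distort the alignment.  Traceback is deterministic
#' (diagonal preferred over gap-in-Q over gap-in-P; gap extension preferred
#' over opening); the `ties` flag reports whether any equal-scoring
#' alternative was seen.
#'
#' @param p,q [protein_sequence()] objects.
#' @param model A `scoring_model` built for `p` and `q` (see
#'   [blosum_model()], [escore_model()], [matrix_model()]).
#' @param mode `"global"` or `"semiglobal"`.
#' @return An `alignment_result`: list with `alignment`
#'   ([pairwise_alignment()]), `score`, `mode`, `scoring_label`, `ties`.
#' @examples
#' p <- protein_sequence("p", "RKD")
#' q <- protein_sequence("q", "DNN")
#' b62 <- read_substitution_matrix(
#'   system.file("extdata", "BLOSUM62.txt", package = "escore"))
#' align_pair(p, q, blosum_model(b62, p, q), mode = "global")
#' @export
align_pair <- function(p, q, model, mode = c("semiglobal", "global")) {
  mode <- match.arg(mode)
  stopifnot(inherits(p, "protein_sequence"),
            inherits(q, "protein_sequence"),
            inherits(model, "scoring_model"))
  if (nrow(model$scores) != length(p) || ncol(model$scores) != length(q))
    stop("scoring model covers ", nrow(model$scores), " x ",
         ncol(model$scores), " positions but sequences have lengths ",
         length(p), " and ", length(q), call. = FALSE)
  res <- .gotoh_align(model$scores, model$gap_open, model$gap_extend,
                      mode == "semiglobal")
  structure(list(alignment = ops_to_alignment(res$ops, p, q),
                 score = res$score, mode = mode,
                 scoring_label = model$label, ties = res$ties),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result> ", x$scoring_label, ", ", x$mode,
      ", score ", format(x$score), if (x$ties) " (ties)" else "", "\n",
      sep = "")
  cat(" P: ", x$alignment$p_row, "\n Q: ", x$alignment$q_row, "\n",
      sep = "")
  invisible(x)
}

# Maximal gap runs of a row's character vector: list(start, end, len)
gap_runs <- function(chars) {
  r <- rle(chars == GAP)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  list(start = starts[keep], end = ends[keep], len = r$lengths[keep])
}

#' Score an existing alignment under a model
#'
#' Re-scores a [pairwise_alignment()]: the sum of positional scores over
#' residue-residue columns plus `gap_open + k * gap_extend` per maximal gap
#' run of length k.  In semiglobal mode, gap runs touching either end of
#' the alignment cost nothing.  Serves as the round-trip verifier for
#' [align_pair()] -- re-scoring a returned alignment reproduces its score.
#'
#' @param alignment A [pairwise_alignment()]; its de-gapped rows must match
#'   the sequences the model was built for.
#' @inheritParams align_pair
#' @return The alignment's score.
#' @export
score_alignment <- function(alignment, model, mode = c("semiglobal", "global")) {
  mode <- match.arg(mode)
  stopifnot(inherits(alignment, "pairwise_alignment"),
            inherits(model, "scoring_model"))
  seqs <- alignment_sequences(alignment)
  if (nchar(seqs$p) != nrow(model$scores) ||
      nchar(seqs$q) != ncol(model$scores))
    stop("alignment does not match the sequences underlying the model",
         call. = FALSE)
  if (!is.null(model$p) && !identical(seqs$p, model$p$residues))
    stop("alignment P row does not de-gap to the model's P sequence",
         call. = FALSE)
  if (!is.null(model$q) && !identical(seqs$q, model$q$residues))
    stop("alignment Q row does not de-gap to the model's Q sequence",
         call. = FALSE)
  pc <- seq_chars(alignment$p_row)
  qc <- seq_chars(alignment$q_row)
  pi <- cumsum(pc != GAP)
  qi <- cumsum(qc != GAP)
  match_cols <- which(pc != GAP & qc != GAP)
  total <- sum(model$scores[cbind(pi[match_cols], qi[match_cols])])
  len <- length(pc)
  for (runs in list(gap_runs(pc), gap_runs(qc))) {
    nr <- length(runs$start)
    if (nr == 0L) next
    terminal <- runs$start == 1L | runs$end == len
    charge <- if (mode == "semiglobal") !terminal else rep(TRUE, nr)
    total <- total + sum(charge * (model$gap_open +
                                     runs$len * model$gap_extend))
  }
  total
}

# Fast path used by the enumeration oracle: score an op path directly
# (0 = match column, 1 = gap in Q row, 2 = gap in P row) without building
# alignment strings.  Same affine cost definition as score_alignment().
score_ops <- function(ops, model, mode) {
  pi <- cumsum(ops != 2L)
  qi <- cumsum(ops != 1L)
  mcols <- ops == 0L
  total <- sum(model$scores[cbind(pi[mcols], qi[mcols])])
  len <- length(ops)
  for (g in 1:2) {
    runs <- gap_runs(ifelse(ops == g, GAP, "x"))
    nr <- length(runs$start)
    if (nr == 0L) next
    charge <- if (mode == "semiglobal")
      !(runs$start == 1L | runs$end == len) else rep(TRUE, nr)
    total <- total + sum(charge * (model$gap_open +
                                     runs$len * model$gap_extend))
  }
  total
}

# Enumerate all op paths (0 diag / 1 up / 2 left) for sequence lengths
# (m, n), as a list of integer vectors.  No double-gap columns arise by
# construction.  Cached per (m, n) within a session.
.op_cache <- new.env(parent = emptyenv())
enumerate_ops <- function(m, n) {
  key <- paste0(m, "_", n)
  if (!is.null(.op_cache[[key]])) return(.op_cache[[key]])
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(list(integer(0L)))
    out <- list()
    if (i > 0L && j > 0L)
      out <- c(out, lapply(rec(i - 1L, j - 1L), function(x) c(x, 0L)))
    if (i > 0L)
      out <- c(out, lapply(rec(i - 1L, j), function(x) c(x, 1L)))
    if (j > 0L)
      out <- c(out, lapply(rec(i, j - 1L), function(x) c(x, 2L)))
    out
  }
  res <- rec(m, n)
  .op_cache[[key]] <- res
  res
}

#' Brute-force optimal alignment by exhaustive enumeration
#'
#' Enumerates every alignment of P and Q (all monotone gap placements
#' without double-gap columns), scores each with [score_alignment()], and
#' returns the true optimum.  Exponential -- only feasible for
#' `|P| + |Q| <= 12` -- and entirely independent of the dynamic-programming
#' recurrences, which makes it the correctness oracle for [align_pair()].
#'
#' @inheritParams align_pair
#' @return An `alignment_result` (with `ties` reporting whether several
#'   alignments attain the optimum).
#' @export
brute_force_align <- function(p, q, model, mode = c("semiglobal", "global")) {
  mode <- match.arg(mode)
  stopifnot(inherits(p, "protein_sequence"),
            inherits(q, "protein_sequence"))
  m <- length(p); n <- length(q)
  if (m + n > 12L)
    stop("brute_force_align is limited to |P| + |Q| <= 12, got ", m + n,
         call. = FALSE)
  paths <- enumerate_ops(m, n)
  best <- NULL; best_score <- -Inf; nbest <- 0L
  for (ops in paths) {
    s <- score_ops(ops, model, mode)
    if (s > best_score) {
      best_score <- s; best <- ops; nbest <- 1L
    } else if (s == best_score) {
      nbest <- nbest + 1L
    }
  }
  structure(list(alignment = ops_to_alignment(best, p, q),
                 score = best_score, mode = mode,
                 scoring_label = model$label, ties = nbest > 1L),
            class = "alignment_result")
}
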
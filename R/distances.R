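# --- Position index maps -------------------------------------------------

# Columns of the alignment occupied by each residue of P (and Q):
# p[i] = column of P[i] in the P row (strictly increasing), likewise q[j].
position_index_map <- function(a) {
  stopifnot(inherits(a, "pairwise_alignment"))
  pc <- seq_chars(a$p_row); qc <- seq_chars(a$q_row)
  list(p = which(pc != GAP), q = which(qc != GAP))
}

# Validate that two alignments align the same underlying sequences.
check_same_sequences <- function(a1, a2) {
  s1 <- alignment_sequences(a1); s2 <- alignment_sequences(a2)
  if (!identical(s1$p, s2$p) || !identical(s1$q, s2$q))
    stop("the two alignments do not align the same sequences",
         call. = FALSE)
  invisible(s1)
}

# --- Relative displacement distance (d_d) --------------------------------

# n x m matrix of displacements p_i - q_j for one alignment.
displacement_profile <- function(a) {
  idx <- position_index_map(a)
  outer(idx$p, idx$q, "-")
}

#' Relative displacement distance between two alignments
#'
#' Measures how differently two alignments of the same sequences P
#' (length n) and Q (length m) place their letters: for every residue pair
#' (i of P, j of Q), the displacement `d_A(i, j) = p_i - q_j` is the
#' column offset between the two residues in alignment A, and
#'
#' `d_d(A1, A2) = sum over i, j of |d_A1(i, j) - d_A2(i, j)| / (m n (m + n))`
#'
#' The normalization uses the bound
#' `|d_A1(i, j) - d_A2(i, j)| <= m + n`, so the value lies in `[0, 1]`;
#' it is 0 exactly when the displacement profiles coincide.
#'
#' @param a1,a2 [pairwise_alignment()] objects of the same two sequences.
#' @return A number in `[0, 1]`.
#' @examples
#' a1 <- pairwise_alignment("-RKD", "DN-N")
#' a2 <- pairwise_alignment("RKD-", "D-NN")
#' relative_displacement_distance(a1, a2)  # 12/54
#' @export
relative_displacement_distance <- function(a1, a2) {
  seqs <- check_same_sequences(a1, a2)
  n <- nchar(seqs$p); m <- nchar(seqs$q)
  diff <- abs(displacement_profile(a1) - displacement_profile(a2))
  sum(diff) / (m * n * (m + n))
}

# --- Closest context distance (d_cc) -------------------------------------

# Count of letters in the half-open range between positions `from` and `to`
# of gapped row `chars` under the reversed-range convention:
# from <= to -> positions from+1 .. to;  from > to -> positions to .. from-1.
range_letter_count <- function(chars, from, to) {
  if (from <= to) {
    if (from + 1L > to) return(0L)
    idx <- (from + 1L):to
  } else {
    if (to > from - 1L) return(0L)
    idx <- to:(from - 1L)
  }
  sum(chars[idx] != GAP)
}

# Contribution of residue i of `own` (the sequence whose row in alignment
# `a` is own_row_*) from alignment `a` (the other alignment is `b`).
# other_row_a / other_row_b are the OPPOSITE sequence's gapped rows.
cc_contribution <- function(i, own_pos_a, own_pos_b,
                            other_row_a, other_row_b) {
  pa <- own_pos_a[i]   # column of the residue in alignment a
  pb <- own_pos_b[i]   # column of the residue in alignment b
  opp <- other_row_a[pa]
  if (opp != GAP) {
    # case (a): opposite symbol is a letter -- fewest letters in the other
    # alignment's opposite row from this residue's column to the nearest
    # occurrence of that same letter
    occ <- which(other_row_b == opp)
    stopifnot(length(occ) > 0L)  # same Q underlies both alignments
    min(vapply(occ, function(k) range_letter_count(other_row_b, pb, k),
               integer(1L)))
  } else {
    # case (b): opposite symbol is a gap -- difference between the numbers
    # of letters in the two opposite rows strictly before the residue's
    # position
    abs(range_letter_count(other_row_a, 0L, pa - 1L) -
          range_letter_count(other_row_b, 0L, pb - 1L))
  }
}

#' Per-residue closest-context contributions
#'
#' The individual terms summed by [closest_context_distance()]: for each
#' residue of P and of Q, and each alignment `l = 1, 2`, how many letters
#' away the *other* alignment places the context symbol found opposite the
#' residue (letter case), or how the opposite rows' preceding letter counts
#' differ (gap case).
#'
#' @inheritParams relative_displacement_distance
#' @return List with matrices `d_p` (n x 2) and `d_q` (m x 2);
#'   `d_p[i, l]` is the contribution of P's residue i from alignment l.
#' @examples
#' a1 <- pairwise_alignment("-RKD", "DN-N")
#' a2 <- pairwise_alignment("RKD-", "D-NN")
#' closest_context_contributions(a1, a2)$d_p[, 1]  # 1 1 0
#' @export
closest_context_contributions <- function(a1, a2) {
  seqs <- check_same_sequences(a1, a2)
  n <- nchar(seqs$p); m <- nchar(seqs$q)
  i1 <- position_index_map(a1); i2 <- position_index_map(a2)
  p1 <- seq_chars(a1$p_row); q1 <- seq_chars(a1$q_row)
  p2 <- seq_chars(a2$p_row); q2 <- seq_chars(a2$q_row)
  d_p <- matrix(0, n, 2L)
  d_q <- matrix(0, m, 2L)
  for (i in seq_len(n)) {
    d_p[i, 1L] <- cc_contribution(i, i1$p, i2$p, q1, q2)
    d_p[i, 2L] <- cc_contribution(i, i2$p, i1$p, q2, q1)
  }
  for (j in seq_len(m)) {
    d_q[j, 1L] <- cc_contribution(j, i1$q, i2$q, p1, p2)
    d_q[j, 2L] <- cc_contribution(j, i2$q, i1$q, p2, p1)
  }
  list(d_p = d_p, d_q = d_q)
}

#' Closest context distance between two alignments
#'
#' Captures both position and context: each residue contributes the letter
#' distance from its position in one alignment to the nearest occurrence,
#' in the other alignment's opposite row, of the symbol it faces (letter
#' case), or the difference in preceding letter counts when it faces a gap.
#' With `|P| = n`, `|Q| = m`, contributions satisfy `d_P <= m` and
#' `d_Q <= n`, and
#'
#' `d_cc(A1, A2) = (sum of all contributions over both alignments) / (4 m n)`
#'
#' lies in `[0, 1]`, equals 0 for identical alignments, and is symmetric in
#' its arguments by construction of the sum over `l = 1, 2`.
#'
#' @inheritParams relative_displacement_distance
#' @return A number in `[0, 1]`.
#' @examples
#' a1 <- pairwise_alignment("-RKD", "DN-N")
#' a2 <- pairwise_alignment("RKD-", "D-NN")
#' closest_context_distance(a1, a2)  # 11/36
#' @export
closest_context_distance <- function(a1, a2) {
  seqs <- check_same_sequences(a1, a2)
  n <- nchar(seqs$p); m <- nchar(seqs$q)
  contrib <- closest_context_contributions(a1, a2)
  (sum(contrib$d_p) + sum(contrib$d_q)) / (4 * m * n)
}

# --- Homology-set distances (d_ssp, d_seq, d_pos) ------------------------

#' Homology sets of a pairwise alignment
#'
#' For each residue position of each sequence, the set of symbols from the
#' other sequence in the same alignment column, under one of three gap
#' treatments:
#' * `"ssp"` -- gaps are ignored: a residue facing a gap has the empty set;
#' * `"seq"` -- every gap in sequence k is the single symbol `g^k`;
#' * `"pos"` -- a gap in sequence k is labeled `g^k` subscripted with the
#'   count of residue letters preceding it in that row.
#'
#' @param a A [pairwise_alignment()].
#' @param variant One of `"ssp"`, `"seq"`, `"pos"`.
#' @return List of two lists (`p`, `q`); element `i` of `p` is the
#'   character-vector homology set of P's residue i (symbols are residue
#'   letters, or gap labels `"g2"` / `"g2_2"`).
#' @examples
#' homology_sets(pairwise_alignment("-RKD", "DN-N"), "pos")$p[[2]]  # g2_2
#' @export
homology_sets <- function(a, variant = c("ssp", "seq", "pos")) {
  variant <- match.arg(variant)
  stopifnot(inherits(a, "pairwise_alignment"))
  pc <- seq_chars(a$p_row); qc <- seq_chars(a$q_row)
  gap_label <- function(k, chars, col) {
    switch(variant,
           ssp = character(0L),
           seq = paste0("g", k),
           pos = paste0("g", k, "_", sum(chars[seq_len(col - 1L)] != GAP)))
  }
  opposite <- function(own, other, other_k) {
    cols <- which(own != GAP)
    lapply(cols, function(col) {
      if (other[col] != GAP) other[col] else gap_label(other_k, other, col)
    })
  }
  list(p = opposite(pc, qc, 2L), q = opposite(qc, pc, 1L))
}

# Flatten both sequences' homology sets of two alignments into aligned
# per-position pairs.
paired_homology_sets <- function(a1, a2, variant) {
  check_same_sequences(a1, a2)
  h1 <- homology_sets(a1, variant)
  h2 <- homology_sets(a2, variant)
  list(h1 = c(h1$p, h1$q), h2 = c(h2$p, h2$q))
}

#' Homology-set distances between two alignments
#'
#' `d_ssp()` is a Jaccard-style distance over the gap-ignoring homology
#' sets: one minus the ratio of summed intersection sizes to summed union
#' sizes over all residue positions of both sequences (0/0 counts as
#' distance 0).  `d_seq()` and `d_pos()` average, over all residue
#' positions, the per-position normalized symmetric difference
#' `|H1 xor H2| / (|H1| + |H2|)` of the gap-relabeled homology sets
#' (all gaps of a sequence equivalent for `"seq"`; labeled by preceding
#' letter count for `"pos"`).  All three lie in `[0, 1]` and are 0 for
#' identical alignments.
#'
#' @inheritParams relative_displacement_distance
#' @return A number in `[0, 1]`.
#' @examples
#' a1 <- pairwise_alignment("-RKD", "DN-N")
#' a2 <- pairwise_alignment("RKD-", "D-NN")
#' d_ssp(a1, a2); d_seq(a1, a2); d_pos(a1, a2)
#' @export
d_ssp <- function(a1, a2) {
  h <- paired_homology_sets(a1, a2, "ssp")
  inter <- sum(mapply(function(x, y) length(intersect(x, y)), h$h1, h$h2))
  uni <- sum(mapply(function(x, y) length(union(x, y)), h$h1, h$h2))
  if (uni == 0L) return(0)
  1 - inter / uni
}

# shared symmetric-difference form of d_seq / d_pos
symdiff_distance <- function(a1, a2, variant) {
  h <- paired_homology_sets(a1, a2, variant)
  terms <- mapply(function(x, y) {
    denom <- length(x) + length(y)
    if (denom == 0L) return(0)
    (length(setdiff(x, y)) + length(setdiff(y, x))) / denom
  }, h$h1, h$h2)
  mean(terms)
}

#' @rdname d_ssp
#' @export
d_seq <- function(a1, a2) symdiff_distance(a1, a2, "seq")

#' @rdname d_ssp
#' @export
d_pos <- function(a1, a2) symdiff_distance(a1, a2, "pos")

# --- Combined report and MSA projection ----------------------------------

#' All five alignment distances
#'
#' Computes the requested subset of the five alignment-comparison
#' distances: closest context (`cc`), relative displacement (`d`),
#' positional-gap (`pos`), sequence-gap (`seq`) and symmetrized
#' sum-of-pairs (`ssp`).
#'
#' @inheritParams relative_displacement_distance
#' @param metrics Character subset of `c("cc", "d", "pos", "seq", "ssp")`.
#' @return Named numeric vector, one entry per requested metric, all in
#'   `[0, 1]` and all 0 when the alignments are identical.
#' @examples
#' a1 <- pairwise_alignment("-RKD", "DN-N")
#' a2 <- pairwise_alignment("RKD-", "D-NN")
#' alignment_distances(a1, a2)
#' @export
alignment_distances <- function(a1, a2,
                                metrics = c("cc", "d", "pos", "seq", "ssp")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  fns <- list(cc = closest_context_distance,
              d = relative_displacement_distance,
              pos = d_pos, seq = d_seq, ssp = d_ssp)
  vapply(metrics, function(mt) fns[[mt]](a1, a2), numeric(1L))
}

#' Pairwise alignment induced by a reference MSA
#'
#' Projects two rows of a multiple sequence alignment onto the pairwise
#' alignment they induce: the two gapped rows with every column that is
#' gapped in both removed.  This is the reference ("true") alignment that
#' computed pairwise alignments are scored against.
#'
#' @param x An [msa()].
#' @param row_i,row_j Distinct row indices.
#' @return A [pairwise_alignment()].
#' @examples
#' m <- msa(c("a", "b", "c"), c("A--C", "A-GC", "AG-C"))
#' induced_pairwise(m, 1, 2)
#' @export
induced_pairwise <- function(x, row_i, row_j) {
  stopifnot(inherits(x, "msa"),
            row_i >= 1L, row_i <= length(x$ids),
            row_j >= 1L, row_j <= length(x$ids))
  if (row_i == row_j)
    stop("row_i and row_j must differ", call. = FALSE)
  pc <- seq_chars(x$rows[row_i])
  qc <- seq_chars(x$rows[row_j])
  keep <- !(pc == GAP & qc == GAP)
  if (!any(pc[keep] != GAP) || !any(qc[keep] != GAP))
    stop("row ", if (!any(pc[keep] != GAP)) row_i else row_j,
         " is all gaps", call. = FALSE)
  pairwise_alignment(paste(pc[keep], collapse = ""),
                     paste(qc[keep], collapse = ""))
}
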
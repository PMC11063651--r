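#' Pairwise alignment object
#'
#' An alignment of two sequences P and Q: a pair of equal-length gapped
#' strings `(P_A, Q_A)` over the residue alphabet plus `'-'`, with no column
#' gapped in both rows.  Removing the gaps from `P_A` recovers P, and from
#' `Q_A` recovers Q.
#'
#' @param p_row Gapped string for the first sequence (P).
#' @param q_row Gapped string for the second sequence (Q).
#' @return Object of class `pairwise_alignment` with fields `p_row`, `q_row`.
#' @examples
#' pairwise_alignment("-RKD", "DN-N")
#' @export
pairwise_alignment <- function(p_row, q_row) {
  stopifnot(is.character(p_row), length(p_row) == 1L,
            is.character(q_row), length(q_row) == 1L)
  p_row <- chartr(".", "-", toupper(p_row))
  q_row <- chartr(".", "-", toupper(q_row))
  if (nchar(p_row) != nchar(q_row))
    stop("alignment rows have different lengths: ", nchar(p_row), " vs ",
         nchar(q_row), call. = FALSE)
  pc <- seq_chars(p_row)
  qc <- seq_chars(q_row)
  both <- which(pc == GAP & qc == GAP)
  if (length(both) > 0L)
    stop("column(s) gapped in both rows: ",
         paste(both, collapse = ", "), call. = FALSE)
  # Validates the residue alphabet of both de-gapped rows.
  protein_sequence("P", paste(pc[pc != GAP], collapse = ""))
  protein_sequence("Q", paste(qc[qc != GAP], collapse = ""))
  structure(list(p_row = p_row, q_row = q_row), class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> length ", nchar(x$p_row), "\n", sep = "")
  cat(" P: ", x$p_row, "\n Q: ", x$q_row, "\n", sep = "")
  invisible(x)
}

# De-gapped sequences underlying an alignment, as plain strings.
alignment_sequences <- function(a) {
  list(p = gsub("-", "", a$p_row, fixed = TRUE),
       q = gsub("-", "", a$q_row, fixed = TRUE))
}

#' Write a pairwise alignment as aligned FASTA
#'
#' Serializes a [pairwise_alignment()] as a two-record aligned FASTA text.
#' The output round-trips through [read_msa()].
#'
#' @param alignment A [pairwise_alignment()].
#' @param ids Character vector of two record identifiers.
#' @param file Optional path; when given, the text is also written there.
#' @return The FASTA text, invisibly when `file` is given.
#' @examples
#' write_alignment(pairwise_alignment("-RKD", "DN-N"), c("p", "q"))
#' @export
write_alignment <- function(alignment, ids = c("P", "Q"), file = NULL) {
  stopifnot(inherits(alignment, "pairwise_alignment"),
            is.character(ids), length(ids) == 2L)
  txt <- format_fasta(ids, c(alignment$p_row, alignment$q_row))
  if (!is.null(file)) {
    writeLines(sub("\n$", "", txt), file)
    return(invisible(txt))
  }
  txt
}
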
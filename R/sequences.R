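#' Protein sequence object
#'
#' A minimal container for an unaligned protein sequence: an identifier and a
#' residue string over the 20 amino-acid letters plus the ambiguity codes
#' B, Z, X, U, O.  Residues are stored uppercase and may not contain gaps.
#'
#' @param id Single string, the sequence identifier.
#' @param residues Single string of residue letters (uppercased on input).
#' @return An object of class `protein_sequence` with fields `id` and
#'   `residues`.
#' @examples
#' protein_sequence("p", "RKD")
#' @export
protein_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) < 1L)
    stop("sequence '", id, "' is empty", call. = FALSE)
  bad <- setdiff(unique(strsplit(residues, "", fixed = TRUE)[[1L]]), AA_ALPHABET)
  if (length(bad) > 0L)
    stop("sequence '", id, "' contains illegal character(s): ",
         paste(sQuote(bad), collapse = ", "), call. = FALSE)
  structure(list(id = id, residues = residues), class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("<protein_sequence> ", x$id, " (", nchar(x$residues), " aa)\n",
      sep = "")
  cat(" ", x$residues, "\n", sep = "")
  invisible(x)
}

#' @export
length.protein_sequence <- function(x) nchar(x$residues)

# Split a residue string into a character vector of single letters.
seq_chars <- function(x) {
  if (inherits(x, "protein_sequence")) x <- x$residues
  strsplit(x, "", fixed = TRUE)[[1L]]
}

# Shared low-level FASTA record parser.  Returns list(ids, seqs) with raw
# (unvalidated) concatenated sequence strings: uppercased, intra-line
# whitespace removed, '*' stop symbols stripped.
parse_fasta_records <- function(lines) {
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*$", lines) | grepl("^>", lines)
  lines <- lines[keep]
  if (length(lines) == 0L)
    stop("empty FASTA input", call. = FALSE)
  hdr <- grepl("^>", lines)
  if (!hdr[1L])
    stop("FASTA input does not start with a '>' header line", call. = FALSE)
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  ids[ids == ""] <- sprintf("unnamed_%d", seq_len(sum(ids == "")))
  seqs <- vapply(split(lines[!hdr], factor(rec[!hdr], levels = seq_along(ids))),
                 function(x) paste(x, collapse = ""), character(1L))
  seqs <- gsub("[[:space:]]", "", toupper(seqs))
  seqs <- gsub("*", "", seqs, fixed = TRUE)
  # De-duplicate repeated ids by suffixing (reference alignment exports can
  # repeat accessions).
  if (anyDuplicated(ids)) {
    dup <- ave(seq_along(ids), ids, FUN = seq_along)
    ids[dup > 1L] <- paste0(ids[dup > 1L], "_", dup[dup > 1L])
  }
  list(ids = ids, seqs = unname(seqs))
}

#' Read protein sequences from FASTA
#'
#' Reads a FASTA file (or connection) of unaligned protein sequences.
#' Residues are uppercased, whitespace inside sequence lines is removed,
#' and `'*'` stop symbols are stripped.  Repeated identifiers are
#' de-duplicated by suffixing `_2`, `_3`, ...
#'
#' @param file Path or connection to FASTA-formatted text.
#' @return List of [protein_sequence()] objects, in file order.
#' @examples
#' f <- textConnection(">a\nRKD\n>b\nDNN")
#' read_fasta(f)
#' @export
read_fasta <- function(file) {
  rec <- parse_fasta_records(readLines(file))
  empty <- nchar(rec$seqs) == 0L
  if (any(empty))
    stop("FASTA record(s) with empty sequence: ",
         paste(sQuote(rec$ids[empty]), collapse = ", "), call. = FALSE)
  gap <- grepl("[-.]", rec$seqs)
  if (any(gap))
    stop("gap characters in unaligned FASTA record(s): ",
         paste(sQuote(rec$ids[gap]), collapse = ", "),
         "; use read_msa() for aligned input", call. = FALSE)
  Map(protein_sequence, rec$ids, rec$seqs, USE.NAMES = FALSE)
}

# Format sequences (named character vector) as FASTA text, wrapped at `width`.
format_fasta <- function(ids, seqs, width = 60L) {
  out <- character(0L)
  for (k in seq_along(ids)) {
    body <- substring(seqs[k],
                      seq(1L, nchar(seqs[k]), by = width),
                      pmin(seq(1L, nchar(seqs[k]), by = width) + width - 1L,
                           nchar(seqs[k])))
    out <- c(out, paste0(">", ids[k]), body)
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
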
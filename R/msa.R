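#' Multiple sequence alignment object
#'
#' Stores a multiple sequence alignment as an ordered set of equal-length
#' gapped rows.  Gap characters `'.'` and `'-'` are both accepted on input
#' and normalized to `'-'`; de-gapping any row must yield a valid
#' [protein_sequence()].
#'
#' @param ids Character vector of row identifiers.
#' @param rows Character vector of gapped residue strings (same length as
#'   `ids`).
#' @return Object of class `msa` with fields `ids`, `rows` and
#'   `alignment_length`.
#' @examples
#' msa(c("a", "b"), c("-RKD", "DN-N"))
#' @export
msa <- function(ids, rows) {
  stopifnot(is.character(ids), is.character(rows),
            length(ids) == length(rows))
  if (length(rows) < 2L)
    stop("an MSA needs at least 2 rows, got ", length(rows), call. = FALSE)
  rows <- chartr(".", "-", toupper(rows))
  len <- nchar(rows)
  if (length(unique(len)) != 1L) {
    len_mode <- as.integer(names(which.max(table(len))))
    off <- ids[len != len_mode]
    stop("MSA rows have unequal lengths; offending row id(s): ",
         paste(sQuote(off), collapse = ", "), call. = FALSE)
  }
  for (k in seq_along(rows)) {
    degapped <- gsub("-", "", rows[k], fixed = TRUE)
    protein_sequence(ids[k], degapped)  # validates residues, non-empty
  }
  structure(list(ids = ids, rows = rows, alignment_length = len[1L]),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", length(x$ids), " rows x ", x$alignment_length,
      " columns\n", sep = "")
  show <- utils::head(seq_along(x$ids), 6L)
  for (k in show)
    cat(sprintf(" %-12s %s\n", x$ids[k],
                if (x$alignment_length > 60L)
                  paste0(substr(x$rows[k], 1L, 57L), "...")
                else x$rows[k]))
  if (length(x$ids) > 6L) cat(" ...\n")
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' Reads an MSA from aligned FASTA or CLUSTAL text.  Both `'.'` and `'-'`
#' are accepted as gaps and normalized to `'-'`.
#'
#' @param file Path or connection.
#' @param format `"fasta"` (aligned FASTA, default) or `"clustal"`.
#' @return An [msa()] object with rows in file order.
#' @examples
#' f <- textConnection(">a\n-RKD\n>b\nDN-N")
#' read_msa(f)
#' @export
read_msa <- function(file, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "fasta") {
    rec <- parse_fasta_records(readLines(file))
    return(msa(rec$ids, rec$seqs))
  }
  # CLUSTAL: header line, then blocks of "name  segment" lines separated by
  # blank lines, optionally followed by unnamed conservation lines.
  lines <- readLines(file)
  if (length(lines) == 0L || !grepl("^CLUSTAL", lines[1L], ignore.case = TRUE))
    stop("not a CLUSTAL file: missing CLUSTAL header line", call. = FALSE)
  lines <- sub("\r$", "", lines[-1L])
  segs <- regmatches(lines,
                     regexec("^(\\S+)\\s+([A-Za-z.\\-]+)\\s*\\d*\\s*$",
                             lines))
  segs <- segs[lengths(segs) == 3L]
  if (length(segs) == 0L)
    stop("no sequence lines found in CLUSTAL input", call. = FALSE)
  ids <- vapply(segs, `[`, character(1L), 2L)
  chunks <- vapply(segs, `[`, character(1L), 3L)
  order_ids <- unique(ids)
  rows <- vapply(order_ids,
                 function(id) paste(chunks[ids == id], collapse = ""),
                 character(1L))
  msa(order_ids, unname(rows))
}

# De-gap one MSA row into a protein_sequence.
msa_sequence <- function(x, row) {
  stopifnot(inherits(x, "msa"), row >= 1L, row <= length(x$ids))
  protein_sequence(x$ids[row], gsub("-", "", x$rows[row], fixed = TRUE))
}
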
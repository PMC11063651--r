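#' Read an NCBI-format substitution matrix
#'
#' Parses the NCBI text dialect used for BLOSUM/PAM matrices: comment lines
#' starting with `'#'`, a header row of column letters, then one labeled row
#' of integer scores per residue.  The matrix must be symmetric and must
#' cover all 20 standard amino acids; entries for ambiguity codes (B, Z, X,
#' ...) are kept when present, and the `'*'` stop row/column is dropped.
#'
#' @param file Path or connection to the matrix text.
#' @param name Matrix name recorded in the result; defaults to the file name.
#' @return Object of class `substitution_matrix` with fields `name` and
#'   `scores` (a symmetric numeric matrix with residue dimnames).
#' @examples
#' b62 <- read_substitution_matrix(
#'   system.file("extdata", "BLOSUM62.txt", package = "escore"))
#' sub_score(b62, "A", "A")
#' @export
read_substitution_matrix <- function(file, name = NULL) {
  if (is.null(name))
    name <- if (is.character(file))
      sub("\\.[^.]*$", "", basename(file)) else "substitution_matrix"
  lines <- readLines(file)
  lines <- lines[!grepl("^\\s*#", lines) & !grepl("^\\s*$", lines)]
  if (length(lines) < 2L)
    stop("not a substitution matrix: no header/score rows found",
         call. = FALSE)
  cols <- toupper(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
  body <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  row_letters <- toupper(vapply(body, `[`, character(1L), 1L))
  vals <- lapply(body, function(x) suppressWarnings(as.numeric(x[-1L])))
  if (any(vapply(vals, function(v) anyNA(v) || length(v) != length(cols),
                 logical(1L))))
    stop("malformed substitution matrix: row lengths do not match header",
         call. = FALSE)
  m <- do.call(rbind, vals)
  dimnames(m) <- list(row_letters, cols)
  keep_r <- row_letters %in% AA_ALPHABET
  keep_c <- cols %in% AA_ALPHABET
  m <- m[keep_r, keep_c, drop = FALSE]
  common <- intersect(rownames(m), colnames(m))
  m <- m[common, common, drop = FALSE]
  asym <- which(m != t(m), arr.ind = TRUE)
  if (nrow(asym) > 0L) {
    k <- asym[1L, ]
    stop("substitution matrix is not symmetric, e.g. (",
         rownames(m)[k[1L]], ",", colnames(m)[k[2L]], ") = ",
         m[k[1L], k[2L]], " but (", colnames(m)[k[2L]], ",",
         rownames(m)[k[1L]], ") = ", m[k[2L], k[1L]], call. = FALSE)
  }
  missing_aa <- setdiff(AA_STANDARD, common)
  if (length(missing_aa) > 0L)
    stop("substitution matrix is missing standard residue(s): ",
         paste(missing_aa, collapse = ", "), call. = FALSE)
  structure(list(name = name, scores = m), class = "substitution_matrix")
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat("<substitution_matrix> ", x$name, " (", nrow(x$scores), " letters)\n",
      sep = "")
  print(x$scores[seq_len(min(6L, nrow(x$scores))),
                 seq_len(min(6L, ncol(x$scores)))])
  invisible(x)
}

#' Look up a substitution score
#'
#' @param matrix A `substitution_matrix`.
#' @param a,b Single residue letters.
#' @return The (symmetric) substitution score for the pair.
#' @rdname read_substitution_matrix
#' @export
sub_score <- function(matrix, a, b) {
  stopifnot(inherits(matrix, "substitution_matrix"))
  a <- toupper(a); b <- toupper(b)
  miss <- setdiff(c(a, b), rownames(matrix$scores))
  if (length(miss) > 0L)
    stop("residue(s) not covered by matrix ", matrix$name, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  matrix$scores[a, b]
}
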
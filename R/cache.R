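#' Persistent embedding cache
#'
#' Per-residue embedding matrices are expensive to compute for real protein
#' language models and are reused across many pairwise alignments, so they
#' are cached on disk.  The cache stores one entry per (model, sequence-id)
#' key together with the residue string it was computed from; retrieving an
#' entry with a different residue string under the same id is an error
#' (a changed sequence under a reused id must not silently return stale
#' vectors).
#'
#' @param dir Directory backing the cache; created if absent.
#' @return Object of class `embedding_cache`.
#' @examples
#' cache <- embedding_cache(tempfile("cache"))
#' seq <- protein_sequence("p1", "RKDNN")
#' emb <- matrix(1:10 / 10, nrow = 5)
#' cache_put(cache, "toy_model", seq, emb)
#' identical(cache_get(cache, "toy_model", seq), emb)
#' @export
embedding_cache <- function(dir) {
  stopifnot(is.character(dir), length(dir) == 1L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  structure(list(dir = dir), class = "embedding_cache")
}

cache_path <- function(cache, model, id) {
  key <- gsub("[^A-Za-z0-9._-]", "_", paste0(model, "__", id))
  file.path(cache$dir, paste0(key, ".rds"))
}

#' @param cache An [embedding_cache()].
#' @param model Model name part of the key.
#' @param seq A [protein_sequence()]; its id completes the key and its
#'   residue string is stored for staleness detection.
#' @param values Numeric embedding matrix, one row per residue.
#' @rdname embedding_cache
#' @export
cache_put <- function(cache, model, seq, values) {
  stopifnot(inherits(cache, "embedding_cache"),
            inherits(seq, "protein_sequence"), is.matrix(values))
  if (nrow(values) != nchar(seq$residues))
    stop("embedding rows (", nrow(values), ") != sequence length (",
         nchar(seq$residues), ") for '", seq$id, "'", call. = FALSE)
  saveRDS(list(residues = seq$residues, values = values),
          cache_path(cache, model, seq$id))
  invisible(values)
}

#' @return `cache_get()` returns the stored matrix, or `NULL` when the key
#'   is absent.
#' @rdname embedding_cache
#' @export
cache_get <- function(cache, model, seq) {
  stopifnot(inherits(cache, "embedding_cache"),
            inherits(seq, "protein_sequence"))
  path <- cache_path(cache, model, seq$id)
  if (!file.exists(path)) return(NULL)
  entry <- readRDS(path)
  if (!identical(entry$residues, seq$residues))
    stop("cache entry for ('", model, "', '", seq$id, "') was computed ",
         "from a different residue string; refusing to return stale ",
         "embeddings", call. = FALSE)
  entry$values
}
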
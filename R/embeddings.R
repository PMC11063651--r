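#' Deterministic synthetic context-sensitive embedder
#'
#' Builds an embedding provider that maps each residue to a vector equal to
#' a fixed per-amino-acid base vector plus a geometrically decaying mixture
#' of the base vectors of its sequence neighbours.  With
#' `context_window = 0` the embedding is context-free (the same amino acid
#' gets the same vector everywhere); with `context_window >= 1` the same
#' amino acid in different contexts gets different vectors, emulating the
#' context sensitivity of protein language model embeddings without any
#' model download.  All output is deterministic given
#' `(sequence, dimension, context_window, seed)`.
#'
#' Base vectors are drawn once per provider from a seeded standard normal;
#' in the dimensions used here (>= 8) they are pairwise near-orthogonal, so
#' distinct amino acids embed to dissimilar vectors while shared context
#' pulls cosine similarity up.  Ambiguity codes (B, Z, X, U, O) receive
#' their own base vectors so every valid sequence is embeddable.
#'
#' @param dimension Embedding dimension (>= 2).
#' @param context_window Number of neighbours mixed in on each side (>= 0).
#' @param seed Integer seed for the base-vector draw.
#' @param decay Geometric decay of neighbour weights: a neighbour at offset
#'   `o` contributes with weight `decay^|o|`.
#' @return An `embedding_provider` with fields `name`, `dimension` and
#'   `embed(seq)`.
#' @examples
#' prov <- synthetic_embedder(dimension = 8, context_window = 1, seed = 1)
#' emb <- prov$embed(protein_sequence("p", "ARA"))
#' dim(emb)
#' @export
synthetic_embedder <- function(dimension = 32L, context_window = 2L,
                               seed = 1L, decay = 0.5) {
  stopifnot(dimension >= 2L, context_window >= 0L, decay > 0, decay <= 1)
  base <- with_local_seed(seed, {
    matrix(rnorm(length(AA_ALPHABET) * dimension),
           nrow = length(AA_ALPHABET), ncol = dimension,
           dimnames = list(AA_ALPHABET, NULL))
  })
  name <- sprintf("synthetic(dim=%d,window=%d,seed=%d)",
                  dimension, context_window, seed)
  embed <- function(seq) {
    stopifnot(inherits(seq, "protein_sequence"))
    chars <- seq_chars(seq)
    m <- length(chars)
    idx <- match(chars, AA_ALPHABET)
    values <- base[idx, , drop = FALSE]
    if (context_window >= 1L) {
      for (o in seq_len(context_window)) {
        w <- decay^o
        # neighbours at offset -o and +o, clipped at the sequence ends
        left <- idx[pmax(seq_len(m) - o, 1L)]
        right <- idx[pmin(seq_len(m) + o, m)]
        left_ok <- seq_len(m) - o >= 1L
        right_ok <- seq_len(m) + o <= m
        values <- values +
          w * (base[left, , drop = FALSE] * left_ok +
               base[right, , drop = FALSE] * right_ok)
      }
    }
    rownames(values) <- NULL
    check_embedding(values, seq, name)
  }
  structure(list(name = name, dimension = dimension,
                 context_window = context_window, seed = seed,
                 decay = decay, base_vectors = base, embed = embed),
            class = "embedding_provider")
}

#' @export
print.embedding_provider <- function(x, ...) {
  cat("<embedding_provider> ", x$name, " (dimension ", x$dimension, ")\n",
      sep = "")
  invisible(x)
}

# Validate the provider shape contract: one row per residue, no zero rows
# (cosine similarity is undefined for the zero vector).
check_embedding <- function(values, seq, model_name) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("embedding for '", seq$id, "' is not a numeric matrix",
         call. = FALSE)
  if (nrow(values) != nchar(seq$residues))
    stop("embedding for '", seq$id, "' has ", nrow(values),
         " rows but the sequence has ", nchar(seq$residues), " residues",
         call. = FALSE)
  norms <- sqrt(rowSums(values^2))
  if (any(norms == 0))
    stop("embedding for '", seq$id, "' from ", model_name,
         " contains all-zero row(s): ",
         paste(which(norms == 0), collapse = ", "), call. = FALSE)
  structure(values, model_name = model_name)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' One-shot synthetic embedding
#'
#' Convenience wrapper building a [synthetic_embedder()] and embedding a
#' single sequence with it.
#'
#' @inheritParams synthetic_embedder
#' @param seq A [protein_sequence()].
#' @return Numeric embedding matrix with one row per residue.
#' @examples
#' synthetic_embed(protein_sequence("p", "ARA"), dimension = 8,
#'                 context_window = 0, seed = 3)
#' @export
synthetic_embed <- function(seq, dimension = 32L, context_window = 2L,
                            seed = 1L, decay = 0.5) {
  synthetic_embedder(dimension, context_window, seed, decay)$embed(seq)
}

# Registry of external model adapters (real protein language models).
.model_registry <- new.env(parent = emptyenv())

#' Register an external embedding-model adapter
#'
#' Adapters wrap real protein language models (ProtT5, ESM2, ...).  The
#' adapter function receives a residue string that has already been mapped
#' for common model vocabularies (`U -> C`, `O -> K`, `B/Z -> X` by default)
#' and must return one embedding row per residue with any special/boundary
#' tokens stripped.
#'
#' @param name Model name used as the cache key and in provenance labels.
#' @param fun Function `(residue_string) -> numeric matrix`.
#' @param vocabulary_map Named character vector of residue substitutions
#'   applied before calling `fun`; set to `NULL` to disable.
#' @return The adapter, invisibly.
#' @export
register_embedding_model <- function(name, fun,
                                     vocabulary_map = c(U = "C", O = "K",
                                                        B = "X", Z = "X")) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, list(fun = fun, vocabulary_map = vocabulary_map),
         envir = .model_registry)
  invisible(fun)
}

#' Embed a sequence with a registered external model
#'
#' Looks the model up in the adapter registry, applies the adapter's
#' vocabulary mapping, and validates the shape contract (one row per
#' residue, no zero rows).  Results are cached when a cache is supplied,
#' and a cache hit skips recomputation entirely.
#'
#' @param seq A [protein_sequence()].
#' @param model_name Name of a model registered with
#'   [register_embedding_model()].
#' @param cache Optional [embedding_cache()].
#' @return Numeric embedding matrix with one row per residue.
#' @export
model_embed <- function(seq, model_name, cache = NULL) {
  stopifnot(inherits(seq, "protein_sequence"))
  if (!exists(model_name, envir = .model_registry, inherits = FALSE))
    stop("no embedding model '", model_name, "' is registered. ",
         "Register an adapter with register_embedding_model(), or use the ",
         "offline synthetic_embedder() which needs no model download.",
         call. = FALSE)
  if (!is.null(cache)) {
    hit <- cache_get(cache, model_name, seq)
    if (!is.null(hit)) return(check_embedding(hit, seq, model_name))
  }
  adapter <- get(model_name, envir = .model_registry)
  residues <- seq$residues
  if (!is.null(adapter$vocabulary_map)) {
    map <- adapter$vocabulary_map
    residues <- chartr(paste(names(map), collapse = ""),
                       paste(unname(map), collapse = ""), residues)
  }
  values <- adapter$fun(residues)
  values <- check_embedding(values, seq, model_name)
  if (!is.null(cache)) cache_put(cache, model_name, seq, values)
  values
}
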
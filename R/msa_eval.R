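#' Evaluation configuration
#'
#' Settings for [evaluate_msa()]: how many row pairs to sample, the RNG
#' seed, the alignment mode, which distances to compute, and the Wilcoxon
#' significance threshold.
#'
#' @param max_pairs Maximum number of sequence pairs sampled from the MSA
#'   (all pairs are used when there are fewer).
#' @param seed Integer seed controlling pair sampling.
#' @param mode Alignment mode, `"semiglobal"` (default) or `"global"`.
#' @param metrics Distances to compute, subset of
#'   `c("cc", "d", "pos", "seq", "ssp")`.
#' @param p_threshold Significance threshold for the paired Wilcoxon
#'   signed-rank tests, in (0, 1).
#' @return List of class `evaluation_config`.
#' @export
evaluation_config <- function(max_pairs = 1000L, seed = 1L,
                              mode = c("semiglobal", "global"),
                              metrics = c("cc", "d", "pos", "seq", "ssp"),
                              p_threshold = 0.01) {
  mode <- match.arg(mode)
  metrics <- match.arg(metrics, several.ok = TRUE)
  stopifnot(max_pairs >= 1L, p_threshold > 0, p_threshold < 1)
  structure(list(max_pairs = as.integer(max_pairs), seed = as.integer(seed),
                 mode = mode, metrics = metrics, p_threshold = p_threshold),
            class = "evaluation_config")
}

#' Sample sequence pairs from an MSA
#'
#' Uniform sampling without replacement from all unordered row pairs.  When
#' the MSA has `max_pairs` or fewer pairs, all pairs are returned in a
#' deterministic order; otherwise a seeded uniform subsample is drawn.
#'
#' @param x An [msa()].
#' @param max_pairs Maximum number of pairs.
#' @param seed Integer seed.
#' @return Two-column integer matrix of row indices, one pair per row.
#' @export
sample_pairs <- function(x, max_pairs = 1000L, seed = 1L) {
  stopifnot(inherits(x, "msa"), length(x$ids) >= 2L)
  all_pairs <- t(combn(length(x$ids), 2L))
  if (nrow(all_pairs) <= max_pairs) return(all_pairs)
  keep <- with_local_seed(seed,
                          sample.int(nrow(all_pairs), max_pairs))
  all_pairs[sort(keep), , drop = FALSE]
}

# Exact per-pair comparison with ties at a tight tolerance (exact ties do
# occur: different scorers can produce the identical alignment).
compare_tally <- function(a, b, tol = 1e-12) {
  d <- a - b
  c(better = sum(d < -tol), equal = sum(abs(d) <= tol),
    worse = sum(d > tol))
}

#' Evaluate scoring schemes against a reference MSA
#'
#' The central benchmark loop: sample sequence pairs from a reference MSA,
#' align each pair under every scoring scheme, measure the distance of each
#' computed alignment to the MSA-induced reference alignment, and aggregate
#' -- per-metric means per scorer, paired Wilcoxon signed-rank p-values
#' between scorers, and better/equal/worse tallies.  The design is fully
#' paired: every sampled pair contributes to every scorer or (if any scorer
#' fails on it) to none.
#'
#' @param x An [msa()].
#' @param scorers Named list of scorer factories; each is a function
#'   `(p, q)` returning a `scoring_model` for that sequence pair.
#' @param cfg An [evaluation_config()].
#' @return List of class `evaluation_result` with elements `per_pair`
#'   (long data frame: pair, scorer, one column per metric), `means`
#'   (scorer x metric), `wilcoxon` (one row per scorer pair and metric),
#'   `tallies` (better/equal/worse counts per scorer pair and metric) and
#'   `config`.
#' @export
evaluate_msa <- function(x, scorers, cfg = evaluation_config()) {
  stopifnot(inherits(x, "msa"), is.list(scorers), length(scorers) >= 1L,
            !is.null(names(scorers)), all(nzchar(names(scorers))))
  pairs <- sample_pairs(x, cfg$max_pairs, cfg$seed)
  snames <- names(scorers)
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    p <- msa_sequence(x, i); q <- msa_sequence(x, j)
    ref <- induced_pairwise(x, i, j)
    rec <- vector("list", length(scorers))
    ok <- TRUE
    for (s in seq_along(scorers)) {
      dist <- tryCatch({
        model <- scorers[[s]](p, q)
        res <- align_pair(p, q, model, cfg$mode)
        alignment_distances(res$alignment, ref, cfg$metrics)
      }, error = function(e) {
        warning("scorer '", snames[s], "' failed on pair (", x$ids[i],
                ", ", x$ids[j], "): ", conditionMessage(e),
                "; pair excluded from all scorers", call. = FALSE)
        NULL
      })
      if (is.null(dist)) { ok <- FALSE; break }
      rec[[s]] <- data.frame(pair = k, row_i = i, row_j = j,
                             scorer = snames[s], t(dist))
    }
    if (ok) rows <- c(rows, rec)
  }
  if (length(rows) == 0L)
    stop("no sequence pair could be evaluated by all scorers", call. = FALSE)
  per_pair <- do.call(rbind, rows)
  rownames(per_pair) <- NULL

  means <- do.call(rbind, lapply(snames, function(s) {
    sub <- per_pair[per_pair$scorer == s, cfg$metrics, drop = FALSE]
    data.frame(scorer = s, t(colMeans(sub)))
  }))

  wil <- list(); tal <- list()
  if (length(snames) >= 2L) {
    for (ab in utils::combn(snames, 2L, simplify = FALSE)) {
      va <- per_pair[per_pair$scorer == ab[1L], cfg$metrics, drop = FALSE]
      vb <- per_pair[per_pair$scorer == ab[2L], cfg$metrics, drop = FALSE]
      for (mt in cfg$metrics) {
        diffs <- va[[mt]] - vb[[mt]]
        pval <- if (all(diffs == 0)) NA_real_ else
          suppressWarnings(
            wilcox.test(va[[mt]], vb[[mt]], paired = TRUE)$p.value)
        wil[[length(wil) + 1L]] <-
          data.frame(scorer_a = ab[1L], scorer_b = ab[2L], metric = mt,
                     p_value = pval,
                     significant = !is.na(pval) & pval < cfg$p_threshold)
        tl <- compare_tally(va[[mt]], vb[[mt]])
        tal[[length(tal) + 1L]] <-
          data.frame(scorer_a = ab[1L], scorer_b = ab[2L], metric = mt,
                     better = tl["better"], equal = tl["equal"],
                     worse = tl["worse"], row.names = NULL)
      }
    }
  }
  structure(list(per_pair = per_pair, means = means,
                 wilcoxon = if (length(wil)) do.call(rbind, wil) else NULL,
                 tallies = if (length(tal)) do.call(rbind, tal) else NULL,
                 config = cfg),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("<evaluation_result> ", length(unique(x$per_pair$pair)),
      " pairs, mode ", x$config$mode, "\n", sep = "")
  print(x$means, row.names = FALSE)
  if (!is.null(x$wilcoxon)) {
    cat("Paired Wilcoxon signed-rank tests:\n")
    print(x$wilcoxon, row.names = FALSE)
  }
  invisible(x)
}

#' Aligned and unaligned average E-score matrices
#'
#' Summarizes what an embedding scorer looks like on an MSA, for comparison
#' with fixed substitution matrices: residue pairs are sampled either from
#' the same MSA column ("aligned") or from different columns ("unaligned"),
#' and the mean E-score per amino-acid pair is accumulated into two 20x20
#' matrices.  Samples for (a, b) and (b, a) are pooled, so both matrices
#' are symmetric by construction; a pair of amino acids never sampled is
#' `NA` (flagged missing, not zero).  Unaligned draws may come from any
#' rows, including the same row; the number of same-row draws is reported.
#'
#' @param x An [msa()].
#' @param provider An `embedding_provider`.
#' @param n_samples Number of sampled residue pairs per category.
#' @param seed Integer seed.
#' @return List with `aligned` and `unaligned` (20x20 mean-score matrices
#'   carrying attributes `n_samples` and, for unaligned, `same_row`), and
#'   `n_samples`.
#' @export
average_score_matrices <- function(x, provider, n_samples = 100000L,
                                   seed = 1L) {
  stopifnot(inherits(x, "msa"), inherits(provider, "embedding_provider"),
            n_samples >= 1L)
  nr <- length(x$ids)
  # Normalized embedding rows for every residue cell of the MSA.
  cells <- list()   # per row: list(cols, letters, rows of unit vectors)
  for (r in seq_len(nr)) {
    seqr <- msa_sequence(x, r)
    emb <- provider$embed(seqr)
    emb <- emb / sqrt(rowSums(emb^2))
    chars <- seq_chars(x$rows[r])
    cols <- which(chars != GAP)
    std <- chars[cols] %in% AA_STANDARD
    cells[[r]] <- list(col = cols[std], letter = chars[cols][std],
                       unit = emb[std, , drop = FALSE])
  }
  col_index <- unlist(lapply(cells, `[[`, "col"))
  row_index <- rep(seq_len(nr), vapply(cells, function(z) length(z$col),
                                       integer(1L)))
  letters_all <- unlist(lapply(cells, `[[`, "letter"))
  units <- do.call(rbind, lapply(cells, `[[`, "unit"))
  ncell <- length(col_index)
  if (ncell < 2L)
    stop("MSA has fewer than two standard-residue cells", call. = FALSE)

  accumulate <- function(ia, ib) {
    score <- rowSums(units[ia, , drop = FALSE] * units[ib, , drop = FALSE])
    score <- pmin(1, pmax(-1, score))
    la <- letters_all[ia]; lb <- letters_all[ib]
    key <- ifelse(la <= lb, paste0(la, lb), paste0(lb, la))
    sums <- tapply(score, key, sum)
    cnts <- tapply(score, key, length)
    m <- matrix(NA_real_, 20L, 20L,
                dimnames = list(AA_STANDARD, AA_STANDARD))
    for (k in names(sums)) {
      a <- substr(k, 1L, 1L); b <- substr(k, 2L, 2L)
      m[a, b] <- m[b, a] <- sums[[k]] / cnts[[k]]
    }
    m
  }

  with_local_seed(seed, {
    # aligned: same column, different rows
    tab <- split(seq_len(ncell), col_index)
    tab <- tab[vapply(tab, function(ix)
      length(unique(row_index[ix])) >= 2L, logical(1L))]
    if (length(tab) == 0L)
      stop("no MSA column holds two standard residues from distinct rows",
           call. = FALSE)
    pick_col <- sample(length(tab), n_samples, replace = TRUE)
    ia <- integer(n_samples); ib <- integer(n_samples)
    for (s in seq_len(n_samples)) {
      ix <- tab[[pick_col[s]]]
      repeat {
        two <- ix[sample.int(length(ix), 2L)]
        if (row_index[two[1L]] != row_index[two[2L]]) break
      }
      ia[s] <- two[1L]; ib[s] <- two[2L]
    }
    aligned <- accumulate(ia, ib)
    attr(aligned, "n_samples") <- n_samples

    # unaligned: different columns, any rows
    ua <- integer(n_samples); ub <- integer(n_samples)
    for (s in seq_len(n_samples)) {
      repeat {
        two <- sample.int(ncell, 2L)
        if (col_index[two[1L]] != col_index[two[2L]]) break
      }
      ua[s] <- two[1L]; ub[s] <- two[2L]
    }
    unaligned <- accumulate(ua, ub)
    attr(unaligned, "n_samples") <- n_samples
    attr(unaligned, "same_row") <- sum(row_index[ua] == row_index[ub])

    list(aligned = aligned, unaligned = unaligned, n_samples = n_samples)
  })
}

#' Pearson correlation between two substitution-score matrices
#'
#' Correlates the 210 upper-triangle-with-diagonal cells of two symmetric
#' 20x20 score matrices (e.g. an averaged E-score matrix against a BLOSUM
#' matrix rescaled to `[-1, 1]`).
#'
#' @param m1,m2 Numeric matrices of identical shape.
#' @return Pearson correlation over the vectorized upper triangle.
#' @export
matrix_correlation <- function(m1, m2) {
  stopifnot(is.matrix(m1), is.matrix(m2))
  if (!all(dim(m1) == dim(m2)))
    stop("matrices have different shapes", call. = FALSE)
  ut <- upper.tri(m1, diag = TRUE)
  v1 <- m1[ut]; v2 <- m2[ut]
  bad <- which(is.na(v1) | is.na(v2))
  if (length(bad) > 0L) {
    cellnames <- outer(rownames(m1), colnames(m1), paste0)[ut]
    stop("missing cells in compared matrices: ",
         paste(cellnames[bad], collapse = ", "), call. = FALSE)
  }
  cor(v1, v2)
}

#' Rescale a substitution matrix to the cosine range
#'
#' Divides all entries by the maximum absolute entry, mapping a BLOSUM-type
#' integer matrix into `[-1, 1]` for heatmap or correlation comparison with
#' averaged E-score matrices.
#'
#' @param matrix A `substitution_matrix` or plain numeric matrix.
#' @return Numeric matrix over the 20 standard amino acids.
#' @export
scale_substitution_matrix <- function(matrix) {
  m <- if (inherits(matrix, "substitution_matrix")) matrix$scores else matrix
  m <- m[AA_STANDARD, AA_STANDARD]
  m / max(abs(m))
}
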
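# Feature engineering: keep candidate signature genes that survived
# degradation (median TIN > threshold), z-normalize expression per gene
# within the cohort at hand, then encode each ordered gene pair as a binary
# indicator z[a] > z[b]. The pair encoding is invariant to any per-gene
# strictly increasing affine transform of the input, which is what makes a
# model trained on one platform (FF RNA-seq TPM) applicable to another
# (FFPE RNA-seq, microarray) without joint renormalization.

#' Log-transform an expression table
#'
#' Elementwise `log2(x + 1)`. Applied by default to TPM-scale inputs before
#' z-normalization; skip it for data already on a log scale (microarray).
#'
#' @param x Expression tibble (`gene_id` + sample columns), values >= 0.
#' @return A tibble of the same shape on the log2 scale.
#' @export
log_transform <- function(x) {
  m <- as_matrix(x)
  if (any(m < 0)) abort("`x` has negative values; log_transform expects abundances")
  matrix_tibble(log2(m + 1), id_col = names(x)[1])
}

#' Z-normalize expression per gene across samples
#'
#' Per gene, subtracts the mean over samples and divides by the sample
#' standard deviation (n - 1 denominator). Constant genes become all-zero
#' rows (with a warning). Normalization is cohort-internal: each dataset
#' (training cohort, each test cohort) is standardized independently, which
#' is what absorbs protocol- and platform-level shifts.
#'
#' @param x Expression tibble with at least two sample columns.
#' @return A tibble of z-scores with the same ids.
#' @export
zscore_genes <- function(x) {
  m <- as_matrix(x)
  if (ncol(m) < 2) {
    abort(paste(
      "z-normalization needs a cohort of >= 2 samples;",
      "single-sample classification is unsupported - classify samples in cohort mode"
    ))
  }
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  constant <- s == 0 | is.na(s)
  if (any(constant)) {
    warn(sprintf("%d constant gene(s) mapped to all-zero z-scores", sum(constant)))
    s[constant] <- 1
  }
  z <- (m - mu) / s
  z[constant, ] <- 0
  matrix_tibble(z, id_col = names(x)[1])
}

#' Select well-preserved feature genes by median TIN
#'
#' Keeps the candidate signature genes whose median TIN across samples is
#' strictly greater than `threshold` (default 20). Candidates absent from
#' the TIN table are dropped with a warning. The result is sorted
#' lexicographically; its order is part of the downstream model contract.
#'
#' @param candidates Character vector of candidate gene ids (e.g. the union
#'   of published CMS signature lists, or [candidate_genes()] of a simulated
#'   cohort).
#' @param gene_tin Wide gene-by-sample TIN tibble.
#' @param threshold Median-TIN cutoff; strictly-greater rule (default 20).
#' @return An object of class `feature_gene_set`: sorted unique `genes` plus
#'   provenance (`threshold`, `n_candidates`, `missing`, `median_tin`).
#' @export
select_feature_genes <- function(candidates, gene_tin, threshold = 20) {
  candidates <- unique(as.character(candidates))
  if (length(candidates) == 0) abort("`candidates` is empty")
  tin_m <- as_matrix(gene_tin)
  missing <- setdiff(candidates, rownames(tin_m))
  if (length(missing) == length(candidates)) {
    abort("no candidate gene is present in the TIN table")
  }
  if (length(missing) > 0) {
    warn(sprintf("%d candidate gene(s) absent from the TIN table were dropped: %s",
                 length(missing), paste(head(missing, 5), collapse = ", ")))
  }
  present <- setdiff(candidates, missing)
  med <- apply(tin_m[present, , drop = FALSE], 1, median, na.rm = TRUE)
  keep <- names(med)[!is.na(med) & med > threshold]
  if (length(keep) == 0) {
    abort(sprintf("no candidate gene has median TIN > %s; nothing to classify with",
                  format(threshold)))
  }
  structure(list(
    genes = sort(keep),
    threshold = threshold,
    n_candidates = length(candidates),
    missing = missing,
    median_tin = med[sort(keep)]
  ), class = "feature_gene_set")
}

#' @export
print.feature_gene_set <- function(x, ...) {
  cat("<feature_gene_set>", length(x$genes), "of", x$n_candidates,
      "candidates with median TIN >", x$threshold, "\n")
  invisible(x)
}

# Accept either a feature_gene_set or a plain character vector of genes.
feature_gene_ids <- function(genes) {
  if (inherits(genes, "feature_gene_set")) genes$genes else sort(unique(as.character(genes)))
}

#' Restrict an expression table to the feature genes
#'
#' Cross-platform application: subsets `x` to the feature genes; genes
#' absent from `x` are injected as constant zero rows (which become z = 0
#' after [zscore_genes()], so every pair involving them falls back to the
#' sign of the partner's z-score) and reported with a warning. Fails when
#' more than `max_missing_frac` of the feature genes are absent.
#'
#' @param x Expression tibble.
#' @param genes A `feature_gene_set` or character vector.
#' @param max_missing_frac Tolerated fraction of absent feature genes
#'   (default 0.2).
#' @return Expression tibble with exactly the feature genes as rows (sorted);
#'   attribute `missing_genes` lists the padded genes.
#' @export
align_features <- function(x, genes, max_missing_frac = 0.2) {
  genes <- feature_gene_ids(genes)
  m <- as_matrix(x)
  missing <- setdiff(genes, rownames(m))
  frac <- length(missing) / length(genes)
  if (frac > max_missing_frac) {
    abort(sprintf(
      "%d of %d feature genes (%.0f%%) missing from input, above the %.0f%% limit: %s",
      length(missing), length(genes), 100 * frac, 100 * max_missing_frac,
      paste(head(missing, 10), collapse = ", ")
    ))
  }
  if (length(missing) > 0) {
    warn(sprintf("%d missing feature gene(s) padded as constant rows: %s",
                 length(missing), paste(head(missing, 10), collapse = ", ")))
    pad <- matrix(0, length(missing), ncol(m),
                  dimnames = list(missing, colnames(m)))
    m <- rbind(m, pad)
  }
  out <- matrix_tibble(m[genes, , drop = FALSE], id_col = names(x)[1])
  attr(out, "missing_genes") <- missing
  out
}

#' Encode z-scores as binary gene-pair features
#'
#' For every ordered pair of feature genes `(a, b)` with `a < b`
#' lexicographically, the feature of sample s is `1` if `z[a, s] > z[b, s]`
#' and `0` otherwise (ties encode 0). The m(m-1)/2 pair columns appear in
#' lexicographic pair order, which is part of the model contract.
#'
#' @param z Standardized expression tibble ([zscore_genes()] output).
#' @param genes A `feature_gene_set` or character vector; all genes must be
#'   present in `z` (run [align_features()] before [zscore_genes()] if not).
#' @return A tibble with `sample_id` and one 0/1 integer column per pair,
#'   named `(a,b)`; attribute `feature_genes` records the gene order.
#' @export
encode_gene_pairs <- function(z, genes) {
  genes <- feature_gene_ids(genes)
  if (length(genes) < 2) abort("need at least 2 feature genes to form pairs")
  zm <- as_matrix(z)
  missing <- setdiff(genes, rownames(zm))
  if (length(missing) > 0) {
    abort(sprintf(
      "feature gene(s) missing from the matrix (run align_features first): %s",
      paste(head(missing, 10), collapse = ", ")
    ))
  }
  zm <- zm[genes, , drop = FALSE]
  idx <- combn(length(genes), 2L)
  pair_ids <- sprintf("(%s,%s)", genes[idx[1, ]], genes[idx[2, ]])
  feat <- t((zm[idx[1, ], , drop = FALSE] > zm[idx[2, ], , drop = FALSE]) * 1L)
  colnames(feat) <- pair_ids
  out <- dplyr::bind_cols(
    tibble(sample_id = colnames(zm)),
    as_tibble(feat, .name_repair = "minimal")
  )
  attr(out, "feature_genes") <- genes
  out
}

#' Full expression-to-pair-features transform
#'
#' Convenience wrapper chaining [align_features()], optional
#' [log_transform()], [zscore_genes()] and [encode_gene_pairs()] for one
#' cohort. Each cohort passed through this function is standardized
#' internally and independently.
#'
#' @param x Expression tibble (non-negative abundances).
#' @param genes A `feature_gene_set` or character vector.
#' @param log2p1 Apply `log2(x + 1)` first (default `TRUE`; set `FALSE` for
#'   inputs already on a log scale).
#' @param max_missing_frac Passed to [align_features()].
#' @return Pair-feature tibble as from [encode_gene_pairs()].
#' @export
pair_features <- function(x, genes, log2p1 = TRUE, max_missing_frac = 0.2) {
  aligned <- align_features(x, genes, max_missing_frac = max_missing_frac)
  if (log2p1) aligned <- log_transform(aligned)
  z <- suppressWarnings(zscore_genes(aligned)) # padded rows warn upstream
  encode_gene_pairs(z, genes)
}
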
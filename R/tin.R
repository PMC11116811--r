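# Transcript integrity number (TIN): an entropy-based score of how uniform
# read coverage is along a transcript. With depths c_1..c_k at k sampled
# positions, p_i = c_i / sum(c), H = -sum(p_i log p_i) over p_i > 0, and
# TIN = 100 * exp(H) / k. Uniform coverage gives exp(H) = k, hence TIN = 100;
# a single covered position gives H = 0, hence TIN = 100/k. The score is the
# effective percentage of the transcript with uniform coverage and proxies
# the RNA integrity of that transcript.

#' Transcript integrity number of one coverage vector
#'
#' @param depths Numeric vector of non-negative read depths at the sampled
#'   mRNA positions, ordered 5' to 3'. Length k >= 1.
#' @return TIN score in \[0, 100\]. Zero total coverage returns 0; exactly
#'   uniform coverage returns 100.
#' @export
#' @examples
#' transcript_tin(rep(5, 100)) # uniform -> 100
#' transcript_tin(c(7, rep(0, 49))) # single spike, k = 50 -> 2
transcript_tin <- function(depths) {
  if (!is.numeric(depths) || length(depths) == 0) {
    abort("`depths` must be a non-empty numeric vector")
  }
  if (anyNA(depths)) abort("`depths` contains missing values")
  if (any(depths < 0)) abort("`depths` contains negative values")
  total <- sum(depths)
  if (total == 0) return(0)
  k <- length(depths)
  if (all(depths == depths[1])) return(100) # exactly uniform, exp(H) = k
  p <- depths / total
  p <- p[p > 0] # 0 * log(0) := 0
  h <- -sum(p * log(p))
  min(100, 100 * exp(h) / k) # cap guards rounding at near-uniform coverage
}

#' Positions sampled along a spliced transcript
#'
#' Coverage is read every `step` nucleotides along the spliced mRNA, with the
#' first and last positions always included, mirroring the sampling
#' convention of reference TIN tooling.
#'
#' @param exon_lengths Positive integer lengths of the transcript's exons.
#' @param step Sampling step in nucleotides (default 10).
#' @return Strictly increasing integer positions in 1..total length.
#' @export
#' @examples
#' sample_positions(25) # 1 11 21 25
sample_positions <- function(exon_lengths, step = 10) {
  if (!is.numeric(step) || length(step) != 1 || step <= 0) {
    abort("`step` must be a single positive number")
  }
  if (!is.numeric(exon_lengths) || length(exon_lengths) == 0 ||
      any(exon_lengths < 1)) {
    abort("`exon_lengths` must be positive integers")
  }
  len <- sum(exon_lengths)
  sort(unique(c(seq(1, len, by = step), len)))
}

#' TIN scores for a table of coverage vectors
#'
#' @param coverage Tibble with columns `transcript_id`, `sample_id` and a
#'   list-column `depths` (see [read_coverage()]).
#' @return The input with added columns `tin` and `mean_depth`.
#' @export
tin_scores <- function(coverage) {
  coverage$tin <- vapply(coverage$depths, transcript_tin, numeric(1))
  coverage$mean_depth <- vapply(coverage$depths, mean, numeric(1))
  coverage
}

#' Transcript-by-sample TIN table from coverage
#'
#' Transcripts whose mean depth in a sample falls below `min_cov` get a
#' missing TIN in that sample (below the coverage floor), matching the
#' convention of reference TIN tooling.
#'
#' @param coverage Coverage tibble, or the output of [tin_scores()].
#' @param min_cov Minimum mean depth for a transcript to receive a score
#'   (default 10).
#' @return A wide tibble: `transcript_id` plus one column per sample, values
#'   TIN in \[0, 100\] or `NA`.
#' @export
tin_table <- function(coverage, min_cov = 10) {
  if (!"tin" %in% names(coverage)) coverage <- tin_scores(coverage)
  scored <- dplyr::mutate(
    coverage,
    tin = dplyr::if_else(.data$mean_depth >= min_cov, .data$tin, NA_real_)
  )
  tidyr::pivot_wider(
    scored[, c("transcript_id", "sample_id", "tin")],
    names_from = "sample_id", values_from = "tin"
  )
}

#' Median TIN of one sample
#'
#' The sample-level quality summary (medTIN): the median TIN over scored
#' transcripts of a sample. When a mean-depth table is supplied, transcripts
#' below `min_cov` in that sample are excluded first; otherwise the coverage
#' floor applied when the TIN table was built is taken as given.
#'
#' @param tins Wide TIN tibble (row id + one column per sample).
#' @param sample Sample id (must be a column of `tins`).
#' @param mean_depth Optional wide mean-depth tibble with the same shape.
#' @param min_cov Mean-depth floor used with `mean_depth` (default 10).
#' @return The median TIN, or `NA` if no transcript qualifies.
#' @export
sample_median_tin <- function(tins, sample, mean_depth = NULL, min_cov = 10) {
  if (!sample %in% names(tins)[-1]) {
    abort(sprintf("sample '%s' not found in TIN table", sample))
  }
  v <- tins[[sample]]
  if (!is.null(mean_depth)) {
    d <- mean_depth[[sample]][match(tins[[1]], mean_depth[[1]])]
    v[is.na(d) | d < min_cov] <- NA_real_
  }
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA_real_)
  median(v)
}

#' Aggregate transcript TINs to gene level
#'
#' The degradation filter operates on genes while TIN is defined per
#' transcript. Two aggregation modes are provided: `max_coverage` (default)
#' takes, per gene and sample, the TIN of the most-covered transcript
#' (requires `mean_depth`; ties resolved toward the first transcript in row
#' order); `mean` averages the non-missing transcript TINs.
#'
#' @param tins Wide transcript-by-sample TIN tibble.
#' @param gene_map Tibble with columns `transcript_id`, `gene_id`; every
#'   transcript must map to at most one gene.
#' @param aggregate `"max_coverage"` or `"mean"`.
#' @param mean_depth Wide transcript-by-sample mean-depth tibble, required
#'   for `max_coverage` when any gene has several transcripts.
#' @return A wide gene-by-sample TIN tibble (`gene_id` + sample columns).
#' @export
gene_tin <- function(tins, gene_map,
                     aggregate = c("max_coverage", "mean"),
                     mean_depth = NULL) {
  aggregate <- match.arg(aggregate)
  map <- unique(gene_map[, c("transcript_id", "gene_id")])
  if (anyDuplicated(map$transcript_id)) {
    dup <- map$transcript_id[duplicated(map$transcript_id)][1]
    abort(sprintf("transcript '%s' maps to more than one gene", dup))
  }
  gene <- map$gene_id[match(tins$transcript_id, map$transcript_id)]
  keep <- !is.na(gene)
  tins <- tins[keep, , drop = FALSE]
  gene <- gene[keep]
  samples <- names(tins)[-1]
  tin_m <- as_matrix(tins)

  if (aggregate == "mean") {
    agg <- rowsum(ifelse(is.na(tin_m), 0, tin_m), gene) /
      rowsum((!is.na(tin_m)) * 1, gene)
    agg[is.nan(agg)] <- NA_real_
  } else {
    multi <- any(duplicated(gene))
    if (multi && is.null(mean_depth)) {
      abort("`mean_depth` is required for max_coverage aggregation of multi-transcript genes")
    }
    if (is.null(mean_depth)) {
      agg <- tin_m
      rownames(agg) <- gene
    } else {
      dep <- as.matrix(mean_depth[, -1, drop = FALSE])
      rownames(dep) <- as.character(mean_depth[[1]])
      dep <- dep[tins$transcript_id, samples, drop = FALSE]
      genes <- sort(unique(gene))
      agg <- matrix(NA_real_, length(genes), length(samples),
                    dimnames = list(genes, samples))
      for (g in genes) {
        rows <- which(gene == g)
        for (j in seq_along(samples)) {
          d <- dep[rows, j]
          if (all(is.na(d))) next
          agg[g, j] <- tin_m[rows[which.max(d)], j]
        }
      }
    }
  }
  agg <- agg[order(rownames(agg)), , drop = FALSE]
  matrix_tibble(agg, id_col = "gene_id")
}
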
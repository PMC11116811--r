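# Validation metrics: accuracy against a benchmark labeling, the 4x4
# contingency table, one-vs-rest sensitivity/specificity per subtype, and
# the exact binomial concordance test. Benchmark samples flagged NOLBL
# (no core call) are excluded; the denominator actually used is always
# carried in the result.

# Inner-join calls and benchmark on sample_id, dropping NOLBL benchmarks.
joint_labels <- function(calls, benchmark) {
  calls <- as_tibble(calls)[, c("sample_id", "cms")]
  names(calls)[2] <- "predicted"
  benchmark <- as_tibble(benchmark)[, c("sample_id", "cms")]
  names(benchmark)[2] <- "benchmark"
  j <- dplyr::inner_join(calls, benchmark, by = "sample_id")
  j <- j[j$benchmark %in% CMS_CLASSES, ]
  if (nrow(j) == 0) {
    abort("no sample has both a call and a benchmark CMS label")
  }
  j
}

#' Classification accuracy against a benchmark
#'
#' @param calls Tibble of predictions (`sample_id`, `cms`), e.g. from
#'   [predict.cms_model()].
#' @param benchmark Tibble of benchmark labels (`sample_id`, `cms`);
#'   `NOLBL` rows are excluded.
#' @return A one-row tibble: `n`, `n_concordant`, `accuracy`.
#' @export
cms_accuracy <- function(calls, benchmark) {
  j <- joint_labels(calls, benchmark)
  tibble(
    n = nrow(j),
    n_concordant = sum(j$predicted == j$benchmark),
    accuracy = mean(j$predicted == j$benchmark)
  )
}

#' Contingency table of predicted versus benchmark subtypes
#'
#' @inheritParams cms_accuracy
#' @return A `cms_contingency` object: a 4x4 integer matrix, rows = predicted
#'   CMS, columns = benchmark CMS.
#' @export
cms_contingency <- function(calls, benchmark) {
  j <- joint_labels(calls, benchmark)
  tab <- table(
    predicted = factor(j$predicted, levels = CMS_CLASSES),
    benchmark = factor(j$benchmark, levels = CMS_CLASSES)
  )
  structure(unclass(tab), class = "cms_contingency")
}

#' @export
print.cms_contingency <- function(x, ...) {
  cat("predicted (rows) vs benchmark (columns); n =", sum(x), "\n")
  print(unclass(x))
  invisible(x)
}

#' @export
tidy.cms_contingency <- function(x, ...) {
  out <- as_tibble(as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE))
  names(out) <- c("predicted", "benchmark", "n")
  out$n <- as.integer(out$n)
  out
}

#' Per-subtype sensitivity and specificity
#'
#' One-vs-rest: sensitivity = TP / (TP + FN), specificity = TN / (TN + FP)
#' for each CMS. A metric whose denominator is zero is reported as `NA`.
#'
#' @inheritParams cms_accuracy
#' @return A tibble with columns `cms`, `sensitivity`, `specificity`.
#' @export
per_class_metrics <- function(calls, benchmark) {
  j <- joint_labels(calls, benchmark)
  purrr::map_dfr(CMS_CLASSES, function(k) {
    tp <- sum(j$predicted == k & j$benchmark == k)
    fn <- sum(j$predicted != k & j$benchmark == k)
    fp <- sum(j$predicted == k & j$benchmark != k)
    tn <- sum(j$predicted != k & j$benchmark != k)
    tibble(
      cms = k,
      sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
      specificity = if (tn + fp == 0) NA_real_ else tn / (tn + fp)
    )
  })
}

#' Exact binomial concordance test
#'
#' One-sided exact test of whether `n_concordant` agreements out of
#' `n_total` exceed chance: `P = sum_{k >= n_concordant} C(n, k) p0^k
#' (1 - p0)^(n - k)`. The null concordance `p0` defaults to 0.25, uniform
#' chance agreement among the four subtypes.
#'
#' @param n_concordant Number of concordant calls.
#' @param n_total Number of jointly labeled samples (>= 1).
#' @param p0 Null concordance probability in (0, 1).
#' @return A one-row tibble: `n_total`, `n_concordant`, `p0`, `p_value`.
#' @export
#' @examples
#' concordance_binomial_test(4, 4) # P = 0.25^4
concordance_binomial_test <- function(n_concordant, n_total, p0 = 0.25) {
  if (length(p0) != 1 || !is.finite(p0) || p0 <= 0 || p0 >= 1) {
    abort("`p0` must lie strictly between 0 and 1")
  }
  if (n_total < 1 || n_concordant < 0 || n_concordant > n_total) {
    abort("need 0 <= n_concordant <= n_total and n_total >= 1")
  }
  tibble(
    n_total = as.integer(n_total),
    n_concordant = as.integer(n_concordant),
    p0 = p0,
    p_value = pbinom(n_concordant - 1, n_total, p0, lower.tail = FALSE)
  )
}

#' Full evaluation report
#'
#' Bundles [cms_accuracy()], [cms_contingency()], [per_class_metrics()] and
#' the [concordance_binomial_test()] for one predictions/benchmark pair.
#'
#' @inheritParams cms_accuracy
#' @param p0 Null concordance probability for the binomial test.
#' @return A `cms_evaluation` object (list with `accuracy`, `contingency`,
#'   `per_class`, `concordance`).
#' @export
cms_evaluate <- function(calls, benchmark, p0 = 0.25) {
  acc <- cms_accuracy(calls, benchmark)
  structure(list(
    accuracy = acc,
    contingency = cms_contingency(calls, benchmark),
    per_class = per_class_metrics(calls, benchmark),
    concordance = concordance_binomial_test(acc$n_concordant, acc$n, p0 = p0)
  ), class = "cms_evaluation")
}

#' @export
print.cms_evaluation <- function(x, ...) {
  cat(sprintf("accuracy: %.1f%% (%d/%d concordant; null p0 = %.2f, exact binomial P = %.3g)\n",
              100 * x$accuracy$accuracy, x$accuracy$n_concordant,
              x$accuracy$n, x$concordance$p0, x$concordance$p_value))
  print(x$contingency)
  print(x$per_class, n = 4)
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Emits `metrics.tsv` (long metric/value pairs, including the denominator
#' and the binomial null used) and `contingency.tsv`.
#'
#' @param x A `cms_evaluation`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(x, dir) {
  stopifnot(inherits(x, "cms_evaluation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  metrics <- dplyr::bind_rows(
    tibble(metric = c("n", "n_concordant", "accuracy", "p0", "p_value"),
           value = c(x$accuracy$n, x$accuracy$n_concordant,
                     x$accuracy$accuracy, x$concordance$p0,
                     x$concordance$p_value)),
    tibble(metric = paste0("sensitivity_", x$per_class$cms),
           value = x$per_class$sensitivity),
    tibble(metric = paste0("specificity_", x$per_class$cms),
           value = x$per_class$specificity)
  )
  readr::write_tsv(metrics, file.path(dir, "metrics.tsv"), na = "NA")
  cont <- tidy(x$contingency)
  readr::write_tsv(cont, file.path(dir, "contingency.tsv"))
  invisible(dir)
}

#' Probability of detecting a rare variant in a cohort
#'
#' Closed-form power check for cohort sizing: a variant present in a
#' fraction `prevalence` of patients is missed by all `n` samples with
#' probability `(1 - prevalence)^n`. With prevalence 3% and n = 104, the
#' miss probability is 0.97^104 <= 0.05, i.e. > 95% certainty to observe
#' the variant at least once.
#'
#' @param n Cohort size.
#' @param prevalence Variant prevalence in (0, 1) (default 0.03).
#' @return A one-row tibble: `n`, `prevalence`, `p_miss`, `p_detect`,
#'   `pct_detect`.
#' @export
variant_detection_power <- function(n, prevalence = 0.03) {
  if (prevalence <= 0 || prevalence >= 1) abort("`prevalence` must be in (0, 1)")
  if (n < 1) abort("`n` must be >= 1")
  p_miss <- (1 - prevalence)^n
  tibble(
    n = as.integer(n),
    prevalence = prevalence,
    p_miss = p_miss,
    p_detect = 1 - p_miss,
    pct_detect = 100 * (1 - p_miss)
  )
}
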
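# End-to-end simulation experiments. These are the package's own study
# design at desk scale: simulate a paired cohort, select degradation-robust
# feature genes on the training half's FFPE TIN table, train on fresh-frozen
# pair features, then measure accuracy on held-out FF data and on degraded
# FFPE data, with and without the TIN filter.

#' One simulated train/test classification experiment
#'
#' Splits a simulated cohort into training and test halves, selects feature
#' genes by median TIN on the training half's FFPE TIN table, trains the
#' random forest on the training half's fresh-frozen pair features, and
#' evaluates on the held-out half: fresh-frozen features (platform-matched
#' ceiling) and degraded FFPE features, the latter both with the TIN-filtered
#' gene set and with the full candidate set (no filter), which is the
#' original-classifier configuration the filter is measured against.
#'
#' @param cfg A [sim_config()]; `cfg$n_samples` is split in half
#'   (first half train, second half test).
#' @param threshold Median-TIN gene-selection cutoff (default 20).
#' @param n_trees,mtry,min_leaf Forest hyperparameters (see [cms_train()]).
#' @return A one-row tibble: `seed`, `n_feature_genes`, `acc_ff`,
#'   `acc_ffpe_filtered`, `acc_ffpe_all`, `oob_accuracy`.
#' @export
run_split_experiment <- function(cfg, threshold = 20, n_trees = 500,
                                 mtry = NULL, min_leaf = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_samples < 8) abort("need at least 8 samples to split")
  cohort <- simulate_cohort(cfg)
  samples <- cohort$true_labels$sample_id
  n_train <- floor(length(samples) / 2)
  train_ids <- samples[seq_len(n_train)]
  test_ids <- setdiff(samples, train_ids)

  subset_cols <- function(x, ids) x[, c(names(x)[1], ids)]
  candidates <- candidate_genes(cohort)
  fs <- select_feature_genes(candidates, subset_cols(cohort$tin, train_ids),
                             threshold = threshold)

  train_labels <- cohort$true_labels[cohort$true_labels$sample_id %in% train_ids, ]
  train_one <- function(genes) {
    feats <- pair_features(subset_cols(cohort$ff_expr, train_ids), genes)
    cms_train(feats, train_labels, n_trees = n_trees, mtry = mtry,
              min_leaf = min_leaf, seed = cfg$seed)
  }
  acc_on <- function(model, expr, genes) {
    feats <- pair_features(subset_cols(expr, test_ids), genes)
    calls <- predict(model, feats)
    cms_accuracy(calls, cohort$true_labels)$accuracy
  }

  model_filtered <- train_one(fs)
  model_all <- train_one(candidates)
  tibble(
    seed = cfg$seed,
    n_feature_genes = length(fs$genes),
    acc_ff = acc_on(model_filtered, cohort$ff_expr, fs),
    acc_ffpe_filtered = acc_on(model_filtered, cohort$ffpe_expr, fs),
    acc_ffpe_all = acc_on(model_all, cohort$ffpe_expr, candidates),
    oob_accuracy = model_filtered$manifest$oob_accuracy
  )
}

#' Multi-seed degradation-robustness benchmark
#'
#' Repeats [run_split_experiment()] over `n_seeds` independent cohorts and
#' returns the per-seed results. Median `acc_ffpe_filtered` exceeding median
#' `acc_ffpe_all` is the desk-scale analogue of the accuracy gain the
#' TIN-filtered classifier shows over the unfiltered one on degraded
#' clinical samples.
#'
#' @param n_seeds Number of independent simulated cohorts (default 20).
#' @param base_seed Seed of the first cohort; cohort i uses
#'   `base_seed + i - 1`.
#' @param cfg Cohort configuration template (default: [sim_config()] with
#'   400 samples, i.e. 200 train + 200 test).
#' @inheritParams run_split_experiment
#' @return A tibble with one row per seed (columns as in
#'   [run_split_experiment()]).
#' @export
degradation_benchmark <- function(n_seeds = 20, base_seed = 1,
                                  cfg = sim_config(n_samples = 400),
                                  threshold = 20, n_trees = 500) {
  purrr::map_dfr(seq_len(n_seeds), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer(base_seed + i - 1)
    run_split_experiment(cfg_i, threshold = threshold, n_trees = n_trees)
  })
}
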
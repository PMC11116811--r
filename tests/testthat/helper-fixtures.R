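# Small in-code fixtures shared across test files.

# A fast cohort configuration: 60 samples, 12-gene marker modules.
small_config <- function(seed = 42, ...) {
  sim_config(
    n_samples = 60,
    module_sizes = c(immune = 12, epithelial = 12, metabolic = 12,
                     stromal = 12, background = 30),
    seed = seed,
    ...
  )
}

# Deterministic tiny expression tibble: genes x samples.
toy_expression <- function(genes = c("GA", "GB", "GC"),
                           samples = c("S1", "S2", "S3", "S4"),
                           seed = 7) {
  set.seed(seed)
  m <- matrix(round(runif(length(genes) * length(samples), 0, 100), 3),
              length(genes), length(samples),
              dimnames = list(genes, samples))
  dplyr::bind_cols(
    tibble::tibble(gene_id = genes),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
}

# Random coverage tibble with k in [kmin, kmax].
random_coverage <- function(n, seed = 1, kmin = 2, kmax = 500) {
  set.seed(seed)
  tibble::tibble(
    transcript_id = sprintf("T%04d", seq_len(n)),
    sample_id = "S1",
    depths = lapply(seq_len(n), function(i) {
      k <- sample(kmin:kmax, 1)
      stats::rpois(k, lambda = stats::runif(1, 0.5, 50))
    })
  )
}
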
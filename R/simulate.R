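# Synthetic paired FF/FFPE cohorts with planted CMS structure. The fresh-
# frozen (FF) layer draws per-gene log2 abundances with a subtype-specific
# mean shift in that subtype's marker module (CMS1 -> immune, CMS2 ->
# epithelial, CMS3 -> metabolic, CMS4 -> stromal). The FFPE layer then
# applies module-specific multiplicative transcript loss with matching TIN
# scores: formalin fixation degrades immune transcripts far more than
# epithelial or stromal ones, which is the property the TIN filter exploits.

SIM_MODULES <- c("immune", "epithelial", "metabolic", "stromal", "background")
SUBTYPE_MODULE <- c(CMS1 = "immune", CMS2 = "epithelial",
                    CMS3 = "metabolic", CMS4 = "stromal")

#' Configuration for the cohort simulator
#'
#' Defaults describe a 200-sample cohort with a subtype mix approximating
#' clinical series (15/40/15/30% for CMS1..4), four 50-gene marker modules
#' plus 300 background genes, a 2-log2 activation shift against unit
#' log-normal noise, and degradation severities with the immune module
#' hardest hit (0.8) and the epithelial/stromal modules best preserved.
#'
#' @param n_samples Number of samples.
#' @param subtype_proportions Four non-negative proportions (CMS1..CMS4)
#'   summing to 1.
#' @param module_sizes Named gene counts for `immune`, `epithelial`,
#'   `metabolic`, `stromal`, `background`.
#' @param delta Log2 mean shift of a subtype's active module (effect size).
#' @param sigma Log2 expression noise standard deviation.
#' @param degradation_severity Per-module expected fraction of transcript
#'   lost in FFPE, each in \[0, 1\].
#' @param sample_quality_range Interval within (0, 1\] for the per-sample
#'   FFPE quality multiplier.
#' @param baseline_log2_range Range of per-gene baseline log2 abundances
#'   (default 2-8, i.e. roughly 3-250 TPM, typical for signature genes).
#' @param tin_noise_sd Standard deviation of the TIN measurement noise, in
#'   TIN units (default 5).
#' @param beta_concentration Concentration of the Beta distribution of
#'   per-gene retained fractions (default 10).
#' @param retention_jitter Concentration of the Beta distribution of the
#'   realized per-gene-per-sample retained fraction around its expectation
#'   `r_g * q_s` (default 2). Lower values mean noisier measurement of
#'   heavily degraded transcripts; the coefficient of variation grows as the
#'   expected retention falls, so badly degraded modules lose signal, not
#'   just scale.
#' @param dropout_scale Fragment-survival scale of library dropout (default
#'   0.15). A transcript yields no usable fragments (measured expression 0,
#'   TIN 0) with probability `exp(-retained / dropout_scale)`: heavily
#'   fragmented transcripts fall below the library's minimum usable insert
#'   regardless of their abundance. Set to 0 to disable dropout.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 200,
                       subtype_proportions = c(CMS1 = 0.15, CMS2 = 0.40,
                                               CMS3 = 0.15, CMS4 = 0.30),
                       module_sizes = c(immune = 50, epithelial = 50,
                                        metabolic = 50, stromal = 50,
                                        background = 300),
                       delta = 2,
                       sigma = 1,
                       degradation_severity = c(immune = 0.8,
                                                epithelial = 0.3,
                                                metabolic = 0.4,
                                                stromal = 0.35,
                                                background = 0.5),
                       sample_quality_range = c(0.4, 1),
                       baseline_log2_range = c(2, 8),
                       tin_noise_sd = 5,
                       beta_concentration = 10,
                       retention_jitter = 2,
                       dropout_scale = 0.15,
                       seed = 1L) {
  if (n_samples < 1) abort("`n_samples` must be positive")
  if (length(subtype_proportions) != 4 || any(subtype_proportions < 0) ||
      abs(sum(subtype_proportions) - 1) > 1e-9) {
    abort("`subtype_proportions` must be 4 non-negative values summing to 1")
  }
  names(subtype_proportions) <- CMS_CLASSES
  if (!all(SIM_MODULES %in% names(module_sizes)) || any(module_sizes < 0)) {
    abort("`module_sizes` must name non-negative counts for all five modules")
  }
  if (!all(SIM_MODULES %in% names(degradation_severity)) ||
      any(degradation_severity < 0 | degradation_severity > 1)) {
    abort("`degradation_severity` must name values in [0, 1] for all five modules")
  }
  if (delta < 0 || sigma <= 0) abort("`delta` must be >= 0 and `sigma` > 0")
  if (length(sample_quality_range) != 2 ||
      sample_quality_range[1] <= 0 || sample_quality_range[2] > 1 ||
      sample_quality_range[1] > sample_quality_range[2]) {
    abort("`sample_quality_range` must be an interval within (0, 1]")
  }
  structure(list(
    n_samples = as.integer(n_samples),
    subtype_proportions = subtype_proportions,
    module_sizes = module_sizes[SIM_MODULES],
    delta = delta,
    sigma = sigma,
    degradation_severity = degradation_severity[SIM_MODULES],
    sample_quality_range = sample_quality_range,
    baseline_log2_range = baseline_log2_range,
    tin_noise_sd = tin_noise_sd,
    beta_concentration = beta_concentration,
    retention_jitter = retention_jitter,
    dropout_scale = dropout_scale,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_samples, "samples, seed", x$seed, "\n")
  cat("  modules:", paste(sprintf("%s=%d", names(x$module_sizes),
                                  x$module_sizes), collapse = " "), "\n")
  cat("  delta =", x$delta, " sigma =", x$sigma, "\n")
  cat("  severity:", paste(sprintf("%s=%.2f", names(x$degradation_severity),
                                   x$degradation_severity), collapse = " "), "\n")
  invisible(x)
}

#' Simulate the fresh-frozen layer of a cohort
#'
#' Log2 abundance of gene g in sample s is
#' `mu_g + delta * [module(g) is active in subtype(s)] + Normal(0, sigma)`,
#' with per-gene baselines `mu_g ~ Uniform(baseline_log2_range)`. Linear
#' expression is `2^x - 1`, clipped at zero, so baseline TPM spans roughly
#' the range of true signature genes and low-abundance transcripts sit near
#' the detection floor.
#'
#' @param cfg A [sim_config()].
#' @return A list with `expr` (expression tibble), `labels`
#'   (`sample_id`, `cms`) and `gene_modules` (`gene_id`, `module`).
#' @export
simulate_ff <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sizes <- cfg$module_sizes
  if (sum(sizes[setdiff(SIM_MODULES, "background")]) == 0) {
    abort("at least one non-background gene is required")
  }
  set.seed(cfg$seed)
  prefix <- c(immune = "IMM", epithelial = "EPI", metabolic = "MET",
              stromal = "STR", background = "BG")
  gene_modules <- tibble(
    gene_id = unlist(lapply(SIM_MODULES, function(m) {
      if (sizes[[m]] == 0) return(character(0))
      sprintf("%s%04d", prefix[[m]], seq_len(sizes[[m]]))
    })),
    module = rep(SIM_MODULES, times = sizes)
  )
  n_genes <- nrow(gene_modules)
  samples <- sprintf("S%04d", seq_len(cfg$n_samples))
  labels <- sample(CMS_CLASSES, cfg$n_samples, replace = TRUE,
                   prob = cfg$subtype_proportions)
  mu <- runif(n_genes, cfg$baseline_log2_range[1], cfg$baseline_log2_range[2])
  active <- outer(gene_modules$module, SUBTYPE_MODULE[labels], `==`)
  x <- mu + cfg$delta * active + rnorm(n_genes * cfg$n_samples, 0, cfg$sigma)
  expr <- pmax(2^x - 1, 0)
  dimnames(expr) <- list(gene_modules$gene_id, samples)
  list(
    expr = matrix_tibble(expr),
    labels = tibble(sample_id = samples, cms = labels),
    gene_modules = gene_modules
  )
}

#' Degrade a fresh-frozen matrix into an FFPE matrix with TIN scores
#'
#' Each gene draws an expected retained fraction `r_g ~ Beta(mean = 1 -
#' severity(module(g)), concentration = beta_concentration)`, each sample a
#' quality multiplier `q_s ~ Uniform(sample_quality_range)`. The realized
#' retained fraction of gene g in sample s is then itself stochastic,
#' `retained_gs ~ Beta(mean = r_g * q_s, concentration = retention_jitter)`:
#' transcript survival in fixed tissue varies molecule by molecule and
#' region by region, so a heavily degraded gene is not merely scaled down
#' but measured with large relative error (Beta CV grows as the mean falls).
#' A transcript whose surviving fragments fall below the library's usable
#' insert size drops out entirely (probability `exp(-retained /
#' dropout_scale)`), leaving measured expression 0 and TIN 0. Detected
#' entries give FFPE expression `ff * retained_gs` (loss is proportional to
#' molecule counts, hence multiplicative on the linear scale) and a TIN
#' score `clip(100 * retained_gs + Normal(0, tin_noise_sd), 0, 100)`, so up
#' to dropout `E[ffpe] = ff * r_g * q_s` and `E[tin] ~ 100 * r_g * q_s`.
#'
#' @param ff Fresh-frozen expression tibble.
#' @param gene_modules Tibble `gene_id`, `module` covering every gene in `ff`.
#' @param cfg A [sim_config()]; the degradation stream is seeded with
#'   `cfg$seed + 1` so it is reproducible yet independent of the FF draw.
#' @return A list with `expr` (FFPE expression tibble) and `tin`
#'   (gene-by-sample TIN tibble).
#' @export
degrade <- function(ff, gene_modules, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ff_m <- as_matrix(ff)
  if (!setequal(rownames(ff_m), gene_modules$gene_id)) {
    abort("`gene_modules` must cover exactly the genes of `ff`")
  }
  set.seed(cfg$seed + 1L)
  module <- gene_modules$module[match(rownames(ff_m), gene_modules$gene_id)]
  sev <- cfg$degradation_severity[module]
  conc <- cfg$beta_concentration
  r <- ifelse(sev == 0, 1,
        ifelse(sev == 1, 0,
               rbeta(nrow(ff_m), (1 - sev) * conc, sev * conc)))
  q <- runif(ncol(ff_m), cfg$sample_quality_range[1], cfg$sample_quality_range[2])
  expected <- outer(r, q)
  kappa <- cfg$retention_jitter
  retained <- matrix(
    rbeta(length(expected), expected * kappa, (1 - expected) * kappa),
    nrow(expected), ncol(expected)
  )
  # Beta degenerates at the boundary; keep perfect and total loss exact.
  retained[expected == 1] <- 1
  retained[expected == 0] <- 0
  if (cfg$dropout_scale > 0) {
    detected <- runif(length(retained)) >= exp(-retained / cfg$dropout_scale)
    # fully intact transcripts are always recovered (no-degradation limit)
    retained <- retained * (detected | retained == 1)
  }
  ffpe <- ff_m * retained
  tin <- 100 * retained + rnorm(length(retained), 0, cfg$tin_noise_sd)
  tin[retained == 0] <- 0 # no coverage, no transcript integrity
  tin <- pmin(pmax(tin, 0), 100)
  dimnames(tin) <- dimnames(ffpe)
  list(expr = matrix_tibble(ffpe), tin = matrix_tibble(tin))
}

#' Simulate a paired FF/FFPE cohort
#'
#' Runs [simulate_ff()] then [degrade()] and bundles the result.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `cms_cohort`: a list with `ff_expr`,
#'   `ffpe_expr`, `tin`, `true_labels`, `gene_modules` and `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 20,
#'   module_sizes = c(immune = 5, epithelial = 5, metabolic = 5,
#'                    stromal = 5, background = 10)))
#' cohort
simulate_cohort <- function(cfg = sim_config()) {
  ff <- simulate_ff(cfg)
  deg <- degrade(ff$expr, ff$gene_modules, cfg)
  structure(list(
    ff_expr = ff$expr,
    ffpe_expr = deg$expr,
    tin = deg$tin,
    true_labels = ff$labels,
    gene_modules = ff$gene_modules,
    config = cfg
  ), class = "cms_cohort")
}

#' @export
print.cms_cohort <- function(x, ...) {
  cat("<cms_cohort>", nrow(x$ff_expr), "genes x", nrow(x$true_labels),
      "samples (paired FF/FFPE + TIN)\n")
  print(table(x$true_labels$cms))
  invisible(x)
}

#' Candidate signature genes of a simulated cohort
#'
#' The analogue of the published CMS signature-gene lists: all marker-module
#' genes (everything except background).
#'
#' @param cohort A `cms_cohort` (or a `gene_modules` tibble).
#' @return Character vector of gene ids.
#' @export
candidate_genes <- function(cohort) {
  gm <- if (inherits(cohort, "cms_cohort")) cohort$gene_modules else cohort
  gm$gene_id[gm$module != "background"]
}

#' Write or read a simulated cohort as TSV fixtures
#'
#' Emits `ff_expr.tsv`, `ffpe_expr.tsv`, `tin.tsv`, `labels.tsv` and
#' `gene_modules.tsv` in the package's standard formats; the files
#' round-trip losslessly through the corresponding readers.
#'
#' @param cohort A `cms_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory (write) or a `cms_cohort`-shaped list (read),
#'   invisibly for the writer.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cms_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$ff_expr, file.path(dir, "ff_expr.tsv"))
  write_expression(cohort$ffpe_expr, file.path(dir, "ffpe_expr.tsv"))
  write_tin(cohort$tin, file.path(dir, "tin.tsv"))
  write_labels(cohort$true_labels, file.path(dir, "labels.tsv"))
  readr::write_tsv(cohort$gene_modules, file.path(dir, "gene_modules.tsv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  gm <- readr::read_tsv(file.path(dir, "gene_modules.tsv"),
                        col_types = readr::cols(.default = readr::col_character()))
  structure(list(
    ff_expr = read_expression(file.path(dir, "ff_expr.tsv")),
    ffpe_expr = read_expression(file.path(dir, "ffpe_expr.tsv")),
    tin = read_tin(file.path(dir, "tin.tsv")),
    true_labels = read_labels(file.path(dir, "labels.tsv")),
    gene_modules = gm,
    config = NULL
  ), class = "cms_cohort")
}

#' Read a flat key-value simulator configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` comments allowed;
#' vector-valued keys use comma-separated entries, named as
#' `name1,name2=v1,v2` order of [sim_config()] defaults. Unknown keys error.
#'
#' @param path Config file path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(sim_config())
  kv <- strsplit(lines, "[=:]", perl = TRUE)
  bad <- vapply(kv, function(p) length(p) != 2, logical(1))
  if (any(bad)) abort(sprintf("malformed config line: '%s'", lines[which(bad)[1]]))
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, `[[`, character(1), 2))
  defaults <- sim_config()
  known <- setdiff(names(unclass(defaults)), character(0))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  args <- list()
  for (i in seq_along(keys)) {
    v <- as.numeric(strsplit(vals[i], ",")[[1]])
    if (anyNA(v)) abort(sprintf("non-numeric value for key '%s'", keys[i]))
    template <- defaults[[keys[i]]]
    if (!is.null(names(template)) && length(v) == length(template)) {
      names(v) <- names(template)
    }
    args[[keys[i]]] <- if (length(v) == 1 && length(template) == 1) v else v
  }
  do.call(sim_config, args)
}
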
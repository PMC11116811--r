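test_that("the simulator is a deterministic function of its configuration", {
  a <- simulate_cohort(small_config(seed = 7))
  b <- simulate_cohort(small_config(seed = 7))
  expect_identical(a$ff_expr, b$ff_expr)
  expect_identical(a$ffpe_expr, b$ffpe_expr)
  expect_identical(a$tin, b$tin)
  expect_identical(a$true_labels, b$true_labels)
  c <- simulate_cohort(small_config(seed = 8))
  expect_false(identical(a$ff_expr, c$ff_expr))
})

test_that("with zero effect size, subtype-conditional means are indistinguishable", {
  cfg <- sim_config(
    n_samples = 120, delta = 0, seed = 31,
    module_sizes = c(immune = 250, epithelial = 250, metabolic = 250,
                     stromal = 250, background = 0)
  )
  ff <- simulate_ff(cfg)
  m <- log2(as.matrix(ff$expr[, -1]) + 1)
  grp <- ff$labels$cms[match(colnames(m), ff$labels$sample_id)]
  active <- c(CMS1 = "immune", CMS2 = "epithelial",
              CMS3 = "metabolic", CMS4 = "stromal")[grp]
  module <- ff$gene_modules$module
  pvals <- vapply(seq_len(nrow(m)), function(g) {
    on <- active == module[g]
    stats::t.test(m[g, on], m[g, !on])$p.value
  }, numeric(1))
  # null case: ~5% rejections at alpha = 0.05
  expect_gt(mean(pvals < 0.05), 0.02)
  expect_lt(mean(pvals < 0.05), 0.09)
})

test_that("the planted effect size is recovered by sample means", {
  cfg <- sim_config(n_samples = 200, delta = 2, sigma = 1, seed = 13)
  ff <- simulate_ff(cfg)
  m <- log2(as.matrix(ff$expr[, -1]) + 1)
  rownames(m) <- ff$expr$gene_id
  grp <- ff$labels$cms[match(colnames(m), ff$labels$sample_id)]
  module <- ff$gene_modules$module[match(rownames(m), ff$gene_modules$gene_id)]
  active_map <- c(CMS1 = "immune", CMS2 = "epithelial",
                  CMS3 = "metabolic", CMS4 = "stromal")
  shifts <- vapply(names(active_map), function(cls) {
    rows <- module == active_map[[cls]]
    mean(m[rows, grp == cls]) - mean(m[rows, grp != cls])
  }, numeric(1))
  # 2^x - 1 clipping and the log return trip bias the recovery slightly
  # downward at low baselines; the estimator must still land within 0.2.
  expect_true(all(abs(shifts - cfg$delta) < 0.2))
})

test_that("degradation vanishes in the no-loss limit", {
  cfg <- small_config(seed = 5)
  cfg$degradation_severity[] <- 0
  cfg$sample_quality_range <- c(1, 1)
  cohort <- simulate_cohort(cfg)
  expect_equal(as.matrix(cohort$ffpe_expr[, -1]),
               as.matrix(cohort$ff_expr[, -1]), tolerance = 1e-12)
  # TIN near 100 up to measurement noise (sd 5, clipped at 100)
  expect_true(all(as.matrix(cohort$tin[, -1]) > 75))
})

test_that("immune genes are more degraded than epithelial genes in every sample", {
  cfg <- sim_config(n_samples = 100, seed = 17)
  cohort <- simulate_cohort(cfg)
  tin <- as.matrix(cohort$tin[, -1])
  rownames(tin) <- cohort$tin$gene_id
  module <- cohort$gene_modules$module[match(rownames(tin),
                                             cohort$gene_modules$gene_id)]
  imm <- apply(tin[module == "immune", ], 2, oracle_median)
  epi <- apply(tin[module == "epithelial", ], 2, oracle_median)
  expect_true(all(imm < epi))
})

test_that("TIN values always lie in [0, 100] and FFPE never exceeds FF", {
  for (seed in c(1, 2)) {
    cohort <- simulate_cohort(small_config(seed = seed))
    tin <- as.matrix(cohort$tin[, -1])
    expect_true(all(tin >= 0 & tin <= 100))
    expect_true(all(as.matrix(cohort$ffpe_expr[, -1]) <=
                      as.matrix(cohort$ff_expr[, -1]) + 1e-12))
  }
})

test_that("raising a module's severity cannot raise its expected median TIN", {
  meds <- vapply(1:20, function(seed) {
    vapply(c(lo = 0.3, hi = 0.7), function(sv) {
      cfg <- small_config(seed = seed)
      cfg$degradation_severity[["metabolic"]] <- sv
      cohort <- simulate_cohort(cfg)
      tin <- as.matrix(cohort$tin[, -1])
      rownames(tin) <- cohort$tin$gene_id
      keep <- cohort$gene_modules$gene_id[cohort$gene_modules$module == "metabolic"]
      median(tin[keep, ])
    }, numeric(1))
  }, numeric(2))
  expect_lt(mean(meds["hi", ]), mean(meds["lo", ]))
})

test_that("realized subtype counts follow the configured multinomial", {
  cfg <- sim_config(n_samples = 1000, seed = 23,
                    module_sizes = c(immune = 5, epithelial = 5, metabolic = 5,
                                     stromal = 5, background = 0))
  ff <- simulate_ff(cfg)
  counts <- table(factor(ff$labels$cms, levels = c("CMS1", "CMS2", "CMS3", "CMS4")))
  gof <- stats::chisq.test(counts, p = cfg$subtype_proportions)
  expect_gt(gof$p.value, 0.01)
})

test_that("cohort fixtures round-trip losslessly through the readers", {
  cohort <- simulate_cohort(small_config(seed = 3))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "ff_expr.tsv", "ffpe_expr.tsv", "tin.tsv", "labels.tsv", "gene_modules.tsv"
  )))))
  back <- read_cohort(dir)
  expect_equal(as.matrix(back$ff_expr[, -1]), as.matrix(cohort$ff_expr[, -1]),
               tolerance = 1e-12)
  expect_equal(as.matrix(back$tin[, -1]), as.matrix(cohort$tin[, -1]),
               tolerance = 1e-12)
  expect_equal(back$true_labels, cohort$true_labels)
  expect_equal(back$gene_modules, cohort$gene_modules)
})

test_that("fixture files have header plus one line per row, labels complete", {
  cfg <- sim_config(n_samples = 4, seed = 2,
                    module_sizes = c(immune = 3, epithelial = 3, metabolic = 2,
                                     stromal = 2, background = 0))
  cohort <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_length(readLines(file.path(dir, "ff_expr.tsv")), 11)
  expect_length(readLines(file.path(dir, "labels.tsv")), 5)
  labs <- read_labels(file.path(dir, "labels.tsv"))
  expect_equal(nrow(labs), 4)
  expect_true(all(labs$cms %in% paste0("CMS", 1:4)))
})

test_that("configuration validation rejects degenerate setups", {
  expect_error(sim_config(n_samples = 0), "positive")
  expect_error(sim_config(subtype_proportions = c(0.5, 0.5, 0.2, -0.2)),
               "summing to 1")
  expect_error(sim_config(sample_quality_range = c(0, 1)), "interval")
  expect_error(
    simulate_ff(sim_config(module_sizes = c(immune = 0, epithelial = 0,
                                            metabolic = 0, stromal = 0,
                                            background = 10))),
    "non-background"
  )
  bad <- simulate_ff(small_config())
  expect_error(degrade(bad$expr, bad$gene_modules[-1, ], small_config()),
               "exactly the genes")
})

test_that("flat key-value config files reproduce sim_config objects", {
  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c(
    "# comment",
    "n_samples = 30",
    "seed = 99",
    "delta = 1.5",
    "subtype_proportions = 0.25, 0.25, 0.25, 0.25"
  ), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_samples, 30L)
  expect_equal(cfg$seed, 99L)
  expect_equal(cfg$delta, 1.5)
  expect_equal(unname(cfg$subtype_proportions), rep(0.25, 4))
  writeLines("not_a_key = 1", path)
  expect_error(read_sim_config(path), "unknown config key")
})
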
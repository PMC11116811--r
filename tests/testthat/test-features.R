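test_that("log_transform is elementwise log2(x + 1)", {
  x <- tibble::tibble(gene_id = c("A", "B"), S1 = c(0, 7), S2 = c(1, 3))
  out <- log_transform(x)
  expect_equal(out$S1, c(0, 3))
  expect_equal(out$S2, c(1, 2))
  x$S1[1] <- -1
  expect_error(log_transform(x), "negative")
})

test_that("zscore_genes standardizes per gene with the n-1 denominator", {
  x <- tibble::tibble(gene_id = "G", S1 = 1, S2 = 3)
  z <- zscore_genes(x)
  expect_equal(unlist(z[1, -1], use.names = FALSE),
               c(-1, 1) / sqrt(2), tolerance = 1e-7)

  set.seed(21)
  big <- toy_expression(paste0("G", 1:30), paste0("S", 1:15), seed = 21)
  zb <- as.matrix(zscore_genes(big)[, -1])
  expect_equal(unname(rowMeans(zb)), rep(0, 30), tolerance = 1e-9)
  expect_equal(unname(apply(zb, 1, sd)), rep(1, 30), tolerance = 1e-9)

  const <- tibble::tibble(gene_id = c("C", "D"), S1 = c(5, 1), S2 = c(5, 2),
                          S3 = c(5, 3))
  expect_warning(zc <- zscore_genes(const), "constant")
  expect_equal(unlist(zc[zc$gene_id == "C", -1], use.names = FALSE), c(0, 0, 0))

  single <- tibble::tibble(gene_id = "G", S1 = 1)
  expect_error(zscore_genes(single), "cohort")
})

test_that("feature-gene selection applies a strict median-TIN threshold", {
  tin <- tibble::tibble(
    gene_id = c("AT20", "OVER", "UNDER"),
    S1 = c(20, 25, 10), S2 = c(20, 25, 15), S3 = c(20, 25, 30)
  )
  fs <- select_feature_genes(c("AT20", "OVER", "UNDER"), tin, threshold = 20)
  expect_s3_class(fs, "feature_gene_set")
  expect_equal(fs$genes, "OVER") # exactly 20 is excluded; strict >
  expect_warning(
    fs2 <- select_feature_genes(c("OVER", "GHOST"), tin),
    "absent"
  )
  expect_equal(fs2$genes, "OVER")
  expect_error(select_feature_genes(c("UNDER"), tin), "median TIN")
  expect_error(select_feature_genes(character(0), tin), "empty")
})

test_that("selection matches a brute-force sort-and-filter oracle", {
  set.seed(33)
  genes <- sprintf("G%03d", 1:500)
  tin_m <- matrix(runif(500 * 9, 0, 60), 500, 9,
                  dimnames = list(genes, paste0("S", 1:9)))
  tin_m[sample(length(tin_m), 200)] <- NA
  tin <- dplyr::bind_cols(tibble::tibble(gene_id = genes),
                          tibble::as_tibble(tin_m, .name_repair = "minimal"))
  cand <- sample(c(genes, paste0("X", 1:20)), 320)
  expected <- oracle_select(cand, tin_m, 20)
  fs <- suppressWarnings(select_feature_genes(cand, tin, threshold = 20))
  expect_equal(fs$genes, expected)
})

test_that("selection at a higher threshold yields a subset", {
  set.seed(8)
  genes <- sprintf("G%02d", 1:60)
  tin <- dplyr::bind_cols(
    tibble::tibble(gene_id = genes),
    tibble::as_tibble(matrix(runif(60 * 5, 0, 80), 60, 5,
                             dimnames = list(NULL, paste0("S", 1:5))),
                      .name_repair = "minimal")
  )
  lo <- select_feature_genes(genes, tin, threshold = 15)$genes
  hi <- select_feature_genes(genes, tin, threshold = 35)$genes
  expect_true(all(hi %in% lo))
})

test_that("pair encoding follows the lexicographic order and tie rule", {
  z <- tibble::tibble(gene_id = c("B", "A", "C"),
                      S1 = c(1, 2, 3), S2 = c(2, 2, 1))
  pf <- encode_gene_pairs(z, c("B", "A", "C"))
  expect_equal(setdiff(names(pf), "sample_id"),
               c("(A,B)", "(A,C)", "(B,C)"))
  expect_equal(pf$`(A,B)`, c(1L, 0L)) # tie in S2 encodes 0
  expect_equal(pf$`(A,C)`, c(0L, 1L))
  expect_equal(pf$`(B,C)`, c(0L, 1L))
})

test_that("pair count is m(m-1)/2 and matches the double-loop oracle", {
  for (m in c(2, 3, 10)) {
    z <- toy_expression(sprintf("G%02d", 1:m), paste0("S", 1:20), seed = m)
    zt <- zscore_genes(z)
    pf <- encode_gene_pairs(zt, z$gene_id)
    expect_equal(ncol(pf) - 1, m * (m - 1) / 2)
    zm <- as.matrix(zt[, -1])
    rownames(zm) <- zt$gene_id
    oracle <- oracle_pair_features(zm)
    got <- as.matrix(pf[, -1])
    rownames(got) <- pf$sample_id
    expect_identical(got[rownames(oracle), colnames(oracle), drop = FALSE],
                     oracle)
  }
  expect_equal(choose(144, 2), 10296) # the m = 144 contract
})

test_that("pair features are invariant to per-gene increasing affine transforms", {
  x <- toy_expression(sprintf("G%02d", 1:10), paste0("S", 1:20), seed = 99)
  base <- encode_gene_pairs(zscore_genes(x), x$gene_id)
  set.seed(100)
  a <- runif(10, 0.2, 5)
  b <- runif(10, -20, 20)
  m <- as.matrix(x[, -1]) * a + b
  warped <- dplyr::bind_cols(tibble::tibble(gene_id = x$gene_id),
                             tibble::as_tibble(m, .name_repair = "minimal"))
  expect_identical(encode_gene_pairs(zscore_genes(warped), x$gene_id), base)
})

test_that("permuting samples permutes feature rows identically", {
  x <- toy_expression(sprintf("G%02d", 1:6), paste0("S", 1:9), seed = 4)
  pf <- encode_gene_pairs(zscore_genes(x), x$gene_id)
  perm <- c(1, sample(2:9))
  xp <- x[, c(1, perm + 1)]
  pfp <- encode_gene_pairs(zscore_genes(xp), x$gene_id)
  reord <- pf[match(pfp$sample_id, pf$sample_id), ]
  expect_equal(pfp$sample_id, reord$sample_id)
  expect_identical(as.matrix(pfp[, -1]), as.matrix(reord[, -1]))
})

test_that("align_features pads tolerable gaps and rejects excessive ones", {
  x <- toy_expression(sprintf("G%02d", 1:10), paste0("S", 1:5), seed = 6)
  all_present <- align_features(x, x$gene_id)
  expect_equal(all_present$gene_id, sort(x$gene_id))

  drop1 <- x[x$gene_id != "G03", ]
  expect_warning(padded <- align_features(drop1, x$gene_id, max_missing_frac = 0.2),
                 "padded")
  expect_equal(attr(padded, "missing_genes"), "G03")
  expect_true(all(as.matrix(padded[padded$gene_id == "G03", -1]) == 0))
  # a padded gene z-scores to 0, so its pairs reduce to the partner's sign
  pf <- suppressWarnings(encode_gene_pairs(zscore_genes(padded), x$gene_id))
  z <- suppressWarnings(zscore_genes(padded))
  zo <- as.matrix(z[z$gene_id == "G04", -1])
  expect_equal(unname(pf$`(G03,G04)`), as.integer(0 > zo)[seq_len(nrow(pf))])

  drop3 <- x[!x$gene_id %in% c("G01", "G02", "G03"), ]
  expect_error(align_features(drop3, x$gene_id, max_missing_frac = 0.2),
               "missing from input")
})

test_that("encode_gene_pairs demands aligned inputs", {
  z <- zscore_genes(toy_expression(c("A", "B"), paste0("S", 1:4)))
  expect_error(encode_gene_pairs(z, c("A", "B", "Z")), "align_features")
  expect_error(encode_gene_pairs(z, "A"), "at least 2")
})
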
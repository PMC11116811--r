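# Random-forest subtype predictor over binary gene-pair features. The
# forest is a classical Breiman/Cutler classification forest (ranger
# engine) with the conventional defaults: 500 trees, mtry = floor(sqrt(P)),
# terminal nodes down to size 1. This file owns the model contract around
# it: frozen feature-gene list, lexicographic pair order, fixed class order
# CMS1..CMS4, vote-fraction probabilities, tie-breaking, a training
# manifest, and an integrity-checked on-disk archive.

#' Train the CMS random-forest classifier
#'
#' @param features Pair-feature tibble ([pair_features()] output):
#'   `sample_id` plus binary pair columns.
#' @param labels Tibble `sample_id`, `cms`. Labels outside CMS1..CMS4
#'   (including `NOLBL` and `NA`) are dropped with a warning; at least two
#'   subtypes must remain, and every retained labeled sample must be present
#'   in `features`.
#' @param n_trees Number of trees (default 500).
#' @param mtry Features tried per split; default `floor(sqrt(P))` for P pair
#'   features.
#' @param min_leaf Minimum terminal-node size (default 1).
#' @param seed Integer seed making training deterministic.
#' @return An object of class `cms_model`.
#' @export
cms_train <- function(features, labels, n_trees = 500, mtry = NULL,
                      min_leaf = 1, seed = 1L) {
  stopifnot(is.data.frame(features), is.data.frame(labels))
  lab <- labels[labels$cms %in% CMS_CLASSES, c("sample_id", "cms")]
  n_dropped <- nrow(labels) - nrow(lab)
  if (n_dropped > 0) {
    warn(sprintf("%d unlabeled sample(s) dropped from training", n_dropped))
  }
  absent <- setdiff(lab$sample_id, features$sample_id)
  if (length(absent) > 0) {
    abort(sprintf("labeled sample(s) missing from the feature matrix: %s",
                  paste(head(absent, 5), collapse = ", ")))
  }
  if (length(unique(lab$cms)) < 2) {
    abort("training labels contain a single class; at least two subtypes are required")
  }
  x <- as.matrix(features[match(lab$sample_id, features$sample_id), -1, drop = FALSE])
  y <- factor(lab$cms, levels = intersect(CMS_CLASSES, unique(lab$cms)))
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  if (mtry > p) abort("`mtry` exceeds the number of pair features")
  rf <- ranger::ranger(
    x = x, y = y, num.trees = n_trees, mtry = mtry,
    min.node.size = min_leaf, num.threads = 1, seed = seed
  )
  oob <- mean(rf$predictions == y, na.rm = TRUE)
  genes <- attr(features, "feature_genes")
  if (is.null(genes)) genes <- genes_from_pairs(colnames(x))
  structure(list(
    forest = rf,
    feature_genes = genes,
    pair_order = colnames(x),
    classes = CMS_CLASSES,
    hyperparams = list(n_trees = as.integer(n_trees), mtry = as.integer(mtry),
                       min_leaf = as.integer(min_leaf), seed = as.integer(seed)),
    manifest = list(
      n_train = nrow(x),
      class_counts = as.list(table(y)),
      oob_accuracy = oob,
      trained_classes = levels(y),
      package_version = as.character(packageVersion("ffpecms"))
    )
  ), class = "cms_model")
}

#' @export
print.cms_model <- function(x, ...) {
  cat("<cms_model>", length(x$feature_genes), "feature genes,",
      length(x$pair_order), "pair features\n")
  cat("  trees:", x$hyperparams$n_trees, " mtry:", x$hyperparams$mtry,
      " seed:", x$hyperparams$seed, "\n")
  cat(sprintf("  out-of-bag accuracy: %.3f on %d samples\n",
              x$manifest$oob_accuracy, x$manifest$n_train))
  invisible(x)
}

#' Predict CMS calls
#'
#' Class probabilities are the fraction of trees voting each subtype; the
#' call is the argmax, with exact ties broken toward the lower-numbered CMS.
#' Every sample receives a call (no reject option). Feature columns must
#' match the model's pair order exactly.
#'
#' @param object A `cms_model`.
#' @param features Pair-feature tibble whose columns equal
#'   `object$pair_order`.
#' @param ... Unused.
#' @return A `cms_calls` tibble: `sample_id`, `cms`, `p_CMS1`..`p_CMS4`.
#' @export
predict.cms_model <- function(object, features, ...) {
  cols <- setdiff(names(features), "sample_id")
  if (length(cols) != length(object$pair_order)) {
    abort(sprintf(
      "feature columns do not match the model's pair order; got %d pair columns, model expects %d",
      length(cols), length(object$pair_order)
    ))
  }
  if (!all(cols == object$pair_order)) {
    bad <- which(cols != object$pair_order)[1]
    abort(sprintf(
      "feature columns do not match the model's pair order; first mismatch at column %d: got '%s', expected '%s'",
      bad, cols[bad], object$pair_order[bad]
    ))
  }
  x <- as.matrix(features[, object$pair_order, drop = FALSE])
  probs <- tree_vote_fractions(object$forest, x)
  calls <- assign_cms_labels(probs)
  out <- dplyr::bind_cols(
    tibble(sample_id = features$sample_id, cms = calls),
    setNames(as_tibble(probs, .name_repair = "minimal"), paste0("p_", CMS_CLASSES))
  )
  new_cms_calls(out)
}

# Per-tree votes tallied into fractions over the fixed CMS1..CMS4 order;
# classes absent from training get probability 0.
tree_vote_fractions <- function(forest, x) {
  pred <- predict(forest, data = x, predict.all = TRUE, num.threads = 1)$predictions
  voted <- forest$forest$levels[pred]
  n_trees <- ncol(pred)
  probs <- matrix(0, nrow(x), length(CMS_CLASSES),
                  dimnames = list(NULL, CMS_CLASSES))
  for (k in intersect(CMS_CLASSES, forest$forest$levels)) {
    probs[, k] <- rowSums(matrix(voted == k, nrow(x), n_trees)) / n_trees
  }
  probs
}

# argmax over the fixed class order; ties go to the lower-numbered CMS
# because max.col with ties.method = "first" scans CMS1..CMS4 in order.
assign_cms_labels <- function(probs) {
  stopifnot(ncol(probs) == length(CMS_CLASSES))
  CMS_CLASSES[max.col(probs, ties.method = "first")]
}

new_cms_calls <- function(x) {
  class(x) <- unique(c("cms_calls", class(as_tibble(x))))
  x
}

#' @export
tidy.cms_model <- function(x, ...) {
  y_counts <- unlist(x$manifest$class_counts)
  tibble(
    cms = names(y_counts),
    n_train = as.integer(y_counts)
  )
}

#' @export
glance.cms_model <- function(x, ...) {
  tibble(
    n_train = x$manifest$n_train,
    n_genes = length(x$feature_genes),
    n_pairs = length(x$pair_order),
    n_trees = x$hyperparams$n_trees,
    mtry = x$hyperparams$mtry,
    oob_accuracy = x$manifest$oob_accuracy
  )
}

#' Save or load a trained model archive
#'
#' The archive is a directory holding `manifest.json` (feature genes, pair
#' count, classes, hyperparameters, training summary, package version) and
#' `forest.rds` (the serialized ensemble). On load, the pair order derived
#' from the manifest's gene list must match the forest's feature names
#' exactly and the major package version must agree, so a tampered or
#' mismatched archive is refused. Save/load round-trips predictions
#' bit-exactly.
#'
#' @param model A `cms_model`.
#' @param path Archive directory.
#' @return `path` invisibly (save); a `cms_model` (load).
#' @export
save_cms_model <- function(model, path) {
  stopifnot(inherits(model, "cms_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = "ffpecms-model",
    package_version = model$manifest$package_version,
    classes = model$classes,
    feature_genes = model$feature_genes,
    n_pairs = length(model$pair_order),
    hyperparams = model$hyperparams,
    training = model$manifest[c("n_train", "class_counts", "oob_accuracy",
                                "trained_classes")]
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  saveRDS(model$forest, file.path(path, "forest.rds"))
  invisible(path)
}

#' @rdname save_cms_model
#' @export
load_cms_model <- function(path) {
  mf_path <- file.path(path, "manifest.json")
  rf_path <- file.path(path, "forest.rds")
  if (!file.exists(mf_path) || !file.exists(rf_path)) {
    abort(sprintf("'%s' is not a model archive (manifest.json + forest.rds expected)", path))
  }
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  if (!identical(manifest$format, "ffpecms-model")) {
    abort("manifest is not an ffpecms model manifest")
  }
  here <- package_version(as.character(packageVersion("ffpecms")))
  there <- package_version(manifest$package_version)
  if (there$major != here$major) {
    abort(sprintf("model archive written by incompatible major version %s (this is %s)",
                  manifest$package_version, here))
  }
  forest <- readRDS(rf_path)
  genes <- sort(unique(as.character(manifest$feature_genes)))
  idx <- combn(length(genes), 2L)
  expected_pairs <- sprintf("(%s,%s)", genes[idx[1, ]], genes[idx[2, ]])
  forest_pairs <- forest$forest$independent.variable.names
  if (length(expected_pairs) != length(forest_pairs) ||
      !all(expected_pairs == forest_pairs)) {
    abort("integrity error: manifest gene list does not match the stored forest's pair features")
  }
  structure(list(
    forest = forest,
    feature_genes = genes,
    pair_order = expected_pairs,
    classes = as.character(manifest$classes),
    hyperparams = lapply(manifest$hyperparams, as.integer),
    manifest = c(manifest$training,
                 list(package_version = manifest$package_version))
  ), class = "cms_model")
}

genes_from_pairs <- function(pair_ids) {
  inner <- sub("^\\(", "", sub("\\)$", "", pair_ids))
  sort(unique(unlist(strsplit(inner, ",", fixed = TRUE))))
}
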
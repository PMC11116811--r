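# File formats are all tab-delimited UTF-8 with Unix newlines and "NA" for
# missing values, so every artifact diffs cleanly in review. Matrix-shaped
# tables carry the row identifier in the first column and one column per
# sample.

#' Read a gene-by-sample expression table
#'
#' Expression tables are TSV files with the gene identifier in the first
#' column (renamed to `gene_id` on read) and one numeric column per sample.
#' Values must be non-negative abundances (TPM or microarray intensity) with
#' no missing entries; violations fail at parse time rather than propagating
#' into downstream stages.
#'
#' @param path Path to a TSV file.
#' @return A tibble with `gene_id` followed by one numeric column per sample.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_expression(tibble::tibble(gene_id = c("A", "B"), S1 = c(1, 2), S2 = c(3, 4)), tf)
#' read_expression(tf)
read_expression <- function(path) {
  x <- read_matrix_tsv(path, id_col = "gene_id")
  vals <- as.matrix(x[, -1])
  if (anyNA(vals)) {
    abort(sprintf("expression table '%s' contains missing values", path))
  }
  if (any(vals < 0)) {
    abort(sprintf("expression table '%s' contains negative values", path))
  }
  x
}

#' Write a gene-by-sample expression table
#'
#' @param x Expression tibble (`gene_id` + sample columns).
#' @param path Output TSV path.
#' @return `x`, invisibly.
#' @export
write_expression <- function(x, path) {
  check_matrix_tibble(x, "expression")
  readr::write_tsv(x, path)
  invisible(x)
}

#' Read or write a TIN table
#'
#' TIN tables hold transcript-integrity numbers in \[0, 100\], rows keyed by
#' transcript or gene, columns by sample. Missing values ("NA") mark
#' transcripts below the coverage floor in that sample.
#'
#' @param path TSV path.
#' @return A tibble with the row identifier in the first column.
#' @export
read_tin <- function(path) {
  x <- read_matrix_tsv(path, id_col = NULL)
  vals <- as.matrix(x[, -1])
  bad <- !is.na(vals) & (vals < 0 | vals > 100)
  if (any(bad)) {
    abort(sprintf("TIN table '%s' has values outside [0, 100]", path))
  }
  x
}

#' @param x TIN tibble.
#' @rdname read_tin
#' @export
write_tin <- function(x, path) {
  check_matrix_tibble(x, "TIN")
  readr::write_tsv(x, path, na = "NA")
  invisible(x)
}

#' Read or write a gene list
#'
#' Gene lists are plain text, one identifier per line; `#` starts a comment
#' and blank lines are ignored.
#'
#' @param path Text file path.
#' @return Character vector of identifiers (duplicates removed, order kept).
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  unique(lines[nzchar(lines)])
}

#' @param genes Character vector of gene identifiers.
#' @rdname read_gene_list
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(genes)
}

#' Read or write subtype labels
#'
#' Label files have columns `sample_id` and `cms`, the latter one of
#' CMS1..CMS4 or `NOLBL` for samples without a benchmark call.
#'
#' @param path TSV path.
#' @return A tibble with columns `sample_id`, `cms` (character).
#' @export
read_labels <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    cms = readr::col_character()
  ))
  bad <- setdiff(unique(x$cms), c(CMS_CLASSES, NO_LABEL))
  if (length(bad) > 0) {
    abort(sprintf(
      "label file '%s' has invalid labels: %s (expected CMS1..CMS4 or %s)",
      path, paste(bad, collapse = ", "), NO_LABEL
    ))
  }
  if (anyDuplicated(x$sample_id)) {
    abort(sprintf("label file '%s' has duplicated sample ids", path))
  }
  x
}

#' @param x Label tibble (`sample_id`, `cms`).
#' @rdname read_labels
#' @export
write_labels <- function(x, path) {
  readr::write_tsv(x[, c("sample_id", "cms")], path)
  invisible(x)
}

#' Read or write per-transcript coverage vectors
#'
#' Coverage files have columns `transcript_id`, `sample_id` and `depths`, the
#' last a comma-separated vector of read depths at the sampled mRNA
#' positions, 5' to 3'. On read the depth string becomes a list-column of
#' numeric vectors.
#'
#' @param path TSV path.
#' @return A tibble with `transcript_id`, `sample_id` and list-column `depths`.
#' @export
read_coverage <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    transcript_id = readr::col_character(),
    sample_id = readr::col_character(),
    depths = readr::col_character()
  ))
  if (nrow(x) == 0) {
    abort(sprintf("coverage file '%s' is empty", path))
  }
  x$depths <- lapply(strsplit(x$depths, ","), as.numeric)
  bad <- vapply(x$depths, function(d) length(d) == 0 || anyNA(d) || any(d < 0),
                logical(1))
  if (any(bad)) {
    abort(sprintf(
      "coverage file '%s': malformed depth vector for transcript %s",
      path, x$transcript_id[which(bad)[1]]
    ))
  }
  x
}

#' @param x Coverage tibble with list-column `depths`.
#' @rdname read_coverage
#' @export
write_coverage <- function(x, path) {
  out <- tibble(
    transcript_id = x$transcript_id,
    sample_id = x$sample_id,
    depths = vapply(x$depths, function(d) paste(format(d, trim = TRUE, scientific = FALSE),
                                                collapse = ","), character(1))
  )
  readr::write_tsv(out, path)
  invisible(x)
}

#' Read or write subtype predictions
#'
#' Prediction files have columns `sample_id`, `cms` and the four per-class
#' probabilities `p_CMS1`..`p_CMS4`.
#'
#' @param path TSV path.
#' @return A tibble of class calls (see [predict.cms_model()]).
#' @export
read_predictions <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    cms = readr::col_character(),
    .default = readr::col_double()
  ))
  new_cms_calls(x)
}

#' @param x Prediction tibble.
#' @rdname read_predictions
#' @export
write_predictions <- function(x, path) {
  cols <- c("sample_id", "cms", paste0("p_", CMS_CLASSES))
  readr::write_tsv(as_tibble(x)[, cols], path)
  invisible(x)
}

# --- internal helpers -------------------------------------------------------

read_matrix_tsv <- function(path, id_col = NULL) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ))
  if (ncol(x) < 2) {
    abort(sprintf("'%s' must have an id column plus at least one sample column", path))
  }
  if (!is.null(id_col)) names(x)[1] <- id_col
  if (anyDuplicated(x[[1]])) {
    abort(sprintf("'%s' has duplicated row ids", path))
  }
  if (anyDuplicated(names(x)[-1])) {
    abort(sprintf("'%s' has duplicated sample ids", path))
  }
  x
}

check_matrix_tibble <- function(x, what) {
  if (!is.data.frame(x) || ncol(x) < 2) {
    abort(sprintf("%s table must be a data frame with an id column plus sample columns", what))
  }
  if (!is.character(x[[1]]) && !is.factor(x[[1]])) {
    abort(sprintf("%s table must have a character id in its first column", what))
  }
  invisible(x)
}

# Convert an id + sample-columns tibble to a numeric matrix with row names.
as_matrix <- function(x) {
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- as.character(x[[1]])
  m
}

# Inverse of as_matrix().
matrix_tibble <- function(m, id_col = "gene_id") {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble(!!id_col := rownames(m)), out)
  out
}
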
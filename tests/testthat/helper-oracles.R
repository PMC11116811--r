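# Independent oracle implementations used to cross-check the package. Each
# takes a deliberately different computational route from the code it
# verifies.

# TIN via the product form of the exponential entropy: exp(H) with
# H = -sum p log p equals prod(p_i^(-p_i)). No call to exp(sum(...)).
oracle_tin <- function(depths) {
  total <- sum(depths)
  if (total == 0) return(0)
  p <- depths[depths > 0] / total
  100 * prod(p^(-p)) / length(depths)
}

# Median by explicit sort (no stats::median).
oracle_median <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
}

# Pair features by a double loop over pairs and samples.
oracle_pair_features <- function(z_matrix) {
  genes <- sort(rownames(z_matrix))
  out <- list()
  for (a in seq_along(genes)) {
    for (b in seq_along(genes)) {
      if (a >= b) next
      id <- sprintf("(%s,%s)", genes[a], genes[b])
      out[[id]] <- as.integer(z_matrix[genes[a], ] > z_matrix[genes[b], ])
    }
  }
  m <- do.call(cbind, out)
  rownames(m) <- colnames(z_matrix)
  m
}

# Exact upper-tail binomial probability by weighted enumeration of all 2^n
# outcome vectors (feasible for n <= 15).
oracle_binomial_tail <- function(k, n, p0) {
  total <- 0
  for (code in 0:(2^n - 1)) {
    ones <- sum(bitwAnd(code, 2^(0:(n - 1))) > 0)
    if (ones >= k) total <- total + p0^ones * (1 - p0)^(n - ones)
  }
  total
}

# Confusion tally by explicit double loop.
oracle_contingency <- function(predicted, benchmark, classes) {
  m <- matrix(0L, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (i in seq_along(predicted)) {
    m[predicted[i], benchmark[i]] <- m[predicted[i], benchmark[i]] + 1L
  }
  m
}

# Strict median-TIN filter by per-gene sort.
oracle_select <- function(candidates, tin_matrix, threshold) {
  keep <- character(0)
  for (g in candidates) {
    if (!g %in% rownames(tin_matrix)) next
    v <- tin_matrix[g, ]
    v <- v[!is.na(v)]
    if (length(v) > 0 && oracle_median(v) > threshold) keep <- c(keep, g)
  }
  sort(keep)
}
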
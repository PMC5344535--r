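# Screen bookkeeping and the Monte-Carlo one-way equal-means test.

#' Filter a screen table by fold change
#'
#' Fold changes are signed ratios (|FC| >= 1; -1.5 means 1.5-fold down).
#' The comparison is inclusive: a gene at exactly the threshold is kept,
#' matching the "equal to or higher than" convention.  Rows with
#' |FC| < 1 are invalid encodings and are set aside rather than silently
#' classified.
#'
#' @param table Data frame with columns `gene_id` (unique) and
#'   `fold_change` (signed ratio).
#' @param threshold Ratio threshold, >= 1 (default 1.5).
#' @return List with data frames `up` (FC >= threshold), `down`
#'   (FC <= -threshold), `excluded` (sub-threshold) and `invalid`
#'   (|FC| < 1 or non-finite).
#' @export
fold_change_filter <- function(table, threshold = 1.5) {
  if (!is.data.frame(table) ||
      !all(c("gene_id", "fold_change") %in% names(table)))
    stop("`table` must have columns gene_id and fold_change")
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 1)
    stop("`threshold` must be a single ratio >= 1")
  if (anyDuplicated(table$gene_id)) stop("gene_ids must be unique")
  fc <- table$fold_change
  invalid <- !is.finite(fc) | abs(fc) < 1
  up <- !invalid & fc >= threshold
  down <- !invalid & fc <= -threshold
  excluded <- !invalid & !up & !down
  list(up = table[up, , drop = FALSE],
       down = table[down, , drop = FALSE],
       excluded = table[excluded, , drop = FALSE],
       invalid = table[invalid, , drop = FALSE])
}

#' Expected number of false positives at a given FDR
#'
#' With `n` identified genes at false discovery rate `fdr`, the expected
#' number of false positives is simply `n * fdr`; the rounded value is
#' what screen reports quote.
#'
#' @param n_identified Number of identified genes, >= 0.
#' @param fdr False discovery rate as a proportion in \[0, 1\].
#' @return List with `expected` (real) and `rounded` (nearest integer).
#' @export
expected_false_positives <- function(n_identified, fdr) {
  if (!is.numeric(n_identified) || n_identified < 0)
    stop("`n_identified` must be non-negative")
  if (!is.numeric(fdr) || fdr < 0 || fdr > 1)
    stop("`fdr` must be a proportion in [0, 1]")
  expected <- n_identified * fdr
  list(expected = expected, rounded = round(expected))
}

ssb_statistic <- function(y, g) {
  gm <- mean(y)
  means <- tapply(y, g, mean)
  ns <- tabulate(g)
  sum(ns * (means - gm)^2)
}

#' Monte-Carlo test for equal means in a one-way layout
#'
#' Permutation version of the one-way ANOVA null: observations are
#' randomly relabelled to groups (sizes preserved) and the between-group
#' sum of squares of the group means about the grand mean is recomputed.
#' Under full enumeration any permutation-exchangeable F-type statistic
#' gives the same p-value, so the simple between-group sum of squares is
#' used.  The add-one estimator `p = (1 + #{S* >= S}) / (1 + B)` avoids
#' reporting p = 0 from a finite resample.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2
#'   observations.
#' @param n_resamples Number of Monte-Carlo relabellings, >= 99.
#' @param seed Optional RNG seed for reproducibility.
#' @return An object of class `htest` with the observed statistic, the
#'   p-value and the resample count.
#' @export
mc_oneway_test <- function(groups, n_resamples = 9999, seed = NULL) {
  if (!is.list(groups) || length(groups) < 2)
    stop("`groups` must be a list of at least 2 samples")
  groups <- lapply(groups, as.numeric)
  if (any(vapply(groups, length, 0L) < 2))
    stop("each group needs at least 2 observations")
  if (any(!vapply(groups, function(g) all(is.finite(g)), TRUE)))
    stop("observations must be finite")
  if (n_resamples < 99) stop("`n_resamples` must be at least 99")
  y <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, 0L))
  y <- y - mean(y)   # centring: exact shift invariance of the comparison
  obs <- ssb_statistic(y, g)
  run <- function() {
    hits <- 0L
    tol <- obs * 1e-12
    for (b in seq_len(n_resamples))
      if (ssb_statistic(sample(y), g) >= obs - tol) hits <- hits + 1L
    hits
  }
  hits <- if (is.null(seed)) run() else with_seed(seed, run())
  p <- (1 + hits) / (1 + n_resamples)
  structure(
    list(statistic = c(SSB = obs), p.value = p,
         parameter = c(resamples = n_resamples),
         method = "Monte-Carlo test for equal means in a one-way layout",
         data.name = deparse(substitute(groups))),
    class = "htest")
}
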
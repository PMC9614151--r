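#' Sample statistics for affinity discretization
#'
#' Sample mean and (n-1)-denominator standard deviation of a continuous
#' affinity column (pKd or KIBA scores), the anchors of the five-class
#' binning scheme.
#'
#' @param values Numeric vector, length >= 2, not all equal.
#' @return A `dpi_affinity_stats` list: `mu`, `sigma`, `n`.
#' @export
compute_stats <- function(values) {
  values <- as.numeric(values)
  stopifnot(length(values) >= 2L, all(is.finite(values)))
  sigma <- stats::sd(values)
  if (sigma == 0) {
    stop("constant affinity values: sigma = 0 makes the classes degenerate")
  }
  structure(list(mu = mean(values), sigma = sigma, n = length(values)),
            class = "dpi_affinity_stats")
}

#' Assign an affinity value to one of five classes
#'
#' The five categories are concentric bands around the mean: with
#' `d = |value - mu| / sigma`, class 0 covers `d <= 1`, class 1 covers
#' `1 < d <= 2`, class 2 `2 < d <= 3`, class 3 `3 < d <= 4`, and class 4 is
#' everything beyond ("other"). The printed nested intervals are resolved to
#' these disjoint annuli so the five categories partition the line; boundary
#' ties go to the inner class.
#'
#' @param value Numeric vector of affinity values.
#' @param stats A `dpi_affinity_stats` from [compute_stats()].
#' @return Integer class indices in `0..4`, vectorized over `value`.
#' @export
assign_class <- function(value, stats) {
  stopifnot(inherits(stats, "dpi_affinity_stats"))
  d <- abs(value - stats$mu) / stats$sigma
  as.integer(pmin(ceiling(pmax(d, .Machine$double.xmin)), 5)) - 1L
}

#' Discretize a full affinity column
#'
#' Computes the stats from `values` themselves (set `stats` to discretize
#' against statistics from a training subset instead, avoiding test
#' leakage in new studies) and labels every value.
#'
#' @param values Numeric affinities.
#' @param stats Optional precomputed `dpi_affinity_stats`.
#' @return A list: `labels` (integer 0..4), `stats`, `freq` (named counts
#'   over the five classes, summing to `length(values)`).
#' @export
discretize_dataset <- function(values, stats = NULL) {
  if (is.null(stats)) stats <- compute_stats(values)
  labels <- assign_class(values, stats)
  freq <- table(factor(labels, levels = 0:4))
  list(labels = labels, stats = stats, freq = freq)
}

#' Convert a dissociation constant in nM to pKd
#'
#' `pKd = -log10(Kd * 1e-9)`: the negative decadic log of the molar Kd.
#' Davis-style affinities in `[0.016, 10000]` nM map to pKd roughly in
#' `[5.0, 10.8]`.
#'
#' @param kd Positive Kd values in nM.
#' @return pKd values (monotone decreasing in `kd`).
#' @export
kd_to_pkd <- function(kd) {
  if (any(kd <= 0)) stop("Kd must be positive")
  -log10(kd * 1e-9)
}
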
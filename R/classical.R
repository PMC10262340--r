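#' Swiger's asymptotic variance of an ANOVA ICC estimate
#'
#' Closed-form large-sample approximation to the sampling variance of a
#' one-way ANOVA intracluster correlation estimate,
#' \deqn{V(\rho, N, k) = \frac{2(N-1)(1-\rho)^2 \{1 + (N/k - 1)\rho\}^2}
#'   {(N/k)^2 (N-k)(k-1)},}
#' where `N` is the total number of participants and `k` the number of
#' clusters. The average cluster size `N/k` is used as a real number; no
#' rounding is applied. The variance is zero exactly when `rho = 1`.
#'
#' @param rho ICC value in `[0, 1]` at which to evaluate the variance.
#' @param n total number of participants (`n > k`).
#' @param k number of clusters (`k >= 2`).
#' @return the variance, a nonnegative number (vectorised over `rho`).
#' @examples
#' swiger_variance(0, 413, 12)     # approx 1.577e-4
#' swiger_variance(0.1, 100, 10)   # approx 7.148e-3
#' @export
swiger_variance <- function(rho, n, k) {
  if (any(!is.finite(k)) || any(k < 2)) stop("k must be at least 2")
  if (any(!is.finite(n)) || any(n <= k)) stop("n must exceed k")
  if (any(!is.finite(rho)) || any(rho < 0) || any(rho > 1))
    stop("rho must lie in [0, 1]")
  m_bar <- n / k
  2 * (n - 1) * (1 - rho)^2 * (1 + (m_bar - 1) * rho)^2 /
    (m_bar^2 * (n - k) * (k - 1))
}

#' Confidence interval for an ICC estimate via Swiger's variance
#'
#' Symmetric normal-approximation interval on the raw ICC scale,
#' `rho +/- z * sqrt(V)`, truncated to `[0, 1]`.
#'
#' @inheritParams swiger_variance
#' @param level confidence level in `(0, 1)`.
#' @return a list of class `"icc_interval"` with elements `point`, `lower`,
#'   `upper`, `level` and `variance`.
#' @examples
#' icc_confidence_interval(0, 413, 12)  # upper approx 0.0246, lower truncated
#' @export
icc_confidence_interval <- function(rho, n, k, level = 0.95) {
  if (length(rho) != 1L) stop("rho must be a single value")
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop("level must lie in (0, 1)")
  v <- swiger_variance(rho, n, k)
  z <- stats::qnorm((1 + level) / 2)
  half <- z * sqrt(v)
  out <- list(point = rho,
              lower = max(0, rho - half),
              upper = min(1, rho + half),
              level = level,
              variance = v)
  class(out) <- "icc_interval"
  out
}

#' @export
print.icc_interval <- function(x, digits = 4, ...) {
  cat(sprintf("ICC %s, %g%% CI [%s, %s]  (Swiger variance %s)\n",
              format(x$point, digits = digits), 100 * x$level,
              format(x$lower, digits = digits),
              format(x$upper, digits = digits),
              format(x$variance, digits = digits)))
  invisible(x)
}

#' Classical multi-estimate ICC summaries
#'
#' The simple comparator summaries used when several external ICC estimates
#' are available and no model is fitted: the median, mean, weighted mean and
#' maximum of the pooled record-level estimates, ignoring the study grouping.
#' The weighted mean uses the outcome-level relevance weights,
#' `sum(w * icc) / sum(w)`. With an even number of records the median is the
#' midpoint of the two central order statistics.
#'
#' None of these accounts for the differing precision or relevance of the
#' source studies; the maximum in particular tends to be overly conservative
#' as a design value.
#'
#' @param tab a [study_table()].
#' @return a list of class `"classical_icc"` with elements `median`, `mean`,
#'   `weighted_mean`, `maximum` and `n_records`.
#' @examples
#' tab <- read_study_table(system.file("extdata", "table1_icc.csv",
#'                                     package = "iccpool"))
#' classical_icc_summaries(tab)  # median 0.05, mean 0.098, maximum 0.4
#' @export
classical_icc_summaries <- function(tab) {
  tab <- validate_study_table(as.data.frame(tab))
  if (nrow(tab) == 0L) stop("empty study table")
  x <- tab$icc
  w <- tab$outcome_weight
  out <- list(median = stats::median(x),
              mean = mean(x),
              weighted_mean = sum(w * x) / sum(w),
              maximum = max(x),
              n_records = length(x))
  class(out) <- "classical_icc"
  out
}

#' @export
print.classical_icc <- function(x, digits = 4, ...) {
  cat("Classical multi-estimate ICC summaries (", x$n_records,
      " records):\n", sep = "")
  cat(sprintf("  median        %s\n", format(x$median, digits = digits)))
  cat(sprintf("  mean          %s\n", format(x$mean, digits = digits)))
  cat(sprintf("  weighted mean %s\n", format(x$weighted_mean, digits = digits)))
  cat(sprintf("  maximum       %s\n", format(x$maximum, digits = digits)))
  invisible(x)
}
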
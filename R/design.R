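#' Design effect for a cluster-randomised trial
#'
#' Variance inflation factor `1 + (m - 1) * rho` by which an individually
#' randomised sample size must be multiplied to allow for clustering, where
#' `m` is the (average) cluster size and `rho` the intracluster correlation.
#'
#' @param m cluster size, `m >= 1` (real values allowed for average sizes).
#' @param rho ICC in `[0, 1]`.
#' @return the design effect (vectorised), `>= 1` whenever `rho >= 0`.
#' @examples
#' design_effect(12, 0.0296)  # 1.3256
#' @export
design_effect <- function(m, rho) {
  if (any(!is.finite(m)) || any(m < 1)) stop("cluster size m must be >= 1")
  if (any(!is.finite(rho)) || any(rho < 0) || any(rho > 1))
    stop("rho must lie in [0, 1]")
  1 + (m - 1) * rho
}

check_design <- function(delta, sd, alpha, icc, k_per_arm) {
  if (!is.finite(sd) || sd <= 0) stop("sd must be positive")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.finite(icc) || icc < 0 || icc > 1) stop("icc must lie in [0, 1]")
  if (!is.finite(k_per_arm) || k_per_arm < 2)
    stop("k_per_arm must be at least 2")
  invisible(TRUE)
}

power_at_neff <- function(delta, sd, alpha, n_eff,
                          method = "normal", k = NULL, m = NULL) {
  ncp <- abs(delta) / (sd * sqrt(2 / n_eff))
  if (method == "normal") {
    z <- stats::qnorm(1 - alpha / 2)
    stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
  } else {
    df <- switch(method,
                 t_cluster_df = 2 * k - 2,
                 t_subject_df = 2 * k * m - 2,
                 stop("unknown power method: ", method))
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp = ncp)
  }
}

#' Power of a two-arm cluster-randomised trial
#'
#' Two-sided power for a difference in means between two arms of `k_per_arm`
#' equal clusters of size `m`, allowing for clustering through the design
#' effect: the effective per-arm sample size is
#' `n_eff = k_per_arm * m / (1 + (m - 1) * icc)` and the power is
#' `pnorm(ncp - z) + pnorm(-ncp - z)` with
#' `ncp = |delta| / (sd * sqrt(2 / n_eff))` and `z` the upper
#' `alpha/2` normal quantile. The `t_cluster_df` and `t_subject_df` variants
#' replace the normal quantile and tail with a noncentral t at
#' `2 * k_per_arm - 2` and `2 * k_per_arm * m - 2` degrees of freedom
#' respectively — conventions differ between sample-size programs.
#'
#' With `delta = 0` the two-sided power equals `alpha`.
#'
#' @param delta between-group difference to detect, in outcome units.
#' @param sd common outcome standard deviation.
#' @param icc intracluster correlation in `[0, 1]`.
#' @param k_per_arm clusters per arm (`>= 2`).
#' @param m participants per cluster (`>= 1`).
#' @param alpha two-sided significance level.
#' @param method power convention, see Details.
#' @return the power, a number in `(0, 1)`.
#' @examples
#' # 2.52-point difference, SD 8.32, ICC 0.0296, 20 clusters of 12 per arm:
#' power_cluster(2.52, 8.32, 0.0296, k_per_arm = 20, m = 12)  # 0.822
#' @export
power_cluster <- function(delta, sd, icc, k_per_arm, m, alpha = 0.05,
                          method = c("normal", "t_cluster_df",
                                     "t_subject_df")) {
  method <- match.arg(method)
  check_design(delta, sd, alpha, icc, k_per_arm)
  if (!is.finite(m) || m < 1) stop("m must be >= 1")
  n_eff <- k_per_arm * m / design_effect(m, icc)
  power_at_neff(delta, sd, alpha, n_eff, method, k = k_per_arm, m = m)
}

#' Smallest cluster size reaching a target power
#'
#' Searches over integer cluster sizes `m` for the smallest one whose
#' design-effect-adjusted power reaches `target_power`, for a fixed number of
#' clusters per arm. Because the effective per-arm size
#' `k * m / (1 + (m - 1) * rho)` tends to the asymptote `k / rho` as `m`
#' grows, no cluster size can rescue an under-clustered design: when the
#' power at that asymptote is below the target the design is reported as
#' infeasible (a result, not an error).
#'
#' @inheritParams power_cluster
#' @param target_power required power in `(0, 1)`.
#' @return a list of class `"sample_size"` with elements `feasible`, `m`,
#'   `n_total` (`2 * k_per_arm * m`), `deff`, `achieved_power`, and the input
#'   design parameters. For infeasible designs `m`, `n_total`, `deff` and
#'   `achieved_power` are `NA`.
#' @examples
#' # the post-stroke incontinence design: delta 2.52, SD 8.32, ICC 0.0296
#' min_cluster_size(2.52, 8.32, 0.0296, k_per_arm = 20)  # m = 12, N = 480
#' min_cluster_size(2.52, 8.32, 0.0296, k_per_arm = 25)  # m = 9,  N = 450
#' min_cluster_size(2.52, 8.32, 0.0682, k_per_arm = 10)  # infeasible
#' @export
min_cluster_size <- function(delta, sd, icc, k_per_arm, alpha = 0.05,
                             target_power = 0.80,
                             method = c("normal", "t_cluster_df",
                                        "t_subject_df")) {
  method <- match.arg(method)
  check_design(delta, sd, alpha, icc, k_per_arm)
  if (!is.finite(target_power) || target_power <= 0 || target_power >= 1)
    stop("target_power must lie in (0, 1)")
  if (delta == 0) stop("delta must be nonzero for a power search")

  base <- list(delta = delta, sd = sd, icc = icc, k_per_arm = k_per_arm,
               alpha = alpha, target_power = target_power, method = method)
  infeasible <- function() {
    structure(c(list(feasible = FALSE, m = NA_integer_, n_total = NA_real_,
                     deff = NA_real_, achieved_power = NA_real_), base),
              class = "sample_size")
  }
  # power at the m -> Inf asymptote n_eff = k / rho (t_subject_df -> normal)
  if (icc > 0) {
    lim_method <- if (method == "t_subject_df") "normal" else method
    lim <- power_at_neff(delta, sd, alpha, k_per_arm / icc, lim_method,
                         k = k_per_arm, m = Inf)
    if (lim <= target_power) return(infeasible())
  }
  pw <- function(m) power_cluster(delta, sd, icc, k_per_arm, m, alpha, method)
  hi <- 1L
  while (pw(hi) < target_power) {
    hi <- hi * 2L
    if (hi > 1e6L) return(infeasible())  # icc = 0 with tiny effect
  }
  lo <- if (hi == 1L) 1L else hi %/% 2L
  while (lo < hi) {                      # smallest m with pw(m) >= target
    mid <- (lo + hi) %/% 2L
    if (pw(mid) >= target_power) hi <- mid else lo <- mid + 1L
  }
  m <- hi
  structure(c(list(feasible = TRUE, m = m,
                   n_total = 2 * k_per_arm * m,
                   deff = design_effect(m, icc),
                   achieved_power = pw(m)), base),
            class = "sample_size")
}

#' @export
print.sample_size <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf(
      "Target power %.0f%% not achievable with k = %d clusters/arm at ICC %.4g\n",
      100 * x$target_power, x$k_per_arm, x$icc))
    cat(sprintf("  (effective per-arm size is capped at k/rho = %.1f)\n",
                x$k_per_arm / x$icc))
  } else {
    cat(sprintf(
      "Cluster-randomised design: k = %d clusters/arm x m = %d  (N = %d)\n",
      x$k_per_arm, x$m, as.integer(x$n_total)))
    cat(sprintf("  design effect %.4f, achieved power %.1f%% (%s method)\n",
                x$deff, 100 * x$achieved_power, x$method))
  }
  invisible(x)
}

#' Sample sizes across posterior ICC quantiles and cluster numbers
#'
#' Runs [min_cluster_size()] for every combination of clusters-per-arm value
#' and ICC quantile, the grid used to communicate how the plausible range of
#' the ICC (typically the posterior interquartile range plus the median)
#' translates into a range of trial sizes. Infeasible cells are kept with
#' `NA` sizes and `feasible = FALSE`.
#'
#' @param icc either a numeric vector of posterior ICC draws (quantiles are
#'   then taken at `probs`), an [icc_fit()] object (its predictive ICC draws
#'   are used), or a named/plain numeric vector of explicit ICC values when
#'   `probs = NULL`.
#' @param k_per_arm vector of clusters-per-arm values.
#' @param probs quantile levels applied when `icc` is a draws vector or fit;
#'   default the quartiles `c(0.25, 0.5, 0.75)`.
#' @inheritParams min_cluster_size
#' @return a data.frame with one row per `(k_per_arm, quantile)` cell:
#'   `k_per_arm`, `prob`, `icc`, `m`, `n_total`, `deff`, `achieved_power`,
#'   `feasible`.
#' @examples
#' qs <- c(q25 = 0.012, median = 0.0296, q75 = 0.0682)
#' sample_size_over_quantiles(qs, k_per_arm = c(20, 25), probs = NULL,
#'                            delta = 2.52, sd = 8.32)
#' @export
sample_size_over_quantiles <- function(icc, k_per_arm,
                                       delta, sd, alpha = 0.05,
                                       target_power = 0.80,
                                       probs = c(0.25, 0.5, 0.75),
                                       method = c("normal", "t_cluster_df",
                                                  "t_subject_df")) {
  method <- match.arg(method)
  if (length(k_per_arm) == 0L) stop("at least one k_per_arm value required")
  if (inherits(icc, "icc_fit")) icc <- predict(icc)
  if (!is.null(probs)) {
    if (any(probs <= 0 | probs >= 1)) stop("probs must lie in (0, 1)")
    icc_vals <- as.numeric(stats::quantile(icc, probs, names = FALSE, type = 7))
    prob_col <- probs
  } else {
    icc_vals <- as.numeric(icc)
    prob_col <- rep(NA_real_, length(icc_vals))
  }
  grid <- expand.grid(q = seq_along(icc_vals), k = k_per_arm)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    res <- min_cluster_size(delta, sd, icc_vals[grid$q[i]], grid$k[i],
                            alpha, target_power, method)
    data.frame(k_per_arm = grid$k[i], prob = prob_col[grid$q[i]],
               icc = icc_vals[grid$q[i]], m = res$m, n_total = res$n_total,
               deff = res$deff, achieved_power = res$achieved_power,
               feasible = res$feasible)
  })
  do.call(rbind, rows)
}
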
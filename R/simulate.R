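#' Simulate a clustered continuous outcome with known ICC
#'
#' Draws `n` Gaussian outcomes spread over `k` clusters under the one-way
#' random-effects model: cluster effects with variance `rho * sigma_total^2`
#' plus residuals with variance `(1 - rho) * sigma_total^2`, so the true
#' intracluster correlation is exactly `rho`. When `n` is not divisible by
#' `k` the remainder is distributed one participant per cluster.
#'
#' @param n total number of participants.
#' @param k number of clusters (`>= 2`).
#' @param rho true ICC in `[0, 1)`.
#' @param mean outcome mean.
#' @param sd_total total outcome standard deviation.
#' @return a data.frame with columns `cluster` (integer) and `y`.
#' @examples
#' set.seed(1)
#' d <- simulate_cluster_trial(200, 10, rho = 0.1)
#' anova_icc(d)
#' @export
simulate_cluster_trial <- function(n, k, rho, mean = 0, sd_total = 1) {
  if (!is.finite(k) || k < 2) stop("k must be at least 2")
  if (!is.finite(n) || n < k) stop("n must be at least k")
  if (!is.finite(rho) || rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  if (sd_total <= 0) stop("sd_total must be positive")
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  cl <- rep.int(seq_len(k), sizes)
  b <- stats::rnorm(k, 0, sd_total * sqrt(rho))
  y <- mean + b[cl] + stats::rnorm(n, 0, sd_total * sqrt(1 - rho))
  data.frame(cluster = cl, y = y)
}

#' One-way ANOVA estimator of the ICC
#'
#' The classical analysis-of-variance estimator
#' `(MSB - MSW) / (MSB + (m0 - 1) * MSW)` with the unbalanced-design
#' adjustment `m0 = (N - sum(n_i^2) / N) / (k - 1)` for the average cluster
#' size. Negative estimates are truncated to zero — this is why small
#' external studies often report an ICC of "0.00". If all values are
#' identical the estimate is 0 by convention.
#'
#' @param data a data.frame with columns `cluster` and `y` (as produced by
#'   [simulate_cluster_trial()]), or a numeric vector `y` with `cluster`
#'   given separately.
#' @param cluster cluster labels when `data` is a numeric vector.
#' @return the truncated ICC estimate in `[0, 1]`.
#' @examples
#' anova_icc(c(0, 0, 1, 1), cluster = c(1, 1, 2, 2))  # 1: clusters separate
#' anova_icc(c(0, 2, 1, 3), cluster = c(1, 1, 2, 2))  # raw -1/3 -> 0
#' @export
anova_icc <- function(data, cluster = NULL) {
  if (is.data.frame(data)) {
    y <- data$y
    cluster <- data$cluster
  } else {
    y <- as.numeric(data)
  }
  cl <- factor(cluster)
  k <- nlevels(cl)
  n <- length(y)
  if (k < 2L) stop("at least two clusters required")
  if (n != length(cl)) stop("y and cluster lengths differ")
  if (stats::var(y) == 0) {
    message("all outcome values identical; ICC set to 0 by convention")
    return(0)
  }
  ni <- as.numeric(table(cl))
  means <- tapply(y, cl, mean)
  grand <- mean(y)
  ssb <- sum(ni * (means - grand)^2)
  ssw <- sum((y - means[cl])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  m0 <- (n - sum(ni^2) / n) / (k - 1)
  est <- (msb - msw) / (msb + (m0 - 1) * msw)
  max(0, min(1, est))
}

#' Simulate a study table from the hierarchical ICC model
#'
#' Generates a [study_table()] forwards from the logit-normal hierarchy with
#' known truth: study means `mu_m ~ N(mu, sigma_b^2 / w_m)`, record-level
#' logit ICCs `logit(rho_ml) ~ N(mu_m, sigma_w^2 / w_ml)`, and observed
#' estimates either drawn directly from the Swiger-variance sampling model
#' `rho_hat ~ N(rho_ml, V(rho_ml, N, k))` (`mode = "direct"`) or produced by
#' actually simulating a clustered trial of that size and applying
#' [anova_icc()] (`mode = "trial"`). Observed estimates are clipped to
#' `[0, 1)`, mirroring the truncated-at-zero values real study reports print.
#'
#' The generating truth (`mu`, `sigma_b`, `sigma_w`, and the per-study /
#' per-record latent values) is attached as `attr(, "truth")` for
#' parameter-recovery scoring.
#'
#' @param n_studies number of studies.
#' @param outcomes_per_study outcomes (records) per study.
#' @param mu grand mean of the logit-ICC hierarchy.
#' @param sigma_b between-study SD on the logit scale.
#' @param sigma_w within-study SD on the logit scale.
#' @param N_range integer range from which each study's total sample size is
#'   drawn uniformly.
#' @param k_range integer range for the number of clusters.
#' @param study_weights,outcome_weights relevance weights used both in the
#'   generative variances and stored in the table; default all 1.
#' @param mode `"direct"` (Swiger sampling model) or `"trial"` (full
#'   clustered-data simulation).
#' @return a [study_table()] with a `"truth"` attribute.
#' @examples
#' set.seed(42)
#' tab <- simulate_study_table(5, 2)
#' attr(tab, "truth")$mu
#' @export
simulate_study_table <- function(n_studies = 30, outcomes_per_study = 3,
                                 mu = -3, sigma_b = 0.5, sigma_w = 0.3,
                                 N_range = c(200, 2000), k_range = c(10, 50),
                                 study_weights = NULL, outcome_weights = NULL,
                                 mode = c("direct", "trial")) {
  mode <- match.arg(mode)
  if (n_studies < 1 || outcomes_per_study < 1) stop("empty design")
  if (sigma_b <= 0 || sigma_w <= 0) stop("sigmas must be positive")
  r <- n_studies
  L <- r * outcomes_per_study
  w_m <- if (is.null(study_weights)) rep(1, r) else rep_len(study_weights, r)
  w_ml <- if (is.null(outcome_weights)) rep(1, L)
          else rep_len(outcome_weights, L)
  study <- rep(seq_len(r), each = outcomes_per_study)

  mu_m <- stats::rnorm(r, mu, sigma_b / sqrt(w_m))
  theta <- stats::rnorm(L, mu_m[study], sigma_w / sqrt(w_ml))
  rho <- stats::plogis(theta)
  draw_range <- function(rng) {
    if (rng[1] == rng[2]) rep(rng[1], r)
    else sample(seq(rng[1], rng[2]), r, replace = TRUE)
  }
  N <- draw_range(N_range)
  k <- pmin(draw_range(k_range), N - 1)

  rho_hat <- numeric(L)
  for (i in seq_len(L)) {
    s <- study[i]
    if (mode == "direct") {
      v <- swiger_variance(rho[i], N[s], k[s])
      rho_hat[i] <- stats::rnorm(1, rho[i], sqrt(v))
    } else {
      d <- simulate_cluster_trial(N[s], k[s], rho[i])
      rho_hat[i] <- anova_icc(d)
    }
  }
  rho_hat <- pmin(pmax(rho_hat, 0), 1 - 1e-9)

  tab <- study_table(study_id = study,
                     outcome_id = rep(seq_len(outcomes_per_study), r),
                     icc = rho_hat, n = N[study], k = k[study],
                     study_weight = w_m[study], outcome_weight = w_ml,
                     label = "simulated")
  attr(tab, "truth") <- list(mu = mu, sigma_b = sigma_b, sigma_w = sigma_w,
                             mu_m = mu_m, rho_ml = rho, mode = mode)
  tab
}

#' Simulate an expert reviewer panel with controllable agreement
#'
#' Generates a ratings matrix (experts in rows, items in columns, values in
#' `[0, 1]`) from a one-factor model: each item carries a latent relevance
#' signal shared by all experts, mixed with independent expert noise so that
#' the latent inter-rater correlation equals `agreement`. Ratings are mapped
#' to `[0, 1]` through the normal CDF. Optionally the last `n_biased` experts
#' are given a systematic shift, emulating panel members whose ratings drift
#' from the consensus and should be detectable by the reliability
#' diagnostics.
#'
#' @param n_experts number of experts (`>= 2`).
#' @param n_items number of rated items.
#' @param agreement latent inter-rater correlation in `[0, 1]`; 1 gives
#'   identical rows, 0 independent raters.
#' @param n_biased number of biased experts (placed in the last rows).
#' @param bias shift (on the latent standard-normal scale) applied to biased
#'   experts before mapping to `[0, 1]`.
#' @return a numeric matrix with rownames `R1..RJ` and ratings in `[0, 1]`.
#' @examples
#' set.seed(7)
#' r <- simulate_reviewer_panel(8, 16, agreement = 0.6, n_biased = 2)
#' cronbach_alpha(r)
#' @export
simulate_reviewer_panel <- function(n_experts, n_items, agreement,
                                    n_biased = 0, bias = 1.5) {
  if (n_experts < 2) stop("at least two experts required")
  if (n_items < 1) stop("at least one item required")
  if (!is.finite(agreement) || agreement < 0 || agreement > 1)
    stop("agreement must lie in [0, 1]")
  if (n_biased < 0 || n_biased > n_experts) stop("invalid n_biased")
  signal <- stats::rnorm(n_items)
  noise <- matrix(stats::rnorm(n_experts * n_items), n_experts, n_items)
  latent <- sqrt(agreement) * matrix(signal, n_experts, n_items, byrow = TRUE) +
    sqrt(1 - agreement) * noise
  if (n_biased > 0)
    latent[seq.int(n_experts - n_biased + 1L, n_experts), ] <-
      latent[seq.int(n_experts - n_biased + 1L, n_experts), ] + bias
  ratings <- stats::pnorm(latent)
  dimnames(ratings) <- list(paste0("R", seq_len(n_experts)),
                            paste0("item", seq_len(n_items)))
  ratings
}
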
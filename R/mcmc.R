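#' Control parameters for the hierarchical ICC model fit
#'
#' Collects the prior specification and sampler settings used by
#' [icc_fit()]. The priors are deliberately vague: a `N(0, 10000)` prior
#' (variance parameterisation) on the grand logit-ICC mean and `U[0, 5]`
#' priors on both hierarchy standard deviations.
#'
#' @param n_chains number of independent chains.
#' @param n_iter iterations per chain (including burn-in).
#' @param n_burnin burn-in iterations discarded per chain; proposal scales
#'   adapt only during burn-in, so retained draws come from a fixed kernel.
#' @param thin keep every `thin`-th retained iteration.
#' @param prior_mu_mean,prior_mu_var normal prior on the grand mean of the
#'   logit ICCs.
#' @param prior_sigma_upper upper bound of the uniform priors on the
#'   between-study and within-study SDs (logit scale).
#' @param variance_at where the Swiger observation variance is evaluated:
#'   `"latent"` (at the latent true ICC, the model as written) or
#'   `"observed"` (fixed at the observed estimate, the plug-in convention).
#' @param proposal_scale initial random-walk SD for the logit-ICC Metropolis
#'   updates; adapted during burn-in towards a 0.2-0.5 acceptance rate.
#' @param variance_inflation multiplier applied to every observation
#'   variance; useful for sensitivity analyses and prior-predictive checks
#'   (a very large value makes the data uninformative).
#' @param seed integer seed making the whole fit reproducible; `NULL` leaves
#'   the RNG state untouched.
#' @return a list of class `"icc_control"`.
#' @export
icc_control <- function(n_chains = 4, n_iter = 30000, n_burnin = 10000,
                        thin = 1, prior_mu_mean = 0, prior_mu_var = 10000,
                        prior_sigma_upper = 5,
                        variance_at = c("latent", "observed"),
                        proposal_scale = 0.5, variance_inflation = 1,
                        seed = NULL) {
  variance_at <- match.arg(variance_at)
  if (n_chains < 1) stop("n_chains must be at least 1")
  if (n_burnin < 0 || n_iter <= n_burnin)
    stop("need n_iter > n_burnin >= 0")
  if (thin < 1) stop("thin must be at least 1")
  if (prior_mu_var <= 0 || prior_sigma_upper <= 0 || proposal_scale <= 0 ||
      variance_inflation <= 0)
    stop("prior and proposal parameters must be positive")
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 prior_mu_mean = prior_mu_mean, prior_mu_var = prior_mu_var,
                 prior_sigma_upper = prior_sigma_upper,
                 variance_at = variance_at,
                 proposal_scale = proposal_scale,
                 variance_inflation = variance_inflation,
                 seed = seed),
            class = "icc_control")
}

# internal: per-record data in sampler order
model_data <- function(tab, control) {
  tab <- validate_study_table(as.data.frame(tab))
  if (nrow(tab) == 0L) stop("empty study table")
  study <- match(tab$study_id, unique(tab$study_id))
  list(tab = tab,
       rho_hat = tab$icc, N = tab$n, k = tab$k,
       w_l = tab$outcome_weight,
       study = study,
       study_ids = unique(tab$study_id),
       w_m = tab$study_weight[!duplicated(study)],
       r = max(study), L = nrow(tab),
       v_obs = swiger_variance(tab$icc, tab$n, tab$k) *
         control$variance_inflation)
}

# internal: vectorised observation log-likelihood per record
obs_loglik <- function(rho, md, control) {
  if (control$variance_at == "latent") {
    v <- swiger_variance(rho, md$N, md$k) * control$variance_inflation
  } else {
    v <- md$v_obs
  }
  stats::dnorm(md$rho_hat, rho, sqrt(v), log = TRUE)
}

#' Joint log posterior of the hierarchical ICC model
#'
#' Evaluates the unnormalised log posterior targeted by [icc_fit()] at one
#' parameter state: the sum of the Swiger-variance normal likelihood of each
#' observed estimate, the logit-normal record level
#' `logit(rho_ml) ~ N(mu_m, sigma_w^2 / w_ml)`, the study level
#' `mu_m ~ N(mu, sigma_b^2 / w_m)`, and the priors. Latent-ICC densities are
#' evaluated on the logit scale (the scale on which the model is specified
#' and the sampler moves). A state outside the support (a sigma outside
#' `(0, upper]`, a latent ICC outside `(0, 1)`) returns `-Inf` rather than
#' raising an error.
#'
#' @param state a list with elements `mu` (scalar), `sigma_b`, `sigma_w`
#'   (scalars), `mu_m` (one value per study, in table order) and `rho`
#'   (one latent ICC per record, in table order).
#' @param tab a [study_table()].
#' @param control an [icc_control()].
#' @return a single number, possibly `-Inf`.
#' @export
icc_log_posterior <- function(state, tab, control = icc_control()) {
  md <- model_data(tab, control)
  if (length(state$mu_m) != md$r || length(state$rho) != md$L)
    stop("state dimensions do not match the table")
  up <- control$prior_sigma_upper
  if (!is.finite(state$mu) ||
      !is.finite(state$sigma_b) || state$sigma_b <= 0 || state$sigma_b > up ||
      !is.finite(state$sigma_w) || state$sigma_w <= 0 || state$sigma_w > up ||
      any(!is.finite(state$mu_m)) ||
      any(!is.finite(state$rho)) || any(state$rho <= 0) || any(state$rho >= 1))
    return(-Inf)
  theta <- stats::qlogis(state$rho)
  sum(obs_loglik(state$rho, md, control)) +
    sum(stats::dnorm(theta, state$mu_m[md$study],
                     state$sigma_w / sqrt(md$w_l), log = TRUE)) +
    sum(stats::dnorm(state$mu_m, state$mu,
                     state$sigma_b / sqrt(md$w_m), log = TRUE)) +
    stats::dnorm(state$mu, control$prior_mu_mean,
                 sqrt(control$prior_mu_var), log = TRUE) +
    stats::dunif(state$sigma_b, 0, up, log = TRUE) +
    stats::dunif(state$sigma_w, 0, up, log = TRUE)
}

# internal: slice sampler for a bounded-support sigma conditional,
# by shrinkage from the full interval (0, upper]
slice_sigma <- function(cur, logf, upper) {
  ly <- logf(cur) - stats::rexp(1)
  lo <- 0
  hi <- upper
  for (i in 1:1000) {
    x <- stats::runif(1, lo, hi)
    if (logf(x) >= ly) return(x)
    if (x < cur) lo <- x else hi <- x
  }
  cur  # interval shrunk to numeric noise; keep current value
}

# internal: one chain of the Metropolis-within-Gibbs sampler
run_chain <- function(md, control, chain_id) {
  L <- md$L; r <- md$r
  study <- md$study
  w_l <- md$w_l; w_m <- md$w_m
  up <- control$prior_sigma_upper
  pm <- control$prior_mu_mean
  pv <- control$prior_mu_var
  sum_w_l <- as.numeric(rowsum(w_l, study))

  # overdispersed but sane initial values
  theta <- stats::qlogis(pmin(pmax(md$rho_hat, 0.002), 0.998)) +
    stats::rnorm(L, 0, 0.3)
  mu_m <- as.numeric(rowsum(w_l * theta, study)) / sum_w_l +
    stats::rnorm(r, 0, 0.3)
  mu <- mean(mu_m) + stats::rnorm(1, 0, 0.5)
  sig_b <- stats::runif(1, 0.3, min(2, up))
  sig_w <- stats::runif(1, 0.2, min(1.5, up))

  s_theta <- rep(control$proposal_scale, L)
  s_shift <- 1
  acc_theta <- numeric(L)
  acc_shift <- 0
  window <- 50L

  n_keep <- (control$n_iter - control$n_burnin) %/% control$thin
  cols <- 3L + r + L + 1L
  out <- matrix(NA_real_, n_keep, cols)
  colnames(out) <- c("mu", "sigma_b", "sigma_w",
                     paste0("mu_m[", md$study_ids, "]"),
                     paste0("rho[", seq_len(L), "]"), "rho_star")
  keep <- 0L
  acc_theta_total <- 0
  n_theta_total <- 0

  for (it in seq_len(control$n_iter)) {
    in_burn <- it <= control$n_burnin

    # mu | mu_m, sig_b  (conjugate)
    prec <- 1 / pv + sum(w_m) / sig_b^2
    mn <- (pm / pv + sum(w_m * mu_m) / sig_b^2) / prec
    mu <- stats::rnorm(1, mn, sqrt(1 / prec))

    # mu_m | theta, mu, sigmas  (conjugate, vectorised over studies)
    prec_m <- w_m / sig_b^2 + sum_w_l / sig_w^2
    mn_m <- (w_m * mu / sig_b^2 +
               as.numeric(rowsum(w_l * theta, study)) / sig_w^2) / prec_m
    mu_m <- stats::rnorm(r, mn_m, sqrt(1 / prec_m))

    # sigma_b, sigma_w | rest  (slice within (0, upper])
    ssb <- sum(w_m * (mu_m - mu)^2)
    sig_b <- slice_sigma(sig_b, function(s)
      -r * log(s) - ssb / (2 * s^2), up)
    ssw <- sum(w_l * (theta - mu_m[study])^2)
    sig_w <- slice_sigma(sig_w, function(s)
      -L * log(s) - ssw / (2 * s^2), up)

    # theta | rest  (vectorised random-walk Metropolis; the theta are
    # conditionally independent given mu_m and sigma_w)
    cur_ll <- obs_loglik(stats::plogis(theta), md, control)
    prop <- theta + s_theta * stats::rnorm(L)
    la <- obs_loglik(stats::plogis(prop), md, control) +
      stats::dnorm(prop, mu_m[study], sig_w / sqrt(w_l), log = TRUE) -
      cur_ll -
      stats::dnorm(theta, mu_m[study], sig_w / sqrt(w_l), log = TRUE)
    acc <- is.finite(la) & log(stats::runif(L)) < la
    theta[acc] <- prop[acc]
    acc_theta <- acc_theta + acc
    acc_theta_total <- acc_theta_total + sum(acc)
    n_theta_total <- n_theta_total + L

    # joint translation move: shift mu, mu_m and all theta together.
    # The hierarchy terms are translation-invariant, so only the mu prior
    # and the observation likelihood enter the ratio; this move carries the
    # chain along the near-flat common-shift direction that the one-at-a-
    # time updates traverse slowly when the likelihood is weak.
    delta <- s_shift * stats::rnorm(1)
    cur_ll <- obs_loglik(stats::plogis(theta), md, control)
    la <- sum(obs_loglik(stats::plogis(theta + delta), md, control)) -
      sum(cur_ll) +
      stats::dnorm(mu + delta, pm, sqrt(pv), log = TRUE) -
      stats::dnorm(mu, pm, sqrt(pv), log = TRUE)
    if (is.finite(la) && log(stats::runif(1)) < la) {
      mu <- mu + delta
      mu_m <- mu_m + delta
      theta <- theta + delta
      acc_shift <- acc_shift + 1
    }

    if (!all(is.finite(c(mu, mu_m, theta, sig_b, sig_w))))
      stop("chain ", chain_id, " diverged at iteration ", it)

    # burn-in only adaptation towards a 0.2-0.5 acceptance band
    if (in_burn && it %% window == 0L) {
      rate <- acc_theta / window
      s_theta <- s_theta * ifelse(rate < 0.2, 0.7,
                                  ifelse(rate > 0.5, 1.4, 1))
      acc_theta <- numeric(L)
      srate <- acc_shift / window
      s_shift <- s_shift * if (srate < 0.2) 0.7 else
        if (srate > 0.5) 1.4 else 1
      acc_shift <- 0
    }

    if (!in_burn && (it - control$n_burnin) %% control$thin == 0L) {
      keep <- keep + 1L
      # posterior predictive ICC for a new study/outcome with unit weights
      mu_star <- stats::rnorm(1, mu, sig_b)
      rho_star <- stats::plogis(stats::rnorm(1, mu_star, sig_w))
      out[keep, ] <- c(mu, sig_b, sig_w, mu_m, stats::plogis(theta),
                       rho_star)
    }
  }
  attr(out, "acceptance") <- c(theta = acc_theta_total / n_theta_total,
                               shift = NA_real_)
  out
}

#' Fit the weighted Bayesian hierarchical ICC synthesis model
#'
#' Pools a table of externally reported ICC estimates through the weighted
#' logit-normal hierarchy
#' \deqn{\hat\rho_{ml} \sim N(\rho_{ml}, V(\rho_{ml}, N_{ml}, k_{ml})),\quad
#'   \mathrm{logit}(\rho_{ml}) \sim N(\mu_m, \sigma_w^2 / w_{ml}),\quad
#'   \mu_m \sim N(\mu, \sigma_b^2 / w_m),}
#' with Swiger's formula for the observation variance `V`, vague priors
#' `mu ~ N(0, 10000)` and `sigma_b, sigma_w ~ U[0, 5]`, and study/outcome
#' relevance weights `w_m`, `w_ml` in `(0, 1]` dividing the hierarchy
#' variances (a half-weight doubles an estimate's effective variance).
#'
#' Sampling is Metropolis-within-Gibbs: exact conjugate Gibbs updates for
#' `mu` and the study means `mu_m`, bounded slice updates for the two SDs,
#' vectorised random-walk Metropolis on the logit scale for the latent
#' record-level ICCs (non-conjugate because `V` depends on the latent value),
#' and a joint translation move along the common-shift direction. Each
#' retained iteration also draws the posterior *predictive* ICC
#' `rho_star` for a new study and outcome with unit weights — the quantity a
#' trial designer needs — by drawing `mu* ~ N(mu, sigma_b^2)` and
#' `rho_star = plogis(rnorm(1, mu*, sigma_w^2))`.
#'
#' @param tab a [study_table()]; all weights must be strictly positive.
#' @param control an [icc_control()].
#' @param seed integer seed (overrides `control$seed`); given a seed the draw
#'   sequence is bit-reproducible.
#' @return an object of class `"icc_fit"`: a list with `draws` (one matrix
#'   per chain, columns `mu`, `sigma_b`, `sigma_w`, `mu_m[...]`, `rho[...]`,
#'   `rho_star`), `table`, `control`, `acceptance` and `call`. Use
#'   [summary.icc_fit()], [predict.icc_fit()], [convergence_diagnostics()]
#'   and [dic()] on it.
#' @examples
#' set.seed(1)
#' tab <- simulate_study_table(8, 2, mu = -3)
#' fit <- icc_fit(tab, icc_control(n_chains = 2, n_iter = 1500,
#'                                 n_burnin = 500), seed = 1)
#' summary(fit)
#' @export
icc_fit <- function(tab, control = icc_control(), seed = control$seed) {
  stopifnot(inherits(control, "icc_control"))
  md <- model_data(tab, control)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(as.integer(seed))
  }
  draws <- vector("list", control$n_chains)
  accept <- numeric(control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    draws[[ch]] <- run_chain(md, control, ch)
    accept[ch] <- attr(draws[[ch]], "acceptance")[["theta"]]
    attr(draws[[ch]], "acceptance") <- NULL
  }
  structure(list(draws = draws, table = md$tab, control = control,
                 acceptance = accept, seed = seed,
                 call = match.call()),
            class = "icc_fit")
}

# internal: pooled draws across chains
as_draws_matrix <- function(fit) {
  do.call(rbind, fit$draws)
}
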
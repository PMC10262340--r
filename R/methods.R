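#' Posterior summary of a vector of MCMC draws
#'
#' Computes the mean, standard deviation (denominator `n - 1`), Monte-Carlo
#' standard error of the mean by batch means with `floor(sqrt(n))` batches,
#' and the 2.5/25/50/75/97.5 empirical percentiles (linear interpolation).
#'
#' @param x numeric vector of at least 100 retained draws.
#' @return a named numeric vector with elements `mean`, `sd`, `mc_error`,
#'   `q2.5`, `q25`, `q50`, `q75`, `q97.5`.
#' @examples
#' posterior_summary(seq_len(10000) / 10001)
#' @export
posterior_summary <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 100L) stop("at least 100 draws required, got ", n)
  b <- floor(sqrt(n))
  nb <- n %/% b
  bm <- colMeans(matrix(x[seq_len(b * nb)], nrow = nb))
  mce <- stats::sd(bm) / sqrt(b)
  q <- stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975),
                       names = FALSE, type = 7)
  c(mean = mean(x), sd = stats::sd(x), mc_error = mce,
    q2.5 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q97.5 = q[5])
}

#' Summarise a fitted ICC synthesis model
#'
#' One row per monitored quantity (grand mean `mu`, hierarchy SDs, study
#' means, latent record ICCs and the predictive ICC `rho_star`), in the
#' format posterior tables for this model are conventionally reported:
#' posterior mean, SD, Monte-Carlo error and the 2.5/25/50/75/97.5
#' percentiles.
#'
#' @param object an [icc_fit()].
#' @param pars optional character vector restricting the rows (exact column
#'   names, or one of the shortcuts `"main"` = mu/sigmas/rho_star).
#' @param ... unused.
#' @return a matrix of class `"summary.icc_fit"`.
#' @export
summary.icc_fit <- function(object, pars = NULL, ...) {
  dm <- as_draws_matrix(object)
  if (!is.null(pars)) {
    if (identical(pars, "main"))
      pars <- c("mu", "sigma_b", "sigma_w", "rho_star")
    miss <- setdiff(pars, colnames(dm))
    if (length(miss)) stop("unknown parameter(s): ", paste(miss, collapse = ", "))
    dm <- dm[, pars, drop = FALSE]
  }
  out <- t(apply(dm, 2L, posterior_summary))
  class(out) <- c("summary.icc_fit", class(out))
  out
}

#' @export
print.summary.icc_fit <- function(x, digits = 4, ...) {
  cat("Posterior summaries (pooled over chains):\n")
  print(signif(unclass(x), digits))
  invisible(x)
}

#' @export
print.icc_fit <- function(x, ...) {
  ctl <- x$control
  cat("Bayesian hierarchical ICC synthesis fit\n")
  cat(sprintf("  %d record(s) from %d study(ies); %d chain(s) x %d iterations (%d burn-in, thin %d)\n",
              nrow(x$table), length(unique(x$table$study_id)),
              ctl$n_chains, ctl$n_iter, ctl$n_burnin, ctl$thin))
  cat(sprintf("  observation variance evaluated at the %s ICC\n",
              ctl$variance_at))
  s <- summary(x, pars = "main")
  cat("\n")
  print(s)
  cat(sprintf("\nMean Metropolis acceptance (latent ICC updates): %.2f\n",
              mean(x$acceptance)))
  invisible(x)
}

#' @export
coef.icc_fit <- function(object, ...) {
  s <- summary(object, pars = c("mu", "sigma_b", "sigma_w", "rho_star"))
  stats::setNames(s[, "q50"], rownames(s))
}

#' Posterior predictive ICC draws or quantiles
#'
#' The predictive ICC `rho_star` is the model's answer to "what ICC should
#' the planned trial expect for a new, fully relevant study and outcome":
#' it integrates over the posterior of the grand mean and both heterogeneity
#' SDs. Feed the draws (or selected quantiles) into
#' [sample_size_over_quantiles()] or [min_cluster_size()].
#'
#' @param object an [icc_fit()].
#' @param type `"draws"` for the raw predictive draws, `"quantiles"` for
#'   selected quantiles.
#' @param probs quantile levels when `type = "quantiles"`.
#' @param ... unused.
#' @return numeric vector of draws, or named vector of quantiles.
#' @export
predict.icc_fit <- function(object, type = c("draws", "quantiles"),
                            probs = c(0.025, 0.25, 0.5, 0.75, 0.975), ...) {
  type <- match.arg(type)
  rs <- as_draws_matrix(object)[, "rho_star"]
  if (type == "draws") return(as.numeric(rs))
  stats::quantile(rs, probs, type = 7)
}

#' Standardised residuals of the observed ICC estimates
#'
#' `(rho_hat - E[rho | data]) / sqrt(V)`, with the Swiger variance evaluated
#' at the posterior mean of each latent ICC: a record whose observed estimate
#' sits far from its shrunken latent value relative to its own sampling
#' error.
#'
#' @param object an [icc_fit()].
#' @param ... unused.
#' @return numeric vector, one value per record (table order).
#' @export
residuals.icc_fit <- function(object, ...) {
  dm <- as_draws_matrix(object)
  rho_cols <- grep("^rho\\[", colnames(dm))
  post_mean <- colMeans(dm[, rho_cols, drop = FALSE])
  tab <- object$table
  v <- swiger_variance(post_mean, tab$n, tab$k) *
    object$control$variance_inflation
  as.numeric((tab$icc - post_mean) / sqrt(v))
}

#' Posterior predictive simulation of observed ICC estimates
#'
#' For each requested replicate, takes one retained posterior draw of the
#' latent record-level ICCs and redraws the observed estimates from the
#' Swiger sampling model at the recorded study sizes (clipped to `[0, 1)` as
#' published estimates are). Useful for posterior predictive checks against
#' the observed table.
#'
#' @param object an [icc_fit()].
#' @param nsim number of replicated tables.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a matrix with `nsim` rows and one column per record.
#' @export
simulate.icc_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dm <- as_draws_matrix(object)
  rho_cols <- grep("^rho\\[", colnames(dm))
  idx <- sample.int(nrow(dm), nsim, replace = nsim > nrow(dm))
  tab <- object$table
  out <- matrix(NA_real_, nsim, length(rho_cols))
  for (i in seq_len(nsim)) {
    rho <- dm[idx[i], rho_cols]
    v <- swiger_variance(rho, tab$n, tab$k) * object$control$variance_inflation
    out[i, ] <- pmin(pmax(stats::rnorm(length(rho), rho, sqrt(v)), 0), 1 - 1e-9)
  }
  colnames(out) <- paste(tab$study_id, tab$outcome_id, sep = ".")
  out
}

#' @export
plot.icc_fit <- function(x, which = c("density", "trace"), ...) {
  which <- match.arg(which)
  if (which == "density") {
    rs <- predict(x)
    graphics::plot(stats::density(rs, from = 0, to = 1),
                   main = "Posterior predictive ICC", xlab = "ICC", ...)
    graphics::abline(v = stats::median(rs), lty = 2)
  } else {
    graphics::matplot(sapply(x$draws, function(d) d[, "rho_star"]),
                      type = "l", lty = 1, xlab = "retained iteration",
                      ylab = "rho_star", main = "Trace by chain", ...)
  }
  invisible(x)
}

#' Split-chain R-hat and effective sample size
#'
#' Per-quantity potential scale reduction factor computed on split chains
#' (each chain halved, between/within variance compared) and a Geyer
#' initial-positive-sequence effective sample size. R-hat is floored at 1;
#' the run is flagged when any monitored quantity exceeds 1.05.
#'
#' @param fit an [icc_fit()] with at least 2 chains, or one chain of at
#'   least 200 retained draws.
#' @param pars optional subset of monitored quantities.
#' @return a data.frame with columns `par`, `rhat`, `ess`, plus an attribute
#'   `"converged"` (`TRUE` if all R-hat <= 1.05).
#' @export
convergence_diagnostics <- function(fit, pars = NULL) {
  chains <- fit$draws
  n <- nrow(chains[[1]])
  if (length(chains) < 2L && n < 200L)
    stop("need at least 2 chains, or one chain of >= 200 draws")
  if (is.null(pars)) pars <- colnames(chains[[1]])
  half <- n %/% 2L
  res <- t(vapply(pars, function(p) {
    segs <- unlist(lapply(chains, function(d)
      list(d[seq_len(half), p], d[seq.int(half + 1L, 2L * half), p])),
      recursive = FALSE)
    m <- vapply(segs, mean, 0)
    v <- vapply(segs, stats::var, 0)
    W <- mean(v)
    B <- half * stats::var(m)
    rhat <- if (W <= 0) 1 else max(1, sqrt(((half - 1) / half * W + B / half) / W))
    c(rhat = rhat, ess = ess_ips(chains, p))
  }, c(rhat = 0, ess = 0)))
  out <- data.frame(par = pars, rhat = res[, "rhat"], ess = res[, "ess"],
                    row.names = NULL)
  attr(out, "converged") <- all(out$rhat <= 1.05)
  out
}

# internal: effective sample size via Geyer's initial positive sequence,
# averaged across chains
ess_ips <- function(chains, p) {
  per_chain <- vapply(chains, function(d) {
    x <- d[, p]
    n <- length(x)
    if (stats::var(x) == 0) return(n)
    ac <- stats::acf(x, lag.max = min(n - 1L, 200L), plot = FALSE,
                     demean = TRUE)$acf[, 1, 1]
    s <- 0
    t <- 1L
    while (t + 1L < length(ac)) {
      pair <- ac[t + 1L] + ac[t + 2L]
      if (pair < 0) break
      s <- s + pair
      t <- t + 2L
    }
    n / (1 + 2 * s)
  }, 0)
  sum(per_chain)
}

#' Deviance information criterion of a fitted ICC synthesis model
#'
#' `DIC = Dbar + pD` with deviance `D = -2 log L` focused on the observation
#' level (the Swiger-variance normal likelihood of the observed estimates
#' given the latent record ICCs). `Dbar` is the posterior mean deviance and
#' `pD = Dbar - D(posterior mean of the latent ICCs)` the effective number
#' of parameters. Lower is better; the criterion is used to compare fits of
#' the same table under different weighting schemes, or full-table fits
#' against most-relevant-subset refits.
#'
#' @param fit an [icc_fit()].
#' @return a list with elements `dic`, `mean_deviance` and `p_d`.
#' @export
dic <- function(fit) {
  md <- model_data(fit$table, fit$control)
  dm <- as_draws_matrix(fit)
  rho_cols <- grep("^rho\\[", colnames(dm))
  if (length(rho_cols) != md$L)
    stop("draws dimension does not match the table")
  dev <- apply(dm[, rho_cols, drop = FALSE], 1L, function(rho)
    -2 * sum(obs_loglik(rho, md, fit$control)))
  dbar <- mean(dev)
  dhat <- -2 * sum(obs_loglik(colMeans(dm[, rho_cols, drop = FALSE]),
                              md, fit$control))
  p_d <- dbar - dhat
  list(dic = dbar + p_d, mean_deviance = dbar, p_d = p_d)
}
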
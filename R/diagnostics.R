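# Convergence and identifiability diagnostics: rank-normalized split
# R-hat, bulk effective sample size, and posterior contraction against the
# priors of the fitting model.

# iterations x chains matrix from an mcmc.list, one parameter
chain_matrix <- function(mcmc, par) {
  sapply(mcmc, function(ch) as.numeric(ch[, par]))
}

# rank-normalize (fractional ranks -> normal scores), then split each
# chain in half; returns iterations x (2*chains) matrix
rank_norm_split <- function(x) {
  z <- stats::qnorm((rank(x) - 3 / 8) / (length(x) + 1 / 4))
  z <- matrix(z, nrow(x), ncol(x))
  half <- nrow(z) %/% 2
  cbind(z[seq_len(half), , drop = FALSE],
        z[nrow(z) - half + seq_len(half), , drop = FALSE])
}

#' Rank-normalized split R-hat
#'
#' Potential scale reduction factor computed on rank-normalized draws with
#' each chain split in half, so it detects both between-chain location
#' differences and within-chain trends.
#'
#' @param x An iterations x chains numeric matrix of draws for one
#'   parameter.
#' @return A single number; values at or below 1.01 indicate convergence.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("R-hat requires at least two chains")
  z <- rank_norm_split(x)
  n <- nrow(z); m <- ncol(z)
  means <- colMeans(z)
  vars <- apply(z, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  var_hat <- (n - 1) / n * W + B / n
  sqrt(var_hat / W)
}

#' Bulk effective sample size
#'
#' Effective number of independent draws for a parameter, computed on
#' rank-normalized split chains with autocorrelations combined across
#' chains and truncated by Geyer's initial monotone positive sequence.
#'
#' @inheritParams split_rhat
#' @return A single number (capped at the total number of draws).
#' @export
bulk_ess <- function(x) {
  x <- as.matrix(x)
  z <- rank_norm_split(x)
  n <- nrow(z); m <- ncol(z)
  if (n < 4L) return(NA_real_)
  vars <- apply(z, 2, stats::var)
  W <- mean(vars)
  var_hat <- (n - 1) / n * W + n * stats::var(colMeans(z)) / n
  if (!is.finite(var_hat) || var_hat <= 0) return(NA_real_)
  # per-chain autocovariances, averaged
  acov <- sapply(seq_len(m), function(j) {
    a <- stats::acf(z[, j], lag.max = n - 1, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_hat
  # Geyer initial positive monotone sequence on paired autocorrelation sums
  pair_sum <- numeric(0)
  t <- 1L
  while (t + 1L <= length(rho)) {
    p <- rho[t] + rho[t + 1L]
    if (p <= 0) break
    pair_sum <- c(pair_sum, p)
    t <- t + 2L
  }
  if (length(pair_sum) > 1L) pair_sum <- cummin(pair_sum)
  # tau = rho_0 + 2 * sum_{t>=1} rho_t, with the paired-sum truncation
  tau <- -rho[1] + 2 * sum(pair_sum)
  ess <- m * n / max(tau, 1 / (m * n))
  min(ess, m * n)
}

# prior variances on the sampling scale; half-Cauchy sigmas handled on the
# log scale where Var(log |Cauchy(0,1)|) = pi^2 / 4
prior_variance_table <- function() {
  c(logB0 = 1, logr = 1, logBmin = 1, beta = 4, gamma = 25,
    log_sigma = pi^2 / 4)
}

#' Convergence and identifiability report
#'
#' Split R-hat and bulk effective sample size for every monitored
#' parameter, plus posterior contraction
#' `1 - Var_posterior / Var_prior` for the model's top-level parameters.
#' Contraction of the half-Cauchy scale parameters is computed on the log
#' scale (their natural-scale prior variance is infinite); jurisdiction
#' random effects are reported for R-hat/ESS but carry no contraction
#' value because their marginal prior variance under the half-Cauchy
#' hyperprior is undefined.
#'
#' @param fit A [fit_reef_model()] result (needs at least two chains).
#' @return A tibble with columns `parameter`, `rhat`, `ess`,
#'   `contraction`.
#' @export
diagnostics <- function(fit) {
  mcmc <- if (inherits(fit, "reef_fit")) fit$mcmc else fit
  if (length(mcmc) < 2L) stop("R-hat requires at least two chains")
  pars <- colnames(mcmc[[1]])
  pv <- prior_variance_table()
  rows <- lapply(pars, function(p) {
    x <- chain_matrix(mcmc, p)
    post <- as.numeric(x)
    contraction <- NA_real_
    if (p %in% c("logB0", "logr", "logBmin", "gamma")) {
      contraction <- 1 - stats::var(post) / pv[[p]]
    } else if (grepl("^beta\\[", p)) {
      contraction <- 1 - stats::var(post) / pv[["beta"]]
    } else if (grepl("^sig_", p)) {
      contraction <- 1 - stats::var(log(post)) / pv[["log_sigma"]]
    }
    tibble::tibble(parameter = p, rhat = split_rhat(x), ess = bulk_ess(x),
                   contraction = contraction)
  })
  dplyr::bind_rows(rows)
}

#' Posterior contraction from explicit variances
#'
#' `1 - Var_posterior / Var_prior`: 0 when the data leave the prior
#' untouched, approaching 1 as the posterior concentrates.
#'
#' @param var_post,var_prior Positive variances.
#' @return Contraction value.
#' @export
posterior_contraction <- function(var_post, var_prior) {
  stopifnot(var_prior > 0, var_post >= 0)
  1 - var_post / var_prior
}
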
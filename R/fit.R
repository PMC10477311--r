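# Joint hierarchical model of reserve recovery, remote-reef baselines and
# fished-reef biomass, fitted by MCMC (JAGS). Three lognormal
# sub-likelihoods share the environmental and sampling effect sizes; the
# reserve sub-model carries the recovery trajectory that identifies r and
# Bmin, the remote sub-model anchors unfished biomass B0, and the fished
# sub-model supplies the sampling/gravity corrections used downstream.

# priors of the fitting model (sampling scale)
reef_priors <- function() {
  list(
    logB0 = list(dist = "normal", mean = log(120), sd = 1),
    logr = list(dist = "normal", mean = -2, sd = 1),
    logBmin = list(dist = "normal", mean = log(10), sd = 1),
    beta = list(dist = "normal", mean = 0, sd = 2),
    gamma = list(dist = "normal", mean = 5, sd = 5),
    sigma = list(dist = "half_cauchy", scale = 1)
  )
}

# JAGS model source; sub-model likelihood blocks are included only when the
# corresponding subset is non-empty (a 1:0 loop is not valid BUGS).
reef_model_code <- function(model, ni, nj, nz) {
  recovery <- if (model$family == "fox") {
    "mui[i] <- logB0i[i] + (logBmin - logB0i[i]) * exp(-r * age[i])"
  } else {
    sprintf(paste0(
      "mui[i] <- logB0i[i] - (1 / (%g)) * log(1 + ",
      "(exp((%g) * (logB0i[i] - logBmin)) - 1) * exp(-r * age[i]))"),
      model$n - 1, model$n - 1)
  }
  blk_i <- sprintf("
  for (i in 1:Ni) {
    logB0i[i] <- logB0 + inprod(Xenv_i[i,], beta[1:4])
    %s
    mu_i[i] <- mui[i] + inprod(Xsamp_i[i,], beta[5:11]) +
      rsize[i] * beta[12] + grav_i[i] * beta[13]
    yi[i] ~ dnorm(mu_i[i], pow(sig_i, -2))
  }", recovery)
  blk_j <- "
  for (j in 1:Nj) {
    logB0j[j] <- logB0 + inprod(Xenv_j[j,], beta[1:4])
    mu_j[j] <- logB0j[j] + inprod(Xsamp_j[j,], beta[5:11])
    yj[j] ~ dnorm(mu_j[j], pow(sig_j, -2))
  }"
  blk_z <- "
  for (z in 1:Nz) {
    mu_z[z] <- gamma + inprod(Xsamp_z[z,], beta[5:11]) +
      grav_z[z] * beta[13] + u[jur[z]]
    yz[z] ~ dnorm(mu_z[z], pow(sig_z, -2))
  }"
  paste0("
model {
  logB0 ~ dnorm(", log(120), ", 1)
  logr ~ dnorm(-2, 1)
  logBmin ~ dnorm(", log(10), ", 1)
  r <- exp(logr)
  for (k in 1:13) { beta[k] ~ dnorm(0, 0.25) }
  gamma ~ dnorm(5, 0.04)
  sig_i ~ dt(0, 1, 1) T(0,)
  sig_j ~ dt(0, 1, 1) T(0,)
  sig_z ~ dt(0, 1, 1) T(0,)
  sig_u ~ dt(0, 1, 1) T(0,)
  for (c in 1:Nc) { u[c] ~ dnorm(0, pow(sig_u, -2)) }
",
  if (ni > 0) blk_i else "",
  if (nj > 0) blk_j else "",
  if (nz > 0) blk_z else "",
"\n}\n")
}

# assemble the per-subset design matrices JAGS needs
reef_model_data <- function(d) {
  is_res <- d$category == "reserve"
  is_rem <- d$category == "remote"
  is_fis <- d$category %in% c("restricted", "open")
  jur_levels <- sort(unique(d$jurisdiction_id[is_fis]))
  jur <- match(d$jurisdiction_id[is_fis], jur_levels)
  dat <- list(
    Ni = sum(is_res), Nj = sum(is_rem), Nz = sum(is_fis),
    Nc = max(1L, length(jur_levels))
  )
  if (dat$Ni > 0) {
    dat$Xenv_i <- as.matrix(d[is_res, ENV_X])
    dat$Xsamp_i <- as.matrix(d[is_res, SAMP_X])
    dat$age <- d$reserve_age[is_res]
    dat$rsize <- d$x_reserve_size[is_res]
    dat$grav_i <- d$x_gravity[is_res]
    dat$yi <- log(d$biomass_obs[is_res])
  }
  if (dat$Nj > 0) {
    dat$Xenv_j <- as.matrix(d[is_rem, ENV_X])
    dat$Xsamp_j <- as.matrix(d[is_rem, SAMP_X])
    dat$yj <- log(d$biomass_obs[is_rem])
  }
  if (dat$Nz > 0) {
    dat$Xsamp_z <- as.matrix(d[is_fis, SAMP_X])
    dat$grav_z <- d$x_gravity[is_fis]
    dat$jur <- jur
    dat$yz <- log(d$biomass_obs[is_fis])
  }
  list(jags = dat, jur_levels = jur_levels,
       is_res = is_res, is_rem = is_rem, is_fis = is_fis)
}

#' Fit the joint hierarchical reference-point model
#'
#' Fits the three-component lognormal biomass model by MCMC: reserve sites
#' follow a common recovery trajectory from `Bmin` towards their
#' environmentally-conditioned unfished biomass (space-for-time
#' substitution, with gravity absorbing net biomass export from reserves in
#' depleted seascapes), remote sites sit at unfished biomass, and fished
#' sites get a free intercept with jurisdiction random effects. Priors:
#' `log B0 ~ N(log 120, 1)`, `log r ~ N(-2, 1)`,
#' `log Bmin ~ N(log 10, 1)`, slopes `~ N(0, 2)`, `gamma ~ N(5, 5)`, and
#' half-Cauchy(0, 1) scale parameters.
#'
#' If a `survey_year` column is present and a reserve was surveyed in
#' several years, one year per reserve is selected at random (seeded) so
#' every reserve contributes a single record to the trajectory.
#'
#' Sampler defaults retain `iter` draws per chain after `warmup` adaptation
#' plus burn-in iterations and thinning by `thin`; thinning compensates for
#' the higher autocorrelation of Gibbs-type samplers relative to
#' Hamiltonian ones.
#'
#' @param sites Site table (simulated or read from CSV). May have zero rows
#'   for a prior-only run.
#' @param model A [surplus_model()] for the recovery trajectory.
#' @param chains Number of MCMC chains (>= 2 for convergence diagnostics;
#'   default 4).
#' @param warmup Adaptation + burn-in iterations per chain (default 1000,
#'   split evenly).
#' @param iter Retained posterior draws per chain (default 1000).
#' @param thin Thinning interval (default 10).
#' @param seed Master seed; chain RNGs and the reserve-year selection
#'   derive from it.
#' @param quiet Suppress JAGS progress output.
#' @return An object of class `reef_fit` carrying the posterior draws
#'   (`$mcmc` as a coda `mcmc.list`, `$draws` as a draws x parameters
#'   matrix with derived `B0`, `r`, `Bmin` appended), the standardization
#'   spec, the data actually fitted, the priors, and the sampler settings.
#' @export
fit_reef_model <- function(sites, model = surplus_model("fox"),
                           chains = 4, warmup = 1000, iter = 1000,
                           thin = 10, seed = 1, quiet = TRUE) {
  stopifnot(chains >= 1, iter >= 2, warmup >= 0, thin >= 1)
  set.seed(seed)
  sites <- tibble::as_tibble(sites)
  if (nrow(sites) > 0 && "survey_year" %in% names(sites)) {
    res <- sites$category == "reserve"
    keep <- rep(TRUE, nrow(sites))
    for (id in unique(sites$site_id[res])) {
      rows <- which(res & sites$site_id == id)
      if (length(rows) > 1L) {
        keep[rows] <- FALSE
        keep[sample(rows, 1L)] <- TRUE
      }
    }
    sites <- sites[keep, ]
  }

  if (nrow(sites) > 0) {
    std <- standardize_covariates(sites)
    md <- reef_model_data(std$data)
    spec <- std$spec
  } else {
    md <- list(jags = list(Ni = 0L, Nj = 0L, Nz = 0L, Nc = 1L),
               jur_levels = character(0))
    spec <- NULL
    std <- list(data = sites)
  }
  code <- reef_model_code(model, md$jags$Ni, md$jags$Nj, md$jags$Nz)
  # JAGS warns on data it never reads; drop counts of empty subsets
  for (nm in c("Ni", "Nj", "Nz")) {
    if (md$jags[[nm]] == 0L) md$jags[[nm]] <- NULL
  }

  inits <- lapply(seq_len(chains), function(ch) {
    set.seed(seed * 1000L + ch)
    list(
      logB0 = log(120) + stats::rnorm(1, 0, 0.2),
      logr = -2 + stats::rnorm(1, 0, 0.2),
      logBmin = log(10) + stats::rnorm(1, 0, 0.2),
      beta = stats::rnorm(13, 0, 0.1),
      gamma = 4 + stats::rnorm(1, 0, 0.3),
      sig_i = stats::runif(1, 0.2, 1), sig_j = stats::runif(1, 0.2, 1),
      sig_z = stats::runif(1, 0.2, 1), sig_u = stats::runif(1, 0.2, 1),
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = seed * 1000L + ch
    )
  })

  jm <- tryCatch(
    rjags::jags.model(textConnection(code), data = md$jags,
                      inits = inits, n.chains = chains,
                      n.adapt = max(100L, warmup %/% 2L), quiet = quiet),
    error = function(e) stop("MCMC initialization failed: ",
                             conditionMessage(e), call. = FALSE)
  )
  if (warmup > 0) update(jm, warmup - warmup %/% 2L, progress.bar = "none")
  vars <- c("logB0", "logr", "logBmin", "beta", "gamma",
            "sig_i", "sig_j", "sig_z", "sig_u", "u")
  mcmc <- rjags::coda.samples(jm, vars, n.iter = iter * thin, thin = thin,
                              progress.bar = if (quiet) "none" else "text")

  draws <- as.matrix(mcmc)
  draws <- cbind(draws,
                 B0 = exp(draws[, "logB0"]),
                 r = exp(draws[, "logr"]),
                 Bmin = exp(draws[, "logBmin"]))
  structure(list(
    mcmc = mcmc, draws = draws, model = model, standardization = spec,
    data = list(sites = sites, std = std$data, subsets = md),
    priors = reef_priors(), seed = seed,
    settings = list(chains = chains, warmup = warmup, iter = iter,
                    thin = thin)
  ), class = "reef_fit")
}

#' @export
print.reef_fit <- function(x, ...) {
  cat("<reef_fit>", x$model$family, "surplus model;",
      x$settings$chains, "chains x", x$settings$iter, "draws\n")
  key <- c("B0", "r", "Bmin", "gamma")
  q <- t(apply(x$draws[, key, drop = FALSE], 2, stats::quantile,
               c(.05, .5, .95)))
  print(round(q, 3))
  invisible(x)
}

#' Expected log-biomass under the joint model
#'
#' The per-site mean of the lognormal biomass likelihood: the recovery
#' trajectory plus sampling, reserve-size and gravity terms for reserves;
#' the environmentally-conditioned unfished biomass plus sampling terms for
#' remote reefs; and the fished intercept plus sampling, gravity and
#' jurisdiction terms for fished reefs.
#'
#' @param params List with `B0`, `r`, `Bmin`, `gamma` and named 13-vector
#'   `beta` (e.g., [sim_params()]).
#' @param data Standardized site table (the `data` element of
#'   [standardize_covariates()]).
#' @param model A [surplus_model()].
#' @param u Named vector of jurisdiction effects (by `jurisdiction_id`);
#'   missing jurisdictions contribute zero.
#' @return Numeric vector of expected log-biomass, one per row.
#' @export
expected_log_biomass <- function(params, data, model = surplus_model("fox"),
                                 u = NULL) {
  n <- nrow(data)
  if (n == 0L) return(numeric(0))
  if (any(!vapply(data[c(ENV_X, SAMP_X)], function(x) all(is.finite(x)),
                  logical(1)))) {
    stop("non-finite covariate in standardized data")
  }
  b <- params$beta[BETA_NAMES]
  log_B0_s <- log(params$B0) + drop(as.matrix(data[ENV_X]) %*% b[1:4])
  samp <- drop(as.matrix(data[SAMP_X]) %*% b[5:11])
  uc <- rep(0, n)
  if (!is.null(u)) {
    hit <- match(data$jurisdiction_id, names(u))
    uc <- ifelse(is.na(hit), 0, u[hit])
  }
  mu <- numeric(n)
  is_res <- data$category == "reserve"
  is_rem <- data$category == "remote"
  is_fis <- data$category %in% c("restricted", "open")
  if (any(is_res)) {
    traj <- recovery_trajectory(data$reserve_age[is_res],
                                exp(log_B0_s[is_res]),
                                params$Bmin, params$r, model)
    mu[is_res] <- log(traj) + samp[is_res] +
      b["reserve_size"] * data$x_reserve_size[is_res] +
      b["gravity"] * data$x_gravity[is_res]
  }
  mu[is_rem] <- log_B0_s[is_rem] + samp[is_rem]
  mu[is_fis] <- params$gamma + samp[is_fis] +
    b["gravity"] * data$x_gravity[is_fis] + uc[is_fis]
  mu
}

#' Joint model log-likelihood
#'
#' Sum of the normal log-densities of observed log-biomass around the
#' expected log-biomass of each sub-model, with subset-specific residual
#' SDs. An empty dataset has log-likelihood zero.
#'
#' @inheritParams expected_log_biomass
#' @param params As in [expected_log_biomass()], plus `sigma_i`, `sigma_j`,
#'   `sigma_z`.
#' @return A single number.
#' @export
log_likelihood <- function(params, data, model = surplus_model("fox"),
                           u = NULL) {
  sum(pointwise_log_density(params, data, model, u))
}

# per-site log-density contributions (vector)
pointwise_log_density <- function(params, data, model, u = NULL) {
  n <- nrow(data)
  if (n == 0L) return(numeric(0))
  mu <- expected_log_biomass(params, data, model, u)
  sig <- ifelse(data$category == "reserve", params$sigma_i,
                ifelse(data$category == "remote", params$sigma_j,
                       params$sigma_z))
  stats::dnorm(log(data$biomass_obs), mu, sig, log = TRUE)
}

#' Pointwise posterior log-likelihood matrix
#'
#' Evaluates, for every posterior draw, the log-density of each
#' observation that entered the fit. This is the input to approximate
#' leave-one-out model comparison.
#'
#' @param fit A [fit_reef_model()] result.
#' @return A draws x observations matrix.
#' @export
pointwise_loglik <- function(fit) {
  d <- fit$data$std
  draws <- fit$draws
  S <- nrow(draws)
  jl <- fit$data$subsets$jur_levels
  out <- matrix(NA_real_, S, nrow(d))
  for (s in seq_len(S)) {
    p <- draw_params(draws, s)
    u <- if (length(jl)) {
      stats::setNames(draws[s, paste0("u[", seq_along(jl), "]")], jl)
    } else NULL
    out[s, ] <- pointwise_log_density(p, d, fit$model, u)
  }
  colnames(out) <- d$site_id
  out
}

# unpack one posterior draw into a params list
draw_params <- function(draws, s) {
  list(
    B0 = exp(draws[s, "logB0"]), r = exp(draws[s, "logr"]),
    Bmin = exp(draws[s, "logBmin"]), gamma = draws[s, "gamma"],
    beta = stats::setNames(draws[s, paste0("beta[", 1:13, "]")], BETA_NAMES),
    sigma_i = draws[s, "sig_i"], sigma_j = draws[s, "sig_j"],
    sigma_z = draws[s, "sig_z"], sigma_u = draws[s, "sig_u"]
  )
}
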
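# Synthetic reef-survey data with the statistical structure the joint
# hierarchical model assumes: a reserve recovery trajectory, remote-reef
# unfished baselines, and fished reefs with jurisdiction random effects.

#' Generating parameters for the synthetic-data model
#'
#' The latent quantities of the joint hierarchical model: community-level
#' unfished biomass `B0` (t/km2, average/most-common conditions), community
#' biomass growth rate `r` (1/y), biomass at reserve age zero `Bmin`
#' (t/km2), the thirteen effect sizes `beta` (environmental effects on log
#' unfished biomass; sampling, reserve-size, and gravity effects on log
#' biomass), the fished-reef intercept `gamma` (log t/km2), residual SDs
#' per data subset (`sigma_i` reserves, `sigma_j` remote, `sigma_z`
#' fished), and the jurisdiction random-effect SD `sigma_u`.
#'
#' Defaults are the package's reference study conditions: `B0 = 120` t/km2
#' and `Bmin = 12` t/km2 (the prior medians of the fitting model),
#' `r = 0.15`/y, `gamma = 3.7` (about 40 t/km2 median fished biomass),
#' moderate effect sizes on the two-SD standardized scale, and a weak
#' negative gravity effect on raw gravity.
#'
#' @param B0,r,Bmin,gamma,sigma_i,sigma_j,sigma_z,sigma_u Scalars, see
#'   description.
#' @param beta Named numeric vector of length 13 (names as in
#'   `reefmsy:::BETA_NAMES`).
#' @return A list of class `reef_params`.
#' @export
sim_params <- function(B0 = 120, r = 0.15, Bmin = 12, gamma = 3.7,
                       beta = c(ocean_prod = 0.2, sst = -0.15, atoll = 0.2,
                                coral = 0.15, depth = 0.1, crest = -0.1,
                                lagoon_backreef = -0.15, flat = -0.2,
                                point_count = 0.15, distance = 0.2,
                                sampling_area = 0.1, reserve_size = 0.1,
                                gravity = -0.02),
                       sigma_i = 0.35, sigma_j = 0.3, sigma_z = 0.5,
                       sigma_u = 0.3) {
  stopifnot(B0 > 0, r > 0, Bmin > 0, Bmin < B0,
            sigma_i >= 0, sigma_j >= 0, sigma_z >= 0, sigma_u >= 0)
  beta <- beta[BETA_NAMES]
  if (any(is.na(beta))) stop("`beta` must be named with all thirteen effects")
  structure(list(B0 = B0, r = r, Bmin = Bmin, gamma = gamma, beta = beta,
                 sigma_i = sigma_i, sigma_j = sigma_j, sigma_z = sigma_z,
                 sigma_u = sigma_u),
            class = "reef_params")
}

#' Sampling design for the synthetic-data generator
#'
#' Counts per management category plus the covariate distributions. The
#' `"paper"` preset mirrors the global compilation's three-subset structure
#' (70 reserves of varying age, 80 remote reefs, 1903 fished sites); the
#' `"desk"` preset (30/20/100) keeps end-to-end runs fast for routine
#' testing.
#'
#' Catch for fished sites is generated as
#' `C = exploitation * surplus(B_latent) * lognormal(0, sigma_catch)`,
#' with a lognormal exploitation mixture so that all four fishery
#' categories (good condition, warning, recovering, unsustainable) arise.
#' This catch process is test scaffolding for the assessment stage, not an
#' estimated quantity.
#'
#' @param preset `"desk"` or `"paper"`.
#' @param n_reserve,n_remote,n_fished Site counts per category.
#' @param n_jurisdiction Number of jurisdictions fished sites are spread
#'   over.
#' @param prop_restricted Proportion of fished sites with gear/effort
#'   restrictions (category `"restricted"` rather than `"open"`).
#' @param exploitation_meanlog,exploitation_sdlog Lognormal mixture for the
#'   per-site exploitation factor multiplying surplus.
#' @param sigma_catch Lognormal observation SD of catches around their
#'   expectation.
#' @param missing_coral_rate Fraction of sites with coral cover masked to
#'   missing, exercising the mean-imputation path.
#' @param remote_travel_range Travel-time range (h) for remote reefs; must
#'   lie above the 20 h remoteness threshold.
#' @return A list of class `reef_design`.
#' @export
sim_design <- function(preset = c("desk", "paper"),
                       n_reserve = NULL, n_remote = NULL, n_fished = NULL,
                       n_jurisdiction = NULL,
                       prop_restricted = 0.5,
                       exploitation_meanlog = log(0.8),
                       exploitation_sdlog = 0.6,
                       sigma_catch = 0.3,
                       missing_coral_rate = 0.1,
                       remote_travel_range = c(21, 60)) {
  preset <- match.arg(preset)
  def <- switch(preset,
    desk = list(n_reserve = 30, n_remote = 20, n_fished = 100, n_jurisdiction = 8),
    paper = list(n_reserve = 70, n_remote = 80, n_fished = 1903, n_jurisdiction = 40)
  )
  d <- list(
    preset = preset,
    n_reserve = n_reserve %||% def$n_reserve,
    n_remote = n_remote %||% def$n_remote,
    n_fished = n_fished %||% def$n_fished,
    n_jurisdiction = n_jurisdiction %||% def$n_jurisdiction,
    prop_restricted = prop_restricted,
    exploitation_meanlog = exploitation_meanlog,
    exploitation_sdlog = exploitation_sdlog,
    sigma_catch = sigma_catch,
    missing_coral_rate = missing_coral_rate,
    remote_travel_range = remote_travel_range
  )
  if (d$n_reserve < 0 || d$n_remote < 0 || d$n_fished < 0) {
    stop("site counts must be non-negative")
  }
  if (d$n_jurisdiction < 1) stop("need at least one jurisdiction")
  if (d$missing_coral_rate < 0 || d$missing_coral_rate >= 1) {
    stop("missing_coral_rate must be in [0, 1)")
  }
  if (min(d$remote_travel_range) <= 20) {
    stop("remote travel times must exceed the 20 h remoteness threshold")
  }
  structure(d, class = "reef_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a synthetic reef-survey dataset
#'
#' Draws covariates, latent expected log-biomass per site (reserve recovery
#' mean, remote unfished mean, fished mean with jurisdiction random
#' effects), lognormal biomass observations, and catches for fished sites,
#' exactly under the joint model's assumptions. The same seed always
#' reproduces the same table.
#'
#' @param params A [sim_params()] truth object.
#' @param design A [sim_design()].
#' @param model A [surplus_model()] governing the reserve recovery
#'   trajectory and the surplus curve behind catch generation.
#' @param seed Master integer seed; all randomness flows from it.
#' @return A list of class `reef_sim` with elements `sites` (one row per
#'   surveyed reef) and `truth` (the generating parameters, per-site
#'   expected log-biomass `mu`, latent site unfished biomass `B0_s`, latent
#'   fished biomass at reference sampling conditions `B_latent`, the
#'   jurisdiction effects, the standardization spec used, the seed and the
#'   design).
#' @export
simulate_reef_data <- function(params = sim_params(), design = sim_design(),
                               model = surplus_model("fox"), seed = 1) {
  stopifnot(inherits(params, "reef_params"), inherits(design, "reef_design"))
  set.seed(seed)
  ni <- design$n_reserve; nj <- design$n_remote; nz <- design$n_fished
  n <- ni + nj + nz
  if (n == 0L) stop("design contains no sites")

  category <- c(rep("reserve", ni), rep("remote", nj),
                ifelse(stats::runif(nz) < design$prop_restricted,
                       "restricted", "open"))
  is_res <- category == "reserve"
  is_rem <- category == "remote"
  is_fis <- !is_res & !is_rem

  jur <- sample.int(design$n_jurisdiction, n, replace = TRUE)
  u <- stats::rnorm(design$n_jurisdiction, 0, params$sigma_u)

  habitat <- character(n)
  habitat[is_res] <- sample(c("slope", "crest", "flat", "lagoon_backreef"),
                            ni, TRUE, prob = c(.4, .25, .2, .15))
  habitat[is_rem] <- sample(c("slope", "crest", "lagoon_backreef"),
                            nj, TRUE, prob = c(.5, .3, .2))
  habitat[is_fis] <- sample(c("slope", "crest", "flat", "lagoon_backreef"),
                            nz, TRUE, prob = c(.4, .25, .2, .15))
  census <- character(n)
  census[is_res] <- sample(c("belt", "point_count"), ni, TRUE, prob = c(.7, .3))
  census[is_rem] <- sample(c("belt", "distance"), nj, TRUE, prob = c(.6, .4))
  census[is_fis] <- sample(c("belt", "point_count", "distance"),
                           nz, TRUE, prob = c(.6, .25, .15))

  sites <- tibble::tibble(
    site_id = sprintf("s%04d", seq_len(n)),
    jurisdiction_id = sprintf("J%02d", jur),
    category = category,
    reserve_age = ifelse(is_res, stats::runif(n, 0.5, 40), NA_real_),
    ocean_prod = stats::rnorm(n, 500, 150),
    sst = stats::rnorm(n, 28, 1.5),
    coral_cover = stats::rbeta(n, 2, 3),
    atoll = stats::rbinom(n, 1, 0.25),
    habitat = habitat,
    depth = stats::runif(n, 2, 15),
    census_method = census,
    sampling_area = stats::rlnorm(n, log(250), 0.5),
    reserve_size = ifelse(is_res, stats::rlnorm(n, log(5), 1), NA_real_),
    gravity = ifelse(is_rem, 0,
                     ifelse(is_res, stats::rlnorm(n, 1, 1),
                            stats::rlnorm(n, 1.5, 1))),
    travel_time_h = ifelse(is_rem,
                           stats::runif(n, design$remote_travel_range[1],
                                        design$remote_travel_range[2]),
                           stats::runif(n, 0.1, 15)),
    uninhabited = is_rem
  )

  std <- standardize_covariates(sites)
  d <- std$data
  b <- params$beta

  # latent site-level unfished biomass from the environmental covariates
  log_B0_s <- log(params$B0) + as.matrix(d[ENV_X]) %*% b[1:4]
  log_B0_s <- drop(log_B0_s)
  samp_term <- drop(as.matrix(d[SAMP_X]) %*% b[5:11])

  mu <- numeric(n)
  # reserves: recovery trajectory from Bmin, plus sampling, size and gravity
  traj <- recovery_trajectory(d$reserve_age[is_res], exp(log_B0_s[is_res]),
                              params$Bmin, params$r, model)
  mu[is_res] <- log(traj) + samp_term[is_res] +
    b["reserve_size"] * d$x_reserve_size[is_res] +
    b["gravity"] * d$x_gravity[is_res]
  # remote: at unfished biomass, sampling effects only (their covariate
  # support excludes flat habitat and point counts)
  mu[is_rem] <- log_B0_s[is_rem] + samp_term[is_rem]
  # fished: intercept + sampling + gravity + jurisdiction effect
  mu[is_fis] <- params$gamma + samp_term[is_fis] +
    b["gravity"] * d$x_gravity[is_fis] + u[jur[is_fis]]

  sig <- ifelse(is_res, params$sigma_i,
                ifelse(is_rem, params$sigma_j, params$sigma_z))
  eps <- stats::rnorm(n, 0, 1) * sig
  sites$biomass_obs <- exp(mu + eps)

  # catches: scattered around a multiple of site-specific surplus evaluated
  # at the latent biomass the site holds at reference sampling conditions
  B_latent <- rep(NA_real_, n)
  B_latent[is_fis] <- exp(mu[is_fis] - samp_term[is_fis] + eps[is_fis])
  catch <- rep(NA_real_, n)
  if (any(is_fis)) {
    exploit <- stats::rlnorm(sum(is_fis), design$exploitation_meanlog,
                             design$exploitation_sdlog)
    P <- surplus(B_latent[is_fis], exp(log_B0_s[is_fis]), params$r, model)
    floor_P <- 0.05 * mmsy(exp(log_B0_s[is_fis]), params$r, model)
    catch[is_fis] <- exploit * pmax(P, floor_P) *
      exp(stats::rnorm(sum(is_fis), 0, design$sigma_catch))
  }
  sites$catch_obs <- catch

  if (design$missing_coral_rate > 0) {
    drop_idx <- stats::runif(n) < design$missing_coral_rate
    sites$coral_cover[drop_idx] <- NA_real_
  }

  truth <- list(params = params, model = model, mu = mu, B0_s = exp(log_B0_s),
                B_latent = B_latent, u = u, jurisdiction = jur,
                standardization = std$spec, seed = seed, design = design)
  structure(list(sites = sites, truth = truth), class = "reef_sim")
}

#' Label remote reefs
#'
#' A reef counts as remote when it is uninhabited and more than
#' `threshold_h` hours of travel time from human settlements (default
#' 20 h). Sites with missing travel time are labelled not-remote with a
#' warning.
#'
#' @param travel_time_h Travel time to the nearest settlement, hours.
#' @param uninhabited Logical flag.
#' @param threshold_h Remoteness cutoff in hours, default 20.
#' @return Logical vector.
#' @export
label_remote <- function(travel_time_h, uninhabited, threshold_h = 20) {
  stopifnot(length(travel_time_h) == length(uninhabited))
  out <- travel_time_h > threshold_h & as.logical(uninhabited)
  if (any(is.na(travel_time_h))) {
    warning("missing travel time; affected sites labelled not remote")
    out[is.na(travel_time_h)] <- FALSE
  }
  out
}

#' Simulate ecosystem metrics for existing sites
#'
#' Generates the four ecosystem responses used in the trade-off analysis
#' from the corresponding regression forms: lognormal mean fish length and
#' total species richness, Bernoulli top-predator presence with a logit
#' link, and hurdle-lognormal parrotfish scraping potential. Linear
#' predictors use the standardized habitat, depth, productivity, census,
#' sampling-area, atoll, SST and gravity covariates plus a jurisdiction
#' random effect.
#'
#' @param sites A site table.
#' @param coefs Named list with per-metric intercepts (`I_length`,
#'   `I_richness`, `I_predator`, `I_scraping`), a shared slope vector
#'   `beta` (length 11, covariate order flat, crest, backreef, depth,
#'   productivity, distance, point-count, sampling area, atoll, SST,
#'   gravity), residual SDs `sigma_length`, `sigma_richness`,
#'   `sigma_scraping`, hurdle zero-probability `delta_scraping`, and
#'   jurisdiction SD `sigma_u`.
#' @param seed Integer seed.
#' @return The site table with columns `mean_length`, `richness`,
#'   `top_predator`, `scraping` added.
#' @export
simulate_metric_data <- function(sites, coefs = metric_coefs(), seed = 1) {
  set.seed(seed)
  d <- standardize_covariates(sites)$data
  X <- metric_design(d)
  jur <- as.integer(factor(d$jurisdiction_id))
  u <- stats::rnorm(max(jur), 0, coefs$sigma_u)
  eta <- drop(X %*% coefs$beta) + u[jur]
  n <- nrow(d)
  sites$mean_length <- exp(coefs$I_length + eta +
                           stats::rnorm(n, 0, coefs$sigma_length))
  sites$richness <- exp(coefs$I_richness + eta +
                        stats::rnorm(n, 0, coefs$sigma_richness))
  sites$top_predator <- stats::rbinom(n, 1,
                                      stats::plogis(coefs$I_predator + eta))
  zero <- stats::rbinom(n, 1, coefs$delta_scraping) == 1
  sites$scraping <- ifelse(zero, 0,
                           exp(coefs$I_scraping + eta +
                               stats::rnorm(n, 0, coefs$sigma_scraping)))
  sites
}

#' Default generating coefficients for the ecosystem-metric simulator
#'
#' @param ... Overrides for any element.
#' @return Named list, see [simulate_metric_data()].
#' @export
metric_coefs <- function(...) {
  out <- list(
    I_length = log(20), I_richness = log(60), I_predator = -0.5,
    I_scraping = log(150),
    beta = c(flat = -0.1, crest = -0.05, backreef = -0.1, depth = 0.05,
             prod = 0.1, distance = 0.05, point_count = -0.05,
             sampling_area = 0.05, atoll = 0.1, sst = -0.1, gravity = -0.02),
    sigma_length = 0.15, sigma_richness = 0.3, sigma_scraping = 0.6,
    delta_scraping = 0.3, sigma_u = 0.2
  )
  dots <- list(...)
  out[names(dots)] <- dots
  out
}

# design matrix for the ecosystem-metric regressions (11 columns)
metric_design <- function(d) {
  cbind(flat = d$x_flat, crest = d$x_crest, backreef = d$x_lagoon_backreef,
        depth = d$x_depth, prod = d$x_ocean_prod, distance = d$x_distance,
        point_count = d$x_point_count, sampling_area = d$x_sampling_area,
        atoll = d$x_atoll, sst = d$x_sst, gravity = d$x_gravity)
}
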
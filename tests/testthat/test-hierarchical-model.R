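# The joint hierarchical model: likelihood construction, prior recovery,
# sampler determinism, convergence diagnostics, and predictive model
# comparison.

test_that("single-site likelihood reduces to a standard normal density", {
  # one reserve with every covariate at its reference value: mu is just
  # the log recovery trajectory
  p <- sim_params()
  t_age <- 12
  d <- tibble::tibble(
    site_id = "s1", jurisdiction_id = "J1", category = "reserve",
    reserve_age = t_age, biomass_obs = 35,
    x_ocean_prod = 0, x_sst = 0, x_atoll = 0, x_coral = 0, x_depth = 0,
    x_crest = 0, x_lagoon_backreef = 0, x_flat = 0, x_point_count = 0,
    x_distance = 0, x_sampling_area = 0, x_reserve_size = 0, x_gravity = 0
  )
  p$sigma_i <- 1
  mu_expected <- log(recovery_trajectory(t_age, p$B0, p$Bmin, p$r))
  expect_equal(expected_log_biomass(p, d), mu_expected)
  expect_equal(log_likelihood(p, d),
               stats::dnorm(log(35), mu_expected, 1, log = TRUE))
  # empty dataset
  expect_equal(log_likelihood(p, d[0, ]), 0)
})

test_that("generator and likelihood agree: noise-off residuals vanish", {
  p <- sim_params(sigma_i = 0, sigma_j = 0, sigma_z = 0, sigma_u = 0)
  sim <- simulate_reef_data(p, sim_design("desk", missing_coral_rate = 0),
                            seed = 23)
  d <- standardize_covariates(sim$sites)$data
  mu <- expected_log_biomass(p, d)
  expect_equal(mu, log(sim$sites$biomass_obs), tolerance = 1e-10)
})

test_that("expected biomass declines with gravity when its effect is negative", {
  p <- sim_params()
  stopifnot(p$beta["gravity"] < 0)
  d0 <- tibble::tibble(
    site_id = c("a", "b"), jurisdiction_id = "J1",
    category = c("reserve", "open"), reserve_age = c(10, NA),
    biomass_obs = 30,
    x_ocean_prod = 0, x_sst = 0, x_atoll = 0, x_coral = 0, x_depth = 0,
    x_crest = 0, x_lagoon_backreef = 0, x_flat = 0, x_point_count = 0,
    x_distance = 0, x_sampling_area = 0, x_reserve_size = 0, x_gravity = 0
  )
  d10 <- d0
  d10$x_gravity <- 10
  expect_true(all(expected_log_biomass(p, d10) <
                    expected_log_biomass(p, d0)))
})

test_that("a prior-only run recovers the prior medians", {
  sim <- desk_sim()
  f0 <- fit_reef_model(sim$sites[0, ], chains = 2, warmup = 200,
                       iter = 1000, thin = 2, seed = 1)
  # log B0 ~ N(log 120, 1): the posterior median of B0 must sit at 120
  # within Monte-Carlo error of the sample median (~1.25/sqrt(n) on logs)
  mc_se <- 3 * 1.25 / sqrt(nrow(f0$draws))
  expect_lt(abs(log(stats::median(f0$draws[, "B0"])) - log(120)), mc_se)
  expect_lt(abs(log(stats::median(f0$draws[, "r"])) - (-2)), mc_se)
})

test_that("sampling is reproducible for a fixed seed", {
  sim <- desk_sim()
  fa <- fit_reef_model(sim$sites, chains = 2, warmup = 300, iter = 150,
                       thin = 2, seed = 9)
  fb <- fit_reef_model(sim$sites, chains = 2, warmup = 300, iter = 150,
                       thin = 2, seed = 9)
  expect_identical(fa$draws, fb$draws)
})

test_that("posterior medians recover the generating parameters", {
  fit <- desk_fit()
  truth <- desk_sim()$truth$params
  draws <- fit$draws
  checks <- list(
    logB0 = log(truth$B0), logr = log(truth$r), logBmin = log(truth$Bmin),
    gamma = truth$gamma
  )
  for (k in seq_along(truth$beta)) {
    checks[[paste0("beta[", k, "]")]] <- unname(truth$beta[k])
  }
  for (par in names(checks)) {
    x <- draws[, par]
    expect_lt(abs(stats::median(x) - checks[[par]]), 3 * stats::sd(x),
              label = paste("recovery of", par))
  }
})

test_that("doubling the data contracts the posterior for B0", {
  fit1 <- desk_fit()
  sim2 <- simulate_reef_data(design = sim_design("desk", n_reserve = 60,
                                                 n_remote = 40,
                                                 n_fished = 200),
                             seed = 42)
  fit2 <- fit_reef_model(sim2$sites, seed = 42, iter = 500)
  expect_lt(stats::sd(fit2$draws[, "logB0"]),
            stats::sd(fit1$draws[, "logB0"]))
})

test_that("split R-hat and bulk ESS behave on constructed chains", {
  set.seed(1)
  good <- matrix(stats::rnorm(4000), 1000, 4)
  expect_lt(split_rhat(good), 1.01)
  expect_gt(bulk_ess(good), 2000)
  # separated chains blow up R-hat; a trending chain is caught by splitting
  apart <- cbind(stats::rnorm(1000), stats::rnorm(1000, 3))
  expect_gt(split_rhat(apart), 1.5)
  trend <- cbind(seq(0, 1, length.out = 1000) + stats::rnorm(1000, 0, .1),
                 stats::rnorm(1000, 0.5, .1))
  expect_gt(split_rhat(trend), 1.01)
  # heavy autocorrelation shrinks ESS
  ar <- matrix(0, 1000, 4)
  for (j in 1:4) {
    e <- stats::rnorm(1000)
    for (i in 2:1000) ar[i, j] <- 0.95 * ar[i - 1, j] + e[i]
  }
  expect_lt(bulk_ess(ar), 500)
  expect_error(split_rhat(good[, 1, drop = FALSE]), "two chains")
})

test_that("posterior contraction follows the variance-ratio definition", {
  expect_equal(posterior_contraction(1, 1), 0)      # posterior = prior
  expect_equal(posterior_contraction(0.25, 1), 0.75) # half the prior SD
  d <- diagnostics(desk_fit())
  expect_true(all(is.na(d$contraction[grepl("^u\\[", d$parameter)])))
  expect_true(all(d$contraction[d$parameter == "logB0"] > 0))
})

test_that("model comparison: self-comparison is exactly zero", {
  fit <- desk_fit()
  mc <- model_compare(a = fit, b = fit)
  expect_equal(mc$elpd_diff, c(0, 0))
  expect_equal(unname(mc$elpd[1]), unname(mc$elpd[2]))
})

test_that("a corrupted likelihood is ranked last", {
  ll_good <- matrix(stats::rnorm(500, -1, 0.1), 50, 10)
  ll_bad <- ll_good
  ll_bad[, 3] <- -1e6
  expect_lt(sum(reefmsy:::loo_pointwise(ll_bad)),
            sum(reefmsy:::loo_pointwise(ll_good)))
})

test_that("LOO favours the generating family on informative recovery data", {
  # the recovery-curve shape is what separates the families, so the
  # oracle design is reserve-heavy with low observation noise
  wins <- 0L
  for (rep in 1:5) {
    p <- sim_params(sigma_i = 0.15)
    s <- simulate_reef_data(p, sim_design("desk", n_reserve = 150,
                                          n_remote = 30, n_fished = 30),
                            seed = 200 + rep)
    ff <- fit_reef_model(s$sites, surplus_model("fox"), chains = 2,
                         warmup = 500, iter = 500, thin = 4, seed = rep)
    fs <- fit_reef_model(s$sites, surplus_model("schaefer"), chains = 2,
                         warmup = 500, iter = 500, thin = 4, seed = rep)
    mc <- model_compare(fox = ff, schaefer = fs)
    d <- mc$elpd[mc$model == "fox"] - mc$elpd[mc$model == "schaefer"]
    wins <- wins + (d >= 0)
  }
  expect_gte(wins, 3L)
})

test_that("comparing fits on different observation sets errors", {
  sim <- desk_sim()
  fit <- desk_fit()
  other <- fit_reef_model(sim$sites[-1, ], chains = 2, warmup = 300,
                          iter = 150, thin = 2, seed = 2)
  expect_error(model_compare(a = fit, b = other), "different observation")
})

test_that("non-fox families fit without error and keep their shape", {
  sim_s <- simulate_reef_data(model = surplus_model("schaefer"),
                              design = sim_design("desk"), seed = 31)
  fs <- fit_reef_model(sim_s$sites, surplus_model("schaefer"), chains = 2,
                       warmup = 400, iter = 300, thin = 3, seed = 31)
  med_B0 <- stats::median(fs$draws[, "B0"])
  expect_gt(med_B0, 60)
  expect_lt(med_B0, 240)
})
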
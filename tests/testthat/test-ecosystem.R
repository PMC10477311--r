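# Ecosystem metrics: Poisson-lognormal richness estimation, parrotfish
# scraping, metric regressions, and trade-off curves.

test_that("PLN richness estimator recovers true richness on simulations", {
  ests <- vapply(1:50, function(rep) {
    cnt <- simulate_pln_counts(100, mu = 1, sigma = 1.5, seed = 1000 + rep)
    estimate_total_richness(cnt)$richness
  }, numeric(1))
  expect_lt(abs(stats::median(ests) - 100) / 100, 0.10)
})

test_that("an abundant community needs no veil correction", {
  cnt <- simulate_pln_counts(80, mu = 5, sigma = 0.5, seed = 5)
  out <- estimate_total_richness(cnt)
  expect_equal(out$observed, 80)
  expect_lt(out$p0, 0.01)
  expect_equal(out$richness, 80, tolerance = 0.02)
})

test_that("degenerate abundance input returns observed richness, flagged", {
  out <- estimate_total_richness(c(7))
  expect_equal(out$richness, 1)
  expect_true(out$poor_fit)
  expect_error(estimate_total_richness(c(0, 2)), "positive integer")
})

test_that("thinning lowers observed richness more than the estimate", {
  # subsampling individuals veils more species; the estimator should
  # recover part of the loss
  obs_drop <- est_drop <- numeric(20)
  for (rep in 1:20) {
    set.seed(3000 + rep)
    cnt <- simulate_pln_counts(120, mu = 1.5, sigma = 1.2, seed = 3000 + rep)
    thin <- stats::rbinom(length(cnt), cnt, 0.3)
    thin <- thin[thin > 0]
    full <- estimate_total_richness(cnt)
    sub <- estimate_total_richness(thin)
    obs_drop[rep] <- length(cnt) - length(thin)
    est_drop[rep] <- full$richness - sub$richness
  }
  expect_lt(stats::median(est_drop), stats::median(obs_drop))
  expect_gt(stats::median(obs_drop), 0)
})

test_that("scraping potential is a linear density-rate-area sum", {
  none <- data.frame(species = character(0), size_class = character(0),
                     density = numeric(0))
  expect_equal(scraping_potential(none), 0)
  one <- data.frame(species = "Scarus niger", size_class = "20-30",
                    density = 0.1)
  rates <- data.frame(species = "Scarus niger", size_class = "20-30",
                      bite_rate = 10, bite_area = 100)
  expect_equal(scraping_potential(one, rates), 0.1 * 10 * 100)
  two <- rbind(one, data.frame(species = "Scarus niger",
                               size_class = "20-30", density = 0.1))
  expect_equal(scraping_potential(two, rates),
               2 * scraping_potential(one, rates))
  doubled <- one
  doubled$density <- one$density * 2
  expect_equal(scraping_potential(doubled, rates),
               2 * scraping_potential(one, rates))
})

test_that("scraping falls back to genus means and errors when absent", {
  novel <- data.frame(species = "Scarus ghostus", size_class = "20-30",
                      density = 1)
  rates <- default_scraping_rates()
  sc <- scraping_potential(novel, rates)
  scarus <- rates[grepl("^Scarus ", rates$species) &
                    rates$size_class == "20-30", ]
  expect_equal(sc, mean(scarus$bite_rate) * mean(scarus$bite_area),
               tolerance = 1e-12)
  alien <- data.frame(species = "Nemo incognitus", size_class = "40+",
                      density = 1)
  expect_error(scraping_potential(alien, rates), "Nemo incognitus 40\\+")
})

test_that("metric regressions recover their generating coefficients", {
  sim <- simulate_reef_data(design = sim_design("desk", n_fished = 800),
                            seed = 51)
  fished <- sim$sites[sim$sites$category %in% c("restricted", "open"), ]
  coefs <- metric_coefs(delta_scraping = 0.4)
  rec <- simulate_metric_data(fished, coefs, seed = 52)
  fl <- fit_metric_model(rec, "length")
  se <- sqrt(diag(as.matrix(stats::vcov(fl$fit))))[-1]
  expect_true(all(abs(fl$slopes - coefs$beta) < 3 * se))
  expect_lt(abs(fl$intercept - coefs$I_length), 0.2)
  # hurdle zero-probability close to the generating 40%
  fs <- fit_metric_model(rec, "scraping")
  expect_lt(abs(fs$delta_P - 0.4), 3 * sqrt(0.4 * 0.6 / nrow(rec)))
  # Bernoulli model finds the negative gravity effect direction
  fp <- fit_metric_model(rec, "predators")
  expect_lt(fp$slopes[["gravity"]], 0)
})

test_that("the hurdle likelihood factorizes into independent parts", {
  sim <- desk_sim()
  fished <- sim$sites[sim$sites$category %in% c("restricted", "open"), ]
  rec <- simulate_metric_data(fished, metric_coefs(), seed = 53)
  f1 <- fit_metric_model(rec, "scraping")
  # doubling the positive values leaves the zero part untouched and only
  # shifts the positive-part intercept by log 2
  rec2 <- rec
  rec2$scraping <- rec$scraping * 2
  f2 <- fit_metric_model(rec2, "scraping")
  expect_equal(f2$delta_P, f1$delta_P)
  expect_equal(f2$slopes, f1$slopes, tolerance = 1e-6)
  expect_equal(f2$intercept, f1$intercept + log(2), tolerance = 1e-6)
  # degenerate responses are refused with a diagnostic
  rec3 <- rec
  rec3$scraping <- 0
  expect_error(fit_metric_model(rec3, "scraping"), "degenerate")
  rec4 <- rec
  rec4$top_predator <- 1
  expect_error(fit_metric_model(rec4, "predators"), "degenerate")
})

# fake metric fit with no covariate effects, for analytic trade-off cases
flat_fit <- function(metric) {
  structure(list(metric = metric, family = "lognormal", intercept = 0,
                 slopes = stats::setNames(rep(0, 11),
                                          colnames(reefmsy:::metric_design(
                                            standardize_covariates(desk_sim()$sites)$data))),
                 sigma = 0, delta_P = NA_real_, u = 0, fit = NULL),
            class = "glmm_fit")
}

test_that("a metric constant in biomass shows zero percent change", {
  fit <- desk_fit()
  sim <- desk_sim()
  fished <- sim$sites[sim$sites$category %in% c("restricted", "open"), ]
  # spread observed biomass so the reference points are inside the support
  set.seed(60)
  fished$biomass_obs <- exp(seq(log(5), log(200),
                                length.out = nrow(fished)))
  fished$mean_length <- 25
  out <- tradeoff_curve(fished, list(length = flat_fit("length")), fit)
  expect_equal(unname(as.numeric(out$percent_change[1, -1])), rep(0, 3),
               tolerance = 1e-8)
})

test_that("a metric proportional to biomass changes like the biomass ratio", {
  fit <- desk_fit()
  sim <- desk_sim()
  fished <- sim$sites[sim$sites$category %in% c("restricted", "open"), ]
  set.seed(61)
  fished$biomass_obs <- exp(seq(log(5), log(250),
                                length.out = nrow(fished)))
  # rebuild the marginalized biomass exactly as the trade-off stage does
  d <- standardize_covariates(fished, spec = fit$standardization)$data
  bmed <- apply(fit$draws[, paste0("beta[", 1:11, "]")], 2, stats::median)
  B_ref <- exp(log(d$biomass_obs) -
               drop(as.matrix(d[reefmsy:::ENV_X]) %*% bmed[1:4]) -
               drop(as.matrix(d[reefmsy:::SAMP_X]) %*% bmed[5:11]))
  fished$mean_length <- 2 * B_ref
  out <- tradeoff_curve(fished, list(length = flat_fit("length")), fit)
  # Fox geometry: value at B_MMSY is 1/e of the value at B0
  expect_equal(out$percent_change$bmmsy_vs_b0,
               100 * (exp(-1) - 1), tolerance = 0.02)
  v <- out$at_reference$length
  expect_gt(v[["PGMY_upper"]], v[["BMMSY"]])
  expect_gt(v[["BMMSY"]], v[["PGMY_lower"]])
  # percent changes are invariant to the metric's units
  fished2 <- fished
  fished2$mean_length <- fished$mean_length * 1000
  out2 <- tradeoff_curve(fished2, list(length = flat_fit("length")), fit)
  expect_equal(out2$percent_change$bmmsy_vs_b0,
               out$percent_change$bmmsy_vs_b0, tolerance = 1e-8)
})
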
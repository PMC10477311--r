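# Shared fixtures, built once per test run. The desk-scale fit is reused
# by the model, reference-point, assessment and acceptance tests.

fixture_env <- new.env(parent = emptyenv())

desk_sim <- function(seed = 42) {
  key <- paste0("sim", seed)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- simulate_reef_data(design = sim_design("desk"),
                                             seed = seed)
  }
  fixture_env[[key]]
}

desk_fit <- function(seed = 42) {
  key <- paste0("fit", seed)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- fit_reef_model(desk_sim(seed)$sites, seed = seed)
  }
  fixture_env[[key]]
}

# all three supported families at fixed shape exponents
family_cases <- function() {
  list(fox = surplus_model("fox"),
       schaefer = surplus_model("schaefer"),
       pt3 = surplus_model("pella_tomlinson", n = 3),
       pt4 = surplus_model("pella_tomlinson", n = 4))
}

# numeric argmax of the surplus curve: the independent oracle for the
# closed-form reference points
grid_argmax_surplus <- function(B0, r, model) {
  stats::optimize(function(B) surplus(B, B0, r, model),
                  interval = c(1e-6, B0), maximum = TRUE,
                  tol = .Machine$double.eps^0.5)
}

# a site whose covariates sit exactly at the fit's standardization centers
reference_site <- function(fit, n = 1) {
  ctr <- fit$standardization$centers
  tibble::tibble(
    site_id = sprintf("ref%02d", seq_len(n)), jurisdiction_id = "J01",
    category = "open", reserve_age = NA_real_, biomass_obs = 40,
    catch_obs = 2, ocean_prod = ctr[["ocean_prod"]], sst = ctr[["sst"]],
    coral_cover = ctr[["coral_cover"]], atoll = 0, habitat = "slope",
    depth = ctr[["depth"]], census_method = "belt",
    sampling_area = ctr[["sampling_area"]], reserve_size = NA_real_,
    gravity = 0, travel_time_h = 1, uninhabited = FALSE
  )
}
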
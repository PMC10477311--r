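# Propagation of posterior draws to site-specific reference points,
# marginalized biomass, and status ratios.

#' Site-specific reference points from posterior draws
#'
#' For every posterior draw and every site, the environmentally-conditioned
#' unfished biomass
#' `B0_s = exp(log B0 + beta1*x_prod + beta2*x_sst + beta3*x_atoll +
#' beta4*x_coral)` and the derived reference points: `MMSY_s` and
#' `BMMSY_s` under the fit's surplus family (`B0_s/e` and `r*B0_s/e` for
#' Gompertz-Fox), plus the pretty-good-yield biomass bounds at `fraction`
#' of MMSY. Covariates are placed on the fit's standardization scale;
#' values outside the range seen during fitting extrapolate with a
#' warning. Missing coral cover is imputed at the fitted mean.
#'
#' @param fit A [fit_reef_model()] result.
#' @param sites Site table to evaluate (defaults to the sites used in the
#'   fit).
#' @param fraction PGMY fraction of MMSY, default 0.8.
#' @return An object of class `reef_refpoints`: draws x sites matrices
#'   `B0_s`, `MMSY_s`, `BMMSY_s`, `pgmy_lower`, `pgmy_upper`, the per-draw
#'   growth rate `r`, the site table, the surplus model and the fraction.
#' @export
site_reference_points <- function(fit, sites = fit$data$sites,
                                  fraction = 0.8) {
  stopifnot(inherits(fit, "reef_fit"))
  std <- standardize_covariates(sites, spec = fit$standardization)
  d <- std$data
  draws <- fit$draws
  beta_env <- draws[, paste0("beta[", 1:4, "]"), drop = FALSE]
  logB0s <- draws[, "logB0"] + beta_env %*% t(as.matrix(d[ENV_X]))
  B0_s <- exp(logB0s)
  r <- draws[, "r"]
  bfrac <- bmmsy_fraction(fit$model)
  BMMSY_s <- B0_s * bfrac
  MMSY_s <- if (fit$model$family == "fox") {
    r * B0_s * exp(-1)
  } else {
    (r / fit$model$n) * B0_s * bfrac
  }
  pg <- pgmy_fractions(fit$model, fraction)
  structure(list(
    B0_s = B0_s, MMSY_s = MMSY_s, BMMSY_s = BMMSY_s,
    pgmy_lower = B0_s * pg[1], pgmy_upper = B0_s * pg[2],
    r = r, sites = tibble::as_tibble(sites), std = d,
    model = fit$model, fraction = fraction
  ), class = "reef_refpoints")
}

#' Marginalized biomass
#'
#' Observed biomass corrected to reference sampling conditions (slope
#' habitat, standard belt transects, average depth and sampling area) by
#' subtracting the posterior sampling-effect terms on the log scale:
#' `B_marg = exp(log B_obs - sum(beta5..beta11 * x))`, per draw.
#'
#' @inheritParams site_reference_points
#' @return A draws x sites matrix of marginalized biomass (t/km2).
#' @export
marginalize_biomass <- function(fit, sites = fit$data$sites) {
  stopifnot(inherits(fit, "reef_fit"))
  std <- standardize_covariates(sites, spec = fit$standardization)
  d <- std$data
  if (any(!is.finite(d$biomass_obs)) || any(d$biomass_obs <= 0)) {
    stop("biomass_obs must be positive to marginalize")
  }
  beta_samp <- fit$draws[, paste0("beta[", 5:11, "]"), drop = FALSE]
  corr <- beta_samp %*% t(as.matrix(d[SAMP_X]))
  exp(matrix(log(d$biomass_obs), nrow(corr), ncol(corr), byrow = TRUE) - corr)
}

#' Site status relative to reference points
#'
#' Draw-wise biomass status `B_marg/BMMSY_s`, fishing status `C/MMSY_s`,
#' surplus production at the marginalized biomass, catch potential
#' `P/MMSY_s`, and the overfishing indicator `C > P`. Sites without catch
#' get biomass-only status; sites without biomass get fishing-only status.
#'
#' @param refpts A [site_reference_points()] result.
#' @param B_marg Draws x sites matrix from [marginalize_biomass()], or
#'   `NULL` for catch-only assessment.
#' @param catch Per-site catch, t/km2/y (`NA` allowed), or `NULL`.
#' @return Object of class `reef_status` with draw-wise matrices
#'   (`B_status`, `F_status`, `P`, `C_pot`, `overfishing`) and a per-site
#'   `summary` tibble (posterior medians with 90% intervals, 5th-95th
#'   percentiles).
#' @export
site_status <- function(refpts, B_marg = NULL, catch = NULL) {
  stopifnot(inherits(refpts, "reef_refpoints"))
  n <- nrow(refpts$sites)
  S <- nrow(refpts$B0_s)
  bad_mmsy <- refpts$MMSY_s <= 0
  if (any(bad_mmsy)) {
    warning("excluding ", sum(bad_mmsy), " draws with non-positive MMSY")
    refpts$MMSY_s[bad_mmsy] <- NA_real_
  }
  B_status <- F_status <- P <- C_pot <- overfishing <- NULL
  if (!is.null(B_marg)) {
    stopifnot(all(dim(B_marg) == dim(refpts$B0_s)))
    B_status <- B_marg / refpts$BMMSY_s
    P <- matrix(NA_real_, S, n)
    for (s in seq_len(S)) {
      P[s, ] <- surplus(B_marg[s, ], refpts$B0_s[s, ], refpts$r[s],
                        refpts$model)
    }
    C_pot <- P / refpts$MMSY_s
  }
  if (!is.null(catch)) {
    stopifnot(length(catch) == n)
    Cm <- matrix(catch, S, n, byrow = TRUE)
    F_status <- Cm / refpts$MMSY_s
    if (!is.null(P)) overfishing <- Cm > P
  }
  summ <- tibble::tibble(site_id = refpts$sites$site_id)
  add_q <- function(summ, mat, name) {
    if (is.null(mat)) return(summ)
    q <- apply(mat, 2, stats::quantile, c(.05, .5, .95), na.rm = TRUE)
    summ[[paste0(name, "_med")]] <- q[2, ]
    summ[[paste0(name, "_lo")]] <- q[1, ]
    summ[[paste0(name, "_hi")]] <- q[3, ]
    summ
  }
  summ <- add_q(summ, refpts$B0_s, "B0_s")
  summ <- add_q(summ, refpts$MMSY_s, "MMSY_s")
  summ <- add_q(summ, refpts$BMMSY_s, "BMMSY_s")
  summ <- add_q(summ, B_marg, "B_marg")
  summ <- add_q(summ, B_status, "B_status")
  summ <- add_q(summ, F_status, "F_status")
  summ <- add_q(summ, P, "P")
  summ <- add_q(summ, C_pot, "C_pot")
  if (!is.null(catch)) summ$catch <- catch
  structure(list(
    B_status = B_status, F_status = F_status, P = P, C_pot = C_pot,
    overfishing = overfishing, B_marg = B_marg, catch = catch,
    refpts = refpts, summary = summ
  ), class = "reef_status")
}

# median + 90% central interval of a draws vector
q90 <- function(x) stats::quantile(x, c(.05, .5, .95), na.rm = TRUE)
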
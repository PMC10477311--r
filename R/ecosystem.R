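# Ecosystem-metric models and the trade-off analysis along the
# surplus-production biomass gradient: Poisson-lognormal species richness,
# parrotfish scraping potential, metric regressions, and penalized-spline
# trade-off curves.

# Gauss-Hermite nodes/weights (physicists' convention, weight e^{-x^2})
# by Golub-Welsch on the symmetric tridiagonal Jacobi matrix.
gauss_hermite <- function(n) {
  if (n == 1L) return(list(x = 0, w = sqrt(pi)))
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  J[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  idx <- order(e$values)
  list(x = e$values[idx], w = sqrt(pi) * e$vectors[1, idx]^2)
}

# Poisson-lognormal P(N = k) for integer k (vectorized over k),
# marginalizing the lognormal rate by Gauss-Hermite quadrature
pln_prob <- function(k, mu, sigma, gh) {
  lam <- exp(mu + sqrt(2) * sigma * gh$x)
  pk <- vapply(k, function(ki) {
    sum(gh$w / sqrt(pi) * stats::dpois(ki, lam))
  }, numeric(1))
  pmax(pk, 1e-300)
}

#' Estimate total species richness from an abundance sample
#'
#' Fits a zero-truncated Poisson-lognormal species-abundance distribution
#' to the observed per-species counts by maximum likelihood (Gauss-Hermite
#' quadrature for the lognormal mixture), estimates the veil probability
#' `p0` that a species present in the community was missed by the sample,
#' and corrects observed richness to `S_obs / (1 - p0)`. Fit quality is
#' flagged by a Pearson chi-square goodness-of-fit test on binned
#' abundances at alpha = 0.05; degenerate inputs (a single species) return
#' observed richness, flagged.
#'
#' @param counts Positive integer abundances, one per observed species.
#' @param gh_nodes Number of quadrature nodes (default 40).
#' @param alpha Goodness-of-fit significance level for the poor-fit flag.
#' @return A list: `richness` (estimated total), `observed`, `p0`, `mu`,
#'   `sigma`, `gof_p`, and `poor_fit` (logical).
#' @export
estimate_total_richness <- function(counts, gh_nodes = 40, alpha = 0.05) {
  counts <- counts[!is.na(counts)]
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("`counts` must be positive integer abundances of observed species")
  }
  S_obs <- length(counts)
  if (S_obs < 2L) {
    return(list(richness = S_obs, observed = S_obs, p0 = NA_real_,
                mu = NA_real_, sigma = NA_real_, gof_p = NA_real_,
                poor_fit = TRUE))
  }
  gh <- gauss_hermite(gh_nodes)
  nll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    p0 <- pln_prob(0L, mu, sigma, gh)
    if (p0 >= 1 - 1e-12) return(1e10)
    -sum(log(pln_prob(counts, mu, sigma, gh))) + S_obs * log(1 - p0)
  }
  init <- c(mean(log(counts)), log(max(stats::sd(log(counts)), 0.2)))
  opt <- stats::optim(init, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000))
  mu <- opt$par[1]; sigma <- exp(opt$par[2])
  p0 <- pln_prob(0L, mu, sigma, gh)
  richness <- S_obs / (1 - p0)
  # goodness of fit on pooled abundance classes 1, 2, 3, 4, 5-8, 9+
  breaks <- c(1, 2, 3, 4, 5, 9)
  obs_bin <- table(cut(counts, breaks = c(breaks - 0.5, Inf), right = TRUE))
  probs <- vapply(seq_len(length(breaks) - 1), function(b) {
    ks <- breaks[b]:(breaks[b + 1] - 1)
    sum(pln_prob(ks, mu, sigma, gh))
  }, numeric(1))
  probs <- c(probs, max(1 - p0 - sum(probs), 1e-12)) # open-ended top bin
  probs <- probs / (1 - p0)
  exp_bin <- S_obs * probs
  keep <- exp_bin > 1e-8
  chi2 <- sum((as.numeric(obs_bin)[keep] - exp_bin[keep])^2 / exp_bin[keep])
  df <- max(1L, sum(keep) - 1L - 2L)
  gof_p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  list(richness = richness, observed = S_obs, p0 = p0, mu = mu,
       sigma = sigma, gof_p = gof_p,
       poor_fit = (opt$convergence != 0) || (gof_p < alpha))
}

#' Simulate Poisson-lognormal abundance counts
#'
#' Draws one abundance per species from a Poisson-lognormal community and
#' returns the observed (non-zero) counts, for validating the richness
#' estimator.
#'
#' @param S True number of species.
#' @param mu,sigma Lognormal parameters of the per-species Poisson rate.
#' @param seed Integer seed.
#' @return Integer vector of observed counts (species with zero
#'   individuals are veiled and omitted).
#' @export
simulate_pln_counts <- function(S, mu, sigma, seed = 1) {
  set.seed(seed)
  lam <- exp(stats::rnorm(S, mu, sigma))
  n <- stats::rpois(S, lam)
  n[n > 0]
}

#' Parrotfish scraping potential
#'
#' Area grazed per minute per unit reef area: the sum over species-size
#' classes of density (ind/m2) x feeding rate (bites/min) x bite area
#' (mm2/bite). Classes missing from the rate table fall back to the
#' genus-level mean rate and bite area; classes without a genus fallback
#' raise an error listing them.
#'
#' @param census Data frame with columns `species`, `size_class`,
#'   `density` (ind/m2). Zero rows (no parrotfish) give zero scraping.
#' @param rates Rate table with columns `species`, `size_class`,
#'   `bite_rate` (bites/min), `bite_area` (mm2). Defaults to the packaged
#'   synthetic rate table.
#' @return Scraping potential, mm2 grazed per minute per m2.
#' @export
scraping_potential <- function(census, rates = default_scraping_rates()) {
  stopifnot(all(c("species", "size_class", "density") %in% names(census)),
            all(c("species", "size_class", "bite_rate", "bite_area") %in%
                  names(rates)))
  if (nrow(census) == 0L) return(0)
  key <- paste(census$species, census$size_class)
  rkey <- paste(rates$species, rates$size_class)
  hit <- match(key, rkey)
  rate <- rates$bite_rate[hit]
  area <- rates$bite_area[hit]
  miss <- is.na(hit)
  if (any(miss)) {
    genus <- function(x) sub(" .*", "", x)
    gmeans <- stats::aggregate(
      cbind(bite_rate, bite_area) ~ genus(species) + size_class,
      data = rates, FUN = mean)
    names(gmeans)[1] <- "genus"
    gkey <- paste(gmeans$genus, gmeans$size_class)
    ghit <- match(paste(genus(census$species[miss]),
                        census$size_class[miss]), gkey)
    if (any(is.na(ghit))) {
      bad <- key[miss][is.na(ghit)]
      stop("no feeding-rate entry (nor genus fallback) for: ",
           paste(unique(bad), collapse = "; "))
    }
    rate[miss] <- gmeans$bite_rate[ghit]
    area[miss] <- gmeans$bite_area[ghit]
  }
  sum(census$density * rate * area)
}

#' Packaged synthetic parrotfish feeding-rate table
#'
#' Size-specific feeding rates (bites/min) and bite areas (mm2) for a set
#' of common Indo-Pacific parrotfish taxa. These values are synthetic
#' placeholders with realistic magnitudes (editable CSV asset); substitute
#' literature rates for real analyses.
#'
#' @return A tibble with columns `species`, `size_class`, `bite_rate`,
#'   `bite_area`.
#' @export
default_scraping_rates <- function() {
  path <- system.file("extdata", "scraping_rates_synthetic.csv",
                      package = "reefmsy", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' Fit an ecosystem-metric regression
#'
#' Multilevel regressions of the four ecosystem metrics on the
#' standardized habitat, depth, productivity, census-method,
#' sampling-area, atoll, SST and gravity covariates with jurisdiction
#' random intercepts: lognormal models for mean fish length and total
#' species richness, a logit-linked Bernoulli model for top-predator
#' presence, and a hurdle-lognormal for parrotfish scraping potential
#' (a Bernoulli zero process with probability `delta_P` plus a lognormal
#' positive part, whose likelihood factorizes into independent parts).
#'
#' @param records Site table including the metric columns produced by
#'   [simulate_metric_data()] (or equivalent observations).
#' @param metric One of `"length"`, `"richness"`, `"predators"`,
#'   `"scraping"`.
#' @return Object of class `glmm_fit`: `intercept`, named `slopes`,
#'   `sigma` (residual SD of the (log)normal part), `delta_P` (zero
#'   probability, scraping only), `u` (jurisdiction effects), `family`,
#'   and the underlying lme4 fit(s).
#' @export
fit_metric_model <- function(records,
                             metric = c("length", "richness", "predators",
                                        "scraping")) {
  metric <- match.arg(metric)
  d <- standardize_covariates(records)$data
  X <- metric_design(d)
  df <- as.data.frame(X)
  df$jurisdiction_id <- d$jurisdiction_id
  covs <- paste(colnames(X), collapse = " + ")
  fe <- function(m) {
    b <- lme4::fixef(m)
    list(intercept = unname(b["(Intercept)"]),
         slopes = b[colnames(X)],
         u = lme4::ranef(m)$jurisdiction_id[, 1])
  }
  if (metric %in% c("length", "richness")) {
    y <- if (metric == "length") records$mean_length else records$richness
    if (any(y <= 0)) stop("lognormal metric requires positive values")
    df$y <- log(y)
    m <- lme4::lmer(stats::as.formula(paste("y ~", covs,
                                            "+ (1 | jurisdiction_id)")),
                    data = df, REML = FALSE)
    p <- fe(m)
    out <- list(metric = metric, family = "lognormal",
                intercept = p$intercept, slopes = p$slopes,
                sigma = stats::sigma(m), delta_P = NA_real_, u = p$u,
                fit = m)
  } else if (metric == "predators") {
    y <- records$top_predator
    if (length(unique(y)) < 2L) {
      stop("degenerate top-predator response (all ", y[1],
           "); the Bernoulli model is not estimable")
    }
    df$y <- y
    m <- lme4::glmer(stats::as.formula(paste("y ~", covs,
                                             "+ (1 | jurisdiction_id)")),
                     data = df, family = stats::binomial())
    p <- fe(m)
    out <- list(metric = metric, family = "bernoulli_logit",
                intercept = p$intercept, slopes = p$slopes,
                sigma = NA_real_, delta_P = NA_real_, u = p$u, fit = m)
  } else {
    y <- records$scraping
    if (all(y == 0)) stop("degenerate scraping response: no positive values")
    delta <- mean(y == 0)
    pos <- y > 0
    dfp <- df[pos, , drop = FALSE]
    dfp$y <- log(y[pos])
    m <- lme4::lmer(stats::as.formula(paste("y ~", covs,
                                            "+ (1 | jurisdiction_id)")),
                    data = dfp, REML = FALSE)
    p <- fe(m)
    out <- list(metric = metric, family = "hurdle_lognormal",
                intercept = p$intercept, slopes = p$slopes,
                sigma = stats::sigma(m), delta_P = delta, u = p$u, fit = m)
  }
  class(out) <- "glmm_fit"
  out
}

#' Trade-off curves along the surplus-production biomass gradient
#'
#' Marginalizes each fitted ecosystem metric and the observed biomass to
#' reference conditions (slope habitat, belt transects, non-atoll, average
#' depth, sampling area, productivity and SST; the gravity-driven fishing
#' gradient is retained), fits a penalized cubic-spline smooth of each
#' metric against marginalized biomass, and reports curve values and
#' percent changes at the four reference biomasses: unfished `B0`,
#' `B_MMSY`, and the lower/upper PGMY bounds (posterior medians for
#' average conditions). Reference biomasses outside the observed biomass
#' range are truncated to the range with a warning.
#'
#' @param records Site table with metric columns (fished sites).
#' @param fits Named list of [fit_metric_model()] objects (any subset of
#'   length/richness/predators/scraping).
#' @param fit A [fit_reef_model()] result supplying the biomass
#'   marginalization and the reference points.
#' @param fraction PGMY fraction, default 0.8.
#' @param k Spline basis dimension, default 10.
#' @return A list: `curves` (tibble metric/biomass/value), `at_reference`
#'   (curve values at the four reference biomasses), `percent_change`
#'   (tibble with changes at B_MMSY vs B0 and PGMY bounds vs B_MMSY), and
#'   `reference_biomass`.
#' @export
tradeoff_curve <- function(records, fits, fit, fraction = 0.8, k = 10) {
  stopifnot(inherits(fit, "reef_fit"), length(fits) >= 1L)
  d <- standardize_covariates(records, spec = fit$standardization)$data
  draws <- fit$draws
  # biomass at reference sampling AND environmental conditions
  bmed <- apply(draws[, paste0("beta[", 1:11, "]")], 2, stats::median)
  env_corr <- drop(as.matrix(d[ENV_X]) %*% bmed[1:4])
  samp_corr <- drop(as.matrix(d[SAMP_X]) %*% bmed[5:11])
  B_ref <- exp(log(d$biomass_obs) - env_corr - samp_corr)

  B0_med <- stats::median(draws[, "B0"])
  r_med <- stats::median(draws[, "r"])
  bref <- c(
    B0 = B0_med,
    BMMSY = bmmsy(B0_med, r_med, fit$model),
    PGMY_lower = unname(pgmy_bounds(B0_med, r_med, fit$model, fraction)[1]),
    PGMY_upper = unname(pgmy_bounds(B0_med, r_med, fit$model, fraction)[2])
  )
  rng <- range(B_ref)
  if (any(bref < rng[1] | bref > rng[2])) {
    warning("reference biomasses outside the observed biomass range; ",
            "truncated to the data support")
    bref <- pmin(pmax(bref, rng[1]), rng[2])
  }

  # covariates removed from the metric (all but gravity)
  X <- metric_design(d)
  marg_cols <- setdiff(colnames(X), "gravity")
  curves <- list(); at_ref <- list(); pc <- list()
  grid <- seq(rng[1], rng[2], length.out = 200)
  for (nm in names(fits)) {
    f <- fits[[nm]]
    adj <- drop(X[, marg_cols, drop = FALSE] %*% f$slopes[marg_cols])
    y_obs <- switch(f$metric,
      length = log(records$mean_length),
      richness = log(records$richness),
      predators = NULL,
      scraping = NULL)
    if (f$metric %in% c("length", "richness")) {
      y_marg <- exp(y_obs - adj)
      g <- mgcv::gam(y ~ s(B, k = k, bs = "cr"),
                     data = data.frame(y = log(y_marg), B = B_ref))
      val <- function(b) exp(as.numeric(stats::predict(
        g, newdata = data.frame(B = b))))
    } else if (f$metric == "predators") {
      # logit-scale marginalization is degenerate for 0/1 data; smooth the
      # observed presence and read it as probability
      g <- mgcv::gam(y ~ s(B, k = k, bs = "cr"),
                     data = data.frame(y = records$top_predator, B = B_ref),
                     family = stats::binomial())
      val <- function(b) as.numeric(stats::predict(
        g, newdata = data.frame(B = b), type = "response"))
    } else {
      y <- records$scraping
      y_marg <- ifelse(y > 0, exp(log(pmax(y, 1e-12)) - adj), 0)
      g <- mgcv::gam(y ~ s(B, k = k, bs = "cr"),
                     data = data.frame(y = y_marg, B = B_ref))
      val <- function(b) pmax(as.numeric(stats::predict(
        g, newdata = data.frame(B = b))), 0)
    }
    curves[[nm]] <- tibble::tibble(metric = nm, biomass = grid,
                                   value = val(grid))
    v <- val(bref)
    names(v) <- names(bref)
    at_ref[[nm]] <- v
    pc[[nm]] <- tibble::tibble(
      metric = nm,
      bmmsy_vs_b0 = unname(100 * (v["BMMSY"] - v["B0"]) / v["B0"]),
      pgmy_lower_vs_bmmsy = unname(100 * (v["PGMY_lower"] - v["BMMSY"]) /
                                     v["BMMSY"]),
      pgmy_upper_vs_bmmsy = unname(100 * (v["PGMY_upper"] - v["BMMSY"]) /
                                     v["BMMSY"])
    )
  }
  list(curves = dplyr::bind_rows(curves),
       at_reference = at_ref,
       percent_change = dplyr::bind_rows(pc),
       reference_biomass = bref)
}
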
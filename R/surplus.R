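#' Surplus-production model specification
#'
#' Defines the functional form of the assemblage-level surplus-production
#' curve. Three members of the Pella-Tomlinson family are supported:
#'
#' * `"fox"` -- the Gompertz-Fox model, the n -> 1 limit of the family,
#'   where production peaks at `B0/e`;
#' * `"schaefer"` -- the Graham-Schaefer (logistic) model, the `n = 2`
#'   case, peaking at `B0/2`;
#' * `"pella_tomlinson"` -- the general case with a free shape exponent
#'   `n > 1`, peaking at `B0 * n^(1/(1-n))`.
#'
#' The Pella-Tomlinson parameterization used throughout is
#' `P = (r/(n-1)) * B * (1 - (B/B0)^(n-1))`, chosen because its n -> 1
#' limit reproduces the Gompertz-Fox curve exactly and n = 2 reproduces
#' Graham-Schaefer.
#'
#' @param family One of `"fox"`, `"schaefer"`, `"pella_tomlinson"`.
#' @param n Shape exponent, required (and `> 1`) only for
#'   `"pella_tomlinson"`.
#' @return An object of class `surplus_model`.
#' @examples
#' surplus_model("fox")
#' surplus_model("pella_tomlinson", n = 3)
#' @export
surplus_model <- function(family = c("fox", "schaefer", "pella_tomlinson"),
                          n = NULL) {
  family <- match.arg(family)
  if (family == "pella_tomlinson") {
    if (is.null(n) || !is.numeric(n) || length(n) != 1L || !is.finite(n)) {
      stop("pella_tomlinson requires a single finite shape exponent `n`")
    }
    if (n <= 1) stop("pella_tomlinson shape exponent `n` must be > 1")
  } else {
    if (!is.null(n)) stop("`n` is only meaningful for family = 'pella_tomlinson'")
    n <- if (family == "schaefer") 2 else NULL
  }
  structure(list(family = family, n = n), class = "surplus_model")
}

#' @export
print.surplus_model <- function(x, ...) {
  lbl <- switch(x$family,
    fox = "Gompertz-Fox (Pella-Tomlinson limit n -> 1)",
    schaefer = "Graham-Schaefer (Pella-Tomlinson n = 2)",
    pella_tomlinson = sprintf("Pella-Tomlinson (n = %g)", x$n)
  )
  cat("<surplus_model>", lbl, "\n")
  invisible(x)
}

check_community_params <- function(B0, r, model) {
  if (any(!is.finite(B0)) || any(B0 <= 0)) stop("B0 must be positive and finite")
  if (any(!is.finite(r)) || any(r < 0)) stop("r must be non-negative and finite")
  if (model$family == "fox" && any(B0 <= 1)) {
    stop("Gompertz-Fox surplus requires B0 > 1 (log(B0) must be positive)")
  }
  invisible(TRUE)
}

#' Annual surplus production
#'
#' Potential yield (annual surplus production, t/km2/y) of the assemblage at
#' standing biomass `B`, given unfished biomass `B0` and community biomass
#' growth rate `r`. For the Gompertz-Fox model
#' `P = log(B0) * r * B * (1 - log(B)/log(B0))`, and for the
#' Pella-Tomlinson family `P = (r/(n-1)) * B * (1 - (B/B0)^(n-1))`
#' (Graham-Schaefer is the n = 2 case `r * B * (1 - B/B0)`). Natural
#' logarithms throughout. Surplus vanishes at `B = B0`; values of `B`
#' above `B0` are permitted and yield negative surplus, so over-baseline
#' observations can still be assessed.
#'
#' @param B Standing biomass, t/km2. Vectorized.
#' @param B0 Unfished community biomass, t/km2.
#' @param r Community biomass growth rate, 1/y.
#' @param model A [surplus_model()].
#' @return Surplus production, t/km2/y (same length as `B`).
#' @examples
#' m <- surplus_model("schaefer")
#' surplus(50, B0 = 100, r = 0.2, model = m)  # r*B0/4 = 5
#' @export
surplus <- function(B, B0, r, model = surplus_model("fox")) {
  check_community_params(B0, r, model)
  if (any(!is.finite(B)) || any(B <= 0)) stop("B must be positive and finite")
  if (model$family == "fox") {
    # identical to log(B0)*r*B*(1 - log(B)/log(B0))
    r * B * (log(B0) - log(B))
  } else {
    n <- model$n
    (r / (n - 1)) * B * (1 - (B / B0)^(n - 1))
  }
}

#' Biomass at multispecies maximum sustainable yield
#'
#' The standing biomass maximizing the surplus curve: `B0/e` for
#' Gompertz-Fox, `B0/2` for Graham-Schaefer, `B0 * n^(1/(1-n))` for
#' Pella-Tomlinson.
#'
#' @inheritParams surplus
#' @return B_MMSY, t/km2.
#' @export
bmmsy <- function(B0, r = 1, model = surplus_model("fox")) {
  check_community_params(B0, r, model)
  B0 * bmmsy_fraction(model)
}

# B_MMSY / B0 for a given family: the depletion at which production peaks
bmmsy_fraction <- function(model) {
  if (model$family == "fox") exp(-1) else model$n^(1 / (1 - model$n))
}

#' Multispecies maximum sustainable yield
#'
#' The peak of the surplus curve: `r*B0/e` for Gompertz-Fox and
#' `surplus(bmmsy(...))` in general.
#'
#' @inheritParams surplus
#' @return MMSY, t/km2/y.
#' @export
mmsy <- function(B0, r, model = surplus_model("fox")) {
  check_community_params(B0, r, model)
  if (model$family == "fox") {
    r * B0 * exp(-1)
  } else {
    n <- model$n
    # surplus at B0*n^(1/(1-n)): (r/(n-1)) * BMMSY * (1 - 1/n)
    (r / n) * B0 * n^(1 / (1 - n))
  }
}

#' Pretty good multispecies yield biomass bounds
#'
#' The biomass interval over which surplus production is at least
#' `fraction` of MMSY: the two roots of `surplus(B) = fraction * MMSY`,
#' bracketing B_MMSY. Because `surplus(B)/MMSY` depends on biomass only
#' through the depletion `B/B0`, the roots are found once on the relative
#' scale by bracketed root-finding (absolute tolerance 1e-10) and rescaled
#' by `B0`.
#'
#' @inheritParams surplus
#' @param fraction Fraction of MMSY defining "pretty good" yield, in
#'   (0, 1]. Default 0.8.
#' @return Named numeric vector `c(lower, upper)` in t/km2, satisfying
#'   `lower <= bmmsy(...) <= upper`.
#' @examples
#' pgmy_bounds(B0 = 100, r = 0.2, model = surplus_model("schaefer"))
#' @export
pgmy_bounds <- function(B0, r, model = surplus_model("fox"), fraction = 0.8) {
  check_community_params(B0, r, model)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("`fraction` must be a single value in (0, 1]")
  }
  b <- pgmy_fractions(model, fraction)
  c(lower = b[[1]] * B0, upper = b[[2]] * B0)
}

# Relative PGMY bounds (as fractions of B0) for a family. Solves
# surplus(b)/mmsy = fraction on the unit-B0 scale.
pgmy_fractions <- function(model, fraction) {
  bpeak <- bmmsy_fraction(model)
  if (fraction == 1) return(c(bpeak, bpeak))
  # relative yield curve: surplus(b*B0)/MMSY, independent of B0 and r
  if (model$family == "fox") {
    rel <- function(b) exp(1) * b * (-log(b))
  } else {
    n <- model$n
    mm <- (1 / n) * bpeak # MMSY at B0 = r = 1
    rel <- function(b) ((1 / (n - 1)) * b * (1 - b^(n - 1))) / mm
  }
  f <- function(b) rel(b) - fraction
  lo <- stats::uniroot(f, lower = 1e-12, upper = bpeak, tol = 1e-12)$root
  hi <- stats::uniroot(f, lower = bpeak, upper = 1 - 1e-12, tol = 1e-12)$root
  c(lo, hi)
}

#' Biomass recovery trajectory
#'
#' Closed-form solution of `dB/dt = surplus(B)` from initial biomass
#' `Bmin` at `t = 0`: the Gompertz curve
#' `B(t) = B0 * exp(log(Bmin/B0) * exp(-r*t))` for the Fox model, and the
#' generalized logistic
#' `B(t) = B0 * (1 + ((B0/Bmin)^(n-1) - 1) * exp(-r*t))^(-1/(n-1))`
#' for the Pella-Tomlinson family (ordinary logistic when n = 2). The
#' trajectory is monotone increasing and approaches `B0` as t grows.
#'
#' @param t Time since protection, years (vectorized, `>= 0` typical but
#'   any real accepted).
#' @param B0 Unfished biomass, t/km2.
#' @param Bmin Initial biomass at `t = 0`, t/km2; must satisfy
#'   `0 < Bmin < B0`.
#' @param r Community biomass growth rate, 1/y.
#' @param model A [surplus_model()].
#' @return Biomass at each `t`, t/km2.
#' @export
recovery_trajectory <- function(t, B0, Bmin, r, model = surplus_model("fox")) {
  check_community_params(B0, r, model)
  if (any(!is.finite(Bmin)) || any(Bmin <= 0)) stop("Bmin must be positive")
  if (any(Bmin >= B0)) stop("Bmin must be below B0")
  if (model$family == "fox") {
    B0 * exp(log(Bmin / B0) * exp(-r * t))
  } else {
    n <- model$n
    B0 * (1 + ((B0 / Bmin)^(n - 1) - 1) * exp(-r * t))^(-1 / (n - 1))
  }
}
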
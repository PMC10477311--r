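# Covariate preparation shared by the hierarchical fit, the reference-point
# propagation, and the ecosystem models.

# continuous covariates standardized as (x - mean) / (2 * sd)
CONT_COVARS <- c("ocean_prod", "sst", "coral_cover", "depth", "sampling_area")

#' Standardize site covariates for model fitting
#'
#' Continuous environmental and methodological covariates (ocean
#' productivity, SST, hard-coral cover, depth, sampling area) and reserve
#' size are mean-centered and divided by two standard deviations, so their
#' slopes are comparable to those of the 0/1 dummy covariates. Categorical
#' covariates (atoll flag, habitat type relative to slope, census method
#' relative to standard belt transects) become 0/1 dummies. Gravity is
#' deliberately left untransformed (not centered), so baseline parameters
#' refer to average environmental conditions at zero human pressure.
#' Missing hard-coral cover is imputed at the mean observed cover before
#' centering.
#'
#' @param sites A site table as produced by [simulate_reef_data()] or
#'   [read_sites()].
#' @param spec Optional standardization spec from a previous call; when
#'   supplied, its stored means/SDs are reused (e.g., to place new sites on
#'   the scale of a fitted model). Covariates falling outside the range the
#'   stored scaling was built from trigger a warning, not an error.
#' @return A list with `data` (the input table plus `x_*` design columns)
#'   and `spec` (per-covariate centers/scales, the imputed coral mean, and
#'   observed covariate ranges).
#' @export
standardize_covariates <- function(sites, spec = NULL) {
  stopifnot(is.data.frame(sites))
  sites <- tibble::as_tibble(sites)

  if (!"coral_cover" %in% names(sites)) {
    stop("missing mandatory covariate column: coral_cover")
  }
  coral_mean <- if (is.null(spec)) {
    mean(sites$coral_cover, na.rm = TRUE)
  } else {
    spec$coral_mean
  }
  sites$coral_cover[is.na(sites$coral_cover)] <- coral_mean

  if (is.null(spec)) {
    centers <- scales <- ranges_lo <- ranges_hi <- numeric(0)
    for (v in CONT_COVARS) {
      x <- sites[[v]]
      if (any(!is.finite(x))) stop("non-finite values in covariate: ", v)
      s <- stats::sd(x)
      if (!is.finite(s) || s == 0) {
        stop("covariate has zero variance and cannot be standardized: ", v)
      }
      centers[v] <- mean(x)
      scales[v] <- 2 * s
      ranges_lo[v] <- min(x)
      ranges_hi[v] <- max(x)
    }
    # reserve size exists only for reserves; scaled within that subset
    rs <- sites$reserve_size[!is.na(sites$reserve_size)]
    if (length(rs) > 1L && stats::sd(rs) > 0) {
      centers["reserve_size"] <- mean(rs)
      scales["reserve_size"] <- 2 * stats::sd(rs)
      ranges_lo["reserve_size"] <- min(rs)
      ranges_hi["reserve_size"] <- max(rs)
    } else if (length(rs) > 0L) {
      stop("covariate has zero variance and cannot be standardized: reserve_size")
    }
    spec <- list(centers = centers, scales = scales, coral_mean = coral_mean,
                 range_lo = ranges_lo, range_hi = ranges_hi)
    class(spec) <- "standardization_spec"
  } else {
    out_of_range <- character(0)
    for (v in intersect(CONT_COVARS, names(spec$centers))) {
      x <- sites[[v]]
      if (any(x < spec$range_lo[v] | x > spec$range_hi[v])) {
        out_of_range <- c(out_of_range, v)
      }
    }
    if (length(out_of_range)) {
      warning("covariates outside the standardization support (extrapolating): ",
              paste(out_of_range, collapse = ", "))
    }
  }

  std <- function(v) {
    if (!v %in% names(spec$centers)) return(rep(0, nrow(sites)))
    (sites[[v]] - spec$centers[v]) / spec$scales[v]
  }

  sites$x_ocean_prod <- std("ocean_prod")
  sites$x_sst <- std("sst")
  sites$x_atoll <- as.numeric(sites$atoll)
  sites$x_coral <- std("coral_cover")
  sites$x_depth <- std("depth")
  sites$x_crest <- as.numeric(sites$habitat == "crest")
  sites$x_lagoon_backreef <- as.numeric(sites$habitat == "lagoon_backreef")
  sites$x_flat <- as.numeric(sites$habitat == "flat")
  sites$x_point_count <- as.numeric(sites$census_method == "point_count")
  sites$x_distance <- as.numeric(sites$census_method == "distance")
  sites$x_sampling_area <- std("sampling_area")
  rs <- sites$reserve_size
  rs[is.na(rs)] <- if ("reserve_size" %in% names(spec$centers)) {
    spec$centers["reserve_size"]
  } else 0
  sites$x_reserve_size <- if ("reserve_size" %in% names(spec$centers)) {
    (rs - spec$centers["reserve_size"]) / spec$scales["reserve_size"]
  } else rep(0, nrow(sites))
  sites$x_gravity <- sites$gravity # not standardized by design

  list(data = sites, spec = spec)
}

# column names of the environmental design (slopes beta1..beta4)
ENV_X <- c("x_ocean_prod", "x_sst", "x_atoll", "x_coral")
# sampling-effect design (slopes beta5..beta11)
SAMP_X <- c("x_depth", "x_crest", "x_lagoon_backreef", "x_flat",
            "x_point_count", "x_distance", "x_sampling_area")
BETA_NAMES <- c("ocean_prod", "sst", "atoll", "coral",
                "depth", "crest", "lagoon_backreef", "flat",
                "point_count", "distance", "sampling_area",
                "reserve_size", "gravity")
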
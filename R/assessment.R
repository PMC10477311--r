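# Fishery classification at site and jurisdiction scales, and headline
# summary percentages.

#' Classify fishery status from biomass, catch and the surplus curve
#'
#' The four-way production-based classification: *good condition* when
#' biomass is above B_MMSY and catch below MMSY; *warning* when biomass is
#' above B_MMSY but catch above MMSY (the stock is expected to decline);
#' *recovering* when biomass is below B_MMSY but catch does not exceed the
#' surplus at current biomass; *unsustainable* when biomass is below
#' B_MMSY and catch exceeds the surplus. A site is of *conservation
#' concern* when it fails either benchmark (catch above MMSY and/or
#' biomass below B_MMSY), *overfished to collapse* when biomass is at or
#' below `collapse_fraction` of its unfished biomass, and subject to
#' *overfishing* when catch exceeds the surplus. "Below" is strict
#' (`< 1`); a ratio of exactly one counts as not-below.
#'
#' @param b_ratio Biomass status B/B_MMSY (vector).
#' @param catch Catch per unit area, t/km2/y (`NA` allowed).
#' @param mmsy,surplus_at_b Reference MMSY and surplus production at the
#'   assessed biomass, same length.
#' @param b_over_b0 Depletion B/B0 (for the collapse flag); optional.
#' @param pgmy_lower_ratio,pgmy_upper_ratio B relative to the PGMY biomass
#'   bounds (B/B_lower, B/B_upper); optional.
#' @param collapse_fraction Depletion at or below which a stock counts as
#'   collapsed; default 0.1.
#' @return A tibble with `category` (factor: good_condition, warning,
#'   recovering, unsustainable; `NA` when catch is missing) and logical
#'   flags `conservation_concern`, `overfishing`, `collapsed`,
#'   `within_pgmy`, `below_pgmy_lower`.
#' @export
classify_status <- function(b_ratio, catch, mmsy, surplus_at_b,
                            b_over_b0 = NULL,
                            pgmy_lower_ratio = NULL,
                            pgmy_upper_ratio = NULL,
                            collapse_fraction = 0.1) {
  n <- length(b_ratio)
  below_b <- b_ratio < 1
  above_mmsy <- !is.na(catch) & catch > mmsy
  above_surplus <- !is.na(catch) & catch > surplus_at_b
  category <- rep(NA_character_, n)
  has_catch <- !is.na(catch)
  category[has_catch & !below_b & !above_mmsy] <- "good_condition"
  category[has_catch & !below_b & above_mmsy] <- "warning"
  category[has_catch & below_b & !above_surplus] <- "recovering"
  category[has_catch & below_b & above_surplus] <- "unsustainable"
  concern <- below_b | above_mmsy
  tibble::tibble(
    category = factor(category, levels = c("good_condition", "warning",
                                           "recovering", "unsustainable")),
    conservation_concern = concern,
    overfishing = ifelse(has_catch, above_surplus, NA),
    collapsed = if (is.null(b_over_b0)) NA else b_over_b0 <= collapse_fraction,
    below_pgmy_lower = if (is.null(pgmy_lower_ratio)) NA else pgmy_lower_ratio < 1,
    within_pgmy = if (is.null(pgmy_lower_ratio) || is.null(pgmy_upper_ratio)) {
      NA
    } else pgmy_lower_ratio >= 1 & pgmy_upper_ratio <= 1
  )
}

#' Site-level fishery classification
#'
#' Applies [classify_status()] to the posterior medians of a
#' [site_status()] result: median marginalized biomass against median
#' B_MMSY, catch against median MMSY and median surplus. Sites without
#' catch retain their biomass-derived flags but no category.
#'
#' @param status A [site_status()] result (needs biomass).
#' @param collapse_fraction Collapse depletion threshold, default 0.1.
#' @return The `summary` tibble of `status` augmented with the category
#'   and flag columns.
#' @export
classify_site <- function(status, collapse_fraction = 0.1) {
  stopifnot(inherits(status, "reef_status"))
  if (is.null(status$B_marg)) stop("site classification needs biomass")
  s <- status$summary
  rp <- status$refpts
  med <- function(m) apply(m, 2, stats::median, na.rm = TRUE)
  cls <- classify_status(
    b_ratio = s$B_status_med,
    catch = if (is.null(status$catch)) rep(NA_real_, nrow(s)) else status$catch,
    mmsy = s$MMSY_s_med,
    surplus_at_b = s$P_med,
    b_over_b0 = s$B_marg_med / s$B0_s_med,
    pgmy_lower_ratio = s$B_marg_med / med(rp$pgmy_lower),
    pgmy_upper_ratio = s$B_marg_med / med(rp$pgmy_upper),
    collapse_fraction = collapse_fraction
  )
  dplyr::bind_cols(s, cls)
}

#' Jurisdiction-level reference points
#'
#' Draw-wise arithmetic means of the member sites' reference points:
#' `B0_c = mean(B0_s)`, `MMSY_c = mean(MMSY_s)`,
#' `BMMSY_c = mean(BMMSY_s)` (so a jurisdiction with one site inherits
#' that site's draws exactly), plus PGMY bounds derived from `B0_c`. The
#' jurisdiction surplus curve uses `B0_c` with the posterior growth rate.
#'
#' @param refpts A [site_reference_points()] result covering the member
#'   sites.
#' @param jurisdictions Optional character vector of jurisdiction ids to
#'   keep (default: all in the site table).
#' @return Object of class `reef_jur_refpoints`: draws x jurisdictions
#'   matrices and the jurisdiction ids.
#' @export
jurisdiction_reference_points <- function(refpts, jurisdictions = NULL) {
  stopifnot(inherits(refpts, "reef_refpoints"))
  jur <- refpts$sites$jurisdiction_id
  ids <- sort(unique(jur))
  if (!is.null(jurisdictions)) ids <- intersect(ids, jurisdictions)
  if (length(ids) == 0L) stop("no sites in the requested jurisdictions")
  agg <- function(mat) {
    sapply(ids, function(id) rowMeans(mat[, jur == id, drop = FALSE]))
  }
  B0_c <- agg(refpts$B0_s)
  pg <- pgmy_fractions(refpts$model, refpts$fraction)
  structure(list(
    jurisdiction_id = ids,
    B0_c = B0_c, MMSY_c = agg(refpts$MMSY_s), BMMSY_c = agg(refpts$BMMSY_s),
    pgmy_lower = B0_c * pg[1], pgmy_upper = B0_c * pg[2],
    r = refpts$r, model = refpts$model, sites = refpts$sites
  ), class = "reef_jur_refpoints")
}

#' Jurisdiction surplus production curve
#'
#' Draw-wise surplus production of a jurisdiction evaluated at biomass
#' `B`, using the jurisdiction unfished biomass and the posterior growth
#' rate.
#'
#' @param jr A [jurisdiction_reference_points()] result.
#' @param B Biomass at which to evaluate the curve: a scalar, a vector of
#'   one value per jurisdiction, or a draws x jurisdictions matrix.
#' @return Draws x jurisdictions matrix of surplus production.
#' @export
jurisdiction_surplus <- function(jr, B) {
  stopifnot(inherits(jr, "reef_jur_refpoints"))
  S <- nrow(jr$B0_c); nc <- ncol(jr$B0_c)
  Bm <- if (is.matrix(B)) B else matrix(B, S, nc, byrow = TRUE)
  out <- matrix(NA_real_, S, nc, dimnames = dimnames(jr$B0_c))
  for (s in seq_len(S)) {
    out[s, ] <- surplus(Bm[s, ], jr$B0_c[s, ], jr$r[s], jr$model)
  }
  out
}

#' Jurisdiction biomass (raw or MPA-weighted)
#'
#' Raw mode: the draw-wise mean marginalized biomass of the fished member
#' sites. Weighted mode additionally assumes the protected proportion of
#' territorial waters sits at unfished biomass:
#' `B_weighted = mean(B_marg) * (1 - p_mpa) + mean(B0_s) * p_mpa`, where
#' the unfished mean is over all member sites.
#'
#' @param refpts A [site_reference_points()] result over all member sites.
#' @param B_marg Draws x sites matrix from [marginalize_biomass()] over
#'   the same sites (`NA` columns allowed for sites without biomass).
#' @param p_mpa Named vector of protected proportions per jurisdiction
#'   (required for `mode = "weighted"`).
#' @param mode `"raw"` or `"weighted"`.
#' @return Draws x jurisdictions matrix.
#' @export
jurisdiction_biomass <- function(refpts, B_marg, p_mpa = NULL,
                                 mode = c("raw", "weighted")) {
  mode <- match.arg(mode)
  stopifnot(inherits(refpts, "reef_refpoints"))
  jur <- refpts$sites$jurisdiction_id
  fished <- refpts$sites$category %in% c("restricted", "open")
  ids <- sort(unique(jur[fished]))
  raw <- sapply(ids, function(id) {
    rowMeans(B_marg[, fished & jur == id, drop = FALSE])
  })
  if (mode == "raw") return(raw)
  if (is.null(p_mpa)) stop("weighted jurisdiction biomass requires p_mpa")
  if (any(is.na(p_mpa)) || any(p_mpa < 0) || any(p_mpa > 1)) {
    stop("p_mpa must lie in [0, 1]")
  }
  missing_p <- setdiff(ids, names(p_mpa))
  if (length(missing_p)) {
    stop("p_mpa missing for jurisdictions: ",
         paste(missing_p, collapse = ", "))
  }
  B0mean <- sapply(ids, function(id) {
    rowMeans(refpts$B0_s[, jur == id, drop = FALSE])
  })
  p <- matrix(p_mpa[ids], nrow(raw), length(ids), byrow = TRUE)
  raw * (1 - p) + B0mean * p
}

#' Jurisdiction status and classification
#'
#' Draw-wise `B_status = B_c/BMMSY_c` and `F_status = C_c/MMSY_c`, with
#' the same category rules as sites evaluated at the posterior medians
#' using the jurisdiction surplus curve. Jurisdictions can be assessed on
#' catch alone (no biomass) or biomass alone.
#'
#' @param jr A [jurisdiction_reference_points()] result.
#' @param B_c Draws x jurisdictions biomass matrix (raw or weighted), or
#'   `NULL`.
#' @param C_c Named per-jurisdiction catch per unit area (t/km2/y), or
#'   `NULL`.
#' @param collapse_fraction Collapse depletion threshold, default 0.1.
#' @return A list with `summary` (tibble of medians, intervals, category
#'   and flags) and draw-wise matrices `B_status`, `F_status`, `P_c`,
#'   `overfishing`.
#' @export
jurisdiction_status <- function(jr, B_c = NULL, C_c = NULL,
                                collapse_fraction = 0.1) {
  stopifnot(inherits(jr, "reef_jur_refpoints"))
  ids <- jr$jurisdiction_id
  S <- nrow(jr$B0_c)
  B_status <- F_status <- P_c <- overfishing <- NULL
  if (!is.null(B_c)) {
    B_status <- B_c / jr$BMMSY_c
    P_c <- jurisdiction_surplus(jr, B_c)
  }
  catch <- rep(NA_real_, length(ids))
  if (!is.null(C_c)) {
    catch <- as.numeric(C_c[ids])
    Cm <- matrix(catch, S, length(ids), byrow = TRUE)
    F_status <- Cm / jr$MMSY_c
    if (!is.null(P_c)) overfishing <- Cm > P_c
  }
  med <- function(m) if (is.null(m)) NULL else apply(m, 2, stats::median)
  summ <- tibble::tibble(jurisdiction_id = ids)
  qq <- function(summ, m, nm) {
    if (is.null(m)) return(summ)
    q <- apply(m, 2, stats::quantile, c(.05, .5, .95), na.rm = TRUE)
    summ[[paste0(nm, "_med")]] <- q[2, ]
    summ[[paste0(nm, "_lo")]] <- q[1, ]
    summ[[paste0(nm, "_hi")]] <- q[3, ]
    summ
  }
  summ <- qq(summ, jr$B0_c, "B0_c")
  summ <- qq(summ, jr$MMSY_c, "MMSY_c")
  summ <- qq(summ, jr$BMMSY_c, "BMMSY_c")
  summ <- qq(summ, B_c, "B_c")
  summ <- qq(summ, B_status, "B_status")
  summ <- qq(summ, F_status, "F_status")
  summ <- qq(summ, P_c, "P_c")
  if (!is.null(C_c)) summ$catch <- catch
  if (!is.null(B_c)) {
    cls <- classify_status(
      b_ratio = summ$B_status_med,
      catch = catch,
      mmsy = summ$MMSY_c_med,
      surplus_at_b = summ$P_c_med,
      b_over_b0 = med(B_c) / med(jr$B0_c),
      pgmy_lower_ratio = med(B_c) / med(jr$pgmy_lower),
      pgmy_upper_ratio = med(B_c) / med(jr$pgmy_upper),
      collapse_fraction = collapse_fraction
    )
    summ <- dplyr::bind_cols(summ, cls)
  }
  list(summary = summ, B_status = B_status, F_status = F_status,
       P_c = P_c, overfishing = overfishing)
}

#' Headline assessment percentages
#'
#' Percentages of assessed units failing each benchmark, with 90%
#' uncertainty intervals constructed from draw-wise unit frequencies:
#' below B_MMSY, catching above MMSY, overfishing (catch above surplus),
#' collapsed, below the lower PGMY biomass, within the PGMY biomass range,
#' of conservation concern, and per fishery category. Point percentages
#' use the posterior-median classification; intervals come from
#' re-classifying every unit within each draw.
#'
#' @param status A [site_status()] result (or the draw-matrix list from
#'   [jurisdiction_status()]).
#' @param classification The median-based classification tibble from
#'   [classify_site()] (or the jurisdiction `summary`).
#' @param collapse_fraction Collapse depletion threshold, default 0.1.
#' @return A tibble with columns `measure`, `percent`, `lo`, `hi`, `n`.
#' @export
summarize_assessment <- function(status, classification,
                                 collapse_fraction = 0.1) {
  cl <- classification
  has_cat <- !is.na(cl$category)
  pct <- function(flag, base = rep(TRUE, nrow(cl))) {
    100 * sum(flag & base, na.rm = TRUE) / max(1L, sum(base))
  }
  draw_pct <- function(mat, fun) {
    if (is.null(mat)) return(c(NA_real_, NA_real_))
    per_draw <- apply(mat, 1, fun)
    unname(stats::quantile(per_draw, c(.05, .95), na.rm = TRUE))
  }
  B_status <- status$B_status
  F_status <- status$F_status
  over <- status$overfishing
  refpts <- status$refpts
  B_marg <- status$B_marg
  below_ci <- draw_pct(B_status, function(x) 100 * mean(x < 1, na.rm = TRUE))
  above_ci <- draw_pct(F_status, function(x) 100 * mean(x > 1, na.rm = TRUE))
  over_ci <- draw_pct(over, function(x) 100 * mean(x, na.rm = TRUE))
  coll_ci <- if (!is.null(B_marg) && !is.null(refpts)) {
    depl <- B_marg / refpts$B0_s
    draw_pct(depl, function(x) 100 * mean(x <= collapse_fraction, na.rm = TRUE))
  } else c(NA_real_, NA_real_)
  concern_ci <- if (!is.null(B_status) && !is.null(F_status)) {
    draw_pct(1 * ((B_status < 1) | (F_status > 1)),
             function(x) 100 * mean(x, na.rm = TRUE))
  } else c(NA_real_, NA_real_)
  # draw-wise category frequencies (needs biomass, catch and surplus)
  cat_ci <- list()
  if (!is.null(B_status) && !is.null(F_status) && !is.null(over)) {
    below <- B_status < 1
    cat_ci <- list(
      good_condition = draw_pct(1 * (!below & !(F_status > 1)),
                                function(x) 100 * mean(x, na.rm = TRUE)),
      warning = draw_pct(1 * (!below & (F_status > 1)),
                         function(x) 100 * mean(x, na.rm = TRUE)),
      recovering = draw_pct(1 * (below & !over),
                            function(x) 100 * mean(x, na.rm = TRUE)),
      unsustainable = draw_pct(1 * (below & over),
                               function(x) 100 * mean(x, na.rm = TRUE))
    )
  }
  mmsy_col <- grep("^MMSY_(s|c)_med$", names(cl), value = TRUE)[1]
  rows <- list(
    tibble::tibble(measure = "below_bmmsy",
                   percent = pct(cl$B_status_med < 1),
                   lo = below_ci[1], hi = below_ci[2]),
    tibble::tibble(measure = "catch_above_mmsy",
                   percent = if (!"catch" %in% names(cl)) NA_real_ else
                     pct(!is.na(cl$catch) & cl$catch > cl[[mmsy_col]],
                         base = !is.na(cl$catch)),
                   lo = above_ci[1], hi = above_ci[2]),
    tibble::tibble(measure = "overfishing",
                   percent = pct(cl$overfishing, base = !is.na(cl$overfishing)),
                   lo = over_ci[1], hi = over_ci[2]),
    tibble::tibble(measure = "conservation_concern",
                   percent = pct(cl$conservation_concern),
                   lo = concern_ci[1], hi = concern_ci[2]),
    tibble::tibble(measure = "collapsed", percent = pct(cl$collapsed),
                   lo = coll_ci[1], hi = coll_ci[2]),
    tibble::tibble(measure = "below_pgmy_lower",
                   percent = pct(cl$below_pgmy_lower),
                   lo = NA_real_, hi = NA_real_),
    tibble::tibble(measure = "within_pgmy", percent = pct(cl$within_pgmy),
                   lo = NA_real_, hi = NA_real_)
  )
  for (lv in levels(cl$category)) {
    ci <- cat_ci[[lv]] %||% c(NA_real_, NA_real_)
    rows <- c(rows, list(tibble::tibble(
      measure = paste0("category_", lv),
      percent = pct(cl$category == lv, base = has_cat),
      lo = ci[1], hi = ci[2]
    )))
  }
  out <- dplyr::bind_rows(rows)
  out$n <- nrow(cl)
  out
}
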
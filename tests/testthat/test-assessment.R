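# Fishery classification rules, jurisdiction aggregation, MPA weighting,
# and the headline summary.

test_that("the four fishery categories follow the exhaustive truth table", {
  # columns: B/BMMSY, catch, MMSY, surplus at B  -> expected category
  cases <- tibble::tribble(
    ~b,    ~c,   ~mmsy, ~surp, ~cat,
    1.2,   0.8,  1.0,   0.9,   "good_condition",   # B high, C < MMSY
    1.3,   1.1,  1.0,   0.9,   "warning",          # B high, C > MMSY
    0.7,   0.5,  1.0,   0.6,   "recovering",       # B low, C <= surplus
    0.7,   0.7,  1.0,   0.6,   "unsustainable",    # B low, C > surplus
    1.0,   0.8,  1.0,   0.9,   "good_condition",   # tie: not below BMMSY
    1.0,   1.2,  1.0,   0.9,   "warning",
    0.99,  0.6,  1.0,   0.6,   "recovering",       # tie: C == surplus
    1.5,   1.0,  1.0,   0.8,   "good_condition"    # tie: C == MMSY
  )
  out <- classify_status(cases$b, cases$c, cases$mmsy, cases$surp)
  expect_equal(as.character(out$category), cases$cat)
  # concern is the complement of passing both benchmarks
  expect_equal(out$conservation_concern,
               cases$b < 1 | cases$c > cases$mmsy)
  # unsustainable implies concern; good condition implies no concern
  expect_true(all(out$conservation_concern[out$category == "unsustainable"]))
  expect_false(any(out$conservation_concern[out$category == "good_condition"]))
  # every case lands in exactly one category
  expect_false(any(is.na(out$category)))
})

test_that("collapse, PGMY and missing-catch flags behave", {
  out <- classify_status(
    b_ratio = c(0.5, 0.5, 1.2), catch = c(NA, 0.2, 0.2),
    mmsy = 1, surplus_at_b = 0.5,
    b_over_b0 = c(0.1, 0.100001, 0.5),
    pgmy_lower_ratio = c(0.9, 1.1, 2.5),
    pgmy_upper_ratio = c(0.3, 0.6, 1.2)
  )
  expect_equal(out$collapsed, c(TRUE, FALSE, FALSE))
  expect_equal(out$below_pgmy_lower, c(TRUE, FALSE, FALSE))
  expect_equal(out$within_pgmy, c(FALSE, TRUE, FALSE))
  # missing catch: no category, no overfishing call, biomass flags intact
  expect_true(is.na(out$category[1]))
  expect_true(is.na(out$overfishing[1]))
  expect_true(out$conservation_concern[1])
  # C = 0 can never flag overfishing of positive surplus
  z <- classify_status(0.7, 0, 1, 0.5)
  expect_false(z$overfishing)
  expect_equal(as.character(z$category), "recovering")
})

test_that("singleton jurisdictions inherit site draws; means are exact", {
  fit <- desk_fit()
  sim <- desk_sim()
  fished <- sim$sites[sim$sites$category %in% c("restricted", "open"), ][1:3, ]
  fished$jurisdiction_id <- c("JA", "JB", "JB")
  rp <- site_reference_points(fit, fished)
  jr <- jurisdiction_reference_points(rp)
  expect_equal(unname(jr$B0_c[, "JA"]), unname(rp$B0_s[, 1]))
  expect_equal(unname(jr$MMSY_c[, "JB"]),
               unname((rp$MMSY_s[, 2] + rp$MMSY_s[, 3]) / 2))
  # explicit two-site mean: site draws 80 and 120 average to 100
  rp2 <- rp
  rp2$B0_s <- matrix(c(50, 80, 120), nrow(rp$B0_s), 3, byrow = TRUE)
  jr2 <- jurisdiction_reference_points(rp2)
  expect_equal(unique(jr2$B0_c[, "JB"]), 100)
  # jurisdiction surplus at BMMSY_c reproduces MMSY_c draw-wise
  P <- jurisdiction_surplus(jr, jr$BMMSY_c)
  expect_equal(P / jr$MMSY_c,
               matrix(1, nrow(P), ncol(P), dimnames = dimnames(P)),
               tolerance = 1e-8)
})

test_that("aggregation is invariant to site order", {
  fit <- desk_fit()
  sim <- desk_sim()
  fished <- sim$sites[sim$sites$category %in% c("restricted", "open"), ][1:10, ]
  rp1 <- site_reference_points(fit, fished)
  perm <- c(7, 2, 9, 1, 5, 10, 3, 8, 6, 4)
  rp2 <- site_reference_points(fit, fished[perm, ])
  jr1 <- jurisdiction_reference_points(rp1)
  jr2 <- jurisdiction_reference_points(rp2)
  expect_equal(jr1$B0_c, jr2$B0_c, tolerance = 1e-12)
})

test_that("MPA weighting mixes fished and unfished biomass as specified", {
  fit <- desk_fit()
  sim <- desk_sim()
  sub <- sim$sites[sim$sites$category %in% c("restricted", "open"), ][1:6, ]
  sub$jurisdiction_id <- rep(c("JA", "JB"), each = 3)
  rp <- site_reference_points(fit, sub)
  bm <- marginalize_biomass(fit, sub)
  raw <- jurisdiction_biomass(rp, bm, mode = "raw")
  w0 <- jurisdiction_biomass(rp, bm, c(JA = 0, JB = 0), mode = "weighted")
  w1 <- jurisdiction_biomass(rp, bm, c(JA = 1, JB = 1), mode = "weighted")
  wh <- jurisdiction_biomass(rp, bm, c(JA = 0.5, JB = 0.5), mode = "weighted")
  expect_equal(w0, raw, tolerance = 1e-12)
  B0mean <- sapply(c("JA", "JB"), function(id) {
    rowMeans(rp$B0_s[, sub$jurisdiction_id == id])
  })
  expect_equal(w1, B0mean, tolerance = 1e-12)
  expect_equal(wh, (raw + B0mean) / 2, tolerance = 1e-12)
  # hand-computed mixture: mean B_marg 40, mean B0 120, p 0.5 -> 80
  expect_equal(0.5 * 40 + 0.5 * 120, 80)
  expect_error(jurisdiction_biomass(rp, bm, mode = "weighted"), "p_mpa")
  expect_error(jurisdiction_biomass(rp, bm, c(JA = 1.2, JB = 0),
                                    mode = "weighted"), "0, 1")
})

test_that("catch-only jurisdictions get fishing status only", {
  fit <- desk_fit()
  sim <- desk_sim()
  sub <- sim$sites[sim$sites$category %in% c("restricted", "open"), ][1:4, ]
  rp <- site_reference_points(fit, sub)
  jr <- jurisdiction_reference_points(rp)
  Cc <- stats::setNames(rep(2, length(jr$jurisdiction_id)),
                        jr$jurisdiction_id)
  js <- jurisdiction_status(jr, B_c = NULL, C_c = Cc)
  expect_true("F_status_med" %in% names(js$summary))
  expect_false("B_status_med" %in% names(js$summary))
  # catch pinned at the median MMSY gives a median fishing status of one
  Cc2 <- stats::setNames(apply(jr$MMSY_c, 2, stats::median),
                         jr$jurisdiction_id)
  js2 <- jurisdiction_status(jr, B_c = NULL, C_c = Cc2)
  expect_equal(unname(js2$summary$F_status_med),
               rep(1, length(Cc2)), tolerance = 1e-6)
})

test_that("headline percentages are coherent and weighting can only help", {
  fit <- desk_fit()
  sim <- desk_sim()
  fished <- sim$sites[sim$sites$category %in% c("restricted", "open"), ]
  rp <- site_reference_points(fit, fished)
  bm <- marginalize_biomass(fit, fished)
  st <- site_status(rp, bm, fished$catch_obs)
  cl <- classify_site(st)
  hl <- summarize_assessment(st, cl)
  g <- function(m) hl$percent[hl$measure == m]
  cats <- c("category_good_condition", "category_warning",
            "category_recovering", "category_unsustainable")
  expect_equal(sum(vapply(cats, g, numeric(1))), 100, tolerance = 1e-9)
  expect_equal(g("conservation_concern"),
               100 - g("category_good_condition"), tolerance = 1e-9)
  expect_true(all(hl$lo <= hl$percent & hl$percent <= hl$hi, na.rm = TRUE))
  # jurisdiction scale: weighting with p_mpa > 0 cannot increase the
  # percent below BMMSY
  jr <- jurisdiction_reference_points(rp)
  ids <- jr$jurisdiction_id
  p1 <- stats::setNames(rep(0.4, length(ids)), ids)
  raw <- jurisdiction_biomass(rp, bm, mode = "raw")
  wtd <- jurisdiction_biomass(rp, bm, p1, mode = "weighted")
  js_raw <- jurisdiction_status(jr, raw)
  js_wtd <- jurisdiction_status(jr, wtd)
  expect_lte(mean(js_wtd$summary$B_status_med < 1),
             mean(js_raw$summary$B_status_med < 1))
})

test_that("degenerate summaries collapse to certainty", {
  fit <- desk_fit()
  rp <- site_reference_points(fit, reference_site(fit))
  # biomass fixed far below BMMSY in every draw
  bm <- rp$BMMSY_s * 0.3
  st <- site_status(rp, bm, catch = 10)
  cl <- classify_site(st)
  hl <- summarize_assessment(st, cl)
  row <- hl[hl$measure == "below_bmmsy", ]
  expect_equal(c(row$percent, row$lo, row$hi), c(100, 100, 100))
})
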
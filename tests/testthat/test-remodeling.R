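make_obs <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(vessel_id = r[[1]], session_day = r[[2]],
               diameter_um = r[[3]], velocity_mm_s = r[[4]],
               age_day = 5, stringsAsFactors = FALSE)))
}

test_that("session pairing keeps consecutive-day pairs with full data", {
  obs <- make_obs(list("a", 1, 20, 1), list("a", 2, 22, 1.2),
                  list("a", 3, 25, NA),          # no velocity on day 3: fine as endpoint
                  list("b", 1, 30, 2), list("b", 3, 31, 2),   # gap: no pair
                  list("c", 1, 15, NA), list("c", 2, 16, 1))  # no velocity day 1
  pts <- pair_sessions(obs)
  expect_identical(nrow(pts), 2L)               # a: days 1->2 and 2->3
  expect_identical(pts$vessel_id, c("a", "a"))
  expect_equal(pts$pct_change, c(10, 100 * 3 / 22), tolerance = 1e-12)
  expect_equal(pts$log10_shear[1], log10(4 * 1 * 1000 / 20),
               tolerance = 1e-12)
  skipped <- attr(pts, "skipped")
  expect_true("c" %in% skipped$vessel_id)
  expect_match(skipped$reason[skipped$vessel_id == "c"], "velocity")

  dup <- rbind(obs, obs[1, ])
  expect_error(pair_sessions(dup), "duplicate",
               class = "pialflow_data_error")
})

test_that("OLS fit matches the closed-form normal equations", {
  set.seed(5)
  pts <- data.frame(vessel_id = sprintf("v%02d", 1:25),
                    log10_shear = runif(25, 0.5, 3.5),
                    pct_change = rnorm(25, 0, 30))
  fit <- fit_remodeling(pts)$without_exclusion
  oracle <- ols_closed_form(pts$log10_shear, pts$pct_change)
  expect_equal(fit$slope, unname(oracle["slope"]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(oracle["intercept"]),
               tolerance = 1e-10)
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
})

test_that("noise-free generated cohorts return the generating law", {
  coh <- generate_cohort(cohort_truth(n_vessels = 12, noise_sd = 0, seed = 3))
  fit <- fit_remodeling(pair_sessions(coh$observations))
  expect_equal(fit$with_exclusion$slope, 15.4, tolerance = 1e-8)
  expect_equal(fit$with_exclusion$intercept, -40.9, tolerance = 1e-8)
  expect_equal(fit$with_exclusion$r_squared, 1, tolerance = 1e-9)
})

test_that("degenerate regressions are handled as specified", {
  flat <- data.frame(log10_shear = c(1, 2, 3, 4), pct_change = rep(5, 4))
  f <- fit_remodeling(flat)$without_exclusion
  expect_equal(f$slope, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 0)

  expect_error(fit_remodeling(flat[1:2, ]), "fewer than 3",
               class = "pialflow_data_error")
  novar <- data.frame(log10_shear = rep(2, 5), pct_change = rnorm(5))
  expect_error(fit_remodeling(novar), "zero variance",
               class = "pialflow_data_error")
})

test_that("the >100% outlier rule excludes from exactly one fit", {
  set.seed(9)
  pts <- data.frame(vessel_id = sprintf("v%02d", 1:10),
                    log10_shear = runif(10, 1, 3),
                    pct_change = c(rnorm(9, 0, 20), 150))
  fit <- fit_remodeling(pts)
  expect_identical(fit$with_exclusion$n_used, 9L)
  expect_identical(fit$with_exclusion$n_excluded, 1L)
  expect_identical(fit$with_exclusion$excluded_ids, "v10")
  expect_identical(fit$without_exclusion$n_used, 10L)
  expect_identical(fit$without_exclusion$n_excluded, 0L)
  expect_identical(fit$with_exclusion$n_used + fit$with_exclusion$n_excluded,
                   nrow(pts))

  # adding any point above the threshold never moves the with-exclusion fit
  base <- fit_remodeling(pts[1:9, ])
  expect_equal(fit$with_exclusion$slope, base$with_exclusion$slope,
               tolerance = 1e-12)
  expect_equal(fit$with_exclusion$intercept, base$with_exclusion$intercept,
               tolerance = 1e-12)
})

test_that("age-binned velocity-diameter correlation behaves as designed", {
  # exact proportionality: r = 1
  obs1 <- data.frame(age_day = 3, diameter_um = seq(10, 60, by = 5),
                     velocity_mm_s = 0.05 * seq(10, 60, by = 5))
  ab <- age_bin_velocity_diameter(obs1, bins = list(c(2, 6)))
  expect_equal(ab$pearson_r, 1, tolerance = 1e-12)

  # independence: |r| small at large n
  set.seed(31)
  obs2 <- data.frame(age_day = 9, diameter_um = exp(runif(400, 2, 4.5)),
                     velocity_mm_s = exp(runif(400, -1, 2)))
  ab2 <- age_bin_velocity_diameter(obs2, bins = list(c(8, 12)))
  expect_lt(abs(ab2$pearson_r), 0.15)

  # sparse bin is reported undefined, not an error
  ab3 <- age_bin_velocity_diameter(obs1[1:2, ], bins = list(c(2, 6)))
  expect_identical(ab3$n, 2L)
  expect_true(is.na(ab3$pearson_r))
})

test_that("copula-built cohorts show the commanded correlation ordering", {
  young <- generate_cohort(cohort_truth(n_vessels = 60, vd_rho = 0,
                                        age_days = rep(3L, 60), seed = 41))
  old <- generate_cohort(cohort_truth(n_vessels = 60, vd_rho = 0.8,
                                      age_days = rep(9L, 60), seed = 42))
  obs <- rbind(young$observations[young$observations$day == 1, ],
               old$observations[old$observations$day == 1, ])
  ab <- age_bin_velocity_diameter(obs)
  r_young <- ab$pearson_r[ab$age_lo == 2]
  r_old <- ab$pearson_r[ab$age_lo == 8]
  expect_lt(r_young, r_old)
  expect_gt(r_old, 0.5)
})
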
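test_that("kymograph generation is deterministic and validates its inputs", {
  tr <- kymograph_truth(velocity = 1.5, n_lines = 256, noise_sd = 0.05,
                        seed = 7)
  k1 <- generate_kymograph(tr)
  k2 <- generate_kymograph(tr)
  expect_identical(k1$image, k2$image)
  expect_identical(dim(k1$image), c(256L, 128L))

  # aliased commanded shift is rejected (must raise line rate instead)
  expect_error(kymograph_truth(velocity = 40, line_rate = 1000,
                               pixel_size = 0.5, n_pixels = 64),
               "aliased", class = "pialflow_data_error")
  expect_error(kymograph_truth(velocity = 1, line_rate = -1), "positive")
  expect_error(kymograph_truth(velocity = 1, n_pixels = 8), "at least 16")
})

test_that("zero-velocity kymographs have identical rows (stalled streaks)", {
  ky <- generate_kymograph(kymograph_truth(velocity = 0, n_lines = 64,
                                           noise_sd = 0, seed = 3))
  for (r in 2:nrow(ky$image))
    expect_identical(ky$image[r, ], ky$image[1, ])
  # and some streak content is actually present
  expect_lt(min(ky$image), max(ky$image))
})

test_that("opposite commanded velocities give exact spatial mirror images", {
  for (seed in c(1, 9)) {
    kp <- generate_kymograph(kymograph_truth(velocity = 3, n_lines = 128,
                                             noise_sd = 0.1, seed = seed))
    kn <- generate_kymograph(kymograph_truth(velocity = -3, n_lines = 128,
                                             noise_sd = 0.1, seed = seed))
    expect_identical(kn$image, kp$image[, ncol(kp$image):1])
  }
})

test_that("commanded streak slope is realized on the image", {
  # 2 mm/s at 2 kHz and 0.5 um/px commands 2 columns per line; track one
  # streak's centroid across rows of the noise-free image
  ky <- generate_kymograph(kymograph_truth(velocity = 2, n_lines = 128,
                                           noise_sd = 0, seed = 5))
  r0 <- 60
  shifts <- vapply(0:5, function(d)
    streak_centroid(ky$image, r0 + d), numeric(1))
  per_line <- diff(shifts)
  expect_true(all(abs(per_line - 2) < 0.1))
})

test_that("synthetic profiles have the commanded FWHM by construction", {
  # tophat: exactly 40 samples above half-max at 20 um / 0.5 um per px
  pr <- generate_profile(20, pixel_size = 0.5, shape = "tophat",
                         noise_sd = 0)
  half <- (max(pr$intensity) + min(pr$intensity)) / 2
  expect_identical(sum(pr$intensity > half), 40L)

  # gaussian: analytic FWHM equals the diameter
  prg <- generate_profile(20, pixel_size = 0.5, shape = "gaussian")
  sig <- 20 / (2 * sqrt(2 * log(2)))
  x <- seq_along(prg$intensity) * 0.5
  expect_equal(prg$intensity,
               0.1 + 0.9 * exp(-(x - prg$truth$centre)^2 / (2 * sig^2)),
               tolerance = 1e-12)

  # reproducible under a fixed seed; unresolvable diameter rejected
  expect_identical(generate_profile(12, noise_sd = 0.1, seed = 4)$intensity,
                   generate_profile(12, noise_sd = 0.1, seed = 4)$intensity)
  expect_error(generate_profile(0.8, pixel_size = 0.5),
               "not resolvable", class = "pialflow_data_error")
})

test_that("noise-free cohorts lie exactly on the remodeling law", {
  tr <- cohort_truth(n_vessels = 25, slope = 15.4, intercept = -40.9,
                     noise_sd = 0, seed = 11)
  coh <- generate_cohort(tr)
  obs <- coh$observations
  d1 <- obs[obs$day == 1, ]
  d2 <- obs[obs$day == 2, ]
  expect_identical(d1$vessel_id, d2$vessel_id)
  pct <- 100 * (d2$diameter_um - d1$diameter_um) / d1$diameter_um
  sh <- shear_rate(d1$velocity_mm_s, d1$diameter_um)
  expect_equal(pct, 15.4 * log10(sh) - 40.9, tolerance = 1e-10)

  # emitted truth shear column is reproducible from the emitted (v, D)
  expect_identical(coh$truth$shear_rate_per_s, sh)

  # zero law: day-2 diameters equal day-1 diameters
  flat <- generate_cohort(cohort_truth(n_vessels = 10, slope = 0,
                                       intercept = 0, noise_sd = 0,
                                       seed = 2))
  f1 <- flat$observations[flat$observations$day == 1, "diameter_um"]
  f2 <- flat$observations[flat$observations$day == 2, "diameter_um"]
  expect_equal(f2, f1, tolerance = 1e-12)
})

test_that("cohort draws respect their ranges and determinism", {
  tr <- cohort_truth(n_vessels = 40, noise_sd = 5, seed = 8)
  coh <- generate_cohort(tr)
  d1 <- coh$observations[coh$observations$day == 1, ]
  expect_true(all(d1$diameter_um >= 10 & d1$diameter_um <= 100))
  expect_true(all(d1$velocity_mm_s >= 0.2 & d1$velocity_mm_s <= 10))
  expect_identical(generate_cohort(tr)$observations, coh$observations)
  expect_error(cohort_truth(n_vessels = 1), "at least 2")
  expect_error(cohort_truth(diameter_range = c(-1, 10)), "positive")
})
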
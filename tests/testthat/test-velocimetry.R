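test_that("compiled projection variance matches an independent R version", {
  set.seed(42)
  blocks <- list(matrix(rnorm(32 * 32), 32),
                 generate_kymograph(kymograph_truth(velocity = 1.2,
                                                    n_lines = 48,
                                                    n_pixels = 40,
                                                    seed = 6))$image)
  angles <- seq(-80, 80, by = 7.3)
  for (b in blocks) {
    b <- b - mean(b)
    expect_equal(radon_angle_scan(b, angles),
                 r_projection_variance(b, angles), tolerance = 1e-10)
  }
})

test_that("Radon window velocimetry recovers commanded noise-free velocity", {
  ky <- generate_kymograph(kymograph_truth(velocity = 2, n_lines = 128,
                                           seed = 3))
  r <- radon_window_velocity(ky)
  expect_identical(r$status, "ok")
  expect_lt(abs(r$velocity - 2) / 2, 0.01)
  expect_gte(r$separability, 1)

  # stalled cells: vertical streaks give (numerically) zero velocity
  ky0 <- generate_kymograph(kymograph_truth(velocity = 0, n_lines = 128,
                                            seed = 5))
  r0 <- radon_window_velocity(ky0)
  expect_identical(r0$status, "ok")
  expect_lt(abs(r0$velocity), 0.01)

  # spatial mirror flips the sign, same magnitude
  b <- ky$image
  rm_ <- radon_window_velocity(b[, ncol(b):1], 2000, 0.5)
  expect_lt(abs(rm_$velocity + r$velocity), 0.02)

  # degenerate constant block is rejected as undefined
  rf <- radon_window_velocity(matrix(1, 64, 64), 2000, 0.5)
  expect_identical(rf$status, "flat")
  expect_true(is.na(rf$velocity))

  expect_error(radon_window_velocity(matrix(0, 16, 64), 2000, 0.5),
               "32", class = "pialflow_data_error")
})

test_that("correlation velocimetry recovers fast flow and handles lags", {
  # 10 mm/s is 10 px/line at 2 kHz, 0.5 um/px
  ky <- generate_kymograph(kymograph_truth(velocity = 10, n_lines = 256,
                                           seed = 7))
  cc <- correlation_window_velocity(ky, line_lag = 1L)
  expect_identical(cc$status, "ok")
  expect_lt(abs(cc$velocity - 10) / 10, 0.02)
  # oracle: argmax of the full discrete correlogram
  expect_equal(round(cc$peak_shift_px),
               discrete_correlogram_peak(ky$image, 1L))

  # lag 2 halves the per-pair shift but recovers the same velocity
  c2 <- correlation_window_velocity(ky, line_lag = 2L)
  expect_lt(abs(c2$velocity - 10) / 10, 0.02)

  # identical repeated lines: zero velocity at peak lag 0
  line <- generate_profile(12, n_pixels = 128, noise_sd = 0.02,
                           seed = 9)$intensity
  blk <- matrix(rep(line, each = 32), 32)
  c0 <- correlation_window_velocity(blk, 2000, 0.5)
  expect_identical(c0$status, "ok")
  expect_equal(c0$velocity, 0, tolerance = 1e-9)

  # shift beyond the search range lands on the boundary: unresolvable
  cb <- correlation_window_velocity(ky, line_lag = 1L, max_shift = 5)
  expect_identical(cb$status, "unresolvable")
})

test_that("Radon and correlation methods agree where both resolve", {
  for (v in c(2, 5, 8)) {
    ky <- generate_kymograph(kymograph_truth(velocity = v, n_lines = 256,
                                             noise_sd = 0.06,
                                             seed = 30 + v))
    r <- radon_window_velocity(ky)
    cc <- correlation_window_velocity(ky)
    expect_identical(r$status, "ok")
    expect_identical(cc$status, "ok")
    expect_lt(abs(r$velocity - cc$velocity), 0.05 * v)
  }
})

test_that("separability of coherent streaks exceeds that of shuffled rows", {
  ky <- generate_kymograph(kymograph_truth(velocity = 2, n_lines = 128,
                                           noise_sd = 0.08, seed = 13))
  r <- radon_window_velocity(ky)
  set.seed(99)
  shuffled <- ky$image[sample(nrow(ky$image)), ]
  rs <- radon_window_velocity(shuffled, 2000, 0.5)
  expect_gt(r$separability, rs$separability)
})

test_that("windowed estimation aggregates accepted windows and applies QC", {
  # clean record: everything accepted, duration matches the record length
  ky <- generate_kymograph(kymograph_truth(velocity = 2, n_lines = 2048,
                                           noise_sd = 0.1, seed = 17))
  e <- estimate_velocity(ky)
  expect_s3_class(e, "velocity_estimate")
  expect_lt(abs(e$velocity - 2) / 2, 0.05)
  expect_true(all(e$per_window$accepted))
  expect_equal(e$accepted_duration,
               nrow(e$per_window) * 64 / 2000, tolerance = 1e-12)
  expect_true(e$below_standard)  # ~1 s record is below the 40 s standard
  expect_identical(e$method, "radon")

  # pure noise: every window rejected, no estimate
  noise <- kymograph(matrix(rnorm(128 * 64), 128, 64), 2000, 0.5)
  expect_error(estimate_velocity(noise), "quality",
               class = "pialflow_compute_error")

  # motion-artifact lines are rejected but clean windows still estimate
  tr <- kymograph_truth(velocity = 2, n_lines = 4096, noise_sd = 0.1,
                        artifact_windows = list(c(1, 1400), c(2000, 3000)),
                        seed = 19)
  ea <- estimate_velocity(generate_kymograph(tr))
  expect_false(all(ea$per_window$accepted))
  expect_lt(abs(ea$velocity - 2) / 2, 0.05)
})
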
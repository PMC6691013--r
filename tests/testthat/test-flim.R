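# Lifetime fitting, map masking, midpoint threshold, and the CDK1 classifier.

test_that("noiseless single-exponential decays fit back exactly", {
  for (tau in c(1.2, 2.0, 3.5)) {
    d <- gen_decay(tau, 1e5, noise = FALSE)
    f <- fit_decay(d)
    expect_true(f$converged)
    expect_lt(abs(f$tau_ns - tau), 1e-4)
  }
})

test_that("degenerate histograms are rejected or flagged", {
  empty <- list(bin_centers_ns = (1:16 - 0.5) * 0.2, counts = rep(0, 16))
  expect_error(fit_decay(empty), "photons|empty")
  spike <- list(bin_centers_ns = (1:16 - 0.5) * 0.2,
                counts = c(500, rep(0, 15)))
  expect_false(fit_decay(spike)$converged)
  few <- gen_decay(2, 10, seed = 1)
  expect_error(fit_decay(few), "20 photons")
})

test_that("tau estimator at 500 photons is unbiased within 2% with SD in
           [1, 2] times the tau/sqrt(N) bound", {
  taus <- vapply(1:500, function(i)
    fit_decay(gen_decay(2.5, 500, seed = 1000 + i))$tau_ns, numeric(1))
  expect_lt(abs(mean(taus) - 2.5) / 2.5, 0.02)
  ideal <- 2.5 / sqrt(500)
  expect_gte(sd(taus), ideal)
  expect_lte(sd(taus), 2 * ideal)
})

test_that("estimator bias shrinks and SD scales as 1/sqrt(N)", {
  sds <- vapply(c(200, 500, 2000), function(n) {
    taus <- vapply(1:120, function(i)
      fit_decay(gen_decay(2.2, n, seed = n + i))$tau_ns, numeric(1))
    expect_lt(abs(mean(taus) - 2.2) / 2.2, 0.05)
    sd(taus)
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
  # SD ratio between N=200 and N=2000 should be near sqrt(10)
  expect_gt(sds[1] / sds[3], sqrt(10) * 0.6)
  expect_lt(sds[1] / sds[3], sqrt(10) * 1.7)
})

test_that("map masking separates cells from background by construction", {
  tf <- matrix(0, 24, 24); tf[, 1:12] <- 2.3
  st <- gen_flim_stack(tf, 500, bg_photons = 5, seed = 21)
  m <- fit_lifetime_map(st, background = matrix(tf == 0, 24, 24))
  expect_true(all(m$valid[, 1:12]))
  expect_false(any(m$valid[, 13:24]))
  expect_true(all(is.na(m$tau_ns[, 13:24])))
  # no valid pixel at or below the mean background level
  expect_true(all(m$intensity[m$valid] > m$background_level))
})

test_that("two-population stack fits back within 3% per region", {
  tf <- matrix(0, 32, 32); tf[, 1:16] <- 2.0; tf[, 17:32] <- 2.6
  st <- gen_flim_stack(tf, 500, seed = 22)
  m <- fit_lifetime_map(st, background = 10)
  expect_lt(abs(median(m$tau_ns[, 1:16], na.rm = TRUE) - 2.0) / 2.0, 0.03)
  expect_lt(abs(median(m$tau_ns[, 17:32], na.rm = TRUE) - 2.6) / 2.6, 0.03)
})

test_that("spatial binning leaves the median lifetime unchanged on a
           uniform stack", {
  tf <- matrix(2.4, 24, 24)
  st <- gen_flim_stack(tf, 500, seed = 23)
  m1 <- fit_lifetime_map(st, background = 10, spatial_binning = 1)
  m2 <- fit_lifetime_map(st, background = 10, spatial_binning = 2)
  med1 <- median(m1$tau_ns, na.rm = TRUE)
  med2 <- median(m2$tau_ns, na.rm = TRUE)
  # binning=2 pools 4x photons, so both are near truth; compare within the
  # single-pixel noise scale
  expect_lt(abs(med1 - med2), 3 * 2.4 / sqrt(500) / sqrt(nrow(tf)))
})

test_that("midpoint threshold is the mean midpoint, symmetric, and flags
           unresolvable groups", {
  thr <- midpoint_threshold(c(2.0), c(3.0))
  expect_equal(as.numeric(thr), 2.5)
  expect_true(attr(thr, "resolvable"))
  a <- rnorm(50, 2.1, 0.05); b <- rnorm(50, 2.7, 0.05)
  expect_equal(as.numeric(midpoint_threshold(a, b)),
               as.numeric(midpoint_threshold(b, a)))
  expect_warning(thr2 <- midpoint_threshold(c(2, 2.1), c(2, 2.1)),
                 "resolvability")
  expect_equal(as.numeric(thr2), 2.05)
  expect_false(attr(thr2, "resolvable"))
  expect_error(midpoint_threshold(numeric(0), 2), "non-empty")
})

test_that("CDK1 classification follows the tie-low rule and conserves counts", {
  r <- classify_cdk1(c(2.0, 2.4, 2.7), 2.5)
  expect_equal(r$fraction_high, 2 / 3)
  # tie classifies as low
  expect_equal(classify_cdk1(c(2.5), 2.5)$labels, "CDK1-low")
  expect_equal(classify_cdk1(c(2.6, 2.8), 2.5)$fraction_high, 0)
  expect_equal(sum(r$labels == "CDK1-high") + sum(r$labels == "CDK1-low"),
               r$n)
  expect_error(classify_cdk1(numeric(0), 2.5), "classify")
})

test_that("fraction high is monotone in the treated-population shift", {
  withr::with_seed(31, {
    base <- rnorm(300, 2.6, 0.1)
    fracs <- vapply(seq(0, 0.6, by = 0.1), function(shift)
      classify_cdk1(base - shift, 2.35)$fraction_high, numeric(1))
    expect_true(all(diff(fracs) >= 0))
  })
})

test_that("lifetime map rendering clamps to the LUT range and blacks out
           invalid pixels", {
  tau <- matrix(c(1.0, 1.9, 2.8, 3.5, NA, 2.3), 2, 3)
  map <- structure(list(tau_ns = tau, valid = !is.na(tau),
                        intensity = matrix(1, 2, 3)),
                   class = "lifetime_map")
  img <- render_lifetime_map(map)
  # below-range tau renders as the range minimum
  expect_equal(img[1, 1, ], img[2, 1, ])
  # above-range tau renders as the range maximum
  expect_equal(img[2, 2, ], img[1, 2, ])
  # invalid pixel is black
  expect_equal(img[1, 3, ], c(0, 0, 0))
  all_bad <- structure(list(tau_ns = matrix(NA_real_, 2, 2),
                            valid = matrix(FALSE, 2, 2),
                            intensity = matrix(0, 2, 2)),
                       class = "lifetime_map")
  expect_true(all(render_lifetime_map(all_bad) == 0))
  expect_error(render_lifetime_map(map, lut_range = c(2.8, 1.9)), "ascending")
})
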
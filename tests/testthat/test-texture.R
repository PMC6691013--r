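# GLCM texture, z-profiles, anisotropy, coverage and contraction area.

test_that("GLCM equals brute-force pair enumeration on small images", {
  withr::with_seed(41, {
    for (side in c(16, 24, 32)) {
      img <- matrix(runif(side * side), side, side)
      for (dir in c(0, 90, 180, 270)) {
        got <- glcm_correlation(compute_glcm(img, 2, dir, n_levels = 8))
        want <- brute_glcm_correlation(img, 2, dir, n_levels = 8)
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  })
})

test_that("GLCM matrices are normalized and respect preconditions", {
  img <- matrix(runif(64), 8, 8)
  P <- compute_glcm(img, 1, 0, n_levels = 4)
  expect_lt(abs(sum(P) - 1), 1e-12)
  expect_error(compute_glcm(img, 8, 0), "extent")
  expect_error(compute_glcm(img, 1, 45), "direction")
  const <- compute_glcm(matrix(1, 8, 8), 1, 0, n_levels = 4)
  expect_true(attr(const, "degenerate"))
  expect_error(glcm_correlation(const), "zero variance")
})

test_that("alternating stripes give correlation -1 at offset 1 and +1 at
           offset 2", {
  img <- matrix(0, 16, 16); img[, seq(1, 16, 2)] <- 1
  expect_equal(glcm_correlation(compute_glcm(img, 1, 0, n_levels = 2)), -1)
  expect_equal(glcm_correlation(compute_glcm(img, 2, 0, n_levels = 2)), 1)
  # brute-force agreement on the same image
  expect_equal(brute_glcm_correlation(img, 1, 0, 2), -1)
})

test_that("i.i.d. noise decorrelates at any offset", {
  withr::with_seed(42, img <- matrix(runif(256^2), 256, 256))
  for (d in c(1, 3)) {
    corr <- glcm_correlation(compute_glcm(img, d, 0, n_levels = 16))
    expect_lt(abs(corr), 0.05)
  }
})

test_that("correlation decay is normalized at distance 1 and slower for
           organized networks", {
  par <- gen_fiber_image(c(192, 192), 60, Inf, seed = 7)
  iso <- gen_fiber_image(c(192, 192), 60, 0, seed = 7)
  c_par <- correlation_decay(par$image, max_distance = 12, n_levels = 16)
  c_iso <- correlation_decay(iso$image, max_distance = 12, n_levels = 16)
  expect_equal(c_par$mean_correlation[1], 1)
  expect_equal(c_iso$mean_correlation[1], 1)
  expect_gt(c_par$auc, c_iso$auc)
})

test_that("white-noise correlation decay stays near zero beyond distance 1", {
  withr::with_seed(43, img <- matrix(runif(128^2), 128, 128))
  cd <- correlation_decay(img, max_distance = 6, n_levels = 16,
                          normalize = FALSE)
  expect_true(all(abs(cd$mean_correlation) < 0.05))
})

test_that("z-profile reports per-slice means, peak and linearity", {
  z <- 20
  stack <- array(0, dim = c(8, 8, z))
  prof_truth <- exp(-((1:z) - 10)^2 / 8)
  for (k in 1:z) stack[, , k] <- prof_truth[k]
  zp <- shg_zprofile(stack, z_step_um = 3)
  expect_equal(zp$peak_index, 10)
  expect_equal(zp$z_um, (0:(z - 1)) * 3)
  zp2 <- shg_zprofile(stack * 2, z_step_um = 3)
  expect_equal(zp2$mean_intensity, zp$mean_intensity * 2)
  expect_equal(zp2$peak_value, zp$peak_value * 2)
  flat <- shg_zprofile(array(5, dim = c(4, 4, 3)))
  expect_equal(flat$peak_value, 5)
  expect_error(shg_zprofile(array(0, dim = c(4, 4, 1))), "slices")
})

test_that("anisotropy hits its extremes on gratings and isotropic noise", {
  x <- matrix(rep(1:256, each = 256), 256, 256)
  grating <- sin(2 * pi * x / 16)
  expect_gt(anisotropy(grating), 0.99)
  withr::with_seed(44, noise <- matrix(rnorm(512^2), 512, 512))
  expect_lt(anisotropy(noise), 0.05)
})

test_that("anisotropy is invariant to 90-degree rotation and intensity
           scaling", {
  img <- gen_fiber_image(c(128, 128), 30, 5, seed = 9)$image
  rot <- t(img)[, nrow(img):1]  # 90-degree rotation
  expect_equal(anisotropy(img), anisotropy(rot), tolerance = 1e-6)
  expect_equal(anisotropy(img), anisotropy(10 * img), tolerance = 1e-9)
  expect_error(anisotropy(matrix(1, 64, 64)), "zero gradient")
  expect_error(anisotropy(matrix(1:400, 20, 20),
                          roi = matrix(FALSE, 20, 20)), "100")
})

test_that("coverage fraction matches constructed half-bright images and
           ground-truth fiber masks", {
  img <- matrix(0, 32, 32); img[, 1:16] <- 1
  expect_equal(coverage_fraction(img, threshold = 0.5), 50)
  expect_equal(coverage_fraction(matrix(0, 16, 16), threshold = 0.5), 0)
  fib <- gen_fiber_image(c(192, 192), 40, 2, seed = 10)
  truth_pct <- 100 * fib$truth$parameters$drawn_fraction
  # threshold at the generator's mask level; symmetric noise cancels
  got <- coverage_fraction(fib$image, threshold = 0.1)
  expect_lt(abs(got - truth_pct), 2)
  excl <- matrix(FALSE, 32, 32); excl[, 17:32] <- TRUE
  img2 <- matrix(1, 32, 32); img2[, 17:32] <- 0
  expect_equal(coverage_fraction(img2, threshold = 0.5,
                                 exclusion_mask = excl), 100)
  expect_error(coverage_fraction(img2, exclusion_mask = matrix(TRUE, 32, 32)),
               "excluded")
})

test_that("coverage is monotone non-increasing in the threshold", {
  withr::with_seed(45, img <- matrix(runif(64^2), 64, 64))
  cov <- vapply(seq(0.1, 0.9, 0.2), function(th)
    coverage_fraction(img, threshold = th), numeric(1))
  expect_true(all(diff(cov) <= 0))
})

test_that("matrix area recovers a disk, keeps the largest component, and
           rejects empty fields", {
  img <- matrix(1, 300, 300)
  disk <- outer(1:300, 1:300, function(i, j) (i - 150)^2 + (j - 150)^2) <= 100^2
  img[disk] <- 0.1
  a <- matrix_area(img, pixel_size_cm = 0.01)
  expect_lt(abs(as.numeric(a) - pi) / pi, 0.02)
  small <- outer(1:300, 1:300, function(i, j) (i - 40)^2 + (j - 40)^2) <= 20^2
  img2 <- img; img2[small] <- 0.1
  a2 <- matrix_area(img2, pixel_size_cm = 0.01)
  expect_equal(attr(a2, "n_pixels"), attr(a, "n_pixels"))
  expect_error(matrix_area(matrix(1, 50, 50), 0.01), "foreground")
})
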
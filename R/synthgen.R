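# Seeded synthetic-data generators. Every pipeline input can be produced here
# with ground truth attached, so each downstream stage is testable end-to-end
# without raw microscopy or instrument data.

#' Simulate a TCSPC photon-decay histogram
#'
#' Draws a single-pixel (or ROI-pooled) time-correlated single-photon counting
#' histogram from a mono-exponential donor decay plus a uniform background.
#' Defaults emulate an 80 MHz acquisition: a 12.5 ns window split into 64 bins.
#'
#' Bin counts are independent Poisson draws with means
#' \eqn{A e^{-t_i/\tau} + B}, where the exponential weight is evaluated at bin
#' centers and normalized over the window; the total photon count is therefore
#' Poisson-distributed around \code{n_photons}, with a fraction
#' \code{bg_fraction} of the budget spread uniformly across bins.
#'
#' @param tau_ns Fluorescence lifetime in ns; must lie inside the window.
#' @param n_photons Expected total photon count (the acquisition budget).
#' @param n_bins Number of time bins (at least 8).
#' @param bin_width_ns Width of one time bin in ns.
#' @param bg_fraction Fraction of photons in the uniform background, in [0, 1).
#' @param seed Integer seed; identical seeds give identical histograms.
#' @param noise If \code{FALSE}, return the noiseless expected counts
#'   (non-integer), i.e. the infinite-photon limit.
#' @return A \code{decay_histogram}: list with \code{bin_centers_ns},
#'   \code{counts}, \code{bin_width_ns}, and a \code{truth} field recording
#'   the generating parameters and seed.
#' @examples
#' d <- gen_decay(tau_ns = 2.5, n_photons = 500, seed = 1)
#' sum(d$counts)
#' @export
gen_decay <- function(tau_ns, n_photons, n_bins = 64L,
                      bin_width_ns = 12.5 / 64, bg_fraction = 0,
                      seed = 1L, noise = TRUE) {
  check_scalar(tau_ns, "tau_ns", lower = 0, closed_lower = FALSE)
  check_scalar(n_photons, "n_photons", lower = 0)
  check_scalar(n_bins, "n_bins", lower = 8)
  check_scalar(bin_width_ns, "bin_width_ns", lower = 0, closed_lower = FALSE)
  check_scalar(bg_fraction, "bg_fraction", lower = 0, upper = 1,
               closed_upper = FALSE)
  n_bins <- as.integer(n_bins)
  window_ns <- n_bins * bin_width_ns
  if (tau_ns >= window_ns)
    stop_data("`tau_ns` must be smaller than the acquisition window")

  centers <- (seq_len(n_bins) - 0.5) * bin_width_ns
  w <- exp(-centers / tau_ns)
  mu <- n_photons * ((1 - bg_fraction) * w / sum(w) + bg_fraction / n_bins)
  counts <- if (noise) {
    with_stream(seed, "gen_decay", stats::rpois(n_bins, mu))
  } else mu

  structure(list(
    bin_centers_ns = centers,
    counts = counts,
    bin_width_ns = bin_width_ns,
    truth = synthetic_truth(list(tau_ns = tau_ns, n_photons = n_photons,
                                 bg_fraction = bg_fraction), seed)
  ), class = "decay_histogram")
}

#' Simulate a FLIM stack over a lifetime field
#'
#' Generates per-pixel photon decays over a 2D field of ground-truth lifetimes.
#' Pixels where \code{tau_field} is zero are background and receive only
#' uniform dark counts (\code{bg_photons} expected per pixel). Per-pixel decays
#' are independent given the seed.
#'
#' @param tau_field Matrix of lifetimes (ns); 0 marks background pixels.
#' @param photons_per_pixel Expected photon budget per foreground pixel.
#' @param n_bins,bin_width_ns Time axis, as in [gen_decay()].
#' @param bg_fraction Uniform-background fraction within foreground decays.
#' @param bg_photons Expected dark counts per background pixel.
#' @param pixel_size_um Pixel pitch, carried as metadata.
#' @param seed Integer seed.
#' @return A \code{flim_stack}: list with \code{counts} (array y within x
#'   within time), \code{bin_centers_ns}, \code{bin_width_ns},
#'   \code{pixel_size_um} and \code{truth}.
#' @export
gen_flim_stack <- function(tau_field, photons_per_pixel, n_bins = 64L,
                           bin_width_ns = 12.5 / 64, bg_fraction = 0,
                           bg_photons = 0, pixel_size_um = 0.4, seed = 1L) {
  if (!is.matrix(tau_field) || !is.numeric(tau_field))
    stop_data("`tau_field` must be a numeric matrix")
  if (any(tau_field < 0) || any(!is.finite(tau_field)))
    stop_data("`tau_field` must be finite and non-negative (0 = background)")
  check_scalar(photons_per_pixel, "photons_per_pixel", lower = 0)
  check_scalar(n_bins, "n_bins", lower = 8)
  n_bins <- as.integer(n_bins)
  window_ns <- n_bins * bin_width_ns
  if (any(tau_field >= window_ns))
    stop_data("all lifetimes must be smaller than the acquisition window")

  centers <- (seq_len(n_bins) - 0.5) * bin_width_ns
  ny <- nrow(tau_field); nx <- ncol(tau_field)
  mu <- array(bg_photons / n_bins, dim = c(ny, nx, n_bins))
  fg <- which(tau_field > 0)
  if (length(fg)) {
    # per-pixel normalizer of the exponential over the window
    z <- vapply(tau_field[fg], function(tau) sum(exp(-centers / tau)),
                numeric(1))
    for (b in seq_len(n_bins)) {
      w_b <- exp(-centers[b] / tau_field[fg])
      mu[fg + (b - 1) * ny * nx] <-
        photons_per_pixel * ((1 - bg_fraction) * w_b / z +
                             bg_fraction / n_bins)
    }
  }
  counts <- with_stream(seed, "gen_flim_stack", {
    array(stats::rpois(length(mu), mu), dim = dim(mu))
  })
  structure(list(
    counts = counts,
    bin_centers_ns = centers,
    bin_width_ns = bin_width_ns,
    pixel_size_um = pixel_size_um,
    truth = synthetic_truth(list(tau_field = tau_field,
                                 photons_per_pixel = photons_per_pixel,
                                 bg_fraction = bg_fraction,
                                 bg_photons = bg_photons), seed)
  ), class = "flim_stack")
}

# von Mises sampler (Best & Fisher rejection); kappa = 0 falls back to uniform.
rvonmises <- function(n, mu, kappa) {
  if (kappa == 0) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- mu + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  out
}

# Separable Gaussian blur with reflected borders (thin wrapper over EBImage).
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  as.matrix(EBImage::gblur(img, sigma = sigma, boundary = "replicate"))
}

#' Simulate a fibrillar-collagen SHG image
#'
#' Draws \code{n_fibers} anti-aliased line segments whose orientations follow
#' an axial von Mises distribution (concentration \code{orientation_kappa};
#' 0 = isotropic, \code{Inf} = perfectly parallel), blurs them with a Gaussian
#' of sigma = \code{fiber_width_px}/2 to emulate fiber width and optics, and
#' adds Gaussian noise with sd = peak signal / \code{snr}. The default SNR of
#' 20 emulates line-averaged SHG acquisition.
#'
#' @param size_px Image size, c(rows, cols); at least 64 in each dimension.
#' @param n_fibers Number of fibers; 0 yields a pure-noise (isotropic) image.
#' @param orientation_kappa Axial von Mises concentration (>= 0 or Inf).
#' @param mean_orientation_rad Preferred axis, radians from the x axis.
#' @param fiber_width_px Fiber width in pixels.
#' @param snr Peak signal-to-noise ratio (> 0).
#' @param seed Integer seed.
#' @return A \code{fiber_image}: list with \code{image} (matrix, float),
#'   \code{truth} recording the drawn orientations, their circular mean and
#'   resultant length, the pre-noise fiber mask, and an \code{isotropic} flag.
#' @export
gen_fiber_image <- function(size_px = c(256L, 256L), n_fibers = 80L,
                            orientation_kappa = 0,
                            mean_orientation_rad = 0,
                            fiber_width_px = 2, snr = 20, seed = 1L) {
  if (length(size_px) != 2 || any(size_px < 64))
    stop_data("`size_px` must be two integers, each at least 64")
  check_scalar(n_fibers, "n_fibers", lower = 0)
  if (!identical(orientation_kappa, Inf))
    check_scalar(orientation_kappa, "orientation_kappa", lower = 0)
  check_scalar(snr, "snr", lower = 0, closed_lower = FALSE)
  ny <- as.integer(size_px[1]); nx <- as.integer(size_px[2])

  res <- with_stream(seed, "gen_fiber_image", {
    img <- matrix(0, ny, nx)
    if (n_fibers > 0) {
      if (is.infinite(orientation_kappa)) {
        theta <- rep(mean_orientation_rad, n_fibers)
      } else {
        # axial data: sample on the doubled circle, halve back
        theta <- mean_orientation_rad +
          rvonmises(n_fibers, 0, orientation_kappa) / 2
      }
      len <- stats::runif(n_fibers, 0.4, 0.9) * min(nx, ny)
      cx <- stats::runif(n_fibers, 1, nx)
      cy <- stats::runif(n_fibers, 1, ny)
      for (i in seq_len(n_fibers)) {
        s <- seq(-len[i] / 2, len[i] / 2, by = 0.35)
        px <- cx[i] + s * cos(theta[i])
        py <- cy[i] - s * sin(theta[i])   # image rows grow downward
        keep <- px >= 1 & px <= nx - 1e-9 & py >= 1 & py <= ny - 1e-9
        px <- px[keep]; py <- py[keep]
        if (!length(px)) next
        # bilinear splat for anti-aliasing
        x0 <- floor(px); y0 <- floor(py)
        fx <- px - x0; fy <- py - y0
        for (corner in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
          xi <- pmin(x0 + corner[1], nx); yi <- pmin(y0 + corner[2], ny)
          wgt <- (if (corner[1]) fx else 1 - fx) *
                 (if (corner[2]) fy else 1 - fy)
          idx <- cbind(yi, xi)
          for (k in seq_along(wgt)) img[idx[k, 1], idx[k, 2]] <-
            img[idx[k, 1], idx[k, 2]] + wgt[k]
        }
      }
      img <- gaussian_blur(img, fiber_width_px / 2)
      if (max(img) > 0) img <- img / max(img)
    } else {
      theta <- numeric(0)
    }
    mask <- img > 0.1
    noisy <- img + stats::rnorm(length(img), 0, 1 / snr)
    list(image = matrix(noisy, ny, nx), mask = mask, theta = theta)
  })

  theta <- res$theta
  if (length(theta)) {
    c2 <- mean(cos(2 * theta)); s2 <- mean(sin(2 * theta))
    mean_orient <- atan2(s2, c2) / 2
    resultant <- sqrt(c2^2 + s2^2)
  } else {
    mean_orient <- NA_real_; resultant <- 0
  }
  structure(list(
    image = res$image,
    truth = synthetic_truth(list(
      orientations_rad = theta,
      circular_mean_rad = mean_orient,
      resultant_length = resultant,
      kappa = orientation_kappa,
      fiber_mask = res$mask,
      drawn_fraction = mean(res$mask),
      isotropic = (n_fibers == 0 || orientation_kappa == 0)
    ), seed)
  ), class = "fiber_image")
}

#' Simulate an RGB brightfield histology image by Beer-Lambert stain mixing
#'
#' Forward model of transmitted-light imaging of absorbing chromogens: each
#' pixel's channel intensity is \eqn{I_c = i0_c \cdot 10^{-\sum_s conc_s
#' V_{sc}}} plus Gaussian noise, clipped to [0, i0].
#'
#' @param conc_fields Named list of non-negative concentration matrices, one
#'   per stain, all the same size; names must match rows of
#'   \code{stain_vectors}.
#' @param stain_vectors Stain matrix (rows = stains, unit optical-density
#'   directions), e.g. [hdab_stain_vectors()].
#' @param i0 Per-channel incident (white) intensity, length 3.
#' @param noise_sd Additive Gaussian noise sd, in intensity units.
#' @param seed Integer seed.
#' @return A \code{histology_rgb}: list with \code{rgb} (array y within x
#'   within channel) and \code{truth} holding the concentration fields.
#' @export
gen_histology_rgb <- function(conc_fields, stain_vectors = hdab_stain_vectors(),
                              i0 = c(255, 255, 255), noise_sd = 0, seed = 1L) {
  if (!is.list(conc_fields) || is.null(names(conc_fields)))
    stop_data("`conc_fields` must be a named list of matrices")
  dims <- lapply(conc_fields, dim)
  if (length(unique(dims)) != 1)
    stop_data("all concentration fields must have the same shape")
  if (any(vapply(conc_fields, function(m) any(m < 0), logical(1))))
    stop_data("stain concentrations must be non-negative")
  V <- validate_stain_vectors(stain_vectors)
  used <- names(conc_fields)
  if (!all(used %in% rownames(V)))
    stop_data("every concentration field must name a stain in `stain_vectors`")
  ny <- dims[[1]][1]; nx <- dims[[1]][2]

  od <- array(0, dim = c(ny, nx, 3))
  for (s in used)
    for (ch in 1:3)
      od[, , ch] <- od[, , ch] + conc_fields[[s]] * V[s, ch]
  rgb <- array(0, dim = c(ny, nx, 3))
  for (ch in 1:3) rgb[, , ch] <- i0[ch] * 10^(-od[, , ch])
  if (noise_sd > 0)
    rgb <- rgb + with_stream(seed, "gen_histology_rgb",
                             stats::rnorm(length(rgb), 0, noise_sd))
  for (ch in 1:3) rgb[, , ch] <- pmin(pmax(rgb[, , ch], 0), i0[ch])

  structure(list(
    rgb = rgb, i0 = i0,
    truth = synthetic_truth(list(conc_fields = conc_fields,
                                 stain_vectors = V, noise_sd = noise_sd), seed)
  ), class = "histology_rgb")
}

#' Simulate a scored organotypic invasion scene
#'
#' Places cells of two genotypes (\code{fl}, \code{mt}) in a 2D field with
#' known invasion structure: invading clusters laid down as pairwise chains
#' with spacing below \code{radius_um}, invading singles rejection-sampled
#' farther than \code{radius_um} from every other invading cell, and
#' non-invading cells filling the remainder. The attached truth records the
#' intended invasive index and per-mode counts, so the scoring stage can be
#' checked exactly.
#'
#' @param n_cells Total number of cells.
#' @param p_invade Fraction of cells that invade, in [0, 1].
#' @param genotype_mix Probability that a non-cluster cell is genotype
#'   \code{mt}.
#' @param cluster_spec List of \code{list(size =, n_mt =)} entries describing
#'   invading clusters; total size must not exceed the invading budget.
#' @param field_um Field extent c(width, height) in micrometres.
#' @param radius_um Proximity radius defining "invading together".
#' @param seed Integer seed.
#' @param max_retries Bounded retries for rejection placement.
#' @return An \code{invasion_scene}: list with \code{cells} (data.frame:
#'   cell_id, x_um, y_um, genotype, invading, section_id) and \code{truth}
#'   (intended invasive index and mode counts under the >4-cell cluster rule).
#' @export
gen_invasion_scene <- function(n_cells, p_invade, genotype_mix = 0.5,
                               cluster_spec = list(),
                               field_um = c(1000, 1000), radius_um = 30,
                               seed = 1L, max_retries = 500L) {
  check_scalar(n_cells, "n_cells", lower = 1)
  check_scalar(p_invade, "p_invade", lower = 0, upper = 1)
  check_scalar(genotype_mix, "genotype_mix", lower = 0, upper = 1)
  check_scalar(radius_um, "radius_um", lower = 0, closed_lower = FALSE)
  n_cells <- as.integer(n_cells)
  n_invading <- round(p_invade * n_cells)
  cl_sizes <- vapply(cluster_spec, function(cl) cl$size, numeric(1))
  cl_mt <- vapply(cluster_spec, function(cl) cl$n_mt, numeric(1))
  if (any(cl_mt > cl_sizes)) stop_data("cluster n_mt cannot exceed its size")
  if (sum(cl_sizes) > n_invading)
    stop_data("cluster sizes exceed the invading-cell budget")
  n_singles <- n_invading - sum(cl_sizes)
  w <- field_um[1]; h <- field_um[2]

  scene <- with_stream(seed, "gen_invasion_scene", {
    pts <- list()   # each: data.frame(x, y, genotype, invading)
    placed <- matrix(numeric(0), ncol = 2)  # invading-cell positions
    sep <- 2 * radius_um  # separation between distinct invading entities

    place_cluster <- function(size, n_mt) {
      for (try in seq_len(max_retries)) {
        cx <- stats::runif(1, sep, w - sep)
        cy <- stats::runif(1, sep, h - sep)
        xs <- cx; ys <- cy
        dir <- stats::runif(1, 0, 2 * pi)
        ok <- TRUE
        for (k in seq_len(size - 1)) {
          step <- stats::runif(1, 0.4, 0.7) * radius_um
          dir <- dir + stats::runif(1, -0.8, 0.8)
          nx2 <- xs[k] + step * cos(dir); ny2 <- ys[k] + step * sin(dir)
          if (nx2 < 1 || nx2 > w - 1 || ny2 < 1 || ny2 > h - 1) { ok <- FALSE; break }
          xs <- c(xs, nx2); ys <- c(ys, ny2)
        }
        if (!ok) next
        if (nrow(placed) &&
            min(sqrt(outer(xs, placed[, 1], "-")^2 +
                     outer(ys, placed[, 2], "-")^2)) <= sep) next
        geno <- c(rep("mt", n_mt), rep("fl", size - n_mt))
        geno <- sample(geno)
        return(data.frame(x = xs, y = ys, genotype = geno, invading = TRUE,
                          stringsAsFactors = FALSE))
      }
      stop_data("could not place a cluster after bounded retries ",
                "(field too small for the requested scene)")
    }

    for (ci in seq_along(cluster_spec)) {
      cl <- place_cluster(cl_sizes[ci], cl_mt[ci])
      pts[[length(pts) + 1]] <- cl
      placed <- rbind(placed, as.matrix(cl[, c("x", "y")]))
    }
    if (n_singles > 0) {
      for (i in seq_len(n_singles)) {
        done <- FALSE
        for (try in seq_len(max_retries)) {
          x <- stats::runif(1, 1, w - 1); y <- stats::runif(1, 1, h - 1)
          if (!nrow(placed) ||
              min(sqrt((placed[, 1] - x)^2 + (placed[, 2] - y)^2)) > sep) {
            g <- if (stats::runif(1) < genotype_mix) "mt" else "fl"
            pts[[length(pts) + 1]] <-
              data.frame(x = x, y = y, genotype = g, invading = TRUE,
                         stringsAsFactors = FALSE)
            placed <- rbind(placed, c(x, y))
            done <- TRUE
            break
          }
        }
        if (!done) stop_data("could not place an isolated invading cell ",
                             "after bounded retries")
      }
    }
    n_rest <- n_cells - n_invading
    if (n_rest > 0) {
      g <- ifelse(stats::runif(n_rest) < genotype_mix, "mt", "fl")
      pts[[length(pts) + 1]] <-
        data.frame(x = stats::runif(n_rest, 1, w - 1),
                   y = stats::runif(n_rest, 1, h - 1),
                   genotype = g, invading = FALSE, stringsAsFactors = FALSE)
    }
    do.call(rbind, pts)
  })

  cells <- data.frame(cell_id = seq_len(nrow(scene)),
                      x_um = scene$x, y_um = scene$y,
                      genotype = scene$genotype, invading = scene$invading,
                      section_id = 1L, stringsAsFactors = FALSE)

  # intended mode counts (fl cells only) under the >4-cell cluster rule
  n_fl_only <- sum(cl_sizes[cl_sizes >= 5 & cl_mt == 0])
  n_mosaic <- sum((cl_sizes - cl_mt)[cl_sizes >= 5 & cl_mt > 0])
  small_fl <- sum((cl_sizes - cl_mt)[cl_sizes < 5])
  single_fl <- sum(cells$invading & cells$genotype == "fl") -
    n_fl_only - n_mosaic
  structure(list(
    cells = cells,
    truth = synthetic_truth(list(
      invasive_index = 100 * n_invading / n_cells,
      n_invading = n_invading, n_total = n_cells,
      mode_counts = c(fl_only_cluster = as.integer(n_fl_only),
                      mosaic_cluster = as.integer(n_mosaic),
                      single = as.integer(single_fl)),
      n_clusters = as.integer(sum(cl_sizes >= 5)),
      radius_um = radius_um
    ), seed)
  ), class = "invasion_scene")
}

#' Simulate an AFM force-indentation curve
#'
#' Produces a tip-sample displacement sweep with a flat pre-contact baseline
#' and a Hertzian spherical-contact rise beyond the contact point, plus
#' additive Gaussian force noise. Probe spring constant defaults to the
#' instrument's 0.06 N/m and is carried as metadata only.
#'
#' @param E_pa Ground-truth Young's modulus (Pa).
#' @param R_um Probe radius (micrometres); default 0.5 (1 um colloidal probe).
#' @param nu Poisson ratio in [0, 0.5].
#' @param contact_nm Contact-point position on the displacement axis (nm).
#' @param max_indent_nm Maximum indentation depth beyond contact (nm).
#' @param n_points Number of samples along the sweep.
#' @param noise_sd_pN Additive force noise sd (pN).
#' @param spring_constant_npm Cantilever spring constant (N/m), metadata.
#' @param seed Integer seed.
#' @return A \code{force_curve}: list with \code{data} (data.frame: z_nm,
#'   force_pN), \code{R_um}, \code{spring_constant_npm} and \code{truth}.
#' @export
gen_force_curve <- function(E_pa, R_um = 0.5, nu = 0.5, contact_nm = 100,
                            max_indent_nm = 300, n_points = 200L,
                            noise_sd_pN = 0, spring_constant_npm = 0.06,
                            seed = 1L) {
  check_scalar(E_pa, "E_pa", lower = 0, closed_lower = FALSE)
  check_scalar(R_um, "R_um", lower = 0, closed_lower = FALSE)
  check_scalar(nu, "nu", lower = 0, upper = 0.5)
  check_scalar(max_indent_nm, "max_indent_nm", lower = 0, closed_lower = FALSE)
  z <- seq(0, contact_nm + max_indent_nm, length.out = n_points)
  delta <- pmax(z - contact_nm, 0)
  f <- hertz_force(delta, E_pa = E_pa, R_um = R_um, nu = nu)
  if (noise_sd_pN > 0)
    f <- f + with_stream(seed, "gen_force_curve",
                         stats::rnorm(n_points, 0, noise_sd_pN))
  structure(list(
    data = data.frame(z_nm = z, force_pN = f),
    R_um = R_um, nu = nu, spring_constant_npm = spring_constant_npm,
    truth = synthetic_truth(list(E_pa = E_pa, contact_nm = contact_nm,
                                 nu = nu, noise_sd_pN = noise_sd_pN), seed)
  ), class = "force_curve")
}

#' Simulate a rheometer strain sweep
#'
#' Storage modulus G' is constant at \code{g0_pa} up to \code{gamma_onset_pct}
#' and decays exponentially beyond it; the strain axis is log-spaced over
#' 0.2-2.0\% oscillation strain (ten points per decade by default), with
#' additive Gaussian noise.
#'
#' @param g0_pa Plateau (linear viscoelastic) storage modulus, Pa.
#' @param gamma_onset_pct Strain at which the plateau ends; a value beyond
#'   2.0 gives a pure plateau sweep.
#' @param decay_rate Exponential decay rate beyond onset (per percent strain).
#' @param n_points Number of strain points over the sweep.
#' @param noise_sd Additive noise sd (Pa).
#' @param strain_range_pct Sweep limits, percent.
#' @param seed Integer seed.
#' @return A \code{strain_sweep}: list with \code{data} (data.frame:
#'   strain_pct, gprime_pa) and \code{truth}.
#' @export
gen_strain_sweep <- function(g0_pa, gamma_onset_pct = 2.5, decay_rate = 1.5,
                             n_points = 11L, noise_sd = 0,
                             strain_range_pct = c(0.2, 2.0), seed = 1L) {
  check_scalar(g0_pa, "g0_pa", lower = 0, closed_lower = FALSE)
  strain <- 10^seq(log10(strain_range_pct[1]), log10(strain_range_pct[2]),
                   length.out = n_points)
  g <- ifelse(strain <= gamma_onset_pct, g0_pa,
              g0_pa * exp(-decay_rate * (strain - gamma_onset_pct)))
  if (noise_sd > 0)
    g <- g + with_stream(seed, "gen_strain_sweep",
                         stats::rnorm(n_points, 0, noise_sd))
  structure(list(
    data = data.frame(strain_pct = strain, gprime_pa = g),
    truth = synthetic_truth(list(g0_pa = g0_pa,
                                 gamma_onset_pct = gamma_onset_pct,
                                 decay_rate = decay_rate,
                                 noise_sd = noise_sd), seed)
  ), class = "strain_sweep")
}
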
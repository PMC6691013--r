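# Collagen-matrix image quantification: GLCM correlation decay versus
# neighbor index, SHG z-profiles, birefringence coverage, gradient-tensor
# streaming anisotropy, and gel contraction area.

glcm_offset <- function(direction, distance) {
  # (row, col) shift for each of the four protocol directions
  switch(as.character(direction),
         "0"   = c(0L, distance),
         "90"  = c(-distance, 0L),
         "180" = c(0L, -distance),
         "270" = c(distance, 0L),
         stop_data("`direction` must be one of 0, 90, 180, 270"))
}

quantize_levels <- function(image, n_levels) {
  rng <- range(image)
  if (rng[1] == rng[2]) {
    q <- matrix(1L, nrow(image), ncol(image))
    attr(q, "degenerate") <- TRUE
    return(q)
  }
  q <- floor((image - rng[1]) / (rng[2] - rng[1]) * n_levels) + 1L
  q[q > n_levels] <- n_levels  # pixels exactly at the max
  storage.mode(q) <- "integer"
  attr(q, "degenerate") <- FALSE
  q
}

#' Gray-level co-occurrence matrix at one offset
#'
#' Joint probability of quantized gray levels at a pixel and at its neighbor
#' \code{distance} pixels away in \code{direction}. Quantization is uniform
#' min-max binning into \code{n_levels}. A constant image yields a single
#' point mass, flagged via the \code{degenerate} attribute.
#'
#' @param image 2D numeric matrix.
#' @param distance Offset in pixels (the "neighbor index").
#' @param direction One of 0, 90, 180, 270 (degrees).
#' @param n_levels Number of gray levels after quantization.
#' @return \code{n_levels x n_levels} matrix of joint probabilities summing
#'   to 1, with attributes \code{degenerate}, \code{distance},
#'   \code{direction}.
#' @export
compute_glcm <- function(image, distance = 1L, direction = 0,
                         n_levels = 64L) {
  if (!is.matrix(image)) stop_data("`image` must be a matrix")
  check_scalar(distance, "distance", lower = 1)
  distance <- as.integer(distance)
  off <- glcm_offset(direction, distance)
  ny <- nrow(image); nx <- ncol(image)
  if (abs(off[1]) >= ny || abs(off[2]) >= nx)
    stop_data("offset distance exceeds the image extent in that direction")
  q <- quantize_levels(image, n_levels)
  rows <- seq_len(ny); cols <- seq_len(nx)
  r1 <- rows[rows + off[1] >= 1 & rows + off[1] <= ny]
  c1 <- cols[cols + off[2] >= 1 & cols + off[2] <= nx]
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  P <- matrix(0, n_levels, n_levels)
  tab <- table(factor(a, levels = seq_len(n_levels)),
               factor(b, levels = seq_len(n_levels)))
  P[] <- as.numeric(tab) / sum(tab)
  attr(P, "degenerate") <- attr(q, "degenerate")
  attr(P, "distance") <- distance
  attr(P, "direction") <- direction
  P
}

#' Haralick correlation of a co-occurrence matrix
#'
#' \eqn{\sum_{ij} p(i,j)(i-\mu_i)(j-\mu_j) / (\sigma_i \sigma_j)} over the
#' level indices; undefined (error) when a marginal standard deviation is
#' zero, e.g. for a constant image.
#'
#' @param glcm Joint probability matrix from [compute_glcm()].
#' @return Correlation in [-1, 1].
#' @export
glcm_correlation <- function(glcm) {
  n <- nrow(glcm)
  i <- seq_len(n)
  pi_ <- rowSums(glcm); pj_ <- colSums(glcm)
  mu_i <- sum(i * pi_); mu_j <- sum(i * pj_)
  var_i <- sum((i - mu_i)^2 * pi_); var_j <- sum((i - mu_j)^2 * pj_)
  if (var_i <= 0 || var_j <= 0)
    stop_data("GLCM correlation undefined: a marginal has zero variance")
  sum(glcm * outer(i - mu_i, i - mu_j)) / sqrt(var_i * var_j)
}

#' GLCM correlation decay versus neighbor index
#'
#' Computes the Haralick correlation for offsets 1..\code{max_distance} in
#' each of the four protocol directions (0, 90, 180, 270 degrees), averages
#' across directions per distance, and optionally normalizes the mean curve
#' by its distance-1 value so curves compare as decay shapes. A slower decay
#' reflects a more organized fiber network; the trapezoidal area under the
#' mean curve is exposed as the \code{auc} summary.
#'
#' @param image 2D numeric matrix.
#' @param max_distance Largest neighbor index (>= 2).
#' @param n_levels Quantization levels.
#' @param normalize Divide the curves by their distance-1 value.
#' @return A \code{glcm_curve}: list with \code{distances},
#'   \code{correlation} (distance x direction matrix),
#'   \code{mean_correlation}, \code{normalized}, \code{auc}.
#' @export
correlation_decay <- function(image, max_distance = 20L, n_levels = 64L,
                              normalize = TRUE) {
  check_scalar(max_distance, "max_distance", lower = 2)
  dirs <- c(0, 90, 180, 270)
  dists <- seq_len(as.integer(max_distance))
  corr <- matrix(NA_real_, length(dists), length(dirs),
                 dimnames = list(NULL, paste0("dir", dirs)))
  for (di in seq_along(dists))
    for (gi in seq_along(dirs))
      corr[di, gi] <- glcm_correlation(
        compute_glcm(image, dists[di], dirs[gi], n_levels))
  mean_corr <- rowMeans(corr)
  if (normalize) {
    corr <- sweep(corr, 2, corr[1, ], "/")
    mean_corr <- mean_corr / mean_corr[1]
  }
  auc <- sum(diff(dists) * (utils::head(mean_corr, -1) +
                            utils::tail(mean_corr, -1)) / 2)
  structure(list(distances = dists, correlation = corr,
                 mean_correlation = mean_corr, normalized = normalize,
                 auc = auc),
            class = "glcm_curve")
}

#' Mean-intensity z-profile of an SHG stack
#'
#' Per-slice mean intensity through an axial stack (e.g. a 60 um z-stack),
#' with the peak value and its slice index.
#'
#' @param stack 3D array (rows x cols x slices).
#' @param z_step_um Axial step between slices, micrometres.
#' @return A \code{z_profile}: list with \code{z_um}, \code{mean_intensity},
#'   \code{peak_value}, \code{peak_index}.
#' @export
shg_zprofile <- function(stack, z_step_um = 1) {
  if (length(dim(stack)) != 3 || dim(stack)[3] < 2)
    stop_data("`stack` must be a 3D array with at least 2 slices")
  prof <- apply(stack, 3, mean)
  structure(list(
    z_um = (seq_along(prof) - 1) * z_step_um,
    mean_intensity = prof,
    peak_value = max(prof),
    peak_index = which.max(prof)
  ), class = "z_profile")
}

#' Gradient-tensor anisotropy of an image region
#'
#' FibrilTool-style orientation statistic: after Gaussian pre-smoothing, the
#' 2x2 nematic tensor of averaged intensity-gradient products is built over
#' the ROI and the anisotropy is the normalized eigenvalue difference
#' \eqn{(\lambda_1-\lambda_2)/(\lambda_1+\lambda_2)}: 0 for isotropic
#' texture, 1 when all gradient energy lies on one axis (perfectly
#' coordinated streaming / parallel fibrils).
#'
#' @param image 2D numeric matrix.
#' @param roi Optional logical matrix; the statistic is averaged over ROI
#'   pixels (at least 100) in the image interior.
#' @param presmooth_sigma Gaussian pre-smoothing sigma in pixels (0 = none).
#' @return Anisotropy in [0, 1].
#' @export
anisotropy <- function(image, roi = NULL, presmooth_sigma = 1) {
  if (!is.matrix(image)) stop_data("`image` must be a matrix")
  img <- gaussian_blur(image, presmooth_sigma)
  ny <- nrow(img); nx <- ncol(img)
  ri <- 2:(ny - 1); ci <- 2:(nx - 1)
  gx <- (img[ri, ci + 1] - img[ri, ci - 1]) / 2
  gy <- (img[ri + 1, ci] - img[ri - 1, ci]) / 2
  if (is.null(roi)) {
    sel <- rep(TRUE, length(gx))
  } else {
    sel <- as.vector(roi[ri, ci])
  }
  if (sum(sel) < 100)
    stop_data("ROI must contain at least 100 interior pixels")
  jxx <- mean(gx[sel]^2); jyy <- mean(gy[sel]^2); jxy <- mean(gx[sel] * gy[sel])
  tr <- jxx + jyy
  # floor relative to the intensity scale: rounding ripple on a flat image
  # must not masquerade as texture
  if (tr <= mean(img^2) * 1e-24)
    stop_data("anisotropy undefined: zero gradient over the ROI")
  d <- sqrt((jxx - jyy)^2 / 4 + jxy^2)
  (2 * d) / tr
}

#' Threshold coverage fraction of an image
#'
#' Percentage of included pixels at or above a threshold — e.g. birefringent
#' fibrillar-collagen coverage of a picrosirius-red section under polarized
#' light. The threshold may be a fixed value or \code{"otsu"}.
#'
#' @param image 2D numeric matrix.
#' @param threshold Numeric threshold or \code{"otsu"}.
#' @param exclusion_mask Optional logical matrix; TRUE pixels are excluded.
#' @return Coverage in percent.
#' @export
coverage_fraction <- function(image, threshold = "otsu",
                              exclusion_mask = NULL) {
  if (!is.matrix(image)) stop_data("`image` must be a matrix")
  inc <- if (is.null(exclusion_mask)) rep(TRUE, length(image))
         else !as.vector(exclusion_mask)
  vals <- as.vector(image)[inc]
  if (!length(vals)) stop_data("all pixels excluded")
  thr <- if (identical(threshold, "otsu")) otsu_threshold(vals) else threshold
  100 * mean(vals >= thr)
}

# Otsu threshold on a numeric vector (256-bin histogram, via EBImage).
otsu_threshold <- function(vals) {
  rng <- range(vals)
  if (rng[1] == rng[2]) return(rng[1])
  u <- (vals - rng[1]) / (rng[2] - rng[1])
  thr01 <- EBImage::otsu(EBImage::Image(matrix(u, nrow = 1)), levels = 256)
  thr01 * (rng[2] - rng[1]) + rng[1]
}

#' Contracted-gel area from a brightfield image
#'
#' Otsu-thresholds the image (gel assumed darker than background unless
#' \code{gel_dark = FALSE}), keeps the largest connected component, and
#' returns its physical area — the readout of a contraction assay.
#'
#' @param brightfield 2D numeric matrix.
#' @param pixel_size_cm Pixel pitch in cm.
#' @param gel_dark Is the gel darker than the background?
#' @return Area in cm^2, with attribute \code{n_pixels}.
#' @export
matrix_area <- function(brightfield, pixel_size_cm, gel_dark = TRUE) {
  if (!is.matrix(brightfield)) stop_data("`brightfield` must be a matrix")
  check_scalar(pixel_size_cm, "pixel_size_cm", lower = 0, closed_lower = FALSE)
  thr <- otsu_threshold(as.vector(brightfield))
  fg <- if (gel_dark) brightfield < thr else brightfield > thr
  if (!any(fg)) stop_data("no foreground component found")
  lab <- EBImage::bwlabel(fg * 1)
  sizes <- tabulate(lab[lab > 0])
  if (!length(sizes)) stop_data("no foreground component found")
  n_px <- max(sizes)
  structure(n_px * pixel_size_cm^2, n_pixels = n_px)
}
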
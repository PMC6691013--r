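# Matrix mechanics: Hertz spherical-indentation fits of AFM force curves and
# linear-viscoelastic storage modulus extraction from rheometer strain sweeps.

#' Hertzian force of a spherical indenter
#'
#' Forward model \eqn{F = \frac{4}{3} \frac{E}{1-\nu^2} \sqrt{R}\,
#' \delta^{3/2}} for a sphere of radius R on an elastic half-space, with
#' consistent unit conversion (E in Pa, R in um, delta in nm, F in pN).
#'
#' @param delta_nm Indentation depth(s), nm (>= 0).
#' @param E_pa Young's modulus, Pa.
#' @param R_um Probe radius, micrometres.
#' @param nu Poisson ratio in [0, 0.5]; 0.5 = incompressible gel.
#' @return Force in pN.
#' @examples
#' hertz_force(100, E_pa = 5000, R_um = 0.5, nu = 0.5)
#' @export
hertz_force <- function(delta_nm, E_pa, R_um = 0.5, nu = 0.5) {
  if (any(delta_nm < 0)) stop_data("indentation depth must be non-negative")
  check_scalar(E_pa, "E_pa", lower = 0, closed_lower = FALSE)
  check_scalar(R_um, "R_um", lower = 0, closed_lower = FALSE)
  check_scalar(nu, "nu", lower = 0, upper = 0.5)
  # SI: F[N] = 4/3 * E/(1-nu^2) * sqrt(R[m]) * delta[m]^1.5 ; report pN
  (4 / 3) * E_pa / (1 - nu^2) * sqrt(R_um * 1e-6) * (delta_nm * 1e-9)^1.5 * 1e12
}

#' Fit the Hertz spherical model to a force curve
#'
#' Nonlinear least squares of the piecewise model: flat baseline before the
#' contact point, Hertzian \eqn{\delta^{3/2}} rise beyond it. By default the
#' contact point is fitted jointly with the modulus and baseline (a
#' mis-specified fixed contact biases the modulus); pass a numeric
#' \code{contact} to fix it.
#'
#' @param curve A \code{force_curve} (see [gen_force_curve()]) or a
#'   data.frame with \code{z_nm} and \code{force_pN}.
#' @param R_um Probe radius, micrometres (taken from the curve if present).
#' @param nu Poisson ratio; the instrument does not measure it, so it is a
#'   declared parameter (default 0.5).
#' @param contact \code{"fit"} or a fixed contact position (nm).
#' @return A \code{hertz_fit}: list with \code{E_pa}, \code{nu},
#'   \code{contact_nm}, \code{baseline_pN}, \code{residual_norm},
#'   \code{converged}.
#' @export
fit_hertz <- function(curve, R_um = NULL, nu = 0.5, contact = "fit") {
  if (inherits(curve, "force_curve")) {
    if (is.null(R_um)) R_um <- curve$R_um
    dat <- curve$data
  } else dat <- curve
  if (is.null(R_um)) stop_data("probe radius `R_um` is required")
  if (!all(c("z_nm", "force_pN") %in% names(dat)))
    stop_data("curve needs columns z_nm and force_pN")
  z <- dat$z_nm; f <- dat$force_pN
  if (length(z) < 10) stop_data("too few points to fit")
  check_scalar(nu, "nu", lower = 0, upper = 0.5)

  pref <- (4 / 3) / (1 - nu^2) * sqrt(R_um * 1e-6) * 1e12 * (1e-9)^1.5
  fixed_contact <- is.numeric(contact)
  if (fixed_contact && max(z) <= contact)
    stop_data("no post-contact data beyond the supplied contact point")

  # starting values: baseline from the leading fifth, contact where the
  # force first clearly exceeds it, modulus from the final point
  n0 <- max(5L, length(z) %/% 5)
  b0 <- stats::median(f[seq_len(n0)])
  spread <- stats::mad(f[seq_len(n0)]) + 1e-6
  above <- which(f > b0 + 3 * spread)
  z0 <- if (fixed_contact) contact
        else if (length(above)) z[above[1]] else z[length(z) %/% 2]
  dmax <- max(z) - z0
  if (dmax <= 0) z0 <- z[length(z) %/% 2]
  e0 <- max((max(f) - b0) / (pref * max(max(z) - z0, 1)^1.5), 1)

  model <- function(E, z0, b) b + pref * E * pmax(z - z0, 0)^1.5
  resid_fn <- if (fixed_contact) {
    function(p) model(exp(p[1]), contact, p[2]) - f
  } else {
    function(p) model(exp(p[1]), p[2], p[3]) - f
  }
  start <- if (fixed_contact) c(log(e0), b0) else c(log(e0), z0, b0)
  fit <- minpack.lm::nls.lm(par = start, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-15, ptol = 1e-15, maxiter = 500))
  p <- fit$par
  E_hat <- exp(p[1])
  c_hat <- if (fixed_contact) contact else p[2]
  b_hat <- if (fixed_contact) p[2] else p[3]
  if (!any(z > c_hat)) stop_data("fit found no post-contact data")
  structure(list(
    E_pa = E_hat, nu = nu, contact_nm = c_hat, baseline_pN = b_hat,
    residual_norm = sqrt(sum(resid_fn(p)^2)),
    converged = fit$info %in% 1:4
  ), class = "hertz_fit")
}

#' Storage modulus over the linear viscoelastic range
#'
#' Finds the maximal leading run of the strain sweep whose G' stays within
#' \code{tol} relative deviation of the median of the first
#' \code{min_points} samples (the low-strain plateau), and returns the mean
#' G' over that run — the linear viscoelastic (LVE) storage modulus.
#'
#' @param sweep A \code{strain_sweep} (see [gen_strain_sweep()]) or a
#'   data.frame with \code{strain_pct} and \code{gprime_pa}.
#' @param tol Relative deviation tolerance defining the plateau.
#' @param min_points Minimum run length (and the reference-median window).
#' @return Mean G' (Pa) over the plateau, with attribute \code{n_points}.
#' @export
lve_storage_modulus <- function(sweep, tol = 0.05, min_points = 3L) {
  dat <- if (inherits(sweep, "strain_sweep")) sweep$data else sweep
  if (!all(c("strain_pct", "gprime_pa") %in% names(dat)))
    stop_data("sweep needs columns strain_pct and gprime_pa")
  g <- dat$gprime_pa[order(dat$strain_pct)]
  n <- length(g)
  if (n < min_points) stop_data("fewer samples than `min_points`")
  ref <- stats::median(g[seq_len(min_points)])
  ok <- abs(g - ref) / ref <= tol
  run <- which(!ok)
  run_len <- if (length(run)) run[1] - 1L else n
  if (run_len < min_points)
    stop_data("no linear viscoelastic plateau of length >= ", min_points)
  structure(mean(g[seq_len(run_len)]), n_points = run_len)
}
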
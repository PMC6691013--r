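# Color-deconvolution optical-density quantification of chromogenic IHC:
# Beer-Lambert unmixing of RGB brightfield images into per-stain optical
# densities, with mean OD per mask and per labeled cell.

#' Standard hematoxylin + DAB stain vectors
#'
#' The published H-DAB unit optical-density directions (the same set the
#' common deconvolution defaults derive from), completed with an orthogonal
#' residual channel; rows are unit-norm.
#'
#' @return 3 x 3 matrix, rows \code{hematoxylin}, \code{dab},
#'   \code{residual}; columns R, G, B.
#' @export
hdab_stain_vectors <- function() {
  h <- c(0.650, 0.704, 0.286)
  d <- c(0.269, 0.568, 0.778)
  r <- c(h[2] * d[3] - h[3] * d[2],
         h[3] * d[1] - h[1] * d[3],
         h[1] * d[2] - h[2] * d[1])
  V <- rbind(hematoxylin = h / sqrt(sum(h^2)),
             dab = d / sqrt(sum(d^2)),
             residual = r / sqrt(sum(r^2)))
  colnames(V) <- c("R", "G", "B")
  V
}

validate_stain_vectors <- function(V) {
  if (!is.matrix(V) || nrow(V) != 3 || ncol(V) != 3)
    stop_data("stain vectors must form a 3 x 3 matrix (stains x channels)")
  norms <- sqrt(rowSums(V^2))
  if (any(abs(norms - 1) > 1e-6))
    stop_data("each stain vector must be unit-norm")
  sv <- svd(V)$d
  if (sv[3] <= 0 || sv[1] / sv[3] >= 1e6)
    stop_data("stain matrix is singular or near-singular")
  V
}

#' Unmix an RGB image into per-stain optical densities
#'
#' Converts each channel to optical density
#' \eqn{OD_c = -\log_{10}(\max(I_c, \epsilon)/i0_c)} and solves the linear
#' Beer-Lambert mixture for per-stain concentrations (in OD units). Negative
#' concentrations are clipped to zero and the clipped-pixel fraction is
#' reported.
#'
#' @param rgb RGB array (rows x cols x 3), intensities in [0, i0].
#' @param vectors Stain matrix (rows = stains, unit OD directions).
#' @param i0 Per-channel incident intensity (> 0).
#' @param eps Intensity floor before the log (default one intensity quantum),
#'   bounding the OD of saturated-black pixels.
#' @return An \code{od_image}: list with \code{stain_od} (rows x cols x
#'   stains), \code{channel_od}, \code{stains}, \code{i0},
#'   \code{clipped_fraction}.
#' @export
unmix <- function(rgb, vectors = hdab_stain_vectors(),
                  i0 = c(255, 255, 255), eps = 1) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop_data("`rgb` must be a rows x cols x 3 array")
  if (any(i0 <= 0)) stop_data("`i0` must be positive per channel")
  V <- validate_stain_vectors(vectors)
  ny <- dim(rgb)[1]; nx <- dim(rgb)[2]
  od <- array(0, dim = dim(rgb))
  for (ch in 1:3)
    od[, , ch] <- -log10(pmax(rgb[, , ch], eps) / i0[ch])
  odm <- matrix(od, ncol = 3)              # pixels x channels
  conc <- odm %*% solve(V)                 # pixels x stains
  clipped <- mean(apply(conc < -1e-9, 1, any))
  conc[conc < 0] <- 0
  stain_od <- array(conc, dim = c(ny, nx, 3),
                    dimnames = list(NULL, NULL, rownames(V)))
  structure(list(stain_od = stain_od, channel_od = od,
                 stains = rownames(V), i0 = i0,
                 clipped_fraction = clipped),
            class = "od_image")
}

#' Mean stain optical density over a mask
#'
#' Average optical density of one stain channel over the masked pixels, e.g.
#' DAB OD over a stromal mask. \code{measure = "raw"} instead averages the
#' reconstructed transmitted intensity \eqn{i0 \cdot 10^{-OD}} of that stain,
#' for pipelines that report raw DAB-channel intensity.
#'
#' @param od An \code{od_image} from [unmix()].
#' @param stain Stain name (e.g. \code{"dab"}).
#' @param mask Logical matrix, TRUE where measured; must be non-empty.
#' @param measure \code{"od"} (default) or \code{"raw"}.
#' @return Mean value over the mask.
#' @export
mean_od <- function(od, stain = "dab", mask, measure = c("od", "raw")) {
  measure <- match.arg(measure)
  if (!stain %in% od$stains) stop_data("unknown stain: ", stain)
  if (missing(mask) || !any(mask)) stop_data("mask is empty")
  vals <- od$stain_od[, , stain][mask]
  if (measure == "raw") vals <- mean(od$i0) * 10^(-vals)
  mean(vals)
}

#' Per-cell mean stain optical density
#'
#' One row per labeled cell: mean OD of the stain over that label's pixels
#' and the label area, reproducing "average DAB intensity per cell" given a
#' labeled cell mask (cell segmentation is an input, not re-implemented).
#'
#' @param od An \code{od_image} from [unmix()].
#' @param stain Stain name.
#' @param labels Integer matrix of cell labels (0 = background).
#' @param measure \code{"od"} or \code{"raw"}, as in [mean_od()].
#' @return data.frame with \code{cell_id}, \code{mean_od}, \code{area_px}.
#' @export
per_cell_od <- function(od, stain = "dab", labels, measure = c("od", "raw")) {
  measure <- match.arg(measure)
  if (!stain %in% od$stains) stop_data("unknown stain: ", stain)
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) stop_data("no labeled cells")
  vals <- od$stain_od[, , stain]
  if (measure == "raw") vals <- mean(od$i0) * 10^(-vals)
  out <- data.frame(
    cell_id = ids,
    mean_od = vapply(ids, function(i) mean(vals[labels == i]), numeric(1)),
    area_px = vapply(ids, function(i) sum(labels == i), numeric(1))
  )
  rownames(out) <- NULL
  out
}
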
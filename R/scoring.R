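# Organotypic invasion scoring: invasive index, proximity clustering with the
# >4-cell rule, mode-of-invasion classification for the fl genotype, plus
# doubling time and aggregation of ordinal local-invasion scores.

check_cell_table <- function(cells) {
  need <- c("x_um", "y_um", "genotype", "invading")
  if (!is.data.frame(cells) || !all(need %in% names(cells)))
    stop_data("cell table needs columns x_um, y_um, genotype, invading")
  if (nrow(cells) == 0) stop_data("empty cell table")
  if (!all(cells$genotype %in% c("fl", "mt")))
    stop_data("genotype must be 'fl' or 'mt'")
  if (any(!is.finite(cells$x_um)) || any(!is.finite(cells$y_um)))
    stop_data("cell coordinates must be finite")
  cells
}

#' Invasive index of a scored cell table
#'
#' Percentage of cells that have invaded into the matrix:
#' \deqn{100 \times n_{invading} / (n_{invading} + n_{non\mbox{-}invading}).}
#'
#' @param cells Cell table (or an \code{invasion_scene}'s \code{cells}) with
#'   a logical \code{invading} column.
#' @return Invasive index in percent.
#' @examples
#' tab <- data.frame(x_um = runif(10), y_um = runif(10),
#'                   genotype = "fl", invading = rep(c(TRUE, FALSE), c(3, 7)))
#' invasive_index(tab)  # 30
#' @export
invasive_index <- function(cells) {
  if (inherits(cells, "invasion_scene")) cells <- cells$cells
  cells <- check_cell_table(cells)
  100 * sum(cells$invading) / nrow(cells)
}

#' Proximity clusters among invading cells
#'
#' Single-linkage connected components of the invading cells under pairwise
#' distance <= \code{radius_um}. Following the ">4 cancer cells in close
#' proximity" definition, a component is a cluster iff it has at least 5
#' members.
#'
#' @param cells Cell table.
#' @param radius_um Proximity radius (micrometres); default 30 (about two
#'   cell diameters) — report alongside results, since the choice is a
#'   scoring convention.
#' @return data.frame over invading cells: \code{cell_id}, \code{component},
#'   \code{size}, \code{is_cluster}.
#' @export
cluster_invading_cells <- function(cells, radius_um = 30) {
  if (inherits(cells, "invasion_scene")) cells <- cells$cells
  cells <- check_cell_table(cells)
  check_scalar(radius_um, "radius_um", lower = 0, closed_lower = FALSE)
  inv <- cells[cells$invading, , drop = FALSE]
  n <- nrow(inv)
  if (n == 0)
    return(data.frame(cell_id = integer(0), component = integer(0),
                      size = integer(0), is_cluster = logical(0)))
  d <- as.matrix(stats::dist(inv[, c("x_um", "y_um")]))
  adj <- d <= radius_um
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize[comp$membership]
  data.frame(cell_id = inv$cell_id, component = comp$membership,
             size = sizes, is_cluster = sizes >= 5)
}

#' Mode-of-invasion counts for invading fl cells
#'
#' Each invading \code{fl} cell is assigned one mode: member of a >4-cell
#' cluster of fl cells only (\code{fl_only_cluster}), member of a >4-cell
#' cluster that also contains mt cells (\code{mosaic_cluster}), or otherwise
#' (\code{single}, including members of 2-4 cell groups, which fall outside
#' the cluster definition).
#'
#' @param cells Cell table.
#' @param radius_um Proximity radius, as in [cluster_invading_cells()].
#' @return Named integer vector with \code{fl_only_cluster},
#'   \code{mosaic_cluster}, \code{single}.
#' @export
classify_invasion_modes <- function(cells, radius_um = 30) {
  if (inherits(cells, "invasion_scene")) cells <- cells$cells
  cells <- check_cell_table(cells)
  comp <- cluster_invading_cells(cells, radius_um)
  inv <- cells[cells$invading, , drop = FALSE]
  counts <- c(fl_only_cluster = 0L, mosaic_cluster = 0L, single = 0L)
  if (!nrow(inv)) return(counts)
  geno <- inv$genotype[match(comp$cell_id, inv$cell_id)]
  for (cid in unique(comp$component)) {
    in_c <- comp$component == cid
    n_fl <- sum(geno[in_c] == "fl")
    if (n_fl == 0) next
    if (comp$size[in_c][1] >= 5) {
      key <- if (any(geno[in_c] == "mt")) "mosaic_cluster" else "fl_only_cluster"
    } else key <- "single"
    counts[key] <- counts[key] + n_fl
  }
  counts
}

#' Population doubling time
#'
#' \deqn{DT = T \ln 2 / \ln(X_e / X_b)} for a co-culture of duration \code{T}
#' hours with \code{xb} cells at start and \code{xe} at endpoint. A declining
#' population returns a negative doubling time flagged with attribute
#' \code{decline}.
#'
#' @param t_hours Culture duration in hours (the assay used 48 h).
#' @param xb,xe Cell counts at start and endpoint (both > 0).
#' @return Doubling time in hours (attribute \code{decline}).
#' @examples
#' doubling_time(48, 1e4, 4e4)  # 24 h
#' @export
doubling_time <- function(t_hours, xb, xe) {
  check_scalar(t_hours, "t_hours", lower = 0, closed_lower = FALSE)
  check_scalar(xb, "xb", lower = 0, closed_lower = FALSE)
  check_scalar(xe, "xe", lower = 0, closed_lower = FALSE)
  if (xe == xb) stop_data("no growth: endpoint equals starting count, ",
                          "doubling time undefined")
  dt <- t_hours * log(2) / log(xe / xb)
  structure(dt, decline = xe < xb)
}

#' Aggregate ordinal local-invasion scores
#'
#' Per-mouse maximum of the ordinal scores, then the group mean of the
#' maxima ("mean maximum score of local invasion").
#'
#' @param scores Named list; one numeric vector of ordinal scores per mouse.
#' @return List with \code{per_mouse_max} (named) and \code{mean_max}.
#' @export
aggregate_local_invasion <- function(scores) {
  if (!is.list(scores) || !length(scores)) stop_data("empty score list")
  if (any(vapply(scores, length, integer(1)) == 0))
    stop_data("every mouse needs at least one score")
  mx <- vapply(scores, max, numeric(1))
  list(per_mouse_max = mx, mean_max = mean(mx))
}
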
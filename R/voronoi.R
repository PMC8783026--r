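#' Field-clipped Voronoi cell areas
#'
#' Computes the Voronoi tessellation of the defect centers and clips every
#' cell to the field rectangle, so cells of edge defects stay finite and the
#' areas sum to the field area.
#'
#' @param set A [defect_set()] with at least 3 distinct defect centers.
#' @return Numeric vector of cell areas in square micrometers, one per
#'   defect, in defect order.
#' @seealso [voronoi_sigma()]
#' @export
voronoi_cell_areas <- function(set) {
  stopifnot(inherits(set, "defect_set"))
  n <- n_defects(set)
  if (n < 3) {
    stop("insufficient points: Voronoi tessellation needs at least 3 defects",
         call. = FALSE)
  }
  xy <- set$defects
  if (anyDuplicated(xy[, c("x", "y")])) {
    stop("degenerate tessellation: duplicate defect coordinates",
         call. = FALSE)
  }
  dd <- deldir::deldir(xy$x, xy$y,
                       rw = c(0, set$field_width, 0, set$field_height),
                       suppressMsge = TRUE)
  tiles <- deldir::tile.list(dd)
  # tile.list order follows input point order (no duplicates present)
  areas_nm2 <- vapply(tiles, function(t) {
    xs <- t$x
    ys <- t$y
    abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  }, numeric(1))
  idx <- vapply(tiles, function(t) t$ptNum, numeric(1))
  unname(areas_nm2[order(idx)]) / 1e6
}

#' Voronoi clustering statistic
#'
#' The clustering statistic sigma is the standard deviation of the
#' normalized Voronoi cell areas: each field-clipped cell area (um^2) is
#' multiplied by the defect density N_def (um^-2), so a perfectly regular
#' pattern has all normalized areas equal to 1 and sigma = 0, while
#' clustered patterns give sigma well above the homogeneous-Poisson level
#' (about 0.53).
#'
#' @param set A [defect_set()] with at least 3 distinct defect centers.
#' @return Non-negative scalar sigma.
#' @examples
#' g <- expand.grid(x = seq(125, 3875, by = 250), y = seq(125, 3875, by = 250))
#' voronoi_sigma(defect_set(g$x, g$y, 4000, 4000))  # regular lattice: 0
#' @export
voronoi_sigma <- function(set) {
  areas <- voronoi_cell_areas(set)
  stats::sd(areas * defect_density(set))
}
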
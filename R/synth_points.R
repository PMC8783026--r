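#' Point-process parameters for synthetic defect patterns
#'
#' Two generators cover the regimes seen on VLY-damaged tBLM surfaces:
#' homogeneous Poisson patterns, and Thomas (Neyman-Scott) cluster
#' processes in which Poisson-distributed parents carry Gaussian-scattered
#' offspring. Clustering strength is controlled by the offspring count per
#' parent and the cluster spread, and is summarized downstream by the
#' Voronoi statistic [voronoi_sigma()].
#'
#' @param kind `"poisson"` or `"thomas"`.
#' @param density Target defect density (um^-2).
#' @param mean_offspring Thomas only: mean offspring per parent cluster.
#' @param spread Thomas only: cluster spread, the standard deviation of
#'   the Gaussian offspring displacement (nm).
#' @param min_sep Optional hard-core separation (nm): points closer than
#'   this to an already accepted point are thinned out (used when the
#'   pattern feeds the EIS solver, whose defect disks must not overlap).
#'   Thinning slightly lowers the realized density.
#' @param seed Optional integer seed.
#' @return An object of class `point_process_params`.
#' @export
point_process_params <- function(kind = c("poisson", "thomas"), density,
                                 mean_offspring = NULL, spread = NULL,
                                 min_sep = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(density) || density <= 0) {
    stop("density must be positive", call. = FALSE)
  }
  if (kind == "thomas") {
    if (is.null(mean_offspring) || is.null(spread) ||
        mean_offspring <= 0 || spread <= 0) {
      stop("thomas process needs positive mean_offspring and spread",
           call. = FALSE)
    }
  }
  structure(list(kind = kind, density = density,
                 mean_offspring = mean_offspring, spread = spread,
                 min_sep = min_sep, seed = seed),
            class = "point_process_params")
}

#' Sample a synthetic defect point pattern
#'
#' Poisson: `N ~ Poisson(density * area)` uniform positions. Thomas:
#' parents are a Poisson process of intensity `density / mean_offspring`
#' sampled on a window padded by `4 * spread` (so edge clusters are not
#' under-represented); each parent carries `Poisson(mean_offspring)`
#' offspring displaced by isotropic Gaussians, and offspring falling
#' outside the field are discarded.
#'
#' @param p A [point_process_params()].
#' @param field_width,field_height Field dimensions (nm), default the
#'   4 um x 4 um test patch.
#' @param label Label for the resulting set.
#' @return A [defect_set()].
#' @export
sample_point_process <- function(p, field_width = 4000, field_height = 4000,
                                 label = p$kind) {
  stopifnot(inherits(p, "point_process_params"))
  area_um2 <- (field_width / 1000) * (field_height / 1000)
  with_seed(p$seed, {
    if (p$kind == "poisson") {
      n <- stats::rpois(1, p$density * area_um2)
      x <- stats::runif(n, 0, field_width)
      y <- stats::runif(n, 0, field_height)
    } else {
      pad <- 4 * p$spread
      wx <- field_width + 2 * pad
      wy <- field_height + 2 * pad
      lam_parent <- p$density / p$mean_offspring      # um^-2
      npar <- stats::rpois(1, lam_parent * (wx / 1000) * (wy / 1000))
      px <- stats::runif(npar, -pad, field_width + pad)
      py <- stats::runif(npar, -pad, field_height + pad)
      noff <- stats::rpois(npar, p$mean_offspring)
      x <- rep(px, noff) + stats::rnorm(sum(noff), 0, p$spread)
      y <- rep(py, noff) + stats::rnorm(sum(noff), 0, p$spread)
      keep <- x >= 0 & x <= field_width & y >= 0 & y <= field_height
      x <- x[keep]
      y <- y[keep]
    }
    if (p$min_sep > 0 && length(x) > 1) {
      keep <- hardcore_thin(x, y, p$min_sep)
      x <- x[keep]
      y <- y[keep]
    }
    if (length(x) < 3) {
      warning("fewer than 3 defects sampled: sigma will be uncomputable",
              call. = FALSE)
    }
    defect_set(x, y, field_width, field_height, label = label)
  })
}

# sequential hard-core thinning: keep a point if no earlier kept point is
# within min_sep
hardcore_thin <- function(x, y, min_sep) {
  n <- length(x)
  keep <- logical(n)
  kx <- numeric(0)
  ky <- numeric(0)
  for (i in seq_len(n)) {
    if (length(kx) == 0 ||
        min((kx - x[i])^2 + (ky - y[i])^2) > min_sep^2) {
      keep[i] <- TRUE
      kx <- c(kx, x[i])
      ky <- c(ky, y[i])
    }
  }
  keep
}

#' Synthetic analogues of the three annotated test surfaces
#'
#' Returns generator parameters whose patterns emulate the density and
#' Voronoi-sigma regime of the three 4 um x 4 um annotated test patches
#' (densities about 10.8, 6.1 and 9.9 um^-2 with sigma about 1.2, 1.0 and
#' 0.9). Cluster parameters were calibrated against the sigma statistic,
#' not against any mechanistic model of toxin insertion.
#'
#' @param surface Integer 1, 2 or 3.
#' @param seed Optional seed stored in the parameters.
#' @return A [point_process_params()].
#' @export
surface_preset <- function(surface, seed = NULL) {
  presets <- list(
    list(density = 10.75, mean_offspring = 5.5, spread = 115),
    list(density = 6.0625, mean_offspring = 3.3, spread = 115),
    list(density = 9.875, mean_offspring = 3.0, spread = 140)
  )
  if (!surface %in% 1:3) stop("surface must be 1, 2 or 3", call. = FALSE)
  p <- presets[[surface]]
  point_process_params("thomas", density = p$density,
                       mean_offspring = p$mean_offspring,
                       spread = p$spread, seed = seed)
}
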
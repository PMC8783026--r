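# run expr with a temporarily seeded RNG, restoring global state afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Gaussian kernel density model of defect positions
#'
#' Places one isotropic Gaussian kernel of common bandwidth on every defect
#' center. The mixture integrates to 1 over the plane; sampling is
#' rejection-restricted to the field rectangle. The model is used to place
#' synthetic defect additions and removals so that the clustering character
#' of the original pattern is preserved.
#'
#' @param set A [defect_set()] with at least one defect.
#' @param bandwidth Kernel standard deviation (nm, default 400).
#' @return An object of class `kde_model`.
#' @export
fit_kde <- function(set, bandwidth = 400) {
  stopifnot(inherits(set, "defect_set"))
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L ||
      !is.finite(bandwidth) || bandwidth <= 0) {
    stop("bandwidth must be a positive scalar", call. = FALSE)
  }
  if (n_defects(set) < 1) stop("KDE needs at least one defect", call. = FALSE)
  structure(
    list(centers = set$defects[, c("x", "y")], bandwidth = bandwidth,
         field_width = set$field_width, field_height = set$field_height),
    class = "kde_model"
  )
}

#' Log density of a KDE model
#'
#' @param model A [fit_kde()] model.
#' @param x,y Coordinates (nm) at which to evaluate; recycled together.
#' @return Log of the mixture probability density (nm^-2).
#' @export
kde_log_density <- function(model, x, y) {
  stopifnot(inherits(model, "kde_model"))
  h2 <- model$bandwidth^2
  n <- nrow(model$centers)
  mapply(function(xi, yi) {
    d2 <- (model$centers$x - xi)^2 + (model$centers$y - yi)^2
    m <- max(-d2 / (2 * h2))
    m + log(sum(exp(-d2 / (2 * h2) - m))) - log(n) - log(2 * pi * h2)
  }, x, y)
}

#' Sample defect positions from a KDE model
#'
#' Mixture sampling: a kernel is chosen uniformly and a Gaussian offset
#' added; draws landing outside the field rectangle are rejected and
#' redrawn.
#'
#' @param model A [fit_kde()] model.
#' @param n Number of points.
#' @param max_tries Rejection budget per point.
#' @return A data.frame with columns `x`, `y` (nm), all inside the field.
#' @export
kde_sample <- function(model, n, max_tries = 1000) {
  stopifnot(inherits(model, "kde_model"))
  if (n == 0) return(data.frame(x = numeric(), y = numeric()))
  out <- matrix(NA_real_, n, 2)
  filled <- 0L
  for (tries in seq_len(max_tries)) {
    m <- n - filled
    k <- sample.int(nrow(model$centers), m, replace = TRUE)
    px <- model$centers$x[k] + stats::rnorm(m, 0, model$bandwidth)
    py <- model$centers$y[k] + stats::rnorm(m, 0, model$bandwidth)
    ok <- px >= 0 & px <= model$field_width & py >= 0 & py <= model$field_height
    nok <- sum(ok)
    if (nok > 0) {
      out[filled + seq_len(nok), ] <- cbind(px[ok], py[ok])
      filled <- filled + nok
    }
    if (filled == n) break
  }
  if (filled < n) stop("KDE rejection sampling exhausted max_tries", call. = FALSE)
  data.frame(x = out[, 1], y = out[, 2])
}
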
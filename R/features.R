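#' Bode phase-minimum features of an EIS spectrum
#'
#' Locates the interior minimum of the admittance phase on the
#' (log10 f, phase) plane. The discrete argmin is refined by a three-point
#' parabola through the neighbouring grid points, giving sub-grid estimates
#' of both the minimum frequency and the phase value there.
#'
#' @param sp An [eis_spectrum()] whose phase attains its minimum strictly
#'   inside the frequency range.
#' @return An object of class `spectral_features`: list with `f_min` (Hz)
#'   and `argy_min` (degrees).
#' @export
spectral_features <- function(sp) {
  stopifnot(inherits(sp, "eis_spectrum"))
  ph <- sp$phase_deg
  i <- which.min(ph)
  n <- length(ph)
  if (i == 1L || i == n) {
    stop("no interior phase minimum: argmin sits at a grid endpoint",
         call. = FALSE)
  }
  lf <- log10(sp$frequency[(i - 1):(i + 1)])
  y <- ph[(i - 1):(i + 1)]
  # parabola through three points; denominators safe on a log-spaced grid
  d21 <- lf[2] - lf[1]
  d32 <- lf[3] - lf[2]
  d31 <- lf[3] - lf[1]
  a <- (y[1] / (d21 * d31)) - (y[2] / (d21 * d32)) + (y[3] / (d32 * d31))
  b <- (y[3] - y[1]) / d31 - a * (lf[1] + lf[3])
  if (a <= 0) {  # flat or concave triple: fall back to the grid point
    lmin <- lf[2]
    ymin <- y[2]
  } else {
    lmin <- -b / (2 * a)
    c0 <- y[2] - a * lf[2]^2 - b * lf[2]
    ymin <- a * lmin^2 + b * lmin + c0
  }
  structure(list(f_min = 10^lmin, argy_min = ymin),
            class = "spectral_features")
}

#' @export
print.spectral_features <- function(x, ...) {
  cat(sprintf("<spectral_features: f_min %.4g Hz, arg Y_min %.3f deg>\n",
              x$f_min, x$argy_min))
  invisible(x)
}

#' Phase-minimum discrepancy between two spectra
#'
#' `delta_f_log = log10 f_min(true) - log10 f_min(pred)` (decades) and
#' `delta_argy = arg Y_min(true) - arg Y_min(pred)` (degrees). Both
#' components negate when the arguments are swapped.
#'
#' @param true_sp,pred_sp [eis_spectrum()]s with interior phase minima.
#' @return An object of class `spectrum_delta`: list with `delta_f_log`
#'   and `delta_argy`.
#' @export
compare_spectra <- function(true_sp, pred_sp) {
  ft <- spectral_features(true_sp)
  fp <- spectral_features(pred_sp)
  structure(
    list(delta_f_log = log10(ft$f_min) - log10(fp$f_min),
         delta_argy = ft$argy_min - fp$argy_min),
    class = "spectrum_delta"
  )
}

#' @export
print.spectrum_delta <- function(x, ...) {
  cat(sprintf("<spectrum_delta: delta f_log %+.4f dec, delta argY %+.3f deg>\n",
              x$delta_f_log, x$delta_argy))
  invisible(x)
}
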
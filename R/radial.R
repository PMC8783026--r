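#' Semi-analytic admittance spectrum of a single centered defect
#'
#' Closed-form solution of the radially symmetric submembrane thin-film
#' problem on a disk: one ideal defect of radius `r_def` at the origin of a
#' circular membrane patch of radius `domain_radius`, with the reservoir
#' potential clamped to the drive at the defect rim and zero flux at the
#' outer edge. The reservoir potential obeys
#' `g_s (u'' + u'/r) = i w (C_H + C_m) u - i w C_m U0`
#' and is expressed through modified Bessel functions `I0`, `K0` of complex
#' argument `k r` with `k^2 = i w (C_H + C_m) / g_s`; the area-normalized
#' admittance `Y = i w C_H <u> / U0` is integrated analytically.
#'
#' This solution serves as the independent verification oracle for the 2D
#' finite-element solver ([model_spectrum()]).
#'
#' @param mp A [membrane_params()] (its `r_def` is the defect radius).
#' @param domain_radius Outer patch radius (nm), `>> r_def`.
#' @param fg Frequency vector (Hz), e.g. [frequency_grid()].
#' @return An [eis_spectrum()].
#' @examples
#' sp <- radial_spectrum(membrane_params(r_def = 5), domain_radius = 172,
#'                       fg = frequency_grid(1, 1e4, 5))
#' spectral_features(sp)
#' @export
radial_spectrum <- function(mp, domain_radius, fg = frequency_grid()) {
  stopifnot(inherits(mp, "membrane_params"))
  r0 <- mp$r_def * 1e-7          # cm
  R <- domain_radius * 1e-7      # cm
  if (R <= r0) stop("domain_radius must exceed r_def", call. = FALSE)
  gs <- sheet_conductance(mp)
  cm <- cm_f(mp)
  ch <- ch_f(mp)
  ct <- cm + ch
  up <- cm / ct                  # particular solution, units of U0
  Fc <- ch / ct                  # rim excess (U0 - up)/U0
  Y <- vapply(fg, function(f) {
    w <- 2 * pi * f
    k <- sqrt(1i * w * ct / gs)  # principal branch: arg(k) = pi/4
    z0 <- k * r0
    zR <- k * R
    b0 <- bessel_ik_scaled(z0)
    bR <- bessel_ik_scaled(zR)
    E <- exp(-2 * (Re(zR) - Re(z0)))  # in (0, 1]
    num <- bR$I1e * b0$K1e - E * bR$K1e * b0$I1e
    den <- E * b0$I0e * bR$K1e + b0$K0e * bR$I1e
    Tt <- Fc * r0 * num / den
    1i * w * ch *
      (up * pi * (R^2 - r0^2) + pi * r0^2 + 2 * pi * Tt / k) / (pi * R^2)
  }, complex(1))
  eis_spectrum(fg, Y)
}
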
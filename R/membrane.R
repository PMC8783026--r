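#' Electrochemical membrane parameters
#'
#' Physical constants of the tBLM model. The submembrane reservoir of
#' thickness `d_sub` and specific resistance `rho_sub` forms a conducting
#' sheet of conductance `g_s = d_sub / rho_sub` (Siemens per square)
#' between the membrane capacitance `c_m` above and the Helmholtz-layer
#' capacitance `c_h` below. Defects are ideal pores of electrochemical
#' radius `r_def` that clamp the reservoir potential to the drive
#' amplitude at their rim.
#'
#' @param r_def Electrochemical defect radius (nm).
#' @param rho_sub Submembrane specific resistance (Ohm cm); default
#'   10^4.5, the customary literature value.
#' @param c_m Membrane capacitance per area (uF/cm^2, default 0.8).
#' @param c_h Helmholtz capacitance per area (uF/cm^2, default 9.0).
#' @param d_sub Submembrane layer thickness (nm, default 1.5).
#' @param u0 Drive amplitude (V). The system is linear, so admittance does
#'   not depend on it; kept explicit for clarity.
#' @return An object of class `membrane_params`.
#' @examples
#' membrane_params(r_def = 5)
#' @export
membrane_params <- function(r_def, rho_sub = 10^4.5, c_m = 0.8, c_h = 9.0,
                            d_sub = 1.5, u0 = 1) {
  vals <- c(r_def = r_def, rho_sub = rho_sub, c_m = c_m, c_h = c_h,
            d_sub = d_sub, u0 = u0)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all membrane parameters must be positive and finite", call. = FALSE)
  }
  structure(list(r_def = r_def, rho_sub = rho_sub, c_m = c_m, c_h = c_h,
                 d_sub = d_sub, u0 = u0),
            class = "membrane_params")
}

#' @export
print.membrane_params <- function(x, ...) {
  cat(sprintf(paste0(
    "<membrane_params: r_def %g nm, rho_sub 10^%.2f Ohm cm, ",
    "C_m %g uF/cm^2, C_H %g uF/cm^2, d_sub %g nm>\n"),
    x$r_def, log10(x$rho_sub), x$c_m, x$c_h, x$d_sub))
  invisible(x)
}

# sheet conductance of the submembrane reservoir, in S (per square)
sheet_conductance <- function(mp) (mp$d_sub * 1e-7) / mp$rho_sub

# capacitances in F/cm^2
cm_f <- function(mp) mp$c_m * 1e-6
ch_f <- function(mp) mp$c_h * 1e-6

#' Logarithmic frequency grid
#'
#' @param f_min,f_max Frequency range (Hz), default 0.1 to 1e5.
#' @param points_per_decade Grid density (default 10).
#' @return Ascending numeric vector of frequencies (Hz).
#' @export
frequency_grid <- function(f_min = 0.1, f_max = 1e5,
                           points_per_decade = 10) {
  if (f_min <= 0 || f_max <= f_min) {
    stop("need 0 < f_min < f_max", call. = FALSE)
  }
  10^seq(log10(f_min), log10(f_max), by = 1 / points_per_decade)
}

#' EIS spectrum container
#'
#' @param frequency Ascending positive frequencies (Hz).
#' @param admittance Complex admittance per area (S/cm^2), same length.
#' @return An object of class `eis_spectrum` with elements `frequency`,
#'   `admittance` and derived `phase_deg` (= atan2(Im Y, Re Y) in degrees).
#' @export
eis_spectrum <- function(frequency, admittance) {
  frequency <- as.numeric(frequency)
  if (length(frequency) != length(admittance)) {
    stop("frequency and admittance lengths differ", call. = FALSE)
  }
  if (any(frequency <= 0) || is.unsorted(frequency, strictly = TRUE)) {
    stop("frequencies must be positive and strictly increasing", call. = FALSE)
  }
  admittance <- as.complex(admittance)
  structure(
    list(frequency = frequency, admittance = admittance,
         phase_deg = atan2(Im(admittance), Re(admittance)) * 180 / pi),
    class = "eis_spectrum"
  )
}

#' @export
print.eis_spectrum <- function(x, ...) {
  cat(sprintf("<eis_spectrum: %d frequencies, %.3g - %.3g Hz>\n",
              length(x$frequency), min(x$frequency), max(x$frequency)))
  invisible(x)
}

#' @export
as.data.frame.eis_spectrum <- function(x, ...) {
  data.frame(frequency_hz = x$frequency,
             y_real_s_cm2 = Re(x$admittance),
             y_imag_s_cm2 = Im(x$admittance),
             phase_deg = x$phase_deg)
}
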
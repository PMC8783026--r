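#' Parameter grid for the (r_def, rho_sub) search
#'
#' @param r_values Defect radii (nm); default 1, 3, ..., 13.
#' @param rho_exponents Base-10 exponents of the submembrane specific
#'   resistance (Ohm cm); default 4.0, 4.1, ..., 5.0. The defaults span
#'   7 x 11 = 77 combinations.
#' @return An object of class `fit_grid`.
#' @export
fit_grid <- function(r_values = seq(1, 13, by = 2),
                     rho_exponents = seq(4, 5, by = 0.1)) {
  if (length(r_values) == 0 || length(rho_exponents) == 0) {
    stop("parameter error: empty grid axis", call. = FALSE)
  }
  if (is.unsorted(r_values, strictly = TRUE) ||
      is.unsorted(rho_exponents, strictly = TRUE)) {
    stop("grid axes must be strictly ascending", call. = FALSE)
  }
  if (any(r_values <= 0)) stop("radii must be positive", call. = FALSE)
  structure(list(r_values = r_values, rho_exponents = rho_exponents),
            class = "fit_grid")
}

#' Enumerate the parameter grid
#'
#' @param g A [fit_grid()].
#' @return Data.frame with columns `r_def` (nm) and `rho_sub` (Ohm cm),
#'   radius varying slowest.
#' @examples
#' nrow(parameter_grid(fit_grid()))  # 77
#' @export
parameter_grid <- function(g = fit_grid()) {
  stopifnot(inherits(g, "fit_grid"))
  data.frame(
    r_def = rep(g$r_values, each = length(g$rho_exponents)),
    rho_sub = rep(10^g$rho_exponents, times = length(g$r_values))
  )
}

#' Grid-search fit of membrane parameters to a reference spectrum
#'
#' For every (r_def, rho_sub) combination the defect-set spectrum is
#' modeled with [model_spectrum()], its phase-minimum features extracted,
#' and the discrepancy to the reference minimum scored as
#' `l1 = |delta log10 f_min| + phase_weight * |delta arg Y_min|`.
#' The phase term is divided by 90 degrees by default so both terms are
#' O(1); the weight is exposed because the mixed decade/degree norm has no
#' canonical scale. Grid points whose spectrum has no interior minimum (or
#' whose geometry is infeasible, e.g. overlapping disks at large radii)
#' score `Inf` and are flagged.
#'
#' @param set The [defect_set()] whose spectrum is matched.
#' @param reference An [eis_spectrum()] with an interior phase minimum.
#' @param g A [fit_grid()].
#' @param mp_base A [membrane_params()] supplying capacitances and
#'   submembrane thickness (its `r_def`/`rho_sub` are overridden).
#' @param fg Frequency vector (Hz).
#' @param ctrl A [mesh_control()].
#' @param phase_weight Weight of the phase term (1/degrees), default 1/90.
#' @return An object of class `fit_result`: `best_r_def`, `best_rho_sub`,
#'   `l1`, and the per-combination `table` (columns `r_def`, `rho_sub`,
#'   `f_min`, `argy_min`, `l1`, `flagged`). Ties in l1 are broken toward
#'   the smaller rho exponent, then the smaller radius.
#' @export
fit_membrane_params <- function(set, reference, g = fit_grid(),
                                mp_base = membrane_params(r_def = 1),
                                fg = frequency_grid(),
                                ctrl = mesh_control(),
                                phase_weight = 1 / 90) {
  stopifnot(inherits(set, "defect_set"), inherits(g, "fit_grid"))
  ref <- spectral_features(reference)
  rows <- vector("list", length(g$r_values) * length(g$rho_exponents))
  k <- 0L
  for (r in g$r_values) {
    # the mesh depends on r_def only: build once per radius
    asm <- tryCatch({
      if (n_defects(set) > 0) fem_assemble(mesh_membrane(set, r, ctrl))
      else NULL
    }, error = function(e) e)
    for (ex in g$rho_exponents) {
      k <- k + 1L
      mp <- membrane_params(r_def = r, rho_sub = 10^ex, c_m = mp_base$c_m,
                            c_h = mp_base$c_h, d_sub = mp_base$d_sub,
                            u0 = mp_base$u0)
      res <- tryCatch({
        Y <- if (is.null(asm)) {
          stop("zero-defect spectrum has no interior minimum", call. = FALSE)
        } else if (inherits(asm, "error")) {
          stop(conditionMessage(asm), call. = FALSE)
        } else {
          fem_spectrum(asm, mp, fg)
        }
        feat <- spectral_features(eis_spectrum(fg, Y))
        data.frame(
          r_def = r, rho_sub = 10^ex, f_min = feat$f_min,
          argy_min = feat$argy_min,
          l1 = abs(log10(ref$f_min) - log10(feat$f_min)) +
            phase_weight * abs(ref$argy_min - feat$argy_min),
          flagged = FALSE)
      }, error = function(e) {
        data.frame(r_def = r, rho_sub = 10^ex, f_min = NA_real_,
                   argy_min = NA_real_, l1 = Inf, flagged = TRUE)
      })
      rows[[k]] <- res
    }
  }
  table <- do.call(rbind, rows)
  if (all(is.infinite(table$l1))) {
    stop("no feasible grid point produced an interior phase minimum",
         call. = FALSE)
  }
  # argmin with ties toward smaller rho exponent, then smaller r
  ord <- order(table$l1, table$rho_sub, table$r_def)
  best <- table[ord[1L], ]
  structure(
    list(best_r_def = best$r_def, best_rho_sub = best$rho_sub,
         l1 = best$l1, table = table, phase_weight = phase_weight),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result: r_def %g nm, rho_sub 10^%.2f Ohm cm, l1 %.4g (%d grid points, %d flagged)>\n",
    x$best_r_def, log10(x$best_rho_sub), x$l1, nrow(x$table),
    sum(x$table$flagged)))
  invisible(x)
}
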
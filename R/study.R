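#' Noisy synthetic reference spectrum
#'
#' Runs [model_spectrum()] and perturbs the admittance phase at every
#' frequency by independent Gaussian noise (degrees), keeping the modulus,
#' to stand in for a measured reference spectrum.
#'
#' @param set A [defect_set()].
#' @param mp A [membrane_params()].
#' @param fg Frequency vector (Hz).
#' @param noise_sd_phase_deg Phase noise standard deviation (degrees).
#' @param seed Optional integer seed.
#' @param ctrl A [mesh_control()].
#' @return An [eis_spectrum()].
#' @export
synth_reference_spectrum <- function(set, mp, fg = frequency_grid(),
                                     noise_sd_phase_deg = 0.5, seed = NULL,
                                     ctrl = mesh_control()) {
  sp <- model_spectrum(set, mp, fg, ctrl)
  if (noise_sd_phase_deg <= 0) return(sp)
  eps <- with_seed(seed,
                   stats::rnorm(length(fg), 0, noise_sd_phase_deg))
  eis_spectrum(fg, sp$admittance * exp(1i * eps * pi / 180))
}

#' Detection-accuracy versus spectral-deviation study
#'
#' Generates degraded detector-output cases from a true defect set, scores
#' each one (precision, recall, F1, Q_N, Voronoi sigma), models the EIS
#' spectrum of the true set and of every case, and records the
#' phase-minimum discrepancies (delta f_log, delta arg Y). Any stage
#' failure aborts with the offending case id in the error message.
#'
#' @param true_set The ground-truth [defect_set()].
#' @param seed Integer seed driving the degradations.
#' @param cases Data.frame with columns `n_remove`, `n_add`; defaults to
#'   the full [case_grid()].
#' @param s,bandwidth Degradation parameters (nm).
#' @param mp A [membrane_params()].
#' @param fg Frequency vector (Hz).
#' @param ctrl A [mesh_control()].
#' @return Data.frame with one row per case: degradation levels, accuracy
#'   metrics, sigma, `delta_f_log`, `delta_argy`.
#' @export
run_accuracy_study <- function(true_set, seed, cases = NULL, s = 4,
                               bandwidth = 400,
                               mp = membrane_params(r_def = 5),
                               fg = frequency_grid(),
                               ctrl = mesh_control()) {
  batch <- generate_batch(true_set, seed = seed, cases = cases, s = s,
                          bandwidth = bandwidth, keep_sets = TRUE)
  sets <- attr(batch, "sets")
  true_sp <- model_spectrum(true_set, mp, fg, ctrl)
  deltas <- lapply(seq_len(nrow(batch)), function(i) {
    tryCatch({
      d <- compare_spectra(true_sp,
                           model_spectrum(sets[[i]], mp, fg, ctrl))
      data.frame(delta_f_log = d$delta_f_log, delta_argy = d$delta_argy)
    }, error = function(e) {
      stop(sprintf("case %d (n_remove %d, n_add %d) failed: %s",
                   batch$case[i], batch$n_remove[i], batch$n_add[i],
                   conditionMessage(e)), call. = FALSE)
    })
  })
  out <- cbind(batch, do.call(rbind, deltas))
  attr(out, "sets") <- NULL
  out
}

#' Summarize spectral deviations per F1 band
#'
#' @param study Output of [run_accuracy_study()].
#' @param breaks F1 band boundaries (default 0.5, 0.6, ..., 1.0); each band
#'   is closed, `[lo, hi]`, so the top band is F1 in `[0.95, 1]` when
#'   `breaks` ends `..., 0.95, 1`.
#' @return Data.frame with per-band counts and mean/sd of `delta_f_log`
#'   and `delta_argy`.
#' @export
summarize_delta_bands <- function(study,
                                  breaks = c(0.5, 0.6, 0.7, 0.8, 0.9,
                                             0.95, 1)) {
  lo <- utils::head(breaks, -1)
  hi <- utils::tail(breaks, -1)
  rows <- lapply(seq_along(lo), function(b) {
    inb <- study$f1 >= lo[b] & study$f1 <= hi[b]
    data.frame(
      f1_lo = lo[b], f1_hi = hi[b], n = sum(inb),
      mean_delta_f_log = mean(study$delta_f_log[inb]),
      sd_delta_f_log = stats::sd(study$delta_f_log[inb]),
      mean_delta_argy = mean(study$delta_argy[inb]),
      sd_delta_argy = stats::sd(study$delta_argy[inb]))
  })
  do.call(rbind, rows)
}

#' Fit study: true versus predicted defect sets against one reference
#'
#' Runs the (r_def, rho_sub) grid fit for the annotated (true) set and a
#' detector-output (predicted) set against the same reference spectrum,
#' side by side.
#'
#' @param true_set,pred_set [defect_set()]s on the same field.
#' @param reference An [eis_spectrum()] with an interior phase minimum.
#' @param g A [fit_grid()].
#' @param mp_base,fg,ctrl Passed to [fit_membrane_params()].
#' @return List with `true_fit`, `pred_fit` (both [fit_membrane_params()]
#'   results) and `reference_features`.
#' @export
run_fit_study <- function(true_set, pred_set, reference, g = fit_grid(),
                          mp_base = membrane_params(r_def = 1),
                          fg = frequency_grid(), ctrl = mesh_control()) {
  list(
    true_fit = fit_membrane_params(true_set, reference, g, mp_base, fg, ctrl),
    pred_fit = fit_membrane_params(pred_set, reference, g, mp_base, fg, ctrl),
    reference_features = spectral_features(reference)
  )
}

#' Write a reproducibility manifest
#'
#' Records the configuration (hashed and verbatim), seeds and package
#' version of a pipeline run as JSON next to its outputs.
#'
#' @param path Output JSON path.
#' @param config Named list of run configuration (must include any seeds).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config) {
  payload <- list(
    package = "tbleis",
    version = as.character(utils::packageVersion("tbleis")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    config_hash = sum(utf8ToInt(paste(deparse(config), collapse = ""))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
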
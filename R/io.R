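#' Read a defect set from CSV (+ YAML sidecar)
#'
#' The CSV carries one defect per row with header `x_nm,y_nm,r_nm` (the
#' `r_nm` column is optional and defaults to 25 nm). Field geometry and the
#' label live in a YAML sidecar `<path>.yaml` with keys `field_width_nm`,
#' `field_height_nm` and `label`, unless passed explicitly.
#'
#' @param path Path to the defect CSV.
#' @param field_width,field_height Field dimensions (nm); if `NULL`, read
#'   from the sidecar.
#' @param label Optional label override.
#' @return A [defect_set()].
#' @export
read_defects <- function(path, field_width = NULL, field_height = NULL,
                         label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(field_width) || is.null(field_height)) {
    sidecar <- paste0(path, ".yaml")
    if (!file.exists(sidecar)) {
      stop("field dimensions not given and sidecar missing: ", sidecar,
           call. = FALSE)
    }
    meta <- yaml::read_yaml(sidecar)
    if (is.null(meta$field_width_nm) || is.null(meta$field_height_nm)) {
      stop("sidecar must contain field_width_nm and field_height_nm",
           call. = FALSE)
    }
    field_width <- meta$field_width_nm
    field_height <- meta$field_height_nm
    if (is.null(label)) label <- meta$label
  }
  if (is.null(label)) label <- ""
  df <- utils::read.csv(path, colClasses = "character",
                        strip.white = TRUE, check.names = FALSE)
  need <- c("x_nm", "y_nm")
  if (!all(need %in% names(df))) {
    stop("defect CSV must have columns x_nm and y_nm; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  parse_col <- function(col, name) {
    v <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(v) & nzchar(col))
    if (length(bad) > 0 || anyNA(v)) {
      row <- if (length(bad) > 0) bad[1L] else which(is.na(v))[1L]
      stop(sprintf("non-numeric value in column %s, row %d", name, row),
           call. = FALSE)
    }
    v
  }
  x <- parse_col(df$x_nm, "x_nm")
  y <- parse_col(df$y_nm, "y_nm")
  r <- if ("r_nm" %in% names(df)) parse_col(df$r_nm, "r_nm") else 25
  defect_set(x, y, field_width, field_height, r_box = r, label = label)
}

#' Write a defect set to CSV (+ YAML sidecar)
#'
#' Coordinates are written as full-precision decimal text
#' (`format(..., digits = 17)`), so write-then-read round-trips the values
#' exactly. The field geometry goes to `<path>.yaml`.
#'
#' @param set A [defect_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_defects <- function(set, path) {
  stopifnot(inherits(set, "defect_set"))
  fmt <- function(v) vapply(v, format, character(1), digits = 17)
  df <- data.frame(x_nm = fmt(set$defects$x),
                   y_nm = fmt(set$defects$y),
                   r_nm = fmt(set$defects$r_box))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(
    list(field_width_nm = set$field_width,
         field_height_nm = set$field_height,
         label = set$label),
    paste0(path, ".yaml"))
  invisible(path)
}

#' Read / write an EIS spectrum CSV
#'
#' Spectrum files carry the header
#' `frequency_hz,y_real_s_cm2,y_imag_s_cm2,phase_deg`.
#'
#' @param path CSV path.
#' @return For `read_spectrum`, an [eis_spectrum()].
#' @export
read_spectrum <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frequency_hz", "y_real_s_cm2", "y_imag_s_cm2")
  if (!all(need %in% names(df))) {
    stop("spectrum CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  eis_spectrum(df$frequency_hz,
               complex(real = df$y_real_s_cm2, imaginary = df$y_imag_s_cm2))
}

#' @rdname read_spectrum
#' @param sp An [eis_spectrum()].
#' @export
write_spectrum <- function(sp, path) {
  stopifnot(inherits(sp, "eis_spectrum"))
  df <- data.frame(frequency_hz = sp$frequency,
                   y_real_s_cm2 = Re(sp$admittance),
                   y_imag_s_cm2 = Im(sp$admittance),
                   phase_deg = sp$phase_deg)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
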
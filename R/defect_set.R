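#' Construct a defect coordinate set
#'
#' A defect set holds the center coordinates (and detection-box half-widths)
#' of membrane defects observed on a rectangular AFM field. Coordinates are
#' continuous nanometers with the origin at the field's top-left corner and
#' y increasing downward (image convention).
#'
#' @param x,y Numeric vectors of defect center coordinates (nm).
#' @param field_width,field_height Field dimensions (nm); must be positive.
#' @param r_box Detection bounding-box half-width (nm). Defaults to 25 nm,
#'   i.e. the 50 nm x 50 nm equalized boxes used throughout detection
#'   scoring. Recycled to the number of defects.
#' @param label Free-text label carried through summaries and file output.
#'
#' @return An object of class `defect_set`: a list with elements
#'   `defects` (data.frame with columns `x`, `y`, `r_box`), `field_width`,
#'   `field_height` and `label`.
#' @examples
#' s <- defect_set(c(100, 300), c(200, 400), 4000, 4000)
#' n_defects(s)
#' defect_density(s)
#' @export
defect_set <- function(x, y, field_width, field_height, r_box = 25,
                       label = "") {
  if (!is.numeric(field_width) || !is.numeric(field_height) ||
      length(field_width) != 1L || length(field_height) != 1L ||
      !is.finite(field_width) || !is.finite(field_height) ||
      field_width <= 0 || field_height <= 0) {
    stop("invalid geometry: field dimensions must be positive finite scalars",
         call. = FALSE)
  }
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    bad <- which(!is.finite(x) | !is.finite(y))[1L]
    stop("non-finite coordinate in row ", bad, call. = FALSE)
  }
  out_of_field <- x < 0 | x > field_width | y < 0 | y > field_height
  if (any(out_of_field)) {
    bad <- which(out_of_field)[1L]
    stop(sprintf(
      "defect in row %d at (%.6g, %.6g) lies outside the %g x %g nm field",
      bad, x[bad], y[bad], field_width, field_height), call. = FALSE)
  }
  r_box <- as.numeric(rep_len(r_box, length(x)))
  if (length(x) > 0 && any(!is.finite(r_box) | r_box <= 0)) {
    stop("r_box must be positive", call. = FALSE)
  }
  structure(
    list(
      defects = data.frame(x = x, y = y, r_box = r_box),
      field_width = as.numeric(field_width),
      field_height = as.numeric(field_height),
      label = as.character(label)[1L]
    ),
    class = "defect_set"
  )
}

#' @export
print.defect_set <- function(x, ...) {
  cat(sprintf("<defect_set%s: %d defects on %g x %g nm field",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              n_defects(x), x$field_width, x$field_height))
  if (n_defects(x) > 0) {
    cat(sprintf(", %.3g um^-2", defect_density(x)))
  }
  cat(">\n")
  invisible(x)
}

#' Number of defects in a set
#' @param set A [defect_set()].
#' @return Integer count N.
#' @export
n_defects <- function(set) {
  stopifnot(inherits(set, "defect_set"))
  nrow(set$defects)
}

#' Defect density per square micrometer
#'
#' @param set A [defect_set()].
#' @return Defects per square micrometer (N / field area).
#' @examples
#' defect_density(defect_set(runif(172, 0, 4000), runif(172, 0, 4000),
#'                           4000, 4000))  # 10.75
#' @export
defect_density <- function(set) {
  stopifnot(inherits(set, "defect_set"))
  area_um2 <- (set$field_width / 1000) * (set$field_height / 1000)
  if (!is.finite(area_um2) || area_um2 <= 0) {
    stop("invalid geometry: field area must be positive", call. = FALSE)
  }
  n_defects(set) / area_um2
}

field_matches <- function(a, b, tol = 1e-9) {
  abs(a$field_width - b$field_width) <= tol * max(1, a$field_width) &&
    abs(a$field_height - b$field_height) <= tol * max(1, a$field_height)
}
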
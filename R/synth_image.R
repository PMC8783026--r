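#' Rendering parameters for AFM-like topography images
#'
#' @param pixel_size Lateral calibration (nm/px); the default 3.90625
#'   corresponds to a 2 um scan at 512 x 512 pixels.
#' @param depth Defect pit depth (nm).
#' @param apparent_radius Gaussian radius of the rendered pit (nm).
#' @param roughness_amp Standard deviation of the correlated background
#'   roughness (nm).
#' @param roughness_scale Correlation length of the roughness (nm).
#' @param scanline_amp Standard deviation of per-line height offsets (nm),
#'   mimicking scan-line noise.
#' @param seed Optional integer seed.
#' @return An object of class `image_render_params`.
#' @export
image_render_params <- function(pixel_size = 3.90625, depth = 2,
                                apparent_radius = 10, roughness_amp = 0.1,
                                roughness_scale = 10, scanline_amp = 0.05,
                                seed = NULL) {
  stopifnot(pixel_size > 0, depth >= 0, apparent_radius > 0,
            roughness_amp >= 0, roughness_scale > 0, scanline_amp >= 0)
  structure(list(pixel_size = pixel_size, depth = depth,
                 apparent_radius = apparent_radius,
                 roughness_amp = roughness_amp,
                 roughness_scale = roughness_scale,
                 scanline_amp = scanline_amp, seed = seed),
            class = "image_render_params")
}

# 1-D Gaussian smoothing with replicated edges, applied to rows or cols
blur_matrix <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  hw <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-hw, hw), sd = sigma_px)
  k <- k / sum(k)
  smooth_vec <- function(v) {
    vp <- c(rep(v[1], hw), v, rep(v[length(v)], hw))
    as.numeric(stats::filter(vp, k, sides = 2))[hw + seq_along(v)]
  }
  m <- apply(m, 2, smooth_vec)
  t(apply(m, 1, smooth_vec))
}

#' Render a synthetic AFM topography image from a defect set
#'
#' Produces a height map (nm) combining a flat background, correlated
#' surface roughness, per-scan-line offset noise and one Gaussian pit per
#' defect. This is a synthetic lookalike for testing detection pipelines,
#' not a simulation of tip-sample convolution.
#'
#' @param set A [defect_set()] whose field is an integral number of pixels.
#' @param p An [image_render_params()].
#' @return Numeric matrix (rows = y scan lines, columns = x) of heights in
#'   nm, with attributes `pixel_size_nm` and `label`.
#' @export
render_afm_image <- function(set, p = image_render_params()) {
  stopifnot(inherits(set, "defect_set"), inherits(p, "image_render_params"))
  nx <- set$field_width / p$pixel_size
  ny <- set$field_height / p$pixel_size
  if (abs(nx - round(nx)) > 1e-6 || abs(ny - round(ny)) > 1e-6) {
    stop("field dimensions must be an integral number of pixels",
         call. = FALSE)
  }
  nx <- round(nx)
  ny <- round(ny)
  xc <- (seq_len(nx) - 0.5) * p$pixel_size
  yc <- (seq_len(ny) - 0.5) * p$pixel_size
  img <- with_seed(p$seed, {
    img <- matrix(0, ny, nx)
    if (p$roughness_amp > 0) {
      r <- matrix(stats::rnorm(ny * nx), ny, nx)
      r <- blur_matrix(r, p$roughness_scale / p$pixel_size)
      img <- img + r * (p$roughness_amp / stats::sd(r))
    }
    if (p$scanline_amp > 0) {
      img <- img + stats::rnorm(ny, 0, p$scanline_amp)
    }
    img
  })
  if (n_defects(set) > 0 && p$depth > 0) {
    two_ar2 <- 2 * p$apparent_radius^2
    for (d in seq_len(n_defects(set))) {
      dx2 <- (xc - set$defects$x[d])^2
      dy2 <- (yc - set$defects$y[d])^2
      # restrict to a 4-radius window for speed
      ix <- which(dx2 <= (4 * p$apparent_radius)^2)
      iy <- which(dy2 <= (4 * p$apparent_radius)^2)
      if (length(ix) && length(iy)) {
        img[iy, ix] <- img[iy, ix] -
          p$depth * exp(-outer(dy2[iy], dx2[ix], "+") / two_ar2)
      }
    }
  }
  attr(img, "pixel_size_nm") <- p$pixel_size
  attr(img, "label") <- set$label
  img
}

#' Export a height map as 16-bit grayscale TIFF with a calibration sidecar
#'
#' Heights are affinely mapped to the full 16-bit range; the mapping and
#' the lateral calibration are written to `<path>.yaml` so the image is
#' recoverable in nm.
#'
#' @param img A matrix from [render_afm_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_afm_tiff <- function(img, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required for TIFF export", call. = FALSE)
  }
  lo <- min(img)
  hi <- max(img)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((img - lo) / scale, path, bits.per.sample = 16L)
  yaml::write_yaml(
    list(pixel_size_nm = attr(img, "pixel_size_nm"),
         height_offset_nm = lo, height_scale_nm = scale,
         label = attr(img, "label")),
    paste0(path, ".yaml"))
  invisible(path)
}
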
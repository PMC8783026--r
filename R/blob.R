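#' Detect defect pits in a topography image
#'
#' Classical multi-scale Laplacian-of-Gaussian blob detection standing in
#' for a learned detector: the height map is smoothed at several Gaussian
#' scales, the scale-normalized Laplacian computed (pits give positive
#' response), and local maxima above a depth-like threshold are reported
#' as defect centers after non-maximum suppression. Detected defects carry
#' the standard 25 nm box half-width.
#'
#' @param img Height map matrix (nm) with a `pixel_size_nm` attribute, or
#'   pass `pixel_size` explicitly.
#' @param pixel_size Lateral calibration (nm/px).
#' @param scales_nm Gaussian scales to probe (nm).
#' @param threshold Minimum scale-normalized response (nm); responses scale
#'   with pit depth, so this acts as a depth threshold.
#' @param min_sep_nm Non-maximum suppression radius (nm).
#' @return A [defect_set()] on the image field (possibly empty, with a
#'   warning when the image is constant).
#' @export
detect_blobs <- function(img, pixel_size = attr(img, "pixel_size_nm"),
                         scales_nm = c(8, 11, 15), threshold = 0.7,
                         min_sep_nm = 25) {
  if (is.null(pixel_size)) {
    stop("pixel_size missing (no pixel_size_nm attribute)", call. = FALSE)
  }
  ny <- nrow(img)
  nx <- ncol(img)
  W <- nx * pixel_size
  H <- ny * pixel_size
  if (max(img) - min(img) < .Machine$double.eps * 100) {
    warning("constant image: no defects detected", call. = FALSE)
    return(defect_set(numeric(), numeric(), W, H))
  }
  # scale-normalized LoG response per scale (positive at pits)
  resp <- array(0, dim = c(ny, nx, length(scales_nm)))
  for (s in seq_along(scales_nm)) {
    sm <- blur_matrix(img, scales_nm[s] / pixel_size)
    up <- sm[c(1, seq_len(ny - 1)), ]
    dn <- sm[c(seq_len(ny - 1) + 1, ny), ]
    lf <- sm[, c(1, seq_len(nx - 1))]
    rt <- sm[, c(seq_len(nx - 1) + 1, nx)]
    lap <- (up + dn + lf + rt - 4 * sm) / pixel_size^2
    resp[, , s] <- scales_nm[s]^2 * lap
  }
  best <- apply(resp, c(1, 2), max)
  # 3x3 local maxima of the scale-collapsed response
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- best
  is_max <- best >= threshold
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nb <- pad[2:(ny + 1) + di, 2:(nx + 1) + dj]
      is_max <- is_max & (best >= nb)
    }
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(defect_set(numeric(), numeric(), W, H))
  }
  v <- best[idx]
  ord <- order(-v)
  idx <- idx[ord, , drop = FALSE]
  px <- (idx[, 2] - 0.5) * pixel_size
  py <- (idx[, 1] - 0.5) * pixel_size
  keep <- hardcore_thin(px, py, min_sep_nm)
  defect_set(px[keep], py[keep], W, H, r_box = 25, label = "blob-detected")
}
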
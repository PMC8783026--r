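# P1 finite-element pieces for the complex thin-film equation
#   g_s lap(u) - i w (C_H + C_m) u = -i w C_m U0      on the patch
#   u = U0 on defect rims, zero normal flux elsewhere.
# Coordinates enter in nm and are converted to cm here; admittance is per
# cm^2 of total patch area.

fem_assemble <- function(mesh) {
  pts <- mesh$points * 1e-7  # nm -> cm
  tri <- mesh$triangles
  p1 <- pts[tri[, 1], , drop = FALSE]
  p2 <- pts[tri[, 2], , drop = FALSE]
  p3 <- pts[tri[, 3], , drop = FALSE]
  d1x <- p2[, 1] - p1[, 1]
  d1y <- p2[, 2] - p1[, 2]
  d2x <- p3[, 1] - p1[, 1]
  d2y <- p3[, 2] - p1[, 2]
  detJ <- d1x * d2y - d1y * d2x
  if (any(abs(detJ) < .Machine$double.xmin)) {
    stop("numerical error: degenerate mesh triangle", call. = FALSE)
  }
  area <- abs(detJ) / 2
  gx <- cbind((p2[, 2] - p3[, 2]) / detJ,
              (p3[, 2] - p1[, 2]) / detJ,
              (p1[, 2] - p2[, 2]) / detJ)
  gy <- cbind((p3[, 1] - p2[, 1]) / detJ,
              (p1[, 1] - p3[, 1]) / detJ,
              (p2[, 1] - p1[, 1]) / detJ)
  n <- nrow(pts)
  m <- nrow(tri)
  It <- Jt <- integer(9 * m)
  Kv <- Mv <- numeric(9 * m)
  s <- 0L
  for (a in 1:3) {
    for (b in 1:3) {
      idx <- s + seq_len(m)
      It[idx] <- tri[, a]
      Jt[idx] <- tri[, b]
      Kv[idx] <- area * (gx[, a] * gx[, b] + gy[, a] * gy[, b])
      Mv[idx] <- area / 12 * (1 + (a == b))
      s <- s + m
    }
  }
  K <- Matrix::sparseMatrix(i = It, j = Jt, x = Kv, dims = c(n, n))
  M <- Matrix::sparseMatrix(i = It, j = Jt, x = Mv, dims = c(n, n))
  load <- numeric(n)
  for (a in 1:3) {
    load <- load + as.vector(Matrix::sparseMatrix(
      i = tri[, a], j = rep(1L, m), x = area / 3, dims = c(n, 1L)))
  }
  list(K = K, M = M, load = load, area_cm2 = sum(area),
       field_area_cm2 = mesh$field_area * 1e-14, n = n,
       dirichlet = mesh$dirichlet)
}

# solve the assembled system over a frequency grid -> complex Y per cm^2
fem_spectrum <- function(asm, mp, fg) {
  gs <- sheet_conductance(mp)
  cm <- cm_f(mp)
  ch <- ch_f(mp)
  ct <- cm + ch
  u0 <- mp$u0
  dir <- asm$dirichlet
  free <- setdiff(seq_len(asm$n), dir)
  hole_cm2 <- asm$field_area_cm2 - asm$area_cm2
  if (length(dir) == 0L) {
    # uniform film: u = U0 C_m / (C_m + C_H) exactly
    w <- 2 * pi * fg
    return(complex(real = 0, imaginary = w * ch * cm / ct))
  }
  if (length(free) == 0L) {
    stop("numerical error: no free nodes (defects cover the patch)",
         call. = FALSE)
  }
  Kff <- asm$K[free, free]
  Mff <- asm$M[free, free]
  Kfd_ud <- as.vector(asm$K[free, dir, drop = FALSE] %*% rep(u0, length(dir)))
  Mfd_ud <- as.vector(asm$M[free, dir, drop = FALSE] %*% rep(u0, length(dir)))
  load_f <- asm$load[free]
  int_dir <- asm$load[dir]  # lumped areas of rim nodes
  nf <- length(free)
  vapply(fg, function(f) {
    w <- 2 * pi * f
    A <- rbind(cbind(gs * Kff, -w * ct * Mff),
               cbind(w * ct * Mff, gs * Kff))
    rhs <- c(-gs * Kfd_ud, w * cm * u0 * load_f - w * ct * Mfd_ud)
    sol <- tryCatch(as.vector(Matrix::solve(A, rhs)),
                    error = function(e) {
                      stop(sprintf(
                        "numerical error: linear solve failed at %g Hz (%s)",
                        f, conditionMessage(e)), call. = FALSE)
                    })
    u <- complex(real = sol[seq_len(nf)], imaginary = sol[nf + seq_len(nf)])
    int_u <- sum(load_f * u) + sum(int_dir) * u0
    1i * w * ch * (int_u + hole_cm2 * u0) / (asm$field_area_cm2 * u0)
  }, complex(1))
}

#' Model the EIS admittance spectrum of a defect-bearing membrane
#'
#' Solves the submembrane thin-film potential problem on the field
#' rectangle by P1 finite elements: the reservoir sheet (conductance
#' `g_s = d_sub/rho_sub`) is loaded capacitively by the membrane above and
#' the Helmholtz layer below, defect rims of radius `r_def` clamp the
#' reservoir potential to the drive, and the outer patch boundary carries
#' zero normal flux. The reported area-normalized admittance is
#' `Y(w) = i w C_H <u> / U0` with `<u>` the patch average of the reservoir
#' potential (defect interiors count at the drive potential).
#'
#' With no defects the uniform-film limit `Y = i w C_m C_H / (C_m + C_H)`
#' (phase 90 degrees at every frequency) is returned exactly.
#'
#' @param set A [defect_set()]; defect disks must be pairwise disjoint.
#' @param mp A [membrane_params()].
#' @param fg Frequency vector (Hz), e.g. [frequency_grid()].
#' @param ctrl A [mesh_control()].
#' @return An [eis_spectrum()].
#' @examples
#' \donttest{
#' s <- sample_point_process(point_process_params("poisson", density = 10,
#'                                                seed = 1),
#'                           field_width = 1000, field_height = 1000)
#' sp <- model_spectrum(s, membrane_params(r_def = 5),
#'                      frequency_grid(1, 1e4, 5))
#' spectral_features(sp)
#' }
#' @export
model_spectrum <- function(set, mp, fg = frequency_grid(),
                           ctrl = mesh_control()) {
  stopifnot(inherits(set, "defect_set"), inherits(mp, "membrane_params"))
  if (n_defects(set) == 0) {
    w <- 2 * pi * fg
    cs <- cm_f(mp) * ch_f(mp) / (cm_f(mp) + ch_f(mp))
    return(eis_spectrum(fg, complex(real = 0, imaginary = w * cs)))
  }
  mesh <- mesh_membrane(set, mp$r_def, ctrl)
  asm <- fem_assemble(mesh)
  eis_spectrum(fg, fem_spectrum(asm, mp, fg))
}

#' FEM spectrum of a single centered defect on a disk patch
#'
#' Finite-element counterpart of [radial_spectrum()], used to verify the
#' 2D solver against the semi-analytic Bessel solution on the one geometry
#' where both are available.
#'
#' @inheritParams radial_spectrum
#' @param ctrl A [mesh_control()].
#' @return An [eis_spectrum()].
#' @export
disk_spectrum_fem <- function(mp, domain_radius, fg = frequency_grid(),
                              ctrl = mesh_control()) {
  stopifnot(inherits(mp, "membrane_params"))
  mesh <- mesh_disk(mp$r_def, domain_radius, ctrl)
  asm <- fem_assemble(mesh)
  eis_spectrum(fg, fem_spectrum(asm, mp, fg))
}
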
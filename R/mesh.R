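#' Mesh generation controls for the thin-film FEM solver
#'
#' The solver meshes the membrane patch with an unstructured triangulation
#' graded from the defect rims outward: each defect carries concentric
#' point rings whose radial spacing grows geometrically, embedded in a
#' quasi-uniform background cloud. Rim vertices sit at an area-matched
#' radius (the rim polygon encloses exactly `pi r_def^2`), which removes
#' the leading geometric discretization error of the Dirichlet rim.
#'
#' @param rim_points Vertices on each defect rim (angular resolution
#'   controls the dominant error; 48 is a few-percent working default, 96
#'   reaches sub-percent admittance accuracy).
#' @param grade Initial geometric growth factor of ring radii.
#' @param grade_growth Additive increase of the growth factor per ring
#'   (accelerates coarsening away from the rim).
#' @param grade_max Cap on the growth factor.
#' @param h_far_frac Background node spacing as a fraction of the shorter
#'   field side.
#' @return An object of class `mesh_control`.
#' @export
mesh_control <- function(rim_points = 48, grade = 1.3, grade_growth = 0.12,
                         grade_max = 2, h_far_frac = 1 / 40) {
  stopifnot(rim_points >= 8, grade > 1, grade_growth >= 0, grade_max > 1,
            h_far_frac > 0, h_far_frac < 1)
  structure(list(rim_points = as.integer(rim_points), grade = grade,
                 grade_growth = grade_growth, grade_max = grade_max,
                 h_far_frac = h_far_frac),
            class = "mesh_control")
}

# deterministic pseudo-random jitter in [-0.5, 0.5), no RNG state touched
hash_jitter <- function(a, b) {
  v <- sin(a * 12.9898 + b * 78.233) * 43758.5453
  v - floor(v) - 0.5
}

# concentric point rings around one defect center
defect_rings <- function(cx, cy, r_def, r_stop, ctrl, phase = 0) {
  n_rim <- ctrl$rim_points
  rc <- r_def * sqrt(2 * pi / (n_rim * sin(2 * pi / n_rim)))  # area match
  radii <- rc
  g <- ctrl$grade
  while (utils::tail(radii, 1) < r_stop) {
    radii <- c(radii, utils::tail(radii, 1) * g)
    g <- min(g + ctrl$grade_growth, ctrl$grade_max)
  }
  n_bg <- max(12L, round(2 * pi / (ctrl$grade - 1)))
  pts <- vector("list", length(radii))
  rim_flag <- vector("list", length(radii))
  for (j in seq_along(radii)) {
    r <- radii[j]
    # angular count decays like sqrt(rc/r): keeps near-rim fidelity without
    # carrying the full rim resolution outward
    n <- if (j == 1L) n_rim else max(n_bg, round(n_rim * sqrt(rc / r)))
    th <- (seq_len(n) - 1) / n * 2 * pi + (j %% 2) * pi / n + phase
    # break exact cocircularity, but keep the rim ring area-true
    rj <- if (j == 1L) {
      r * (1 + 1e-9 * hash_jitter(seq_len(n), j))
    } else {
      r * (1 + 1e-4 * hash_jitter(seq_len(n) + cx, j + cy))
    }
    pts[[j]] <- cbind(cx + rj * cos(th), cy + rj * sin(th))
    rim_flag[[j]] <- rep(j == 1L, n)
  }
  list(pts = do.call(rbind, pts), rim = unlist(rim_flag), rc = rc)
}

# triangulate a point cloud, dropping triangles whose centroid falls in a
# defect disk; returns P1 mesh pieces shared by both domain builders
triangulate_cloud <- function(pts, centers, rc, dirichlet) {
  dd <- deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE)
  if (nrow(dd$summary) != nrow(pts)) {
    stop("mesh degeneracy: duplicate nodes collapsed during triangulation",
         call. = FALSE)
  }
  tri <- deldir::triMat(dd)
  if (length(rc) > 0) {
    cx <- rowMeans(matrix(pts[tri, 1], ncol = 3))
    cy <- rowMeans(matrix(pts[tri, 2], ncol = 3))
    inside <- rep(FALSE, nrow(tri))
    for (d in seq_along(rc)) {
      inside <- inside |
        ((cx - centers[d, 1])^2 + (cy - centers[d, 2])^2 < (rc[d] * 0.9995)^2)
    }
    tri <- tri[!inside, , drop = FALSE]
  }
  # drop nodes that ended up unused (e.g. rim nodes of fully clipped arcs)
  used <- sort(unique(as.vector(tri)))
  remap <- integer(nrow(pts))
  remap[used] <- seq_along(used)
  list(points = pts[used, , drop = FALSE],
       triangles = matrix(remap[tri], ncol = 3),
       dirichlet = remap[intersect(dirichlet, used)])
}

#' Mesh a rectangular membrane patch with defect holes
#'
#' @param set A [defect_set()]; defect disks of radius `r_def` must be
#'   pairwise disjoint (disks may touch the field boundary, where they are
#'   clipped).
#' @param r_def Electrochemical defect radius (nm).
#' @param ctrl A [mesh_control()].
#' @return A mesh list: `points` (nm), `triangles` (index triplets),
#'   `dirichlet` (rim node indices), `field_area` (nm^2).
#' @keywords internal
mesh_membrane <- function(set, r_def, ctrl = mesh_control()) {
  stopifnot(inherits(set, "defect_set"))
  W <- set$field_width
  H <- set$field_height
  n <- n_defects(set)
  cx <- set$defects$x
  cy <- set$defects$y
  if (n > 1) {
    dmin <- min(stats::dist(cbind(cx, cy)))
    if (dmin <= 2 * r_def) {
      stop(sprintf(
        "geometry error: defect disks overlap (min center distance %.3g nm <= 2 r_def = %.3g nm)",
        dmin, 2 * r_def), call. = FALSE)
    }
  }
  h_far <- min(W, H) * ctrl$h_far_frac
  if (r_def >= h_far / 2) {
    stop("r_def too large for the background spacing; refine h_far_frac",
         call. = FALSE)
  }
  r_stop <- 2.5 * h_far
  pts <- list()
  rim_idx <- integer()
  rc <- numeric(n)
  total <- 0L
  for (d in seq_len(n)) {
    rg <- defect_rings(cx[d], cy[d], r_def, r_stop, ctrl,
                       phase = hash_jitter(d, 17))
    keep <- rg$pts[, 1] >= 0 & rg$pts[, 1] <= W &
      rg$pts[, 2] >= 0 & rg$pts[, 2] <= H
    # a ring point belongs to its own defect's territory only
    if (n > 1) {
      own <- (rg$pts[, 1] - cx[d])^2 + (rg$pts[, 2] - cy[d])^2
      for (e in seq_len(n)) {
        if (e == d) next
        keep <- keep &
          (own <= (rg$pts[, 1] - cx[e])^2 + (rg$pts[, 2] - cy[e])^2)
      }
    }
    p <- rg$pts[keep, , drop = FALSE]
    rim_idx <- c(rim_idx, total + which(rg$rim[keep]))
    total <- total + nrow(p)
    pts[[d]] <- p
    rc[d] <- rg$rc
  }
  # rectangle boundary
  nx <- max(2L, ceiling(W / h_far))
  ny <- max(2L, ceiling(H / h_far))
  bx <- seq(0, W, length.out = nx + 1)
  by <- seq(0, H, length.out = ny + 1)
  bpts <- rbind(cbind(bx, 0), cbind(bx, H),
                cbind(rep(0, ny - 1), by[2:ny]), cbind(rep(W, ny - 1), by[2:ny]))
  # background interior cloud, jittered off the lattice
  gx <- if (nx >= 2) bx[2:nx] else numeric()
  gy <- if (ny >= 2) by[2:ny] else numeric()
  bg <- as.matrix(expand.grid(x = gx, y = gy))
  if (nrow(bg) > 0) {
    bg[, 1] <- bg[, 1] + 0.25 * h_far * hash_jitter(bg[, 1], bg[, 2])
    bg[, 2] <- bg[, 2] + 0.25 * h_far * hash_jitter(bg[, 2], bg[, 1] + 3)
  }
  aux <- rbind(bpts, bg)
  if (n > 0 && nrow(aux) > 0) {
    clear <- rep(TRUE, nrow(aux))
    for (d in seq_len(n)) {
      d2 <- (aux[, 1] - cx[d])^2 + (aux[, 2] - cy[d])^2
      clear <- clear & d2 > (0.8 * r_stop)^2
    }
    aux <- aux[clear, , drop = FALSE]
  }
  allpts <- rbind(do.call(rbind, c(pts, list(matrix(numeric(), 0, 2)))), aux)
  # Dirichlet: tracked rim nodes plus anything inside a disk (clipped rims)
  dir_extra <- integer()
  if (n > 0 && nrow(aux) > 0) {
    for (d in seq_len(n)) {
      d2 <- (aux[, 1] - cx[d])^2 + (aux[, 2] - cy[d])^2
      dir_extra <- c(dir_extra, total + which(d2 <= (rc[d] * (1 + 1e-9))^2))
    }
  }
  m <- triangulate_cloud(allpts, cbind(cx, cy), rc,
                         sort(unique(c(rim_idx, dir_extra))))
  m$field_area <- W * H
  m
}

#' Mesh a circular membrane patch with one centered defect
#'
#' @param r_def Defect radius (nm).
#' @param domain_radius Outer patch radius (nm).
#' @param ctrl A [mesh_control()].
#' @keywords internal
mesh_disk <- function(r_def, domain_radius, ctrl = mesh_control()) {
  rg <- defect_rings(0, 0, r_def, domain_radius * 0.995, ctrl)
  rr <- sqrt(rg$pts[, 1]^2 + rg$pts[, 2]^2)
  keep <- rr < domain_radius * 0.999
  p <- rg$pts[keep, , drop = FALSE]
  rim <- which(rg$rim[keep])
  n_out <- max(48L, 2L * round(pi / (ctrl$grade - 1)))
  th <- (seq_len(n_out) - 1) / n_out * 2 * pi
  # area-matched outer polygon, so the patch area bookkeeping stays exact
  Rp <- domain_radius * sqrt(2 * pi / (n_out * sin(2 * pi / n_out)))
  outer_ring <- cbind(Rp * cos(th), Rp * sin(th))
  allpts <- rbind(p, outer_ring)
  m <- triangulate_cloud(allpts, matrix(c(0, 0), 1, 2), rg$rc, rim)
  m$field_area <- pi * domain_radius^2
  m
}
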
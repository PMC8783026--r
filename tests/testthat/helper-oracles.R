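# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately written without touching the package's
# internal code paths, so agreement is a genuine cross-check.

# --- finite-difference solver for the radially symmetric thin-film ODE ---
# g_s (u'' + u'/r) = i w (C_H + C_m) u - i w C_m U0, u(r0) = U0, u'(R) = 0,
# on a dense uniform radial grid; admittance integrated by trapezoid.
fd_radial_admittance <- function(f, r_def_nm, R_nm, rho_ohm_cm,
                                 cm_uF = 0.8, ch_uF = 9.0, dsub_nm = 1.5,
                                 n = 6000) {
  r0 <- r_def_nm * 1e-7
  R <- R_nm * 1e-7
  gs <- (dsub_nm * 1e-7) / rho_ohm_cm
  cm <- cm_uF * 1e-6
  ch <- ch_uF * 1e-6
  ct <- cm + ch
  w <- 2 * pi * f
  r <- seq(r0, R, length.out = n)
  h <- r[2] - r[1]
  lo <- gs * (1 / h^2 - 1 / (2 * h * r))
  di <- rep(-2 * gs / h^2 - 1i * w * ct, n)
  up <- gs * (1 / h^2 + 1 / (2 * h * r))
  b <- rep(-1i * w * cm, n)
  di[1] <- 1; up[1] <- 0; b[1] <- 1
  lo[n] <- 2 * gs / h^2
  # Thomas algorithm (complex)
  cp <- dp <- complex(length.out = n)
  cp[1] <- up[1] / di[1]
  dp[1] <- b[1] / di[1]
  for (i in 2:n) {
    m <- di[i] - lo[i] * cp[i - 1]
    cp[i] <- up[i] / m
    dp[i] <- (b[i] - lo[i] * dp[i - 1]) / m
  }
  u <- complex(length.out = n)
  u[n] <- dp[n]
  for (i in (n - 1):1) u[i] <- dp[i] - cp[i] * u[i + 1]
  integ <- sum((u[-1] * r[-1] + u[-n] * r[-n]) / 2 * h) * 2 * pi
  1i * w * ch * (integ + pi * r0^2) / (pi * R^2)
}

# --- exhaustive maximum-cardinality matching among IoU-feasible pairs ---
max_matching_tp <- function(iou, thr) {
  nt <- nrow(iou)
  np <- ncol(iou)
  feas <- iou > thr
  best <- 0L
  recurse <- function(i, used_p, count) {
    if (count + (nt - i + 1L) <= best) return()
    if (i > nt) {
      best <<- max(best, count)
      return()
    }
    recurse(i + 1L, used_p, count)  # leave true i unmatched
    for (j in which(feas[i, ] & !used_p)) {
      used_p[j] <- TRUE
      recurse(i + 1L, used_p, count + 1L)
      used_p[j] <- FALSE
    }
  }
  recurse(1L, logical(np), 0L)
  best
}

# --- fixtures ---
lattice_set <- function(n_side = 16, field = 4000) {
  sp <- field / n_side
  g <- expand.grid(x = seq(sp / 2, field - sp / 2, by = sp),
                   y = seq(sp / 2, field - sp / 2, by = sp))
  defect_set(g$x, g$y, field, field, label = "lattice")
}

# homogeneous pattern with an exact point count (binomial process)
uniform_set <- function(n, field_w, field_h, seed, min_sep = 0) {
  set.seed(seed)
  x <- numeric(0)
  y <- numeric(0)
  while (length(x) < n) {
    cx <- runif(1, 0, field_w)
    cy <- runif(1, 0, field_h)
    if (min_sep == 0 || length(x) == 0 ||
        min((x - cx)^2 + (y - cy)^2) > min_sep^2) {
      x <- c(x, cx)
      y <- c(y, cy)
    }
  }
  defect_set(x, y, field_w, field_h)
}

# tight clusters: k cluster centers on a coarse lattice, m defects each
clustered_set <- function(k = 4, m = 4, field = 1000, cluster_spacing = 35) {
  cc <- expand.grid(x = seq(field / 4, 3 * field / 4, length.out = sqrt(k)),
                    y = seq(field / 4, 3 * field / 4, length.out = sqrt(k)))
  ang <- (seq_len(m) - 1) / m * 2 * pi
  x <- as.vector(outer(cluster_spacing * cos(ang), cc$x, "+"))
  y <- as.vector(outer(cluster_spacing * sin(ang), cc$y, "+"))
  defect_set(x, y, field, field, label = "clustered")
}

# coarse-but-honest mesh/frequency settings for multi-spectrum tests
coarse_ctrl <- function() mesh_control(rim_points = 24, grade = 1.4,
                                       grade_growth = 0.15,
                                       h_far_frac = 1 / 16)
coarse_fg <- function() frequency_grid(1, 1e4, 4)
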
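#' Degradation parameters for synthetic detector output
#'
#' @param n_remove Number of defects to delete (introduces false negatives).
#' @param n_add Number of defects to insert (introduces false positives).
#' @param s Standard deviation of the per-coordinate position jitter
#'   (nm, default 4).
#' @param bandwidth KDE bandwidth guiding removals/additions (nm, default
#'   400).
#' @param seed Optional integer seed making the case reproducible.
#' @return An object of class `degradation_params`.
#' @export
degradation_params <- function(n_remove = 0, n_add = 0, s = 4,
                               bandwidth = 400, seed = NULL) {
  if (s < 0) stop("jitter s must be non-negative", call. = FALSE)
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  if (n_remove < 0 || n_add < 0) {
    stop("n_remove and n_add must be non-negative", call. = FALSE)
  }
  structure(list(n_remove = as.integer(n_remove), n_add = as.integer(n_add),
                 s = s, bandwidth = bandwidth, seed = seed),
            class = "degradation_params")
}

#' Degrade a true defect set into synthetic detector output
#'
#' Emulates an imperfect detector in three steps: (1) every defect's x and
#' y are shifted by independent N(0, s^2) draws, clamped to the field;
#' (2) `n_remove` defects are deleted, each chosen as the not-yet-removed
#' defect nearest to a fresh draw from the KDE fitted on the *true*
#' coordinates; (3) `n_add` defects are inserted at KDE draws. The KDE
#' guidance keeps the clustering character of the pattern roughly intact
#' while recall and precision drop.
#'
#' @param true_set The annotated ground-truth [defect_set()].
#' @param params A [degradation_params()].
#' @return A [defect_set()] with `N - n_remove + n_add` defects.
#' @export
degrade_set <- function(true_set, params) {
  stopifnot(inherits(true_set, "defect_set"),
            inherits(params, "degradation_params"))
  n <- n_defects(true_set)
  if (params$n_remove > n) {
    stop("n_remove exceeds the number of defects", call. = FALSE)
  }
  kde <- fit_kde(true_set, params$bandwidth)
  with_seed(params$seed, {
    x <- true_set$defects$x
    y <- true_set$defects$y
    if (params$s > 0 && n > 0) {
      x <- x + stats::rnorm(n, 0, params$s)
      y <- y + stats::rnorm(n, 0, params$s)
      x <- pmin(pmax(x, 0), true_set$field_width)
      y <- pmin(pmax(y, 0), true_set$field_height)
    }
    alive <- rep(TRUE, n)
    if (params$n_remove > 0) {
      targets <- kde_sample(kde, params$n_remove)
      for (k in seq_len(params$n_remove)) {
        d2 <- (x - targets$x[k])^2 + (y - targets$y[k])^2
        d2[!alive] <- Inf
        alive[which.min(d2)] <- FALSE
      }
    }
    x <- x[alive]
    y <- y[alive]
    if (params$n_add > 0) {
      added <- kde_sample(kde, params$n_add)
      x <- c(x, added$x)
      y <- c(y, added$y)
    }
    defect_set(x, y, true_set$field_width, true_set$field_height,
               r_box = 25,
               label = sprintf("%s [degraded -%d +%d s=%g]",
                               true_set$label, params$n_remove,
                               params$n_add, params$s))
  })
}

#' Grid of degradation cases
#'
#' Both `n_remove` and `n_add` step from 0 in increments of 3% of the true
#' defect count N (rounded to the nearest integer) while staying strictly
#' below floor(N/2); the case grid is the full Cartesian product. For
#' N = 172 this gives step 5, levels 0,5,...,85 and 18^2 = 324 cases; for
#' N = 158 and N = 97 it gives 256 cases each.
#'
#' @param n True defect count N (>= 2).
#' @param step Optional explicit step, required when round(0.03 N) = 0.
#' @return A data.frame with columns `n_remove`, `n_add` (n_remove varying
#'   slowest).
#' @export
case_grid <- function(n, step = NULL) {
  if (n < 2) stop("case grid needs N >= 2", call. = FALSE)
  if (is.null(step)) {
    step <- round(0.03 * n)
    if (step == 0) {
      stop("3% step rounds to 0 for N = ", n,
           "; pass an explicit step", call. = FALSE)
    }
  }
  vals <- seq(0L, floor(n / 2), by = step)
  vals <- vals[vals < floor(n / 2)]
  g <- expand.grid(n_add = vals, n_remove = vals,
                   KEEP.OUT.ATTRS = FALSE)[, c("n_remove", "n_add")]
  rownames(g) <- NULL
  g
}

#' Generate and score a batch of degraded defect sets
#'
#' Runs [degrade_set()] for every [case_grid()] entry (or an explicitly
#' supplied case table), scores each case against the true set with
#' [match_defects()]/[accuracy_metrics()], and annotates it with its
#' Voronoi sigma. Per-case seeds are drawn once from `seed`, so the whole
#' batch is reproducible.
#'
#' @param true_set The ground-truth [defect_set()].
#' @param seed Integer seed for the batch.
#' @param cases Optional data.frame with columns `n_remove`, `n_add`;
#'   defaults to `case_grid(n_defects(true_set))`.
#' @param s,bandwidth Passed to [degradation_params()].
#' @param keep_sets Keep the degraded sets themselves (list column of the
#'   attribute `sets`)? Default `TRUE`.
#' @return A data.frame with one row per case: `case`, `n_remove`, `n_add`,
#'   `seed`, `n`, `precision`, `recall`, `f1`, `q_n`, `sigma`. If
#'   `keep_sets`, the degraded sets are attached as attribute `"sets"`.
#' @export
generate_batch <- function(true_set, seed, cases = NULL, s = 4,
                           bandwidth = 400, keep_sets = TRUE) {
  stopifnot(inherits(true_set, "defect_set"))
  if (is.null(cases)) cases <- case_grid(n_defects(true_set))
  ncase <- nrow(cases)
  case_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, ncase))
  sets <- vector("list", ncase)
  rows <- vector("list", ncase)
  for (i in seq_len(ncase)) {
    p <- degradation_params(n_remove = cases$n_remove[i],
                            n_add = cases$n_add[i], s = s,
                            bandwidth = bandwidth, seed = case_seeds[i])
    d <- degrade_set(true_set, p)
    met <- accuracy_metrics(match_defects(true_set, d), true_set, d)
    sig <- if (n_defects(d) >= 3 &&
               !anyDuplicated(d$defects[, c("x", "y")])) {
      voronoi_sigma(d)
    } else NA_real_
    sets[[i]] <- d
    rows[[i]] <- data.frame(case = i, n_remove = cases$n_remove[i],
                            n_add = cases$n_add[i], seed = case_seeds[i],
                            n = n_defects(d), precision = met$precision,
                            recall = met$recall, f1 = met$f1,
                            q_n = met$q_n, sigma = sig)
  }
  out <- do.call(rbind, rows)
  if (keep_sets) attr(out, "sets") <- sets
  out
}
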
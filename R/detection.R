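#' Detection bounding boxes of a defect set
#'
#' Detection scoring equalizes every defect to a square box centered on the
#' defect. By default the stored `r_box` half-widths are overridden with
#' 25 nm, giving the 50 nm x 50 nm boxes used for IoU matching.
#'
#' @param set A [defect_set()].
#' @param half_width Box half-width (nm) applied to all defects, or `NULL`
#'   to use each defect's stored `r_box`.
#' @return A data.frame with columns `x_min`, `y_min`, `x_max`, `y_max`.
#' @export
defect_boxes <- function(set, half_width = 25) {
  stopifnot(inherits(set, "defect_set"))
  hw <- if (is.null(half_width)) set$defects$r_box else half_width
  data.frame(x_min = set$defects$x - hw, y_min = set$defects$y - hw,
             x_max = set$defects$x + hw, y_max = set$defects$y + hw)
}

#' Intersection over union of two bounding boxes
#'
#' @param a,b Boxes: numeric vectors (or one-row data.frames) with elements
#'   `x_min`, `y_min`, `x_max`, `y_max`.
#' @return IoU (Jaccard index) in \[0, 1\]; disjoint boxes give 0.
#' @examples
#' b <- c(x_min = 0, y_min = 0, x_max = 50, y_max = 50)
#' box_iou(b, b)             # 1
#' box_iou(b, b + 25)        # offset by 25 nm in both axes
#' @export
box_iou <- function(a, b) {
  a <- unlist(a)[c("x_min", "y_min", "x_max", "y_max")]
  b <- unlist(b)[c("x_min", "y_min", "x_max", "y_max")]
  if (anyNA(a) || anyNA(b) || a["x_max"] <= a["x_min"] ||
      a["y_max"] <= a["y_min"] || b["x_max"] <= b["x_min"] ||
      b["y_max"] <= b["y_min"]) {
    stop("invalid bounding box", call. = FALSE)
  }
  wx <- min(a["x_max"], b["x_max"]) - max(a["x_min"], b["x_min"])
  wy <- min(a["y_max"], b["y_max"]) - max(a["y_min"], b["y_min"])
  inter <- max(0, wx) * max(0, wy)
  area_a <- (a["x_max"] - a["x_min"]) * (a["y_max"] - a["y_min"])
  area_b <- (b["x_max"] - b["x_min"]) * (b["y_max"] - b["y_min"])
  unname(inter / (area_a + area_b - inter))
}

# IoU of all true x pred pairs of axis-aligned square boxes, vectorized
iou_matrix <- function(bt, bp) {
  nt <- nrow(bt)
  np <- nrow(bp)
  ix <- pmax(0, outer(bt$x_max, bp$x_max, pmin) - outer(bt$x_min, bp$x_min, pmax))
  iy <- pmax(0, outer(bt$y_max, bp$y_max, pmin) - outer(bt$y_min, bp$y_min, pmax))
  inter <- ix * iy
  at <- (bt$x_max - bt$x_min) * (bt$y_max - bt$y_min)
  ap <- (bp$x_max - bp$x_min) * (bp$y_max - bp$y_min)
  inter / (outer(at, ap, "+") - inter)
}

#' Match predicted against true defects
#'
#' Builds a one-to-one assignment between true and predicted defects.
#' Candidate pairs are those whose equalized bounding boxes overlap with
#' IoU strictly above the threshold; candidates are consumed greedily in
#' order of ascending center distance (ties broken by lower predicted, then
#' lower true index). Matched pairs are true positives; unmatched true
#' defects are false negatives and unmatched predictions false positives.
#'
#' @param true_set,pred_set [defect_set()]s on the same field.
#' @param iou_threshold IoU that a pair must strictly exceed (default 0.5).
#' @param half_width Equalized box half-width in nm (default 25).
#' @return An object of class `match_result`: list with `pairs`
#'   (data.frame `true_idx`, `pred_idx`, `iou`, `dist`), counts `tp`, `fp`,
#'   `fn`, and `iou_threshold`.
#' @export
match_defects <- function(true_set, pred_set, iou_threshold = 0.5,
                          half_width = 25) {
  stopifnot(inherits(true_set, "defect_set"), inherits(pred_set, "defect_set"))
  if (!field_matches(true_set, pred_set)) {
    stop("geometry error: true and predicted sets are on different fields",
         call. = FALSE)
  }
  nt <- n_defects(true_set)
  np <- n_defects(pred_set)
  pairs <- data.frame(true_idx = integer(), pred_idx = integer(),
                      iou = numeric(), dist = numeric())
  if (nt > 0 && np > 0) {
    bt <- defect_boxes(true_set, half_width)
    bp <- defect_boxes(pred_set, half_width)
    iou <- iou_matrix(bt, bp)
    d <- sqrt(outer(true_set$defects$x, pred_set$defects$x, "-")^2 +
                outer(true_set$defects$y, pred_set$defects$y, "-")^2)
    cand <- which(iou > iou_threshold, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(d[cand], cand[, 2L], cand[, 1L])
      cand <- cand[ord, , drop = FALSE]
      used_t <- logical(nt)
      used_p <- logical(np)
      keep <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1L]
        j <- cand[k, 2L]
        if (!used_t[i] && !used_p[j]) {
          used_t[i] <- TRUE
          used_p[j] <- TRUE
          keep[k] <- TRUE
        }
      }
      cand <- cand[keep, , drop = FALSE]
      pairs <- data.frame(true_idx = cand[, 1L], pred_idx = cand[, 2L],
                          iou = iou[cand], dist = d[cand])
    }
  }
  structure(
    list(pairs = pairs, tp = nrow(pairs), fp = np - nrow(pairs),
         fn = nt - nrow(pairs), iou_threshold = iou_threshold),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: TP %d, FP %d, FN %d at IoU > %g>\n",
              x$tp, x$fp, x$fn, x$iou_threshold))
  invisible(x)
}

#' Detection accuracy metrics
#'
#' Precision TP/(TP+FP), recall TP/(TP+FN), their harmonic mean F1, and the
#' density ratio Q_N = N_def(pred)/N_def(true). Undefined ratios (empty
#' prediction or true set) are reported as `NaN` with a warning.
#'
#' @param m A [match_defects()] result.
#' @param true_set,pred_set The matched [defect_set()]s (used for Q_N).
#' @return An object of class `accuracy_metrics`: list with `precision`,
#'   `recall`, `f1`, `q_n`, `tp`, `fp`, `fn`.
#' @examples
#' f1_score(0.775, 0.581)  # 0.664
#' @export
accuracy_metrics <- function(m, true_set, pred_set) {
  stopifnot(inherits(m, "match_result"))
  precision <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else {
    warning("empty prediction set: precision undefined (NaN)", call. = FALSE)
    NaN
  }
  recall <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else {
    warning("empty true set: recall undefined (NaN)", call. = FALSE)
    NaN
  }
  q_n <- if (n_defects(true_set) > 0) {
    defect_density(pred_set) / defect_density(true_set)
  } else NaN
  structure(
    list(precision = precision, recall = recall,
         f1 = f1_score(precision, recall), q_n = q_n,
         tp = m$tp, fp = m$fp, fn = m$fn),
    class = "accuracy_metrics"
  )
}

#' @export
print.accuracy_metrics <- function(x, ...) {
  cat(sprintf(
    "<accuracy_metrics: precision %.3f, recall %.3f, F1 %.3f, Q_N %.3f>\n",
    x$precision, x$recall, x$f1, x$q_n))
  invisible(x)
}

#' @rdname accuracy_metrics
#' @param precision,recall Scalars in \[0, 1\].
#' @export
f1_score <- function(precision, recall) {
  if (is.nan(precision) || is.nan(recall)) return(NaN)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}
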
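box <- function(cx, cy, hw = 25) {
  c(x_min = cx - hw, y_min = cy - hw, x_max = cx + hw, y_max = cy + hw)
}

test_that("IoU of rectangles matches closed-form arithmetic", {
  expect_equal(box_iou(box(0, 0), box(0, 0)), 1)
  expect_equal(box_iou(box(0, 0), box(500, 0)), 0)
  # 50 nm boxes offset by 25 nm in x: (25*50)/(2*2500 - 1250) = 1/3
  expect_equal(box_iou(box(0, 0), box(25, 0)), 1 / 3)
  # 2 nm shift: (48*50)/(5000 - 2400)
  expect_equal(box_iou(box(0, 0), box(2, 0)), 2400 / 2600)
  expect_error(box_iou(c(x_min = 1, y_min = 0, x_max = 0, y_max = 1),
                       box(0, 0)), "invalid")
})

test_that("an exact copy matches perfectly; jitter plus a far box scores 2/1/1", {
  s <- uniform_set(20, 2000, 2000, seed = 3)
  m <- match_defects(s, s)
  expect_equal(m$tp, 20)
  expect_equal(m$fp, 0)
  expect_equal(m$fn, 0)

  true <- defect_set(c(500, 1000, 1500), c(500, 500, 500), 2000, 2000)
  pred <- defect_set(c(502, 1002, 300), c(498, 500, 1800), 2000, 2000)
  m <- match_defects(true, pred)
  expect_equal(m$tp, 2)
  expect_equal(m$fp, 1)
  expect_equal(m$fn, 1)
  expect_true(all(m$pairs$iou > 0.5))

  expect_error(match_defects(true, defect_set(1, 1, 1000, 1000)),
               "different fields")
})

test_that("greedy matching attains the exhaustive optimum on small sets", {
  hits <- 0L
  trials <- 200L
  for (i in seq_len(trials)) {
    set.seed(i)
    nt <- sample(2:6, 1)
    np <- sample(2:6, 1)
    true <- defect_set(runif(nt, 25, 275), runif(nt, 25, 275), 300, 300)
    pred <- defect_set(runif(np, 25, 275), runif(np, 25, 275), 300, 300)
    m <- match_defects(true, pred)
    iou <- tbleis:::iou_matrix(defect_boxes(true), defect_boxes(pred))
    if (m$tp == max_matching_tp(iou, 0.5)) hits <- hits + 1L
  }
  expect_gte(hits / trials, 0.95)
})

test_that("precision, recall, F1 and Q_N follow their definitions", {
  expect_equal(round(f1_score(0.775, 0.581), 3), 0.664)
  expect_equal(round(f1_score(0.555, 0.680), 3), 0.611)

  true <- uniform_set(160, 4000, 4000, seed = 7)  # 10.0 um^-2
  pred <- uniform_set(120, 4000, 4000, seed = 8)  # 7.5 um^-2
  met <- accuracy_metrics(match_defects(true, pred), true, pred)
  expect_equal(met$q_n, 0.75)
  expect_equal(met$precision, met$tp / (met$tp + met$fp))
  expect_equal(met$recall, met$tp / (met$tp + met$fn))

  empty <- defect_set(numeric(), numeric(), 4000, 4000)
  expect_warning(
    met0 <- accuracy_metrics(match_defects(true, empty), true, empty),
    "precision undefined")
  expect_true(is.nan(met0$precision))
  suppressWarnings(
    metE <- accuracy_metrics(match_defects(empty, empty), empty, empty))
  expect_true(is.nan(metE$precision) && is.nan(metE$recall) &&
                is.nan(metE$f1) && is.nan(metE$q_n))
})

test_that("swapping true and predicted swaps precision and recall", {
  a <- uniform_set(40, 2000, 2000, seed = 21)
  b <- uniform_set(30, 2000, 2000, seed = 22)
  m_ab <- accuracy_metrics(match_defects(a, b), a, b)
  m_ba <- accuracy_metrics(match_defects(b, a), b, a)
  expect_equal(m_ab$precision, m_ba$recall)
  expect_equal(m_ab$recall, m_ba$precision)
  expect_equal(m_ab$f1, m_ba$f1)
})

test_that("F1 lies between min and max of precision and recall", {
  set.seed(9)
  for (i in 1:50) {
    p <- runif(1)
    r <- runif(1)
    f1 <- f1_score(p, r)
    expect_gte(f1 + 1e-12, min(p, r))
    expect_lte(f1 - 1e-12, max(p, r))
    expect_lte(f1, 2 * min(p, r) / (1 + min(p, r)) + 1e-12)
  }
})

test_that("an extra false positive lowers precision and leaves recall fixed", {
  true <- uniform_set(30, 2000, 2000, seed = 31, min_sep = 80)
  set.seed(33)
  pred <- defect_set(true$defects$x[1:20] + rnorm(20, 0, 2),
                     true$defects$y[1:20] + rnorm(20, 0, 2), 2000, 2000)
  m1 <- accuracy_metrics(match_defects(true, pred), true, pred)
  # the appended box sits > 40 nm from every true defect, so it matches none
  far <- c(1999, 1999)
  stopifnot(min(sqrt((true$defects$x - far[1])^2 +
                       (true$defects$y - far[2])^2)) > 40)
  pred2 <- defect_set(c(pred$defects$x, far[1]), c(pred$defects$y, far[2]),
                      2000, 2000)
  m2 <- accuracy_metrics(match_defects(true, pred2), true, pred2)
  expect_equal(m2$tp, m1$tp)
  expect_lt(m2$precision, m1$precision)
  expect_equal(m2$recall, m1$recall)
})
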
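test_that("KDE log density equals the closed-form Gaussian mixture", {
  s <- defect_set(c(500, 1500), c(500, 1500), 2000, 2000)
  k <- fit_kde(s, bandwidth = 300)
  mix <- function(x, y) {
    log(mean(exp(-((c(500, 1500) - x)^2 + (c(500, 1500) - y)^2) /
                   (2 * 300^2))) / (2 * pi * 300^2))
  }
  for (pt in list(c(500, 500), c(1000, 1000), c(40, 1900))) {
    expect_equal(kde_log_density(k, pt[1], pt[2]), mix(pt[1], pt[2]),
                 tolerance = 1e-12)
  }
  # unimodal: single defect peaks at its own center
  k1 <- fit_kde(defect_set(700, 900, 2000, 2000), bandwidth = 200)
  at_center <- kde_log_density(k1, 700, 900)
  grid <- expand.grid(x = seq(0, 2000, by = 250), y = seq(0, 2000, by = 250))
  expect_true(all(kde_log_density(k1, grid$x, grid$y) <= at_center))
  expect_error(fit_kde(s, bandwidth = 0), "bandwidth")
})

test_that("KDE samples stay in the field with plausible first moments", {
  s <- sample_point_process(point_process_params("thomas", 9,
                                                 mean_offspring = 5,
                                                 spread = 100, seed = 2))
  k <- fit_kde(s, bandwidth = 400)
  pts <- tbleis:::with_seed(99, kde_sample(k, 10000))
  expect_true(all(pts$x >= 0 & pts$x <= 4000 & pts$y >= 0 & pts$y <= 4000))
  # mixture mean is the kernel-center mean, up to boundary truncation;
  # 3 standard errors of the mixture spread (sd ~ sqrt(var(centers) + bw^2))
  se <- sqrt(stats::var(s$defects$x) + 400^2) / sqrt(10000)
  expect_lt(abs(mean(pts$x) - mean(s$defects$x)), 3 * se + 40)
  expect_lt(abs(mean(pts$y) - mean(s$defects$y)), 3 * se + 40)
})

test_that("degradation without edits is the identity", {
  s <- uniform_set(50, 4000, 4000, seed = 4)
  d <- degrade_set(s, degradation_params(0, 0, s = 0, seed = 1))
  expect_equal(d$defects$x, s$defects$x)
  expect_equal(d$defects$y, s$defects$y)
  met <- accuracy_metrics(match_defects(s, d), s, d)
  expect_equal(met$precision, 1)
  expect_equal(met$recall, 1)
})

test_that("4 nm jitter alone almost never breaks a match", {
  s <- uniform_set(200, 4000, 4000, seed = 12, min_sep = 60)
  rec <- sapply(1:5, function(i) {
    d <- degrade_set(s, degradation_params(0, 0, s = 4, seed = i))
    accuracy_metrics(match_defects(s, d), s, d)$recall
  })
  expect_gte(mean(rec), 0.999)
})

test_that("heavy removal plus addition lands near the counting-argument score", {
  s <- uniform_set(172, 4000, 4000, seed = 13)
  prec <- sapply(1:3, function(i) {
    d <- degrade_set(s, degradation_params(85, 85, seed = 50 + i))
    accuracy_metrics(match_defects(s, d), s, d)$precision
  })
  expect_lt(abs(mean(prec) - 87 / 172), 0.03)
})

test_that("count bookkeeping is exact and invalid parameters are rejected", {
  s <- uniform_set(40, 2000, 2000, seed = 14)
  for (cs in list(c(0, 0), c(7, 3), c(19, 19))) {
    d <- degrade_set(s, degradation_params(cs[1], cs[2], seed = 3))
    expect_equal(n_defects(d), 40 - cs[1] + cs[2])
  }
  expect_error(degrade_set(s, degradation_params(41, 0)), "n_remove")
  expect_error(degradation_params(s = -1), "non-negative")
})

test_that("case grid reproduces the printed stepping convention", {
  g172 <- case_grid(172)
  expect_equal(nrow(g172), 324)
  expect_equal(sort(unique(g172$n_remove)), seq(0, 85, by = 5))
  expect_equal(nrow(case_grid(158)), 256)
  expect_equal(nrow(case_grid(100)), 289)
  expect_equal(sort(unique(case_grid(100)$n_add)), seq(0, 48, by = 3))
  expect_error(case_grid(16), "explicit step")
  expect_equal(nrow(case_grid(16, step = 2)), 16)
})

test_that("recall falls with removals and precision with additions", {
  s <- uniform_set(60, 3000, 3000, seed = 15)
  cases <- expand.grid(n_remove = c(0, 10, 20), n_add = c(0, 10, 20))
  agg <- Reduce(`+`, lapply(1:4, function(i) {
    b <- generate_batch(s, seed = 200 + i, cases = cases, keep_sets = FALSE)
    cbind(recall = b$recall, precision = b$precision)
  })) / 4
  b <- cbind(cases, agg)
  for (ad in c(0, 10, 20)) {
    r <- b$recall[b$n_add == ad][order(b$n_remove[b$n_add == ad])]
    expect_true(all(diff(r) < 0))
  }
  for (rm in c(0, 10, 20)) {
    p <- b$precision[b$n_remove == rm][order(b$n_add[b$n_remove == rm])]
    expect_true(all(diff(p) < 0))
  }
})

test_that("a scored batch is reproducible and brackets the true sigma", {
  s <- sample_point_process(point_process_params("thomas", 7,
                                                 mean_offspring = 4,
                                                 spread = 120, seed = 6),
                            3000, 3000)
  cases <- case_grid(n_defects(s), step = round(n_defects(s) / 8))
  b1 <- generate_batch(s, seed = 77, cases = cases, keep_sets = FALSE)
  b2 <- generate_batch(s, seed = 77, cases = cases, keep_sets = FALSE)
  expect_identical(b1, b2)
  expect_equal(b1$n, n_defects(s) - b1$n_remove + b1$n_add)
  jitter_only <- b1$f1[b1$n_remove == 0 & b1$n_add == 0]
  expect_true(all(jitter_only >= 0.99))
  sig_true <- voronoi_sigma(s)
  expect_gt(sig_true, quantile(b1$sigma, 0.01, na.rm = TRUE))
  expect_lt(sig_true, quantile(b1$sigma, 0.99, na.rm = TRUE))
})

test_that("bandwidth limits behave as uniform and co-locating extremes", {
  s <- clustered_set(4, 4, field = 1000)
  wide <- degrade_set(s, degradation_params(0, 200, bandwidth = 3000,
                                            s = 0, seed = 8))
  added <- wide$defects[-seq_len(16), ]
  # near-uniform additions: quadrant counts roughly equal
  qx <- added$x > 500
  qy <- added$y > 500
  counts <- table(qx, qy)
  expect_gt(min(counts), 200 / 4 * 0.5)
  tight <- degrade_set(s, degradation_params(0, 50, bandwidth = 1,
                                             s = 0, seed = 9))
  added_t <- tight$defects[-seq_len(16), ]
  d2 <- sapply(seq_len(nrow(added_t)), function(i) {
    min((s$defects$x - added_t$x[i])^2 + (s$defects$y - added_t$y[i])^2)
  })
  expect_lt(max(sqrt(d2)), 10)
})
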
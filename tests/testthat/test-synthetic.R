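test_that("point processes hit their target densities and regimes", {
  ns <- sapply(1:30, function(i) {
    n_defects(sample_point_process(
      point_process_params("poisson", 10.75, seed = i)))
  })
  expect_lt(abs(mean(ns) - 172), 3 * sqrt(172 / 30) + 1)
  suppressWarnings(
    s <- sample_point_process(point_process_params("poisson", 1e-3, seed = 1),
                              500, 500))
  expect_lte(n_defects(s), 1)
  expect_identical(
    sample_point_process(point_process_params("thomas", 9, mean_offspring = 4,
                                              spread = 100, seed = 5))$defects,
    sample_point_process(point_process_params("thomas", 9, mean_offspring = 4,
                                              spread = 100, seed = 5))$defects)
  hc <- sample_point_process(point_process_params("poisson", 10, min_sep = 40,
                                                  seed = 3), 2000, 2000)
  expect_gt(min(dist(hc$defects[, c("x", "y")])), 40)
})

test_that("surface presets emulate the annotated density and sigma regimes", {
  for (k in 1:3) {
    p <- surface_preset(k)
    stats <- sapply(1:12, function(i) {
      p$seed <- 300 + 20 * k + i
      s <- sample_point_process(p)
      c(defect_density(s), voronoi_sigma(s))
    })
    expect_gt(mean(stats[1, ]), 6 * 0.85)
    expect_lt(mean(stats[1, ]), 11 * 1.15)
    expect_gt(mean(stats[2, ]), 0.7)
    expect_lt(mean(stats[2, ]), 1.35)
  }
  expect_error(surface_preset(4), "surface")
})

test_that("rendered images have pits where the defects are", {
  flat <- render_afm_image(
    defect_set(numeric(), numeric(), 500, 500),
    image_render_params(pixel_size = 3.90625 * 2, roughness_amp = 0,
                        scanline_amp = 0))
  expect_equal(max(flat) - min(flat), 0)
  one <- render_afm_image(
    defect_set(200, 300, 500, 500),
    image_render_params(pixel_size = 3.90625 * 2, roughness_amp = 0,
                        scanline_amp = 0))
  idx <- which(one == min(one), arr.ind = TRUE)
  px <- 3.90625 * 2
  expect_lt(abs((idx[1, 2] - 0.5) * px - 200), px)
  expect_lt(abs((idx[1, 1] - 0.5) * px - 300), px)
  expect_error(render_afm_image(defect_set(100, 100, 500, 500),
                                image_render_params(pixel_size = 3)),
               "integral")
})

test_that("the blob detector closes the loop on rendered defects", {
  s <- uniform_set(50, 2000, 2000, seed = 71, min_sep = 120)
  img <- render_afm_image(s, image_render_params(roughness_amp = 0,
                                                 scanline_amp = 0))
  det <- detect_blobs(img)
  met <- accuracy_metrics(match_defects(s, det), s, det)
  expect_equal(met$precision, 1)
  expect_equal(met$recall, 1)
  # with low noise the count stays within 5%
  img_n <- render_afm_image(s, image_render_params(roughness_amp = 0.05,
                                                   seed = 72))
  det_n <- detect_blobs(img_n)
  expect_lte(abs(n_defects(det_n) - 50) / 50, 0.05)
})

test_that("pure noise yields at most a couple of false positives", {
  empty <- defect_set(numeric(), numeric(), 2000, 2000)
  fps <- sapply(1:4, function(i) {
    img <- render_afm_image(empty, image_render_params(seed = 80 + i))
    n_defects(detect_blobs(img))
  })
  expect_lte(mean(fps), 2)
  expect_warning(
    detect_blobs(matrix(1, 64, 64), pixel_size = 10), "constant")
})

test_that("clustered pits are harder to resolve than spread-out ones", {
  n_cl <- 36
  th <- sample_point_process(point_process_params("thomas", 9,
                                                  mean_offspring = 6,
                                                  spread = 50, seed = 73),
                             2000, 2000)
  po <- uniform_set(n_defects(th), 2000, 2000, seed = 74, min_sep = 80)
  rp <- image_render_params(roughness_amp = 0, scanline_amp = 0)
  rec <- function(s) {
    det <- detect_blobs(render_afm_image(s, rp))
    accuracy_metrics(match_defects(s, det), s, det)$recall
  }
  expect_lt(rec(th), rec(po))
})

test_that("TIFF export writes a recoverable calibrated image", {
  skip_if_not_installed("tiff")
  s <- uniform_set(5, 500, 500, seed = 75, min_sep = 100)
  img <- render_afm_image(s, image_render_params(pixel_size = 3.90625 * 2,
                                                 seed = 1))
  p <- file.path(tempdir(), "afm.tiff")
  write_afm_tiff(img, p)
  meta <- yaml::read_yaml(paste0(p, ".yaml"))
  back <- tiff::readTIFF(p) * meta$height_scale_nm + meta$height_offset_nm
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), meta$height_scale_nm / 2^15)
})
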
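test_that("a defect-free membrane is the exact series-capacitor limit", {
  fg <- frequency_grid(1, 1e4, 5)
  sp <- model_spectrum(defect_set(numeric(), numeric(), 2000, 2000),
                       membrane_params(r_def = 5), fg)
  cs <- 0.8e-6 * 9.0e-6 / (0.8e-6 + 9.0e-6)
  expect_equal(sp$admittance, complex(real = 0, imaginary = 2 * pi * fg * cs))
  expect_true(all(abs(sp$phase_deg - 90) < 1e-9))
  expect_error(spectral_features(sp), "interior")
})

test_that("admittance does not depend on the drive amplitude", {
  s <- uniform_set(8, 1000, 1000, seed = 51, min_sep = 80)
  fg <- c(10, 100, 1000)
  a <- model_spectrum(s, membrane_params(r_def = 5, u0 = 1), fg, coarse_ctrl())
  b <- model_spectrum(s, membrane_params(r_def = 5, u0 = 3.7), fg, coarse_ctrl())
  expect_equal(a$admittance, b$admittance, tolerance = 1e-10)
})

test_that("modeled spectra are passive with phase in [0, 90] degrees", {
  fg <- coarse_fg()
  sets <- list(
    uniform_set(12, 1500, 1500, seed = 52, min_sep = 60),
    clustered_set(4, 3, field = 1500, cluster_spacing = 40)
  )
  for (s in sets) {
    sp <- model_spectrum(s, membrane_params(r_def = 5), fg, coarse_ctrl())
    expect_true(all(Re(sp$admittance) >= -1e-15))
    expect_true(all(sp$phase_deg >= 0 & sp$phase_deg <= 90 + 1e-9))
    expect_gt(sp$phase_deg[1], 85)          # blocking limit at low f
    n <- length(fg)
    i <- which.min(sp$phase_deg)
    expect_true(all(diff(sp$phase_deg[i:n]) > 0))  # rises back toward 90
  }
})

test_that("raising the submembrane resistance lowers the phase-minimum frequency", {
  s <- uniform_set(10, 1200, 1200, seed = 53, min_sep = 70)
  fg <- coarse_fg()
  f_lo <- spectral_features(model_spectrum(
    s, membrane_params(r_def = 5, rho_sub = 10^4.2), fg, coarse_ctrl()))
  f_hi <- spectral_features(model_spectrum(
    s, membrane_params(r_def = 5, rho_sub = 10^4.8), fg, coarse_ctrl()))
  expect_lt(f_hi$f_min, f_lo$f_min)
})

test_that("clustering shifts the spectral features at equal density", {
  # same N on the same field: 16 spread out vs 16 in four tight clusters
  homog <- lattice_set(4, 1500)
  clust <- clustered_set(4, 4, field = 1500, cluster_spacing = 40)
  fg <- coarse_fg()
  fh <- spectral_features(model_spectrum(homog, membrane_params(r_def = 5),
                                         fg, coarse_ctrl()))
  fc <- spectral_features(model_spectrum(clust, membrane_params(r_def = 5),
                                         fg, coarse_ctrl()))
  moved <- abs(log10(fh$f_min) - log10(fc$f_min)) > 0.03 ||
    abs(fh$argy_min - fc$argy_min) > 1
  expect_true(moved)
})

test_that("overlapping defect disks are refused", {
  s <- defect_set(c(500, 507), c(500, 500), 1000, 1000)
  expect_error(model_spectrum(s, membrane_params(r_def = 5), c(10, 100)),
               "overlap")
})

test_that("a noisy reference keeps the modulus and perturbs only the phase", {
  s <- uniform_set(8, 1000, 1000, seed = 55, min_sep = 80)
  fg <- coarse_fg()
  clean <- model_spectrum(s, membrane_params(r_def = 5), fg, coarse_ctrl())
  noisy <- synth_reference_spectrum(s, membrane_params(r_def = 5), fg,
                                    noise_sd_phase_deg = 0.5, seed = 3,
                                    ctrl = coarse_ctrl())
  expect_equal(Mod(noisy$admittance), Mod(clean$admittance), tolerance = 1e-12)
  expect_gt(sd(noisy$phase_deg - clean$phase_deg), 0.1)
  same <- synth_reference_spectrum(s, membrane_params(r_def = 5), fg,
                                   noise_sd_phase_deg = 0, ctrl = coarse_ctrl())
  expect_equal(same$admittance, clean$admittance)
  # 0.5 degree phase noise moves the extracted minimum by well under 0.05 dec
  shifts <- sapply(1:5, function(i) {
    n <- synth_reference_spectrum(s, membrane_params(r_def = 5), fg,
                                  noise_sd_phase_deg = 0.5, seed = 10 + i,
                                  ctrl = coarse_ctrl())
    abs(log10(spectral_features(n)$f_min) - log10(spectral_features(clean)$f_min))
  })
  expect_lt(mean(shifts), 0.05)
})
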
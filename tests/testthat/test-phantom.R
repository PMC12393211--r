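# Synthetic phantom: B0 field generator, MFG computation by central
# differences, and the complex k-space EPI forward model.

test_that("B0 field generator is reproducible and spans the requested gradients", {
  b0a <- make_b0_field(c(48, 48), seed = 7, gradient_max = 86)
  b0b <- make_b0_field(c(48, 48), seed = 7, gradient_max = 86)
  expect_identical(b0a, b0b)
  expect_false(identical(b0a, make_b0_field(c(48, 48), seed = 8,
                                            gradient_max = 86)))
  expect_equal(make_b0_field(c(16, 16), amplitude = 0, seed = 1),
               matrix(0, 16, 16))
  g <- compute_mfg(b0a)
  expect_equal(max(sqrt(g$Gy_map^2 + g$Gx_map^2)), 86, tolerance = 1e-6)
  expect_error(make_b0_field(c(16, 16)), "seed")
})

test_that("central-difference MFGs are exact for linear and quadratic fields", {
  n <- 16
  dy <- 3.5
  # linear ramp in Hz along rows: slope g_hz Hz/mm -> constant Gy map
  g_hz <- 2
  b0 <- matrix(rep(g_hz * dy * (seq_len(n) - 1), n), n, n)
  g <- compute_mfg(b0, voxel_sizes = c(dy, dy))
  exp_uT <- 2 * pi * g_hz / 267.51e6 * 1e9
  expect_equal(g$Gy_map, matrix(exp_uT, n, n), tolerance = 1e-12)
  expect_equal(g$Gx_map, matrix(0, n, n), tolerance = 1e-12)
  expect_equal(compute_mfg(matrix(5, n, n))$Gy_map, matrix(0, n, n))
  # quadratic field: central differences exact at interior voxels
  yy <- dy * (seq_len(n) - 1)
  b0q <- matrix(rep(0.1 * yy^2, n), n, n)
  gq <- compute_mfg(b0q, voxel_sizes = c(dy, dy))
  inner <- 2:(n - 1)
  analytic <- 2 * pi * 0.2 * yy / 267.51e6 * 1e9
  expect_equal(gq$Gy_map[inner, 5], analytic[inner], tolerance = 1e-9)
  # rad/s input declared as such
  g2 <- compute_mfg(2 * pi * b0, voxel_sizes = c(dy, dy), unit = "rad/s")
  expect_equal(g2$Gy_map, g$Gy_map)
  expect_error(compute_mfg(matrix(1, 2, 5)), "dim")
})

test_that("the reconstruction transform pair is unitary", {
  ro <- phantom_readout(16)
  ln <- echoshift:::.pe_lines(ro, 0)
  y <- (seq_len(16) - 1 - ro$i_center) * ro$dy
  M <- exp(-1i * outer(ln$ky, y))
  expect_equal(Mod(Conj(t(M)) %*% M / 16), diag(16), tolerance = 1e-12)
})

test_that("unshifted phantom reproduces the closed-form signal", {
  tis <- gm_tissue()
  ro <- phantom_readout(32)
  ph <- small_phantom(32)
  img <- forward_epi_acquisition(ph, ro, tau = 24)
  s_true <- ase_signal(24, tis, TE = ro$TE)
  interior <- erode_mask(ph$mask, 2)
  expect_lt(max(abs(Mod(img[interior]) / s_true - 1)), 0.01)
  # far background stays dark
  expect_lt(max(Mod(img[ph$rho == 0])), 0.05 * s_true)
})

test_that("shifted phantom magnitude matches the echo-shift model away from edges", {
  tis <- gm_tissue()
  n <- 64
  ro <- phantom_readout(n)
  for (gy in c(20, 40, 59)) { # up to gamma*Gy/v = 0.2
    ph <- small_phantom(n, gy = gy)
    img <- forward_epi_acquisition(ph, ro, 48)
    pred <- ase_signal_shifted(48, tis, field_state(Gy = gy), ro)
    e <- abs(Mod(img[erode_mask(ph$mask, 3)]) / pred - 1)
    expect_lt(max(e), 0.02)
  }
  ph <- small_phantom(n, k0y = 0.45)
  img <- forward_epi_acquisition(ph, ro, 48)
  pred <- ase_signal_shifted(48, tis, field_state(k0y = 0.45), ro)
  expect_lt(max(abs(Mod(img[erode_mask(ph$mask, 3)]) / pred - 1)), 0.02)
})

test_that("a coherent region's k-space energy sits at the predicted echo line", {
  tis <- gm_tissue()
  ro <- phantom_readout(32)
  gy <- 40
  ph <- small_phantom(32, gy = gy)
  img <- forward_epi_acquisition(ph, ro, 48)
  ln <- echoshift:::.pe_lines(ro, 48)
  y <- (seq_len(32) - 1 - ro$i_center) * ro$dy
  K <- Mod(exp(-1i * outer(ln$ky, y)) %*% img[, ro$i_center + 1])
  te <- tau_eff(48, field_state(Gy = gy), ro)
  i_pred <- ro$i_center + (te - 48) / ro$t_eff_es
  expect_lt(abs((which.max(K) - 1) - i_pred), 1)
})

test_that("k-space noise is reproducible under a fixed seed", {
  tis <- gm_tissue()
  ro <- phantom_readout(16)
  ph <- small_phantom(16)
  a <- forward_epi_acquisition(ph, ro, 12, noise_sd = 0.05, seed = 3)
  b <- forward_epi_acquisition(ph, ro, 12, noise_sd = 0.05, seed = 3)
  d <- forward_epi_acquisition(ph, ro, 12, noise_sd = 0.05, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a, d))
  expect_error(forward_epi_acquisition(ph, ro, 12, noise_sd = 0.05), "seed")
})

test_that("reversed pair is identical without gradients and antisymmetric with them", {
  tis <- gm_tissue()
  ro <- phantom_readout(32)
  ph0 <- small_phantom(32)
  pair0 <- make_reversed_pair(ph0, ro, tau_list = c(0, 48))
  expect_equal(Mod(pair0$fwd$data), Mod(pair0$rev$data), tolerance = 1e-10)
  # ground-truth offsets transform per Gy -> -Gy under reversal
  ph <- small_phantom(32, gy = 30)
  pair <- make_reversed_pair(ph, ro, tau_list = c(48))
  ro_rev <- reverse_pe(ro)
  expect_equal(pair$tau_eff_true[1, 17, 17],
               tau_eff(48, field_state(Gy = 30), ro))
  expect_equal(pair$tau_eff_true_rev[1, 17, 17],
               tau_eff(48, field_state(Gy = 30), ro_rev))
})

test_that("reversed-pair log-ratio follows the linear-regime prediction", {
  tis <- gm_tissue()
  n <- 48
  ro <- phantom_readout(n)
  gy <- 35
  ph <- small_phantom(n, gy = gy)
  pair <- make_reversed_pair(ph, ro, tau_list = c(48))
  lr <- ln_ratio_map(pair$fwd, pair$rev, 48)
  te_f <- tau_eff(48, field_state(Gy = gy), ro)
  te_r <- tau_eff(48, field_state(Gy = gy), reverse_pe(ro))
  pred <- predict_ln_ratio_from_taueff(tis$R2, r2prime(tis), te_f, te_r)
  med <- median(lr[erode_mask(ph$mask, 2)])
  expect_equal(med, pred, tolerance = 0.05)
})

test_that("NIfTI round trip preserves the complex stack and metadata", {
  tis <- gm_tissue()
  ro <- phantom_readout(16)
  st <- acquire_stack(small_phantom(16, gy = 20), ro, tau_list = c(0, 24))
  pre <- file.path(tempdir(), "stack_test")
  write_stack_nifti(st, pre)
  back <- read_stack_nifti(pre, mask = st$mask)
  expect_equal(Mod(back$data), Mod(st$data), tolerance = 1e-6)
  expect_equal(back$tau, st$tau)
  expect_equal(back$readout$t_eff_es, ro$t_eff_es)
  expect_equal(back$pe_direction, st$pe_direction)
  # estimator result is unchanged through the file round trip
  e1 <- estimate_tau_eff(st, 24)
  e2 <- estimate_tau_eff(back, 24)
  expect_equal(e1$i_min, e2$i_min)
  unlink(paste0(pre, c("_mag.nii", "_phase.nii", ".json")))
})

test_that("trajectory CSV round trip is lossless", {
  tr <- ase_trajectory(gm_tissue(), gm_readout(), field_state(Gy = 30),
                       tau = default_tau_grid(101))
  p <- file.path(tempdir(), "traj.csv")
  write_trajectory_csv(tr, p)
  back <- read_trajectory_csv(p)
  expect_equal(back$signal, tr$signal, tolerance = 1e-12)
  expect_equal(back$dropout, tr$dropout)
  unlink(p)
})
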
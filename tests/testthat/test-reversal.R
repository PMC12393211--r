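# Reversal analysis: log-ratio maps, Theil-Sen regression, slope-vs-tau
# tables, and the mitigation operators.

test_that("log-ratio map identities and exclusions", {
  ro <- phantom_readout(32)
  ph <- small_phantom(32, gy = 25)
  st <- acquire_stack(ph, ro, tau_list = c(48))
  expect_equal(ln_ratio_map(st, st, 48)[ph$mask], rep(0, sum(ph$mask)))
  pair <- make_reversed_pair(ph, ro, tau_list = c(48))
  lr <- ln_ratio_map(pair$fwd, pair$rev, 48)
  lr_swap <- ln_ratio_map(pair$rev, pair$fwd, 48)
  expect_equal(lr_swap, -lr)
  expect_true(all(is.na(lr[ph$rho == 0][Mod(pair$fwd$data[1, , ])[ph$rho == 0] == 0])))
  st16 <- acquire_stack(small_phantom(16, gy = 25), phantom_readout(16),
                        tau_list = c(48))
  expect_error(ln_ratio_map(pair$fwd, st16, 48), "mismatch")
})

test_that("Theil-Sen recovers exact lines and resists gross outliers", {
  x <- seq_len(50)
  f <- theil_sen_fit(x, 2 * x + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_true(f$ci_low <= f$slope && f$slope <= f$ci_high)
  # brute-force all-pairs oracle on small n
  set.seed(11)
  xs <- rnorm(40)
  ys <- 1.7 * xs + rnorm(40, sd = 0.3)
  sl <- outer(ys, ys, "-") / outer(xs, xs, "-")
  oracle <- median(sl[upper.tri(sl)][is.finite(sl[upper.tri(sl)])])
  expect_equal(theil_sen_fit(xs, ys)$slope, oracle, tolerance = 1e-12)
  # 30% gross outliers on a known line
  set.seed(12)
  n <- 200
  x2 <- runif(n, 0, 10)
  y2 <- -3 * x2 + 0.5
  idx <- sample(n, 60)
  y2[idx] <- y2[idx] + rnorm(60, 20, 10)
  expect_equal(theil_sen_fit(x2, y2)$slope, -3, tolerance = 0.05)
  expect_error(theil_sen_fit(rep(1, 10), rnorm(10)), "degenerate")
  expect_error(theil_sen_fit(1:2, 1:2), "at least 3")
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "slope"], 2)
})

test_that("subsampled Theil-Sen approximates the exact estimate", {
  set.seed(5)
  n <- 500
  x <- runif(n)
  y <- 4 * x + rnorm(n, sd = 0.5)
  exact <- theil_sen_fit(x, y)
  sub <- theil_sen_fit(x, y, n_exact = 100, max_pairs = 4e4, seed = 9)
  expect_false(sub$exact)
  expect_equal(sub$slope, exact$slope, tolerance = 0.05)
})

test_that("noiseless phantom regression recovers -(R2' + R2)", {
  tis <- gm_tissue()
  n <- 64
  ro <- phantom_readout(n)
  gmax <- 0.15 * ro$v / (267.51e6 * 1e-12)
  gy_map <- matrix(seq(-gmax, gmax, length.out = n), n, n, byrow = TRUE)
  ph <- small_phantom(n, gy = gy_map)
  pair <- make_reversed_pair(ph, ro, tau_list = c(36, 48))
  for (tau in c(36, 48)) {
    lr <- ln_ratio_map(pair$fwd, pair$rev, tau)
    ef <- estimate_tau_eff(pair$fwd, tau)
    er <- estimate_tau_eff(pair$rev, tau)
    dd <- tau_eff_difference(ef, er)
    keep <- erode_mask(ph$mask, 2) & dd$reliable & is.finite(lr)
    ts <- theil_sen_fit(dd$diff[keep], lr[keep])
    pred <- -(r2prime(tis) + tis$R2) * 1e-3 # per ms
    expect_equal(ts$slope, pred, tolerance = 0.05)
  }
})

test_that("slope table shows tau-proportional Gy slopes that shrink with velocity", {
  tis <- gm_tissue()
  n <- 48
  ro <- phantom_readout(n)
  gmax <- 0.12 * ro$v / (267.51e6 * 1e-12)
  gy_map <- matrix(seq(-gmax, gmax, length.out = n), n, n, byrow = TRUE)
  ph <- small_phantom(n, gy = gy_map)
  taus <- c(0, 24, 48)
  pair <- make_reversed_pair(ph, ro, tau_list = taus)
  tab <- slope_vs_tau_table(pair$fwd, pair$rev, gy_map = gy_map)
  expect_s3_class(tab, "slope_table")
  expect_true(all(tab$ci_low <= tab$slope & tab$slope <= tab$ci_high))
  g <- dplyr::filter(tab, x_label == "Gy")
  expect_equal(nrow(g), 3)
  # near zero at tau = 0, then growing proportionally to tau
  pred48 <- predict_ln_ratio_from_gy(tis$R2, r2prime(tis), 48, 1, ro$v)
  expect_lt(abs(g$slope[g$tau == 0]), 0.1 * abs(pred48))
  expect_equal(g$slope[g$tau == 48], pred48, tolerance = 0.05)
  expect_equal(g$slope[g$tau == 48] / g$slope[g$tau == 24], 2,
               tolerance = 0.1)
  # doubled k-space velocity (halved echo spacing) halves the slope
  ro2 <- phantom_readout(n, t_eff_es = ro$t_eff_es / 2)
  pair2 <- make_reversed_pair(ph, ro2, tau_list = c(48))
  tab2 <- slope_vs_tau_table(pair2$fwd, pair2$rev, gy_map = gy_map,
                             taus = c(48))
  g2 <- dplyr::filter(tab2, x_label == "Gy")
  expect_equal(g2$slope / g$slope[g$tau == 48], 0.5, tolerance = 0.1)
})

test_that("geometric mean of a reversed pair cancels the shift to first order", {
  tis <- gm_tissue()
  n <- 32
  ro <- phantom_readout(n)
  # identical pair: combination equals either input
  p0 <- make_reversed_pair(small_phantom(n), ro, tau_list = c(48))
  gm0 <- geometric_mean_combine(p0$fwd, p0$rev)
  expect_equal(gm0, Mod(p0$fwd$data), tolerance = 1e-8)
  # symmetric in its arguments
  ph <- small_phantom(n, gy = 20)
  pr <- make_reversed_pair(ph, ro, tau_list = c(48))
  expect_equal(geometric_mean_combine(pr$fwd, pr$rev),
               geometric_mean_combine(pr$rev, pr$fwd))
  # residual vs unshifted scales quadratically: halving Gy quarters it
  s_ref <- ase_signal(48, tis, TE = ro$TE)
  resid <- vapply(c(40, 20), function(gy) {
    p <- make_reversed_pair(small_phantom(n, gy = gy), ro, tau_list = c(48))
    gm <- geometric_mean_combine(p$fwd, p$rev)
    core <- erode_mask(ph$mask, 3)
    abs(median(gm[1, , ][core]) / s_ref - 1)
  }, numeric(1))
  expect_equal(resid[1] / resid[2], 4, tolerance = 0.35)
})

test_that("closed-form geometric-mean residual is second order in the gradient", {
  # trajectory-level check, free of discretisation: slope of log residual
  # vs log Gy equals 2
  tis <- gm_tissue()
  ro <- gm_readout()
  s0 <- ase_signal(48, tis, TE = ro$TE)
  gys <- c(5, 10, 20, 40)
  res <- vapply(gys, function(gy) {
    sf <- ase_signal_shifted(48, tis, field_state(Gy = gy), ro)
    sr <- ase_signal_shifted(48, tis, field_state(Gy = gy), reverse_pe(ro))
    abs(sqrt(sf * sr) / s0 - 1)
  }, numeric(1))
  fitsl <- coef(lm(log(res) ~ log(gys)))[2]
  expect_equal(unname(fitsl), 2, tolerance = 0.05)
})

test_that("RMS combination of y-shimmed trajectories behaves like the model", {
  tis <- gm_tissue()
  ro <- gm_readout()
  tau <- default_tau_grid(2001)
  k0s <- seq(-0.9, 0.9, length.out = 11)
  trajs <- lapply(k0s, function(k0)
    ase_trajectory(tis, ro, field_state(k0y = k0), tau = tau))
  rms <- rms_combine(trajs)
  # identical trajectories: unchanged
  same <- rms_combine(list(trajs[[6]], trajs[[6]]))
  expect_equal(same$signal, trajs[[6]]$signal)
  # a +/-k0y pair without R2 decay gives an even RMS trajectory (with R2
  # the contamination term breaks the symmetry -- that is the point of the
  # echo-shift model)
  tis0 <- gm_tissue(R2 = 0)
  tr_p <- ase_trajectory(tis0, ro, field_state(k0y = 0.9), tau = tau)
  tr_m <- ase_trajectory(tis0, ro, field_state(k0y = -0.9), tau = tau)
  pairst <- rms_combine(list(tr_p, tr_m))
  mid <- which.min(abs(tau))
  expect_equal(pairst$signal[mid + 100], pairst$signal[mid - 100],
               tolerance = 1e-10)
  # the 11-trajectory combination exceeds the unshifted curve at tau = 20 ms
  i20 <- which.min(abs(tau - 20))
  expect_gt(rms$signal[i20], trajs[[6]]$signal[i20])
  expect_error(rms_combine(list(trajs[[1]])), "length")
  short <- ase_trajectory(tis, ro, tau = default_tau_grid(101))
  expect_error(rms_combine(list(trajs[[1]], short)), "common tau grid")
})
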
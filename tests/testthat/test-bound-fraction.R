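test_that("corrected axial thickness evaluates the printed calibration", {
  expect_equal(corrected_dz(0), 0.700 + 0.20811)
  expect_equal(corrected_dz(4), 0.700 + 0.15716 * 2 + 0.20811)
  # monotone non-decreasing in D
  d <- seq(0, 20, length.out = 50)
  expect_true(all(diff(corrected_dz(d)) >= 0))
})

test_that("defocus factor has the correct limits and monotonicity", {
  expect_identical(z_corr(0, 0.0045), 1)
  # raw absorbing-slab model: everything diffuses out at very large D
  expect_lt(z_corr(1e6, 0.0045, corrected = FALSE), 0.01)
  # corrected model: the sqrt(D)-growing effective slab keeps a small floor
  expect_lt(z_corr(1e6, 0.0045), 0.2)
  grid_d <- c(0.2, 0.5, 1, 2, 5, 10, 20)
  grid_t <- c(0.0045, 0.009, 0.0135, 0.0225, 0.0315)
  vals <- outer(grid_d, grid_t, Vectorize(function(d, t) z_corr(d, t)))
  expect_true(all(vals >= 0 & vals <= 1))
  expect_true(all(apply(vals, 2, diff) <= 1e-12))  # decreasing in D
  expect_true(all(apply(vals, 1, diff) <= 1e-12))  # decreasing in lag
})

test_that("defocus factor agrees with the Monte-Carlo absorption oracle", {
  mc <- z_corr_mc(2, 0.0135, n_paths = 4e4, n_steps = 150, seed = 3)
  expect_lt(abs(z_corr(2, 0.0135) - mc) / mc, 0.015)
})

test_that("discrete defocus survival matches the simulator's per-lag stay probability", {
  # free-only molecules, no bleaching: the fraction of in-slice detections
  # still detected at every one of the next k frames is the transfer-
  # operator survival
  p <- kinetic_params(2, 2, 0, 0, sigma_loc = 0, k_photobleach = 0)
  acq <- acquisition_settings(n_frames = 120)
  trk <- simulate_two_state_tracks(p, acq, 15000, seed = 12)
  df <- as.data.frame(trk)
  df <- df[order(df$particle, df$frame), ]
  n <- nrow(df)
  run <- cumsum(c(TRUE, df$particle[-1] != df$particle[-n] | diff(df$frame) != 1L))
  pred <- defocus_survival(2, 0.0045, 7)
  for (k in c(1, 4, 7)) {
    i <- seq_len(n - k)
    ok <- run[i] == run[i + k]
    denom <- sum(df$frame <= max(df$frame) - k)
    emp <- sum(ok) / denom
    se <- sqrt(emp * (1 - emp) / denom)
    expect_lt(abs(emp - pred[k]), max(4 * se, 0.01))
  }
})

test_that("jump histograms pool displacements at exact frame lags", {
  # one two-point track with displacement 0.1 um
  df <- data.frame(trajectory_id = c(0, 0), frame = c(0, 1),
                   x_um = c(0, 0.1), y_um = c(0, 0))
  trk <- trajectory_set(df, 0.0045)
  h <- jump_histogram(trk, lags = 1)
  expect_equal(h[["1"]]$n_jumps, 1)
  expect_equal(sum(h[["1"]]$counts[h[["1"]]$mid > 0.09 & h[["1"]]$mid < 0.11]), 1)
  # static particles: all mass in the first bin
  df2 <- data.frame(trajectory_id = rep(1:3, each = 5),
                    frame = rep(0:4, 3), x_um = 1, y_um = 2)
  h2 <- jump_histogram(trajectory_set(df2, 0.0045), lags = c(1, 2))
  for (lag in c("1", "2")) {
    expect_equal(h2[[lag]]$counts[1], h2[[lag]]$n_jumps)
  }
  # pairs spanning a blink gap are skipped: only (0,1) and (3,4) count at
  # lag 1, and the gap-spanning lag-2 pair (1,3) leaves that lag empty
  df3 <- data.frame(trajectory_id = 0, frame = c(0, 1, 3, 4),
                    x_um = 0:3, y_um = 0)
  expect_warning(
    h3 <- jump_histogram(trajectory_set(df3, 0.0045), lags = c(1, 2)),
    "lag 2")
  expect_equal(h3[["1"]]$n_jumps, 2)
  expect_null(h3[["2"]])
  # per-lag density integrates to 1
  trk4 <- simulate_two_state_tracks(kinetics_for_fb(0.3), fast_acq(60), 300,
                                    seed = 4)
  h4 <- jump_histogram(trk4, 1:3)
  for (hh in h4)
    expect_equal(sum(hh$density) * attr(h4, "bin_width"), 1, tolerance = 1e-9)
})

test_that("per-lag mean squared jump matches 4(D dtau + sigma^2)", {
  p <- kinetic_params(2, 2, 0, 0, sigma_loc = 0.035, k_photobleach = 0)
  acq <- acquisition_settings(n_frames = 80, slice_half_width = 4,
                              cell_half_depth = 4)
  trk <- simulate_two_state_tracks(p, acq, 1200, seed = 5)
  df <- as.data.frame(trk)
  for (k in 1:3) {
    i <- seq_len(nrow(df) - k)
    ok <- df$particle[i + k] == df$particle[i] & df$frame[i + k] - df$frame[i] == k
    r2 <- ((df$x_um[i + k] - df$x_um[i])^2 + (df$y_um[i + k] - df$y_um[i])^2)[ok]
    expected <- 4 * (2 * k * 0.0045 + 0.035^2)
    # overlapping pairs within a particle are correlated: aggregate per
    # particle before forming the standard error
    pp <- tapply(r2, df$particle[i][ok], mean)
    expect_lt(abs(mean(pp) - expected), 3 * sd(pp) / sqrt(length(pp)))
  }
})

test_that("two-state model density has the Rayleigh structure", {
  # zero at r = 0
  expect_equal(two_state_density(0, 0.0045, 0.3, 2, 0.01), 0)
  # pure bound component peaks at sqrt(2 (D_B dtau + sigma^2))
  dtau <- 0.009; db <- 0.02; sg <- 0.035
  peak <- optimize(function(r) two_state_density(r, dtau, 1, 2, db, sg),
                   c(0, 0.5), maximum = TRUE, tol = 1e-9)$maximum
  expect_equal(peak, sqrt(2 * (db * dtau + sg^2)), tolerance = 1e-5)
  # raw model integrates to F + Zcorr (1 - F); normalized to 1
  for (f in c(0, 0.31, 0.8, 1)) {
    zc <- z_corr(2.5, dtau)
    raw <- integrate(two_state_density, 0, Inf, delta_tau = dtau, f_bound = f,
                     d_free = 2.5, d_bound = 0.01, sigma = sg,
                     rel.tol = 1e-9)$value
    expect_equal(raw, f + zc * (1 - f), tolerance = 1e-6)
    norm <- integrate(two_state_density, 0, Inf, delta_tau = dtau, f_bound = f,
                      d_free = 2.5, d_bound = 0.01, sigma = sg,
                      normalize = TRUE, rel.tol = 1e-9)$value
    expect_equal(norm, 1, tolerance = 1e-6)
  }
})

test_that("two-state fit recovers simulated parameters", {
  fb <- 0.309
  trk <- simulate_fast_tracking_cells(kinetics_for_fb(fb), fast_acq(120),
                                      n_cells = 4, particles_per_cell = 900,
                                      seed = 6)
  h <- jump_histogram(trk, 1:7)
  fit <- fit_two_state(h)
  expect_true(fit$converged)
  expect_lt(abs(fit$f_bound - fb), 0.05)
  expect_lt(abs(fit$d_free - 2) / 2, 0.15)
  # all-bound boundary: f_bound pinned near 1
  pb <- kinetic_params(2, 0.01, 1, 0, sigma_loc = 0.035, k_photobleach = 1)
  trk_b <- simulate_two_state_tracks(pb, fast_acq(120), 600, seed = 7)
  fit_b <- fit_two_state(jump_histogram(trk_b, 1:3))
  expect_gte(fit_b$f_bound, 0.97)
})

test_that("fit is stable under histogram bin-width halving", {
  trk <- simulate_fast_tracking_cells(kinetics_for_fb(0.3), fast_acq(120),
                                      n_cells = 4, particles_per_cell = 800,
                                      seed = 8)
  f1 <- fit_two_state(jump_histogram(trk, 1:5, bin_width = 0.01))$f_bound
  f2 <- fit_two_state(jump_histogram(trk, 1:5, bin_width = 0.005))$f_bound
  expect_lt(abs(f1 - f2), 0.01)
})
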
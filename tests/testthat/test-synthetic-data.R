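test_that("parameter containers enforce their invariants", {
  expect_error(kinetic_params(1, 2, 0.1, 0.1), "d_free")
  expect_error(kinetic_params(-1, 0, 0.1, 0.1), "finite")
  expect_error(acquisition_settings(frame_interval = 0), "frame_interval")
  expect_error(acquisition_settings(exposure = 0.01, frame_interval = 0.0045),
               "exposure")
  p <- kinetic_params(2, 0.01, 0.036, 0.08)
  expect_equal(stationary_bound_fraction(p), 0.036 / (0.036 + 0.08))
  expect_equal(stationary_bound_fraction(kinetic_params(1, 0, 0, 0)), 0)
})

test_that("zero motion and zero noise give exactly zero jumps", {
  p <- kinetic_params(0, 0, 0.5, 0.5, sigma_loc = 0, k_photobleach = 0)
  acq <- fast_acq(n_frames = 20)
  trk <- simulate_two_state_tracks(p, acq, 30, seed = 1)
  sp <- split(as.data.frame(trk), trk$trajectory_id)
  for (d in sp) {
    expect_true(all(diff(d$x_um) == 0))
    expect_true(all(diff(d$y_um) == 0))
  }
})

test_that("simulated state occupancy matches the stationary bound fraction", {
  fb <- 0.309
  p <- kinetics_for_fb(fb, k_off = 0.5, k_pb = 0)
  # slice covering the whole cell: every frame of every particle is recorded
  acq <- acquisition_settings(n_frames = 50, slice_half_width = 4,
                              cell_half_depth = 4)
  trk <- simulate_two_state_tracks(p, acq, 1500, seed = 42)
  per_particle <- tapply(trk$true_state == "bound", trk$particle, mean)
  est <- mean(per_particle)
  se <- sd(per_particle) / sqrt(length(per_particle))
  expect_lt(abs(est - fb), 3 * se + 1e-12)
})

test_that("free diffusion reproduces the analytic mean squared jump", {
  # closed form: E[r^2] = 4 D dtau + 4 sigma^2
  p <- kinetic_params(2, 2, 0, 0, sigma_loc = 0.035, k_photobleach = 0)
  acq <- acquisition_settings(n_frames = 60, slice_half_width = 4,
                              cell_half_depth = 4)
  trk <- simulate_two_state_tracks(p, acq, 2500, seed = 7)
  df <- as.data.frame(trk)
  df <- df[order(df$particle, df$frame), ]
  i <- which(diff(df$particle) == 0 & diff(df$frame) == 1)
  r2 <- (df$x_um[i + 1] - df$x_um[i])^2 + (df$y_um[i + 1] - df$y_um[i])^2
  expect_gt(length(r2), 1e5)
  expected <- 4 * 2 * 0.0045 + 4 * 0.035^2  # 0.0409
  # per-particle aggregation: overlapping jumps share endpoints
  pp <- tapply(r2, df$particle[i], mean)
  expect_lt(abs(mean(pp) - expected), 3 * sd(pp) / sqrt(length(pp)))
})

test_that("jump lengths of free-only motion follow the Rayleigh law", {
  p <- kinetic_params(1, 1, 0, 0, sigma_loc = 0.02, k_photobleach = 0)
  acq <- acquisition_settings(n_frames = 60, slice_half_width = 4,
                              cell_half_depth = 4)
  trk <- simulate_two_state_tracks(p, acq, 2500, seed = 8)
  df <- as.data.frame(trk)
  i <- which(diff(df$particle) == 0 & diff(df$frame) == 1)
  r <- sqrt((df$x_um[i + 1] - df$x_um[i])^2 + (df$y_um[i + 1] - df$y_um[i])^2)
  s2 <- 2 * (1 * 0.0045 + 0.02^2)      # Rayleigh scale^2
  edges <- c(seq(0, 0.4, by = 0.02), Inf)
  counts <- tabulate(findInterval(r, edges), nbins = length(edges) - 1)
  probs <- diff(1 - exp(-edges^2 / (2 * s2)))
  keep <- probs * length(r) >= 5
  if (any(!keep)) {
    counts <- c(counts[keep], sum(counts[!keep]))
    probs <- c(probs[keep], sum(probs[!keep]))
  }
  p_val <- suppressWarnings(chisq.test(counts, p = probs / sum(probs))$p.value)
  expect_gt(p_val, 0.001)
})

test_that("track survival of a no-unbinding species is exponential in the bleach rate", {
  k_pb <- 2
  p <- kinetic_params(0.01, 0.01, 1, 0, sigma_loc = 0, k_photobleach = k_pb)
  acq <- acquisition_settings(n_frames = 400, slice_half_width = 4,
                              cell_half_depth = 4)
  trk <- simulate_two_state_tracks(p, acq, 4000, seed = 9)
  # all-bound, whole-cell slice: one trajectory per particle, length = frames
  # survived; survival of the track length is geometric ~ Exp(k_pb) on frames
  len <- track_lengths(trk)$dwell_s
  expect_gt(dwell_gof_p(len, k_pb, 0.0045, type = "ceiling"), 0.01)
})

test_that("dwell-time generator matches its exponential-mixture construction", {
  acq <- slow_acq()
  # pure specific component, no bleaching: Exp(k_s)
  dw <- simulate_slow_tracking_dwells(0, 1, 0.2, 0, acq, 5000, seed = 1)
  expect_gt(dwell_gof_p(dw$dwell_s, 0.2, 0.5), 0.01)
  expect_true(all(!dw$censored))
  # minimum of independent exponentials: Exp(k_s + k_pb)
  dw2 <- simulate_slow_tracking_dwells(0, 1, 0.2, 0.1, acq, 5000, seed = 2)
  expect_gt(dwell_gof_p(dw2$dwell_s, 0.3, 0.5), 0.01)
  expect_gt(mean(dw2$censored), 0.2)  # bleaching censors 1/3 of events
  # identifiability guard and invariants
  expect_error(simulate_slow_tracking_dwells(0.5, 0.1, 0.2, 0, acq, 10),
               "identifiable")
  expect_true(all(dw$dwell_s >= 0.5))
  expect_true(all(abs(dw$dwell_s / 0.5 - round(dw$dwell_s / 0.5)) < 1e-9))
})

test_that("noiseless FRAP curve crosses 90% of plateau at ln(10)/k", {
  k <- 0.7
  gt <- frap_ground_truth(k = k, recovered_fraction = 1, noise_sd = 0,
                          duration_s = 60)
  raw <- simulate_frap_curve(gt, seed = 1)
  # analytic inversion on the raw generator output (spot relative to 1)
  post <- raw[raw$time_s >= 5, ]
  t90 <- post$time_s[min(which(post$spot - 0.05 >= 0.9))] - 5
  expect_lte(abs(t90 - log(10) / k), 1)   # within one 1-Hz frame
  # A = 0: flat post-bleach at the bleach floor
  raw0 <- simulate_frap_curve(frap_ground_truth(k = 1, recovered_fraction = 0,
                                                noise_sd = 0), seed = 1)
  expect_true(all(abs(raw0$spot[raw0$time_s >= 5] - 0.05) < 1e-12))
})

test_that("rendered image pairs have the prescribed intensity structure", {
  # rho = 1: TF statistically uniform inside vs outside the chromosome region
  sp1 <- cell_render_spec(rho = 1, photon_budget = 500)
  pr1 <- render_cell_image_pair(sp1, seed = 1)
  inside <- pr1$tf[pr1$chrom_mask]
  outside <- pr1$tf[pr1$cell_mask & !pr1$chrom_mask]
  se <- sqrt(var(inside) / length(inside) + var(outside) / length(outside))
  expect_lt(abs(mean(inside) - mean(outside)), 4 * se)
  # analytic ground truth from the geometry
  sp <- cell_render_spec(rho = 2.5)
  alpha <- sum(render_cell_image_pair(sp, seed = 2)$chrom_mask) /
    sum(render_cell_image_pair(sp, seed = 2)$cell_mask)
  expect_equal(true_log2_enrichment(sp),
               log2(2.5 / (alpha * 2.5 + (1 - alpha))))
  # geometry validation
  expect_error(cell_render_spec(chrom_center = c(90, 48)), "inside the cell")
  expect_error(cell_render_spec(cell_axes = c(60, 60)), "image bounds")
  expect_error(cell_render_spec(rho = 0), "rho")
})

test_that("generators are reproducible: identical seed, identical output", {
  p <- kinetics_for_fb(0.3)
  acq <- fast_acq(20)
  expect_identical(simulate_two_state_tracks(p, acq, 50, seed = 5),
                   simulate_two_state_tracks(p, acq, 50, seed = 5))
  expect_identical(simulate_slow_tracking_dwells(0.7, 2, 0.08, 0.05, slow_acq(),
                                                 200, seed = 5),
                   simulate_slow_tracking_dwells(0.7, 2, 0.08, 0.05, slow_acq(),
                                                 200, seed = 5))
  gt <- frap_ground_truth(k = 1, noise_sd = 0.02)
  expect_identical(simulate_frap_curve(gt, seed = 5),
                   simulate_frap_curve(gt, seed = 5))
  sp <- cell_render_spec()
  expect_identical(render_cell_image_pair(sp, seed = 5),
                   render_cell_image_pair(sp, seed = 5))
})
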
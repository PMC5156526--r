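# Shared fixtures: small, fast parameter sets used across test files.

fast_acq <- function(n_frames = 100, ...) {
  acquisition_settings(frame_interval = 0.0045, n_frames = n_frames, ...)
}

slow_acq <- function(n_frames = 200) {
  acquisition_settings(frame_interval = 0.5, n_frames = n_frames)
}

# kinetics with a target stationary bound fraction at a given specific off-rate
kinetics_for_fb <- function(fb, k_off = 0.08, d_free = 2, d_bound = 0.01,
                            sigma = 0.035, k_pb = 8) {
  kinetic_params(d_free, d_bound, k_on_star = k_off * fb / (1 - fb),
                 k_off = k_off, sigma_loc = sigma, k_photobleach = k_pb)
}

# chi-square goodness of fit of frame-quantized durations against an
# exponential(k) null. type "floor1": duration = max(1, floor(T/dt)) * dt
# (the dwell generator); type "ceiling": duration = ceiling(T/dt) * dt
# (track length in frames). The largest observed bin absorbs the tail.
dwell_gof_p <- function(dwell_s, k, dt, type = c("floor1", "ceiling")) {
  type <- match.arg(type)
  j <- round(dwell_s / dt)
  jmax <- max(j)
  jj <- seq_len(jmax)
  if (type == "floor1") {
    probs <- exp(-k * jj * dt) - exp(-k * (jj + 1) * dt)
    probs[1] <- 1 - exp(-2 * k * dt)
    probs[jmax] <- exp(-k * jmax * dt)            # P(dwell >= jmax frames)
  } else {
    probs <- exp(-k * (jj - 1) * dt) - exp(-k * jj * dt)
    probs[jmax] <- exp(-k * (jmax - 1) * dt)      # tail
  }
  counts <- tabulate(j, nbins = jmax)
  keep <- probs * length(dwell_s) >= 5
  if (any(!keep)) {
    counts <- c(counts[keep], sum(counts[!keep]))
    probs <- c(probs[keep], sum(probs[!keep]))
  }
  suppressWarnings(stats::chisq.test(counts, p = probs / sum(probs))$p.value)
}
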
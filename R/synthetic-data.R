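#' Simulate two-state single-particle tracking data
#'
#' Brownian-dynamics simulator of fast single-molecule tracking of a
#' two-state (bound/free) factor. Each particle alternates between the bound
#' and free state with exponential durations (rates `k_off`, `k_on_star`),
#' starting from the stationary state distribution. Per frame interval the
#' 2D displacement per axis is Gaussian with variance integrated piecewise
#' over the states visited within the interval (`2 * sum_i D_i t_i`), so
#' state switches within a frame are handled exactly. The axial position
#' diffuses with the same state-dependent coefficient and reflects at
#' `+/- cell_half_depth`; a localization is emitted only while
#' `|z| <= slice_half_width` (the axial detection slice). Emitted x/y are
#' perturbed by localization noise, particles photobleach permanently with
#' per-frame probability `1 - exp(-k_photobleach * frame_interval)`, and
#' detections separated by at most `blink_max_gap` missed frames share a
#' trajectory id (blinking re-connection).
#'
#' @param params a [kinetic_params()] object.
#' @param acq an [acquisition_settings()] object.
#' @param n_particles number of simulated molecules (>= 1).
#' @param seed integer RNG seed (`NULL` to use the current RNG state).
#' @return A [trajectory_set()] with a `true_state` column
#'   (`"bound"`/`"free"` at the emission time).
#' @export
#' @examples
#' trk <- simulate_two_state_tracks(
#'   kinetic_params(2, 0.01, 0.036, 0.08), acquisition_settings(), 50, seed = 1)
#' head(trk)
simulate_two_state_tracks <- function(params, acq, n_particles, seed = NULL) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(acq, "acquisition_settings"))
  if (n_particles < 1) stop_mk("n_particles must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  df <- sim_two_state_cpp(
    as.integer(n_particles), acq$n_frames, acq$frame_interval,
    params$d_free, params$d_bound, params$k_on_star, params$k_off,
    params$sigma_loc, params$k_photobleach,
    acq$cell_half_depth, acq$slice_half_width, acq$blink_max_gap, acq$fov)
  df$true_state <- ifelse(df$true_state == 1L, "bound", "free")
  trajectory_set(df, acq$frame_interval, source = "simulate_two_state_tracks",
                 seed = seed %||% NA)
}

#' Simulate a multi-cell fast-tracking experiment
#'
#' Convenience wrapper around [simulate_two_state_tracks()]: simulates
#' `n_cells` independent cells with per-cell sub-seeds derived from `seed`
#' and pools the trajectories (with disjoint trajectory ids) into one
#' [trajectory_set()], mirroring how displacement histograms are pooled over
#' cells in a tracking experiment.
#'
#' @inheritParams simulate_two_state_tracks
#' @param n_cells number of cells.
#' @param particles_per_cell simulated molecules per cell.
#' @return A [trajectory_set()].
#' @export
simulate_fast_tracking_cells <- function(params, acq, n_cells = 24,
                                         particles_per_cell = 280,
                                         seed = 1) {
  parts <- vector("list", n_cells)
  offset <- 0L
  for (i in seq_len(n_cells)) {
    trk <- as.data.frame(
      simulate_two_state_tracks(params, acq, particles_per_cell,
                                seed = seed * 1000L + i))
    if (nrow(trk)) {
      trk$trajectory_id <- trk$trajectory_id + offset
      offset <- max(trk$trajectory_id) + 1L
    }
    parts[[i]] <- trk
  }
  trajectory_set(do.call(rbind, parts), acq$frame_interval,
                 source = "simulate_fast_tracking_cells", seed = seed)
}

#' Simulate slow-tracking dwell times
#'
#' Generates observed dwell times for the residence-time stage. At long
#' exposures only bound molecules appear as diffraction-limited spots, so
#' slow-tracking data reduce to per-event dwell durations. Each event draws
#' a true binding duration from the two-exponential mixture
#' `f_ns * Exp(k_ns) + (1 - f_ns) * Exp(k_s)` (non-specific and specific
#' binding) and an independent photobleaching time from
#' `Exp(k_photobleach)`; the observed dwell is the minimum of the two,
#' floored to whole frames with a minimum of one frame.
#'
#' @param f_ns mixture weight of the non-specific (fast) component, in `[0, 1]`.
#' @param k_ns non-specific unbinding rate (1/s); must exceed `k_s`.
#' @param k_s specific unbinding rate (1/s); must be > 0.
#' @param k_photobleach photobleaching rate (1/s); 0 disables bleaching.
#' @param acq an [acquisition_settings()]; only `frame_interval` is used
#'   (0.5 s for 2 Hz slow tracking).
#' @param n_events number of binding events (>= 1).
#' @param seed integer RNG seed.
#' @return A `dwell_sample`: list with `dwell_s` (observed durations),
#'   `censored` (`TRUE` where photobleaching ended the observation) and
#'   `frame_interval`.
#' @export
simulate_slow_tracking_dwells <- function(f_ns, k_ns, k_s, k_photobleach,
                                          acq, n_events, seed = NULL) {
  stopifnot(inherits(acq, "acquisition_settings"))
  if (!(k_ns > k_s) || !(k_s > 0))
    stop_mk("need k_ns > k_s > 0 (got k_ns = %g, k_s = %g): components not identifiable",
            k_ns, k_s)
  if (f_ns < 0 || f_ns > 1) stop_mk("f_ns must be in [0, 1]")
  if (n_events < 1) stop_mk("n_events must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  dt <- acq$frame_interval
  ns <- runif(n_events) < f_ns
  t_bind <- ifelse(ns, rexp(n_events, k_ns), rexp(n_events, k_s))
  t_bleach <- if (k_photobleach > 0) rexp(n_events, k_photobleach) else rep(Inf, n_events)
  obs <- pmin(t_bind, t_bleach)
  dwell <- pmax(1, floor(obs / dt)) * dt
  structure(list(dwell_s = dwell, censored = t_bleach < t_bind,
                 frame_interval = dt),
            class = "dwell_sample")
}

#' @export
print.dwell_sample <- function(x, ...) {
  cat(sprintf("Dwell sample: %d events (dt = %g s, %.1f%% bleach-censored), median %.2f s\n",
              length(x$dwell_s), x$frame_interval, 100 * mean(x$censored),
              median(x$dwell_s)))
  invisible(x)
}

#' Ground truth for a simulated FRAP experiment
#'
#' @param k recovery rate (1/s).
#' @param recovered_fraction mobile (recovered) fraction `A` in `[0, 1]`.
#' @param bleach_depth fraction of the pre-bleach signal removed by the
#'   bleach pulse (1 = bleached to zero).
#' @param noise_sd additive Gaussian noise SD on the intensity columns.
#' @param rate_hz sampling rate (Hz); 1 Hz is typical for confocal FRAP.
#' @param pre_bleach_frames number of frames acquired before the bleach.
#' @param duration_s total movie duration (s).
#' @param acq_bleach_rate slow whole-cell acquisition-bleaching rate (1/s).
#' @return A `frap_ground_truth` object.
#' @export
frap_ground_truth <- function(k, recovered_fraction = 1, bleach_depth = 1,
                              noise_sd = 0, rate_hz = 1, pre_bleach_frames = 5,
                              duration_s = 60, acq_bleach_rate = 0) {
  if (k <= 0) stop_mk("recovery rate k must be > 0")
  if (recovered_fraction < 0 || recovered_fraction > 1)
    stop_mk("recovered_fraction must be in [0, 1]")
  if (noise_sd < 0) stop_mk("noise_sd must be >= 0")
  structure(list(k = k, recovered_fraction = recovered_fraction,
                 bleach_depth = bleach_depth, noise_sd = noise_sd,
                 rate_hz = rate_hz, pre_bleach_frames = as.integer(pre_bleach_frames),
                 duration_s = duration_s, acq_bleach_rate = acq_bleach_rate),
            class = "frap_ground_truth")
}

#' Simulate a FRAP intensity table
#'
#' Produces the raw three-column FRAP record the analysis stage consumes:
#' bleach-spot, whole-cell and background intensities on a uniform time grid.
#' The underlying recovery is saturating-exponential,
#' `spot(t) = 1 - bleach_depth * (1 - A * (1 - exp(-k t)))` relative to the
#' pre-bleach level (so the plateau sits at `A` of the bleached depth);
#' both spot and whole cell decay slowly with the acquisition-bleaching rate,
#' and Gaussian noise is added to the measured columns.
#'
#' @param gt a [frap_ground_truth()].
#' @param seed integer RNG seed.
#' @param background constant background level added to all columns.
#' @return data frame with `time_s`, `spot`, `whole_cell`, `background`.
#' @export
simulate_frap_curve <- function(gt, seed = NULL, background = 0.05) {
  stopifnot(inherits(gt, "frap_ground_truth"))
  if (!is.null(seed)) set.seed(seed)
  dt <- 1 / gt$rate_hz
  time_s <- seq(0, gt$duration_s, by = dt)
  n <- length(time_s)
  t_bleach <- gt$pre_bleach_frames * dt
  rel <- ifelse(time_s < t_bleach, 1,
                1 - gt$bleach_depth *
                  (1 - gt$recovered_fraction *
                     (1 - exp(-gt$k * (time_s - t_bleach)))))
  decay <- exp(-gt$acq_bleach_rate * time_s)
  spot <- background + rel * decay + rnorm(n, 0, gt$noise_sd)
  whole <- background + decay + rnorm(n, 0, gt$noise_sd)
  data.frame(time_s = time_s, spot = spot, whole_cell = whole,
             background = rep(background, n))
}

#' Rendering specification for a synthetic two-channel cell image
#'
#' Geometry and intensity model for a synthetic mitotic cell: an elliptical
#' cell region containing an elliptical chromosome region, an H2B channel
#' bright on chromosomes, and a TF channel whose mean intensity on
#' chromosomes is `rho`-fold the mean off-chromosome (within-cell) level.
#'
#' @param size_px image side length in pixels (square image).
#' @param pixel_size_um pixel size (um).
#' @param cell_center,cell_axes ellipse center and semi-axes of the cell, px.
#' @param chrom_center,chrom_axes ellipse center and semi-axes of the
#'   chromosome region, px; must lie strictly inside the cell and the image.
#' @param rho true TF intensity ratio on vs off chromosomes (> 0).
#' @param photon_budget expected photons per pixel for the off-chromosome TF
#'   signal; Poisson noise is applied at this budget.
#' @param background expected background photons per pixel outside the cell
#'   (added everywhere).
#' @param noise `"poisson"` or `"none"`.
#' @return A `cell_render_spec` object.
#' @export
cell_render_spec <- function(size_px = 96, pixel_size_um = 0.2,
                             cell_center = c(48, 48), cell_axes = c(40, 36),
                             chrom_center = c(44, 50), chrom_axes = c(22, 15),
                             rho = 2, photon_budget = 1000, background = 10,
                             noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  if (rho <= 0) stop_mk("rho must be > 0")
  if (photon_budget <= 0) stop_mk("photon_budget must be > 0")
  spec <- structure(list(size_px = as.integer(size_px),
                         pixel_size_um = pixel_size_um,
                         cell_center = cell_center, cell_axes = cell_axes,
                         chrom_center = chrom_center, chrom_axes = chrom_axes,
                         rho = rho, photon_budget = photon_budget,
                         background = background, noise = noise),
                    class = "cell_render_spec")
  m <- render_masks(spec)
  if (any(m$chrom & !m$cell))
    stop_mk("chromosome region must lie strictly inside the cell region")
  if (ellipse_touches_border(cell_center, cell_axes, size_px))
    stop_mk("cell region exceeds image bounds")
  spec
}

ellipse_mask <- function(size_px, center, axes) {
  xy <- seq_len(size_px)
  gx <- matrix(xy, size_px, size_px)
  gy <- t(gx)
  ((gx - center[1]) / axes[1])^2 + ((gy - center[2]) / axes[2])^2 <= 1
}

ellipse_touches_border <- function(center, axes, size_px) {
  center[1] - axes[1] < 1 || center[1] + axes[1] > size_px ||
    center[2] - axes[2] < 1 || center[2] + axes[2] > size_px
}

render_masks <- function(spec) {
  list(cell = ellipse_mask(spec$size_px, spec$cell_center, spec$cell_axes),
       chrom = ellipse_mask(spec$size_px, spec$chrom_center, spec$chrom_axes))
}

#' Expected log2 chromosome enrichment of a render specification
#'
#' Analytic ground truth for [render_cell_image_pair()]: with chromosome area
#' fraction `alpha` of the cell and intensity ratio `rho`, the
#' background-subtracted statistic is
#' `log2(rho / (alpha * rho + (1 - alpha)))`.
#'
#' @param spec a [cell_render_spec()].
#' @return the expected log2 enrichment (numeric scalar).
#' @export
true_log2_enrichment <- function(spec) {
  m <- render_masks(spec)
  alpha <- sum(m$chrom) / sum(m$cell)
  log2(spec$rho / (alpha * spec$rho + (1 - alpha)))
}

#' Render a synthetic two-channel cell image pair
#'
#' Draws the H2B (chromosome marker) and TF channels described by a
#' [cell_render_spec()], applies Poisson noise at the photon budget, and
#' returns the images together with the ground-truth chromosome and cell
#' masks.
#'
#' @param spec a [cell_render_spec()].
#' @param seed integer RNG seed.
#' @return An `image_pair`: list with matrices `h2b`, `tf`, logical matrices
#'   `chrom_mask`, `cell_mask` (ground truth), `pixel_size_um`, and the spec.
#' @export
render_cell_image_pair <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cell_render_spec"))
  if (!is.null(seed)) set.seed(seed)
  m <- render_masks(spec)
  P <- spec$photon_budget
  tf_lambda <- spec$background + P * (m$cell * 1 + m$chrom * (spec$rho - 1))
  h2b_lambda <- spec$background + P * (0.25 * m$cell + 4 * m$chrom)
  n <- spec$size_px^2
  if (spec$noise == "poisson") {
    tf <- matrix(rpois(n, tf_lambda), spec$size_px)
    h2b <- matrix(rpois(n, h2b_lambda), spec$size_px)
  } else {
    tf <- matrix(tf_lambda, spec$size_px)
    h2b <- matrix(h2b_lambda, spec$size_px)
  }
  structure(list(h2b = h2b, tf = tf, chrom_mask = m$chrom, cell_mask = m$cell,
                 pixel_size_um = spec$pixel_size_um, spec = spec),
            class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("Two-channel image pair: %d x %d px (%.2g um/px), chromosome area %.1f%% of cell\n",
              nrow(x$tf), ncol(x$tf), x$pixel_size_um,
              100 * sum(x$chrom_mask) / sum(x$cell_mask)))
  invisible(x)
}
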
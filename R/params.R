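#' Kinetic parameters of a two-state (bound/free) transcription factor
#'
#' Container for the rate constants and noise terms that drive the two-state
#' Brownian switching model used throughout the package: a freely diffusing
#' state with coefficient `d_free`, a chromatin-bound state with `d_bound`,
#' exponential state durations with rates `k_on_star` (binding, while free)
#' and `k_off` (unbinding, while bound), static localization error and a
#' photobleaching rate.
#'
#' @param d_free free-state diffusion coefficient (um^2/s).
#' @param d_bound bound-state diffusion coefficient (um^2/s); must be smaller
#'   than `d_free`.
#' @param k_on_star pseudo-first-order binding rate while free (1/s).
#' @param k_off unbinding rate while bound (1/s).
#' @param sigma_loc 1D localization error standard deviation (um). Default
#'   0.035 um (35 nm), typical of HiLo single-molecule imaging.
#' @param k_photobleach per-second photobleaching rate (1/s).
#'
#' @return An object of class `kinetic_params`.
#' @seealso [acquisition_settings()], [spt_preset()]
#' @export
#' @examples
#' kinetic_params(d_free = 2, d_bound = 0.01, k_on_star = 0.036, k_off = 0.08)
kinetic_params <- function(d_free, d_bound, k_on_star, k_off,
                           sigma_loc = 0.035, k_photobleach = 0) {
  vals <- c(d_free = d_free, d_bound = d_bound, k_on_star = k_on_star,
            k_off = k_off, sigma_loc = sigma_loc, k_photobleach = k_photobleach)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop_mk("all kinetic parameters must be finite and >= 0")
  if (d_free < d_bound)
    stop_mk("d_free (%g) must be >= d_bound (%g)", d_free, d_bound)
  structure(as.list(vals), class = "kinetic_params")
}

#' Stationary bound fraction of a two-state kinetic model
#'
#' @param params a [kinetic_params()] object.
#' @return `k_on_star / (k_on_star + k_off)`, the equilibrium probability of
#'   the bound state (0 when both rates are zero).
#' @export
stationary_bound_fraction <- function(params) {
  tot <- params$k_on_star + params$k_off
  if (tot == 0) return(0)
  params$k_on_star / tot
}

#' Acquisition settings for single-particle tracking
#'
#' @param frame_interval time between frames (s).
#' @param n_frames number of frames in the movie.
#' @param exposure exposure per frame (s); must not exceed `frame_interval`.
#' @param slice_half_width axial detection half-thickness dz/2 (um); a
#'   localization is emitted only while |z| is below this value. Default
#'   0.35 um (a ~0.7 um HiLo detection slice).
#' @param blink_max_gap maximum number of consecutive missed frames that are
#'   re-connected into the same trajectory (fluorophore blinking). Default 1.
#' @param fov side length of the square field of view (um); particles are
#'   seeded uniformly in it.
#' @param cell_half_depth axial half-extent of the cell (um); z-diffusion
#'   reflects at +/- this value.
#'
#' @return An object of class `acquisition_settings`.
#' @export
acquisition_settings <- function(frame_interval = 0.0045, n_frames = 100,
                                 exposure = frame_interval,
                                 slice_half_width = 0.35, blink_max_gap = 1,
                                 fov = 25, cell_half_depth = 4) {
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop_mk("frame_interval must be > 0")
  if (exposure > frame_interval + 1e-12)
    stop_mk("exposure (%g s) must not exceed frame_interval (%g s)",
            exposure, frame_interval)
  if (slice_half_width <= 0) stop_mk("slice_half_width must be > 0")
  if (blink_max_gap < 0) stop_mk("blink_max_gap must be >= 0")
  structure(list(frame_interval = frame_interval, n_frames = as.integer(n_frames),
                 exposure = exposure, slice_half_width = slice_half_width,
                 blink_max_gap = as.integer(blink_max_gap), fov = fov,
                 cell_half_depth = cell_half_depth),
            class = "acquisition_settings")
}

#' Cell-cycle presets for the simulators
#'
#' Named parameter presets for an interphase-like and a mitosis-like TF.
#' The presets encode stationary bound fractions of 0.309 (interphase) and
#' 0.183 (mitosis) and a mitotic specific off-rate 1/0.54 times the
#' interphase one, i.e. a mitotic residence time of 54% of interphase.
#' Diffusion coefficients are plausible defaults for a nuclear TF
#' (`d_free` = 2 um^2/s, `d_bound` = 0.01 um^2/s), not measured values;
#' they are configuration, not hard-coded truth. The fast-tracking
#' photobleaching rate (8 1/s) reflects stroboscopic maximal-intensity
#' illumination of photoactivatable dyes, where tracks last tens of frames;
#' the slow-tracking preset uses a low rate (0.05 1/s) matching
#' low-intensity 2 Hz imaging.
#'
#' The slow-tracking (dwell-time) components of the preset follow the
#' two-exponential mixture convention: a fast non-specific rate `k_ns`,
#' a slow specific rate `k_s`, mixture weight `f_ns` on the non-specific
#' component, and a photobleaching rate.
#'
#' @param phase `"interphase"` or `"mitosis"`.
#' @return A list with elements `kinetics` (a [kinetic_params()]),
#'   `dwell` (list `f_ns`, `k_ns`, `k_s`, `k_photobleach`), and
#'   `f_bound` (the stationary bound fraction implied by `kinetics`).
#' @export
#' @examples
#' spt_preset("mitosis")$f_bound   # 0.183
spt_preset <- function(phase = c("interphase", "mitosis")) {
  phase <- match.arg(phase)
  k_s_inter <- 0.08                       # interphase specific off-rate, 1/s
  if (phase == "interphase") {
    fb <- 0.309
    k_off <- k_s_inter
  } else {
    fb <- 0.183
    k_off <- k_s_inter / 0.54             # 54% relative residence time
  }
  k_on_star <- k_off * fb / (1 - fb)
  list(
    phase = phase,
    kinetics = kinetic_params(d_free = 2.0, d_bound = 0.01,
                              k_on_star = k_on_star, k_off = k_off,
                              sigma_loc = 0.035, k_photobleach = 8.0),
    dwell = list(f_ns = 0.7, k_ns = 2.0, k_s = k_off, k_photobleach = 0.05),
    f_bound = fb
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Two-state kinetic parameters\n")
  cat(sprintf("  D_free  = %g um^2/s   D_bound = %g um^2/s\n", x$d_free, x$d_bound))
  cat(sprintf("  k_on*   = %g 1/s      k_off   = %g 1/s  (bound fraction %.3f)\n",
              x$k_on_star, x$k_off, stationary_bound_fraction(x)))
  cat(sprintf("  sigma   = %g um       k_bleach = %g 1/s\n", x$sigma_loc, x$k_photobleach))
  invisible(x)
}
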
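#' Normalize a raw FRAP time series
#'
#' Double normalization of fluorescence recovery data: the background is
#' subtracted from both the bleach-spot and whole-cell traces, the spot is
#' divided by the whole-cell signal (correcting acquisition bleaching), and
#' the result is scaled so its pre-bleach mean is exactly 1:
#' `I(t) = [(spot - bg) / (whole_cell - bg)] / prebleach_mean`.
#' The bleach frame is detected as the largest single-frame drop of the
#' normalized trace after the pre-bleach window, and must exceed 3 SD of the
#' pre-bleach noise (or a small absolute floor on noiseless data).
#'
#' @param raw data frame with columns `time_s`, `spot`, `whole_cell`,
#'   `background` (see [simulate_frap_curve()]).
#' @param pre_bleach_frames number of pre-bleach frames (>= 3).
#' @return A `frap_curve`: data frame `time_s`, `intensity` with attributes
#'   `bleach_index`, `pre_bleach_frames`.
#' @export
normalize_frap <- function(raw, pre_bleach_frames = 5) {
  need <- c("time_s", "spot", "whole_cell", "background")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop_mk("missing column(s): %s", paste(miss, collapse = ", "))
  if (pre_bleach_frames < 3) stop_mk("need >= 3 pre-bleach frames")
  if (nrow(raw) < pre_bleach_frames + 10)
    stop_mk("need >= 10 post-bleach frames")
  if (any(raw$whole_cell <= raw$background))
    stop_mk("whole_cell must exceed background throughout")
  ratio <- (raw$spot - raw$background) / (raw$whole_cell - raw$background)
  pre <- seq_len(pre_bleach_frames)
  inten <- ratio / mean(ratio[pre])
  drops <- -diff(inten)
  cand <- which.max(replace(drops, pre[-length(pre)], -Inf)) + 1L
  noise <- sd(inten[pre])
  thresh <- max(3 * noise, 1e-6)
  if (drops[cand - 1L] <= thresh)
    stop_mk("no bleach event detectable (largest drop %.3g <= %.3g)",
            drops[cand - 1L], thresh)
  structure(data.frame(time_s = raw$time_s, intensity = inten),
            bleach_index = cand, pre_bleach_frames = as.integer(pre_bleach_frames),
            class = c("frap_curve", "data.frame"))
}

#' @export
print.frap_curve <- function(x, ...) {
  bi <- attr(x, "bleach_index")
  cat(sprintf("FRAP curve: %d frames, bleach at frame %d (t = %g s), floor %.3f\n",
              nrow(x), bi, x$time_s[bi], x$intensity[bi]))
  invisible(x)
}

#' @export
plot.frap_curve <- function(x, ...) {
  plot(x$time_s, x$intensity, xlab = "time (s)",
       ylab = "normalized intensity", type = "l", ...)
  abline(v = x$time_s[attr(x, "bleach_index")], lty = 2, col = "grey50")
  invisible(x)
}

#' Time to fractional FRAP recovery
#'
#' The package's FRAP summary statistic: the time after the bleach at which
#' the normalized intensity first reaches `fraction` (default 90%) of the
#' recovered plateau, measured from the bleach floor. The plateau is the
#' mean of the final 10% of post-bleach frames (at least 5); the threshold
#' is `floor + fraction * (plateau - floor)`; the crossing time is linearly
#' interpolated between frames. Measuring from the floor (rather than from
#' the pre-bleach level) makes the statistic well defined for partial
#' recoveries, and makes it invariant under affine intensity transforms.
#'
#' @param curve a `frap_curve` from [normalize_frap()], or a data frame with
#'   `time_s`, `intensity` whose first post-bleach frame is the floor
#'   (supply `bleach_index` via attribute in that case).
#' @param fraction recovery fraction in (0, 1); default 0.9.
#' @return A list with `t_recovery_s` (time from bleach to the crossing),
#'   `plateau`, `bleach_floor`, `n_frames`.
#' @export
time_to_recovery <- function(curve, fraction = 0.9) {
  if (fraction <= 0 || fraction >= 1) stop_mk("fraction must be in (0, 1)")
  bi <- attr(curve, "bleach_index")
  if (is.null(bi)) stop_mk("curve has no bleach_index attribute; use normalize_frap()")
  post <- curve[bi:nrow(curve), , drop = FALSE]
  if (nrow(post) < 10) stop_mk("need >= 10 post-bleach frames, got %d", nrow(post))
  tail_n <- max(5L, ceiling(0.1 * nrow(post)))
  plateau <- mean(tail(post$intensity, tail_n))
  floor_v <- post$intensity[1]
  if (plateau <= floor_v)
    stop_mk("no recovery: plateau (%.3f) does not exceed bleach floor (%.3f)",
            plateau, floor_v)
  thr <- floor_v + fraction * (plateau - floor_v)
  above <- which(post$intensity >= thr)
  above <- above[above > 1]
  if (!length(above)) stop_mk("no recovery: curve never crosses the %g%% threshold",
                              100 * fraction)
  j <- above[1]
  t0 <- post$time_s[j - 1]; t1 <- post$time_s[j]
  y0 <- post$intensity[j - 1]; y1 <- post$intensity[j]
  t_cross <- if (y1 > y0) t0 + (thr - y0) / (y1 - y0) * (t1 - t0) else t1
  list(t_recovery_s = t_cross - post$time_s[1], plateau = plateau,
       bleach_floor = floor_v, n_frames = nrow(curve))
}

#' Diagnostic single-exponential FRAP fit
#'
#' Optional diagnostic: fits `I(t) = floor + (plateau - floor) *
#' (1 - exp(-k t))` to the post-bleach segment by nonlinear least squares.
#' Not used by [time_to_recovery()], which is model-free.
#'
#' @param curve a `frap_curve`.
#' @return list with `k` (1/s), `plateau`, `floor`, and the implied
#'   `t90_model = log(10)/k`.
#' @export
fit_frap_exponential <- function(curve) {
  bi <- attr(curve, "bleach_index")
  post <- curve[bi:nrow(curve), , drop = FALSE]
  tt <- post$time_s - post$time_s[1]
  yy <- post$intensity
  fit <- minpack.lm::nlsLM(
    yy ~ f0 + (pl - f0) * (1 - exp(-k * tt)),
    start = list(f0 = yy[1], pl = tail(yy, 1), k = 0.5),
    lower = c(-0.5, 0, 1e-4), upper = c(1.5, 1.5, 100))
  p <- coef(fit)
  list(k = unname(p["k"]), plateau = unname(p["pl"]), floor = unname(p["f0"]),
       t90_model = log(10) / unname(p["k"]))
}
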
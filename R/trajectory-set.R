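#' Construct a trajectory set
#'
#' A `trajectory_set` is a data frame of single-particle localizations with
#' columns `trajectory_id`, `frame`, `time_s`, `x_um`, `y_um` and optionally
#' `true_state` (`"bound"`/`"free"`, known only for simulated data), carrying
#' the frame interval, a source tag and the simulation seed as attributes.
#' It is the common currency of the tracking stages.
#'
#' @param df data frame with at least `trajectory_id`, `frame`, `x_um`, `y_um`.
#' @param frame_interval time between frames (s).
#' @param source free-text provenance tag.
#' @param seed simulation seed, or `NA` for experimental data.
#' @return A `trajectory_set` (a validated, sorted data frame).
#' @export
trajectory_set <- function(df, frame_interval, source = "unknown", seed = NA) {
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop_mk("frame_interval must be > 0")
  need <- c("trajectory_id", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_mk("missing column(s): %s", paste(miss, collapse = ", "))
  df <- df[order(df$trajectory_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df)) {
    bad <- !is.finite(df$x_um) | !is.finite(df$y_um)
    if (any(bad))
      stop_mk("non-finite coordinates at row(s) %s",
              paste(head(which(bad), 5), collapse = ", "))
    same <- c(FALSE, df$trajectory_id[-1] == df$trajectory_id[-nrow(df)])
    nonmono <- same & c(FALSE, diff(df$frame) <= 0)
    if (any(nonmono))
      stop_mk("frames not strictly increasing within trajectory at row(s) %s",
              paste(head(which(nonmono), 5), collapse = ", "))
  }
  df$time_s <- df$frame * frame_interval
  first <- c("trajectory_id", "frame", "time_s", "x_um", "y_um")
  df <- df[, c(first, setdiff(names(df), first)), drop = FALSE]
  structure(df, frame_interval = frame_interval, source = source, seed = seed,
            class = c("trajectory_set", "data.frame"))
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("Trajectory set: %d localizations in %d trajectories (dt = %g s, source: %s)\n",
              nrow(x), length(unique(x$trajectory_id)),
              attr(x, "frame_interval"), attr(x, "source")))
  if (nrow(x)) print(head(as.data.frame(x), 6))
  invisible(x)
}

#' Frame interval of a trajectory set
#' @param tracks a [trajectory_set()].
#' @return the frame interval (s).
#' @export
frame_interval <- function(tracks) attr(tracks, "frame_interval")

#' Track lengths in frames and seconds
#'
#' Bookkeeping summary: per-trajectory number of localizations, spanned
#' frames and dwell time (span in frames times the frame interval).
#'
#' @param tracks a [trajectory_set()].
#' @return data frame with `trajectory_id`, `n_loc`, `span_frames`, `dwell_s`.
#' @export
track_lengths <- function(tracks) {
  if (!nrow(tracks))
    return(data.frame(trajectory_id = integer(), n_loc = integer(),
                      span_frames = integer(), dwell_s = numeric()))
  sp <- split(tracks$frame, tracks$trajectory_id)
  dt <- frame_interval(tracks)
  data.frame(
    trajectory_id = as.integer(names(sp)),
    n_loc = lengths(sp),
    span_frames = vapply(sp, function(f) max(f) - min(f) + 1L, integer(1)),
    dwell_s = vapply(sp, function(f) (max(f) - min(f) + 1) * dt, numeric(1)),
    row.names = NULL)
}
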
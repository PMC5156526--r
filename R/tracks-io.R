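#' Read a trajectory CSV
#'
#' Reads the package's trajectory dialect: header-mandatory CSV with columns
#' `trajectory_id,frame,time_s,x_um,y_um[,true_state]` (UTF-8, '.' decimal
#' separator). Rows are validated and sorted by `(trajectory_id, frame)`.
#'
#' @param path file path.
#' @param frame_interval frame interval (s) to attach as metadata.
#' @return A [trajectory_set()]. A header-only file yields an empty set.
#' @export
read_trajectories <- function(path, frame_interval) {
  if (!file.exists(path)) stop_mk("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trajectory_id", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_mk("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  if (nrow(df)) {
    bad <- !complete.cases(df[, need]) |
      !is.finite(df$x_um) | !is.finite(df$y_um)
    if (any(bad))
      stop_mk("%s: missing/non-finite values at data row(s) %s", path,
              paste(head(which(bad), 5), collapse = ", "))
    key <- paste(df$trajectory_id, df$frame)
    dup <- duplicated(key)
    if (any(dup))
      stop_mk("%s: duplicated (trajectory_id, frame) at data row(s) %s", path,
              paste(head(which(dup), 5), collapse = ", "))
  }
  trajectory_set(df, frame_interval, source = path)
}

#' Write a trajectory CSV
#'
#' @param tracks a [trajectory_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(tracks, path) {
  df <- as.data.frame(tracks)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a localization CSV
#'
#' Dialect `frame,x_um,y_um[,intensity]`, header mandatory.
#'
#' @param path file path.
#' @return a data frame usable as input to [link_localizations()].
#' @export
read_localizations <- function(path) {
  if (!file.exists(path)) stop_mk("file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("frame", "x_um", "y_um"), names(df))
  if (length(miss))
    stop_mk("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  if (nrow(df) && any(df$frame < 0)) stop_mk("%s: negative frame indices", path)
  df
}

#' Link localizations into trajectories (greedy nearest neighbour)
#'
#' Simple greedy frame-to-frame linker used as plumbing in place of a full
#' multiple-target tracker. Detections are processed frame by frame; each
#' detection links to the nearest unclaimed open track end within `max_jump`
#' (Euclidean, um) whose last detection is at most `max_gap + 1` frames in
#' the past (blinking re-connection); candidate links are resolved globally
#' per frame in order of increasing distance, ties by lower trajectory id.
#' Unlinked detections start new trajectories. Adequate at the low densities
#' this package simulates (<= 0.1 particles/um^2); not a globally optimal
#' assignment.
#'
#' @param locs data frame with `frame`, `x_um`, `y_um` (see
#'   [read_localizations()]).
#' @param max_jump maximum link distance (um, > 0).
#' @param max_gap maximum number of missed frames to bridge (>= 0).
#' @param frame_interval frame interval (s) for the output metadata.
#' @return A [trajectory_set()].
#' @export
link_localizations <- function(locs, max_jump, max_gap = 1,
                               frame_interval = 0.0045) {
  if (max_jump <= 0) stop_mk("max_jump must be > 0")
  if (max_gap < 0) stop_mk("max_gap must be >= 0")
  if (!nrow(locs)) {
    return(trajectory_set(data.frame(trajectory_id = integer(), frame = integer(),
                                     x_um = numeric(), y_um = numeric()),
                          frame_interval, source = "link_localizations"))
  }
  locs <- locs[order(locs$frame), , drop = FALSE]
  frames <- sort(unique(locs$frame))
  # open track ends
  end_id <- integer(0); end_frame <- integer(0)
  end_x <- numeric(0); end_y <- numeric(0)
  next_id <- 0L
  out_id <- integer(nrow(locs))
  idx_by_frame <- split(seq_len(nrow(locs)), locs$frame)
  for (f in frames) {
    idx <- idx_by_frame[[as.character(f)]]
    keep <- f - end_frame <= max_gap + 1L
    end_id <- end_id[keep]; end_frame <- end_frame[keep]
    end_x <- end_x[keep]; end_y <- end_y[keep]
    assigned_det <- rep(FALSE, length(idx))
    claimed_end <- rep(FALSE, length(end_id))
    if (length(end_id)) {
      dx <- outer(locs$x_um[idx], end_x, "-")
      dy <- outer(locs$y_um[idx], end_y, "-")
      d <- sqrt(dx^2 + dy^2)
      cand <- which(d <= max_jump, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(d[cand], end_id[cand[, 2]])
        for (r in ord) {
          i <- cand[r, 1]; j <- cand[r, 2]
          if (!assigned_det[i] && !claimed_end[j]) {
            assigned_det[i] <- TRUE; claimed_end[j] <- TRUE
            out_id[idx[i]] <- end_id[j]
            end_frame[j] <- f
            end_x[j] <- locs$x_um[idx[i]]; end_y[j] <- locs$y_um[idx[i]]
          }
        }
      }
    }
    new <- which(!assigned_det)
    if (length(new)) {
      ids <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
      out_id[idx[new]] <- ids
      end_id <- c(end_id, ids)
      end_frame <- c(end_frame, rep(f, length(new)))
      end_x <- c(end_x, locs$x_um[idx[new]])
      end_y <- c(end_y, locs$y_um[idx[new]])
    }
  }
  trajectory_set(data.frame(trajectory_id = out_id, frame = locs$frame,
                            x_um = locs$x_um, y_um = locs$y_um),
                 frame_interval, source = "link_localizations")
}
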
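#' Otsu threshold of a masked pixel set
#'
#' Thin wrapper over `EBImage::otsu` operating on the pixels selected by a
#' mask, rescaled to the unit range first (so the threshold is invariant to
#' positive rescaling of the intensities).
#'
#' @param img numeric matrix.
#' @param mask logical matrix; only `TRUE` pixels enter the histogram.
#' @return threshold on the original intensity scale.
#' @keywords internal
otsu_in_mask <- function(img, mask = NULL) {
  vals <- if (is.null(mask)) as.numeric(img) else img[mask]
  rng <- range(vals)
  if (diff(rng) == 0) return(rng[1])
  scaled <- (vals - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(matrix(scaled, ncol = 1)),
                       range = c(0, 1), levels = 256)
  rng[1] + thr * diff(rng)
}

clean_mask <- function(mask, min_px = 20) {
  img <- EBImage::fillHull(EBImage::Image(mask * 1))
  lab <- EBImage::bwlabel(img)
  sizes <- table(lab[lab > 0])
  keep <- as.integer(names(sizes)[sizes >= min_px])
  matrix(as.integer(lab) %in% keep, nrow(mask))
}

#' Segment the cell from a two-channel image
#'
#' Otsu threshold on the log-transformed summed channels (the log keeps the
#' threshold between background and cell body rather than between cell body
#' and the much brighter chromosomes), keeping the largest connected
#' component with holes filled. A manually drawn ROI can be supplied to any
#' downstream function instead; this automatic mask is a convenience.
#'
#' @param pair an `image_pair` (see [render_cell_image_pair()]).
#' @return logical matrix.
#' @export
cell_mask <- function(pair) {
  s <- log1p(pair$h2b + pair$tf)
  thr <- otsu_in_mask(s)
  m <- s > thr
  lab <- EBImage::bwlabel(EBImage::fillHull(EBImage::Image(m * 1)))
  sizes <- table(lab[lab > 0])
  if (!length(sizes)) stop_mk("cell segmentation failed: no foreground")
  keep <- as.integer(names(sizes)[which.max(sizes)])
  matrix(as.integer(lab) == keep, nrow(m))
}

#' Chromosome mask from the H2B channel
#'
#' Thresholds the chromosome-marker (H2B) channel within the cell mask by
#' Otsu's method, fills holes and removes connected components smaller than
#' `min_px` pixels. Rejects images whose H2B signal is not bimodal within
#' the cell (above/below-threshold mean ratio below `min_contrast`), i.e.
#' no chromosome signal.
#'
#' @param h2b H2B channel matrix (or an `image_pair`, whose `h2b` is used).
#' @param cell cell mask (logical matrix); computed via [cell_mask()] when an
#'   `image_pair` is given and `cell` is `NULL`.
#' @param min_px minimum component size (pixels).
#' @param min_contrast minimum above/below-threshold mean intensity ratio.
#' @return logical matrix.
#' @export
chromosome_mask <- function(h2b, cell = NULL, min_px = 20, min_contrast = 1.5) {
  if (inherits(h2b, "image_pair")) {
    if (is.null(cell)) cell <- cell_mask(h2b)
    h2b <- h2b$h2b
  }
  if (is.null(cell) || !any(cell)) stop_mk("cell mask is empty")
  thr <- otsu_in_mask(h2b, cell)
  above <- cell & (h2b > thr)
  below <- cell & !(h2b > thr)
  if (!any(above) || !any(below))
    stop_mk("no chromosome signal: H2B is not bimodal within the cell")
  if (mean(h2b[above]) < min_contrast * mean(h2b[below]))
    stop_mk("no chromosome signal: H2B contrast %.2f below %.2f within the cell",
            mean(h2b[above]) / mean(h2b[below]), min_contrast)
  m <- clean_mask(above, min_px) & cell
  if (!any(m)) stop_mk("no chromosome signal: mask empty after cleaning")
  m
}

#' Log2 chromosome-enrichment statistic
#'
#' `E = log2[(mean TF on chromosomes - background) /
#' (mean TF over the whole cell - background)]`, where the whole-cell mean
#' includes the chromosome pixels. Positive values mean enrichment on
#' mitotic chromosomes, negative values apparent exclusion; a spatially
#' uniform TF gives 0. By default the background is the median intensity
#' outside the cell mask.
#'
#' @param tf TF channel matrix (or an `image_pair`).
#' @param chrom chromosome mask; computed via [chromosome_mask()] when an
#'   `image_pair` is given and `chrom` is `NULL`.
#' @param cell cell mask; computed via [cell_mask()] likewise.
#' @param background scalar background level; `NULL` for the median outside
#'   the cell.
#' @return log2 enrichment (numeric scalar) with attribute `mask_area_px`.
#' @export
log2_enrichment <- function(tf, chrom = NULL, cell = NULL, background = NULL) {
  if (inherits(tf, "image_pair")) {
    pair <- tf
    if (is.null(cell)) cell <- cell_mask(pair)
    if (is.null(chrom)) chrom <- chromosome_mask(pair$h2b, cell)
    tf <- pair$tf
  }
  if (!any(cell) || !any(chrom)) stop_mk("empty mask")
  if (any(chrom & !cell)) stop_mk("chromosome mask must lie within the cell mask")
  if (is.null(background)) {
    out <- !cell
    background <- if (any(out)) median(tf[out]) else 0
  }
  num <- mean(tf[chrom]) - background
  den <- mean(tf[cell]) - background
  if (num <= 0 || den <= 0)
    stop_mk("non-positive background-subtracted mean (chromosomes %.3g, cell %.3g)",
            num, den)
  structure(log2(num / den), mask_area_px = sum(chrom))
}

#' Chromosome enrichment over a fixative-addition time lapse
#'
#' Computes, frame by frame, the chromosome mask from the H2B channel and
#' the normalized chromosome intensity (mean TF within the mask over mean
#' TF within the cell) together with its log2, and reports the trace plus
#' the value at `addition_time + query_time` (linearly interpolated between
#' frames). Chromosomes move, so every frame is re-masked; no registration
#' is attempted. Frames whose masking fails are dropped; more than 10%
#' failures reject the movie.
#'
#' @param stack list of `image_pair` objects (one per frame).
#' @param times frame times (s); defaults to the pairs' `time_s` fields or a
#'   0.5 s grid (2 Hz).
#' @param addition_time time of fixative addition (s).
#' @param query_time readout delay after addition (s), default 60.
#' @param background scalar background; `NULL` for per-frame median outside
#'   the cell.
#' @return An `enrichment_trace`: data frame `time_s`,
#'   `norm_chrom_intensity`, `log2_enrichment`, with attributes
#'   `addition_time`, `query_time` and `value_at_query` (the normalized
#'   chromosome intensity at the query time).
#' @export
timelapse_enrichment <- function(stack, times = NULL, addition_time = 10,
                                 query_time = 60, background = NULL) {
  if (query_time < 0) stop_mk("query_time must be >= 0 (relative to addition)")
  if (is.null(times)) {
    times <- vapply(seq_along(stack),
                    function(i) stack[[i]]$time_s %||% (0.5 * (i - 1)),
                    numeric(1))
  }
  tq <- addition_time + query_time
  if (tq > max(times))
    stop_mk("stack (%.1f s) does not cover addition + query time (%.1f s)",
            max(times), tq)
  if (addition_time > max(times) || addition_time < min(times))
    stop_mk("addition_time outside the movie")
  res <- lapply(stack, function(pair) {
    tryCatch({
      cm <- cell_mask(pair)
      ch <- chromosome_mask(pair$h2b, cm)
      bg <- background
      if (is.null(bg)) bg <- if (any(!cm)) median(pair$tf[!cm]) else 0
      nci <- (mean(pair$tf[ch]) - bg) / (mean(pair$tf[cm]) - bg)
      c(nci, log2(nci))
    }, error = function(e) c(NA_real_, NA_real_))
  })
  m <- do.call(rbind, res)
  fail <- !is.finite(m[, 1])
  if (mean(fail) > 0.1)
    stop_mk("mask failure on %.0f%% of frames (> 10%%)", 100 * mean(fail))
  tr <- data.frame(time_s = times[!fail], norm_chrom_intensity = m[!fail, 1],
                   log2_enrichment = m[!fail, 2])
  vq <- approx(tr$time_s, tr$norm_chrom_intensity, xout = tq, rule = 2)$y
  structure(tr, addition_time = addition_time, query_time = query_time,
            value_at_query = vq,
            class = c("enrichment_trace", "data.frame"))
}

#' @export
print.enrichment_trace <- function(x, ...) {
  cat(sprintf("Enrichment trace: %d frames, addition at %g s; normalized chromosome intensity at +%g s = %.3f\n",
              nrow(x), attr(x, "addition_time"), attr(x, "query_time"),
              attr(x, "value_at_query")))
  invisible(x)
}

#' @export
plot.enrichment_trace <- function(x, ...) {
  plot(x$time_s, x$norm_chrom_intensity, type = "l", xlab = "time (s)",
       ylab = "normalized chromosome intensity", ...)
  abline(v = attr(x, "addition_time"), lty = 2, col = "grey50")
  invisible(x)
}

#' Write / read a two-channel image pair as multi-page TIFF
#'
#' Channel order (H2B, TF), 16-bit unsigned; the ground-truth chromosome
#' mask, when present, can be written alongside as a single-page 8-bit TIFF.
#'
#' @param pair an `image_pair`.
#' @param path output TIFF path.
#' @param mask_path optional path for the ground-truth mask TIFF.
#' @return `path`, invisibly.
#' @export
write_image_pair <- function(pair, path, mask_path = NULL) {
  scale <- 65535
  pages <- list(pmin(pair$h2b, scale) / scale, pmin(pair$tf, scale) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  if (!is.null(mask_path) && !is.null(pair$chrom_mask))
    tiff::writeTIFF(pair$chrom_mask * 1, mask_path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_image_pair
#' @param pixel_size_um pixel size metadata for the read pair.
#' @param time_s optional frame time metadata.
#' @export
read_image_pair <- function(path, pixel_size_um = 0.2, time_s = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 2) stop_mk("%s: expected a 2-page (H2B, TF) TIFF", path)
  structure(list(h2b = round(pages[[1]] * 65535), tf = round(pages[[2]] * 65535),
                 chrom_mask = NULL, cell_mask = NULL,
                 pixel_size_um = pixel_size_um, time_s = time_s),
            class = "image_pair")
}
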
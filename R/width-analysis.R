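#' Measurement line across a vessel
#'
#' Continuous 0-based pixel coordinates (pixel centers at integers), as on
#' the measurement line drawn across a vein in the slit-lamp image.
#'
#' @param x0,y0,x1,y1 endpoints in pixels.
#' @return an object of class `sampling_line`.
#' @export
sampling_line <- function(x0, y0, x1, y1) {
  v <- c(x0, y0, x1, y1)
  if (!all(vapply(v, is_number, TRUE)))
    stop_aquacol("line endpoints must be finite numbers",
                 "aquacol_parameter_error")
  if (x0 == x1 && y0 == y1)
    stop_aquacol("line endpoints must be distinct", "aquacol_parameter_error")
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "sampling_line")
}

#' Sample an intensity profile along a line
#'
#' Bilinear interpolation at (approximately) unit-pixel spacing along the
#' line, endpoints inclusive: the line is divided into `round(length)` equal
#' steps, so axis-aligned lines of integer length reproduce the raw pixel
#' values exactly.
#'
#' @param frame a numeric matrix (one video frame, rows = y).
#' @param line a [sampling_line()]; both endpoints must lie inside the
#'   frame.
#' @return an object of class `intensity_profile` with fields `positions`
#'   (distance along the line, uniformly spaced from 0) and `intensities`.
#' @export
extract_profile <- function(frame, line) {
  stopifnot(is.matrix(frame), inherits(line, "sampling_line"))
  h <- nrow(frame); w <- ncol(frame)
  xs <- c(line$x0, line$x1); ys <- c(line$y0, line$y1)
  if (any(xs < 0) || any(xs > w - 1) || any(ys < 0) || any(ys > h - 1))
    stop_aquacol("sampling line extends outside the frame",
                 "aquacol_parameter_error")
  len <- sqrt((line$x1 - line$x0)^2 + (line$y1 - line$y0)^2)
  nseg <- max(1L, as.integer(round(len)))
  u <- seq(0, 1, length.out = nseg + 1L)
  vals <- bilinear(frame, line$x0 + u * (line$x1 - line$x0),
                   line$y0 + u * (line$y1 - line$y0))
  structure(list(positions = u * len, intensities = vals,
                 spacing = len / nseg),
            class = "intensity_profile")
}

#' Aqueous column width from a cross-sectional profile
#'
#' The column width is the distance between the two intensity minima
#' flanking the bright aqueous core: the profile is Gaussian-smoothed, the
#' global maximum located (it must not sit at the profile edge), the
#' deepest local minimum found on each side, and each minimum refined to
#' subpixel position by parabolic interpolation over its 3-point
#' neighborhood. Ties between equally deep minima are broken toward the
#' minimum nearer the central maximum.
#'
#' @param profile an [extract_profile()] result, or a numeric vector of
#'   intensities at unit spacing.
#' @param smooth_sigma_px Gaussian smoothing sd in pixels applied before
#'   the minima search (stabilizes the minima under sensor noise; set to 0
#'   to measure on the raw profile).
#' @return the width in pixels.
#' @export
measure_width <- function(profile, smooth_sigma_px = 2) {
  if (is.numeric(profile) && is.null(dim(profile)))
    profile <- structure(list(positions = seq_along(profile) - 1,
                              intensities = as.numeric(profile), spacing = 1),
                         class = "intensity_profile")
  stopifnot(inherits(profile, "intensity_profile"))
  y <- profile$intensities
  n <- length(y)
  if (n < 5)
    stop_aquacol("profile too short to contain two minima and a maximum",
                 "aquacol_unmeasurable")
  if (smooth_sigma_px > 0)
    y <- smooth_reflect(y, gaussian_kernel(smooth_sigma_px / profile$spacing))

  imax <- which.max(y)
  if (imax <= 1L || imax >= n)
    stop_aquacol("profile maximum lies at the edge: no flanked core",
                 "aquacol_unmeasurable")

  local_minima <- function(idx) {
    idx[y[idx] < y[idx - 1L] & y[idx] <= y[idx + 1L]]
  }
  pick <- function(cands) {
    if (length(cands) == 0) return(NA_integer_)
    depth <- y[cands]
    best <- cands[depth == min(depth)]
    best[which.min(abs(best - imax))]  # tie toward the central maximum
  }
  il <- pick(local_minima(seq(2L, max(2L, imax - 1L))[seq(2L, max(2L, imax - 1L)) < imax]))
  ir <- pick(local_minima(seq(min(n - 1L, imax + 1L), n - 1L)[seq(min(n - 1L, imax + 1L), n - 1L) > imax]))
  if (is.na(il) || is.na(ir))
    stop_aquacol("profile lacks a local minimum on each side of the core",
                 "aquacol_unmeasurable")

  refine <- function(i) i - 1 + parabolic_offset(-y[i - 1L], -y[i], -y[i + 1L])
  (refine(ir) - refine(il)) * profile$spacing
}

#' Width of the aqueous column over the frames of a clip
#'
#' Applies [measure_width()] to the same line on each of the first
#' `n_frames` frames (30 by convention). Frames on which no width is
#' measurable are excluded and counted; the measurement fails if more than
#' half the frames are unmeasurable.
#'
#' @param clip a single-channel [video_clip()] with at least `n_frames`
#'   frames.
#' @param line a [sampling_line()].
#' @param n_frames number of frames to measure.
#' @param smooth_sigma_px passed to [measure_width()].
#' @param observer_label optional label for the observer/line placement.
#' @return an object of class `width_measurement`: `per_frame_widths`
#'   (NA where unmeasurable), `mean_width_px`, `sd_width_px`,
#'   `n_excluded`, `observer_label`.
#' @export
measure_width_clip <- function(clip, line, n_frames = 30, smooth_sigma_px = 2,
                               observer_label = NA_character_) {
  stopifnot(inherits(clip, "video_clip"))
  if (clip$channel_tag == "rgb")
    stop_aquacol("measure on a single-channel clip (extract_green_channel first)",
                 "aquacol_parameter_error")
  if (n_frames(clip) < n_frames)
    stop_aquacol(sprintf("clip has %d frames; %d required", n_frames(clip),
                         n_frames), "aquacol_parameter_error")
  widths <- vapply(seq_len(n_frames), function(i) {
    tryCatch(measure_width(extract_profile(clip$frames[, , i], line),
                           smooth_sigma_px = smooth_sigma_px),
             aquacol_unmeasurable = function(e) NA_real_)
  }, numeric(1))
  n_excl <- sum(is.na(widths))
  if (n_excl > n_frames / 2)
    stop_aquacol(sprintf("%d of %d frames unmeasurable", n_excl, n_frames),
                 "aquacol_measurement_failure")
  ok <- widths[!is.na(widths)]
  structure(list(per_frame_widths = widths,
                 mean_width_px = mean(ok),
                 sd_width_px = if (length(ok) > 1) stats::sd(ok) else NA_real_,
                 n_excluded = n_excl,
                 observer_label = observer_label),
            class = "width_measurement")
}

#' @export
print.width_measurement <- function(x, ...) {
  cat(sprintf(
    "<width_measurement> mean %.2f px (sd %.2f) over %d frame(s), %d excluded%s\n",
    x$mean_width_px, x$sd_width_px,
    sum(!is.na(x$per_frame_widths)), x$n_excluded,
    if (is.na(x$observer_label)) "" else paste0(", observer ", x$observer_label)))
  invisible(x)
}

#' Average two observers' width measurements
#'
#' The protocol has two independent observers measure the same clip and
#' averages their mean widths.
#'
#' @param m1,m2 [measure_width_clip()] results (or plain numbers).
#' @return the arithmetic mean of the two mean widths, in pixels.
#' @export
average_observers <- function(m1, m2) {
  val <- function(m) {
    if (inherits(m, "width_measurement")) m$mean_width_px
    else if (is_number(m)) m
    else stop_aquacol("expected a width_measurement or a number",
                      "aquacol_parameter_error")
  }
  (val(m1) + val(m2)) / 2
}

#' Percent change from baseline
#'
#' @param baseline_px baseline width (must be positive).
#' @param value_px width at the later timepoint.
#' @return `100 * (value - baseline) / baseline`. Note that a mean of
#'   per-subject percent changes differs from the percent change of the
#'   mean widths; study summaries use the former.
#' @export
percent_change <- function(baseline_px, value_px) {
  if (!is.numeric(baseline_px) || any(!is.finite(baseline_px)) ||
      any(baseline_px <= 0))
    stop_aquacol("baseline must be positive", "aquacol_parameter_error")
  100 * (value_px - baseline_px) / baseline_px
}
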
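#' Detect blinks from global intensity dips
#'
#' During a blink the eyelid occludes the field and the global mean frame
#' intensity drops sharply. A frame is flagged as a blink frame when its
#' mean intensity falls below `dim_factor` times the rolling median of the
#' mean-intensity trace (the rolling median makes the rule self-normalizing
#' under slow illumination drift); maximal runs of flagged frames are merged
#' into events.
#'
#' @param clip a single-channel [video_clip()] with at least `window`
#'   frames.
#' @param dim_factor dip threshold relative to the rolling median.
#' @param window odd rolling-median window length in frames.
#' @return a data frame of class `blink_events` with columns `start`,
#'   `end`: half-open 0-based frame intervals `[start, end)`.
#' @export
detect_blinks <- function(clip, dim_factor = 0.6, window = 31) {
  stopifnot(inherits(clip, "video_clip"))
  if (window %% 2 != 1 || window < 3)
    stop_aquacol("`window` must be an odd integer >= 3",
                 "aquacol_parameter_error")
  t <- n_frames(clip)
  if (t < window)
    stop_aquacol(sprintf("clip has %d frames; rolling window needs %d",
                         t, window), "aquacol_parameter_error")
  means <- apply(clip$frames, length(dim(clip$frames)), mean)
  med <- stats::runmed(means, window, endrule = "median")
  is_blink <- means < dim_factor * med
  r <- rle(is_blink)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(start = starts[keep] - 1L, end = ends[keep])
  class(out) <- c("blink_events", "data.frame")
  out
}

#' Select the measurement segment immediately after a blink
#'
#' Aqueous flow slows without blinking, so measurements are made on the
#' frames immediately following a blink. Returns the `segment_len` frames
#' starting at the first frame after the end of the earliest blink that
#' leaves room for a full segment.
#'
#' @param clip a [video_clip()].
#' @param blinks a [detect_blinks()] result (or data frame with 0-based
#'   half-open `start`, `end` columns).
#' @param segment_len segment length in frames (30 by convention).
#' @return a [video_clip()] of `segment_len` frames, with attribute
#'   `"segment_start"` giving the 0-based index of its first frame in the
#'   input clip.
#' @export
select_post_blink_segment <- function(clip, blinks, segment_len = 30) {
  stopifnot(inherits(clip, "video_clip"))
  t <- n_frames(clip)
  if (is.null(blinks) || nrow(blinks) == 0)
    stop_aquacol("no blink events: cannot anchor a post-blink segment",
                 "aquacol_no_segment")
  blinks <- blinks[order(blinks$start), , drop = FALSE]
  for (i in seq_len(nrow(blinks))) {
    s <- blinks$end[i]  # first frame after the blink (end is exclusive)
    if (s + segment_len <= t) {
      keep <- seq(s + 1L, length.out = segment_len)
      frames <- if (clip$channel_tag == "rgb")
        clip$frames[, , , keep, drop = FALSE]
      else clip$frames[, , keep, drop = FALSE]
      out <- video_clip(frames, clip$fps, clip$channel_tag)
      attr(out, "segment_start") <- as.integer(s)
      return(out)
    }
  }
  stop_aquacol("no blink leaves room for a full segment after it",
               "aquacol_no_segment")
}

# phase correlation between two equally sized frames; returns c(dx, dy)
# such that moving ~ translate(ref) by (dx, dy), i.e.
# moving(x, y) ~= ref(x - dx, y - dy). The cross-power spectrum gives
# sharp candidate peaks (subpixel via parabolic fit); when the scene
# contains internally moving structure (flowing blood speckle) a secondary
# peak can outgrow the camera-shake peak in the whitened correlation, so
# the top candidate peaks are disambiguated by actual image agreement:
# the shift whose corrected frame best matches the reference (SSD on the
# overlap) wins.
phase_correlate <- function(ref, moving, n_candidates = 6L, prior = NULL) {
  h <- nrow(ref); w <- ncol(ref)
  win <- outer(0.5 - 0.5 * cos(2 * pi * seq_len(h) / (h + 1)),
               0.5 - 0.5 * cos(2 * pi * seq_len(w) / (w + 1)))
  f1 <- stats::fft(win * (ref - mean(ref)))
  f2 <- stats::fft(win * (moving - mean(moving)))
  cross <- Conj(f1) * f2
  denom <- Mod(cross)
  eps <- max(denom) * 1e-8 + .Machine$double.eps
  r <- Re(stats::fft(cross / (denom + eps), inverse = TRUE)) / (h * w)
  rc <- Re(stats::fft(cross, inverse = TRUE))  # plain cross-correlation

  wrap <- function(i, n) ((i - 1) %% n) + 1
  unwrap_peak <- function(mat) {
    pk <- arrayInd(which.max(mat), dim(mat))
    dy <- pk[1] - 1; if (dy > h / 2) dy <- dy - h
    dx <- pk[2] - 1; if (dx > w / 2) dx <- dx - w
    list(ix = pk[2], iy = pk[1], dx = dx, dy = dy)
  }
  # integer candidates: whitened-spectrum peaks (sharp, robust to
  # illumination) plus the plain-correlation peak (energy-weighted),
  # 3-px non-maximum suppression
  cands <- list()
  rm_work <- r
  for (k in seq_len(n_candidates)) {
    pk <- unwrap_peak(rm_work)
    cands[[length(cands) + 1L]] <- c(pk$dx, pk$dy)
    rm_work[wrap(pk$iy + (-3:3), h), wrap(pk$ix + (-3:3), w)] <- -Inf
  }
  pk <- unwrap_peak(rc)
  cands[[length(cands) + 1L]] <- c(pk$dx, pk$dy)
  if (!is.null(prior)) cands[[length(cands) + 1L]] <- round(prior)

  # judge every candidate on a fixed central region by direct image
  # agreement, averaging only over samples that stay inside the frame so
  # large shifts are compared fairly
  m <- max(4L, round(0.08 * min(h, w)))
  yi <- (m + 1):(h - m); xi <- (m + 1):(w - m)
  xs0 <- rep(xi - 1, each = length(yi))
  ys0 <- rep(yi - 1, times = length(xi))
  refpatch <- as.vector(ref[yi, xi])
  ssd <- function(dx, dy) {
    xs <- xs0 + dx; ys <- ys0 + dy
    ok <- xs >= 0 & xs <= w - 1 & ys >= 0 & ys <= h - 1
    if (mean(ok) < 0.5) return(Inf)
    d <- bilinear(moving, xs[ok], ys[ok]) - refpatch[ok]
    mean(d^2)
  }
  score <- vapply(cands, function(sh) ssd(sh[1], sh[2]), numeric(1))
  best <- cands[[which.min(score)]]

  # local integer descent on the SSD surface, then subpixel parabola
  repeat {
    moved <- FALSE
    for (step in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      cand <- best + step
      if (ssd(cand[1], cand[2]) < ssd(best[1], best[2])) {
        best <- cand; moved <- TRUE
      }
    }
    if (!moved) break
  }
  s0 <- ssd(best[1], best[2])
  dxo <- parabolic_offset(-ssd(best[1] - 1, best[2]), -s0,
                          -ssd(best[1] + 1, best[2]))
  dyo <- parabolic_offset(-ssd(best[1], best[2] - 1), -s0,
                          -ssd(best[1], best[2] + 1))
  c(dx = best[1] + dxo, dy = best[2] + dyo)
}

# translate a frame by (-dx, -dy) with bilinear sampling, edge replication
shift_frame <- function(frame, dx, dy) {
  h <- nrow(frame); w <- ncol(frame)
  xs <- rep(0:(w - 1), each = h) + dx
  ys <- rep(0:(h - 1), times = w) + dy
  matrix(bilinear(frame, xs, ys), h, w)
}

#' Stabilize a clip by removing per-frame translation
#'
#' Camera-shake compensation for slit-lamp footage: each frame's global
#' translation relative to a reference frame is estimated by phase
#' correlation (cross-power spectrum with Hann windowing, subpixel peak
#' refinement by local quadratic fit) and removed by bilinear resampling
#' with edge replication. Only translation is corrected; rotation in
#' slit-lamp footage is negligible, a documented limitation.
#'
#' @param clip a single-channel [video_clip()] with at least 2 frames.
#' @param reference_index 0-based index of the reference frame (default:
#'   first frame, the frame immediately after the blink when called on a
#'   post-blink segment).
#' @return a list with elements `clip` (stabilized [video_clip()]) and
#'   `shifts` (class `shift_trace`: data frame `frame`, `dx`, `dy` of the
#'   estimated shifts relative to the reference; exactly 0 at the
#'   reference frame), plus `reference_index`.
#' @export
stabilize <- function(clip, reference_index = 0) {
  stopifnot(inherits(clip, "video_clip"))
  if (clip$channel_tag == "rgb")
    stop_aquacol("stabilize a single-channel clip", "aquacol_parameter_error")
  t <- n_frames(clip)
  if (t < 2)
    stop_aquacol("stabilization needs at least 2 frames",
                 "aquacol_parameter_error")
  if (!is_count(reference_index, positive = FALSE) || reference_index >= t)
    stop_aquacol("reference_index out of range", "aquacol_parameter_error")
  ref <- clip$frames[, , reference_index + 1]
  degenerate_ref <- stats::sd(ref) == 0
  if (degenerate_ref)
    warning("reference frame is constant; shifts set to zero")
  dx <- numeric(t); dy <- numeric(t)
  degen <- logical(t)
  for (i in seq_len(t)) {
    if (stats::sd(clip$frames[, , i]) == 0) {
      degen[i] <- TRUE
      if (!degenerate_ref && i != reference_index + 1)
        warning(sprintf("frame %d is constant; shift 0", i - 1))
    }
  }
  # first pass: sequential frame-to-frame estimates, accumulated into
  # shifts relative to the reference (consecutive shifts are small, so
  # each pairwise match is easy and the sum provides a trustworthy prior
  # even for frames far from the reference)
  if (!degenerate_ref) {
    step_dx <- numeric(t); step_dy <- numeric(t)
    for (i in seq_len(t)[-1]) {
      if (degen[i] || degen[i - 1]) next
      sh <- phase_correlate(clip$frames[, , i - 1], clip$frames[, , i])
      step_dx[i] <- sh[["dx"]]; step_dy[i] <- sh[["dy"]]
    }
    dx <- cumsum(step_dx) - cumsum(step_dx)[reference_index + 1]
    dy <- cumsum(step_dy) - cumsum(step_dy)[reference_index + 1]
    dx[degen] <- 0; dy[degen] <- 0
  }

  # second pass against the temporal median of the first-pass alignment:
  # internally moving structure (flowing blood speckle) averages out of
  # the median template, so it cannot attract the match the way it can
  # when registering frame against frame
  if (!degenerate_ref && t >= 3) {
    aligned <- clip$frames
    for (i in seq_len(t))
      if (!degen[i] && (dx[i] != 0 || dy[i] != 0))
        aligned[, , i] <- shift_frame(clip$frames[, , i], dx[i], dy[i])
    template <- apply(aligned, c(1, 2), stats::median)
    for (i in seq_len(t)) {
      if (degen[i]) next
      sh <- phase_correlate(template, clip$frames[, , i],
                            prior = c(dx[i], dy[i]))
      dx[i] <- sh[["dx"]]; dy[i] <- sh[["dy"]]
    }
    # the trace is defined relative to the reference frame
    dx <- dx - dx[reference_index + 1]
    dy <- dy - dy[reference_index + 1]
  }

  out <- clip$frames
  for (i in seq_len(t))
    if (dx[i] != 0 || dy[i] != 0)
      out[, , i] <- shift_frame(clip$frames[, , i], dx[i], dy[i])
  shifts <- data.frame(frame = 0:(t - 1), dx = dx, dy = dy)
  class(shifts) <- c("shift_trace", "data.frame")
  list(clip = video_clip(clamp01(out), clip$fps, clip$channel_tag),
       shifts = shifts,
       reference_index = as.integer(reference_index))
}
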
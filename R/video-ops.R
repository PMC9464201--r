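#' Extract the green channel from an RGB clip
#'
#' Hemoglobin video imaging relies on a green filter (505-575 nm), in which
#' hemoglobin absorbs strongly: blood lanes appear dark and the aqueous
#' column bright. When footage arrives as RGB, the green plane carries that
#' contrast and is the plane analyzed downstream.
#'
#' @param clip an RGB [video_clip()]. Single-channel clips are returned
#'   unchanged with a warning.
#' @return a single-channel [video_clip()] with `channel_tag`
#'   `"green-extracted"`.
#' @export
extract_green_channel <- function(clip) {
  stopifnot(inherits(clip, "video_clip"))
  if (clip$channel_tag != "rgb") {
    warning("clip is already single-channel; returning it unchanged")
    return(clip)
  }
  video_clip(clip$frames[, , 2, , drop = TRUE], clip$fps, "green-extracted")
}

#' Halve the frame rate by dropping alternate frames
#'
#' 60 fps capture is reduced to 30 fps for analysis by keeping every other
#' frame. Frames with even 0-based index are kept (a fixed convention; which
#' alternate frame is dropped is immaterial to the downstream measurements).
#'
#' @param clip a [video_clip()], nominally at 60 fps (a warning is issued
#'   otherwise).
#' @return a [video_clip()] with `ceiling(n/2)` frames at half the frame
#'   rate.
#' @export
subsample_alternate_frames <- function(clip) {
  stopifnot(inherits(clip, "video_clip"))
  if (abs(clip$fps - 60) > 1e-6)
    warning(sprintf("clip fps is %.4g, not 60; subsampling anyway", clip$fps))
  t <- n_frames(clip)
  keep <- seq(1L, t, by = 2L)
  frames <- if (clip$channel_tag == "rgb") clip$frames[, , , keep, drop = FALSE]
            else clip$frames[, , keep, drop = FALSE]
  video_clip(frames, clip$fps / 2, clip$channel_tag)
}
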
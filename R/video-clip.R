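#' Video clip container
#'
#' A `video_clip` holds an ordered stack of frames with a frame rate and a
#' channel tag. Grayscale clips store frames as a numeric array of dimension
#' `height x width x n_frames`; RGB clips as `height x width x 3 x n_frames`.
#' Intensities are on a common `[0, 1]` scale.
#'
#' @param frames numeric array, `h x w x t` (grayscale) or `h x w x 3 x t`
#'   (RGB), values in `[0, 1]`.
#' @param fps positive frame rate in frames per second.
#' @param channel_tag one of `"grayscale"`, `"green-extracted"`, `"rgb"`.
#' @return an object of class `video_clip`.
#' @export
video_clip <- function(frames, fps,
                       channel_tag = c("grayscale", "green-extracted", "rgb")) {
  channel_tag <- match.arg(channel_tag)
  if (!is.array(frames) || !is.numeric(frames))
    stop_aquacol("`frames` must be a numeric array", "aquacol_parameter_error")
  nd <- length(dim(frames))
  if (channel_tag == "rgb") {
    if (nd != 4L || dim(frames)[3] != 3L)
      stop_aquacol("rgb clips need a h x w x 3 x t array",
                   "aquacol_parameter_error")
  } else if (nd != 3L) {
    stop_aquacol("single-channel clips need a h x w x t array",
                 "aquacol_parameter_error")
  }
  if (!is_number(fps) || fps <= 0)
    stop_aquacol("`fps` must be a positive number", "aquacol_parameter_error")
  if (dim(frames)[nd] < 1L)
    stop_aquacol("clip needs at least one frame", "aquacol_parameter_error")
  rng <- range(frames)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop_aquacol("frame intensities must lie in [0, 1]",
                 "aquacol_parameter_error")
  structure(list(frames = frames, fps = fps, channel_tag = channel_tag),
            class = "video_clip")
}

#' Number of frames in a clip
#' @param clip a [video_clip()].
#' @return integer frame count.
#' @export
n_frames <- function(clip) {
  stopifnot(inherits(clip, "video_clip"))
  unname(dim(clip$frames)[length(dim(clip$frames))])
}

#' Extract one frame
#' @param clip a [video_clip()].
#' @param index 0-based frame index (frame indices are 0-based throughout the
#'   package, matching video-frame conventions).
#' @return a numeric matrix (grayscale) or `h x w x 3` array (RGB).
#' @export
clip_frame <- function(clip, index) {
  stopifnot(inherits(clip, "video_clip"))
  t <- n_frames(clip)
  if (!is_count(index, positive = FALSE) || index >= t)
    stop_aquacol("frame index out of range", "aquacol_parameter_error")
  if (clip$channel_tag == "rgb") clip$frames[, , , index + 1]
  else clip$frames[, , index + 1]
}

frame_dims <- function(clip) dim(clip$frames)[1:2]

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_clip> %d x %d px, %d frame(s), %.4g fps, %s\n",
              d[2], d[1], d[length(d)], x$fps, x$channel_tag))
  invisible(x)
}
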
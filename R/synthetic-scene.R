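#' Parameters of a synthetic episcleral-vein scene
#'
#' Describes a vein video with known ground truth: a bright central aqueous
#' column flanked by darker blood lanes carrying moving speckle, on a
#' brighter scleral background, with optional blink dimming, camera jitter
#' and sensor noise. The noiseless cross-sectional intensity profile is
#' built so that its two local minima (the blood-lane centers at the column
#' edges) lie exactly `column_width_px` apart: the ground-truth width is
#' exact by construction, not fitted.
#'
#' @param image_height_px,image_width_px frame dimensions in pixels.
#' @param axis_point `(x, y)` point (0-based pixel coordinates) the vessel
#'   axis passes through.
#' @param axis_angle_deg axis direction in degrees (0 = along +x).
#' @param vessel_width_px full vessel width (background-to-background), px.
#' @param column_width_px true aqueous column width: the distance between
#'   the two blood-lane intensity minima of the noiseless cross-section, px.
#' @param flow_speed_px_per_frame speckle advection speed along the axis,
#'   px/frame (0 = static blood).
#' @param background_intensity,aqueous_intensity,blood_intensity scene
#'   intensities in `[0, 1]`; the aqueous core must be brighter than the
#'   blood lanes.
#' @param speckle_grain_px correlation length (Gaussian sd) of the blood
#'   speckle texture, px.
#' @param speckle_turnover frame-to-frame correlation of the speckle
#'   texture itself (AR(1)): red blood cells rearrange as they travel, so
#'   the pattern decorrelates over a few frames on top of being advected.
#'   1 = frozen pattern, purely advected.
#' @param background_texture_amp amplitude (intensity units per texture
#'   sd) of the static scleral texture outside the vessel; it anchors
#'   registration the way episcleral surface detail does. Set to 0 for a
#'   featureless plateau.
#' @param background_texture_grain_px correlation length of that texture,
#'   px.
#' @param noise_sd additive white sensor noise sd (intensity units).
#' @param jitter_sd_px per-frame global translation sd (camera shake), px.
#' @param blink_frames list of `c(start, length)` frame intervals (0-based
#'   start) during which the frame is globally dimmed by `blink_factor`.
#' @param blink_factor multiplicative occlusion factor applied during
#'   blinks; must be below 0.5 so blinks are unambiguous intensity dips.
#' @param fps nominal frame rate.
#' @param n_frames number of frames to render.
#' @param seed integer seed governing all randomness of the render.
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(image_height_px = 120,
                         image_width_px = 160,
                         axis_point = c((image_width_px - 1) / 2,
                                        (image_height_px - 1) / 2),
                         axis_angle_deg = 0,
                         vessel_width_px = 60,
                         column_width_px = 30,
                         flow_speed_px_per_frame = 2,
                         background_intensity = 0.5,
                         aqueous_intensity = 0.9,
                         blood_intensity = 0.15,
                         speckle_grain_px = 2,
                         speckle_turnover = 0.9,
                         background_texture_amp = 0.1,
                         background_texture_grain_px = 2,
                         noise_sd = 0.01,
                         jitter_sd_px = 0.5,
                         blink_frames = list(),
                         blink_factor = 0.3,
                         fps = 60,
                         n_frames = 60,
                         seed = 1L) {
  p <- list(image_height_px = image_height_px, image_width_px = image_width_px,
            axis_point = axis_point, axis_angle_deg = axis_angle_deg,
            vessel_width_px = vessel_width_px, column_width_px = column_width_px,
            flow_speed_px_per_frame = flow_speed_px_per_frame,
            background_intensity = background_intensity,
            aqueous_intensity = aqueous_intensity,
            blood_intensity = blood_intensity,
            speckle_grain_px = speckle_grain_px,
            speckle_turnover = speckle_turnover,
            background_texture_amp = background_texture_amp,
            background_texture_grain_px = background_texture_grain_px,
            noise_sd = noise_sd,
            jitter_sd_px = jitter_sd_px, blink_frames = blink_frames,
            blink_factor = blink_factor, fps = fps, n_frames = n_frames,
            seed = as.integer(seed))
  validate_scene_params(p)
  structure(p, class = "scene_params")
}

validate_scene_params <- function(p) {
  ok_dim <- is_count(p$image_height_px) && is_count(p$image_width_px)
  if (!ok_dim)
    stop_aquacol("image dimensions must be positive integers",
                 "aquacol_parameter_error")
  if (!is_number(p$column_width_px) || !is_number(p$vessel_width_px) ||
      p$column_width_px <= 0 ||
      p$column_width_px >= p$vessel_width_px ||
      p$vessel_width_px >= min(p$image_height_px, p$image_width_px))
    stop_aquacol(
      "need 0 < column_width_px < vessel_width_px < min(image dims)",
      "aquacol_parameter_error")
  ints <- c(p$background_intensity, p$aqueous_intensity, p$blood_intensity)
  if (any(!vapply(ints, is_number, TRUE)) || any(ints < 0) || any(ints > 1))
    stop_aquacol("intensities must lie in [0, 1]", "aquacol_parameter_error")
  if (p$blood_intensity >= p$aqueous_intensity)
    stop_aquacol("blood_intensity must be below aqueous_intensity",
                 "aquacol_parameter_error")
  if (p$blood_intensity >= p$background_intensity)
    stop_aquacol("blood_intensity must be below background_intensity",
                 "aquacol_parameter_error")
  if (!is_number(p$flow_speed_px_per_frame) || p$flow_speed_px_per_frame < 0)
    stop_aquacol("flow speed must be nonnegative", "aquacol_parameter_error")
  if (!is_number(p$noise_sd) || p$noise_sd < 0 ||
      !is_number(p$jitter_sd_px) || p$jitter_sd_px < 0)
    stop_aquacol("noise_sd and jitter_sd_px must be nonnegative",
                 "aquacol_parameter_error")
  if (!is_number(p$speckle_grain_px) || p$speckle_grain_px <= 0)
    stop_aquacol("speckle_grain_px must be positive", "aquacol_parameter_error")
  if (!is_number(p$speckle_turnover) || p$speckle_turnover < 0 ||
      p$speckle_turnover > 1)
    stop_aquacol("speckle_turnover must lie in [0, 1]",
                 "aquacol_parameter_error")
  if (!is_number(p$background_texture_amp) || p$background_texture_amp < 0 ||
      !is_number(p$background_texture_grain_px) ||
      p$background_texture_grain_px <= 0)
    stop_aquacol("background texture amplitude must be nonnegative and grain positive",
                 "aquacol_parameter_error")
  if (2.2 * p$background_texture_amp >= p$background_intensity - p$blood_intensity)
    stop_aquacol(paste("background texture (clamped at 2.2 sd) may not dip below",
                       "the blood lanes: need 2.2 * amp < background - blood"),
                 "aquacol_parameter_error")
  if (!is_number(p$blink_factor) || p$blink_factor <= 0 || p$blink_factor >= 0.5)
    stop_aquacol("blink_factor must lie in (0, 0.5)", "aquacol_parameter_error")
  if (!is_count(p$n_frames) || !is_number(p$fps) || p$fps <= 0)
    stop_aquacol("need n_frames >= 1 and fps > 0", "aquacol_parameter_error")
  for (b in p$blink_frames) {
    if (length(b) != 2 || b[1] < 0 || b[2] < 1 ||
        b[1] + b[2] > p$n_frames)
      stop_aquacol("blink intervals must lie within [0, n_frames)",
                   "aquacol_parameter_error")
  }
  invisible(p)
}

# cubic Hermite segment: value/slope (y0, s0) at x0 and (y1, s1) at x1
hermite <- function(x, x0, x1, y0, s0, y1, s1) {
  L <- x1 - x0
  t <- (x - x0) / L
  t2 <- t * t; t3 <- t2 * t
  y0 * (2 * t3 - 3 * t2 + 1) + s0 * L * (t3 - 2 * t2 + t) +
    y1 * (-2 * t3 + 3 * t2) + s1 * L * (t3 - t2)
}

# Noiseless cross-sectional intensity as a function of signed distance d
# from the vessel axis. The blood-lane minima at d = +/- column/2 sit at
# the bottom of a quadratic valley that is locally even around each
# minimum, so Gaussian smoothing (which preserves even symmetry) cannot
# displace them: the ground-truth width is exact by construction. C^1
# cubic segments join the valley to the bright aqueous peak at d = 0 and
# to the background plateau at |d| >= vessel/2.
vein_profile <- function(d, p) {
  m <- p$column_width_px / 2
  v <- p$vessel_width_px / 2
  rho <- min(0.5 * min(m, v - m), 8)    # valley half-width; capped so the
                                        # valley stays steep for wide vessels
  E <- 0.5 * min(p$aqueous_intensity - p$blood_intensity,
                 p$background_intensity - p$blood_intensity)
  c2 <- E / rho^2
  a <- abs(d)
  out <- rep(p$background_intensity, length(d))
  val <- a >= m - rho & a <= m + rho
  out[val] <- p$blood_intensity + c2 * (a[val] - m)^2
  core <- a < m - rho
  out[core] <- hermite(a[core], 0, m - rho, p$aqueous_intensity, 0,
                       p$blood_intensity + E, -2 * c2 * rho)
  flank <- a > m + rho & a < v
  out[flank] <- hermite(a[flank], m + rho, v, p$blood_intensity + E,
                        2 * c2 * rho, p$background_intensity, 0)
  out
}

# weight of the moving speckle texture across the vessel: a smooth bump
# over each blood lane with a guard gap at the lane minima and the vessel
# edge, so speckle cannot move the ground-truth minima
lane_weight <- function(d, p) {
  m <- p$column_width_px / 2
  v <- p$vessel_width_px / 2
  g <- 0.35 * (v - m)
  a <- abs(d)
  w <- numeric(length(d))
  inside <- a > m + g & a < v - g
  w[inside] <- sin(pi * (a[inside] - m - g) / (v - m - 2 * g))^2
  w
}

# weight of the static scleral texture: zero inside the vessel and at its
# edge, ramping to one over 4 px of the background plateau
background_weight <- function(d, p) {
  v <- p$vessel_width_px / 2
  smoothstep((abs(d) - v) / 4)
}

# stationary band-limited speckle field on an (s, d) grid, unit sd;
# advection samples it at s - speed * t
make_speckle_field <- function(s_range, d_range, grain) {
  s_grid <- seq(floor(s_range[1]) - 1, ceiling(s_range[2]) + 1)
  d_grid <- seq(floor(d_range[1]) - 1, ceiling(d_range[2]) + 1)
  z <- matrix(stats::rnorm(length(d_grid) * length(s_grid)),
              length(d_grid), length(s_grid))
  k <- gaussian_kernel(grain)
  z <- apply(z, 2, smooth_reflect, kernel = k)
  z <- t(apply(z, 1, smooth_reflect, kernel = k))
  z <- (z - mean(z)) / stats::sd(z)
  list(values = z, s0 = s_grid[1], d0 = d_grid[1])
}

#' Render a synthetic vein video with ground truth
#'
#' Produces a deterministic function of `params` (including its seed): the
#' same parameters always give bit-identical frame stacks. Randomness (one
#' generator) covers, in order, the speckle texture, per-frame jitter and
#' sensor noise.
#'
#' @param params a [scene_params()] object.
#' @return a list with elements `clip` (a grayscale [video_clip()]) and
#'   `truth` (class `ground_truth`: per-frame applied jitter `shifts`
#'   data frame with columns `frame`, `dx`, `dy`; `column_width_px`;
#'   `flow_speed_px_per_frame`; 0-based `blink_frames` vector).
#' @export
render_video <- function(params) {
  if (!inherits(params, "scene_params")) params <- do.call(scene_params, params)
  validate_scene_params(params)
  p <- params
  h <- p$image_height_px; w <- p$image_width_px; nt <- p$n_frames
  th <- p$axis_angle_deg * pi / 180
  ax <- cos(th); ay <- sin(th)      # axis direction
  nx <- -sin(th); ny <- cos(th)     # normal direction

  xs <- rep(0:(w - 1), each = h)
  ys <- rep(0:(h - 1), times = w)

  with_seed(p$seed, {
    # coordinate extents over all frames, with slack for jitter excursions
    pad <- 6 * p$jitter_sd_px + 2
    s_all <- (c(0, w - 1, 0, w - 1) - p$axis_point[1]) * ax +
             (c(0, 0, h - 1, h - 1) - p$axis_point[2]) * ay
    s_lo <- min(s_all) - pad - p$flow_speed_px_per_frame * (nt - 1) - 1
    s_hi <- max(s_all) + pad
    v <- p$vessel_width_px / 2
    speckle <- make_speckle_field(c(s_lo, s_hi), c(-v, v), p$speckle_grain_px)
    fresh_speckle <- function() {
      f <- make_speckle_field(c(s_lo, s_hi), c(-v, v), p$speckle_grain_px)
      f$values
    }

    # static scleral texture in image coordinates (moves only with jitter)
    bg <- if (p$background_texture_amp > 0)
      make_speckle_field(c(-pad, w - 1 + pad), c(-pad, h - 1 + pad),
                         p$background_texture_grain_px)
    else NULL

    dx <- if (p$jitter_sd_px > 0) stats::rnorm(nt, 0, p$jitter_sd_px) else numeric(nt)
    dy <- if (p$jitter_sd_px > 0) stats::rnorm(nt, 0, p$jitter_sd_px) else numeric(nt)

    blink_set <- integer(0)
    for (b in p$blink_frames)
      blink_set <- c(blink_set, seq(b[1], length.out = b[2]))
    blink_set <- sort(unique(as.integer(blink_set)))

    speckle_amp <- 0.12
    frames <- array(0, c(h, w, nt))
    for (t in seq_len(nt)) {
      # scene translated by (dx, dy): sample scene coordinates at the
      # un-shifted position
      px <- xs - dx[t] - p$axis_point[1]
      py <- ys - dy[t] - p$axis_point[2]
      d <- px * nx + py * ny
      s <- px * ax + py * ay
      if (t > 1 && p$speckle_turnover < 1)
        speckle$values <- p$speckle_turnover * speckle$values +
          sqrt(1 - p$speckle_turnover^2) * fresh_speckle()
      frame <- vein_profile(d, p)
      lw <- lane_weight(d, p)
      in_lane <- lw > 0
      if (any(in_lane)) {
        sp <- bilinear(speckle$values,
                       x = s[in_lane] - p$flow_speed_px_per_frame * (t - 1) -
                         speckle$s0,
                       y = d[in_lane] - speckle$d0)
        frame[in_lane] <- frame[in_lane] + speckle_amp * lw[in_lane] *
          pmin(pmax(sp, -2.5), 2.5)
      }
      if (!is.null(bg)) {
        wb <- background_weight(d, p)
        on_bg <- wb > 0
        tex <- bilinear(bg$values, x = px[on_bg] + p$axis_point[1] - bg$s0,
                        y = py[on_bg] + p$axis_point[2] - bg$d0)
        # dark-dominant texture: scleral vessels absorb strongly in green
        # light while inter-vessel brightness varies mildly, and capping
        # the bright side keeps the plateau below the aqueous core
        frame[on_bg] <- frame[on_bg] + p$background_texture_amp *
          wb[on_bg] * pmin(pmax(tex, -2.2), 0.6)
      }
      if ((t - 1L) %in% blink_set) frame <- frame * p$blink_factor
      if (p$noise_sd > 0)
        frame <- frame + stats::rnorm(length(frame), 0, p$noise_sd)
      frames[, , t] <- matrix(clamp01(frame), h, w)
    }
  })

  truth <- structure(
    list(shifts = data.frame(frame = 0:(nt - 1), dx = dx, dy = dy),
         column_width_px = p$column_width_px,
         flow_speed_px_per_frame = p$flow_speed_px_per_frame,
         blink_frames = blink_set),
    class = "ground_truth")
  list(clip = video_clip(frames, p$fps, "grayscale"), truth = truth)
}

#' A sampling line across the rendered vessel
#'
#' Convenience: the line through the scene's axis point, perpendicular to
#' the vessel axis, spanning the full vessel plus margin — the canonical
#' measurement-line placement for width analysis on synthetic clips.
#'
#' @param params a [scene_params()] object.
#' @param margin_px extra half-length beyond the vessel half-width.
#' @return a [sampling_line()].
#' @export
scene_cross_section_line <- function(params, margin_px = 8) {
  half <- params$vessel_width_px / 2 + margin_px
  th <- params$axis_angle_deg * pi / 180
  nx <- -sin(th); ny <- cos(th)
  sampling_line(params$axis_point[1] - half * nx,
                params$axis_point[2] - half * ny,
                params$axis_point[1] + half * nx,
                params$axis_point[2] + half * ny)
}

#' Blood-lane pixel mask for a synthetic scene
#'
#' The pixels (at zero jitter) whose moving-speckle weight is at least
#' `min_weight`: the lane-center band where the advected blood texture is
#' strongest. This is the natural region of interest for the flow metric
#' on synthetic clips.
#'
#' @param params a [scene_params()] object.
#' @param min_weight minimum speckle weight (0-1).
#' @return a logical matrix of frame size.
#' @export
scene_lane_mask <- function(params, min_weight = 0.5) {
  stopifnot(inherits(params, "scene_params"))
  h <- params$image_height_px; w <- params$image_width_px
  th <- params$axis_angle_deg * pi / 180
  xs <- rep(0:(w - 1), each = h) - params$axis_point[1]
  ys <- rep(0:(h - 1), times = w) - params$axis_point[2]
  d <- xs * (-sin(th)) + ys * cos(th)
  matrix(lane_weight(d, params) >= min_weight, h, w)
}
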
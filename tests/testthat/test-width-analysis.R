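test_that("profile extraction reproduces raw pixels on axis-aligned lines", {
  set.seed(2)
  frame <- matrix(runif(20 * 30), 20, 30)
  # horizontal line along row y = 7 (0-based), columns 3..23
  prof <- extract_profile(frame, sampling_line(3, 7, 23, 7))
  expect_equal(prof$intensities, frame[8, 4:24])
  expect_equal(prof$positions, 0:20)
  # constant frame -> constant profile, any direction
  cf <- matrix(0.42, 20, 30)
  prof2 <- extract_profile(cf, sampling_line(1.5, 2.5, 25, 17))
  expect_true(all(abs(prof2$intensities - 0.42) < 1e-12))
  # line outside the frame errors
  expect_error(extract_profile(frame, sampling_line(-2, 0, 10, 0)),
               class = "aquacol_parameter_error")
})

test_that("a vertical dark stripe is located by a horizontal profile", {
  frame <- matrix(0.8, 40, 60)
  frame[, 24 + 1] <- 0.1  # stripe at x = 24 (0-based)
  frame[, 24] <- 0.4
  frame[, 24 + 2] <- 0.4
  prof <- extract_profile(frame, sampling_line(5, 20, 55, 20))
  expect_equal(prof$positions[which.min(prof$intensities)] + 5, 24,
               tolerance = 0.5 / 24)
})

test_that("width of a closed-form double-well profile is exact", {
  # piecewise profile with quadratic wells centered exactly at 12 and 52,
  # a raised-cosine bright core between them, linear rises outside
  f <- function(x) {
    v <- numeric(length(x))
    well <- function(c0) 0.15 + 0.004 * (x - c0)^2
    core <- 0.346 + (0.9 - 0.346) * 0.5 * (1 - cos(2 * pi * (x - 19) / 26))
    v <- ifelse(x < 5, 0.346 + 0.03 * (5 - x),
         ifelse(x <= 19, well(12),
         ifelse(x < 45, core,
         ifelse(x <= 59, well(52), 0.346 + 0.03 * (x - 59)))))
    v
  }
  prof <- structure(list(positions = 0:64, intensities = f(0:64),
                         spacing = 1), class = "intensity_profile")
  expect_equal(measure_width(prof), 40, tolerance = 0.1 / 40)
  # insensitive to a half-sample phase of the grid
  prof2 <- structure(list(positions = 0:63 + 0.5,
                          intensities = f(0:63 + 0.5), spacing = 1),
                     class = "intensity_profile")
  expect_equal(measure_width(prof2), 40, tolerance = 0.1 / 40)
})

test_that("degenerate profiles raise an unmeasurable error", {
  expect_error(measure_width(seq(0, 1, length.out = 50)),
               class = "aquacol_unmeasurable")   # monotone ramp
  expect_error(measure_width(c(0.2, 0.5, 0.3)),
               class = "aquacol_unmeasurable")   # too short
  expect_error(measure_width(0.5 - abs(seq(-1, 1, length.out = 30))^2),
               class = "aquacol_unmeasurable")   # single peak, no wells
})

test_that("noiseless render measures at the constructed column width", {
  p <- width_scene(40, seed = 2, noise_sd = 0)
  r <- render_video(p)
  m <- measure_width_clip(r$clip, scene_cross_section_line(p))
  expect_equal(m$mean_width_px, 40, tolerance = 0.5 / 40)
})

test_that("width is recovered within a pixel across the width range", {
  for (w in c(10, 40, 80)) {
    p <- width_scene(w, seed = w, noise_sd = 0.03)
    m <- measure_width_clip(render_video(p)$clip, scene_cross_section_line(p))
    expect_lt(abs(m$mean_width_px - w), 1)
  }
})

test_that("measurement is invariant to translating frame and line together", {
  p <- width_scene(30, seed = 6, noise_sd = 0)
  frame <- clip_frame(render_video(p)$clip, 0)
  l0 <- scene_cross_section_line(p)
  w0 <- measure_width(extract_profile(frame, l0))
  shifted <- aquacol:::shift_frame(frame, -2.3, -1.7)  # scene moved (+2.3, +1.7)
  l1 <- sampling_line(l0$x0 + 2.3, l0$y0 + 1.7, l0$x1 + 2.3, l0$y1 + 1.7)
  w1 <- measure_width(extract_profile(shifted, l1))
  expect_equal(w1, w0, tolerance = 0.1 / w0)
})

test_that("clip measurement enforces frame count and failure threshold", {
  p <- quick_scene(n_frames = 10)
  clip <- render_video(p)$clip
  expect_error(measure_width_clip(clip, scene_cross_section_line(p),
                                  n_frames = 30),
               class = "aquacol_parameter_error")
  # a line on the featureless background is unmeasurable on every frame
  plain <- render_video(quick_scene(background_texture_amp = 0))$clip
  flat <- sampling_line(5, 2, 95, 2)
  expect_error(measure_width_clip(plain, flat, n_frames = 10),
               class = "aquacol_measurement_failure")
})

test_that("static noiseless clips give identical per-frame widths", {
  p <- quick_scene(flow_speed_px_per_frame = 0, speckle_turnover = 1,
                   n_frames = 10)
  m <- measure_width_clip(render_video(p)$clip, scene_cross_section_line(p),
                          n_frames = 10)
  expect_equal(m$sd_width_px, 0)
  expect_equal(m$n_excluded, 0)
})

test_that("observer averaging and percent change are plain arithmetic", {
  expect_equal(average_observers(80, 82), 81)
  p <- quick_scene(n_frames = 10)
  m <- measure_width_clip(render_video(p)$clip, scene_cross_section_line(p),
                          n_frames = 10)
  expect_equal(average_observers(m, m), m$mean_width_px)
  expect_equal(percent_change(50, 50), 0)
  expect_equal(percent_change(50, 75), 50)
  expect_equal(percent_change(63.7, 81.2), 100 * (81.2 - 63.7) / 63.7)
  expect_error(percent_change(0, 10), class = "aquacol_parameter_error")
})

test_that("two offset line placements average back to the truth", {
  p <- width_scene(40, seed = 3, noise_sd = 0.02)
  clip <- render_video(p)$clip
  l <- scene_cross_section_line(p)
  m1 <- measure_width_clip(clip, sampling_line(l$x0 - 2, l$y0, l$x1 - 2, l$y1),
                           observer_label = "A")
  m2 <- measure_width_clip(clip, sampling_line(l$x0 + 2, l$y0, l$x1 + 2, l$y1),
                           observer_label = "B")
  expect_lt(abs(average_observers(m1, m2) - 40), 1)
})
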
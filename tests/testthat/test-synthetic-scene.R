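test_that("scene parameter invariants are enforced", {
  expect_error(scene_params(column_width_px = 50, vessel_width_px = 40),
               class = "aquacol_parameter_error")
  expect_error(scene_params(vessel_width_px = 200, image_height_px = 100),
               class = "aquacol_parameter_error")
  expect_error(scene_params(blood_intensity = 0.95),
               class = "aquacol_parameter_error")
  expect_error(scene_params(aqueous_intensity = 1.4),
               class = "aquacol_parameter_error")
  expect_error(scene_params(blink_frames = list(c(55, 10)), n_frames = 60),
               class = "aquacol_parameter_error")
  expect_error(scene_params(noise_sd = -0.1),
               class = "aquacol_parameter_error")
})

test_that("noiseless cross-section has its minima exactly a column width apart", {
  for (cw in c(12, 20, 40)) {
    p <- scene_params(image_height_px = 2 * cw + 60,
                      image_width_px = 2 * cw + 60,
                      column_width_px = cw, vessel_width_px = 2 * cw,
                      noise_sd = 0, jitter_sd_px = 0,
                      background_texture_amp = 0, n_frames = 1, seed = 1)
    # evaluate the analytic profile on a fine grid across the vessel
    d <- seq(-cw - 5, cw + 5, by = 0.01)
    f <- aquacol:::vein_profile(d, p)
    mins <- d[c(FALSE, diff(sign(diff(f))) > 0, FALSE)]
    expect_length(mins, 2)
    expect_equal(diff(mins), cw, tolerance = 0.02 / cw)
  }
})

test_that("rendering is a pure function of the scene parameters", {
  p <- quick_scene(noise_sd = 0.02, jitter_sd_px = 1)
  r1 <- render_video(p)
  r2 <- render_video(p)
  expect_identical(r1$clip$frames, r2$clip$frames)
  expect_identical(r1$truth$shifts, r2$truth$shifts)
  # a different seed changes the render
  r3 <- render_video(quick_scene(noise_sd = 0.02, jitter_sd_px = 1, seed = 2))
  expect_false(identical(r1$clip$frames, r3$clip$frames))
})

test_that("rendering leaves the caller's RNG stream untouched", {
  set.seed(123)
  a <- rnorm(3)
  set.seed(123)
  invisible(render_video(quick_scene()))
  b <- rnorm(3)
  expect_identical(a, b)
})

test_that("ground truth records one shift pair per frame and the blink set", {
  p <- quick_scene(n_frames = 20, jitter_sd_px = 1.5,
                   blink_frames = list(c(5, 3), c(12, 2)))
  r <- render_video(p)
  expect_equal(nrow(r$truth$shifts), 20)
  expect_equal(r$truth$blink_frames, c(5:7, 12:13))
  expect_equal(r$truth$column_width_px, p$column_width_px)
  expect_equal(r$truth$flow_speed_px_per_frame, p$flow_speed_px_per_frame)
})

test_that("blink frames are dimmed well below the surrounding intensity", {
  p <- scene_params(n_frames = 120, blink_frames = list(c(100, 5)),
                    noise_sd = 0.01, seed = 3)
  r <- render_video(p)
  blink_mean <- mean(clip_frame(r$clip, 102))
  pre_blink <- stats::median(vapply(80:99, function(i)
    mean(clip_frame(r$clip, i)), numeric(1)))
  expect_lt(blink_mean, 0.5 * pre_blink)
})

test_that("speckle advects along the axis at the configured speed", {
  # frozen pattern (no turnover), pure advection: lane pixels at frame t
  # match lane pixels up-axis at frame t + k
  p <- quick_scene(flow_speed_px_per_frame = 2, speckle_turnover = 1,
                   background_texture_amp = 0, n_frames = 6)
  r <- render_video(p)
  mask <- scene_lane_mask(p)
  row <- which(apply(mask, 1, any))[1]
  f0 <- clip_frame(r$clip, 0)[row, 21:60]
  f2 <- clip_frame(r$clip, 2)[row, 21:60 + 4]  # 2 frames * 2 px/frame
  expect_gt(stats::cor(f0, f2), 0.95)
})

test_that("crossover study generator matches its stated normal models", {
  # structure: 16 subjects, 8 per sequence, 6 rows each
  st <- render_crossover_study(seed = 5)
  tab <- st$table
  expect_equal(nrow(tab), 16 * 6)
  base1 <- tab[tab$timepoint == "baseline" & tab$period == 1, ]
  expect_equal(as.integer(table(base1$sequence)), c(8L, 8L))
  # drug determined by sequence and period
  expect_true(all(
    tab$drug == ifelse(tab$period == 1,
                       sub("-.*$", "", tab$sequence),
                       sub("^.*-", "", tab$sequence))))
  # law of large numbers on the headline effect: mean of 10,000 simulated
  # ripasudil 2 h percent changes within 28.8 +/- 0.5
  big <- render_crossover_study(study_design_params(n_subjects = 10000),
                                seed = 6)
  pc <- merge(big$table[big$table$timepoint == "2h", ],
              big$table[big$table$timepoint == "baseline",
                        c("subject_id", "drug", "width_px")],
              by = c("subject_id", "drug"), suffixes = c("", "_base"))
  rip <- pc[pc$drug == "ripasudil", ]
  expect_equal(mean(percent_change(rip$width_px_base, rip$width_px)), 28.8,
               tolerance = 0.5 / 28.8)
})

test_that("zero effect and zero noise give exactly zero percent change", {
  des <- study_design_params(
    baseline_sd = 0,
    effects = data.frame(drug = c("ripasudil", "ripasudil", "latanoprost",
                                  "latanoprost"),
                         timepoint = c("2h", "8h", "2h", "8h"),
                         mean = 0, sd = 0))
  st <- render_crossover_study(des, seed = 1)
  pc <- merge(st$table[st$table$timepoint != "baseline", ],
              st$table[st$table$timepoint == "baseline",
                       c("subject_id", "drug", "width_px")],
              by = c("subject_id", "drug"), suffixes = c("", "_base"))
  expect_equal(percent_change(pc$width_px_base, pc$width_px),
               rep(0, nrow(pc)))
})

test_that("study generator rejects invalid designs", {
  expect_error(study_design_params(n_subjects = 15),
               class = "aquacol_parameter_error")
  expect_error(study_design_params(baseline_sd = -1),
               class = "aquacol_parameter_error")
  bad_eff <- data.frame(drug = "ripasudil", timepoint = "2h",
                        mean = 10, sd = -2)
  expect_error(study_design_params(effects = bad_eff),
               class = "aquacol_parameter_error")
})
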
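# shared fixture builders; everything is generated in code at test time

# small fast scene for structural tests
quick_scene <- function(...) {
  args <- list(image_height_px = 80, image_width_px = 100,
               vessel_width_px = 40, column_width_px = 20,
               n_frames = 10, noise_sd = 0, jitter_sd_px = 0, seed = 1)
  do.call(scene_params, utils::modifyList(args, list(...)))
}

# geometry used for ground-truth width recovery: vessel twice the column,
# frame sized to the vessel
width_scene <- function(width, seed, noise_sd = 0.03, n_frames = 30, ...) {
  scene_params(image_height_px = 2 * width + 60,
               image_width_px = 2 * width + 80,
               column_width_px = width, vessel_width_px = 2 * width,
               noise_sd = noise_sd, jitter_sd_px = 0,
               n_frames = n_frames, seed = seed, ...)
}

# tiny deterministic rgb clip
tiny_rgb_clip <- function() {
  set.seed(5)
  fr <- array(runif(6 * 8 * 3 * 4), c(6, 8, 3, 4))
  video_clip(fr, fps = 60, channel_tag = "rgb")
}

# grayscale clip with values exactly on the 8-bit grid (AVI-exact)
quantized_clip <- function(h = 10, w = 12, t = 5, fps = 60, seed = 7) {
  set.seed(seed)
  video_clip(array(sample(0:255, h * w * t, replace = TRUE) / 255,
                   c(h, w, t)), fps, "grayscale")
}

# brute-force signed-rank two-sided p over all sign patterns
brute_signed_rank_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(d))))
  Vall <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(Vall <= V), mean(Vall >= V)))
}

# brute-force rank-sum two-sided p over all group assignments
brute_rank_sum_p <- function(x, y) {
  n <- length(x)
  rr <- rank(c(x, y))
  W <- sum(rr[seq_len(n)])
  Wall <- utils::combn(length(rr), n, FUN = function(i) sum(rr[i]))
  min(1, 2 * min(mean(Wall <= W), mean(Wall >= W)))
}

# direct-loop evaluation of the printed autocorrelation formula
loop_autocorrelation <- function(p, n, mu = mean(p),
                                 sigma2 = mean((p - mean(p))^2)) {
  T <- length(p)
  acc <- 0
  for (t in seq_len(T - n)) acc <- acc + (p[t] - mu) * (p[t + n] - mu)
  (acc / (T - n)) / sigma2
}
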
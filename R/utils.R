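# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# The seed argument is forced BEFORE the state is captured: a lazily
# supplied seed expression may itself consume random numbers (e.g.
# seed = sample.int(...)), and that draw must count against the caller's
# stream, not be rolled back.
with_seed <- function(seed, code) {
  seed <- as.integer(seed)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

is_count <- function(x, positive = TRUE) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) &&
    (if (positive) x >= 1 else x >= 0)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_aquacol <- function(msg, class) {
  stop(structure(class = c(class, "aquacol_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# cubic smoothstep on [0, 1]; zero derivative at both ends
smoothstep <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

# 1-D Gaussian kernel with sd `sigma` (in samples), radius 3*sigma
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# convolve with reflect padding, output same length
smooth_reflect <- function(x, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  n <- length(x)
  xp <- c(x[pmin(r:1 + 1L, n)], x, x[pmax(n - seq_len(r), 1L)])
  as.numeric(stats::filter(xp, kernel, sides = 2))[(r + 1L):(r + n)]
}

# bilinear interpolation of matrix `m` (rows = y, cols = x) at continuous
# 0-based pixel-center coordinates; coordinates are clamped to the frame
# (edge replication)
bilinear <- function(m, x, y) {
  h <- nrow(m); w <- ncol(m)
  x <- pmin(pmax(x, 0), w - 1)
  y <- pmin(pmax(y, 0), h - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- y0 + 1 + h * x0; i10 <- y0 + 1 + h * x1
  i01 <- y1 + 1 + h * x0; i11 <- y1 + 1 + h * x1
  m[i00] * (1 - fx) * (1 - fy) + m[i10] * fx * (1 - fy) +
    m[i01] * (1 - fx) * fy + m[i11] * fx * fy
}

# offset of the vertex of the parabola through (-1, ym1), (0, y0), (+1, yp1);
# returns 0 when the three points are collinear
parabolic_offset <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (!is.finite(den) || abs(den) < .Machine$double.eps * 100) return(0)
  d <- 0.5 * (ym1 - yp1) / den
  max(min(d, 0.5), -0.5)
}
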
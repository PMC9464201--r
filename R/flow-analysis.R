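#' Temporal autocorrelation of a pixel time series
#'
#' The flow metric is built on the normalized autocorrelation
#' `R(n) = E[(p(t) - mu)(p(t + n) - mu)] / sigma^2`, the expectation taken
#' over the `T - n` valid frame pairs (denominator `T - n`). Two
#' normalization conventions are supported:
#' \describe{
#'   \item{`per-pixel-temporal`}{`mu` and `sigma` are the series' own mean
#'     and (population) standard deviation, so `R(0) = 1` exactly and the
#'     curve is a correlation.}
#'   \item{`segment-spatial`}{`mu` and `sigma` are supplied from the
#'     segmented image region, as when one normalization is shared by all
#'     pixels of a segment.}
#' }
#'
#' @param series numeric vector, one pixel's intensities over `T >= 2`
#'   frames.
#' @param lag integer delay `n`, `0 <= n < T`.
#' @param convention normalization convention (see above).
#' @param mu,sigma segment mean and standard deviation; required under the
#'   `segment-spatial` convention, ignored otherwise.
#' @return the scalar `R(n)`.
#' @export
autocorrelation <- function(series, lag,
                            convention = c("per-pixel-temporal",
                                           "segment-spatial"),
                            mu = NULL, sigma = NULL) {
  convention <- match.arg(convention)
  p <- as.numeric(series)
  T <- length(p)
  if (T < 2) stop_aquacol("series needs at least 2 frames",
                          "aquacol_parameter_error")
  if (!is_count(lag, positive = FALSE) || lag >= T)
    stop_aquacol("lag must satisfy 0 <= n < T", "aquacol_parameter_error")
  if (convention == "per-pixel-temporal") {
    mu <- mean(p)
    sigma <- sqrt(mean((p - mu)^2))
  } else {
    if (!is_number(mu) || !is_number(sigma))
      stop_aquacol("segment-spatial convention needs mu and sigma",
                   "aquacol_parameter_error")
  }
  if (sigma <= 0)
    stop_aquacol("sigma is zero: constant (degenerate) signal",
                 "aquacol_degenerate_signal")
  idx <- seq_len(T - lag)
  mean((p[idx] - mu) * (p[idx + lag] - mu)) / sigma^2
}

#' Autocorrelation curve over lags 0..max_lag
#'
#' @inheritParams autocorrelation
#' @param max_lag largest lag, `< T`.
#' @return an object of class `autocorr_curve`: `lags`, `values`,
#'   `normalization_mu`, `normalization_sigma`, `convention_tag`.
#' @export
autocorrelation_curve <- function(series, max_lag,
                                  convention = c("per-pixel-temporal",
                                                 "segment-spatial"),
                                  mu = NULL, sigma = NULL) {
  convention <- match.arg(convention)
  p <- as.numeric(series)
  if (convention == "per-pixel-temporal") {
    mu <- mean(p)
    sigma <- sqrt(mean((p - mu)^2))
  }
  vals <- vapply(0:max_lag, function(n)
    autocorrelation(p, n, convention, mu = mu, sigma = sigma), numeric(1))
  structure(list(lags = 0:max_lag, values = vals,
                 normalization_mu = mu, normalization_sigma = sigma,
                 convention_tag = convention),
            class = "autocorr_curve")
}

#' @export
print.autocorr_curve <- function(x, ...) {
  cat(sprintf("<autocorr_curve> %s, lags 0..%d, mu=%.4g sigma=%.4g\n",
              x$convention_tag, max(x$lags), x$normalization_mu,
              x$normalization_sigma))
  print(round(stats::setNames(x$values, x$lags), 4))
  invisible(x)
}

#' Decorrelation-lag flow metric over a region of interest
#'
#' For each ROI pixel the per-pixel temporal autocorrelation curve is
#' computed and reduced to the decorrelation lag `n*`: the smallest lag at
#' which `R(n)` falls below `threshold`. Faster flow turns the speckle over
#' faster, giving smaller `n*`. The region summary is the median of
#' `1 / n*` (frames^-1) over pixels with a defined lag. Constant pixels
#' (degenerate) and pixels whose curve never crosses the threshold within
#' `max_lag` are excluded and counted; if every pixel is excluded the
#' result flags "no decorrelation detected" rather than erroring.
#'
#' @param clip a single-channel [video_clip()] with more than `max_lag`
#'   frames.
#' @param roi logical matrix of frame size (TRUE = analyze), or a list
#'   `list(x0, y0, x1, y1)` of an inclusive 0-based pixel rectangle.
#' @param max_lag largest lag examined.
#' @param threshold decorrelation threshold on `R(n)`.
#' @return an object of class `flow_estimate`: `n_star` (matrix, NA
#'   outside the ROI and where undefined), `flow_proxy` (median of
#'   `1/n*`), `median_lag`, counts `n_pixels`, `n_degenerate`,
#'   `n_no_decorrelation`, flag `no_decorrelation`, plus `threshold` and
#'   `max_lag`.
#' @export
flow_metric <- function(clip, roi, max_lag = 15, threshold = 0.5) {
  stopifnot(inherits(clip, "video_clip"))
  if (clip$channel_tag == "rgb")
    stop_aquacol("flow metric needs a single-channel clip",
                 "aquacol_parameter_error")
  d <- dim(clip$frames)
  h <- d[1]; w <- d[2]; T <- d[3]
  if (T <= max_lag)
    stop_aquacol("clip must be longer than max_lag", "aquacol_parameter_error")
  if (is.list(roi) && !is.matrix(roi)) {
    mask <- matrix(FALSE, h, w)
    mask[(roi$y0:roi$y1) + 1, (roi$x0:roi$x1) + 1] <- TRUE
    roi <- mask
  }
  stopifnot(is.logical(roi), all(dim(roi) == c(h, w)))
  idx <- which(roi)
  if (length(idx) == 0)
    stop_aquacol("ROI is empty", "aquacol_parameter_error")

  X <- matrix(clip$frames, h * w, T)[idx, , drop = FALSE]
  mu <- rowMeans(X)
  Xc <- X - mu
  v <- rowMeans(Xc^2)  # population variance, so R(0) = 1
  degen <- v <= 0

  npx <- length(idx)
  n_star <- rep(NA_real_, npx)
  undecided <- !degen
  for (n in seq_len(max_lag)) {
    if (!any(undecided)) break
    a <- seq_len(T - n)
    Rn <- rowMeans(Xc[, a, drop = FALSE] * Xc[, a + n, drop = FALSE]) / v
    hit <- undecided & Rn < threshold
    n_star[hit] <- n
    undecided <- undecided & !hit
  }

  defined <- !is.na(n_star)
  res <- structure(list(
    n_star = {
      m <- matrix(NA_real_, h, w); m[idx] <- n_star; m
    },
    flow_proxy = if (any(defined)) stats::median(1 / n_star[defined]) else NA_real_,
    median_lag = if (any(defined)) stats::median(n_star[defined]) else NA_real_,
    n_pixels = npx,
    n_degenerate = sum(degen),
    n_no_decorrelation = sum(undecided),
    no_decorrelation = !any(defined),
    threshold = threshold,
    max_lag = as.integer(max_lag),
    convention_tag = "per-pixel-temporal"),
    class = "flow_estimate")
  res
}

#' @export
print.flow_estimate <- function(x, ...) {
  if (x$no_decorrelation) {
    cat(sprintf("<flow_estimate> no decorrelation detected (%d px: %d degenerate, %d above threshold)\n",
                x$n_pixels, x$n_degenerate, x$n_no_decorrelation))
  } else {
    cat(sprintf("<flow_estimate> median lag %.3g frames, proxy %.4g /frame (%d px, %d excluded)\n",
                x$median_lag, x$flow_proxy, x$n_pixels,
                x$n_degenerate + x$n_no_decorrelation))
  }
  invisible(x)
}
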
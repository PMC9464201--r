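#' Pearson chi-square test for a 2x2 table
#'
#' Pearson's chi-square without continuity correction (df = 1, two-sided),
#' the form used for the baseline-characteristics comparisons.
#'
#' @param a,b,c,d cell counts, rows = groups: `[[a, b], [c, d]]`.
#' @return list with `statistic` and `p.value`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(!vapply(x, is_count, TRUE, positive = FALSE)))
    stop_aquacol("counts must be nonnegative integers",
                 "aquacol_parameter_error")
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    stop_aquacol("a zero margin makes the test undefined",
                 "aquacol_undefined_test")
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat, p.value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE))
}

#' Two-sample pooled-variance t-test from summary statistics
#'
#' Two-sided unpaired t-test computed from group means, standard
#' deviations and sizes (as needed when only summaries are reported).
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return the two-sided p-value.
#' @export
unpaired_t_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (!is_count(n1) || !is_count(n2) || n1 < 2 || n2 < 2 ||
      !is_number(sd1) || !is_number(sd2) || sd1 <= 0 || sd2 <= 0)
    stop_aquacol("need n >= 2 and positive sds", "aquacol_parameter_error")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * stats::pt(-abs(t), df = n1 + n2 - 2)
}

# exact distribution of the signed-rank statistic over sign patterns,
# on a doubled-rank integer grid (handles midranks under ties):
# counts[s + 1] = number of sign patterns with doubled positive-rank sum s
signed_rank_counts <- function(ranks2) {
  total <- sum(ranks2)
  counts <- numeric(total + 1)
  counts[1] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1 - r)])
    counts <- counts + shifted
  }
  counts
}

#' Wilcoxon signed-rank test
#'
#' Two-sided one-sample signed-rank test on paired differences, the
#' within-group test for change from baseline. Zero differences are
#' dropped (the classic Wilcoxon convention). For `n <= 25` non-zero
#' differences the p-value is exact, from the full distribution of the
#' statistic over all `2^n` sign patterns (computed by convolution on
#' doubled midranks, which keeps the distribution exact under ties);
#' otherwise a normal approximation with tie correction is used (no
#' continuity correction).
#'
#' @param differences numeric vector of paired differences; at least one
#'   must be non-zero.
#' @param exact_max largest `n` for which the exact distribution is used.
#' @return list with `statistic` (V, sum of positive ranks), `p.value`,
#'   `n_used` (non-zero differences) and `method`.
#' @export
wilcoxon_signed_rank <- function(differences, exact_max = 25) {
  d <- as.numeric(differences)
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    stop_aquacol("all differences are zero: test is degenerate",
                 "aquacol_degenerate_signal")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))
    counts <- signed_rank_counts(r2)
    tot <- 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(counts[seq_len(v2 + 1)]) / tot
    p_ge <- sum(counts[(v2 + 1):length(counts)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approximation"
  }
  list(statistic = V, p.value = p, n_used = n, method = method)
}

# exact null distribution of the doubled rank sum of a size-n subset of
# the combined doubled midranks: dp[k + 1, s + 1] = number of subsets of
# size k with doubled-rank sum s
rank_sum_counts <- function(ranks2, n) {
  total <- sum(ranks2)
  dp <- matrix(0, n + 1, total + 1)
  dp[1, 1] <- 1
  for (r in ranks2) {
    for (k in n:1) {
      src <- dp[k, seq_len(total + 1 - r)]
      dp[k + 1, (r + 1):(total + 1)] <- dp[k + 1, (r + 1):(total + 1)] + src
    }
  }
  dp[n + 1, ]
}

#' Wilcoxon rank-sum test
#'
#' Two-sided two-sample rank-sum (Mann-Whitney) test. When both groups
#' have at most `exact_max` observations the p-value is exact, from the
#' combinatorial null distribution of the rank sum over all group
#' assignments (exact under ties via doubled midranks); otherwise a normal
#' approximation with tie correction is used.
#'
#' @param x,y numeric samples.
#' @param exact_max per-group size bound for the exact computation.
#' @return list with `statistic` (rank sum W of `x`), `p.value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10) {
  x <- as.numeric(x[!is.na(x)]); y <- as.numeric(y[!is.na(y)])
  n <- length(x); m <- length(y)
  if (n == 0 || m == 0)
    stop_aquacol("both samples must be non-empty", "aquacol_parameter_error")
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  if (n <= exact_max && m <= exact_max) {
    r2 <- as.integer(round(2 * r))
    counts <- rank_sum_counts(r2, n)
    tot <- choose(n + m, n)
    w2 <- as.integer(round(2 * W))
    p_le <- sum(counts[seq_len(w2 + 1)]) / tot
    p_ge <- sum(counts[(w2 + 1):length(counts)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    N <- n + m
    mu <- n * (N + 1) / 2
    ties <- table(r)
    v <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (W - mu) / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal-approximation"
  }
  list(statistic = W, p.value = p, method = method)
}
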
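test_that("2x2 chi-square is Pearson without continuity correction", {
  # identical rows: statistic 0, p 1
  r <- chi_square_2x2(4, 4, 4, 4)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  # agrees with the base implementation with correct = FALSE
  ref <- suppressWarnings(
    stats::chisq.test(matrix(c(2, 6, 3, 5), 2, byrow = TRUE),
                      correct = FALSE))
  mine <- chi_square_2x2(2, 6, 3, 5)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$p.value, ref$p.value)
  expect_error(chi_square_2x2(0, 0, 3, 5), class = "aquacol_undefined_test")
  expect_error(chi_square_2x2(1.5, 2, 3, 4),
               class = "aquacol_parameter_error")
})

test_that("summary-statistics t-test matches a closed-form evaluation", {
  # equal means -> t = 0 -> p = 1 exactly
  expect_equal(unpaired_t_test(26, 5.1, 8, 26, 4.2, 8), 1)
  # direct t-distribution evaluation, df = 14
  t <- (10 - 14) / sqrt(((7 * 1 + 7 * 1) / 14) * (1 / 8 + 1 / 8))
  expect_equal(unpaired_t_test(10, 1, 8, 14, 1, 8),
               2 * stats::pt(-abs(t), 14))
  # agrees with t.test on raw data when summaries are computed from it
  set.seed(1)
  x <- rnorm(9); y <- rnorm(11, 0.8)
  ref <- stats::t.test(x, y, var.equal = TRUE)$p.value
  expect_equal(unpaired_t_test(mean(x), sd(x), 9, mean(y), sd(y), 11), ref)
  expect_error(unpaired_t_test(1, 0, 8, 2, 1, 8),
               class = "aquacol_parameter_error")
})

test_that("signed-rank exact p equals brute-force sign enumeration", {
  set.seed(31)
  for (rep in 1:12) {
    d <- round(stats::rnorm(sample(4:10, 1), 0.4, 1), 2)
    d <- d[d != 0]
    if (length(d) == 0) next
    expect_equal(wilcoxon_signed_rank(d)$p.value, brute_signed_rank_p(d),
                 tolerance = 1e-12)
  }
  # frozen analytic cases
  expect_equal(wilcoxon_signed_rank(rep(1, 16))$p.value, 2 / 2^16)
  expect_equal(wilcoxon_signed_rank(c(1, -1))$p.value, 1)
  expect_error(wilcoxon_signed_rank(c(0, 0)),
               class = "aquacol_degenerate_signal")
  # tie-free case agrees with the base exact implementation
  set.seed(32)
  d <- rnorm(12)
  expect_equal(wilcoxon_signed_rank(d)$p.value,
               stats::wilcox.test(d)$p.value)
})

test_that("rank-sum exact p equals brute-force subset enumeration", {
  set.seed(33)
  for (rep in 1:12) {
    x <- round(stats::rnorm(sample(3:8, 1), 0.5), 1)
    y <- round(stats::rnorm(sample(3:8, 1)), 1)
    expect_equal(wilcoxon_rank_sum(x, y)$p.value, brute_rank_sum_p(x, y),
                 tolerance = 1e-12)
  }
  expect_equal(wilcoxon_rank_sum(11:18, 1:8)$p.value, 2 / choose(16, 8))
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  set.seed(34)
  x <- rnorm(7); y <- rnorm(9)
  expect_equal(wilcoxon_rank_sum(x, y)$p.value,
               stats::wilcox.test(x, y)$p.value)
})

test_that("large-sample branches use the tie-corrected normal approximation", {
  set.seed(35)
  d <- round(rnorm(40, 0.3), 1)
  r <- wilcoxon_signed_rank(d)
  expect_equal(r$method, "normal-approximation")
  ref <- stats::wilcox.test(d, exact = FALSE, correct = FALSE)$p.value
  expect_equal(r$p.value, ref, tolerance = 1e-10)
  x <- round(rnorm(15), 1); y <- round(rnorm(20, 0.4), 1)
  r2 <- wilcoxon_rank_sum(x, y)
  expect_equal(r2$method, "normal-approximation")
  ref2 <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(r2$p.value, ref2, tolerance = 1e-10)
})

test_that("crossover LMM agrees with the reference mixed-model fitter", {
  skip_if_not_installed("lme4")
  study <- render_crossover_study(seed = 7)
  fit <- fit_crossover_lmm(study$table)
  d <- aquacol:::build_outcome_rows(study$table, "percent_change_width", "2h")
  ref <- lme4::lmer(y ~ sequence + drug + period + (1 | subject_id),
                    data = transform(d, period = factor(period)),
                    REML = TRUE)
  fe <- lme4::fixef(ref)
  expect_equal(unname(coef(fit)[["drug"]]), unname(fe[["drugripasudil"]]),
               tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(ref))$vcov
  expect_equal(fit$sigma_u2, vc[1], tolerance = 1e-4)
  expect_equal(fit$sigma_e2, vc[2], tolerance = 1e-4)
  expect_equal(fit$se[["drug"]],
               sqrt(as.matrix(vcov(ref))["drugripasudil", "drugripasudil"]),
               tolerance = 1e-5)
})

test_that("a noiseless pure drug effect is recovered exactly", {
  des <- study_design_params(
    baseline_sd = 0,
    effects = data.frame(
      drug = c("ripasudil", "ripasudil", "latanoprost", "latanoprost"),
      timepoint = c("2h", "8h", "2h", "8h"),
      mean = c(25, 0, 0, 0), sd = 0))
  st <- render_crossover_study(des, seed = 2)
  fit <- fit_crossover_lmm(st$table)
  expect_equal(unname(coef(fit)[["drug"]]), 25, tolerance = 1e-9)
  expect_lt(fit$sigma_e2, 1e-12)
  expect_lt(fit$p_drug, 1e-9)
})

test_that("with the variance ratio profiled to zero the LMM is OLS", {
  # anti-correlated within-subject residuals drive the REML estimate of
  # the subject variance to the zero boundary, where the GLS solution
  # must coincide with least squares
  seqs <- rep(c("ripasudil-latanoprost", "latanoprost-ripasudil"), each = 8)
  rows <- list()
  set.seed(13)
  sgn <- sample(c(-1, 1), 16, replace = TRUE)
  for (i in 1:16) {
    drugs <- strsplit(seqs[i], "-")[[1]]
    for (period in 1:2) {
      eps <- sgn[i] * (-1)^period * 4 + stats::rnorm(1, 0, 0.5)
      w2h <- 100 * (1 + (5 * (drugs[period] == "ripasudil") + eps) / 100)
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sprintf("S%02d", i), sequence = seqs[i],
        period = period, drug = drugs[period],
        timepoint = c("baseline", "2h"),
        width_px = c(100, w2h), iop_mmHg = 12)
    }
  }
  tab <- do.call(rbind, rows)
  f0 <- fit_crossover_lmm(tab)
  expect_equal(f0$lambda, 0)
  d0 <- aquacol:::build_outcome_rows(tab, "percent_change_width", "2h")
  X0 <- cbind(1, as.numeric(d0$sequence == "latanoprost-ripasudil"),
              as.numeric(d0$drug == "ripasudil"),
              as.numeric(d0$period == 2))
  ols0 <- stats::lm.fit(X0, d0$y)
  expect_equal(unname(coef(f0)), unname(ols0$coefficients),
               tolerance = 1e-6)
  s2 <- sum(ols0$residuals^2) / (32 - 4)
  expect_equal(f0$sigma_e2, s2, tolerance = 1e-6)
})

test_that("degenerate designs are rejected with design errors", {
  study <- render_crossover_study(seed = 5)
  one_seq <- study$table[study$table$sequence == "ripasudil-latanoprost", ]
  expect_error(fit_crossover_lmm(one_seq), class = "aquacol_design_error")
  no_base <- study$table[study$table$timepoint != "baseline", ]
  expect_error(fit_crossover_lmm(no_base), class = "aquacol_schema_error")
  expect_error(fit_crossover_lmm(study$table[, -6]),
               class = "aquacol_schema_error")
})

test_that("model methods behave like standard fitted-model accessors", {
  study <- render_crossover_study(seed = 8)
  fit <- fit_crossover_lmm(study$table)
  expect_named(coef(fit), c("(Intercept)", "sequence", "drug", "period"))
  expect_equal(dim(vcov(fit)), c(4, 4))
  expect_equal(length(residuals(fit)), 32)
  expect_equal(fitted(fit) + residuals(fit), fit$data$y)
  expect_equal(predict(fit), fitted(fit))
  nd <- data.frame(sequence = "ripasudil-latanoprost",
                   drug = c("ripasudil", "latanoprost"), period = c(1, 2))
  pr <- predict(fit, nd)
  expect_equal(pr[1] - pr[2],
               unname(coef(fit)[["drug"]] - coef(fit)[["period"]]))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(32, 3))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 1))
  s <- summary(fit)
  expect_s3_class(s, "summary.crossover_lmm")
  expect_output(print(s), "Drug effect")
})

test_that("study summaries mirror the generator truth at scale", {
  big <- render_crossover_study(study_design_params(n_subjects = 400),
                                seed = 12)
  s <- summarize_study(big$table)
  wt <- s$width_table
  g <- function(drug, tp, col)
    wt[wt$drug == drug & wt$timepoint == tp, col]
  expect_equal(g("ripasudil", "2h", "pct_change_mean"), 28.8,
               tolerance = 3 * 16.3 / sqrt(400) / 28.8)
  expect_equal(g("latanoprost", "2h", "pct_change_mean"), -2.5,
               tolerance = 3 * 5.7 / sqrt(400) / 2.5)
  expect_equal(g("ripasudil", "baseline", "width_mean_px"), 63.7,
               tolerance = 3 * 19.3 / sqrt(400) / 63.7)
  it <- s$iop_table
  expect_equal(it[it$drug == "ripasudil" & it$timepoint == "2h",
                  "iop_mean_mmHg"], 10.6, tolerance = 3 * 2.1 / sqrt(400) / 10.6)
  # headline contrasts detected
  expect_lt(s$lmm_table$p_between_lmm[s$lmm_table$timepoint == "2h"], 1e-6)
})

test_that("single-subject cells are summarized with flagged SDs", {
  st <- render_crossover_study(seed = 9)
  one <- st$table[st$table$subject_id == "S01", ]
  one$sequence <- one$sequence[1]
  s <- summarize_study(one)
  row <- s$width_table[s$width_table$drug == one$drug[1] &
                         s$width_table$timepoint == "2h", ]
  expect_equal(row$n, 1)
  expect_true(is.na(row$width_sd_px))
  expect_equal(row$width_mean_px,
               one$width_px[one$timepoint == "2h" & one$drug == one$drug[1]])
  # LMM cannot run on one sequence; reported as non-converged, not fatal
  expect_false(any(s$lmm_table$converged))
})
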
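#' Design parameters of a synthetic 2x2 crossover study
#'
#' Defaults reproduce the published study conditions: 16 subjects
#' randomized 1:1 to the two drug sequences, widths in pixels with per-drug
#' baselines of 63.7 and 66.0 px (sd 19.3, of which 80\% is
#' between-subject), per-drug per-timepoint percent-change effects of
#' 28.8 (sd 16.3) and 7.6 (sd 12.6) for ripasudil at 2 h and 8 h and
#' -2.5 (sd 5.7) and -4.3 (sd 8.1) for latanoprost, and IOP distributions
#' matching the reported per-timepoint means.
#'
#' @param n_subjects even number of subjects (half per sequence).
#' @param baseline_mean named numeric, mean baseline width (px) per drug.
#' @param baseline_sd total baseline sd (px).
#' @param between_subject_frac fraction of baseline variance that is
#'   between-subject (shared by a subject's two periods).
#' @param effects data frame `drug`, `timepoint`, `mean`, `sd`: the
#'   per-subject percent-change distribution of width from the same-drug
#'   baseline.
#' @param iop data frame `drug`, `timepoint`, `mean`, `sd` of IOP (mmHg).
#' @return an object of class `study_design_params`.
#' @export
study_design_params <- function(
    n_subjects = 16,
    baseline_mean = c(ripasudil = 63.7, latanoprost = 66.0),
    baseline_sd = 19.3,
    between_subject_frac = 0.8,
    effects = data.frame(
      drug = c("ripasudil", "ripasudil", "latanoprost", "latanoprost"),
      timepoint = c("2h", "8h", "2h", "8h"),
      mean = c(28.8, 7.6, -2.5, -4.3),
      sd = c(16.3, 12.6, 5.7, 8.1)),
    iop = data.frame(
      drug = rep(c("ripasudil", "latanoprost"), each = 3),
      timepoint = rep(c("baseline", "2h", "8h"), 2),
      mean = c(12.8, 10.6, 11.4, 12.6, 12.3, 10.3),
      sd = c(2.5, 2.1, 2.2, 1.7, 2.2, 2.0))) {
  if (!is_count(n_subjects) || n_subjects %% 2 != 0 || n_subjects < 4)
    stop_aquacol("n_subjects must be an even integer >= 4",
                 "aquacol_parameter_error")
  if (any(effects$sd < 0) || baseline_sd < 0 || any(iop$sd < 0))
    stop_aquacol("standard deviations must not be negative",
                 "aquacol_parameter_error")
  if (!all(c("ripasudil", "latanoprost") %in% names(baseline_mean)))
    stop_aquacol("baseline_mean needs entries for both drugs",
                 "aquacol_parameter_error")
  if (between_subject_frac < 0 || between_subject_frac > 1)
    stop_aquacol("between_subject_frac must lie in [0, 1]",
                 "aquacol_parameter_error")
  structure(list(n_subjects = as.integer(n_subjects),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 between_subject_frac = between_subject_frac,
                 effects = effects, iop = iop),
            class = "study_design_params")
}

#' Simulate a complete crossover study table
#'
#' Draws a long-format measurement table with known ground truth under the
#' design's normal models: subjects are randomized 1:1 to the
#' ripasudil-latanoprost or latanoprost-ripasudil sequence; each
#' subject x period gets a baseline width (between-subject intercept plus
#' period-level draw); each post-instillation timepoint gets a per-subject
#' percent change drawn from the design's effect distribution, and the
#' width at that timepoint is `baseline * (1 + pct/100)`.
#'
#' @param design a [study_design_params()] object.
#' @param seed integer seed for the draw.
#' @return a list of class `crossover_study`: `table` (long-format data
#'   frame: `subject_id`, `sequence`, `period`, `drug`, `timepoint`,
#'   `width_px`, `iop_mmHg`) and `truth` (per-observation drawn percent
#'   changes).
#' @export
render_crossover_study <- function(design = study_design_params(), seed = 1L) {
  stopifnot(inherits(design, "study_design_params"))
  n <- design$n_subjects
  half <- n %/% 2
  seqs <- c("ripasudil-latanoprost", "latanoprost-ripasudil")
  with_seed(seed, {
    order_ids <- sample(seq_len(n))
    sequence_of <- character(n)
    sequence_of[order_ids[seq_len(half)]] <- seqs[1]
    sequence_of[order_ids[half + seq_len(half)]] <- seqs[2]

    sd_b <- design$baseline_sd * sqrt(design$between_subject_frac)
    sd_w <- design$baseline_sd * sqrt(1 - design$between_subject_frac)
    b_i <- stats::rnorm(n, 0, sd_b)

    rows <- list(); truths <- list()
    for (i in seq_len(n)) {
      drugs <- strsplit(sequence_of[i], "-", fixed = TRUE)[[1]]
      for (period in 1:2) {
        drug <- drugs[period]
        base <- max(design$baseline_mean[[drug]] + b_i[i] +
                      stats::rnorm(1, 0, sd_w), 5)
        for (tp in c("baseline", "2h", "8h")) {
          if (tp == "baseline") {
            width <- base
            pct <- 0
          } else {
            eff <- design$effects[design$effects$drug == drug &
                                    design$effects$timepoint == tp, ]
            if (nrow(eff) != 1)
              stop_aquacol(sprintf("no effect row for %s at %s", drug, tp),
                           "aquacol_parameter_error")
            pct <- stats::rnorm(1, eff$mean, eff$sd)
            width <- max(base * (1 + pct / 100), 1)
          }
          io <- design$iop[design$iop$drug == drug &
                             design$iop$timepoint == tp, ]
          iop <- stats::rnorm(1, io$mean, io$sd)
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = sprintf("S%02d", i), sequence = sequence_of[i],
            period = period, drug = drug, timepoint = tp,
            width_px = width, iop_mmHg = iop)
          truths[[length(truths) + 1L]] <- data.frame(
            subject_id = sprintf("S%02d", i), drug = drug, timepoint = tp,
            true_pct_change = pct)
        }
      }
    }
  })
  structure(list(table = do.call(rbind, rows),
                 truth = do.call(rbind, truths),
                 design = design, seed = as.integer(seed)),
            class = "crossover_study")
}

#' @export
print.crossover_study <- function(x, ...) {
  tab <- table(x$table$sequence[x$table$timepoint == "baseline" &
                                  x$table$period == 1])
  cat(sprintf("<crossover_study> %d subjects (%s), %d rows, seed %d\n",
              x$design$n_subjects,
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              nrow(x$table), x$seed))
  invisible(x)
}
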
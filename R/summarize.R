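#' Summary tables of a crossover study
#'
#' Produces the study's three report tables from a long-format measurement
#' table: per-drug per-timepoint mean and SD of the aqueous-column width
#' and of the per-subject percent change from baseline, with within-group
#' signed-rank p-values and between-group LMM p-values at 2 h and 8 h
#' (width table); the IOP table with within-group signed-rank p-values;
#' and the LMM fit diagnostics.
#'
#' Missing cells are reported as `NA` per cell, not treated as fatal; with
#' a single subject the SD is `NA` and within-group tests are skipped.
#'
#' @param table long-format measurement table (see
#'   [render_crossover_study()]).
#' @return an object of class `study_summary`: `width_table`,
#'   `iop_table`, `lmm_table`, and `fits` (the two `crossover_lmm`
#'   objects).
#' @export
summarize_study <- function(table) {
  req <- c("subject_id", "sequence", "period", "drug", "timepoint",
           "width_px", "iop_mmHg")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols) > 0)
    stop_aquacol(paste("measurement table is missing column(s):",
                       paste(missing_cols, collapse = ", ")),
                 "aquacol_schema_error")

  drugs <- c("ripasudil", "latanoprost")
  tps <- c("baseline", "2h", "8h")
  msd <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(c(NA_real_, NA_real_, 0))
    c(mean(x), if (length(x) > 1) stats::sd(x) else NA_real_, length(x))
  }
  cell <- function(d) {
    key <- function(dd) paste(dd$subject_id, dd$drug, sep = "\r")
    function(drug, tp, var) {
      rows <- d[d$drug == drug & d$timepoint == tp, ]
      rows[[var]]
    }
  }
  get_cell <- cell(table)

  paired_change <- function(drug, tp, var = "width_px") {
    base <- table[table$drug == drug & table$timepoint == "baseline", ]
    post <- table[table$drug == drug & table$timepoint == tp, ]
    i <- match(post$subject_id, base$subject_id)
    list(base = base[[var]][i], post = post[[var]],
         subject = post$subject_id)
  }

  wtab <- list()
  for (drug in drugs) {
    for (tp in tps) {
      w <- msd(get_cell(drug, tp, "width_px"))
      if (tp == "baseline") {
        pct <- c(NA, NA); pw <- NA_real_
      } else {
        pc <- paired_change(drug, tp)
        pcs <- percent_change(pc$base, pc$post)
        pct <- msd(pcs)[1:2]
        diffs <- pc$post - pc$base
        pw <- if (sum(diffs != 0, na.rm = TRUE) > 0 && length(diffs) > 1)
          wilcoxon_signed_rank(diffs[!is.na(diffs)])$p.value else NA_real_
      }
      wtab[[length(wtab) + 1L]] <- data.frame(
        drug = drug, timepoint = tp, n = w[3],
        width_mean_px = w[1], width_sd_px = w[2],
        pct_change_mean = pct[1], pct_change_sd = pct[2],
        p_within_signed_rank = pw)
    }
  }
  width_table <- do.call(rbind, wtab)

  itab <- list()
  for (drug in drugs) {
    for (tp in tps) {
      io <- msd(get_cell(drug, tp, "iop_mmHg"))
      if (tp == "baseline") {
        pw <- NA_real_
      } else {
        pc <- paired_change(drug, tp, "iop_mmHg")
        diffs <- pc$post - pc$base
        pw <- if (sum(diffs != 0, na.rm = TRUE) > 0 && length(diffs) > 1)
          wilcoxon_signed_rank(diffs[!is.na(diffs)])$p.value else NA_real_
      }
      itab[[length(itab) + 1L]] <- data.frame(
        drug = drug, timepoint = tp, n = io[3],
        iop_mean_mmHg = io[1], iop_sd_mmHg = io[2],
        p_within_signed_rank = pw)
    }
  }
  iop_table <- do.call(rbind, itab)

  fit_tp <- function(tp) {
    tryCatch(fit_crossover_lmm(table, timepoint = tp),
             aquacol_error = function(e) e)
  }
  fits <- list(`2h` = fit_tp("2h"), `8h` = fit_tp("8h"))
  lmm_row <- function(tp) {
    f <- fits[[tp]]
    if (inherits(f, "crossover_lmm"))
      data.frame(timepoint = tp, drug_effect = f$coefficients[["drug"]],
                 se = f$se[["drug"]], p_between_lmm = f$p_drug,
                 converged = f$converged)
    else
      data.frame(timepoint = tp, drug_effect = NA_real_, se = NA_real_,
                 p_between_lmm = NA_real_, converged = FALSE)
  }
  lmm_table <- rbind(lmm_row("2h"), lmm_row("8h"))

  structure(list(width_table = width_table, iop_table = iop_table,
                 lmm_table = lmm_table, fits = fits),
            class = "study_summary")
}

#' @export
print.study_summary <- function(x, digits = 3, ...) {
  cat("Aqueous column width (px) and percent change from baseline\n")
  print(format(x$width_table, digits = digits), row.names = FALSE)
  cat("\nBetween-group (drug) effect, crossover LMM on percent change\n")
  print(format(x$lmm_table, digits = digits), row.names = FALSE)
  cat("\nIntraocular pressure (mmHg)\n")
  print(format(x$iop_table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write a study summary to CSV/JSON files
#'
#' @param summary a [summarize_study()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written: the three report tables as CSV
#'   and the LMM diagnostics as JSON.
#' @export
write_study_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "study_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(width = file.path(dir, "width_table.csv"),
             iop = file.path(dir, "iop_table.csv"),
             lmm = file.path(dir, "lmm_table.csv"),
             diag = file.path(dir, "lmm_diagnostics.json"))
  utils::write.csv(summary$width_table, paths["width"], row.names = FALSE)
  utils::write.csv(summary$iop_table, paths["iop"], row.names = FALSE)
  utils::write.csv(summary$lmm_table, paths["lmm"], row.names = FALSE)
  diag <- lapply(summary$fits, function(f) {
    if (!inherits(f, "crossover_lmm")) return(list(error = conditionMessage(f)))
    list(coefficients = as.list(f$coefficients), se = as.list(f$se),
         sigma_u2 = f$sigma_u2, sigma_e2 = f$sigma_e2,
         p_drug = f$p_drug, converged = f$converged,
         reml_criterion = f$reml_criterion, n = f$n)
  })
  jsonlite::write_json(diag, paths["diag"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
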
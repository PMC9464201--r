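# Pipeline commands over a plain-text run configuration.
#
# The config file is INI-style: `[section]` headers and `key = value`
# lines; values are parsed as numbers, logicals, or comma-separated lists
# where they look like them, strings otherwise. Every stochastic step must
# carry an explicit seed.

parse_config_value <- function(s) {
  s <- trimws(s)
  if (grepl(",", s, fixed = TRUE))
    return(unlist(lapply(strsplit(s, ",")[[1]], parse_config_value)))
  if (toupper(s) %in% c("TRUE", "FALSE")) return(as.logical(toupper(s)))
  num <- suppressWarnings(as.numeric(s))
  if (!is.na(num)) return(num)
  s
}

deparse_config_value <- function(v) {
  if (is.logical(v)) return(paste(ifelse(v, "true", "false"), collapse = ", "))
  if (is.numeric(v)) return(paste(format(v, digits = 15), collapse = ", "))
  paste(v, collapse = ", ")
}

#' Read a pipeline run configuration
#'
#' @param path path to an INI-style config file: `[section]` headers with
#'   `key = value` entries. `#` starts a comment.
#' @return a nested named list of class `run_config`.
#' @seealso [write_run_config()]
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_aquacol(sprintf("config file '%s' not found", path),
                 "aquacol_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  cfg <- list()
  section <- NULL
  for (ln in trimws(lines)) {
    if (ln == "") next
    if (grepl("^\\[.+\\]$", ln)) {
      section <- sub("^\\[(.+)\\]$", "\\1", ln)
      if (is.null(cfg[[section]])) cfg[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section))
        stop_aquacol("config entry outside any [section]",
                     "aquacol_validation_error")
      kv <- regmatches(ln, regexpr("=", ln, fixed = TRUE), invert = TRUE)[[1]]
      cfg[[section]][[trimws(kv[1])]] <- parse_config_value(kv[2])
    } else {
      stop_aquacol(sprintf("cannot parse config line: '%s'", ln),
                   "aquacol_validation_error")
    }
  }
  structure(cfg, class = "run_config")
}

#' Write a pipeline run configuration
#'
#' The written file round-trips losslessly through [read_run_config()].
#'
#' @param config a `run_config` (nested named list of sections).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  out <- character(0)
  for (section in names(config)) {
    out <- c(out, sprintf("[%s]", section))
    for (key in names(config[[section]]))
      out <- c(out, sprintf("%s = %s", key,
                            deparse_config_value(config[[section]][[key]])))
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

require_config <- function(config, section, keys) {
  if (is.null(config[[section]]))
    stop_aquacol(sprintf("config is missing the [%s] section", section),
                 "aquacol_validation_error")
  missing_keys <- setdiff(keys, names(config[[section]]))
  if (length(missing_keys) > 0)
    stop_aquacol(sprintf("config [%s] is missing: %s", section,
                         paste(missing_keys, collapse = ", ")),
                 "aquacol_validation_error")
  invisible(config[[section]])
}

#' Simulate a study: videos, ground truth, and measurement table
#'
#' Renders the configured synthetic crossover study to disk: the
#' long-format measurement table, per-observation ground truth, optional
#' vein videos with JSON ground-truth sidecars, and a manifest with MD5
#' checksums. Deterministic given the config seeds.
#'
#' @param config a `run_config` with an `[output] dir` entry and a
#'   `[study]` section (`seed`, `n_subjects`; optional `n_videos` and a
#'   `[scene]` section with `seed` plus [scene_params()] overrides).
#' @return invisibly, the manifest data frame (`file`, `md5`).
#' @export
cmd_simulate <- function(config) {
  out <- require_config(config, "output", "dir")$dir
  st <- require_config(config, "study", c("seed", "n_subjects"))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  design <- study_design_params(n_subjects = st$n_subjects)
  study <- render_crossover_study(design, seed = st$seed)
  files <- c(study = file.path(out, "study_measurements.csv"),
             truth = file.path(out, "study_truth.csv"))
  utils::write.csv(study$table, files["study"], row.names = FALSE)
  utils::write.csv(study$truth, files["truth"], row.names = FALSE)

  n_videos <- config$study$n_videos
  if (!is.null(n_videos) && n_videos > 0) {
    sc <- require_config(config, "scene", "seed")
    # blink intervals are written "start:length" in config files
    if (!is.null(sc$blink_frames) && is.character(sc$blink_frames))
      sc$blink_frames <- lapply(strsplit(sc$blink_frames, ":"),
                                function(v) as.numeric(v))
    for (k in seq_len(n_videos)) {
      args <- sc[setdiff(names(sc), "seed")]
      args$seed <- sc$seed + k - 1
      params <- do.call(scene_params, args)
      r <- render_video(params)
      vpath <- file.path(out, sprintf("clip_%03d.avi", k))
      spath <- file.path(out, sprintf("clip_%03d_truth.json", k))
      write_video(r$clip, vpath)
      jsonlite::write_json(
        list(column_width_px = r$truth$column_width_px,
             flow_speed_px_per_frame = r$truth$flow_speed_px_per_frame,
             blink_frames = r$truth$blink_frames,
             shifts = r$truth$shifts, seed = args$seed),
        spath, auto_unbox = TRUE, digits = NA, dataframe = "columns")
      files <- c(files, vpath, spath)
    }
  }

  manifest <- data.frame(file = basename(unname(files)),
                         md5 = unname(tools::md5sum(unname(files))))
  utils::write.csv(manifest, file.path(out, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Measure aqueous-column widths for a batch of clips
#'
#' Runs the measurement chain on each configured video: optional 60-to-30
#' fps subsampling, blink detection, post-blink segment selection,
#' stabilization, then the 30-frame width measurement on the configured
#' line. Per-clip failures are flagged in the summary, leaving other clips
#' unaffected.
#'
#' @param config a `run_config` with `[measure]` keys `videos`
#'   (comma-separated paths), `line` (`x0, y0, x1, y1`), and optional
#'   `subsample` (logical), `dim_factor`, `window`, `segment_len`,
#'   `smooth_sigma`; plus `[output] dir`.
#' @return the per-clip summary data frame (also written to
#'   `widths.csv`): `clip`, `status`, `segment_start`, `mean_width_px`,
#'   `sd_width_px`, `n_excluded`.
#' @export
cmd_measure <- function(config) {
  out <- require_config(config, "output", "dir")$dir
  ms <- require_config(config, "measure", c("videos", "line"))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  line <- do.call(sampling_line, as.list(ms$line))
  opts <- function(key, default) if (is.null(ms[[key]])) default else ms[[key]]

  rows <- lapply(ms$videos, function(path) {
    res <- tryCatch({
      clip <- read_video(path)
      if (clip$channel_tag == "rgb") clip <- extract_green_channel(clip)
      if (isTRUE(opts("subsample", FALSE)))
        clip <- subsample_alternate_frames(clip)
      blinks <- detect_blinks(clip, dim_factor = opts("dim_factor", 0.6),
                              window = opts("window", 31))
      seg <- select_post_blink_segment(clip, blinks,
                                       segment_len = opts("segment_len", 30))
      st <- stabilize(seg)
      m <- measure_width_clip(st$clip, line,
                              n_frames = opts("segment_len", 30),
                              smooth_sigma_px = opts("smooth_sigma", 2))
      data.frame(clip = basename(path), status = "ok",
                 segment_start = attr(seg, "segment_start"),
                 mean_width_px = m$mean_width_px,
                 sd_width_px = m$sd_width_px, n_excluded = m$n_excluded)
    },
    aquacol_no_segment = function(e) data.frame(
      clip = basename(path), status = "no segment",
      segment_start = NA_integer_, mean_width_px = NA_real_,
      sd_width_px = NA_real_, n_excluded = NA_integer_),
    aquacol_error = function(e) data.frame(
      clip = basename(path), status = paste("failed:", conditionMessage(e)),
      segment_start = NA_integer_, mean_width_px = NA_real_,
      sd_width_px = NA_real_, n_excluded = NA_integer_))
    res
  })
  summary <- do.call(rbind, rows)
  utils::write.csv(summary, file.path(out, "widths.csv"), row.names = FALSE)
  summary
}

#' Flow metric for a batch of clips
#'
#' @param config a `run_config` with `[flow]` keys `videos`, `roi`
#'   (`x0, y0, x1, y1`, inclusive 0-based rectangle) and optional
#'   `max_lag`, `threshold`; plus `[output] dir`.
#' @return the per-clip flow summary data frame (also written to
#'   `flow.csv`).
#' @export
cmd_flow <- function(config) {
  out <- require_config(config, "output", "dir")$dir
  fl <- require_config(config, "flow", c("videos", "roi"))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  roi <- as.list(stats::setNames(fl$roi, c("x0", "y0", "x1", "y1")))
  max_lag <- if (is.null(fl$max_lag)) 15 else fl$max_lag
  thr <- if (is.null(fl$threshold)) 0.5 else fl$threshold
  opts <- function(key, default) if (is.null(fl[[key]])) default else fl[[key]]
  rows <- lapply(fl$videos, function(path) {
    clip <- read_video(path)
    if (clip$channel_tag == "rgb") clip <- extract_green_channel(clip)
    # same preprocessing as the width chain: anchor on a post-blink
    # segment when one exists, and remove camera shake (unstabilized
    # jitter would masquerade as decorrelation)
    seg <- tryCatch({
      blinks <- detect_blinks(clip, dim_factor = opts("dim_factor", 0.6),
                              window = opts("window", 31))
      select_post_blink_segment(clip, blinks,
                                segment_len = opts("segment_len",
                                                   max_lag * 3 + 1))
    }, aquacol_error = function(e) clip)
    seg <- stabilize(seg)$clip
    fe <- flow_metric(seg, roi, max_lag = max_lag, threshold = thr)
    data.frame(clip = basename(path), median_lag = fe$median_lag,
               flow_proxy = fe$flow_proxy, n_pixels = fe$n_pixels,
               n_excluded = fe$n_degenerate + fe$n_no_decorrelation,
               no_decorrelation = fe$no_decorrelation)
  })
  summary <- do.call(rbind, rows)
  utils::write.csv(summary, file.path(out, "flow.csv"), row.names = FALSE)
  summary
}

#' Statistical analysis of a measurement table
#'
#' Reads the long-format measurement CSV and writes the three report
#' tables and LMM diagnostics (see [summarize_study()]).
#'
#' @param config a `run_config` with `[analyze] table` (CSV path) and
#'   `[output] dir`.
#' @return the [summarize_study()] result, invisibly.
#' @export
cmd_analyze <- function(config) {
  out <- require_config(config, "output", "dir")$dir
  an <- require_config(config, "analyze", "table")
  tab <- utils::read.csv(an$table, stringsAsFactors = FALSE)
  s <- summarize_study(tab)  # schema errors name the missing columns
  write_study_summary(s, out)
  invisible(s)
}
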
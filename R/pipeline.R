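resolve_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$duration_s)) abort("Config needs `duration_s`.")
  if (is.null(config$out_dir)) abort("Config needs `out_dir`.")
  det <- config$detection %||% list()
  config$detection <- list(
    window_size = det$window_size %||% 10,
    tol_peakstart = det$tol_peakstart %||% 0.05,
    tol_peakend = det$tol_peakend %||% 0.90,
    prominence_k = det$prominence_k %||% 4
  )
  config$smoothing <- config$smoothing %||% list(method = "none")
  config$seed <- config$seed %||% 1L
  config$write_plots <- config$write_plots %||% TRUE
  config$background <- config$background %||% NULL
  config
}

load_input_table <- function(config) {
  if (!is.null(config$table)) {
    read_multimeasure(config$table, duration_s = config$duration_s,
                      background = config$background)
  } else if (!is.null(config$stack) && !is.null(config$mask)) {
    extract_mean_intensities(
      read_stack_tiff(config$stack), read_label_mask(config$mask),
      duration_s = config$duration_s,
      background_label = config$background_label
    )
  } else {
    abort("Config needs either `table` or `stack` + `mask`.")
  }
}

#' Run the full per-recording analysis
#'
#' End-to-end pipeline for one recording: read an intensity table (or
#' extract it from a TIFF stack + label mask), normalize to background,
#' optionally smooth, detect transients, apply manual edits, compute
#' per-transient and per-cell features, and write the output bundle:
#' `transients.csv`, `cells.csv`, `cells_transposed.csv`, a per-cell
#' diagnostic plot with start/peak/end markers, the fully-resolved
#' configuration (`config_resolved.yaml`) and a structured run log.
#' Re-running from the resolved config reproduces the tables
#' byte-identically. A cell whose trace is corrupt (non-finite after
#' normalization) or whose detection fails is logged and skipped; the
#' remaining cells are unaffected and the failure count is reported.
#'
#' @param config A list or YAML file path with fields: `table` (CSV path)
#'   or `stack` + `mask` (+ `background_label`) TIFF paths; `duration_s`;
#'   optional `background` column name; optional `detection` sublist
#'   (window_size, tol_peakstart, tol_peakend, prominence_k); optional
#'   `smoothing` sublist (`method` = none/fft_lowpass/moving_average with
#'   `cutoff_hz`/`window`); optional `edits` CSV path; `out_dir`;
#'   `seed`; `write_plots`.
#' @return Invisibly, a list with `events`, `transients`, `cells`,
#'   `failed_cells`, `paths` and the resolved `config`.
#' @export
run_analyze <- function(config) {
  config <- resolve_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  say <- function(level, fmt, ...) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
  set.seed(config$seed)
  table <- load_input_table(config)
  acq <- acquisition(table)
  say("INFO", "input: %d frames / %.6g s, %d cell ROI(s), background '%s'",
      acq$frame_count, acq$duration_s, length(cell_columns(table)),
      background_column(table))
  traces <- normalize_to_background(table)
  # screen out cells whose normalized trace is corrupt, keep the rest
  ok_tbl <- traces %>%
    dplyr::group_by(.data$cell_id) %>%
    dplyr::summarise(ok = all(is.finite(.data$dff)), .groups = "drop")
  failed <- ok_tbl$cell_id[!ok_tbl$ok]
  for (cid in failed) say("WARN", "cell %s: non-finite trace values; skipped", cid)
  m <- traces_meta(traces)
  traces <- new_ca_traces(traces[!traces$cell_id %in% failed, ],
                          m$duration_s, m$frame_count, m$smoothing)
  if (!identical(config$smoothing$method %||% "none", "none")) {
    traces <- smooth_traces(traces, config$smoothing$method,
                            cutoff_hz = config$smoothing$cutoff_hz,
                            window = config$smoothing$window)
    say("INFO", "smoothing: %s", traces_meta(traces)$smoothing)
  }
  params <- detection_params(
    window_size = config$detection$window_size,
    tol_peakstart = config$detection$tol_peakstart,
    tol_peakend = config$detection$tol_peakend,
    prominence_k = config$detection$prominence_k
  )
  cell_ids <- unique(traces$cell_id)
  events_list <- list()
  for (cid in cell_ids) {
    tr <- traces[traces$cell_id == cid, ]
    ev <- tryCatch(
      locate_bounds(tr$dff, detect_peaks(tr$dff, params), params),
      error = function(e) {
        say("WARN", "cell %s: detection failed (%s); skipped", cid,
            conditionMessage(e))
        NULL
      }
    )
    if (is.null(ev)) {
      failed <- c(failed, cid)
    } else {
      ev$cell_id <- cid
      events_list[[cid]] <- dplyr::relocate(ev, "cell_id")
    }
  }
  traces <- new_ca_traces(traces[!traces$cell_id %in% failed, ],
                          m$duration_s, m$frame_count,
                          traces_meta(traces)$smoothing)
  events <- dplyr::bind_rows(events_list)
  if (!is.null(config$edits)) {
    events <- apply_edits(events, traces, config$edits)
    say("INFO", "applied %d manual edit(s)", nrow(read_edits(config$edits)))
  }
  transients <- transient_features(traces, events)
  cells <- summarize_cells(transients, acq$duration_s,
                           cell_ids = unique(traces$cell_id))
  say("INFO", "detected %d transient(s) across %d cell(s); %d cell(s) failed",
      nrow(events), length(cell_ids) - sum(cell_ids %in% failed),
      length(unique(failed)))
  paths <- write_features(transients, cells, config$out_dir)
  if (isTRUE(config$write_plots)) {
    plot_dir <- file.path(config$out_dir, "plots")
    dir.create(plot_dir, showWarnings = FALSE)
    for (cid in unique(traces$cell_id)) {
      render_cell_plot(traces, events, cid,
                       file.path(plot_dir, paste0("cell_", cid, ".pdf")))
    }
  }
  cfg_path <- file.path(config$out_dir, "config_resolved.yaml")
  yaml::write_yaml(config, cfg_path)
  log_path <- file.path(config$out_dir, "run_log.txt")
  writeLines(log_lines, log_path)
  invisible(list(
    events = events, transients = transients, cells = cells,
    failed_cells = unique(failed),
    paths = c(paths, config = cfg_path, log = log_path),
    config = config
  ))
}

#' Compare per-cell summaries from several groups
#'
#' Reads one `cells.csv` per group (as written by [run_analyze()]), binds
#' them with a group label, runs [compare_features()], and writes a tidy
#' statistics table (`comparison.csv`), the per-feature ANOVA table
#' (`anova.csv`) and a feature plot (`comparison.pdf`).
#'
#' @param group_files Named character vector: names are group labels,
#'   values paths to `cells.csv` files.
#' @param out_dir Output directory.
#' @param features Feature subset (default all eleven).
#' @return Invisibly, the `ca_comparison` object.
#' @export
run_compare <- function(group_files, out_dir, features = ca_feature_names()) {
  if (is.null(names(group_files)) || any(names(group_files) == "")) {
    abort("`group_files` must be a named vector of group = path.")
  }
  cells <- purrr::imap_dfr(group_files, function(path, grp) {
    df <- readr::read_csv(path, show_col_types = FALSE)
    df$group <- grp
    df
  })
  cmp <- compare_features(cells, group, features = features)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_formatted_csv(tidy(cmp), file.path(out_dir, "comparison.csv"))
  write_formatted_csv(glance(cmp), file.path(out_dir, "anova.csv"))
  ggplot2::ggsave(file.path(out_dir, "comparison.pdf"), autoplot(cmp),
                  width = 9, height = 7)
  invisible(cmp)
}
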
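events_marker_data <- function(traces, events) {
  split_tr <- split(traces, traces$cell_id)
  purrr::map_dfr(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    tr <- split_tr[[ev$cell_id]]
    idx <- c(start = ev$start_idx, peak = ev$peak_idx, end = ev$end_idx)
    tibble(
      cell_id = ev$cell_id, event = ev$event,
      point = names(idx), idx = as.integer(idx),
      complete = ev$complete
    ) %>%
      dplyr::filter(!is.na(.data$idx)) %>%
      dplyr::mutate(time_s = tr$time_s[.data$idx], dff = tr$dff[.data$idx])
  })
}

#' Plot traces with detected transient markers
#'
#' Line plot of the normalized trace against seconds, with the
#' conventional marker colours of interactive review: transient starts
#' as green points, ends as blue crosses, peaks as orange triangles.
#' Markers belonging to incomplete transients (excluded from per-cell
#' averages) are drawn hollow/grey. Use this to review each cell before
#' trusting the summary, supplying corrections via [adjust_event()].
#'
#' @param traces A `ca_traces` tibble.
#' @param events Optional events tibble from [detect_transients()].
#' @param cells Optional character vector restricting which cells to draw.
#' @return A ggplot object (facetted by cell when several are drawn).
#' @export
#' @examples
#' sim <- simulate_traces(seed = 1)
#' traces <- normalize_to_background(sim$table)
#' plot_cell_trace(traces, detect_transients(traces))
plot_cell_trace <- function(traces, events = NULL, cells = NULL) {
  stopifnot(inherits(traces, "ca_traces"))
  if (!is.null(cells)) {
    traces <- traces[traces$cell_id %in% cells, ]
    if (!is.null(events)) events <- events[events$cell_id %in% cells, ]
  }
  p <- ggplot2::ggplot(traces, ggplot2::aes(x = .data$time_s, y = .data$dff)) +
    ggplot2::geom_line(colour = "grey25", linewidth = 0.4) +
    ggplot2::labs(x = "Time (s)", y = expression(Delta * F / F)) +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events)) {
    mk <- events_marker_data(traces, events)
    shapes <- c(start = 16, peak = 17, end = 4)
    colours <- c(start = "forestgreen", peak = "darkorange", end = "blue")
    p <- p +
      ggplot2::geom_point(
        data = mk[mk$complete, ],
        ggplot2::aes(shape = .data$point, colour = .data$point), size = 2
      ) +
      ggplot2::geom_point(
        data = mk[!mk$complete, ],
        ggplot2::aes(shape = .data$point), colour = "grey60", size = 2,
        stroke = 0.8
      ) +
      ggplot2::scale_shape_manual(values = shapes, name = NULL) +
      ggplot2::scale_colour_manual(values = colours, name = NULL)
  }
  if (dplyr::n_distinct(traces$cell_id) > 1L) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$cell_id))
  }
  p
}

#' Render one cell's diagnostic plot to a file
#'
#' @param traces,events As in [plot_cell_trace()].
#' @param cell_id Which cell to render.
#' @param path Output file; the device is chosen from the extension
#'   (pdf recommended for headless use).
#' @param width,height Plot size in inches.
#' @return The path, invisibly.
#' @export
render_cell_plot <- function(traces, events, cell_id, path,
                             width = 7, height = 3) {
  p <- plot_cell_trace(traces, events, cells = cell_id)
  ggplot2::ggsave(path, p, width = width, height = height)
  invisible(path)
}

#' Plot per-feature group comparisons
#'
#' Mean +/- SEM per group with the individual per-cell values overlaid,
#' one panel per feature, mirroring how per-cell features are typically
#' presented across cell lines.
#'
#' @param object A `ca_comparison` from [compare_features()].
#' @param features Optional subset of features to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ca_comparison
#' @export
autoplot.ca_comparison <- function(object, features = NULL, ...) {
  feats <- features %||% object$features
  gs <- object$group_stats[object$group_stats$feature %in% feats, ]
  long <- object$data %>%
    dplyr::select(dplyr::all_of(c(object$group_var, feats))) %>%
    tidyr::pivot_longer(dplyr::all_of(feats), names_to = "feature",
                        values_to = "value") %>%
    dplyr::filter(!is.na(.data$value))
  names(long)[1] <- "group"
  ggplot2::ggplot(gs, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_jitter(
      data = long, ggplot2::aes(y = .data$value), width = 0.12,
      alpha = 0.45, size = 1, colour = "grey40"
    ) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      width = 0.25, colour = "red3"
    ) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), colour = "red3",
                        size = 2.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$feature), scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
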
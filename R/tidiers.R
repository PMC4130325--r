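#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a trained study
#'
#' One row per layer with its configuration and, when training was run, the
#' final-epoch mean absolute weight change.
#'
#' @param x a `visnet_study`.
#' @param ... unused.
#' @export
tidy.visnet_study <- function(x, ...) {
  base <- purrr::imap(x$net$layers, function(l, i) {
    cfg <- l$config
    tibble(layer = i, grid_size = cfg$grid_size, fan_in = cfg$fan_in,
           learning_rate = cfg$learning_rate,
           sparseness_percentile = cfg$sparseness_percentile,
           active_fraction = mean(l$y > 0.5))
  }) |> bind_rows()
  if (!is.null(x$history)) {
    last <- filter(x$history, epoch == max(epoch)) |>
      select(layer, final_mean_abs_dw = mean_abs_dw)
    base <- left_join(base, last, by = "layer")
  }
  base
}

#' @rdname tidy.visnet_study
#' @export
glance.visnet_study <- function(x, ...) {
  tibble(profile = x$config$profile, seed = x$config$seed,
         n_cells_readout = length(x$cells),
         n_transforms = nrow(x$trainset$data[[1]]),
         epochs = x$config$epochs,
         max_cell_bits = max(x$info$bits),
         coverage = x$net$coverage)
}

#' Tidy a scene evaluation report
#'
#' @param x a `scene_report`.
#' @param ... unused.
#' @export
tidy.scene_report <- function(x, ...) x$patches

#' @rdname tidy.scene_report
#' @export
glance.scene_report <- function(x, ...) x$accuracy

#' Plot a saliency map
#'
#' @param object a `saliency_map`.
#' @param ... unused.
#' @export
autoplot.saliency_map <- function(object, ...) {
  df <- tibble(
    row = rep(seq_len(nrow(object)), times = ncol(object)),
    col = rep(seq_len(ncol(object)), each = nrow(object)),
    saliency = as.vector(unclass(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$saliency)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "saliency")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot fixation-offset distribution
#'
#' Histogram of the distances between saliency-peak fixations and true
#' object centres, the quantity that sets how much translation invariance
#' the recognition stream must supply.
#'
#' @param offsets tibble from [offset_statistics()] (or a `scene_report`).
#' @param binwidth histogram bin width in pixels.
#' @export
plot_offset_histogram <- function(offsets, binwidth = 8) {
  if (inherits(offsets, "scene_report")) offsets <- offsets$offsets
  ggplot2::ggplot(filter(offsets, .data$matched),
                  ggplot2::aes(.data$offset_px)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey30", colour = "white") +
    ggplot2::labs(x = "fixation offset from object centre (px)", y = "count")
}

#' Plot an evaluation sweep
#'
#' @param sweep tibble from [evaluate_translation_sweep()] or
#'   [evaluate_view_sweep()].
#' @export
plot_sweep <- function(sweep) {
  xvar <- if ("distance" %in% names(sweep)) "distance" else "view_deg"
  ggplot2::ggplot(sweep, ggplot2::aes(.data[[xvar]], .data$percent_correct)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$trained), size = 2) +
    ggplot2::geom_hline(yintercept = 25, linetype = 2) +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(y = "percent correct",
                  x = if (xvar == "distance") "offset from centre (px)" else "view (deg)",
                  colour = "trained")
}
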
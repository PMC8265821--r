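#' Heatmap of a confusion matrix
#'
#' @param cm a [confusion_matrix()].
#' @param title plot title.
#' @return a ggplot object.
#' @export
plot_confusion <- function(cm, title = "Confusion matrix") {
  d <- as.data.frame(as.table(unclass(cm)))
  names(d) <- c("truth", "prediction", "count")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                  fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 2.5) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(levels(d$truth))) +
    ggplot2::labs(title = title, x = "predicted class", y = "true class") +
    ggplot2::theme_minimal()
}

#' Polar plot of the per-orientation Gabor feature maxima
#'
#' @param result an `orientation_result` from [classify_gabor()] with a
#'   profile (i.e. a gated double-tag image).
#' @return a ggplot object.
#' @export
plot_gabor_profile <- function(result) {
  if (is.null(result$profile))
    stop("result has no Gabor profile (single-tag or no detection)")
  d <- data.frame(orientation = as.numeric(names(result$profile)),
                  feature = as.numeric(result$profile))
  d <- rbind(d, transform(d, orientation = orientation + 180))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$orientation, y = .data$feature)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 330, 30)) +
    ggplot2::labs(title = sprintf("Max Gabor feature by filter orientation (reported %.0f deg)",
                                  result$orientation_deg),
                  x = NULL, y = "max feature") +
    ggplot2::theme_minimal()
}

#' Time series of a sequential track
#'
#' @param tracks a [sequence_track()] or list of them.
#' @return a ggplot object; double-tag orientations as lines, single-tag
#'   frames as points at the axis.
#' @export
plot_track <- function(tracks) {
  if (inherits(tracks, "sequence_track")) tracks <- list(tracks)
  d <- do.call(rbind, lapply(tracks, function(tr) {
    data.frame(id = factor(tr$id), time = tr$timestamps,
               orientation = tr$orientations_deg,
               single = !is.na(tr$labels) & tr$labels == 12L)
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$orientation,
                                  colour = .data$id)) +
    ggplot2::geom_line(data = d[!d$single, ], na.rm = TRUE) +
    ggplot2::geom_point(data = d[!d$single, ], na.rm = TRUE) +
    ggplot2::geom_point(data = transform(d[d$single, ], orientation = -90),
                        shape = 4, na.rm = TRUE) +
    ggplot2::labs(x = "time (s)", y = "orientation (deg)") +
    ggplot2::ylim(-90, 90) +
    ggplot2::theme_minimal()
}

#' Render an evaluation report to files
#'
#' Writes confusion-matrix heatmaps, optional Gabor polar profiles and track
#' time series as PNGs, plus a `summary.json` with the scalar metrics.
#' Output files are a deterministic function of the input.
#'
#' @param results named list; recognized elements: `confusion` (named list
#'   of [confusion_matrix()]), `profiles` (named list of
#'   `orientation_result`), `tracks` (list of [sequence_track()]),
#'   `metrics` (named list of scalars).
#' @param out_dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
report <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if (length(results) == 0) warning("empty results; writing empty report")
  for (nm in names(results$confusion)) {
    f <- file.path(out_dir, paste0("confusion_", nm, ".png"))
    ggplot2::ggsave(f, plot_confusion(results$confusion[[nm]],
                                      title = paste("Confusion matrix:", nm)),
                    width = 7, height = 6, dpi = 150)
    written <- c(written, f)
  }
  for (nm in names(results$profiles)) {
    f <- file.path(out_dir, paste0("gabor_profile_", nm, ".png"))
    ggplot2::ggsave(f, plot_gabor_profile(results$profiles[[nm]]),
                    width = 6, height = 6, dpi = 150)
    written <- c(written, f)
  }
  if (length(results$tracks)) {
    f <- file.path(out_dir, "tracks.png")
    ggplot2::ggsave(f, plot_track(results$tracks), width = 7, height = 5,
                    dpi = 150)
    written <- c(written, f)
  }
  summary <- results$metrics
  if (is.null(summary)) summary <- list()
  for (nm in names(results$confusion)) {
    acc <- cm_accuracy(results$confusion[[nm]])
    summary[[paste0("accuracy_", nm)]] <- acc$accuracy
  }
  f <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  written <- c(written, f)
  invisible(written)
}
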
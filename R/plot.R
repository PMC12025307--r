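#' Raw oscillograph of segmental rotation with stance delineation
#'
#' Small-multiples oscillograph of the raw recording: one panel per segment,
#' ordered pelvis (bottom) to C7 (top), observation number on the abscissa
#' starting with the first Initial Contact of the right foot, rotation in
#' degrees on the ordinate (positive = rotation to the left) with a shared
#' symmetric scale across panels so segments are directly comparable, a zero
#' reference line per panel, and the right-stance cycle boundaries delineated
#' with vertical black lines taken from the annotation (never re-detected).
#'
#' @param annotation A `gait_annotation` from [annotate_gait()].
#' @param file Optional output path; when given the figure is written there
#'   (format from the extension) and the path returned invisibly.
#' @param width,height Device size in inches when writing to file.
#' @return A ggplot object (or `file`, invisibly, when writing).
#' @examples
#' sim <- simulate_recording(gait_sim_params("typical", seed = 1))
#' p <- plot_raw_oscillograph(annotate_gait(sim$rotation, sim$force))
#' @export
plot_raw_oscillograph <- function(annotation, file = NULL, width = 7, height = 12) {
  stopifnot(inherits(annotation, "gait_annotation"))
  ic_frames <- annotation$events$frame_index[annotation$events$kind == "IC_RIGHT"]
  if (length(ic_frames) == 0 || nrow(annotation$cycles) == 0) {
    stop("no annotated gait cycles to plot", call. = FALSE)
  }
  first_ic <- min(ic_frames)
  long <- annotation$rotation |>
    dplyr::filter(.data$frame >= first_ic) |>
    tidyr::pivot_longer(cols = dplyr::all_of(segment_labels()),
                        names_to = "segment", values_to = "rotation_deg") |>
    dplyr::mutate(
      observation = .data$frame - first_ic,
      segment = factor(.data$segment, levels = rev(segment_labels()))
    )
  ylim <- oscillograph_ylim(long$rotation_deg)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$observation,
                                          y = .data$rotation_deg)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = ic_frames - first_ic,
                        colour = "black", linewidth = 0.3) +
    ggplot2::geom_line(colour = "#2a6fb0") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$segment)) +
    ggplot2::scale_y_continuous(limits = ylim) +
    ggplot2::labs(x = "Observation number (60 Hz frames from first IC right)",
                  y = "Transverse rotation (deg, positive = left)") +
    oscillograph_theme()
  finish_oscillograph(p, file, width, height)
}

#' Oscillograph of a standardized gait cycle
#'
#' SGC counterpart of [plot_raw_oscillograph()]: x-axis is percent of gait
#' cycle 0-100, the mean right-stance interval is shaded, and the normalized
#' raw samples can be overlaid behind the spline curves.
#'
#' @param object An `sgc` object.
#' @param samples Optional long tibble from [normalize_cycles()] to overlay
#'   behind the curves.
#' @param show_symmetry_line Draw each segment's symmetry line (the mean
#'   level its rotation oscillates around) as a dashed line, making level
#'   shifts away from zero visible per panel. Default `TRUE`.
#' @param file,width,height As in [plot_raw_oscillograph()].
#' @param ... Unused.
#' @return A ggplot object (or `file`, invisibly, when writing).
#' @export
autoplot.sgc <- function(object, samples = NULL, show_symmetry_line = TRUE,
                         file = NULL, width = 7, height = 12, ...) {
  long <- tidy(object) |>
    dplyr::mutate(segment = factor(.data$segment, levels = rev(segment_labels())))
  ylim <- oscillograph_ylim(c(long$rotation_deg,
                              if (!is.null(samples)) samples$rotation_deg))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$pct, y = .data$rotation_deg))
  if (!is.na(object$mean_stance_pct)) {
    p <- p + ggplot2::annotate("rect", xmin = 0, xmax = object$mean_stance_pct,
                               ymin = -Inf, ymax = Inf,
                               fill = "grey85", alpha = 0.6)
  }
  p <- p + ggplot2::geom_hline(yintercept = 0, colour = "grey60", linewidth = 0.3)
  if (!is.null(samples)) {
    pts <- dplyr::mutate(samples,
                         segment = factor(.data$segment,
                                          levels = rev(segment_labels())))
    p <- p + ggplot2::geom_point(data = pts, size = 0.3, alpha = 0.4,
                                 colour = "grey40")
  }
  if (show_symmetry_line) {
    sl <- long |>
      dplyr::filter(.data$pct < 100) |>
      dplyr::group_by(.data$segment) |>
      dplyr::summarise(symmetry_line = mean(.data$rotation_deg), .groups = "drop")
    p <- p + ggplot2::geom_hline(
      data = sl, ggplot2::aes(yintercept = .data$symmetry_line),
      colour = "#b03a2a", linetype = "dashed", linewidth = 0.3
    )
  }
  p <- p +
    ggplot2::geom_line(colour = "#2a6fb0") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$segment)) +
    ggplot2::scale_x_continuous(limits = c(0, 100)) +
    ggplot2::scale_y_continuous(limits = ylim) +
    ggplot2::labs(x = "Gait cycle (%)",
                  y = "Transverse rotation (deg, positive = left)") +
    oscillograph_theme()
  finish_oscillograph(p, file, width, height)
}

#' Render a gallery of anonymized SGC oscillographs
#'
#' Writes one figure per standardized gait cycle plus a plain-text index.
#' Files are named by graph number only (`graph_001` etc.), never by subject
#' code, so the gallery can be shared without identifying metadata.
#'
#' @param sgcs A list of `sgc` objects.
#' @param out_dir Output directory (created if missing).
#' @param format `"png"`, `"svg"` or `"pdf"`.
#' @return Character vector of written paths (figures then index), invisibly.
#' @export
plot_gallery <- function(sgcs, out_dir, format = c("png", "svg", "pdf")) {
  format <- match.arg(format)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (length(sgcs) == 0) {
    warning("empty SGC list; writing index only", call. = FALSE)
  }
  figs <- character(0)
  for (i in seq_along(sgcs)) {
    path <- file.path(out_dir, sprintf("graph_%03d.%s", i, format))
    autoplot(sgcs[[i]], file = path)
    figs <- c(figs, path)
  }
  index <- file.path(out_dir, "index.md")
  writeLines(c(
    "# Standardized gait cycle gallery",
    "",
    sprintf("%d anonymized graph(s).", length(sgcs)),
    "",
    sprintf("- graph %03d: `%s`", seq_along(figs), basename(figs))
  ), index)
  invisible(c(figs, index))
}

# shared symmetric y-limits, rounded up to the next 5 degrees
oscillograph_ylim <- function(values) {
  m <- max(abs(values), na.rm = TRUE)
  lim <- max(5, ceiling(m / 5) * 5)
  c(-lim, lim)
}

oscillograph_theme <- function() {
  ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(
      strip.text.y = ggplot2::element_text(angle = 0),
      panel.grid.minor = ggplot2::element_blank()
    )
}

finish_oscillograph <- function(p, file, width, height) {
  if (is.null(file)) return(p)
  ggplot2::ggsave(file, p, width = width, height = height, dpi = 150)
  invisible(file)
}
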
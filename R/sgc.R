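#' Time-normalize gait cycles to the 0-100% scale
#'
#' Maps every frame of every complete gait cycle onto percent-of-cycle:
#' `pct = 100 * (frame - start_frame) / (end_frame - start_frame)`, in
#' `[0, 100)`. Measurements differing in cadence (and hence in frames per
#' cycle) become comparable on this shared scale.
#'
#' @param rotation Rotation tibble at 60 Hz (18 segment columns).
#' @param cycles Cycle table from [segment_cycles()].
#' @return A long tibble: `cycle_index`, `frame`, `pct`, `segment`,
#'   `rotation_deg`, with one row per (cycle frame, segment).
#' @export
normalize_cycles <- function(rotation, cycles) {
  if (nrow(cycles) == 0) stop("no complete gait cycles to normalize", call. = FALSE)
  if (any(cycles$end_frame <= cycles$start_frame)) {
    stop("zero-length gait cycle", call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(cycles)), function(i) {
    sel <- rotation$frame >= cycles$start_frame[i] &
      rotation$frame < cycles$end_frame[i]
    rotation[sel, c("frame", segment_labels())] |>
      dplyr::mutate(
        cycle_index = cycles$cycle_index[i],
        pct = 100 * (.data$frame - cycles$start_frame[i]) /
          (cycles$end_frame[i] - cycles$start_frame[i])
      )
  }) |>
    tidyr::pivot_longer(cols = dplyr::all_of(segment_labels()),
                        names_to = "segment", values_to = "rotation_deg") |>
    dplyr::select("cycle_index", "frame", "pct", "segment", "rotation_deg")
}

#' Fit a Standardized Gait Cycle from pooled normalized cycles
#'
#' Pools the time-normalized samples of three or more gait cycles and fits,
#' per segment, one cubic smoothing spline over percent-of-cycle, evaluated
#' on the fixed 101-point grid 0, 1, ..., 100. Pooling before fitting (rather
#' than resampling each cycle and averaging) lets all observed points inform
#' one smooth curve per measurement.
#'
#' With `smoothing = "auto"` the penalty is chosen per segment by
#' generalized cross-validation; a non-negative number is used directly as
#' the smoothing penalty (`lambda`), with 0 approaching the interpolant of
#' the pooled points. With `periodic = TRUE` a cyclic cubic spline basis
#' (via [mgcv::gam()]) constrains the curve to close exactly,
#' `curve(0) == curve(100)`; the default is non-periodic, allowing the
#' slight end mismatches real measurements show.
#'
#' @param samples Long tibble from [normalize_cycles()] (columns
#'   `cycle_index`, `pct`, `segment`, `rotation_deg`). Needs at least 3
#'   distinct cycles and 10 non-missing samples per segment; `NA` samples are
#'   excluded from the fit, never imputed.
#' @param smoothing `"auto"` (GCV) or a non-negative smoothing penalty.
#' @param periodic Logical; use a cyclic spline basis.
#' @param mean_stance_pct Optional mean right-stance percentage carried from
#'   [segment_cycles()] for downstream phase annotations.
#' @return An object of class `sgc`: `curves` (tibble `pct` 0-100 plus one
#'   column per segment, degrees), `grid`, `n_cycles_used`,
#'   `mean_stance_pct`, `periodic`, `smoothing` (per-segment fitted penalty),
#'   `segments_omitted`.
#' @examples
#' sim <- simulate_recording(gait_sim_params("typical", seed = 2))
#' ann <- annotate_gait(sim$rotation, sim$force)
#' sgc <- normalize_cycles(sim$rotation, ann$cycles) |>
#'   fit_sgc(mean_stance_pct = ann$mean_stance_pct)
#' sgc
#' @export
fit_sgc <- function(samples, smoothing = "auto", periodic = FALSE,
                    mean_stance_pct = NA_real_) {
  stopifnot(all(c("cycle_index", "pct", "segment", "rotation_deg") %in% names(samples)))
  n_cycles <- dplyr::n_distinct(samples$cycle_index)
  if (n_cycles < 3) {
    stop("a standardized gait cycle requires at least 3 gait cycles; got ",
         n_cycles, call. = FALSE)
  }
  if (!identical(smoothing, "auto") &&
      !(is.numeric(smoothing) && length(smoothing) == 1 && smoothing >= 0)) {
    stop("smoothing must be \"auto\" or a non-negative number", call. = FALSE)
  }

  grid <- 0:100
  fits <- purrr::map(segment_labels(), function(seg) {
    d <- samples[samples$segment == seg & !is.na(samples$rotation_deg), ]
    if (nrow(d) == 0) return(NULL)
    if (nrow(d) < 10) {
      stop("segment ", seg, " has fewer than 10 samples", call. = FALSE)
    }
    fit_segment_spline(d$pct, d$rotation_deg, grid, smoothing, periodic)
  })
  names(fits) <- segment_labels()
  omitted <- names(fits)[purrr::map_lgl(fits, is.null)]
  if (length(omitted) > 0) {
    warning("segment(s) with no usable samples omitted: ",
            paste(omitted, collapse = ", "), call. = FALSE)
    fits <- fits[!purrr::map_lgl(fits, is.null)]
  }
  curves <- dplyr::bind_cols(
    tibble::tibble(pct = grid),
    tibble::as_tibble(purrr::map(fits, "curve"))
  )
  structure(
    list(
      curves = curves,
      grid = grid,
      n_cycles_used = n_cycles,
      mean_stance_pct = mean_stance_pct,
      periodic = periodic,
      smoothing = purrr::map_dbl(fits, "lambda"),
      segments_omitted = omitted
    ),
    class = "sgc"
  )
}

# one segment: cubic smoothing spline over pooled (pct, deg) points.
# Constant segments short-circuit (a spline reproduces constants anyway,
# but degenerate zero-variance input can upset GCV).
fit_segment_spline <- function(pct, deg, grid, smoothing, periodic) {
  if (diff(range(deg)) < 1e-12) {
    return(list(curve = rep(deg[1], length(grid)), lambda = 0))
  }
  if (periodic) {
    k <- min(30L, max(6L, length(unique(pct)) - 1L))
    args <- list(
      formula = deg ~ s(pct, bs = "cc", k = k),
      data = data.frame(pct = pct, deg = deg),
      knots = list(pct = c(0, 100)),
      method = "GCV.Cp"
    )
    if (!identical(smoothing, "auto")) args$sp <- smoothing
    fit <- do.call(mgcv::gam, args)
    list(curve = as.numeric(stats::predict(fit, data.frame(pct = grid))),
         lambda = unname(fit$sp[1]))
  } else {
    if (identical(smoothing, "auto")) {
      fit <- stats::smooth.spline(pct, deg, cv = FALSE)  # GCV
    } else {
      fit <- stats::smooth.spline(pct, deg, lambda = max(smoothing, 1e-10))
    }
    list(curve = stats::predict(fit, grid)$y, lambda = fit$lambda)
  }
}

#' @export
print.sgc <- function(x, ...) {
  cat("<sgc> standardized gait cycle on the 0-100% grid (101 points)\n")
  cat("  segments:", ncol(x$curves) - 1L, " cycles pooled:", x$n_cycles_used,
      if (x$periodic) " (periodic basis)\n" else "\n")
  if (!is.na(x$mean_stance_pct)) {
    cat("  mean right-stance:", round(x$mean_stance_pct, 1), "% of cycle\n")
  }
  invisible(x)
}

#' Tidy a standardized gait cycle into a long tibble
#'
#' @param x An `sgc` object.
#' @param ... Unused.
#' @return Tibble with `pct`, `segment` (factor in caudal-to-cranial order),
#'   `rotation_deg`.
#' @export
tidy.sgc <- function(x, ...) {
  tidyr::pivot_longer(x$curves, cols = -"pct", names_to = "segment",
                      values_to = "rotation_deg") |>
    dplyr::mutate(segment = segment_factor(.data$segment)) |>
    dplyr::arrange(.data$segment, .data$pct)
}

#' One-row summary of a standardized gait cycle
#'
#' @inheritParams tidy.sgc
#' @return One-row tibble: `n_segments`, `n_cycles_used`, `mean_stance_pct`,
#'   `periodic`, `median_lambda`.
#' @export
glance.sgc <- function(x, ...) {
  tibble::tibble(
    n_segments = ncol(x$curves) - 1L,
    n_cycles_used = x$n_cycles_used,
    mean_stance_pct = x$mean_stance_pct,
    periodic = x$periodic,
    median_lambda = stats::median(x$smoothing)
  )
}

#' Write / read a standardized gait cycle table
#'
#' The SGC table is a CSV with `pct,PELVIS,...,C7` and rows 0-100. Object
#' metadata (cycles pooled, mean stance, periodic flag) is carried in `#`
#' comment lines so a write-read round trip is lossless.
#'
#' @param sgc An `sgc` object.
#' @param path File path.
#' @return `write_sgc_csv()` returns `path` invisibly; `read_sgc_csv()`
#'   returns an `sgc` object.
#' @rdname sgc_io
#' @export
write_sgc_csv <- function(sgc, path) {
  stopifnot(inherits(sgc, "sgc"))
  meta <- c(
    sprintf("# n_cycles_used: %d", sgc$n_cycles_used),
    sprintf("# mean_stance_pct: %s", format(sgc$mean_stance_pct, digits = 15)),
    sprintf("# periodic: %s", sgc$periodic)
  )
  writeLines(meta, path)
  readr::write_csv(sgc$curves, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname sgc_io
#' @export
read_sgc_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 10)
  meta_lines <- grep("^#", header, value = TRUE)
  meta_get <- function(key, default) {
    hit <- grep(paste0("^# ", key, ": "), meta_lines, value = TRUE)
    if (length(hit) == 0) default else sub(paste0("^# ", key, ": "), "", hit[1])
  }
  curves <- readr::read_csv(path, comment = "#", progress = FALSE,
                            col_types = readr::cols(.default = readr::col_double()))
  if (!"pct" %in% names(curves)) stop("malformed SGC table: no pct column", call. = FALSE)
  if (nrow(curves) != 101 || !identical(as.integer(curves$pct), 0:100)) {
    stop("malformed SGC grid: expected pct 0, 1, ..., 100 (101 rows)", call. = FALSE)
  }
  unknown <- setdiff(names(curves), c("pct", segment_labels()))
  if (length(unknown) > 0) {
    stop("unknown column(s) in SGC table: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(
      curves = curves,
      grid = 0:100,
      n_cycles_used = as.integer(meta_get("n_cycles_used", NA)),
      mean_stance_pct = as.numeric(meta_get("mean_stance_pct", NA)),
      periodic = as.logical(meta_get("periodic", FALSE)),
      smoothing = NULL,
      segments_omitted = setdiff(segment_labels(), names(curves))
    ),
    class = "sgc"
  )
}
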
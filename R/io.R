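#' Read a per-measurement rotation export
#'
#' Reads one rotation CSV in the package's export dialect: comma-separated,
#' UTF-8, header `frame,time_s,PELVIS,L4,...,C7` (all 18 canonical segment
#' columns), one row per 60 Hz frame, rotation in degrees with positive
#' values denoting rotation to the left. A dot decimal separator is written;
#' a comma decimal is accepted on read. The subject code and treadmill speed
#' are recovered from the filename unless given explicitly.
#'
#' Validation is strict so that a mislabelled export can never be read in
#' silently: a missing or unknown segment column is a hard error naming the
#' column, a non-numeric cell is an error naming the row, and the frame index
#' must be gapless from 0. Empty cells become explicit `NA`s (flagged by
#' [plausibility_report()], excluded from spline fits, never dropped).
#'
#' @param path Path to the CSV file.
#' @param subject_code,speed_kmh Optional metadata overriding the filename.
#' @return A tibble (`frame`, `time_s`, 18 segment columns) with attributes
#'   `subject_code` and `speed_kmh`.
#' @seealso [write_rotation_csv()], [parse_export_filename()], [merge_exports()]
#' @export
read_rotation_csv <- function(path, subject_code = NULL, speed_kmh = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("frame", "time_s", segment_labels())
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(names(raw), required)
  if (length(unknown) > 0) {
    stop("unknown column(s) in ", basename(path), ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(lapply(stats::setNames(required, required), function(col) {
    parse_numeric_col(raw[[col]], col, path)
  }))
  out$frame <- as.integer(out$frame)
  if (nrow(out) == 0) stop("empty export: ", basename(path), call. = FALSE)
  if (anyNA(out$frame) || !identical(out$frame, seq_len(nrow(out)) - 1L)) {
    stop("frame index must be gapless and start at 0 in ", basename(path),
         call. = FALSE)
  }
  if (is.null(subject_code) || is.null(speed_kmh)) {
    meta <- parse_export_filename(path)
    subject_code <- subject_code %||% meta$subject_code
    speed_kmh <- speed_kmh %||% meta$speed_kmh
  }
  attr(out, "subject_code") <- subject_code
  attr(out, "speed_kmh") <- speed_kmh
  out
}

# tolerant numeric parse: dot decimal canonical, comma decimal accepted;
# empty/NA cells stay NA; anything else errors with the offending row
parse_numeric_col <- function(x, col, path) {
  x_clean <- sub(",", ".", x, fixed = TRUE)
  val <- suppressWarnings(as.numeric(x_clean))
  bad <- which(!is.na(x) & x != "" & x != "NA" & is.na(val))
  if (length(bad) > 0) {
    stop("non-numeric value ", dQuote(x[bad[1]]), " in column ", col,
         ", data row ", bad[1], " of ", basename(path), call. = FALSE)
  }
  val
}

#' Read a per-measurement foot-pressure export
#'
#' Reads one force CSV in the dialect `sample,time_s,force_left,force_right`,
#' one row per 120 Hz sample, per-foot total vertical force in force units
#' (non-negative).
#'
#' @inheritParams read_rotation_csv
#' @return A tibble (`sample`, `time_s`, `force_left`, `force_right`).
#' @export
read_force_csv <- function(path, subject_code = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- c("sample", "time_s", "force_left", "force_right")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(lapply(stats::setNames(required, required), function(col) {
    parse_numeric_col(raw[[col]], col, path)
  }))
  out$sample <- as.integer(out$sample)
  if (!identical(out$sample, seq_len(nrow(out)) - 1L)) {
    stop("sample index must be gapless and start at 0 in ", basename(path),
         call. = FALSE)
  }
  if (any(out$force_left < 0 | out$force_right < 0, na.rm = TRUE)) {
    stop("negative force values in ", basename(path), call. = FALSE)
  }
  attr(out, "subject_code") <- subject_code
  out
}

#' Write rotation / force tables in the export dialect
#'
#' Values are rounded to 6 decimal places on write; a read-write round trip
#' is the identity at that printed precision, and output is byte-stable.
#'
#' @param x The rotation or force tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @rdname write_export
#' @export
write_rotation_csv <- function(x, path) {
  stopifnot(all(c("frame", "time_s", segment_labels()) %in% names(x)))
  write_rounded_csv(x[, c("frame", "time_s", segment_labels())], path)
}

#' @rdname write_export
#' @export
write_force_csv <- function(x, path) {
  stopifnot(all(c("sample", "time_s", "force_left", "force_right") %in% names(x)))
  write_rounded_csv(x[, c("sample", "time_s", "force_left", "force_right")], path)
}

write_rounded_csv <- function(x, path) {
  x <- dplyr::mutate(x, dplyr::across(dplyr::where(is.double), ~ round(.x, 6)))
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Parse subject code and speed from an export filename
#'
#' Export filenames carry the measurement metadata as
#' `<subjectcode>_<speed>kmh*.csv`; the speed accepts a dot or comma decimal.
#' A filename that does not match is an error — there are no silent defaults.
#'
#' @param path File path or name.
#' @return A list with `subject_code` (character) and `speed_kmh` (numeric).
#' @examples
#' parse_export_filename("subj041_5.0kmh_rotation.csv")
#' @export
parse_export_filename <- function(path) {
  name <- basename(path)
  m <- regmatches(name, regexec("^(.+?)_([0-9]+(?:[.,][0-9]+)?)kmh.*\\.(csv|json)$", name))[[1]]
  if (length(m) == 0) {
    stop("filename does not match '<code>_<speed>kmh*.csv': ", name, call. = FALSE)
  }
  list(
    subject_code = m[2],
    speed_kmh = as.numeric(sub(",", ".", m[3], fixed = TRUE))
  )
}

#' Merge per-measurement rotation exports into one long raw-data table
#'
#' Reads every file, reshapes to long format and stacks them into one
#' complete raw data table with one row per (measurement, frame, segment).
#' Ordering is stable — subject code, speed, frame, then segment in
#' caudal-to-cranial order — and independent of the input path order. A
#' provenance column records the source filename. Duplicate
#' (subject, speed, frame) combinations across files are an ambiguous merge
#' and raise an error.
#'
#' @param paths Character vector of rotation CSV paths (at least one).
#' @return A tibble with columns `subject_code`, `speed_kmh`, `frame`,
#'   `time_s`, `segment`, `ordinal`, `rotation_deg`, `source_file`. Row count
#'   is the sum of per-file frame counts times 18 segments.
#' @export
merge_exports <- function(paths) {
  if (length(paths) == 0) stop("no export files given", call. = FALSE)
  tables <- purrr::map(paths, function(p) {
    rec <- read_rotation_csv(p)
    tidyr::pivot_longer(rec, cols = dplyr::all_of(segment_labels()),
                        names_to = "segment", values_to = "rotation_deg") |>
      dplyr::mutate(
        subject_code = attr(rec, "subject_code"),
        speed_kmh = attr(rec, "speed_kmh"),
        ordinal = segment_ordinal(.data$segment),
        source_file = basename(p)
      )
  })
  merged <- dplyr::bind_rows(tables) |>
    dplyr::select("subject_code", "speed_kmh", "frame", "time_s",
                  "segment", "ordinal", "rotation_deg", "source_file") |>
    dplyr::arrange(.data$subject_code, .data$speed_kmh, .data$frame, .data$ordinal)
  dup <- merged |>
    dplyr::count(.data$subject_code, .data$speed_kmh, .data$frame) |>
    dplyr::filter(.data$n > length(segment_labels()))
  if (nrow(dup) > 0) {
    stop("ambiguous merge: duplicate (subject, speed, frame) across files, e.g. ",
         dup$subject_code[1], " @ ", dup$speed_kmh[1], " km/h frame ",
         dup$frame[1], call. = FALSE)
  }
  merged
}

#' Plausibility report for a merged raw-data table
#'
#' Screens the complete raw data table for outlying values and gaps before
#' any modelling: per-segment minimum/maximum/range, count of missing cells,
#' and every cell whose absolute rotation exceeds the outlier bound.
#' Transverse-plane segmental rotation during normal gait stays well inside
#' +/-30 degrees, so the default bound flags gross export errors rather than
#' unusual gait.
#'
#' @param merged A table from [merge_exports()].
#' @param outlier_bound Absolute rotation (degrees) beyond which a cell is
#'   flagged. Default 30.
#' @return A list of class `plausibility_report`: `segments` (per-segment
#'   summary tibble), `outliers` (flagged rows), `gaps` (frame gaps per
#'   measurement; empty when indices are gapless).
#' @export
plausibility_report <- function(merged, outlier_bound = 30) {
  segments <- merged |>
    dplyr::group_by(.data$segment, .data$ordinal) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_missing = sum(is.na(.data$rotation_deg)),
      min_deg = suppressWarnings(min(.data$rotation_deg, na.rm = TRUE)),
      max_deg = suppressWarnings(max(.data$rotation_deg, na.rm = TRUE)),
      range_deg = .data$max_deg - .data$min_deg,
      n_outliers = sum(abs(.data$rotation_deg) > outlier_bound, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$ordinal)
  outliers <- merged |>
    dplyr::filter(abs(.data$rotation_deg) > outlier_bound)
  gaps <- merged |>
    dplyr::distinct(.data$subject_code, .data$speed_kmh, .data$frame) |>
    dplyr::group_by(.data$subject_code, .data$speed_kmh) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(
      n_gaps = sum(diff(.data$frame) != 1L),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$n_gaps > 0)
  structure(
    list(segments = segments, outliers = outliers, gaps = gaps,
         outlier_bound = outlier_bound),
    class = "plausibility_report"
  )
}

#' @export
print.plausibility_report <- function(x, ...) {
  cat("<plausibility_report> outlier bound +/-", x$outlier_bound, "deg\n")
  print(x$segments, n = 18)
  cat(nrow(x$outliers), "outlying cell(s);", nrow(x$gaps),
      "measurement(s) with frame gaps\n")
  invisible(x)
}
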
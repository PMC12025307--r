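# round-half-up: the documented rounding convention for mapping event times
# onto the 60 Hz frame grid (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

FORCE_RATE <- 120
FRAME_RATE <- 60

#' Detect initial-contact and initial-swing events from foot pressure
#'
#' Per foot, a sample is in ground contact when its force exceeds a relative
#' threshold: `threshold_frac` times the 95th percentile of that foot's force
#' trace. Initial Contact (IC) is the first sample of each contact run;
#' Initial Swing (IS, toe-off) is the first sample after it. Runs are
#' debounced: sub-threshold gaps shorter than `min_phase_duration` are merged
#' into the surrounding contact, and contact runs shorter than
#' `min_phase_duration` are discarded. A relative threshold keeps detection
#' independent of the absolute force scale; the debounce suppresses noise
#' spikes without moving genuine events.
#'
#' Because the true transition occurs somewhere between the last sample of
#' the old phase and the first sample of the new one, events are timestamped
#' at the midpoint of that 120 Hz interval (clamped at the recording start)
#' and mapped to the nearest 60 Hz frame by round-half-up; this keeps both IC
#' and IS unbiased at sub-sample resolution.
#'
#' @param force A force tibble (`sample`, `time_s`, `force_left`,
#'   `force_right`) at 120 Hz, e.g. from [simulate_recording()] or
#'   [read_force_csv()].
#' @param threshold_frac Contact threshold as a fraction of the per-foot 95th
#'   force percentile, in (0, 1). Default 0.05.
#' @param min_phase_duration Minimum credible stance/swing duration in
#'   seconds (debounce window). Default 0.1 s.
#' @return A tibble of events: `kind` (`IC_RIGHT`, `IS_RIGHT`, `IC_LEFT`,
#'   `IS_LEFT`), `foot`, `time` (s), `force_sample_index` (0-based 120 Hz
#'   sample), `frame_index` (nearest 60 Hz frame, round-half-up), ordered by
#'   time. An all-zero trace yields zero rows with a warning.
#' @examples
#' sim <- simulate_recording(gait_sim_params("typical", seed = 1))
#' detect_events(sim$force)
#' @export
detect_events <- function(force, threshold_frac = 0.05, min_phase_duration = 0.1) {
  stopifnot(all(c("sample", "time_s", "force_left", "force_right") %in% names(force)))
  if (!(threshold_frac > 0 && threshold_frac < 1)) {
    stop("threshold_frac must be in (0, 1)", call. = FALSE)
  }
  if (any(force$force_left < 0 | force$force_right < 0, na.rm = TRUE)) {
    stop("force must be non-negative", call. = FALSE)
  }
  min_samples <- round(min_phase_duration * FORCE_RATE)
  events <- dplyr::bind_rows(
    foot_events(force$force_right, "right", threshold_frac, min_samples),
    foot_events(force$force_left, "left", threshold_frac, min_samples)
  )
  if (nrow(events) == 0) {
    warning("no contact detected in force trace; empty event list", call. = FALSE)
    return(tibble::tibble(kind = character(), foot = character(),
                          time = numeric(), force_sample_index = integer(),
                          frame_index = integer()))
  }
  # The transition happens between the last sample of the old phase and the
  # first sample of the new one; timestamp it at the midpoint of that 120 Hz
  # interval (clamped at the recording start) so neither IC nor IS is biased.
  events |>
    dplyr::mutate(
      time = pmax(.data$force_sample_index - 0.5, 0) / FORCE_RATE,
      frame_index = as.integer(round_half_up(.data$time * FRAME_RATE))
    ) |>
    dplyr::arrange(.data$time, .data$kind) |>
    dplyr::select("kind", "foot", "time", "force_sample_index", "frame_index")
}

# contact runs for one foot after debouncing; returns IC/IS rows (0-based samples)
foot_events <- function(f, foot, threshold_frac, min_samples) {
  thr <- threshold_frac * stats::quantile(f, 0.95, names = FALSE, na.rm = TRUE)
  contact <- !is.na(f) & f > thr
  runs <- contact_runs(contact, min_samples)
  if (nrow(runs) == 0) {
    return(tibble::tibble(kind = character(), foot = character(),
                          force_sample_index = integer()))
  }
  ic <- tibble::tibble(
    kind = paste0("IC_", toupper(foot)), foot = foot,
    force_sample_index = runs$start - 1L
  )
  # IS only when the run ends inside the recording
  ends_inside <- runs$end < length(f)
  is_ <- tibble::tibble(
    kind = paste0("IS_", toupper(foot)), foot = foot,
    force_sample_index = runs$end[ends_inside]  # first sample after the run
  )
  dplyr::bind_rows(ic, is_)
}

# run-length debounce: close short FALSE gaps between contacts, then drop
# short TRUE runs; returns 1-based [start, end] inclusive sample runs
contact_runs <- function(contact, min_samples) {
  r <- rle(contact)
  # merge sub-threshold gaps strictly inside the trace
  if (length(r$lengths) > 2) {
    inner <- seq(2, length(r$lengths) - 1)
    gap <- inner[!r$values[inner] & r$lengths[inner] < min_samples]
    r$values[gap] <- TRUE
    r <- rle(inverse.rle(r))
  }
  keep <- r$values & r$lengths >= min_samples
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(start = starts[keep], end = ends[keep])
}

#' Encode per-frame stance/swing phase codes
#'
#' Maps the detected events onto the 60 Hz frame grid: frame `f` is stance
#' for a foot iff it lies in the half-open interval `[IC_frame, IS_frame)` of
#' some contact run of that foot. Frames before the first event of a foot are
#' unannotated (`NA`) and are excluded from gait cycles rather than
#' extrapolated.
#'
#' @param events Event tibble from [detect_events()].
#' @param n_frames Number of 60 Hz frames in the rotation recording.
#' @return A tibble with `frame` (0-based), `stance_right`, `stance_left`
#'   (logical; `NA` = unannotated).
#' @export
encode_phases <- function(events, n_frames) {
  stopifnot(n_frames >= 1)
  tibble::tibble(
    frame = seq_len(n_frames) - 1L,
    stance_right = foot_phase_codes(events, "right", n_frames),
    stance_left = foot_phase_codes(events, "left", n_frames)
  )
}

foot_phase_codes <- function(events, foot, n_frames) {
  ev <- events[events$foot == foot, , drop = FALSE]
  code <- rep(NA, n_frames)
  if (nrow(ev) == 0) return(as.logical(code))
  ev <- ev[order(ev$time), , drop = FALSE]
  kinds <- sub("_.*", "", ev$kind)
  if (kinds[1] != "IC" || any(kinds[-1] == kinds[-length(kinds)])) {
    stop("events for ", foot, " foot do not alternate IC, IS, IC, ...",
         call. = FALSE)
  }
  frames <- seq_len(n_frames) - 1L
  ic_frames <- ev$frame_index[kinds == "IC"]
  is_frames <- ev$frame_index[kinds == "IS"]
  annotated <- frames >= ic_frames[1]
  code[annotated] <- FALSE
  for (i in seq_along(ic_frames)) {
    end <- if (i <= length(is_frames)) is_frames[i] else n_frames
    code[frames >= ic_frames[i] & frames < end] <- TRUE
  }
  as.logical(code)
}

#' Pair 60 Hz spine frames with the nearest 120 Hz force samples
#'
#' The spine camera and the pressure plate start simultaneously but sample at
#' different rates, so observation times must be reconciled before phases can
#' be attached to spine frames. Each frame `k` (time `k/60`) is paired with
#' the force sample nearest in time (round-half-up); with the exact 2:1 rate
#' ratio that is sample `2k`. Frames beyond the end of the force stream are
#' marked unannotated with a warning.
#'
#' @param force Force tibble at 120 Hz.
#' @param rotation Rotation tibble at 60 Hz.
#' @return `rotation`'s frame grid with `force_sample`, `force_left`,
#'   `force_right`, `annotated` columns.
#' @export
synchronize <- function(force, rotation) {
  frames <- rotation$frame
  idx <- as.integer(round_half_up(frames / FRAME_RATE * FORCE_RATE))
  ok <- idx <= max(force$sample)
  if (!all(ok)) {
    warning(sum(!ok), " trailing frame(s) extend past the force stream and ",
            "are unannotated", call. = FALSE)
  }
  pos <- match(idx, force$sample)
  tibble::tibble(
    frame = frames,
    time_s = rotation$time_s,
    force_sample = ifelse(ok, idx, NA_integer_),
    force_left = ifelse(ok, force$force_left[pos], NA_real_),
    force_right = ifelse(ok, force$force_right[pos], NA_real_),
    annotated = ok
  )
}

#' Segment the recording into complete gait cycles
#'
#' A gait cycle starts at the first full Initial Contact of the right foot
#' and ends at (excludes) the next right-foot IC, so `n` right ICs delimit
#' `n - 1` complete cycles; leading and trailing data outside complete cycles
#' are discarded. Cycles tile the annotated region without overlap
#' (half-open frame intervals).
#'
#' @param phases Phase-code tibble from [encode_phases()].
#' @param events Event tibble from [detect_events()].
#' @return A tibble with `cycle_index` (1-based), `start_frame`, `end_frame`
#'   (half-open `[start, end)`), `n_frames`, `stance_right_pct` (right-foot
#'   stance frames as a percentage of cycle frames). Fewer than two right ICs
#'   yields zero rows with a warning.
#' @export
segment_cycles <- function(phases, events) {
  ic <- sort(events$frame_index[events$kind == "IC_RIGHT"])
  if (length(ic) < 2) {
    warning("fewer than 2 right initial contacts; no complete gait cycle",
            call. = FALSE)
    return(tibble::tibble(cycle_index = integer(), start_frame = integer(),
                          end_frame = integer(), n_frames = integer(),
                          stance_right_pct = numeric()))
  }
  purrr::map_dfr(seq_len(length(ic) - 1), function(i) {
    start <- ic[i]
    end <- ic[i + 1]
    in_cycle <- phases$frame >= start & phases$frame < end
    tibble::tibble(
      cycle_index = i,
      start_frame = start,
      end_frame = end,
      n_frames = end - start,
      stance_right_pct = 100 * sum(phases$stance_right[in_cycle], na.rm = TRUE) /
        (end - start)
    )
  })
}

#' Annotate a rotation recording with gait phases and cycles
#'
#' Convenience wrapper chaining [detect_events()], [encode_phases()] and
#' [segment_cycles()], and attaching the per-frame phase codes and cycle
#' index to the rotation table.
#'
#' @param rotation Rotation tibble at 60 Hz.
#' @param force Force tibble at 120 Hz.
#' @inheritParams detect_events
#' @return A list of class `gait_annotation`: `rotation` (input plus
#'   `stance_right`, `stance_left`, `cycle_index` columns), `events`,
#'   `phases`, `cycles`, `mean_stance_pct`.
#' @examples
#' sim <- simulate_recording(gait_sim_params("typical", seed = 1))
#' ann <- annotate_gait(sim$rotation, sim$force)
#' ann$cycles
#' @export
annotate_gait <- function(rotation, force, threshold_frac = 0.05,
                          min_phase_duration = 0.1) {
  events <- detect_events(force, threshold_frac, min_phase_duration)
  phases <- encode_phases(events, nrow(rotation))
  cycles <- segment_cycles(phases, events)
  cycle_index <- rep(NA_integer_, nrow(rotation))
  for (i in seq_len(nrow(cycles))) {
    sel <- rotation$frame >= cycles$start_frame[i] &
      rotation$frame < cycles$end_frame[i]
    cycle_index[sel] <- cycles$cycle_index[i]
  }
  annotated <- rotation |>
    dplyr::mutate(
      stance_right = phases$stance_right,
      stance_left = phases$stance_left,
      cycle_index = cycle_index
    )
  structure(
    list(
      rotation = annotated,
      events = events,
      phases = phases,
      cycles = cycles,
      mean_stance_pct = if (nrow(cycles) > 0) mean(cycles$stance_right_pct) else NA_real_
    ),
    class = "gait_annotation"
  )
}

#' @export
print.gait_annotation <- function(x, ...) {
  cat("<gait_annotation>", nrow(x$events), "events,", nrow(x$cycles),
      "complete gait cycle(s)\n")
  if (nrow(x$cycles) > 0) {
    cat("  mean right-stance:", round(x$mean_stance_pct, 1), "% of cycle\n")
  }
  invisible(x)
}
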
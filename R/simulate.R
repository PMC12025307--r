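#' Simulate a synchronized spinal-rotation and foot-pressure recording
#'
#' Generates a 60 Hz per-segment transverse-plane rotation recording and a
#' 120 Hz per-foot force recording with known ground truth, so every
#' downstream stage (event detection, phase encoding, standardization,
#' feature extraction) can be validated without the measurement device.
#'
#' Rotation of segment \eqn{s} at time \eqn{t} is
#' \deqn{\theta_s(t) = \ell_s + A_s \sin(2\pi(t/T - \phi_s)) + r \sin(2\pi m (t/T - \phi_s)) + \epsilon}
#' with stride duration \eqn{T}, level shift \eqn{\ell_s}, amplitude
#' \eqn{A_s}, phase lag \eqn{\phi_s} (fraction of a stride relative to the
#' pelvis), optional rhythm term (multiplier \eqn{m}, amplitude \eqn{r}) and
#' Gaussian noise. Positive rotation denotes rotation to the left.
#'
#' Each right-foot stance interval starts at a stride boundary; the left foot
#' is offset by half a stride. During stance the noiseless force follows a
#' smooth double-bump profile (heel-strike and push-off raised-cosine peaks),
#' strictly positive over the stance interval and exactly zero during swing;
#' noise is clipped so force never goes negative. Both streams start at
#' \eqn{t = 0}.
#'
#' @param params A [gait_sim_params()] object.
#' @param check_sgc_ready If `TRUE` (default), warn when `n_strides` is too
#'   small to yield the three complete gait cycles a standardized gait cycle
#'   requires (four right initial contacts).
#'
#' @return A list of class `gait_simulation` with elements
#' \describe{
#'   \item{`rotation`}{tibble: `frame`, `time_s`, one column per segment
#'     (degrees), sampled at 60 Hz.}
#'   \item{`force`}{tibble: `sample`, `time_s`, `force_left`, `force_right`,
#'     sampled at 120 Hz.}
#'   \item{`truth`}{list with `ic_right_times`, `is_right_times`,
#'     `ic_left_times`, `is_left_times` (seconds) and a `segments` tibble of
#'     the true amplitude/phase-lag/level per segment.}
#'   \item{`params`}{the input parameters.}
#' }
#' @examples
#' sim <- simulate_recording(gait_sim_params("typical", seed = 7))
#' sim$rotation[1:3, 1:5]
#' length(sim$truth$ic_right_times)
#' @export
simulate_recording <- function(params, check_sgc_ready = TRUE) {
  stopifnot(inherits(params, "gait_sim_params"))
  if (check_sgc_ready && params$n_strides < 4) {
    warning("n_strides = ", params$n_strides, " yields fewer than 3 complete ",
            "gait cycles; a standardized gait cycle needs >= 4 right initial ",
            "contacts", call. = FALSE)
  }

  stride <- params$stride_duration
  duration <- params$n_strides * stride
  n_rot <- round(60 * duration) + 1L
  n_force <- round(120 * duration) + 1L
  t_rot <- (seq_len(n_rot) - 1L) / 60
  t_force <- (seq_len(n_force) - 1L) / 120

  withr::with_seed(params$seed, {
    rotation <- rotation_table(t_rot, params)
    force <- force_table(t_force, params)
  })
  attr(rotation, "subject_code") <- params$subject_code
  attr(rotation, "speed_kmh") <- params$speed_kmh
  attr(force, "subject_code") <- params$subject_code

  structure(
    list(
      rotation = rotation,
      force = force,
      truth = ground_truth(params, duration),
      params = params
    ),
    class = "gait_simulation"
  )
}

rotation_table <- function(t, params) {
  stride <- params$stride_duration
  labs <- segment_labels()
  cols <- lapply(labs, function(s) {
    phase <- t / stride - params$segment_phase_lags[[s]]
    y <- params$segment_level_shifts[[s]] +
      params$segment_amplitudes[[s]] * sin(2 * pi * phase)
    if (!is.null(params$superimposed_rhythm)) {
      y <- y + params$superimposed_rhythm$amplitude *
        sin(2 * pi * params$superimposed_rhythm$multiplier * phase)
    }
    if (params$noise_sd_rotation > 0) {
      y <- y + stats::rnorm(length(t), 0, params$noise_sd_rotation)
    }
    y
  })
  names(cols) <- labs
  dplyr::bind_cols(
    tibble::tibble(frame = seq_along(t) - 1L, time_s = t),
    tibble::as_tibble(cols)
  )
}

# Double-bump stance profile on the unit stance interval: raised-cosine peaks
# at 25% (weight acceptance) and 75% (push-off) of stance, half-width 0.35,
# so the profile is strictly positive over the whole stance interval.
stance_profile <- function(u) {
  bump <- function(u, center, width) {
    ifelse(abs(u - center) < width,
           cos(pi * (u - center) / (2 * width))^2, 0)
  }
  bump(u, 0.25, 0.35) + bump(u, 0.75, 0.35)
}

force_trace <- function(t, stance_starts, stance_dur, peak, noise_sd) {
  f <- numeric(length(t))
  for (s0 in stance_starts) {
    in_stance <- t >= s0 & t < s0 + stance_dur  # half-open [start, end)
    u <- (t[in_stance] - s0) / stance_dur
    f[in_stance] <- peak * stance_profile(u)
  }
  if (noise_sd > 0) {
    f <- pmax(f + stats::rnorm(length(t), 0, noise_sd), 0)
  }
  f
}

force_table <- function(t, params) {
  stride <- params$stride_duration
  stance_dur <- params$stance_fraction * stride
  starts_r <- (seq_len(params$n_strides) - 1L) * stride
  starts_l <- starts_r + stride / 2
  tibble::tibble(
    sample = seq_along(t) - 1L,
    time_s = t,
    force_left = force_trace(t, starts_l, stance_dur, params$force_peak,
                             params$noise_sd_force),
    force_right = force_trace(t, starts_r, stance_dur, params$force_peak,
                              params$noise_sd_force)
  )
}

ground_truth <- function(params, duration) {
  stride <- params$stride_duration
  stance_dur <- params$stance_fraction * stride
  within_rec <- function(x) x[x < duration]
  starts_r <- (seq_len(params$n_strides) - 1L) * stride
  starts_l <- starts_r + stride / 2
  list(
    ic_right_times = within_rec(starts_r),
    is_right_times = within_rec(starts_r + stance_dur),
    ic_left_times = within_rec(starts_l),
    is_left_times = within_rec(starts_l + stance_dur),
    segments = tibble::tibble(
      segment = segment_labels(),
      amplitude_deg = unname(params$segment_amplitudes),
      phase_lag = unname(params$segment_phase_lags),
      level_deg = unname(params$segment_level_shifts)
    ),
    stance_fraction = params$stance_fraction,
    stride_duration = stride
  )
}

#' @export
print.gait_simulation <- function(x, ...) {
  cat("<gait_simulation>", x$params$preset, "preset,",
      x$params$n_strides, "strides of", x$params$stride_duration, "s\n")
  cat("  rotation:", nrow(x$rotation), "frames at 60 Hz;",
      "force:", nrow(x$force), "samples at 120 Hz\n")
  invisible(x)
}

#' Write a simulated recording to disk as a fixture set
#'
#' Emits the rotation CSV, force CSV and ground-truth JSON for one simulated
#' measurement in the package's export dialect. Filenames follow the
#' `<subjectcode>_<speed>kmh_<stream>.{csv,json}` convention from which
#' [parse_export_filename()] recovers the subject code and treadmill speed.
#' Output is deterministic: the same parameters (including seed) give
#' byte-identical files.
#'
#' @param params A [gait_sim_params()] object.
#' @param out_dir Writable output directory (created if missing).
#' @return Named character vector of the three file paths
#'   (`rotation`, `force`, `truth`), invisibly a tibble is not returned.
#' @examples
#' dir <- tempfile("fixtures")
#' paths <- write_fixture_set(gait_sim_params("typical", seed = 3), dir)
#' basename(paths)
#' @export
write_fixture_set <- function(params, out_dir) {
  stopifnot(inherits(params, "gait_sim_params"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sim <- simulate_recording(params, check_sgc_ready = FALSE)
  stem <- sprintf("%s_%.1fkmh", params$subject_code, params$speed_kmh)
  paths <- c(
    rotation = file.path(out_dir, paste0(stem, "_rotation.csv")),
    force = file.path(out_dir, paste0(stem, "_force.csv")),
    truth = file.path(out_dir, paste0(stem, "_truth.json"))
  )
  write_rotation_csv(sim$rotation, paths[["rotation"]])
  write_force_csv(sim$force, paths[["force"]])
  truth <- sim$truth
  truth$segments <- as.list(truth$segments)
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  paths
}
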
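#' Simulation parameters for synthetic gait recordings
#'
#' Builds a validated parameter set for [simulate_recording()]. The generative
#' model is one near-sinusoidal transverse-plane rotation oscillation per
#' stride for every spinal segment, with a caudal-to-cranial phase gradient,
#' optional level shifts and an optional superimposed higher-frequency rhythm,
#' plus double-bump foot-pressure traces with a configurable stance fraction.
#'
#' Presets reproduce the qualitative patterns seen in healthy walkers:
#' \describe{
#'   \item{`typical`}{pelvis and L4 in phase, lag increasing linearly up the
#'     spine to antiphase at T8 and above; T12 has a small amplitude near the
#'     directional crossing.}
#'   \item{`superimposed`}{the typical pattern with a third-harmonic rhythm
#'     superimposed on every segment.}
#'   \item{`amble`}{all segments rotate in phase with the pelvis (zero lags).}
#'   \item{`shifted`}{the typical pattern with the whole thoracic spine's
#'     symmetry line shifted 4 degrees to the right (negative).}
#' }
#'
#' @param preset One of `"typical"`, `"superimposed"`, `"amble"`, `"shifted"`.
#' @param stride_duration Stride (full gait cycle) duration in seconds, > 0.
#' @param n_strides Number of strides to simulate, integer >= 1. At least 4
#'   strides are needed for the 4 right initial contacts that delimit the 3
#'   complete cycles a standardized gait cycle requires.
#' @param stance_fraction Fraction of the stride each foot is in ground
#'   contact, strictly between 0 and 1. Default 0.60, the canonical 60/40
#'   stance/swing split.
#' @param segment_amplitudes Named numeric vector (degrees >= 0), one entry per
#'   segment label; `NULL` uses the preset values.
#' @param segment_phase_lags Named numeric vector of per-segment phase lags as
#'   fractions of a stride relative to the pelvis, wrapped into `[0, 1)`;
#'   `NULL` uses the preset values.
#' @param segment_level_shifts Named numeric vector of per-segment level
#'   shifts in degrees (the symmetry line offset); `NULL` uses the preset.
#' @param superimposed_rhythm `NULL`, or a list with `multiplier` (integer
#'   frequency multiplier >= 2) and `amplitude` (degrees >= 0).
#' @param noise_sd_rotation Gaussian noise SD on rotation, degrees >= 0.
#' @param noise_sd_force Gaussian noise SD on force (clipped so force stays
#'   non-negative), force units >= 0.
#' @param force_peak Peak of the noiseless stance force profile, force units.
#' @param subject_code,speed_kmh Metadata carried into exports and filenames.
#' @param seed Integer seed; the same seed and parameters give identical
#'   recordings.
#'
#' @return A list of class `gait_sim_params`.
#' @examples
#' p <- gait_sim_params("typical", seed = 1)
#' p$segment_phase_lags[c("PELVIS", "L4", "T8")]
#' @seealso [simulate_recording()], [write_fixture_set()]
#' @export
gait_sim_params <- function(preset = c("typical", "superimposed", "amble", "shifted"),
                            stride_duration = 1.2,
                            n_strides = 4L,
                            stance_fraction = 0.60,
                            segment_amplitudes = NULL,
                            segment_phase_lags = NULL,
                            segment_level_shifts = NULL,
                            superimposed_rhythm = NULL,
                            noise_sd_rotation = 0.5,
                            noise_sd_force = 5,
                            force_peak = 700,
                            subject_code = "sim001",
                            speed_kmh = 5.0,
                            seed = 1L) {
  preset <- match.arg(preset)
  def <- preset_defaults(preset)

  amplitudes <- segment_amplitudes %||% def$amplitudes
  lags <- segment_phase_lags %||% def$lags
  levels <- segment_level_shifts %||% def$levels
  rhythm <- if (is.null(segment_amplitudes) && is.null(superimposed_rhythm)) {
    def$rhythm
  } else {
    superimposed_rhythm
  }

  labs <- segment_labels()
  for (nm in c("amplitudes", "lags", "levels")) {
    v <- get(nm)
    if (!all(labs %in% names(v))) {
      stop("segment_", nm, " must be named for all 18 segments; missing: ",
           paste(setdiff(labs, names(v)), collapse = ", "), call. = FALSE)
    }
  }
  amplitudes <- amplitudes[labs]
  lags <- lags[labs] %% 1  # phase lags wrap modulo 1
  levels <- levels[labs]

  stopifnot(
    "stride_duration must be > 0" = is.numeric(stride_duration) && stride_duration > 0,
    "n_strides must be an integer >= 1" = n_strides >= 1,
    "stance_fraction must be strictly between 0 and 1" =
      stance_fraction > 0 && stance_fraction < 1,
    "amplitudes must be non-negative" = all(amplitudes >= 0),
    "noise SDs must be non-negative" = noise_sd_rotation >= 0 && noise_sd_force >= 0,
    "force_peak must be positive" = force_peak > 0
  )
  if (!is.null(rhythm)) {
    stopifnot(
      "superimposed_rhythm needs $multiplier and $amplitude" =
        all(c("multiplier", "amplitude") %in% names(rhythm)),
      "rhythm multiplier must be an integer >= 2" =
        rhythm$multiplier >= 2 && rhythm$multiplier == round(rhythm$multiplier),
      "rhythm amplitude must be non-negative" = rhythm$amplitude >= 0
    )
  }

  structure(
    list(
      preset = preset,
      stride_duration = stride_duration,
      n_strides = as.integer(n_strides),
      stance_fraction = stance_fraction,
      segment_amplitudes = amplitudes,
      segment_phase_lags = lags,
      segment_level_shifts = levels,
      superimposed_rhythm = rhythm,
      noise_sd_rotation = noise_sd_rotation,
      noise_sd_force = noise_sd_force,
      force_peak = force_peak,
      subject_code = subject_code,
      speed_kmh = speed_kmh,
      seed = as.integer(seed)
    ),
    class = "gait_sim_params"
  )
}

# Preset amplitude/lag/level tables. Amplitudes: the pelvis and mid-thoracic
# region (T7/T8) carry the largest excursions, T12 very little (it sits near
# the directional crossing); values are illustrative magnitudes in degrees.
# Lags: fraction of a stride relative to the pelvis; the typical gradient
# ramps linearly from L4 (in phase) to T8 (antiphase) and stays antiphase
# above; the ramp crosses the quarter-cycle mark between T12 and T11.
preset_defaults <- function(preset) {
  labs <- segment_labels()
  amplitudes <- c(
    PELVIS = 6, L4 = 5.5, L3 = 5, L2 = 4.5, L1 = 3.5,
    T12 = 1.5, T11 = 3, T10 = 4, T9 = 5, T8 = 6, T7 = 6, T6 = 5.5,
    T5 = 5, T4 = 4.5, T3 = 4, T2 = 3.5, T1 = 3, C7 = 3
  )
  ord <- segment_ordinal(labs)
  lags <- pmin(pmax(0.5 * (ord - 1) / 8, 0), 0.5)
  names(lags) <- labs
  levels <- stats::setNames(rep(0, length(labs)), labs)

  out <- list(amplitudes = amplitudes, lags = lags, levels = levels, rhythm = NULL)
  if (preset == "amble") {
    out$lags[] <- 0
  } else if (preset == "superimposed") {
    out$rhythm <- list(multiplier = 3L, amplitude = 1.5)
  } else if (preset == "shifted") {
    thoracic <- paste0("T", 12:1)
    out$levels[thoracic] <- -4
  }
  out
}

#' @export
print.gait_sim_params <- function(x, ...) {
  cat("<gait_sim_params>\n")
  cat("  preset:          ", x$preset, "\n")
  cat("  strides:         ", x$n_strides, "x", x$stride_duration, "s\n")
  cat("  stance fraction: ", x$stance_fraction, "\n")
  cat("  noise SD:        ", x$noise_sd_rotation, "deg rotation,",
      x$noise_sd_force, "units force\n")
  cat("  seed:            ", x$seed, "\n")
  invisible(x)
}
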
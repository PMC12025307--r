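# Shared fixture builders for the test suite. Everything is generated in
# code at test time; no stored data files.

# noiseless canonical recording (typical preset, default stride/stance)
noiseless_sim <- function(preset = "typical", seed = 1, ...) {
  simulate_recording(
    gait_sim_params(preset, noise_sd_rotation = 0, noise_sd_force = 0,
                    seed = seed, ...),
    check_sgc_ready = FALSE
  )
}

noisy_sim <- function(seed, preset = "typical", ...) {
  simulate_recording(gait_sim_params(preset, seed = seed, ...),
                     check_sgc_ready = FALSE)
}

# build an sgc object directly from closed-form per-segment curves:
# A_s * sin(2*pi*(pct/100 - lag_s)) + level_s on the 0..100 grid
sgc_from_params <- function(lags, amps = NULL, levels = NULL,
                            mean_stance_pct = 60) {
  labs <- segment_labels()
  if (is.null(amps)) amps <- stats::setNames(rep(6, 18), labs)
  if (is.null(levels)) levels <- stats::setNames(rep(0, 18), labs)
  pct <- 0:100
  curves <- tibble::as_tibble(c(
    list(pct = pct),
    stats::setNames(lapply(labs, function(s) {
      levels[[s]] + amps[[s]] * sin(2 * pi * (pct / 100 - lags[[s]]))
    }), labs)
  ))
  structure(
    list(curves = curves, grid = pct, n_cycles_used = 3L,
         mean_stance_pct = mean_stance_pct, periodic = FALSE,
         smoothing = stats::setNames(rep(0, 18), labs),
         segments_omitted = character(0)),
    class = "sgc"
  )
}

# independent brute-force event oracle: per foot, ICs are the first samples
# of each run with force above the threshold, ISs the first samples after
# (no debounce; for noiseless traces only)
brute_force_events <- function(f, threshold) {
  contact <- f > threshold
  d <- diff(c(FALSE, contact))
  list(
    ic_samples = which(d == 1) - 1L,   # 0-based
    is_samples = which(d == -1) - 1L
  )
}

# independent PoI oracle on true generator lags: first segment in ordinal
# order with folded phase lag > a quarter cycle, skipping low-movement ones
brute_force_poi <- function(lags, amps, low_movement_threshold = 5) {
  labs <- segment_labels()
  for (s in labs) {
    if (2 * amps[[s]] < low_movement_threshold) next
    if (2 * min(lags[[s]], 1 - lags[[s]]) * 100 > 50) return(s)
  }
  NA_character_
}
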
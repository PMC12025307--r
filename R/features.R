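#' Phase shift between two periodic curves on the antagonism percentage scale
#'
#' Quantifies the phase relation between two segments' standardized curves on
#' the scale where exact antiphase (a half-cycle lag, 180 degrees) maps to
#' 100%, a quarter-cycle lag (90 degrees, sine-to-cosine) to 50%, and
#' in-phase oscillation to 0%. Both curves are mean-centered and circularly
#' cross-correlated over the periodic 0-100% domain; the best-aligning lag
#' `L` is folded into `d = min(L, 100 - L)` (ties resolved to the smallest
#' folded lag) and the result is `2 d`. The equivalent phase angle is
#' `3.6 * d` degrees. The cross-correlation estimate is robust for periodic
#' but non-sinusoidal curves (e.g. steep-rise patterns); `method = "peak"`
#' instead folds the lag between the two curve maxima, reported for
#' comparison.
#'
#' @param curve_a,curve_b Numeric vectors of length 101 on the shared 0-100%
#'   grid (the duplicated period endpoint at 100% is dropped internally).
#' @param method `"xcorr"` (default, circular cross-correlation) or `"peak"`.
#' @return A percentage in `[0, 100]`.
#' @examples
#' pct <- 0:100
#' phase_shift_pct(sin(2 * pi * pct / 100), -sin(2 * pi * pct / 100)) # 100
#' phase_shift_pct(sin(2 * pi * pct / 100), cos(2 * pi * pct / 100))  # 50
#' @export
phase_shift_pct <- function(curve_a, curve_b, method = c("xcorr", "peak")) {
  method <- match.arg(method)
  stopifnot(length(curve_a) == 101, length(curve_b) == 101)
  a <- curve_a[1:100]
  b <- curve_b[1:100]
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
    stop("phase undefined: constant curve has no systematic course", call. = FALSE)
  }
  if (method == "peak") {
    lag <- (which.max(b) - which.max(a)) %% 100
    return(2 * min(lag, 100 - lag))
  }
  a <- a - mean(a)
  b <- b - mean(b)
  lags <- 0:99
  r <- vapply(lags, function(L) sum(a * b[(lags + L) %% 100 + 1]), numeric(1))
  best <- lags[r >= max(r) - 1e-9 * max(abs(r))]
  d <- min(pmin(best, 100 - best))  # ties -> smallest folded lag
  2 * d
}

#' Per-segment motion descriptors of a standardized gait cycle
#'
#' Computes, for every segment curve, the descriptive constructs used to
#' characterize individual gait patterns:
#' \describe{
#'   \item{symmetry line (SL)}{the stable level the rotation oscillates
#'     around: the mean over one period of the curve (grid points 0-99, the
#'     duplicated endpoint counted once). The midrange
#'     `(max + min) / 2` is reported alongside as `symmetry_line_midrange`.}
#'   \item{level shift (LS)}{the signed offset of the symmetry line from the
#'     zero line (equal to SL; positive = shifted toward left rotation).}
#'   \item{range / half-amplitude}{total excursion `max - min` and half of
#'     it.}
#'   \item{low-movement flag}{`TRUE` when the total excursion is below
#'     `low_movement_threshold` (default 5 degrees).}
#'   \item{maximum timing}{`max_left_pct`, the grid position of the curve
#'     maximum (ties take the earliest percent).}
#'   \item{phase shift vs pelvis}{[phase_shift_pct()] against the reference
#'     segment's curve; `NA` for constant curves.}
#' }
#'
#' @param sgc An `sgc` object.
#' @param low_movement_threshold Total-excursion threshold in degrees below
#'   which a segment is flagged as showing very little movement. Default 5.
#' @param reference Reference segment for phase shifts. Default `"PELVIS"`.
#' @return A tibble with one row per segment: `segment`, `ordinal`,
#'   `symmetry_line`, `symmetry_line_midrange`, `level_shift`, `range_deg`,
#'   `half_amplitude`, `low_movement`, `max_left_pct`,
#'   `phase_shift_vs_pelvis_pct`.
#' @examples
#' sim <- simulate_recording(gait_sim_params("typical", seed = 2))
#' ann <- annotate_gait(sim$rotation, sim$force)
#' sgc <- fit_sgc(normalize_cycles(sim$rotation, ann$cycles))
#' segment_features(sgc)
#' @export
segment_features <- function(sgc, low_movement_threshold = 5,
                             reference = "PELVIS") {
  stopifnot(inherits(sgc, "sgc"))
  segs <- intersect(segment_labels(), names(sgc$curves))
  if (!reference %in% segs) {
    stop("reference segment ", reference, " not present in the SGC", call. = FALSE)
  }
  ref_curve <- sgc$curves[[reference]]
  purrr::map_dfr(segs, function(seg) {
    y <- sgc$curves[[seg]]
    period <- y[1:100]
    sl <- mean(period)
    rng <- max(y) - min(y)
    shift <- if (stats::sd(period) < 1e-12 || stats::sd(ref_curve[1:100]) < 1e-12) {
      NA_real_
    } else {
      phase_shift_pct(ref_curve, y)
    }
    tibble::tibble(
      segment = seg,
      ordinal = segment_ordinal(seg),
      symmetry_line = sl,
      symmetry_line_midrange = (max(y) + min(y)) / 2,
      level_shift = sl,
      range_deg = rng,
      half_amplitude = rng / 2,
      low_movement = rng < low_movement_threshold,
      max_left_pct = sgc$grid[which.max(y)],  # ties -> earliest percent
      phase_shift_vs_pelvis_pct = shift
    )
  })
}

#' Pairwise phase-shift matrix across all segments
#'
#' @inheritParams segment_features
#' @return A symmetric numeric matrix (zero diagonal) of
#'   [phase_shift_pct()] values with segment labels as dimnames; rows and
#'   columns of constant segments are `NA`.
#' @export
phase_shift_matrix <- function(sgc) {
  stopifnot(inherits(sgc, "sgc"))
  segs <- intersect(segment_labels(), names(sgc$curves))
  n <- length(segs)
  m <- matrix(NA_real_, n, n, dimnames = list(segs, segs))
  usable <- vapply(segs, function(s) stats::sd(sgc$curves[[s]][1:100]) > 1e-12,
                   logical(1))
  for (i in seq_len(n)) {
    if (!usable[i]) next
    m[i, i] <- 0
    for (j in seq_len(n)[-seq_len(i)]) {
      if (!usable[j]) next
      m[i, j] <- m[j, i] <- phase_shift_pct(sgc$curves[[segs[i]]],
                                            sgc$curves[[segs[j]]])
    }
  }
  m
}

#' Find the point of intersection of movement directions
#'
#' The point of intersection (PoI) is the spinal level where the direction of
#' rotation relative to the pelvis flips from in-phase to antagonistic.
#' Segments are scanned in caudal-to-cranial order (pelvis toward C7); the
#' PoI is the first segment whose phase shift versus the pelvis exceeds 50%
#' (more than a quarter-cycle lag). Segments flagged as low-movement are
#' skipped — they sit near the zero line where the directional exchange takes
#' place and carry no reliable phase. When no segment crosses (an amble-like
#' pattern with the whole spine in phase), there is no PoI.
#'
#' @param features Per-segment feature tibble from [segment_features()].
#' @return A segment label, or `NA_character_` when no crossing exists.
#' @export
find_point_of_intersection <- function(features) {
  stopifnot(all(c("segment", "ordinal", "low_movement",
                  "phase_shift_vs_pelvis_pct") %in% names(features)))
  f <- features[order(features$ordinal), ]
  f <- f[!f$low_movement & !is.na(f$phase_shift_vs_pelvis_pct), ]
  hit <- which(f$phase_shift_vs_pelvis_pct > 50)
  if (length(hit) == 0) NA_character_ else f$segment[hit[1]]
}

#' Classify each segment's rotation maximum against the phases of gait
#'
#' Places the timing of each segment's leftward rotation maximum within the
#' right-foot gait phases: `[0, stance/2)` is IC to mid-stance,
#' `[stance/2, stance)` mid- to terminal stance, `[stance, 100)` swing
#' (half-open intervals). In typical gait the pelvis maximum falls between
#' initial contact and mid-stance.
#'
#' @param features Per-segment feature tibble from [segment_features()].
#' @param mean_stance_pct Mean right-foot stance percentage of the gait cycle
#'   (e.g. from [annotate_gait()]).
#' @return `features` with an added factor column `max_gait_phase` with
#'   levels `IC_to_mid_stance`, `mid_to_terminal_stance`, `swing`.
#' @export
maxima_vs_gait_phase <- function(features, mean_stance_pct) {
  stopifnot("max_left_pct" %in% names(features),
            is.numeric(mean_stance_pct), mean_stance_pct > 0,
            mean_stance_pct < 100)
  half <- mean_stance_pct / 2
  phase <- dplyr::case_when(
    features$max_left_pct < half ~ "IC_to_mid_stance",
    features$max_left_pct < mean_stance_pct ~ "mid_to_terminal_stance",
    TRUE ~ "swing"
  )
  dplyr::mutate(features, max_gait_phase = factor(
    phase, levels = c("IC_to_mid_stance", "mid_to_terminal_stance", "swing")))
}

#' Full per-measurement feature set
#'
#' Bundles [segment_features()], the pairwise [phase_shift_matrix()], the
#' [find_point_of_intersection()] scan and the [maxima_vs_gait_phase()]
#' classification for one standardized gait cycle.
#'
#' @inheritParams segment_features
#' @param mean_stance_pct Right-stance percentage; defaults to the value
#'   stored in the SGC, or 60 if absent.
#' @return A list of class `spine_features`: `segments` (feature tibble with
#'   gait-phase classification), `phase_shift_matrix`,
#'   `point_of_intersection`, `mean_stance_pct`.
#' @export
spine_features <- function(sgc, low_movement_threshold = 5,
                           mean_stance_pct = NULL) {
  stance <- mean_stance_pct %||%
    (if (is.na(sgc$mean_stance_pct)) 60 else sgc$mean_stance_pct)
  feats <- segment_features(sgc, low_movement_threshold) |>
    maxima_vs_gait_phase(stance)
  structure(
    list(
      segments = feats,
      phase_shift_matrix = phase_shift_matrix(sgc),
      point_of_intersection = find_point_of_intersection(feats),
      mean_stance_pct = stance
    ),
    class = "spine_features"
  )
}

#' @export
print.spine_features <- function(x, ...) {
  cat("<spine_features>\n")
  poi <- x$point_of_intersection
  cat("  point of intersection:", if (is.na(poi)) "none (in-phase pattern)" else poi, "\n")
  cat("  mean right-stance:", round(x$mean_stance_pct, 1), "% of cycle\n")
  print(x$segments, n = 18)
  invisible(x)
}
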
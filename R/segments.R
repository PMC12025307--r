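#' The measured spinal segment set
#'
#' The surface-topography spine model estimates one transverse-plane rotation
#' per vertebral segment from the pelvis up to C7. L5 is not measured (surface
#' structure correlates poorly with spinal position in the lower back), so the
#' canonical set has 18 labels: PELVIS, L4-L1, T12-T1, C7. The ordinal gives
#' the caudal-to-cranial scan order used e.g. when searching for the point of
#' intersection (PELVIS = 0, increasing cranially).
#'
#' @return A tibble with columns `segment` (character) and `ordinal` (integer).
#' @examples
#' spine_segments()
#' @export
spine_segments <- function() {
  tibble::tibble(
    segment = segment_labels(),
    ordinal = 0:17
  )
}

#' Canonical segment labels in caudal-to-cranial order
#'
#' @return Character vector of the 18 segment labels, PELVIS first, C7 last.
#' @export
segment_labels <- function() {
  c("PELVIS", paste0("L", 4:1), paste0("T", 12:1), "C7")
}

# ordinal lookup; errors on unknown labels so bad column names never pass silently
segment_ordinal <- function(segment) {
  ord <- match(segment, segment_labels()) - 1L
  if (anyNA(ord)) {
    stop("unknown segment label(s): ",
         paste(unique(segment[is.na(ord)]), collapse = ", "),
         call. = FALSE)
  }
  ord
}

# coerce a segment character vector to a factor in anatomical order
segment_factor <- function(segment) {
  factor(segment, levels = segment_labels())
}
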
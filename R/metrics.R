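#' Mirror-technique skill metrics
#'
#' The four evaluation metrics computed from a screenshot measurement plus
#' timing: distance between the mirror and lesion-image centres (mm),
#' relative area ratio of the lesion image on the mirror surface (%),
#' ellipticity of the lesion image (minor/major, 1 = perfect circle), and
#' manipulation time (s).
#'
#' @name metrics
NULL

#' Distance between the mirror and lesion-image centres
#'
#' Euclidean pixel distance between the fitted centres, converted to
#' millimetres with the measurement's per-image scale.
#'
#' @param m a [measure()] result.
#' @return distance in mm (>= 0).
#' @export
distance_between_centers <- function(m) {
  sqrt((m$dm$cx_px - m$bc$cx_px)^2 + (m$dm$cy_px - m$bc$cy_px)^2) * m$mm_per_px
}

#' Relative area ratio of the lesion image on the mirror surface
#'
#' `100 * (a_bc * b_bc) / (a_dm * b_dm)` from the fitted semi-axes (the
#' pi factors cancel).
#'
#' @param m a [measure()] result.
#' @return percentage in (0, 100] for a lesion image inside the mirror.
#' @export
relative_ratio <- function(m) {
  100 * (m$bc$a_px * m$bc$b_px) / (m$dm$a_px * m$dm$b_px)
}

#' Ellipticity of the lesion image
#'
#' Minor/major axis ratio `b/a` in (0, 1]; 1 means the lesion is projected
#' as a perfect circle (the ideal, face-on view).
#'
#' @param m a [measure()] result.
#' @return ratio in (0, 1].
#' @export
ellipticity <- function(m) {
  m$bc$b_px / m$bc$a_px
}

#' Pixel-count area ratio (cross-check utility)
#'
#' The relative ratio computed directly from label pixel counts rather than
#' fitted axes; agrees with [relative_ratio()] within raster tolerance on
#' clean screenshots (the same-area fitting convention makes the two
#' nearly identical by construction).
#'
#' @param screenshot a labelled screenshot.
#' @return percentage.
#' @export
relative_ratio_pixels <- function(screenshot) {
  n_bc <- sum(screenshot$labels == LABEL_BC)
  n_dm <- sum(screenshot$labels >= LABEL_DM)
  100 * n_bc / n_dm
}

#' Assemble a per-task metric record
#'
#' Records failing the validity criteria are retained and flagged, not
#' dropped; downstream statistics use valid records by default.
#'
#' @param group group label, one of "ID", "GS", "TD", "ST".
#' @param participant participant identifier.
#' @param trial 1 or 2.
#' @param task_index task number 1..8.
#' @param tooth FDI tooth label.
#' @param m a [measure()] result.
#' @param time_s manipulation time in seconds (> 0; NA allowed for
#'   measurement-only records).
#' @param validity a [check_criteria()] result, or NULL.
#' @return one-row data.frame with all metrics, theta, calibration scale and
#'   validity flags (`valid` is the conjunction of the non-NA flags).
#' @export
make_record <- function(group, participant, trial, task_index, tooth, m,
                        time_s = NA_real_, validity = NULL) {
  if (!is.na(time_s) && time_s <= 0) stop("time_s must be positive")
  fl <- validity %||% list(mirror_fully_visible = NA, no_penetration = NA,
                           tip_in_box = NA, tip_clear_of_bc = NA)
  flags <- c(fl$mirror_fully_visible, fl$no_penetration,
             fl$tip_in_box, fl$tip_clear_of_bc)
  valid <- if (all(is.na(flags))) NA else all(flags[!is.na(flags)])
  data.frame(
    group = as.character(group), participant_id = as.character(participant),
    trial = as.integer(trial), task_index = as.integer(task_index),
    tooth = as.integer(tooth),
    distance_mm = distance_between_centers(m),
    ratio_pct = relative_ratio(m),
    ellipticity = ellipticity(m),
    theta_deg = m$theta_deg,
    time_s = as.numeric(time_s),
    mm_per_px = m$mm_per_px,
    mirror_fully_visible = fl$mirror_fully_visible,
    no_penetration = fl$no_penetration,
    tip_in_box = fl$tip_in_box,
    tip_clear_of_bc = fl$tip_clear_of_bc,
    valid = valid,
    stringsAsFactors = FALSE
  )
}
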
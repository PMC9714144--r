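# Scalar metrics derived from cine CMR: ventricular remodelling index and
# its adverse cutoff, ejection fraction, TAPSE, inter-ventricular synchrony,
# right atrial area, global longitudinal strain at end systole and pulmonary
# artery relative area change.

#' Ventricular remodelling index
#'
#' Ratio of RV to LV end-diastolic volume. Values above the control-derived
#' cutoff (see [adverse_cutoff()]) denote adverse RV remodelling.
#'
#' @param rvedv,lvedv End-diastolic volumes in ml (> 0).
#' @return Dimensionless RVEDV/LVEDV ratio.
#' @export
remodelling_index <- function(rvedv, lvedv) {
  if (any(rvedv <= 0) || any(lvedv <= 0)) stop("volumes must be > 0")
  rvedv / lvedv
}

#' Adverse-remodelling cutoff from healthy-control indices
#'
#' Mean plus three sample standard deviations (n - 1 denominator) of the
#' control remodelling indices, rounded to 2 decimals for reporting. A
#' summary-statistic entry point (`mean_value`, `sd_value`) is provided for
#' use with published cohort summaries.
#'
#' @param control_indices Remodelling indices of >= 2 healthy controls.
#' @param mean_value,sd_value Alternative entry point: supply the control
#'   mean and SD directly instead of raw values.
#' @return List with the unrounded `cutoff` and the reported
#'   `cutoff_reported` (2 decimals).
#' @export
adverse_cutoff <- function(control_indices = NULL,
                           mean_value = NULL, sd_value = NULL) {
  if (is.null(mean_value)) {
    if (length(control_indices) < 2L) stop("need >= 2 control values")
    mean_value <- mean(control_indices)
    sd_value <- stats::sd(control_indices)
  }
  cutoff <- mean_value + 3 * sd_value
  list(mean = mean_value, sd = sd_value,
       cutoff = cutoff, cutoff_reported = round(cutoff, 2))
}

#' Classify a remodelling index against the adverse cutoff
#' @param index Remodelling index (RVEDV/LVEDV).
#' @param cutoff Cutoff from [adverse_cutoff()] (the list or a number).
#' @return Logical: adverse remodelling (`index > cutoff`).
#' @export
is_adverse_remodelling <- function(index, cutoff) {
  if (is.list(cutoff)) cutoff <- cutoff$cutoff
  index > cutoff
}

#' Ejection fraction in percent
#' @param edv,esv End-diastolic and end-systolic volumes in ml
#'   (`edv > 0`, `esv >= 0`).
#' @return `100 * (edv - esv) / edv`.
#' @export
ejection_fraction <- function(edv, esv) {
  if (any(edv <= 0)) stop("edv must be > 0")
  if (any(esv < 0)) stop("esv must be >= 0")
  100 * (edv - esv) / edv
}

#' Tricuspid annular plane systolic excursion (TAPSE)
#'
#' Maximum displacement of the lateral tricuspid insertion point within
#' ventricular systole. Displacement curves are relative to frame 0 by the
#' tracking convention, so no re-referencing is applied.
#'
#' @param displacement Per-frame displacement in mm (lateral tricuspid
#'   insertion), or a [landmark_curves()] object.
#' @param systole 0-based frame indices of ventricular systole.
#' @return TAPSE in mm.
#' @export
tapse <- function(displacement, systole) {
  if (inherits(displacement, "landmark_curves"))
    displacement <- displacement$tricuspid_lateral
  if (length(systole) == 0) stop("empty systolic interval")
  if (any(systole < 0 | systole >= length(displacement)))
    stop("systole frames out of range")
  max(displacement[systole + 1L])
}

#' Inter-ventricular synchrony index
#'
#' Time difference to maximal displacement between the lateral mitral and
#' lateral tricuspid insertion points (earliest frame on ties). Reported as
#' an absolute difference, with the signed RV-minus-LV value alongside.
#'
#' @param mitral_lateral,tricuspid_lateral Displacement curves in mm, equal
#'   length.
#' @param frame_interval Frame interval in ms.
#' @return List with `synchrony_ms` (absolute) and `signed_ms`
#'   (tricuspid minus mitral).
#' @export
synchrony_index <- function(mitral_lateral, tricuspid_lateral, frame_interval) {
  if (length(mitral_lateral) != length(tricuspid_lateral))
    stop("curves must have equal length")
  dt <- (which.max(tricuspid_lateral) - which.max(mitral_lateral)) * frame_interval
  list(synchrony_ms = abs(dt), signed_ms = dt)
}

#' Planimetered area of a contour polygon, in cm^2
#'
#' Shoelace formula over the ordered vertices (absolute value, so vertex
#' orientation does not matter); vertices in mm give an area converted to
#' cm^2.
#'
#' @param contour A [contour_polygon()] or an n x 2 vertex matrix in mm.
#' @return Area in cm^2.
#' @export
polygon_area <- function(contour) {
  v <- if (inherits(contour, "contour_polygon")) contour$vertices
       else contour_polygon(contour)$vertices  # runs the validity checks
  n <- nrow(v)
  nxt <- c(2:n, 1)
  area_mm2 <- abs(sum(v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2])) / 2
  area_mm2 / 100
}

#' Global longitudinal strain at end systole
#'
#' Reads the strain curve at the end-systolic frame; the sign/magnitude
#' convention of the input curve is preserved.
#'
#' @param strain Per-frame strain in \%, or a [landmark_curves()] object with
#'   a strain curve.
#' @param es_frame 0-based end-systolic frame index.
#' @return Strain value in \%.
#' @export
gls_at_es <- function(strain, es_frame) {
  if (inherits(strain, "landmark_curves")) strain <- strain$strain
  if (is.null(strain)) stop("no strain curve available")
  if (es_frame < 0 || es_frame >= length(strain))
    stop("es_frame out of range")
  strain[es_frame + 1L]
}

#' Pulmonary artery relative area change, in percent
#'
#' `100 * (max - min) / min` of the PA cross-sectional area over the cycle.
#'
#' @param areas Per-frame PA areas in cm^2 (all > 0).
#' @return Relative area change in \%.
#' @export
pa_relative_area_change <- function(areas) {
  if (any(areas <= 0)) stop("areas must be > 0")
  100 * (max(areas) - min(areas)) / min(areas)
}
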
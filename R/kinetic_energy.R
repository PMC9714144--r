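# Phasic blood kinetic energy of the ventricular blood pool.
#
# KE(t) = sum over labelled voxels of 1/2 * rho * V_voxel * |v|^2, reported
# in uJ; indexing to end-diastolic volume gives KEI_EDV in uJ/ml. Note the
# unit identity 1 J/m^3 = 1 uJ/ml, so for a uniform-speed pool with mask
# volume equal to EDV, KEI_EDV = 1/2 * rho * |v|^2 expressed in J/m^3.

#' Default blood density, kg/m^3
#' @export
BLOOD_DENSITY <- 1060

#' Per-frame kinetic energy of a ventricular blood pool
#'
#' Sums `1/2 * rho * V_voxel * |v|^2` over the labelled voxels of each frame.
#' Velocities stored in cm/s are converted to m/s and voxel volumes to m^3 at
#' this single site; the result is reported in uJ.
#'
#' @param field A [velocity_field()].
#' @param mask A [phase_mask()] on the same grid and frame count.
#' @param ventricle `"LV"` or `"RV"`.
#' @param rho Blood density in kg/m^3 (default 1060).
#' @return Numeric vector of per-frame KE in uJ.
#' @export
ke_curve <- function(field, mask, ventricle, rho = BLOOD_DENSITY) {
  if (!identical(field$grid_shape, mask$grid_shape) ||
      field$n_frames != mask$n_frames)
    stop("field and mask must share grid shape and frame count")
  if (rho <= 0) stop("rho must be > 0")
  code <- MASK_LABELS[[match.arg(ventricle, c("LV", "RV"))]]
  vox_m3 <- prod(field$voxel_size) * 1e-9       # mm^3 -> m^3
  T_ <- field$n_frames
  nvox <- prod(field$grid_shape)
  ke <- numeric(T_)
  for (f in seq_len(T_)) {
    sel <- which(mask$labels[, , , f] == code)
    if (length(sel) == 0) { ke[f] <- 0; next }
    off <- (f - 1L) * 3L * nvox
    v2 <- field$velocity[off + sel]^2 +
          field$velocity[off + nvox + sel]^2 +
          field$velocity[off + 2L * nvox + sel]^2
    # cm/s -> m/s squared = 1e-4; J -> uJ = 1e6
    ke[f] <- 0.5 * rho * vox_m3 * sum(v2) * 1e-4 * 1e6
  }
  ke
}

#' Index a kinetic energy curve to end-diastolic volume
#'
#' @param ke Per-frame KE in uJ.
#' @param edv End-diastolic volume in ml (> 0).
#' @return Per-frame KEI_EDV in uJ/ml.
#' @export
kei_edv <- function(ke, edv) {
  if (!is.finite(edv) || edv <= 0) stop("edv must be > 0")
  ke / edv
}

#' Cardiac phase landmarks from a ventricular volume curve
#'
#' End diastole is the frame of maximum volume and end systole the frame of
#' minimum volume (earliest frame on ties). The early-filling (E-wave) search
#' window is the first `e_wave_fraction` of diastole: frames
#' `ES + 1 ... ES + ceil(e_wave_fraction * n_diastolic_frames)` (cyclic),
#' which excludes the late-diastolic A-wave by construction.
#'
#' @param volumes Per-frame volume in ml.
#' @param e_wave_fraction Fraction of diastole searched for the E-wave peak
#'   (default 0.5).
#' @return List with 0-based `ed_frame`, `es_frame`, `e_wave_window`
#'   (0-based frame indices) and `systole_frames` (count of frame intervals
#'   ED to ES).
#' @export
phase_landmarks <- function(volumes, e_wave_fraction = 0.5) {
  T_ <- length(volumes)
  if (T_ < 2L || diff(range(volumes)) == 0)
    stop("volume curve must be non-constant")
  ed <- which.max(volumes) - 1L  # which.max takes the earliest on ties
  es <- which.min(volumes) - 1L
  sys <- (es - ed) %% T_
  dia <- T_ - sys
  n_e <- ceiling(e_wave_fraction * dia)
  window <- (es + seq_len(n_e)) %% T_
  list(ed_frame = ed, es_frame = es, e_wave_window = window,
       systole_frames = sys)
}

#' Phasic summary of a KEI_EDV curve
#'
#' Peak systolic = maximum over the closed systolic interval `[ED, ES]`;
#' average systolic = arithmetic mean over the same frames; peak E-wave =
#' maximum over the E-wave window.
#'
#' @param keiedv Per-frame KEI_EDV in uJ/ml.
#' @param landmarks Result of [phase_landmarks()] (or a compatible list).
#' @return List with `peak_systolic`, `average_systolic`, `peak_e_wave`
#'   (uJ/ml).
#' @export
extract_phasic <- function(keiedv, landmarks) {
  T_ <- length(keiedv)
  sys_idx <- (landmarks$ed_frame + 0:landmarks$systole_frames) %% T_
  if (length(landmarks$e_wave_window) == 0) stop("empty E-wave window")
  sys_vals <- keiedv[sys_idx + 1L]
  list(peak_systolic = max(sys_vals),
       average_systolic = mean(sys_vals),
       peak_e_wave = max(keiedv[landmarks$e_wave_window + 1L]))
}

#' Full kinetic-energy analysis of one ventricle
#'
#' Computes the KE curve, indexes it to EDV, locates the phase landmarks on
#' the ventricular volume curve (unless supplied, as for static-mask
#' phantoms) and extracts the phasic summary.
#'
#' @inheritParams ke_curve
#' @param landmarks Optional [phase_landmarks()] result overriding
#'   volume-curve detection.
#' @param e_wave_fraction See [phase_landmarks()].
#' @return An object of class `ke_result` with `ke_uj`, `kei_edv_uj_ml`,
#'   `edv_ml`, `landmarks` and `summary`.
#' @export
ke_analysis <- function(field, mask, ventricle, rho = BLOOD_DENSITY,
                        landmarks = NULL, e_wave_fraction = 0.5) {
  ke <- ke_curve(field, mask, ventricle, rho)
  ed_vol <- edv(mask, ventricle)
  kei <- kei_edv(ke, ed_vol)
  if (is.null(landmarks))
    landmarks <- phase_landmarks(volume_curve(mask, ventricle), e_wave_fraction)
  structure(list(ventricle = ventricle,
                 ke_uj = ke,
                 kei_edv_uj_ml = kei,
                 edv_ml = ed_vol,
                 landmarks = landmarks,
                 summary = extract_phasic(kei, landmarks)),
            class = "ke_result")
}

#' @export
print.ke_result <- function(x, ...) {
  cat(sprintf("kinetic energy (%s): EDV %.1f ml\n", x$ventricle, x$edv_ml))
  cat(sprintf("  peak systolic KEI_EDV    %7.2f uJ/ml\n", x$summary$peak_systolic))
  cat(sprintf("  average systolic KEI_EDV %7.2f uJ/ml\n", x$summary$average_systolic))
  cat(sprintf("  peak E-wave KEI_EDV      %7.2f uJ/ml\n", x$summary$peak_e_wave))
  invisible(x)
}
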
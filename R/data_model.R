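# Domain containers and file I/O for 4D flow fields, phase masks, cine
# landmark/contour curves, CPET series and cohort tables.
#
# Unit conventions (fixed across the package):
#   positions / voxel size  mm
#   time                    ms (cardiac cycle), s (CPET)
#   velocity                cm/s (phase-contrast convention)
#   volume                  ml
#   kinetic energy          uJ, indexed values uJ/ml

#' Construct a time-resolved 3D velocity field
#'
#' Holds the sampled blood velocity `v(x, t)` on a regular voxel grid over one
#' cardiac cycle. The cycle is treated as periodic: frame `n_frames` wraps to
#' frame 0, as in retrospectively gated phase-contrast acquisitions. The grid
#' is voxel-centered: voxel `(i, j, k)` (0-based) sits at physical position
#' `(i, j, k) * voxel_size` mm.
#'
#' @param velocity Either a 5-D numeric array of dimension
#'   `c(X, Y, Z, 3, n_frames)` (4th axis = velocity component) or a list of
#'   three 4-D arrays `c(X, Y, Z, n_frames)` giving the x, y, z components.
#'   Units cm/s.
#' @param voxel_size Numeric length-3, voxel edge lengths in mm.
#' @param frame_interval Time between consecutive cardiac phases in ms.
#' @param venc Velocity-encoding limit in cm/s (metadata only; not enforced
#'   voxelwise).
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(velocity, voxel_size, frame_interval, venc = NA_real_) {
  if (is.list(velocity)) {
    dims <- lapply(velocity, dim)
    if (length(velocity) != 3L || any(vapply(dims, length, 1L) != 4L))
      stop("velocity list must hold three 4-D component arrays")
    if (!all(vapply(dims, identical, TRUE, dims[[1]])))
      stop("component volume shape mismatch")
    if (length(unique(vapply(dims, `[`, 1L, 4L))) != 1L)
      stop("frame count mismatch between component volumes")
    d <- dims[[1]]
    v <- array(NA_real_, c(d[1:3], 3L, d[4]))
    for (c_i in 1:3) v[, , , c_i, ] <- velocity[[c_i]]
    velocity <- v
  }
  d <- dim(velocity)
  if (length(d) != 5L || d[4] != 3L)
    stop("velocity must be a 5-D array [X, Y, Z, 3, n_frames]")
  if (d[5] < 2L) stop("n_frames must be >= 2")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive lengths in mm")
  frame_interval <- as.numeric(frame_interval)
  if (!is.finite(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be a positive time in ms")
  n_bad <- sum(!is.finite(velocity))
  if (n_bad > 0)
    stop(sprintf("velocity contains %d non-finite voxel values", n_bad))
  structure(
    list(velocity = velocity,
         grid_shape = d[1:3],
         voxel_size = voxel_size,
         n_frames = d[5],
         frame_interval = frame_interval,
         venc = as.numeric(venc)),
    class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("velocity_field: %d x %d x %d voxels (%.2f x %.2f x %.2f mm), %d frames x %.1f ms (cycle %.0f ms)\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$n_frames, x$frame_interval, cycle_duration(x)))
  cat(sprintf("  peak speed %.2f cm/s, VENC %s cm/s\n",
              sqrt(max(apply(x$velocity^2, c(5), max))),
              format(x$venc)))
  invisible(x)
}

#' Cardiac cycle duration in ms
#' @param field A `velocity_field` or `phase_mask`.
#' @return Cycle duration `n_frames * frame_interval` in ms.
#' @export
cycle_duration <- function(field) field$n_frames * field$frame_interval

# Label codes for the per-phase segmentation
MASK_LABELS <- c(background = 0L, LV = 1L, RV = 2L)

#' Construct per-phase ventricular masks
#'
#' Binary/categorical blood-pool labels per voxel per cardiac phase.
#' Labels: 0 = background, 1 = LV, 2 = RV. Per-ventricle volume curves are
#' derived as labelled-voxel count times voxel volume; end-diastolic and
#' end-systolic volumes are the per-cycle extrema of the curve.
#'
#' @param labels 4-D integer array `c(X, Y, Z, n_frames)` of label codes.
#' @param voxel_size Numeric length-3, mm.
#' @param frame_interval Frame interval in ms.
#' @return An object of class `phase_mask` with `volume_curves` (ml) attached.
#' @export
phase_mask <- function(labels, voxel_size, frame_interval) {
  d <- dim(labels)
  if (length(d) != 4L) stop("labels must be a 4-D array [X, Y, Z, n_frames]")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive lengths in mm")
  bad <- setdiff(unique(as.integer(labels)), unname(MASK_LABELS))
  if (length(bad) > 0)
    stop(sprintf("unknown label value(s): %s", paste(sort(bad), collapse = ", ")))
  storage.mode(labels) <- "integer"
  vox_ml <- prod(voxel_size) / 1000  # mm^3 -> ml
  curves <- list()
  flat <- matrix(labels, ncol = d[4])
  for (vent in c("LV", "RV")) {
    counts <- colSums(flat == MASK_LABELS[[vent]])
    if (any(counts > 0)) {
      if (any(counts == 0))
        stop(sprintf("%s empty at frame(s) %s",
                     vent, paste(which(counts == 0) - 1L, collapse = ", ")))
      curves[[vent]] <- counts * vox_ml
    }
  }
  if (length(curves) == 0) stop("mask labels no ventricle at any frame")
  structure(
    list(labels = labels,
         grid_shape = d[1:3],
         n_frames = d[4],
         voxel_size = voxel_size,
         frame_interval = as.numeric(frame_interval),
         volume_curves = curves),
    class = "phase_mask")
}

#' @export
print.phase_mask <- function(x, ...) {
  cat(sprintf("phase_mask: %d x %d x %d voxels, %d frames\n",
              x$grid_shape[1], x$grid_shape[2], x$grid_shape[3], x$n_frames))
  for (vent in names(x$volume_curves))
    cat(sprintf("  %s: EDV %.1f ml, ESV %.1f ml\n", vent, edv(x, vent), esv(x, vent)))
  invisible(x)
}

.ventricle_curve <- function(mask, ventricle) {
  ventricle <- match.arg(ventricle, c("LV", "RV"))
  cv <- mask$volume_curves[[ventricle]]
  if (is.null(cv)) stop(sprintf("mask labels no %s voxels", ventricle))
  cv
}

#' Ventricular volume curve in ml
#' @param mask A `phase_mask`.
#' @param ventricle `"LV"` or `"RV"`.
#' @return Numeric vector, one volume (ml) per frame.
#' @export
volume_curve <- function(mask, ventricle) .ventricle_curve(mask, ventricle)

#' End-diastolic volume (ml): maximum of the volume curve
#' @inheritParams volume_curve
#' @export
edv <- function(mask, ventricle) max(.ventricle_curve(mask, ventricle))

#' End-systolic volume (ml): minimum of the volume curve
#' @inheritParams volume_curve
#' @export
esv <- function(mask, ventricle) min(.ventricle_curve(mask, ventricle))

## ---- NIfTI + sidecar I/O ---------------------------------------------------

.strip_nifti <- function(img) {
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  a
}

#' Write a velocity field as three NIfTI volumes plus a JSON sidecar
#'
#' Files written: `<stem>_vx.nii.gz`, `<stem>_vy.nii.gz`, `<stem>_vz.nii.gz`
#' (each 4-D, X.Y.Z.T, cm/s) and `<stem>_meta.json` with keys
#' `voxel_size_mm`, `frame_interval_ms`, `venc_cms`.
#'
#' @param field A `velocity_field`.
#' @param stem File stem (path without suffix).
#' @return `stem`, invisibly.
#' @export
write_velocity_field <- function(field, stem) {
  stopifnot(inherits(field, "velocity_field"))
  comps <- c("vx", "vy", "vz")
  for (c_i in 1:3) {
    vol <- field$velocity[, , , c_i, , drop = TRUE]
    dim(vol) <- c(field$grid_shape, field$n_frames)
    img <- RNifti::asNifti(vol)
    RNifti::pixdim(img) <- c(field$voxel_size, field$frame_interval)
    RNifti::writeNifti(img, paste0(stem, "_", comps[c_i], ".nii.gz"))
  }
  jsonlite::write_json(
    list(voxel_size_mm = field$voxel_size,
         frame_interval_ms = field$frame_interval,
         venc_cms = field$venc),
    paste0(stem, "_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Read a velocity field from three NIfTI volumes plus a JSON sidecar
#'
#' @param stem File stem as used by [write_velocity_field()].
#' @return A `velocity_field`.
#' @export
read_velocity_field <- function(stem) {
  meta_path <- paste0(stem, "_meta.json")
  if (!file.exists(meta_path)) stop("missing metadata sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (key in c("voxel_size_mm", "frame_interval_ms", "venc_cms"))
    if (is.null(meta[[key]])) stop("missing metadata key: ", key)
  vols <- lapply(c("vx", "vy", "vz"), function(cmp) {
    p <- paste0(stem, "_", cmp, ".nii.gz")
    if (!file.exists(p)) stop("missing component volume: ", p)
    .strip_nifti(RNifti::readNifti(p))
  })
  velocity_field(vols, meta$voxel_size_mm, meta$frame_interval_ms, meta$venc_cms)
}

#' Write a phase mask as one NIfTI label volume
#'
#' Labels: 0 = background, 1 = LV, 2 = RV. Voxel size and frame interval are
#' stored in the NIfTI `pixdim`.
#'
#' @param mask A `phase_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_masks <- function(mask, path) {
  stopifnot(inherits(mask, "phase_mask"))
  img <- RNifti::asNifti(mask$labels)
  RNifti::pixdim(img) <- c(mask$voxel_size, mask$frame_interval)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read per-phase ventricular masks from a NIfTI label volume
#'
#' @param path NIfTI file of integer labels (0 = background, 1 = LV, 2 = RV),
#'   4-D X.Y.Z.T. Voxel size and frame interval are taken from `pixdim`
#'   unless overridden.
#' @param voxel_size,frame_interval Optional overrides (mm, ms).
#' @return A `phase_mask` with per-frame LV/RV volume curves in ml.
#' @export
read_masks <- function(path, voxel_size = NULL, frame_interval = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (is.null(voxel_size)) voxel_size <- pd[1:3]
  if (is.null(frame_interval)) frame_interval <- if (length(pd) >= 4) pd[4] else 1
  phase_mask(.strip_nifti(img), voxel_size, frame_interval)
}

## ---- cine landmark curves and contours -------------------------------------

#' Construct tracked-landmark displacement curves
#'
#' Displacement magnitude (mm, toward the apex reference) of the valve-plane
#' insertion points tracked on the four-chamber cine, one value per frame.
#' Displacement at frame 0 is 0 by construction of the tracking.
#'
#' @param time Per-frame time in ms (length `n_frames`).
#' @param tricuspid_lateral,tricuspid_medial,mitral_lateral Displacement
#'   curves in mm; `tricuspid_medial` optional.
#' @param strain Optional strain curve in \% per frame.
#' @return An object of class `landmark_curves`.
#' @export
landmark_curves <- function(time, tricuspid_lateral, mitral_lateral,
                            tricuspid_medial = NULL, strain = NULL) {
  n <- length(time)
  curves <- list(tricuspid_lateral = tricuspid_lateral,
                 mitral_lateral = mitral_lateral,
                 tricuspid_medial = tricuspid_medial,
                 strain = strain)
  curves <- curves[!vapply(curves, is.null, TRUE)]
  if (any(vapply(curves, length, 1L) != n))
    stop("all curves must have the same length as time")
  for (nm in setdiff(names(curves), "strain"))
    if (abs(curves[[nm]][1]) > 1e-9)
      stop(sprintf("%s displacement at frame 0 must be 0", nm))
  structure(c(list(time = as.numeric(time)), curves), class = "landmark_curves")
}

#' Write landmark curves to CSV
#' @param lm A `landmark_curves`.
#' @param path Output CSV path.
#' @export
write_landmark_curves <- function(lm, path) {
  df <- as.data.frame(unclass(lm))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read landmark curves from CSV
#' @param path CSV with columns `time`, `tricuspid_lateral`, `mitral_lateral`
#'   and optionally `tricuspid_medial`, `strain`.
#' @export
read_landmark_curves <- function(path) {
  df <- utils::read.csv(path)
  for (col in c("time", "tricuspid_lateral", "mitral_lateral"))
    if (is.null(df[[col]])) stop("missing mandatory column: ", col)
  landmark_curves(df$time, df$tricuspid_lateral, df$mitral_lateral,
                  df$tricuspid_medial, df$strain)
}

#' Construct a planar contour polygon
#'
#' @param vertices n x 2 matrix of ordered planar vertices in mm.
#' @param frame Frame index (0-based).
#' @param chamber Chamber tag, e.g. `"RA"`, `"PA"`.
#' @return An object of class `contour_polygon`.
#' @export
contour_polygon <- function(vertices, frame = 0L, chamber = "RA") {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L)
    stop("polygon needs >= 3 planar vertices")
  if (.polygon_self_intersects(vertices))
    stop("polygon is self-intersecting")
  structure(list(vertices = vertices, frame = as.integer(frame),
                 chamber = chamber),
            class = "contour_polygon")
}

# Pairwise segment-intersection check on non-adjacent edges.
.polygon_self_intersects <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), , drop = FALSE])  # x1 y1 x2 y2 per edge
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (j == i + 1 || (i == 1 && j == n)) next  # adjacent edges share a vertex
      a <- seg[i, ]; b <- seg[j, ]
      d1 <- cross2(b[1], b[2], b[3], b[4], a[1], a[2])
      d2 <- cross2(b[1], b[2], b[3], b[4], a[3], a[4])
      d3 <- cross2(a[1], a[2], a[3], a[4], b[1], b[2])
      d4 <- cross2(a[1], a[2], a[3], a[4], b[3], b[4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Write contour polygons to CSV
#' @param contours A `contour_polygon` or list of them.
#' @param path Output CSV path.
#' @export
write_contours <- function(contours, path) {
  if (inherits(contours, "contour_polygon")) contours <- list(contours)
  df <- do.call(rbind, lapply(contours, function(p)
    data.frame(frame = p$frame, chamber = p$chamber,
               x_mm = p$vertices[, 1], y_mm = p$vertices[, 2])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read contour polygons from CSV
#' @param path CSV with columns `frame`, `chamber`, `x_mm`, `y_mm`; one
#'   polygon per (frame, chamber) pair, vertices in row order.
#' @return List of `contour_polygon`.
#' @export
read_contours <- function(path) {
  df <- utils::read.csv(path)
  for (col in c("frame", "chamber", "x_mm", "y_mm"))
    if (is.null(df[[col]])) stop("missing mandatory column: ", col)
  keys <- unique(df[, c("frame", "chamber")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$frame == keys$frame[i] & df$chamber == keys$chamber[i], ]
    contour_polygon(cbind(sub$x_mm, sub$y_mm), keys$frame[i], keys$chamber[i])
  })
}

## ---- CPET series -----------------------------------------------------------

CPET_PHASES <- c("rest", "exercise", "recovery")

#' Construct a CPET gas-exchange series
#'
#' Breath-by-breath gas exchange averaged onto a 10-s grid.
#'
#' @param time Sample times in s, strictly increasing.
#' @param ve Minute ventilation, L/min.
#' @param vo2 Oxygen uptake, ml/kg/min.
#' @param vco2 Carbon dioxide output, L/min.
#' @param phase Character per-sample phase: `"rest"`, `"exercise"` or
#'   `"recovery"`.
#' @return An object of class `cpet_series`.
#' @export
cpet_series <- function(time, ve, vo2, vco2, phase) {
  n <- length(time)
  if (any(lengths(list(ve, vo2, vco2, phase)) != n))
    stop("all series must share the length of time")
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (any(c(ve, vo2, vco2) < 0)) stop("gas-exchange values must be >= 0")
  if (!all(phase %in% CPET_PHASES))
    stop("phase values must be rest/exercise/recovery")
  structure(list(time = as.numeric(time), ve = as.numeric(ve),
                 vo2 = as.numeric(vo2), vco2 = as.numeric(vco2),
                 phase = as.character(phase)),
            class = "cpet_series")
}

#' Write a CPET series to CSV
#' @param series A `cpet_series`.
#' @param path Output CSV path.
#' @export
write_cpet_series <- function(series, path) {
  utils::write.csv(as.data.frame(unclass(series)), path, row.names = FALSE)
  invisible(path)
}

#' Read a CPET series from CSV
#' @param path CSV with columns `time`, `ve`, `vo2`, `vco2`, `phase`.
#' @export
read_cpet_series <- function(path) {
  df <- utils::read.csv(path)
  for (col in c("time", "ve", "vo2", "vco2", "phase"))
    if (is.null(df[[col]])) stop("missing mandatory column: ", col)
  cpet_series(df$time, df$ve, df$vo2, df$vco2, df$phase)
}

## ---- cohort table ----------------------------------------------------------

# Mandatory columns and the numeric subset of the cohort schema.
COHORT_MANDATORY <- c("id", "group")
COHORT_NUMERIC <- c(
  "age", "bsa",
  "lv_direct", "lv_retained", "lv_delayed", "lv_residual",
  "rv_direct", "rv_retained", "rv_delayed", "rv_residual",
  "ffr", "ke_discordance",
  "lv_peak_sys_kei", "lv_avg_sys_kei", "lv_peak_e_kei",
  "rv_peak_sys_kei", "rv_avg_sys_kei", "rv_peak_e_kei",
  "lvedv_i", "lvesv_i", "lvef", "rvedv_i", "rvesv_i", "rvef",
  "remodelling_index", "tapse", "rv_gls", "ra_area", "pa_rac",
  "peak_vo2", "pct_pred_vo2", "vevco2_slope", "risk_grade", "reveal_score")

#' Read a cohort table from CSV
#'
#' One row per subject. Mandatory columns `id` and `group` (`control` or
#' `PAH`, case-insensitive; normalized on read). Known numeric columns are
#' validated and coerced; unknown columns are preserved untouched.
#'
#' @param path CSV path.
#' @return A `data.frame` with class `cohort_table` prepended.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_cohort(df)
}

#' Validate and normalize a cohort data frame
#' @param df Data frame with at least `id` and `group` columns.
#' @return The validated `cohort_table`.
#' @export
as_cohort <- function(df) {
  for (col in COHORT_MANDATORY)
    if (is.null(df[[col]])) stop("missing mandatory column: ", col)
  grp <- tolower(trimws(as.character(df$group)))
  if (!all(grp %in% c("control", "pah")))
    stop("group values must be control or PAH (case-insensitive)")
  df$group <- ifelse(grp == "pah", "PAH", "control")
  for (col in intersect(COHORT_NUMERIC, names(df))) {
    x <- df[[col]]
    if (!is.numeric(x)) {
      conv <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & x != "" & is.na(conv))
      if (length(bad) > 0)
        stop(sprintf("non-numeric cell(s) in numeric column %s (rows %s)",
                     col, paste(bad, collapse = ", ")))
      df[[col]] <- conv
    }
  }
  pct_cols <- intersect(c("lv_direct", "lv_retained", "lv_delayed", "lv_residual",
                          "rv_direct", "rv_retained", "rv_delayed", "rv_residual"),
                        names(df))
  for (col in pct_cols)
    if (any(df[[col]] < 0 | df[[col]] > 100, na.rm = TRUE))
      stop("flow component percentages must lie in [0, 100]: ", col)
  if (!is.null(df$risk_grade) &&
      !all(is.na(df$risk_grade) | df$risk_grade %in% 1:3))
    stop("risk_grade values must be in {1, 2, 3}")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort table to CSV
#' @param cohort A `cohort_table` (or compatible data frame).
#' @param path Output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}
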
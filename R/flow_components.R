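# Four-component decomposition of the end-diastolic blood pool.
#
# Every particle seeded in the ventricle at end diastole (ED) is traced
# forward over systole [ED -> ES] and backward over the preceding diastole
# [ED -> previous ES]. Whether the particle was ever outside the
# time-varying ventricular mask on each leg decides its component:
#
#   entered & ejected      -> direct flow
#   entered & !ejected     -> retained inflow
#   !entered & ejected     -> delayed ejection flow
#   !entered & !ejected    -> residual volume

FLOW_COMPONENTS <- c("direct_flow", "retained_inflow",
                     "delayed_ejection_flow", "residual_volume")

#' Bidirectional particle tracing for flow-component analysis
#'
#' Seeds the ventricle at the end-diastolic frame and integrates every seed
#' forward over the systolic interval and backward over the preceding
#' diastolic interval, attaching inside-ventricle flags at each recorded
#' frame. ED and ES default to the argmax/argmin of the ventricular volume
#' curve (earliest frame on ties); for static-mask phantoms, whose volume
#' curve is flat, pass `ed_frame`/`es_frame` explicitly.
#'
#' @param field A [velocity_field()].
#' @param mask A [phase_mask()] on the same grid and frame count.
#' @param ventricle `"LV"` or `"RV"`.
#' @param ed_frame,es_frame Optional 0-based frame indices overriding the
#'   volume-curve landmarks.
#' @param dt_fraction RK4 sub-step as a fraction of the frame interval
#'   (default 0.2).
#' @param seed_spacing Integer seed lattice spacing in voxels (default 1).
#' @return List with `seeds`, per-particle logical matrices
#'   `forward_outside` / `backward_outside` (recorded frames after the seed
#'   frame), the landmark frames, and per-particle `forward_status` /
#'   `backward_status`.
#' @export
trace_bidirectional <- function(field, mask, ventricle,
                                ed_frame = NULL, es_frame = NULL,
                                dt_fraction = 0.2, seed_spacing = 1L) {
  ventricle <- match.arg(ventricle, c("LV", "RV"))
  if (!identical(field$grid_shape, mask$grid_shape) ||
      field$n_frames != mask$n_frames)
    stop("field and mask must share grid shape and frame count")
  if (is.null(ed_frame) || is.null(es_frame)) {
    lmk <- phase_landmarks(volume_curve(mask, ventricle))
    if (is.null(ed_frame)) ed_frame <- lmk$ed_frame
    if (is.null(es_frame)) es_frame <- lmk$es_frame
  }
  if (ed_frame == es_frame) stop("degenerate volume curve: ED frame equals ES frame")
  T_ <- field$n_frames
  dl <- field$frame_interval
  sys_frames <- (es_frame - ed_frame) %% T_  # frames ED -> ES forward
  dia_frames <- T_ - sys_frames              # frames previous ES -> ED
  seeds <- seed_particles(mask, ed_frame, ventricle, seed_spacing)
  dt <- dl * dt_fraction
  t_ed <- ed_frame * dl
  fwd <- advect_particles(field, seeds, t_ed, t_ed + sys_frames * dl, dt)
  bwd <- advect_particles(field, seeds, t_ed, t_ed - dia_frames * dl, dt)
  code <- MASK_LABELS[[ventricle]]
  outside_at <- function(tr, s) {
    pos_s <- tr$positions[, , s, drop = FALSE]
    dim(pos_s) <- dim(pos_s)[1:2]
    lab <- mask_labels_at(mask, pos_s, tr$times[s])
    !(tr$in_grid[, s] & lab == code)
  }
  n_f <- length(fwd$times); n_b <- length(bwd$times)
  forward_outside <- vapply(2:n_f, function(s) outside_at(fwd, s),
                            logical(nrow(seeds)))
  backward_outside <- vapply(2:n_b, function(s) outside_at(bwd, s),
                             logical(nrow(seeds)))
  if (nrow(seeds) == 1L) {  # vapply drops to vectors for a single seed
    forward_outside <- matrix(forward_outside, nrow = 1L)
    backward_outside <- matrix(backward_outside, nrow = 1L)
  }
  list(ventricle = ventricle, seeds = seeds,
       ed_frame = ed_frame, es_frame = es_frame,
       forward_outside = forward_outside,
       backward_outside = backward_outside,
       forward_status = fwd$status, backward_status = bwd$status)
}

#' Classify one particle from its flagged forward and backward traces
#'
#' `entered` means the backward trace (preceding diastole) was outside the
#' seeding ventricle at one or more recorded frames; `ejected` means the
#' forward trace (systole) was. Leaving the grid counts as leaving the mask.
#'
#' @param forward,backward `pathline` objects flagged with [flag_pathline()]
#'   against the seeding ventricle.
#' @param min_outside_frames Number of outside recorded frames required to
#'   count as entered/ejected (default 1; exposed for sensitivity analysis).
#' @return One of `"direct_flow"`, `"retained_inflow"`,
#'   `"delayed_ejection_flow"`, `"residual_volume"`.
#' @export
classify_particle <- function(forward, backward, min_outside_frames = 1L) {
  if (is.null(forward$inside) || is.null(backward$inside))
    stop("pathlines must be flagged with flag_pathline() first")
  ejected <- sum(!forward$inside[-1]) >= min_outside_frames
  entered <- sum(!backward$inside[-1]) >= min_outside_frames
  classify_flags(entered, ejected)
}

#' Vectorized component labelling from entered/ejected flags
#' @param entered,ejected Logical vectors.
#' @return Factor of component labels.
#' @export
classify_flags <- function(entered, ejected) {
  lab <- ifelse(entered & ejected, "direct_flow",
         ifelse(entered & !ejected, "retained_inflow",
         ifelse(!entered & ejected, "delayed_ejection_flow",
                "residual_volume")))
  factor(lab, levels = FLOW_COMPONENTS)
}

#' Classify all particles of a bidirectional trace
#'
#' @param trace Result of [trace_bidirectional()].
#' @param min_outside_frames See [classify_particle()].
#' @return Factor of component labels, one per seed.
#' @export
classify_trace <- function(trace, min_outside_frames = 1L) {
  ejected <- rowSums(trace$forward_outside) >= min_outside_frames
  entered <- rowSums(trace$backward_outside) >= min_outside_frames
  classify_flags(entered, ejected)
}

#' Component fractions and fractional flow ratio
#'
#' Percentages of seeded end-diastolic blood per component. The fractional
#' flow ratio is direct flow over residual volume; when the residual-volume
#' percentage is zero the ratio is undefined and reported as `NA`, not
#' infinity.
#'
#' @param labels Factor or character vector of component labels.
#' @param ventricle Ventricle tag carried through to the result.
#' @return An object of class `flow_components`: per-component percentages
#'   (summing to 100), `n_particles`, and `fractional_flow_ratio`.
#' @export
component_fractions <- function(labels, ventricle = NA_character_) {
  labels <- factor(labels, levels = FLOW_COMPONENTS)
  if (length(labels) == 0 || anyNA(labels)) stop("labels must be non-empty component names")
  counts <- table(labels)
  pct <- 100 * as.numeric(counts) / length(labels)
  names(pct) <- FLOW_COMPONENTS
  ffr <- if (pct[["residual_volume"]] > 0)
    pct[["direct_flow"]] / pct[["residual_volume"]] else NA_real_
  structure(list(ventricle = ventricle,
                 n_particles = length(labels),
                 percentages = pct,
                 fractional_flow_ratio = ffr),
            class = "flow_components")
}

#' @export
print.flow_components <- function(x, ...) {
  cat(sprintf("flow components (%s, %d particles):\n",
              x$ventricle, x$n_particles))
  for (cmp in FLOW_COMPONENTS)
    cat(sprintf("  %-22s %6.2f %%\n", cmp, x$percentages[[cmp]]))
  cat(sprintf("  fractional flow ratio  %s\n",
              ifelse(is.na(x$fractional_flow_ratio), "undefined",
                     sprintf("%.3f", x$fractional_flow_ratio))))
  invisible(x)
}

#' Full flow-component analysis of one ventricle
#'
#' Convenience wrapper: bidirectional tracing, classification and fraction
#' computation in one call.
#'
#' @inheritParams trace_bidirectional
#' @param min_outside_frames See [classify_particle()].
#' @return A `flow_components` result.
#' @export
flow_component_analysis <- function(field, mask, ventricle,
                                    ed_frame = NULL, es_frame = NULL,
                                    dt_fraction = 0.2, seed_spacing = 1L,
                                    min_outside_frames = 1L) {
  tr <- trace_bidirectional(field, mask, ventricle, ed_frame, es_frame,
                            dt_fraction, seed_spacing)
  component_fractions(classify_trace(tr, min_outside_frames), ventricle)
}

#' Kinetic-energy discordance between the ventricles
#'
#' Ratio of RV to LV average systolic kinetic energy indexed to EDV.
#'
#' @param rv_avg_sys_keiedv,lv_avg_sys_keiedv Average systolic KEI_EDV in
#'   uJ/ml.
#' @return Dimensionless RV/LV ratio; `NA` when the LV value is zero.
#' @export
ke_discordance <- function(rv_avg_sys_keiedv, lv_avg_sys_keiedv) {
  ifelse(lv_avg_sys_keiedv > 0, rv_avg_sys_keiedv / lv_avg_sys_keiedv, NA_real_)
}
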
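# Synthetic data generators: analytic 4D flow phantoms whose component
# fractions and kinetic energy are known in closed form, and simulated
# control/patient cohorts with planted group effects, so that every pipeline
# stage can be verified without patient data.

#' Specify an analytic flow phantom
#'
#' Four kinds are available:
#' \describe{
#'   \item{`uniform`}{Constant velocity everywhere; static box chamber.
#'     Closed-form kinetic energy: KEI_EDV = 1/2 rho |v|^2 in J/m^3 (=
#'     uJ/ml) times mask volume over EDV.}
#'   \item{`rotation`}{Rigid rotation about the z axis with period equal to
#'     the cycle; cylindrical chamber. Orbits are closed, so every particle
#'     is residual volume.}
#'   \item{`plug_transit`}{A static channel chamber of length `L` voxels
#'     along z. Plug inflow advances particles by `a` voxel lengths over
#'     diastole and plug outflow by `b` over systole. Per unit length,
#'     direct = max(0, a + b - L), retained = a - direct, delayed =
#'     b - direct, residual = L - a - b + direct, each scaled to % of L
#'     (exact for the voxel-center seed lattice when `a` and `b` are
#'     integers).}
#'   \item{`two_channel`}{The plug-transit channel in parallel with an
#'     equal-volume zero-velocity channel; the ground truth is the
#'     volume-weighted average with (0, 0, 0, 100), so all four components
#'     are nonzero.}
#' }
#'
#' The phantom chamber walls do not move: the ED/ES frames are declared in
#' the ground truth rather than inferred from a (flat) volume curve.
#'
#' @param kind One of `"uniform"`, `"rotation"`, `"plug_transit"`,
#'   `"two_channel"`.
#' @param L Chamber length along the flow axis, voxels (plug kinds).
#' @param a,b Diastolic and systolic transit lengths in voxel units
#'   (plug kinds); specs with `a > L` or `b > L` (whole-chamber transit in
#'   one phase) are rejected.
#' @param cross_section Chamber cross-section in voxels, length 2 (x, y).
#' @param margin Grid padding below/above the chamber along the flow axis,
#'   voxels.
#' @param n_frames Cardiac phases per cycle.
#' @param frame_interval Frame interval, ms.
#' @param es_frame End-systolic frame (0-based); end diastole is frame 0.
#' @param voxel_size Isotropic voxel edge, mm.
#' @param speed Uniform kind: constant velocity vector, cm/s.
#' @param radius Rotation kind: chamber cylinder radius, voxels.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("uniform", "rotation", "plug_transit",
                                  "two_channel"),
                         L = 10L, a = 6L, b = 7L,
                         cross_section = c(6L, 6L), margin = c(8L, 8L),
                         n_frames = 30L, frame_interval = 30,
                         es_frame = 12L, voxel_size = 2.5,
                         speed = c(10, 0, 0), radius = 5) {
  kind <- match.arg(kind)
  if (kind %in% c("plug_transit", "two_channel")) {
    if (a > L || b > L)
      stop("transit length exceeding the chamber (a > L or b > L) is not supported")
    if (a <= 0 || b <= 0) stop("a and b must be positive")
    if (es_frame < 1L || es_frame > n_frames - 2L)
      stop("es_frame must leave >= 1 systolic and >= 2 diastolic frames")
  }
  structure(list(kind = kind, L = L, a = a, b = b,
                 cross_section = cross_section, margin = margin,
                 n_frames = n_frames, frame_interval = frame_interval,
                 es_frame = es_frame, voxel_size = voxel_size,
                 speed = speed, radius = radius),
            class = "phantom_spec")
}

# Frame-sampled plug speeds (mm/ms along z) realizing exact transit lengths
# under linear-in-time interpolation: systole (frames 0..es) is sampled
# constant, so the forward displacement is exactly b; the diastolic samples
# blend linearly with the systolic value over the first and last diastolic
# frame intervals, so backward displacement = dt * (u_d * (T_d - 1) + u_s).
.plug_speeds <- function(spec) {
  dl <- spec$frame_interval
  vx <- spec$voxel_size
  t_d <- spec$n_frames - spec$es_frame
  u_s <- spec$b * vx / (spec$es_frame * dl)
  u_d <- (spec$a * vx / dl - u_s) / (t_d - 1)
  if (u_d < 0) stop("infeasible spec: diastolic transit too short for this timing")
  list(u_s = u_s, u_d = u_d)  # mm/ms
}

#' Build an analytic flow phantom
#'
#' @param spec A [phantom_spec()].
#' @return List with `field` ([velocity_field()]), `mask` ([phase_mask()],
#'   chamber labelled RV) and `ground_truth` (component fractions in %,
#'   declared `ed_frame`/`es_frame`, and kind-specific closed forms).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  switch(spec$kind,
         uniform = .phantom_uniform(spec),
         rotation = .phantom_rotation(spec),
         plug_transit = .phantom_plug(spec, two_channel = FALSE),
         two_channel = .phantom_plug(spec, two_channel = TRUE))
}

.static_labels <- function(dims, n_frames, sel) {
  vol <- array(0L, dims)
  vol[sel] <- MASK_LABELS[["RV"]]
  array(rep(vol, n_frames), c(dims, n_frames))
}

.phantom_uniform <- function(spec) {
  cs <- spec$cross_section
  dims <- c(cs[1] + 4L, cs[2] + 4L, spec$L + sum(spec$margin))
  T_ <- spec$n_frames
  vel <- array(0, c(dims, 3L, T_))
  for (c_i in 1:3) vel[, , , c_i, ] <- spec$speed[c_i]
  field <- velocity_field(vel, rep(spec$voxel_size, 3), spec$frame_interval,
                          venc = 1.5 * sqrt(sum(spec$speed^2)))
  sel <- as.matrix(expand.grid(2 + seq_len(cs[1]), 2 + seq_len(cs[2]),
                               spec$margin[1] + seq_len(spec$L)))
  labels <- .static_labels(dims, T_, sel)
  mask <- phase_mask(labels, rep(spec$voxel_size, 3), spec$frame_interval)
  speed_ms <- sqrt(sum(spec$speed^2)) / 100  # cm/s -> m/s
  list(field = field, mask = mask,
       ground_truth = list(
         kind = "uniform", ed_frame = 0L, es_frame = spec$es_frame,
         speed_m_s = speed_ms,
         kei_edv_uj_ml = 0.5 * BLOOD_DENSITY * speed_ms^2,
         fractions = NULL))
}

.phantom_rotation <- function(spec) {
  n_xy <- 2L * ceiling(spec$radius) + 9L
  dims <- c(n_xy, n_xy, 7L)
  T_ <- spec$n_frames
  vx <- spec$voxel_size
  cycle <- T_ * spec$frame_interval
  omega <- 2 * pi / cycle  # rad/ms; one revolution per cycle
  ctr <- (dims - 1) / 2 * vx
  xs <- (seq_len(dims[1]) - 1) * vx - ctr[1]
  ys <- (seq_len(dims[2]) - 1) * vx - ctr[2]
  vel <- array(0, c(dims, 3L, T_))
  vxp <- -outer(rep(1, dims[1]), ys) * omega * 100  # mm/ms -> cm/s
  vyp <- outer(xs, rep(1, dims[2])) * omega * 100
  for (f in seq_len(T_)) {
    vel[, , , 1, f] <- array(vxp, dims)
    vel[, , , 2, f] <- array(vyp, dims)
  }
  field <- velocity_field(vel, rep(vx, 3), spec$frame_interval,
                          venc = 1.5 * omega * spec$radius * vx * 100)
  grid_idx <- as.matrix(expand.grid(seq_len(dims[1]), seq_len(dims[2]),
                                    3:(dims[3] - 2)))
  r2 <- (xs[grid_idx[, 1]])^2 + (ys[grid_idx[, 2]])^2
  sel <- grid_idx[r2 <= (spec$radius * vx)^2, , drop = FALSE]
  # Orbits of the seeded disc stay within radius R in continuous space, but
  # nearest-voxel membership of a point at radius r can land on a center up
  # to r + sqrt(2)/2 voxels out. Away from the seeding frame the labelled
  # disc is dilated by that margin so the voxelized membership agrees with
  # the continuous chamber and closed orbits never register an exit.
  sel_guard <- grid_idx[r2 <= ((spec$radius + 1.5) * vx)^2, , drop = FALSE]
  labels <- .static_labels(dims, T_, sel_guard)
  vol0 <- array(0L, dims)
  vol0[sel] <- MASK_LABELS[["RV"]]
  labels[, , , 1] <- vol0
  mask <- phase_mask(labels, rep(vx, 3), spec$frame_interval)
  list(field = field, mask = mask,
       ground_truth = list(
         kind = "rotation", ed_frame = 0L, es_frame = spec$es_frame,
         omega_rad_ms = omega,
         fractions = c(direct_flow = 0, retained_inflow = 0,
                       delayed_ejection_flow = 0, residual_volume = 100)))
}

.phantom_plug <- function(spec, two_channel) {
  cs <- spec$cross_section
  ny <- if (two_channel) 2L * cs[2] else cs[2]
  dims <- c(cs[1], ny, spec$L + sum(spec$margin))
  T_ <- spec$n_frames
  sp <- .plug_speeds(spec)
  # frame-sampled z speed in cm/s: systolic frames 0..es get u_s
  frame_speed <- ifelse(seq_len(T_) - 1 <= spec$es_frame,
                        sp$u_s, sp$u_d) * 100
  vel <- array(0, c(dims, 3L, T_))
  for (f in seq_len(T_))
    vel[, seq_len(cs[2]), , 3, f] <- frame_speed[f]
  field <- velocity_field(vel, rep(spec$voxel_size, 3), spec$frame_interval,
                          venc = 1.5 * max(frame_speed))
  z_sel <- spec$margin[1] + seq_len(spec$L)
  sel <- as.matrix(expand.grid(seq_len(cs[1]), seq_len(ny), z_sel))
  labels <- .static_labels(dims, T_, sel)
  mask <- phase_mask(labels, rep(spec$voxel_size, 3), spec$frame_interval)
  direct <- max(0, spec$a + spec$b - spec$L)
  fr <- c(direct_flow = direct,
          retained_inflow = spec$a - direct,
          delayed_ejection_flow = spec$b - direct,
          residual_volume = spec$L - spec$a - spec$b + direct) / spec$L * 100
  if (two_channel) fr <- fr / 2 + c(0, 0, 0, 50)
  list(field = field, mask = mask,
       ground_truth = list(
         kind = spec$kind, ed_frame = 0L, es_frame = spec$es_frame,
         u_s_mm_ms = sp$u_s, u_d_mm_ms = sp$u_d,
         a = spec$a, b = spec$b, L = spec$L,
         fractions = fr))
}

#' Deforming-chamber mask with programmed volume curve
#'
#' A wall-motion stand-in for exercising the volume-curve landmark path: a
#' single-ventricle mask whose labelled voxel count per frame is programmed,
#' so EDV and ESV are known exactly.
#'
#' @param counts Integer vector: labelled voxel count per frame (all > 0).
#' @param ventricle `"LV"` or `"RV"`.
#' @param voxel_size Isotropic voxel edge, mm.
#' @param frame_interval Frame interval, ms.
#' @return A [phase_mask()] whose volume curve equals
#'   `counts * voxel_size^3 / 1000` ml.
#' @export
make_deforming_mask <- function(counts, ventricle = "RV", voxel_size = 2,
                                frame_interval = 30) {
  if (any(counts <= 0)) stop("counts must be positive at every frame")
  n_side <- ceiling(max(counts)^(1 / 3)) + 2L
  dims <- c(n_side, n_side, n_side)
  code <- MASK_LABELS[[match.arg(ventricle, c("LV", "RV"))]]
  labels <- array(0L, c(dims, length(counts)))
  for (f in seq_along(counts)) {
    vol <- array(0L, dims)
    vol[seq_len(counts[f])] <- code  # fill in column-major order
    labels[, , , f] <- vol
  }
  phase_mask(labels, rep(voxel_size, 3), frame_interval)
}

## ---- synthetic cohorts -----------------------------------------------------

# Per-variable marginal distributions of the simulated cohorts.
# "normal" rows carry (mean, sd) per group and truncation bounds; variables
# reported as median (IQR) in cohort summaries are right-skewed and carry
# log-normal marginals matched to the two quantiles.
.cohort_marginals <- function() {
  n <- function(var, cm, cs, pm, ps, lo = -Inf, hi = Inf)
    data.frame(variable = var, family = "normal", p1_control = cm,
               p2_control = cs, p1_pah = pm, p2_pah = ps, lo = lo, hi = hi)
  l <- function(var, cm, ci, pm, pi, lo = 0, hi = Inf)
    data.frame(variable = var, family = "lognormal", p1_control = cm,
               p2_control = ci, p1_pah = pm, p2_pah = pi, lo = lo, hi = hi)
  rbind(
    n("age", 46, 14, 46, 11, 18, 90),
    n("bsa", 1.64, 0.17, 1.64, 0.19, 1.0, 2.6),
    n("lvedv_i", 76, 11, 76, 34, 20, 250),
    n("lvesv_i", 32, 6, 30, 21, 5, 200),
    n("lvef", 59, 5, 62, 9, 10, 90),
    n("rvedv_i", 74, 13, 102, 41, 20, 350),
    n("rvesv_i", 35, 8, 61, 31, 5, 300),
    n("rvef", 54, 6, 42, 12, 5, 90),
    n("remodelling_index", 0.97, 0.10, 1.43, 0.64, 0.3, 5),
    n("tapse", 19.8, 2.8, 15.0, 3.9, 2, 40),
    n("rv_gls", 24.3, 3.9, 17.9, 4.7, 2, 45),
    n("ra_area", 19.3, 4.0, 25.3, 11.2, 5, 80),
    n("pa_rac", 56, 20, 25, 13, 2, 150),
    l("lv_direct", 34, 10, 31, 12, 0, 100),
    l("lv_retained", 17, 5, 17, 8, 0, 100),
    l("lv_delayed", 17, 5, 16, 7, 0, 100),
    l("lv_residual", 33, 6, 36, 10, 0, 100),
    l("rv_direct", 37, 7, 24, 16, 0, 100),
    l("rv_retained", 16, 6, 16, 5, 0, 100),
    l("rv_delayed", 17, 5, 14, 6, 0, 100),
    l("rv_residual", 29, 10, 44, 16, 0, 100),
    l("lv_peak_sys_kei", 16.1, 5.1, 19.3, 15.0),
    l("lv_avg_sys_kei", 8.9, 3.1, 11.5, 8.0),
    l("lv_peak_e_kei", 27.0, 12.0, 19.0, 17.4),
    l("rv_peak_sys_kei", 21.2, 8.5, 19.4, 18.3),
    l("rv_avg_sys_kei", 12.2, 4.5, 10.4, 6.9),
    l("rv_peak_e_kei", 13.9, 7.6, 8.4, 6.3),
    l("ke_discordance", 1.30, 0.53, 0.94, 0.66),
    l("ffr", 1.24, 0.60, 0.51, 0.40),
    l("peak_vo2", 22.6, 10.5, 13.2, 4.4, 3, 60),
    l("pct_pred_vo2", 87, 33, 48, 23, 10, 160),
    l("vevco2_slope", 27, 4, 41, 10, 10, 120))
}

#' Specify a synthetic two-group cohort
#'
#' Marginals default to the summary statistics of a healthy-control /
#' pulmonary-arterial-hypertension contrast: normal marginals for variables
#' reported as mean +/- SD, log-normal marginals solved from the median and
#' interquartile range for skewed variables, both truncated to physical
#' ranges. Cross-variable dependence uses a Gaussian copula; by default the
#' only nonzero entry is the remodelling-index / RV-direct-flow correlation
#' (-0.624), the one pairwise magnitude carried by the default parameter
#' set.
#'
#' @param n_control,n_pah Group sizes (defaults 51 and 45).
#' @param seed Integer seed; the generator is bit-reproducible given the
#'   seed.
#' @param null_effects If TRUE, the patient group is sampled from the
#'   control marginals (no planted effects; for type-I-error studies).
#' @param marginals Optional replacement marginal table (advanced).
#' @param correlations Optional data frame `var_a, var_b, r` overriding the
#'   default copula entries.
#' @param male_fraction Length-2 male fractions (control, PAH).
#' @param risk_probs Probabilities of risk grades 1..3 among patients.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 51L, n_pah = 45L, seed = 1L,
                        null_effects = FALSE, marginals = NULL,
                        correlations = NULL,
                        male_fraction = c(17 / 51, 7 / 45),
                        risk_probs = c(0.40, 0.45, 0.15)) {
  marg <- if (is.null(marginals)) .cohort_marginals() else marginals
  if (null_effects) {
    marg$p1_pah <- marg$p1_control
    marg$p2_pah <- marg$p2_control
  }
  if (is.null(correlations))
    correlations <- data.frame(var_a = "remodelling_index",
                               var_b = "rv_direct", r = -0.624)
  structure(list(n_control = n_control, n_pah = n_pah, seed = seed,
                 marginals = marg, correlations = correlations,
                 male_fraction = male_fraction, risk_probs = risk_probs),
            class = "cohort_spec")
}

# log-normal parameters matched to a median and an interquartile range
.lnorm_from_median_iqr <- function(median, iqr) {
  list(meanlog = log(median),
       sdlog = asinh(iqr / (2 * median)) / stats::qnorm(0.75))
}

#' Generate a synthetic cohort table
#'
#' Samples one row per subject from the declared marginals through the
#' Gaussian copula, with group effects planted exactly as declared in the
#' spec. Given the same spec (including seed) the output is bit-identical.
#'
#' @param spec A [cohort_spec()].
#' @return A `cohort_table` with `n_control + n_pah` rows.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  marg <- spec$marginals
  p <- nrow(marg)
  R <- diag(p)
  rownames(R) <- colnames(R) <- marg$variable
  for (i in seq_len(nrow(spec$correlations))) {
    a <- spec$correlations$var_a[i]; b <- spec$correlations$var_b[i]
    R[a, b] <- R[b, a] <- spec$correlations$r[i]
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("infeasible correlation matrix (not positive-definite)")
  n <- spec$n_control + spec$n_pah
  group <- rep(c("control", "PAH"), c(spec$n_control, spec$n_pah))
  z <- matrix(stats::rnorm(n * p), n, p) %*% chol(R)
  u <- stats::pnorm(z)
  df <- data.frame(id = sprintf("S%03d", seq_len(n)), group = group)
  is_pah <- group == "PAH"
  for (j in seq_len(p)) {
    m <- marg[j, ]
    p1 <- ifelse(is_pah, m$p1_pah, m$p1_control)
    p2 <- ifelse(is_pah, m$p2_pah, m$p2_control)
    if (m$family == "normal") {
      plo <- stats::pnorm(m$lo, p1, p2); phi <- stats::pnorm(m$hi, p1, p2)
      df[[m$variable]] <- stats::qnorm(plo + u[, j] * (phi - plo), p1, p2)
    } else {
      par_all <- list(meanlog = log(p1),
                      sdlog = vapply(seq_len(n), function(i)
                        .lnorm_from_median_iqr(p1[i], p2[i])$sdlog, 1.0))
      plo <- stats::plnorm(m$lo, par_all$meanlog, par_all$sdlog)
      phi <- stats::plnorm(m$hi, par_all$meanlog, par_all$sdlog)
      df[[m$variable]] <- stats::qlnorm(plo + u[, j] * (phi - plo),
                                        par_all$meanlog, par_all$sdlog)
    }
  }
  mf <- ifelse(is_pah, spec$male_fraction[2], spec$male_fraction[1])
  df$sex <- ifelse(stats::runif(n) < mf, "M", "F")
  df$risk_grade <- NA_integer_
  df$risk_grade[is_pah] <- sample.int(3L, sum(is_pah), replace = TRUE,
                                      prob = spec$risk_probs)
  as_cohort(df)
}

## ---- synthetic CPET and landmark series ------------------------------------

#' Generate a synthetic CPET series with planted slope and peak
#'
#' Rest, incremental exercise and recovery phases on a 10-s grid. During
#' exercise, VCO2 ramps linearly, VE follows `slope * VCO2 + intercept` plus
#' Gaussian noise, and VO2 ramps to exactly `peak` at end-exercise, so the
#' planted peak and (at zero noise) the planted slope are recovered exactly
#' by [peak_vo2()] and [ve_vco2_slope()].
#'
#' @param slope Planted VE/VCO2 slope.
#' @param peak Planted peak VO2, ml/kg/min.
#' @param noise_sd Gaussian noise SD added to VE, L/min.
#' @param n_exercise Number of 10-s exercise samples (default 60).
#' @param intercept VE intercept, L/min.
#' @param seed Optional integer seed.
#' @return A [cpet_series()].
#' @export
make_cpet_series <- function(slope = 30, peak = 25, noise_sd = 0,
                             n_exercise = 60L, intercept = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_rest <- 6L; n_rec <- 12L
  n <- n_rest + n_exercise + n_rec
  time <- seq_len(n) * 10
  phase <- rep(c("rest", "exercise", "recovery"),
               c(n_rest, n_exercise, n_rec))
  ramp <- seq_len(n_exercise) / n_exercise
  vo2 <- c(rep(4, n_rest), 4 + (peak - 4) * ramp,
           peak * exp(-seq_len(n_rec) / 4))
  vco2 <- c(rep(0.35, n_rest), 0.35 + 2.2 * ramp,
            2.55 * exp(-seq_len(n_rec) / 4))
  ve <- slope * vco2 + intercept
  ve[phase == "exercise"] <- ve[phase == "exercise"] +
    stats::rnorm(n_exercise, 0, noise_sd)
  cpet_series(time, pmax(ve, 0), vo2, vco2, phase)
}

#' Generate synthetic landmark displacement curves
#'
#' Half-sine displacement curves with programmed peak amplitudes and a
#' programmed tricuspid-vs-mitral peak-time offset, so TAPSE and the
#' inter-ventricular synchrony index are recovered exactly.
#'
#' @param n_frames Frames per cycle.
#' @param frame_interval Frame interval, ms.
#' @param tapse_peak Peak lateral-tricuspid displacement, mm.
#' @param mitral_peak Peak lateral-mitral displacement, mm.
#' @param mitral_peak_frame Frame of the mitral displacement maximum.
#' @param offset_frames Tricuspid peak frame minus mitral peak frame.
#' @param strain_es Strain value planted at `es_frame`, \%.
#' @param es_frame End-systolic frame (0-based).
#' @return A [landmark_curves()].
#' @export
make_landmark_curves <- function(n_frames = 30L, frame_interval = 30,
                                 tapse_peak = 19.8, mitral_peak = 15,
                                 mitral_peak_frame = 10L, offset_frames = 0L,
                                 strain_es = 24.3, es_frame = 10L) {
  f <- seq_len(n_frames) - 1
  bump <- function(peak, at) {
    x <- peak * sin(pi * f / (2 * at))
    x[f > 2 * at] <- 0
    pmax(x, 0)
  }
  tri_at <- mitral_peak_frame + offset_frames
  landmark_curves(
    time = f * frame_interval,
    tricuspid_lateral = bump(tapse_peak, tri_at),
    mitral_lateral = bump(mitral_peak, mitral_peak_frame),
    strain = bump(strain_es, es_frame))
}
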
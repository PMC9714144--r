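# Spatiotemporal velocity interpolation and numerical advection of particles
# through the periodic cardiac cycle.
#
# All particle state is carried as n x 3 matrices so that one RK4 step
# advances every particle at once; the per-seed `advect()` interface wraps
# the vectorized kernel.

# cm/s -> mm/ms
.CMS_TO_MM_MS <- 0.01

# Voxel-continuous coordinates (0-based; voxel centers at integers).
.to_voxel_coords <- function(field, positions) {
  sweep(positions, 2, field$voxel_size, "/")
}

# Rows of `pv` inside the grid bounding box [0, n-1] per axis (small slack
# for floating-point round-off at the faces).
.in_box <- function(field, pv, tol = 1e-9) {
  n <- field$grid_shape
  ok <- pv[, 1] >= -tol & pv[, 1] <= n[1] - 1 + tol &
        pv[, 2] >= -tol & pv[, 2] <= n[2] - 1 + tol &
        pv[, 3] >= -tol & pv[, 3] <= n[3] - 1 + tol
  ok & !is.na(ok)
}

# Trilinear gather of one stored frame at fractional voxel coordinates.
# i0/j0/k0 are 0-based lower corner indices, fx/fy/fz in [0,1].
.gather_frame <- function(vel, nshape, i0, j0, k0, fx, fy, fz, frame) {
  X <- nshape[1]; Y <- nshape[2]; Z <- nshape[3]
  out <- matrix(0, length(i0), 3L)
  plane <- X * Y * Z
  foff <- plane * 3L * frame
  for (di in 0:1) {
    wi <- if (di == 0) 1 - fx else fx
    for (dj in 0:1) {
      wj <- if (dj == 0) 1 - fy else fy
      for (dk in 0:1) {
        wk <- if (dk == 0) 1 - fz else fz
        w <- wi * wj * wk
        base <- 1 + (i0 + di) + X * ((j0 + dj) + Y * (k0 + dk)) + foff
        out[, 1] <- out[, 1] + w * vel[base]
        out[, 2] <- out[, 2] + w * vel[base + plane]
        out[, 3] <- out[, 3] + w * vel[base + 2L * plane]
      }
    }
  }
  out
}

# Vectorized interpolation kernel: returns n x 3 velocities (cm/s); rows
# outside the bounding box are NA.
.interp_velocity <- function(field, positions, time) {
  pv <- .to_voxel_coords(field, positions)
  ok <- .in_box(field, pv)
  n <- nrow(positions)
  out <- matrix(NA_real_, n, 3L)
  if (!any(ok)) return(out)
  pv <- pv[ok, , drop = FALSE]
  nshape <- field$grid_shape
  # clamp so the upper grid face uses the last cell with fraction 1
  i0 <- pmin(pmax(floor(pv[, 1]), 0), nshape[1] - 2L)
  j0 <- pmin(pmax(floor(pv[, 2]), 0), nshape[2] - 2L)
  k0 <- pmin(pmax(floor(pv[, 3]), 0), nshape[3] - 2L)
  fx <- pmin(pmax(pv[, 1] - i0, 0), 1)
  fy <- pmin(pmax(pv[, 2] - j0, 0), 1)
  fz <- pmin(pmax(pv[, 3] - k0, 0), 1)
  T_ <- field$n_frames
  tv <- (time / field$frame_interval) %% T_
  f0 <- floor(tv)
  wt <- tv - f0
  f0 <- as.integer(f0) %% T_
  f1 <- (f0 + 1L) %% T_  # periodic wrap: frame T == frame 0
  v0 <- .gather_frame(field$velocity, nshape, i0, j0, k0, fx, fy, fz, f0)
  v <- if (wt < 1e-12) v0 else {
    v1 <- .gather_frame(field$velocity, nshape, i0, j0, k0, fx, fy, fz, f1)
    (1 - wt) * v0 + wt * v1
  }
  out[ok, ] <- v
  out
}

#' Interpolate the velocity field at arbitrary positions and time
#'
#' Trilinear in space, linear in time between the two bracketing cardiac
#' phases; the cycle is periodic, so any real time is wrapped modulo the
#' cycle duration. At a voxel center on a frame time the stored vector is
#' reproduced exactly.
#'
#' @param field A [velocity_field()].
#' @param position Length-3 position in mm, or an n x 3 matrix of positions.
#' @param time Time in ms (single value).
#' @return Velocity in cm/s: length-3 vector for a single position (error of
#'   class `flow4d_out_of_grid` if outside the bounding box), or an n x 3
#'   matrix with NA rows for out-of-grid positions.
#' @export
interpolate_velocity <- function(field, position, time) {
  single <- is.null(dim(position))
  pos <- if (single) matrix(position, 1L, 3L) else as.matrix(position)
  v <- .interp_velocity(field, pos, time)
  if (single) {
    if (anyNA(v))
      stop(structure(class = c("flow4d_out_of_grid", "error", "condition"),
                     list(message = "position outside grid bounding box",
                          call = sys.call(-1))))
    return(drop(v))
  }
  v
}

# One vectorized RK4 step of size h (ms, signed) starting at time t.
# Returns list(pos = new positions, ok = particles still integrable).
.rk4_step <- function(field, pos, t, h) {
  f <- function(p, tt) .CMS_TO_MM_MS * .interp_velocity(field, p, tt)
  k1 <- f(pos, t)
  k2 <- f(pos + (h / 2) * k1, t + h / 2)
  k3 <- f(pos + (h / 2) * k2, t + h / 2)
  k4 <- f(pos + h * k3, t + h)
  new <- pos + (h / 6) * (k1 + 2 * k2 + 2 * k3 + k4)
  ok <- !(is.na(k1[, 1]) | is.na(k2[, 1]) | is.na(k3[, 1]) | is.na(k4[, 1]))
  list(pos = new, ok = ok)
}

#' Advect many particles through the velocity field
#'
#' Fixed-step classic fourth-order Runge-Kutta integration from `t0` to `t1`
#' (backward when `t1 < t0`), with positions recorded at the seed time and at
#' every frame time crossed. A particle whose integration sub-step exits the
#' grid bounding box is frozen at its last computed position and flagged
#' `left_grid`; it stays frozen for the remaining samples.
#'
#' @param field A [velocity_field()].
#' @param seeds n x 3 matrix of seed positions in mm.
#' @param t0,t1 Integration endpoints in ms (`t1 < t0` integrates backward).
#' @param dt Sub-step size in ms (positive); values above the frame interval
#'   are clamped to it with a warning. Default `frame_interval / 5`.
#' @return List with `times` (recorded times, ms), `positions`
#'   (n x 3 x n_samples array), `in_grid` (n x n_samples logical) and
#'   `status` (`"complete"` or `"left_grid"` per particle).
#' @export
advect_particles <- function(field, seeds, t0, t1, dt = field$frame_interval / 5) {
  seeds <- as.matrix(seeds)
  stopifnot(ncol(seeds) == 3L)
  if (dt <= 0) stop("dt must be > 0")
  if (dt > field$frame_interval) {
    warning("dt larger than frame interval; clamped")
    dt <- field$frame_interval
  }
  dir <- sign(t1 - t0)
  if (dir == 0) stop("t0 and t1 must differ")
  dl <- field$frame_interval
  # frame times strictly beyond t0 up to t1, plus the endpoints
  k0 <- if (dir > 0) floor(t0 / dl + 1e-9) + 1 else ceiling(t0 / dl - 1e-9) - 1
  frames <- seq(k0 * dl, t1, by = dir * dl)
  frames <- frames[if (dir > 0) frames <= t1 + 1e-9 else frames >= t1 - 1e-9]
  times <- c(t0, frames)
  if (abs(times[length(times)] - t1) > 1e-9) times <- c(times, t1)
  n <- nrow(seeds)
  ns <- length(times)
  pos <- seeds
  alive <- rep(TRUE, n)
  res <- array(NA_real_, c(n, 3L, ns))
  in_grid <- matrix(FALSE, n, ns)
  res[, , 1] <- pos
  in_grid[, 1] <- .in_box(field, .to_voxel_coords(field, pos))
  alive <- alive & in_grid[, 1]
  for (s in 2:ns) {
    gap <- times[s] - times[s - 1]
    n_sub <- max(1L, ceiling(abs(gap) / dt - 1e-9))
    h <- gap / n_sub
    t <- times[s - 1]
    for (sub in seq_len(n_sub)) {
      if (any(alive)) {
        idx <- which(alive)
        st <- .rk4_step(field, pos[idx, , drop = FALSE], t, h)
        moved <- idx[st$ok]
        pos[moved, ] <- st$pos[st$ok, , drop = FALSE]
        alive[idx[!st$ok]] <- FALSE
        # a completed step may still land outside the box
        out_now <- moved[!.in_box(field, .to_voxel_coords(
          field, pos[moved, , drop = FALSE]))]
        alive[out_now] <- FALSE
      }
      t <- t + h
    }
    res[, , s] <- pos
    in_grid[, s] <- alive
  }
  list(times = times, positions = res, in_grid = in_grid,
       status = ifelse(alive, "complete", "left_grid"))
}

#' Advect a single particle, returning a pathline
#'
#' @inheritParams advect_particles
#' @param seed Length-3 seed position in mm.
#' @return An object of class `pathline`: time-ordered `(time, position)`
#'   samples at frame resolution, `in_grid` flags, `status`, and (after
#'   [flag_pathline()]) per-sample `inside` flags for the seeding ventricle.
#' @export
advect <- function(field, seed, t0, t1, dt = field$frame_interval / 5) {
  tr <- advect_particles(field, matrix(seed, 1L, 3L), t0, t1, dt)
  structure(list(seed = as.numeric(seed),
                 times = tr$times,
                 positions = matrix(tr$positions[1, , ], ncol = 3L, byrow = TRUE),
                 in_grid = tr$in_grid[1, ],
                 inside = NULL,
                 status = tr$status[1]),
            class = "pathline")
}

#' @export
print.pathline <- function(x, ...) {
  cat(sprintf("pathline: %d samples over [%.1f, %.1f] ms, status %s\n",
              length(x$times), x$times[1], x$times[length(x$times)], x$status))
  invisible(x)
}

#' Mask labels at arbitrary positions (nearest voxel, nearest frame)
#'
#' Labels are categorical, so lookups use nearest-voxel / nearest-frame
#' membership with no interpolation. Out-of-grid positions get label 0.
#'
#' @param mask A [phase_mask()].
#' @param positions n x 3 matrix of positions in mm.
#' @param time Time in ms (wrapped periodically, rounded to nearest frame).
#' @return Integer label vector (0 = background, 1 = LV, 2 = RV).
#' @export
mask_labels_at <- function(mask, positions, time) {
  positions <- as.matrix(positions)
  iv <- round(sweep(positions, 2, mask$voxel_size, "/"))
  n <- mask$grid_shape
  ok <- iv[, 1] >= 0 & iv[, 1] < n[1] &
        iv[, 2] >= 0 & iv[, 2] < n[2] &
        iv[, 3] >= 0 & iv[, 3] < n[3]
  frame <- as.integer(round(time / mask$frame_interval)) %% mask$n_frames
  lab <- integer(nrow(positions))
  idx <- 1 + iv[ok, 1] + n[1] * (iv[ok, 2] + n[2] * (iv[ok, 3] + n[3] * frame))
  lab[ok] <- mask$labels[idx]
  lab
}

#' Attach inside-ventricle flags to a pathline
#'
#' @param path A `pathline`.
#' @param mask A [phase_mask()] on the same grid.
#' @param ventricle `"LV"` or `"RV"`.
#' @return The pathline with `inside` logical flags per recorded sample
#'   (FALSE once the particle has left the grid).
#' @export
flag_pathline <- function(path, mask, ventricle) {
  code <- MASK_LABELS[[match.arg(ventricle, c("LV", "RV"))]]
  inside <- vapply(seq_along(path$times), function(s)
    path$in_grid[s] &&
      mask_labels_at(mask, path$positions[s, , drop = FALSE],
                     path$times[s]) == code,
    TRUE)
  path$inside <- inside
  path
}

#' Seed particles at labelled voxel centers
#'
#' Seeds are placed at the voxel centers of the ventricle label at the given
#' frame, optionally on a coarser sub-lattice, in deterministic lexicographic
#' `(i, j, k)` order. Seed count times voxel volume times `spacing^3`
#' approximates the chamber volume at the frame.
#'
#' @param mask A [phase_mask()].
#' @param frame Frame index (0-based), normally the end-diastolic frame.
#' @param ventricle `"LV"` or `"RV"`.
#' @param spacing Integer >= 1; 1 seeds every labelled voxel.
#' @return n x 3 matrix of seed positions in mm, with 0-based voxel indices
#'   in attribute `"voxel"`.
#' @export
seed_particles <- function(mask, frame, ventricle, spacing = 1L) {
  spacing <- as.integer(spacing)
  if (spacing < 1L) stop("spacing must be an integer >= 1")
  code <- MASK_LABELS[[match.arg(ventricle, c("LV", "RV"))]]
  vol <- mask$labels[, , , frame + 1L, drop = TRUE]
  dim(vol) <- mask$grid_shape
  hit <- which(vol == code, arr.ind = TRUE) - 1L  # 0-based voxel indices
  if (nrow(hit) == 0) stop(sprintf("no %s voxels at frame %d", ventricle, frame))
  keep <- hit[, 1] %% spacing == 0L & hit[, 2] %% spacing == 0L &
          hit[, 3] %% spacing == 0L
  hit <- hit[keep, , drop = FALSE]
  hit <- hit[order(hit[, 1], hit[, 2], hit[, 3]), , drop = FALSE]
  seeds <- sweep(hit, 2, mask$voxel_size, "*")
  dimnames(seeds) <- NULL
  attr(seeds, "voxel") <- hit
  seeds
}
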
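# Shared builders for small in-code fixtures.

# Constant-velocity field on a small grid (speed in cm/s).
uniform_test_field <- function(speed = c(10, 0, 0), dims = c(8L, 8L, 8L),
                               n_frames = 10L, voxel = 2, dt = 40) {
  vel <- array(0, c(dims, 3L, n_frames))
  for (c_i in 1:3) vel[, , , c_i, ] <- speed[c_i]
  velocity_field(vel, rep(voxel, 3), dt, venc = 150)
}

# Static single-ventricle box mask filling the whole grid.
full_box_mask <- function(dims = c(8L, 8L, 8L), n_frames = 10L,
                          voxel = 2, dt = 40, ventricle = "RV") {
  code <- c(LV = 1L, RV = 2L)[[ventricle]]
  labels <- array(code, c(dims, n_frames))
  phase_mask(labels, rep(voxel, 3), dt)
}

# Hand-built pathline with given inside flags (for classification tests).
fake_pathline <- function(inside) {
  structure(list(seed = c(0, 0, 0),
                 times = seq_along(inside) - 1,
                 positions = matrix(0, length(inside), 3),
                 in_grid = rep(TRUE, length(inside)),
                 inside = inside, status = "complete"),
            class = "pathline")
}

# Brute-force Youden threshold search: direct enumeration over observed
# cut-points with explicit sensitivity/specificity counting.
brute_force_youden <- function(x, y) {
  cuts <- sort(unique(x))
  best <- NULL
  for (c_ in cuts) {
    sens <- sum(x[y] >= c_) / sum(y)
    spec <- sum(x[!y] < c_) / sum(!y)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && spec > best$spec))
      best <- list(threshold = c_, j = j, sens = sens, spec = spec)
  }
  best
}
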
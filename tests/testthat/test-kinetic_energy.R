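test_that("uniform-speed KE matches the closed form", {
  # KE = 1/2 * rho * V * |v|^2: at |v| = 0.1 m/s, rho = 1060 kg/m^3 a
  # 100 ml pool carries 530 uJ, i.e. 5.3 uJ per ml of pool
  f <- uniform_test_field(speed = c(10, 0, 0), dims = c(10L, 10L, 10L),
                          n_frames = 6L, voxel = 2, dt = 40)
  labels <- array(0L, c(10, 10, 10, 6))
  labels[1:5, 1:5, 1:5, ] <- 2L  # 125 voxels x 8 mm^3 = 1 ml
  m <- phase_mask(labels, rep(2, 3), 40)
  ke <- ke_curve(f, m, "RV", rho = 1060)
  vol_ml <- 125 * 8 / 1000
  expect_equal(ke, rep(530 * vol_ml / 100, 6), tolerance = 1e-12)

  zero <- uniform_test_field(speed = c(0, 0, 0), dims = c(10L, 10L, 10L),
                             n_frames = 6L)
  expect_equal(ke_curve(zero, m, "RV"), rep(0, 6))
})

test_that("KEI_EDV identities hold exactly", {
  ph <- make_phantom(phantom_spec("uniform", speed = c(10, 0, 0)))
  ke <- ke_curve(ph$field, ph$mask, "RV")
  kei <- kei_edv(ke, edv(ph$mask, "RV"))
  # static mask: mask volume = EDV, so KEI_EDV = 1/2 rho |v|^2 in J/m^3
  expect_equal(kei, rep(ph$ground_truth$kei_edv_uj_ml, ph$field$n_frames),
               tolerance = 1e-12)
  # halving EDV with fixed KE doubles KEI_EDV
  expect_equal(kei_edv(ke, 50), 2 * kei_edv(ke, 100))
  expect_error(kei_edv(ke, 0), "edv")
})

test_that("KE sums are invariant under axis relabelling of the velocity", {
  set.seed(5)
  dims <- c(6L, 6L, 6L); nf <- 4L
  vel <- array(rnorm(prod(dims) * 3 * nf, sd = 20), c(dims, 3L, nf))
  f1 <- velocity_field(vel, rep(2, 3), 30)
  rot <- vel[, , , c(2, 3, 1), , drop = FALSE]  # permute components
  rot[, , , 1, ] <- -rot[, , , 1, ]             # plus a flip: rigid rotation
  f2 <- velocity_field(rot, rep(2, 3), 30)
  labels <- array(0L, c(dims, nf)); labels[2:5, 2:5, 2:5, ] <- 1L
  m <- phase_mask(labels, rep(2, 3), 30)
  expect_equal(ke_curve(f1, m, "LV"), ke_curve(f2, m, "LV"), tolerance = 1e-12)
})

test_that("voxel-sum KE matches the analytic integral for a linear shear", {
  # v_x = g * y over a box: KE = 1/2 rho g^2 integral(y^2) dV; the voxel sum
  # is the midpoint rule, within 0.5% of the closed form at this resolution
  dims <- c(8L, 20L, 8L); nf <- 3L; vox <- 2
  g <- 1.5  # (cm/s) per mm
  vel <- array(0, c(dims, 3L, nf))
  for (j in seq_len(dims[2])) vel[, j, , 1, ] <- g * (j - 1) * vox
  f <- velocity_field(vel, rep(vox, 3), 30)
  labels <- array(0L, c(dims, nf)); labels[, , , ] <- 2L
  m <- phase_mask(labels, rep(vox, 3), 30)
  ke <- ke_curve(f, m, "RV", rho = 1060)[1]
  y_max <- dims[2] * vox  # integrate voxel extents [0, y_max) about centers
  area <- dims[1] * dims[3] * vox^2
  integral <- area * (y_max^3 / 3 - y_max^2 * vox / 2 + y_max * vox^2 / 4)
  ke_exact <- 0.5 * 1060 * (g / 100)^2 * integral * 1e-9 * 1e6
  expect_equal(ke, ke_exact, tolerance = 5e-3)
})

test_that("phase landmarks follow the volume-curve rule", {
  lmk <- phase_landmarks(c(100, 80, 60, 50, 70, 90))
  expect_equal(lmk$ed_frame, 0L)
  expect_equal(lmk$es_frame, 3L)
  expect_equal(sort(lmk$e_wave_window), c(4, 5))  # first half of diastole

  saw <- phase_landmarks(c(60, 80, 120, 90, 70, 50, 55, 58))
  expect_equal(saw$ed_frame, 2L)
  expect_equal(saw$es_frame, 5L)

  ties <- phase_landmarks(c(90, 100, 70, 100, 60, 60))
  expect_equal(ties$ed_frame, 1L)  # earliest maximum
  expect_equal(ties$es_frame, 4L)  # earliest minimum
  expect_error(phase_landmarks(rep(5, 6)), "non-constant")
})

test_that("phasic extraction takes the right extrema and averages", {
  lmk <- list(ed_frame = 0L, es_frame = 2L, systole_frames = 2L,
              e_wave_window = 4L)
  ph <- extract_phasic(c(4, 6, 5, 2, 9, 3), lmk)
  expect_equal(ph$peak_systolic, 6)
  expect_equal(ph$average_systolic, 5)
  expect_equal(ph$peak_e_wave, 9)

  const <- extract_phasic(rep(7, 6), lmk)
  expect_equal(unlist(const), c(peak_systolic = 7, average_systolic = 7,
                                peak_e_wave = 7))
  expect_error(extract_phasic(1:6, list(ed_frame = 0L, es_frame = 2L,
                                        systole_frames = 2L,
                                        e_wave_window = integer(0))),
               "empty")
})

test_that("average systolic KEI never exceeds the peak on random curves", {
  set.seed(21)
  for (i in 1:20) {
    vols <- 80 + cumsum(rnorm(12))  # jittered volume curve
    vols[which.max(vols)] <- max(vols) + 1  # ensure non-constant
    lmk <- phase_landmarks(vols)
    kei <- rexp(12, 0.1)
    ph <- extract_phasic(kei, lmk)
    expect_lte(ph$average_systolic, ph$peak_systolic)
  }
})

test_that("a sinusoidal phantom speed yields the expected phasic peaks", {
  # programmed speed |v|(f) = s0 * |sin(pi f / T)|: KE peaks at the frame
  # closest to the analytic extremum of the systolic window
  dims <- c(6L, 6L, 6L); nf <- 20L
  s0 <- 40
  vel <- array(0, c(dims, 3L, nf))
  speeds <- s0 * abs(sin(pi * (0:(nf - 1)) / nf))
  for (f_ in seq_len(nf)) vel[, , , 1, f_] <- speeds[f_]
  fld <- velocity_field(vel, rep(2, 3), 30)
  labels <- array(0L, c(dims, nf)); labels[2:5, 2:5, 2:5, ] <- 2L
  m <- phase_mask(labels, rep(2, 3), 30)
  kei <- kei_edv(ke_curve(fld, m, "RV"), edv(m, "RV"))
  lmk <- list(ed_frame = 0L, es_frame = 12L, systole_frames = 12L,
              e_wave_window = 13:16)
  ph <- extract_phasic(kei, lmk)
  # analytic systolic max at f = T/2 = frame 10
  expect_equal(which.max(kei[1:13]) - 1L, 10L)
  expect_equal(ph$peak_systolic, max(kei[11]), tolerance = 1e-12)
})
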
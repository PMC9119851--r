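test_that("envelope + modulation reconstructs the stack exactly", {
  stk <- fx_stack()
  dec <- fx_dyn()$dec
  expect_equal(dec$env + dec$mod, stk$data, tolerance = 1e-12)
})

test_that("decomposition separates envelope from modulation", {
  # pure envelope (decaying to ~zero at the stack edges): no modulation
  # survives the split
  z <- seq(-1400, 1400, by = 20)
  env <- exp(-z^2 / (2 * 350^2))
  stk <- bead_stack(array(rep(env, each = 9), dim = c(3, 3, length(z), 1)),
                    voxel = c(100, 100, 20), channels = "c1")
  dec <- decompose_psf(stk)
  expect_lt(max(abs(dec$mod)), 1e-3 * max(dec$env))

  # E(z) (1 + cos kz): the modulation component recovers E(z) cos(kz)
  k <- 2 * pi / 252.6
  full <- env * (1 + cos(k * z))
  stk2 <- bead_stack(array(rep(full, each = 9),
                           dim = c(3, 3, length(z), 1)),
                     voxel = c(100, 100, 20), channels = "c1")
  dec2 <- decompose_psf(stk2)
  interior <- 25:116
  expect_equal(dec2$mod[2, 2, interior, 1],
               (env * cos(k * z))[interior], tolerance = 0.02)
  # Hilbert quadrature of cos is sin
  expect_equal(dec2$mod90[2, 2, interior, 1],
               (env * sin(k * z))[interior], tolerance = 0.05)
})

test_that("phase shifts are identities at 0 and 2 pi and compose", {
  dec <- fx_dyn()$dec
  stk <- fx_stack()
  s0 <- phase_shift_psf(dec, 0)
  expect_equal(s0$data, stk$data, tolerance = 1e-12)
  s2pi <- phase_shift_psf(dec, 2 * pi)
  expect_lt(max(abs(s2pi$data - stk$data)), 1e-3 * max(stk$data))
  # composition: shift by a then b equals one shift by a + b
  a <- 0.7; b <- 1.9
  sab <- phase_shift_psf(decompose_psf(phase_shift_psf(dec, a)), b)
  s_direct <- phase_shift_psf(dec, a + b)
  interior <- 20:130
  expect_lt(max(abs(sab$data[, , interior, ] -
                      s_direct$data[, , interior, ])),
            1e-3 * max(stk$data))
})

test_that("numerical phase shifting matches a PSF generated at that phase", {
  dec <- fx_dyn()$dec
  cfg2 <- fx_cfg()
  cfg2$phase <- 0.8
  target <- make_symmetric_4pi_psf(cfg2, n_xy = 17, n_z = 150, z_step = 20)
  shifted <- phase_shift_psf(dec, 0.8)
  interior <- 25:125
  expect_lt(max(abs(shifted$data[, , interior, ] -
                      target$data[, , interior, ])) / max(target$data),
            0.01)
})

test_that("the phase estimate is zero for images from the base model", {
  dyn <- fx_dyn()
  ims <- sim_images(psf_at_phase(dyn, 0), 60, seed = 21)
  est <- estimate_phase(ims, dyn, z_start_range = c(-250, 250))
  expect_lt(abs(wrap_angle(est$phase)), 3 * max(est$precision, 0.02))
  expect_false(est$low_confidence)
})

test_that("the sine-fit minimum agrees with a dense model scan", {
  dyn <- fx_dyn()
  phi <- 1.3
  ims <- sim_images(psf_at_phase(dyn, phi), 80, seed = 22)
  est <- estimate_phase(ims, dyn, z_start_range = c(-250, 250))
  dense <- estimate_phase(ims, dyn, n_phase_models = 36,
                          z_start_range = c(-250, 250))
  expect_lt(abs(wrap_angle(est$phase - dense$phase)), 0.05)
  expect_lt(abs(wrap_angle(est$phase - phi)), 0.15)
})

test_that("a phase trace recovers injected drift and stays flat without", {
  dyn <- fx_dyn()
  phis <- c(0.9, 1.15, 1.4)
  ims <- list()
  withr::with_seed(23, {
    for (w in seq_along(phis)) for (i in 1:80) {
      im <- simulate_emitter_image(
        psf_at_phase(dyn, phis[w]),
        ground_truth_emitter(x = runif(1, -60, 60), y = runif(1, -60, 60),
                             z = runif(1, -100, 100), photons = 8000,
                             background = 10))
      im$time <- (w - 1) * 100 + i
      ims[[length(ims) + 1]] <- im
    }
  })
  tr <- phase_trace(ims, dyn, window = 80, z_start_range = c(-250, 250))
  expect_equal(nrow(tr), 3)
  slope_true <- (phis[3] - phis[1]) / (tr$time[3] - tr$time[1])
  slope_est <- (tr$phase[3] - tr$phase[1]) / (tr$time[3] - tr$time[1])
  prec <- sqrt(tr$precision[1]^2 + tr$precision[3]^2) /
    (tr$time[3] - tr$time[1])
  expect_lt(abs(slope_est - slope_true), 2 * prec + 0.2 * slope_true)
  # per-window estimates track the injected values
  expect_lt(max(abs(wrap_angle(tr$phase - phis))), 0.15)
})

test_that("phase-to-z calibration matches the fringe geometry", {
  dyn <- fx_dyn()
  cal <- calibrate_phase_to_z(dyn)
  p <- dyn$template$fringe_period
  expect_equal(cal$slope, -p / (2 * pi), tolerance = 0.05)
  expect_gt(cal$r_squared, 0.99)
  expect_false(cal$nonlinear)
  # slope consistent across the sliced planes
  expect_lt(max(abs(cal$per_plane - cal$slope)) / abs(cal$slope), 0.05)
  expect_error(calibrate_phase_to_z(dyn, phase_span = 0), "degenerate")
})

test_that("phase-drift correction is exact for flat and stepped traces", {
  cal <- list(slope = -40.2)
  locs <- data.frame(z = c(100, 200, 300), time = c(1, 2, 3))
  flat <- data.frame(time = c(0, 4), phase = c(1.2, 1.2),
                     precision = 0.01, n = 100)
  out <- correct_phase_drift(locs, flat, cal, reference_phase = 1.2)
  expect_equal(out$z, locs$z)
  # a 0.5 rad phase step shifts z by slope * 0.5
  stepped <- data.frame(time = c(0.9, 1.1, 2.9, 3.1),
                        phase = c(1.2, 1.2, 1.7, 1.7),
                        precision = 0.01, n = 100)
  out2 <- correct_phase_drift(locs, stepped, cal, reference_phase = 1.2)
  expect_equal(out2$z[1] - locs$z[1], 0)
  expect_equal(out2$z[3] - locs$z[3], -cal$slope * 0.5)
})
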
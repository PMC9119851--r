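test_that("a known quadratic warp is recovered from bead pairs", {
  set.seed(41)
  n <- 40
  x <- runif(n, 0, 4000); y <- runif(n, 0, 4000)
  wx <- 5 + 1.001 * x + 0.002 * y + 1e-6 * x^2 - 5e-7 * x * y + 2e-7 * y^2
  wy <- -3 + 0.999 * y + 0.001 * x - 8e-7 * y^2 + 3e-7 * x * y
  pairs <- data.frame(x_ref = x, y_ref = y,
                      x = wx + rnorm(n), y = wy + rnorm(n))
  tr <- fit_channel_transform(pairs)
  # held-out residual at the injected 1 nm/axis noise level
  expect_lt(tr$rmsd, 2)
  expect_false(tr$rmsd_insample)
  pred <- apply_transform(tr, x, y)
  expect_lt(sqrt(mean((pred[, 1] - wx)^2 + (pred[, 2] - wy)^2)), 1)

  # identity mapping, zero residual
  tr0 <- fit_channel_transform(data.frame(x_ref = x, y_ref = y,
                                          x = x, y = y))
  expect_lt(tr0$rmsd, 1e-9)
  # collinear bead geometry is degenerate
  expect_error(fit_channel_transform(
    data.frame(x_ref = 1:10, y_ref = 2 * (1:10),
               x = 1:10, y = 2 * (1:10))), "degenerate")
  expect_error(fit_channel_transform(pairs[1:5, ]), "6")
})

test_that("cubic-convolution warping is exact for identity and shifts", {
  set.seed(42)
  img <- outer(dnorm(seq(-2, 2, length.out = 40), sd = 1.2),
               dnorm(seq(-2.2, 1.8, length.out = 40), sd = 1.2))
  w0 <- warp_channel(img, NULL)
  interior <- !attr(w0, "fill_mask")
  expect_identical(w0[interior], img[interior])

  xy <- expand.grid(x = seq(2, 38, by = 4), y = seq(2, 38, by = 4))
  tr <- fit_channel_transform(data.frame(x_ref = xy$x, y_ref = xy$y,
                                         x = xy$x + 4, y = xy$y - 3))
  ws <- warp_channel(img, tr)
  ok <- which(!attr(ws, "fill_mask"), arr.ind = TRUE)
  ok <- ok[ok[, 1] + 4 <= 40 & ok[, 2] - 3 >= 1, ]
  expect_equal(ws[ok], img[cbind(ok[, 1] + 4, ok[, 2] - 3)],
               tolerance = 1e-12)

  # sub-pixel warp then inverse warp returns the smooth interior
  trs <- fit_channel_transform(data.frame(x_ref = xy$x, y_ref = xy$y,
                                          x = xy$x + 1.37, y = xy$y + 0.58))
  tri <- fit_channel_transform(data.frame(x_ref = xy$x, y_ref = xy$y,
                                          x = xy$x - 1.37, y = xy$y - 0.58))
  rt <- warp_channel(warp_channel(img, trs), tri)
  core <- 8:32
  expect_lt(max(abs(rt[core, core] - img[core, core])),
            1e-3 * max(img))
  # intensity is preserved over the interior
  expect_equal(sum(warp_channel(img, trs)[5:35, 5:35]),
               sum(img[5 + 1:31, 5 + 0:30]), tolerance = 1e-2)
})

test_that("redundant cross-correlation recovers injected 3D drift", {
  set.seed(43)
  nl <- 4000
  tt <- runif(nl, 0, 100)
  drift <- cbind(30 * sin(tt / 40), 20 * (tt / 100), 15 * cos(tt / 50))
  locs <- data.frame(
    x = rnorm(nl, rep(c(-200, 0, 300), length.out = nl), 15) + drift[, 1],
    y = rnorm(nl, rep(c(100, -250, 50), length.out = nl), 15) + drift[, 2],
    z = rnorm(nl, rep(c(0, 80, -90), length.out = nl), 10) + drift[, 3],
    time = tt)
  traj <- estimate_sample_drift(locs, n_windows = 6, voxel = 10)
  truth <- cbind(30 * sin(traj$time / 40), 20 * (traj$time / 100),
                 15 * cos(traj$time / 50))
  truth <- sweep(truth, 2, truth[1, ])
  est <- as.matrix(traj[, c("dx", "dy", "dz")])
  expect_lt(sqrt(mean((est - truth)^2)), 10 / 4) # render voxel / 4

  # idempotence: re-estimating after correction gives ~zero drift
  corr <- apply_drift_correction(locs, traj)
  traj2 <- estimate_sample_drift(corr, n_windows = 6, voxel = 10)
  expect_lt(max(abs(as.matrix(traj2[, c("dx", "dy", "dz")]))), 10 / 2)

  # zero drift in, ~zero trajectory out
  locs0 <- locs
  for (ax in 1:3) locs0[[c("x", "y", "z")[ax]]] <-
      locs0[[c("x", "y", "z")[ax]]] - drift[, ax]
  traj0 <- estimate_sample_drift(locs0, n_windows = 6, voxel = 10)
  expect_lt(max(abs(as.matrix(traj0[, c("dx", "dy", "dz")]))), 10 / 2)
})

test_that("z rescaling applies the wavelength and index factors", {
  iwc <- index_wavelength_config()
  locs <- data.frame(z = c(100, -200, 350))
  out <- rescale_z(locs, iwc, "AF647")
  f <- (680 / 712) * (1.346 / 1.406)
  expect_equal(out$z, locs$z * f)
  expect_equal(unname(attr(out, "z_rescale")["combined"]), f)
  # rescaling is linear and the identity when nothing differs
  out2 <- rescale_z(data.frame(z = 2 * locs$z), iwc, "AF647")
  expect_equal(out2$z, 2 * out$z)
  iwc0 <- index_wavelength_config(lambda_bead = 680,
                                  lambda_dyes = c(AF647 = 680),
                                  n_sample = 1.4, n_immersion = 1.4)
  expect_equal(rescale_z(locs, iwc0, "AF647")$z, locs$z)
  expect_error(rescale_z(locs, iwc, "FITC"), "unknown dye")
})

test_that("the stage phase-shift prediction evaluates the index formula", {
  cfg <- fx_cfg()
  expect_equal(predict_step_phase_shift(0, cfg), 0)
  same <- fourpi_config(n_immersion = 1.346)
  expect_equal(predict_step_phase_shift(700, same), 0)
  # direct evaluation at the standard constants, 500 nm step
  expect_equal(predict_step_phase_shift(500, cfg), 1.0851, tolerance = 1e-4)
  expect_equal(predict_step_phase_shift(-500, cfg), -1.0851,
               tolerance = 1e-4)
})

test_that("multistep analysis merges steps at their own phases", {
  cfg <- fx_cfg()
  dyn <- fx_dyn()
  step_dz <- 500
  sched <- data.frame(frame_start = c(1, 121), frame_end = c(120, 240),
                      stage_z = c(0, step_dz))
  # sparse activation (about one emitter on per frame), steps overlapping
  # by construction because each step sees the other's emitters defocused
  set.seed(45)
  ems <- lapply(1:16, function(i) ground_truth_emitter(
    x = runif(1, -2100, 2100), y = runif(1, -2100, 2100),
    z = runif(1, 50, 450) + ifelse(i > 8, step_dz, 0),
    frames_on = sort(sample(1:240, 14))))
  drift <- drift_traces(240, stage_z = rep(c(0, step_dz), each = 120))
  sim <- simulate_experiment(cfg, ems, drift = drift, n_frames = 240,
                             field_px = 44, seed = 45)
  out <- analyze_multistep(sim$movie, sched, dyn, cfg = cfg,
                           min_phase_locs = 15)
  log <- attr(out, "step_log")
  expect_equal(nrow(log), 2)
  # the estimated inter-step phase difference tracks the index-mismatch
  # prediction (which the simulator injects for stage steps)
  dphi_est <- wrap_angle(log$phase_hat[2] - log$phase_hat[1])
  dphi_pred <- wrap_angle(predict_step_phase_shift(step_dz, cfg))
  expect_lt(abs(dphi_est - dphi_pred), 0.2 * abs(dphi_pred))
  # merged z extent covers both steps
  expect_gt(diff(range(out$z)), step_dz * 0.8)
  # a single-step schedule reduces to the standard pipeline
  sub <- sim$movie[, , , 1:120, drop = FALSE]
  attr(sub, "pixel") <- attr(sim$movie, "pixel")
  attr(sub, "frame_time") <- attr(sim$movie, "frame_time")
  one <- analyze_multistep(
    sub, data.frame(frame_start = 1, frame_end = 120, stage_z = 0),
    dyn, cfg = cfg, min_phase_locs = 15)
  expect_true(all(one$step == 1))
  expect_gt(nrow(one), 3)
})
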
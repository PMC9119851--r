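test_that("candidates are detected on the interference-free channel sum", {
  cfg <- fx_cfg()
  em <- ground_truth_emitter(x = -300, y = 450, z = 200, frames_on = 1L)
  sim <- simulate_experiment(cfg, em, n_frames = 1, field_px = 24,
                             seed = 31)
  cands <- detect_candidates(sim$movie)
  expect_equal(nrow(cands), 1)
  px <- cfg$pixel_size_lateral
  expect_lt(abs(cands$x_px - (12.5 - 300 / px)), 1)
  expect_lt(abs(cands$y_px - (12.5 + 450 / px)), 1)

  # background-only movie yields no candidates at the default threshold
  bg <- withr::with_seed(32, array(rpois(24 * 24 * 4 * 5, 10),
                                   dim = c(24, 24, 4, 5)))
  expect_equal(nrow(detect_candidates(bg)), 0)
})

test_that("events persisting over frames are grouped and summed", {
  cfg <- fx_cfg()
  ems <- list(
    ground_truth_emitter(x = -600, y = 500, z = 100, frames_on = 2:4),
    ground_truth_emitter(x = 700, y = -650, z = -150, frames_on = 2:3))
  sim <- simulate_experiment(cfg, ems, n_frames = 5, field_px = 24,
                             seed = 33)
  ev <- group_events(detect_candidates(sim$movie), sim$movie)
  expect_equal(length(ev), 2)
  expect_setequal(vapply(ev, function(e) e$frame_count, 0), c(3, 2))
  # photon conservation: grouped counts equal the sum of per-frame crops
  e1 <- ev[[which.max(vapply(ev, function(e) e$frame_count, 0))]]
  manual <- 0
  for (fr in e1$frame_start:(e1$frame_start + e1$frame_count - 1))
    manual <- manual + sum(sim$movie[
      e1$roi_origin[1]:(e1$roi_origin[1] + 6),
      e1$roi_origin[2]:(e1$roi_origin[2] + 6), , fr])
  expect_equal(sum(e1$pixels), manual)
})

test_that("noiseless self-consistent fits recover parameters exactly", {
  psf <- fx_psf()
  th <- list(x0 = 31, y0 = -44, z0 = 287, A = 5000, b = 4)
  img <- evaluate_model(psf, th)
  fit <- fit_localization(list(structure(list(
    pixels = img, frame_start = 1, frame_count = 1, time = 0,
    roi_origin = c(NA, NA), xy0 = c(0, 0), pixel = psf$spacing[1]),
    class = "emitter_image")), psf, weighting = "none")
  expect_true(fit$converged)
  expect_equal(fit$x, 31, tolerance = 1e-6)
  expect_equal(fit$y, -44, tolerance = 1e-6)
  expect_equal(fit$z, 287, tolerance = 1e-6)
  expect_lt(fit$chi2, 1e-10)
})

test_that("multi-start finds the global minimum of the fringe landscape", {
  psf <- fx_psf()
  cfg <- fx_cfg()
  p <- psf$fringe_period
  set.seed(34)
  for (q in 1:12) {
    zt <- runif(1, -600, 600)
    im <- simulate_emitter_image(cfg, ground_truth_emitter(
      x = runif(1, -60, 60), y = runif(1, -60, 60), z = zt,
      photons = 9200, background = 10))
    fit <- fit_localization(im, psf)
    # dense restricted scans around each candidate fringe
    scan <- vapply(seq(-1200, 1200, by = p / 2), function(z0) {
      f <- fit_localization(im, psf, z_range = c(z0 - p / 3, z0 + p / 3))
      if (isTRUE(f$converged)) f$chi2 else Inf
    }, 0)
    expect_lte(fit$chi2, min(scan) * (1 + 1e-6))
    # single starts far from the optimum end in worse local minima
    wrong <- fit_localization(im, psf,
                              z_range = fit$z + p + c(-60, 60))
    expect_gt(wrong$chi2, fit$chi2)
  }
})

test_that("the CRLB scales with photons and matches numeric Fisher", {
  psf <- fx_psf()
  A <- 8000 / psf_flux(psf, 0)
  c1 <- compute_crlb(psf, c(0, 0, 0, A, 0))
  c2 <- compute_crlb(psf, c(0, 0, 0, 2 * A, 0))
  expect_equal(c2$crlb_x / c1$crlb_x, 1 / sqrt(2), tolerance = 1e-6)
  expect_equal(c2$crlb_z / c1$crlb_z, 1 / sqrt(2), tolerance = 1e-6)

  # numeric Fisher information from finite-difference model gradients
  th <- c(10, -15, 120, A, 10)
  ev <- evaluate_gradient(psf, th)
  mu <- as.numeric(ev$mu)
  h <- 1e-3
  Jnum <- vapply(1:5, function(a) {
    tp <- th; tm <- th
    tp[a] <- tp[a] + h; tm[a] <- tm[a] - h
    (as.numeric(evaluate_model(psf, tp)) -
       as.numeric(evaluate_model(psf, tm))) / (2 * h)
  }, numeric(length(mu)))
  Inum <- crossprod(Jnum / sqrt(mu))
  Iana <- crossprod(matrix(ev$J, ncol = 5) / sqrt(mu))
  expect_equal(Inum, Iana, tolerance = 1e-3)
  ca <- compute_crlb(psf, th)
  expect_equal(ca$crlb_z, sqrt(solve(Inum)[3, 3]), tolerance = 1e-3)
})

test_that("artifact bookkeeping is exact for clean and corrupted fits", {
  p <- 252.6
  fits <- data.frame(z = c(0, 100, 100 + p, -50, -50 - 2 * p, 200),
                     converged = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  truth <- c(0, 100, 100, -50, -50, 0)
  af <- artifact_fraction(fits, truth, p)
  expect_equal(af$overall, 2 / 5)
  clean <- artifact_fraction(
    data.frame(z = truth, converged = TRUE), truth, p)
  expect_equal(clean$overall, 0)
})

test_that("photon estimates are conserved within shot noise", {
  psf <- fx_psf()
  cfg <- fx_cfg()
  set.seed(35)
  ims <- lapply(1:80, function(i) simulate_emitter_image(
    cfg, ground_truth_emitter(x = runif(1, -60, 60),
                              y = runif(1, -60, 60),
                              z = runif(1, -80, 80),
                              photons = 8000, background = 10)))
  fits <- fit_localization(ims, psf, z_range = c(-300, 300))
  se <- sd(fits$photons) / sqrt(nrow(fits))
  expect_lt(abs(mean(fits$photons) - 8000), 3 * se + 0.02 * 8000)
})

test_that("the compiled LM fitter agrees with an independent optimizer", {
  skip_if_not_installed("minpack.lm")
  psf <- fx_psf()
  cfg <- fx_cfg()
  set.seed(36)
  im <- simulate_emitter_image(cfg, ground_truth_emitter(
    x = 20, y = -35, z = 140, photons = 8000, background = 10))
  ours <- fit_localization(im, psf, z_range = c(80, 200),
                           weighting = "none")
  resid_fn <- function(th) {
    as.numeric(im$pixels) -
      as.numeric(evaluate_model(psf, th))
  }
  ref <- minpack.lm::nls.lm(
    par = c(0, 0, 140, ours$A * 0.9, 8), fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  expect_equal(ours$x, ref$par[1], tolerance = 1e-3)
  expect_equal(ours$y, ref$par[2], tolerance = 1e-3)
  expect_equal(ours$z, ref$par[3], tolerance = 1e-3)
  expect_equal(ours$chi2, sum(resid_fn(ref$par)^2), tolerance = 1e-6)
})
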
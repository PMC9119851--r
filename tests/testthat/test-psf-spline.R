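test_that("bead-scan preprocessing downsamples and smooths as specified", {
  cfg <- fx_cfg()
  raw <- simulate_bead_scan(cfg, z_range = 3000, n_steps = 3000, n_xy = 21)
  out <- preprocess_bead_scan(raw)
  expect_equal(dim(out$data), c(17L, 17L, 300L, 4L))
  expect_equal(out$voxel[3], 10)

  # a z-constant stack passes through the filters unchanged
  lat <- outer(exp(-((1:19 - 10)^2) / 20), exp(-((1:19 - 10)^2) / 20))
  const <- bead_stack(array(rep(lat, 200 * 4), dim = c(19, 19, 200, 4)),
                      voxel = c(100, 100, 10))
  outc <- preprocess_bead_scan(const, downsample = 4)
  expect_equal(outc$data[, , 10, 2], lat[2:18, 2:18], tolerance = 1e-12)

  # cosine attenuation matches a direct convolution oracle
  k <- 2 * pi / 252.6
  nz <- 1200
  prof <- 2 + cos(k * (1:nz))
  gxy <- exp(-((1:17 - 9)^2) / 18)
  lat <- outer(gxy, gxy)
  arr <- aperm(array(outer(prof, as.numeric(lat)),
                     dim = c(nz, 17, 17)), c(2, 3, 1))
  stk <- bead_stack(array(arr, dim = c(17, 17, nz, 1)),
                    voxel = c(138.2, 138.2, 2.5), channels = "c1")
  sm <- preprocess_bead_scan(stk, downsample = 4, smooth_nm = 50)
  # oracle: average in blocks of 4, then a 5-plane boxcar (50 nm / 10 nm)
  box <- function(x, w) as.numeric(stats::filter(x, rep(1 / w, w)))
  down <- colMeans(matrix(prof, nrow = 4))
  ref <- box(down, round(50 / 10))
  mid <- 40:260
  expect_equal(sm$data[9, 9, mid, 1], ref[mid], tolerance = 1e-10)

  # off-center bead rejected with a diagnostic
  shifted <- raw
  shifted$data <- raw$data[c(12:21, 1:11), , , , drop = FALSE]
  lat <- apply(shifted$data, c(1, 2), sum)
  if (which(lat == max(lat), arr.ind = TRUE)[1, 1] <= 2)
    expect_error(preprocess_bead_scan(shifted), "border")
})

test_that("spline coefficient bookkeeping matches the cell structure", {
  psf <- fx_psf()
  expect_equal(n_spline_coefficients(psf), 64 * 16 * 16 * 149 * 4)
  expect_equal(dim(psf$coef), c(64L, 16L, 16L, 149L, 4L))
})

test_that("constant and trilinear volumes are reproduced exactly", {
  const <- bead_stack(array(2.25, dim = c(5, 5, 6, 1)),
                      voxel = c(100, 100, 50), channels = "c1")
  ps <- compute_spline_coefficients(const)
  expect_equal(ps$coef[1, , , , 1], array(2.25, dim = c(4, 4, 5)))
  expect_lt(max(abs(ps$coef[-1, , , , 1])), 1e-12)

  g <- expand.grid(x = 1:7, y = 1:7, z = 1:8)
  ramp <- array(1 + 0.3 * g$x - 0.2 * g$y + 0.05 * g$z, dim = c(7, 7, 8))
  stk <- bead_stack(array(ramp, dim = c(7, 7, 8, 1)),
                    voxel = c(50, 50, 25), channels = "c1")
  ps <- compute_spline_coefficients(stk)
  set.seed(3)
  for (q in 1:20) {
    x <- runif(1, ps$origin[1], ps$origin[1] + 6 * 50)
    y <- runif(1, ps$origin[2], ps$origin[2] + 6 * 50)
    z <- runif(1, ps$origin[3], ps$origin[3] + 7 * 25)
    ref <- 1 + 0.3 * ((x - ps$origin[1]) / 50 + 1) -
      0.2 * ((y - ps$origin[2]) / 50 + 1) +
      0.05 * ((z - ps$origin[3]) / 25 + 1)
    expect_equal(spline_value(ps, x, y, z, 1), ref, tolerance = 1e-10)
  }
})

test_that("the spline interpolates the stack at every knot", {
  stk <- fx_stack()
  psf <- fx_psf()
  xs <- stack_xy <- (1:17 - 9) * stk$voxel[1]
  zc <- stk$z_origin + (0:149) * stk$voxel[3]
  mx <- max(stk$data)
  for (ch in c(1, 4)) for (iz in c(1, 40, 75, 150)) {
    v <- spline_value(psf, rep(xs, 17), rep(xs, each = 17), zc[iz], ch)
    expect_lt(max(abs(v - as.numeric(stk$data[, , iz, ch]))) / mx, 1e-6)
  }
})

test_that("value and first derivatives are continuous across cell faces", {
  psf <- fx_psf()
  set.seed(4)
  eps <- 1e-7
  for (q in 1:30) {
    # a random point on a random z-cell face
    kz <- sample(2:148, 1)
    zf <- psf$origin[3] + (kz - 1) * psf$spacing[3]
    x <- runif(1, -900, 900); y <- runif(1, -900, 900)
    ch <- sample(4, 1)
    th <- function(z) c(-x, -y, z, 1, 0)
    lo <- evaluate_gradient(psf, th(zf - eps), roi_half = 0)
    hi <- evaluate_gradient(psf, th(zf + eps), roi_half = 0)
    expect_equal(lo$mu[1, 1, ch], hi$mu[1, 1, ch], tolerance = 1e-6)
    expect_equal(lo$J[1, 1, ch, 3], hi$J[1, 1, ch, 3], tolerance = 1e-4)
  }
})

test_that("compiled evaluation matches the literal triple-sum oracle", {
  psf <- fx_psf()
  set.seed(5)
  worst <- 0
  for (q in 1:200) {
    x <- runif(1, -1050, 1050); y <- runif(1, -1050, 1050)
    z <- runif(1, -1400, 1400); ch <- sample(4, 1)
    a <- spline_value(psf, x, y, z, ch)
    b <- oracle_spline_eval(psf, x, y, z, ch)
    worst <- max(worst, abs(a - b) / max(abs(b), 1e-12))
  }
  expect_lt(worst, 1e-10)
})

test_that("the model is affine in amplitude and background", {
  psf <- fx_psf()
  base <- evaluate_model(psf, c(20, -30, 150, 1, 0))
  scaled <- evaluate_model(psf, c(20, -30, 150, 2, 5))
  expect_equal(scaled, 2 * base + 5, tolerance = 1e-12)
})

test_that("analytic gradients agree with central differences", {
  psf <- fx_psf()
  th <- c(25, -35, 210, 4000, 6)
  g <- evaluate_gradient(psf, th)
  h <- 1e-3
  for (a in 1:5) {
    tp <- th; tm <- th
    tp[a] <- tp[a] + h; tm[a] <- tm[a] - h
    num <- (evaluate_model(psf, tp) - evaluate_model(psf, tm)) / (2 * h)
    expect_equal(as.numeric(g$J[, , , a]), as.numeric(num),
                 tolerance = 1e-4)
  }
  expect_equal(range(g$J[, , , 5]), c(1, 1)) # d/db is 1 everywhere
})

test_that("out-of-support evaluation is an explicit error", {
  psf <- fx_psf()
  expect_error(spline_value(psf, 5000, 0, 0, 1), "support")
  expect_error(evaluate_model(psf, c(0, 0, 5000, 1, 0)), "support")
})

test_that("rendering reproduces and round-trips the model", {
  cfg <- fx_cfg()
  small <- make_symmetric_4pi_psf(cfg, n_xy = 9, n_z = 60, z_step = 30)
  ps <- compute_spline_coefficients(small)
  r1 <- render_psf(ps, sampling = 1)
  expect_equal(r1$data, small$data, tolerance = 1e-9)
  r3 <- render_psf(ps, sampling = 3)
  expect_equal(dim(r3$data)[1:3], c(25L, 25L, 178L))
  ps2 <- compute_spline_coefficients(r3)
  mid <- evaluate_model(ps, c(5, -12, 33, 1, 0), pixel = ps$spacing[1])
  mid2 <- evaluate_model(ps2, c(5, -12, 33, 1, 0), pixel = ps$spacing[1])
  expect_equal(mid2, mid, tolerance = 1e-3)
})
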
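#' Four-channel bead stack
#'
#' Container for a pixelated four-channel 3D PSF measurement (a bead
#' z-scan): intensities on a voxel grid plus the voxel geometry. Lateral
#' coordinates are centered on the stack; the z origin is the coordinate of
#' the first plane center (by default the stack is centered on focus).
#'
#' @param data numeric array `[nx, ny, nz, 4]`, channels ordered p1, s1,
#'   p2, s2
#' @param voxel voxel sizes `(dx, dy, dz)` in nm
#' @param z_origin z coordinate of the first plane center, nm; default
#'   centers the stack on z = 0
#' @param channels channel labels
#' @param fringe_period optional known axial fringe period, nm
#' @return an object of class `bead_stack`
#' @export
bead_stack <- function(data, voxel, z_origin = NULL,
                       channels = c("p1", "s1", "p2", "s2"),
                       fringe_period = NULL) {
  d <- dim(data)
  stopifnot(length(d) == 4, d[4] == length(channels), all(voxel > 0),
            length(voxel) == 3)
  if (is.null(z_origin)) z_origin <- -(d[3] - 1) / 2 * voxel[3]
  structure(list(data = data, voxel = as.numeric(voxel),
                 z_origin = z_origin, channels = channels,
                 fringe_period = fringe_period), class = "bead_stack")
}

#' @export
print.bead_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bead_stack %d x %d x %d voxels, %d channels\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  voxel %g x %g x %g nm, z in [%g, %g] nm\n", x$voxel[1],
              x$voxel[2], x$voxel[3], x$z_origin,
              x$z_origin + (d[3] - 1) * x$voxel[3]))
  invisible(x)
}

stack_z_centers <- function(stack) {
  stack$z_origin + (seq_len(dim(stack$data)[3]) - 1) * stack$voxel[3]
}

stack_xy_centers <- function(stack) {
  n <- dim(stack$data)[1]
  (seq_len(n) - (n + 1) / 2) * stack$voxel[1]
}

#' Preprocess a raw bead z-scan
#'
#' Crops a lateral region centered on the bead, downsamples along z with an
#' averaging filter, and smooths along z with a boxcar filter of fixed
#' physical width. A 3 um / 3000-step raw scan becomes a 17 x 17 x 300
#' stack with 10 nm z voxels.
#'
#' @param raw a [bead_stack()] from the camera (or simulator)
#' @param crop_xy lateral crop size, pixels
#' @param downsample z downsampling factor
#' @param smooth_nm boxcar width in nm (window = `round(smooth_nm / dz)`
#'   planes after downsampling; edges are padded by replication)
#' @return a processed [bead_stack()]
#' @export
preprocess_bead_scan <- function(raw, crop_xy = 17, downsample = 10,
                                 smooth_nm = 50) {
  d <- dim(raw$data)
  stopifnot(d[1] >= crop_xy, d[2] >= crop_xy, downsample >= 1)
  lat <- apply(raw$data, c(1, 2), sum)
  pk <- which(lat == max(lat), arr.ind = TRUE)[1, ]
  if (pk[1] <= 2 || pk[2] <= 2 || pk[1] >= d[1] - 1 || pk[2] >= d[2] - 1)
    stop("bead peak within 2 px of the stack border; re-center the scan ",
         "(peak at ", pk[1], ",", pk[2], ")")
  h <- (crop_xy - 1) / 2
  x1 <- pk[1] - floor(h); x2 <- pk[1] + ceiling(h)
  y1 <- pk[2] - floor(h); y2 <- pk[2] + ceiling(h)
  if (x1 < 1 || y1 < 1 || x2 > d[1] || y2 > d[2])
    stop("bead too close to the border for a ", crop_xy, " px crop")
  dat <- raw$data[x1:x2, y1:y2, , , drop = FALSE]

  nz2 <- floor(d[3] / downsample)
  if (downsample > 1) {
    dat <- dat[, , seq_len(nz2 * downsample), , drop = FALSE]
    dm <- dim(dat)
    dat <- array(dat, dim = c(dm[1], dm[2], downsample, nz2, dm[4]))
    dat <- apply(dat, c(1, 2, 4, 5), mean)
  }
  dz <- raw$voxel[3] * downsample
  z0 <- raw$z_origin + (downsample - 1) / 2 * raw$voxel[3]

  wbox <- round(smooth_nm / dz)
  if (wbox > 1) {
    pad <- floor(wbox / 2)
    dm <- dim(dat)
    idx <- c(rep(1, pad), seq_len(dm[3]), rep(dm[3], wbox - 1 - pad))
    padded <- dat[, , idx, , drop = FALSE]
    sm <- array(0, dim = dm)
    for (o in seq_len(wbox))
      sm <- sm + padded[, , o:(o + dm[3] - 1), , drop = FALSE]
    dat <- sm / wbox
  }
  bead_stack(dat, voxel = c(raw$voxel[1], raw$voxel[2], dz), z_origin = z0,
             channels = raw$channels, fringe_period = raw$fringe_period)
}

# per-interval coefficients of the 1D natural cubic interpolating spline on
# a unit grid; Y is an n x K matrix of knot values, result 4 x (n-1) x K
spline1d_pp <- function(Y) {
  n <- nrow(Y); K <- ncol(Y)
  M <- matrix(0, n, K) # second derivatives at the knots
  if (n > 2) {
    nn <- n - 2
    rhs <- 6 * (Y[seq_len(nn), , drop = FALSE] -
                  2 * Y[seq_len(nn) + 1, , drop = FALSE] +
                  Y[seq_len(nn) + 2, , drop = FALSE])
    cp <- numeric(nn)
    cp[1] <- 0.25
    rhs[1, ] <- rhs[1, ] / 4
    if (nn > 1) {
      for (i in 2:nn) {
        m <- 4 - cp[i - 1]
        cp[i] <- 1 / m
        rhs[i, ] <- (rhs[i, ] - rhs[i - 1, ]) / m
      }
      for (i in (nn - 1):1)
        rhs[i, ] <- rhs[i, ] - cp[i] * rhs[i + 1, ]
    }
    M[2:(n - 1), ] <- rhs
  }
  lo <- seq_len(n - 1); hi <- lo + 1
  out <- array(0, dim = c(4, n - 1, K))
  out[1, , ] <- Y[lo, , drop = FALSE]
  out[2, , ] <- Y[hi, , drop = FALSE] - Y[lo, , drop = FALSE] -
    (2 * M[lo, , drop = FALSE] + M[hi, , drop = FALSE]) / 6
  out[3, , ] <- M[lo, , drop = FALSE] / 2
  out[4, , ] <- (M[hi, , drop = FALSE] - M[lo, , drop = FALSE]) / 6
  out
}

#' Compute multichannel 3D cubic-spline PSF coefficients
#'
#' Converts a pixelated four-channel bead stack into a tensor-product cubic
#' spline: 64 polynomial coefficients per volume cell per channel,
#' interpolating the stack values at the knots (voxel centers) with
#' continuous value and derivatives across cell faces. The construction is
#' separable -- a 1D natural cubic interpolating spline applied along x,
#' then y, then z -- so a 17 x 17 x 300 four-channel stack yields
#' 4 x 64 x 16 x 16 x 299 coefficients.
#'
#' @param stack a [bead_stack()] with at least 4 voxels per axis
#' @return an object of class `spline_psf`
#' @export
compute_spline_coefficients <- function(stack) {
  d <- dim(stack$data)
  if (any(d[1:3] < 4))
    stop("stack must have at least 4 voxels per axis")
  nx <- d[1]; ny <- d[2]; nz <- d[3]; nch <- d[4]
  coef <- array(0, dim = c(64, nx - 1, ny - 1, nz - 1, nch))
  for (ch in seq_len(nch)) {
    v <- stack$data[, , , ch]
    cx <- spline1d_pp(matrix(v, nrow = nx))            # (m, i, j*k)
    dim(cx) <- c(4, nx - 1, ny, nz)
    cx <- aperm(cx, c(3, 1, 2, 4))                     # (j, m, i, k)
    cy <- spline1d_pp(matrix(cx, nrow = ny))           # (n, j, m*i*k)
    dim(cy) <- c(4, ny - 1, 4, nx - 1, nz)
    cy <- aperm(cy, c(5, 1, 2, 3, 4))                  # (k, n, j, m, i)
    cz <- spline1d_pp(matrix(cy, nrow = nz))           # (o, k, n*j*m*i)
    dim(cz) <- c(4, nz - 1, 4, ny - 1, 4, nx - 1)
    cz <- aperm(cz, c(5, 3, 1, 6, 4, 2))               # (m, n, o, i, j, k)
    dim(cz) <- c(64, nx - 1, ny - 1, nz - 1)
    coef[, , , , ch] <- cz
  }
  xs <- (seq_len(nx) - (nx + 1) / 2) * stack$voxel[1]
  ys <- (seq_len(ny) - (ny + 1) / 2) * stack$voxel[2]
  flux <- apply(stack$data, 3, sum)
  fp <- stack$fringe_period
  if (is.null(fp)) fp <- estimate_fringe_period(stack)
  out <- structure(list(
    coef = coef,
    dims = c(64L, nx - 1L, ny - 1L, nz - 1L, as.integer(nch)),
    origin = c(xs[1], ys[1], stack$z_origin),
    spacing = stack$voxel,
    n_knots = c(nx, ny, nz),
    channels = stack$channels,
    phase_offset = 0,
    fringe_period = fp,
    flux_z = stack_z_centers(stack),
    flux = flux,
    sp_scale = NA_real_
  ), class = "spline_psf")
  out$sp_scale <- psf_sp_ratio(out)
  out
}

#' @export
print.spline_psf <- function(x, ...) {
  cat(sprintf(
    "spline_psf: %d coefficients (%d x %d x %d cells, %d channels)\n",
    n_spline_coefficients(x), x$dims[2], x$dims[3], x$dims[4], x$dims[5]))
  cat(sprintf("  knot spacing %g x %g x %g nm, phase offset %.3f rad\n",
              x$spacing[1], x$spacing[2], x$spacing[3], x$phase_offset))
  invisible(x)
}

#' Total number of spline coefficients of a PSF model
#'
#' `n_channels * 64 * prod(cells)`; 4 x 64 x 16 x 16 x 299 (about 1.96e7)
#' for the standard 17 x 17 x 300 four-channel stack.
#'
#' @param psf a `spline_psf`
#' @return integer coefficient count
#' @export
n_spline_coefficients <- function(psf) {
  length(psf$coef)
}

#' Build a spline PSF model from a raw bead scan
#'
#' Convenience pipeline: [preprocess_bead_scan()] (cropping, z-downsampling,
#' boxcar smoothing) followed by [compute_spline_coefficients()]. Raw scans
#' finer than ~5 nm per z step are downsampled by 10 as in the standard
#' 3 um / 3000-step protocol; already-processed stacks pass `downsample = 1`.
#'
#' @param scan a [bead_stack()]
#' @param ... passed to [preprocess_bead_scan()]
#' @return a `spline_psf`
#' @export
calibrate_psf <- function(scan, ...) {
  compute_spline_coefficients(preprocess_bead_scan(scan, ...))
}

#' Evaluate the spline PSF at arbitrary points
#'
#' Direct evaluation of the multichannel spline function `f_S`. Points must
#' lie inside the spline support (the knot bounding box); evaluation outside
#' is an error, never silent extrapolation.
#'
#' @param psf a `spline_psf`
#' @param x,y,z coordinates, nm (recycled to common length)
#' @param channel channel index 1..4 (recycled)
#' @return numeric vector of spline values
#' @export
spline_value <- function(psf, x, y, z, channel = 1L) {
  n <- max(length(x), length(y), length(z), length(channel))
  cpp_spline_eval(psf$coef, psf$dims, psf$origin, psf$spacing,
                  rep_len(as.numeric(x), n), rep_len(as.numeric(y), n),
                  rep_len(as.numeric(z), n), rep_len(as.integer(channel), n))
}

roi_params <- function(params) {
  if (is.list(params))
    params <- c(params$x0, params$y0, params$z0, params$A, params$b)
  stopifnot(length(params) == 5)
  as.numeric(params)
}

#' Expected ROI image under the spline PSF model
#'
#' Returns `b + A * f_S(x - x0, y - y0, z0, c)` sampled at the pixel centers
#' of a square ROI, for all four channels.
#'
#' @param psf a `spline_psf`
#' @param params list or vector `(x0, y0, z0, A, b)`
#' @param roi_half ROI half width in pixels
#' @param pixel pixel size, nm
#' @return array `(2*roi_half+1, 2*roi_half+1, n_channels)`
#' @export
evaluate_model <- function(psf, params, roi_half = 3,
                           pixel = psf$spacing[1]) {
  th <- roi_params(params)
  w <- 2 * roi_half + 1
  out <- cpp_eval_roi(psf$coef, psf$dims, psf$origin, psf$spacing, th,
                      as.integer(roi_half), pixel, FALSE)
  array(out$mu, dim = c(w, w, psf$dims[5]))
}

#' Analytic model gradient over an ROI
#'
#' Partial derivatives of the expected ROI image with respect to
#' `(x0, y0, z0, A, b)`: `d/dA = f_S`, `d/db = 1`,
#' `d/dx0 = -A dF/dx`, etc.
#'
#' @inheritParams evaluate_model
#' @return list with `mu` (ROI array) and `J`
#'   (array `(w, w, n_channels, 5)`)
#' @export
evaluate_gradient <- function(psf, params, roi_half = 3,
                              pixel = psf$spacing[1]) {
  th <- roi_params(params)
  w <- 2 * roi_half + 1
  out <- cpp_eval_roi(psf$coef, psf$dims, psf$origin, psf$spacing, th,
                      as.integer(roi_half), pixel, TRUE)
  list(mu = array(out$mu, dim = c(w, w, psf$dims[5])),
       J = array(out$J, dim = c(w, w, psf$dims[5], 5)))
}

#' Render a spline PSF back onto a voxel grid
#'
#' Samples the spline at a grid `sampling` times denser than the knot grid
#' (sampling = 1 reproduces the source stack by the interpolation property).
#'
#' @param psf a `spline_psf`
#' @param sampling oversampling factor per axis (>= 1)
#' @return a [bead_stack()] with voxel sizes divided by `sampling`
#' @export
render_psf <- function(psf, sampling = 1) {
  stopifnot(sampling >= 1)
  nk <- psf$n_knots
  ax <- lapply(1:3, function(a)
    seq(psf$origin[a], psf$origin[a] + (nk[a] - 1) * psf$spacing[a],
        by = psf$spacing[a] / sampling))
  nx <- length(ax[[1]]); ny <- length(ax[[2]]); nz <- length(ax[[3]])
  nch <- psf$dims[5]
  out <- array(0, dim = c(nx, ny, nz, nch))
  lat <- expand.grid(x = ax[[1]], y = ax[[2]])
  for (ch in seq_len(nch))
    for (iz in seq_len(nz))
      out[, , iz, ch] <- spline_value(psf, lat$x, lat$y, ax[[3]][iz], ch)
  bead_stack(out, voxel = psf$spacing / sampling, z_origin = psf$origin[3],
             channels = psf$channels, fringe_period = psf$fringe_period)
}

#' Lateral flux of the PSF model at a given z
#'
#' Channel-summed in-window flux per unit amplitude, interpolated between
#' the knot planes of the source stack; used to convert the fitted
#' amplitude into a photon estimate.
#'
#' @param psf a `spline_psf`
#' @param z z coordinate(s), nm
#' @return flux value(s)
#' @export
psf_flux <- function(psf, z) {
  approx(psf$flux_z, psf$flux, xout = z, rule = 2)$y
}

#' Estimate the axial fringe period of a measured PSF
#'
#' Dominant axial frequency of the central modulation column, from the
#' discrete Fourier spectrum of the center pixel's z profile after removing
#' its low-frequency envelope. The spectral peak is refined by a local
#' 3-point parabolic fit on the log power.
#'
#' @param stack a [bead_stack()]
#' @param cutoff_period envelope/modulation split period, nm
#' @return fringe period, nm
#' @export
estimate_fringe_period <- function(stack, cutoff_period = 500) {
  d <- dim(stack$data)
  cx <- ceiling(d[1] / 2); cy <- ceiling(d[2] / 2)
  col <- stack$data[cx, cy, , 1]
  nz <- length(col); dz <- stack$voxel[3]
  sp <- Mod(fft(col - mean(col)))^2
  kmax <- floor(nz / 2)
  klo <- max(2, ceiling(nz * dz / cutoff_period))
  k <- which.max(sp[(klo + 1):(kmax + 1)]) + klo - 1 # DFT index (0-based)
  pk <- k
  if (k > 1 && k < kmax) {
    lp <- log(sp[k:(k + 2)] + 1e-300)
    denom <- lp[1] - 2 * lp[2] + lp[3]
    if (abs(denom) > 1e-12) pk <- k + 0.5 * (lp[1] - lp[3]) / denom
  }
  nz * dz / pk
}
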
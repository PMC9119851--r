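#' Decompose a 4Pi PSF into envelope and modulation components
#'
#' Splits each z column of the stack into a slowly varying envelope
#' (Fourier low-pass with a hard cutoff, components with period shorter
#' than `cutoff_period` removed) and the interference modulation
#' (stack minus envelope), plus the 90-degree quadrature of the modulation
#' obtained by a Hilbert transform along z. By construction
#' `env + mod` reconstructs the source stack exactly.
#'
#' @param stack a [bead_stack()]
#' @param cutoff_period low-pass cutoff period, nm (default 500, well above
#'   the ~lambda/2 fringe period)
#' @return an object of class `psf_decomposition` with fields `env`, `mod`,
#'   `mod90` (arrays shaped like the stack) and the stack geometry
#' @export
decompose_psf <- function(stack, cutoff_period = 500) {
  d <- dim(stack$data)
  nz <- d[3]; dz <- stack$voxel[3]
  if (nz * dz <= cutoff_period)
    stop("stack z extent must exceed the cutoff period")
  cols <- matrix(aperm(stack$data, c(3, 1, 2, 4)), nrow = nz)
  Fc <- mvfft(cols)
  kk <- 0:(nz - 1)
  cyc <- pmin(kk, nz - kk)
  keep <- cyc <= nz * dz / cutoff_period
  env <- Re(mvfft(Fc * keep, inverse = TRUE)) / nz
  modc <- cols - env
  # Hilbert quadrature: shifts every sinusoid by 90 deg (cos -> sin)
  h <- rep(0 + 0i, nz)
  pos <- kk >= 1 & kk < nz / 2
  neg <- kk > nz / 2
  h[pos] <- complex(imaginary = -1)
  h[neg] <- complex(imaginary = 1)
  q <- Re(mvfft(mvfft(modc) * h, inverse = TRUE)) / nz
  reshape <- function(m) aperm(array(m, dim = c(nz, d[1], d[2], d[4])),
                               c(2, 3, 1, 4))
  structure(list(env = reshape(env), mod = reshape(modc),
                 mod90 = reshape(q), voxel = stack$voxel,
                 z_origin = stack$z_origin, channels = stack$channels,
                 cutoff_period = cutoff_period,
                 fringe_period = stack$fringe_period),
            class = "psf_decomposition")
}

dec_component_stack <- function(dec, which) {
  bead_stack(dec[[which]], voxel = dec$voxel, z_origin = dec$z_origin,
             channels = dec$channels, fringe_period = dec$fringe_period)
}

#' Shift the interference phase of a decomposed PSF
#'
#' Recombines the decomposition with a phase factor:
#' `env + cos(dphi) * mod + sin(dphi) * mod90`. A positive shift moves the
#' fringes towards +z by `dphi / (2*pi)` fringe periods.
#'
#' @param dec a [decompose_psf()] result
#' @param dphi phase shift, radians
#' @return a [bead_stack()] with the shifted modulation phase
#' @export
phase_shift_psf <- function(dec, dphi) {
  bead_stack(dec$env + cos(dphi) * dec$mod + sin(dphi) * dec$mod90,
             voxel = dec$voxel, z_origin = dec$z_origin,
             channels = dec$channels, fringe_period = dec$fringe_period)
}

#' Dynamic spline PSF model
#'
#' The central model object: cubic-spline representations of the envelope,
#' modulation and quadrature components of a measured 4Pi PSF. Because the
#' spline construction is linear in the data, the spline of the
#' phase-shifted PSF equals the same linear combination of the three
#' component splines, so a model at any phase is available without
#' re-fitting coefficients.
#'
#' @param stack a [bead_stack()] (a processed bead scan), or a
#'   [decompose_psf()] result
#' @param cutoff_period envelope low-pass cutoff, nm
#' @return an object of class `dyn_spline_psf`
#' @export
dynamic_spline_psf <- function(stack, cutoff_period = 500) {
  if (inherits(stack, "psf_decomposition")) {
    dec <- stack
    stack <- phase_shift_psf(dec, 0)
  } else {
    stopifnot(inherits(stack, "bead_stack"))
    dec <- decompose_psf(stack, cutoff_period)
  }
  env_psf <- compute_spline_coefficients(dec_component_stack(dec, "env"))
  mod_psf <- compute_spline_coefficients(dec_component_stack(dec, "mod"))
  q_psf <- compute_spline_coefficients(dec_component_stack(dec, "mod90"))
  base <- compute_spline_coefficients(stack)
  structure(list(
    env_coef = env_psf$coef, mod_coef = mod_psf$coef, q_coef = q_psf$coef,
    template = base,    # spline_psf at phase 0 (the measured phase)
    stack = stack, dec = dec
  ), class = "dyn_spline_psf")
}

#' @export
print.dyn_spline_psf <- function(x, ...) {
  cat("dynamic spline PSF model\n")
  print(x$template)
  invisible(x)
}

#' Extract the spline PSF at a given phase shift
#'
#' @param psf a [dynamic_spline_psf()]
#' @param dphi phase shift relative to the measured PSF, radians
#' @return a `spline_psf` with `phase_offset = dphi`
#' @export
psf_at_phase <- function(psf, dphi = 0) {
  stopifnot(inherits(psf, "dyn_spline_psf"))
  out <- psf$template
  if (dphi != 0)
    out$coef <- psf$env_coef + cos(dphi) * psf$mod_coef +
      sin(dphi) * psf$q_coef
  out$phase_offset <- dphi
  out
}

as_spline_psf <- function(psf) {
  if (inherits(psf, "dyn_spline_psf")) psf$template else psf
}

#' Estimate the PSF phase from a set of emitter images
#'
#' Fits every image with a series of phase-shifted PSF models equally
#' spaced over 0..2pi (each with the full multi-start procedure), computes
#' the mean Chi-square per model, and locates the minimum of the
#' mean-Chi-square versus phase curve by a sine fit
#' `a + c cos(dphi - psi)` through the points around the grid minimum.
#' The returned phase is the fitted minimum mapped to [0, 2pi); its
#' precision is estimated by a bootstrap over images.
#'
#' @param images list of `emitter_image` or array `(w, w, 4, n)`
#' @param psf a [dynamic_spline_psf()]
#' @param n_phase_models number of phase-shifted models (12 by default)
#' @param z_start_range z range for the multi-start initial fit, nm
#'   (NULL = full model support); narrow it when the emitters are known to
#'   lie near focus
#' @param max_abs_z images whose initial fit lies farther than this from
#'   focus are excluded from the phase estimate (far-off-focus images have
#'   weak fringe contrast and contribute mostly noise)
#' @param ... passed to [fit_localization()]
#' @return list with `phase`, `precision` (radians), `curve` (data.frame of
#'   `dphi`, `mean_chi2`), `low_confidence` flag and `n_used`
#' @export
estimate_phase <- function(images, psf, n_phase_models = 12,
                           z_start_range = NULL, max_abs_z = Inf, ...) {
  stopifnot(inherits(psf, "dyn_spline_psf"), n_phase_models >= 4)
  base <- psf_at_phase(psf, 0)
  f0 <- fit_localization(images, base, z_range = z_start_range, ...)
  ok <- which(f0$converged & abs(f0$z) <= max_abs_z)
  if (length(ok) < 3) stop("too few images could be fit with the base model")
  p <- base$fringe_period
  dphis <- 2 * pi * (seq_len(n_phase_models) - 1) / n_phase_models
  im_mat <- images_to_matrix(images)

  # Each image is refit with every phase-shifted model using the same
  # multi-start procedure as the initial localization (all fringe minima
  # sampled, global Chi-square optimum kept). Restricted warm starts are
  # not sufficient here: under noise they miss the global optimum
  # asymmetrically and bias the curve minimum.
  zlim <- range(f0$z[ok]) + c(-1, 1) * (p / 2 + 20)
  if (!is.null(z_start_range)) {
    zlim[1] <- max(zlim[1], z_start_range[1])
    zlim[2] <- min(zlim[2], z_start_range[2])
  }
  chi <- matrix(NA_real_, length(ok), n_phase_models)
  for (j in seq_len(n_phase_models)) {
    mj <- psf_at_phase(psf, dphis[j])
    fj <- fit_localization(im_mat[, ok, drop = FALSE], mj,
                           z_range = zlim, ...)
    chi[, j] <- ifelse(fj$converged, fj$chi2, NA)
  }
  used <- complete.cases(chi)
  if (sum(used) < 3) stop("too few images converged under all phase models")
  chiu <- chi[used, , drop = FALSE]
  mc <- colMeans(chiu)

  # The sine is fit to the window of points around the grid minimum: the
  # walls of the curve far from the minimum are skewed by the asymmetric
  # z structure of the PSF, and including them would bias the fitted
  # minimum; near the minimum the curve is symmetric and sinusoidal.
  sine_vertex <- function(mc) {
    jmin <- which.min(mc)
    win <- ((jmin - 1) + (-1:1)) %% n_phase_models + 1
    dw <- dphis[jmin] + (-1:1) * 2 * pi / n_phase_models
    cf <- coef(lm(mc[win] ~ cos(dw) + sin(dw)))
    if (any(!is.finite(cf[2:3])) || sum(cf[2:3]^2) < 1e-24)
      return(c(dphis[jmin], 0))
    raw <- atan2(cf[3], cf[2]) + pi
    c((raw - 2 * pi * round((raw - dphis[jmin]) / (2 * pi))) %% (2 * pi),
      sqrt(sum(cf[2:3]^2)))
  }
  v <- sine_vertex(mc)
  phase <- v[1]
  # precision: nonparametric bootstrap over images (the three-point sine
  # fit is exact, so no residual-based error estimate exists)
  boots <- withr::with_seed(1203L, {
    n <- nrow(chiu)
    vapply(seq_len(25), function(b)
      sine_vertex(colMeans(chiu[sample.int(n, n, replace = TRUE), ,
                                drop = FALSE]))[1], 0)
  })
  prec <- sd(wrap_angle(boots - phase))
  curve_amp <- (max(mc) - min(mc)) / 2
  resid_scale <- sd(apply(chiu, 2, sd)) / sqrt(sum(used))
  low_conf <- v[2] <= 0 || curve_amp < 5 * resid_scale
  list(phase = unname(phase), precision = unname(prec),
       curve = data.frame(dphi = dphis, mean_chi2 = mc),
       low_confidence = low_conf, n_used = sum(used))
}

#' Time-resolved PSF phase trace
#'
#' Splits a time-ordered stream of emitter images into windows of a fixed
#' number of localizations, estimates the PSF phase in each, and unwraps
#' the per-window phases by nearest-multiple-of-2pi continuation.
#'
#' @param images list of `emitter_image` (with `time` fields) or array
#' @param times event times, s (required if `images` is an array)
#' @param psf a [dynamic_spline_psf()]
#' @param window number of localizations per time window
#' @param min_window windows smaller than this are merged into the previous
#' @param ... passed to [estimate_phase()]
#' @return a `phase_trace`: data.frame with `time`, `phase` (unwrapped,
#'   radians), `precision` and `n`
#' @export
phase_trace <- function(images, psf, times = NULL, window = 250,
                        min_window = 50, ...) {
  if (is.list(images) && is.null(times))
    times <- vapply(images, function(im) im$time, 0)
  n <- if (is.list(images)) length(images) else dim(images)[4]
  if (is.null(times)) times <- seq_len(n)
  ord <- order(times)
  starts <- seq(1, n, by = window)
  if (length(starts) > 1 && n - starts[length(starts)] + 1 < min_window)
    starts <- starts[-length(starts)]
  rows <- lapply(seq_along(starts), function(w) {
    idx <- ord[starts[w]:(if (w < length(starts)) starts[w + 1] - 1 else n)]
    sub <- if (is.list(images)) images[idx] else
      images[, , , idx, drop = FALSE]
    est <- estimate_phase(sub, psf, ...)
    data.frame(time = mean(times[idx]), phase = est$phase,
               precision = est$precision, n = est$n_used)
  })
  out <- do.call(rbind, rows)
  # unwrap across windows
  for (i in seq_len(nrow(out))[-1])
    out$phase[i] <- out$phase[i] -
      2 * pi * round((out$phase[i] - out$phase[i - 1]) / (2 * pi))
  class(out) <- c("phase_trace", "data.frame")
  out
}

#' Calibrate the phase-to-z conversion slope
#'
#' Fits z-plane slices of the measured PSF with phase-shifted versions of
#' the full model over a span of phase shifts; the apparent fitted z shifts
#' linearly with the model phase. The returned slope is expressed as the
#' apparent z displacement per radian of *PSF phase advance* (the negative
#' of the fitted-z-versus-model-phase slope), so that
#' `z_corrected = z - slope * (phase(t) - reference_phase)` undoes phase
#' drift. For a fringe period p the slope is approximately -p/(2*pi).
#'
#' @param psf a [dynamic_spline_psf()]
#' @param phase_span total span of applied phase shifts, radians
#' @param n_shifts number of phase shifts across the span
#' @param planes z coordinates of the PSF slices to fit (default: five
#'   planes within +-400 nm of focus)
#' @return a `phase_z_calibration`: list with `slope` (nm/rad),
#'   `r_squared`, `per_plane` slopes and a `nonlinear` flag
#' @export
calibrate_phase_to_z <- function(psf, phase_span = 2, n_shifts = 9,
                                 planes = NULL) {
  stopifnot(inherits(psf, "dyn_spline_psf"))
  if (phase_span <= 0) stop("phase_span must be positive (degenerate fit)")
  stack <- psf$stack
  p <- psf$template$fringe_period
  if (is.null(planes)) planes <- seq(-400, 400, length.out = 5)
  zc <- stack_z_centers(stack)
  dphis <- seq(-phase_span / 2, phase_span / 2, length.out = n_shifts)
  res <- list()
  d <- dim(stack$data)
  cx <- ceiling(d[1] / 2)
  for (zpl in planes) {
    iz <- which.min(abs(zc - zpl))
    img <- stack$data[(cx - 3):(cx + 3), (cx - 3):(cx + 3), iz, ,
                      drop = FALSE]
    dim(img) <- c(7, 7, d[4])
    scale <- 1e4 / max(sum(img), 1e-12)
    imat <- matrix(img * scale, ncol = 1)
    for (dphi in dphis) {
      mj <- psf_at_phase(psf, dphi)
      zst <- matrix(zc[iz] + dphi * p / (2 * pi), nrow = 1)
      fj <- fit_rois_core(mj, imat, x0s = 0, y0s = 0, b0s = 0,
                          zstarts = zst)
      if (fj[, "converged"] > 0)
        res[[length(res) + 1]] <- data.frame(plane = zc[iz], dphi = dphi,
                                             zhat = fj[, "z"])
    }
  }
  res <- do.call(rbind, res)
  res$dz <- res$zhat - res$plane
  fit <- lm(dz ~ dphi, data = res)
  r2 <- summary(fit)$r.squared
  per_plane <- vapply(split(res, res$plane), function(s)
    unname(coef(lm(dz ~ dphi, data = s))[2]), 0)
  slope <- -unname(coef(fit)[2])
  structure(list(slope = slope, r_squared = r2,
                 per_plane = -per_plane, nonlinear = r2 < 0.99,
                 fringe_period = p),
            class = "phase_z_calibration")
}

#' Correct localization z coordinates for PSF phase drift
#'
#' Rescales the measured phase trace to an apparent z drift via the
#' calibration slope and subtracts it:
#' `z_corrected = z - slope * (phase(t) - reference_phase)`. The reference
#' phase defaults to the mean of the unwrapped trace (the phase the fitting
#' model was shifted to).
#'
#' @param locs localization data.frame with `z` and `time` columns
#' @param trace a [phase_trace()]
#' @param cal a [calibrate_phase_to_z()] result
#' @param reference_phase radians; default `mean(trace$phase)`
#' @return `locs` with corrected `z`
#' @export
correct_phase_drift <- function(locs, trace, cal, reference_phase = NULL) {
  stopifnot(all(c("z", "time") %in% names(locs)))
  if (is.null(reference_phase)) reference_phase <- mean(trace$phase)
  rng <- range(trace$time)
  if (any(locs$time < rng[1] | locs$time > rng[2]))
    warning("localization times outside the phase trace; ",
            "nearest-window extrapolation used")
  ph <- if (nrow(trace) == 1) rep(trace$phase, nrow(locs)) else
    approx(trace$time, trace$phase, xout = locs$time, rule = 2)$y
  locs$z <- locs$z - cal$slope * (ph - reference_phase)
  locs
}
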
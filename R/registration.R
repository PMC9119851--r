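poly2_design <- function(x, y) cbind(1, x, y, x^2, x * y, y^2)

#' Fit a quadratic channel-registration transform
#'
#' Least-squares second-order (quadratic) 2D polynomial mapping between a
#' detection channel and the reference channel (p1), from paired bead
#' coordinates recorded at multiple positions in the field of view. Both
#' directions are fit: `fwd` maps reference coordinates into the channel
#' (used for image warping) and `inv` maps channel coordinates to the
#' reference (used for localization coordinates).
#'
#' @param pairs data.frame with columns `x_ref, y_ref, x, y` (same units
#'   throughout, typically nm or pixels)
#' @param holdout_frac fraction of pairs held out for the residual RMSD
#'   when at least 12 pairs are available (otherwise the RMSD is in-sample
#'   and flagged)
#' @return a `channel_transform`: list with `fwd`, `inv` (6 x 2 coefficient
#'   matrices), `rmsd` and `rmsd_insample`
#' @export
fit_channel_transform <- function(pairs, holdout_frac = 0.25) {
  need <- c("x_ref", "y_ref", "x", "y")
  if (!all(need %in% names(pairs)))
    stop("pairs must have columns ", paste(need, collapse = ", "))
  n <- nrow(pairs)
  if (n < 6) stop("at least 6 bead positions are required for a quadratic fit")
  X <- poly2_design(pairs$x_ref, pairs$y_ref)
  if (qr(X)$rank < 6)
    stop("degenerate bead geometry (collinear positions)")
  hold <- integer(0)
  if (n >= 12) hold <- seq(1, n, by = round(1 / holdout_frac))
  trn <- setdiff(seq_len(n), hold)
  fit_dir <- function(from_x, from_y, to_x, to_y, idx) {
    X <- poly2_design(from_x[idx], from_y[idx])
    cbind(qr.solve(X, to_x[idx]), qr.solve(X, to_y[idx]))
  }
  fwd <- fit_dir(pairs$x_ref, pairs$y_ref, pairs$x, pairs$y, trn)
  inv <- fit_dir(pairs$x, pairs$y, pairs$x_ref, pairs$y_ref, trn)
  ev <- if (length(hold) > 0) hold else trn
  P <- poly2_design(pairs$x_ref[ev], pairs$y_ref[ev]) %*% fwd
  rmsd <- sqrt(mean((P[, 1] - pairs$x[ev])^2 + (P[, 2] - pairs$y[ev])^2))
  structure(list(fwd = fwd, inv = inv, rmsd = rmsd,
                 rmsd_insample = length(hold) == 0),
            class = "channel_transform")
}

#' Apply a channel transform to coordinates
#'
#' @param tr a [fit_channel_transform()] result
#' @param x,y coordinates
#' @param direction `"fwd"` (reference to channel) or `"inv"`
#' @return matrix with transformed `x`, `y` columns
#' @export
apply_transform <- function(tr, x, y, direction = c("fwd", "inv")) {
  direction <- match.arg(direction)
  out <- poly2_design(x, y) %*% tr[[direction]]
  colnames(out) <- c("x", "y")
  out
}

# Keys cubic convolution kernel, a = -0.5
cubic_kernel <- function(t, a = -0.5) {
  t <- abs(t)
  ifelse(t <= 1, (a + 2) * t^3 - (a + 3) * t^2 + 1,
         ifelse(t < 2, a * t^3 - 5 * a * t^2 + 8 * a * t - 4 * a, 0))
}

#' Warp an image with a channel transform
#'
#' Resamples `image` onto the reference grid: each output pixel takes the
#' input value at the forward-transformed position, interpolated by cubic
#' convolution. Positions falling outside the input are set to `fill`.
#'
#' @param image numeric matrix (one channel)
#' @param transform a `channel_transform`, or NULL for identity
#' @param fill value for out-of-range pixels
#' @return warped matrix with attribute `"fill_mask"` (logical matrix)
#' @export
warp_channel <- function(image, transform = NULL, fill = 0) {
  nx <- nrow(image); ny <- ncol(image)
  g <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  if (is.null(transform)) {
    src <- cbind(x = g$x, y = g$y)
  } else {
    src <- apply_transform(transform, g$x, g$y, "fwd")
  }
  sx <- src[, 1]; sy <- src[, 2]
  i0 <- floor(sx); j0 <- floor(sy)
  valid <- i0 >= 2 & i0 <= nx - 2 & j0 >= 2 & j0 <= ny - 2
  out <- rep(fill, nx * ny)
  if (any(valid)) {
    sxv <- sx[valid]; syv <- sy[valid]
    i0v <- i0[valid]; j0v <- j0[valid]
    acc <- numeric(sum(valid))
    for (oy in -1:2) {
      wy <- cubic_kernel(syv - (j0v + oy))
      rowacc <- numeric(sum(valid))
      for (ox in -1:2) {
        wx <- cubic_kernel(sxv - (i0v + ox))
        rowacc <- rowacc + wx * image[cbind(i0v + ox, j0v + oy)]
      }
      acc <- acc + wy * rowacc
    }
    out[valid] <- acc
  }
  out <- matrix(out, nx, ny)
  attr(out, "fill_mask") <- matrix(!valid, nx, ny)
  out
}

render_hist3d <- function(x, y, z, ranges, voxel) {
  nb <- pmax(2, ceiling(vapply(ranges, diff, 0) / voxel))
  ix <- pmin(nb[1], pmax(1, floor((x - ranges[[1]][1]) / voxel) + 1))
  iy <- pmin(nb[2], pmax(1, floor((y - ranges[[2]][1]) / voxel) + 1))
  iz <- pmin(nb[3], pmax(1, floor((z - ranges[[3]][1]) / voxel) + 1))
  h <- array(0, dim = nb)
  idx <- cbind(ix, iy, iz)
  for (i in seq_len(nrow(idx))) h[idx[i, 1], idx[i, 2], idx[i, 3]] <-
      h[idx[i, 1], idx[i, 2], idx[i, 3]] + 1
  h
}

fft3_xcorr_peak <- function(a, b) {
  # cross-correlation C(d) = sum_r a(r) b(r - d): peak at the displacement
  # of b relative to a
  Fa <- fft(a); Fb <- fft(b)
  cc <- Re(fft(Fa * Conj(Fb), inverse = TRUE)) / length(a)
  d <- dim(cc)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  # sub-voxel refinement: 3-point Gaussian (log-parabolic) fit per axis
  shift <- numeric(3)
  for (ax in 1:3) {
    idx <- pk
    getv <- function(o) {
      idx[ax] <- ((pk[ax] - 1 + o) %% d[ax]) + 1
      max(cc[idx[1], idx[2], idx[3]], 1e-12)
    }
    lp <- log(c(getv(-1), getv(0), getv(1)))
    den <- lp[1] - 2 * lp[2] + lp[3]
    off <- if (abs(den) > 1e-12) 0.5 * (lp[1] - lp[3]) / den else 0
    off <- max(-1, min(1, off))
    ctr <- pk[ax] - 1
    if (ctr > d[ax] / 2) ctr <- ctr - d[ax]
    shift[ax] <- ctr + off
  }
  list(shift = -shift, height = max(cc))
}

#' Estimate 3D sample drift by redundant cross-correlation
#'
#' Splits the localizations into time windows, renders a 3D histogram
#' image for each, measures the 3D cross-correlation peak (Gaussian
#' sub-voxel refinement) between every pair of windows, and combines all
#' pairwise offsets into one trajectory by weighted least squares -- the
#' robust all-pairs variant, which averages down the error of any single
#' correlation.
#'
#' @param locs data.frame with `x, y, z, time`
#' @param n_windows number of time windows
#' @param voxel rendering voxel size, nm
#' @param min_locs windows with fewer localizations are dropped
#' @return a `drift_trajectory`: data.frame `time, dx, dy, dz` (nm),
#'   anchored so the first window has zero offset
#' @export
estimate_sample_drift <- function(locs, n_windows = 5, voxel = 10,
                                  min_locs = 10) {
  stopifnot(all(c("x", "y", "z", "time") %in% names(locs)),
            n_windows >= 2)
  br <- seq(min(locs$time), max(locs$time), length.out = n_windows + 1)
  win <- pmin(n_windows, pmax(1, findInterval(locs$time, br,
                                              rightmost.closed = TRUE)))
  pad <- 5 * voxel
  ranges <- list(range(locs$x) + c(-pad, pad),
                 range(locs$y) + c(-pad, pad),
                 range(locs$z) + c(-pad, pad))
  nvox <- prod(pmax(2, ceiling(vapply(ranges, diff, 0) / voxel)))
  if (nvox > 4e6) stop("rendering volume too large; increase voxel")
  hists <- lapply(seq_len(n_windows), function(w) {
    s <- locs[win == w, ]
    if (nrow(s) < min_locs) return(NULL)
    render_hist3d(s$x, s$y, s$z, ranges, voxel)
  })
  keep <- which(!vapply(hists, is.null, TRUE))
  if (length(keep) < 2) stop("not enough populated windows for drift")
  pairs <- utils::combn(keep, 2)
  rows <- matrix(0, ncol(pairs), length(keep))
  obs <- matrix(0, ncol(pairs), 3)
  wts <- numeric(ncol(pairs))
  for (q in seq_len(ncol(pairs))) {
    i <- pairs[1, q]; j <- pairs[2, q]
    pk <- fft3_xcorr_peak(hists[[i]], hists[[j]])
    obs[q, ] <- pk$shift * voxel
    wts[q] <- pk$height
    rows[q, match(j, keep)] <- 1
    rows[q, match(i, keep)] <- -1
  }
  # solve d_j - d_i = obs with d_first = 0, weighted least squares
  A <- rows[, -1, drop = FALSE]
  sw <- sqrt(wts / max(wts))
  sol <- vapply(1:3, function(ax)
    c(0, qr.solve(A * sw, obs[, ax] * sw)), numeric(length(keep)))
  times <- (br[keep] + br[keep + 1]) / 2
  out <- data.frame(time = times, dx = sol[, 1], dy = sol[, 2],
                    dz = sol[, 3])
  class(out) <- c("drift_trajectory", "data.frame")
  out
}

#' Subtract a drift trajectory from localization coordinates
#'
#' @param locs data.frame with `x, y, z, time`
#' @param traj a [estimate_sample_drift()] trajectory
#' @return corrected `locs`
#' @export
apply_drift_correction <- function(locs, traj) {
  for (ax in c("x", "y", "z")) {
    col <- c(x = "dx", y = "dy", z = "dz")[ax]
    off <- if (nrow(traj) == 1) rep(traj[[col]], nrow(locs)) else
      approx(traj$time, traj[[col]], xout = locs$time, rule = 2)$y
    locs[[ax]] <- locs[[ax]] - off
  }
  locs
}

#' Wavelength and refractive-index z rescaling
#'
#' Linear rescaling of fitted z coordinates that corrects (i) the
#' difference between the calibration bead's emission wavelength and the
#' dye's, which changes the fringe period, and (ii) the refractive-index
#' mismatch between sample medium and immersion oil, relevant because the
#' PSF is calibrated by a piezo stage scan of a bead rather than by moving
#' an emitter through the sample medium. The combined factor is
#' `(lambda_dye / lambda_bead) * (n_sample / n_immersion)`.
#'
#' @param locs data.frame with a `z` column
#' @param cfg an [index_wavelength_config()]
#' @param dye dye name, one of `names(cfg$lambda_dyes)`
#' @return `locs` with rescaled `z`; the factors are attached as
#'   attribute `"z_rescale"`
#' @export
rescale_z <- function(locs, cfg, dye) {
  if (!dye %in% names(cfg$lambda_dyes))
    stop("unknown dye '", dye, "'; expected one of ",
         paste(names(cfg$lambda_dyes), collapse = ", "))
  fw <- cfg$lambda_dyes[[dye]] / cfg$lambda_bead
  fi <- cfg$n_sample / cfg$n_immersion
  locs$z <- locs$z * fw * fi
  attr(locs, "z_rescale") <- c(wavelength = fw, index = fi,
                               combined = fw * fi)
  locs
}

#' Predicted PSF phase shift for a z-stage displacement
#'
#' Low-NA approximation of the interference-phase shift caused by moving
#' the sample stage by `delta_z` in an index-mismatched system:
#' \deqn{\Delta\varphi = (n_{imm}/n_s - n_s/n_{imm}) \,
#'   4\pi n_s / \lambda_0 \, \Delta z}
#' Used as a logged consistency check in multistep scanning; the per-step
#' phase is always measured from the data, not taken from this formula.
#'
#' @param delta_z stage displacement, nm
#' @param cfg a [fourpi_config()] (or any list with `n_immersion`,
#'   `n_sample` and `wavelength_vacuum`)
#' @return phase shift, radians
#' @export
predict_step_phase_shift <- function(delta_z, cfg) {
  (cfg$n_immersion / cfg$n_sample - cfg$n_sample / cfg$n_immersion) *
    4 * pi * cfg$n_sample / cfg$wavelength_vacuum * delta_z
}

#' Analyze a multistep z-stage scanning acquisition
#'
#' Treats each step of the staircase scan as an independent measurement:
#' per step, events are detected and grouped, the experimental PSF phase is
#' estimated from the step's own emitter images, the step is refit with a
#' model shifted to that phase, and the stage offset is added back to the
#' fitted z. Residual inter-step registration is resolved by the redundant
#' cross-correlation drift estimator on the overlap regions. The
#' low-NA phase-shift prediction is recorded per step as a consistency
#' check only.
#'
#' @param movie four-channel movie array
#' @param step_schedule data.frame `frame_start, frame_end, stage_z` (nm)
#' @param psf a [dynamic_spline_psf()]
#' @param cfg a [fourpi_config()] (for the logged phase prediction)
#' @param min_phase_locs minimum images per step for phase estimation;
#'   steps below it inherit the previous step's phase with a warning
#' @param register_steps resolve residual inter-step offsets with
#'   [estimate_sample_drift()] (needs enough localizations per step)
#' @param ... passed to [fit_localization()]
#' @return merged localization data.frame with `step`, `stage_z` and
#'   `phase_hat` columns; per-step log in attribute `"step_log"`
#' @export
analyze_multistep <- function(movie, step_schedule, psf, cfg = NULL,
                              min_phase_locs = 25, register_steps = TRUE,
                              ...) {
  stopifnot(inherits(psf, "dyn_spline_psf"),
            all(c("frame_start", "frame_end", "stage_z") %in%
                  names(step_schedule)))
  prev_phase <- 0
  all_locs <- list()
  log <- list()
  for (s in seq_len(nrow(step_schedule))) {
    frs <- step_schedule$frame_start[s]:step_schedule$frame_end[s]
    sub <- movie[, , , frs, drop = FALSE]
    attr(sub, "pixel") <- attr(movie, "pixel")
    attr(sub, "frame_time") <- attr(movie, "frame_time")
    cands <- detect_candidates(sub)
    ev <- group_events(cands, sub)
    if (length(ev) == 0) next
    if (length(ev) >= min_phase_locs) {
      dots <- list(...)
      est <- do.call(estimate_phase,
                     c(list(ev, psf, z_start_range = dots$z_range,
                            max_abs_z = 500),
                       dots[setdiff(names(dots), "z_range")]))
      ph <- est$phase
    } else {
      warning("step ", s, ": too few localizations for phase estimation; ",
              "inheriting previous step's phase")
      ph <- prev_phase
    }
    ph_c <- wrap_angle(ph)
    fits <- fit_localization(ev, psf_at_phase(psf, ph_c), ...)
    fits$frame_start <- fits$frame_start + frs[1] - 1
    ft <- attr(movie, "frame_time")
    if (is.null(ft)) ft <- 1
    fits$time <- fits$time + (frs[1] - 1) * ft
    fits$z <- fits$z + step_schedule$stage_z[s]
    fits$step <- s
    fits$stage_z <- step_schedule$stage_z[s]
    fits$phase_hat <- ph_c
    px <- attr(movie, "pixel")
    if (is.null(px)) px <- 1
    fits$x <- fits$x + (fits$frame_start * 0 +
                          vapply(ev, function(e)
                            e$roi_origin[1] + 3 - (dim(movie)[1] + 1) / 2,
                            0)) * px
    fits$y <- fits$y + (vapply(ev, function(e)
      e$roi_origin[2] + 3 - (dim(movie)[2] + 1) / 2, 0)) * px
    prev_phase <- ph_c
    all_locs[[s]] <- fits
    log[[s]] <- data.frame(
      step = s, stage_z = step_schedule$stage_z[s], phase_hat = ph_c,
      n_locs = nrow(fits),
      phase_predicted = if (is.null(cfg)) NA_real_ else
        wrap_angle(predict_step_phase_shift(
          step_schedule$stage_z[s] - step_schedule$stage_z[1], cfg)))
  }
  out <- do.call(rbind, all_locs)
  out <- out[out$converged, ]
  if (register_steps && length(unique(out$step)) > 1 && nrow(out) > 50) {
    traj <- try(estimate_sample_drift(
      transform(out, time = out$step),
      n_windows = length(unique(out$step)), voxel = 20), silent = TRUE)
    if (!inherits(traj, "try-error")) {
      for (s in unique(out$step)) {
        k <- which.min(abs(traj$time - s))
        sel <- out$step == s
        out$x[sel] <- out$x[sel] - traj$dx[k]
        out$y[sel] <- out$y[sel] - traj$dy[k]
        out$z[sel] <- out$z[sel] - traj$dz[k]
      }
    }
  }
  attr(out, "step_log") <- do.call(rbind, log)
  out
}
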
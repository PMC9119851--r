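images_to_matrix <- function(images) {
  if (is.matrix(images)) return(images)
  if (is.array(images) && length(dim(images)) == 4)
    return(matrix(images, ncol = dim(images)[4]))
  if (inherits(images, "emitter_image")) images <- list(images)
  vapply(images, function(im) as.numeric(im$pixels),
         numeric(length(images[[1]]$pixels)))
}

images_meta <- function(images, n) {
  if (is.list(images) && inherits(images[[1]], "emitter_image")) {
    data.frame(
      frame_start = vapply(images, function(i) i$frame_start, 0),
      frame_count = vapply(images, function(i) i$frame_count, 0),
      time = vapply(images, function(i) i$time, 0),
      x0 = vapply(images, function(i) i$xy0[1], 0),
      y0 = vapply(images, function(i) i$xy0[2], 0))
  } else {
    data.frame(frame_start = rep(NA_real_, n), frame_count = NA_real_,
               time = NA_real_, x0 = 0, y0 = 0)
  }
}

# shared low-level multi-start fit wrapper around the compiled LM core
fit_rois_core <- function(psf, data_mat, x0s, y0s, b0s, zstarts,
                          roi_half = 3, pixel = psf$spacing[1],
                          z_range = NULL, max_iter = 50L,
                          rel_tol = 1e-6,
                          weighting = c("poisson", "mle", "none")) {
  weighting <- match.arg(weighting)
  nk <- psf$n_knots
  sup <- function(a) c(psf$origin[a], psf$origin[a] + (nk[a] - 1) *
                         psf$spacing[a])
  eps <- 1e-3
  xl <- sup(1); yl <- sup(2); zl <- sup(3)
  r <- roi_half * pixel
  bounds <- c(xl[1] + r + eps, xl[2] - r - eps,
              yl[1] + r + eps, yl[2] - r - eps,
              zl[1] + eps, zl[2] - eps)
  if (!is.null(z_range)) {
    bounds[5] <- max(bounds[5], z_range[1])
    bounds[6] <- min(bounds[6], z_range[2])
  }
  n <- ncol(data_mat)
  cpp_fit_rois(psf$coef, psf$dims, psf$origin, psf$spacing, data_mat,
               rep_len(as.numeric(x0s), n), rep_len(as.numeric(y0s), n),
               rep_len(as.numeric(b0s), n), zstarts,
               as.integer(roi_half), pixel, bounds, as.integer(max_iter),
               rel_tol, switch(weighting, none = 0L, poisson = 1L, mle = 2L))
}

#' Fit emitter images with the spline PSF model
#'
#' Multi-start least-squares localization: each four-channel ROI is fit by
#' Levenberg-Marquardt (analytic gradients) from several initial z offsets
#' spaced more finely than the PSF fringe period, so that every local
#' minimum of the periodic Chi-square landscape is sampled; the converged
#' start with the lowest Chi-square wins. Lateral starts come from the
#' detection centroid; ties in Chi-square resolve to the smaller |z|.
#'
#' @param images list of `emitter_image`, an array `(w, w, 4, n)`, or a
#'   pixel matrix
#' @param psf a `spline_psf` (or [dynamic_spline_psf()], in which case its
#'   phase-0 template is used)
#' @param z_start_spacing spacing of z starting points, nm; default half
#'   the fringe period
#' @param z_range optional `c(zmin, zmax)` restriction for starts and fits
#' @param roi_half ROI half width (3 for 7x7)
#' @param pixel pixel size, nm
#' @param max_iter,rel_tol Levenberg-Marquardt controls
#' @param weighting `"poisson"` (default) minimizes the data-weighted
#'   Chi-square `sum (d - mu)^2 / max(d, 1)`, asymptotically efficient
#'   for shot-noise-limited data; `"mle"` maximizes the Poisson
#'   likelihood by Fisher scoring (reported `chi2` is then the deviance);
#'   `"none"` is ordinary least squares (appropriate for noiseless
#'   model-comparison studies)
#' @return data.frame with `x, y, z` (nm), `A`, `b`, `chi2`, `photons`,
#'   `converged`, `n_starts`, `fringe_index` and per-image metadata
#' @export
fit_localization <- function(images, psf, z_start_spacing = NULL,
                             z_range = NULL, roi_half = 3,
                             pixel = NULL, max_iter = 50L,
                             rel_tol = 1e-6,
                             weighting = c("poisson", "mle", "none")) {
  weighting <- match.arg(weighting)
  psf <- as_spline_psf(psf)
  if (is.null(pixel)) pixel <- psf$spacing[1]
  dat <- images_to_matrix(images)
  n <- ncol(dat)
  meta <- images_meta(images, n)
  p <- psf$fringe_period
  if (is.null(z_start_spacing)) z_start_spacing <- p / 2
  nk <- psf$n_knots
  zlim <- c(psf$origin[3], psf$origin[3] + (nk[3] - 1) * psf$spacing[3])
  if (!is.null(z_range)) {
    zlim[1] <- max(zlim[1], z_range[1])
    zlim[2] <- min(zlim[2], z_range[2])
  }
  marg <- min(20, diff(zlim) * 0.01)
  zst <- matrix(seq(zlim[1] + marg, zlim[2] - marg, by = z_start_spacing),
                ncol = 1)
  # robust per-image background start: lower quantile over all pixels
  b0s <- apply(dat, 2, quantile, probs = 0.2)
  res <- fit_rois_core(psf, dat, x0s = meta$x0, y0s = meta$y0, b0s = b0s,
                       zstarts = zst, roi_half = roi_half, pixel = pixel,
                       z_range = z_range, max_iter = max_iter,
                       rel_tol = rel_tol, weighting = weighting)
  out <- as.data.frame(res)
  out$b <- pmax(out$b, 0)
  out$converged <- out$converged > 0
  out$photons <- out$A * psf_flux(psf, ifelse(is.na(out$z), 0, out$z))
  out$fringe_index <- as.integer(round(out$z / p))
  names(out)[names(out) == "n_converged"] <- "n_starts"
  cbind(out, meta[, c("frame_start", "frame_count", "time")])
}

#' Detect emitter candidates in a four-channel movie
#'
#' Sums the four channels of each frame (the quadrature phase offsets make
#' the sum effectively interference-free, so detection is insensitive to
#' the emitter z), finds local maxima above `median + k * mad`, and refines
#' each with a 2D Gaussian fit on a square window.
#'
#' @param movie array `(nx, ny, 4, n_frames)`
#' @param threshold_k detection threshold in robust standard deviations
#' @param fit_window Gaussian fit window, pixels (odd)
#' @param min_sep candidates closer than this (pixels) merge into one
#' @return data.frame `frame, x_px, y_px, sigma_px, amplitude, offset, peak`
#' @export
detect_candidates <- function(movie, threshold_k = 6, fit_window = 11,
                              min_sep = 2) {
  d <- dim(movie)
  stopifnot(length(d) == 4, d[3] == 4)
  half <- (fit_window - 1) / 2
  out <- list()
  for (fr in seq_len(d[4])) {
    ss <- rowSums(movie[, , , fr, drop = FALSE], dims = 2)
    thr <- median(ss) + threshold_k * max(mad(ss), 1e-9)
    peaks <- which(ss > thr, arr.ind = TRUE)
    if (nrow(peaks) == 0) next
    keep <- logical(nrow(peaks))
    for (i in seq_len(nrow(peaks))) {
      px <- peaks[i, 1]; py <- peaks[i, 2]
      nb <- ss[max(1, px - 1):min(d[1], px + 1),
               max(1, py - 1):min(d[2], py + 1)]
      keep[i] <- ss[px, py] >= max(nb)
    }
    peaks <- peaks[keep, , drop = FALSE]
    if (nrow(peaks) > 1) { # merge near-coincident peaks, keep the brighter
      vals <- ss[peaks]
      ord <- order(vals, decreasing = TRUE)
      sel <- logical(nrow(peaks))
      for (i in ord) {
        if (any(sel & abs(peaks[, 1] - peaks[i, 1]) < min_sep &
                  abs(peaks[, 2] - peaks[i, 2]) < min_sep)) next
        sel[i] <- TRUE
      }
      peaks <- peaks[sel, , drop = FALSE]
    }
    for (i in seq_len(nrow(peaks))) {
      px <- peaks[i, 1]; py <- peaks[i, 2]
      wx <- max(1, px - half):min(d[1], px + half)
      wy <- max(1, py - half):min(d[2], py + half)
      g <- fit_gauss2d(ss[wx, wy], wx, wy)
      out[[length(out) + 1]] <- data.frame(
        frame = fr, x_px = g$x, y_px = g$y, sigma_px = g$sigma,
        amplitude = g$amp, offset = g$offset, peak = ss[px, py])
    }
  }
  if (length(out) == 0)
    return(data.frame(frame = integer(), x_px = numeric(),
                      y_px = numeric(), sigma_px = numeric(),
                      amplitude = numeric(), offset = numeric(),
                      peak = numeric()))
  do.call(rbind, out)
}

# 2D Gaussian least-squares fit on a small window (moments + Nelder-Mead)
fit_gauss2d <- function(img, xs, ys) {
  off <- min(img)
  w <- pmax(img - off, 0)
  tot <- sum(w)
  if (tot <= 0) return(list(x = mean(xs), y = mean(ys), sigma = 1,
                            amp = 0, offset = off))
  mx <- sum(outer(xs, rep(1, length(ys))) * w) / tot
  my <- sum(outer(rep(1, length(xs)), ys) * w) / tot
  vx <- sum(outer((xs - mx)^2, rep(1, length(ys))) * w) / tot
  vy <- sum(outer(rep(1, length(xs)), (ys - my)^2) * w) / tot
  s0 <- sqrt(max((vx + vy) / 2, 0.25))
  p0 <- c(mx, my, log(s0), max(img) - off, off)
  obj <- function(p) {
    mdl <- p[5] + p[4] * exp(-(outer((xs - p[1])^2, (ys - p[2])^2, "+")) /
                               (2 * exp(2 * p[3])))
    sum((img - mdl)^2)
  }
  o <- stats::optim(p0, obj, method = "Nelder-Mead",
                    control = list(maxit = 300))
  px <- o$par
  # clipped or low-signal windows can send the unconstrained fit astray;
  # fall back to the moment estimates then
  bad <- px[1] < min(xs) || px[1] > max(xs) || px[2] < min(ys) ||
    px[2] > max(ys) || exp(px[3]) < 0.3 || exp(px[3]) > length(xs)
  if (bad) px <- p0
  list(x = px[1], y = px[2], sigma = exp(px[3]),
       amp = px[4], offset = px[5])
}

#' Group per-frame candidates into switching events
#'
#' Links candidates within `link_radius` pixels across consecutive frames
#' (no gap tolerance) into one fluorophore switching event, and sums the
#' cropped four-channel pixel data over the event's frames.
#'
#' @param cands a [detect_candidates()] data.frame (frame-ordered)
#' @param movie the source movie array `(nx, ny, 4, n_frames)`
#' @param link_radius maximum per-frame movement, pixels
#' @param roi_half crop half width (3 for the 7x7 ROI)
#' @param pixel pixel size, nm
#' @param frame_time seconds per frame
#' @return list of `emitter_image`
#' @export
group_events <- function(cands, movie, link_radius = 1, roi_half = 3,
                         pixel = attr(movie, "pixel"),
                         frame_time = attr(movie, "frame_time")) {
  d <- dim(movie)
  if (is.null(pixel)) pixel <- 1
  if (is.null(frame_time)) frame_time <- 1
  if (nrow(cands) == 0) return(list())
  cands <- cands[order(cands$frame), ]
  cands$track <- NA_integer_
  ntr <- 0
  last <- data.frame(track = integer(), frame = integer(), x = numeric(),
                     y = numeric())
  for (i in seq_len(nrow(cands))) {
    fr <- cands$frame[i]
    prev <- last[last$frame == fr - 1, ]
    hit <- which(abs(prev$x - cands$x_px[i]) <= link_radius &
                   abs(prev$y - cands$y_px[i]) <= link_radius)
    if (length(hit) > 0) {
      tr <- prev$track[hit[1]]
    } else {
      ntr <- ntr + 1
      tr <- ntr
    }
    cands$track[i] <- tr
    last <- last[last$track != tr, ]
    last <- rbind(last, data.frame(track = tr, frame = fr,
                                   x = cands$x_px[i], y = cands$y_px[i]))
    last <- last[last$frame >= fr - 1, ]
  }
  events <- list()
  for (tr in unique(cands$track)) {
    sub <- cands[cands$track == tr, ]
    cx <- round(sub$x_px[1]); cy <- round(sub$y_px[1])
    if (cx - roi_half < 1 || cy - roi_half < 1 ||
        cx + roi_half > d[1] || cy + roi_half > d[2]) next
    px <- array(0, dim = c(2 * roi_half + 1, 2 * roi_half + 1, 4))
    for (fr in sub$frame)
      px <- px + movie[(cx - roi_half):(cx + roi_half),
                       (cy - roi_half):(cy + roi_half), , fr]
    events[[length(events) + 1]] <- structure(list(
      pixels = px, frame_start = sub$frame[1], frame_count = nrow(sub),
      roi_origin = c(cx - roi_half, cy - roi_half),
      time = (mean(sub$frame) - 1) * frame_time,
      xy0 = c((mean(sub$x_px) - cx) * pixel, (mean(sub$y_px) - cy) * pixel),
      pixel = pixel), class = "emitter_image")
  }
  events
}

#' Cramer-Rao lower bound for spline PSF localization
#'
#' Fisher information of the four-channel imaging model under Poisson
#' noise, `I_ab = sum_pixels (dmu/da)(dmu/db) / mu` with
#' `mu = A f_S + b`, inverted to give the minimum standard deviation of an
#' unbiased estimator of each coordinate. When the background is zero the
#' `b` parameter is dropped from the information matrix (its information
#' diverges as pixels approach zero mean).
#'
#' @param psf a `spline_psf`
#' @param params `(x0, y0, z0, A, b)` at which to evaluate the bound
#' @param roi_half,pixel ROI geometry
#' @return list with `crlb_x`, `crlb_y`, `crlb_z` (nm), `crlb_photons`,
#'   `crlb_b` and `fisher_condition`
#' @export
compute_crlb <- function(psf, params, roi_half = 3,
                         pixel = psf$spacing[1]) {
  psf <- as_spline_psf(psf)
  th <- roi_params(params)
  ev <- evaluate_gradient(psf, th, roi_half = roi_half, pixel = pixel)
  mu <- as.numeric(ev$mu)
  J <- matrix(ev$J, nrow = length(mu))
  use_b <- th[5] > 1e-9
  if (!use_b) J <- J[, 1:4, drop = FALSE]
  ok <- mu > 1e-12
  Jw <- J[ok, , drop = FALSE] / sqrt(mu[ok])
  I <- crossprod(Jw)
  cond <- kappa(I, exact = TRUE)
  if (!is.finite(cond) || cond > 1e14)
    return(list(crlb_x = NA_real_, crlb_y = NA_real_, crlb_z = NA_real_,
                crlb_photons = NA_real_, crlb_b = NA_real_,
                fisher_condition = cond))
  cr <- sqrt(diag(solve(I)))
  list(crlb_x = cr[1], crlb_y = cr[2], crlb_z = cr[3],
       crlb_photons = cr[4] * psf_flux(psf, th[3]),
       crlb_b = if (use_b) cr[5] else NA_real_,
       fisher_condition = cond)
}

#' Fraction of localizations assigned to the wrong interference fringe
#'
#' A localization is misassigned when its fitted z differs from the true z
#' by more than half the fringe period -- the signature of the periodic
#' ghost-image artifact, which displaces emitters by multiples of ~lambda/2
#' along z.
#'
#' @param fits a [fit_localization()] data.frame
#' @param true_z true z per fit, nm
#' @param fringe_period nm
#' @param bin_width z bin width for the per-bin breakdown, nm
#' @return list with `overall` (fraction over converged fits) and `by_bin`
#'   (data.frame `z_bin`, `n`, `fraction`)
#' @export
artifact_fraction <- function(fits, true_z, fringe_period,
                              bin_width = 100) {
  ok <- fits$converged
  mis <- abs(fits$z[ok] - true_z[ok]) > fringe_period / 2
  zb <- round(true_z[ok] / bin_width) * bin_width
  by_bin <- do.call(rbind, lapply(split(mis, zb), function(m)
    data.frame(n = length(m), fraction = mean(m))))
  by_bin$z_bin <- as.numeric(rownames(by_bin))
  rownames(by_bin) <- NULL
  list(overall = mean(mis), by_bin = by_bin[, c("z_bin", "n", "fraction")])
}
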
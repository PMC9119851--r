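#' Scalar 4Pi PSF intensity model
#'
#' Evaluates the simulator's scalar interference model of the symmetric 4Pi
#' PSF as an intensity density (per nm^2). The channel-summed density
#' integrates to 1 over the lateral plane at every z: the quadrature phase
#' offsets cancel the modulation in the sum, and detected flux is conserved
#' along z (defocus spreads the light, the coherence envelope only reduces
#' fringe contrast).
#'
#' @param x,y,z coordinates relative to the emitter, nm (recycled)
#' @param cfg a [fourpi_config()]
#' @param channel channel index 1..4 (p1, s1, p2, s2), recycled
#' @return intensity density values
#' @export
fourpi_intensity <- function(x, y, z, cfg, channel) {
  k <- 2 * pi / fringe_period(cfg)
  sig <- sqrt(cfg$envelope_lateral_sigma0^2 +
                (cfg$defocus_spread_rate * (z - cfg$focus_offset))^2)
  lat <- exp(-(x^2 + y^2) / (2 * sig^2)) / (2 * pi * sig^2)
  az <- exp(-z^2 / (2 * cfg$envelope_axial_sigma^2))
  w <- c(1, cfg$sp_amplitude_ratio, 1, cfg$sp_amplitude_ratio)
  delta <- cfg$channel_phase_offsets[channel]
  modc <- 1 + cfg$modulation_depth * az * cos(k * z + delta - cfg$phase)
  w[channel] * lat * modc / (2 * (1 + cfg$sp_amplitude_ratio))
}

#' Generate a noiseless symmetric 4Pi PSF on a voxel grid
#'
#' Samples the scalar interference model at pixel centers, producing a
#' four-channel bead stack like the one measured by scanning a fluorescent
#' bead through focus. Each plane holds expected counts per pixel for unit
#' total flux; the stack is normalized so the four-channel z = 0 lateral
#' sum over the grid equals 1.
#'
#' @param cfg a [fourpi_config()]
#' @param n_xy lateral extent in pixels (odd recommended)
#' @param n_z number of z planes
#' @param z_step axial plane spacing, nm
#' @param pixel lateral pixel size, nm (defaults to the config value)
#' @return a [bead_stack()]
#' @export
make_symmetric_4pi_psf <- function(cfg, n_xy = 17, n_z = 150, z_step = 20,
                                   pixel = cfg$pixel_size_lateral) {
  stopifnot(n_xy >= 3, n_z >= 2, z_step > 0, pixel > 0)
  span <- (n_z - 1) * z_step
  if (span < fringe_period(cfg))
    stop("axial grid does not contain one interference fringe period")
  xs <- (seq_len(n_xy) - (n_xy + 1) / 2) * pixel
  zs <- (seq_len(n_z) - (n_z + 1) / 2) * z_step
  r2 <- outer(xs^2, xs^2, "+")
  k <- 2 * pi / fringe_period(cfg)
  w <- c(1, cfg$sp_amplitude_ratio, 1, cfg$sp_amplitude_ratio)
  norm <- 2 * (1 + cfg$sp_amplitude_ratio)
  dat <- array(0, dim = c(n_xy, n_xy, n_z, 4))
  for (iz in seq_len(n_z)) {
    z <- zs[iz]
    sig <- sqrt(cfg$envelope_lateral_sigma0^2 +
                  (cfg$defocus_spread_rate * (z - cfg$focus_offset))^2)
    lat <- exp(-r2 / (2 * sig^2)) / (2 * pi * sig^2) * pixel^2
    az <- exp(-z^2 / (2 * cfg$envelope_axial_sigma^2))
    for (c in 1:4) {
      modc <- 1 + cfg$modulation_depth * az *
        cos(k * z + cfg$channel_phase_offsets[c] - cfg$phase)
      dat[, , iz, c] <- lat * (w[c] * modc / norm)
    }
  }
  # normalize by the in-window four-channel flux at z = 0
  sig0 <- sqrt(cfg$envelope_lateral_sigma0^2 +
                 (cfg$defocus_spread_rate * cfg$focus_offset)^2)
  f0 <- sum(exp(-r2 / (2 * sig0^2)) / (2 * pi * sig0^2) * pixel^2)
  bead_stack(dat / f0, voxel = c(pixel, pixel, z_step),
             fringe_period = fringe_period(cfg))
}

#' Ground-truth emitter description
#'
#' @param x,y,z true emitter coordinates, nm (x, y relative to the ROI or
#'   field center)
#' @param photons expected detected photons per switching event, all four
#'   channels combined
#' @param background expected background photons per pixel per frame
#' @param frames_on frame indices during which the emitter is on
#' @param color dye label
#' @return an object of class `gt_emitter`
#' @export
ground_truth_emitter <- function(x = 0, y = 0, z = 0, photons = 8000,
                                 background = 10, frames_on = 1L,
                                 color = "AF647") {
  stopifnot(photons > 0, background >= 0)
  structure(list(x = x, y = y, z = z, photons = photons,
                 background = background, frames_on = as.integer(frames_on),
                 color = color), class = "gt_emitter")
}

#' Simulate a four-channel emitter image
#'
#' Draws a cropped four-channel ROI of one switching event: Poisson counts
#' around `photons * PSF + background`. The PSF may be the analytic scalar
#' model (a config) or a spline model; in both cases the expected total
#' signal equals `emitter$photons` up to the loss from truncating the PSF at
#' the ROI border.
#'
#' @param psf a [fourpi_config()] or a `spline_psf`
#' @param emitter a [ground_truth_emitter()]
#' @param roi_half ROI half width in pixels (3 gives the 7x7 ROI)
#' @param pixel pixel size, nm
#' @param seed optional RNG seed
#' @param noiseless if TRUE return the expectation instead of Poisson draws
#' @return an `emitter_image`: list with `pixels` (roi x roi x 4 counts),
#'   `frame_start`, `frame_count`, `time`
#' @export
simulate_emitter_image <- function(psf, emitter, roi_half = 3,
                                   pixel = NULL, seed = NULL,
                                   noiseless = FALSE) {
  run <- function() {
    w <- 2 * roi_half + 1
    if (inherits(psf, "fourpi_config")) {
      px <- if (is.null(pixel)) psf$pixel_size_lateral else pixel
      xs <- (seq_len(w) - roi_half - 1) * px
      g <- expand.grid(x = xs, y = xs, c = 1:4)
      mu <- emitter$photons * px^2 *
        fourpi_intensity(g$x - emitter$x, g$y - emitter$y, emitter$z,
                         psf, g$c)
      mu <- array(mu, dim = c(w, w, 4))
    } else if (inherits(psf, "spline_psf")) {
      px <- if (is.null(pixel)) psf$spacing[1] else pixel
      flux <- psf_flux(psf, emitter$z)
      mu <- evaluate_model(psf,
                           list(x0 = emitter$x, y0 = emitter$y,
                                z0 = emitter$z,
                                A = emitter$photons / flux, b = 0),
                           roi_half = roi_half, pixel = px)
    } else stop("psf must be a fourpi_config or a spline_psf")
    mu <- mu + emitter$background
    pixels <- if (noiseless) mu else
      array(rpois(length(mu), mu), dim = dim(mu))
    structure(list(pixels = pixels, frame_start = emitter$frames_on[1],
                   frame_count = length(emitter$frames_on),
                   roi_origin = c(NA_real_, NA_real_), time = 0,
                   xy0 = c(0, 0), pixel = px),
              class = "emitter_image")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a bead z-scan
#'
#' Emulates scanning a fluorescent bead through the focal plane: one frame
#' per stage position, evenly spaced over `z_range`. With
#' `photons_per_frame = NULL` the scan is noiseless with unit per-frame flux
#' (the oracle mode); otherwise each frame holds Poisson counts with the
#' requested mean total intensity.
#'
#' @param cfg a [fourpi_config()]
#' @param z_range total scan depth, nm
#' @param n_steps number of stage steps (frames)
#' @param photons_per_frame expected detected photons per frame, or NULL
#' @param background background photons per pixel per frame
#' @param n_xy lateral extent, pixels
#' @param seed optional RNG seed
#' @return a raw [bead_stack()] with voxel z size `z_range / n_steps`
#' @export
simulate_bead_scan <- function(cfg, z_range = 3000, n_steps = 3000,
                               photons_per_frame = NULL, background = 0,
                               n_xy = 17, seed = NULL) {
  stopifnot(n_steps >= 2, z_range > 0)
  run <- function() {
    dz <- z_range / n_steps
    stk <- make_symmetric_4pi_psf(cfg, n_xy = n_xy, n_z = n_steps,
                                  z_step = dz)
    if (!is.null(photons_per_frame)) {
      dat <- stk$data * photons_per_frame + background
      stk$data <- array(rpois(length(dat), dat), dim = dim(dat))
    }
    stk
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Drift traces for a simulated experiment
#'
#' Per-frame PSF-phase drift, 3D sample drift and (optionally) a staircase
#' z-stage schedule. All traces are defined for every frame.
#'
#' @param n_frames number of movie frames
#' @param phase PSF phase per frame, radians (scalar recycled)
#' @param xyz n_frames x 3 matrix of sample drift, nm (or NULL for none)
#' @param stage_z stage z position per frame, nm (scalar recycled)
#' @return an object of class `drift_traces`
#' @export
drift_traces <- function(n_frames, phase = 0, xyz = NULL, stage_z = 0) {
  phase <- rep_len(phase, n_frames)
  stage_z <- rep_len(stage_z, n_frames)
  if (is.null(xyz)) xyz <- matrix(0, n_frames, 3)
  stopifnot(nrow(xyz) == n_frames, ncol(xyz) == 3)
  structure(list(n_frames = as.integer(n_frames), phase = phase,
                 xyz = xyz, stage_z = stage_z), class = "drift_traces")
}

#' Simulate a 4Pi-STORM experiment
#'
#' Composes the scalar PSF model with per-frame phase drift, 3D sample drift
#' and an optional stage schedule into a four-channel movie plus a
#' ground-truth table. Emitter positions are given in nm relative to the
#' field center. A stage displacement shifts the apparent emitter z and adds
#' the index-mismatch phase shift predicted by the low-NA approximation
#' (see [predict_step_phase_shift()]).
#'
#' @param cfg a [fourpi_config()]
#' @param emitters list of [ground_truth_emitter()]
#' @param drift a [drift_traces()] (defaults to no drift)
#' @param n_frames number of frames
#' @param field_px field width in pixels
#' @param frame_time seconds per frame
#' @param seed optional RNG seed
#' @return list with `movie` (field x field x 4 x n_frames counts),
#'   `truth` (data.frame of per-frame emitter ground truth) and `drift`
#' @export
simulate_experiment <- function(cfg, emitters, drift = NULL, n_frames = 100,
                                field_px = 32, frame_time = 0.01,
                                seed = NULL) {
  if (inherits(emitters, "gt_emitter")) emitters <- list(emitters)
  if (is.null(drift)) drift <- drift_traces(n_frames)
  stopifnot(drift$n_frames >= n_frames)
  run <- function() {
    px <- cfg$pixel_size_lateral
    movie <- array(0, dim = c(field_px, field_px, 4, n_frames))
    bg <- max(vapply(emitters, function(e) e$background, 0))
    centers <- (seq_len(field_px) - (field_px + 1) / 2) * px
    truth <- list()
    for (fr in seq_len(n_frames)) {
      mu <- array(bg, dim = c(field_px, field_px, 4))
      cfr <- cfg
      cfr$phase <- cfg$phase + drift$phase[fr] +
        predict_step_phase_shift(drift$stage_z[fr], cfg)
      for (ie in seq_along(emitters)) {
        e <- emitters[[ie]]
        if (!(fr %in% e$frames_on)) next
        ex <- e$x + drift$xyz[fr, 1]
        ey <- e$y + drift$xyz[fr, 2]
        ez <- e$z + drift$xyz[fr, 3] - drift$stage_z[fr]
        ix <- which.min(abs(centers - ex))
        iy <- which.min(abs(centers - ey))
        wx <- max(1, ix - 5):min(field_px, ix + 5)
        wy <- max(1, iy - 5):min(field_px, iy + 5)
        g <- expand.grid(x = centers[wx], y = centers[wy], c = 1:4)
        val <- e$photons * px^2 *
          fourpi_intensity(g$x - ex, g$y - ey, ez, cfr, g$c)
        mu[wx, wy, ] <- mu[wx, wy, ] +
          array(val, dim = c(length(wx), length(wy), 4))
        truth[[length(truth) + 1]] <- data.frame(
          frame = fr, id = ie, x = ex, y = ey, z = e$z + drift$xyz[fr, 3],
          z_apparent = ez, photons = e$photons,
          phase = cfr$phase, stage_z = drift$stage_z[fr],
          time = (fr - 1) * frame_time, color = e$color)
      }
      movie[, , , fr] <- array(rpois(length(mu), mu), dim = dim(mu))
    }
    attr(movie, "pixel") <- px
    attr(movie, "frame_time") <- frame_time
    list(movie = movie, truth = do.call(rbind, truth), drift = drift)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
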
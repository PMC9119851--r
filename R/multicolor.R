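#' Ratio of s-polarized to p-polarized photons
#'
#' Background-corrected photon ratio between the two s channels (s1, s2)
#' and the two p channels (p1, p2) of an emitter image. With the multicolor
#' spectral filters in place this ratio is ~0.6 for Alexa Fluor 647 and
#' ~0.9 for Cy5.5 and provides the initial color assignment.
#'
#' @param img an `emitter_image` (or bare `(w, w, 4)` array)
#' @param b fitted per-pixel background (shared across channels); 0 if the
#'   image is already background-free
#' @return the s/p ratio, or NA if the background-corrected p signal is
#'   not positive (unclassifiable)
#' @export
compute_sp_ratio <- function(img, b = 0) {
  px <- if (inherits(img, "emitter_image")) img$pixels else img
  stopifnot(length(dim(px)) == 3, dim(px)[3] == 4)
  npx <- prod(dim(px)[1:2])
  s <- sum(px[, , c(2, 4)]) - 2 * npx * b
  p <- sum(px[, , c(1, 3)]) - 2 * npx * b
  if (p <= 0) return(NA_real_)
  s / p
}

#' Rescale the s-channel amplitude of a PSF model
#'
#' Produces a fluorophore-specific PSF by multiplying the s-channel (s1,
#' s2) spline coefficients so their amplitude relative to the p channels
#' becomes `s_scale`. Rescaling is exact on the model (linear in the
#' coefficients) and invertible.
#'
#' @param psf a `spline_psf` or [dynamic_spline_psf()]
#' @param s_scale target absolute s/p amplitude ratio (e.g. 0.6 for
#'   AF647, 0.9 for Cy5.5); the current ratio is measured from the model
#'   with [psf_sp_ratio()]
#' @return the rescaled model (same class as the input)
#' @export
rescale_psf <- function(psf, s_scale) {
  stopifnot(s_scale > 0)
  scale_coef <- function(co, f) {
    co[, , , , c(2, 4)] <- co[, , , , c(2, 4)] * f
    co
  }
  if (inherits(psf, "dyn_spline_psf")) {
    f <- s_scale / psf_sp_ratio(psf$template)
    psf$env_coef <- scale_coef(psf$env_coef, f)
    psf$mod_coef <- scale_coef(psf$mod_coef, f)
    psf$q_coef <- scale_coef(psf$q_coef, f)
    psf$template <- rescale_psf(psf$template, s_scale)
    return(psf)
  }
  stopifnot(inherits(psf, "spline_psf"))
  f <- s_scale / psf_sp_ratio(psf)
  psf$coef <- scale_coef(psf$coef, f)
  psf$sp_scale <- s_scale
  psf
}

#' Estimate the s/p amplitude scale of a fluorophore from data
#'
#' Fits a sample of localizations with a series of PSF models of varying
#' s/p amplitude ratio; the mean Chi-square versus scale curve has its
#' minimum at the data's true ratio, located by a parabola fit through the
#' three points around the grid minimum.
#'
#' @param images emitter images of one color species
#' @param psf a `spline_psf` or [dynamic_spline_psf()]
#' @param scale_grid candidate s/p scales
#' @param ... passed to [fit_localization()]
#' @return list with `scale`, `curve` (data.frame `scale`, `mean_chi2`)
#'   and a `flat` flag
#' @export
estimate_sp_scale <- function(images, psf,
                              scale_grid = seq(0.4, 1.1, by = 0.05),
                              ...) {
  base <- as_spline_psf(psf)
  mc <- vapply(scale_grid, function(s) {
    fits <- fit_localization(images, rescale_psf(base, s), ...)
    mean(fits$chi2[fits$converged])
  }, 0)
  k <- which.min(mc)
  best <- scale_grid[k]
  if (k > 1 && k < length(mc)) {
    den <- mc[k - 1] - 2 * mc[k] + mc[k + 1]
    if (den > 1e-12)
      best <- best + 0.5 * (mc[k - 1] - mc[k + 1]) / den *
        (scale_grid[2] - scale_grid[1])
  }
  flat <- (max(mc) - min(mc)) < 1e-3 * max(abs(mc), 1e-12)
  list(scale = best, curve = data.frame(scale = scale_grid, mean_chi2 = mc),
       flat = flat)
}

#' Effective s/p amplitude ratio of a PSF model
#'
#' Ratio of the total s-channel (s1 + s2) to p-channel (p1 + p2) model
#' flux in a near-focus ROI.
#'
#' @param psf a `spline_psf`
#' @return the s/p flux ratio
#' @export
psf_sp_ratio <- function(psf) {
  psf <- as_spline_psf(psf)
  if (psf$dims[5] < 4) return(NA_real_)
  half_extent <- (psf$n_knots[1] - 1) / 2 * psf$spacing[1]
  rh <- max(1, min(5, floor(half_extent / psf$spacing[1] / 2)))
  zmid <- psf$origin[3] + (psf$n_knots[3] - 1) / 2 * psf$spacing[3]
  img <- evaluate_model(psf, c(0, 0, zmid, 1, 0), roi_half = rh)
  sum(img[, , c(2, 4)]) / sum(img[, , c(1, 3)])
}

#' Two-dye PSF model set for ratiometric color assignment
#'
#' @param psf_af647 spline model with the AF647 s/p scale (~0.6)
#' @param psf_cy55 spline model with the Cy5.5 s/p scale (~0.9)
#' @param threshold s/p ratio cut for the initial assignment (midpoint of
#'   the two dye ratios by default)
#' @param chromatic_z_offset residual chromatic z offset between the dyes,
#'   nm, subtracted from the `offset_dye` coordinates
#' @param offset_dye which dye carries the chromatic offset
#' @return a `color_model_set`
#' @export
color_model_set <- function(psf_af647, psf_cy55, threshold = 0.75,
                            chromatic_z_offset = 10,
                            offset_dye = c("Cy5.5", "AF647")) {
  offset_dye <- match.arg(offset_dye)
  s1 <- psf_sp_ratio(as_spline_psf(psf_af647))
  s2 <- psf_sp_ratio(as_spline_psf(psf_cy55))
  if (!(threshold > min(s1, s2) && threshold < max(s1, s2)))
    stop("threshold must lie strictly between the two dye s/p ratios")
  structure(list(psf_af647 = psf_af647, psf_cy55 = psf_cy55,
                 threshold = threshold,
                 chromatic_z_offset = chromatic_z_offset,
                 offset_dye = offset_dye), class = "color_model_set")
}

#' Assign fluorophore colors by best-fitting PSF model
#'
#' Fits every image with both fluorophore-specific (s/p-rescaled) PSF
#' models and assigns the color of the better fit (lower Chi-square). The
#' localization coordinates are taken from the winning fit, and the
#' chromatic z offset is subtracted from the designated dye's z
#' coordinates. Images for which neither fit converges stay unclassified.
#'
#' @param images emitter images
#' @param models a [color_model_set()]
#' @param ... passed to [fit_localization()]
#' @return data.frame: winning fit parameters plus `color`, `chi2_af647`,
#'   `chi2_cy55` and `sp_ratio`
#' @export
assign_color <- function(images, models, ...) {
  f1 <- fit_localization(images, models$psf_af647, ...)
  f2 <- fit_localization(images, models$psf_cy55, ...)
  n <- nrow(f1)
  pick1 <- ifelse(is.na(f1$chi2), FALSE,
                  ifelse(is.na(f2$chi2), TRUE, f1$chi2 <= f2$chi2))
  out <- f1
  out[!pick1, ] <- f2[!pick1, ]
  out$color <- ifelse(!f1$converged & !f2$converged, NA_character_,
                      ifelse(pick1, "AF647", "Cy5.5"))
  off_col <- if (models$offset_dye == "Cy5.5") "Cy5.5" else "AF647"
  sel <- !is.na(out$color) & out$color == off_col
  out$z[sel] <- out$z[sel] - models$chromatic_z_offset
  out$chi2_af647 <- f1$chi2
  out$chi2_cy55 <- f2$chi2
  mat <- images_to_matrix(images)
  w2 <- nrow(mat) / 4
  out$sp_ratio <- vapply(seq_len(n), function(i) {
    px <- array(mat[, i], dim = c(sqrt(w2), sqrt(w2), 4))
    compute_sp_ratio(px, b = max(0, out$b[i]))
  }, 0)
  out
}
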
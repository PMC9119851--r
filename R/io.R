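LOCS_SCHEMA_V <- "fourpi-locs-v1"
LOCS_REQUIRED <- c("frame", "x", "y", "z", "photons", "background", "chi2")

#' Write a four-channel movie or bead stack as multi-page TIFF
#'
#' Two dialects are supported and recorded in a JSON sidecar
#' (`<path>.json`): `"per_channel"` writes one page per channel per frame
#' (channel-major within each frame), `"quadrant"` writes one page per
#' frame with the four channels as quadrants (p1 top-left, s1 top-right,
#' p2 bottom-left, s2 bottom-right in array coordinates). 16-bit storage
#' round-trips integer counts up to 65535 exactly; 32-bit stores float32.
#'
#' @param movie array `(nx, ny, 4, n_frames)` or a [bead_stack()]
#' @param path output TIFF path
#' @param dialect page layout
#' @param bits 16 (integer counts) or 32 (float)
#' @return `path`, invisibly
#' @export
write_movie <- function(movie, path, dialect = c("per_channel", "quadrant"),
                        bits = 16) {
  dialect <- match.arg(dialect)
  meta <- list(format = "fourpi-movie-v1", dialect = dialect, bits = bits)
  if (inherits(movie, "bead_stack")) {
    meta$voxel <- movie$voxel
    meta$z_origin <- movie$z_origin
    meta$kind <- "bead_stack"
    movie <- aperm(movie$data, c(1, 2, 4, 3)) # one "frame" per z plane
  } else {
    meta$kind <- "movie"
    meta$pixel <- attr(movie, "pixel")
    meta$frame_time <- attr(movie, "frame_time")
  }
  d <- dim(movie)
  stopifnot(length(d) == 4, d[3] == 4 || d[4] >= 1)
  if (d[3] != 4) stop("expected channels in the third dimension")
  meta$dim <- d
  if (bits == 16) {
    if (any(movie < 0) || any(movie > 65535) ||
        any(abs(movie - round(movie)) > 1e-6))
      stop("16-bit storage requires integer counts in [0, 65535]")
    sc <- 65535
  } else sc <- 1
  pages <- list()
  for (fr in seq_len(d[4])) {
    if (dialect == "per_channel") {
      for (c in 1:4) pages[[length(pages) + 1]] <- movie[, , c, fr] / sc
    } else {
      q <- matrix(0, 2 * d[1], 2 * d[2])
      q[seq_len(d[1]), seq_len(d[2])] <- movie[, , 1, fr]
      q[seq_len(d[1]), d[2] + seq_len(d[2])] <- movie[, , 2, fr]
      q[d[1] + seq_len(d[1]), seq_len(d[2])] <- movie[, , 3, fr]
      q[d[1] + seq_len(d[1]), d[2] + seq_len(d[2])] <- movie[, , 4, fr]
      pages[[length(pages) + 1]] <- q / sc
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a movie or bead stack written by [write_movie()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must exist)
#' @return the movie array with attributes, or a [bead_stack()]
#' @export
read_movie <- function(path) {
  metafile <- paste0(path, ".json")
  if (!file.exists(metafile)) stop("missing metadata sidecar ", metafile)
  meta <- jsonlite::read_json(metafile, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- meta$dim
  expect_pages <- if (meta$dialect == "per_channel") 4 * d[4] else d[4]
  if (length(pages) != expect_pages)
    stop("inconsistent page count: expected ", expect_pages, ", found ",
         length(pages))
  sc <- if (meta$bits == 16) 65535 else 1
  movie <- array(0, dim = d)
  for (fr in seq_len(d[4])) {
    if (meta$dialect == "per_channel") {
      for (c in 1:4) {
        v <- pages[[(fr - 1) * 4 + c]] * sc
        movie[, , c, fr] <- if (meta$bits == 16) round(v) else v
      }
    } else {
      q <- pages[[fr]] * sc
      if (meta$bits == 16) q <- round(q)
      movie[, , 1, fr] <- q[seq_len(d[1]), seq_len(d[2])]
      movie[, , 2, fr] <- q[seq_len(d[1]), d[2] + seq_len(d[2])]
      movie[, , 3, fr] <- q[d[1] + seq_len(d[1]), seq_len(d[2])]
      movie[, , 4, fr] <- q[d[1] + seq_len(d[1]), d[2] + seq_len(d[2])]
    }
  }
  if (identical(meta$kind, "bead_stack"))
    return(bead_stack(aperm(movie, c(1, 2, 4, 3)), voxel = meta$voxel,
                      z_origin = meta$z_origin))
  attr(movie, "pixel") <- meta$pixel
  attr(movie, "frame_time") <- meta$frame_time
  movie
}

#' Write a localization table as versioned CSV
#'
#' The first line is a schema comment naming the version and units
#' (nm, photons, seconds); mandatory columns are `frame, x, y, z, photons,
#' background, chi2`.
#'
#' @param locs localization data.frame
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_locs <- function(locs, path) {
  miss <- setdiff(LOCS_REQUIRED, names(locs))
  if (length(miss) > 0)
    stop("localization table missing mandatory columns: ",
         paste(miss, collapse = ", "))
  con <- file(path, "w")
  writeLines(sprintf("# %s | units: nm, photons, s", LOCS_SCHEMA_V), con)
  close(con)
  data.table::fwrite(locs, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a localization table written by [write_locs()]
#'
#' @param path CSV path
#' @return data.frame of localizations
#' @export
read_locs <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl(LOCS_SCHEMA_V, first, fixed = TRUE))
    stop("not a ", LOCS_SCHEMA_V, " file: ", path)
  out <- as.data.frame(data.table::fread(path, skip = 1))
  miss <- setdiff(LOCS_REQUIRED, names(out))
  if (length(miss) > 0)
    stop("localization table missing mandatory columns: ",
         paste(miss, collapse = ", "))
  out
}

gauss_blur_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Render localizations as a blurred histogram image
#'
#' Bins localizations on a 2D (x, y) or 3D (x, y, z) grid and applies a
#' separable Gaussian blur. Total weight equals the number of
#' localizations. For 2D rendering the mean z per pixel is returned
#' alongside, supporting z-colored display.
#'
#' @param locs data.frame with `x, y` (and `z` for `dims = 3`)
#' @param voxel bin size, nm
#' @param sigma blur sigma in voxels
#' @param dims 2 or 3
#' @return for `dims = 2`, a list with `image`, `mean_z`, `xlim`, `ylim`;
#'   for `dims = 3` the blurred 3D array
#' @export
render_image <- function(locs, voxel = 10, sigma = 1, dims = 2) {
  if (nrow(locs) == 0) {
    warning("empty localization table; returning empty image")
    return(if (dims == 2) list(image = matrix(0, 1, 1), mean_z = NA)
           else array(0, dim = c(1, 1, 1)))
  }
  pad <- 3 * sigma * voxel + voxel
  k <- gauss_blur_kernel(sigma)
  blur1 <- function(a, axis) {
    if (length(k) == 1) return(a)
    apply(a, setdiff(seq_along(dim(a)), axis), function(v)
      as.numeric(stats::filter(c(numeric(length(k) %/% 2), v,
                                 numeric(length(k) %/% 2)),
                               k, sides = 2))[
        (length(k) %/% 2 + 1):(length(k) %/% 2 + length(v))])
  }
  if (dims == 3) {
    ranges <- list(range(locs$x) + c(-pad, pad),
                   range(locs$y) + c(-pad, pad),
                   range(locs$z) + c(-pad, pad))
    h <- render_hist3d(locs$x, locs$y, locs$z, ranges, voxel)
    h <- aperm(blur1(h, 1), c(3, 1, 2))
    h <- aperm(blur1(h, 1), c(3, 1, 2))
    h <- aperm(blur1(h, 1), c(3, 1, 2))
    return(h)
  }
  xl <- range(locs$x) + c(-pad, pad)
  yl <- range(locs$y) + c(-pad, pad)
  nb <- c(ceiling(diff(xl) / voxel), ceiling(diff(yl) / voxel))
  ix <- pmin(nb[1], floor((locs$x - xl[1]) / voxel) + 1)
  iy <- pmin(nb[2], floor((locs$y - yl[1]) / voxel) + 1)
  img <- matrix(0, nb[1], nb[2])
  zsum <- matrix(0, nb[1], nb[2])
  has_z <- "z" %in% names(locs)
  for (i in seq_along(ix)) {
    img[ix[i], iy[i]] <- img[ix[i], iy[i]] + 1
    if (has_z) zsum[ix[i], iy[i]] <- zsum[ix[i], iy[i]] + locs$z[i]
  }
  mean_z <- ifelse(img > 0, zsum / pmax(img, 1), NA)
  sm <- t(blur1(t(blur1(img, 1)), 1))
  list(image = sm, mean_z = mean_z, xlim = xl, ylim = yl)
}

#' Save / load a spline PSF model container
#'
#' Serializes the model (coefficients, knot grid, phase offset, optional
#' decomposition) to an RDS container.
#'
#' @param psf a `spline_psf` or [dynamic_spline_psf()]
#' @param path file path
#' @return `path` (write) or the model object (read)
#' @export
write_psf <- function(psf, path) {
  saveRDS(psf, path)
  invisible(path)
}

#' @rdname write_psf
#' @export
read_psf <- function(path) readRDS(path)
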
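# Shared fixtures, built once per test run. The standard stack is a
# noiseless 17 x 17 x 150 scan with 20 nm z steps (3 um depth, ~12 fringe
# periods), enough axial range for multi-start fitting tests while keeping
# the spline build fast.
.fx <- new.env(parent = emptyenv())

fx_cfg <- function() fourpi_config()

fx_stack <- function() {
  if (is.null(.fx$stack))
    .fx$stack <- make_symmetric_4pi_psf(fx_cfg(), n_xy = 17, n_z = 150,
                                        z_step = 20)
  .fx$stack
}

fx_psf <- function() {
  if (is.null(.fx$psf)) .fx$psf <- compute_spline_coefficients(fx_stack())
  .fx$psf
}

fx_dyn <- function() {
  if (is.null(.fx$dyn)) .fx$dyn <- dynamic_spline_psf(fx_stack())
  .fx$dyn
}

# literal evaluation of the 64-term tricubic polynomial sum, independent
# of the compiled evaluation path
oracle_spline_eval <- function(psf, x, y, z, ch) {
  sp <- psf$spacing; o <- psf$origin; d <- psf$dims
  loc <- function(v, o1, s1, nc) {
    u <- (v - o1) / s1
    i <- min(max(floor(u), 0), nc - 1)
    list(i = i, t = u - i)
  }
  lx <- loc(x, o[1], sp[1], d[2])
  ly <- loc(y, o[2], sp[2], d[3])
  lz <- loc(z, o[3], sp[3], d[4])
  s <- 0
  for (m in 0:3) for (n in 0:3) for (oo in 0:3)
    s <- s + psf$coef[m + 4 * n + 16 * oo + 1, lx$i + 1, ly$i + 1,
                      lz$i + 1, ch] * lx$t^m * ly$t^n * lz$t^oo
  s
}

sim_images <- function(gen, n, z_range = c(-100, 100), photons = 8000,
                       background = 10, seed = NULL) {
  run <- function() lapply(seq_len(n), function(i) simulate_emitter_image(
    gen, ground_truth_emitter(x = runif(1, -60, 60), y = runif(1, -60, 60),
                              z = runif(1, z_range[1], z_range[2]),
                              photons = photons, background = background)))
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
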
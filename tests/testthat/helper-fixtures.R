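# Shared closed-form oracles and memoised fixtures for the test suite.

# Frequency at which a Gaussian MTF exp(-2 pi^2 sigma^2 f^2) falls to
# percent/100 (closed form).
gauss_f_pct <- function(sigma, percent) {
  sqrt(log(100 / percent) / (2 * pi^2 * sigma^2))
}

gauss_mtf <- function(f, sigma) exp(-2 * pi^2 * sigma^2 * f^2)

# Wire-method options for the standard noiseless fixtures (256 px grid,
# 0.05 mm pitch): a large crop so the annulus sits clear of the PSF tails.
wire_opts_noiseless <- list(crop = 128L, pad = 512L, annulus = c(48, 60))
# Smaller crop for noisy fixtures: less noise power inside the crop window
# corrupting the DC normalisation.
wire_opts_noisy <- list(crop = 64L, pad = 512L, annulus = c(26, 31))

# Independent quadrature oracle for a uniform disc of radius R convolved
# with an isotropic Gaussian (polar-coordinate convolution integral with a
# scaled Bessel I0; no shared code with the generator's closed form).
disc_blur_quad <- function(R, sigma, r) {
  vapply(r, function(ri) {
    stats::integrate(function(s)
      s / sigma^2 * exp(-(s - ri)^2 / (2 * sigma^2)) *
        besselI(s * ri / sigma^2, 0, expon.scaled = TRUE),
      lower = 0, upper = R, rel.tol = 1e-9)$value
  }, numeric(1))
}

# memoised fixtures: expensive simulations shared across test files
.fx_cache <- new.env(parent = emptyenv())
fixture <- function(name, expr) {
  if (!exists(name, envir = .fx_cache))
    assign(name, force(expr), envir = .fx_cache)
  get(name, envir = .fx_cache)
}

# exact clockwise 90-degree rotation of a square matrix (pixel permutation)
rot_cw <- function(m) t(m)[, rev(seq_len(nrow(m)))]

`%||%` <- function(a, b) if (is.null(a)) b else a
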
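# shared small fixtures; everything is generated in code at test time

tiny_grid <- function() make_wavelength_grid(900, 2494, 60)

tiny_layout <- function() {
  plate_layout(rows = 2L, cols = 2L, well_diameter_px = 8L,
               well_pitch_px = 12L, image_width_px = 28L)
}

tiny_noise <- function(additive_sd = 0.002) {
  noise_model(additive_sd = additive_sd, scatter_slope_sd = 0.005,
              scatter_offset_sd = 0.001, baseline_tilt_sd = 0.001)
}

tiny_design <- function(wells = c(0, 0, 25, 50), seed = 11L) {
  mixture_design("apricot", 1L, wells, 1L, seed = seed)
}

tiny_plate <- function(wells = c(0, 0, 25, 50), seed = 11L,
                       noise = tiny_noise()) {
  render_plate_cube(tiny_design(wells, seed), tiny_layout(),
                    default_endmembers(), noise, tiny_grid(),
                    plate_id = "tp")
}

# multivariate standard-normal spectral matrix
gauss_matrix <- function(n, J, seed) {
  set.seed(seed)
  matrix(rnorm(n * J), n, J)
}

# independent chi-square quantile oracle: numeric CDF inversion of the
# integrated chi-square density (does not call qchisq)
chisq_quantile_oracle <- function(p, k) {
  dens <- function(x) x^(k / 2 - 1) * exp(-x / 2) / (2^(k / 2) * gamma(k / 2))
  cdf <- function(q) integrate(dens, 0, q, rel.tol = 1e-12)$value
  uniroot(function(q) cdf(q) - p, c(1e-8, 40 + 10 * k), tol = 1e-10)$root
}

# fixture with an exact 3-dimensional latent structure plus small noise
latent3_matrix <- function(n = 80, J = 40, noise_sd = 0.05, seed = 42) {
  set.seed(seed)
  L <- matrix(rnorm(3 * J), 3, J)
  matrix(rnorm(n * 3), n, 3) %*% L + matrix(rnorm(n * J, 0, noise_sd), n, J)
}

# shrunken end-to-end study configuration (one well per concentration)
tiny_study_config <- function(seed = 3L) {
  cfg <- default_study_config(seed)
  for (nm in names(cfg$designs)) {
    w <- cfg$designs[[nm]]$wells_pct
    cfg$designs[[nm]]$wells_pct <- if (all(w == 0)) rep(0, 5) else
      rep(sort(unique(w)), each = 1)
  }
  cfg$plsr$methods <- c("snv", "sg_second", "raw")
  cfg$plsr$max_factors <- 6L
  cfg
}
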
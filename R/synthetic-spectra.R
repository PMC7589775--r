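#' Uniform wavelength grid
#'
#' Builds the uniform wavelength axis of a pushbroom SWIR imager. The default
#' acquisition grid used throughout the package is 900--2494 nm in 275 bands
#' (about 5.8 nm per band).
#'
#' @param start_nm first wavelength (nm).
#' @param stop_nm last wavelength (nm); must exceed `start_nm`.
#' @param n_bands number of bands (integer, >= 2).
#' @return An object of class `wl_grid`: list with `start_nm`, `stop_nm`,
#'   `n_bands`, `step_nm` and the ascending `values` vector.
#' @examples
#' g <- make_wavelength_grid(900, 2494, 275)
#' g$step_nm
#' @export
make_wavelength_grid <- function(start_nm, stop_nm, n_bands) {
  if (!is.numeric(start_nm) || !is.numeric(stop_nm) || length(start_nm) != 1L ||
      length(stop_nm) != 1L || !is.finite(start_nm) || !is.finite(stop_nm)) {
    stop("start_nm and stop_nm must be finite scalars")
  }
  if (stop_nm <= start_nm) stop("stop_nm must be greater than start_nm")
  n_bands <- as.integer(n_bands)
  if (is.na(n_bands) || n_bands < 2L) stop("n_bands must be an integer >= 2")
  values <- seq(start_nm, stop_nm, length.out = n_bands)
  structure(
    list(start_nm = start_nm, stop_nm = stop_nm, n_bands = n_bands,
         step_nm = (stop_nm - start_nm) / (n_bands - 1L), values = values),
    class = "wl_grid"
  )
}

#' @export
print.wl_grid <- function(x, ...) {
  cat(sprintf("<wl_grid> %g-%g nm, %d bands, step %.4g nm\n",
              x$start_nm, x$stop_nm, x$n_bands, x$step_nm))
  invisible(x)
}

# coerce a wl_grid or plain numeric vector to the numeric wavelength vector
wl_values <- function(wavelengths) {
  if (inherits(wavelengths, "wl_grid")) return(wavelengths$values)
  if (!is.numeric(wavelengths) || any(!is.finite(wavelengths)) ||
      any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be a strictly increasing numeric vector or wl_grid")
  }
  as.numeric(wavelengths)
}

#' Endmember specification
#'
#' Describes a pure powder's reflectance spectrum as a flat baseline minus a
#' sum of Gaussian absorption features. Band positions follow the known SWIR
#' assignment for nut powders: C-H lipid overtones near 1165, 1395, 1692 and
#' 1734 nm, protein near 1200 nm, and O-H water bands at 1450 and 1940 nm.
#'
#' @param name endmember identifier (e.g. "almond").
#' @param bands data.frame with columns `center_nm`, `width_nm`, `amplitude`
#'   (all amplitudes >= 0).
#' @param baseline_level flat reflectance baseline in (0, 1).
#' @param variety_shift fractional amplitude perturbation distinguishing the
#'   two varieties (>= 0); variety 1 renders at `1 + variety_shift`, variety 2
#'   at `1 - variety_shift`.
#' @return An object of class `endmember_spec`.
#' @export
endmember_spec <- function(name, bands, baseline_level = 0.6,
                           variety_shift = 0.04) {
  stopifnot(is.character(name), length(name) == 1L)
  bands <- as.data.frame(bands)
  need <- c("center_nm", "width_nm", "amplitude")
  if (!all(need %in% names(bands))) {
    stop("bands must have columns center_nm, width_nm, amplitude")
  }
  if (any(bands$amplitude < 0)) stop("amplitudes must be >= 0")
  if (any(bands$width_nm <= 0)) stop("widths must be > 0")
  if (baseline_level <= 0 || baseline_level >= 1) {
    stop("baseline_level must lie in (0, 1)")
  }
  if (variety_shift < 0) stop("variety_shift must be >= 0")
  structure(list(name = name, bands = bands[, need],
                 baseline_level = baseline_level,
                 variety_shift = variety_shift),
            class = "endmember_spec")
}

#' Default almond / apricot / peanut endmembers
#'
#' The three pure-powder endmembers share the SWIR band centers listed above;
#' amplitudes encode the compositional ordering reported for these powders:
#' peanut absorbs more than almond at the 1165/1395 nm lipid-peroxide bands
#' and the 1200 nm protein band, almond has the deepest long-chain fatty-acid
#' feature at 1734 nm, and apricot's lipid bands are scaled to 0.6 of
#' almond's, making apricot spectrally farther from almond than peanut is.
#'
#' @param baseline_level shared flat baseline.
#' @param variety_shift shared variety perturbation.
#' @return Named list of three `endmember_spec` objects.
#' @export
default_endmembers <- function(baseline_level = 0.6, variety_shift = 0.04) {
  centers <- c(1165, 1200, 1395, 1450, 1692, 1734, 1940)
  widths  <- c(  35,   30,   40,   55,   30,   30,   65)
  almond  <- c(0.10, 0.060, 0.10, 0.12, 0.070, 0.140, 0.20)
  peanut  <- c(0.13, 0.090, 0.13, 0.12, 0.080, 0.120, 0.20)
  # apricot: lipid bands (1165/1395/1692/1734) at 0.6 x almond, less protein,
  # stronger water/carbohydrate absorption
  apricot <- c(0.06, 0.040, 0.06, 0.15, 0.042, 0.084, 0.26)
  mk <- function(name, amp) {
    endmember_spec(name,
                   data.frame(center_nm = centers, width_nm = widths,
                              amplitude = amp),
                   baseline_level = baseline_level,
                   variety_shift = variety_shift)
  }
  list(almond  = mk("almond", almond),
       apricot = mk("apricot", apricot),
       peanut  = mk("peanut", peanut))
}

#' Render an endmember to a reflectance spectrum
#'
#' Evaluates `baseline - sum of Gaussian absorptions` on a wavelength grid,
#' with amplitudes perturbed by the variety shift, and clips the result to
#' (0.01, 0.99). Deterministic given the spec and variety.
#'
#' @param spec an [endmember_spec()].
#' @param grid a [make_wavelength_grid()] grid (or numeric wavelength vector).
#' @param variety 1 or 2 (amplitude factor `1 + variety_shift` resp.
#'   `1 - variety_shift`).
#' @return Numeric reflectance spectrum, one value per band.
#' @export
render_endmember <- function(spec, grid, variety = 1L) {
  stopifnot(inherits(spec, "endmember_spec"))
  wl <- wl_values(grid)
  variety <- as.integer(variety)
  if (!variety %in% c(1L, 2L)) stop("variety must be 1 or 2")
  if (nrow(spec$bands) > 0 &&
      (any(spec$bands$center_nm < min(wl)) ||
       any(spec$bands$center_nm > max(wl)))) {
    stop("endmember band centers must lie inside the wavelength grid")
  }
  fac <- 1 + (if (variety == 1L) spec$variety_shift else -spec$variety_shift)
  r <- rep(spec$baseline_level, length(wl))
  for (k in seq_len(nrow(spec$bands))) {
    b <- spec$bands[k, ]
    r <- r - b$amplitude * fac * exp(-0.5 * ((wl - b$center_nm) / b$width_nm)^2)
  }
  if (any(r <= 0) || any(r >= 1)) {
    stop("endmember amplitudes drive reflectance outside (0, 1)")
  }
  pmin(pmax(r, 0.01), 0.99)
}

#' Linear binary mixing of two spectra
#'
#' @param pure spectrum of the pure (majority) powder.
#' @param adulterant spectrum of the adulterant powder.
#' @param fraction adulterant mass fraction in \[0, 1\].
#' @return `(1 - fraction) * pure + fraction * adulterant`.
#' @export
mix_spectra <- function(pure, adulterant, fraction) {
  if (length(pure) != length(adulterant)) stop("spectra lengths differ")
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1) {
    stop("fraction must be a scalar in [0, 1]")
  }
  (1 - fraction) * pure + fraction * adulterant
}

#' Measurement noise model
#'
#' Pixel-level corruption applied to an ideal reflectance spectrum:
#' a multiplicative scatter slope `b ~ N(1, scatter_slope_sd)`, an additive
#' scatter offset `a ~ N(0, scatter_offset_sd)`, a linear baseline tilt across
#' the band axis with slope `~ N(0, baseline_tilt_sd)`, and iid additive
#' sensor noise `N(0, additive_sd)` per band. All SDs are in reflectance
#' units.
#'
#' @param additive_sd,scatter_slope_sd,scatter_offset_sd,baseline_tilt_sd
#'   non-negative standard deviations.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(additive_sd = 0.01, scatter_slope_sd = 0.02,
                        scatter_offset_sd = 0.005, baseline_tilt_sd = 0.005) {
  v <- c(additive_sd = additive_sd, scatter_slope_sd = scatter_slope_sd,
         scatter_offset_sd = scatter_offset_sd,
         baseline_tilt_sd = baseline_tilt_sd)
  if (any(!is.finite(v)) || any(v < 0)) stop("noise SDs must be >= 0")
  structure(as.list(v), class = "noise_model")
}

# run expr with a private RNG stream seeded by `seed`, restoring global state
with_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# corrupt a pixel matrix (rows = pixels, cols = bands) in one draw; the draw
# order (b, a, tilt, eps) is part of the reproducibility contract
corrupt_matrix <- function(X, noise, rng_seed) {
  stopifnot(inherits(noise, "noise_model"))
  n <- nrow(X); J <- ncol(X)
  lam <- seq(0, 1, length.out = J) - 0.5
  with_rng(rng_seed, {
    b <- stats::rnorm(n, 1, noise$scatter_slope_sd)
    a <- stats::rnorm(n, 0, noise$scatter_offset_sd)
    tl <- stats::rnorm(n, 0, noise$baseline_tilt_sd)
    eps <- matrix(stats::rnorm(n * J, 0, noise$additive_sd), n, J)
    X * b + a + outer(tl, lam) + eps
  })
}

#' Corrupt a spectrum with scatter and sensor noise
#'
#' @param s ideal reflectance spectrum.
#' @param noise a [noise_model()].
#' @param rng_seed integer seed; the same seed reproduces the same draw.
#' @return Corrupted spectrum of the same length.
#' @export
corrupt_spectrum <- function(s, noise, rng_seed) {
  drop(corrupt_matrix(matrix(s, nrow = 1L), noise, rng_seed))
}
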
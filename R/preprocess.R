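#' Spectral pretreatment specification
#'
#' The pretreatments evaluated for powder spectra: row-wise normalizations
#' (`mean_norm`, `max_norm`, `range_norm`), standard normal variate (`snv`),
#' multiplicative scatter correction (`msc`, reference learned from the
#' calibration set), Savitzky-Golay smoothing and derivatives (`sg_smooth`,
#' `sg_first`, `sg_second`), and `raw` (identity).
#'
#' SG filters use only positions where the full window fits: the band axis
#' shrinks by `window - 1` and wavelengths are updated, so no edge values are
#' fabricated. Derivatives are per band index (the uniform-grid step is a
#' constant factor, irrelevant to downstream regression/classification).
#'
#' @param method one of `"raw"`, `"mean_norm"`, `"max_norm"`, `"range_norm"`,
#'   `"snv"`, `"msc"`, `"sg_smooth"`, `"sg_first"`, `"sg_second"`.
#' @param window odd SG window length (>= 5); default 11 (about 64 nm at
#'   5.8 nm resolution).
#' @param polyorder SG polynomial order (>= 2, < window); default 2.
#' @return Object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(method = c("raw", "mean_norm", "max_norm",
                                       "range_norm", "snv", "msc",
                                       "sg_smooth", "sg_first", "sg_second"),
                            window = 11L, polyorder = 2L) {
  method <- match.arg(method)
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  if (startsWith(method, "sg_")) {
    if (window < 5L || window %% 2L == 0L) stop("window must be odd and >= 5")
    if (polyorder < 2L || polyorder >= window) {
      stop("polyorder must satisfy 2 <= polyorder < window")
    }
  }
  structure(list(method = method, window = window, polyorder = polyorder,
                 reference = NULL, fitted = (method != "msc")),
            class = "preprocess_spec")
}

#' Fit a pretreatment on calibration data
#'
#' Only MSC is stateful: its reference becomes the mean calibration spectrum.
#' Every other method passes through unchanged. Validation data must be
#' transformed with the spec fitted on the calibration set so no validation
#' statistics leak into the transform.
#'
#' @param spec a [preprocess_spec()].
#' @param calibration a `spectral_set` (or matrix).
#' @return The fitted `preprocess_spec`.
#' @export
fit_preprocess <- function(spec, calibration) {
  stopifnot(inherits(spec, "preprocess_spec"))
  X <- if (inherits(calibration, "spectral_set")) calibration$spectra
       else as.matrix(calibration)
  if (nrow(X) == 0) stop("calibration set is empty")
  if (spec$method == "msc") {
    spec$reference <- colMeans(X)
    spec$fitted <- TRUE
  }
  spec
}

#' Savitzky-Golay convolution kernel
#'
#' Least-squares polynomial-derivative filter coefficients for a centered
#' window. The smoothing kernel (`deriv = 0`) sums to 1; derivative kernels
#' sum to 0 and annihilate polynomials of degree below `deriv`. Output units
#' are per band index.
#'
#' @param window odd window length.
#' @param polyorder polynomial order, `window > polyorder >= deriv`.
#' @param deriv derivative order (0, 1, 2, ...).
#' @return Numeric kernel of length `window`.
#' @export
sg_coefficients <- function(window, polyorder, deriv = 0L) {
  window <- as.integer(window); polyorder <- as.integer(polyorder)
  deriv <- as.integer(deriv)
  if (window %% 2L == 0L || window < 3L) stop("window must be odd and >= 3")
  if (polyorder >= window || polyorder < deriv) {
    stop("need window > polyorder >= deriv")
  }
  m <- (window - 1L) %/% 2L
  A <- outer(seq(-m, m), 0:polyorder, `^`)
  G <- solve(crossprod(A), t(A))
  G[deriv + 1L, ] * factorial(deriv)
}

# row-wise valid convolution with an SG kernel; X is n x J
sg_filter_rows <- function(X, kernel) {
  J <- ncol(X); w <- length(kernel); m <- (w - 1L) %/% 2L
  if (J < w) stop("spectrum shorter than the SG window")
  K <- matrix(0, J, J - w + 1L)
  for (j in seq_len(J - w + 1L)) K[j:(j + w - 1L), j] <- kernel
  X %*% K
}

# which rows of X are degenerate for a given method (used by pixel mapping
# to flag pixels instead of failing)
preprocess_bad_rows <- function(spec, X) {
  switch(spec$method,
    mean_norm = rowMeans(X) == 0,
    max_norm = apply(X, 1, max) == 0,
    range_norm = apply(X, 1, max) == apply(X, 1, min),
    snv = apply(X, 1, stats::sd) == 0,
    msc = {
      ref <- spec$reference
      rc <- ref - mean(ref)
      b <- as.vector(X %*% rc - rowMeans(X) * sum(rc)) / sum(rc^2)
      abs(b) < 1e-8
    },
    rep(FALSE, nrow(X))
  )
}

#' Apply a fitted pretreatment
#'
#' @param spec a fitted [preprocess_spec()].
#' @param x a `spectral_set` or numeric matrix (rows = spectra).
#' @param wavelengths wavelength vector for matrix input (needed only so SG
#'   methods can return updated wavelengths as an attribute).
#' @return Transformed object of the same kind; SG methods shrink the band
#'   axis by `window - 1`.
#' @export
apply_preprocess <- function(spec, x, wavelengths = NULL) {
  stopifnot(inherits(spec, "preprocess_spec"))
  if (!spec$fitted) stop("msc spec must be fitted before applying")
  is_set <- inherits(x, "spectral_set")
  X <- if (is_set) x$spectra else as.matrix(x)
  wl <- if (is_set) x$wavelengths else wavelengths
  if (spec$method == "msc" && length(spec$reference) != ncol(X)) {
    stop("band count does not match the fitted msc reference")
  }

  out_wl <- wl
  Y <- switch(spec$method,
    raw = X,
    mean_norm = {
      mu <- rowMeans(X)
      if (any(mu == 0)) stop("mean_norm: row with zero mean")
      X / mu
    },
    max_norm = {
      mx <- apply(X, 1, max)
      if (any(mx == 0)) stop("max_norm: row with zero maximum")
      X / mx
    },
    range_norm = {
      mn <- apply(X, 1, min); mx <- apply(X, 1, max)
      if (any(mx == mn)) stop("range_norm: constant row")
      (X - mn) / (mx - mn)
    },
    snv = {
      mu <- rowMeans(X)
      sdv <- apply(X, 1, stats::sd)
      if (any(sdv == 0)) stop("snv: constant row")
      (X - mu) / sdv
    },
    msc = {
      ref <- spec$reference
      rc <- ref - mean(ref)
      ss <- sum(rc^2)
      b <- as.vector(X %*% rc - rowMeans(X) * sum(rc)) / ss
      if (any(abs(b) < 1e-8)) stop("msc: fitted slope magnitude below 1e-8")
      a <- rowMeans(X) - b * mean(ref)
      (X - a) / b
    },
    sg_smooth = sg_filter_rows(X, sg_coefficients(spec$window, spec$polyorder, 0L)),
    sg_first = sg_filter_rows(X, sg_coefficients(spec$window, spec$polyorder, 1L)),
    sg_second = sg_filter_rows(X, sg_coefficients(spec$window, spec$polyorder, 2L))
  )
  if (startsWith(spec$method, "sg_") && !is.null(wl)) {
    m <- (spec$window - 1L) %/% 2L
    out_wl <- wl[(m + 1L):(length(wl) - m)]
  }

  if (is_set) {
    spectral_set(Y, out_wl, x$meta)
  } else {
    if (!is.null(out_wl)) attr(Y, "wavelengths") <- out_wl
    Y
  }
}

# serialize / deserialize a preprocess spec for model files
preprocess_to_list <- function(spec) {
  list(method = spec$method, window = spec$window,
       polyorder = spec$polyorder,
       reference = if (is.null(spec$reference)) NULL
                   else as.numeric(spec$reference))
}

preprocess_from_list <- function(lst) {
  spec <- preprocess_spec(lst$method, lst$window, lst$polyorder)
  if (!is.null(lst$reference)) {
    spec$reference <- as.numeric(lst$reference)
    spec$fitted <- TRUE
  }
  spec
}
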
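#' Hyperspectral cube
#'
#' A 3-D raster with axis order (line, sample, band), its wavelength axis and
#' a radiometric state flag.
#'
#' @param data numeric 3-D array `(line, sample, band)`.
#' @param wavelengths a `wl_grid` or numeric wavelength vector; length must
#'   equal `dim(data)[3]`.
#' @param state `"raw"` (radiance counts) or `"reflectance"`.
#' @return Object of class `hypercube`.
#' @export
hypercube <- function(data, wavelengths, state = c("raw", "reflectance")) {
  state <- match.arg(state)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("data must be a 3-D array (line, sample, band)")
  }
  wl <- wl_values(wavelengths)
  if (dim(data)[3] != length(wl)) {
    stop("band dimension does not match wavelength count")
  }
  if (state == "reflectance" && any(!is.finite(data))) {
    stop("reflectance cube contains non-finite values")
  }
  structure(list(data = data, wavelengths = wl, state = state),
            class = "hypercube")
}

#' @export
print.hypercube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hypercube> %d lines x %d samples x %d bands (%g-%g nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$state))
  invisible(x)
}

#' Dark/white reference pair
#'
#' @param dark,white `hypercube`s (same shape as the target cube) or numeric
#'   per-band reference spectra of length `bands`.
#' @return Object of class `reference_pair`.
#' @export
reference_pair <- function(dark, white) {
  structure(list(dark = dark, white = white), class = "reference_pair")
}

# broadcast a reference (hypercube | per-band vector) against cube dims
ref_array <- function(ref, d) {
  if (inherits(ref, "hypercube")) ref <- ref$data
  if (is.array(ref) && length(dim(ref)) == 3L) {
    if (!all(dim(ref) == d)) stop("reference cube shape mismatch")
    return(ref)
  }
  if (is.numeric(ref) && length(ref) == d[3]) {
    return(aperm(array(ref, c(d[3], d[1], d[2])), c(2, 3, 1)))
  }
  stop("reference must be a cube of matching shape or a per-band vector")
}

#' Reflectance calibration
#'
#' Converts raw radiance to relative reflectance using dark-current and white
#' references: `(raw - dark) / (white - dark)`, elementwise. Values are not
#' clipped; reflectance above 1 (specular highlights, noise) is kept as-is.
#'
#' @param raw a `hypercube` with `state == "raw"`.
#' @param refs a [reference_pair()] (or list with `dark` and `white`).
#' @return Reflectance `hypercube`.
#' @export
calibrate_reflectance <- function(raw, refs) {
  stopifnot(inherits(raw, "hypercube"))
  if (raw$state != "raw") stop("cube is already calibrated")
  d <- dim(raw$data)
  dark <- ref_array(refs$dark, d)
  white <- ref_array(refs$white, d)
  denom <- white - dark
  bad <- which(apply(denom == 0, 3, any))
  if (length(bad) > 0) {
    stop(sprintf("white equals dark at band(s) %s (%.1f nm): dead reference",
                 paste(utils::head(bad, 5), collapse = ", "),
                 raw$wavelengths[bad[1]]))
  }
  hypercube((raw$data - dark) / denom, raw$wavelengths, state = "reflectance")
}

#' Foreground segmentation by two-cluster thresholding
#'
#' Computes the mean-over-bands intensity image, splits it with 2-means
#' (initialized at the intensity extremes), and thresholds at the midpoint of
#' the two cluster means -- the "average of background and powder pixels"
#' rule. Foreground components smaller than `min_component_px` pixels are
#' removed.
#'
#' @param cube reflectance `hypercube`.
#' @param min_component_px minimum connected-component size kept (default 10).
#' @return Object of class `foreground_mask`: list with the logical `mask`
#'   and the `threshold` used.
#' @export
segment_background <- function(cube, min_component_px = 10L) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$state != "reflectance") stop("segment a calibrated cube")
  m <- rowMeans(matrix(cube$data, prod(dim(cube$data)[1:2]), dim(cube$data)[3]))
  m <- matrix(m, dim(cube$data)[1], dim(cube$data)[2])
  if (diff(range(m)) == 0) {
    stop("single-intensity image: no background/powder contrast to threshold")
  }
  km <- stats::kmeans(as.vector(m), centers = matrix(range(m), 2, 1))
  threshold <- mean(km$centers)
  mask <- m > threshold
  if (any(mask) && min_component_px > 0) {
    lab <- EBImage::bwlabel(mask)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_component_px)
    mask <- matrix(lab %in% keep & lab > 0, nrow(m), ncol(m))
  }
  structure(list(mask = mask, threshold = threshold),
            class = "foreground_mask")
}

#' Crop the spectral axis to a wavelength window
#'
#' Retains bands with `low_nm <= wavelength <= high_nm`. Works on a
#' `hypercube` or a `spectral_set`; wavelengths are updated consistently. The
#' standard analysis window is 935--1965 nm.
#'
#' @param x `hypercube` or `spectral_set`.
#' @param low_nm,high_nm window bounds, `low_nm < high_nm`.
#' @return Object of the same class with the reduced band axis.
#' @export
crop_bands <- function(x, low_nm = 935, high_nm = 1965) {
  if (low_nm >= high_nm) stop("low_nm must be below high_nm")
  wl <- if (inherits(x, "hypercube")) x$wavelengths else x$wavelengths
  keep <- which(wl >= low_nm & wl <= high_nm)
  if (length(keep) == 0) stop("crop window retains no bands")
  if (inherits(x, "hypercube")) {
    hypercube(x$data[, , keep, drop = FALSE], wl[keep], state = x$state)
  } else if (inherits(x, "spectral_set")) {
    spectral_set(x$spectra[, keep, drop = FALSE], wl[keep], x$meta)
  } else {
    stop("crop_bands expects a hypercube or spectral_set")
  }
}

#' Set of extracted spectra
#'
#' Rows are specimens (well halves or whole wells), columns are bands. The
#' metadata carries the mixture labels used downstream.
#'
#' @param spectra numeric matrix, rows = specimens.
#' @param wavelengths band wavelengths (length = `ncol(spectra)`).
#' @param meta data.frame with columns `specimen_id`, `well_id`, `half`,
#'   `variety`, `adulterant`, `concentration_pct`; missing columns are filled
#'   with defaults.
#' @return Object of class `spectral_set`.
#' @export
spectral_set <- function(spectra, wavelengths, meta = NULL) {
  spectra <- as.matrix(spectra)
  wl <- wl_values(wavelengths)
  if (ncol(spectra) != length(wl)) stop("band count mismatch")
  n <- nrow(spectra)
  if (is.null(meta)) meta <- data.frame(specimen_id = sprintf("s%04d", seq_len(n)))
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != n) stop("meta rows must match spectra rows")
  if (is.null(meta$specimen_id)) meta$specimen_id <- sprintf("s%04d", seq_len(n))
  if (is.null(meta$well_id)) meta$well_id <- meta$specimen_id
  if (is.null(meta$half)) meta$half <- "whole"
  if (is.null(meta$variety)) meta$variety <- NA_integer_
  if (is.null(meta$adulterant)) meta$adulterant <- NA_character_
  if (is.null(meta$concentration_pct)) meta$concentration_pct <- NA_real_
  meta$specimen_id <- as.character(meta$specimen_id)
  meta$well_id <- as.character(meta$well_id)
  meta$half <- as.character(meta$half)
  meta$variety <- as.integer(meta$variety)
  meta$concentration_pct <- as.numeric(meta$concentration_pct)
  rownames(spectra) <- meta$specimen_id
  structure(list(spectra = spectra, wavelengths = wl,
                 meta = meta[, c("specimen_id", "well_id", "half", "variety",
                                 "adulterant", "concentration_pct")]),
            class = "spectral_set")
}

#' @export
print.spectral_set <- function(x, ...) {
  cat(sprintf("<spectral_set> %d spectra x %d bands (%g-%g nm)\n",
              nrow(x$spectra), ncol(x$spectra), min(x$wavelengths),
              max(x$wavelengths)))
  invisible(x)
}

#' Combine spectral sets row-wise
#'
#' @param ... `spectral_set`s on identical wavelength axes.
#' @return A single `spectral_set`.
#' @export
bind_spectral_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "spectral_set")) sets <- sets[[1]]
  wl <- sets[[1]]$wavelengths
  for (s in sets) {
    if (!isTRUE(all.equal(s$wavelengths, wl))) stop("wavelength axes differ")
  }
  spectral_set(do.call(rbind, lapply(sets, function(s) s$spectra)), wl,
               do.call(rbind, lapply(sets, function(s) s$meta)))
}

#' Extract averaged well spectra
#'
#' For each well in the truth table, collects its foreground pixels (inside
#' the well disk and in the mask). With `halves = TRUE` (the default,
#' matching the two-halves averaging scheme) the pixels are split at the
#' well's centroid column -- the centroid column itself goes to the left half
#' -- and each half is averaged to one spectrum; otherwise the whole well is
#' averaged.
#'
#' @param cube reflectance `hypercube`.
#' @param mask a [segment_background()] result (or logical matrix).
#' @param truth well table as produced by [render_plate_cube()] (needs
#'   `well_id`, `center_row_px`, `center_col_px`, `radius_px`,
#'   `concentration_pct`, `adulterant`, `variety`).
#' @param halves logical; split each well into two averaged halves.
#' @return A [spectral_set()] with one row per half (or per well).
#' @export
extract_well_spectra <- function(cube, mask, truth, halves = TRUE) {
  stopifnot(inherits(cube, "hypercube"))
  if (cube$state != "reflectance") stop("extract from a calibrated cube")
  mk <- if (inherits(mask, "foreground_mask")) mask$mask else mask
  d <- dim(cube$data)
  if (!all(dim(mk) == d[1:2])) stop("mask shape mismatch")
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  idx <- seq_len(d[1] * d[2])
  rowpix <- (idx - 1L) %% d[1]
  colpix <- (idx - 1L) %/% d[1]

  rows <- list(); meta <- list()
  for (w in seq_len(nrow(truth))) {
    tw <- truth[w, ]
    pix <- which(mk &
                   (rowpix - tw$center_row_px)^2 +
                   (colpix - tw$center_col_px)^2 <= tw$radius_px^2)
    if (halves) {
      ccol <- mean(colpix[pix])
      left <- pix[colpix[pix] <= ccol]
      right <- pix[colpix[pix] > ccol]
      if (length(left) < 2L || length(right) < 2L) {
        stop(sprintf("well %s has fewer than 2 foreground pixels per half",
                     tw$well_id))
      }
      for (hh in c("L", "R")) {
        p <- if (hh == "L") left else right
        rows[[length(rows) + 1L]] <- colMeans(flat[p, , drop = FALSE])
        meta[[length(meta) + 1L]] <- data.frame(
          specimen_id = paste0(tw$well_id, "_", hh), well_id = tw$well_id,
          half = hh, variety = tw$variety, adulterant = tw$adulterant,
          concentration_pct = tw$concentration_pct, stringsAsFactors = FALSE)
      }
    } else {
      if (length(pix) < 2L) {
        stop(sprintf("well %s has fewer than 2 foreground pixels", tw$well_id))
      }
      rows[[length(rows) + 1L]] <- colMeans(flat[pix, , drop = FALSE])
      meta[[length(meta) + 1L]] <- data.frame(
        specimen_id = tw$well_id, well_id = tw$well_id, half = "whole",
        variety = tw$variety, adulterant = tw$adulterant,
        concentration_pct = tw$concentration_pct, stringsAsFactors = FALSE)
    }
  }
  spectral_set(do.call(rbind, rows), cube$wavelengths, do.call(rbind, meta))
}
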
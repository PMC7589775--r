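make_cube <- function(value, nl = 4, ns = 5, J = 6, state = "raw") {
  hypercube(array(value, c(nl, ns, J)), seq(1000, 1500, length.out = J),
            state = state)
}

test_that("reflectance calibration implements (raw-dark)/(white-dark)", {
  white <- make_cube(110); dark <- make_cube(10)
  refs <- reference_pair(dark, white)

  expect_equal(unique(as.vector(
    calibrate_reflectance(make_cube(110), refs)$data)), 1)
  expect_equal(unique(as.vector(
    calibrate_reflectance(make_cube(10), refs)$data)), 0)
  expect_equal(unique(as.vector(
    calibrate_reflectance(make_cube(60), refs)$data)), 0.5)

  out <- calibrate_reflectance(make_cube(60), refs)
  expect_equal(out$state, "reflectance")
  expect_error(calibrate_reflectance(out, refs), "already")

  # dead reference band is named
  same <- reference_pair(make_cube(10), make_cube(10))
  expect_error(calibrate_reflectance(make_cube(60), same), "band")
})

test_that("calibration is invariant to a common per-band gain", {
  set.seed(5)
  raw <- array(runif(4 * 5 * 6, 20, 90), c(4, 5, 6))
  wl <- seq(1000, 1500, length.out = 6)
  dark <- rep(10, 6); white <- rep(110, 6)
  gain <- runif(6, 0.5, 2)
  r1 <- calibrate_reflectance(hypercube(raw, wl),
                              reference_pair(dark, white))
  scaled <- sweep(raw, 3, gain, `*`)
  r2 <- calibrate_reflectance(hypercube(scaled, wl),
                              reference_pair(dark * gain, white * gain))
  expect_equal(r1$data, r2$data, tolerance = 1e-12)
})

test_that("two-cluster thresholding finds the midpoint and the bright region", {
  img <- array(0.1, c(6, 6, 3))
  img[1:3, , ] <- 0.7
  cube <- hypercube(img, c(1000, 1100, 1200), state = "reflectance")
  m <- segment_background(cube, min_component_px = 0L)
  expect_equal(m$threshold, 0.4)
  expect_true(all(m$mask[1:3, ]))
  expect_false(any(m$mask[4:6, ]))

  flat <- hypercube(array(0.5, c(6, 6, 3)), c(1000, 1100, 1200),
                    state = "reflectance")
  expect_error(segment_background(flat), "single-intensity")
})

test_that("segmentation recovers the simulated well disks", {
  p <- tiny_plate()
  refl <- calibrate_reflectance(p$raw, reference_pair(p$dark, p$white))
  m <- segment_background(refl)
  truth_mask <- p$labels > 0
  jaccard <- sum(m$mask & truth_mask) / sum(m$mask | truth_mask)
  expect_gte(jaccard, 0.99)
})

test_that("band cropping retains exactly the in-window bands", {
  g <- make_wavelength_grid(900, 2494, 275)
  cube <- hypercube(array(0.5, c(2, 2, 275)), g, state = "reflectance")
  cropped <- crop_bands(cube, 935, 1965)
  expect_equal(dim(cropped$data)[3], 177L)
  expect_equal(length(cropped$wavelengths), 177L)
  expect_true(all(cropped$wavelengths >= 935 & cropped$wavelengths <= 1965))

  whole <- crop_bands(cube, 900, 2494)
  expect_identical(whole$data, cube$data)
  expect_error(crop_bands(cube, 3000, 4000), "no bands")

  # same operation on a spectral set
  s <- spectral_set(matrix(1, 2, 275), g)
  expect_equal(ncol(crop_bands(s, 935, 1965)$spectra), 177L)
})

test_that("well extraction averages halves correctly", {
  # constant-spectrum wells: both half-spectra equal the well spectrum
  p <- tiny_plate(noise = noise_model(0, 0, 0, 0))
  refl <- calibrate_reflectance(p$raw, reference_pair(p$dark, p$white))
  mask <- structure(list(mask = p$labels > 0, threshold = NA_real_),
                    class = "foreground_mask")
  s <- extract_well_spectra(refl, mask, p$truth, halves = TRUE)
  expect_equal(nrow(s$spectra), 8L)  # 4 wells x 2 halves
  pure <- render_endmember(default_endmembers()$almond, tiny_grid(), 1)
  expect_equal(unname(s$spectra[1, ]), pure, tolerance = 1e-12)
  expect_equal(unname(s$spectra[2, ]), pure, tolerance = 1e-12)
  expect_equal(s$meta$half[1:2], c("L", "R"))
  expect_equal(s$meta$concentration_pct, rep(c(0, 0, 25, 50), each = 2))

  # equal-sized halves: mean of the two half-spectra == whole-well mean
  p2 <- tiny_plate()
  refl2 <- calibrate_reflectance(p2$raw, reference_pair(p2$dark, p2$white))
  mask2 <- structure(list(mask = p2$labels > 0, threshold = NA_real_),
                     class = "foreground_mask")
  halves <- extract_well_spectra(refl2, mask2, p2$truth, halves = TRUE)
  whole <- extract_well_spectra(refl2, mask2, p2$truth, halves = FALSE)
  expect_equal((halves$spectra[1, ] + halves$spectra[2, ]) / 2,
               whole$spectra[1, ], tolerance = 1e-12,
               ignore_attr = TRUE)

  # extraction commutes with band cropping
  a <- crop_bands(extract_well_spectra(refl2, mask2, p2$truth), 1100, 2000)
  b <- extract_well_spectra(crop_bands(refl2, 1100, 2000), mask2, p2$truth)
  expect_equal(a$spectra, b$spectra, tolerance = 1e-12)
  expect_equal(a$wavelengths, b$wavelengths)
})

test_that("ENVI round trip is bit-exact and validates its header", {
  p <- tiny_plate()
  path <- file.path(tempdir(), "cube.envi")
  write_envi(p$raw, path)
  back <- read_envi(path)
  expect_identical(back$data, p$raw$data)
  expect_identical(back$wavelengths, p$raw$wavelengths)
  expect_equal(back$state, "raw")

  # corrupt the header band count -> error
  hdr <- readLines(paste0(path, ".hdr"))
  hdr <- sub("^bands = .*", "bands = 59", hdr)
  writeLines(hdr, paste0(path, ".hdr"))
  expect_error(read_envi(path), "does not match")
})

test_that("spectra CSV round trip is bit-exact including labels", {
  p <- tiny_plate()
  refl <- calibrate_reflectance(p$raw, reference_pair(p$dark, p$white))
  mask <- structure(list(mask = p$labels > 0, threshold = NA_real_),
                    class = "foreground_mask")
  s <- extract_well_spectra(refl, mask, p$truth)
  path <- file.path(tempdir(), "spectra.csv")
  write_spectra_csv(s, path)
  back <- read_spectra_csv(path)
  expect_identical(unname(back$spectra), unname(s$spectra))
  expect_identical(back$wavelengths, s$wavelengths)
  expect_identical(back$meta, s$meta)
})
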
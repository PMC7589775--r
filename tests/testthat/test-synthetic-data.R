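test_that("wavelength grid is uniform with the documented step and bounds", {
  g <- make_wavelength_grid(900, 2494, 275)
  expect_equal(g$n_bands, 275L)
  expect_equal(length(g$values), 275L)
  expect_equal(g$values[1], 900)
  expect_equal(g$values[275], 2494)
  expect_equal(g$step_nm, (2494 - 900) / 274)
  expect_true(all(diff(g$values) > 0))

  expect_equal(make_wavelength_grid(0, 1, 2)$values, c(0, 1))

  # enumeration oracle for the analysis window
  inside <- sum(g$values >= 935 & g$values <= 1965)
  expect_equal(inside, 177L)

  expect_error(make_wavelength_grid(2494, 900, 275), "greater")
  expect_error(make_wavelength_grid(900, 2494, 1), ">= 2")
})

test_that("endmember rendering honors baseline, band depths and positions", {
  g <- make_wavelength_grid(900, 2494, 275)
  flat <- endmember_spec("flat", data.frame(center_nm = 1450, width_nm = 50,
                                            amplitude = 0),
                         baseline_level = 0.55, variety_shift = 0)
  expect_equal(render_endmember(flat, g), rep(0.55, 275))

  # deeper long-chain fatty-acid dip for almond than apricot at 1734 nm
  em <- default_endmembers()
  alm <- render_endmember(em$almond, g)
  apr <- render_endmember(em$apricot, g)
  i1734 <- which.min(abs(g$values - 1734))
  expect_lt(alm[i1734], apr[i1734])

  # minimum of a single-band spectrum lies at the grid value nearest the
  # band center (argmin oracle)
  one <- endmember_spec("w", data.frame(center_nm = 1450, width_nm = 50,
                                        amplitude = 0.2),
                        baseline_level = 0.6, variety_shift = 0)
  r <- render_endmember(one, g)
  expect_equal(which.min(r), which.min(abs(g$values - 1450)))

  # rendering is deterministic and variety-dependent
  expect_identical(render_endmember(em$almond, g, 1), alm)
  expect_false(identical(render_endmember(em$almond, g, 2), alm))

  bad <- endmember_spec("bad", data.frame(center_nm = 1450, width_nm = 50,
                                          amplitude = 0.7),
                        baseline_level = 0.6, variety_shift = 0)
  expect_error(render_endmember(bad, g), "outside")
})

test_that("linear mixing satisfies its affine identities exactly", {
  g <- tiny_grid()
  em <- default_endmembers()
  p <- render_endmember(em$almond, g)
  a <- render_endmember(em$apricot, g)
  expect_identical(mix_spectra(p, a, 0), p)
  expect_identical(mix_spectra(p, a, 1), a)
  expect_equal(mix_spectra(p, a, 0.5), (p + a) / 2)
  for (f in c(0.1, 0.25, 0.37, 0.8)) {
    expect_equal(mix_spectra(p, a, f), (1 - f) * p + f * a)
  }
  expect_error(mix_spectra(p, a, 1.2), "\\[0, 1\\]")
  expect_error(mix_spectra(p, a[-1], 0.5), "lengths")
})

test_that("spectrum corruption is seeded, unbiased and correctly scaled", {
  s <- seq(0.3, 0.7, length.out = 50)
  none <- noise_model(0, 0, 0, 0)
  expect_identical(corrupt_spectrum(s, none, 1), s)

  nm <- noise_model()
  expect_identical(corrupt_spectrum(s, nm, 7), corrupt_spectrum(s, nm, 7))
  expect_false(identical(corrupt_spectrum(s, nm, 7), corrupt_spectrum(s, nm, 8)))

  # Monte-Carlo: additive-only noise SD recovered within 5%
  addn <- noise_model(additive_sd = 0.01, 0, 0, 0)
  draws <- corrupt_matrix(matrix(0.5, 1e4, 1), addn, 99)
  expect_lt(abs(sd(draws) - 0.01) / 0.01, 0.05)

  expect_error(noise_model(-0.1, 0, 0, 0), ">= 0")
})

test_that("plate rendering is deterministic, reference-consistent and labeled", {
  p1 <- tiny_plate()
  p2 <- tiny_plate()
  expect_identical(p1$raw$data, p2$raw$data)           # bit-identical per seed
  expect_false(identical(p1$raw$data, tiny_plate(seed = 12L)$raw$data))

  expect_true(all(p1$dark$data < p1$white$data))

  # truth table structure
  expect_equal(nrow(p1$truth), 4L)
  expect_equal(p1$truth$concentration_pct, c(0, 0, 25, 50))

  # ground-truth label mask has exactly one connected component per well
  lab <- EBImage::bwlabel(p1$labels > 0)
  expect_equal(max(lab), 4)

  # round trip: reflectance recovered by calibration matches the pure
  # endmember inside a 0% well, within the noise budget
  refl <- calibrate_reflectance(p1$raw, reference_pair(p1$dark, p1$white))
  pure <- render_endmember(default_endmembers()$almond, tiny_grid(), 1)
  pix <- which(p1$labels == 1)
  flat <- matrix(refl$data, prod(dim(refl$data)[1:2]), dim(refl$data)[3])
  wellmean <- colMeans(flat[pix, ])
  expect_lt(max(abs(wellmean - pure)), 3 * tiny_noise()$additive_sd +
              3 * (tiny_noise()$scatter_slope_sd * max(pure) +
                     tiny_noise()$scatter_offset_sd +
                     tiny_noise()$baseline_tilt_sd))

  expect_error(render_plate_cube(tiny_design(rep(0, 9)), tiny_layout()),
               "holds")
})

test_that("mixing linearity holds through the renderer before corruption", {
  g <- tiny_grid()
  em <- default_endmembers()
  p <- render_endmember(em$almond, g, 1)
  a <- render_endmember(em$peanut, g, 1)
  for (f in c(0, 0.2, 0.5, 1)) {
    expect_equal(mix_spectra(p, a, f), (1 - f) * p + f * a, tolerance = 1e-12)
  }
})
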
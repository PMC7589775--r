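#' Binary mixture design
#'
#' Describes one set of powder wells: which adulterant, which almond variety,
#' and the per-well adulterant concentrations. The canonical designs are
#' 0--50% in 5% steps (variety 1) and 0, 7, 15, 22, 30% (variety 2).
#'
#' @param adulterant "apricot" or "peanut" (any endmember name).
#' @param variety almond variety, 1 or 2.
#' @param concentrations_pct concentrations in percent, each in \[0, 100\].
#' @param replicates_per_concentration wells per listed concentration.
#' @param seed integer seed controlling every random draw for this design.
#' @return Object of class `mixture_design`; `$wells_pct` is the expanded
#'   per-well concentration vector.
#' @export
mixture_design <- function(adulterant, variety, concentrations_pct,
                           replicates_per_concentration = 1L, seed = 1L) {
  if (any(concentrations_pct < 0) || any(concentrations_pct > 100)) {
    stop("concentrations must lie in [0, 100] percent")
  }
  reps <- as.integer(replicates_per_concentration)
  if (is.na(reps) || reps < 1L) stop("replicates_per_concentration must be >= 1")
  structure(
    list(adulterant = adulterant, variety = as.integer(variety),
         concentrations_pct = as.numeric(concentrations_pct),
         replicates_per_concentration = reps,
         wells_pct = rep(as.numeric(concentrations_pct), each = reps),
         seed = as.integer(seed)),
    class = "mixture_design"
  )
}

#' Plate geometry
#'
#' A black plate with `rows x cols` circular powder wells on a regular pitch,
#' imaged by a line-scan camera of fixed spatial width.
#'
#' @param rows,cols well grid (default 5 x 5 = 25 wells).
#' @param well_diameter_px well diameter in pixels.
#' @param well_pitch_px center-to-center well spacing in pixels.
#' @param image_width_px samples per line (default 324, the imager's fixed
#'   spatial width).
#' @return Object of class `plate_layout`.
#' @export
plate_layout <- function(rows = 5L, cols = 5L, well_diameter_px = 40L,
                         well_pitch_px = 64L, image_width_px = 324L) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  d <- as.integer(well_diameter_px); p <- as.integer(well_pitch_px)
  w <- as.integer(image_width_px)
  if (rows < 1L || cols < 1L) stop("rows and cols must be >= 1")
  if (d < 4L) stop("well_diameter_px must be >= 4")
  if (p < d) stop("wells overlap: well_pitch_px < well_diameter_px")
  if (cols * p > w) stop("wells do not fit inside the image width")
  structure(list(rows = rows, cols = cols, well_diameter_px = d,
                 well_pitch_px = p, image_width_px = w,
                 n_wells = rows * cols, image_lines_px = rows * p),
            class = "plate_layout")
}

# well centers in pixel coordinates (0-based rows/cols of the raster); the
# center of a block of `pitch` pixels starting at k is k + (pitch - 1)/2,
# so for even pitches centers fall between pixels and the well disks are
# symmetric about their centroid column (the two halves are equal-sized)
well_centers <- function(layout) {
  off <- floor((layout$image_width_px - layout$cols * layout$well_pitch_px) / 2)
  grid <- expand.grid(col = seq_len(layout$cols), row = seq_len(layout$rows))
  data.frame(
    well = seq_len(nrow(grid)),
    row = grid$row, col = grid$col,
    center_row_px = (grid$row - 1L) * layout$well_pitch_px +
      (layout$well_pitch_px - 1) / 2,
    center_col_px = off + (grid$col - 1L) * layout$well_pitch_px +
      (layout$well_pitch_px - 1) / 2,
    radius_px = layout$well_diameter_px / 2
  )
}

#' Render a synthetic plate hypercube
#'
#' Simulates one line-scan acquisition of a plate of binary powder mixtures:
#' each well carries its mixture spectrum, independently corrupted per pixel,
#' mapped to radiance counts through simulated white (0.9 full scale) and
#' dark (0.05 full scale) reference levels, so that reflectance calibration
#' inverts the construction exactly. Background pixels sit near the dark
#' level (reflectance about 0.02).
#'
#' @param design a [mixture_design()]; needs at most `layout$n_wells` wells.
#' @param layout a [plate_layout()].
#' @param endmembers named list of `endmember_spec`s containing `pure` and
#'   `design$adulterant`.
#' @param noise a [noise_model()].
#' @param grid wavelength grid (default the 900--2494 nm / 275-band grid).
#' @param pure name of the majority endmember (default "almond").
#' @param plate_id character tag used in well ids.
#' @return List with `raw`, `dark`, `white` hypercubes, `truth` well table
#'   (well_id, row, col, pixel center/radius, concentration_pct, adulterant,
#'   variety) and `labels`, the ground-truth integer well-label raster
#'   (0 = background).
#' @export
render_plate_cube <- function(design, layout, endmembers = default_endmembers(),
                              noise = noise_model(),
                              grid = make_wavelength_grid(900, 2494, 275),
                              pure = "almond", plate_id = "plate1") {
  stopifnot(inherits(design, "mixture_design"), inherits(layout, "plate_layout"))
  n_wells <- length(design$wells_pct)
  if (n_wells > layout$n_wells) {
    stop(sprintf("design needs %d wells but the plate holds %d",
                 n_wells, layout$n_wells))
  }
  wl <- wl_values(grid)
  J <- length(wl)
  nl <- layout$image_lines_px; ns <- layout$image_width_px

  pure_spec <- render_endmember(endmembers[[pure]], grid, design$variety)
  adul_spec <- render_endmember(endmembers[[design$adulterant]], grid, 1L)

  full_scale <- 10000
  white_level <- 0.9 * full_scale
  dark_level <- 0.05 * full_scale
  bg_refl <- 0.02

  centers <- well_centers(layout)[seq_len(n_wells), , drop = FALSE]
  labels <- matrix(0L, nl, ns)
  plane <- as.numeric(nl) * ns
  bg_idx <- seq_len(nl * ns)
  rowpix <- (bg_idx - 1L) %% nl   # 0-based raster coordinates
  colpix <- (bg_idx - 1L) %/% nl

  # background: flat dark reflectance with sensor noise only
  bg_noise <- noise_model(additive_sd = noise$additive_sd, 0, 0, 0)
  bg <- corrupt_matrix(matrix(bg_refl, nl * ns, J), bg_noise,
                       design$seed + 11L)
  refl <- array(bg, c(nl, ns, J))  # column-major: bg columns are bands

  for (w in seq_len(n_wells)) {
    cw <- centers[w, ]
    inside <- (rowpix - cw$center_row_px)^2 + (colpix - cw$center_col_px)^2 <=
      cw$radius_px^2
    pix <- which(inside)
    labels[pix] <- w
    mix <- mix_spectra(pure_spec, adul_spec, design$wells_pct[w] / 100)
    wseed <- (design$seed + 104729 * w) %% 2147483647
    spectra <- corrupt_matrix(matrix(mix, length(pix), J, byrow = TRUE),
                              noise, wseed)
    refl[outer(pix, (seq_len(J) - 1) * plane, "+")] <- spectra
  }

  raw <- dark_level + refl * (white_level - dark_level)
  dark <- array(dark_level, c(nl, ns, J))
  white <- array(white_level, c(nl, ns, J))

  truth <- data.frame(
    well_id = sprintf("%s_w%02d", plate_id, centers$well),
    row = centers$row, col = centers$col,
    center_row_px = centers$center_row_px,
    center_col_px = centers$center_col_px,
    radius_px = centers$radius_px,
    concentration_pct = design$wells_pct,
    adulterant = design$adulterant,
    variety = design$variety,
    stringsAsFactors = FALSE
  )

  list(raw = hypercube(raw, grid, state = "raw"),
       dark = hypercube(dark, grid, state = "raw"),
       white = hypercube(white, grid, state = "raw"),
       truth = truth, labels = labels)
}
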
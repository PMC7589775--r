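#' Per-pixel adulterant concentration map
#'
#' Applies a PLS1 model's beta vector to every foreground pixel spectrum of a
#' calibrated, band-cropped cube: each pixel spectrum is transformed with the
#' model's embedded pretreatment and scored as `intercept + sum_i I_i * R_i`.
#' Background pixels are missing (`NA`), never a sentinel concentration.
#' Pixels whose spectrum is degenerate under the pretreatment (e.g. constant
#' under SNV) are set missing and counted.
#'
#' @param cube reflectance `hypercube`, cropped to the model's band range.
#' @param mask a [segment_background()] mask (or logical matrix).
#' @param model a [pls1_fit()] model.
#' @param scale display scale in percent, default `c(0, 50)`.
#' @param model_id identifier recorded in the map.
#' @return Object of class `concentration_map`: `values` (2-D raster, `NA`
#'   off-mask), `mask`, `scale`, `model_id`, `n_failed`.
#' @export
map_concentration <- function(cube, mask, model, scale = c(0, 50),
                              model_id = "plsr1") {
  stopifnot(inherits(cube, "hypercube"), inherits(model, "plsr1"))
  if (cube$state != "reflectance") stop("map a calibrated cube")
  if (scale[1] >= scale[2]) stop("scale must be (low, high) with low < high")
  mk <- if (inherits(mask, "foreground_mask")) mask$mask else mask
  d <- dim(cube$data)
  if (!all(dim(mk) == d[1:2])) stop("mask shape mismatch")
  pix <- which(mk)
  values <- matrix(NA_real_, d[1], d[2])
  n_failed <- 0L
  if (length(pix) > 0) {
    flat <- matrix(cube$data, d[1] * d[2], d[3])[pix, , drop = FALSE]
    ok <- rep(TRUE, length(pix))
    if (!is.null(model$preprocess)) {
      ok <- !preprocess_bad_rows(model$preprocess, flat)
      n_failed <- sum(!ok)
      if (n_failed > 0) {
        warning(sprintf("%d pixel(s) failed preprocessing; set missing",
                        n_failed))
      }
    }
    if (any(ok)) {
      values[pix[ok]] <- predict(model, flat[ok, , drop = FALSE])
    }
  }
  structure(list(values = values, mask = mk, scale = as.numeric(scale),
                 model_id = model_id, n_failed = n_failed),
            class = "concentration_map")
}

#' Per-well statistics of a concentration map
#'
#' @param map a [map_concentration()] result.
#' @param truth well table (as from [render_plate_cube()]).
#' @return data.frame with `well_id`, `concentration_pct` (truth), `mean`,
#'   `sd`, `n_pixels` over non-missing pixels in each well disk.
#' @export
summarize_wells <- function(map, truth) {
  stopifnot(inherits(map, "concentration_map"))
  d <- dim(map$values)
  idx <- seq_len(d[1] * d[2])
  rowpix <- (idx - 1L) %% d[1]
  colpix <- (idx - 1L) %/% d[1]
  out <- lapply(seq_len(nrow(truth)), function(w) {
    tw <- truth[w, ]
    pix <- which((rowpix - tw$center_row_px)^2 +
                   (colpix - tw$center_col_px)^2 <= tw$radius_px^2)
    vals <- map$values[pix]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) stop(sprintf("well %s is empty", tw$well_id))
    data.frame(well_id = tw$well_id,
               concentration_pct = tw$concentration_pct,
               mean = mean(vals),
               sd = if (length(vals) > 1) stats::sd(vals) else 0,
               n_pixels = length(vals), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# blue -> red colormap (values in [0,1]); fixed anchors keep rendering
# deterministic
map_palette <- function(t) {
  ramp <- grDevices::colorRamp(c("#00007F", "#0000FF", "#00FFFF",
                                 "#FFFF00", "#FF0000", "#7F0000"),
                               space = "rgb")
  ramp(pmin(pmax(t, 0), 1)) / 255
}

#' Render a concentration map to PNG
#'
#' Values are clipped to the map scale and rendered with a blue-to-red
#' colormap; missing/background pixels are black. A JSON sidecar
#' (`<path>.json`) records the scale and model id. Rendering is
#' deterministic: the same map yields byte-identical files.
#'
#' @param map a `concentration_map`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
render_map <- function(map, path) {
  stopifnot(inherits(map, "concentration_map"))
  v <- map$values
  t <- (v - map$scale[1]) / diff(map$scale)
  miss <- is.na(v)
  t[miss] <- 0
  cols <- map_palette(as.vector(t))
  img <- array(0, c(nrow(v), ncol(v), 3))
  for (ch in 1:3) {
    plane <- matrix(cols[, ch], nrow(v), ncol(v))
    plane[miss] <- 0
    img[, , ch] <- plane
  }
  png::writePNG(img, path)
  jsonlite::write_json(
    list(scale_pct = map$scale, model_id = map$model_id,
         n_failed_pixels = map$n_failed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
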
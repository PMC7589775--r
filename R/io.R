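#' Write a hypercube as ENVI band-sequential raster + header
#'
#' The raster goes to `path` as little-endian doubles in band-sequential
#' (BSQ) order; the ASCII header goes to `<path>.hdr` with the wavelength
#' list and the cube's radiometric state. The round trip is bit-exact.
#'
#' @param cube a `hypercube`.
#' @param path data-file path (header written alongside as `<path>.hdr`).
#' @return `path`, invisibly.
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "hypercube"))
  d <- dim(cube$data)
  hdr <- c(
    "ENVI",
    "description = {swirauth hypercube}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    "interleave = bsq",
    "byte order = 0",
    sprintf("radiometric state = %s", cube$state),
    "wavelength units = Nanometers",
    paste0("wavelength = {",
           paste(sprintf("%.17g", cube$wavelengths), collapse = ", "), "}")
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(path, "wb")
  on.exit(close(con))
  # BSQ: per band, lines of samples (sample index fastest)
  for (b in seq_len(d[3])) {
    writeBin(as.vector(t(cube$data[, , b])), con, size = 8L,
             endian = "little")
  }
  invisible(path)
}

# minimal ENVI header parser: key = value, with {...} blocks possibly
# spanning lines
parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  out <- list()
  pat <- gregexpr("([a-zA-Z ][a-zA-Z0-9 ]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)",
                  txt, perl = TRUE)
  for (m in regmatches(txt, pat)[[1]]) {
    eq <- regexpr("=", m)
    key <- trimws(substr(m, 1, eq - 1))
    val <- trimws(substr(m, eq + 1, nchar(m)))
    out[[tolower(key)]] <- val
  }
  out
}

#' Read an ENVI band-sequential hypercube
#'
#' @param path data-file path written by [write_envi()] (header expected at
#'   `<path>.hdr`).
#' @return A `hypercube`.
#' @export
read_envi <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(hdr_path)) stop("missing ENVI header: ", hdr_path)
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "interleave", "data type")
  miss <- setdiff(need, names(h))
  if (length(miss) > 0) {
    stop("ENVI header missing field(s): ", paste(miss, collapse = ", "))
  }
  if (tolower(h$interleave) != "bsq") stop("only bsq interleave is supported")
  if (trimws(h$`data type`) != "5") stop("only data type 5 (double) is supported")
  ns <- as.integer(h$samples); nl <- as.integer(h$lines)
  nb <- as.integer(h$bands)
  if (is.null(h$wavelength)) stop("ENVI header missing wavelength block")
  wl <- as.numeric(strsplit(gsub("[{}]", "", h$wavelength), ",")[[1]])
  if (length(wl) != nb) {
    stop(sprintf("header band count (%d) does not match wavelength list (%d)",
                 nb, length(wl)))
  }
  state <- if (!is.null(h$`radiometric state`)) h$`radiometric state` else "raw"
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = ns * nl * nb, size = 8L,
                  endian = "little")
  if (length(vals) != ns * nl * nb) stop("raster size does not match header")
  data <- array(NA_real_, c(nl, ns, nb))
  per <- ns * nl
  for (b in seq_len(nb)) {
    data[, , b] <- t(matrix(vals[((b - 1) * per + 1):(b * per)], ns, nl))
  }
  hypercube(data, wl, state = state)
}

#' Write a spectral set as CSV
#'
#' Columns: `specimen_id, well_id, half, variety, adulterant,
#' concentration_pct`, then one column per band named `wl_<nm>`. Numeric
#' values are printed with 17 significant digits so the round trip is
#' bit-exact.
#'
#' @param set a `spectral_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(set, path) {
  stopifnot(inherits(set, "spectral_set"))
  sp <- apply(set$spectra, 2, function(x) sprintf("%.17g", x))
  if (is.null(dim(sp))) sp <- matrix(sp, nrow = nrow(set$spectra))
  colnames(sp) <- sprintf("wl_%.17g", set$wavelengths)
  df <- cbind(set$meta, as.data.frame(sp, stringsAsFactors = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a spectral set from CSV
#'
#' @param path CSV path written by [write_spectra_csv()].
#' @return A `spectral_set`.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  wl_cols <- grep("^wl_", names(df))
  if (length(wl_cols) == 0) stop("no wavelength (wl_) columns found")
  wl <- as.numeric(sub("^wl_", "", names(df)[wl_cols]))
  spectra <- as.matrix(df[, wl_cols, drop = FALSE])
  storage.mode(spectra) <- "double"
  spectral_set(spectra, wl, df[, -wl_cols, drop = FALSE])
}
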
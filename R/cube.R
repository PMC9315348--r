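#' Hyperspectral cube
#'
#' A 3-D raster of `rows x cols x bands` values with a wavelength axis
#' and a processing-stage tag. The stage records what the values mean
#' (`raw` camera counts, unitless `reflectance`, SNV-standardized
#' spectra, or `absorbance`) and is checked by every transformation so
#' that stages cannot be mixed accidentally.
#'
#' @param values numeric 3-D array, `rows x cols x bands`.
#' @param wavelengths numeric vector of band-center wavelengths in nm,
#'   strictly increasing, one per band.
#' @param stage processing stage, one of `"raw"`, `"reflectance"`,
#'   `"snv"`, `"absorbance"`.
#' @param meta named list of free-form metadata (calibration epsilon,
#'   saturation mask, SNV input stage, ...).
#' @return An object of class `hs_cube`.
#' @export
hs_cube <- function(values, wavelengths,
                    stage = c("raw", "reflectance", "snv", "absorbance"),
                    meta = list()) {
  stage <- match.arg(stage)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a rows x cols x bands array")
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) != dim(values)[3L])
    stop("length(wavelengths) must equal the number of bands")
  if (any(diff(wavelengths) <= 0))
    stop("`wavelengths` must be strictly increasing")
  structure(list(values = values, wavelengths = wavelengths,
                 stage = stage, meta = meta),
            class = "hs_cube")
}

#' @export
print.hs_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hs_cube> %d x %d pixels, %d bands (%.0f-%.0f nm), stage: %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$stage))
  invisible(x)
}

#' @export
dim.hs_cube <- function(x) dim(x$values)

cube_check_stage <- function(cube, expected, op) {
  if (!inherits(cube, "hs_cube")) stop(op, ": input is not an hs_cube")
  if (!cube$stage %in% expected)
    stop(sprintf("%s: cube stage is '%s' but must be one of: %s",
                 op, cube$stage, paste(expected, collapse = ", ")))
  invisible(TRUE)
}

## ---- ENVI raster I/O -------------------------------------------------
## ENVI stores a bare binary raster next to a small text header. Only the
## numeric types and interleaves produced by line-scan NIR cameras are
## supported: data types 2 (int16), 4 (float32), 5 (float64), 12 (uint16).

envi_type <- function(code) {
  switch(as.character(code),
         "2"  = list(what = "integer", size = 2L, signed = TRUE),
         "4"  = list(what = "numeric", size = 4L, signed = TRUE),
         "5"  = list(what = "numeric", size = 8L, signed = TRUE),
         "12" = list(what = "integer", size = 2L, signed = FALSE),
         stop("unsupported ENVI data type: ", code))
}

#' Write a cube as an ENVI raster + header
#'
#' Writes `<base>.raw` (binary, BIL interleave, little endian, float32)
#' and `<base>.hdr` (text header carrying dimensions, interleave and the
#' wavelength vector).
#'
#' @param cube an [hs_cube()].
#' @param base path without extension; directory must exist.
#' @return `base`, invisibly.
#' @export
write_envi <- function(cube, base) {
  stopifnot(inherits(cube, "hs_cube"))
  d <- dim(cube$values)
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 4",
           "interleave = bil",
           "byte order = 0",
           sprintf("stage = %s", cube$stage),
           paste0("wavelength = { ",
                  paste(format(cube$wavelengths, trim = TRUE), collapse = ", "),
                  " }"))
  writeLines(hdr, paste0(base, ".hdr"))
  ## BIL: samples fastest, then bands, then lines
  v <- aperm(cube$values, c(2L, 3L, 1L))
  con <- file(paste0(base, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(v), con, size = 4L, endian = "little")
  invisible(base)
}

parse_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  fields <- list()
  ## match `key = value` where value may be a brace block
  pat <- "(?m)^\\s*([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] == -1) stop("not an ENVI header: ", path)
  starts <- as.vector(m); lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    piece <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    key <- tolower(trimws(sub("=.*", "", piece)))
    val <- trimws(sub("^[^=]*=", "", piece))
    fields[[key]] <- val
  }
  fields
}

#' Read an ENVI raster + header into a cube
#'
#' Autodetects BIL/BSQ/BIP interleave and the numeric type from the
#' header; wavelengths are parsed from the header `wavelength` field.
#'
#' @param base path without extension, or the path to the `.hdr` file.
#' @param stage stage tag to assign (headers written by [write_envi()]
#'   carry one; it wins when present).
#' @return An [hs_cube()].
#' @export
read_envi <- function(base, stage = "raw") {
  hdr_path <- if (grepl("\\.hdr$", base)) base else paste0(base, ".hdr")
  raw_path <- sub("\\.hdr$", ".raw", hdr_path)
  if (!file.exists(raw_path)) {
    alt <- sub("\\.hdr$", "", hdr_path)
    if (file.exists(alt)) raw_path <- alt else stop("raster not found for ", hdr_path)
  }
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss)) stop("ENVI header missing fields: ", paste(miss, collapse = ", "))
  samples <- as.integer(h[["samples"]]); lines <- as.integer(h[["lines"]])
  bands <- as.integer(h[["bands"]])
  tp <- envi_type(as.integer(h[["data type"]]))
  interleave <- tolower(trimws(h[["interleave"]]))
  byte_order <- if (!is.null(h[["byte order"]]) && trimws(h[["byte order"]]) == "1")
    "big" else "little"
  n <- samples * lines * bands
  con <- file(raw_path, "rb")
  on.exit(close(con))
  offset <- if (!is.null(h[["header offset"]])) as.integer(h[["header offset"]]) else 0L
  if (offset > 0) readBin(con, "raw", n = offset)
  x <- readBin(con, tp$what, n = n, size = tp$size, signed = tp$signed,
               endian = byte_order)
  if (length(x) != n) stop("raster truncated: expected ", n, " values, got ", length(x))
  vals <- switch(interleave,
                 bil = aperm(array(x, c(samples, bands, lines)), c(3L, 1L, 2L)),
                 bip = aperm(array(x, c(bands, samples, lines)), c(3L, 2L, 1L)),
                 bsq = aperm(array(x, c(samples, lines, bands)), c(2L, 1L, 3L)),
                 stop("unsupported interleave: ", interleave))
  wl <- if (!is.null(h[["wavelength"]])) {
    as.numeric(strsplit(gsub("[{}]", "", h[["wavelength"]]), ",")[[1]])
  } else seq_len(bands)
  if (!is.null(h[["stage"]])) stage <- trimws(h[["stage"]])
  hs_cube(vals, wl, stage = stage)
}
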
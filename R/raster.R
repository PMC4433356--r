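#' Multi-band raster stack
#'
#' The basic carrier of all per-pixel math in the package: a rows x cols x B
#' array of real values (digital numbers, radiance, reflectance or index
#' values) with unique band names, a shared nodata mask, and a square pixel
#' size in metres. Pixel coordinates are 1-based in R, row-major, with the
#' band axis last; all modules share this convention.
#'
#' Any non-finite value in `data` is folded into the nodata mask: a pixel
#' masked in one band is masked in all bands (nodata propagates).
#'
#' @param data numeric matrix (single band) or rows x cols x B array.
#' @param band_names character vector of length B; unique. Defaults to
#'   `band1..bandB`, or `c("blue","green","red","nir")` when B = 4.
#' @param pixel_size metres per pixel (one number, square pixels).
#' @param mask optional logical rows x cols matrix, `TRUE` = nodata. Merged
#'   with non-finite cells of `data`.
#' @return an object of class `raster_stack`.
#' @export
raster_stack <- function(data, band_names = NULL, pixel_size = 1, mask = NULL) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a matrix or a rows x cols x B array")
  if (dim(data)[3] < 1L) stop("raster stack needs at least one band")
  b <- dim(data)[3]
  if (is.null(band_names)) {
    band_names <- if (b == 4L) c("blue", "green", "red", "nir")
                  else paste0("band", seq_len(b))
  }
  if (length(band_names) != b) stop("band_names length must equal band count")
  if (anyDuplicated(band_names)) stop("band_names must be unique")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  nonfinite <- apply(!is.finite(data), c(1, 2), any)
  if (is.null(mask)) {
    mask <- nonfinite
  } else {
    if (!is.logical(mask) || !identical(dim(mask), dim(data)[1:2]))
      stop("mask must be a logical matrix matching the band shape")
    mask <- mask | nonfinite
  }
  if (any(mask)) data[array(mask, dim(data))] <- NA_real_
  structure(
    list(data = data, band_names = as.character(band_names),
         mask = mask, pixel_size = as.numeric(pixel_size)),
    class = "raster_stack")
}

#' @export
dim.raster_stack <- function(x) dim(x$data)

#' Number of bands in a stack
#' @param x a `raster_stack`.
#' @return integer band count.
#' @export
n_bands <- function(x) dim(x$data)[3]

#' @export
print.raster_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<raster_stack> %d x %d pixels, %d band(s), pixel %g m\n",
              d[1], d[2], d[3], x$pixel_size))
  cat("  bands: ", paste(x$band_names, collapse = ", "), "\n", sep = "")
  cat(sprintf("  nodata: %d of %d pixels\n", sum(x$mask), d[1] * d[2]))
  invisible(x)
}

#' Extract one band as a matrix
#'
#' @param x a `raster_stack`.
#' @param band band name or index.
#' @return numeric matrix with `NA` at nodata pixels.
#' @export
get_band <- function(x, band) {
  stopifnot(inherits(x, "raster_stack"))
  if (is.character(band)) {
    i <- match(band, x$band_names)
    if (is.na(i)) stop("no band named '", band, "'")
  } else i <- as.integer(band)
  if (i < 1L || i > n_bands(x)) stop("band index out of range")
  m <- x$data[, , i, drop = FALSE]
  dim(m) <- dim(x$data)[1:2]
  m[x$mask] <- NA_real_
  m
}

# pixel x band matrix in row-major pixel order; masked pixels are NA rows
band_matrix <- function(x) {
  d <- dim(x$data)
  m <- matrix(aperm(x$data, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  colnames(m) <- x$band_names
  m
}

# inverse of band_matrix
matrix_to_stack <- function(m, rows, cols, band_names, pixel_size, mask = NULL) {
  a <- aperm(array(m, dim = c(cols, rows, ncol(m))), c(2, 1, 3))
  raster_stack(a, band_names = band_names, pixel_size = pixel_size, mask = mask)
}

stop_unless_same_geometry <- function(a, b, what = "rasters") {
  da <- dim(a)[1:2]; db <- dim(b)[1:2]
  if (!identical(da, db))
    stop(sprintf("%s have mismatched shapes: %dx%d vs %dx%d",
                 what, da[1], da[2], db[1], db[2]))
  invisible(TRUE)
}

#' Stack bands of several rasters into one
#'
#' @param ... `raster_stack` objects sharing one geometry.
#' @param suffixes optional per-input suffix appended to band names to keep
#'   them unique.
#' @return a `raster_stack` with the concatenated bands; the nodata mask is
#'   the union of the input masks.
#' @export
stack_bands <- function(..., suffixes = NULL) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "raster_stack"))
    xs <- xs[[1]]
  stopifnot(length(xs) >= 1L)
  for (x in xs) stopifnot(inherits(x, "raster_stack"))
  for (x in xs[-1]) stop_unless_same_geometry(xs[[1]], x)
  nm <- lapply(seq_along(xs), function(i) {
    bn <- xs[[i]]$band_names
    if (!is.null(suffixes)) bn <- paste0(bn, suffixes[i])
    bn
  })
  nm <- unlist(nm)
  if (anyDuplicated(nm)) nm <- make.unique(nm, sep = "_")
  mask <- Reduce(`|`, lapply(xs, `[[`, "mask"))
  data <- array(unlist(lapply(xs, `[[`, "data")),
                dim = c(dim(xs[[1]]$data)[1:2], length(nm)))
  raster_stack(data, band_names = nm, pixel_size = xs[[1]]$pixel_size,
               mask = mask)
}

sidecar_path <- function(path) paste0(path, ".aux.json")

#' Write a raster stack to disk
#'
#' Two formats, chosen by extension. `.tif`/`.tiff`: one 32-bit float TIFF
#' page per band, each band affinely rescaled into [0, 1] (the storage range
#' of the TIFF writer) with the per-band offset/slope, band names, pixel size
#' and nodata mask recorded in a `<file>.aux.json` sidecar; values round-trip
#' to about single precision. `.grd`: the package's plain-text grid format —
#' a JSON header line followed by one full-precision number per line — which
#' round-trips exactly and needs no sidecar.
#'
#' @param x a `raster_stack`.
#' @param path output file path ending in `.tif`, `.tiff` or `.grd`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(x, path) {
  stopifnot(inherits(x, "raster_stack"))
  ext <- tolower(tools::file_ext(path))
  d <- dim(x$data)
  if (ext %in% c("tif", "tiff")) {
    pages <- vector("list", d[3])
    offs <- numeric(d[3]); slopes <- numeric(d[3])
    for (i in seq_len(d[3])) {
      m <- x$data[, , i]
      m[x$mask] <- NA
      lo <- suppressWarnings(min(m, na.rm = TRUE))
      hi <- suppressWarnings(max(m, na.rm = TRUE))
      if (!is.finite(lo)) { lo <- 0; hi <- 1 }        # all-nodata band
      if (hi <= lo) hi <- lo + 1                       # constant band
      offs[i] <- lo; slopes[i] <- hi - lo
      m <- (m - lo) / (hi - lo)
      m[!is.finite(m)] <- 0
      pages[[i]] <- m
    }
    pages[[d[3] + 1L]] <- matrix(as.numeric(x$mask), d[1], d[2])
    suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                     compression = "none"))
    jsonlite::write_json(
      list(band_names = x$band_names, pixel_size = x$pixel_size,
           offset = offs, slope = slopes, mask_page = d[3] + 1L),
      sidecar_path(path), auto_unbox = TRUE, digits = NA)
  } else if (ext == "grd") {
    con <- file(path, "w")
    on.exit(close(con))
    hdr <- jsonlite::toJSON(list(rows = d[1], cols = d[2], bands = d[3],
                                 band_names = x$band_names,
                                 pixel_size = x$pixel_size),
                            auto_unbox = TRUE, digits = NA)
    writeLines(as.character(hdr), con)
    v <- as.vector(x$data)          # column-major within band, bands last
    v[as.vector(array(x$mask, d))] <- NA
    writeLines(format(v, digits = 17, trim = TRUE, scientific = TRUE), con)
  } else stop("unsupported raster extension '.", ext, "' (use .tif or .grd)")
  invisible(path)
}

#' Read a raster stack from disk
#'
#' Reads the formats produced by [write_raster()]. For TIFF the `.aux.json`
#' sidecar restores band names, pixel size, per-band scaling and the nodata
#' mask; a TIFF without a sidecar is read as-is with default band names.
#'
#' @param path file path.
#' @return a `raster_stack`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
    sc <- sidecar_path(path)
    if (file.exists(sc)) {
      meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
      mask <- pages[[meta$mask_page]] > 0.5
      nb <- meta$mask_page - 1L
      data <- array(NA_real_, c(dim(pages[[1]]), nb))
      for (i in seq_len(nb))
        data[, , i] <- meta$offset[i] + meta$slope[i] * pages[[i]]
      return(raster_stack(data, band_names = meta$band_names,
                          pixel_size = meta$pixel_size, mask = mask))
    }
    data <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
    return(raster_stack(data))
  }
  if (ext == "grd") {
    lines <- readLines(path)
    meta <- jsonlite::fromJSON(lines[1])
    n <- meta$rows * meta$cols * meta$bands
    if (length(lines) - 1L != n) stop("corrupt .grd file: value count mismatch")
    vals <- lines[-1]
    v <- rep(NA_real_, n)
    ok <- vals != "NA"
    v[ok] <- as.numeric(vals[ok])
    data <- array(v, dim = c(meta$rows, meta$cols, meta$bands))
    return(raster_stack(data, band_names = meta$band_names,
                        pixel_size = meta$pixel_size))
  }
  stop("unsupported raster extension '.", ext, "'")
}
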
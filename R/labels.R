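#' Labeled sample raster
#'
#' Integer raster of species codes (0 = unlabeled/background) tagged with a
#' role and a species look-up table. Shape must match the companion
#' `raster_stack`; every nonzero code must appear in `species_table`.
#'
#' @param labels integer matrix of species codes, 0 for unlabeled.
#' @param species_table data frame with at least columns `code` and `abbrev`
#'   (optionally `name`, `family`, sample counts).
#' @param role `"training"` or `"test"`.
#' @return an object of class `label_raster`.
#' @export
label_raster <- function(labels, species_table, role = c("training", "test")) {
  role <- match.arg(role)
  if (!is.matrix(labels)) stop("`labels` must be an integer matrix")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE)) stop("species codes must be >= 0")
  if (!all(c("code", "abbrev") %in% names(species_table)))
    stop("species_table needs columns `code` and `abbrev`")
  present <- setdiff(unique(labels[labels > 0L]), species_table$code)
  if (length(present))
    stop("codes in raster missing from species_table: ",
         paste(present, collapse = ", "))
  structure(list(labels = labels, species_table = species_table, role = role),
            class = "label_raster")
}

#' @export
print.label_raster <- function(x, ...) {
  cat(sprintf("<label_raster> %d x %d, role=%s, %d labeled pixels, %d species\n",
              nrow(x$labels), ncol(x$labels), x$role, sum(x$labels > 0L),
              length(unique(x$labels[x$labels > 0L]))))
  invisible(x)
}

#' Rasterize simple crown-like regions into a label matrix
#'
#' Supports axis-aligned rectangles and discs, enough to emulate digitised
#' crown polygons. A pixel is labeled when its centre falls inside the
#' region; later regions overwrite earlier ones.
#'
#' @param rows,cols raster shape.
#' @param regions list of lists: `list(type = "rect", code, row0, row1, col0,
#'   col1)` or `list(type = "disc", code, row, col, radius)` (pixel units,
#'   1-based centres).
#' @return integer matrix of codes.
#' @export
rasterize_regions <- function(rows, cols, regions) {
  lab <- matrix(0L, rows, cols)
  for (rg in regions) {
    if (rg$type == "rect") {
      r <- max(1L, rg$row0):min(rows, rg$row1)
      c <- max(1L, rg$col0):min(cols, rg$col1)
      lab[r, c] <- as.integer(rg$code)
    } else if (rg$type == "disc") {
      r0 <- max(1L, floor(rg$row - rg$radius)):min(rows, ceiling(rg$row + rg$radius))
      c0 <- max(1L, floor(rg$col - rg$radius)):min(cols, ceiling(rg$col + rg$radius))
      for (i in r0) for (j in c0)
        if ((i - rg$row)^2 + (j - rg$col)^2 <= rg$radius^2)
          lab[i, j] <- as.integer(rg$code)
    } else stop("unknown region type: ", rg$type)
  }
  lab
}

#' Read / write a species look-up table
#'
#' CSV with columns `code,abbrev,name` (extra columns such as `family`,
#' `training_n`, `test_n` are kept).
#'
#' @param path CSV file path.
#' @return data frame.
#' @export
read_species_table <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("code", "abbrev") %in% names(tb)))
    stop("species table must have columns `code` and `abbrev`")
  tb
}

#' @rdname read_species_table
#' @param tb species table data frame.
#' @export
write_species_table <- function(tb, path) {
  utils::write.csv(tb, path, row.names = FALSE)
  invisible(path)
}

#' The 40-species reference sampling table
#'
#' The stratified reference-sample bookkeeping shipped with the package:
#' 40 subtropical overstorey tree species with their family, abbreviation
#' and per-species training/test pixel counts. Useful for sizing emulated
#' scenes and for sample-count bookkeeping checks.
#'
#' @return data frame with columns `code`, `abbrev`, `name`, `family`,
#'   `training_n`, `test_n`.
#' @export
reference_species_table <- function() {
  read_species_table(system.file("extdata", "species_samples.csv",
                                 package = "spectex", mustWork = TRUE))
}

#' Extract per-species feature vectors from a stack
#'
#' One record per labeled, non-nodata pixel, in deterministic row-major scan
#' order. The per-species counts conserve: their sum equals the number of
#' labeled pixels outside the nodata mask.
#'
#' @param stack a `raster_stack` of features.
#' @param labels a `label_raster` of matching shape.
#' @return an object of class `sample_set`: list with `features` (n x B
#'   matrix), `codes` (integer n), `counts` (named per-species counts),
#'   `band_names`, `role`.
#' @export
extract_samples <- function(stack, labels) {
  stopifnot(inherits(stack, "raster_stack"), inherits(labels, "label_raster"))
  lab <- labels$labels
  if (!identical(dim(stack$data)[1:2], dim(lab)))
    stop("stack and labels have mismatched shapes")
  keep <- lab > 0L & !stack$mask
  if (!any(keep)) stop("no usable pixels: all labeled pixels are nodata or absent")
  # row-major scan order
  ord <- which(t(keep))
  X <- band_matrix(stack)[ord, , drop = FALSE]
  codes <- as.integer(t(lab))[ord]
  counts <- table(factor(codes, levels = sort(unique(codes))))
  structure(list(features = X, codes = codes,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 band_names = stack$band_names, role = labels$role),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d pixels, %d bands, %d species, role=%s\n",
              nrow(x$features), ncol(x$features), length(x$counts), x$role))
  invisible(x)
}
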
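#' Vegetation-index parameters
#'
#' Tunable constants of the five index layers. Defaults follow common
#' practice: SAVI soil-adjustment L = 0.5 (moderate green cover), ARVI
#' gamma = 1 (aerosol model unknown), EVI G = 2.5, C1 = 6, C2 = 7.5, L = 1.
#' `eps` guards near-zero denominators: pixels whose index denominator has
#' magnitude below `eps` become nodata rather than +/-Inf.
#'
#' @param savi_L soil-adjustment factor, >= 0.
#' @param arvi_gamma gamma weighting of the blue-red difference.
#' @param evi_G,evi_C1,evi_C2,evi_L enhanced-vegetation-index constants.
#' @param eps small positive denominator guard.
#' @return list of class `vi_params`.
#' @export
vi_params <- function(savi_L = 0.5, arvi_gamma = 1.0, evi_G = 2.5,
                      evi_C1 = 6, evi_C2 = 7.5, evi_L = 1, eps = 1e-6) {
  if (savi_L < 0) stop("savi_L must be >= 0")
  if (evi_G <= 0) stop("evi_G must be > 0")
  if (eps <= 0) stop("eps must be > 0")
  structure(list(savi_L = savi_L, arvi_gamma = arvi_gamma, evi_G = evi_G,
                 evi_C1 = evi_C1, evi_C2 = evi_C2, evi_L = evi_L, eps = eps),
            class = "vi_params")
}

vi_band <- function(stack, name) {
  if (!(name %in% stack$band_names))
    stop("stack is missing required band '", name, "'")
  get_band(stack, name)
}

vi_wrap <- function(num, den, stack, out_name, eps, plus = 0) {
  val <- num / (den + plus)
  guard <- abs(den + plus) < eps
  guard[is.na(guard)] <- FALSE
  val[guard] <- NA_real_
  raster_stack(array(val, c(dim(val), 1L)), band_names = out_name,
               pixel_size = stack$pixel_size, mask = stack$mask | guard)
}

#' Normalized difference vegetation index
#'
#' `(nir - red) / (nir + red)`, in [-1, 1] wherever defined.
#'
#' @param stack reflectance `raster_stack` with `red` and `nir` bands.
#' @param p a [vi_params()].
#' @return single-band `raster_stack` named `ndvi`.
#' @export
ndvi <- function(stack, p = vi_params()) {
  nir <- vi_band(stack, "nir"); red <- vi_band(stack, "red")
  vi_wrap(nir - red, nir + red, stack, "ndvi", p$eps)
}

#' Soil-adjusted vegetation index
#'
#' `(nir - red) / (nir + red + L) * (1 + L)`; reduces to NDVI at L = 0.
#'
#' @inheritParams ndvi
#' @return single-band `raster_stack` named `savi`.
#' @export
savi <- function(stack, p = vi_params()) {
  nir <- vi_band(stack, "nir"); red <- vi_band(stack, "red")
  L <- p$savi_L
  out <- vi_wrap(nir - red, nir + red + L, stack, "savi", p$eps)
  out$data <- out$data * (1 + L)
  out
}

#' Atmospherically resistant vegetation index
#'
#' Uses the aerosol-corrected red `rb = red - gamma * (blue - red)`:
#' `(nir - rb) / (nir + rb)`. Equals NDVI when blue = red.
#'
#' @param stack reflectance `raster_stack` with `blue`, `red`, `nir` bands.
#' @inheritParams ndvi
#' @return single-band `raster_stack` named `arvi`.
#' @export
arvi <- function(stack, p = vi_params()) {
  nir <- vi_band(stack, "nir"); red <- vi_band(stack, "red")
  blue <- vi_band(stack, "blue")
  rb <- red - p$arvi_gamma * (blue - red)
  vi_wrap(nir - rb, nir + rb, stack, "arvi", p$eps)
}

#' Visible atmospherically resistant index
#'
#' `(green - red) / (green + red - blue)`, from the visible bands only.
#'
#' @param stack reflectance `raster_stack` with `blue`, `green`, `red` bands.
#' @inheritParams ndvi
#' @return single-band `raster_stack` named `vari`.
#' @export
vari <- function(stack, p = vi_params()) {
  green <- vi_band(stack, "green"); red <- vi_band(stack, "red")
  blue <- vi_band(stack, "blue")
  vi_wrap(green - red, green + red - blue, stack, "vari", p$eps)
}

#' Enhanced vegetation index
#'
#' `G * (nir - red) / (nir + C1 * red - C2 * blue + L)`.
#'
#' @param stack reflectance `raster_stack` with `blue`, `red`, `nir` bands.
#' @inheritParams ndvi
#' @return single-band `raster_stack` named `evi`.
#' @export
evi <- function(stack, p = vi_params()) {
  nir <- vi_band(stack, "nir"); red <- vi_band(stack, "red")
  blue <- vi_band(stack, "blue")
  out <- vi_wrap(nir - red, nir + p$evi_C1 * red - p$evi_C2 * blue + p$evi_L,
                 stack, "evi", p$eps)
  out$data <- out$data * p$evi_G
  out
}

#' Assemble the five-band vegetation-index stack
#'
#' Computes NDVI, SAVI, EVI, ARVI and VARI from a 4-band reflectance stack
#' and stacks them in that fixed order; the output nodata mask is the union
#' of the per-index masks.
#'
#' @param stack 4-band reflectance `raster_stack` (blue, green, red, nir).
#' @param p a [vi_params()].
#' @return 5-band `raster_stack` `[ndvi, savi, evi, arvi, vari]`.
#' @export
build_hms5vi <- function(stack, p = vi_params()) {
  if (n_bands(stack) != 4L)
    stop("expected a 4-band reflectance stack, got ", n_bands(stack), " bands")
  stack_bands(list(ndvi(stack, p), savi(stack, p), evi(stack, p),
                   arvi(stack, p), vari(stack, p)))
}
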
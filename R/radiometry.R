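#' Per-band radiometric calibration table
#'
#' Coefficients for converting 16-bit digital numbers to at-sensor spectral
#' radiance: for band i,
#' \deqn{L_i = a_i k_i \mathrm{DN}_i / \Delta\lambda_i}
#' with calibration gain `a` (W m-2 sr-1 count-1), revised factor `k`
#' (W m-2 sr-1 count-1, exposure/TDI dependent and therefore configurable)
#' and nominal bandpass width `bandwidth_um` (micrometres), giving radiance
#' in W m-2 um-1 sr-1.
#'
#' @param band character band names.
#' @param a,k positive calibration coefficients, one per band.
#' @param bandwidth_um positive bandpass widths in micrometres, one per band.
#' @return data frame of class `calibration_table`.
#' @seealso [quickbird_calibration()] for the packaged defaults.
#' @export
calibration_table <- function(band, a, k, bandwidth_um) {
  stopifnot(length(band) == length(a), length(a) == length(k),
            length(k) == length(bandwidth_um))
  if (any(a <= 0) || any(k <= 0) || any(bandwidth_um <= 0))
    stop("a, k and bandwidth_um must all be positive")
  structure(data.frame(band = as.character(band), a = a, k = k,
                       bandwidth_um = bandwidth_um,
                       stringsAsFactors = FALSE),
            class = c("calibration_table", "data.frame"))
}

#' Default QuickBird calibration coefficients
#'
#' Absolute radiance calibration for 16-bit QuickBird products at 10 TDI
#' levels (pan plus the four multispectral bands); bandpass widths converted
#' from nm to micrometres.
#'
#' @return a `calibration_table`.
#' @export
quickbird_calibration <- function() {
  calibration_table(
    band        = c("pan",      "blue",     "green",    "red",      "nir"),
    k           = c(0.0838188,  0.0160412,  0.0143847,  0.0126735,  0.0154242),
    a           = c(0.06269,    0.01431,    0.01045,    0.00968,    0.01568),
    bandwidth_um = c(0.455,     0.070,      0.080,      0.060,      0.140))
}

cal_rows_for <- function(cal, band_names) {
  i <- match(band_names, cal$band)
  if (anyNA(i))
    stop("no calibration row for band(s): ",
         paste(band_names[is.na(i)], collapse = ", "))
  cal[i, , drop = FALSE]
}

#' Convert digital numbers to at-sensor radiance
#'
#' Applies `L = a k DN / bandwidth` per band. Nodata propagates.
#'
#' @param dn_stack `raster_stack` of nonnegative digital numbers.
#' @param cal `calibration_table` with one row per band of `dn_stack`
#'   (matched by band name).
#' @return `raster_stack` of radiance (W m-2 um-1 sr-1).
#' @export
dn_to_radiance <- function(dn_stack, cal) {
  stopifnot(inherits(dn_stack, "raster_stack"),
            inherits(cal, "calibration_table"))
  if (any(dn_stack$data < 0, na.rm = TRUE))
    stop("digital numbers must be >= 0")
  rows <- cal_rows_for(cal, dn_stack$band_names)
  out <- dn_stack$data
  for (i in seq_len(n_bands(dn_stack)))
    out[, , i] <- rows$a[i] * rows$k[i] * dn_stack$data[, , i] / rows$bandwidth_um[i]
  raster_stack(out, band_names = dn_stack$band_names,
               pixel_size = dn_stack$pixel_size, mask = dn_stack$mask)
}

#' Reflectance conversion parameters
#'
#' Parameters of the dark-object-subtraction reflectance model
#' \deqn{\rho = \pi (L - L_{path}) d^2 / (E_{sun} \cos\theta_z)}
#' where the per-band path radiance `L_path` is derived from a dark-object
#' DN estimate through the calibration equation, `d` is the Earth-Sun
#' distance in AU and `theta_z` the solar zenith angle.
#'
#' @param esun named numeric vector, per-band exoatmospheric solar
#'   irradiance (W m-2 um-1).
#' @param sun_elevation solar elevation in degrees, in (0, 90].
#' @param earth_sun_distance AU, in [0.983, 1.017].
#' @param dark_object_dn named per-band dark-object DN estimates (0 = no
#'   path-radiance subtraction).
#' @return list of class `reflectance_params`.
#' @export
reflectance_params <- function(esun = quickbird_esun(),
                               sun_elevation = 60,
                               earth_sun_distance = 1,
                               dark_object_dn = 0) {
  if (sun_elevation <= 0 || sun_elevation > 90)
    stop("sun_elevation must be in (0, 90] degrees")
  if (earth_sun_distance < 0.983 || earth_sun_distance > 1.017)
    stop("earth_sun_distance must be in [0.983, 1.017] AU")
  structure(list(esun = esun, sun_elevation = sun_elevation,
                 earth_sun_distance = earth_sun_distance,
                 dark_object_dn = dark_object_dn),
            class = "reflectance_params")
}

#' Default QuickBird band-averaged solar irradiance
#'
#' @return named vector of ESUN values (W m-2 um-1) for the pan and four
#'   multispectral bands.
#' @export
quickbird_esun <- function() {
  c(pan = 1381.79, blue = 1924.59, green = 1843.08, red = 1574.77,
    nir = 1113.71)
}

#' Convert at-sensor radiance to surface reflectance
#'
#' Dark-object-subtraction (path-radiance) atmospheric correction: the
#' per-band path radiance is obtained by pushing `dark_object_dn` through
#' the calibration equation, then
#' `rho = pi * (L - L_path) * d^2 / (ESUN * cos(solar zenith))`, clipped to
#' [0, 1]. Negative post-subtraction values are clipped to 0 rather than
#' masked, keeping dark crown pixels usable.
#'
#' @param rad_stack `raster_stack` of radiance.
#' @param params a `reflectance_params`.
#' @param cal `calibration_table` used to turn `dark_object_dn` into path
#'   radiance (only needed when any dark-object DN is nonzero).
#' @return `raster_stack` of dimensionless reflectance in [0, 1].
#' @export
radiance_to_reflectance <- function(rad_stack, params, cal = quickbird_calibration()) {
  stopifnot(inherits(rad_stack, "raster_stack"),
            inherits(params, "reflectance_params"))
  if (any(rad_stack$data < 0, na.rm = TRUE))
    stop("radiance must be >= 0")
  bn <- rad_stack$band_names
  esun <- params$esun[bn]
  if (anyNA(esun)) stop("esun missing for band(s): ",
                        paste(bn[is.na(esun)], collapse = ", "))
  dod <- params$dark_object_dn
  if (length(dod) == 1L && is.null(names(dod)))
    dod <- stats::setNames(rep(dod, length(bn)), bn)
  dod <- dod[bn]
  dod[is.na(dod)] <- 0
  lpath <- if (all(dod == 0)) stats::setNames(rep(0, length(bn)), bn) else {
    rows <- cal_rows_for(cal, bn)
    stats::setNames(rows$a * rows$k * dod / rows$bandwidth_um, bn)
  }
  coszen <- cos((90 - params$sun_elevation) * pi / 180)
  d2 <- params$earth_sun_distance^2
  out <- rad_stack$data
  for (i in seq_along(bn)) {
    rho <- pi * (rad_stack$data[, , i] - lpath[i]) * d2 / (esun[i] * coszen)
    out[, , i] <- pmin(pmax(rho, 0), 1)
  }
  raster_stack(out, band_names = bn, pixel_size = rad_stack$pixel_size,
               mask = rad_stack$mask)
}
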
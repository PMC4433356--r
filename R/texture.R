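#' Lee-sigma filter parameters
#'
#' @param window odd window side length, >= 3 (default 7).
#' @param sigma_multiplier half-width of the acceptance range in units of
#'   the local standard deviation (default 2, i.e. centre +/- 2 sigma).
#' @param min_in_range minimum number of in-range neighbours (excluding the
#'   centre) required to accept the window average; below it the centre
#'   value is kept unchanged, preserving isolated spikes.
#' @return list of class `lee_sigma_params`.
#' @export
lee_sigma_params <- function(window = 7L, sigma_multiplier = 2,
                             min_in_range = 1L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  if (sigma_multiplier <= 0) stop("sigma_multiplier must be > 0")
  structure(list(window = window, sigma_multiplier = sigma_multiplier,
                 min_in_range = as.integer(min_in_range)),
            class = "lee_sigma_params")
}

# neighbour view of `pad` shifted by (di, dj); pad has an h-cell NA border
shift_view <- function(pad, di, dj, R, C, h) {
  pad[(1 + h + di):(R + h + di), (1 + h + dj):(C + h + dj), drop = FALSE]
}

#' Lee-sigma filter of one band
#'
#' Standard-deviation (sigma) filtering: each pixel is replaced by the mean
#' of the window values lying within `centre +/- sigma_multiplier * sigma`,
#' where sigma is the sample standard deviation (n - 1 denominator) of the
#' unmasked window values. The centre always counts as in range. Windows
#' are truncated at image borders; `NA` (nodata) pixels are excluded from
#' windows and stay `NA` in the output. Smooths noise while preserving
#' edges: out-of-range neighbours (the other side of an edge) never enter
#' the average.
#'
#' @param band numeric matrix; `NA` marks nodata.
#' @param p a [lee_sigma_params()].
#' @return filtered matrix of the same shape.
#' @export
lee_sigma_band <- function(band, p = lee_sigma_params()) {
  stopifnot(is.matrix(band), inherits(p, "lee_sigma_params"))
  R <- nrow(band); C <- ncol(band)
  if (p$window > R || p$window > C)
    stop("window larger than the image in at least one dimension")
  h <- (p$window - 1L) %/% 2L
  pad <- matrix(NA_real_, R + 2L * h, C + 2L * h)
  pad[(h + 1L):(h + R), (h + 1L):(h + C)] <- band
  offs <- expand.grid(di = -h:h, dj = -h:h)
  # pass 1: local sample sd over unmasked window values
  cnt <- matrix(0, R, C); s1 <- matrix(0, R, C); s2 <- matrix(0, R, C)
  for (k in seq_len(nrow(offs))) {
    S <- shift_view(pad, offs$di[k], offs$dj[k], R, C, h)
    ok <- !is.na(S)
    cnt <- cnt + ok
    S[!ok] <- 0
    s1 <- s1 + S
    s2 <- s2 + S * S
  }
  v <- (s2 - s1 * s1 / pmax(cnt, 1)) / pmax(cnt - 1, 1)
  v[cnt < 2] <- 0
  sigma <- sqrt(pmax(v, 0))
  thr <- p$sigma_multiplier * sigma
  # pass 2: mean over values within centre +/- thr
  rcnt <- matrix(0, R, C); rsum <- matrix(0, R, C)
  for (k in seq_len(nrow(offs))) {
    S <- shift_view(pad, offs$di[k], offs$dj[k], R, C, h)
    inr <- !is.na(S) & !is.na(band) & abs(S - band) <= thr
    S[!inr] <- 0
    rcnt <- rcnt + inr
    rsum <- rsum + S
  }
  out <- rsum / pmax(rcnt, 1)
  fallback <- (rcnt - 1) < p$min_in_range      # too few in-range neighbours
  out[fallback] <- band[fallback]
  out[is.na(band)] <- NA_real_
  out
}

#' Spectral-spatial texture stack
#'
#' Applies the Lee-sigma filter to every band of a stack: an L-band input
#' produces an L-band texture stack carrying the spectral information of
#' the input plus the spatial smoothness structure the filter imposes.
#'
#' @param stack `raster_stack`.
#' @param p a [lee_sigma_params()].
#' @param suffix appended to each band name (default `"_tex"`).
#' @return `raster_stack` with the same band count.
#' @export
build_spectex <- function(stack, p = lee_sigma_params(), suffix = "_tex") {
  stopifnot(inherits(stack, "raster_stack"))
  out <- stack$data
  for (i in seq_len(n_bands(stack)))
    out[, , i] <- lee_sigma_band(get_band(stack, i), p)
  raster_stack(out, band_names = paste0(stack$band_names, suffix),
               pixel_size = stack$pixel_size, mask = stack$mask)
}
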
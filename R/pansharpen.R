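#' Upsample a stack to a finer grid
#'
#' Separable bilinear (default) or nearest-neighbour resampling by an
#' integer factor. Coarse and fine grids are aligned on pixel centres;
#' bilinear weights are clamped at the borders. A fine pixel influenced by
#' a nodata coarse pixel becomes nodata (nodata propagates).
#'
#' @param x `raster_stack`.
#' @param factor integer upsampling factor (>= 1).
#' @param method `"bilinear"` or `"nearest"`.
#' @return `raster_stack` on the fine grid, pixel size divided by `factor`.
#' @export
upsample <- function(x, factor, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(inherits(x, "raster_stack"))
  f <- as.integer(factor)
  if (f < 1L || abs(factor - f) > 1e-9) stop("factor must be a positive integer")
  if (f == 1L) return(x)
  d <- dim(x$data)
  idx <- function(n) {
    u <- (seq_len(n * f) - 0.5) / f + 0.5      # position in coarse index space
    if (method == "nearest" || n == 1L) {
      i0 <- pmin(pmax(round(u), 1L), n)
      list(i0 = i0, i1 = i0, t = rep(0, n * f))
    } else {
      i0 <- pmin(pmax(floor(u), 1L), n - 1L)
      list(i0 = i0, i1 = i0 + 1L, t = pmin(pmax(u - i0, 0), 1))
    }
  }
  ri <- idx(d[1]); ci <- idx(d[2])
  out <- array(NA_real_, c(d[1] * f, d[2] * f, d[3]))
  for (b in seq_len(d[3])) {
    m <- x$data[, , b]
    m[x$mask] <- NA
    a00 <- m[ri$i0, ci$i0]; a01 <- m[ri$i0, ci$i1]
    a10 <- m[ri$i1, ci$i0]; a11 <- m[ri$i1, ci$i1]
    tr <- matrix(ri$t, d[1] * f, d[2] * f)
    tc <- matrix(ci$t, d[1] * f, d[2] * f, byrow = TRUE)
    out[, , b] <- (1 - tr) * (1 - tc) * a00 + (1 - tr) * tc * a01 +
                  tr * (1 - tc) * a10 + tr * tc * a11
  }
  raster_stack(out, band_names = x$band_names,
               pixel_size = x$pixel_size / f)
}

# forward PCT on the unmasked pixels of a pixel x band matrix
pct_forward <- function(X, keep) {
  mu <- colMeans(X[keep, , drop = FALSE])
  S <- stats::cov(X[keep, , drop = FALSE])
  e <- eigen(S, symmetric = TRUE)
  V <- e$vectors
  if (sum(V[, 1]) < 0) V[, 1] <- -V[, 1]        # deterministic PC1 orientation
  scores <- sweep(X, 2, mu) %*% V
  list(loadings = V, band_means = mu, scores = scores)
}

#' Principal-component-substitution pansharpening
#'
#' Fuses a coarse multispectral stack with a single fine panchromatic band:
#' the multispectral bands are upsampled to the pan grid, rotated into
#' principal components (covariance PCT, PC1 sign fixed so its loadings sum
#' positive), the first component is replaced by the pan band stretched
#' affinely onto the PC1 range,
#' \deqn{H = min_{PC1} + (Pan - min_{Pan}) (max_{PC1} - min_{PC1}) /
#'       (max_{Pan} - min_{Pan}),}
#' and the rotation inverted. Extrema are taken over non-nodata pixels.
#'
#' @param ms `raster_stack` of B multispectral bands (coarse grid).
#' @param pan single-band `raster_stack` whose pixel size divides the
#'   multispectral pixel size by an integer factor.
#' @param resample upsampling kernel for the multispectral bands.
#' @return fused B-band `raster_stack` on the pan grid, with the fitted
#'   transform attached as attribute `"fusion_transform"` (loadings, band
#'   means, PC1 and pan extrema).
#' @export
pct_fuse <- function(ms, pan, resample = c("bilinear", "nearest")) {
  resample <- match.arg(resample)
  stopifnot(inherits(ms, "raster_stack"), inherits(pan, "raster_stack"))
  if (n_bands(pan) != 1L) stop("pan must have exactly one band")
  ratio <- ms$pixel_size / pan$pixel_size
  f <- round(ratio)
  if (f < 1L || abs(ratio - f) > 1e-6)
    stop("pan pixel size must divide the multispectral pixel size by an integer factor")
  up <- upsample(ms, f, method = resample)
  stop_unless_same_geometry(up, pan, "upsampled MS and pan")
  X <- band_matrix(up)
  p <- as.vector(t(get_band(pan, 1L)))
  mask <- up$mask | pan$mask
  keep <- !as.vector(t(mask)) & stats::complete.cases(X) & !is.na(p)
  if (!any(keep)) stop("no overlapping valid pixels between MS and pan")
  fw <- pct_forward(X, keep)
  pc1 <- fw$scores[, 1]
  pc1_min <- min(pc1[keep]); pc1_max <- max(pc1[keep])
  pan_min <- min(p[keep]);   pan_max <- max(p[keep])
  if (pan_max <= pan_min) stop("flat panchromatic band: no fusion possible")
  H <- pc1_min + (p - pan_min) * (pc1_max - pc1_min) / (pan_max - pan_min)
  scores <- fw$scores
  scores[, 1] <- H
  Xf <- sweep(scores %*% t(fw$loadings), 2, fw$band_means, `+`)
  out <- matrix_to_stack(Xf, dim(up$data)[1], dim(up$data)[2],
                         ms$band_names, pan$pixel_size, mask = mask)
  attr(out, "fusion_transform") <- list(
    loadings = fw$loadings, band_means = fw$band_means,
    pc1_min = pc1_min, pc1_max = pc1_max,
    pan_min = pan_min, pan_max = pan_max)
  out
}
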
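#' Synthetic canopy scene configuration
#'
#' Describes a seeded mosaic of tree crowns over a soil background, with
#' the statistical structure the classification pipeline assumes: each
#' species has a distinct multivariate-Gaussian 4-band reflectance
#' signature; within-crown reflectance carries a spatially correlated
#' texture field (Gaussian-smoothed white noise) plus independent pixel
#' noise; a stated fraction of crown pixels are intra-canopy gaps (convex
#' mixtures of crown and background spectra); and the scene exists at two
#' resolutions — a fine grid (pan) and a coarse multispectral grid obtained
#' by block averaging.
#'
#' Species mean spectra are laid out deterministically on a ring in the
#' green/NIR plane around a common vegetation spectrum, with a per-species
#' brightness scaling; `mean_separation` (ring radius, reflectance units)
#' is the single difficulty knob, and `brightness_range` controls how much
#' of the separation lives in overall brightness (information that
#' ratio-based vegetation indices discard).
#'
#' @param n_species number of species K (default 10, up to 40).
#' @param ms_rows,ms_cols coarse multispectral grid size.
#' @param resolution_ratio integer MS-to-pan factor (default 4, e.g. 2.4 m
#'   MS over 0.6 m pan).
#' @param crowns_per_species crowns placed per species.
#' @param crown_radius_range fine-grid crown radius range in pixels.
#' @param species_means optional K x 4 matrix of mean reflectance (blue,
#'   green, red, nir); default ring layout.
#' @param species_sd per-band within-crown Gaussian standard deviations.
#' @param mean_separation ring radius of the default species layout.
#' @param brightness_range per-species brightness scale range.
#' @param texture_amplitude standard deviation of the correlated texture
#'   field (reflectance units).
#' @param texture_length correlation length (Gaussian kernel sigma, fine
#'   pixels).
#' @param intra_gap_prob probability a crown pixel is an intra-canopy gap.
#' @param background_mean background (bright soil) reflectance, length 4.
#' @param background_sd background pixel noise sd.
#' @param pan_weights length-4 weights synthesising the pan band.
#' @param pan_noise_sd independent noise added to the pan band.
#' @param ms_noise_sd sensor noise added to the coarse MS bands.
#' @param pixel_size_pan fine-grid pixel size in metres.
#' @param seed integer seed making the scene fully deterministic.
#' @return list of class `scene_config`.
#' @export
scene_config <- function(n_species = 10L,
                         ms_rows = 48L, ms_cols = 48L,
                         resolution_ratio = 4L,
                         crowns_per_species = 5L,
                         crown_radius_range = c(6, 9),
                         species_means = NULL,
                         species_sd = c(0.008, 0.012, 0.010, 0.030),
                         mean_separation = 0.030,
                         brightness_range = c(0.75, 1.35),
                         texture_amplitude = 0.080,
                         texture_length = 1.5,
                         intra_gap_prob = 0.15,
                         background_mean = c(0.15, 0.20, 0.25, 0.28),
                         background_sd = 0.01,
                         pan_weights = c(0.15, 0.25, 0.30, 0.30),
                         pan_noise_sd = 0.005,
                         ms_noise_sd = 0.002,
                         pixel_size_pan = 0.6,
                         seed = 1L) {
  n_species <- as.integer(n_species)
  if (n_species < 2L || n_species > 40L) stop("n_species must be in 2..40")
  if (intra_gap_prob < 0 || intra_gap_prob > 1)
    stop("intra_gap_prob must be in [0, 1]")
  resolution_ratio <- as.integer(resolution_ratio)
  if (resolution_ratio < 1L) stop("resolution_ratio must be >= 1")
  if (is.null(species_means))
    species_means <- default_species_means(n_species, mean_separation,
                                           brightness_range)
  species_means <- as.matrix(species_means)
  if (!identical(dim(species_means), c(n_species, 4L)))
    stop("species_means must be n_species x 4")
  if (any(species_means < 0) || any(species_means > 1))
    stop("species mean reflectance must lie in [0, 1]")
  if (any(species_sd < 0)) stop("species_sd must be >= 0")
  cfg <- list(n_species = n_species, ms_rows = as.integer(ms_rows),
              ms_cols = as.integer(ms_cols),
              resolution_ratio = resolution_ratio,
              crowns_per_species = as.integer(crowns_per_species),
              crown_radius_range = crown_radius_range,
              species_means = species_means, species_sd = species_sd,
              texture_amplitude = texture_amplitude,
              texture_length = texture_length,
              intra_gap_prob = intra_gap_prob,
              background_mean = background_mean,
              background_sd = background_sd,
              pan_weights = pan_weights, pan_noise_sd = pan_noise_sd,
              ms_noise_sd = ms_noise_sd, pixel_size_pan = pixel_size_pan,
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  cfg
}

# deterministic ring layout of species mean spectra around a vegetation
# spectrum: separation in the green/NIR plane plus a brightness scale
default_species_means <- function(K, sep, brightness_range) {
  v0 <- c(blue = 0.05, green = 0.09, red = 0.06, nir = 0.45)
  theta <- 2 * pi * (seq_len(K) - 1) / K
  u1 <- c(0, 1, 0, 0); u2 <- c(0, 0, 0, 1)
  scales <- seq(brightness_range[1], brightness_range[2], length.out = K)
  # interleave the brightness ladder so ring neighbours differ in brightness
  scales <- scales[order(rep(c(1, 2), length.out = K), seq_len(K))]
  m <- t(vapply(seq_len(K), function(s)
    scales[s] * (v0 + sep * (cos(theta[s]) * u1 + sin(theta[s]) * u2)),
    numeric(4)))
  colnames(m) <- names(v0)
  pmin(pmax(m, 0.005), 0.995)
}

# Gaussian-kernel smoothing of white noise, unit-variance normalised
correlated_field <- function(rows, cols, sigma) {
  w <- rnorm(rows * cols)
  if (sigma <= 0) return(matrix(w, rows, cols))
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  m <- matrix(w, rows, cols)
  # separable convolution with edge renormalisation
  conv1 <- function(M) {
    out <- matrix(0, nrow(M), ncol(M))
    wsum <- matrix(0, nrow(M), ncol(M))
    for (o in -half:half) {
      src <- (1 + max(0, o)):(nrow(M) + min(0, o))
      dst <- src - o
      kk <- kern[o + half + 1]
      out[dst, ] <- out[dst, ] + kk * M[src, ]
      wsum[dst, ] <- wsum[dst, ] + kk
    }
    out / wsum
  }
  m <- conv1(m)
  m <- t(conv1(t(m)))
  m / stats::sd(as.vector(m))
}

#' Generate a seeded synthetic canopy scene
#'
#' Places non-overlapping crown discs for every species on the fine grid,
#' draws crown reflectance from the species Gaussian plus the correlated
#' texture field, converts the stated fraction of crown pixels into
#' intra-canopy gaps (convex crown/background mixtures), fills the
#' inter-canopy background with a noisy soil spectrum, and derives the two
#' sensor products: the coarse multispectral stack (block average of the
#' fine truth plus sensor noise) and the fine panchromatic band (weighted
#' band sum plus noise). Labels mark pure (non-gap) crown pixels on the
#' fine grid. Bit-identical for a given seed.
#'
#' @param cfg a [scene_config()].
#' @return list with elements `ms` (coarse 4-band `raster_stack`), `pan`
#'   (fine single-band `raster_stack`), `labels` (fine `label_raster`),
#'   `truth` (fine 4-band reflectance `raster_stack`, the noise-free sensor
#'   input), `species_table`, and `config`.
#' @export
generate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  set.seed(cfg$seed)
  f <- cfg$resolution_ratio
  R <- cfg$ms_rows * f; C <- cfg$ms_cols * f
  K <- cfg$n_species
  # --- crown placement (rejection sampling, no overlap between crowns) ---
  centers <- matrix(NA_real_, 0, 3)  # row, col, radius
  labels <- matrix(0L, R, C)
  species_of_crown <- integer(0)
  for (s in seq_len(K)) for (cr in seq_len(cfg$crowns_per_species)) {
    placed <- FALSE
    for (try in seq_len(400L)) {
      rad <- stats::runif(1, cfg$crown_radius_range[1], cfg$crown_radius_range[2])
      ro <- stats::runif(1, 1 + rad, R - rad)
      co <- stats::runif(1, 1 + rad, C - rad)
      if (nrow(centers) == 0 ||
          all(sqrt((centers[, 1] - ro)^2 + (centers[, 2] - co)^2) >
              centers[, 3] + rad + 1)) {
        centers <- rbind(centers, c(ro, co, rad))
        species_of_crown <- c(species_of_crown, s)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place all crowns; enlarge the scene or shrink crowns")
  }
  crown_id <- matrix(0L, R, C)
  for (ci in seq_len(nrow(centers))) {
    ro <- centers[ci, 1]; co <- centers[ci, 2]; rad <- centers[ci, 3]
    ri <- max(1L, floor(ro - rad)):min(R, ceiling(ro + rad))
    cj <- max(1L, floor(co - rad)):min(C, ceiling(co + rad))
    sub <- outer(ri - ro, cj - co, function(a, b) a^2 + b^2) <= rad^2
    crown_id[ri, cj][sub] <- ci
  }
  in_crown <- crown_id > 0L
  labels[in_crown] <- species_of_crown[crown_id[in_crown]]
  # --- fine-grid reflectance truth ---
  truth <- array(NA_real_, c(R, C, 4L))
  nbg <- sum(!in_crown)
  for (b in 1:4) {
    bg <- cfg$background_mean[b] + stats::rnorm(nbg, 0, cfg$background_sd)
    m <- matrix(0, R, C)
    m[!in_crown] <- bg
    truth[, , b] <- m
  }
  tex <- if (cfg$texture_amplitude > 0)
    lapply(1:4, function(b)
      cfg$texture_amplitude * correlated_field(R, C, cfg$texture_length))
  else lapply(1:4, function(b) matrix(0, R, C))
  idx <- which(in_crown)
  sp <- labels[idx]
  for (b in 1:4) {
    draw <- cfg$species_means[sp, b] + stats::rnorm(length(idx), 0, cfg$species_sd[b])
    truth[, , b][idx] <- draw + tex[[b]][idx]
  }
  # --- intra-canopy gaps: convex crown/background mixtures, unlabeled ---
  if (cfg$intra_gap_prob > 0 && length(idx)) {
    gap <- stats::runif(length(idx)) < cfg$intra_gap_prob
    if (any(gap)) {
      w <- stats::runif(sum(gap), 0.3, 0.9)
      gi <- idx[gap]
      for (b in 1:4) {
        bgv <- cfg$background_mean[b] + stats::rnorm(sum(gap), 0, cfg$background_sd)
        truth[, , b][gi] <- (1 - w) * truth[, , b][gi] + w * bgv
      }
      labels[gi] <- 0L
    }
  }
  truth <- pmin(pmax(truth, 0), 1)
  truth_stack <- raster_stack(truth, band_names = c("blue", "green", "red", "nir"),
                              pixel_size = cfg$pixel_size_pan)
  # --- sensor products ---
  pan_mat <- matrix(0, R, C)
  for (b in 1:4) pan_mat <- pan_mat + cfg$pan_weights[b] * truth[, , b]
  pan_mat <- pan_mat + stats::rnorm(R * C, 0, cfg$pan_noise_sd)
  pan <- raster_stack(array(pan_mat, c(R, C, 1L)), band_names = "pan",
                      pixel_size = cfg$pixel_size_pan)
  ms_data <- array(NA_real_, c(cfg$ms_rows, cfg$ms_cols, 4L))
  for (b in 1:4) {
    m <- truth[, , b]
    blk <- matrix(0, cfg$ms_rows, cfg$ms_cols)
    for (i in seq_len(f)) for (j in seq_len(f))
      blk <- blk + m[seq(i, R, by = f), seq(j, C, by = f)]
    ms_data[, , b] <- blk / f^2 +
      stats::rnorm(cfg$ms_rows * cfg$ms_cols, 0, cfg$ms_noise_sd)
  }
  ms <- raster_stack(ms_data, band_names = c("blue", "green", "red", "nir"),
                     pixel_size = cfg$pixel_size_pan * f)
  ref <- reference_species_table()
  st <- data.frame(code = seq_len(K),
                   abbrev = ref$abbrev[seq_len(K)],
                   name = ref$name[seq_len(K)],
                   stringsAsFactors = FALSE)
  list(ms = ms, pan = pan,
       labels = label_raster(labels, st, role = "training"),
       truth = truth_stack, species_table = st, config = cfg)
}

#' Species-stratified train/test sampling
#'
#' Draws, per species, a seeded random subset of the labeled pixels and
#' splits it into disjoint training and test label rasters with the
#' requested counts.
#'
#' @param labels a `label_raster`.
#' @param counts requested pixels per species: a single number or a vector
#'   named by species code.
#' @param split fraction of each species' requested pixels assigned to
#'   training (default 0.5).
#' @param seed RNG seed.
#' @return list with `train` and `test` `label_raster`s (disjoint pixel
#'   sets, counts honoured exactly).
#' @export
stratified_sample <- function(labels, counts, split = 0.5, seed = 1L) {
  stopifnot(inherits(labels, "label_raster"))
  set.seed(seed)
  lab <- labels$labels
  codes <- sort(unique(lab[lab > 0L]))
  if (length(counts) == 1L && is.null(names(counts)))
    counts <- stats::setNames(rep(counts, length(codes)), codes)
  train <- matrix(0L, nrow(lab), ncol(lab))
  test <- matrix(0L, nrow(lab), ncol(lab))
  for (cc in codes) {
    want <- counts[as.character(cc)]
    if (is.na(want)) next
    avail <- which(lab == cc)
    if (length(avail) < want)
      stop("species ", cc, " has only ", length(avail),
           " labeled pixels; ", want, " requested")
    pick <- avail[sample.int(length(avail), want)]
    ntr <- round(split * want)
    train[pick[seq_len(ntr)]] <- cc
    if (want > ntr) test[pick[(ntr + 1L):want]] <- cc
  }
  list(train = label_raster(train, labels$species_table, role = "training"),
       test = label_raster(test, labels$species_table, role = "test"))
}
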
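# Synthetic parcel-scene generator. Emulates the statistical structure the
# method assumes in real imagery: Voronoi-tessellated field parcels with a
# long-tailed class mix, class-dependent 4-band spectra with additive noise
# and a smooth scene-level illumination trend, narrow background gaps along
# parcel boundaries (roads/field margins), and rectangular masked regions.

# Pixel shares of (other, rice, maize, soybean) in the reference survey of
# 23,561,400 labeled pixels.
DEFAULT_CLASS_PROBS <-
  c(other = 15116388, rice = 4685724, maize = 2833795, soybean = 925493) /
  23561400

# Class x band mean reflectances (red, green, blue, NIR). Chosen so classes
# are separable but overlapping: pairwise separations of roughly 1-3 noise
# standard deviations at the default noise_sd.
DEFAULT_BAND_MEANS <- matrix(
  c(0.10, 0.12, 0.11, 0.25,   # other (towns, water, roads, bare soil)
    0.06, 0.10, 0.08, 0.42,   # rice
    0.09, 0.14, 0.07, 0.48,   # maize
    0.07, 0.12, 0.06, 0.35),  # soybean
  nrow = 4, byrow = TRUE,
  dimnames = list(c("other", "rice", "maize", "soybean"),
                  c("red", "green", "blue", "nir")))

#' Synthetic scene configuration
#'
#' Defaults describe a 512 x 512 four-band scene with 150 Voronoi parcels,
#' the reference class imbalance, ~2-noise-SD spectral separation between
#' class means, 2-pixel background gaps along parcel boundaries and two
#' random rectangular masks.
#'
#' @param height,width Scene size in pixels.
#' @param n_parcels Number of Voronoi seed points.
#' @param class_probs Length-4 class probabilities (must sum to 1).
#' @param band_means 4 x 4 matrix of class-by-band mean reflectances.
#' @param noise_sd SD of the i.i.d. Gaussian pixel noise (reflectance
#'   units).
#' @param illum_amplitude Amplitude of the smooth multiplicative
#'   illumination field (a low-order 2-d polynomial scaled to `1 +/-`
#'   amplitude).
#' @param gap_width Width in pixels of the background strip along parcel
#'   boundaries (0 disables gaps).
#' @param mask_rects Number of random rectangular masks to apply.
#' @param seed Integer seed; the whole generator is deterministic given it.
#' @return A `cropseg_synth_config`.
#' @export
synth_config <- function(height = 512L, width = 512L, n_parcels = 150L,
                         class_probs = DEFAULT_CLASS_PROBS,
                         band_means = DEFAULT_BAND_MEANS,
                         noise_sd = 0.04, illum_amplitude = 0.05,
                         gap_width = 2L, mask_rects = 2L, seed = 1L) {
  if (abs(sum(class_probs) - 1) > 1e-9) stop("class_probs must sum to 1")
  if (length(class_probs) != nrow(band_means)) {
    stop("class_probs and band_means disagree on the number of classes")
  }
  if (noise_sd < 0 || illum_amplitude < 0 || gap_width < 0 || mask_rects < 0) {
    stop("noise_sd, illum_amplitude, gap_width, mask_rects must be >= 0")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_parcels = as.integer(n_parcels),
                 class_probs = unname(class_probs),
                 band_means = band_means, noise_sd = noise_sd,
                 illum_amplitude = illum_amplitude,
                 gap_width = as.integer(gap_width),
                 mask_rects = as.integer(mask_rects),
                 seed = as.integer(seed)),
            class = "cropseg_synth_config")
}

#' Generate a Voronoi parcel label map
#'
#' Seeds `n_parcels` points uniformly, labels every pixel by its nearest
#' seed (the Voronoi tessellation), assigns each parcel a class drawn from
#' `class_probs`, and sets pixels within `gap_width` of a parcel boundary to
#' the background class 0, emulating roads and field margins.
#'
#' @param cfg A [synth_config()].
#' @return `[H, W]` integer label matrix (classes `0..C-1`).
#' @export
generate_parcels <- function(cfg) {
  H <- cfg$height; W <- cfg$width
  if (cfg$n_parcels < 1L) stop("n_parcels must be >= 1")
  if (cfg$n_parcels > H * W) stop("more parcels than pixels")
  with_seed(cfg$seed, {
    seeds <- cbind(runif(cfg$n_parcels, 0, H), runif(cfg$n_parcels, 0, W))
    grid <- cbind(rep(seq_len(H) - 0.5, times = W),
                  rep(seq_len(W) - 0.5, each = H))
    pid <- as.integer(class::knn1(seeds, grid, seq_len(cfg$n_parcels)))
    pid <- matrix(pid, H, W)
    cls <- sample.int(length(cfg$class_probs), cfg$n_parcels,
                      replace = TRUE, prob = cfg$class_probs) - 1L
    labels <- matrix(cls[pid], H, W)
    if (cfg$gap_width > 0L) {
      # boundary = pixel with a 4-neighbour in a different parcel
      b <- matrix(FALSE, H, W)
      b[-H, ] <- b[-H, ] | pid[-H, ] != pid[-1, ]
      b[-1, ] <- b[-1, ] | pid[-1, ] != pid[-H, ]
      b[, -W] <- b[, -W] | pid[, -W] != pid[, -1]
      b[, -1] <- b[, -1] | pid[, -1] != pid[, -W]
      for (it in seq_len(cfg$gap_width - 1L)) {
        g <- b
        g[-H, ] <- g[-H, ] | b[-1, ]
        g[-1, ] <- g[-1, ] | b[-H, ]
        g[, -W] <- g[, -W] | b[, -1]
        g[, -1] <- g[, -1] | b[, -W]
        b <- g
      }
      labels[b] <- 0L
    }
    labels
  })
}

#' Render 4-band reflectances for a label map
#'
#' Pixel value = class band mean, modulated by a smooth multiplicative
#' illumination surface (a random quadratic polynomial scaled to
#' `1 +/- illum_amplitude`), plus i.i.d. Gaussian noise of SD `noise_sd`.
#' Reflectances are clamped to `[0, 1]`.
#'
#' @param labels `[H, W]` integer class map (values `< nrow(band_means)`).
#' @param cfg A [synth_config()].
#' @return `[H, W, 4]` reflectance array.
#' @export
render_bands <- function(labels, cfg) {
  H <- nrow(labels); W <- ncol(labels)
  nb <- ncol(cfg$band_means)
  if (any(labels >= nrow(cfg$band_means))) stop("label outside class range")
  with_seed(cfg$seed + 1L, {
    illum <- matrix(1, H, W)
    if (cfg$illum_amplitude > 0) {
      u <- matrix(rep(seq_len(H) / H, W) - 0.5, H, W)
      v <- matrix(rep(seq_len(W) / W, each = H) - 0.5, H, W)
      co <- rnorm(5)
      p <- co[1] * u + co[2] * v + co[3] * u * v + co[4] * u^2 + co[5] * v^2
      if (max(abs(p)) > 0) p <- p / max(abs(p))
      illum <- 1 + cfg$illum_amplitude * p
    }
    img <- array(0, c(H, W, nb))
    for (b in seq_len(nb)) {
      base <- matrix(cfg$band_means[labels + 1L, b], H, W)
      img[, , b] <- base * illum + rnorm(H * W, sd = cfg$noise_sd)
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    img
  })
}

# Random mask rectangles covering roughly 5-20% of each dimension.
random_mask_rects <- function(cfg) {
  if (cfg$mask_rects < 1L) {
    return(matrix(integer(0), 0, 4,
                  dimnames = list(NULL, c("row0", "col0", "row1", "col1"))))
  }
  H <- cfg$height; W <- cfg$width
  with_seed(cfg$seed + 2L, {
    hs <- pmax(1L, as.integer(runif(cfg$mask_rects, 0.05, 0.2) * H))
    ws <- pmax(1L, as.integer(runif(cfg$mask_rects, 0.05, 0.2) * W))
    r0 <- as.integer(runif(cfg$mask_rects, 0, H - hs))
    c0 <- as.integer(runif(cfg$mask_rects, 0, W - ws))
    cbind(row0 = r0, col0 = c0, row1 = r0 + hs, col1 = c0 + ws)
  })
}

#' Generate a complete synthetic scene
#'
#' Composes [generate_parcels()], [render_bands()] and [apply_mask()] with
#' `mask_rects` random rectangles. Deterministic given `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @return A `cropseg_scene`; the applied rectangles are attached as
#'   attribute `"mask_rects"`.
#' @export
generate_scene <- function(cfg = synth_config()) {
  labels <- generate_parcels(cfg)
  image <- render_bands(labels, cfg)
  scn <- scene(image, labels)
  rects <- random_mask_rects(cfg)
  scn <- apply_mask(scn, rects)
  attr(scn, "mask_rects") <- rects
  scn
}
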
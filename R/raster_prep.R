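# Scene -> patch preparation: rectangular masking, sliding-window tiling,
# masked-fraction filtering, and seeded ratio splits.
#
# Conventions: pixel coordinates are 0-based and rectangles half-open
# [row0, row1) x [col0, col1); label maps are integers 0..C-1 with 255 as
# the ignore value; image tensors are channels-last [H, W, bands].

IGNORE_VALUE <- 255L

#' Construct a scene
#'
#' A scene bundles a co-registered multiband image, an integer label map and
#' a validity map for one geographic extent. Invalid pixels (unlabeled or
#' masked) carry the ignore value in `labels` and are excluded from every
#' loss and metric downstream.
#'
#' @param image `[H, W, bands]` numeric array (reflectance, any scale).
#' @param labels `[H, W]` integer matrix, classes `0..C-1` or 255.
#' @param valid Optional `[H, W]` logical matrix; defaults to
#'   `labels != 255`.
#' @return A `cropseg_scene`.
#' @export
scene <- function(image, labels, valid = NULL) {
  if (length(dim(image)) != 3L) stop("image must be [H, W, bands]")
  if (!all(dim(labels) == dim(image)[1:2])) {
    stop("labels and image must share spatial dimensions")
  }
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (is.null(valid)) valid <- labels != IGNORE_VALUE
  if (!all(dim(valid) == dim(labels))) {
    stop("valid and labels must share spatial dimensions")
  }
  labels[!valid] <- IGNORE_VALUE
  structure(list(image = image, labels = labels, valid = valid),
            class = "cropseg_scene")
}

#' @export
print.cropseg_scene <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<cropseg_scene> %d x %d pixels, %d bands, %.1f%% valid\n",
              d[1], d[2], d[3], 100 * mean(x$valid)))
  invisible(x)
}

#' Mask rectangular regions of a scene
#'
#' Marks every pixel inside the given rectangles as invalid and sets its
#' label to the ignore value; all other pixels are unchanged. Rectangles are
#' 0-based half-open `(row0, col0, row1, col1)`.
#'
#' @param scn A `cropseg_scene`.
#' @param rectangles Matrix or data frame with columns
#'   `row0, col0, row1, col1` (one rectangle per row); may have zero rows.
#' @return The masked `cropseg_scene`.
#' @export
apply_mask <- function(scn, rectangles) {
  stopifnot(inherits(scn, "cropseg_scene"))
  r <- as.matrix(rectangles)
  if (length(r) == 0L || nrow(r) == 0L) return(scn)
  if (ncol(r) != 4L) stop("rectangles must have 4 columns (row0,col0,row1,col1)")
  H <- nrow(scn$labels); W <- ncol(scn$labels)
  for (i in seq_len(nrow(r))) {
    r0 <- r[i, 1]; c0 <- r[i, 2]; r1 <- r[i, 3]; c1 <- r[i, 4]
    if (r0 < 0 || c0 < 0 || r1 > H || c1 > W || r0 >= r1 || c0 >= c1) {
      stop(sprintf(
        "rectangle %d (%d,%d,%d,%d) outside scene bounds %dx%d or degenerate",
        i, r0, c0, r1, c1, H, W))
    }
    scn$valid[(r0 + 1):r1, (c0 + 1):c1] <- FALSE
  }
  scn$labels[!scn$valid] <- IGNORE_VALUE
  scn
}

#' Tile-grid offsets for a sliding window
#'
#' 0-based offsets of every fully contained `size x size` window placed at
#' multiples of `stride`; partial edge tiles are dropped, not padded.
#'
#' @param H,W Scene extent in pixels.
#' @param size Window size.
#' @param stride Window stride.
#' @return Data frame with columns `row`, `col`, in row-major order.
#' @export
tile_grid <- function(H, W, size = 256L, stride = 256L) {
  if (size > min(H, W)) {
    stop(sprintf("tile size %d exceeds scene extent %dx%d", size, H, W))
  }
  if (stride < 1L) stop("stride must be >= 1")
  rows <- seq(0L, H - size, by = stride)
  cols <- seq(0L, W - size, by = stride)
  data.frame(row = rep(rows, each = length(cols)),
             col = rep(cols, times = length(rows)))
}

#' Cut a scene into square patches
#'
#' Slides a `size x size` window with the given stride over the scene and
#' extracts every fully contained tile in row-major offset order. Masked
#' pixels carry the ignore value in the patch labels; each patch records its
#' 0-based origin and masked fraction.
#'
#' @param scn A `cropseg_scene`.
#' @param size Patch size in pixels (default 256).
#' @param stride Window stride in pixels (default 256, i.e. non-overlapping
#'   so the later splits cannot share pixels).
#' @return List of patches, each a list with `image` `[S, S, bands]`,
#'   `labels` `[S, S]`, `origin` `(row, col)` and `masked_fraction`.
#' @export
tile <- function(scn, size = 256L, stride = 256L) {
  stopifnot(inherits(scn, "cropseg_scene"))
  H <- nrow(scn$labels); W <- ncol(scn$labels)
  grid <- tile_grid(H, W, size, stride)
  lapply(seq_len(nrow(grid)), function(i) {
    r <- grid$row[i]; c <- grid$col[i]
    lab <- scn$labels[(r + 1):(r + size), (c + 1):(c + size)]
    list(image = scn$image[(r + 1):(r + size), (c + 1):(c + size), ,
                           drop = FALSE],
         labels = lab,
         origin = c(row = r, col = c),
         masked_fraction = mean(lab == IGNORE_VALUE))
  })
}

#' Discard patches dominated by masked pixels
#'
#' Retains exactly the patches whose masked fraction is `<= threshold`
#' (a patch at exactly the threshold is kept: only strictly higher fractions
#' are discarded). Order is preserved.
#'
#' @param patches List of patches from [tile()].
#' @param threshold Maximum tolerated masked fraction (default 0.15).
#' @return The retained sublist.
#' @export
filter_masked <- function(patches, threshold = 0.15) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  keep <- vapply(patches, `[[`, 0, "masked_fraction") <= threshold
  patches[keep]
}

#' Seeded train/validation/test split
#'
#' Randomly assigns `n` patches to train/validation/test. With the default
#' 8:1:1 ratios, `n_val = n_test = floor(n / 10)` and the remainder goes to
#' training — the convention that maps 177 retained patches to 143/17/17.
#' The assignment is a seeded uniform shuffle; the three index sets are
#' disjoint and exhaustive.
#'
#' @param n Number of patches (or a list of patches).
#' @param ratios Positive split ratios (train, val, test).
#' @param seed Integer seed for the shuffle.
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
split_patches <- function(n, ratios = c(8, 1, 1), seed = 1L) {
  if (is.list(n)) n <- length(n)
  n <- as.integer(n)
  if (n < 3L) stop("need at least 3 patches to split")
  if (length(ratios) != 3L || any(ratios < 0) || ratios[1] <= 0) {
    stop("ratios must be 3 non-negative values with a positive train share")
  }
  tot <- sum(ratios)
  n_val <- floor(n * ratios[2] / tot)
  n_test <- floor(n * ratios[3] / tot)
  n_train <- n - n_val - n_test
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       val = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}

#' Per-band normalisation statistics from the training split
#'
#' Optional z-score normalisation: means and standard deviations are
#' computed on the training patches only and can then be applied to every
#' split, so no information leaks from validation or test pixels.
#'
#' @param patches List of patches.
#' @param train_idx Indices of the training split.
#' @return List with numeric vectors `mean` and `sd` (one entry per band).
#' @export
band_stats <- function(patches, train_idx) {
  stopifnot(length(train_idx) >= 1L)
  nb <- dim(patches[[1]]$image)[3]
  acc_s <- acc_s2 <- numeric(nb)
  acc_n <- 0
  for (i in train_idx) {
    img <- patches[[i]]$image
    acc_s <- acc_s + apply(img, 3, sum)
    acc_s2 <- acc_s2 + apply(img, 3, function(b) sum(b * b))
    acc_n <- acc_n + prod(dim(img)[1:2])
  }
  m <- acc_s / acc_n
  v <- acc_s2 / acc_n - m^2
  list(mean = m, sd = sqrt(pmax(v, 0)))
}

#' Apply per-band z-score normalisation to patches
#'
#' @param patches List of patches.
#' @param stats Result of [band_stats()].
#' @return The normalised patch list.
#' @export
normalize_patches <- function(patches, stats) {
  sdv <- ifelse(stats$sd > 0, stats$sd, 1)
  lapply(patches, function(p) {
    for (b in seq_along(stats$mean)) {
      p$image[, , b] <- (p$image[, , b] - stats$mean[b]) / sdv[b]
    }
    p
  })
}
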
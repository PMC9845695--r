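# Inference over patch sets and stitching back to scene extent.

stack_images <- function(patches, idx) {
  d <- dim(patches[[idx[1]]]$image)
  x <- array(0, c(d[1], d[2], d[3], length(idx)))
  for (j in seq_along(idx)) x[, , , j] <- patches[[idx[j]]]$image
  x
}

stack_labels <- function(patches, idx) {
  d <- dim(patches[[idx[1]]]$labels)
  y <- array(IGNORE_VALUE, c(d[1], d[2], length(idx)))
  for (j in seq_along(idx)) y[, , j] <- patches[[idx[j]]]$labels
  y
}

#' Predict label maps for a set of patches
#'
#' Runs the model in inference mode (batch-norm running statistics, point
#' refinement applied to all pixels) over mini-batches.
#'
#' @param model A `cropseg_model`.
#' @param patches List of patches.
#' @param idx Indices to predict (default all).
#' @param batch_size Mini-batch size.
#' @return List of `[S, S]` integer label maps (classes 0-based), one per
#'   index.
#' @export
predict_patches <- function(model, patches, idx = seq_along(patches),
                            batch_size = 16L) {
  out <- vector("list", length(idx))
  for (start in seq(1L, length(idx), by = batch_size)) {
    bi <- idx[start:min(start + batch_size - 1L, length(idx))]
    x <- stack_images(patches, bi)
    fw <- forward(model, x, training = FALSE, with_cache = FALSE)
    for (j in seq_along(bi)) {
      out[[start + j - 1L]] <- fw$label_map[, , j]
    }
  }
  out
}

#' Stitch patch predictions into a scene-sized label map
#'
#' Places each patch's prediction at its recorded origin; pixels covered by
#' no patch receive the ignore value.
#'
#' @param maps List of `[S, S]` label maps.
#' @param origins List (or matrix rows) of 0-based `(row, col)` origins.
#' @param H,W Output extent.
#' @param ignore Fill value for uncovered pixels.
#' @return `[H, W]` integer label map.
#' @export
stitch_predictions <- function(maps, origins, H, W, ignore = IGNORE_VALUE) {
  out <- matrix(as.integer(ignore), H, W)
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    o <- origins[[i]]
    out[o[[1]] + seq_len(nrow(m)), o[[2]] + seq_len(ncol(m))] <- m
  }
  out
}
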
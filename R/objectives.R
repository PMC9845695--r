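# Loss functions of the two branches. All losses operate on softmax
# probabilities and integer label maps; pixels carrying the ignore value are
# excluded from every sum. Each function can return its analytic gradient
# with respect to the probabilities (used by the training engine and by the
# finite-difference tests).

#' Loss configuration
#'
#' The master branch optimises `alpha * CE + beta * Dice`; the point branch
#' adds `cp_weight` times its own cross-entropy. The default weights
#' (`alpha = 0`, `beta = 1`) use the Dice loss alone, the best-performing
#' ratio in the loss sweep; weights are plain multipliers, so integer ratios
#' such as 1:10 are expressed directly.
#'
#' @param alpha Cross-entropy weight (>= 0).
#' @param beta Dice weight (>= 0). `alpha + beta` must be positive.
#' @param cp_weight Weight of the point-branch cross-entropy.
#' @param ignore Integer label treated as unlabeled/masked.
#' @param dice_smooth Smoothing constant added to the Dice numerator and
#'   denominator.
#' @return A `cropseg_loss_config` list.
#' @export
loss_config <- function(alpha = 0, beta = 1, cp_weight = 1, ignore = 255L,
                        dice_smooth = 1e-6) {
  if (alpha < 0 || beta < 0 || cp_weight < 0) stop("weights must be >= 0")
  if (alpha + beta <= 0) stop("alpha + beta must be positive")
  structure(list(alpha = alpha, beta = beta, cp_weight = cp_weight,
                 ignore = as.integer(ignore), dice_smooth = dice_smooth),
            class = "cropseg_loss_config")
}

#' The nine CE:Dice weight ratios of the loss sweep
#'
#' @return Named list of [loss_config()] objects (`ce`, `dice`, `ce1_dice1`,
#'   ..., `ce10_dice1`).
#' @export
loss_sweep_presets <- function() {
  ratios <- list(ce = c(1, 0), dice = c(0, 1),
                 ce1_dice1 = c(1, 1), ce1_dice2 = c(1, 2),
                 ce1_dice5 = c(1, 5), ce1_dice10 = c(1, 10),
                 ce2_dice1 = c(2, 1), ce5_dice1 = c(5, 1),
                 ce10_dice1 = c(10, 1))
  lapply(ratios, function(r) loss_config(alpha = r[1], beta = r[2]))
}

# Flat indices of the true-class probability entries for valid pixels.
label_flat_index <- function(d, labels, ignore) {
  HW <- d[1] * d[2]; C <- d[3]
  lab <- as.vector(labels)
  pos <- which(lab != ignore)
  if (length(pos) == 0L) stop("all pixels are ignored; loss undefined")
  hw <- (pos - 1L) %% HW
  n <- (pos - 1L) %/% HW
  list(pos = pos, flat = hw + HW * (lab[pos] + C * n) + 1L)
}

#' Masked cross-entropy loss
#'
#' Mean over non-ignored pixels of the negative log probability assigned to
#' the true class.
#'
#' @param scores Softmax probability tensor `[H, W, C]` or `[H, W, C, N]`.
#' @param labels Integer map `[H, W]` / `[H, W, N]` with classes
#'   `0..C-1` or `ignore`.
#' @param ignore Ignore value.
#' @param grad Also return the gradient w.r.t. `scores`.
#' @return The loss, or `list(value, grad)` when `grad = TRUE`.
#' @export
cross_entropy_loss <- function(scores, labels, ignore = 255L, grad = FALSE) {
  x <- as_batch(scores)
  d <- dim(x)
  li <- label_flat_index(d, labels, ignore)
  p <- pmax(x[li$flat], 1e-12)
  value <- -mean(log(p))
  if (!grad) return(value)
  g <- array(0, d)
  g[li$flat] <- -1 / (p * length(li$flat))
  dim(g) <- dim(scores)
  list(value = value, grad = g)
}

#' Masked multi-class soft Dice loss
#'
#' `1 - (1/C) * sum_c (2 * sum_j x_cj y_cj + eps) / (sum_j x_cj + sum_j y_cj
#' + eps)` with sums over non-ignored pixels only; `y` is the one-hot truth.
#' Values lie in `[0, 1)`: 0 for an exact one-hot match (up to `eps`), near
#' 1 for disjoint supports. The per-class-then-macro-average form targets
#' class imbalance: every class contributes equally regardless of its pixel
#' share.
#'
#' @inheritParams cross_entropy_loss
#' @param smooth Smoothing constant.
#' @return The loss, or `list(value, grad)` when `grad = TRUE`.
#' @export
dice_loss <- function(scores, labels, ignore = 255L, smooth = 1e-6,
                      grad = FALSE) {
  x <- as_batch(scores)
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  lab <- as.vector(labels)
  valid <- lab != ignore
  if (!any(valid)) stop("all pixels are ignored; loss undefined")
  vpos <- which(valid)
  hw <- (vpos - 1L) %% HW
  n <- (vpos - 1L) %/% HW
  num <- den <- dnum <- numeric(C)
  xv <- matrix(0, length(vpos), C)
  yv <- matrix(FALSE, length(vpos), C)
  for (c in seq_len(C)) {
    xv[, c] <- x[hw + HW * ((c - 1L) + C * n) + 1L]
    yv[, c] <- lab[vpos] == (c - 1L)
  }
  inter <- colSums(xv * yv)
  sx <- colSums(xv)
  sy <- colSums(yv)
  dice_c <- (2 * inter + smooth) / (sx + sy + smooth)
  value <- 1 - mean(dice_c)
  if (!grad) return(value)
  g <- array(0, d)
  for (c in seq_len(C)) {
    den_c <- sx[c] + sy[c] + smooth
    gc <- -(2 * yv[, c] * den_c - (2 * inter[c] + smooth)) / (C * den_c^2)
    g[hw + HW * ((c - 1L) + C * n) + 1L] <- gc
  }
  dim(g) <- dim(scores)
  list(value = value, grad = g)
}

#' Compound master-branch loss
#'
#' `alpha * CE + beta * Dice` with masked pixels ignored throughout.
#'
#' @inheritParams cross_entropy_loss
#' @param cfg A [loss_config()].
#' @return The loss, or `list(value, grad, ce, dice)` when `grad = TRUE`.
#' @export
master_loss <- function(scores, labels, cfg = loss_config(), grad = FALSE) {
  ce <- di <- 0
  gce <- gdi <- NULL
  if (cfg$alpha > 0) {
    r <- cross_entropy_loss(scores, labels, cfg$ignore, grad = grad)
    if (grad) { ce <- r$value; gce <- r$grad } else ce <- r
  }
  if (cfg$beta > 0) {
    r <- dice_loss(scores, labels, cfg$ignore, cfg$dice_smooth, grad = grad)
    if (grad) { di <- r$value; gdi <- r$grad } else di <- r
  }
  value <- cfg$alpha * ce + cfg$beta * di
  if (!grad) return(value)
  g <- array(0, dim(scores))
  if (!is.null(gce)) g <- g + cfg$alpha * gce
  if (!is.null(gdi)) g <- g + cfg$beta * gdi
  list(value = value, grad = g, ce = ce, dice = di)
}

#' Point-branch cross-entropy
#'
#' Mean cross-entropy of the refinement logits over counted points; points
#' whose label is the ignore value are dropped. When every selected point is
#' ignored the loss contributes 0 (with a warning) rather than failing, so
#' a fully masked selection cannot abort a training step.
#'
#' @param cp_logits `k x C` matrix of point logits (pre-softmax).
#' @param point_labels Integer vector of length `k` (classes `0..C-1` or
#'   `ignore`).
#' @param ignore Ignore value.
#' @param grad Also return the gradient w.r.t. `cp_logits`.
#' @return The loss, or `list(value, grad)` when `grad = TRUE`.
#' @export
cp_loss <- function(cp_logits, point_labels, ignore = 255L, grad = FALSE) {
  keep <- point_labels != ignore
  if (!any(keep)) {
    warning("all selected points are ignored; point loss contributes 0")
    if (!grad) return(0)
    return(list(value = 0, grad = matrix(0, nrow(cp_logits), ncol(cp_logits))))
  }
  z <- cp_logits[keep, , drop = FALSE]
  lab <- point_labels[keep]
  z <- z - apply(z, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  pt <- pmax(p[cbind(seq_len(nrow(p)), lab + 1L)], 1e-12)
  value <- -mean(log(pt))
  if (!grad) return(value)
  g <- matrix(0, nrow(cp_logits), ncol(cp_logits))
  gk <- p
  gk[cbind(seq_len(nrow(p)), lab + 1L)] <-
    gk[cbind(seq_len(nrow(p)), lab + 1L)] - 1
  g[keep, ] <- gk / nrow(p)
  list(value = value, grad = g)
}
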
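# The two-branch segmentation network: five-level convolutional encoder with
# multi-stage channel attention, bilinear-upsampling decoder, and a
# point-refinement branch that re-classifies the hardest pixels.

#' Network configuration
#'
#' Assembles the architecture hyperparameters. The encoder widths are
#' `base_width * c(1, 2, 4, 8, 16)` (64..1024 at the default width); each
#' encoder level below the first halves the spatial resolution and doubles
#' the channels. Channel attention is applied to encoder levels 1-4 before
#' they are used as skip connections. The point-refinement branch
#' (`cp_enabled`) selects the `cp_k` pixels with the smallest top-1 minus
#' top-2 softmax margin, samples their feature vectors from the level
#' `cp_source_level` encoder map (after attention when `cp_after_eca`), and
#' re-classifies them with a small shared MLP whose decision overrides the
#' master branch at those pixels.
#'
#' @param in_bands Number of input bands (4: red, green, blue, NIR).
#' @param n_classes Number of label classes.
#' @param base_width First-level channel count; 64 reproduces the full-size
#'   architecture, smaller values give proportionally lighter models.
#' @param activation `"prelu"` (learnable negative slope, initialised at
#'   `prelu_init`) or `"relu"`.
#' @param prelu_init Initial PReLU negative-branch slope.
#' @param eca Apply efficient channel attention at encoder levels 1-4.
#' @param eca_kernel Odd size of the 1-d channel convolution.
#' @param cp_enabled Enable the point-refinement branch.
#' @param cp_k Number of refined points per image. `NULL` selects 8096 for
#'   256x256 inputs and `round(0.1235 * H * W)` (the same ~12.35% pixel
#'   fraction) otherwise.
#' @param cp_source_level Encoder level whose feature map supplies point
#'   features (1-5; default 2).
#' @param cp_after_eca Sample point features after (`TRUE`) or before
#'   (`FALSE`) channel attention.
#' @param cp_hidden Hidden-layer widths of the point MLP.
#' @return A `cropseg_net_config` list.
#' @export
net_config <- function(in_bands = 4L, n_classes = 4L, base_width = 64L,
                       activation = c("prelu", "relu"), prelu_init = 0.25,
                       eca = TRUE, eca_kernel = 3L,
                       cp_enabled = TRUE, cp_k = NULL, cp_source_level = 2L,
                       cp_after_eca = TRUE, cp_hidden = c(256L, 256L)) {
  activation <- match.arg(activation)
  if (eca_kernel %% 2L == 0L) stop("eca_kernel must be odd")
  if (!is.null(cp_k) && cp_k < 1L) stop("cp_k must be >= 1")
  if (!cp_source_level %in% 1:5) stop("cp_source_level must be in 1..5")
  cfg <- list(
    in_bands = as.integer(in_bands), n_classes = as.integer(n_classes),
    base_width = as.integer(base_width),
    encoder_channels = as.integer(base_width) * c(1L, 2L, 4L, 8L, 16L),
    activation = activation, prelu_init = prelu_init,
    eca = isTRUE(eca), eca_kernel = as.integer(eca_kernel),
    cp_enabled = isTRUE(cp_enabled),
    cp_k = if (is.null(cp_k)) NULL else as.integer(cp_k),
    cp_source_level = as.integer(cp_source_level),
    cp_after_eca = isTRUE(cp_after_eca),
    cp_hidden = as.integer(cp_hidden))
  class(cfg) <- "cropseg_net_config"
  cfg
}

cp_k_for <- function(cfg, H, W) {
  if (!is.null(cfg$cp_k)) return(cfg$cp_k)
  if (H == 256L && W == 256L) 8096L else as.integer(round(0.1235 * H * W))
}

# ---- parameter initialisation ------------------------------------------

kaiming <- function(fan_in, n) rnorm(n, sd = sqrt(2 / fan_in))

dc_param_set <- function(cin, cout, cfg) {
  p <- list(
    conv1_w = matrix(kaiming(cin * 9, cin * 9 * cout), cin * 9, cout),
    conv1_b = numeric(cout),
    bn1_g = rep(1, cout), bn1_b = numeric(cout),
    bn1_rm = numeric(cout), bn1_rv = rep(1, cout),
    conv2_w = matrix(kaiming(cout * 9, cout * 9 * cout), cout * 9, cout),
    conv2_b = numeric(cout),
    bn2_g = rep(1, cout), bn2_b = numeric(cout),
    bn2_rm = numeric(cout), bn2_rv = rep(1, cout))
  if (cfg$activation == "prelu") {
    p$act1_s <- rep(cfg$prelu_init, cout)
    p$act2_s <- rep(cfg$prelu_init, cout)
  }
  p
}

init_params <- function(cfg, seed = 1L) {
  with_seed(seed, {
    params <- list()
    ch <- cfg$encoder_channels
    cin <- cfg$in_bands
    for (i in 1:5) {
      dc <- dc_param_set(cin, ch[i], cfg)
      names(dc) <- paste0(sprintf("enc%d_", i), names(dc))
      params <- c(params, dc)
      cin <- ch[i]
    }
    if (cfg$eca) {
      for (i in 1:4) {
        params[[sprintf("eca%d_w", i)]] <-
          rnorm(cfg$eca_kernel, sd = sqrt(1 / cfg$eca_kernel))
      }
    }
    for (s in 1:4) {
      skip <- ch[5 - s]
      up <- if (s == 1) ch[5] else ch[5 - s + 1]
      dc <- dc_param_set(up + skip, ch[5 - s], cfg)
      names(dc) <- paste0(sprintf("dec%d_", s), names(dc))
      params <- c(params, dc)
    }
    params$final_w <- matrix(kaiming(ch[1], ch[1] * cfg$n_classes),
                             ch[1], cfg$n_classes)
    params$final_b <- numeric(cfg$n_classes)
    if (cfg$cp_enabled) {
      din <- ch[cfg$cp_source_level] + cfg$n_classes
      for (j in seq_along(cfg$cp_hidden)) {
        dout <- cfg$cp_hidden[j]
        params[[sprintf("cp%d_w", j)]] <- matrix(kaiming(din, din * dout),
                                                 din, dout)
        params[[sprintf("cp%d_b", j)]] <- numeric(dout)
        if (cfg$activation == "prelu") {
          params[[sprintf("cp%d_s", j)]] <- rep(cfg$prelu_init, dout)
        }
        din <- dout
      }
      params$cp_out_w <- matrix(kaiming(din, din * cfg$n_classes),
                                din, cfg$n_classes)
      params$cp_out_b <- numeric(cfg$n_classes)
    }
    params
  })
}

is_trainable <- function(name) !grepl("_(rm|rv)$", name)

#' Create a segmentation model
#'
#' Initialises all network weights (Kaiming fan-in normals for convolutions,
#' unit/zero batch-norm affine terms, PReLU slopes at their configured
#' initial value) under the given seed. No pretraining is used.
#'
#' @param cfg A [net_config()].
#' @param seed Integer seed for weight initialisation.
#' @return A `cropseg_model` with elements `params` and `cfg`.
#' @export
crop_model <- function(cfg = net_config(), seed = 1L) {
  structure(list(params = init_params(cfg, seed), cfg = cfg, seed = seed),
            class = "cropseg_model")
}

#' @export
print.cropseg_model <- function(x, ...) {
  np <- sum(vapply(x$params[is_trainable(names(x$params))], length, 0L))
  cat("<cropseg_model> base width", x$cfg$base_width,
      "| activation", x$cfg$activation,
      "| ECA", if (x$cfg$eca) "on" else "off",
      "| point refinement", if (x$cfg$cp_enabled) "on" else "off", "\n")
  cat("  trainable parameters:", format(np, big.mark = ","), "\n")
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model A `cropseg_model`.
#' @return Named integer vector of per-tensor parameter counts.
#' @export
parameter_census <- function(model) {
  p <- model$params
  keep <- is_trainable(names(p))
  vapply(p[keep], length, 0L)
}

# ---- double convolution block ------------------------------------------

dc_slopes <- function(params, pfx, which, cfg, cout) {
  if (cfg$activation == "prelu") params[[paste0(pfx, "act", which, "_s")]]
  else numeric(cout)
}

dc_fw <- function(x, params, pfx, cfg, training) {
  g <- function(n) params[[paste0(pfx, n)]]
  z1 <- conv_fw(x, g("conv1_w"), g("conv1_b"), 3L)
  cout <- ncol(g("conv1_w"))
  b1 <- bn_fw(z1, g("bn1_g"), g("bn1_b"), g("bn1_rm"), g("bn1_rv"), training)
  a1 <- act_fw(b1$y, dc_slopes(params, pfx, 1, cfg, cout))
  z2 <- conv_fw(a1$y, g("conv2_w"), g("conv2_b"), 3L)
  b2 <- bn_fw(z2, g("bn2_g"), g("bn2_b"), g("bn2_rm"), g("bn2_rv"), training)
  a2 <- act_fw(b2$y, dc_slopes(params, pfx, 2, cfg, cout))
  st <- list(b1$rm, b1$rv, b2$rm, b2$rv)
  names(st) <- paste0(pfx, c("bn1_rm", "bn1_rv", "bn2_rm", "bn2_rv"))
  list(out = a2$y,
       cache = list(x = x, z1 = z1, bn1 = b1[c("mu", "inv")], h1 = b1$y,
                    h1a = a1$y, z2 = z2, bn2 = b2[c("mu", "inv")],
                    h2 = b2$y, m1 = a1$m, m2 = a2$m),
       state = st)
}

dc_bw <- function(cache, params, pfx, cfg, gout, acc) {
  g <- function(n) params[[paste0(pfx, n)]]
  prelu_on <- cfg$activation == "prelu"
  ab2 <- act_bw(cache$h2, cache$m2, gout, prelu_on)
  if (prelu_on) acc(paste0(pfx, "act2_s"), ab2$gslope)
  bb2 <- bn_bw(cache$z2, cache$bn2$mu, cache$bn2$inv, g("bn2_g"), ab2$gx)
  acc(paste0(pfx, "bn2_g"), bb2$ggamma)
  acc(paste0(pfx, "bn2_b"), bb2$gbeta)
  cb2 <- conv_bw(cache$h1a, g("conv2_w"), bb2$gx, 3L)
  acc(paste0(pfx, "conv2_w"), cb2$gw)
  acc(paste0(pfx, "conv2_b"), cb2$gb)
  ab1 <- act_bw(cache$h1, cache$m1, cb2$gx, prelu_on)
  if (prelu_on) acc(paste0(pfx, "act1_s"), ab1$gslope)
  bb1 <- bn_bw(cache$z1, cache$bn1$mu, cache$bn1$inv, g("bn1_g"), ab1$gx)
  acc(paste0(pfx, "bn1_g"), bb1$ggamma)
  acc(paste0(pfx, "bn1_b"), bb1$gbeta)
  cb1 <- conv_bw(cache$x, g("conv1_w"), bb1$gx, 3L)
  acc(paste0(pfx, "conv1_w"), cb1$gw)
  acc(paste0(pfx, "conv1_b"), cb1$gb)
  cb1$gx
}

#' Apply one double-convolution block
#'
#' Two rounds of (3x3 same convolution, batch normalisation, activation),
#' preserving the spatial grid. Mostly useful for structural inspection;
#' [forward()] runs the full network.
#'
#' @param model A `cropseg_model`.
#' @param x Input tensor `[H, W, C]` or `[H, W, C, N]`.
#' @param block Block prefix, e.g. `"enc1_"`.
#' @return Output tensor with the block's channel count.
#' @export
double_conv <- function(model, x, block = "enc1_") {
  x4 <- as_batch(x)
  out <- dc_fw(x4, model$params, block, model$cfg, training = FALSE)$out
  if (length(dim(x)) == 3L) dim(out) <- dim(out)[1:3]
  out
}

# ---- encoder / decoder -------------------------------------------------

encode_fw <- function(params, cfg, x, training) {
  d <- dim(x)
  if (d[1] %% 16L != 0L || d[2] %% 16L != 0L) {
    stop(sprintf("input size %dx%d is not divisible by 16", d[1], d[2]))
  }
  levels <- vector("list", 5)
  caches <- vector("list", 5)
  pool_idx <- vector("list", 5)
  state <- list()
  cur <- x
  for (i in 1:5) {
    if (i > 1) {
      mp <- .maxpool2_fw(cur)
      pool_idx[[i]] <- mp$idx
      cur <- mp$y
    }
    dc <- dc_fw(cur, params, sprintf("enc%d_", i), cfg, training)
    levels[[i]] <- dc$out
    caches[[i]] <- dc$cache
    state <- c(state, dc$state)
    cur <- dc$out
  }
  attended <- levels
  eca_caches <- vector("list", 4)
  if (cfg$eca) {
    for (i in 1:4) {
      e <- eca_fw(levels[[i]], params[[sprintf("eca%d_w", i)]])
      attended[[i]] <- e$y
      eca_caches[[i]] <- e[c("g", "omega")]
    }
  }
  list(levels = levels, attended = attended, caches = caches,
       pool_idx = pool_idx, eca_caches = eca_caches, state = state)
}

decode_fw <- function(params, cfg, enc, training) {
  y <- enc$levels[[5]]
  caches <- vector("list", 4)
  for (s in 1:4) {
    skip <- enc$attended[[5 - s]]
    ds <- dim(skip)
    up <- .bilinear_resize_fw(y, ds[1], ds[2])
    xin <- cat_channels(up, skip)
    dc <- dc_fw(xin, params, sprintf("dec%d_", s), cfg, training)
    caches[[s]] <- list(dc = dc$cache, up_ch = dim(up)[3],
                        in_dim = dim(y)[1:2], state = dc$state)
    y <- dc$out
  }
  logits <- conv_fw(y, params$final_w, params$final_b, 1L)
  state <- do.call(c, lapply(caches, `[[`, "state"))
  list(logits = logits, feat = y, caches = caches, state = state)
}

#' Run the encoder
#'
#' Produces the five-level feature pyramid of an image (or batch) together
#' with the attention-weighted maps used as skip connections. Spatial
#' dimensions must be divisible by 16; no silent padding is performed.
#'
#' @param model A `cropseg_model`.
#' @param image `[H, W, bands]` or `[H, W, bands, N]` array.
#' @return List with `levels` (5 tensors, channels
#'   `base_width * c(1,2,4,8,16)` at scales `1, 1/2, ..., 1/16`) and
#'   `attended` (the channel-attention outputs for levels 1-4, identical in
#'   shape to `levels`).
#' @export
encode <- function(model, image) {
  enc <- encode_fw(model$params, model$cfg, as_batch(image), training = FALSE)
  enc[c("levels", "attended")]
}

#' Run the decoder on an encoder pyramid
#'
#' Four stages of (bilinear x2 upsampling, concatenation with the attended
#' skip, double convolution), then a 1x1 convolution from the 64-channel
#' (at default width) final feature map to per-class logits at input
#' resolution.
#'
#' @param model A `cropseg_model`.
#' @param pyramid Result of [encode()] (internally, of `encode_fw`).
#' @return Logit tensor `[H, W, n_classes, N]`.
#' @export
decode <- function(model, pyramid) {
  decode_fw(model$params, model$cfg, pyramid, training = FALSE)$logits
}

# ---- point selection ----------------------------------------------------

#' Per-pixel classification difficulty margin
#'
#' The difference between the largest and second-largest class probability
#' at each pixel. A margin near 0 marks a hard pixel (near-tied classes), a
#' margin of 1 a maximally confident one.
#'
#' @param scores Softmax probability tensor `[H, W, C]` or `[H, W, C, N]`
#'   (each pixel's probabilities summing to 1).
#' @return Margin map `[H, W]` (or `[H, W, N]`).
#' @export
point_difficulty <- function(scores) {
  nd <- length(dim(scores))
  x <- as_batch(scores)
  d <- dim(x); C <- d[3]
  if (C < 2L) stop("need at least 2 classes to compute a margin")
  sub <- function(c) array(x[, , c, ], d[-3])
  m1 <- sub(1)
  m2 <- array(-Inf, d[-3])
  for (c in seq_len(C)[-1]) {
    v <- sub(c)
    m2 <- pmax(m2, pmin(m1, v))
    m1 <- pmax(m1, v)
  }
  out <- m1 - m2
  if (nd == 3L) dim(out) <- d[1:2]
  out
}

#' Select the k hardest valid pixels
#'
#' Returns the (column-major) flat indices of the `min(k, #valid)` valid
#' pixels with the smallest margins. Ties are broken by ascending flat
#' index, making the selection deterministic.
#'
#' @param margins Margin map `[H, W]` from [point_difficulty()].
#' @param valid Logical map `[H, W]`; masked pixels are never selected.
#' @param k Number of points to select.
#' @return Integer vector of 1-based flat indices, hardest first.
#' @export
select_topk <- function(margins, valid = NULL, k) {
  if (k < 1L) stop("k must be >= 1")
  m <- as.vector(margins)
  vi <- if (is.null(valid)) seq_along(m) else which(as.vector(valid))
  if (length(vi) == 0L) stop("no valid pixels to select from")
  ord <- vi[order(m[vi], method = "radix")]
  head(ord, min(as.integer(k), length(vi)))
}

#' Sample point features from a coarser feature map
#'
#' Bilinearly interpolates a `[h, w, C]` feature map at the centres of
#' full-resolution pixels given by flat indices on an `H x W` grid
#' (half-pixel alignment, corners not aligned). Equivalent to upsampling the
#' map to `H x W` and gathering.
#'
#' @param feature_map `[h, w, C]` array.
#' @param indices 1-based column-major flat pixel indices on the full grid.
#' @param H,W Full-resolution grid size.
#' @return `length(indices) x C` matrix of feature vectors.
#' @export
sample_point_features <- function(feature_map, indices, H, W) {
  idx <- as.integer(indices) - 1L
  if (any(idx < 0L | idx >= H * W)) stop("point index out of range")
  .point_sample_fw(feature_map, idx %% H, idx %/% H,
                   as.integer(H), as.integer(W))
}

# ---- point-refinement MLP ----------------------------------------------

mlp_fw <- function(X, params, cfg) {
  caches <- list()
  h <- X
  for (j in seq_along(cfg$cp_hidden)) {
    w <- params[[sprintf("cp%d_w", j)]]
    z <- h %*% w + rep(params[[sprintf("cp%d_b", j)]], each = nrow(h))
    slope <- if (cfg$activation == "prelu") params[[sprintf("cp%d_s", j)]]
             else numeric(ncol(w))
    a <- mact_fw(z, slope)
    caches[[j]] <- list(x = h, z = z, m = a$m)
    h <- a$y
  }
  logits <- h %*% params$cp_out_w +
    rep(params$cp_out_b, each = nrow(h))
  list(logits = logits, caches = caches, top = h)
}

mlp_bw <- function(glogits, fw, params, cfg, acc) {
  acc("cp_out_w", crossprod(fw$top, glogits))
  acc("cp_out_b", colSums(glogits))
  gh <- glogits %*% t(params$cp_out_w)
  prelu_on <- cfg$activation == "prelu"
  for (j in rev(seq_along(cfg$cp_hidden))) {
    cc <- caches_j <- fw$caches[[j]]
    ab <- mact_bw(cc$z, cc$m, gh, prelu_on)
    if (prelu_on) acc(sprintf("cp%d_s", j), ab$gslope)
    acc(sprintf("cp%d_w", j), crossprod(cc$x, ab$gx))
    acc(sprintf("cp%d_b", j), colSums(ab$gx))
    gh <- ab$gx %*% t(params[[sprintf("cp%d_w", j)]])
  }
  gh
}

#' Re-classify selected points with the refinement MLP
#'
#' Concatenates each point's sampled feature vector with the master branch's
#' class probabilities at that point and applies the shared pointwise MLP.
#'
#' @param model A `cropseg_model` with `cp_enabled`.
#' @param features `k x C2` matrix of sampled point features.
#' @param master_scores `k x n_classes` matrix of master-branch softmax
#'   probabilities at the same points.
#' @return `k x n_classes` matrix of refinement logits.
#' @export
cp_head <- function(model, features, master_scores) {
  if (!model$cfg$cp_enabled) stop("model was built without the point branch")
  if (nrow(features) != nrow(master_scores)) stop("row counts must match")
  mlp_fw(cbind(features, master_scores), model$params, model$cfg)$logits
}

# ---- full forward ------------------------------------------------------

channel_argmax <- function(p) {
  d <- dim(p); C <- d[3]
  best <- chan_slice(p, 1, d)
  am <- array(0L, d[-3])
  for (c in seq_len(C)[-1]) {
    v <- chan_slice(p, c, d)
    upd <- v > best
    am[upd] <- c - 1L
    best <- pmax(best, v)
  }
  am
}

gather_scores <- function(probs, idx, n) {
  d <- dim(probs); HW <- d[1] * d[2]; C <- d[3]
  out <- matrix(0, length(idx), C)
  base <- (n - 1L) * C * HW
  for (c in seq_len(C)) out[, c] <- probs[base + (c - 1L) * HW + idx]
  out
}

#' Full network forward pass
#'
#' Runs encoder, attention, decoder and channel softmax; when the point
#' branch is enabled it then computes per-pixel difficulty margins, selects
#' the hardest valid pixels of each image, samples their features, applies
#' the refinement MLP, and overrides the master label at the selected
#' pixels with the refined decision.
#'
#' @param model A `cropseg_model`.
#' @param image `[H, W, bands]` or `[H, W, bands, N]` array; `H`, `W`
#'   divisible by 16.
#' @param labels Optional `[H, W]` / `[H, W, N]` integer labels. During
#'   training they define pixel validity: pixels carrying `ignore` are never
#'   selected by the point branch.
#' @param training Use batch statistics (and record caches for backprop).
#' @param ignore Ignore value in `labels`.
#' @param with_cache Keep intermediate activations (needed for backprop).
#' @return A `cropseg_prediction`: `master_logits` and `probs`
#'   (`[H, W, C, N]`), `label_map` (`[H, W, N]`, classes 0-based),
#'   `selection` (per image: `indices`, `margins`, `features`,
#'   `master_scores`), `cp_logits` (row-bound over images), and bookkeeping
#'   needed by the training engine.
#' @export
forward <- function(model, image, labels = NULL, training = FALSE,
                    ignore = 255L, with_cache = training) {
  params <- model$params; cfg <- model$cfg
  x <- as_batch(image)
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[4]
  enc <- encode_fw(params, cfg, x, training)
  dec <- decode_fw(params, cfg, enc, training)
  probs <- softmax_fw(dec$logits)
  label_map <- channel_argmax(probs)
  if (length(dim(label_map)) < 3L) dim(label_map) <- c(H, W, N)

  selection <- NULL; cp_logits <- NULL; cp_rows <- NULL; mlp_cache <- NULL
  if (cfg$cp_enabled) {
    margins <- point_difficulty(probs)
    if (length(dim(margins)) < 3L) dim(margins) <- c(H, W, N)
    k <- cp_k_for(cfg, H, W)
    lvl <- cfg$cp_source_level
    src <- if (cfg$cp_after_eca) enc$attended[[lvl]] else enc$levels[[lvl]]
    ds <- dim(src)
    lab3 <- if (!is.null(labels)) {
      l <- labels; if (length(dim(l)) < 3L) dim(l) <- c(H, W, N); l
    } else NULL
    selection <- vector("list", N)
    Xs <- vector("list", N)
    for (n in seq_len(N)) {
      valid_n <- if (!is.null(lab3)) lab3[, , n] != ignore else NULL
      mg <- margins[, , n]
      idx <- select_topk(mg, valid_n, k)
      feats <- .point_sample_fw(array(src[, , , n], ds[1:3]),
                                (idx - 1L) %% H, (idx - 1L) %/% H, H, W)
      sc <- gather_scores(probs, idx, n)
      selection[[n]] <- list(indices = idx, margins = mg[idx],
                             features = feats, master_scores = sc)
      Xs[[n]] <- cbind(feats, sc)
    }
    cp_rows <- vapply(Xs, nrow, 0L)
    mlp <- mlp_fw(do.call(rbind, Xs), params, cfg)
    cp_logits <- mlp$logits
    mlp_cache <- mlp
    # Override the master decision at the selected points.
    off <- 0L
    HW <- H * W
    for (n in seq_len(N)) {
      kn <- cp_rows[n]
      cl <- cp_logits[off + seq_len(kn), , drop = FALSE]
      label_map[(n - 1L) * HW + selection[[n]]$indices] <-
        max.col(cl, ties.method = "first") - 1L
      off <- off + kn
    }
  }

  out <- list(master_logits = dec$logits, probs = probs,
              label_map = label_map, selection = selection,
              cp_logits = cp_logits, cp_rows = cp_rows,
              state = c(enc$state, dec$state), dims = d)
  if (with_cache) {
    out$cache <- list(enc = enc, dec = dec, mlp = mlp_cache)
  }
  class(out) <- "cropseg_prediction"
  out
}

#' @export
print.cropseg_prediction <- function(x, ...) {
  d <- x$dims
  cat("<cropseg_prediction>", d[1], "x", d[2], "pixels,",
      d[4], "image(s)")
  if (!is.null(x$selection)) {
    cat(",", nrow(x$cp_logits), "refined points")
  }
  cat("\n")
  invisible(x)
}

# ---- full backward -----------------------------------------------------

# gprobs: gradient of the loss w.r.t. the master softmax probabilities;
# gcp_logits: gradient w.r.t. the point-branch logits (or NULL).
# The margin/top-k selection is treated as non-differentiable.
net_backward <- function(model, fwd, gprobs, gcp_logits = NULL) {
  params <- model$params; cfg <- model$cfg
  if (is.null(fwd$cache)) stop("forward pass was run without with_cache")
  enc <- fwd$cache$enc; dec <- fwd$cache$dec
  d <- fwd$dims; H <- d[1]; W <- d[2]; N <- d[4]; HW <- H * W
  C <- cfg$n_classes

  genv <- new.env(parent = emptyenv())
  acc <- function(name, v) {
    cur <- genv[[name]]
    genv[[name]] <- if (is.null(cur)) v else cur + v
  }

  lvl <- cfg$cp_source_level
  g_cp_src <- NULL
  if (cfg$cp_enabled && !is.null(gcp_logits)) {
    gX <- mlp_bw(gcp_logits, fwd$cache$mlp, params, cfg, acc)
    C2 <- ncol(gX) - C
    src_dim <- dim(if (cfg$cp_after_eca) enc$attended[[lvl]]
                   else enc$levels[[lvl]])
    g_cp_src <- array(0, src_dim)
    off <- 0L
    for (n in seq_len(N)) {
      sel <- fwd$selection[[n]]
      kn <- length(sel$indices)
      rows <- off + seq_len(kn)
      # probability inputs of the MLP feed back into the master softmax
      for (c in seq_len(C)) {
        flat <- (n - 1L) * C * HW + (c - 1L) * HW + sel$indices
        gprobs[flat] <- gprobs[flat] + gX[rows, C2 + c]
      }
      gsrc <- .point_sample_bw(gX[rows, seq_len(C2), drop = FALSE],
                               (sel$indices - 1L) %% H,
                               (sel$indices - 1L) %/% H,
                               src_dim[1], src_dim[2], H, W)
      g_cp_src[, , , n] <- g_cp_src[, , , n] + gsrc
      off <- off + kn
    }
  }

  glogits <- softmax_bw(fwd$probs, gprobs)

  # final 1x1 classifier
  cb <- conv_bw(dec$feat, params$final_w, glogits, 1L)
  acc("final_w", cb$gw)
  acc("final_b", cb$gb)
  gy <- cb$gx

  # decoder stages in reverse
  g_attended <- vector("list", 4)
  for (s in 4:1) {
    dcache <- dec$caches[[s]]
    gin <- dc_bw(dcache$dc, params, sprintf("dec%d_", s), cfg, gy, acc)
    sp <- split_channels(gin, dcache$up_ch)
    skip_lvl <- 5 - s
    g_attended[[skip_lvl]] <-
      if (is.null(g_attended[[skip_lvl]])) sp$b else g_attended[[skip_lvl]] + sp$b
    gy <- .bilinear_resize_bw(sp$a, dcache$in_dim[1], dcache$in_dim[2])
  }
  g_levels <- vector("list", 5)
  g_levels[[5]] <- gy

  if (!is.null(g_cp_src)) {
    if (cfg$cp_after_eca && lvl <= 4) {
      g_attended[[lvl]] <- g_attended[[lvl]] + g_cp_src
    } else if (lvl == 5L) {
      g_levels[[5]] <- g_levels[[5]] + g_cp_src
    } else {
      g_levels[[lvl]] <- g_cp_src  # pre-attention tap; merged below
    }
  }

  for (i in 1:4) {
    ga <- g_attended[[i]]
    if (is.null(ga)) next
    if (cfg$eca) {
      eb <- eca_bw(enc$levels[[i]], enc$eca_caches[[i]]$g,
                   enc$eca_caches[[i]]$omega,
                   params[[sprintf("eca%d_w", i)]], ga)
      acc(sprintf("eca%d_w", i), eb$gw)
      ga <- eb$gx
    }
    g_levels[[i]] <- if (is.null(g_levels[[i]])) ga else g_levels[[i]] + ga
  }

  # encoder in reverse
  for (i in 5:1) {
    gin <- dc_bw(enc$caches[[i]], params, sprintf("enc%d_", i), cfg,
                 g_levels[[i]], acc)
    if (i > 1) {
      dprev <- dim(enc$levels[[i - 1]])
      gpool <- .maxpool2_bw(enc$pool_idx[[i]], gin, dprev[1], dprev[2])
      g_levels[[i - 1]] <- if (is.null(g_levels[[i - 1]])) gpool
                           else g_levels[[i - 1]] + gpool
    }
  }

  as.list(genv)
}
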
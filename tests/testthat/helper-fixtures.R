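# Shared fixtures, built in code at test time.

# A small labeled scene with a deterministic pattern (no RNG).
toy_scene <- function(H = 10L, W = 10L, bands = 4L) {
  img <- array(seq_len(H * W * bands) / (H * W * bands), c(H, W, bands))
  lab <- matrix((seq_len(H * W) - 1L) %% 4L, H, W)
  scene(img, lab)
}

# Synthetic patches shared across engine/acceptance tests.
small_patch_set <- function(seed = 11L, patch = 64L) {
  scn <- generate_scene(synth_config(seed = seed))
  filter_masked(tile(scn, patch, patch))
}

# Tiny trainable setup for fast engine tests.
tiny_setup <- function(seed = 3L, n = 8L, S = 32L) {
  scn <- generate_scene(synth_config(height = 128L, width = 128L,
                                     n_parcels = 20L, mask_rects = 1L,
                                     seed = seed))
  patches <- filter_masked(tile(scn, S, S))
  list(patches = patches[seq_len(min(n, length(patches)))],
       cfg = net_config(base_width = 4L, cp_hidden = c(16L), cp_k = 50L))
}

# Independent per-pixel top-2 margin via full sorting.
margin_oracle <- function(scores) {
  d <- dim(scores)
  m <- matrix(scores, d[1] * d[2], d[3])
  v <- apply(m, 1, function(r) { s <- sort(r, decreasing = TRUE); s[1] - s[2] })
  matrix(v, d[1], d[2])
}

# Independent top-k selection: filter valid, full stable sort.
topk_oracle <- function(margins, valid, k) {
  df <- data.frame(idx = seq_along(margins), m = as.vector(margins),
                   v = as.vector(valid))
  df <- df[df$v, ]
  df <- df[order(df$m, df$idx), ]
  head(df$idx, min(k, nrow(df)))
}

expect_same_patches <- function(a, b) {
  expect_equal(length(a), length(b))
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$image, b[[i]]$image)
    expect_identical(a[[i]]$labels, b[[i]]$labels)
    expect_identical(a[[i]]$origin, b[[i]]$origin)
  }
}
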
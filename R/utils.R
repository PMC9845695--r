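# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package operations never disturb the user's stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce [H,W,C] to [H,W,C,1]; pass 4-d arrays through.
as_batch <- function(x) {
  d <- dim(x)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  else if (length(d) != 4L) stop("expected a 3-d or 4-d array")
  x
}

# Per-channel sums over H, W for each image: returns a C x N matrix.
chan_stat_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3], d[4])
  m <- colSums(x)
  if (is.null(dim(m))) dim(m) <- c(d[3], d[4])
  m
}

# Per-channel sums over H, W and the batch: vector of length C.
chan_sum <- function(x) rowSums(chan_stat_mat(x))

# Broadcast a length-C vector over [H,W,C,N] (relies on exact recycling).
chan_rep <- function(v, HW) rep(v, each = HW)

# Broadcast a C x N matrix over [H,W,C,N].
chanimg_rep <- function(m, HW) rep(as.vector(m), each = HW)

# Concatenate two [H,W,Ca,N] / [H,W,Cb,N] tensors along the channel axis.
cat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_channels <- function(x, c1) {
  d <- dim(x)
  list(a = x[, , seq_len(c1), , drop = FALSE],
       b = x[, , c1 + seq_len(d[3] - c1), , drop = FALSE])
}
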
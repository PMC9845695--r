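# Numerical primitives: convolution against a naive oracle, gradients
# against finite differences, and the activation/attention contracts.

naive_conv <- function(x, w, b, k) {
  d <- dim(x); H <- d[1]; W <- d[2]; Cin <- d[3]; N <- d[4]
  Cout <- ncol(w); pad <- (k - 1) / 2
  y <- array(0, c(H, W, Cout, N))
  for (n in 1:N) for (co in 1:Cout) for (i in 1:H) for (j in 1:W) {
    s <- b[co]
    for (c in 1:Cin) for (dh in 0:(k - 1)) for (dw in 0:(k - 1)) {
      si <- i + dh - pad; sj <- j + dw - pad
      if (si >= 1 && si <= H && sj >= 1 && sj <= W) {
        s <- s + x[si, sj, c, n] * w[(c - 1) * k * k + dh * k + dw + 1, co]
      }
    }
    y[i, j, co, n] <- s
  }
  y
}

num_grad <- function(f, p, eps = 1e-6) {
  g <- p
  for (i in seq_along(p)) {
    p1 <- p; p1[i] <- p1[i] + eps
    p2 <- p; p2[i] <- p2[i] - eps
    g[i] <- (f(p1) - f(p2)) / (2 * eps)
  }
  g
}

test_that("convolution matches a naive direct implementation", {
  set.seed(1)
  x <- array(rnorm(5 * 6 * 3 * 2), c(5, 6, 3, 2))
  b <- rnorm(4)
  w3 <- matrix(rnorm(27 * 4), 27, 4)
  expect_equal(cropseg:::.conv2d_fw(x, w3, b, 3L), naive_conv(x, w3, b, 3),
               tolerance = 1e-12)
  w1 <- matrix(rnorm(3 * 4), 3, 4)
  expect_equal(cropseg:::.conv2d_fw(x, w1, b, 1L), naive_conv(x, w1, b, 1),
               tolerance = 1e-12)
})

test_that("primitive backward passes agree with finite differences", {
  set.seed(2)
  x <- array(rnorm(4 * 4 * 2 * 2), c(4, 4, 2, 2))
  w <- matrix(rnorm(18 * 3), 18, 3)
  b <- rnorm(3)
  R <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  bw <- cropseg:::.conv2d_bw(x, w, R, 3L)
  expect_equal(bw$gx, num_grad(function(p)
    sum(cropseg:::.conv2d_fw(p, w, b, 3L) * R), x), tolerance = 1e-6)
  expect_equal(unname(as.matrix(bw$gw)), unname(num_grad(function(p)
    sum(cropseg:::.conv2d_fw(x, p, b, 3L) * R), w)), tolerance = 1e-6)

  mp <- cropseg:::.maxpool2_fw(x)
  Rp <- array(rnorm(length(mp$y)), dim(mp$y))
  expect_equal(cropseg:::.maxpool2_bw(mp$idx, Rp, 4L, 4L),
               num_grad(function(p)
                 sum(cropseg:::.maxpool2_fw(p)$y * Rp), x),
               tolerance = 1e-6)

  br <- cropseg:::.bilinear_resize_fw(x, 8L, 6L)
  Rb <- array(rnorm(length(br)), dim(br))
  expect_equal(cropseg:::.bilinear_resize_bw(Rb, 4L, 4L),
               num_grad(function(p)
                 sum(cropseg:::.bilinear_resize_fw(p, 8L, 6L) * Rb), x),
               tolerance = 1e-6)
})

test_that("bilinear upsampling preserves constants and matches point sampling", {
  cst <- array(7, c(4, 4, 2, 1))
  expect_equal(cropseg:::.bilinear_resize_fw(cst, 8L, 8L),
               array(7, c(8, 8, 2, 1)))
  set.seed(3)
  fm <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  fm4 <- fm; dim(fm4) <- c(4, 4, 3, 1)
  up <- cropseg:::.bilinear_resize_fw(fm4, 8L, 8L)
  idx <- sample(64L, 12L)
  ps <- sample_point_features(fm, idx, 8, 8)
  expect_equal(ps, sapply(1:3, function(c) up[, , c, 1][idx]),
               tolerance = 1e-12)
  # constant feature map: every sampled vector equals the constant
  expect_equal(sample_point_features(array(2.5, c(2, 2, 3)), idx, 8, 8),
               matrix(2.5, 12, 3))
})

test_that("prelu follows its piecewise definition", {
  expect_equal(prelu(3, 0.25), 3)
  expect_equal(prelu(-2, 0.25), -0.5)
  expect_equal(prelu(-5, 0), 0)   # slope 0 reduces to ReLU
  x <- c(-2, -1, 0, 1, 2)
  expect_equal(prelu(x, 0.1), ifelse(x > 0, x, 0.1 * x))
})

test_that("channel attention computes GAP + 1-d conv + sigmoid reweighting", {
  # channel means 1,2,3,4; kernel (0.25,0.5,0.25) with zero padding:
  # s = (0.5*1+0.25*2, 0.25*1+0.5*2+0.25*3, 2.0+1 ,0.25*3+0.5*4) =
  #     (1.0, 2.0, 3.0, 2.75)
  x <- array(0, c(2, 2, 4))
  for (c in 1:4) x[, , c] <- c
  w <- c(0.25, 0.5, 0.25)
  omega <- plogis(c(1, 2, 3, 2.75))
  out <- eca(x, w)
  for (c in 1:4) {
    expect_equal(out[, , c], matrix(c * omega[c], 2, 2), tolerance = 1e-12)
  }
  # shape preserved and contraction: |out| <= |x| elementwise
  set.seed(4)
  xr <- array(rnorm(8 * 8 * 6), c(8, 8, 6))
  ar <- eca(xr, rnorm(3))
  expect_identical(dim(ar), dim(xr))
  expect_true(all(abs(ar) <= abs(xr) + 1e-12))
  # all-zero input stays zero (weights multiply a zero map)
  expect_equal(eca(array(0, c(4, 4, 5)), w), array(0, c(4, 4, 5)))
})

test_that("eca backward agrees with finite differences", {
  set.seed(5)
  x <- array(rnorm(3 * 3 * 5 * 2), c(3, 3, 5, 2))
  w <- rnorm(3)
  R <- array(rnorm(length(x)), dim(x))
  fw <- cropseg:::eca_fw(x, w)
  bw <- cropseg:::eca_bw(x, fw$g, fw$omega, w, R)
  expect_equal(bw$gx, num_grad(function(p)
    sum(cropseg:::eca_fw(p, w)$y * R), x), tolerance = 1e-6)
  expect_equal(bw$gw, num_grad(function(p)
    sum(cropseg:::eca_fw(x, p)$y * R), w), tolerance = 1e-6)
})

test_that("batch-norm and activation backward agree with finite differences", {
  set.seed(6)
  x <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  gamma <- runif(2, 0.5, 1.5); beta <- rnorm(2)
  R <- array(rnorm(length(x)), dim(x))
  f <- function(p) sum(cropseg:::bn_fw(p, gamma, beta, numeric(2), rep(1, 2),
                                       training = TRUE)$y * R)
  fw <- cropseg:::bn_fw(x, gamma, beta, numeric(2), rep(1, 2), training = TRUE)
  bw <- cropseg:::bn_bw(x, fw$mu, fw$inv, gamma, R)
  expect_equal(bw$gx, num_grad(f, x, 1e-5), tolerance = 1e-4)

  slope <- c(0.25, 0.1)
  afw <- cropseg:::act_fw(x, slope)
  abw <- cropseg:::act_bw(x, afw$m, R, TRUE)
  expect_equal(abw$gslope, num_grad(function(s)
    sum(cropseg:::act_fw(x, s)$y * R), slope), tolerance = 1e-6)
})

test_that("double_conv preserves the spatial grid and its parameter count", {
  cfg <- net_config(base_width = 64L, cp_enabled = FALSE)
  model <- crop_model(cfg, seed = 1)
  x <- array(rnorm(64 * 64 * 4), c(64, 64, 4))
  y <- double_conv(model, x, "enc1_")
  expect_identical(dim(y), c(64L, 64L, 64L))
  # (4*9*64 + 64) weights+bias, 2*64 BN affine, per conv round; PReLU slopes
  census <- parameter_census(model)
  enc1 <- census[grep("^enc1_", names(census))]
  conv_bn <- (4 * 9 * 64 + 64) + 2 * 64 + (64 * 9 * 64 + 64) + 2 * 64
  expect_equal(sum(enc1[!grepl("act", names(enc1))]), conv_bn)
})
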
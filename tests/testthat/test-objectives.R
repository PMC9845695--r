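# Loss functions: closed forms, hand-computed oracles, masking invariance
# and analytic-vs-numerical gradients.

onehot_scores <- function(lab, C = 4L) {
  d <- dim(lab)
  s <- array(0, c(d, C))
  for (c in seq_len(C)) s[, , c] <- (lab == c - 1L)
  s
}

test_that("cross-entropy matches closed forms and a hand sum", {
  lab <- matrix(c(0L, 1L, 2L, 3L), 2, 2)
  expect_equal(cross_entropy_loss(pmin(pmax(onehot_scores(lab), 1e-12), 1),
                                  lab), 0, tolerance = 1e-9)
  expect_equal(cross_entropy_loss(array(0.25, c(2, 2, 4)), lab), log(4),
               tolerance = 1e-12)
  # 3x3 map with one ignored pixel: hand sum over the 8 counted pixels
  set.seed(31)
  s <- array(runif(9 * 4), c(3, 3, 4))
  s <- s / array(rep(apply(s, c(1, 2), sum), 4), dim(s))
  lab3 <- matrix(sample(0:3, 9, TRUE), 3, 3)
  lab3[2, 2] <- 255L
  hand <- 0
  for (i in 1:3) for (j in 1:3) {
    if (lab3[i, j] != 255L) hand <- hand - log(s[i, j, lab3[i, j] + 1])
  }
  expect_equal(cross_entropy_loss(s, lab3), hand / 8, tolerance = 1e-12)
  expect_error(cross_entropy_loss(s, matrix(255L, 3, 3)), "all pixels")
})

test_that("dice loss matches its hand-evaluated formula", {
  lab <- matrix(c(0L, 1L, 2L, 3L), 2, 2)
  expect_lt(dice_loss(onehot_scores(lab), lab), 1e-6)
  wrong <- onehot_scores((lab + 1L) %% 4L)
  expect_gt(dice_loss(wrong, lab), 1 - 1e-4)
  # 2x2, C=2: scores ((0.8,0.2),(0.6,0.4),(0.3,0.7),(0.1,0.9)), labels 0,0,1,1
  s <- array(0, c(2, 2, 2))
  s[, , 1] <- matrix(c(0.8, 0.6, 0.3, 0.1), 2, 2)
  s[, , 2] <- 1 - s[, , 1]
  lab2 <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  eps <- 1e-6
  d0 <- (2 * (0.8 + 0.6) + eps) / ((0.8 + 0.6 + 0.3 + 0.1) + 2 + eps)
  d1 <- (2 * (0.7 + 0.9) + eps) / ((0.2 + 0.4 + 0.7 + 0.9) + 2 + eps)
  expect_equal(dice_loss(s, lab2, smooth = eps), 1 - (d0 + d1) / 2,
               tolerance = 1e-12)
})

test_that("the compound loss is linear in its weights", {
  set.seed(32)
  s <- array(runif(4 * 4 * 4), c(4, 4, 4))
  s <- s / array(rep(apply(s, c(1, 2), sum), 4), dim(s))
  lab <- matrix(sample(0:3, 16, TRUE), 4, 4)
  ce <- cross_entropy_loss(s, lab)
  di <- dice_loss(s, lab)
  expect_equal(master_loss(s, lab, loss_config(alpha = 1, beta = 0)), ce)
  expect_equal(master_loss(s, lab, loss_config(alpha = 0, beta = 1)), di)
  expect_equal(master_loss(s, lab, loss_config(alpha = 1, beta = 10)),
               ce + 10 * di, tolerance = 1e-12)
  expect_error(loss_config(alpha = 0, beta = 0), "positive")
})

test_that("point-branch cross-entropy matches a scalar oracle", {
  z1 <- matrix(c(100, 0, 0, 0), 1, 4)
  expect_lt(cp_loss(z1, 0L), 1e-9)
  set.seed(33)
  z <- matrix(rnorm(5 * 4), 5, 4)
  lab <- c(0L, 3L, 1L, 255L, 2L)
  hand <- 0; n <- 0
  for (i in 1:5) {
    if (lab[i] == 255L) next
    p <- exp(z[i, ]) / sum(exp(z[i, ]))
    hand <- hand - log(p[lab[i] + 1]); n <- n + 1
  }
  expect_equal(cp_loss(z, lab), hand / n, tolerance = 1e-12)
  expect_warning(v <- cp_loss(z, rep(255L, 5)), "contributes 0")
  expect_equal(v, 0)
})

test_that("losses are blind to scores at ignored pixels", {
  set.seed(34)
  s <- array(runif(4 * 4 * 4), c(4, 4, 4))
  s <- s / array(rep(apply(s, c(1, 2), sum), 4), dim(s))
  lab <- matrix(sample(0:3, 16, TRUE), 4, 4)
  lab[1, ] <- 255L
  s2 <- s
  s2[1, , ] <- runif(16)  # arbitrary garbage at ignored pixels
  expect_identical(cross_entropy_loss(s, lab), cross_entropy_loss(s2, lab))
  expect_identical(dice_loss(s, lab), dice_loss(s2, lab))
  expect_identical(master_loss(s, lab, loss_config(alpha = 2, beta = 3)),
                   master_loss(s2, lab, loss_config(alpha = 2, beta = 3)))
})

test_that("loss bounds hold on random instances", {
  set.seed(35)
  for (rep in 1:20) {
    s <- array(runif(3 * 3 * 4), c(3, 3, 4))
    s <- s / array(rep(apply(s, c(1, 2), sum), 4), dim(s))
    lab <- matrix(sample(c(0:3, 255L), 9, TRUE, prob = c(rep(0.23, 4), 0.08)),
                  3, 3)
    if (all(lab == 255L)) next
    expect_gte(cross_entropy_loss(s, lab), 0)
    d <- dice_loss(s, lab)
    expect_gte(d, 0)
    expect_lt(d, 1)
  }
})

test_that("analytic loss gradients match finite differences on 2x2 maps", {
  set.seed(36)
  s <- array(runif(2 * 2 * 4, 0.05, 1), c(2, 2, 4))
  s <- s / array(rep(apply(s, c(1, 2), sum), 4), dim(s))
  lab <- matrix(c(0L, 2L, 255L, 3L), 2, 2)
  num_grad <- function(f, p, eps = 1e-6) {
    g <- p
    for (i in seq_along(p)) {
      p1 <- p; p1[i] <- p1[i] + eps
      p2 <- p; p2[i] <- p2[i] - eps
      g[i] <- (f(p1) - f(p2)) / (2 * eps)
    }
    g
  }
  rel <- function(a, b) max(abs(a - b)) / max(1e-8, max(abs(b)))
  g_ce <- cross_entropy_loss(s, lab, grad = TRUE)$grad
  expect_lt(rel(g_ce, num_grad(function(p)
    cross_entropy_loss(p, lab), s)), 1e-4)
  g_d <- dice_loss(s, lab, grad = TRUE)$grad
  expect_lt(rel(g_d, num_grad(function(p) dice_loss(p, lab), s)), 1e-4)
  cfg <- loss_config(alpha = 1, beta = 2)
  g_m <- master_loss(s, lab, cfg, grad = TRUE)$grad
  expect_lt(rel(g_m, num_grad(function(p) master_loss(p, lab, cfg), s)), 1e-4)
  z <- matrix(rnorm(3 * 4), 3, 4)
  plab <- c(1L, 255L, 3L)
  g_cp <- cp_loss(z, plab, grad = TRUE)$grad
  expect_lt(rel(g_cp, num_grad(function(p) cp_loss(p, plab), z)), 1e-4)
})
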
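# Architecture contracts: pyramid shapes, point selection, the refinement
# head, baseline reduction and gradient flow.

test_that("point_difficulty equals a full-sort margin oracle", {
  expect_equal(point_difficulty(array(c(1, 0, 0, 0), c(1, 1, 4)))[1, 1], 1)
  expect_equal(point_difficulty(array(0.25, c(1, 1, 4)))[1, 1], 0)
  expect_error(point_difficulty(array(1, c(2, 2, 1))), "at least 2 classes")
  set.seed(21)
  s <- array(runif(8 * 8 * 4), c(8, 8, 4))
  s <- s / array(rep(apply(s, c(1, 2), sum), 4), dim(s))
  expect_equal(point_difficulty(s), margin_oracle(s), tolerance = 1e-12)
})

test_that("select_topk matches a stable full sort and respects validity", {
  set.seed(22)
  m <- matrix(runif(16 * 16), 16, 16)
  v <- matrix(runif(256) > 0.3, 16, 16)
  expect_identical(select_topk(m, v, 40L), topk_oracle(m, v, 40))
  # saturation: k >= #valid returns all valid pixels
  expect_identical(sort(select_topk(m, NULL, 10000L)), 1:256)
  expect_identical(sort(select_topk(m, v, sum(v))), which(as.vector(v)))
  expect_error(select_topk(m, matrix(FALSE, 16, 16), 5L), "no valid pixels")
  # ties resolved by ascending flat index
  expect_identical(select_topk(matrix(0.5, 4, 4), NULL, 3L), 1:3)
})

test_that("the default point budget is 8096 at 256x256 and ~12.35% elsewhere", {
  cfg <- net_config()
  expect_identical(cropseg:::cp_k_for(cfg, 256L, 256L), 8096L)
  expect_equal(8096 / (256 * 256), 0.1235, tolerance = 1e-3)
  expect_identical(cropseg:::cp_k_for(cfg, 64L, 64L),
                   as.integer(round(0.1235 * 64 * 64)))
  expect_identical(cropseg:::cp_k_for(net_config(cp_k = 123L), 256L, 256L),
                   123L)
})

test_that("encoder pyramid shapes follow the halving/doubling rule", {
  model <- crop_model(net_config(base_width = 4L, cp_enabled = FALSE),
                      seed = 1)
  x <- array(rnorm(64 * 64 * 4), c(64, 64, 4))
  pyr <- encode(model, x)
  ch <- 4L * c(1L, 2L, 4L, 8L, 16L)
  sz <- as.integer(64 / c(1, 2, 4, 8, 16))
  for (i in 1:5) {
    expect_identical(dim(pyr$levels[[i]]), c(sz[i], sz[i], ch[i], 1L))
  }
  # attention never changes a shape
  for (i in 1:4) {
    expect_identical(dim(pyr$attended[[i]]), dim(pyr$levels[[i]]))
  }
  logits <- decode(model, cropseg:::encode_fw(model$params, model$cfg,
                                              cropseg:::as_batch(x), FALSE))
  expect_identical(dim(logits), c(64L, 64L, 4L, 1L))
  expect_error(forward(model, array(0, c(60, 64, 4))), "not divisible by 16")
})

test_that("the refinement head is pointwise and correctly sized", {
  cfg <- net_config(base_width = 64L, cp_hidden = c(256L, 256L))
  model <- crop_model(cfg, seed = 2)
  census <- parameter_census(model)
  cp <- census[grep("^cp", names(census))]
  # input dim 128 + 4 = 132; two hidden layers of 256; 4 outputs
  expect_equal(sum(cp[!grepl("_s$", names(cp))]),
               (132 * 256 + 256) + (256 * 256 + 256) + (256 * 4 + 4))
  set.seed(23)
  f <- matrix(rnorm(10 * 128), 10, 128)
  s <- matrix(runif(10 * 4), 10, 4)
  out <- cp_head(model, f, s)
  expect_identical(dim(out), c(10L, 4L))
  perm <- sample(10)
  expect_equal(cp_head(model, f[perm, ], s[perm, ]), out[perm, ],
               tolerance = 1e-12)
  # zero weights with bias b give constant logits b
  m0 <- model
  for (nm in grep("^cp", names(m0$params), value = TRUE)) {
    m0$params[[nm]] <- m0$params[[nm]] * 0
  }
  m0$params$cp_out_b <- c(1, 2, 3, 4)
  expect_equal(unname(cp_head(m0, f, s)),
               matrix(c(1, 2, 3, 4), 10, 4, byrow = TRUE))
})

test_that("sampled point feature dimension matches the source level", {
  model <- crop_model(net_config(base_width = 16L, cp_k = 30L), seed = 3)
  fw <- forward(model, array(runif(32 * 32 * 4), c(32, 32, 4)))
  expect_identical(dim(fw$selection[[1]]$features), c(30L, 32L))  # 2*16
  expect_true(all(fw$selection[[1]]$margins >= 0))
  expect_identical(anyDuplicated(fw$selection[[1]]$indices), 0L)
})

test_that("disabling the point branch reduces to the master argmax", {
  x <- array(runif(32 * 32 * 4), c(32, 32, 4))
  base <- crop_model(net_config(base_width = 4L, cp_enabled = FALSE),
                     seed = 4)
  fw <- forward(base, x)
  am <- apply(fw$probs[, , , 1], c(1, 2), which.max) - 1L
  expect_identical(fw$label_map[, , 1], am)
  expect_null(fw$selection)
})

test_that("the point branch overrides only the selected pixels", {
  x <- array(runif(32 * 32 * 4), c(32, 32, 4))
  cfg <- net_config(base_width = 4L, cp_k = 100L, cp_hidden = c(16L))
  model <- crop_model(cfg, seed = 5)
  fw <- forward(model, x)
  am <- apply(fw$probs[, , , 1], c(1, 2), which.max) - 1L
  diff_idx <- which(fw$label_map[, , 1] != am)
  expect_true(all(diff_idx %in% fw$selection[[1]]$indices))
  expect_lte(length(diff_idx), 100L)
  # repeated inference is deterministic
  fw2 <- forward(model, x)
  expect_identical(fw$label_map, fw2$label_map)
  expect_equal(fw$cp_logits, fw2$cp_logits, tolerance = 0)
})

test_that("masked pixels are never selected during training", {
  x <- array(runif(32 * 32 * 4), c(32, 32, 4))
  lab <- matrix(0L, 32, 32)
  lab[1:16, ] <- 255L
  model <- crop_model(net_config(base_width = 4L, cp_k = 2000L,
                                 cp_hidden = c(8L)), seed = 6)
  fw <- forward(model, x, labels = lab, training = TRUE)
  sel <- fw$selection[[1]]$indices
  expect_true(all(lab[sel] != 255L))
  expect_length(sel, sum(lab != 255L))  # clamped to the valid count
})

test_that("the baseline configuration is a plain bilinear U-Net by census", {
  cfg <- net_config(base_width = 8L, activation = "relu", eca = FALSE,
                    cp_enabled = FALSE)
  census <- parameter_census(crop_model(cfg, seed = 7))
  expect_false(any(grepl("eca|cp|act", names(census))))
  # independent hand count of a symmetric U-Net at base width 8
  b <- 8
  dc <- function(cin, cout) (cin * 9 * cout + cout) + 2 * cout +
    (cout * 9 * cout + cout) + 2 * cout
  enc <- dc(4, b) + dc(b, 2 * b) + dc(2 * b, 4 * b) + dc(4 * b, 8 * b) +
    dc(8 * b, 16 * b)
  dec <- dc(16 * b + 8 * b, 8 * b) + dc(8 * b + 4 * b, 4 * b) +
    dc(4 * b + 2 * b, 2 * b) + dc(2 * b + b, b)
  expect_equal(sum(census), enc + dec + (b * 4 + 4))
})

test_that("every trainable tensor receives gradient after one step", {
  setup <- tiny_setup()
  model <- crop_model(setup$cfg, seed = 8)
  p <- setup$patches[[1]]
  x <- p$image; dim(x) <- c(dim(x), 1L)
  y <- p$labels; dim(y) <- c(dim(y), 1L)
  fw <- forward(model, x, labels = y, training = TRUE, with_cache = TRUE)
  ml <- master_loss(fw$probs, y, loss_config(alpha = 1, beta = 1),
                    grad = TRUE)
  plab <- y[, , 1][fw$selection[[1]]$indices]
  cl <- cp_loss(fw$cp_logits, plab, grad = TRUE)
  grads <- cropseg:::net_backward(model, fw, ml$grad, cl$grad)
  trainable <- names(model$params)[cropseg:::is_trainable(names(model$params))]
  expect_setequal(names(grads), trainable)
  for (nm in names(grads)) {
    expect_false(all(grads[[nm]] == 0), info = nm)
  }
})
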
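# Training loop, early stopping, cross-validation and the ablation grid.
# Runs use deliberately tiny models and patch sets.

test_that("early stopping halts after patience non-improving epochs", {
  setup <- tiny_setup()
  sp <- list(train = 1:4, val = 5:6, test = 7:8)
  # lr = 0 freezes the weights, so the monitored metric can never improve
  fit <- train_net(setup$patches, sp, setup$cfg, loss_config(),
                   train_config(lr = 0, epochs = 10L, patience = 1L,
                                batch_size = 2L, seed = 1L))
  expect_equal(fit$stopped_epoch, 2L)
  expect_equal(fit$best_epoch, 1L)
  fit3 <- train_net(setup$patches, sp, setup$cfg, loss_config(),
                    train_config(lr = 0, epochs = 10L, patience = 3L,
                                 batch_size = 2L, seed = 1L))
  expect_equal(fit3$stopped_epoch, 4L)
})

test_that("restored weights come from the best monitored epoch", {
  setup <- tiny_setup()
  sp <- list(train = 1:5, val = 6:7, test = 8L)
  fit <- train_net(setup$patches, sp, setup$cfg, loss_config(),
                   train_config(epochs = 4L, patience = 3L, batch_size = 4L,
                                seed = 2L))
  expect_equal(fit$history$monitor[fit$best_epoch], max(fit$history$monitor))
  expect_lte(fit$best_epoch, fit$stopped_epoch)
  # re-evaluating the returned model reproduces the best validation metric
  oa <- evaluate(fit$model, setup$patches, sp$val)$oa
  expect_equal(oa, max(fit$history$monitor), tolerance = 1e-9)
})

test_that("identical seeds give identical training results", {
  setup <- tiny_setup()
  sp <- list(train = 1:5, val = 6:7, test = 8L)
  run <- function() train_net(setup$patches, sp, setup$cfg, loss_config(),
                              train_config(epochs = 2L, patience = 1L,
                                           batch_size = 4L, seed = 9L))
  a <- run(); b <- run()
  expect_identical(a$report$confusion, b$report$confusion)
  expect_equal(a$history, b$history, tolerance = 0)
  expect_identical(a$best_epoch, b$best_epoch)
  expect_equal(a$model$params, b$model$params, tolerance = 0)
})

test_that("masked pixels affect neither the loss nor the metrics", {
  setup <- tiny_setup()
  p <- setup$patches[[1]]
  p$labels[1:8, 1:8] <- 255L
  model <- crop_model(setup$cfg, seed = 3)
  x <- p$image; dim(x) <- c(dim(x), 1L)
  y <- p$labels; dim(y) <- c(dim(y), 1L)
  fw <- forward(model, x, labels = y, training = TRUE)
  s <- fw$probs
  s2 <- s
  s2[1:8, 1:8, , 1] <- runif(8 * 8 * 4)
  lc <- loss_config(alpha = 1, beta = 1)
  expect_identical(master_loss(s, y, lc), master_loss(s2, y, lc))
  pred <- fw$label_map[, , 1]
  pred2 <- pred
  pred2[1:8, 1:8] <- sample(0:3, 64, TRUE)
  c1 <- accumulate_confusion(pred, p$labels)
  c2 <- accumulate_confusion(pred2, p$labels)
  expect_identical(c1, c2)
})

test_that("training rejects empty splits and patience >= epochs", {
  setup <- tiny_setup()
  expect_error(train_net(setup$patches, list(train = integer(0), val = 1L),
                         setup$cfg), "nonempty")
  expect_error(train_config(epochs = 5L, patience = 5L), "smaller")
})

test_that("cross-validation re-splits per fold and aggregates fold means", {
  setup <- tiny_setup(n = 12L)
  cv <- cross_validate(setup$patches, setup$cfg, loss_config(),
                       train_config(epochs = 2L, patience = 1L,
                                    batch_size = 4L),
                       n_folds = 2L, base_seed = 5L)
  expect_length(cv$folds, 2L)
  expect_false(identical(cv$folds[[1]]$splits, cv$folds[[2]]$splits))
  oas <- vapply(cv$folds, function(f) f$report$oa, 0)
  expect_equal(cv$aggregate$mean[cv$aggregate$metric == "oa"], mean(oas))
  expect_equal(cv$aggregate$sd[cv$aggregate$metric == "oa"], sd(oas))
  expect_error(cross_validate(setup$patches, n_folds = 1L), ">= 2")
})

test_that("the ablation grid is complete and its baseline row is plain", {
  presets <- ablation_presets(base_width = 4L, cp_hidden = c(8L))
  expect_length(presets, 10L)
  base <- presets$Baseline
  expect_equal(base$net$activation, "relu")
  expect_false(base$net$eca)
  expect_false(base$net$cp_enabled)
  expect_equal(base$loss$alpha, 1)
  expect_equal(base$loss$beta, 0)
  full <- presets[["Baseline+Dice+PReLU+ECA+CP(afterECA)"]]
  expect_equal(full$net$activation, "prelu")
  expect_true(full$net$eca && full$net$cp_enabled && full$net$cp_after_eca)
  expect_false(presets[["Baseline+Dice+PReLU+ECA+CP(beforeECA)"]]$net$cp_after_eca)

  setup <- tiny_setup(n = 12L)
  tab <- ablate(setup$patches, presets["Baseline"],
                train_config(epochs = 2L, patience = 1L, batch_size = 4L),
                n_folds = 2L, base_seed = 4L)
  expect_equal(nrow(tab), 1L)
  expect_true(tab$oa > 0 && tab$oa < 100)
  expect_error(ablate(setup$patches, list()), "empty")
})

test_that("the loss sweep presets cover the nine studied ratios", {
  sw <- loss_sweep_presets()
  expect_length(sw, 9L)
  expect_equal(sw$dice$alpha, 0)
  expect_equal(sw$dice$beta, 1)
  expect_equal(sw$ce10_dice1$alpha, 10)
  expect_equal(sw$ce10_dice1$beta, 1)
})
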
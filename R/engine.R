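# Training engine: Adam over the summed two-branch loss, early stopping on
# a monitored validation metric with best-weight restoration, repeated
# random-split cross-validation, and the ablation switchboard.

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam at learning rate 3e-4,
#' up to 150 epochs with batch size 16, early stopping after 20 epochs
#' without improvement of the monitored validation metric (overall
#' accuracy by default), masked pixels ignored throughout.
#'
#' @param lr Adam learning rate.
#' @param epochs Maximum number of epochs.
#' @param batch_size Mini-batch size.
#' @param patience Non-improving epochs tolerated before stopping (must be
#'   `< epochs`).
#' @param seed Seed for weight initialisation; the data-loader shuffle uses
#'   its own stream derived from `seed + 1`.
#' @param monitor `"val_oa"` (maximised) or `"val_loss"` (minimised).
#' @param ignore Ignore label value.
#' @return A `cropseg_train_config`.
#' @export
train_config <- function(lr = 3e-4, epochs = 150L, batch_size = 16L,
                         patience = 20L, seed = 1L,
                         monitor = c("val_oa", "val_loss"),
                         ignore = 255L) {
  monitor <- match.arg(monitor)
  if (patience >= epochs) stop("patience must be smaller than epochs")
  structure(list(lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience), seed = as.integer(seed),
                 monitor = monitor, ignore = as.integer(ignore)),
            class = "cropseg_train_config")
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

config_hash <- function(net_cfg, loss_cfg, train_cfg) {
  s <- paste(deparse(list(net_cfg[order(names(net_cfg))],
                          loss_cfg[order(names(loss_cfg))],
                          train_cfg[order(names(train_cfg))])),
             collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 251)) %% .Machine$integer.max)
}

#' Evaluate a model on a patch set
#'
#' Inference-mode prediction (point refinement applied) scored against the
#' patch labels; ignored pixels never enter the confusion matrix.
#'
#' @param model A `cropseg_model`.
#' @param patches List of patches.
#' @param idx Indices to evaluate (default all).
#' @param batch_size Mini-batch size.
#' @param ignore Ignore label value.
#' @return A `cropseg_metrics` report.
#' @export
evaluate <- function(model, patches, idx = seq_along(patches),
                     batch_size = 16L, ignore = 255L) {
  conf <- matrix(0L, model$cfg$n_classes, model$cfg$n_classes)
  maps <- predict_patches(model, patches, idx, batch_size)
  for (j in seq_along(idx)) {
    conf <- accumulate_confusion(maps[[j]], patches[[idx[j]]]$labels,
                                 ignore, conf)
  }
  summarize_metrics(conf)
}

run_epoch <- function(model, patches, train_idx, loss_cfg, tcfg,
                      adam_state, t0) {
  order_idx <- sample(train_idx)
  total <- 0; nb <- 0; t <- t0
  for (start in seq(1L, length(order_idx), by = tcfg$batch_size)) {
    bi <- order_idx[start:min(start + tcfg$batch_size - 1L,
                              length(order_idx))]
    x <- stack_images(patches, bi)
    y <- stack_labels(patches, bi)
    fw <- forward(model, x, labels = y, training = TRUE,
                  ignore = tcfg$ignore, with_cache = TRUE)
    ml <- master_loss(fw$probs, y, loss_cfg, grad = TRUE)
    loss <- ml$value
    gcp <- NULL
    if (model$cfg$cp_enabled) {
      plab <- unlist(lapply(seq_along(bi), function(n) {
        y[, , n][fw$selection[[n]]$indices]
      }))
      cl <- cp_loss(fw$cp_logits, plab, tcfg$ignore, grad = TRUE)
      loss <- loss + loss_cfg$cp_weight * cl$value
      gcp <- loss_cfg$cp_weight * cl$grad
    }
    if (!is.finite(loss)) {
      stop(sprintf("training diverged: non-finite loss at step %d", t + 1L))
    }
    grads <- net_backward(model, fw, ml$grad, gcp)
    model$params[names(fw$state)] <- fw$state  # batch-norm running stats
    t <- t + 1L
    up <- adam_step(model$params, grads, adam_state, tcfg$lr, t)
    model$params <- up$params
    adam_state <- up$state
    total <- total + loss; nb <- nb + 1
  }
  list(model = model, adam_state = adam_state, t = t,
       train_loss = total / nb)
}

monitor_value <- function(model, patches, idx, loss_cfg, tcfg) {
  if (tcfg$monitor == "val_oa") {
    evaluate(model, patches, idx, tcfg$batch_size, tcfg$ignore)$oa
  } else {
    tot <- 0; n <- 0
    for (start in seq(1L, length(idx), by = tcfg$batch_size)) {
      bi <- idx[start:min(start + tcfg$batch_size - 1L, length(idx))]
      fw <- forward(model, stack_images(patches, bi), training = FALSE)
      tot <- tot + master_loss(fw$probs, stack_labels(patches, bi), loss_cfg)
      n <- n + 1
    }
    -(tot / n)  # negated so "higher is better" uniformly
  }
}

#' Train a model on one split
#'
#' Optimises the summed two-branch loss (master compound loss plus weighted
#' point-branch cross-entropy) with Adam, monitors the validation metric
#' each epoch, stops once `patience` epochs pass without strict
#' improvement, restores the best epoch's weights, and evaluates on the
#' test split when one is given.
#'
#' @param patches List of patches.
#' @param splits List with `train`, `val` and optionally `test` index
#'   vectors (see [split_patches()]).
#' @param net_cfg A [net_config()].
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @return A `cropseg_fit`: the trained `model`, `best_epoch`,
#'   `stopped_epoch`, per-epoch `history`, the test `report` (or `NULL`),
#'   `seed` and `config_hash`.
#' @export
train_net <- function(patches, splits, net_cfg = net_config(),
                      loss_cfg = loss_config(),
                      train_cfg = train_config(), verbose = FALSE) {
  if (length(splits$train) < 1L || length(splits$val) < 1L) {
    stop("train and validation splits must be nonempty")
  }
  model <- crop_model(net_cfg, seed = train_cfg$seed)
  adam_state <- list(m = list(), v = list())
  hist <- data.frame()
  best <- -Inf; best_epoch <- 0L; best_params <- model$params
  bad <- 0L; t <- 0L
  rng_old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(train_cfg$seed + 1L)  # data-loader stream
  on.exit(if (!is.null(rng_old))
    assign(".Random.seed", rng_old, envir = globalenv()))
  stopped_epoch <- train_cfg$epochs
  for (epoch in seq_len(train_cfg$epochs)) {
    ep <- run_epoch(model, patches, splits$train, loss_cfg, train_cfg,
                    adam_state, t)
    model <- ep$model; adam_state <- ep$adam_state; t <- ep$t
    mv <- monitor_value(model, patches, splits$val, loss_cfg, train_cfg)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = ep$train_loss,
                                   monitor = mv))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  %s %.3f", epoch,
                      ep$train_loss, train_cfg$monitor, mv))
    }
    if (mv > best) {
      best <- mv; best_epoch <- epoch; best_params <- model$params
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= train_cfg$patience) { stopped_epoch <- epoch; break }
    }
  }
  model$params <- best_params
  report <- if (length(splits$test %||% integer(0)) > 0L) {
    evaluate(model, patches, splits$test, train_cfg$batch_size,
             train_cfg$ignore)
  } else NULL
  structure(list(model = model, best_epoch = best_epoch,
                 stopped_epoch = stopped_epoch, history = hist,
                 report = report, seed = train_cfg$seed,
                 config_hash = config_hash(net_cfg, loss_cfg, train_cfg)),
            class = "cropseg_fit")
}

#' @export
print.cropseg_fit <- function(x, ...) {
  cat(sprintf("<cropseg_fit> best epoch %d/%d\n", x$best_epoch,
              x$stopped_epoch))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Repeated-random-split cross-validation
#'
#' Runs `n_folds` independent experiments; each re-splits the retained
#' patches with seed `base_seed + fold` (repeated random subsampling at the
#' given ratios, not disjoint k-fold partitions), re-initialises and trains
#' a model, and evaluates on that fold's test split. Aggregates mean and SD
#' of OA/AA/mIoU across folds (macro over folds, each fold summarised from
#' its pooled test confusion matrix).
#'
#' @param patches List of patches.
#' @param net_cfg,loss_cfg,train_cfg Configurations (see [train_net()]).
#' @param n_folds Number of repeated splits (>= 2).
#' @param base_seed Base seed for fold splits and fold-specific model
#'   initialisation.
#' @param ratios Split ratios.
#' @param verbose Print fold progress.
#' @return A `cropseg_cv`: `folds` (list of `cropseg_fit` with `$fold` and
#'   `$splits` recorded) and `aggregate` (data frame of mean/sd per
#'   metric).
#' @export
cross_validate <- function(patches, net_cfg = net_config(),
                           loss_cfg = loss_config(),
                           train_cfg = train_config(), n_folds = 10L,
                           base_seed = 1L, ratios = c(8, 1, 1),
                           verbose = FALSE) {
  if (n_folds < 2L) stop("n_folds must be >= 2")
  folds <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    sp <- split_patches(length(patches), ratios, seed = base_seed + f)
    tc <- train_cfg
    tc$seed <- as.integer(base_seed + 1000L + f)
    fit <- train_net(patches, sp, net_cfg, loss_cfg, tc, verbose = verbose)
    fit$fold <- f
    fit$splits <- sp
    folds[[f]] <- fit
    if (verbose) {
      message(sprintf("fold %d: OA %.2f%%", f, fit$report$oa))
    }
  }
  m <- vapply(folds, function(f) c(f$report$oa, f$report$aa, f$report$miou),
              numeric(3))
  aggregate <- data.frame(metric = c("oa", "aa", "miou"),
                          mean = rowMeans(m),
                          sd = apply(m, 1, sd))
  structure(list(folds = folds, aggregate = aggregate),
            class = "cropseg_cv")
}

#' @export
print.cropseg_cv <- function(x, ...) {
  cat(sprintf("<cropseg_cv> %d folds\n", length(x$folds)))
  print(x$aggregate)
  invisible(x)
}

#' Ablation configuration presets
#'
#' The named network/loss pairs of the module ablation: the baseline (plain
#' bilinear U-Net with ReLU and cross-entropy loss) plus each module alone
#' and the studied combinations, including the point branch fed from
#' before- vs after-attention features.
#'
#' @param base_width Encoder base width for every configuration.
#' @param cp_hidden Point-MLP hidden widths.
#' @return Named list of `list(net = , loss = )` pairs.
#' @export
ablation_presets <- function(base_width = 64L, cp_hidden = c(256L, 256L)) {
  mk <- function(act, dice, eca, cp, after = TRUE) {
    list(net = net_config(base_width = base_width, activation = act,
                          eca = eca, cp_enabled = cp, cp_after_eca = after,
                          cp_hidden = cp_hidden),
         loss = if (dice) loss_config(alpha = 0, beta = 1)
                else loss_config(alpha = 1, beta = 0))
  }
  list(
    "Baseline" = mk("relu", FALSE, FALSE, FALSE),
    "Baseline+PReLU" = mk("prelu", FALSE, FALSE, FALSE),
    "Baseline+Dice" = mk("relu", TRUE, FALSE, FALSE),
    "Baseline+ECA" = mk("relu", FALSE, TRUE, FALSE),
    "Baseline+CP" = mk("relu", FALSE, FALSE, TRUE),
    "Baseline+Dice+ECA" = mk("relu", TRUE, TRUE, FALSE),
    "Baseline+Dice+PReLU+ECA" = mk("prelu", TRUE, TRUE, FALSE),
    "Baseline+Dice+ECA+CP(afterECA)" = mk("relu", TRUE, TRUE, TRUE, TRUE),
    "Baseline+Dice+PReLU+ECA+CP(beforeECA)" =
      mk("prelu", TRUE, TRUE, TRUE, FALSE),
    "Baseline+Dice+PReLU+ECA+CP(afterECA)" =
      mk("prelu", TRUE, TRUE, TRUE, TRUE))
}

#' Run an ablation grid
#'
#' Cross-validates every named configuration and collects the aggregated
#' metrics into one table.
#'
#' @param patches List of patches.
#' @param grid Named list of `list(net = , loss = )` pairs, e.g.
#'   [ablation_presets()].
#' @param train_cfg A [train_config()].
#' @param n_folds,base_seed,ratios Passed to [cross_validate()].
#' @param verbose Print progress.
#' @return Data frame with one row per configuration (OA/AA/mIoU mean and
#'   SD).
#' @export
ablate <- function(patches, grid, train_cfg = train_config(),
                   n_folds = 10L, base_seed = 1L, ratios = c(8, 1, 1),
                   verbose = FALSE) {
  if (length(grid) < 1L) stop("empty ablation grid")
  rows <- lapply(names(grid), function(nm) {
    cv <- cross_validate(patches, grid[[nm]]$net, grid[[nm]]$loss,
                         train_cfg, n_folds, base_seed, ratios, verbose)
    a <- cv$aggregate
    data.frame(config = nm,
               oa = a$mean[a$metric == "oa"], oa_sd = a$sd[a$metric == "oa"],
               aa = a$mean[a$metric == "aa"], aa_sd = a$sd[a$metric == "aa"],
               miou = a$mean[a$metric == "miou"],
               miou_sd = a$sd[a$metric == "miou"])
  })
  do.call(rbind, rows)
}
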
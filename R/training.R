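#' Training configuration
#'
#' Defaults follow the published recipe: Adam with initial learning rate
#' `1e-5` (2D) or `1e-4` (spatio-temporal variants), weight decay `1e-4`,
#' batch size 128 (2D) or 8 (3D/(2+1)D), at most 200 epochs with early
#' stopping on the validation loss (patience 10) and a reduce-on-plateau
#' scheduler.  The scheduler's own factor/patience are not published;
#' the defaults here are factor 0.5, patience 5.
#'
#' @param variant model variant, used only to pick rate/batch defaults.
#' @param learning_rate initial Adam learning rate.
#' @param weight_decay L2 coefficient added to the Adam gradient.
#' @param batch_size training batch size.
#' @param max_epochs maximum epochs.
#' @param early_stop_patience epochs without validation-loss improvement
#'   before stopping; the best-validation weights are restored.
#' @param scheduler_factor,scheduler_patience reduce-on-plateau settings
#'   (monitoring validation loss).
#' @param seed seed for sampling, augmentation and initialisation.
#' @param augment apply the per-clip augmentation pipeline to training
#'   clips.
#' @param weighted_sampler draw training samples with inverse-frequency
#'   weights (with replacement, one dataset-size draw per epoch).
#' @param epoch_size draws per epoch; `NULL` (default) uses the dataset
#'   size.  Smaller values scale an epoch down for CPU budgets.
#' @param prior_masking optional scan-prior list (see [read_priors()]);
#'   when set, disallowed logits are masked with a large negative additive
#'   constant before the loss, per each sample's scan id.
#' @return a `train_config` list.
#' @export
train_config <- function(variant = "2d",
                         learning_rate = if (variant == "2d") 1e-5 else 1e-4,
                         weight_decay = 1e-4,
                         batch_size = if (variant == "2d") 128L else 8L,
                         max_epochs = 200L,
                         early_stop_patience = 10L,
                         scheduler_factor = 0.5,
                         scheduler_patience = 5L,
                         seed = 0L,
                         augment = TRUE,
                         weighted_sampler = TRUE,
                         epoch_size = NULL,
                         prior_masking = NULL) {
  stopifnot(learning_rate > 0, weight_decay >= 0, batch_size >= 1,
            max_epochs >= 1, early_stop_patience < max_epochs)
  structure(list(variant = variant, learning_rate = learning_rate,
                 weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 scheduler_factor = scheduler_factor,
                 scheduler_patience = as.integer(scheduler_patience),
                 seed = as.integer(seed), augment = isTRUE(augment),
                 weighted_sampler = isTRUE(weighted_sampler),
                 epoch_size = if (is.null(epoch_size)) NULL
                              else as.integer(epoch_size),
                 prior_masking = prior_masking),
            class = "train_config")
}

#' Read a training configuration from YAML
#'
#' @param path YAML file whose keys mirror [train_config()].
#' @return a `train_config`.
#' @export
read_train_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(train_config, y[intersect(names(y), names(formals(train_config)))])
}

# softmax cross-entropy over a C x N probability matrix; y is 0-based
cross_entropy <- function(probs, y) {
  n <- ncol(probs)
  p <- probs[cbind(y + 1L, seq_len(n))]
  -mean(log(pmax(p, 1e-12)))
}

# one Adam step over every trainable tensor; weight decay is L2 added to
# the gradient (the torch-style Adam convention)
adam_step <- function(model, lr, wd, step, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^step
  bc2 <- 1 - beta2^step
  upd <- function(ly, par, grad, mslot, vslot) {
    g <- get(grad, envir = ly)
    if (is.null(g)) return(invisible(NULL))
    p <- get(par, envir = ly)
    g <- g + wd * p
    m <- get0(mslot, envir = ly, ifnotfound = NULL)
    v <- get0(vslot, envir = ly, ifnotfound = NULL)
    if (is.null(m)) m <- g * 0
    if (is.null(v)) v <- g * 0
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    assign(mslot, m, envir = ly)
    assign(vslot, v, envir = ly)
    assign(par, p - lr * (m / bc1) / (sqrt(v / bc2) + eps), envir = ly)
  }
  for (ly in model$layers) {
    if (ly$kind == "conv" && !is.null(ly$gW))
      upd(ly, "W", "gW", "mW", "vW")
    if (ly$kind == "bn" && !is.null(ly$ggamma)) {
      upd(ly, "gamma", "ggamma", "mgamma", "vgamma")
      upd(ly, "beta", "gbeta", "mbeta", "vbeta")
    }
  }
  invisible(NULL)
}

zero_grads <- function(model) {
  for (ly in model$layers) {
    ly$gW <- NULL
    ly$ggamma <- NULL
    ly$gbeta <- NULL
  }
  invisible(NULL)
}

# total L2 norm of trainable parameters (used by the weight-decay test)
param_norm <- function(model) {
  s <- 0
  for (ly in model$layers) {
    if (ly$kind == "conv") s <- s + sum(ly$W^2)
    if (ly$kind == "bn") s <- s + sum(ly$gamma^2) + sum(ly$beta^2)
  }
  sqrt(s)
}

# assemble the network input for a set of dataset indices, applying the 2D
# central-frame reduction when the model is 2D, plus optional augmentation
batch_input <- function(dataset, idx, variant, augment = FALSE) {
  clips <- lapply(idx, function(i) {
    x <- dataset$x[[i]]
    if (augment) x <- augment_clip(x)
    if (variant == "2d") {
      ci <- dataset$clips$central_index[i] - dataset$clips$start[i] + 1L
      x <- x[, , ci, drop = FALSE]
    }
    x
  })
  stack_clips(clips)
}

# additive training mask (C x n) from each sample's scan prior; -1e9 keeps
# the loss finite
train_mask <- function(dataset, idx, priors, K) {
  m <- matrix(0, nrow = K, ncol = length(idx))
  for (j in seq_along(idx)) {
    allowed <- priors[[as.character(dataset$clips$scan_id[idx[j]])]]
    m[setdiff(seq_len(K) - 1L, allowed) + 1L, j] <- -1e9
  }
  m
}

mean_val_loss <- function(model, dataset, cfg, K, batch = 32L) {
  n <- length(dataset$y)
  losses <- numeric(0)
  correct <- 0L
  for (b0 in seq(1L, n, by = batch)) {
    idx <- b0:min(n, b0 + batch - 1L)
    x <- batch_input(dataset, idx, model$config$variant, augment = FALSE)
    mask <- if (!is.null(cfg$prior_masking))
      train_mask(dataset, idx, cfg$prior_masking, K) else NULL
    probs <- nn_forward(model, x, training = FALSE, mask = mask)$probs
    losses <- c(losses, cross_entropy(probs, dataset$y[idx]) * length(idx))
    correct <- correct + sum(max.col(t(probs)) - 1L == dataset$y[idx])
  }
  list(loss = sum(losses) / n, acc = correct / n)
}

#' Train a model with the published recipe
#'
#' Optimises softmax cross-entropy with Adam and the inverse-frequency
#' weighted sampler, evaluating the validation loss each epoch.  Training
#' stops at `max_epochs` or after `early_stop_patience` epochs without
#' validation improvement; the best-validation weights are restored.  With
#' `prior_masking` set, logits of classes disallowed for the sample's scan
#' are masked (additively, -1e9) before the loss.
#'
#' @param model a `sononet_model` (modified in place and returned).
#' @param train_set,val_set clip datasets from [build_clip_dataset()].
#' @param config a [train_config()].
#' @return list with `model`, `history` (data.frame epoch, train_loss,
#'   val_loss, val_acc, lr), and `best_epoch`.
#' @export
train_model <- function(model, train_set, val_set, config) {
  stopifnot(inherits(model, "sononet_model"), inherits(config, "train_config"))
  n <- length(train_set$y)
  if (n == 0L || length(val_set$y) == 0L)
    stop("training and validation sets must be non-empty")
  K <- model$config$num_classes
  present <- sort(unique(train_set$y))
  if (length(present) < K)
    warning(sprintf("only %d of %d classes present in the training set; %s",
                    length(present), K,
                    "sampler weights computed over present classes"))
  set.seed(config$seed)
  weights <- if (config$weighted_sampler) sampler_weights(train_set$y)
             else rep(1, n)
  lr <- config$learning_rate
  history <- NULL
  best_loss <- Inf
  best_state <- NULL
  best_epoch <- 0L
  bad_epochs <- 0L
  plateau <- 0L
  step <- 0L
  n_draw <- if (is.null(config$epoch_size)) n else config$epoch_size
  for (epoch in seq_len(config$max_epochs)) {
    order_idx <- sample.int(n, n_draw, replace = TRUE, prob = weights)
    epoch_loss <- 0
    for (b0 in seq(1L, n_draw, by = config$batch_size)) {
      idx <- order_idx[b0:min(n_draw, b0 + config$batch_size - 1L)]
      x <- batch_input(train_set, idx, model$config$variant,
                       augment = config$augment)
      mask <- if (!is.null(config$prior_masking))
        train_mask(train_set, idx, config$prior_masking, K) else NULL
      zero_grads(model)
      fwd <- nn_forward(model, x, training = TRUE, mask = mask, cache = TRUE)
      y <- train_set$y[idx]
      loss <- cross_entropy(fwd$probs, y)
      epoch_loss <- epoch_loss + loss * length(idx)
      onehot <- matrix(0, nrow = K, ncol = length(idx))
      onehot[cbind(y + 1L, seq_along(idx))] <- 1
      dlogits <- (fwd$probs - onehot) / length(idx)
      nn_backward(model, fwd, dlogits)
      step <- step + 1L
      adam_step(model, lr, config$weight_decay, step)
    }
    val <- mean_val_loss(model, val_set, config, K)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = epoch_loss / n_draw, val_loss = val$loss,
      val_acc = val$acc, lr = lr))
    if (val$loss < best_loss - 1e-12) {
      best_loss <- val$loss
      best_state <- snapshot_state(model)
      best_epoch <- epoch
      bad_epochs <- 0L
      plateau <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      plateau <- plateau + 1L
      if (plateau >= config$scheduler_patience) {
        lr <- lr * config$scheduler_factor
        plateau <- 0L
      }
      if (bad_epochs >= config$early_stop_patience) break
    }
  }
  if (!is.null(best_state)) restore_state(model, best_state)
  list(model = model, history = history, best_epoch = best_epoch)
}

#' Write a training history to CSV
#'
#' @param history the `history` data.frame returned by [train_model()].
#' @param path output CSV path.
#' @export
write_history <- function(history, path) {
  write.csv(history, path, row.names = FALSE)
  invisible(path)
}

#' Three-seed hold-out protocol
#'
#' Repeats training over `n_splits` independent train/validation splits
#' (one seed each) while the test set stays fixed, and reports the mean
#' and standard deviation of the test accuracy.
#'
#' @param model_config a [model_config()].
#' @param manifest an exam manifest (see [generate_dataset()] /
#'   [read_manifest()]).
#' @param frames frame store matching the manifest.
#' @param train_cfg a [train_config()]; its seed is replaced by each
#'   split's seed.
#' @param clip_len clip length N.
#' @param n_splits number of splits (>= 2).
#' @param seeds integer seeds, one per split (default `0:(n_splits-1)`).
#' @param test_frac,val_frac split fractions.
#' @return list with `accuracies`, `mean`, `sd` (sample sd over splits),
#'   and the per-split training results.
#' @export
run_holdout <- function(model_config, manifest, frames, train_cfg,
                        clip_len = 10L, n_splits = 3L, seeds = NULL,
                        test_frac = 0.15, val_frac = 0.2) {
  if (n_splits < 2L) stop("n_splits must be >= 2")
  if (is.null(seeds)) seeds <- seq_len(n_splits) - 1L
  stopifnot(length(seeds) == n_splits)
  # fixed test set: drawn once, independent of the per-split seeds
  base_split <- make_splits(manifest, test_frac = test_frac,
                            val_frac = val_frac, seed = 0L)
  test_patients <- base_split$test
  accs <- numeric(n_splits)
  runs <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    split <- make_splits(manifest, test_frac = test_frac,
                         val_frac = val_frac, seed = seeds[s],
                         test_patients = test_patients)
    sets <- lapply(c(train = "train", val = "val", test = "test"),
                   function(part) build_clip_dataset(
                     manifest, clip_len, frames,
                     patients = split[[part]]))
    cfg <- train_cfg
    cfg$seed <- as.integer(seeds[s])
    model <- build_model(model_config, seed = seeds[s])
    fit <- train_model(model, sets$train, sets$val, cfg)
    ev <- mean_val_loss(fit$model, sets$test, cfg, model_config$num_classes)
    accs[s] <- ev$acc
    runs[[s]] <- fit
  }
  list(accuracies = accs, mean = mean(accs), sd = sd(accs), runs = runs)
}
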
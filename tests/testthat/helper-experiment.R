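# The pulsating-vs-static discrimination experiment backing the
# substituted acceptance criteria: tiny models (B = 8) on 64x64, N = 10
# clips from 20 synthetic patients, restricted to the {Heart, Other}
# subset whose classes differ only in temporal dynamics.
#
# The training recipe is the published one scaled down for a single CPU:
# no augmentation, lr 1e-3, 448 weighted draws per epoch, 2 epochs.
# Results are memoised so several acceptance tests can share one run.

experiment_cache <- new.env(parent = emptyenv())

run_discrimination_experiment <- function(seed = 0L) {
  key <- paste0("seed", seed)
  if (!is.null(experiment_cache[[key]])) return(experiment_cache[[key]])
  ds <- generate_dataset(20L, seed = seed)
  split <- make_splits(ds$manifest, seed = seed)
  sets <- lapply(c(train = "train", val = "val", test = "test"),
                 function(p) build_clip_dataset(ds$manifest, 10L, ds$frames,
                                                patients = split[[p]],
                                                labels_keep = c(3L, 6L)))
  fit_one <- function(variant, batch) {
    cfg <- train_config(variant, learning_rate = 1e-3, batch_size = batch,
                        max_epochs = 2L, early_stop_patience = 1L,
                        seed = seed, augment = FALSE, epoch_size = 448L)
    model <- build_model(model_config(variant, base_filters = 8L),
                         seed = seed)
    fit <- train_model(model, sets$train, sets$val, cfg)
    acc <- sononet:::mean_val_loss(fit$model, sets$test, cfg, 7L)$acc
    list(model = fit$model, acc = acc)
  }
  res <- list(
    data = ds, split = split, sets = sets,
    r2d = suppressWarnings(fit_one("2d", 32L)),
    r3d = suppressWarnings(fit_one("3d", 8L)),
    r21 = suppressWarnings(fit_one("2p1d", 8L)))
  experiment_cache[[key]] <- res
  res
}
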
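#' Build an executable network from a configuration
#'
#' Materialises the layer-spec list of `config` into an executable network:
#' convolution weights are allocated (He initialisation, no biases) and
#' batch-normalisation layers get unit scale / zero shift with running
#' statistics.  Layers are environments so that training updates them in
#' place.
#'
#' Tensors are R arrays laid out `(H, W, T, C, N)`.  The 2D variant is the
#' degenerate case `T = 1`.
#'
#' @param config a [model_config()].
#' @param seed integer seed controlling weight initialisation.
#' @return a `sononet_model`: list with `config`, `specs` (declarative
#'   layer list) and `layers` (executable layers).
#' @examples
#' m <- build_model(model_config("2d", base_filters = 4, num_classes = 3,
#'                               input_size = c(32, 32)))
#' x <- array(0, c(32, 32, 1, 1, 2))
#' p <- predict_proba(m, x)
#' rowSums(p)  # 1 1
#' @export
build_model <- function(config, seed = 0L) {
  stopifnot(inherits(config, "sononet_config"))
  specs <- build_layer_specs(config)
  if (!is.null(seed)) set.seed(as.integer(seed))
  layers <- lapply(specs, function(s) {
    e <- new.env(parent = emptyenv())
    e$kind <- s$kind
    e$spec <- s
    if (s$kind == "conv") {
      K <- prod(s$kernel) * s$in_channels
      e$W <- matrix(rnorm(K * s$out_channels, sd = sqrt(2 / K)),
                    nrow = K, ncol = s$out_channels)
    } else if (s$kind == "bn") {
      C <- s$out_channels
      e$gamma <- rep(1, C)
      e$beta <- rep(0, C)
      e$running_mean <- rep(0, C)
      e$running_var <- rep(1, C)
      e$momentum <- 0.1
      e$eps <- 1e-5
    }
    e
  })
  structure(list(config = config, specs = specs, layers = layers),
            class = "sononet_model")
}

#' @export
print.sononet_model <- function(x, ...) {
  cat(sprintf("sononet model (%s, B=%d, C=%d): %s trainable parameters\n",
              x$config$variant, x$config$base_filters, x$config$num_classes,
              format(count_params_enumerate(x), big.mark = ",")))
  invisible(x)
}

# Forward pass.  `x` is (H, W, T, C_in, N); `mask` is an optional additive
# logit mask, either a length-C vector or a C x N matrix (use large
# negative values to inhibit classes).  Returns probs/logits (C x N) and,
# when `cache = TRUE`, the per-layer activations and auxiliaries needed by
# the backward pass.
nn_forward <- function(model, x, training = FALSE, mask = NULL,
                       cache = FALSE) {
  cfg <- model$config
  d <- dim(x)
  if (length(d) != 5L)
    stop("input must be a 5-d array (H, W, T, C, N)")
  if (d[4] != cfg$in_channels)
    stop(sprintf("input has %d channels, config expects %d", d[4],
                 cfg$in_channels))
  a <- x
  acts <- if (cache) vector("list", length(model$layers)) else NULL
  aux <- if (cache) vector("list", length(model$layers)) else NULL
  logits <- NULL
  stage <- 0L
  nL <- length(model$layers)
  # a BN immediately followed by ReLU is computed in one fused pass
  kinds <- vapply(model$layers, function(l) l$kind, character(1))
  fuse_bn <- kinds == "bn" & c(kinds[-1], "") == "relu"
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (cache) acts[[i]] <- a
    if (ly$kind == "conv") {
      a <- .conv3d_forward(a, dim(a), ly$W, ly$spec$kernel, ly$spec$padding)
    } else if (ly$kind == "bn") {
      r <- .bn_forward(a, dim(a), ly$gamma, ly$beta, ly$running_mean,
                       ly$running_var, training, ly$momentum, ly$eps,
                       fuse_relu = fuse_bn[i])
      if (training) {
        ly$running_mean <- r$running_mean
        ly$running_var <- r$running_var
      }
      if (cache) aux[[i]] <- list(mean = r$mean, invstd = r$invstd)
      a <- r$y
    } else if (ly$kind == "relu") {
      if (i == 1L || !fuse_bn[i - 1L]) a <- .relu_forward(a)
      # else: already applied inside the preceding fused BN
    } else if (ly$kind == "pool") {
      stage <- stage + 1L
      dd <- dim(a)
      k <- ly$spec$kernel
      if (any(dd[c(3L, 1L, 2L)] %/% k < 1L))
        stop(sprintf(
          "input of shape (%d,%d,%d) collapses to zero at pooling stage %d",
          dd[3], dd[1], dd[2], stage))
      r <- .maxpool3d_forward(a, dd, k)
      if (cache) aux[[i]] <- list(idx = r$idx, in_dim = dd)
      a <- r$y
    } else if (ly$kind == "avgpool") {
      dd <- dim(a)
      if (cache) aux[[i]] <- list(in_dim = dd)
      m <- a
      dim(m) <- c(prod(dd[1:3]), dd[4] * dd[5])
      a <- matrix(colMeans(m), nrow = dd[4], ncol = dd[5])
    } else if (ly$kind == "softmax") {
      if (!is.null(mask)) a <- a + mask
      logits <- a
      z <- sweep(a, 2L, apply(a, 2L, max))
      ez <- exp(z)
      a <- sweep(ez, 2L, colSums(ez), "/")
    }
  }
  list(probs = a, logits = logits, acts = acts, aux = aux)
}

# Backward pass from d(loss)/d(logits); accumulates gradients into the
# layer environments (fields gW / ggamma / gbeta).
nn_backward <- function(model, fwd, dlogits) {
  da <- dlogits
  kinds <- vapply(model$layers, function(l) l$kind, character(1))
  fuse_bn <- kinds == "bn" & c(kinds[-1], "") == "relu"
  relu_mask <- NULL  # pending fused-ReLU output for the next BN backward
  for (i in rev(seq_along(model$layers))) {
    ly <- model$layers[[i]]
    a_in <- fwd$acts[[i]]
    if (ly$kind == "softmax") {
      next  # folded into the cross-entropy gradient
    } else if (ly$kind == "avgpool") {
      dd <- fwd$aux[[i]]$in_dim
      S <- prod(dd[1:3])
      dmat <- matrix(0, nrow = S, ncol = dd[4] * dd[5])
      dmat[] <- rep(as.vector(da) / S, each = S)
      dim(dmat) <- dd
      da <- dmat
    } else if (ly$kind == "pool") {
      da <- .maxpool3d_backward(da, fwd$aux[[i]]$idx, fwd$aux[[i]]$in_dim)
    } else if (ly$kind == "relu") {
      if (i > 1L && fuse_bn[i - 1L]) {
        # defer the mask to the preceding BN's backward pass
        relu_mask <- fwd$acts[[i + 1L]]
      } else {
        da <- .relu_backward(da, a_in)
      }
    } else if (ly$kind == "bn") {
      r <- .bn_backward(da, a_in, dim(a_in), ly$gamma,
                        fwd$aux[[i]]$mean, fwd$aux[[i]]$invstd,
                        relu_y = if (fuse_bn[i]) relu_mask
                                 else numeric(0))
      relu_mask <- NULL
      ly$ggamma <- if (is.null(ly$ggamma)) r$dgamma else ly$ggamma + r$dgamma
      ly$gbeta <- if (is.null(ly$gbeta)) r$dbeta else ly$gbeta + r$dbeta
      da <- r$dx
    } else if (ly$kind == "conv") {
      r <- .conv3d_backward(a_in, dim(a_in), ly$W, ly$spec$kernel,
                            ly$spec$padding, da, need_dx = i > 1L)
      ly$gW <- if (is.null(ly$gW)) r$dw else ly$gW + r$dw
      da <- r$dx
    }
  }
  invisible(NULL)
}

#' Class probabilities for a batch
#'
#' @param model a `sononet_model`.
#' @param x array `(H, W, T, C_in, N)`; for the 2D variant use `T = 1`.
#' @param mask optional additive logit mask (length-C vector or C x N
#'   matrix); see [mask_logits()].
#' @return N x C matrix of probabilities, rows summing to 1.
#' @export
predict_proba <- function(model, x, mask = NULL) {
  t(nn_forward(model, x, training = FALSE, mask = mask)$probs)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single RDS file with the config and all layer
#' parameters (including BN running statistics).
#'
#' @param model a `sononet_model`.
#' @param path file path.
#' @return `save_checkpoint`: the path, invisibly.  `load_checkpoint`: the
#'   restored `sononet_model`.
#' @export
save_checkpoint <- function(model, path) {
  state <- lapply(model$layers, function(ly) {
    if (ly$kind == "conv") list(W = ly$W)
    else if (ly$kind == "bn") list(gamma = ly$gamma, beta = ly$beta,
                                   running_mean = ly$running_mean,
                                   running_var = ly$running_var)
    else list()
  })
  saveRDS(list(config = model$config, state = state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config, seed = 0L)
  restore_state(model, ck$state)
  model
}

# copy a saved state into a model's layer environments
restore_state <- function(model, state) {
  stopifnot(length(state) == length(model$layers))
  for (i in seq_along(state)) {
    for (nm in names(state[[i]])) assign(nm, state[[i]][[nm]],
                                         envir = model$layers[[i]])
  }
  invisible(model)
}

# snapshot of all trainable + running parameters (used for best-epoch
# restore during early stopping)
snapshot_state <- function(model) {
  lapply(model$layers, function(ly) {
    if (ly$kind == "conv") list(W = ly$W)
    else if (ly$kind == "bn") list(gamma = ly$gamma, beta = ly$beta,
                                   running_mean = ly$running_mean,
                                   running_var = ly$running_var)
    else list()
  })
}

#' Stack a list of clips into a network input batch
#'
#' @param clips list of `(H, W, T)` arrays (or `(H, W)` matrices for
#'   single frames), already normalised to `[0, 1]`.
#' @return array `(H, W, T, 1, N)`.
#' @export
stack_clips <- function(clips) {
  d <- dim(clips[[1]])
  if (length(d) == 2L) d <- c(d, 1L)
  out <- array(0, dim = c(d[1], d[2], d[3], 1L, length(clips)))
  for (i in seq_along(clips)) out[, , , 1L, i] <- clips[[i]]
  out
}
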
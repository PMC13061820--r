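#' Declarative layer specifications
#'
#' The executable network and the audit module share a single declarative
#' representation: a flat list of primitive layers (`conv`, `bn`, `relu`,
#' `pool`, `avgpool`, `softmax`).  Convolutions never carry biases -- the
#' batch normalisation that follows each one supplies the shift.
#'
#' @param kind one of `"conv"`, `"bn"`, `"relu"`, `"pool"`, `"avgpool"`,
#'   `"softmax"`.
#' @param in_channels,out_channels channel counts (convolutions and BN).
#' @param kernel length-3 integer `(k_t, k_h, k_w)`.
#' @param stride length-3 integer stride (always 1 for convolutions;
#'   pooling uses kernel == stride).
#' @param padding length-3 integer symmetric padding.
#' @param has_bias logical; convolutions in this family are bias-free.
#' @param stage `"extractor"` or `"adaptation"`, for structural queries.
#' @param block integer id of the originating 3x3(x3) convolution slot
#'   (1..13), `NA` for adaptation layers.
#' @return a `layer_spec` list.
#' @export
layer_spec <- function(kind, in_channels = NA_integer_,
                       out_channels = NA_integer_,
                       kernel = c(1L, 1L, 1L), stride = c(1L, 1L, 1L),
                       padding = c(0L, 0L, 0L), has_bias = FALSE,
                       stage = "extractor", block = NA_integer_) {
  kinds <- c("conv", "bn", "relu", "pool", "avgpool", "softmax")
  if (!kind %in% kinds)
    stop(sprintf("unknown layer kind '%s'", kind))
  if (any(kernel < 1L)) stop("kernel entries must be >= 1")
  if (kind == "conv" && isTRUE(has_bias))
    stop("convolutions are bias-free in this architecture (BN supplies the shift)")
  structure(list(kind = kind,
                 in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel = as.integer(kernel),
                 stride = as.integer(stride),
                 padding = as.integer(padding),
                 has_bias = isTRUE(has_bias),
                 stage = stage,
                 block = as.integer(block)),
            class = "layer_spec")
}

#' Channel plan of the VGG16-style feature extractor
#'
#' The trunk has 13 convolution slots in blocks of 2-2-3-3-3 with a
#' max-pooling after each of the first four blocks.  Widths start at the
#' base width `B`, double after each of the first three pools, and stay at
#' `8B` in the fifth block (no doubling after the last pool) -- the plan
#' that reproduces the published parameter counts of all three 2D base
#' widths exactly.
#'
#' @param base_filters base width `B`.
#' @param in_channels input channels of the first convolution.
#' @return a list of 13 `c(in, out)` integer pairs.
#' @examples
#' plan_channels(32)[[1]]   # c(1, 32)
#' plan_channels(32)[[13]]  # c(256, 256)
#' @export
plan_channels <- function(base_filters, in_channels = 1L) {
  B <- as.integer(base_filters)
  if (is.na(B) || B < 1L)
    stop("invalid config: base_filters must be a positive integer")
  outs <- c(B, B, 2L * B, 2L * B, 4L * B, 4L * B, 4L * B,
            8L * B, 8L * B, 8L * B, 8L * B, 8L * B, 8L * B)
  ins <- c(as.integer(in_channels), outs[-13L])
  lapply(seq_len(13L), function(i) c(ins[i], outs[i]))
}

# pooling sits after these convolution slots (blocks 2-2-3-3-3, 4 pools)
.pool_after <- c(2L, 4L, 7L, 10L)

#' Adaptation module layer specs
#'
#' The fully connected head of VGG16 is replaced by two pointwise
#' convolutions: `8B -> 4B` (BN + ReLU) then `4B -> C` (BN), followed by a
#' global average pool over every remaining spatial(-temporal) position
#' and a softmax.  Pointwise kernels are dimension-free, so the 2D and 3D
#' adaptation modules have identical parameter counts.
#'
#' @param base_filters base width `B` of the trunk.
#' @param num_classes number of classes `C`.
#' @param dims 2 or 3 (controls only the kernel triplet notation).
#' @return list of `layer_spec`s.
#' @export
build_adaptation <- function(base_filters, num_classes, dims = 2L) {
  B <- as.integer(base_filters)
  C <- as.integer(num_classes)
  if (is.na(B) || B < 1L || is.na(C) || C < 1L)
    stop("invalid config: base_filters and num_classes must be positive")
  k1 <- c(1L, 1L, 1L)
  list(
    layer_spec("conv", 8L * B, 4L * B, kernel = k1, stage = "adaptation"),
    layer_spec("bn", 4L * B, 4L * B, stage = "adaptation"),
    layer_spec("relu", stage = "adaptation"),
    layer_spec("conv", 4L * B, C, kernel = k1, stage = "adaptation"),
    layer_spec("bn", C, C, stage = "adaptation"),
    layer_spec("avgpool", stage = "adaptation"),
    layer_spec("softmax", stage = "adaptation")
  )
}

#' Mid-channel width of the parameter-matched (2+1)D block
#'
#' Factorizing a `k_t x k_h x k_w` convolution with `n_in` inputs and
#' `n_out` outputs into a spatial and a temporal convolution introduces an
#' intermediate width `M`.  Choosing
#' `M = floor(k_t*k_h*k_w*n_in*n_out / (k_h*k_w*n_in + k_t*n_out))`
#' makes the factorized pair carry approximately as many weights as the
#' full 3D kernel ("star" variant).
#'
#' @param n_in,n_out channel counts of the original 3D convolution.
#' @param k_t,k_h,k_w kernel extents (default 3).
#' @return integer `M >= 1`.
#' @examples
#' midplanes_star(256, 256)  # 576
#' midplanes_star(1, 32)     # 8
#' @export
midplanes_star <- function(n_in, n_out, k_t = 3L, k_h = 3L, k_w = 3L) {
  if (any(c(n_in, n_out, k_t, k_h, k_w) < 1L))
    stop("invalid config: channels and kernel extents must be >= 1")
  M <- (k_t * k_h * k_w * n_in * n_out) %/% (k_h * k_w * n_in + k_t * n_out)
  max(1L, as.integer(M))
}

#' Spatio-temporal ((2+1)D) block specification
#'
#' One 3D convolution slot becomes: spatial convolution `(1, k_h, k_w)`
#' `n_in -> M`, optional BN(M), ReLU, temporal convolution `(k_t, 1, 1)`
#' `M -> n_out`.  The ReLU between the two convolutions doubles the
#' nonlinearity without adding parameters.  `mid_rule = "plain"` sets
#' `M = n_out` (size derived directly from the 3D trunk); `"star"` uses
#' [midplanes_star()].
#'
#' @param n_in,n_out channel counts.
#' @param mid_rule `"plain"` or `"star"`.
#' @param mid_bn keep the intermediate batch normalisation.
#' @param k_t temporal kernel extent.
#' @return an `st_block_spec` list with fields `n_in`, `n_out`,
#'   `mid_channels`, `mid_bn`, `spatial_kernel`, `temporal_kernel`,
#'   `weight_total`.
#' @export
make_st_block <- function(n_in, n_out, mid_rule = c("plain", "star"),
                          mid_bn = TRUE, k_t = 3L) {
  mid_rule <- match.arg(mid_rule)
  if (any(c(n_in, n_out) < 1L))
    stop("invalid config: channels must be >= 1")
  M <- if (mid_rule == "plain") as.integer(n_out)
       else midplanes_star(n_in, n_out, k_t = k_t)
  wt <- 9L * n_in * M + k_t * M * n_out + if (isTRUE(mid_bn)) 2L * M else 0L
  structure(list(n_in = as.integer(n_in), n_out = as.integer(n_out),
                 mid_channels = M, mid_bn = isTRUE(mid_bn),
                 spatial_kernel = c(1L, 3L, 3L),
                 temporal_kernel = c(as.integer(k_t), 1L, 1L),
                 weight_total = as.integer(wt)),
            class = "st_block_spec")
}

#' Full layer-spec list for a model configuration
#'
#' Expands a [model_config()] into the flat list of primitive layers that
#' both the executable network and the audit share.  For 2d/3d variants
#' each of the 13 trunk slots is conv + BN + ReLU; for (2+1)D variants it
#' is spatial conv + (optional BN) + ReLU + temporal conv + BN + ReLU.
#'
#' @param config a `sononet_config`.
#' @return list of `layer_spec`s.
#' @export
build_layer_specs <- function(config) {
  stopifnot(inherits(config, "sononet_config"))
  pairs <- plan_channels(config$base_filters, config$in_channels)
  kt <- config$temporal_extent
  conv_kernel <- switch(config$variant,
                        "2d" = c(1L, 3L, 3L),
                        "3d" = c(kt, 3L, 3L),
                        c(kt, 3L, 3L))  # factorized below for 2p1d
  mid_rule <- if (config$variant == "2p1d_star") "star" else "plain"
  specs <- list()
  for (i in seq_len(13L)) {
    nin <- pairs[[i]][1L]; nout <- pairs[[i]][2L]
    if (config$variant %in% c("2d", "3d")) {
      k <- conv_kernel
      specs <- c(specs, list(
        layer_spec("conv", nin, nout, kernel = k,
                   padding = (k - 1L) %/% 2L, block = i),
        layer_spec("bn", nout, nout, block = i),
        layer_spec("relu", block = i)))
    } else {
      blk <- make_st_block(nin, nout, mid_rule = mid_rule,
                           mid_bn = config$mid_bn, k_t = kt)
      M <- blk$mid_channels
      specs <- c(specs, list(
        layer_spec("conv", nin, M, kernel = blk$spatial_kernel,
                   padding = (blk$spatial_kernel - 1L) %/% 2L, block = i)))
      if (config$mid_bn)
        specs <- c(specs, list(layer_spec("bn", M, M, block = i)))
      specs <- c(specs, list(
        layer_spec("relu", block = i),
        layer_spec("conv", M, nout, kernel = blk$temporal_kernel,
                   padding = (blk$temporal_kernel - 1L) %/% 2L, block = i),
        layer_spec("bn", nout, nout, block = i),
        layer_spec("relu", block = i)))
    }
    if (i %in% .pool_after) {
      stagei <- match(i, .pool_after)
      pk <- config$pool_schedule[stagei, ]
      specs <- c(specs, list(
        layer_spec("pool", kernel = pk, stride = pk, block = i)))
    }
  }
  c(specs, build_adaptation(config$base_filters, config$num_classes,
                            dims = if (config$variant == "2d") 2L else 3L))
}

#' Count layers of one kind in a spec list
#'
#' @param specs list of `layer_spec`s (e.g. from [build_layer_specs()]).
#' @param kind layer kind to count.
#' @param stage optionally restrict to `"extractor"` or `"adaptation"`.
#' @return integer count.
#' @export
count_layers <- function(specs, kind, stage = NULL) {
  sum(vapply(specs, function(s) {
    s$kind == kind && (is.null(stage) || s$stage == stage)
  }, logical(1)))
}

#' Export an architecture summary as JSON
#'
#' Writes every layer spec with its per-layer parameter count.
#'
#' @param config a `sononet_config`.
#' @param path output JSON path.
#' @return the summary list, invisibly.
#' @export
export_architecture <- function(config, path) {
  specs <- build_layer_specs(config)
  rows <- lapply(specs, function(s) {
    list(kind = s$kind, stage = s$stage, block = s$block,
         in_channels = s$in_channels, out_channels = s$out_channels,
         kernel = s$kernel, stride = s$stride, padding = s$padding,
         params = layer_param_count(s))
  })
  out <- list(config = unclass(config)[c("variant", "base_filters",
                                         "num_classes", "in_channels",
                                         "clip_len", "mid_bn")],
              total_params = count_params_closed_form(specs),
              layers = rows)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
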
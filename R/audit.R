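#' Per-layer trainable parameter count
#'
#' @param spec a `layer_spec`.
#' @return integer parameter count (0 for parameter-free layers).
#' @export
layer_param_count <- function(spec) {
  switch(spec$kind,
         conv = {
           n <- prod(spec$kernel) * spec$in_channels * spec$out_channels
           if (spec$has_bias) n <- n + spec$out_channels
           as.integer(n)
         },
         bn = 2L * spec$out_channels,
         relu = 0L, pool = 0L, avgpool = 0L, softmax = 0L,
         stop(sprintf("unknown layer kind '%s'", spec$kind)))
}

#' Closed-form parameter count of a layer-spec list
#'
#' Sums `k_t*k_h*k_w*in*out` (+ `out` if biased) over convolutions and
#' `2*channels` over batch-normalisation layers.
#'
#' @param layers list of `layer_spec`s.
#' @return integer total.
#' @examples
#' cfg <- model_config("2d", base_filters = 32)
#' count_params_closed_form(build_layer_specs(cfg))  # 3715630
#' @export
count_params_closed_form <- function(layers) {
  if (length(layers) == 0L) return(0L)
  sum(vapply(layers, layer_param_count, integer(1)))
}

#' Enumerated parameter count of a built network
#'
#' Walks the executable network's tensors and sums their sizes -- the
#' independent oracle for [count_params_closed_form()].  Running BN
#' statistics are not trainable and are excluded.
#'
#' @param model a `sononet_model` from [build_model()].
#' @return integer total.
#' @export
count_params_enumerate <- function(model) {
  stopifnot(inherits(model, "sononet_model"))
  total <- 0L
  for (ly in model$layers) {
    if (ly$kind == "conv") total <- total + length(ly$W)
    if (ly$kind == "bn") total <- total + length(ly$gamma) + length(ly$beta)
  }
  total
}

#' Multiply-accumulate estimate for one input
#'
#' Per convolution, MACs = weight count x number of output positions,
#' tracking the shape through same-padded stride-1 convolutions and
#' floor-divided pooling.  BN, activations, and pooling are counted as 0.
#'
#' @param layers list of `layer_spec`s.
#' @param input_shape `c(T, H, W)` of one input sample (use `T = 1` for
#'   the 2D variant).
#' @return MAC count (double; can exceed integer range).
#' @export
estimate_macs <- function(layers, input_shape) {
  shp <- as.integer(input_shape)
  if (length(shp) != 3L || any(shp < 1L))
    stop("input_shape must be c(T, H, W) with positive entries")
  macs <- 0
  for (s in layers) {
    if (s$kind == "conv") {
      macs <- macs + prod(s$kernel) * s$in_channels * s$out_channels *
        prod(shp)
    } else if (s$kind == "pool") {
      shp <- shp %/% s$kernel
      if (any(shp < 1L))
        stop(sprintf(
          "input shape collapses to zero at a pooling layer (block %d)",
          s$block))
    } else if (s$kind == "avgpool") {
      shp <- c(1L, 1L, 1L)
    }
  }
  macs
}

#' Architecture audit report
#'
#' Computes the closed-form and enumerated parameter counts and a MAC /
#' G-FLOP estimate (1 MAC = 2 FLOPs; BN, activations and pooling excluded)
#' for a configuration at a stated input shape.  The two parameter counts
#' must agree; published G-FLOP figures depend on an unstated input
#' resolution and convention, so the report prints the computed value
#' without asserting equality to any external figure.
#'
#' @param config a `sononet_config`.
#' @param input_shape `c(T, H, W)`; defaults to the config's clip length
#'   and input size.
#' @param seed seed for the (cheap) weight allocation of the enumeration.
#' @return an `audit_report` list.
#' @examples
#' rep <- audit_model(model_config("2d", base_filters = 16))
#' rep$param_count_closed  # 930334
#' @export
audit_model <- function(config, input_shape = NULL, seed = 0L) {
  stopifnot(inherits(config, "sononet_config"))
  if (is.null(input_shape))
    input_shape <- c(config$clip_len, config$input_size)
  specs <- build_layer_specs(config)
  model <- build_model(config, seed = seed)
  closed <- count_params_closed_form(specs)
  enum <- count_params_enumerate(model)
  if (closed != enum)
    stop(sprintf("parameter count mismatch: closed %d vs enumerated %d",
                 closed, enum))
  macs <- estimate_macs(specs, input_shape)
  structure(list(config = config,
                 param_count_closed = closed,
                 param_count_enumerated = enum,
                 macs = macs,
                 gflops = 2 * macs / 1e9,
                 input_shape = as.integer(input_shape)),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("%s B=%d C=%d: %s params, %.2f GFLOPs at input (%s)\n",
              x$config$variant, x$config$base_filters, x$config$num_classes,
              format(x$param_count_closed, big.mark = ","),
              x$gflops, paste(x$input_shape, collapse = "x")))
  invisible(x)
}

#' Write an audit report to JSON
#'
#' @param report an `audit_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_audit_report <- function(report, path) {
  out <- list(
    config = unclass(report$config)[c("variant", "base_filters",
                                      "num_classes", "in_channels",
                                      "clip_len", "mid_bn")],
    param_count_closed = report$param_count_closed,
    param_count_enumerated = report$param_count_enumerated,
    macs = report$macs,
    gflops = report$gflops,
    input_shape = report$input_shape)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
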
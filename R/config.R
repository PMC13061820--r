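#' Model configuration for the SonoNet family
#'
#' A `ModelConfig` fully determines one architecture of the family: the 2D
#' baseline, the 3D lift, or a (2+1)D factorized variant.  The base width
#' `B` is the number of filters of the first convolution (16/32/64 are the
#' canonical choices); widths double after each of the first three pooling
#' stages and stay at `8B` in the last block.
#'
#' @param variant `"2d"`, `"3d"`, `"2p1d"` (spatial-then-temporal
#'   factorization with mid width `M = n_out`), or `"2p1d_star"` (mid width
#'   chosen to approximately match the 3D parameter count).
#' @param base_filters positive integer, filters of the first convolution.
#' @param num_classes positive integer, output classes `C`.
#' @param in_channels positive integer, input image channels (1 for
#'   grayscale ultrasound).
#' @param clip_len frames per clip `N`; ignored for the 2D variant.
#' @param mid_bn logical; keep the batch normalisation between the spatial
#'   and temporal convolution of a (2+1)D block.  `FALSE` reproduces the
#'   "without BN" ablation.  Ignored for 2d/3d.
#' @param pool_schedule 4x3 integer matrix of pooling kernels/strides,
#'   one row per pooling stage, columns (temporal, height, width).  The
#'   default for spatio-temporal variants is `(1,2,2)` then three
#'   `(2,2,2)`, so a 10-frame clip shrinks 10 -> 10 -> 5 -> 2 -> 1; the 2D
#'   variant always pools `(1,2,2)`.
#' @param temporal_extent temporal kernel size `k_t` of the 3D (or
#'   factorized temporal) convolutions, default 3.
#' @param input_size `c(H, W)` expected input resolution, used for shape
#'   validation and MAC estimates (the synthetic default is 64x64).
#'
#' @return an object of class `sononet_config`.
#' @examples
#' cfg <- model_config("3d", base_filters = 32, num_classes = 7)
#' cfg$clip_len
#' @export
model_config <- function(variant = c("2d", "3d", "2p1d", "2p1d_star"),
                         base_filters = 32L,
                         num_classes = 7L,
                         in_channels = 1L,
                         clip_len = 10L,
                         mid_bn = TRUE,
                         pool_schedule = NULL,
                         temporal_extent = 3L,
                         input_size = c(64L, 64L)) {
  variant <- match.arg(variant)
  base_filters <- as.integer(base_filters)
  num_classes <- as.integer(num_classes)
  in_channels <- as.integer(in_channels)
  clip_len <- as.integer(clip_len)
  if (is.na(base_filters) || base_filters < 1L)
    stop("invalid config: base_filters must be a positive integer")
  if (is.na(num_classes) || num_classes < 1L)
    stop("invalid config: num_classes must be a positive integer")
  if (is.na(in_channels) || in_channels < 1L)
    stop("invalid config: in_channels must be a positive integer")
  if (variant == "2d") {
    pool_schedule <- matrix(rep(c(1L, 2L, 2L), 4L), nrow = 4L, byrow = TRUE)
    clip_len <- 1L
  } else {
    if (is.na(clip_len) || clip_len < 1L)
      stop("invalid config: clip_len must be a positive integer")
    if (is.null(pool_schedule))
      pool_schedule <- rbind(c(1L, 2L, 2L), c(2L, 2L, 2L),
                             c(2L, 2L, 2L), c(2L, 2L, 2L))
  }
  pool_schedule <- matrix(as.integer(pool_schedule), nrow = 4L)
  if (ncol(pool_schedule) != 3L || any(pool_schedule < 1L))
    stop("invalid config: pool_schedule must be a 4x3 matrix of kernels >= 1")
  # the clip length must survive all four pooling stages
  t <- clip_len
  for (s in seq_len(4L)) {
    t <- t %/% pool_schedule[s, 1L]
    if (t < 1L)
      stop(sprintf(
        "invalid config: clip_len %d collapses to zero frames at pooling stage %d",
        clip_len, s))
  }
  structure(list(
    variant = variant,
    base_filters = base_filters,
    num_classes = num_classes,
    in_channels = in_channels,
    clip_len = clip_len,
    mid_bn = isTRUE(mid_bn),
    pool_schedule = pool_schedule,
    temporal_extent = as.integer(temporal_extent),
    input_size = as.integer(input_size)
  ), class = "sononet_config")
}

#' @export
print.sononet_config <- function(x, ...) {
  cat(sprintf("SonoNet config: variant=%s B=%d C=%d in=%d N=%d mid_bn=%s\n",
              x$variant, x$base_filters, x$num_classes, x$in_channels,
              x$clip_len, x$mid_bn))
  invisible(x)
}

#' Read a model configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [model_config()].
#'
#' @param path path to a YAML file.
#' @return a `sononet_config`.
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(model_config, y[intersect(names(y), names(formals(model_config)))])
}
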
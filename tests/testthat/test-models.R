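# architecture construction: channel plan, adaptation, (2+1)D blocks

test_that("plan_channels produces the halved-VGG plan", {
  p32 <- plan_channels(32, 1)
  expect_length(p32, 13L)
  expect_equal(p32[[1]], c(1L, 32L))
  expect_equal(
    vapply(p32, `[`, integer(1), 2L),
    c(32L, 32L, 64L, 64L, 128L, 128L, 128L, 256L, 256L, 256L, 256L,
      256L, 256L))
  # halving the base width halves every width, last width 128
  p16 <- plan_channels(16, 1)
  expect_equal(vapply(p16, `[`, integer(1), 2L)[-1],
               vapply(p32, `[`, integer(1), 2L)[-1] / 2L)
  expect_equal(p16[[13]][2], 128L)
  # any base: 13 pairs, final width 8B, chained ins
  for (B in c(4L, 7L, 48L)) {
    p <- plan_channels(B)
    expect_length(p, 13L)
    expect_equal(p[[13]][2], 8L * B)
    ins <- vapply(p, `[`, integer(1), 1L)
    outs <- vapply(p, `[`, integer(1), 2L)
    expect_equal(ins[-1], outs[-13])
  }
  expect_error(plan_channels(0), "invalid config")
})

test_that("adaptation module layout and parameter total", {
  ad <- build_adaptation(32, 7, dims = 2)
  expect_equal(vapply(ad, function(s) s$kind, character(1)),
               c("conv", "bn", "relu", "conv", "bn", "avgpool", "softmax"))
  expect_equal(sum(vapply(ad, layer_param_count, integer(1))),
               32768L + 256L + 896L + 14L)
  # pointwise kernels are dimension-free
  ad3 <- build_adaptation(32, 7, dims = 3)
  expect_equal(sum(vapply(ad3, layer_param_count, integer(1))), 33934L)
  # C = 1: final BN carries 2 parameters
  ad1 <- build_adaptation(32, 1)
  expect_equal(layer_param_count(ad1[[5]]), 2L)
})

test_that("midplanes_star reproduces the parameter-matching widths", {
  expect_equal(midplanes_star(256, 256), 576L)
  expect_equal(midplanes_star(1, 32), 8L)
  expect_equal(midplanes_star(64, 64), 144L)
  expect_error(midplanes_star(0, 32), "invalid config")
})

test_that("make_st_block weight totals", {
  b <- make_st_block(128, 256, "plain", mid_bn = TRUE)
  expect_equal(b$mid_channels, 256L)
  expect_equal(b$weight_total, 294912L + 196608L + 512L)
  expect_equal(make_st_block(128, 256, "star")$mid_channels, 460L)
  b2 <- make_st_block(64, 64, "plain", mid_bn = FALSE)
  expect_equal(b2$weight_total, 9L * 64L * 64L + 3L * 64L * 64L)
  expect_error(make_st_block(64, 64, "wrong"))
})

test_that("feature extractor structure: 13 convs, 4 pools", {
  for (variant in c("2d", "3d")) {
    specs <- build_layer_specs(model_config(variant))
    expect_equal(count_layers(specs, "conv", stage = "extractor"), 13L)
    expect_equal(count_layers(specs, "pool"), 4L)
    expect_equal(count_layers(specs, "conv", stage = "adaptation"), 2L)
  }
  # (2+1)D: 13 factorized blocks = 26 trunk convolutions
  specs <- build_layer_specs(model_config("2p1d"))
  expect_equal(count_layers(specs, "conv", stage = "extractor"), 26L)
  expect_equal(count_layers(specs, "pool"), 4L)
})

test_that("convolutions are bias-free and same-padded", {
  specs <- build_layer_specs(model_config("3d"))
  convs <- Filter(function(s) s$kind == "conv", specs)
  for (s in convs) {
    expect_false(s$has_bias)
    expect_equal(s$stride, c(1L, 1L, 1L))
    expect_equal(s$padding, (s$kernel - 1L) %/% 2L)
  }
  expect_error(layer_spec("conv", 1, 1, has_bias = TRUE), "bias-free")
  expect_error(layer_spec("dense"), "unknown layer kind")
})

test_that("built models map inputs to normalized class probabilities", {
  m3 <- build_model(model_config("3d", base_filters = 4L), seed = 1)
  x <- array(0, c(64, 64, 10, 1, 2))
  p <- predict_proba(m3, x)
  expect_equal(dim(p), c(2L, 7L))
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
  expect_true(all(p >= 0))
  m2 <- build_model(tiny_config("2d", size = c(16L, 16L)), seed = 1)
  p2 <- predict_proba(m2, array(runif(16 * 16 * 2), c(16, 16, 1, 1, 2)))
  expect_equal(rowSums(p2), c(1, 1), tolerance = 1e-6)
})

test_that("collapsing spatial input raises a shape error naming the stage", {
  m <- build_model(tiny_config("3d", size = c(16L, 16L)), seed = 1)
  x <- array(0, c(2, 2, 4, 1, 1))   # dies at the 2nd pooling stage
  expect_error(predict_proba(m, x), "pooling stage")
})

test_that("invalid configurations are rejected", {
  expect_error(model_config("3d", base_filters = 0), "invalid config")
  expect_error(model_config("3d", clip_len = 1,
                            pool_schedule = rbind(c(2L, 2L, 2L),
                                                  c(2L, 2L, 2L),
                                                  c(2L, 2L, 2L),
                                                  c(2L, 2L, 2L))),
               "collapses to zero frames")
})

test_that("temporal-extent identity: degenerate 3d equals 2d count", {
  cfg3 <- model_config("3d", base_filters = 16L, temporal_extent = 1L,
                       pool_schedule = matrix(rep(c(1L, 2L, 2L), 4L),
                                              nrow = 4L, byrow = TRUE),
                       clip_len = 1L)
  cfg2 <- model_config("2d", base_filters = 16L)
  expect_equal(count_params_closed_form(build_layer_specs(cfg3)),
               count_params_closed_form(build_layer_specs(cfg2)))
})

test_that("parameter-count relations across variants", {
  c3 <- count_params_closed_form(build_layer_specs(model_config("3d")))
  cp <- count_params_closed_form(build_layer_specs(model_config("2p1d")))
  cs <- count_params_closed_form(build_layer_specs(model_config("2p1d_star")))
  expect_lt(cp, c3)
  expect_lte(cp / c3, 0.5)            # "halving the figures"
  expect_lt(abs(cs - c3) / c3, 0.01)  # star matches the 3D size
  # quadrupling check: doubling B roughly quadruples the count
  r <- count_params_closed_form(build_layer_specs(model_config("2d", base_filters = 64L))) /
    count_params_closed_form(build_layer_specs(model_config("2d", base_filters = 32L)))
  expect_gt(r, 3.9); expect_lt(r, 4.1)
})

test_that("no-mid-BN ablation removes exactly the mid BN parameters", {
  with_bn <- count_params_closed_form(build_layer_specs(model_config("2p1d")))
  without <- count_params_closed_form(
    build_layer_specs(model_config("2p1d", mid_bn = FALSE)))
  mids <- vapply(plan_channels(32L), `[`, integer(1), 2L)
  expect_equal(with_bn - without, sum(2L * mids))
})
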
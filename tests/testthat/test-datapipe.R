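# clip extraction, splits, sampling, normalisation, augmentation

test_that("extract_clips follows the run-wise non-overlapping rule", {
  cl <- extract_clips(rep(3L, 25), 10)
  expect_equal(cl$start, c(0L, 10L))
  expect_equal(cl$end, c(10L, 20L))
  expect_equal(cl$label, c(3L, 3L))
  expect_equal(cl$central_index, c(5L, 15L))
  # no clip crosses a label change
  cl2 <- extract_clips(c(rep(1L, 10), rep(2L, 10)), 10)
  expect_equal(nrow(cl2), 2L)
  expect_equal(cl2$label, c(1L, 2L))
  expect_equal(cl2$start, c(0L, 10L))
  expect_equal(nrow(extract_clips(rep(0L, 9), 10)), 0L)
  expect_equal(nrow(extract_clips(integer(0), 10)), 0L)
  expect_error(extract_clips(1:5, 0), "N must be")
})

test_that("clip count equals the sum of floor(run/N) over runs", {
  set.seed(31)
  for (i in 1:20) {
    labels <- rep(sample(0:6, 12, replace = TRUE),
                  times = sample(1:15, 12, replace = TRUE))
    N <- sample(2:8, 1)
    r <- rle(labels)
    expect_equal(nrow(extract_clips(labels, N)), sum(r$lengths %/% N))
    cl <- extract_clips(labels, N)
    if (nrow(cl)) {
      expect_true(all(cl$end - cl$start == N))
      # all frames inside a clip share its label
      for (j in seq_len(nrow(cl)))
        expect_true(all(labels[(cl$start[j] + 1):cl$end[j]] == cl$label[j]))
    }
  }
})

test_that("central_frame is start + floor(N/2)", {
  expect_equal(central_frame(data.frame(start = 0L, end = 10L)), 5L)
  expect_equal(central_frame(data.frame(start = 10L, end = 20L)), 15L)
  expect_equal(central_frame(data.frame(start = 0L, end = 5L)), 2L)
})

test_that("make_splits reproduces the published split sizes", {
  # 413 patients, 377 with complete exams: floor(.15*377)=56 test,
  # 357 remaining, floor(.8*357)=285 train / 72 val
  m <- stub_manifest(413L, n_complete = 377L)
  s <- make_splits(m, test_frac = 0.15, val_frac = 0.2, seed = 0)
  expect_length(s$test, 56L)
  expect_length(s$train, 285L)
  expect_length(s$val, 72L)
  # disjoint cover
  all_ids <- sort(c(s$test, s$train, s$val))
  expect_equal(all_ids, sort(vapply(m$patients, function(p) p$patient_id,
                                    character(1))))
  # test patients all have complete exams
  expect_true(all(s$test %in% sprintf("p%04d", 1:377)))
})

test_that("splits are seeded and the test set can be held fixed", {
  m <- stub_manifest(40L, n_complete = 30L)
  s1 <- make_splits(m, seed = 7)
  s2 <- make_splits(m, seed = 7)
  expect_identical(s1, s2)
  s3 <- make_splits(m, seed = 8, test_patients = s1$test)
  expect_identical(s3$test, s1$test)
  expect_false(identical(s3$train, s1$train))
  expect_error(make_splits(stub_manifest(5L, n_complete = 0L)),
               "no complete exams")
  # JSON round trip
  path <- tempfile(fileext = ".json")
  write_split(s1, path)
  expect_equal(read_split(path)$train, s1$train)
})

test_that("sampler weights are inverse class frequencies", {
  w <- sampler_weights(c(0, 1, 1, 1))
  expect_equal(w[1] / w[2], 3)
  expect_equal(sampler_weights(rep(2, 5)), rep(0.2, 5))
  # the printed training-set counts: class 5 largest, class 6 smallest
  counts <- c(1168, 3362, 768, 3244, 4381, 643, 12428)
  labels <- rep(0:6, times = counts)
  w <- sampler_weights(labels)
  per_class <- tapply(w, labels, unique)
  expect_equal(unname(which.max(per_class)) - 1L, 5L)
  expect_equal(unname(which.min(per_class)) - 1L, 6L)
  expect_error(sampler_weights(integer(0)), "non-empty")
})

test_that("weighted draws approach the uniform class distribution", {
  counts <- c(1168, 3362, 768, 3244, 4381, 643, 12428)
  labels <- rep(0:6, times = counts)
  w <- sampler_weights(labels)
  set.seed(33)
  draws <- sample(labels, 10000, replace = TRUE, prob = w)
  shares <- as.numeric(table(factor(draws, levels = 0:6))) / 10000
  expect_true(all(abs(shares - 1 / 7) < 0.02))
})

test_that("class shares match the published distribution", {
  counts <- c(1168, 3362, 768, 3244, 4381, 643, 12428)
  labels <- rep(0:6, times = counts)
  sh <- class_distribution(labels)
  expect_equal(sum(sh), 100, tolerance = 1e-9)
  expect_equal(round(sh[["6"]], 1), 47.8)
  expect_equal(round(sh[["0"]], 1), 4.5)
  expect_equal(round(sh[["5"]], 1), 2.5)
  expect_equal(unname(class_distribution(rep(4, 10))), 100)
  expect_error(class_distribution(c()), "non-empty")
})

test_that("normalisation maps 8-bit to [0, 1]", {
  expect_equal(normalize_frames(255), 1)
  expect_equal(normalize_frames(0), 0)
  expect_equal(normalize_frames(128), 128 / 255)
})

test_that("augmentation: neutral draw is the identity", {
  set.seed(34)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3))
  id <- list(hflip = FALSE, vflip = FALSE, gamma = 1, scale = 1, angle = 0)
  expect_equal(augment_clip(x, id), x)
})

test_that("augmentation preserves shape, range, and temporal consistency", {
  set.seed(35)
  x <- array(runif(16 * 16 * 4), c(16, 16, 4))
  for (i in 1:5) {
    params <- draw_augmentation()
    y <- augment_clip(x, params)
    expect_equal(dim(y), dim(x))
    expect_gte(min(y), 0); expect_lte(max(y), 1)
    # applying the same draw to frame 1 alone equals frame 1 of the clip
    y1 <- augment_clip(x[, , 1], params)
    expect_equal(y1, y[, , 1])
  }
  expect_error(augment_clip(x * 2), "normalised")
})

test_that("manifest validation catches malformed input", {
  m <- stub_manifest(2L)
  expect_silent(validate_manifest(m))
  bad <- m
  bad$patients[[1]]$exams[[1]]$scans[[1]]$labels <- list(9L)
  expect_error(validate_manifest(bad), "out of range")
  bad2 <- m
  bad2$patients[[1]]$exams[[1]]$scans[[2]]$scan_id <- 1L
  expect_error(validate_manifest(bad2), "duplicate scan ids")
})

test_that("clip dataset pairs the 3D clips with 2D central frames", {
  m <- stub_manifest(3L, labels = rep(c(2L, 6L), each = 12L))
  frames <- stub_frames(m)
  ds <- build_clip_dataset(m, 6L, frames)
  # 2 clips per run, 2 runs, 5 scans, 3 patients
  expect_length(ds$y, 2 * 2 * 5 * 3)
  expect_equal(sort(unique(ds$y)), c(2L, 6L))
  # label multiset identical between clip and central-frame datasets
  expect_equal(table(ds$y), table(ds$clips$label))
  # clip pixel content matches the source frames
  i <- 5L
  vf <- frames[[ds$clips$video_id[i]]]
  expect_equal(ds$x[[i]],
               normalize_frames(vf[, , (ds$clips$start[i] + 1):ds$clips$end[i]]))
  # patient filtering
  ds2 <- build_clip_dataset(m, 6L, frames, patients = "p0001")
  expect_true(all(ds2$clips$patient_id == "p0001"))
})
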
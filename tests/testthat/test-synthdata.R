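# synthetic exam generator

test_that("rendering is seeded and deterministic", {
  ph <- phantom_spec(3L, c(0.5, 0.5), c(0.2, 0.2), dynamics = "pulsating")
  set.seed(41); f1 <- render_frame(list(ph), 3L)
  set.seed(41); f2 <- render_frame(list(ph), 3L)
  expect_identical(f1, f2)
  expect_true(is.integer(f1))
  expect_true(all(f1 >= 0 & f1 <= 255))
  expect_error(render_frame(list(ph), 0L, size = c(16L, 16L)),
               "at least 32x32")
})

test_that("zero pulsation amplitude degenerates to the static phantom", {
  stat <- phantom_spec(3L, c(0.5, 0.5), c(0.2, 0.15))
  puls <- phantom_spec(3L, c(0.5, 0.5), c(0.2, 0.15),
                       dynamics = "pulsating", amplitude = 0)
  set.seed(42); f1 <- render_frame(list(stat), 5L)
  set.seed(42); f2 <- render_frame(list(puls), 5L)
  expect_identical(f1, f2)
})

test_that("phantoms are brighter inside their mask than outside", {
  ph <- phantom_spec(2L, c(0.5, 0.5), c(0.2, 0.2), intensity = 0.9)
  mask <- phantom_mask(ph, 0L)
  set.seed(43)
  diffs <- replicate(20, {
    f <- render_frame(list(ph), 0L)
    mean(f[mask]) - mean(f[!mask])
  })
  expect_true(all(diffs > 0))
})

test_that("exam labels follow the protocol and heart segments pulsate", {
  ex <- generate_exam("pA", seed = 5)
  expect_length(ex$patient$exams[[1]]$scans, 5L)
  expect_true(ex$patient$exams[[1]]$complete)
  proto <- default_protocol()
  for (i in 1:5) {
    scan <- ex$patient$exams[[1]]$scans[[i]]
    labs <- unlist(scan$labels)
    expect_equal(labs, rep(proto[[i]]$segments$class,
                           proto[[i]]$segments$duration))
    expect_equal(dim(ex$frames[[scan$video_id]])[3], length(labs))
    # observed labels within the scan's allowed set
    expect_true(all(labs %in% proto[[i]]$allowed))
  }
  # heart frames change over time within a segment; static twin does not
  heart_vid <- ex$frames[["pA_scan3"]]
  expect_gt(sd(apply(heart_vid[, , 1:8], 3, mean)), 0)
})

test_that("generated datasets are reproducible and correctly sized", {
  d1 <- generate_dataset(3L, seed = 9)
  d2 <- generate_dataset(3L, seed = 9)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$frames, d2$frames)
  d3 <- generate_dataset(3L, seed = 10)
  expect_false(identical(d1$frames, d3$frames))
  # same label structure regardless of seed
  expect_identical(
    lapply(d1$manifest$patients[[1]]$exams[[1]]$scans, `[[`, "labels"),
    lapply(d3$manifest$patients[[1]]$exams[[1]]$scans, `[[`, "labels"))
  expect_length(d1$frames, 15L)   # 5 scans per patient
  expect_error(generate_dataset(2L), "n_patients")
  # label histogram matches protocol segment durations
  proto <- default_protocol()
  labs <- unlist(lapply(d1$manifest$patients[[1]]$exams[[1]]$scans,
                        function(s) unlist(s$labels)))
  want <- table(unlist(lapply(proto, function(sc)
    rep(sc$segments$class, sc$segments$duration))))
  expect_equal(table(labs), want, ignore_attr = TRUE)
})

test_that("scan priors derive from the protocol and always allow Other", {
  d <- generate_dataset(3L, seed = 1)
  proto <- default_protocol()
  for (s in seq_along(proto)) {
    expect_true(6L %in% d$priors[[as.character(s)]])
    expect_equal(sort(d$priors[[as.character(s)]]), proto[[s]]$allowed)
  }
  expect_equal(sort(d$priors[["3"]]), c(3L, 6L))
  path <- tempfile(fileext = ".json")
  write_priors(d$priors, path)
  expect_equal(read_priors(path), lapply(d$priors, as.integer))
})

test_that("clip extraction composes with the protocol durations", {
  d <- generate_dataset(3L, seed = 2)
  idx <- clip_index(d$manifest, 10L)
  # 40-frame segments yield 4 clips each; 25 segments per patient
  expect_equal(nrow(idx), 3L * 25L * 4L)
  expect_true(all(idx$end - idx$start == 10L))
})

test_that("short segments warn and yield no clips", {
  proto <- default_protocol(segment_frames = 6L)
  w <- capture_warnings(generate_exam("pB", proto, seed = 1,
                                      clip_len = 10L))
  expect_true(all(grepl("shorter than N", w)))
  expect_length(w, 5L)   # one warning per scan
})

test_that("pulsating vs static is a temporal-only distinction", {
  # single frames at random phase, matched axes: mean intensities from the
  # same distribution; the 10-frame mask-area series separates perfectly
  set.seed(44)
  g_axes <- c(0.16, 0.22)
  puls_means <- numeric(50); stat_means <- numeric(50)
  for (i in 1:50) {
    phase <- runif(1)
    puls <- phantom_spec(3L, c(0.5, 0.5), g_axes, dynamics = "pulsating",
                         period = 8L, amplitude = 0.25)
    t_at <- phase * 8
    stat <- phantom_spec(6L, c(0.5, 0.5),
                         g_axes * (1 + 0.25 * sin(2 * pi * t_at / 8)))
    puls_means[i] <- mean(render_frame(list(puls), t_at))
    stat_means[i] <- mean(render_frame(list(stat), 0L))
  }
  expect_gt(t.test(puls_means, stat_means)$p.value, 0.05)
  # area time series: positive variance iff pulsating
  areas_p <- vapply(0:9, function(t)
    sum(phantom_mask(phantom_spec(3L, c(0.5, 0.5), g_axes,
                                  dynamics = "pulsating"), t)), numeric(1))
  areas_s <- vapply(0:9, function(t)
    sum(phantom_mask(phantom_spec(6L, c(0.5, 0.5), g_axes), t)), numeric(1))
  expect_gt(var(areas_p), 0)
  expect_equal(var(areas_s), 0)
})

test_that("dataset files round-trip through disk", {
  dir <- tempfile("synth")
  d <- generate_dataset(3L, seed = 3, dir = dir)
  m <- read_manifest(file.path(dir, "manifest.json"))
  expect_length(m$patients, 3L)
  first <- m$patients[[1]]$exams[[1]]$scans[[1]]
  expect_true(file.exists(first$frames[[1]]))
  img <- png::readPNG(first$frames[[1]])
  expect_equal(round(img * 255),
               d$frames[[first$video_id]][, , 1], ignore_attr = TRUE)
  pr <- read_priors(file.path(dir, "priors.json"))
  expect_equal(pr, lapply(d$priors, as.integer))
  unlink(dir, recursive = TRUE)
})
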
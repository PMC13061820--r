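#' Extract non-overlapping fixed-length clips from a label sequence
#'
#' Within each maximal run of identical per-frame labels, emits
#' `floor(run_length / N)` consecutive non-overlapping clips anchored at
#' the run's first frame; no clip crosses a label change and remainder
#' frames are dropped.  Frame indices are 0-based with half-open ranges
#' `[start, end)`; the central frame is `start + floor(N/2)`.
#'
#' @param labels integer vector of per-frame class labels.
#' @param N clip length (frames).
#' @return data.frame with columns `start`, `end`, `label`,
#'   `central_index` (0-based).
#' @examples
#' extract_clips(rep(3L, 25), 10)  # [0,10) and [10,20)
#' @export
extract_clips <- function(labels, N) {
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("N must be >= 1")
  if (length(labels) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      label = integer(0), central_index = integer(0)))
  r <- rle(as.integer(labels))
  run_start <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  out <- list()
  for (i in seq_along(r$lengths)) {
    k <- r$lengths[i] %/% N
    if (k == 0L) next
    starts <- run_start[i] + (seq_len(k) - 1L) * N
    out[[length(out) + 1L]] <- data.frame(
      start = starts, end = starts + N, label = r$values[i],
      central_index = starts + N %/% 2L)
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      label = integer(0), central_index = integer(0)))
  do.call(rbind, out)
}

#' Central frame of a clip
#'
#' @param clip a one-row clip record (with `start` and `end`), or a clip
#'   data.frame.
#' @return 0-based central frame index `start + floor(N/2)`.
#' @export
central_frame <- function(clip) {
  clip$start + (clip$end - clip$start) %/% 2L
}

#' Clip index for a whole manifest
#'
#' Applies [extract_clips()] to every scan video of a manifest.
#'
#' @param manifest an exam manifest (see [read_manifest()]).
#' @param N clip length.
#' @return data.frame with columns `patient_id`, `video_id`, `scan_id`,
#'   `start`, `end`, `label`, `central_index`.
#' @export
clip_index <- function(manifest, N) {
  rows <- list()
  for (pat in manifest$patients) {
    for (exam in pat$exams) {
      for (scan in exam$scans) {
        cl <- extract_clips(scan$labels, N)
        if (nrow(cl) == 0L) next
        cl$patient_id <- pat$patient_id
        cl$video_id <- scan$video_id
        cl$scan_id <- scan$scan_id
        rows[[length(rows) + 1L]] <- cl
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(patient_id = character(0), video_id = character(0),
                      scan_id = integer(0), start = integer(0),
                      end = integer(0), label = integer(0),
                      central_index = integer(0)))
  out <- do.call(rbind, rows)
  out[, c("patient_id", "video_id", "scan_id", "start", "end", "label",
          "central_index")]
}

#' Patient-disjoint train/validation/test splits
#'
#' The test set is drawn only from patients whose exam is complete (all 5
#' scans present), taking `floor(test_frac * n_complete)` patients.  The
#' remaining patients are split into train/validation with
#' `floor((1 - val_frac) * n)` train patients and the remainder as
#' validation.  Partitions are disjoint and cover all patients.
#'
#' @param manifest an exam manifest.
#' @param test_frac fraction of complete-exam patients assigned to test.
#' @param val_frac validation fraction of the remaining patients.
#' @param seed RNG seed for the train/validation shuffle (and, when
#'   `test_patients` is not supplied, the test draw).
#' @param test_patients optional fixed test patient ids (used by
#'   [run_holdout()] to keep the test set identical across splits).
#' @return a `split_spec` list with `seed`, `test`, `train`, `val`.
#' @export
make_splits <- function(manifest, test_frac = 0.15, val_frac = 0.2,
                        seed = 0L, test_patients = NULL) {
  pats <- vapply(manifest$patients, function(p) p$patient_id, character(1))
  complete <- vapply(manifest$patients, function(p)
    any(vapply(p$exams, function(e) isTRUE(e$complete), logical(1))),
    logical(1))
  if (!any(complete)) stop("no complete exams: cannot form a test set")
  if (is.null(test_patients)) {
    n_test <- floor(test_frac * sum(complete))
    set.seed(as.integer(seed))
    test_patients <- sort(sample(pats[complete], n_test))
  }
  rest <- setdiff(pats, test_patients)
  set.seed(as.integer(seed) + 1L)
  rest <- sample(rest)
  n_train <- floor((1 - val_frac) * length(rest))
  structure(list(seed = as.integer(seed),
                 test = sort(test_patients),
                 train = sort(rest[seq_len(n_train)]),
                 val = sort(rest[-seq_len(n_train)])),
            class = "split_spec")
}

#' Write / read a split to JSON
#'
#' @param split a `split_spec`.
#' @param path JSON path.
#' @export
write_split <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = FALSE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(seed = as.integer(s$seed), test = as.character(s$test),
                 train = as.character(s$train), val = as.character(s$val)),
            class = "split_spec")
}

#' Inverse-frequency sampler weights
#'
#' Weight of sample `i` is `1 / count(class(i))`; drawing with replacement
#' with these weights gives each class an expected share of `1/K` per
#' batch.
#'
#' @param labels class ids of the training samples.
#' @return numeric weights, one per sample.
#' @export
sampler_weights <- function(labels) {
  if (length(labels) == 0L) stop("labels must be non-empty")
  counts <- table(labels)
  as.numeric(1 / counts[as.character(labels)])
}

#' Per-class shares in percent
#'
#' @param labels class ids.
#' @return named numeric vector of shares summing to 100.
#' @export
class_distribution <- function(labels) {
  if (length(labels) == 0L) stop("labels must be non-empty")
  counts <- table(labels)
  setNames(100 * as.numeric(counts) / sum(counts), names(counts))
}

#' Scale 8-bit pixel values to `[0, 1]`
#'
#' @param frames numeric/integer array of 8-bit values (0..255).
#' @return same-shaped array divided by 255.
#' @export
normalize_frames <- function(frames) {
  frames / 255
}

# bilinear sample of `img` at input coordinates implied by mapping output
# pixel (i, j) through scale s and rotation theta about the image center;
# out-of-range samples are 0
affine_sample <- function(img, scale = 1, theta = 0) {
  H <- nrow(img); W <- ncol(img)
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  gi <- matrix(rep(seq_len(H), W), nrow = H) - ci
  gj <- matrix(rep(seq_len(W), each = H), nrow = H) - cj
  # inverse map: un-rotate then un-scale
  si <- (cos(theta) * gi + sin(theta) * gj) / scale + ci
  sj <- (-sin(theta) * gi + cos(theta) * gj) / scale + cj
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0; fj <- sj - j0
  val <- function(ii, jj) {
    ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
    v <- numeric(length(ii))
    v[ok] <- img[cbind(ii[ok], jj[ok])]
    v
  }
  v <- (1 - fi) * (1 - fj) * val(i0, j0) +
    fi * (1 - fj) * val(i0 + 1, j0) +
    (1 - fi) * fj * val(i0, j0 + 1) +
    fi * fj * val(i0 + 1, j0 + 1)
  matrix(v, nrow = H, ncol = W)
}

#' Draw one set of augmentation parameters
#'
#' Flips with probability 50% each, gamma in `[0.7, 1.4]`, scale in
#' `[0.8, 1.2]`, rotation in `[-10, 10]` degrees.  Drawn once per clip and
#' applied identically to every frame (temporal consistency).
#'
#' @return list with `hflip`, `vflip`, `gamma`, `scale`, `angle`.
#' @export
draw_augmentation <- function() {
  list(hflip = runif(1) < 0.5, vflip = runif(1) < 0.5,
       gamma = runif(1, 0.7, 1.4), scale = runif(1, 0.8, 1.2),
       angle = runif(1, -10, 10))
}

#' Augment a clip
#'
#' Applies, in order: flips, gamma correction, scale about the center
#' (center-crop when zooming in, zero-pad when zooming out), rotation
#' (bilinear, zero fill).  One parameter draw is shared by all frames;
#' values are clipped to `[0, 1]` and the shape is preserved.
#'
#' @param frames `(H, W, T)` array (or `(H, W)` matrix) in `[0, 1]`.
#' @param params optional parameter draw from [draw_augmentation()];
#'   drawn from the current RNG stream when `NULL`.
#' @return augmented array of the same shape.
#' @export
augment_clip <- function(frames, params = NULL) {
  rng <- range(frames)
  if (rng[1] < 0 || rng[2] > 1)
    stop("frames must be normalised to [0, 1] before augmentation")
  if (is.null(params)) params <- draw_augmentation()
  d <- dim(frames)
  single <- length(d) == 2L
  if (single) dim(frames) <- c(d, 1L)
  out <- frames
  for (t in seq_len(dim(frames)[3])) {
    img <- frames[, , t]
    if (params$vflip) img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
    if (params$hflip) img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    img <- img^params$gamma
    if (params$scale != 1) img <- affine_sample(img, scale = params$scale)
    if (params$angle != 0)
      img <- affine_sample(img, theta = params$angle * pi / 180)
    out[, , t] <- pmin(pmax(img, 0), 1)
  }
  if (single) dim(out) <- d
  out
}

#' Read / write an exam manifest
#'
#' The JSON schema is `patients -> exams -> scans`, each scan carrying
#' `scan_id`, `video_id`, ordered `frames` (paths) and per-frame integer
#' `labels` (0..6).  `complete` marks exams with all 5 scans.
#'
#' @param path JSON path.
#' @return a manifest list.
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = FALSE)
  validate_manifest(m)
  m
}

#' @rdname read_manifest
#' @param manifest the manifest to write.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Validate a manifest
#'
#' Checks frame/label agreement, label range, and scan-id uniqueness.
#'
#' @param manifest a manifest list.
#' @return the manifest, invisibly; errors on violation.
#' @export
validate_manifest <- function(manifest) {
  for (pat in manifest$patients) {
    for (exam in pat$exams) {
      sids <- vapply(exam$scans, function(s) as.integer(s$scan_id),
                     integer(1))
      if (anyDuplicated(sids))
        stop(sprintf("duplicate scan ids for patient %s", pat$patient_id))
      for (scan in exam$scans) {
        labs <- unlist(scan$labels)
        if (length(scan$frames) > 0 && length(scan$frames) != length(labs))
          stop(sprintf("frame/label count mismatch in %s", scan$video_id))
        if (any(labs < 0 | labs > 6))
          stop(sprintf("labels out of range 0..6 in %s", scan$video_id))
      }
    }
  }
  invisible(manifest)
}

#' Assemble a clip dataset from a manifest and frame store
#'
#' Cuts every scan video into clips (see [extract_clips()]), loads and
#' normalises the pixel data, and returns an in-memory dataset usable for
#' both the spatio-temporal models (full clips) and the 2D model (which
#' takes the central frame of each clip at batch time, so the two datasets
#' have identical label multisets).
#'
#' @param manifest an exam manifest.
#' @param clip_len clip length N.
#' @param frames frame store: either `NULL` (frames read from the PNG
#'   paths in the manifest) or the in-memory store returned by
#'   [generate_dataset()] (a list `video_id -> (H, W, T)` 8-bit array).
#' @param patients optional patient-id filter.
#' @param labels_keep optional label filter (e.g. `c(3, 6)` for the
#'   temporally-defined subset task).
#' @return list with `x` (list of `(H, W, N)` arrays in `[0, 1]`), `y`
#'   (0-based labels), and `clips` (the clip index rows).
#' @export
build_clip_dataset <- function(manifest, clip_len, frames = NULL,
                               patients = NULL, labels_keep = NULL) {
  idx <- clip_index(manifest, clip_len)
  if (!is.null(patients)) idx <- idx[idx$patient_id %in% patients, ]
  if (!is.null(labels_keep)) idx <- idx[idx$label %in% labels_keep, ]
  video_frames <- function(vid) {
    if (!is.null(frames)) return(frames[[vid]])
    # locate the scan and read its PNG frames
    for (pat in manifest$patients) for (exam in pat$exams)
      for (scan in exam$scans) if (scan$video_id == vid) {
        imgs <- lapply(scan$frames, function(p) round(png::readPNG(p) * 255))
        return(array(unlist(imgs),
                     dim = c(dim(imgs[[1]])[1], dim(imgs[[1]])[2],
                             length(imgs))))
      }
    stop(sprintf("video %s not found in manifest", vid))
  }
  x <- vector("list", nrow(idx))
  cache_vid <- ""
  vf <- NULL
  for (i in seq_len(nrow(idx))) {
    if (idx$video_id[i] != cache_vid) {
      vf <- video_frames(idx$video_id[i])
      cache_vid <- idx$video_id[i]
    }
    x[[i]] <- normalize_frames(vf[, , (idx$start[i] + 1L):idx$end[i],
                                  drop = FALSE])
  }
  list(x = x, y = as.integer(idx$label), clips = idx)
}

#' Write a clip index to CSV
#'
#' @param clips data.frame from [clip_index()].
#' @param path CSV path.
#' @export
write_clip_index <- function(clips, path) {
  write.csv(clips, path, row.names = FALSE)
  invisible(path)
}
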
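#' Phantom specification
#'
#' A phantom is a bright anti-aliased ellipse over a speckled background,
#' with one of three dynamics: `static`, `pulsating` (axes scaled by
#' `1 + amplitude * sin(2*pi*t/period)`) or `drifting` (center moves by
#' `velocity` per frame).  Coordinates and axes are fractions of the
#' image size.
#'
#' @param class_id class this phantom renders (0..5; 6-labelled segments
#'   also render a phantom, a static heart-like twin).
#' @param center `c(row, col)` fractional center.
#' @param axes `c(row, col)` fractional semi-axes (positive).
#' @param intensity peak echogenicity in `(0, 1]`.
#' @param dynamics `"static"`, `"pulsating"` or `"drifting"`.
#' @param period pulsation period in frames (>= 2).
#' @param amplitude pulsation amplitude as a fraction of the axes.
#' @param phase pulsation phase offset in cycles; randomising it per
#'   segment makes the single-frame appearance of a pulsating phantom
#'   match a random-phase static twin exactly.
#' @param velocity `c(row, col)` drift in fractional units per frame.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(class_id, center, axes, intensity = 0.8,
                         dynamics = c("static", "pulsating", "drifting"),
                         period = 8L, amplitude = 0.25, phase = 0,
                         velocity = c(0, 0)) {
  dynamics <- match.arg(dynamics)
  if (any(axes <= 0)) stop("axes must be positive")
  if (intensity <= 0 || intensity > 1) stop("intensity must be in (0, 1]")
  if (dynamics == "pulsating" && period < 2L) stop("period must be >= 2")
  structure(list(class_id = as.integer(class_id), center = center,
                 axes = axes, intensity = intensity, dynamics = dynamics,
                 period = as.integer(period), amplitude = amplitude,
                 phase = phase, velocity = velocity),
            class = "phantom_spec")
}

# geometry and dynamics of each scan-plane class at the default 64x64
# resolution; centers/axes are image fractions.  Class 3 ("Heart") is the
# temporally-defined class (pulsating); class 6 ("Other") gets a static
# ellipse drawn from the heart's single-frame distribution so that the
# two are indistinguishable without temporal context.
.class_geometry <- list(
  "0" = list(center = c(0.30, 0.30), axes = c(0.10, 0.25), intensity = 0.70),
  "1" = list(center = c(0.30, 0.70), axes = c(0.25, 0.10), intensity = 0.75),
  "2" = list(center = c(0.70, 0.30), axes = c(0.18, 0.18), intensity = 0.90),
  "3" = list(center = c(0.50, 0.50), axes = c(0.16, 0.22), intensity = 0.80),
  "4" = list(center = c(0.70, 0.70), axes = c(0.12, 0.28), intensity = 0.70),
  "5" = list(center = c(0.25, 0.50), axes = c(0.08, 0.08), intensity = 0.60))

.heart_period <- 8L
.heart_amplitude <- 0.25

# phantom for one protocol segment, with per-segment jitter drawn from the
# current RNG stream
segment_phantom <- function(class_id, jitter = TRUE) {
  if (class_id == 6L) {
    g <- .class_geometry[["3"]]
    # static twin of the heart: same center/axes jitter as the heart, with
    # the axes frozen at a random pulsation phase, so the single-frame
    # appearance distribution matches the heart's
    phase <- if (jitter) runif(1) else 0
    scalef <- 1 + .heart_amplitude * sin(2 * pi * phase)
    jc <- if (jitter) runif(2, -0.03, 0.03) else c(0, 0)
    ja <- if (jitter) runif(1, 0.9, 1.1) else 1
    return(phantom_spec(6L, g$center + jc, g$axes * ja * scalef,
                        intensity = g$intensity, dynamics = "static"))
  }
  g <- .class_geometry[[as.character(class_id)]]
  jc <- if (jitter) runif(2, -0.03, 0.03) else c(0, 0)
  ja <- if (jitter) runif(1, 0.9, 1.1) else 1
  if (class_id == 3L)
    return(phantom_spec(3L, g$center + jc, g$axes * ja,
                        intensity = g$intensity, dynamics = "pulsating",
                        period = .heart_period,
                        amplitude = .heart_amplitude,
                        phase = if (jitter) runif(1) else 0))
  phantom_spec(class_id, g$center + jc, g$axes * ja,
               intensity = g$intensity, dynamics = "drifting",
               velocity = if (jitter) runif(2, -8e-4, 8e-4) else c(0, 0))
}

#' Render one synthetic ultrasound frame
#'
#' Background is multiplicative speckle (unit-mean gamma field over a low
#' base echogenicity); each phantom adds a bright anti-aliased ellipse
#' whose geometry at frame `t` follows its dynamics.  Draws from the
#' current RNG stream: seed the RNG for reproducible frames.
#'
#' @param phantoms list of [phantom_spec()]s.
#' @param t 0-based frame index (drives the dynamics).
#' @param size `c(H, W)`, at least 32x32.
#' @param base_intensity background echogenicity.
#' @param speckle_shape gamma shape of the unit-mean speckle field.
#' @return integer matrix `(H, W)` of 8-bit values.
#' @export
render_frame <- function(phantoms, t, size = c(64L, 64L),
                         base_intensity = 0.15, speckle_shape = 4) {
  size <- as.integer(size)
  if (any(size < 32L)) stop("size must be at least 32x32")
  H <- size[1]; W <- size[2]
  u <- (seq_len(H) - 0.5) / H
  v <- (seq_len(W) - 0.5) / W
  E <- matrix(base_intensity, H, W)
  for (ph in phantoms) {
    center <- ph$center
    axes <- ph$axes
    if (ph$dynamics == "pulsating")
      axes <- axes * (1 + ph$amplitude *
                        sin(2 * pi * (t / ph$period + ph$phase)))
    if (ph$dynamics == "drifting")
      center <- center + ph$velocity * t
    d <- sqrt(outer((u - center[1]) / axes[1], rep(1, W))^2 +
                outer(rep(1, H), (v - center[2]) / axes[2])^2)
    alpha <- pmin(1, pmax(0, (1 - d) / 0.15))
    E <- E + alpha * (ph$intensity - base_intensity)
  }
  speckle <- matrix(rgamma(H * W, shape = speckle_shape,
                           rate = speckle_shape), H, W)
  img <- pmin(pmax(E * speckle, 0), 1)
  matrix(as.integer(round(img * 255)), H, W)
}

#' Ellipse support mask of a phantom at frame t
#'
#' Utility for the temporal-discriminability analysis: the binary mask of
#' pixels inside the (possibly pulsating/drifting) ellipse.
#'
#' @inheritParams render_frame
#' @param phantom a [phantom_spec()].
#' @return logical matrix `(H, W)`.
#' @export
phantom_mask <- function(phantom, t, size = c(64L, 64L)) {
  size <- as.integer(size)
  H <- size[1]; W <- size[2]
  u <- (seq_len(H) - 0.5) / H
  v <- (seq_len(W) - 0.5) / W
  center <- phantom$center
  axes <- phantom$axes
  if (phantom$dynamics == "pulsating")
    axes <- axes * (1 + phantom$amplitude *
                      sin(2 * pi * (t / phantom$period + phantom$phase)))
  if (phantom$dynamics == "drifting")
    center <- center + phantom$velocity * t
  d <- sqrt(outer((u - center[1]) / axes[1], rep(1, W))^2 +
              outer(rep(1, H), (v - center[2]) / axes[2])^2)
  d <= 1
}

#' Default 5-scan acquisition protocol
#'
#' Each scan visits an ordered sequence of landmarks with Other segments
#' between them, 40 frames per segment (200 frames per scan).  Heart
#' (class 3) and Other segments are balanced 10:10 per exam so that the
#' temporally-defined {Heart, Other} subset is class-balanced; every
#' scan's allowed-class set contains class 6.
#'
#' @param segment_frames frames per segment.
#' @return a `protocol_spec`: list of 5 scans, each with `scan_id`,
#'   `segments` (data.frame `class`, `duration`) and `allowed` classes.
#' @export
default_protocol <- function(segment_frames = 40L) {
  paths <- list(c(0L, 6L, 3L, 6L, 3L),
                c(1L, 6L, 3L, 6L, 3L),
                c(3L, 6L, 3L, 6L, 3L),
                c(4L, 6L, 3L, 6L, 3L),
                c(5L, 6L, 3L, 6L, 2L))
  structure(lapply(seq_along(paths), function(i) {
    segs <- data.frame(class = paths[[i]],
                       duration = rep(as.integer(segment_frames),
                                      length(paths[[i]])))
    list(scan_id = i, segments = segs,
         allowed = sort(unique(c(segs$class, 6L))))
  }), class = "protocol_spec")
}

#' Generate one synthetic exam
#'
#' Renders the 5 scans of `protocol` for one patient: per-frame labels
#' follow the protocol segments, heart segments pulsate, Other segments
#' carry the static heart twin.  Reproducible given `seed`.
#'
#' @param patient_id patient identifier string.
#' @param protocol a [default_protocol()]-style protocol.
#' @param seed integer seed.
#' @param size `c(H, W)` frame size.
#' @param clip_len clip length used only to warn about segments too short
#'   to yield any clip.
#' @return list with `patient` (manifest entry) and `frames`
#'   (named list `video_id -> (H, W, T)` integer array).
#' @export
generate_exam <- function(patient_id, protocol = default_protocol(),
                          seed = 0L, size = c(64L, 64L), clip_len = 10L) {
  set.seed(as.integer(seed))
  scans <- list()
  frames <- list()
  for (sc in protocol) {
    segs <- sc$segments
    short <- segs$duration < clip_len
    if (any(short))
      warning(sprintf(
        "scan %d: %d segment(s) shorter than N=%d will yield no clips",
        sc$scan_id, sum(short), clip_len))
    video_id <- sprintf("%s_scan%d", patient_id, sc$scan_id)
    labels <- integer(0)
    vid <- array(0L, dim = c(size[1], size[2], sum(segs$duration)))
    t0 <- 0L
    for (k in seq_len(nrow(segs))) {
      ph <- segment_phantom(segs$class[k])
      for (tt in seq_len(segs$duration[k]))
        vid[, , t0 + tt] <- render_frame(list(ph), tt - 1L, size = size)
      labels <- c(labels, rep(segs$class[k], segs$duration[k]))
      t0 <- t0 + segs$duration[k]
    }
    scans[[length(scans) + 1L]] <- list(scan_id = sc$scan_id,
                                        video_id = video_id,
                                        frames = list(),
                                        labels = as.list(labels))
    frames[[video_id]] <- vid
  }
  patient <- list(patient_id = patient_id,
                  exams = list(list(exam_id = paste0(patient_id, "_exam1"),
                                    complete = length(scans) == 5L,
                                    scans = scans)))
  list(patient = patient, frames = frames)
}

#' Generate a synthetic dataset
#'
#' Generates `n_patients` exams (5 scans each) plus the scan-prior table
#' derived from the protocol.  With `dir` set, frames are written as 8-bit
#' grayscale PNGs and the manifest/priors as JSON; otherwise frames stay
#' in memory.
#'
#' @param n_patients number of patients (>= 3, to allow a split).
#' @param protocol acquisition protocol.
#' @param seed master seed; per-patient seeds are derived from it.
#' @param size frame size `c(H, W)`.
#' @param dir optional output directory.
#' @param clip_len clip length for short-segment warnings.
#' @return list with `manifest`, `frames` (in-memory store), `priors`.
#' @export
generate_dataset <- function(n_patients, protocol = default_protocol(),
                             seed = 0L, size = c(64L, 64L), dir = NULL,
                             clip_len = 10L) {
  if (n_patients < 3L) stop("n_patients must be >= 3 to allow a split")
  set.seed(as.integer(seed))
  patient_seeds <- sample.int(.Machine$integer.max - 1L, n_patients)
  patients <- vector("list", n_patients)
  frames <- list()
  for (p in seq_len(n_patients)) {
    ex <- generate_exam(sprintf("p%03d", p), protocol,
                        seed = patient_seeds[p], size = size,
                        clip_len = clip_len)
    patients[[p]] <- ex$patient
    frames <- c(frames, ex$frames)
  }
  manifest <- list(patients = patients)
  priors <- setNames(lapply(protocol, function(sc) sc$allowed),
                     vapply(protocol, function(sc) as.character(sc$scan_id),
                            character(1)))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (p in seq_len(n_patients)) {
      pat <- manifest$patients[[p]]
      for (ei in seq_along(pat$exams)) for (si in seq_along(pat$exams[[ei]]$scans)) {
        scan <- pat$exams[[ei]]$scans[[si]]
        vdir <- file.path(dir, "frames", scan$video_id)
        dir.create(vdir, recursive = TRUE, showWarnings = FALSE)
        vid <- frames[[scan$video_id]]
        paths <- character(dim(vid)[3])
        for (t in seq_len(dim(vid)[3])) {
          paths[t] <- file.path(vdir, sprintf("frame_%04d.png", t - 1L))
          png::writePNG(vid[, , t] / 255, paths[t])
        }
        manifest$patients[[p]]$exams[[ei]]$scans[[si]]$frames <-
          as.list(paths)
      }
    }
    write_manifest(manifest, file.path(dir, "manifest.json"))
    write_priors(priors, file.path(dir, "priors.json"))
  }
  list(manifest = manifest, frames = frames, priors = priors)
}

#' Write / read a scan-prior table
#'
#' JSON schema: `{scan_id: [allowed class ids]}`.  Class 6 (Other) must be
#' in every allowed set.
#'
#' @param priors named list `scan_id -> integer vector`.
#' @param path JSON path.
#' @export
write_priors <- function(priors, path) {
  jsonlite::write_json(priors, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_priors
#' @export
read_priors <- function(path) {
  pr <- jsonlite::read_json(path, simplifyVector = TRUE)
  pr <- lapply(pr, as.integer)
  for (s in names(pr)) {
    if (length(pr[[s]]) == 0L) stop("empty allowed set for scan ", s)
    if (!6L %in% pr[[s]])
      stop("scan ", s, " prior must allow class 6 (Other)")
  }
  pr
}
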
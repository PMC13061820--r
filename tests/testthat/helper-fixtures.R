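# shared fixtures: all built in code, no files

# tiny config whose shapes survive the pooling schedule
tiny_config <- function(variant = "3d", B = 2L, C = 3L, N = 4L,
                        size = c(16L, 16L)) {
  model_config(variant, base_filters = B, num_classes = C, clip_len = N,
               pool_schedule = rbind(c(1L, 2L, 2L), c(2L, 2L, 2L),
                                     c(2L, 1L, 1L), c(1L, 1L, 1L)),
               input_size = size)
}

# reference 3D convolution: direct nested loops, independent of the
# im2col/GEMM path.  Weight rows follow the engine layout:
# r = dh + kh*(dw + kw*(dt + kt*cin)), 0-based.
naive_conv3d <- function(x, w, kernel, pad) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; T <- d[3]; Cin <- d[4]; N <- d[5]
  kt <- kernel[1]; kh <- kernel[2]; kw <- kernel[3]
  Cout <- ncol(w)
  y <- array(0, c(H, W, T, Cout, N))
  for (n in seq_len(N)) for (co in seq_len(Cout))
    for (t in seq_len(T)) for (ww in seq_len(W)) for (h in seq_len(H)) {
      acc <- 0
      for (ci in seq_len(Cin)) for (dt in seq_len(kt))
        for (dw in seq_len(kw)) for (dh in seq_len(kh)) {
          hs <- h + dh - 1L - pad[2]
          ws <- ww + dw - 1L - pad[3]
          ts <- t + dt - 1L - pad[1]
          if (hs >= 1 && hs <= H && ws >= 1 && ws <= W &&
              ts >= 1 && ts <= T) {
            r <- (dh - 1L) + kh * ((dw - 1L) + kw * ((dt - 1L) +
                                                       kt * (ci - 1L)))
            acc <- acc + x[hs, ws, ts, ci, n] * w[r + 1L, co]
          }
        }
      y[h, ww, t, co, n] <- acc
    }
  y
}

# manifest skeleton without pixel data (for split/clip logic tests)
stub_manifest <- function(n_patients, n_complete = n_patients,
                          labels = rep(0L, 20L), n_scans = 5L) {
  patients <- lapply(seq_len(n_patients), function(p) {
    complete <- p <= n_complete
    ns <- if (complete) n_scans else n_scans - 1L
    scans <- lapply(seq_len(ns), function(s)
      list(scan_id = s, video_id = sprintf("p%04d_s%d", p, s),
           frames = list(), labels = as.list(labels)))
    list(patient_id = sprintf("p%04d", p),
         exams = list(list(exam_id = sprintf("p%04d_e1", p),
                           complete = complete, scans = scans)))
  })
  list(patients = patients)
}

# tiny in-memory frame store for a manifest: deterministic gradient images
stub_frames <- function(manifest, size = c(16L, 16L)) {
  frames <- list()
  for (pat in manifest$patients) for (exam in pat$exams)
    for (scan in exam$scans) {
      T <- length(scan$labels)
      a <- array(0L, c(size[1], size[2], T))
      for (t in seq_len(T))
        a[, , t] <- matrix(as.integer((seq_len(size[1]) + t) %% 256),
                           size[1], size[2])
      frames[[scan$video_id]] <- a
    }
  frames
}
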
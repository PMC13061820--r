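#' Mask logits to a set of allowed classes
#'
#' Replaces the logits of disallowed classes by `-Inf` (inference
#' convention), so that the softmax assigns them probability 0 and the
#' allowed-class probabilities renormalise to 1.  With `additive`, a
#' finite negative constant is added instead (the training convention,
#' keeping the loss finite).
#'
#' @param logits length-K numeric vector (or K x N matrix).
#' @param allowed non-empty integer set of allowed 0-based class ids.
#' @param additive if not `NULL`, add this constant (e.g. `-1e9`) to
#'   disallowed entries instead of setting `-Inf`.
#' @return masked logits of the same shape.
#' @examples
#' mask_logits(c(5, 1, 1), allowed = c(1, 2))
#' @export
mask_logits <- function(logits, allowed, additive = NULL) {
  K <- if (is.matrix(logits)) nrow(logits) else length(logits)
  allowed <- as.integer(allowed)
  if (length(allowed) == 0L) stop("allowed set must be non-empty")
  if (any(allowed < 0L | allowed >= K))
    stop("allowed ids must be in 0..K-1")
  block <- setdiff(seq_len(K) - 1L, allowed) + 1L
  if (is.matrix(logits)) {
    logits[block, ] <- if (is.null(additive)) -Inf
                       else logits[block, ] + additive
  } else {
    logits[block] <- if (is.null(additive)) -Inf
                     else logits[block] + additive
  }
  logits
}

#' Per-clip predictions for one video
#'
#' Cuts the video into `floor(T/N)` consecutive non-overlapping clips from
#' frame 0 and classifies each one -- the whole clip for spatio-temporal
#' models, the central frame for the 2D model, so both consume identical
#' clip boundaries.  With a scan prior, logits are masked before the
#' argmax.
#'
#' @param model a `sononet_model`.
#' @param frames `(H, W, T)` array of 8-bit values (0..255) or values
#'   already in `[0, 1]` (detected from the range).
#' @param N clip length.
#' @param prior optional vector of allowed 0-based class ids.
#' @param batch_size clips per forward batch.
#' @return data.frame with `start`, `end` (0-based, half-open), `pred`,
#'   and probability columns `p0..p{K-1}`.
#' @export
predict_video <- function(model, frames, N, prior = NULL,
                          batch_size = 16L) {
  d <- dim(frames)
  if (length(d) != 3L) stop("frames must be an (H, W, T) array")
  if (d[3] < N) stop(sprintf("video has %d frames, need at least N=%d",
                             d[3], N))
  if (max(frames) > 1) frames <- normalize_frames(frames)
  n_clips <- d[3] %/% N
  starts <- (seq_len(n_clips) - 1L) * N
  K <- model$config$num_classes
  mask <- if (!is.null(prior)) {
    m <- rep(0, K)
    m[setdiff(seq_len(K) - 1L, as.integer(prior)) + 1L] <- -Inf
    m
  } else NULL
  probs <- matrix(NA_real_, nrow = n_clips, ncol = K)
  for (b0 in seq(1L, n_clips, by = batch_size)) {
    idx <- b0:min(n_clips, b0 + batch_size - 1L)
    clips <- lapply(idx, function(i) {
      x <- frames[, , (starts[i] + 1L):(starts[i] + N), drop = FALSE]
      if (model$config$variant == "2d")
        x <- x[, , 1L + N %/% 2L, drop = FALSE]
      x
    })
    x <- stack_clips(clips)
    probs[idx, ] <- predict_proba(model, x,
                                  mask = if (is.null(mask)) NULL
                                         else matrix(mask, K, length(idx)))
  }
  out <- data.frame(start = starts, end = starts + N,
                    pred = max.col(probs) - 1L)
  colnames(probs) <- paste0("p", seq_len(K) - 1L)
  cbind(out, probs)
}

#' Ground-truth label of a possibly mixed-label clip
#'
#' In the protocol-style evaluation, videos are cut into consecutive clips
#' regardless of label changes; a mixed clip takes the central frame's
#' label (default) or the majority label.
#'
#' @param labels per-frame labels of the video.
#' @param start,end 0-based half-open clip range.
#' @param rule `"central"` or `"majority"`.
#' @return integer label.
#' @export
clip_truth <- function(labels, start, end, rule = c("central", "majority")) {
  rule <- match.arg(rule)
  seg <- labels[(start + 1L):end]
  if (rule == "central") return(as.integer(seg[1L + (end - start) %/% 2L]))
  as.integer(names(which.max(table(seg))))
}

#' Confusion matrix and summary scores
#'
#' Builds the K x K confusion matrix (rows = truth), the overall accuracy,
#' per-class recalls, their mean (MA) and population standard deviation
#' (SD) over classes with support, and -- when `video_ids` are supplied --
#' per-video accuracies with mean and standard deviation.
#'
#' @param preds,truths equal-length 0-based class id vectors.
#' @param K number of classes.
#' @param video_ids optional video id per prediction.
#' @return an `eval_report` list.
#' @export
confusion_and_scores <- function(preds, truths, K = 7L, video_ids = NULL) {
  if (length(preds) != length(truths))
    stop("preds and truths must have equal length")
  cm <- matrix(0L, nrow = K, ncol = K,
               dimnames = list(truth = seq_len(K) - 1L,
                               pred = seq_len(K) - 1L))
  for (i in seq_along(preds))
    cm[truths[i] + 1L, preds[i] + 1L] <- cm[truths[i] + 1L, preds[i] + 1L] + 1L
  support <- rowSums(cm)
  recalls <- ifelse(support > 0, diag(cm) / support, NA_real_)
  have <- support > 0
  ma <- mean(recalls[have])
  # population (not sample) standard deviation over classes
  sdv <- sqrt(mean((recalls[have] - ma)^2))
  rep <- list(confusion = cm,
              overall_accuracy = sum(diag(cm)) / length(preds),
              per_class_recall = recalls,
              classes_without_support = unname(which(!have)) - 1L,
              MA = ma, SD = sdv)
  if (!is.null(video_ids)) {
    acc <- tapply(preds == truths, video_ids, mean)
    acc <- setNames(as.numeric(acc), names(acc))
    rep$per_video_accuracy <- acc
    rep$per_video_mean <- mean(acc)
    rep$per_video_sd <- sqrt(mean((acc - mean(acc))^2))
  }
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("overall accuracy %.3f | MA %.3f | SD %.3f\n",
              x$overall_accuracy, x$MA, x$SD))
  if (!is.null(x$per_video_mean))
    cat(sprintf("per-video accuracy %.3f +/- %.3f (n=%d)\n",
                x$per_video_mean, x$per_video_sd,
                length(x$per_video_accuracy)))
  invisible(x)
}

#' Write an evaluation report
#'
#' Writes the summary as JSON and the confusion matrix as CSV.
#'
#' @param report an `eval_report`.
#' @param dir output directory.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(report$confusion, file.path(dir, "confusion.csv"))
  out <- report[c("overall_accuracy", "MA", "SD")]
  out$per_class_recall <- unname(report$per_class_recall)
  if (!is.null(report$per_video_mean)) {
    out$per_video_mean <- report$per_video_mean
    out$per_video_sd <- report$per_video_sd
  }
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Evaluate a model over the videos of a manifest
#'
#' Runs [predict_video()] on every scan video of the given patients,
#' assigns ground truth per clip via [clip_truth()], and aggregates with
#' [confusion_and_scores()].
#'
#' @param model a `sononet_model`.
#' @param manifest exam manifest.
#' @param frames frame store (see [build_clip_dataset()]).
#' @param N clip length.
#' @param patients optional patient filter.
#' @param priors optional scan-prior table (`scan_id -> allowed ids`).
#' @param truth_rule `"central"` or `"majority"` for mixed clips.
#' @return an `eval_report` (with per-video accuracies).
#' @export
evaluate_videos <- function(model, manifest, frames, N, patients = NULL,
                            priors = NULL, truth_rule = "central") {
  preds <- integer(0); truths <- integer(0); vids <- character(0)
  for (pat in manifest$patients) {
    if (!is.null(patients) && !pat$patient_id %in% patients) next
    for (exam in pat$exams) for (scan in exam$scans) {
      vf <- frames[[scan$video_id]]
      labs <- unlist(scan$labels)
      prior <- if (!is.null(priors)) priors[[as.character(scan$scan_id)]]
               else NULL
      pv <- predict_video(model, vf, N, prior = prior)
      tr <- vapply(seq_len(nrow(pv)), function(i)
        clip_truth(labs, pv$start[i], pv$end[i], rule = truth_rule),
        integer(1))
      preds <- c(preds, pv$pred)
      truths <- c(truths, tr)
      vids <- c(vids, rep(scan$video_id, nrow(pv)))
    }
  }
  confusion_and_scores(preds, truths, K = model$config$num_classes,
                       video_ids = vids)
}
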
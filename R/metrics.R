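#' Mean squared error on the 8-bit intensity scale
#'
#' @param i,k equally shaped images. Values are expected on the \[0, 255\]
#'   scale at this boundary; [to_8bit()] maps internal \[0, 1\] images.
#' @return mean squared difference over all pixels (channels averaged).
#' @export
mse <- function(i, k) {
  if (!identical(dim(i), dim(k))) stop("shape mismatch")
  mean((i - k)^2)
}

#' Map an internal \[0, 1\] image to the 8-bit scale
#'
#' @param img image in \[0, 1\].
#' @param round quantize to integer codes (default keeps the continuous
#'   scale, matching how the denoiser's continuous output is scored).
#' @return image on \[0, 255\].
#' @export
to_8bit <- function(img, round = FALSE) {
  out <- img * 255
  if (round) out <- base::round(out)
  out
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(MAX^2 / MSE)` with `MAX = 255` for 8-bit images. Identical
#' images have zero MSE; that case returns `Inf`, a distinct sentinel for
#' a perfect reconstruction.
#'
#' @param i,k images on the \[0, 255\] scale.
#' @param max_val peak intensity (255).
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(i, k, max_val = 255) {
  m <- mse(i, k)
  if (m == 0) return(Inf)
  10 * log10(max_val^2 / m)
}

#' Intersection over union of two axis-aligned boxes
#'
#' Boxes are `(x_min, y_min, x_max, y_max)` with `x_min < x_max`,
#' `y_min < y_max` (any units, as long as both boxes share them). The
#' matching criterion follows the usual reading of overlap "ratio to the
#' summation area" as intersection over union: intersection over the sum
#' of areas could never exceed 1/2 and would make a 0.5 threshold
#' unsatisfiable.
#'
#' @param a,b numeric length-4 vectors or single-row data frames.
#' @return scalar in \[0, 1\].
#' @export
iou <- function(a, b) {
  a <- as.numeric(a[c("x_min", "y_min", "x_max", "y_max")])
  b <- as.numeric(b[c("x_min", "y_min", "x_max", "y_max")])
  iw <- min(a[3L], b[3L]) - max(a[1L], b[1L])
  ih <- min(a[4L], b[4L]) - max(a[2L], b[2L])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  union <- (a[3L] - a[1L]) * (a[4L] - a[2L]) +
    (b[3L] - b[1L]) * (b[4L] - b[2L]) - inter
  inter / union
}

iou_matrix <- function(gt, det) {
  m <- matrix(0, nrow(det), nrow(gt))
  for (i in seq_len(nrow(det)))
    for (j in seq_len(nrow(gt)))
      m[i, j] <- iou(det[i, ], gt[j, ])
  m
}

#' Greedy matching of detections to ground truth
#'
#' Detections are processed in descending score order (ties keep input
#' order); each matches the unmatched ground-truth box of highest IoU if
#' that IoU reaches the threshold (a true positive), otherwise it is a
#' false positive. Ground-truth boxes left unmatched are false negatives,
#' so a second detection on an already-matched animal counts against
#' precision.
#'
#' @param gt data.frame of ground-truth boxes.
#' @param det data.frame of detections with a `score` column.
#' @param iou_threshold matching threshold (0.5).
#' @return list with counts `tp`, `fp`, `fn` and `det_tp`, a logical flag
#'   per detection in the original input order.
#' @export
match_detections <- function(gt, det, iou_threshold = 0.5) {
  n_det <- if (is.null(det)) 0L else nrow(det)
  n_gt <- if (is.null(gt)) 0L else nrow(gt)
  det_tp <- logical(n_det)
  if (n_det > 0L) {
    ord <- order(-det$score)
    matched <- logical(n_gt)
    if (n_gt > 0L) {
      m <- iou_matrix(gt, det)
      for (i in ord) {
        ious <- m[i, ]
        ious[matched] <- -1
        j <- which.max(ious)
        if (length(j) && ious[j] >= iou_threshold) {
          matched[j] <- TRUE
          det_tp[i] <- TRUE
        }
      }
    }
  }
  tp <- sum(det_tp)
  list(tp = tp, fp = n_det - tp, fn = n_gt - tp, det_tp = det_tp)
}

#' Average precision of a single-class detector
#'
#' Pools the scored detections of all frames, sweeps the score threshold
#' (greedy per-frame matching in global descending score order) and
#' integrates the precision-recall curve. The default uses all-points
#' interpolation (area under the running precision envelope); the
#' 11-point VOC-style average is available via `interpolation`.
#'
#' @param gt_all list of per-frame ground-truth data.frames.
#' @param det_all list of per-frame detection data.frames (with `score`).
#' @param iou_threshold matching threshold.
#' @param interpolation `"all_points"` or `"eleven_point"`.
#' @return AP in \[0, 1\] (0 when there are no ground-truth boxes or no
#'   detections).
#' @export
average_precision <- function(gt_all, det_all, iou_threshold = 0.5,
                              interpolation = c("all_points",
                                                "eleven_point")) {
  interpolation <- match.arg(interpolation)
  stopifnot(length(gt_all) == length(det_all))
  n_gt_total <- sum(vapply(gt_all, function(g) if (is.null(g)) 0L else nrow(g),
                           integer(1)))
  scores <- numeric(0)
  frame <- integer(0)
  local_i <- integer(0)
  for (f in seq_along(det_all)) {
    d <- det_all[[f]]
    if (is.null(d) || nrow(d) == 0L) next
    scores <- c(scores, d$score)
    frame <- c(frame, rep(f, nrow(d)))
    local_i <- c(local_i, seq_len(nrow(d)))
  }
  if (length(scores) == 0L || n_gt_total == 0L) return(0)
  ord <- order(-scores)
  matched <- lapply(gt_all, function(g)
    logical(if (is.null(g)) 0L else nrow(g)))
  tp_flags <- logical(length(ord))
  for (k in seq_along(ord)) {
    idx <- ord[k]
    f <- frame[idx]
    g <- gt_all[[f]]
    if (!is.null(g) && nrow(g) > 0L) {
      ious <- vapply(seq_len(nrow(g)), function(j)
        iou(det_all[[f]][local_i[idx], ], g[j, ]), numeric(1))
      ious[matched[[f]]] <- -1
      j <- which.max(ious)
      if (ious[j] >= iou_threshold) {
        matched[[f]][j] <- TRUE
        tp_flags[k] <- TRUE
      }
    }
  }
  cum_tp <- cumsum(tp_flags)
  cum_fp <- cumsum(!tp_flags)
  recall <- cum_tp / n_gt_total
  precision <- cum_tp / (cum_tp + cum_fp)
  if (interpolation == "eleven_point") {
    mean(vapply(seq(0, 1, by = 0.1), function(r) {
      sel <- recall >= r
      if (any(sel)) max(precision[sel]) else 0
    }, numeric(1)))
  } else {
    # running maximum of precision from the high-recall end (envelope)
    penv <- rev(cummax(rev(precision)))
    r_prev <- c(0, recall[-length(recall)])
    sum((recall - r_prev) * penv)
  }
}

#' Full detection evaluation report
#'
#' @param gt_all,det_all per-frame box sets as in [average_precision()].
#' @param iou_threshold matching threshold.
#' @return list with `precision`, `recall`, `ap`, and counts `tp`, `fp`,
#'   `fn`; precision/recall use every supplied detection as the operating
#'   point.
#' @export
eval_detections <- function(gt_all, det_all, iou_threshold = 0.5) {
  tp <- fp <- fn <- 0L
  for (f in seq_along(gt_all)) {
    m <- match_detections(gt_all[[f]], det_all[[f]], iou_threshold)
    tp <- tp + m$tp
    fp <- fp + m$fp
    fn <- fn + m$fn
  }
  list(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       ap = average_precision(gt_all, det_all, iou_threshold),
       tp = tp, fp = fp, fn = fn,
       iou_threshold = iou_threshold)
}

#' Oracle detector with configurable degradation
#'
#' Detection files are consumed, never produced, by this package (the
#' detector is an external system). For testing the evaluation pipeline
#' this helper derives detections from ground truth: boxes are jittered,
#' dropped, and polluted with spurious boxes under a fixed seed, so the
#' expected direction of every metric is known.
#'
#' @param gt_all list of per-frame ground-truth data.frames.
#' @param image_dim `(H, W)` used to keep jittered boxes inside the frame.
#' @param jitter standard deviation of the corner jitter in pixels.
#' @param drop_rate probability of missing an animal.
#' @param fp_rate expected number of spurious boxes per frame.
#' @param seed RNG seed.
#' @return list of per-frame detection data.frames with scores.
#' @export
jitter_detections <- function(gt_all, image_dim, jitter = 1,
                              drop_rate = 0, fp_rate = 0, seed = 1L) {
  with_seed(seed, {
    lapply(gt_all, function(g) {
      out <- data.frame(x_min = numeric(0), y_min = numeric(0),
                        x_max = numeric(0), y_max = numeric(0),
                        score = numeric(0))
      if (!is.null(g) && nrow(g) > 0L) {
        for (j in seq_len(nrow(g))) {
          if (stats::runif(1) < drop_rate) next
          b <- as.numeric(g[j, c("x_min", "y_min", "x_max", "y_max")]) +
            stats::rnorm(4, 0, jitter)
          b[1L] <- max(0, min(b[1L], image_dim[2L] - 2))
          b[2L] <- max(0, min(b[2L], image_dim[1L] - 2))
          b[3L] <- max(b[1L] + 1, min(b[3L], image_dim[2L]))
          b[4L] <- max(b[2L] + 1, min(b[4L], image_dim[1L]))
          out <- rbind(out, data.frame(x_min = b[1L], y_min = b[2L],
                                       x_max = b[3L], y_max = b[4L],
                                       score = stats::runif(1, 0.6, 1)))
        }
      }
      n_fp <- stats::rpois(1, fp_rate)
      for (k in seq_len(n_fp)) {
        w <- stats::runif(1, 4, image_dim[2L] / 3)
        h <- stats::runif(1, 4, image_dim[1L] / 3)
        x0 <- stats::runif(1, 0, image_dim[2L] - w)
        y0 <- stats::runif(1, 0, image_dim[1L] - h)
        out <- rbind(out, data.frame(x_min = x0, y_min = y0, x_max = x0 + w,
                                     y_max = y0 + h,
                                     score = stats::runif(1, 0.1, 0.7)))
      }
      out
    })
  })
}
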
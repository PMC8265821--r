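#' Confusion matrix over the 13 classes
#'
#' @param truth integer vector of true labels (0..12).
#' @param prediction integer vector of predicted labels (0..12; NA allowed,
#'   counted in an extra `none` column).
#' @param n_classes number of classes (default 13).
#' @return an integer matrix of class `confusion_matrix` (rows = truth,
#'   cols = prediction; an extra `none` column if any prediction is NA).
#' @export
confusion_matrix <- function(truth, prediction, n_classes = 13) {
  stopifnot(length(truth) == length(prediction))
  lv <- 0:(n_classes - 1)
  has_na <- anyNA(prediction)
  pf <- factor(ifelse(is.na(prediction), "none", as.character(prediction)),
               levels = c(as.character(lv), if (has_na) "none"))
  tf <- factor(as.character(truth), levels = as.character(lv))
  cm <- unclass(table(truth = tf, prediction = pf))
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Accuracy and per-class recall of a confusion matrix
#'
#' @param cm a [confusion_matrix()].
#' @param exclude_single drop the single-tag class (12) from both axes
#'   before computing the overall accuracy (default FALSE).
#' @return list with `accuracy` (trace / total) and `per_class_recall`.
#' @export
cm_accuracy <- function(cm, exclude_single = FALSE) {
  m <- unclass(cm)
  if (exclude_single) {
    keep_r <- rownames(m) != "12"
    m <- m[keep_r, , drop = FALSE]
  }
  total <- sum(m)
  if (total == 0) stop("empty confusion matrix")
  k <- intersect(rownames(m), colnames(m))
  diag_sum <- sum(m[cbind(k, k)])
  recall <- m[cbind(k, k)] / pmax(rowSums(m)[k], 1)
  list(accuracy = diag_sum / total,
       per_class_recall = stats::setNames(as.numeric(recall), k))
}

#' Fraction of orientation errors within one adjacent bin
#'
#' Among misclassified double-tag samples (true classes 0-11), the fraction
#' whose predicted bin is one of the two axial neighbours of the true bin
#' (bins wrap modulo 12 since orientation has period 180 degrees).
#' Predictions of the single-tag class or missed detections count as
#' non-adjacent errors.
#'
#' @param cm a [confusion_matrix()].
#' @return fraction in \[0, 1\], or NA with attribute `no_errors = TRUE`
#'   when there are no misclassifications.
#' @export
adjacent_bin_error <- function(cm) {
  m <- unclass(cm)
  rows <- as.character(0:11)
  errors <- 0; adjacent <- 0
  for (b in 0:11) {
    r <- as.character(b)
    wrong <- setdiff(colnames(m), r)
    errors <- errors + sum(m[r, wrong])
    nb <- as.character(c((b + 1) %% 12, (b - 1) %% 12))
    adjacent <- adjacent + sum(m[r, intersect(nb, colnames(m))])
  }
  if (errors == 0) {
    out <- NA_real_
    attr(out, "no_errors") <- TRUE
    return(out)
  }
  adjacent / errors
}

#' Sequential-frame track of one monomer
#'
#' @param id monomer identifier.
#' @param labels integer class labels per frame (0..12, NA for no detection).
#' @param orientations_deg estimated orientation per frame (NA for
#'   single-tag/none frames).
#' @param timestamps frame times in s (default 10-s spacing).
#' @return an object of class `sequence_track`.
#' @export
sequence_track <- function(id, labels, orientations_deg,
                           timestamps = 10 * (seq_along(labels) - 1)) {
  stopifnot(length(labels) == length(orientations_deg),
            length(timestamps) == length(labels),
            !is.unsorted(timestamps))
  structure(list(id = id, labels = as.integer(labels),
                 orientations_deg = orientations_deg,
                 timestamps = timestamps),
            class = "sequence_track")
}

#' Orientation dispersion of a sequential track
#'
#' Standard deviation of the per-frame orientation estimates over the frames
#' classified as double-tagged (single-tag frames carry no orientation and
#' are excluded), computed two ways: `naive` is the ordinary linear SD of
#' the angles as printed; `axial` doubles the angles, takes the circular
#' mean, wraps the residuals to (-90, 90\] and computes their linear SD,
#' which is immune to the +/-90-degree wrap artifact.
#'
#' @param track a [sequence_track()].
#' @return list with `naive_sd`, `axial_sd` (degrees) and `n_used`;
#'   both SDs are NA with attribute `insufficient = TRUE` when fewer than
#'   two double-tag frames exist.
#' @export
orientation_dispersion <- function(track) {
  stopifnot(inherits(track, "sequence_track"))
  ok <- !is.na(track$labels) & track$labels < 12L &
    !is.na(track$orientations_deg)
  th <- track$orientations_deg[ok]
  if (length(th) < 2) {
    out <- list(naive_sd = NA_real_, axial_sd = NA_real_,
                n_used = length(th))
    attr(out, "insufficient") <- TRUE
    return(out)
  }
  naive <- sd(th)
  d <- th * pi / 90                        # doubled angles, radians
  mean_axis <- atan2(mean(sin(d)), mean(cos(d))) * 90 / pi
  resid <- wrap_axial(th - mean_axis)
  list(naive_sd = naive, axial_sd = sd(resid), n_used = length(th))
}

#' Photobleaching drift between sequential frames
#'
#' Mean and standard deviation of the pixelwise differences
#' `frame_t - frame_(t+1)` pooled over all pixels and all consecutive frame
#' pairs.  A positive mean indicates a decaying signal.
#'
#' @param frames list of numeric matrices of equal shape.
#' @return list with `mean` and `sd` in counts, and `n_pairs`.
#' @export
photobleach_drift <- function(frames) {
  stopifnot(length(frames) >= 2)
  dims <- lapply(frames, dim)
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("frames must share one shape")
  diffs <- unlist(lapply(seq_len(length(frames) - 1L), function(t) {
    as.numeric(frames[[t]]) - as.numeric(frames[[t + 1L]])
  }))
  list(mean = mean(diffs), sd = sd(diffs), n_pairs = length(frames) - 1L)
}

# 8-connected components of a logical mask (small images; plain R scan)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- (p - 1L) %% nr + 1L; c <- (p - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          q <- rr + (cc - 1L) * nr
          if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
        }
      }
    }
  }
  lab
}

#' Detect and track monomers across sequential frames
#'
#' In each frame, candidate monomers are 8-connected components of pixels
#' above `threshold`; a patch around each centroid is classified with the
#' Gabor pipeline or a trained CNN.  Candidates are linked across frames by
#' nearest centroid within `match_radius` pixels; unmatched frames are
#' marked missing (NA).
#'
#' @param frames list of count matrices (background already subtracted), in
#'   time order.
#' @param method `"gabor"` or `"cnn"`.
#' @param model a trained `cnn_model` (required for `method = "cnn"`).
#' @param threshold detection count threshold (default 175).
#' @param patch_size side of the classified patch in pixels (default 25).
#' @param match_radius centroid matching radius in pixels (default 3).
#' @param timestamps frame times in s (default 10-s spacing).
#' @param ... further arguments to [classify_gabor()].
#' @return list of [sequence_track()] objects, one per monomer detected in
#'   the first frame.
#' @export
track_monomers <- function(frames, method = c("gabor", "cnn"), model = NULL,
                           threshold = 175, patch_size = 25,
                           match_radius = 3,
                           timestamps = 10 * (seq_along(frames) - 1), ...) {
  method <- match.arg(method)
  if (method == "cnn" && is.null(model))
    stop("method='cnn' needs a trained model")
  half <- (patch_size - 1L) %/% 2L
  crop <- function(frame, cy, cx) {
    nr <- nrow(frame); nc <- ncol(frame)
    r <- pmin(pmax(round(cy) + (-half:half) + 1L, 1L), nr)
    c <- pmin(pmax(round(cx) + (-half:half) + 1L, 1L), nc)
    frame[r, c]
  }
  classify_patch <- function(patch) {
    if (method == "gabor") {
      res <- classify_gabor(patch, gate_threshold = threshold, ...)
      c(label = res$label, orientation = res$orientation_deg)
    } else {
      lab <- cnn_predict(model, patch)$labels
      c(label = lab,
        orientation = class_to_orientation(lab))
    }
  }
  centroids_of <- function(frame) {
    lab <- label_components(frame > threshold)
    if (max(lab) == 0L) return(matrix(numeric(0), 0, 2))
    t(vapply(seq_len(max(lab)), function(k) {
      w <- which(lab == k, arr.ind = TRUE)
      c(mean(w[, 1]) - 1, mean(w[, 2]) - 1)   # (y, x), 0-based
    }, numeric(2)))
  }
  first <- centroids_of(frames[[1]])
  if (nrow(first) == 0L) return(list())
  lapply(seq_len(nrow(first)), function(m) {
    ref <- first[m, ]
    labels <- rep(NA_integer_, length(frames))
    oris <- rep(NA_real_, length(frames))
    for (t in seq_along(frames)) {
      cand <- centroids_of(frames[[t]])
      if (nrow(cand) == 0L) next
      d <- sqrt((cand[, 1] - ref[1])^2 + (cand[, 2] - ref[2])^2)
      j <- which.min(d)
      if (d[j] > match_radius) next
      res <- classify_patch(crop(frames[[t]], cand[j, 1], cand[j, 2]))
      labels[t] <- res["label"]
      oris[t] <- res["orientation"]
    }
    sequence_track(id = m, labels = labels, orientations_deg = oris,
                   timestamps = timestamps)
  })
}
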
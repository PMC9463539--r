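#' Multi-class accuracy
#'
#' Fraction of exact matches between predicted and true labels.
#'
#' @param pred_labels,true_labels label vectors of equal length (any form
#'   accepted by [as_class_label()]).
#' @return a fraction in \[0, 1\].
#' @export
multiclass_accuracy <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels) || length(pred_labels) < 1)
    stop("pred_labels and true_labels must have equal length >= 1")
  mean(as_class_label(pred_labels) == as_class_label(true_labels))
}

#' One-vs-rest AUC per class
#'
#' For each class, the area under the ROC curve treating that class as
#' positive and all others as negative, computed from the class's probability
#' column with the midrank tie convention:
#' `AUC = P(score_pos > score_neg) + 0.5 P(score_pos = score_neg)` over all
#' positive-negative pairs. Classes without both a positive and a negative
#' example have undefined AUC, are reported as `NA` and excluded from the
#' unweighted mean (with a warning).
#'
#' @param prob_matrix N x 5 matrix of class probabilities (or scores).
#' @param true_labels length-N vector of true labels.
#' @return list with `auc_per_class` (named 5-vector, possibly with NA) and
#'   `auc_mean` (unweighted mean over defined classes).
#' @export
auc_ovr <- function(prob_matrix, true_labels) {
  prob_matrix <- rbind(prob_matrix)
  y <- label_index(true_labels)
  if (nrow(prob_matrix) != length(y))
    stop("prob_matrix rows must match true_labels length")
  aucs <- vapply(seq_len(N_CLASSES), function(k) {
    pos <- y == k
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    # midrank (Mann-Whitney) formulation
    r <- rank(prob_matrix[, k])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, 0)
  names(aucs) <- class_labels()
  if (anyNA(aucs))
    warning("AUC undefined for class(es) without both positives and negatives: ",
            paste(names(aucs)[is.na(aucs)], collapse = ", "),
            "; excluded from the mean")
  list(auc_per_class = aucs, auc_mean = mean(aucs, na.rm = TRUE))
}

#' Row-proportion confusion matrix
#'
#' Entry `[t, p]` is the fraction of images with true class `t` predicted as
#' `p`. Rows of classes absent from `true_labels` are reported as all zero.
#'
#' @inheritParams multiclass_accuracy
#' @return 5 x 5 matrix with rows summing to 1 (or 0 for empty rows).
#' @export
confusion_row_proportions <- function(pred_labels, true_labels) {
  t_ <- as_class_label(true_labels)
  p_ <- as_class_label(pred_labels)
  counts <- table(true = t_, predicted = p_)
  m <- matrix(as.numeric(counts), N_CLASSES, N_CLASSES,
              dimnames = list(true = class_labels(), predicted = class_labels()))
  rs <- rowSums(m)
  m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
  m
}

#' Accuracy by group
#'
#' Per-group classification accuracy, e.g. by site or by age bin. Numeric
#' grouping variables can be binned by supplying `breaks` (passed to
#' [cut()], right-open).
#'
#' @inheritParams multiclass_accuracy
#' @param groups vector of group values aligned with the labels.
#' @param breaks optional numeric breaks for binning a numeric `groups`.
#' @return named numeric vector mapping group to accuracy.
#' @export
grouped_accuracy <- function(pred_labels, true_labels, groups, breaks = NULL) {
  if (length(groups) != length(true_labels))
    stop("groups must be aligned with the labels")
  if (!is.null(breaks))
    groups <- cut(groups, breaks = breaks, right = FALSE)
  ok <- as_class_label(pred_labels) == as_class_label(true_labels)
  vapply(split(ok, groups), mean, 0)
}

#' Full evaluation report
#'
#' @param pred_labels predicted labels.
#' @param true_labels reference labels.
#' @param prob_matrix optional N x 5 probability matrix for AUCs.
#' @param groups optional named list of grouping vectors (each aligned with
#'   the labels), e.g. `list(site = ..., age_bin = ...)`.
#' @return object of class `eval_report`.
#' @export
eval_report <- function(pred_labels, true_labels, prob_matrix = NULL,
                        groups = NULL) {
  rep <- list(
    n = length(true_labels),
    accuracy = multiclass_accuracy(pred_labels, true_labels),
    confusion = confusion_row_proportions(pred_labels, true_labels))
  if (!is.null(prob_matrix)) {
    a <- auc_ovr(prob_matrix, true_labels)
    rep$auc_per_class <- a$auc_per_class
    rep$auc_mean <- a$auc_mean
  }
  if (!is.null(groups))
    rep$group_accuracy <- lapply(groups, function(g)
      grouped_accuracy(pred_labels, true_labels, g))
  structure(rep, class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: n = %d, accuracy = %.3f", x$n, x$accuracy))
  if (!is.null(x$auc_mean)) cat(sprintf(", mean one-vs-rest AUC = %.3f", x$auc_mean))
  cat("\n")
  invisible(x)
}

#' Write an evaluation report as JSON
#'
#' @param report an `eval_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_eval_report <- function(report, path) {
  out <- unclass(report)
  out$confusion <- as.data.frame(out$confusion)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Grad-CAM saliency heatmap
#'
#' Gradient-weighted class activation map at the final convolutional layer of
#' the backbone: the gradient of the target-class logit with respect to the
#' final conv activations is averaged spatially into per-channel weights, the
#' weighted channel sum is rectified, bilinearly upsampled to the input grid,
#' and max-normalized to \[0, 1\] (an all-zero map stays zero). For
#' reader-embedding models a `reader_id` may be given to explain that
#' reader's prediction; otherwise the baseline path is explained.
#'
#' @param model a `readernet_model` with the toy convolutional backbone.
#' @param image image pixels or `synth_image`.
#' @param target_class class whose logit is explained.
#' @param reader_id optional reader (id or index).
#' @return H x W matrix in \[0, 1\] aligned with the input image.
#' @export
gradcam <- function(model, image, target_class, reader_id = NULL) {
  if (model$spec$backbone != "toy_cnn")
    stop("gradcam requires a convolutional backbone")
  x <- as_image_batch(image)
  if (dim(x)[4] != 1) stop("gradcam explains a single image")
  t_idx <- label_index(target_class)
  idx <- if (is.null(reader_id)) NULL else resolve_reader_idx(model, reader_id)
  fwd <- model_forward(model, x, reader_idx = idx, keep_cache = TRUE)
  cache <- fwd$cache$backbone
  A <- cache$a3                       # final conv activations (h, w, D, 1)
  # d logit_t / d embedding coordinate (modulated path included)
  demb <- model$params$fc_w[, t_idx]
  if (!is.null(idx)) demb <- demb * fwd$cache$mod$m[, 1]
  # route through GAP and the final max-pool to the conv activations
  d <- cache$pooled_dim
  hw <- d[1] * d[2]
  dpool <- array(rep(demb / hw, each = hw), d)
  dA <- maxpool2_bw(dpool, cache$pool_idx3, cache$adim3)
  alpha <- apply(dA[, , , 1, drop = FALSE], 3, mean)  # channel weights
  heat <- matrix(0, dim(A)[1], dim(A)[2])
  for (c_ in seq_along(alpha)) heat <- heat + alpha[c_] * A[, , c_, 1]
  heat[heat < 0] <- 0
  heat <- as.matrix(EBImage::resize(heat, w = nrow(x), h = ncol(x)))
  heat[heat < 0] <- 0
  if (max(heat) > 0) heat <- heat / max(heat)
  heat
}

#' Save a Grad-CAM overlay as PNG
#'
#' Writes the grayscale image with the heatmap blended in as brightness.
#'
#' @param image image pixels or `synth_image`.
#' @param heatmap matrix from [gradcam()].
#' @param path output PNG path.
#' @param alpha blend weight of the heatmap.
#' @return the path, invisibly.
#' @export
write_gradcam_overlay <- function(image, heatmap, path, alpha = 0.5) {
  if (inherits(image, "synth_image")) image <- image$pixels
  rgb <- array(0, c(nrow(image), ncol(image), 3))
  rgb[, , 1] <- clamp01(image * (1 - alpha) + heatmap * alpha)
  rgb[, , 2] <- image * (1 - alpha)
  rgb[, , 3] <- image * (1 - alpha)
  png::writePNG(rgb, path)
  invisible(path)
}

#' Most dissimilar same-site reader pair
#'
#' Among the initial-reader pairs that share a site (and therefore annotated
#' the same images), returns the pair whose confusion matrices are farthest
#' apart in L1 distance. Restricting to same-site pairs keeps the
#' identifiability comparison paired: both readers labelled every image of
#' their site, so agreement rates are computed on a common image set.
#'
#' @param data a `panel_data`.
#' @return list with `pair` (two reader ids), `site`, and `distance`.
#' @export
most_dissimilar_site_pair <- function(data) {
  stopifnot(inherits(data, "panel_data"))
  best <- NULL
  for (site in names(data$site_readers)) {
    pr <- data$site_readers[[site]]
    d <- sum(abs(data$profiles[[pr[1]]]$confusion -
                 data$profiles[[pr[2]]]$confusion))
    if (is.null(best) || d > best$distance)
      best <- list(pair = pr, site = site, distance = d)
  }
  best
}

#' Reader-conditional agreement: confusion-pattern distances
#'
#' For a pair of readers who annotated the same held-out images, measures how
#' closely each reader-conditional prediction stream reproduces each reader's
#' labelling pattern. Within every true class, the stream's mean predicted
#' label distribution is compared (L1 distance) with the reader's empirical
#' label distribution; distances are averaged over classes weighted by class
#' frequency. Aggregating at the class-distribution level pools all of a
#' reader's labels, which makes the comparison far less sensitive to
#' individual label draws than a per-image likelihood.
#'
#' A model that has learned reader-specific behaviour yields a matrix whose
#' diagonal is strictly smaller than its off-diagonal in each row: each
#' stream's predicted pattern is closer to its own reader's labels than to
#' the other reader's.
#'
#' @param model a reader-embedding `readernet_model`.
#' @param data a `panel_data`.
#' @param image_ids images to evaluate on (e.g. the test images); reduced to
#'   those with INITIAL annotations from both readers.
#' @param pair two reader ids (default: [most_dissimilar_site_pair()]).
#' @return 2 x 2 matrix of distances, rows = prediction stream, columns =
#'   label source (smaller = closer).
#' @export
reader_agreement_matrix <- function(model, data, image_ids, pair = NULL) {
  if (is.null(pair)) pair <- most_dissimilar_site_pair(data)$pair
  ann <- data$annotations
  ann <- ann[ann$phase == "INITIAL" & ann$reader_id %in% pair &
               ann$image_id %in% image_ids, ]
  labs <- lapply(pair, function(r)
    stats::setNames(ann$label[ann$reader_id == r], ann$image_id[ann$reader_id == r]))
  ids <- intersect(names(labs[[1]]), names(labs[[2]]))
  if (!length(ids)) stop("the two readers share no annotated images")
  x <- stack_pixels(data$images, ids)
  truth <- label_index(vapply(data$images[ids], function(im)
    as.character(im$true_class), ""))
  streams <- lapply(1:2, function(i)
    t(predict_probs_batch(model, x,
                          reader_idx = resolve_reader_idx(model, pair[i]))))
  emp <- lapply(1:2, function(j) {
    lj <- label_index(labs[[j]][ids])
    t(vapply(sort(unique(truth)), function(t)
      tabulate(lj[truth == t], N_CLASSES) / sum(truth == t), numeric(N_CLASSES)))
  })
  classes <- sort(unique(truth))
  wts <- vapply(classes, function(t) mean(truth == t), 0)
  out <- matrix(0, 2, 2, dimnames = list(stream = pair, labels = pair))
  for (i in 1:2) {
    pred_by_class <- t(vapply(classes, function(t)
      colMeans(streams[[i]][truth == t, , drop = FALSE]), numeric(N_CLASSES)))
    for (j in 1:2)
      out[i, j] <- sum(wts * rowSums(abs(pred_by_class - emp[[j]])))
  }
  out
}
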
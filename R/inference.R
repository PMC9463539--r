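#' Per-reader prediction matrix for one image
#'
#' Runs the backbone once and applies the reader branch for each requested
#' reader, producing one row of class probabilities per reader — the full set
#' of predictions a reader-embedding model can make for a single image.
#'
#' @param model a `readernet_model` with reader embeddings.
#' @param image image pixels or a `synth_image`.
#' @param reader_ids character ids or 1-based indices; defaults to all
#'   readers known to the model.
#' @return R x 5 matrix of row-stochastic predictions, rows named by reader.
#' @export
predict_panel <- function(model, image, reader_ids = NULL) {
  if (!model$spec$use_reader_embeddings)
    stop("predict_panel requires a model with reader embeddings")
  if (is.null(reader_ids)) reader_ids <- model$reader_ids
  if (length(reader_ids) == 0) stop("reader_ids must be nonempty")
  idx <- resolve_reader_idx(model, reader_ids)
  emb <- backbone_forward(model, as_image_batch(image))$emb  # D x 1
  mod <- reader_modulation(model, idx)                       # D x R
  h <- mod$m * as.vector(emb)
  logits <- crossprod(model$params$fc_w, h) + model$params$fc_b
  P <- t(softmax_cols(logits))
  dimnames(P) <- list(
    if (is.character(reader_ids)) reader_ids else model$reader_ids[idx],
    class_labels())
  P
}

#' Unweighted-mean aggregation of per-reader predictions
#'
#' The final prediction is the arithmetic column mean of the per-reader
#' probability rows; the label is the argmax, with ties broken toward the
#' lowest canonical class index.
#'
#' @param P an R x 5 matrix of row-stochastic per-reader predictions.
#' @return list with `probs` (named 5-vector) and `label` (factor).
#' @export
aggregate_mean <- function(P) {
  P <- rbind(P)
  if (nrow(P) < 1 || ncol(P) != N_CLASSES)
    stop("P must be a nonempty R x 5 prediction matrix")
  probs <- colMeans(P)
  list(probs = stats::setNames(probs, class_labels()),
       label = as_class_label(class_labels()[which.max(probs)]))
}

#' Classify an image
#'
#' For reader-embedding models, aggregates per-reader predictions over all
#' readers (every reader the model knows, regardless of who annotated the
#' image) with an unweighted mean; for baseline models, uses the plain
#' forward pass. Returns the argmax label with lowest-index tie-breaking.
#'
#' @param model a `readernet_model`.
#' @param image image pixels or `synth_image`.
#' @param reader_ids optional subset of readers to aggregate over.
#' @return factor of length 1 (the predicted class).
#' @export
classify <- function(model, image, reader_ids = NULL) {
  if (model$spec$use_reader_embeddings) {
    aggregate_mean(predict_panel(model, image, reader_ids))$label
  } else {
    pr <- forward_baseline(model, image)
    as_class_label(class_labels()[which.max(pr)])
  }
}

# Batched panel prediction over an image array: returns a list with
# `per_reader` (R x 5 x N array) and `aggregated` (N x 5 matrix). Used by the
# evaluation helpers; runs the backbone once per image batch.
predict_panel_batch <- function(model, x, reader_ids = NULL, batch_size = 64L) {
  if (is.null(reader_ids)) reader_ids <- model$reader_ids
  idx <- resolve_reader_idx(model, reader_ids)
  n <- dim(x)[4]
  R <- length(idx)
  per_reader <- array(0, c(R, N_CLASSES, n),
                      dimnames = list(model$reader_ids[idx], class_labels(), NULL))
  mod <- reader_modulation(model, idx)  # D x R, constant across images
  p <- model$params
  for (b in seq(1, n, by = batch_size)) {
    sel <- b:min(b + batch_size - 1L, n)
    emb <- backbone_forward(model, x[, , , sel, drop = FALSE])$emb  # D x nb
    for (r in seq_len(R)) {
      h <- emb * mod$m[, r]
      per_reader[r, , sel] <- softmax_cols(crossprod(p$fc_w, h) + p$fc_b)
    }
  }
  aggregated <- t(apply(per_reader, c(2, 3), mean))
  colnames(aggregated) <- class_labels()
  list(per_reader = per_reader, aggregated = aggregated)
}

#' Write per-reader and aggregated predictions to CSV
#'
#' @param model a reader-embedding model.
#' @param data a `panel_data`.
#' @param image_ids images to predict.
#' @param per_reader_path,aggregated_path output CSV paths (NULL to skip).
#' @return invisibly, the aggregated prediction data.frame.
#' @export
write_predictions <- function(model, data, image_ids,
                              per_reader_path = NULL, aggregated_path = NULL) {
  x <- stack_pixels(data$images, image_ids)
  pred <- predict_panel_batch(model, x)
  lv <- class_labels()
  if (!is.null(per_reader_path)) {
    R <- dim(pred$per_reader)[1]
    long <- data.frame(
      image_id = rep(image_ids, each = R),
      reader_id = rep(rownames(pred$per_reader), times = length(image_ids)),
      stringsAsFactors = FALSE)
    probs <- t(matrix(aperm(pred$per_reader, c(2, 1, 3)), nrow = N_CLASSES))
    colnames(probs) <- paste0("p_", lv)
    utils::write.csv(cbind(long, probs), per_reader_path, row.names = FALSE)
  }
  agg <- data.frame(
    image_id = image_ids,
    label = lv[max.col(pred$aggregated, ties.method = "first")],
    stringsAsFactors = FALSE)
  probs <- pred$aggregated
  colnames(probs) <- paste0("p_", lv)
  agg <- cbind(agg, probs)
  if (!is.null(aggregated_path))
    utils::write.csv(agg, aggregated_path, row.names = FALSE)
  invisible(agg)
}
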
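#' Training configuration
#'
#' Hyper-parameters for the training loop. Learning rates and weight decays
#' are per parameter group (convolutional layers, classifier head, reader
#' projection, reader-embedding table), mirroring the tuned dimensions of the
#' method's hyper-parameter search. The optimizer is Adam by default, with
#' momentum SGD available; the learning rate of every group follows
#' [lr_at_epoch()].
#'
#' @param batch_size minibatch size.
#' @param epochs number of training epochs.
#' @param base_lr_conv,base_lr_fc,base_lr_proj,base_lr_emb base learning
#'   rates for the four parameter groups.
#' @param wd_conv,wd_fc,wd_proj L2 weight-decay coefficients (the embedding
#'   table is regularized by the max-norm constraint instead).
#' @param dropout dropout proportion on the pre-classifier embedding.
#' @param p_affine,p_color probabilities of affine and brightness/contrast
#'   augmentation (used by the 224x224 augmentation pipeline).
#' @param max_norm optional max L2 norm of embedding rows.
#' @param optimizer `"adam"` (default; robust for training the compact
#'   backbone from scratch) or `"sgd"` (momentum SGD).
#' @param momentum momentum for the SGD optimizer.
#' @param lr_milestones epochs after which the learning rate is halved.
#' @param target `"final_label"` (baseline: arbitrated final labels) or
#'   `"reader_label"` (one sampled reader annotation per image per epoch).
#' @param seed integer seed for sampling, dropout and shuffling.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 32L, epochs = 150L,
                         base_lr_conv = 2e-3, base_lr_fc = 2e-3,
                         base_lr_proj = 2e-3, base_lr_emb = 0.01,
                         wd_conv = 1e-4, wd_fc = 1e-4, wd_proj = 1e-4,
                         dropout = 0.1, p_affine = 0, p_color = 0,
                         max_norm = NULL, optimizer = c("adam", "sgd"),
                         momentum = 0.9,
                         lr_milestones = c(50L, 100L),
                         target = c("final_label", "reader_label"),
                         seed = 1L) {
  target <- match.arg(target)
  optimizer <- match.arg(optimizer)
  if (epochs < 1) stop("epochs must be >= 1")
  stopifnot(batch_size >= 1, dropout >= 0, dropout < 1,
            p_affine >= 0, p_affine <= 1, p_color >= 0, p_color <= 1)
  structure(as.list(environment()), class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Step schedule: the base rate is halved after each milestone epoch
#' (defaults 50 and 100), i.e. `base` for epochs 0-49, `base/2` for 50-99 and
#' `base/4` from epoch 100 on.
#'
#' @param base base learning rate.
#' @param epoch zero-based epoch index.
#' @param milestones increasing epochs at which the rate is halved.
#' @return the effective learning rate.
#' @export
#' @examples
#' lr_at_epoch(0.01, 0)
#' lr_at_epoch(0.01, 50)
#' lr_at_epoch(0.01, 149)
lr_at_epoch <- function(base, epoch, milestones = c(50, 100)) {
  if (any(epoch < 0)) stop("epoch must be nonnegative")
  vapply(epoch, function(e) base * 0.5^sum(e >= milestones), 0)
}

#' Sample one annotation per training image
#'
#' For every training image, one of its reader annotations is chosen
#' uniformly at random (all phases with a single identifiable reader:
#' INITIAL, ARBITRATION and QC; consensus records are attributed to a reader
#' pair and are excluded), and the resulting (image, reader, label) triples
#' are returned in shuffled order. Models trained on reader labels therefore
#' perform the same number of weight updates per epoch as models trained on
#' final labels.
#'
#' @param annotations data.frame with columns `image_id`, `reader_id`,
#'   `label` (and optionally `phase`).
#' @param train_images character vector of image ids to sample for.
#' @return data.frame with one row per training image: `image_id`,
#'   `reader_id`, `label`.
#' @export
epoch_sample <- function(annotations, train_images) {
  ann <- annotations
  if (!is.null(ann$phase)) ann <- ann[ann$phase != "CONSENSUS", ]
  idx_by_image <- split(seq_len(nrow(ann)), ann$image_id)
  missing <- setdiff(train_images, names(idx_by_image))
  if (length(missing))
    stop("image(s) without any reader annotation: ",
         paste(utils::head(missing, 5), collapse = ", "))
  rows <- vapply(train_images, function(id) {
    ix <- idx_by_image[[id]]
    if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
  }, 0L)
  out <- ann[rows, c("image_id", "reader_id", "label")]
  out <- out[sample.int(nrow(out)), ]
  rownames(out) <- NULL
  out
}

# stack selected images of a panel_data into an (H, W, 1, N) array
stack_pixels <- function(images, ids) {
  px <- lapply(ids, function(id) images[[id]]$pixels)
  h <- nrow(px[[1]]); w <- ncol(px[[1]])
  array(unlist(px, use.names = FALSE), c(h, w, 1L, length(ids)))
}

# one optimizer step over all parameter groups (Adam or momentum SGD)
optimizer_step <- function(model, grads, opt_state, cfg, epoch) {
  group_of <- function(nm) {
    if (startsWith(nm, "conv")) "conv"
    else if (startsWith(nm, "fc")) "fc"
    else if (startsWith(nm, "proj")) "proj"
    else "emb"
  }
  lr <- c(conv = lr_at_epoch(cfg$base_lr_conv, epoch, cfg$lr_milestones),
          fc = lr_at_epoch(cfg$base_lr_fc, epoch, cfg$lr_milestones),
          proj = lr_at_epoch(cfg$base_lr_proj, epoch, cfg$lr_milestones),
          emb = lr_at_epoch(cfg$base_lr_emb, epoch, cfg$lr_milestones))
  wd <- c(conv = cfg$wd_conv, fc = cfg$wd_fc, proj = cfg$wd_proj, emb = 0)
  adam <- identical(cfg$optimizer %||% "adam", "adam")
  if (adam) opt_state$t <- (opt_state$t %||% 0L) + 1L
  for (nm in names(model$params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    grp <- group_of(nm)
    if (wd[[grp]] > 0) g <- g + wd[[grp]] * model$params[[nm]]
    if (adam) {
      b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
      m <- opt_state[[paste0(nm, ".m")]]
      v <- opt_state[[paste0(nm, ".v")]]
      if (is.null(m)) { m <- g * 0; v <- g * 0 }
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      opt_state[[paste0(nm, ".m")]] <- m
      opt_state[[paste0(nm, ".v")]] <- v
      mhat <- m / (1 - b1^opt_state$t)
      vhat <- v / (1 - b2^opt_state$t)
      model$params[[nm]] <- model$params[[nm]] -
        lr[[grp]] * mhat / (sqrt(vhat) + eps)
    } else {
      v <- opt_state[[nm]]
      if (is.null(v)) v <- g * 0
      v <- cfg$momentum * v - lr[[grp]] * g
      opt_state[[nm]] <- v
      model$params[[nm]] <- model$params[[nm]] + v
    }
  }
  if (!is.null(cfg$max_norm) && model$spec$use_reader_embeddings)
    model <- apply_max_norm(model, cfg$max_norm)
  list(model = model, opt_state = opt_state)
}

#' Train a model on a simulated panel dataset
#'
#' Minibatch training with per-group learning rates and weight decays, the
#' halving learning-rate schedule, cross-entropy loss (mean over the batch),
#' and the max-norm constraint on embedding rows after every step. The
#' optimizer is Adam by default (robust when training the compact backbone
#' from scratch); momentum SGD is available via the configuration.
#' With `target = "reader_label"` each epoch draws one (image, reader, label)
#' triple per training image via [epoch_sample()] and feeds the reader index
#' through the embedding branch; with `target = "final_label"` the arbitrated
#' final labels are used and reader identity is ignored.
#'
#' After every epoch the model is evaluated on the validation images:
#' baseline models predict directly and are scored against the arbitrated
#' final labels, while reader-label models predict conditionally on one
#' uniformly sampled annotating reader per validation image and are scored
#' against that reader's own annotation — the validation target matches the
#' training target for each variant, so the reader-label curve reflects the
#' noisier individual-annotation objective (aggregation over all readers is
#' an inference-time operation, see [classify()]).
#'
#' @param model a `readernet_model`.
#' @param data a `panel_data` dataset.
#' @param split a `dataset_split`; training uses `train_images`, validation
#'   uses `test_images` unless `val_images` is given.
#' @param cfg a [train_config()].
#' @param val_images optional explicit validation image ids.
#' @param opt_state optional optimizer state (momentum buffers) to resume.
#' @param start_epoch zero-based epoch offset when resuming (keeps the
#'   learning-rate schedule aligned).
#' @param verbose print per-epoch metrics.
#' @return list with `model`, `history` (data.frame epoch, train_loss,
#'   val_loss, val_accuracy, lr_conv, lr_fc, lr_proj, lr_emb), `opt_state`,
#'   `steps` (gradient steps performed), `max_row_norms` (max embedding-row
#'   norm recorded after each step, or NULL).
#' @export
train_loop <- function(model, data, split, cfg, val_images = NULL,
                       opt_state = NULL, start_epoch = 0L, verbose = FALSE) {
  stopifnot(inherits(model, "readernet_model"), inherits(cfg, "train_config"),
            inherits(data, "panel_data"))
  if (cfg$target == "reader_label" && !model$spec$use_reader_embeddings)
    stop("reader_label target requires a model with reader embeddings")
  model$spec$dropout <- cfg$dropout
  train_ids <- split$train_images
  val_ids <- val_images %||% split$test_images
  finals <- stats::setNames(as.character(data$finals$label), data$finals$image_id)

  x_train <- stack_pixels(data$images, train_ids)
  x_val <- stack_pixels(data$images, val_ids)
  val_final_idx <- label_index(finals[val_ids])
  ann <- data$annotations[data$annotations$phase != "CONSENSUS", ]
  ann <- ann[ann$image_id %in% c(train_ids, val_ids), ]

  n_train <- length(train_ids)
  steps <- 0L
  max_row_norms <- if (model$spec$use_reader_embeddings) numeric(0) else NULL
  hist <- vector("list", cfg$epochs)
  set.seed(derive_seed(cfg$seed, 101L + start_epoch))

  for (ep in seq_len(cfg$epochs)) {
    epoch <- start_epoch + ep - 1L
    if (cfg$target == "reader_label") {
      es <- epoch_sample(ann, train_ids)
      order_ids <- es$image_id
      targets <- label_index(es$label)
      readers <- resolve_reader_idx(model, es$reader_id)
    } else {
      order_ids <- sample(train_ids)
      targets <- label_index(finals[order_ids])
      readers <- NULL
    }
    pos <- match(order_ids, train_ids)
    losses <- numeric(0)
    for (b in seq(1, n_train, by = cfg$batch_size)) {
      sel <- b:min(b + cfg$batch_size - 1L, n_train)
      xb <- x_train[, , , pos[sel], drop = FALSE]
      fwd <- model_forward(model, xb,
                           reader_idx = if (is.null(readers)) NULL else readers[sel],
                           train = TRUE, keep_cache = TRUE)
      grads <- model_backward(model, fwd, targets[sel])
      if (!is.finite(grads$loss))
        stop("non-finite training loss at epoch ", epoch, ", step ", steps + 1L,
             "; consider lowering the learning rates")
      upd <- optimizer_step(model, grads, opt_state %||% list(), cfg, epoch)
      model <- upd$model; opt_state <- upd$opt_state
      steps <- steps + 1L
      losses <- c(losses, grads$loss)
      if (!is.null(max_row_norms))
        max_row_norms <- c(max_row_norms, max(sqrt(rowSums(model$params$emb^2))))
    }
    val <- validate_epoch(model, x_val, val_ids, val_final_idx, ann, cfg)
    hist[[ep]] <- data.frame(
      epoch = epoch, train_loss = mean(losses), val_loss = val$loss,
      val_accuracy = val$accuracy,
      lr_conv = lr_at_epoch(cfg$base_lr_conv, epoch, cfg$lr_milestones),
      lr_fc = lr_at_epoch(cfg$base_lr_fc, epoch, cfg$lr_milestones),
      lr_proj = lr_at_epoch(cfg$base_lr_proj, epoch, cfg$lr_milestones),
      lr_emb = lr_at_epoch(cfg$base_lr_emb, epoch, cfg$lr_milestones))
    if (verbose)
      message(sprintf("epoch %3d  train_loss %.4f  val_loss %.4f  val_acc %.3f",
                      epoch, mean(losses), val$loss, val$accuracy))
  }
  list(model = model, history = do.call(rbind, hist), opt_state = opt_state,
       steps = steps, max_row_norms = max_row_norms)
}

# per-epoch validation (eval mode, no dropout); the target matches the
# training target: final labels for the baseline, the sampled reader's own
# annotation for reader-label models
validate_epoch <- function(model, x_val, val_ids, val_final_idx, ann, cfg) {
  if (cfg$target == "reader_label") {
    es <- epoch_sample(ann, val_ids)
    es <- es[match(val_ids, es$image_id), ]
    readers <- resolve_reader_idx(model, es$reader_id)
    target_idx <- label_index(es$label)
  } else {
    readers <- NULL
    target_idx <- val_final_idx
  }
  probs <- predict_probs_batch(model, x_val, reader_idx = readers,
                               batch_size = cfg$batch_size)
  n <- length(val_ids)
  loss <- -mean(log(pmax(probs[cbind(target_idx, seq_len(n))], 1e-12)))
  acc <- mean(max.col(t(probs), ties.method = "first") == target_idx)
  list(loss = loss, accuracy = acc)
}

# batched eval-mode probabilities; reader_idx NULL (baseline), scalar, or
# length-N vector. Returns n_classes x N matrix.
predict_probs_batch <- function(model, x, reader_idx = NULL, batch_size = 64L) {
  n <- dim(x)[4]
  if (!is.null(reader_idx) && length(reader_idx) == 1L)
    reader_idx <- rep(reader_idx, n)
  out <- matrix(0, model$spec$n_classes, n)
  for (b in seq(1, n, by = batch_size)) {
    sel <- b:min(b + batch_size - 1L, n)
    out[, sel] <- model_forward(
      model, x[, , , sel, drop = FALSE],
      reader_idx = if (is.null(reader_idx)) NULL else reader_idx[sel])$probs
  }
  out
}
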
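#' Model specification
#'
#' Describes the classifier architecture. The backbone produces a D-dimensional
#' image embedding by global average pooling (GAP) of its final convolutional
#' feature map; the reader branch maps a reader identifier through an
#' `n_readers x reader_emb_dim` embedding table and an affine projection to
#' dimension D, applies the chosen activation, and modulates the image
#' embedding element-wise before the shared 5-way softmax head.
#'
#' `toy_cnn` (three 3x3 conv + ReLU + 2x2 maxpool blocks with channel widths
#' `c(8, 16, embed_dim)`) is the supported, trainable backbone. The residual
#' backbones (`resnet18`/`resnet34`/`resnet50`, D = 512/512/2048) are accepted
#' by the specification for completeness but are not implemented in this
#' package and raise an error at build time.
#'
#' @param backbone one of `"toy_cnn"`, `"resnet18"`, `"resnet34"`, `"resnet50"`.
#' @param n_readers number of readers in the embedding table (>= 1).
#' @param reader_emb_dim width of the reader embedding table (default 32).
#' @param activation activation applied to the projected reader embedding:
#'   `"identity"`, `"relu"`, `"tanh"` or `"sigmoid"`.
#' @param max_norm optional positive maximum L2 norm of embedding rows,
#'   enforced after every optimizer step.
#' @param dropout dropout proportion in \[0, 1) applied to the (modulated)
#'   image embedding during training.
#' @param use_reader_embeddings if `FALSE`, the model is the plain baseline
#'   classifier and ignores reader identity.
#' @param embed_dim image-embedding dimension D of the toy backbone.
#' @param n_classes number of output classes (5).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(backbone = c("toy_cnn", "resnet18", "resnet34", "resnet50"),
                       n_readers = 1L, reader_emb_dim = 32L,
                       activation = c("identity", "relu", "tanh", "sigmoid"),
                       max_norm = NULL, dropout = 0,
                       use_reader_embeddings = TRUE,
                       embed_dim = 32L, n_classes = 5L) {
  backbone <- match.arg(backbone)
  activation <- match.arg(activation)
  if (n_readers < 1) stop("n_readers must be >= 1")
  if (reader_emb_dim < 1) stop("reader_emb_dim must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (!is.null(max_norm) && max_norm <= 0) stop("max_norm must be positive")
  D <- switch(backbone, toy_cnn = as.integer(embed_dim),
              resnet18 = 512L, resnet34 = 512L, resnet50 = 2048L)
  structure(
    list(backbone = backbone, n_classes = as.integer(n_classes),
         n_readers = as.integer(n_readers),
         reader_emb_dim = as.integer(reader_emb_dim),
         activation = activation, max_norm = max_norm, dropout = dropout,
         use_reader_embeddings = isTRUE(use_reader_embeddings),
         embed_dim = D, channels = c(8L, 16L, D)),
    class = "model_spec")
}

#' Build a model from a specification
#'
#' Initializes all parameters from `init_seed` (two builds with the same seed
#' are bit-identical). Convolutional weights use He initialization; the
#' reader-embedding table starts as small Gaussian noise (sd 0.01) and the
#' projection bias at 1, so that with the identity activation the modulation
#' vector starts near all-ones and training begins close to the baseline
#' model.
#'
#' @param spec a [model_spec()].
#' @param reader_ids optional character vector of reader identifiers; its
#'   length overrides `spec$n_readers`.
#' @param init_seed integer seed for parameter initialization.
#' @return object of class `readernet_model`.
#' @export
build_model <- function(spec, reader_ids = NULL, init_seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$backbone != "toy_cnn")
    stop("backbone '", spec$backbone, "' is not implemented in this package; ",
         "use the 'toy_cnn' backbone")
  if (!is.null(reader_ids)) {
    spec$n_readers <- length(reader_ids)
  } else {
    reader_ids <- sprintf("r%d", seq_len(spec$n_readers))
  }
  D <- spec$embed_dim
  ch <- c(1L, spec$channels)
  params <- with_seed(init_seed, {
    p <- list()
    for (k in 1:3) {
      fan_in <- 9 * ch[k]
      p[[paste0("conv_w", k)]] <-
        array(rnorm(9 * ch[k] * ch[k + 1], sd = sqrt(2 / fan_in)),
              c(3, 3, ch[k], ch[k + 1]))
      p[[paste0("conv_b", k)]] <- numeric(ch[k + 1])
    }
    p$fc_w <- matrix(rnorm(D * spec$n_classes, sd = 1 / sqrt(D)), D, spec$n_classes)
    p$fc_b <- numeric(spec$n_classes)
    if (spec$use_reader_embeddings) {
      p$emb <- matrix(rnorm(spec$n_readers * spec$reader_emb_dim, sd = 0.01),
                      spec$n_readers, spec$reader_emb_dim)
      p$proj_w <- matrix(rnorm(spec$reader_emb_dim * D,
                               sd = 1 / sqrt(spec$reader_emb_dim)),
                         spec$reader_emb_dim, D)
      p$proj_b <- rep(1, D)
    }
    p
  })
  structure(list(spec = spec, params = params, reader_ids = reader_ids),
            class = "readernet_model")
}

# activation of the projected reader embedding and its derivative
mod_activation <- function(pre, kind) {
  switch(kind,
         identity = pre,
         relu = pre * (pre > 0),
         tanh = tanh(pre),
         sigmoid = 1 / (1 + exp(-pre)))
}

mod_activation_grad <- function(pre, act, kind) {
  switch(kind,
         identity = array(1, dim(pre) %||% length(pre)),
         relu = (pre > 0) + 0,
         tanh = 1 - act^2,
         sigmoid = act * (1 - act))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# coerce pixels (matrix, synth_image, or (H,W,1,N) array) to a 4-d batch
as_image_batch <- function(x) {
  if (inherits(x, "synth_image")) x <- x$pixels
  if (is.matrix(x)) dim(x) <- c(nrow(x), ncol(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  if (length(dim(x)) != 4L) stop("image input must be H x W (x 1 x N)")
  x
}

# backbone forward: returns D x N embedding matrix and per-layer caches
backbone_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  cache <- list(x = x)
  for (k in 1:3) {
    z <- conv2d_fw(x, p[[paste0("conv_w", k)]], p[[paste0("conv_b", k)]])
    a <- z * (z > 0)
    pl <- maxpool2_fw(a)
    if (keep_cache) {
      cache[[paste0("in", k)]] <- x
      cache[[paste0("relu_mask", k)]] <- (z > 0)
      cache[[paste0("a", k)]] <- a
      cache[[paste0("pool_idx", k)]] <- pl$idx
      cache[[paste0("adim", k)]] <- dim(a)
    }
    x <- pl$y
  }
  d <- dim(x)  # (h, w, D, N)
  hw <- d[1] * d[2]
  emb <- matrix(colMeans(matrix(x, nrow = hw)), d[3], d[4])
  if (keep_cache) {
    cache$pooled_dim <- d
    cache$emb <- emb
  }
  list(emb = emb, cache = if (keep_cache) cache else NULL)
}

# backbone backward: demb is D x N; returns gradients for conv params
backbone_backward <- function(model, cache, demb) {
  p <- model$params
  d <- cache$pooled_dim
  hw <- d[1] * d[2]
  # GAP backward: every spatial cell receives demb / hw
  dpool <- array(rep(as.vector(demb / hw), each = hw), d)
  grads <- list()
  for (k in 3:1) {
    da <- maxpool2_bw(dpool, cache[[paste0("pool_idx", k)]],
                      cache[[paste0("adim", k)]])
    dz <- da * cache[[paste0("relu_mask", k)]]
    g <- conv2d_bw(cache[[paste0("in", k)]], p[[paste0("conv_w", k)]], dz)
    grads[[paste0("conv_w", k)]] <- g$dw
    grads[[paste0("conv_b", k)]] <- g$db
    if (k > 1) dpool <- g$dx
  }
  grads
}

# modulation vectors for a vector of reader indices: returns list(m, pre, E)
# with m and pre D x N, E the reader_emb_dim x N selected embedding rows
reader_modulation <- function(model, reader_idx) {
  p <- model$params
  E <- t(p$emb[reader_idx, , drop = FALSE])      # emb_dim x N
  pre <- crossprod(p$proj_w, E) + p$proj_b       # D x N
  m <- mod_activation(pre, model$spec$activation)
  list(m = m, pre = pre, E = E)
}

softmax_cols <- function(logits) {
  z <- exp(sweep(logits, 2, apply(logits, 2, max)))
  sweep(z, 2, colSums(z), "/")
}

# full forward pass on a batch; reader_idx NULL for the baseline path.
# train = TRUE applies (and caches) a dropout mask on the pre-classifier
# embedding. Returns probs (n_classes x N) and optionally caches.
model_forward <- function(model, x, reader_idx = NULL, train = FALSE,
                          keep_cache = FALSE) {
  spec <- model$spec
  p <- model$params
  bb <- backbone_forward(model, as_image_batch(x), keep_cache = keep_cache)
  h <- bb$emb
  mod <- NULL
  if (!is.null(reader_idx)) {
    if (!spec$use_reader_embeddings)
      stop("model was built without reader embeddings")
    if (any(reader_idx < 1 | reader_idx > spec$n_readers))
      stop("reader index out of range 1..", spec$n_readers)
    mod <- reader_modulation(model, reader_idx)
    h <- h * mod$m
  }
  drop_mask <- NULL
  if (train && spec$dropout > 0) {
    drop_mask <- matrix(rbinom(length(h), 1, 1 - spec$dropout), nrow(h)) /
      (1 - spec$dropout)
    h <- h * drop_mask
  }
  logits <- crossprod(p$fc_w, h) + p$fc_b
  probs <- softmax_cols(logits)
  if (!keep_cache) return(list(probs = probs))
  list(probs = probs,
       cache = list(backbone = bb$cache, emb = bb$cache$emb, mod = mod,
                    reader_idx = reader_idx, drop_mask = drop_mask, h = h))
}

# backward from class targets (1-based indices); returns gradient list and
# the mean cross-entropy loss. probs/cache from model_forward(keep_cache=TRUE).
model_backward <- function(model, fwd, target_idx) {
  p <- model$params
  probs <- fwd$probs
  n <- ncol(probs)
  loss <- -mean(log(pmax(probs[cbind(target_idx, seq_len(n))], 1e-12)))
  dlogits <- probs
  dlogits[cbind(target_idx, seq_len(n))] <-
    dlogits[cbind(target_idx, seq_len(n))] - 1
  dlogits <- dlogits / n
  cache <- fwd$cache
  grads <- list(fc_w = cache$h %*% t(dlogits), fc_b = rowSums(dlogits))
  dh <- p$fc_w %*% dlogits
  if (!is.null(cache$drop_mask)) dh <- dh * cache$drop_mask
  if (!is.null(cache$mod)) {
    mod <- cache$mod
    demb_img <- dh * mod$m
    dm <- dh * cache$emb
    dpre <- dm * mod_activation_grad(mod$pre, mod$m, model$spec$activation)
    grads$proj_w <- mod$E %*% t(dpre)
    grads$proj_b <- rowSums(dpre)
    dE <- p$proj_w %*% dpre  # emb_dim x N
    demb_tab <- matrix(0, model$spec$n_readers, model$spec$reader_emb_dim)
    agg <- rowsum(t(dE), group = cache$reader_idx)
    demb_tab[as.integer(rownames(agg)), ] <- agg
    grads$emb <- demb_tab
  } else {
    demb_img <- dh
  }
  c(grads, backbone_backward(model, cache$backbone, demb_img),
    list(loss = loss))
}

#' Per-reader forward pass
#'
#' Predicts how a given reader would classify an image: the image embedding is
#' modulated element-wise by the reader's activated projected embedding before
#' the softmax head.
#'
#' @param model a `readernet_model` built with reader embeddings.
#' @param image image pixels (matrix in \[0, 1\]) or a `synth_image`.
#' @param reader_id reader identifier (character) or 1-based index.
#' @return named numeric vector of 5 class probabilities (sums to 1).
#' @export
forward_reader <- function(model, image, reader_id) {
  idx <- resolve_reader_idx(model, reader_id)
  pr <- model_forward(model, image, reader_idx = idx)$probs[, 1]
  stats::setNames(pr, class_labels())
}

#' Baseline forward pass
#'
#' Class probabilities ignoring reader identity (the plain backbone + head
#' path).
#'
#' @inheritParams forward_reader
#' @return named numeric vector of 5 class probabilities.
#' @export
forward_baseline <- function(model, image) {
  pr <- model_forward(model, image)$probs[, 1]
  stats::setNames(pr, class_labels())
}

resolve_reader_idx <- function(model, reader_id) {
  if (is.character(reader_id)) {
    idx <- match(reader_id, model$reader_ids)
    if (anyNA(idx)) stop("unknown reader id: ",
                         paste(reader_id[is.na(idx)], collapse = ", "))
    return(idx)
  }
  idx <- as.integer(reader_id)
  if (any(idx < 1 | idx > model$spec$n_readers))
    stop("reader index out of range 1..", model$spec$n_readers)
  idx
}

#' Project embedding rows onto the max-norm ball
#'
#' Rows of the reader-embedding table whose L2 norm exceeds `max_norm` are
#' rescaled to norm exactly `max_norm`; other rows are untouched. Applied
#' after every optimizer step during training when the spec sets a max norm.
#'
#' @param x a `readernet_model` or an embedding matrix (rows = readers).
#' @param max_norm positive scalar.
#' @return object of the same type as `x` with constrained rows.
#' @export
apply_max_norm <- function(x, max_norm) {
  if (max_norm <= 0) stop("max_norm must be positive")
  if (inherits(x, "readernet_model")) {
    x$params$emb <- apply_max_norm(x$params$emb, max_norm)
    return(x)
  }
  nrm <- sqrt(rowSums(x^2))
  scale <- ifelse(nrm > max_norm, max_norm / nrm, 1)
  x * scale
}

#' Parameter counts of a model
#'
#' @param model a `readernet_model`.
#' @return named list with per-group counts, the total, and
#'   `reader_branch_extra`, the parameters added by the reader branch:
#'   `n_readers * reader_emb_dim + reader_emb_dim * D + D`.
#' @export
count_parameters <- function(model) {
  p <- model$params
  sizes <- vapply(p, length, 0L)
  conv <- sum(sizes[grep("^conv", names(sizes))])
  fc <- sum(sizes[c("fc_w", "fc_b")])
  extra <- if (model$spec$use_reader_embeddings)
    length(p$emb) + length(p$proj_w) + length(p$proj_b) else 0L
  list(conv = conv, classifier = fc, reader_branch_extra = extra,
       total = conv + fc + extra)
}

#' @export
print.readernet_model <- function(x, ...) {
  s <- x$spec
  n <- count_parameters(x)
  cat("readernet model —", s$backbone,
      if (s$use_reader_embeddings) "with reader embeddings" else "baseline", "\n")
  cat("  embedding dim D =", s$embed_dim, "; classes =", s$n_classes, "\n")
  if (s$use_reader_embeddings)
    cat("  readers =", s$n_readers, "; reader_emb_dim =", s$reader_emb_dim,
        "; activation =", s$activation,
        "; reader-branch parameters =", n$reader_branch_extra, "\n")
  cat("  parameters: conv", n$conv, "+ classifier", n$classifier,
      if (s$use_reader_embeddings) paste("+ reader branch", n$reader_branch_extra),
      "=", n$total, "\n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the spec, all parameters, the reader identifiers and
#' the RNG state in a single file.
#'
#' @param model a `readernet_model`.
#' @param path file path.
#' @return `load_model` returns the model; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  rng <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  saveRDS(list(spec = model$spec, params = model$params,
               reader_ids = model$reader_ids, rng_state = rng), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  structure(list(spec = obj$spec, params = obj$params,
                 reader_ids = obj$reader_ids),
            class = "readernet_model")
}
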
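#' Hyper-parameter search space
#'
#' Random-search samplers for the tuned training dimensions: log-uniform for
#' learning rates and weight decays, uniform for dropout and augmentation
#' proportions, categorical for batch size, activation and the embedding
#' max-norm.
#'
#' @param lr_range,wd_range log-uniform ranges for learning rates / decays.
#' @param dropout_range,p_range uniform ranges for dropout and the two
#'   augmentation proportions.
#' @param batch_sizes,activations,max_norms categorical choices.
#' @return object of class `hpo_space`: a named list of sampler
#'   specifications.
#' @export
hpo_space <- function(lr_range = c(1e-5, 1e-1), wd_range = c(1e-6, 1e-1),
                      dropout_range = c(0, 0.5), p_range = c(0, 1),
                      batch_sizes = c(8L, 16L, 32L),
                      activations = c("identity", "relu", "tanh", "sigmoid"),
                      max_norms = c(1, 2, 4)) {
  stopifnot(length(batch_sizes) >= 1, length(activations) >= 1,
            length(max_norms) >= 1, all(lr_range > 0), all(wd_range > 0))
  loguni <- function(r) list(kind = "loguniform", min = r[1], max = r[2])
  uni <- function(r) list(kind = "uniform", min = r[1], max = r[2])
  cat_ <- function(v) list(kind = "categorical", values = v)
  structure(list(
    base_lr_conv = loguni(lr_range), base_lr_fc = loguni(lr_range),
    base_lr_proj = loguni(lr_range), base_lr_emb = loguni(lr_range),
    wd_conv = loguni(wd_range), wd_fc = loguni(wd_range),
    wd_proj = loguni(wd_range),
    dropout = uni(dropout_range), p_affine = uni(p_range),
    p_color = uni(p_range),
    batch_size = cat_(batch_sizes), activation = cat_(activations),
    max_norm = cat_(max_norms)), class = "hpo_space")
}

sample_dim <- function(sampler) {
  switch(sampler$kind,
         loguniform = exp(runif(1, log(sampler$min), log(sampler$max))),
         uniform = runif(1, sampler$min, sampler$max),
         categorical = sampler$values[[sample.int(length(sampler$values), 1)]],
         stop("unknown sampler kind: ", sampler$kind))
}

#' Draw one configuration from the search space
#'
#' Each dimension is drawn independently from its sampler using the current
#' R RNG stream (reproducible under a fixed seed).
#'
#' @param space an [hpo_space()].
#' @return named list of sampled hyper-parameter values (includes an
#'   `activation` entry, consumed by the model spec rather than
#'   [train_config()]).
#' @export
sample_config <- function(space) {
  stopifnot(inherits(space, "hpo_space"))
  lapply(space, sample_dim)
}

#' Synchronous successive-halving hyper-parameter search
#'
#' Random search with successive halving: `n_samples` configurations are
#' drawn from `space` and trained to the first rung (epoch budget); at each
#' rung the top `1/eta` fraction by validation metric is promoted to the next
#' rung; survivors of the last rung are trained to the full epoch `budget`.
#' Ties are broken by the previous rung's metric, then by configuration draw
#' order. This is the deterministic synchronous variant of asynchronous
#' successive halving (ASHA); asynchrony is a cluster-efficiency device and
#' does not change the selection rule in expectation.
#'
#' `train_fn(config, epochs, state)` must train the configuration for
#' `epochs` *additional* epochs, resuming from `state` (NULL on first call),
#' and return `list(metric = <validation accuracy>, state = <opaque>)`.
#' A failing trial is marked `FAILED` and excluded from promotion.
#'
#' @param space an [hpo_space()].
#' @param train_fn trial evaluation function (see Details).
#' @param n_samples number of sampled configurations.
#' @param rungs strictly increasing epoch rungs (paper-scale default
#'   `c(10, 20, 40, 80)`; see `preset`).
#' @param eta promotion factor (>= 2): top `1/eta` survive each rung.
#' @param budget total epoch budget per surviving trial.
#' @param seed integer seed for sampling.
#' @param preset `"desk"` (n = 16, rungs 2/4/8, budget 12) or `"paper"`
#'   (n = 300, rungs 10/20/40/80, budget 150); explicit arguments override
#'   the preset.
#' @return list with `best_config`, `best_metric`, `trials` (list of per-
#'   trial records: config, metric at each visited rung, status,
#'   epochs_charged), and `total_epochs` (exact epoch accounting).
#' @export
run_halving <- function(space, train_fn, n_samples = NULL, rungs = NULL,
                        eta = 2, budget = NULL, seed = 1,
                        preset = c("desk", "paper")) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
                     desk = list(n = 16L, rungs = c(2L, 4L, 8L), budget = 12L),
                     paper = list(n = 300L, rungs = c(10L, 20L, 40L, 80L),
                                  budget = 150L))
  n_samples <- n_samples %||% defaults$n
  rungs <- rungs %||% defaults$rungs
  budget <- budget %||% defaults$budget
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (eta < 2) stop("eta must be >= 2")
  if (any(diff(rungs) <= 0)) stop("rungs must be strictly increasing")
  if (budget < rungs[length(rungs)]) stop("budget must cover the last rung")

  set.seed(derive_seed(seed, 7L))
  rungs <- as.integer(rungs)
  budget <- as.integer(budget)
  trials <- lapply(seq_len(n_samples), function(i)
    list(trial_id = i, config = sample_config(space),
         metrics = stats::setNames(numeric(0), character(0)),
         status = "PENDING", epochs_charged = 0L, state = NULL))

  run_to <- function(tr, target_epochs) {
    add <- target_epochs - tr$epochs_charged
    res <- tryCatch(train_fn(tr$config, add, tr$state), error = function(e) e)
    if (inherits(res, "error")) {
      tr$status <- "FAILED"
      tr$error <- conditionMessage(res)
    } else {
      tr$state <- res$state
      tr$epochs_charged <- as.integer(target_epochs)
      tr$metrics[as.character(target_epochs)] <- res$metric
    }
    tr
  }

  alive <- seq_len(n_samples)
  for (k in seq_along(rungs)) {
    for (i in alive) trials[[i]] <- run_to(trials[[i]], rungs[k])
    alive <- alive[vapply(trials[alive], function(t) t$status != "FAILED", TRUE)]
    if (!length(alive)) stop("all trials failed at rung ", rungs[k])
    ord <- order_trials(trials, alive, rungs[seq_len(k)])
    n_keep <- if (k < length(rungs)) max(1L, ceiling(length(alive) / eta))
              else length(alive)
    stopped <- alive[setdiff(seq_along(alive), ord[seq_len(n_keep)])]
    for (i in stopped) trials[[i]]$status <- "STOPPED"
    alive <- alive[ord[seq_len(n_keep)]]
    for (i in alive)
      trials[[i]]$status <- if (k < length(rungs)) "PROMOTED" else "SURVIVED"
  }
  if (budget > rungs[length(rungs)]) {
    for (i in alive) trials[[i]] <- run_to(trials[[i]], budget)
    alive <- alive[vapply(trials[alive], function(t) t$status != "FAILED", TRUE)]
    if (!length(alive)) stop("all surviving trials failed at the final budget")
  }
  for (i in alive) trials[[i]]$status <- "COMPLETED"
  ord <- order_trials(trials, alive, c(rungs, budget))
  best <- trials[[alive[ord[1]]]]
  trials <- lapply(trials, function(t) { t$state <- NULL; t })
  list(best_config = best$config,
       best_metric = unname(best$metrics[length(best$metrics)]),
       best_trial_id = best$trial_id,
       trials = trials,
       total_epochs = sum(vapply(trials, `[[`, 0L, "epochs_charged")))
}

# rank alive trials: latest-rung metric desc, earlier rungs desc, draw order
order_trials <- function(trials, alive, visited_rungs) {
  keys <- lapply(rev(visited_rungs), function(r)
    -vapply(trials[alive], function(t) {
      m <- t$metrics[as.character(r)]
      if (is.na(m) || !length(m)) -Inf else unname(m)
    }, 0))
  do.call(order, c(keys, list(vapply(trials[alive], `[[`, 0L, "trial_id"))))
}

#' Trials log as a data.frame
#'
#' One row per visited rung per trial: `trial_id, rung, epochs,
#' val_accuracy, status`.
#'
#' @param result the return value of [run_halving()].
#' @return data.frame suitable for writing as the trials CSV.
#' @export
trials_log <- function(result) {
  do.call(rbind, lapply(result$trials, function(t) {
    if (!length(t$metrics))
      return(data.frame(trial_id = t$trial_id, rung = NA_integer_,
                        epochs = 0L, val_accuracy = NA_real_,
                        status = t$status))
    data.frame(trial_id = t$trial_id,
               rung = seq_along(t$metrics),
               epochs = as.integer(names(t$metrics)),
               val_accuracy = unname(t$metrics),
               status = t$status)
  }))
}

#' Build a trial-evaluation function over a simulated dataset
#'
#' Returns a `train_fn` for [run_halving()] that trains the requested model
#' variant on the given dataset, resuming across rungs (the trial state holds
#' the model, optimizer buffers and epoch counter) and reporting validation
#' accuracy against final labels as the promotion metric.
#'
#' @param data a `panel_data`.
#' @param split a `dataset_split`.
#' @param use_reader_embeddings train the reader-label model (TRUE) or the
#'   baseline (FALSE).
#' @param embed_dim toy backbone embedding dimension.
#' @param base_seed seed offset for trial reproducibility.
#' @return function(config, epochs, state) -> list(metric, state).
#' @export
make_train_fn <- function(data, split, use_reader_embeddings = TRUE,
                          embed_dim = 32L, base_seed = 1L) {
  readers <- sort(unique(
    data$annotations$reader_id[data$annotations$phase != "CONSENSUS"]))
  function(config, epochs, state) {
    if (is.null(state)) {
      spec <- model_spec("toy_cnn", n_readers = length(readers),
                         activation = config$activation %||% "identity",
                         max_norm = config$max_norm,
                         dropout = config$dropout %||% 0,
                         use_reader_embeddings = use_reader_embeddings,
                         embed_dim = embed_dim)
      model <- build_model(spec, reader_ids = if (use_reader_embeddings) readers,
                           init_seed = derive_seed(base_seed, 23L))
      state <- list(model = model, opt_state = NULL, epoch = 0L)
    }
    cfg <- train_config(
      batch_size = as.integer(config$batch_size %||% 32L), epochs = epochs,
      base_lr_conv = config$base_lr_conv %||% 0.02,
      base_lr_fc = config$base_lr_fc %||% 0.02,
      base_lr_proj = config$base_lr_proj %||% 0.01,
      base_lr_emb = config$base_lr_emb %||% 0.05,
      wd_conv = config$wd_conv %||% 0, wd_fc = config$wd_fc %||% 0,
      wd_proj = config$wd_proj %||% 0,
      dropout = config$dropout %||% 0, max_norm = config$max_norm,
      target = if (use_reader_embeddings) "reader_label" else "final_label",
      seed = derive_seed(base_seed, 31L + state$epoch))
    fit <- train_loop(state$model, data, split, cfg,
                      opt_state = state$opt_state, start_epoch = state$epoch)
    metric <- fit$history$val_accuracy[nrow(fit$history)]
    list(metric = metric,
         state = list(model = fit$model, opt_state = fit$opt_state,
                      epoch = state$epoch + epochs))
  }
}
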
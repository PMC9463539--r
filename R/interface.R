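ANNOTATION_COLUMNS <- c("image_id", "patient_id", "site", "age_months",
                        "reader_id", "role", "phase", "label", "true_class")

#' Read an annotation manifest
#'
#' Reads and validates the annotation CSV (header
#' `image_id,patient_id,site,age_months,reader_id,role,phase,label,true_class`).
#' Labels are parsed to the canonical classes; malformed rows are rejected
#' with their line numbers.
#'
#' @param path CSV path.
#' @return validated annotations data.frame.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(ANNOTATION_COLUMNS, names(df))
  if (length(missing))
    stop("annotation manifest is missing column(s): ",
         paste(missing, collapse = ", "))
  lv <- class_labels()
  bad <- which(!(df$label %in% lv) | !(df$true_class %in% lv))
  if (length(bad))
    stop("unknown class label at line(s) ",
         paste(utils::head(bad + 1L, 10), collapse = ", "),
         " of ", path)  # +1 for the header line
  bad_phase <- which(!df$phase %in% c("INITIAL", "ARBITRATION", "CONSENSUS", "QC"))
  if (length(bad_phase))
    stop("unknown phase at line(s) ",
         paste(utils::head(bad_phase + 1L, 10), collapse = ", "), " of ", path)
  df[, ANNOTATION_COLUMNS]
}

#' Write the annotation manifest
#'
#' @param annotations annotations data.frame (from a `panel_data`).
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.csv(annotations[, ANNOTATION_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Read / write final arbitrated labels
#'
#' CSV with header `image_id,label,provenance`.
#'
#' @param finals data.frame of final labels.
#' @param path CSV path.
#' @return `read_finals` returns the data.frame; `write_finals` the path.
#' @export
write_finals <- function(finals, path) {
  utils::write.csv(finals[, c("image_id", "label", "provenance")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_finals
#' @export
read_finals <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "label", "provenance")
  if (length(setdiff(need, names(df))))
    stop("final-label file must have columns image_id,label,provenance")
  bad <- which(!(df$label %in% class_labels()))
  if (length(bad))
    stop("unknown class label at line(s) ",
         paste(utils::head(bad + 1L, 10), collapse = ", "), " of ", path)
  df[, need]
}

#' Write dataset images as 8-bit grayscale PNG files
#'
#' @param data a `panel_data`.
#' @param dir output directory (created if needed); files are named
#'   `<image_id>.png`.
#' @return invisibly, the written paths.
#' @export
write_images <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(data$images, function(im) {
    p <- file.path(dir, paste0(im$image_id, ".png"))
    png::writePNG(im$pixels, p)
    p
  }, "")
  invisible(paths)
}

#' Default experiment configuration
#'
#' The desk-scale experiment: 1,500 images at 64 x 64 with the default class
#' prior, 6 initial readers (three sites) and 2 arbitrators with
#' heterogeneous confusion matrices, a 20% patient-level hold-out, and 30
#' epochs of training for both model variants.
#'
#' @param seed root seed propagated to all stages.
#' @return nested list of class `experiment_config` with sections
#'   `simulation`, `model`, `training`, `evaluation`.
#' @export
default_experiment_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulation = list(
      n_images = 1500L, n_initial_readers = 6L, n_arbitrators = 2L,
      image_size = 64L, prior = unname(class_prior()),
      acc_initial = c(0.55, 0.9), acc_arbitrator = c(0.85, 0.92)),
    split = list(test_fraction = 0.2),
    model = list(backbone = "toy_cnn", embed_dim = 32L, reader_emb_dim = 32L,
                 activation = "identity", max_norm = 4, dropout = 0.1),
    training = list(batch_size = 16L, epochs = 30L,
                    base_lr_conv = 0.01, base_lr_fc = 0.01,
                    base_lr_proj = 0.01, base_lr_emb = 0.01,
                    wd_conv = 1e-4, wd_fc = 1e-4, wd_proj = 1e-4,
                    lr_milestones = c(15L, 25L),
                    # the reader-label variant trains on noisier targets;
                    # its embedding branch gets a hotter rate (the two
                    # variants have different optimization sweet spots)
                    reader_embedding = list(base_lr_emb = 0.03)),
    evaluation = list(group_keys = "site", age_breaks = c(0, 12, 60))),
    class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Missing keys fall back to [default_experiment_config()] values.
#'
#' @param path YAML file.
#' @return `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_experiment_config(seed = user$seed %||% 1L)
  merge_cfg <- function(base, user) {
    for (k in names(user)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(user[[k]]))
        merge_cfg(base[[k]], user[[k]]) else user[[k]]
    }
    base
  }
  out <- merge_cfg(unclass(base), user)
  structure(out, class = "experiment_config")
}

config_hash <- function(config) string_hash(as.character(canonical_json(unclass(config))))

#' Run a complete simulation-to-evaluation experiment
#'
#' Executes the full pipeline: simulate the annotated panel dataset, split by
#' patient, train the final-label baseline and the reader-label
#' reader-embedding variant, evaluate both on the held-out patients
#' (aggregating the reader-embedding model's per-reader predictions with an
#' unweighted mean), and write all artifacts (manifests, history, reports,
#' comparison JSON) into `out_dir`. Fully reproducible from (config, seed).
#'
#' @param config an `experiment_config` (see [default_experiment_config()]).
#' @param out_dir output directory for run artifacts (NULL: no files
#'   written).
#' @param variants which model variants to run.
#' @param verbose print stage progress.
#' @return list of class `run_manifest`: run id, config hash, artifact
#'   paths, and the in-memory `results` (per-variant eval reports, history,
#'   models, dataset and split).
#' @export
run_experiment <- function(config = default_experiment_config(),
                           out_dir = NULL,
                           variants = c("baseline", "reader_embedding"),
                           verbose = FALSE) {
  variants <- match.arg(variants, several.ok = TRUE)
  seed <- config$seed
  sim <- config$simulation
  say <- function(...) if (verbose) message(...)

  stage <- "simulate"
  res <- tryCatch({
    say("simulating panel dataset ...")
    profiles <- make_reader_profiles(
      sim$n_initial_readers, sim$n_arbitrators,
      acc_initial = sim$acc_initial, acc_arbitrator = sim$acc_arbitrator)
    # n_images -> n_patients via the images-per-patient multiplicity (~4%)
    n_patients <- round(sim$n_images / 1.04)
    data <- build_panel_dataset(
      n_patients = n_patients, n_initial_readers = sim$n_initial_readers,
      n_arbitrators = sim$n_arbitrators, prior = class_prior(sim$prior),
      profiles = profiles, image_size = sim$image_size,
      seed = derive_seed(seed, 1L))

    stage <- "split"
    split <- split_by_patient(data, config$split$test_fraction,
                              seed = derive_seed(seed, 2L))

    readers <- sort(unique(
      data$annotations$reader_id[data$annotations$phase != "CONSENSUS"]))
    mc <- config$model
    tc <- config$training
    results <- list()
    for (variant in variants) {
      stage <- paste0("train:", variant)
      say("training ", variant, " ...")
      use_emb <- variant == "reader_embedding"
      spec <- model_spec(mc$backbone,
                         activation = mc$activation, max_norm = mc$max_norm,
                         dropout = mc$dropout,
                         use_reader_embeddings = use_emb,
                         embed_dim = mc$embed_dim,
                         reader_emb_dim = mc$reader_emb_dim,
                         n_readers = max(1L, length(readers)))
      model <- build_model(spec, reader_ids = if (use_emb) readers,
                           init_seed = derive_seed(seed, 3L))
      # per-variant overrides, mirroring variant-specific hyper-parameter
      # optima (the two variants have different optimal learning rates)
      tc <- config$training
      if (!is.null(tc[[variant]]))
        tc <- utils::modifyList(tc, tc[[variant]])
      cfg <- train_config(
        batch_size = tc$batch_size, epochs = tc$epochs,
        base_lr_conv = tc$base_lr_conv, base_lr_fc = tc$base_lr_fc,
        base_lr_proj = tc$base_lr_proj, base_lr_emb = tc$base_lr_emb,
        wd_conv = tc$wd_conv, wd_fc = tc$wd_fc, wd_proj = tc$wd_proj,
        lr_milestones = tc$lr_milestones %||% c(50L, 100L),
        dropout = mc$dropout, max_norm = mc$max_norm,
        target = if (use_emb) "reader_label" else "final_label",
        seed = derive_seed(seed, 4L))
      fit <- train_loop(model, data, split, cfg)

      stage <- paste0("evaluate:", variant)
      say("evaluating ", variant, " ...")
      results[[variant]] <- evaluate_variant(fit$model, data, split, config,
                                             history = fit$history)
    }
    list(data = data, split = split, results = results)
  }, error = function(e) {
    stop("experiment failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- build_manifest(config, res, out_dir)
  if (!is.null(out_dir)) write_run_artifacts(manifest, res, out_dir)
  manifest
}

# evaluate one trained variant on the held-out images
evaluate_variant <- function(model, data, split, config, history = NULL) {
  ids <- split$test_images
  x <- stack_pixels(data$images, ids)
  finals <- stats::setNames(as.character(data$finals$label),
                            data$finals$image_id)
  truth <- finals[ids]
  meta_i <- match(ids, names(data$images))
  site <- vapply(data$images[meta_i], `[[`, "", "site")
  age <- vapply(data$images[meta_i], `[[`, 0, "age_months")
  if (model$spec$use_reader_embeddings) {
    pred <- predict_panel_batch(model, x)
    probs <- pred$aggregated
  } else {
    probs <- t(predict_probs_batch(model, x))
    colnames(probs) <- class_labels()
    pred <- NULL
  }
  labels <- class_labels()[max.col(probs, ties.method = "first")]
  rep <- eval_report(labels, truth, prob_matrix = probs,
                     groups = list(site = site,
                                   age_bin = cut(age, config$evaluation$age_breaks,
                                                 right = FALSE)))
  list(report = rep, history = history, model = model,
       pred_labels = labels, probs = probs, per_reader = pred$per_reader,
       test_truth = truth)
}

build_manifest <- function(config, res, out_dir) {
  structure(list(
    run_id = paste0("run-", config_hash(config), "-seed", config$seed),
    config = config, config_hash = config_hash(config),
    out_dir = out_dir,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    results = res$results, data = res$data, split = res$split),
    class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("run_manifest", x$run_id, "\n")
  for (v in names(x$results)) {
    r <- x$results[[v]]$report
    cat(sprintf("  %-18s accuracy %.3f  mean AUC %.3f\n", v, r$accuracy,
                r$auc_mean %||% NA))
  }
  invisible(x)
}

write_run_artifacts <- function(manifest, res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_annotations(res$data$annotations, file.path(out_dir, "annotations.csv"))
  write_finals(res$data$finals, file.path(out_dir, "final_labels.csv"))
  comparison <- lapply(res$results, function(r) {
    list(accuracy = r$report$accuracy, auc_mean = r$report$auc_mean,
         auc_per_class = as.list(r$report$auc_per_class))
  })
  jsonlite::write_json(
    list(run_id = manifest$run_id, config_hash = manifest$config_hash,
         comparison = comparison),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
  for (v in names(res$results)) {
    r <- res$results[[v]]
    if (!is.null(r$history))
      utils::write.csv(r$history[, c("epoch", "train_loss", "val_loss",
                                     "val_accuracy")],
                       file.path(out_dir, paste0("history_", v, ".csv")),
                       row.names = FALSE)
    save_model(r$model, file.path(out_dir, paste0("model_", v, ".rds")))
    write_eval_report(r$report, file.path(out_dir, paste0("report_", v, ".json")))
  }
  invisible(out_dir)
}
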
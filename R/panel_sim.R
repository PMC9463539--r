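#' Default class prevalence of the five radiograph categories
#'
#' Returns the marginal prior over the five WHO-style categories used by the
#' simulator: 15% consolidation, 24% other infiltrate, 11% both, 40% normal,
#' 10% uninterpretable, matching the prevalence observed in large multi-site
#' paediatric pneumonia studies.
#'
#' @param override optional 5-vector of probabilities replacing the default;
#'   must sum to 1.
#' @return named numeric 5-vector summing to 1.
#' @export
#' @examples
#' class_prior()
class_prior <- function(override = NULL) {
  p <- if (is.null(override)) c(0.15, 0.24, 0.11, 0.40, 0.10) else as.numeric(override)
  stopifnot_prob_vector(p, what = "class prior")
  stats::setNames(p, class_labels())
}

#' Construct a reader profile
#'
#' A reader is described by a 5x5 row-stochastic confusion matrix
#' `confusion[t, o] = P(observed = o | true = t)` and an age-noise slope that
#' controls how strongly the reader's error rate shrinks for older children.
#'
#' @param reader_id character scalar.
#' @param role `"INITIAL"` or `"ARBITRATOR"`.
#' @param confusion 5x5 row-stochastic matrix in canonical class order.
#' @param age_noise_slope nonnegative scalar; 0 disables the age effect.
#' @return object of class `reader_profile`.
#' @export
reader_profile <- function(reader_id, role = c("INITIAL", "ARBITRATOR"),
                           confusion, age_noise_slope = 1) {
  role <- match.arg(role)
  confusion <- validate_confusion(confusion)
  stopifnot(is.numeric(age_noise_slope), age_noise_slope >= 0)
  structure(
    list(reader_id = as.character(reader_id), role = role,
         confusion = confusion, age_noise_slope = age_noise_slope),
    class = "reader_profile")
}

validate_confusion <- function(m, tol = 1e-9) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(N_CLASSES, N_CLASSES)))
    stop("confusion matrix must be 5 x 5")
  if (any(m < -tol) || any(m > 1 + tol))
    stop("confusion entries must lie in [0, 1]")
  if (any(abs(rowSums(m) - 1) > tol))
    stop("every confusion row must sum to 1")
  dimnames(m) <- list(true = class_labels(), observed = class_labels())
  m
}

#' Age-adjusted confusion matrix
#'
#' Reader agreement with the reference improves with the child's age: the
#' off-diagonal mass of each row is scaled by
#' `max(0.3, 1 - age_noise_slope * age_months / 120)` and the diagonal absorbs
#' the freed mass, so each row still sums to 1. At age 0 the matrix is
#' unchanged; errors shrink monotonically with age down to a floor of 30% of
#' their base rate.
#'
#' @param confusion 5x5 row-stochastic matrix.
#' @param age_months nonnegative age in months.
#' @param age_noise_slope nonnegative scalar (0 = no age effect).
#' @return 5x5 row-stochastic matrix.
#' @export
age_adjust_confusion <- function(confusion, age_months, age_noise_slope = 1) {
  confusion <- validate_confusion(confusion)
  stopifnot(age_months >= 0)
  f <- max(0.3, 1 - age_noise_slope * age_months / 120)
  out <- confusion * f
  diag(out) <- 1 - (rowSums(out) - diag(out))
  out
}

#' Simulate one reader's label for an image
#'
#' Draws a label from the reader's age-adjusted confusion row for the image's
#' true class, using the current R random number stream.
#'
#' @param profile a [reader_profile()].
#' @param true_class true class (any form accepted by [as_class_label()]).
#' @param age_months child age in months.
#' @return factor of length 1 with canonical levels.
#' @export
sample_reader_label <- function(profile, true_class, age_months = 0) {
  stopifnot(inherits(profile, "reader_profile"))
  row <- age_adjust_confusion(profile$confusion, age_months,
                              profile$age_noise_slope)[label_index(true_class), ]
  as_class_label(sample(class_labels(), 1L, prob = row))
}

#' Default heterogeneous reader panel
#'
#' Builds a panel of initial readers and arbitrators with distinct confusion
#' matrices. Diagonal accuracies are evenly spaced across the given ranges
#' (heterogeneous reader quality); off-diagonal mass follows a fixed clinical
#' confusability pattern (consolidation is most often confused with "both",
#' other infiltrate with "normal", etc.) plus a reader-specific bias class so
#' that readers are mutually distinguishable, not merely noisy.
#'
#' Accuracies are assigned so that the two readers of a site are closely
#' matched (same training at the site) while sites span the full range:
#' site-level accuracies are evenly spaced over `acc_initial` and the second
#' reader of each site sits `pair_gap` above the first. Bias classes are
#' distinct within every site pair, so within-pair dissimilarity is dominated
#' by systematic bias rather than marginal accuracy — the property that makes
#' reader-conditional predictions identifiable.
#'
#' @param n_initial even number of initial readers (two per site).
#' @param n_arbitrators number of arbitrators (at least 2).
#' @param acc_initial length-2 range of initial-reader diagonal accuracy.
#' @param acc_arbitrator length-2 range of arbitrator diagonal accuracy.
#' @param age_noise_slope slope passed to every profile.
#' @param bias_strength extra off-diagonal weight put on each reader's bias
#'   class; 0 gives all readers the same error pattern.
#' @param pair_gap within-site accuracy difference between the two readers
#'   (0 keeps the pair exactly matched on marginal accuracy, so that pair
#'   dissimilarity is purely systematic bias).
#' @return named list of `reader_profile` objects (initial readers `R01`...,
#'   arbitrators `A1`...).
#' @export
make_reader_profiles <- function(n_initial = 6, n_arbitrators = 2,
                                 acc_initial = c(0.55, 0.9),
                                 acc_arbitrator = c(0.85, 0.92),
                                 age_noise_slope = 1, bias_strength = 3,
                                 pair_gap = 0) {
  if (n_initial < 2 || n_initial %% 2 != 0)
    stop("n_initial must be an even number >= 2")
  if (n_arbitrators < 2) stop("at least 2 arbitrators are required")
  # clinical confusability weights, rows = true class (diagonal unused)
  confusability <- matrix(c(
    0,    0.20, 0.45, 0.20, 0.15,
    0.15, 0,    0.30, 0.40, 0.15,
    0.40, 0.40, 0,    0.10, 0.10,
    0.10, 0.45, 0.05, 0,    0.40,
    0.10, 0.15, 0.05, 0.70, 0), nrow = 5, byrow = TRUE)
  one_profile <- function(id, role, acc, bias_class, slope) {
    m <- matrix(0, 5, 5)
    for (t in 1:5) {
      w <- confusability[t, ]
      if (!is.na(bias_class) && bias_class != t)
        w[bias_class] <- w[bias_class] + bias_strength
      w[t] <- 0
      m[t, ] <- (1 - acc) * w / sum(w)
      m[t, t] <- acc
    }
    reader_profile(id, role, m, slope)
  }
  acc_i <- rep(seq(acc_initial[1], acc_initial[2] - pair_gap,
                   length.out = n_initial / 2), each = 2) +
    rep(c(0, pair_gap), n_initial / 2)
  acc_a <- seq(acc_arbitrator[1], acc_arbitrator[2], length.out = n_arbitrators)
  profs <- c(
    lapply(seq_len(n_initial), function(r)
      one_profile(sprintf("R%02d", r), "INITIAL", acc_i[r],
                  bias_class = ((r - 1L) %% 5L) + 1L, slope = age_noise_slope)),
    lapply(seq_len(n_arbitrators), function(r)
      one_profile(sprintf("A%d", r), "ARBITRATOR", acc_a[r],
                  bias_class = NA, slope = age_noise_slope / 2)))
  stats::setNames(profs, vapply(profs, `[[`, "", "reader_id"))
}

#' Render a synthetic radiograph-like image
#'
#' Produces a grayscale stand-in for a paediatric chest radiograph: two
#' darker elliptical lung fields on a brighter thorax background, with
#' class-dependent findings. `consolidation` adds one dense bright blob inside
#' a lung field; `other_infiltrate` adds diffuse patchy mid-intensity texture
#' within the lung fields; `both` adds both findings; `normal` adds neither;
#' `uninterpretable` applies heavy global blur, contrast compression and
#' occluding bands so that the lung fields are not resolvable. The output is
#' deterministic given `rng_seed` and includes the generator's own region
#' masks (thorax, lungs, blob) for downstream localization checks.
#'
#' @param true_class class label.
#' @param size image side length in pixels (>= 32).
#' @param rng_seed integer seed controlling all randomness for this image.
#' @return object of class `synth_image` with fields `pixels` (`size` x
#'   `size` matrix in \[0, 1\]), `true_class`, and `masks` (logical matrices).
#' @export
synth_image <- function(true_class, size = 64, rng_seed = 1) {
  if (size < 32) stop("size must be at least 32")
  true_class <- as_class_label(true_class)
  px <- with_seed(rng_seed, {
    s <- size
    xs <- matrix(rep(seq_len(s), each = s), s) / s   # column fraction
    ys <- matrix(rep(seq_len(s), times = s), s) / s  # row fraction
    ell <- function(cx, cy, rx, ry) ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
    jit <- function(a) runif(1, -a, a)
    thorax <- ell(0.5 + jit(0.02), 0.53 + jit(0.02), 0.42 + jit(0.03), 0.45 + jit(0.03))
    lcx <- 0.33 + jit(0.02); rcx <- 0.67 + jit(0.02)
    lcy <- 0.46 + jit(0.02); rr <- 0.13 + jit(0.015); ry <- 0.22 + jit(0.02)
    lungL <- ell(lcx, lcy, rr, ry) & thorax
    lungR <- ell(rcx, lcy, rr, ry) & thorax
    lungs <- lungL | lungR
    img <- matrix(0.12, s, s)
    img[thorax] <- 0.55
    img[lungs] <- 0.25
    blob <- NULL
    add_blob <- function(img) {
      side <- sample(c("L", "R"), 1)
      cx <- if (side == "L") lcx else rcx
      bx <- cx + jit(0.05); by <- lcy + jit(0.1)
      br <- runif(1, 0.35, 0.6) * rr
      d2 <- ((xs - bx) / br)^2 + ((ys - by) / br)^2
      blob <<- d2 <= 1 & lungs
      img + 0.4 * exp(-d2) * (d2 <= 2.5) * lungs
    }
    add_infiltrate <- function(img) {
      noise <- matrix(rnorm(s * s), s)
      sm <- as.matrix(EBImage::gblur(noise, sigma = s / 24))
      img + 0.15 * (sm > 0) * lungs + 0.05 * pmax(sm, 0) * lungs
    }
    if (true_class %in% c("consolidation", "both")) img <- add_blob(img)
    if (true_class %in% c("other_infiltrate", "both")) img <- add_infiltrate(img)
    img <- img + matrix(rnorm(s * s, sd = 0.02), s)
    if (true_class == "uninterpretable") {
      img <- as.matrix(EBImage::gblur(img, sigma = s / 8))
      img <- 0.5 + 0.3 * (img - 0.5)  # contrast compression
      nb <- sample(2:3, 1)
      for (b in seq_len(nb)) {        # occluding bands at the image mean
        r0 <- sample.int(s - s %/% 6, 1)
        img[r0:(r0 + s %/% 8), ] <- mean(img)
      }
    }
    list(pixels = clamp01(img),
         masks = list(thorax = thorax, lungs = lungs, blob = blob))
  })
  structure(
    list(image_id = NA_character_, patient_id = NA_character_,
         site = NA_character_, age_months = NA_real_,
         true_class = true_class, pixels = px$pixels, masks = px$masks),
    class = "synth_image")
}

#' Arbitrate the final label of one image
#'
#' Implements the multi-reader adjudication protocol: if the two initial
#' readers agree, their label is final (`INITIAL_CONCORDANT`) and with
#' probability 0.10 one randomly chosen arbitrator re-reads the image for
#' quality control (the QC read never changes the final label). If the initial
#' readers disagree, two distinct arbitrators chosen uniformly at random each
#' read the image; if they agree their label is final
#' (`ARBITRATOR_CONCORDANT`), otherwise the consensus discussion is simulated
#' as a single draw from the average of the two chosen arbitrators'
#' age-adjusted confusion rows (`CONSENSUS`).
#'
#' @param initial data.frame with exactly 2 rows (`reader_id`, `label`) of
#'   initial reads for the image.
#' @param arbitrator_pool list of at least 2 arbitrator [reader_profile()]s.
#' @param image a `synth_image` (uses `true_class`, `age_months`, `image_id`).
#' @return list with `final` (one-row data.frame `image_id,label,provenance`)
#'   and `records` (data.frame of extra annotation records, possibly empty).
#' @export
arbitrate <- function(initial, arbitrator_pool, image) {
  if (nrow(initial) != 2) stop("exactly 2 initial records are required")
  if (length(arbitrator_pool) < 2)
    stop("at least 2 arbitrators are required for arbitration")
  age <- if (is.na(image$age_months)) 0 else image$age_months
  lab1 <- as_class_label(initial$label[1]); lab2 <- as_class_label(initial$label[2])
  rec <- function(reader_id, label, phase)
    data.frame(image_id = image$image_id, reader_id = reader_id,
               label = as.character(label), phase = phase,
               stringsAsFactors = FALSE)
  empty <- data.frame(image_id = character(0), reader_id = character(0),
                      label = character(0), phase = character(0),
                      stringsAsFactors = FALSE)

  if (lab1 == lab2) {
    records <- empty
    if (runif(1) < 0.10) {  # QC re-read of 10% of concordant images
      qc <- arbitrator_pool[[sample.int(length(arbitrator_pool), 1)]]
      records <- rec(qc$reader_id, sample_reader_label(qc, image$true_class, age), "QC")
    }
    final <- data.frame(image_id = image$image_id, label = as.character(lab1),
                        provenance = "INITIAL_CONCORDANT", stringsAsFactors = FALSE)
    return(list(final = final, records = records))
  }

  pick <- sample.int(length(arbitrator_pool), 2)  # uniform without replacement
  a1 <- arbitrator_pool[[pick[1]]]; a2 <- arbitrator_pool[[pick[2]]]
  l1 <- sample_reader_label(a1, image$true_class, age)
  l2 <- sample_reader_label(a2, image$true_class, age)
  records <- rbind(rec(a1$reader_id, l1, "ARBITRATION"),
                   rec(a2$reader_id, l2, "ARBITRATION"))
  if (l1 == l2) {
    final <- data.frame(image_id = image$image_id, label = as.character(l1),
                        provenance = "ARBITRATOR_CONCORDANT", stringsAsFactors = FALSE)
    return(list(final = final, records = records))
  }
  t <- label_index(image$true_class)
  row1 <- age_adjust_confusion(a1$confusion, age, a1$age_noise_slope)[t, ]
  row2 <- age_adjust_confusion(a2$confusion, age, a2$age_noise_slope)[t, ]
  cons <- as_class_label(sample(class_labels(), 1L, prob = (row1 + row2) / 2))
  records <- rbind(records,
                   rec(paste0(a1$reader_id, "+", a2$reader_id), cons, "CONSENSUS"))
  final <- data.frame(image_id = image$image_id, label = as.character(cons),
                      provenance = "CONSENSUS", stringsAsFactors = FALSE)
  list(final = final, records = records)
}

#' Simulate a complete multi-reader annotated radiograph dataset
#'
#' Generates patients (with site and age), one or more synthetic images per
#' patient, initial reads by the two site readers, and arbitrated final
#' labels. Sites have unequal class priors (lower `normal` share at the first
#' sites, mimicking the between-site prevalence differences seen in multi-site
#' studies). All randomness flows from `seed` through per-image substreams, so
#' the dataset is fully reproducible, including under re-ordering of image
#' generation.
#'
#' @param n_patients number of patients.
#' @param images_per_patient probability vector over 1, 2, ... images per
#'   patient (default about 4% of patients contribute a second image).
#' @param n_initial_readers even number of initial readers; two are assigned
#'   to each of `n_initial_readers / 2` sites.
#' @param n_arbitrators number of arbitrators (>= 2), shared by all sites.
#' @param prior global class prior (see [class_prior()]).
#' @param profiles optional named list of [reader_profile()]s covering all
#'   readers; defaults to [make_reader_profiles()].
#' @param image_size side length of generated images.
#' @param site_normal_scale range of the per-site scaling of the `normal`
#'   prior share, spread evenly across sites.
#' @param seed integer root seed.
#' @return object of class `panel_data`: list with `images` (named list of
#'   `synth_image`), `patients`, `annotations`, `finals` data.frames,
#'   `profiles`, `prior`, `seed`.
#' @export
build_panel_dataset <- function(n_patients, images_per_patient = c(0.96, 0.04),
                                n_initial_readers = 6, n_arbitrators = 2,
                                prior = class_prior(), profiles = NULL,
                                image_size = 64,
                                site_normal_scale = c(0.65, 1.1), seed = 1) {
  if (n_initial_readers < 2 || n_initial_readers %% 2 != 0)
    stop("n_initial_readers must be even and >= 2")
  if (is.null(profiles))
    profiles <- make_reader_profiles(n_initial_readers, n_arbitrators)
  roles <- vapply(profiles, `[[`, "", "role")
  initial_ids <- names(profiles)[roles == "INITIAL"]
  arb_ids <- names(profiles)[roles == "ARBITRATOR"]
  if (length(initial_ids) != n_initial_readers || length(arb_ids) != n_arbitrators)
    stop("profiles must cover exactly the requested initial readers and arbitrators")
  stopifnot_prob_vector(prior, what = "class prior")

  n_sites <- n_initial_readers / 2
  sites <- paste0("site_", LETTERS[seq_len(n_sites)])
  # per-site priors: scale the `normal` share, renormalize the rest
  scl <- if (n_sites == 1) 1 else
    seq(site_normal_scale[1], site_normal_scale[2], length.out = n_sites)
  site_priors <- lapply(scl, function(f) {
    p <- prior
    p["normal"] <- p["normal"] * f
    p / sum(p)
  })
  names(site_priors) <- sites
  site_readers <- stats::setNames(
    lapply(seq_len(n_sites), function(s) initial_ids[c(2 * s - 1, 2 * s)]), sites)

  patients <- with_seed(derive_seed(seed, 0), {
    data.frame(
      patient_id = sprintf("P%05d", seq_len(n_patients)),
      site = sample(sites, n_patients, replace = TRUE),
      age_months = sample(1:59, n_patients, replace = TRUE),
      n_images = sample(seq_along(images_per_patient), n_patients,
                        replace = TRUE, prob = images_per_patient),
      stringsAsFactors = FALSE)
  })

  img_owner <- rep(seq_len(n_patients), patients$n_images)
  n_images <- length(img_owner)
  images <- vector("list", n_images)
  ann <- vector("list", n_images)
  fin <- vector("list", n_images)
  arb_pool <- profiles[arb_ids]

  for (i in seq_len(n_images)) {
    p <- patients[img_owner[i], ]
    true_class <- with_seed(derive_seed(seed, 3L * i), {
      sample(class_labels(), 1, prob = site_priors[[p$site]])
    })
    img <- synth_image(true_class, size = image_size,
                       rng_seed = derive_seed(seed, 3L * i + 1L))
    img$image_id <- sprintf("I%06d", i)
    img$patient_id <- p$patient_id
    img$site <- p$site
    img$age_months <- p$age_months
    images[[i]] <- img

    res <- with_seed(derive_seed(seed, 3L * i + 2L), {
      rids <- site_readers[[p$site]]
      init <- data.frame(
        image_id = img$image_id, reader_id = rids,
        label = vapply(rids, function(r)
          as.character(sample_reader_label(profiles[[r]], true_class, p$age_months)), ""),
        phase = "INITIAL", stringsAsFactors = FALSE)
      arb <- arbitrate(init, arb_pool, img)
      list(records = rbind(init, arb$records), final = arb$final)
    })
    ann[[i]] <- res$records
    fin[[i]] <- res$final
  }

  annotations <- do.call(rbind, ann)
  finals <- do.call(rbind, fin)
  meta <- data.frame(
    image_id = vapply(images, `[[`, "", "image_id"),
    patient_id = vapply(images, `[[`, "", "patient_id"),
    site = vapply(images, `[[`, "", "site"),
    age_months = vapply(images, `[[`, 0, "age_months"),
    true_class = vapply(images, function(im) as.character(im$true_class), ""),
    stringsAsFactors = FALSE)
  mi <- match(annotations$image_id, meta$image_id)
  annotations$patient_id <- meta$patient_id[mi]
  annotations$site <- meta$site[mi]
  annotations$age_months <- meta$age_months[mi]
  annotations$true_class <- meta$true_class[mi]
  annotations$role <- ifelse(annotations$reader_id %in% initial_ids, "INITIAL",
                             ifelse(annotations$phase == "CONSENSUS", "PANEL",
                                    "ARBITRATOR"))
  annotations <- annotations[, c("image_id", "patient_id", "site", "age_months",
                                 "reader_id", "role", "phase", "label", "true_class")]
  rownames(annotations) <- NULL
  structure(
    list(images = stats::setNames(images, meta$image_id), patients = patients,
         annotations = annotations, finals = finals, profiles = profiles,
         prior = prior, site_priors = site_priors, site_readers = site_readers,
         seed = seed),
    class = "panel_data")
}

#' @export
print.panel_data <- function(x, ...) {
  cat("panel_data:", length(x$images), "images from", nrow(x$patients),
      "patients,", sum(x$finals$provenance == "INITIAL_CONCORDANT"),
      "initially concordant\n")
  invisible(x)
}

#' Patient-level train/test split
#'
#' Splits patients (not images) into train and test sets by simple random
#' sampling, so that all images of a patient fall on the same side of the
#' split.
#'
#' @param data a `panel_data` object, or a data.frame with `image_id` and
#'   `patient_id` columns.
#' @param test_fraction fraction of patients held out (0 < f < 1).
#' @param seed integer seed.
#' @return object of class `dataset_split` with `train_patients`,
#'   `test_patients`, `train_images`, `test_images`, `seed`.
#' @export
split_by_patient <- function(data, test_fraction = 0.2, seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be strictly between 0 and 1")
  df <- if (inherits(data, "panel_data")) {
    data.frame(image_id = names(data$images),
               patient_id = vapply(data$images, `[[`, "", "patient_id"),
               stringsAsFactors = FALSE)
  } else as.data.frame(data)[, c("image_id", "patient_id")]
  patients <- unique(df$patient_id)
  if (length(patients) < 2) stop("need at least 2 patients to split")
  n_test <- round(test_fraction * length(patients))
  n_test <- max(1L, min(length(patients) - 1L, n_test))
  test_patients <- with_seed(derive_seed(seed, 17L),
                             sort(sample(patients, n_test)))
  train_patients <- sort(setdiff(patients, test_patients))
  structure(
    list(train_patients = train_patients, test_patients = test_patients,
         train_images = df$image_id[df$patient_id %in% train_patients],
         test_images = df$image_id[df$patient_id %in% test_patients],
         seed = seed),
    class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("dataset_split:", length(x$train_patients), "train /",
      length(x$test_patients), "test patients (",
      length(x$train_images), "/", length(x$test_images), "images )\n")
  invisible(x)
}
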
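test_that("class prior defaults to the observed prevalence and validates overrides", {
  p <- class_prior()
  expect_equal(unname(p), c(0.15, 0.24, 0.11, 0.40, 0.10))
  expect_equal(sum(p), 1)
  expect_equal(unname(class_prior(rep(0.2, 5))), rep(0.2, 5))
  expect_error(class_prior(c(0.5, 0.5, 0.5, 0, 0)), "sum to 1")
})

test_that("labels coerce between names and canonical codes", {
  expect_equal(label_code(c("consolidation", "uninterpretable")), c(0L, 4L))
  expect_equal(as.character(as_class_label(c(3, 0))), c("normal", "consolidation"))
  expect_error(as_class_label("pneumonia"), "unknown class label")
})

test_that("synthetic images are deterministic and carry class-dependent findings", {
  a <- synth_image("normal", 64, rng_seed = 1)
  b <- synth_image("normal", 64, rng_seed = 1)
  expect_identical(a$pixels, b$pixels)
  expect_true(all(a$pixels >= 0 & a$pixels <= 1))
  expect_error(synth_image("normal", 16), "at least 32")

  cons <- synth_image("consolidation", 64, rng_seed = 7)
  blob <- cons$masks$blob
  lung_rest <- cons$masks$lungs & !blob
  expect_gt(mean(cons$pixels[blob]), mean(cons$pixels[lung_rest]))

  un <- synth_image("uninterpretable", 64, rng_seed = 3)
  nm <- synth_image("normal", 64, rng_seed = 3)
  expect_lt(var(as.vector(un$pixels)), var(as.vector(nm$pixels)))
})

test_that("age adjustment shrinks errors monotonically and keeps rows stochastic", {
  prof <- make_reader_profiles(4, 2)[["R01"]]
  ages <- c(0, 12, 36, 59, 200)
  errs <- vapply(ages, function(a) {
    m <- age_adjust_confusion(prof$confusion, a, prof$age_noise_slope)
    expect_equal(rowSums(m), rep(1, 5), tolerance = 1e-9,
                 ignore_attr = TRUE)
    1 - mean(diag(m))
  }, 0)
  expect_true(all(diff(errs) <= 0))
  expect_identical(age_adjust_confusion(prof$confusion, 59, 0), prof$confusion)
})

test_that("reader labels follow the age-adjusted confusion row", {
  ident <- reader_profile("perfect", "INITIAL", diag(5), 0)
  set.seed(1)
  expect_true(all(replicate(20,
    as.character(sample_reader_label(ident, "both", 30))) == "both"))

  m <- diag(5); m[1, ] <- c(0, 0, 0, 1, 0)
  degen <- reader_profile("degen", "INITIAL", m, 0)
  expect_true(all(replicate(20,
    as.character(sample_reader_label(degen, "consolidation", 0))) == "normal"))

  expect_error(reader_profile("bad", "INITIAL", matrix(0.3, 5, 5)), "sum to 1")
})

test_that("sampled label frequencies match the confusion row", {
  m <- diag(5)
  m[1, ] <- c(0.7, 0.1, 0.1, 0.05, 0.05)
  prof <- reader_profile("r", "INITIAL", m, age_noise_slope = 0)
  set.seed(7)
  draws <- replicate(4000, as.character(sample_reader_label(prof, "consolidation", 0)))
  freq <- table(factor(draws, levels = class_labels())) / length(draws)
  expect_true(all(abs(as.numeric(freq) - m[1, ]) < 0.03))
})

test_that("arbitration follows the adjudication protocol", {
  arbs <- list(two_class_profile("A1", "ARBITRATOR", 1),
               two_class_profile("A2", "ARBITRATOR", 1))
  img <- synth_image("consolidation", 32, 1)
  img$image_id <- "I1"; img$age_months <- 0

  init <- data.frame(image_id = "I1", reader_id = c("R01", "R02"),
                     label = c("normal", "normal"))
  set.seed(1)
  res <- arbitrate(init, arbs, img)
  expect_equal(res$final$label, "normal")
  expect_equal(res$final$provenance, "INITIAL_CONCORDANT")

  # discordant initial reads with perfect arbitrators recover the truth
  init2 <- data.frame(image_id = "I1", reader_id = c("R01", "R02"),
                      label = c("consolidation", "normal"))
  set.seed(2)
  res2 <- arbitrate(init2, arbs, img)
  expect_equal(res2$final$label, "consolidation")
  expect_equal(res2$final$provenance, "ARBITRATOR_CONCORDANT")
  expect_equal(sum(res2$records$phase == "ARBITRATION"), 2L)

  expect_error(arbitrate(init, arbs[1], img), "at least 2 arbitrators")
  expect_error(arbitrate(init[1, ], arbs, img), "exactly 2 initial")
})

test_that("QC re-reads appear for about 10% of concordant images and never change finals", {
  arbs <- list(two_class_profile("A1", "ARBITRATOR", 0.9),
               two_class_profile("A2", "ARBITRATOR", 0.9))
  img <- synth_image("normal", 32, 1); img$image_id <- "I1"; img$age_months <- 0
  init <- data.frame(image_id = "I1", reader_id = c("R01", "R02"),
                     label = c("normal", "normal"))
  set.seed(11)
  outs <- replicate(600, arbitrate(init, arbs, img), simplify = FALSE)
  qc <- vapply(outs, function(o) any(o$records$phase == "QC"), TRUE)
  expect_gt(mean(qc), 0.06)
  expect_lt(mean(qc), 0.15)
  expect_true(all(vapply(outs, function(o) o$final$label == "normal", TRUE)))
})

test_that("panel dataset counting, determinism and the noiseless-panel identity", {
  ident <- lapply(c("R01", "R02", "R03", "R04"), function(id)
    reader_profile(id, "INITIAL", diag(5), 0))
  arbs <- lapply(c("A1", "A2"), function(id)
    reader_profile(id, "ARBITRATOR", diag(5), 0))
  profs <- stats::setNames(c(ident, arbs), c("R01", "R02", "R03", "R04", "A1", "A2"))
  d <- build_panel_dataset(10, images_per_patient = 1, n_initial_readers = 4,
                           profiles = profs, image_size = 32, seed = 5)
  expect_equal(nrow(d$finals), 10L)
  expect_equal(sum(d$annotations$phase == "INITIAL"), 20L)
  # noiseless panel: every final equals the true class
  truth <- vapply(d$images[d$finals$image_id], function(im)
    as.character(im$true_class), "")
  expect_equal(d$finals$label, unname(truth))
  expect_true(all(d$finals$provenance == "INITIAL_CONCORDANT"))

  d2 <- build_panel_dataset(10, images_per_patient = 1, n_initial_readers = 4,
                            profiles = profs, image_size = 32, seed = 5)
  expect_identical(d$annotations, d2$annotations)
  expect_identical(d$finals, d2$finals)
  expect_identical(d$images[[3]]$pixels, d2$images[[3]]$pixels)
})

test_that("every image has exactly two initial reads by its site readers", {
  d <- tiny_panel()
  ini <- d$annotations[d$annotations$phase == "INITIAL", ]
  counts <- table(ini$image_id)
  expect_true(all(counts == 2))
  # initial readers belong to the image's site
  ok <- mapply(function(img, rid) rid %in% d$site_readers[[d$images[[img]]$site]],
               ini$image_id, ini$reader_id)
  expect_true(all(ok))
})

test_that("simulated initial concordance matches the closed-form row product", {
  p <- 0.8; q <- 0.75
  r1 <- two_class_profile("R01", "INITIAL", p)
  r2 <- two_class_profile("R02", "INITIAL", q)
  prior <- c(0.5, 0, 0, 0.5, 0)
  expected <- sum(vapply(1:5, function(t)
    prior[t] * sum(r1$confusion[t, ] * r2$confusion[t, ]), 0))
  set.seed(3)
  n <- 20000
  truth <- sample(c(1L, 4L), n, replace = TRUE)
  agree <- vapply(seq_len(n), function(i) {
    t <- class_labels()[truth[i]]
    sample_reader_label(r1, t, 0) == sample_reader_label(r2, t, 0)
  }, TRUE)
  expect_lt(abs(mean(agree) - expected), 0.01)
})

test_that("patient-level split is disjoint, grouped and correctly sized", {
  d <- tiny_panel()
  s <- split_by_patient(d, 0.2, seed = 9)
  expect_length(intersect(s$train_patients, s$test_patients), 0)
  expect_setequal(c(s$train_patients, s$test_patients), d$patients$patient_id)
  pid <- vapply(d$images, `[[`, "", "patient_id")
  for (p in unique(pid[duplicated(pid)])) {
    imgs <- names(pid)[pid == p]
    expect_true(all(imgs %in% s$train_images) || all(imgs %in% s$test_images))
  }
  # the reference cohort size: 20% of 4008 patients = 802
  df <- data.frame(image_id = sprintf("I%04d", 1:4008),
                   patient_id = sprintf("P%04d", 1:4008))
  expect_length(split_by_patient(df, 0.2, seed = 1)$test_patients, 802L)
  expect_error(split_by_patient(d, 1.2), "between 0 and 1")
})
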
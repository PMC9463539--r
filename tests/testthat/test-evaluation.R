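test_that("multi-class accuracy counts exact matches", {
  expect_equal(multiclass_accuracy(c(0, 3, 3, 1), c(0, 3, 1, 2)), 0.5)
  expect_equal(multiclass_accuracy(c("normal", "both"), c("normal", "both")), 1)
  expect_equal(multiclass_accuracy(c(0, 1), c(2, 3)), 0)
  expect_error(multiclass_accuracy(c(0, 1), c(0)), "equal length")
})

test_that("one-vs-rest AUC matches hand-counted and degenerate cases", {
  # scores (0.9, 0.8, 0.3, 0.2), labels (+,-,+,-): wins 3 of 4 pairs
  probs <- matrix(0.25, 4, 5)
  probs[, 1] <- c(0.9, 0.8, 0.3, 0.2)
  y <- c("consolidation", "normal", "consolidation", "normal")
  expect_equal(suppressWarnings(auc_ovr(probs, y))$auc_per_class[["consolidation"]],
               0.75)
  # perfect separation and all-ties
  probs2 <- matrix(0.25, 4, 5)
  probs2[, 1] <- c(0.9, 0.8, 0.2, 0.1)
  y2 <- c("consolidation", "consolidation", "normal", "normal")
  expect_equal(suppressWarnings(auc_ovr(probs2, y2))$auc_per_class[[1]], 1)
  probs3 <- matrix(0.25, 4, 5)
  expect_equal(suppressWarnings(auc_ovr(probs3, y))$auc_per_class[[1]], 0.5)
  # degenerate classes are NA, excluded from the mean, and warn
  expect_warning(res <- auc_ovr(probs, y), "undefined")
  expect_true(is.na(res$auc_per_class[["both"]]))
  expect_false(is.na(res$auc_mean))
})

test_that("AUC implementation agrees exactly with the exhaustive pairwise oracle", {
  set.seed(13)
  for (i in 1:60) {
    n <- sample(4:30, 1)
    probs <- matrix(round(runif(n * 5), 2), n, 5)  # rounding induces ties
    y <- sample(class_labels(), n, replace = TRUE)
    res <- suppressWarnings(auc_ovr(probs, y))
    for (k in 1:5) {
      oracle <- auc_pairwise_oracle(probs[, k], label_index(y) == k)
      expect_identical(is.na(res$auc_per_class[[k]]), is.na(oracle))
      if (!is.na(oracle)) expect_equal(res$auc_per_class[[k]], oracle)
    }
  }
})

test_that("AUC agrees with an independent ROC library on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(21)
  n <- 80
  scores <- round(runif(n), 2)
  y <- sample(c(0, 1), n, replace = TRUE)
  probs <- matrix(0, n, 5); probs[, 1] <- scores
  labels <- ifelse(y == 1, "consolidation", "normal")
  ours <- suppressWarnings(auc_ovr(probs, labels))$auc_per_class[[1]]
  ref <- as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("confusion row proportions are exact on a hand-built case", {
  truth <- c("normal", "normal", "normal", "consolidation", "consolidation", "both")
  pred <- c("normal", "normal", "consolidation", "consolidation", "normal", "both")
  m <- confusion_row_proportions(pred, truth)
  expect_equal(m["normal", "normal"], 2 / 3)
  expect_equal(m["normal", "consolidation"], 1 / 3)
  expect_equal(m["consolidation", "consolidation"], 1 / 2)
  expect_equal(m["both", "both"], 1)
  expect_equal(unname(rowSums(m)[c("uninterpretable")]), 0)  # empty row all-zero
  # perfect predictions give the identity on nonempty rows
  mm <- confusion_row_proportions(truth, truth)
  expect_equal(unname(diag(mm)[1:4][c(1, 3, 4)]), c(1, 1, 1))
})

test_that("accuracy decomposes over the confusion diagonal and over groups", {
  set.seed(31)
  truth <- sample(class_labels(), 200, replace = TRUE)
  pred <- ifelse(runif(200) < 0.6, truth,
                 sample(class_labels(), 200, replace = TRUE))
  acc <- multiclass_accuracy(pred, truth)
  m <- confusion_row_proportions(pred, truth)
  counts <- table(factor(truth, levels = class_labels()))
  expect_equal(sum(counts / 200 * diag(m)), acc)
  groups <- sample(c("g1", "g2", "g3"), 200, replace = TRUE)
  ga <- grouped_accuracy(pred, truth, groups)
  sizes <- table(groups)[names(ga)]
  expect_equal(sum(ga * sizes) / 200, acc)
  expect_equal(unname(grouped_accuracy(pred, truth, rep("all", 200))), acc)
})

test_that("grouped accuracy supports numeric age binning", {
  truth <- rep("normal", 6)
  pred <- c("normal", "both", "normal", "normal", "normal", "both")
  ages <- c(3, 6, 11, 14, 30, 50)
  ga <- grouped_accuracy(pred, truth, ages, breaks = c(0, 12, 60))
  expect_equal(unname(ga), c(2 / 3, 2 / 3))
})

test_that("gradcam heatmaps are nonnegative, normalized and image-shaped", {
  m <- tiny_model(n_readers = 2, embed_dim = 16)
  img <- synth_image("consolidation", 64, rng_seed = 2)
  h <- gradcam(m, img, "consolidation")
  expect_equal(dim(h), c(64L, 64L))
  expect_true(all(h >= 0))
  expect_true(max(h) <= 1)
  hr <- gradcam(m, img, "consolidation", reader_id = 2)
  expect_equal(dim(hr), c(64L, 64L))
})

test_that("eval report serializes to JSON with all components", {
  set.seed(41)
  truth <- sample(class_labels(), 50, replace = TRUE)
  probs <- matrix(rexp(250), 50); probs <- probs / rowSums(probs)
  pred <- class_labels()[max.col(probs, ties.method = "first")]
  rep <- suppressWarnings(
    eval_report(pred, truth, probs, groups = list(site = rep(c("a", "b"), 25))))
  expect_s3_class(rep, "eval_report")
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 1)
  path <- tempfile(fileext = ".json")
  write_eval_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$accuracy, rep$accuracy)
  expect_length(back$auc_per_class, 5)
})

test_that("the most dissimilar site pair is found by L1 distance", {
  d <- tiny_panel()
  md <- most_dissimilar_site_pair(d)
  expect_length(md$pair, 2)
  expect_setequal(md$pair, d$site_readers[[md$site]])
  dist <- function(pr) sum(abs(d$profiles[[pr[1]]]$confusion -
                               d$profiles[[pr[2]]]$confusion))
  for (site in names(d$site_readers))
    expect_lte(dist(d$site_readers[[site]]), md$distance)
})
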
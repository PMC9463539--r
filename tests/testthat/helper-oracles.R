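# Independent oracles and small fixtures shared across tests.

# 1-based canonical class index (tests run against the installed exports)
label_index <- function(x) as.integer(as_class_label(x))

# Exhaustive pairwise one-vs-rest AUC: P(pos > neg) + 0.5 P(tie) by brute
# force over all positive-negative pairs.
auc_pairwise_oracle <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  if (!length(pos) || !length(neg)) return(NA_real_)
  wins <- 0
  for (p in pos) for (n in neg) {
    if (p > n) wins <- wins + 1
    else if (p == n) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# Two-class reader profile: accuracy `acc` split between consolidation and
# normal; other true classes (never drawn in the toy) read correctly.
two_class_profile <- function(id, role, acc) {
  m <- diag(5)
  ci <- 1L; ni <- 4L  # consolidation, normal in canonical order
  m[ci, ci] <- acc; m[ci, ni] <- 1 - acc
  m[ni, ni] <- acc; m[ni, ci] <- 1 - acc
  reader_profile(id, role, m, age_noise_slope = 0)
}

# Exact final-label accuracy of the arbitration protocol by enumeration of
# every outcome path: initial pair -> (concordance | arbitrator pair ->
# (concordance | consensus draw from the averaged row)).
protocol_accuracy_exact <- function(init_profiles, arb_profiles, prior) {
  stopifnot(length(init_profiles) == 2)
  pairs <- utils::combn(length(arb_profiles), 2)
  acc <- 0
  for (t in which(prior > 0)) {
    r1 <- init_profiles[[1]]$confusion[t, ]
    r2 <- init_profiles[[2]]$confusion[t, ]
    for (l1 in 1:5) for (l2 in 1:5) {
      p12 <- r1[l1] * r2[l2]
      if (p12 == 0) next
      if (l1 == l2) {
        if (l1 == t) acc <- acc + prior[t] * p12
        next
      }
      for (pp in seq_len(ncol(pairs))) {
        a1 <- arb_profiles[[pairs[1, pp]]]$confusion[t, ]
        a2 <- arb_profiles[[pairs[2, pp]]]$confusion[t, ]
        pw <- p12 / ncol(pairs)
        for (m1 in 1:5) for (m2 in 1:5) {
          q <- a1[m1] * a2[m2]
          if (q == 0) next
          if (m1 == m2) {
            if (m1 == t) acc <- acc + prior[t] * pw * q
          } else {
            acc <- acc + prior[t] * pw * q * (a1[t] + a2[t]) / 2
          }
        }
      }
    }
  }
  unname(acc)
}

# Small simulated dataset shared by training/inference/interface tests,
# built once per test run.
tiny_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_panel_dataset(60, n_initial_readers = 4,
                                    n_arbitrators = 2, image_size = 32,
                                    seed = 42)
    cache
  }
})

tiny_model <- function(n_readers = 6, use_emb = TRUE, activation = "identity",
                       embed_dim = 16, dropout = 0, seed = 1, ...) {
  spec <- model_spec("toy_cnn", n_readers = n_readers, activation = activation,
                     use_reader_embeddings = use_emb, embed_dim = embed_dim,
                     dropout = dropout, ...)
  build_model(spec, init_seed = seed)
}

# force the reader branch to the all-ones modulation (baseline equivalence)
force_all_ones <- function(model) {
  model$params$proj_w[] <- 0
  model$params$proj_b[] <- 1
  model
}

random_image <- function(size = 32, seed = 1) {
  set.seed(seed)
  matrix(runif(size * size), size, size)
}
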
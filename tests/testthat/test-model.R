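test_that("model builds are seeded, shaped and counted correctly", {
  spec <- model_spec("toy_cnn", n_readers = 18, reader_emb_dim = 32,
                     embed_dim = 32)
  m1 <- build_model(spec, init_seed = 4)
  m2 <- build_model(spec, init_seed = 4)
  expect_identical(m1$params, m2$params)
  expect_equal(dim(m1$params$emb), c(18L, 32L))
  expect_equal(dim(m1$params$proj_w), c(32L, 32L))
  expect_equal(m1$params$proj_b, rep(1, 32))
  # reader branch bookkeeping: table + projection weights + projection bias
  n <- count_parameters(m1)
  expect_equal(n$reader_branch_extra, 18 * 32 + 32 * 32 + 32)
  expect_equal(n$total, n$conv + n$classifier + n$reader_branch_extra)

  base <- build_model(model_spec("toy_cnn", use_reader_embeddings = FALSE))
  expect_null(base$params$emb)
  expect_equal(count_parameters(base)$reader_branch_extra, 0L)
  expect_error(build_model(model_spec("resnet18")), "not implemented")
})

test_that("forward passes return probability simplexes and respect reader bounds", {
  m <- tiny_model(n_readers = 4)
  img <- random_image(32, 1)
  pr <- forward_reader(m, img, 2)
  expect_equal(sum(pr), 1, tolerance = 1e-6)
  expect_true(all(pr >= 0))
  pb <- forward_baseline(m, img)
  expect_equal(sum(pb), 1, tolerance = 1e-6)
  expect_identical(pb, forward_baseline(m, img))  # eval mode determinism
  expect_error(forward_reader(m, img, 9), "out of range")
  expect_error(forward_reader(m, img, "nobody"), "unknown reader")
  # totality on a constant-zero image
  expect_equal(sum(forward_baseline(m, matrix(0, 32, 32))), 1, tolerance = 1e-6)
})

test_that("simplex property holds over many random inputs", {
  m <- tiny_model(n_readers = 3)
  set.seed(2)
  for (i in 1:25) {
    p <- forward_reader(m, matrix(runif(32 * 32), 32), sample(3, 1))
    expect_true(all(p >= 0) && abs(sum(p) - 1) < 1e-6)
  }
})

test_that("all-ones modulation makes the reader path equal the baseline", {
  m <- force_all_ones(tiny_model(n_readers = 5, activation = "identity"))
  set.seed(3)
  for (i in 1:10) {
    img <- matrix(runif(32 * 32), 32)
    pb <- forward_baseline(m, img)
    for (r in 1:5)
      expect_lt(max(abs(forward_reader(m, img, r) - pb)), 1e-6)
  }
})

test_that("readers with different modulation vectors produce different outputs", {
  m <- tiny_model(n_readers = 2, activation = "identity", embed_dim = 16)
  m$params$proj_w[] <- 0
  m$params$proj_b <- rep(1, 16)
  m$params$emb[] <- 0
  img <- random_image(32, 4)
  # flip reader 2's modulation in one coordinate where the image embedding
  # is nonzero
  emb_img <- readernet:::backbone_forward(m, readernet:::as_image_batch(img))$emb[, 1]
  d <- which(abs(emb_img) > 1e-6)[1]
  m$params$emb[2, 1] <- 1
  m$params$proj_w[1, d] <- 0.5
  p1 <- forward_reader(m, img, 1)
  p2 <- forward_reader(m, img, 2)
  expect_gt(max(abs(p1 - p2)), 1e-8)
})

test_that("nonnegative activations cannot flip feature directions across readers", {
  set.seed(5)
  for (act in c("relu", "sigmoid")) {
    m <- tiny_model(n_readers = 6, activation = act)
    m$params$emb <- matrix(rnorm(6 * 32, sd = 2), 6, 32)
    mod <- readernet:::reader_modulation(m, 1:6)
    expect_true(all(mod$m >= 0))
  }
  # identity/tanh can flip: construct a sign flip explicitly
  m <- tiny_model(n_readers = 2, activation = "identity", embed_dim = 16)
  m$params$proj_w[] <- 0; m$params$emb[] <- 0
  m$params$proj_b <- rep(1, 16)
  m$params$emb[2, 1] <- 1
  m$params$proj_w[1, ] <- -2   # reader 2 modulation = -1 everywhere
  mod <- readernet:::reader_modulation(m, 1:2)
  expect_true(all(mod$m[, 1] > 0) && all(mod$m[, 2] < 0))
})

test_that("max-norm projects only the rows outside the ball", {
  tab <- rbind(c(2, 0), c(0.3, 0.4), c(3, 4))
  out <- apply_max_norm(tab, 1)
  expect_equal(sqrt(rowSums(out^2)), c(1, 0.5, 1))
  expect_equal(out[2, ], tab[2, ])
  # rows at norms (3.9, 4.0, 4.1) under max-norm 4 -> (3.9, 4.0, 4.0)
  tab2 <- diag(c(3.9, 4.0, 4.1)) %*% matrix(rep(c(1, 0, 0), 3), 3, byrow = TRUE)
  expect_equal(sqrt(rowSums(apply_max_norm(tab2, 4)^2)), c(3.9, 4.0, 4.0))
  expect_error(apply_max_norm(tab, -1), "positive")
})

test_that("dropout is stochastic in train mode and absent in eval mode", {
  m <- tiny_model(n_readers = 2, dropout = 0.5)
  img <- random_image(32, 6)
  set.seed(1)
  p1 <- readernet:::model_forward(m, img, train = TRUE)$probs
  p2 <- readernet:::model_forward(m, img, train = TRUE)$probs
  expect_gt(max(abs(p1 - p2)), 0)
  e1 <- readernet:::model_forward(m, img)$probs
  e2 <- readernet:::model_forward(m, img)$probs
  expect_identical(e1, e2)
  # inverted dropout is unbiased at the pre-classifier embedding: averaging
  # the masked embeddings over many train-mode passes recovers the eval one
  set.seed(2)
  h_eval <- readernet:::backbone_forward(m, readernet:::as_image_batch(img))$emb
  hs <- replicate(400, as.vector(
    readernet:::model_forward(m, img, train = TRUE, keep_cache = TRUE)$cache$h))
  expect_lt(max(abs(rowMeans(hs) - h_eval)), 0.25 * max(abs(h_eval)) + 0.05)
})

test_that("checkpoints round-trip through save/load", {
  m <- tiny_model(n_readers = 3)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m$params, m2$params)
  expect_identical(m$spec, m2$spec)
  img <- random_image(32, 2)
  expect_identical(forward_baseline(m, img), forward_baseline(m2, img))
})

test_that("backbone gradients match finite differences", {
  m <- tiny_model(n_readers = 2, embed_dim = 8)
  x <- readernet:::as_image_batch(random_image(32, 3))
  fwd <- readernet:::model_forward(m, x, reader_idx = 2L, keep_cache = TRUE)
  g <- readernet:::model_backward(m, fwd, target_idx = 3L)
  eps <- 1e-6
  for (nm in c("conv_w1", "conv_w3", "fc_w", "proj_w", "emb")) {
    p <- m$params[[nm]]
    i <- if (is.matrix(p)) cbind(1, 2) else rbind(c(2, 2, 1, 1))
    m2 <- m
    m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
    f2 <- readernet:::model_forward(m2, x, reader_idx = 2L)
    loss2 <- -log(f2$probs[3, 1])
    loss1 <- -log(fwd$probs[3, 1])
    expect_equal((loss2 - loss1) / eps, g[[nm]][i], tolerance = 1e-3)
  }
})
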
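test_that("encode and decode perform the stated affine-activation maps", {
  lay <- ae_layer(W = matrix(0, 2, 2), b = c(0, 0),
                  W_tilde = matrix(0, 2, 2), b_tilde = c(0, 0),
                  f = "sigmoid", g = "linear")
  expect_equal(encode(c(3, -1), lay), c(0.5, 0.5))

  id <- ae_layer(W = diag(2), b = c(0, 0), W_tilde = diag(2), b_tilde = c(0, 0),
                 f = "linear", g = "linear")
  expect_equal(encode(c(1.5, -2), id), c(1.5, -2))
  expect_equal(decode(encode(c(1.5, -2), id), id), c(1.5, -2))

  lay2 <- ae_layer(W = matrix(c(1, 1), 1, 2), b = -1,
                   W_tilde = matrix(c(2, 0), 2, 1), b_tilde = c(0, 1),
                   f = "linear", g = "linear")
  expect_equal(encode(c(2, 3), lay2), 4)
  expect_equal(decode(3, lay2), c(6, 1))

  # decoder with zero weights returns its bias
  lay3 <- ae_layer(W = matrix(1, 1, 2), b = 0,
                   W_tilde = matrix(0, 2, 1), b_tilde = c(7, -2), g = "linear")
  expect_equal(decode(0.3, lay3), c(7, -2))

  expect_error(encode(c(1, 2, 3), lay2), "dimension")
  expect_error(ae_layer(W = matrix(0, 2, 3), b = 1:2,
                        W_tilde = matrix(0, 2, 2), b_tilde = 1:2),
               "transpose shape")
})

test_that("reconstruction losses match direct arithmetic", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(c(1, 0), c(0, 0)), 1)
  set.seed(2)
  a <- rnorm(6); b <- rnorm(6)
  expect_equal(mse_loss(a, b), mse_loss(b, a))
  expect_equal(mse_loss(a, b), sum((a - b)^2))

  expect_equal(xent_loss(1, 0.5), -log(0.5))
  expect_equal(xent_loss(c(0, 1), c(0.5, 0.5)), -2 * log(0.5))
  expect_equal(xent_loss(c(0, 1), c(0.5, 0.5)), 1.3863, tolerance = 1e-4)
  expect_error(xent_loss(c(0.5, 1), c(0.5, 0.5)), "0/1")
  # minimized at z = x (up to clipping)
  x <- c(1, 0, 1)
  z_grid <- seq(0.05, 0.95, by = 0.05)
  best <- min(vapply(z_grid, function(z) xent_loss(x, rep(z, 3)), numeric(1)))
  expect_lte(xent_loss(x, pmin(pmax(x, 1e-7), 1 - 1e-7)), best)
})

test_that("training drives reconstruction error to ~0 on constant data", {
  X <- matrix(rep(c(1, 2, 3), each = 40), nrow = 40)
  m <- sae(X, sizes = c(3, 2, 3),
           control = sae_control(nb_epoch = 300, batch_size = 10, seed = 1,
                                 patience = 300, optimizer = "adam", lr = 0.01),
           hidden_activation = "linear", output_activation = "linear")
  expect_lt(tail(m$training_log$train_error, 1), 1e-4)
})

test_that("a linear bottleneck auto-encoder approaches the PCA residual", {
  set.seed(7)
  n <- 500; d <- 20; k <- 5
  Z <- matrix(rnorm(n * k), ncol = k) %*% matrix(rnorm(k * d, sd = 2), nrow = k)
  X <- scale(Z + matrix(rnorm(n * d, sd = 0.5), ncol = d), scale = FALSE)
  sv <- svd(X)
  pca_residual <- sum(sv$d[(k + 1):d]^2) / n  # optimal rank-k mean residual

  m <- sae(X, sizes = c(d, k, d),
           control = sae_control(nb_epoch = 500, batch_size = 50, seed = 3,
                                 patience = 500),
           hidden_activation = "linear", output_activation = "linear")
  recon <- decode(encode(X, m$layers[[1]]), m$layers[[1]])
  ae_err <- sum((X - recon)^2) / n
  expect_gte(ae_err, pca_residual * (1 - 1e-8))  # PCA is the optimum
  expect_lt(ae_err, 1.10 * pca_residual)
})

test_that("full-batch small-step gradient descent has non-increasing loss", {
  set.seed(9)
  X <- matrix(rnorm(50 * 5), 50, 5)
  m <- sae(X, sizes = c(5, 3, 5),
           control = sae_control(nb_epoch = 40, batch_size = 50, seed = 2,
                                 patience = 40, optimizer = "sgd", lr = 1e-3,
                                 training_ratio = 1 - 1e-9,
                                 validation_ratio = 1e-9),
           hidden_activation = "linear", output_activation = "linear")
  err <- m$training_log$train_error
  expect_true(all(diff(err) <= 1e-10))
})

test_that("early stopping halts within patience of the best validation error", {
  set.seed(4)
  X <- matrix(rnorm(120 * 6), 120, 6)
  patience <- 4
  m <- sae(X, sizes = c(6, 2, 6),
           control = sae_control(nb_epoch = 200, batch_size = 20, seed = 8,
                                 patience = patience, min_delta = 1e-3))
  log <- m$training_log
  best_epoch <- log$epoch[which.min(log$val_error)]
  expect_lte(max(log$epoch) - best_epoch, patience)
})

test_that("training is bit-reproducible for a fixed seed and config", {
  set.seed(21)
  X <- matrix(rnorm(60 * 8), 60, 8)
  ctrl <- sae_control(nb_epoch = 15, batch_size = 16, seed = 77)
  m1 <- sae(X, sizes = c(8, 4, 2, 4, 8), control = ctrl)
  m2 <- sae(X, sizes = c(8, 4, 2, 4, 8), control = ctrl)
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$training_log, m2$training_log)
  e1 <- predict(m1, X)
  expect_identical(e1, predict(m2, X))
  expect_identical(e1, predict(m1, X))  # embedding is a pure function
  expect_equal(ncol(e1), 2)
})

test_that("architecture contracts hold: palindromic sizes, bottleneck width, defaults", {
  expect_error(sae(matrix(rnorm(40), 10, 4), sizes = c(4, 3, 2)), "palindromic")
  expect_error(sae(matrix(rnorm(40), 10, 4), sizes = c(5, 2, 5)), "sizes\\[1\\]")
  expect_error(sae(matrix(numeric(0), 0, 4)), "empty")

  # the default control mirrors the published training protocol
  ctrl <- sae_control()
  expect_equal(ctrl$nb_epoch, 100L)
  expect_equal(ctrl$batch_size, 100L)
  expect_equal(ctrl$optimizer, "adadelta")
  expect_equal(ctrl$loss, "mean_square")
  expect_equal(ctrl$training_ratio, 0.7)
  expect_equal(ctrl$validation_ratio, 0.3)

  # paper-shaped model: 283-dim input embeds to 10 dims through 140-unit layers
  sch <- default_protein_schema()
  expect_equal(feature_dimension(sch), 283)
  X <- matrix(rnorm(3 * 283), 3, 283)
  sizes <- c(283, 140, 10, 140, 283)
  set.seed(1)
  layers <- list(
    ae_layer(matrix(rnorm(140 * 283, sd = 0.01), 140), numeric(140),
             matrix(rnorm(283 * 140, sd = 0.01), 283), numeric(283)),
    ae_layer(matrix(rnorm(10 * 140, sd = 0.01), 10), numeric(10),
             matrix(rnorm(140 * 10, sd = 0.01), 140), numeric(140))
  )
  model <- structure(list(layers = layers, layer_sizes = sizes,
                          bottleneck_index = 3L,
                          training_log = data.frame(),
                          control = ctrl, hidden_activation = "sigmoid",
                          output_activation = "linear", fine_tuned = FALSE),
                     class = "sae")
  expect_equal(dim(predict(model, X)), c(3L, 10L))
})

test_that("models serialize to JSON and reload with identical behavior", {
  set.seed(31)
  X <- matrix(rnorm(40 * 6), 40, 6)
  m <- sae(X, sizes = c(6, 3, 6), control = sae_control(nb_epoch = 5, seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_sae(m, path)
  back <- read_sae(path)
  expect_equal(back$layer_sizes, m$layer_sizes)
  expect_equal(predict(back, X), predict(m, X), tolerance = 1e-12)
})
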
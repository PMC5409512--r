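test_that("kernel evaluations match closed forms and are symmetric", {
  x <- c(1, 2); z <- c(2, 2)
  expect_equal(kernel_eval(x, x, "rbf", gamma = 3), 1)
  expect_equal(kernel_eval(x, z, "rbf", gamma = 1), exp(-1))
  expect_equal(kernel_eval(x, z, "linear"), 6)
  expect_error(kernel_eval(c(1, 2), c(1, 2, 3), "linear"), "mismatch")
  expect_error(kernel_eval(x, z, "rbf"), "gamma")
  set.seed(12)
  for (i in 1:5) {
    a <- rnorm(4); b <- rnorm(4); g <- runif(1, 0.1, 3)
    expect_equal(kernel_eval(a, b, "rbf", g), kernel_eval(b, a, "rbf", g))
  }
})

test_that("a symmetric separable pair sits exactly on the margins", {
  X <- matrix(c(-1, 1), ncol = 1)
  y <- c(-1, 1)
  fit <- bsvm(X, y, kernel = "linear", C_plus = 1000, C_minus = 1000,
              tol = 1e-10)
  pred <- predict(fit, X, decision.values = TRUE)
  expect_equal(attr(pred, "decision.values"), c(-1, 1), tolerance = 1e-8)
  expect_equal(as.numeric(pred), y)
  expect_equal(length(fit$support_index), 2)
})

test_that("the SMO dual matches a dense QP oracle on random instances", {
  set.seed(42)
  for (trial in 1:8) {
    n <- sample(8:30, 1)
    fx <- random_xy(n, d = 3, seed = trial + 100)
    cp <- runif(1, 0.5, 30); cm <- runif(1, 0.1, 5); g <- runif(1, 0.2, 2)
    fit <- bsvm(fx$X, fx$y, kernel = "rbf", gamma = g, C_plus = cp,
                C_minus = cm, tol = 1e-8, max_passes = 1e5)
    a_or <- qp_oracle_alpha(fx$X, fx$y, g, cp, cm)
    K <- rbf_K(fx$X, g)
    expect_equal(fit$dual_objective, dual_objective_of(a_or, fx$y, K),
                 tolerance = 1e-6)
    # KKT: equality constraint and box constraints
    expect_lt(abs(sum(fit$alpha * fx$y)), 1e-8)
    expect_true(all(fit$alpha >= 0))
    expect_true(all(fit$alpha <= ifelse(fx$y > 0, cp, cm) + 1e-12))
  }
})

test_that("decision values agree with the QP oracle on a 6-point fixture", {
  X <- matrix(c(0, 0, 1, 0, 0, 1, 2, 2, 3, 2, 2, 3), ncol = 2, byrow = TRUE)
  y <- c(-1, -1, -1, 1, 1, 1)
  g <- 1; cp <- 10; cm <- 1
  fit <- bsvm(X, y, kernel = "rbf", gamma = g, C_plus = cp, C_minus = cm,
              tol = 1e-9, max_passes = 1e5)
  a_or <- qp_oracle_alpha(X, y, g, cp, cm)
  K <- rbf_K(X, g)
  expect_equal(fit$dual_objective, dual_objective_of(a_or, y, K),
               tolerance = 1e-6)
  # oracle decision values: offset from a free oracle SV
  free <- a_or > 1e-6 & a_or < ifelse(y > 0, cp, cm) - 1e-6
  dec_nb <- as.vector(K %*% (a_or * y))
  b_or <- mean(y[free] - dec_nb[free])
  dec <- attr(predict(fit, X, decision.values = TRUE), "decision.values")
  expect_equal(dec, dec_nb + b_or, tolerance = 1e-5)
  # free support vectors lie on the +-1 margins
  my_free <- fit$alpha > 1e-6 & fit$alpha < ifelse(y > 0, cp, cm) - 1e-6
  expect_equal(abs(dec[my_free]), rep(1, sum(my_free)), tolerance = 1e-6)
  # training points are classified correctly
  expect_equal(as.numeric(predict(fit, X)), y)
})

test_that("equal penalties reproduce a reference symmetric soft-margin SVM", {
  for (trial in 1:4) {
    fx <- random_xy(20, d = 3, seed = trial + 7)
    C <- c(0.7, 2, 10, 0.3)[trial]; g <- c(0.5, 1, 0.8, 1.5)[trial]
    fit <- bsvm(fx$X, fx$y, kernel = "rbf", gamma = g, C_plus = C,
                C_minus = C, tol = 1e-8, max_passes = 1e5)
    ref <- e1071::svm(fx$X, factor(fx$y, levels = c(-1, 1)), scale = FALSE,
                      kernel = "radial", gamma = g, cost = C,
                      tolerance = 1e-8)
    dec_ref <- attr(predict(ref, fx$X, decision.values = TRUE),
                    "decision.values")
    sgn <- if (colnames(dec_ref)[1] == "1/-1") 1 else -1
    dec <- attr(predict(fit, fx$X, decision.values = TRUE), "decision.values")
    expect_equal(dec, sgn * as.numeric(dec_ref), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("raising C+/C- never lowers training recall of the positives", {
  set.seed(99)
  X <- rbind(matrix(rnorm(10 * 2, mean = 1), ncol = 2),
             matrix(rnorm(100 * 2, mean = 0), ncol = 2))
  y <- rep(c(1, -1), c(10, 100))
  cm <- 1
  recalls <- vapply(c(1, 3, 10, 30), function(r) {
    fit <- bsvm(X, y, kernel = "rbf", gamma = 0.5, C_plus = r * cm,
                C_minus = cm, tol = 1e-6, max_passes = 1e5)
    pred <- predict(fit, X)
    sum(pred == 1 & y == 1) / sum(y == 1)
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
})

test_that("heuristic penalty ratio balances class totals", {
  expect_equal(heuristic_ratio(10, 10), 1)
  expect_equal(heuristic_ratio(517, 5376), 5376 / 517)
  expect_equal(heuristic_ratio(517, 5376), 10.398, tolerance = 1e-3)
  expect_error(heuristic_ratio(0, 5), "> 0")
  ratios <- vapply(1:6, function(np) heuristic_ratio(np, 60), numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("grid search enumerates candidates and matches an exhaustive oracle", {
  fx <- random_xy(40, d = 2, seed = 5)
  grid1 <- bsvm_grid(gamma_values = 1, C_minus_values = 2,
                     C_plus_values = 6, criterion = "train_f1")
  res1 <- grid_search_bsvm(fx$X, fx$y, grid1, tol = 1e-6)
  expect_equal(res1$best, list(kernel = "rbf", gamma = 1, C_plus = 6,
                               C_minus = 2))

  grid <- bsvm_grid(gamma_values = c(0.5, 2), C_minus_values = c(0.5, 2),
                    C_plus_values = c(1, 5), criterion = "train_f1")
  res <- grid_search_bsvm(fx$X, fx$y, grid, tol = 1e-6)
  # independent loop over fit + score
  best_score <- -Inf; best <- NULL
  for (g in c(0.5, 2)) for (cm in c(0.5, 2)) for (cp in c(1, 5)) {
    fit <- bsvm(fx$X, fx$y, kernel = "rbf", gamma = g, C_plus = cp,
                C_minus = cm, tol = 1e-6)
    pred <- predict(fit, fx$X)
    tp <- sum(pred == 1 & fx$y == 1)
    f1 <- if (tp == 0) 0 else {
      2 * tp / (2 * tp + sum(pred == 1 & fx$y == -1) +
                  sum(pred == -1 & fx$y == 1))
    }
    if (f1 > best_score) { best_score <- f1; best <- c(g, cp, cm) }
  }
  expect_equal(res$best_score, best_score)
  expect_equal(res$best$gamma, best[1])
  expect_equal(nrow(res$table), 8)

  # ratio-locked candidates satisfy the class-balance heuristic exactly
  gridr <- bsvm_grid(gamma_values = c(0.5, 1), C_minus_values = c(0.5, 1),
                     ratio_locked = TRUE)
  resr <- grid_search_bsvm(fx$X, fx$y, gridr, tol = 1e-6)
  r <- heuristic_ratio(sum(fx$y == 1), sum(fx$y == -1))
  expect_equal(resr$table$C_plus / resr$table$C_minus, rep(r, 4))
})

test_that("degenerate inputs are rejected with clear messages", {
  X <- matrix(rnorm(10), ncol = 1)
  expect_error(bsvm(X, rep(1, 10)), "both classes")
  expect_error(bsvm(X, c(rep(1, 5), rep(0, 5))), "-1 or \\+1")
  X[1] <- NA
  expect_error(bsvm(X, rep(c(1, -1), 5)), "non-finite")
  expect_error(bsvm(matrix(1:4, 2), c(1, -1), kernel = "rbf"), "gamma")
  expect_error(bsvm(matrix(1:4, 2), c(1, -1), kernel = "linear",
                    C_plus = -1), "penalties")
})

test_that("fitted models serialize and reload with identical predictions", {
  fx <- random_xy(25, d = 3, seed = 3)
  fit <- bsvm(fx$X, fx$y, kernel = "rbf", gamma = 0.7, C_plus = 4,
              C_minus = 1, tol = 1e-6)
  path <- withr::local_tempfile(fileext = ".json")
  write_bsvm(fit, path)
  back <- read_bsvm(path)
  expect_equal(predict(back, fx$X, decision.values = TRUE),
               predict(fit, fx$X, decision.values = TRUE), tolerance = 1e-12)
})
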
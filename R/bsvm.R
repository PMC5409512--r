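# Biased SVM: soft-margin kernel SVM with asymmetric slack penalties
# (C+ on labeled positives, C- on unlabeled-treated-as-negative), the
# cost-sensitive classifier of PU learning. Solved in the dual by an
# SMO-style maximal-violating-pair working-set method with per-class box
# bounds, so the asymmetric penalties enter only through the bounds.

#' Evaluate the classifier kernel
#'
#' @param x1,x2 numeric vectors of equal length.
#' @param kernel `"rbf"` (Gaussian, `exp(-gamma * ||x1 - x2||^2)`) or
#'   `"linear"` (dot product).
#' @param gamma RBF width parameter (> 0); required for `kernel = "rbf"`.
#' @return A single kernel value.
#' @export
kernel_eval <- function(x1, x2, kernel = c("rbf", "linear"), gamma = NULL) {
  kernel <- match.arg(kernel)
  if (length(x1) != length(x2)) {
    stop_ctx("kernel_eval: dimension mismatch (%d vs %d)", length(x1), length(x2))
  }
  if (kernel == "linear") return(sum(x1 * x2))
  if (is.null(gamma) || gamma <= 0) stop_ctx("kernel_eval: rbf kernel requires gamma > 0")
  exp(-gamma * sum((x1 - x2)^2))
}

# full cross-kernel matrix K(X1, X2)
kernel_matrix <- function(X1, X2, kernel, gamma) {
  if (kernel == "linear") return(X1 %*% t(X2))
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * X1 %*% t(X2)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

#' Fit a biased support vector machine
#'
#' Solves the soft-margin SVM whose primal penalizes slack on the k labeled
#' positives with weight `C_plus` and slack on the remaining
#' unlabeled-as-negative records with weight `C_minus`:
#' \deqn{\min \tfrac12 w^T w + C_+ \sum_{i=1}^{k}\zeta_i +
#'       C_- \sum_{i=k+1}^{n}\zeta_i}
#' subject to \eqn{y_i(w^T\phi(x_i)+b) \ge 1-\zeta_i,\ \zeta_i \ge 0}.
#' Setting \eqn{C_+ > C_-} makes positive-side margin violations expensive
#' and biases the decision boundary toward recalling the minority positives,
#' the standard PU-learning device when unlabeled records are treated as
#' negatives.
#'
#' The dual quadratic program with per-class box constraints
#' \eqn{0 \le \alpha_i \le C_{class(i)}} is solved by sequential minimal
#' optimization with maximal-violating-pair working-set selection; the fit
#' stops when the KKT violation falls below `tol`.
#'
#' @param x numeric feature matrix (rows = samples) or [feature_matrix()].
#' @param y labels in \{-1, +1\} (`+1` = labeled positive). When `x` is a
#'   `feature_matrix` and `y` is omitted, labels are derived from its PU row
#'   labels (`positive` = +1, `unlabeled` = -1).
#' @param kernel,gamma see [kernel_eval()].
#' @param C_plus,C_minus positive slack penalties for the +1 / -1 class.
#' @param tol KKT tolerance of the solver.
#' @param max_passes iteration budget, expressed in sweep-equivalents (one
#'   pass = n pairwise updates).
#' @return An object of class `bsvm`: support vectors, dual coefficients
#'   (alpha_i * y_i), offset, the full alpha vector, and solver diagnostics.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(20, 2), ncol = 2), matrix(rnorm(80, -1), ncol = 2))
#' y <- rep(c(1, -1), c(10, 40))
#' fit <- bsvm(x, y, kernel = "rbf", gamma = 0.5, C_plus = 10, C_minus = 1)
#' table(truth = y, predicted = predict(fit, x))
#' @export
bsvm <- function(x, y = NULL, kernel = c("rbf", "linear"), gamma = NULL,
                 C_plus = 1, C_minus = 1, tol = 1e-3, max_passes = 1e4) {
  kernel <- match.arg(kernel)
  if (inherits(x, "feature_matrix")) {
    if (is.null(y)) y <- ifelse(x$row_labels == "positive", 1, -1)
    x <- x$values
  }
  X <- as.matrix(x)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop_ctx("bsvm: %d labels for %d rows", length(y), nrow(X))
  if (!all(y %in% c(-1, 1))) stop_ctx("bsvm: labels must be -1 or +1")
  if (length(unique(y)) < 2) stop_ctx("bsvm: both classes must be present")
  if (anyNA(X) || any(!is.finite(X))) stop_ctx("bsvm: non-finite feature values")
  if (C_plus <= 0 || C_minus <= 0) stop_ctx("bsvm: penalties must be > 0")
  if (kernel == "rbf" && (is.null(gamma) || gamma <= 0)) {
    stop_ctx("bsvm: rbf kernel requires gamma > 0")
  }

  n <- nrow(X)
  K <- kernel_matrix(X, X, kernel, gamma)
  Kdiag <- diag(K)
  Cbox <- ifelse(y > 0, C_plus, C_minus)

  alpha <- numeric(n)
  G <- rep(-1, n)          # gradient of 1/2 a'Qa - e'a at alpha = 0
  max_iter <- max_passes * n
  iter <- 0L
  repeat {
    yG <- -y * G
    up <- (y > 0 & alpha < Cbox - 1e-12) | (y < 0 & alpha > 1e-12)
    low <- (y < 0 & alpha < Cbox - 1e-12) | (y > 0 & alpha > 1e-12)
    if (!any(up) || !any(low)) break
    i <- which(up)[which.max(yG[up])]
    j <- which(low)[which.min(yG[low])]
    gap <- yG[i] - yG[j]
    if (gap <= tol) break
    if (iter >= max_iter) {
      stop_ctx("bsvm: no convergence after %g passes (KKT gap %.3g > tol %.3g); increase max_passes or tol",
               max_passes, gap, tol)
    }
    eta <- Kdiag[i] + Kdiag[j] - 2 * K[i, j]
    if (eta <= 1e-12) eta <- 1e-12
    t_star <- gap / eta
    # box limits along the feasible direction (alpha_i moves by y_i*t)
    t_max_i <- if (y[i] > 0) Cbox[i] - alpha[i] else alpha[i]
    t_max_j <- if (y[j] > 0) alpha[j] else Cbox[j] - alpha[j]
    t_step <- min(t_star, t_max_i, t_max_j)
    alpha[i] <- alpha[i] + y[i] * t_step
    alpha[j] <- alpha[j] - y[j] * t_step
    G <- G + t_step * y * (K[, i] - K[, j])
    iter <- iter + 1L
  }

  # offset from free support vectors; fall back to the violating-pair midpoint
  free <- alpha > 1e-8 & alpha < Cbox - 1e-8
  dec_no_b <- as.vector(K %*% (alpha * y))
  b <- if (any(free)) {
    mean(y[free] - dec_no_b[free])
  } else {
    yG <- -y * G
    up <- (y > 0 & alpha < Cbox - 1e-12) | (y < 0 & alpha > 1e-12)
    low <- (y < 0 & alpha < Cbox - 1e-12) | (y > 0 & alpha > 1e-12)
    hi <- if (any(up)) max(yG[up]) else 0
    lo <- if (any(low)) min(yG[low]) else 0
    (hi + lo) / 2
  }

  sv <- which(alpha > 1e-8)
  obj <- sum(alpha) - 0.5 * sum((alpha * y) * (K %*% (alpha * y)))
  structure(list(
    support_index = sv,
    support_vectors = X[sv, , drop = FALSE],
    dual_coef = (alpha * y)[sv],
    offset = b,
    alpha = alpha,
    y = y,
    config = list(kernel = kernel, gamma = gamma,
                  C_plus = C_plus, C_minus = C_minus),
    dual_objective = obj,
    kkt_gap = {
      yG <- -y * G
      up <- (y > 0 & alpha < Cbox - 1e-12) | (y < 0 & alpha > 1e-12)
      low <- (y < 0 & alpha < Cbox - 1e-12) | (y > 0 & alpha > 1e-12)
      if (any(up) && any(low)) max(yG[up]) - min(yG[low]) else 0
    },
    iterations = iter,
    tol = tol,
    n_train = n
  ), class = "bsvm")
}

#' @export
print.bsvm <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Biased SVM (%s kernel%s), C+ = %g, C- = %g\n",
              cfg$kernel,
              if (cfg$kernel == "rbf") sprintf(", gamma = %g", cfg$gamma) else "",
              cfg$C_plus, cfg$C_minus))
  cat(sprintf("  %d support vectors of %d training rows; KKT gap %.2e after %d updates\n",
              length(x$support_index), x$n_train, x$kkt_gap, x$iterations))
  invisible(x)
}

#' @export
summary.bsvm <- function(object, ...) {
  at_bound <- sum(abs(abs(object$dual_coef) -
                        ifelse(object$dual_coef > 0, object$config$C_plus,
                               object$config$C_minus)) < 1e-8)
  structure(list(model = object, bounded_svs = at_bound), class = "summary.bsvm")
}

#' @export
print.summary.bsvm <- function(x, ...) {
  print(x$model)
  cat(sprintf("  %d support vectors at their box bound; dual objective %.6g\n",
              x$bounded_svs, x$model$dual_objective))
  invisible(x)
}

#' @export
coef.bsvm <- function(object, ...) {
  stats::setNames(c(object$dual_coef, object$offset),
                  c(paste0("alpha_y_", object$support_index), "offset"))
}

#' Predict with a fitted biased SVM
#'
#' The decision value is `sum_i alpha_i y_i K(x_i, x) + b`; the predicted
#' label is its sign, with a value of exactly zero mapped to the negative
#' class (conservative for candidate retrieval).
#'
#' @param object a fitted [bsvm()].
#' @param x feature matrix (or [feature_matrix()]) of points to classify.
#' @param decision.values if `TRUE`, attach the raw decision values as the
#'   `"decision.values"` attribute.
#' @param ... unused.
#' @return Numeric vector of labels in \{-1, +1\}.
#' @export
predict.bsvm <- function(object, x, decision.values = FALSE, ...) {
  X <- if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
  if (ncol(X) != ncol(object$support_vectors)) {
    stop_ctx("predict.bsvm: %d columns but the model was trained on %d",
             ncol(X), ncol(object$support_vectors))
  }
  K <- kernel_matrix(X, object$support_vectors, object$config$kernel,
                     object$config$gamma)
  dec <- as.vector(K %*% object$dual_coef) + object$offset
  lab <- ifelse(dec > 0, 1, -1)
  if (decision.values) attr(lab, "decision.values") <- dec
  lab
}

#' Heuristic penalty ratio for PU class weighting
#'
#' Returns the ratio `C_plus / C_minus = n_neg / n_pos` implied by the
#' balance heuristic `C+ |P| = C- |N|`, used to shrink the penalty grid to a
#' single free parameter.
#'
#' @param n_pos,n_neg positive and (unlabeled-as-)negative counts, both > 0.
#' @return The ratio `n_neg / n_pos`.
#' @export
heuristic_ratio <- function(n_pos, n_neg) {
  if (n_pos <= 0 || n_neg <= 0) stop_ctx("heuristic_ratio: counts must be > 0")
  n_neg / n_pos
}

#' Specify a BSVM hyperparameter grid
#'
#' @param gamma_values candidate RBF widths (ascending order is imposed).
#' @param C_minus_values candidate penalties for the negative class.
#' @param C_plus_values candidate penalties for the positive class; ignored
#'   when `ratio_locked`.
#' @param ratio_locked if `TRUE`, each candidate sets
#'   `C_plus = heuristic_ratio(n_pos, n_neg) * C_minus`, reducing the search
#'   to (gamma, C-).
#' @param criterion `"train_f1"` (F1 of the positive class on the training
#'   data itself, the primary protocol) or `"cv_f1"` (mean positive-class F1
#'   over stratified folds).
#' @param cv_folds number of folds for `criterion = "cv_f1"`.
#' @return A list of class `bsvm_grid`.
#' @export
bsvm_grid <- function(gamma_values, C_minus_values, C_plus_values = NULL,
                      ratio_locked = FALSE,
                      criterion = c("train_f1", "cv_f1"), cv_folds = 5) {
  criterion <- match.arg(criterion)
  if (!length(gamma_values) || !length(C_minus_values)) {
    stop_ctx("bsvm_grid: candidate lists must be non-empty")
  }
  if (!ratio_locked && !length(C_plus_values)) {
    stop_ctx("bsvm_grid: C_plus_values required unless ratio_locked")
  }
  if (criterion == "cv_f1" && cv_folds < 2) stop_ctx("bsvm_grid: cv_folds must be >= 2")
  structure(list(gamma_values = sort(as.numeric(gamma_values)),
                 C_minus_values = sort(as.numeric(C_minus_values)),
                 C_plus_values = if (is.null(C_plus_values)) NULL else sort(as.numeric(C_plus_values)),
                 ratio_locked = ratio_locked,
                 criterion = criterion, cv_folds = as.integer(cv_folds)),
            class = "bsvm_grid")
}

# stratified fold assignment, seeded
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

positive_f1 <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == -1 & pred == 1)
  fn <- sum(truth == 1 & pred == -1)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Grid search for BSVM hyperparameters
#'
#' Evaluates every candidate (gamma, C-, C+) combination under the chosen
#' criterion and returns the argmax. Candidates are visited with gamma
#' ascending, then C- ascending, then C+ ascending, and ties keep the first
#' maximum, so the search is deterministic. Per-candidate fit failures are
#' recorded in the score table rather than aborting, unless every candidate
#' fails.
#'
#' @param x feature matrix (rows = samples) or [feature_matrix()].
#' @param y labels in \{-1, +1\} (derived from PU row labels when omitted
#'   and `x` is a `feature_matrix`).
#' @param grid a [bsvm_grid()].
#' @param seed seed for the cross-validation folds.
#' @param ... further arguments passed to [bsvm()] (e.g. `tol`).
#' @return A list with `best` (the winning parameter list), `best_score`,
#'   and `table` (data frame of gamma, C_plus, C_minus, score, error).
#' @export
grid_search_bsvm <- function(x, y = NULL, grid, seed = 1L, ...) {
  stopifnot(inherits(grid, "bsvm_grid"))
  if (inherits(x, "feature_matrix")) {
    if (is.null(y)) y <- ifelse(x$row_labels == "positive", 1, -1)
    x <- x$values
  }
  X <- as.matrix(x); y <- as.numeric(y)
  n_pos <- sum(y == 1); n_neg <- sum(y == -1)
  cplus_for <- function(cm) {
    if (grid$ratio_locked) heuristic_ratio(n_pos, n_neg) * cm else grid$C_plus_values
  }
  fold <- if (grid$criterion == "cv_f1") stratified_folds(y, grid$cv_folds, seed) else NULL

  rows <- list()
  best <- NULL; best_score <- -Inf
  for (g in grid$gamma_values) {
    for (cm in grid$C_minus_values) {
      for (cp in cplus_for(cm)) {
        score <- NA_real_; err <- NA_character_
        res <- tryCatch({
          if (grid$criterion == "train_f1") {
            fit <- bsvm(X, y, kernel = "rbf", gamma = g,
                        C_plus = cp, C_minus = cm, ...)
            positive_f1(y, predict(fit, X))
          } else {
            f1s <- numeric(0)
            for (k in seq_len(grid$cv_folds)) {
              tr <- fold != k
              if (length(unique(y[tr])) < 2 || !any(!tr)) next
              fit <- bsvm(X[tr, , drop = FALSE], y[tr], kernel = "rbf",
                          gamma = g, C_plus = cp, C_minus = cm, ...)
              f1s <- c(f1s, positive_f1(y[!tr], predict(fit, X[!tr, , drop = FALSE])))
            }
            mean(f1s)
          }
        }, error = function(e) e)
        if (inherits(res, "error")) err <- conditionMessage(res) else score <- res
        rows[[length(rows) + 1L]] <- data.frame(
          gamma = g, C_plus = cp, C_minus = cm, score = score,
          error = err, stringsAsFactors = FALSE)
        if (!is.na(score) && score > best_score) {
          best_score <- score
          best <- list(kernel = "rbf", gamma = g, C_plus = cp, C_minus = cm)
        }
      }
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(best)) {
    stop_ctx("grid_search_bsvm: every candidate failed; first error: %s", tab$error[1])
  }
  list(best = best, best_score = best_score, table = tab)
}

#' Serialize a fitted BSVM to JSON
#'
#' @param model a fitted [bsvm()].
#' @param path file path.
#' @return `path` (write) or a `bsvm` object (read).
#' @export
write_bsvm <- function(model, path) {
  stopifnot(inherits(model, "bsvm"))
  payload <- list(support_vectors = model$support_vectors,
                  dual_coef = model$dual_coef,
                  offset = model$offset,
                  support_index = model$support_index,
                  config = model$config,
                  dual_objective = model$dual_objective,
                  kkt_gap = model$kkt_gap)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_bsvm
#' @export
read_bsvm <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(support_index = as.integer(p$support_index),
                 support_vectors = as.matrix(p$support_vectors),
                 dual_coef = as.numeric(p$dual_coef),
                 offset = p$offset,
                 alpha = NULL, y = NULL,
                 config = p$config,
                 dual_objective = p$dual_objective,
                 kkt_gap = p$kkt_gap,
                 iterations = NA_integer_, tol = NA_real_,
                 n_train = NA_integer_),
            class = "bsvm")
}
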
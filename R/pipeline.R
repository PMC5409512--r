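# Experiment pipeline: repeated stratified hold-out evaluation of the
# PU classifier under three representations (SAE embedding, wrapper-selected
# raw features, or the full encoded matrix), plus doubtful-target retrieval.

#' Stratified train/test split
#'
#' Splits rows into train and test sets preserving the class proportions:
#' per class, the training count is `round(fraction * class size)`
#' (round-half-up). Sampling is without replacement and seeded.
#'
#' @param labels a [property_table()], [feature_matrix()], or a vector of
#'   class labels (any two-or-more-level labelling).
#' @param train_fraction fraction of each class assigned to training,
#'   strictly between 0 and 1.
#' @param seed integer seed.
#' @return A list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(labels, train_fraction = 0.7, seed = 1L) {
  if (inherits(labels, "property_table")) labels <- labels$label
  if (inherits(labels, "feature_matrix")) labels <- labels$row_labels
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop_ctx("stratified_split: train_fraction must be in (0, 1)")
  }
  classes <- unique(labels)
  if (length(classes) < 2) stop_ctx("stratified_split: need at least two classes")
  train <- integer(0)
  with_seed(seed, {
    for (cls in classes) {
      idx <- which(labels == cls)
      if (length(idx) < 2) {
        stop_ctx("stratified_split: class '%s' has fewer than 2 records", cls)
      }
      n_tr <- round_half_up(train_fraction * length(idx))
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      train <- c(train, sample(idx, n_tr))
    }
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

#' Confusion counts for PU evaluation
#'
#' Labeled positives (drug targets) are scored as class +1 and unlabeled
#' records as class -1, following the PU convention of treating the
#' unlabeled set as negative during evaluation.
#'
#' @param observed labels: `"positive"`/`"unlabeled"` or +1/-1.
#' @param predicted labels in \{-1, +1\}.
#' @return A list of class `confusion_counts` with integers `TP`, `FP`,
#'   `FN`, `TN`.
#' @export
confusion_counts <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop_ctx("confusion_counts: length mismatch (%d vs %d)",
             length(observed), length(predicted))
  }
  if (is.character(observed) || is.factor(observed)) {
    observed <- ifelse(as.character(observed) == "positive", 1, -1)
  }
  structure(list(
    TP = sum(observed == 1 & predicted == 1),
    FP = sum(observed == -1 & predicted == 1),
    FN = sum(observed == 1 & predicted == -1),
    TN = sum(observed == -1 & predicted == -1)
  ), class = "confusion_counts")
}

#' F-beta score from confusion counts
#'
#' Computes the weighted harmonic mean of precision and recall of the
#' positive class,
#' \deqn{F_\beta = (1+\beta^2)\,\frac{P\,R}{\beta^2 P + R},}
#' with `beta = 1` (equal weight, the F1 score) as the evaluation default.
#' Returns 0 when no true positives exist but errors were made; the
#' degenerate all-zero case returns 0 with a warning.
#'
#' @param counts a [confusion_counts()] or a list with `TP`, `FP`, `FN`.
#' @param beta positive recall/precision trade-off weight.
#' @return The F-beta score in \[0, 1\].
#' @export
fbeta <- function(counts, beta = 1) {
  if (beta <= 0) stop_ctx("fbeta: beta must be > 0")
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  if (any(c(tp, fp, fn) < 0)) stop_ctx("fbeta: negative counts")
  if (tp == 0) {
    if (fp == 0 && fn == 0) {
      warning("fbeta: no positives observed or predicted; returning 0", call. = FALSE)
    }
    return(0)
  }
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  (1 + beta^2) * p * r / (beta^2 * p + r)
}

#' Evaluate PU predictions
#'
#' @param observed labels: `"positive"`/`"unlabeled"` or +1/-1.
#' @param predicted labels in \{-1, +1\}.
#' @return A list with `counts` ([confusion_counts()]), `f1_dtp` (F1 of the
#'   positive class), `recall_dtp` (TP / (TP + FN)) and `precision_ndtp`
#'   (TN / (TN + FN), the precision of the predicted-negative class).
#' @export
evaluate_predictions <- function(observed, predicted) {
  cc <- confusion_counts(observed, predicted)
  recall <- if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else 0
  prec_n <- if (cc$TN + cc$FN > 0) cc$TN / (cc$TN + cc$FN) else 0
  list(counts = cc,
       f1_dtp = suppressWarnings(fbeta(cc, 1)),
       recall_dtp = recall,
       precision_ndtp = prec_n)
}

#' Sequential forward wrapper feature selection
#'
#' Greedy forward selection driven by the downstream classifier: at each
#' step the candidate feature whose addition maximizes the stratified
#' cross-validated positive-class F1 of the BSVM is accepted, until no
#' candidate improves the score by at least `min_delta` (or `max_features`
#' is reached). Folds with a single class are skipped with a warning.
#'
#' @param x feature matrix (rows = samples) or [feature_matrix()].
#' @param y labels in \{-1, +1\} (derived from PU row labels when omitted).
#' @param config named list of [bsvm()] arguments used for every candidate
#'   fit (kernel, gamma, C_plus, C_minus, ...).
#' @param cv_folds number of stratified folds.
#' @param min_delta minimum score improvement to accept a feature.
#' @param max_features optional cap on the number of selected features.
#' @param seed seed for the fold assignment.
#' @return Integer vector of selected column indices, in acceptance order,
#'   with the per-step scores as the `"scores"` attribute.
#' @export
wrapper_select <- function(x, y = NULL, config = list(kernel = "rbf", gamma = 1,
                                                      C_plus = 10, C_minus = 1),
                           cv_folds = 5, min_delta = 1e-4,
                           max_features = NULL, seed = 1L) {
  if (inherits(x, "feature_matrix")) {
    if (is.null(y)) y <- ifelse(x$row_labels == "positive", 1, -1)
    x <- x$values
  }
  X <- as.matrix(x); y <- as.numeric(y)
  if (ncol(X) < 1) stop_ctx("wrapper_select: no features to select from")
  fold <- stratified_folds(y, cv_folds, seed)
  cv_score <- function(cols) {
    f1s <- numeric(0)
    for (k in seq_len(cv_folds)) {
      tr <- fold != k
      if (length(unique(y[tr])) < 2 || length(unique(y[!tr])) < 1) {
        warning("wrapper_select: degenerate fold skipped", call. = FALSE)
        next
      }
      fit <- do.call(bsvm, c(list(x = X[tr, cols, drop = FALSE], y = y[tr]), config))
      f1s <- c(f1s, positive_f1(y[!tr], predict(fit, X[!tr, cols, drop = FALSE])))
    }
    if (!length(f1s)) return(0)
    mean(f1s)
  }

  selected <- integer(0)
  scores <- numeric(0)
  best <- 0
  cap <- max_features %||% ncol(X)
  while (length(selected) < cap) {
    remaining <- setdiff(seq_len(ncol(X)), selected)
    if (!length(remaining)) break
    cand_scores <- vapply(remaining, function(j) cv_score(c(selected, j)), numeric(1))
    jbest <- remaining[which.max(cand_scores)]
    sbest <- max(cand_scores)
    if (length(selected) > 0 && sbest < best + min_delta) break
    if (length(selected) == 0 && sbest <= 0) {
      # accept the best first feature even under a flat score so the
      # representation is never empty
      selected <- jbest; scores <- sbest; best <- sbest
      next
    }
    selected <- c(selected, jbest)
    scores <- c(scores, sbest)
    best <- sbest
  }
  attr(selected, "scores") <- scores
  selected
}

#' Retrieve doubtful drug-target candidates
#'
#' The doubtful set consists of the unlabeled records that the fitted
#' classifier predicts as positive, merging those flagged in the training
#' portion with those flagged in the test portion; the retrieved proportion
#' is taken over all unlabeled records.
#'
#' @param representation a [feature_matrix()] carrying PU row labels and ids.
#' @param model a fitted [bsvm()] trained on this representation's training
#'   rows.
#' @param split optional list with `train`/`test` indices (all rows are
#'   scored either way; the split is echoed for bookkeeping).
#' @return A list of class `retrieval_result`: sorted `doubtful_ids`,
#'   `proportion`, and the decision values of the doubtful records.
#' @export
retrieve_doubtful <- function(representation, model, split = NULL) {
  stopifnot(inherits(representation, "feature_matrix"), inherits(model, "bsvm"))
  pred <- predict(model, representation, decision.values = TRUE)
  dec <- attr(pred, "decision.values")
  unl <- representation$row_labels == "unlabeled"
  if (!any(unl)) stop_ctx("retrieve_doubtful: no unlabeled records")
  hit <- unl & (as.numeric(pred) == 1)
  ids <- representation$row_ids[hit]
  ord <- order(ids)
  structure(list(doubtful_ids = ids[ord],
                 decision_values = stats::setNames(dec[hit][ord], ids[ord]),
                 proportion = sum(hit) / sum(unl),
                 split = split),
            class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat(sprintf("Doubtful drug-target candidates: %d unlabeled records flagged (%.1f%% of the unlabeled set)\n",
              length(x$doubtful_ids), 100 * x$proportion))
  invisible(x)
}

#' Write a doubtful-candidate list as TSV
#'
#' @param result a [retrieve_doubtful()] result.
#' @param path output path (two columns: id, decision value).
#' @return `path`, invisibly.
#' @export
write_retrieval <- function(result, path) {
  utils::write.table(
    data.frame(id = result$doubtful_ids,
               decision_value = as.numeric(result$decision_values)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# population (divisor n) or sample variance of a vector
variance_of <- function(x, type = "population") {
  m <- mean(x)
  s <- sum((x - m)^2)
  s / if (type == "population") length(x) else max(1, length(x) - 1)
}

#' Run the repeated stratified PU experiment
#'
#' The full evaluation protocol: for each of `n_iterations` independent
#' iterations, a representation of the proteins is built according to
#' `variant`, the rows are split 70/30 per class with a fresh seed, the BSVM
#' hyperparameters are chosen by grid search on the training split, the
#' winning model is refitted and evaluated on both splits, and the doubtful
#' unlabeled records (predicted positive anywhere) are retrieved. Metric
#' means and variances over iterations are reported per split.
#'
#' Variants:
#' \describe{
#'   \item{`sae`}{the stacked auto-encoder is retrained on all rows (its
#'     internal 70/30 split only drives early stopping) with a fresh seed,
#'     and its bottleneck embedding is the representation;}
#'   \item{`wrapper`}{sequential forward selection on the training rows
#'     picks a column subset of the encoded matrix;}
#'   \item{`origin`}{the full encoded matrix is used unchanged.}
#' }
#'
#' @param table a [property_table()], or a precomputed [feature_matrix()].
#' @param variant `"sae"`, `"wrapper"` or `"origin"`.
#' @param n_iterations number of independent iterations (default 10).
#' @param train_fraction per-class training fraction (default 0.7).
#' @param grid a [bsvm_grid()]; default is a small heuristic-ratio-locked
#'   grid searched on training F1.
#' @param sae_sizes,sae_opts architecture and [sae_control()] overrides for
#'   the `sae` variant (the per-iteration seed is always injected).
#' @param wrapper_opts named list of [wrapper_select()] arguments for the
#'   `wrapper` variant.
#' @param svm_tol solver tolerance passed to every [bsvm()] fit.
#' @param variance_type `"population"` (divisor n, default) or `"sample"`.
#' @param seed master seed; every per-iteration seed derives from it, so a
#'   run is bit-reproducible end to end.
#' @return An object of class `pu_experiment` with per-iteration results,
#'   Table-style summary statistics, and the retrieval results.
#' @export
run_experiment <- function(table, variant = c("sae", "wrapper", "origin"),
                           n_iterations = 10, train_fraction = 0.7,
                           grid = NULL, sae_sizes = NULL, sae_opts = list(),
                           wrapper_opts = list(), svm_tol = 1e-3,
                           variance_type = c("population", "sample"),
                           seed = 1L) {
  variant <- match.arg(variant)
  variance_type <- match.arg(variance_type)
  if (n_iterations < 1) stop_ctx("run_experiment: n_iterations must be >= 1")

  fm <- if (inherits(table, "feature_matrix")) {
    table
  } else {
    predict(fit_preprocessor(table), table)
  }
  y <- ifelse(fm$row_labels == "positive", 1, -1)
  if (is.null(grid)) {
    grid <- bsvm_grid(gamma_values = c(0.5, 2), C_minus_values = c(0.5, 1),
                      ratio_locked = TRUE, criterion = "train_f1")
  }
  iter_seeds <- derive_seeds(seed, n_iterations)

  iterations <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    s <- iter_seeds[it]
    rep_fm <- switch(variant,
      sae = {
        ctrl <- do.call(sae_control, utils::modifyList(sae_opts, list(seed = s)))
        model <- sae(fm, sizes = sae_sizes, control = ctrl)
        predict(model, fm)
      },
      wrapper = NULL,  # needs the split first; built below
      origin = fm
    )
    split <- stratified_split(fm$row_labels, train_fraction, seed = s)
    if (variant == "wrapper") {
      sel <- do.call(wrapper_select,
                     c(list(x = fm$values[split$train, , drop = FALSE],
                            y = y[split$train], seed = s), wrapper_opts))
      rep_fm <- feature_matrix(fm$values[, sel, drop = FALSE],
                               fm$provenance[sel, , drop = FALSE],
                               fm$row_ids, fm$row_labels)
    }
    gs <- grid_search_bsvm(rep_fm$values[split$train, , drop = FALSE],
                           y[split$train], grid, seed = s, tol = svm_tol)
    fit <- bsvm(rep_fm$values[split$train, , drop = FALSE], y[split$train],
                kernel = gs$best$kernel, gamma = gs$best$gamma,
                C_plus = gs$best$C_plus, C_minus = gs$best$C_minus,
                tol = svm_tol)
    pred_train <- predict(fit, rep_fm$values[split$train, , drop = FALSE])
    pred_test <- predict(fit, rep_fm$values[split$test, , drop = FALSE])
    ev_train <- evaluate_predictions(y[split$train], pred_train)
    ev_test <- evaluate_predictions(y[split$test], pred_test)
    iterations[[it]] <- list(
      seed = s, split = split, best_config = gs$best,
      train = ev_train, test = ev_test,
      retrieval = retrieve_doubtful(rep_fm, fit, split)
    )
  }

  metrics <- c("f1_dtp", "recall_dtp", "precision_ndtp")
  summ <- expand.grid(split = c("train", "test"), metric = metrics,
                      stringsAsFactors = FALSE)
  summ$mean <- summ$variance <- NA_real_
  for (r in seq_len(nrow(summ))) {
    vals <- vapply(iterations,
                   function(itr) itr[[summ$split[r]]][[summ$metric[r]]],
                   numeric(1))
    summ$mean[r] <- mean(vals)
    summ$variance[r] <- variance_of(vals, variance_type)
  }
  props <- vapply(iterations, function(itr) itr$retrieval$proportion, numeric(1))

  structure(list(variant = variant, n_iterations = n_iterations,
                 iterations = iterations, summary = summ,
                 doubtful_proportion_mean = mean(props),
                 doubtful_proportions = props,
                 variance_type = variance_type, seed = seed),
            class = "pu_experiment")
}

#' @export
print.pu_experiment <- function(x, digits = 3, ...) {
  cat(sprintf("PU experiment, variant '%s': %d iteration(s), %s variance\n",
              x$variant, x$n_iterations, x$variance_type))
  s <- x$summary
  wide <- data.frame(Dataset = c("Training", "Testing"))
  for (m in unique(s$metric)) {
    col <- vapply(c("train", "test"), function(sp) {
      row <- s[s$split == sp & s$metric == m, ]
      sprintf("%s(%s)", format(round(row$mean, digits)),
              format(round(row$variance, digits)))
    }, character(1))
    wide[[m]] <- col
  }
  print(wide, row.names = FALSE)
  cat(sprintf("Mean doubtful proportion among unlabeled: %.3f\n",
              x$doubtful_proportion_mean))
  invisible(x)
}

#' @export
summary.pu_experiment <- function(object, ...) object$summary

#' Write experiment outputs as TSV
#'
#' `write_experiment_summary` emits the per-metric mean/variance table;
#' `write_experiment_log` emits one row per iteration with its seed, chosen
#' hyperparameters and metrics.
#'
#' @param experiment a [run_experiment()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_experiment_summary <- function(experiment, path) {
  s <- experiment$summary
  s <- cbind(variant = experiment$variant, s)
  utils::write.table(s, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_experiment_summary
#' @export
write_experiment_log <- function(experiment, path) {
  rows <- lapply(seq_along(experiment$iterations), function(i) {
    itr <- experiment$iterations[[i]]
    data.frame(iteration = i, seed = itr$seed,
               gamma = itr$best_config$gamma,
               C_plus = itr$best_config$C_plus,
               C_minus = itr$best_config$C_minus,
               train_f1 = itr$train$f1_dtp,
               train_recall = itr$train$recall_dtp,
               train_precision_ndtp = itr$train$precision_ndtp,
               test_f1 = itr$test$f1_dtp,
               test_recall = itr$test$recall_dtp,
               test_precision_ndtp = itr$test$precision_ndtp,
               doubtful_proportion = itr$retrieval$proportion)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
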
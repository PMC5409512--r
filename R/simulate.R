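# Contamination-mixture simulator: positive and unlabeled protein records
# with hidden ground truth, following the PU mixture
# h_u(x) = alpha * h+(x) + (1 - alpha) * h-(x).

#' Default paper-shaped property schema
#'
#' Builds a schema with `n_continuous` continuous properties and one nominal
#' property per entry of `nominal_states` (that many states each). The
#' default shape — 31 continuous properties and 8 nominal properties whose
#' state counts sum to 252 — mirrors the drug-target property table and
#' yields a 283-dimensional encoded feature space.
#'
#' @param n_continuous number of continuous properties.
#' @param nominal_states integer vector of state counts, one nominal
#'   property each.
#' @return A [property_schema()].
#' @export
default_protein_schema <- function(n_continuous = 31,
                                   nominal_states = c(31, 31, 31, 31, 32, 32, 32, 32)) {
  cn <- sprintf("cont_%02d", seq_len(n_continuous))
  nn <- sprintf("nom_%02d", seq_along(nominal_states))
  states <- stats::setNames(
    lapply(nominal_states, function(s) sprintf("s%02d", seq_len(s))), nn)
  property_schema(name = c(cn, nn),
                  kind = c(rep("continuous", n_continuous),
                           rep("nominal", length(nominal_states))),
                  states = states)
}

#' Simulate a contaminated positive-unlabeled protein dataset
#'
#' Draws `n_pos` labeled positives from the positive-class distribution h+
#' and `n_unl` unlabeled records from the mixture
#' `h_u = alpha * h+ + (1 - alpha) * h-`, recording each unlabeled record's
#' hidden true class. Informative continuous properties are unit-variance
#' Gaussians whose class means differ by `effect_size` standard deviations;
#' uninformative ones are identical across classes. Informative nominal
#' properties tilt the positive class's state probabilities toward the first
#' state with weight `exp(effect_size)` (negative class uniform);
#' uninformative nominal properties are uniform in both classes.
#'
#' Defaults mimic the real drug-target table: 517 positives, 5376 unlabeled,
#' 31 continuous + 8 nominal properties encoding to 283 columns, and a
#' contamination fraction of 0.23.
#'
#' @param n_pos number of labeled positive records.
#' @param n_unl number of unlabeled records.
#' @param alpha contamination fraction in \[0, 1): probability an unlabeled
#'   record is drawn from h+.
#' @param n_continuous number of continuous properties.
#' @param nominal_states integer vector of nominal state counts.
#' @param effect_size class-mean separation of informative features, in
#'   standard-deviation units.
#' @param informative_fraction fraction of properties (continuous and
#'   nominal alike, rounded up) carrying class signal.
#' @param seed integer seed; the dataset is a deterministic function of the
#'   full configuration and this seed.
#' @return An object of class `sim_dataset`: `table` (a validated
#'   [property_table()]), `hidden_truth` (named +1/-1 vector over all ids;
#'   labeled positives are truly positive), and `config`.
#' @export
simulate_pu_dataset <- function(n_pos = 517, n_unl = 5376, alpha = 0.23,
                                n_continuous = 31,
                                nominal_states = c(31, 31, 31, 31, 32, 32, 32, 32),
                                effect_size = 1, informative_fraction = 0.5,
                                seed = 1L) {
  if (n_pos < 1 || n_unl < 1) stop_ctx("simulate_pu_dataset: n_pos and n_unl must be >= 1")
  if (alpha < 0 || alpha >= 1) stop_ctx("simulate_pu_dataset: alpha must be in [0, 1)")
  if (informative_fraction < 0 || informative_fraction > 1) {
    stop_ctx("simulate_pu_dataset: informative_fraction must be in [0, 1]")
  }
  schema <- default_protein_schema(n_continuous, nominal_states)
  n_inf_cont <- ceiling(informative_fraction * n_continuous)
  n_inf_nom <- ceiling(informative_fraction * length(nominal_states))

  draw_rows <- function(n, positive) {
    cont <- matrix(stats::rnorm(n * n_continuous), nrow = n)
    if (positive && n_inf_cont > 0) {
      cont[, seq_len(n_inf_cont)] <- cont[, seq_len(n_inf_cont), drop = FALSE] + effect_size
    }
    noms <- lapply(seq_along(nominal_states), function(j) {
      s <- nominal_states[j]
      prob <- rep(1, s)
      if (positive && j <= n_inf_nom) prob[1] <- exp(effect_size)
      sprintf("s%02d", sample.int(s, n, replace = TRUE, prob = prob / sum(prob)))
    })
    df <- as.data.frame(cont)
    colnames(df) <- sprintf("cont_%02d", seq_len(n_continuous))
    for (j in seq_along(noms)) df[[sprintf("nom_%02d", j)]] <- noms[[j]]
    df
  }

  with_seed(seed, {
    pos_rows <- draw_rows(n_pos, positive = TRUE)
    hidden_unl <- ifelse(stats::runif(n_unl) < alpha, 1, -1)
    n_hid_pos <- sum(hidden_unl == 1)
    unl_pos <- if (n_hid_pos > 0) draw_rows(n_hid_pos, positive = TRUE) else NULL
    unl_neg <- if (n_hid_pos < n_unl) draw_rows(n_unl - n_hid_pos, positive = FALSE) else NULL
    unl_rows <- as.data.frame(matrix(nrow = n_unl, ncol = ncol(pos_rows)))
    colnames(unl_rows) <- colnames(pos_rows)
    if (!is.null(unl_pos)) unl_rows[hidden_unl == 1, ] <- unl_pos
    if (!is.null(unl_neg)) unl_rows[hidden_unl == -1, ] <- unl_neg
    for (j in seq_len(n_continuous)) unl_rows[[j]] <- as.numeric(unl_rows[[j]])

    ids <- c(sprintf("P%05d", seq_len(n_pos)), sprintf("U%05d", seq_len(n_unl)))
    labels <- rep(c("positive", "unlabeled"), c(n_pos, n_unl))
    table <- property_table(schema, ids, labels, rbind(pos_rows, unl_rows))
    hidden <- stats::setNames(c(rep(1, n_pos), hidden_unl), ids)
    structure(list(table = table, hidden_truth = hidden,
                   config = list(n_pos = n_pos, n_unl = n_unl, alpha = alpha,
                                 n_continuous = n_continuous,
                                 nominal_states = nominal_states,
                                 effect_size = effect_size,
                                 informative_fraction = informative_fraction,
                                 seed = seed)),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cfg <- x$config
  unl <- x$table$label == "unlabeled"
  cat(sprintf("Simulated PU dataset: %d positives + %d unlabeled (alpha = %g; %d hidden positives)\n",
              cfg$n_pos, cfg$n_unl, cfg$alpha,
              sum(x$hidden_truth[x$table$id[unl]] == 1)))
  print(x$table$schema)
  invisible(x)
}

#' Score predictions against the hidden simulation truth
#'
#' Restricted to the unlabeled records — the only ones whose truth the
#' classifier never saw — compares predicted labels with the simulator's
#' hidden classes.
#'
#' @param predictions named vector of predicted labels (+1/-1) covering
#'   every unlabeled id of the dataset.
#' @param dataset a [simulate_pu_dataset()] result.
#' @return A list with `counts` ([confusion_counts()] against hidden truth),
#'   `recall` and `precision` of the hidden positives.
#' @export
score_against_truth <- function(predictions, dataset) {
  stopifnot(inherits(dataset, "sim_dataset"))
  unl_ids <- dataset$table$id[dataset$table$label == "unlabeled"]
  missing <- setdiff(unl_ids, names(predictions))
  if (length(missing)) {
    stop_ctx("score_against_truth: predictions missing for %d unlabeled id(s), e.g. %s",
             length(missing), missing[1])
  }
  truth <- dataset$hidden_truth[unl_ids]
  pred <- as.numeric(predictions[unl_ids])
  cc <- confusion_counts(truth, pred)
  list(counts = cc,
       recall = if (cc$TP + cc$FN > 0) cc$TP / (cc$TP + cc$FN) else NA_real_,
       precision = if (cc$TP + cc$FP > 0) cc$TP / (cc$TP + cc$FP) else NA_real_)
}

#' Write a simulated dataset to disk
#'
#' Emits the property table (CSV/TSV per extension), the schema (JSON, same
#' stem with `_schema.json`), and the hidden truth as a separate TSV (same
#' stem with `_truth.tsv`) so that pipeline code cannot accidentally consume
#' the truth.
#'
#' @param dataset a [simulate_pu_dataset()] result.
#' @param path path for the property table; companion files derive from it.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_sim_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "sim_dataset"))
  write_property_table(dataset$table, path)
  stem <- tools::file_path_sans_ext(path)
  schema_path <- paste0(stem, "_schema.json")
  write_schema(dataset$table$schema, schema_path)
  truth_path <- paste0(stem, "_truth.tsv")
  utils::write.table(
    data.frame(id = names(dataset$hidden_truth),
               true_class = as.integer(dataset$hidden_truth)),
    truth_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(table = path, schema = schema_path, truth = truth_path))
}
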
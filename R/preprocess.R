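#' Z-score a numeric vector
#'
#' Applies the normalization z = (x - mu) / sigma used for every continuous
#' protein property before embedding and classification.
#'
#' @param x numeric vector.
#' @param mu center (the population mean of the property).
#' @param sigma scale (the standard deviation of the property); must be > 0.
#' @return Numeric vector of the same length.
#' @export
zscore <- function(x, mu, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop_ctx("zscore: sigma must be a single value > 0 (got %s)", format(sigma))
  }
  (as.numeric(x) - mu) / sigma
}

#' One-hot encode a nominal state
#'
#' Represents a d-state nominal property as a d-dimensional bit vector with a
#' single active bit at the state's position.
#'
#' @param value a state name.
#' @param states ordered character vector of admissible states.
#' @return Integer 0/1 vector of length `length(states)`.
#' @export
one_hot <- function(value, states) {
  idx <- match(value, states)
  if (is.na(idx)) {
    stop_ctx("one_hot: unknown state '%s'; allowed: %s",
             value, paste(states, collapse = ", "))
  }
  v <- integer(length(states))
  v[idx] <- 1L
  v
}

#' Fit the preprocessing statistics of a property table
#'
#' Computes, per continuous property, the mean and standard deviation used to
#' z-score it, and records each nominal property's state order for one-hot
#' encoding. By default statistics are fitted on all rows (positives and
#' unlabeled together), reproducing the protocol of normalizing the whole
#' dataset before any train/test split; pass the training row indices in
#' `rows` for a strictly split-respecting fit.
#'
#' @param table a [property_table()].
#' @param sd_type `"population"` (divisor n, the default) or `"sample"`
#'   (divisor n - 1).
#' @param rows optional integer vector of row indices to fit on.
#' @return An object of class `pu_preprocessor` holding `mu`, `sigma` and the
#'   nominal state lists.
#' @export
fit_preprocessor <- function(table, sd_type = c("population", "sample"), rows = NULL) {
  stopifnot(inherits(table, "property_table"))
  sd_type <- match.arg(sd_type)
  if (length(table$id) == 0) stop_ctx("fit_preprocessor: empty table")
  values <- if (is.null(rows)) table$values else table$values[rows, , drop = FALSE]
  sch <- table$schema
  cont <- sch$name[sch$kind == "continuous"]
  mu <- sigma <- stats::setNames(numeric(length(cont)), cont)
  n <- nrow(values)
  for (p in cont) {
    x <- values[[p]]
    mu[p] <- mean(x)
    v <- sum((x - mu[p])^2) / if (sd_type == "population") n else (n - 1)
    sigma[p] <- sqrt(v)
    if (sigma[p] <= 0) {
      stop_ctx("fit_preprocessor: property '%s' is constant (sigma = 0); drop it or fix the data", p)
    }
  }
  structure(list(schema = sch, mu = mu, sigma = sigma,
                 states = sch$states, sd_type = sd_type),
            class = "pu_preprocessor")
}

#' @export
print.pu_preprocessor <- function(x, ...) {
  cat(sprintf("PU preprocessor: %d continuous (z-score, %s sd), %d nominal (one-hot)\n",
              length(x$mu), x$sd_type, length(x$states)))
  invisible(x)
}

#' Transform a property table into a numeric feature matrix
#'
#' Applies the fitted z-scoring to continuous properties and one-hot encoding
#' to nominal ones, concatenated in schema order. Column provenance records
#' which property (and which state, for bit columns) each output column
#' derives from.
#'
#' @param object a fitted [fit_preprocessor()].
#' @param table a [property_table()] with the same schema.
#' @param ... unused.
#' @return A `feature_matrix`: list with `values` (n x d numeric matrix),
#'   `provenance` (data frame of property/component per column), `row_ids`
#'   and `row_labels`.
#' @export
predict.pu_preprocessor <- function(object, table, ...) {
  stopifnot(inherits(table, "property_table"))
  if (!identical(object$schema$name, table$schema$name) ||
      !identical(object$schema$kind, table$schema$kind)) {
    stop_ctx("predict.pu_preprocessor: table schema does not match the fitted schema")
  }
  sch <- table$schema
  n <- length(table$id)
  cols <- vector("list", length(sch$name))
  prov <- vector("list", length(sch$name))
  for (i in seq_along(sch$name)) {
    nm <- sch$name[i]
    if (sch$kind[i] == "continuous") {
      cols[[i]] <- matrix(zscore(table$values[[nm]], object$mu[nm], object$sigma[nm]),
                          ncol = 1)
      prov[[i]] <- data.frame(property = nm, component = "zscore",
                              stringsAsFactors = FALSE)
    } else {
      states <- object$states[[nm]]
      idx <- match(table$values[[nm]], states)
      m <- matrix(0, nrow = n, ncol = length(states))
      m[cbind(seq_len(n), idx)] <- 1
      cols[[i]] <- m
      prov[[i]] <- data.frame(property = nm, component = states,
                              stringsAsFactors = FALSE)
    }
  }
  values <- do.call(cbind, cols)
  provenance <- do.call(rbind, prov)
  colnames(values) <- ifelse(provenance$component == "zscore",
                             provenance$property,
                             paste(provenance$property, provenance$component, sep = "="))
  feature_matrix(values, provenance, table$id, table$label)
}

#' Construct a feature matrix container
#'
#' @param values numeric n x d matrix with no missing entries.
#' @param provenance data frame with columns `property` and `component`
#'   (`"zscore"` for continuous columns, the state name for bit columns).
#' @param row_ids,row_labels protein ids and PU labels carried along rows.
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, provenance, row_ids, row_labels) {
  values <- as.matrix(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop_ctx("feature_matrix: non-finite entries are not allowed")
  }
  if (nrow(provenance) != ncol(values)) {
    stop_ctx("feature_matrix: provenance (%d) does not match columns (%d)",
             nrow(provenance), ncol(values))
  }
  if (length(row_ids) != nrow(values) || length(row_labels) != nrow(values)) {
    stop_ctx("feature_matrix: row ids/labels do not match rows")
  }
  structure(list(values = values, provenance = provenance,
                 row_ids = as.character(row_ids),
                 row_labels = as.character(row_labels)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("Feature matrix: %d proteins x %d features (%d positive, %d unlabeled)\n",
              nrow(x$values), ncol(x$values),
              sum(x$row_labels == "positive"), sum(x$row_labels == "unlabeled")))
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$values)

#' @export
as.matrix.feature_matrix <- function(x, ...) x$values

#' Write a feature matrix as CSV with a provenance header block
#'
#' Provenance lines are prefixed with `#` so the numeric block remains
#' machine-readable with standard CSV readers using `comment.char = "#"`.
#'
#' @param fm a [feature_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# column %d: property=%s component=%s",
                     seq_len(ncol(fm$values)), fm$provenance$property,
                     fm$provenance$component), con)
  df <- cbind(data.frame(id = fm$row_ids, label = fm$row_labels,
                         stringsAsFactors = FALSE),
              as.data.frame(fm$values))
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Kolmogorov-Smirnov screening of properties between PU classes
#'
#' Runs a two-sample KS test per property between the labeled positives and
#' the unlabeled records, to assess whether individual physicochemical
#' properties carry signal. Continuous properties are tested on their raw
#' values; nominal properties are tested on the integer state index, with a
#' warning that the KS test on discrete data is conservative.
#'
#' @param table a [property_table()] with both classes present.
#' @param alpha_level significance level for the `significant` flag.
#' @return Data frame with one row per property: `property`, `D`, `p_value`,
#'   `significant`.
#' @export
ks_screen <- function(table, alpha_level = 0.05) {
  stopifnot(inherits(table, "property_table"))
  pos <- table$label == "positive"
  if (sum(pos) < 2 || sum(!pos) < 2) {
    stop_ctx("ks_screen: each label group needs at least 2 records (have %d positive, %d unlabeled)",
             sum(pos), sum(!pos))
  }
  sch <- table$schema
  if (any(sch$kind == "nominal")) {
    warning("ks_screen: nominal properties are screened on their integer state index; ",
            "the KS test is conservative on discrete data", call. = FALSE)
  }
  out <- data.frame(property = sch$name, D = NA_real_, p_value = NA_real_,
                    significant = NA, stringsAsFactors = FALSE)
  for (i in seq_along(sch$name)) {
    nm <- sch$name[i]
    x <- table$values[[nm]]
    if (sch$kind[i] == "nominal") x <- match(x, sch$states[[nm]])
    kt <- suppressWarnings(stats::ks.test(x[pos], x[!pos], exact = FALSE))
    out$D[i] <- unname(kt$statistic)
    out$p_value[i] <- kt$p.value
  }
  out$significant <- out$p_value < alpha_level
  out
}

#' Write a KS screening report as TSV
#'
#' @param report the data frame returned by [ks_screen()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ks_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
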
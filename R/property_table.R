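#' Define a protein property schema
#'
#' A schema fixes the ordered list of physicochemical properties a protein
#' record must carry, the kind of each (continuous or nominal) and, for
#' nominal properties, the ordered set of admissible states. The schema
#' drives validation, one-hot encoding and the final feature dimension.
#'
#' @param name character vector of unique property names, in column order.
#' @param kind character vector, one of `"continuous"` or `"nominal"` per
#'   property.
#' @param states named list mapping each nominal property name to its ordered
#'   character vector of states. Continuous properties must not appear.
#' @return An object of class `property_schema`.
#' @examples
#' property_schema(
#'   name   = c("mol_weight", "signal_peptide"),
#'   kind   = c("continuous", "nominal"),
#'   states = list(signal_peptide = c("yes", "no"))
#' )
#' @export
property_schema <- function(name, kind, states = list()) {
  name <- as.character(name)
  kind <- as.character(kind)
  if (length(name) != length(kind)) {
    stop_ctx("schema: 'name' and 'kind' must have equal length (%d vs %d)",
             length(name), length(kind))
  }
  if (anyDuplicated(name)) {
    stop_ctx("schema: duplicated property name(s): %s",
             paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  bad <- setdiff(kind, c("continuous", "nominal"))
  if (length(bad)) stop_ctx("schema: unknown kind(s): %s", paste(bad, collapse = ", "))
  nominal <- name[kind == "nominal"]
  missing_states <- setdiff(nominal, names(states))
  if (length(missing_states)) {
    stop_ctx("schema: nominal propert%s without states: %s",
             if (length(missing_states) > 1) "ies" else "y",
             paste(missing_states, collapse = ", "))
  }
  extra <- setdiff(names(states), nominal)
  if (length(extra)) {
    stop_ctx("schema: states given for non-nominal propert%s: %s",
             if (length(extra) > 1) "ies" else "y", paste(extra, collapse = ", "))
  }
  for (p in nominal) {
    st <- as.character(states[[p]])
    if (length(st) < 1) stop_ctx("schema: property '%s' has an empty state list", p)
    if (anyDuplicated(st)) stop_ctx("schema: property '%s' has duplicated states", p)
    states[[p]] <- st
  }
  structure(
    list(name = name, kind = kind, states = states[nominal]),
    class = "property_schema"
  )
}

#' @export
print.property_schema <- function(x, ...) {
  n_cont <- sum(x$kind == "continuous")
  n_nom <- sum(x$kind == "nominal")
  cat(sprintf("Property schema: %d properties (%d continuous, %d nominal)\n",
              length(x$name), n_cont, n_nom))
  if (n_nom > 0) {
    cat(sprintf("  nominal state counts: %s\n",
                paste(vapply(x$states, length, 1L), collapse = ", ")))
  }
  cat(sprintf("  encoded feature dimension: %d\n", feature_dimension(x)))
  invisible(x)
}

#' Encoded feature dimension implied by a schema
#'
#' Continuous properties contribute one z-scored column each; a nominal
#' property with d states contributes a d-dimensional bit vector.
#'
#' @param schema a [property_schema()].
#' @return Integer dimension of the encoded feature space.
#' @export
feature_dimension <- function(schema) {
  stopifnot(inherits(schema, "property_schema"))
  sum(schema$kind == "continuous") +
    sum(vapply(schema$states, length, integer(1)))
}

#' Read or write a schema as JSON
#'
#' The on-disk form is a JSON array of `{name, kind, states}` records so a
#' schema can travel next to the delimited property table it describes.
#'
#' @param path file path.
#' @param schema a [property_schema()] (for writing).
#' @return `read_schema` returns a `property_schema`; `write_schema` returns
#'   `path` invisibly.
#' @export
read_schema <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  name <- vapply(raw, function(r) r$name, "")
  kind <- vapply(raw, function(r) r$kind, "")
  states <- list()
  for (r in raw) {
    if (identical(r$kind, "nominal")) states[[r$name]] <- unlist(r$states)
  }
  property_schema(name, kind, states)
}

#' @rdname read_schema
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "property_schema"))
  recs <- lapply(seq_along(schema$name), function(i) {
    nm <- schema$name[i]
    list(name = nm, kind = schema$kind[i],
         states = if (schema$kind[i] == "nominal") as.list(schema$states[[nm]]) else list())
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Construct a validated protein property table
#'
#' Bundles protein identifiers, positive/unlabeled (PU) labels and the raw
#' mixed-type property values under a schema. Labeled positives are the known
#' drug-target proteins; the unlabeled records are the contaminated
#' non-target set from which candidates are later retrieved.
#'
#' @param schema a [property_schema()].
#' @param id character vector of unique protein identifiers.
#' @param label character vector, `"positive"` or `"unlabeled"` per record.
#' @param values data frame with one column per schema property (schema
#'   order is imposed), continuous columns numeric, nominal columns character.
#' @return An object of class `property_table`.
#' @export
property_table <- function(schema, id, label, values) {
  stopifnot(inherits(schema, "property_schema"))
  id <- as.character(id)
  label <- as.character(label)
  n <- length(id)
  if (length(label) != n || nrow(values) != n) {
    stop_ctx("property_table: id (%d), label (%d) and values (%d rows) disagree",
             n, length(label), nrow(values))
  }
  if (anyDuplicated(id)) {
    stop_ctx("property_table: duplicate id(s): %s",
             paste(utils::head(unique(id[duplicated(id)]), 5), collapse = ", "))
  }
  bad_lab <- setdiff(unique(label), c("positive", "unlabeled"))
  if (length(bad_lab)) {
    stop_ctx("property_table: labels must be 'positive' or 'unlabeled'; found: %s",
             paste(bad_lab, collapse = ", "))
  }
  missing_cols <- setdiff(schema$name, colnames(values))
  if (length(missing_cols)) {
    stop_ctx("property_table: missing propert%s: %s",
             if (length(missing_cols) > 1) "ies" else "y",
             paste(missing_cols, collapse = ", "))
  }
  values <- values[, schema$name, drop = FALSE]
  for (i in seq_along(schema$name)) {
    nm <- schema$name[i]
    col <- values[[nm]]
    if (anyNA(col)) {
      stop_ctx("property_table: missing value(s) in property '%s' (row %d); missing data are rejected, not imputed",
               nm, which(is.na(col))[1])
    }
    if (schema$kind[i] == "continuous") {
      if (is.character(col) || is.factor(col)) {
        num <- suppressWarnings(as.numeric(as.character(col)))
        if (anyNA(num)) {
          r <- which(is.na(num))[1]
          stop_ctx("property_table: non-numeric value '%s' in continuous property '%s' (row %d)",
                   as.character(col)[r], nm, r)
        }
        col <- num
      }
      if (!is.numeric(col)) stop_ctx("property_table: property '%s' is not numeric", nm)
      values[[nm]] <- as.numeric(col)
    } else {
      col <- as.character(col)
      known <- schema$states[[nm]]
      bad <- which(!(col %in% known))
      if (length(bad)) {
        stop_ctx("property_table: unknown state '%s' for nominal property '%s' (row %d); allowed: %s",
                 col[bad[1]], nm, bad[1], paste(known, collapse = ", "))
      }
      values[[nm]] <- col
    }
  }
  rownames(values) <- NULL
  structure(list(schema = schema, id = id, label = label, values = values),
            class = "property_table")
}

#' @export
print.property_table <- function(x, ...) {
  cat(sprintf("Protein property table: %d records (%d positive, %d unlabeled)\n",
              length(x$id), sum(x$label == "positive"), sum(x$label == "unlabeled")))
  print(x$schema)
  invisible(x)
}

#' @export
dim.property_table <- function(x) c(length(x$id), length(x$schema$name))

#' Read a protein property table from delimited text or XLSX
#'
#' Expects an `id` column, a `label` column (`positive`/`unlabeled`) and one
#' column per schema property. Delimiter is inferred from the extension
#' (`.tsv`/`.txt` tab, otherwise comma); `.xlsx` is read via the readxl
#' package when installed. Validation errors report the offending row and
#' property.
#'
#' @param path path to a CSV/TSV/XLSX file with a header row.
#' @param schema a [property_schema()] describing the property columns.
#' @param id_col,label_col names of the identifier and label columns.
#' @return A validated [property_table()] with row order preserved.
#' @export
read_property_table <- function(path, schema, id_col = "id", label_col = "label") {
  ext <- tolower(tools::file_ext(path))
  if (ext == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop_ctx("reading '%s' requires the readxl package", path)
    }
    df <- as.data.frame(readxl::read_excel(path), stringsAsFactors = FALSE)
  } else {
    sep <- if (ext %in% c("tsv", "txt")) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE, check.names = FALSE,
                            colClasses = "character")
  }
  for (col in c(id_col, label_col)) {
    if (!col %in% colnames(df)) stop_ctx("file '%s' lacks required column '%s'", path, col)
  }
  property_table(schema, id = df[[id_col]], label = df[[label_col]],
                 values = df[, setdiff(colnames(df), c(id_col, label_col)), drop = FALSE])
}

#' Write a property table as delimited text
#'
#' @param table a [property_table()].
#' @param path output path; `.tsv` extension writes tab-delimited, anything
#'   else comma-delimited.
#' @return `path`, invisibly.
#' @export
write_property_table <- function(table, path) {
  stopifnot(inherits(table, "property_table"))
  df <- cbind(data.frame(id = table$id, label = table$label,
                         stringsAsFactors = FALSE),
              table$values)
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
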
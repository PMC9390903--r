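#' Clinical dataset container
#'
#' Bundles a samples x features numeric table with per-column variable kinds
#' (`"continuous"` or `"discrete"`) and a binary outcome label per sample.
#' Missing entries are `NA`. Discrete variables are stored as numeric category
#' codes (clinical flags are typically 0/1); their non-missing entries must
#' come from a finite category set.
#'
#' @param values numeric matrix (or data frame coercible to one), one row per
#'   sample, one column per feature; `NA` marks a missing entry.
#' @param kinds character vector, one of `"continuous"`/`"discrete"` per column.
#' @param labels integer vector of 0/1 class labels, one per row
#'   (1 = positive class).
#' @param column_names optional column names; defaults to `colnames(values)`
#'   or `V1..Vp`.
#' @return An object of class `clinical_dataset`: a list with elements
#'   `values` (numeric matrix with column names), `kinds` (named character
#'   vector) and `labels` (integer vector).
#' @examples
#' x <- matrix(c(1, 2, NA, 0, 1, 1), nrow = 3)
#' d <- clinical_dataset(x, c("continuous", "discrete"), c(0, 1, 1))
#' d
#' @export
clinical_dataset <- function(values, kinds, labels, column_names = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  p <- ncol(values)
  if (length(kinds) != p)
    stop("`kinds` must have one entry per column (", p, ")")
  if (!all(kinds %in% c("continuous", "discrete")))
    stop("column kinds must be 'continuous' or 'discrete'")
  if (length(labels) != nrow(values))
    stop("`labels` must have one entry per row")
  if (anyNA(labels) || !all(labels %in% c(0, 1)))
    stop("labels must be binary 0/1 with no missing values")
  if (is.null(column_names)) column_names <- colnames(values)
  if (is.null(column_names)) column_names <- paste0("V", seq_len(p))
  if (length(column_names) != p || anyDuplicated(column_names))
    stop("column names must be unique, one per column")
  colnames(values) <- column_names
  structure(
    list(values = values, kinds = stats::setNames(as.character(kinds), column_names),
         labels = as.integer(labels)),
    class = "clinical_dataset")
}

#' @export
print.clinical_dataset <- function(x, ...) {
  nmiss <- sum(is.na(x$values))
  cat(sprintf("clinical_dataset: %d samples x %d features (%d continuous, %d discrete)\n",
              nrow(x$values), ncol(x$values),
              sum(x$kinds == "continuous"), sum(x$kinds == "discrete")))
  cat(sprintf("  labels: %d positive / %d negative; missing entries: %d (%.1f%%)\n",
              sum(x$labels == 1), sum(x$labels == 0), nmiss,
              100 * nmiss / length(x$values)))
  invisible(x)
}

#' @export
dim.clinical_dataset <- function(x) dim(x$values)

# keep only the given columns, preserving order
subset_columns <- function(dataset, keep) {
  clinical_dataset(dataset$values[, keep, drop = FALSE],
                   dataset$kinds[keep], dataset$labels,
                   colnames(dataset$values)[keep])
}

#' Read a clinical table and its schema
#'
#' The table is delimited text with a header row. The schema is plain text
#' with one `name,kind` line per column, where `kind` is `continuous`,
#' `discrete`, or `label` (exactly one column must be the label). Declared
#' missing tokens and unparseable numeric cells become `NA`.
#'
#' @param table_path path to the CSV data file.
#' @param schema_path path to the schema file.
#' @param missing_tokens character values treated as missing.
#' @param sep field separator of the data file.
#' @return a [clinical_dataset()].
#' @seealso [write_clinical()]
#' @export
read_clinical <- function(table_path, schema_path,
                          missing_tokens = c("", "NA", "?"), sep = ",") {
  schema <- read_schema(schema_path)
  tab <- utils::read.table(table_path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  unknown <- setdiff(colnames(tab), names(schema))
  if (length(unknown))
    stop("schema error: table column(s) not declared in schema: ",
         paste(unknown, collapse = ", "))
  label_col <- names(schema)[schema == "label"]
  if (!label_col %in% colnames(tab))
    stop("schema error: label column '", label_col, "' absent from table")
  feat_cols <- intersect(colnames(tab), names(schema)[schema != "label"])

  to_num <- function(v) {
    v[v %in% missing_tokens] <- NA
    suppressWarnings(as.numeric(v))
  }
  labels <- to_num(tab[[label_col]])
  if (anyNA(labels) || !all(labels %in% c(0, 1)))
    stop("validation error: label column must contain only 0/1")
  vals <- vapply(feat_cols, function(cn) to_num(tab[[cn]]), numeric(nrow(tab)))
  if (nrow(tab) == 1L) vals <- matrix(vals, nrow = 1, dimnames = list(NULL, feat_cols))
  clinical_dataset(vals, unname(schema[feat_cols]), labels, feat_cols)
}

#' Write a clinical table and its schema
#'
#' Inverse of [read_clinical()]: writes the values plus label column as CSV
#' and the per-column kinds as a `name,kind` schema file.
#'
#' @param dataset a [clinical_dataset()].
#' @param table_path,schema_path output paths.
#' @param label_name column name used for the label in the CSV.
#' @export
write_clinical <- function(dataset, table_path, schema_path,
                           label_name = "label") {
  stopifnot(inherits(dataset, "clinical_dataset"))
  if (label_name %in% colnames(dataset$values))
    stop("label_name collides with a feature column")
  df <- as.data.frame(dataset$values, check.names = FALSE)
  df[[label_name]] <- dataset$labels
  utils::write.table(df, table_path, sep = ",", row.names = FALSE,
                     quote = FALSE, na = "")
  lines <- c(paste(colnames(dataset$values), unname(dataset$kinds), sep = ","),
             paste(label_name, "label", sep = ","))
  writeLines(lines, schema_path)
  invisible(dataset)
}

read_schema <- function(schema_path) {
  lines <- readLines(schema_path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, ",")
  if (any(lengths(parts) != 2))
    stop("schema error: each line must be 'name,kind'")
  kinds <- trimws(vapply(parts, `[`, "", 2))
  names(kinds) <- trimws(vapply(parts, `[`, "", 1))
  if (!all(kinds %in% c("continuous", "discrete", "label")))
    stop("schema error: kind must be continuous, discrete or label")
  if (sum(kinds == "label") != 1)
    stop("schema error: schema must declare exactly one label column")
  kinds
}
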
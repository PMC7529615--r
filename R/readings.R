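#' Validate a table of SBCE readings against a schema
#'
#' Checks that every feature column declared by the schema is present, holds
#' integer level codes within its declared range, and that any `marsh` /
#' `disease` label columns use known tokens.  Errors name the offending row
#' and column.  Feature columns are coerced to integer and label tokens to
#' their canonical spelling (`disease` is case-insensitive on input).
#'
#' @param data A data frame with one row per reading: feature columns as
#'   named by the schema (canonically `f1`..`f9`), plus optional columns
#'   `marsh`, `disease`, `patient_id`, `reader_id`.
#' @param schema An `sbce_schema`; defaults to the canonical [sbce_schema()].
#' @return The validated readings as a tibble, row order preserved.
#' @export
validate_readings <- function(data, schema = sbce_schema()) {
  data <- tibble::as_tibble(data)
  cols <- schema_columns(schema)
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    stop("missing feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (f in schema$features) {
    v <- data[[f$column]]
    num <- suppressWarnings(as.numeric(v))
    bad <- is.na(num) | num != as.integer(num)
    if (any(bad)) {
      stop("non-integer level code in column ", f$column, ", row ",
           which(bad)[1L], call. = FALSE)
    }
    k <- as.integer(num)
    oob <- k < 1L | k > f$K
    if (any(oob)) {
      stop("level code out of range in column ", f$column, ", row ",
           which(oob)[1L], " (value ", k[which(oob)[1L]], ", allowed 1..",
           f$K, ")", call. = FALSE)
    }
    data[[f$column]] <- k
  }
  if ("marsh" %in% names(data)) {
    m <- as.character(data$marsh)
    bad <- !is.na(m) & !(m %in% marsh_levels())
    if (any(bad)) {
      stop("unknown marsh token ", sQuote(m[which(bad)[1L]]), " in row ",
           which(bad)[1L], call. = FALSE)
    }
    data$marsh <- m
  }
  if ("disease" %in% names(data)) {
    d <- toupper(as.character(data$disease))
    bad <- !is.na(d) & !(d %in% disease_levels())
    if (any(bad)) {
      stop("unknown disease token ", sQuote(data$disease[which(bad)[1L]]),
           " in row ", which(bad)[1L], call. = FALSE)
    }
    data$disease <- d
  }
  data
}

#' Read SBCE readings from a delimited text file
#'
#' Expects a comma-separated file with a header row: one row per reading,
#' feature columns named as in the schema (`f1`..`f9` canonically, integer
#' level codes), and optional `marsh`, `disease`, `patient_id`, `reader_id`
#' columns.  The result is validated with [validate_readings()].
#'
#' @param path Path to a CSV file (UTF-8).
#' @inheritParams validate_readings
#' @return A validated tibble of readings; row order as in the file.
#' @seealso [write_readings()]
#' @export
read_readings <- function(path, schema = sbce_schema()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  validate_readings(tibble::as_tibble(raw), schema)
}

#' Write SBCE readings to a delimited text file
#'
#' Inverse of [read_readings()]: feature columns round-trip cell for cell,
#' label tokens are written in canonical spelling.
#'
#' @param data A readings table (validated against `schema` before writing).
#' @param path Output CSV path.
#' @inheritParams validate_readings
#' @return `path`, invisibly.
#' @export
write_readings <- function(data, path, schema = sbce_schema()) {
  data <- validate_readings(data, schema)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Two-class codes of each reading for a prediction task
#'
#' For `task = "severity"` the code is derived from the `marsh` column via
#' [marsh_to_severity()]; for `task = "disease"` from the `disease` column
#' (SNVA = 1, CD = 2).  A reading lacking the required label is an error that
#' identifies the row.
#'
#' @param data A readings table.
#' @param task `"severity"` or `"disease"`.
#' @return Integer vector of class codes in 1..2, one per reading.
#' @export
class_codes <- function(data, task) {
  task <- match_task(task)
  col <- switch(task, severity = "marsh", disease = "disease")
  if (!col %in% names(data)) {
    stop("task '", task, "' needs a '", col, "' column", call. = FALSE)
  }
  lab <- data[[col]]
  if (anyNA(lab) || any(lab == "")) {
    stop("reading(s) without a ", col, " label: row ",
         paste(which(is.na(lab) | lab == ""), collapse = ", "),
         call. = FALSE)
  }
  if (task == "severity") {
    marsh_to_severity(lab)
  } else {
    ifelse(toupper(lab) == "CD", 2L, 1L)
  }
}

#' Per-class reading counts for a task
#'
#' @inheritParams class_codes
#' @return Named integer vector `c(N_1, N_2)`; the names are the task's class
#'   labels.  `N_1 + N_2` equals the number of readings.
#' @examples
#' d <- reference_cohort(seed = 0)
#' class_counts(d, "severity")  # mild 31, severe 50
#' class_counts(d, "disease")   # SNVA 18, CD 63
#' @export
class_counts <- function(data, task) {
  task <- match_task(task)
  if (nrow(data) == 0L) {
    return(stats::setNames(c(0L, 0L), task_class_labels(task)))
  }
  cc <- class_codes(data, task)
  stats::setNames(c(sum(cc == 1L), sum(cc == 2L)), task_class_labels(task))
}

## Integer matrix of feature level codes (n x 9), used by fit and predict.
feature_matrix <- function(data, schema = sbce_schema()) {
  cols <- schema_columns(schema)
  m <- as.matrix(data[, cols, drop = FALSE])
  storage.mode(m) <- "integer"   # an empty tibble otherwise coerces logical
  m
}
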
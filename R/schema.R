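#' @keywords internal
"_PACKAGE"

## Package-level cache for the canonical schema (read once per session).
.sbce_env <- new.env(parent = emptyenv())

#' Valid Marsh histology categories
#'
#' The six grades of the modified Marsh classification of duodenal biopsies,
#' as character tokens in increasing severity order.
#'
#' @return Character vector `c("0", "1", "2", "3a", "3b", "3c")`.
#' @export
marsh_levels <- function() c("0", "1", "2", "3a", "3b", "3c")

#' Disease-class tokens
#'
#' @return Character vector `c("SNVA", "CD")`: seronegative villous atrophy
#'   (class 1) and celiac disease (class 2).
#' @export
disease_levels <- function() c("SNVA", "CD")

#' Class labels for a prediction task
#'
#' @param task `"severity"` or `"disease"`.
#' @return Length-2 character vector: the label of class 1 then class 2
#'   (`mild`/`severe` or `SNVA`/`CD`).
#' @export
task_class_labels <- function(task) {
  task <- match_task(task)
  switch(task,
    severity = c("mild", "severe"),
    disease  = disease_levels()
  )
}

match_task <- function(task) {
  match.arg(task, c("severity", "disease"))
}

#' Read a feature schema from a YAML file
#'
#' A schema file declares, in order, each categorical SBCE feature: its data
#' column name, a human-readable name, and its ordered level labels (level
#' code 1 first, always the normal/absent condition).
#'
#' @param path Path to a YAML schema file.
#' @return An object of class `sbce_schema`: a list with element `features`,
#'   each feature a list with `column`, `name`, `K` (number of levels) and
#'   `levels` (character vector of length `K`).
#' @seealso [sbce_schema()] for the packaged canonical 9-feature schema.
#' @export
read_schema <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$features) || length(raw$features) == 0L) {
    stop("schema file '", path, "' declares no features", call. = FALSE)
  }
  feats <- lapply(raw$features, function(f) {
    if (is.null(f$column) || is.null(f$levels)) {
      stop("each schema feature needs 'column' and 'levels'", call. = FALSE)
    }
    levels <- as.character(unlist(f$levels))
    if (length(levels) < 2L) {
      stop("feature '", f$column, "' must have at least 2 levels",
           call. = FALSE)
    }
    list(
      column = as.character(f$column),
      name   = as.character(if (is.null(f$name)) f$column else f$name),
      K      = length(levels),
      levels = levels
    )
  })
  structure(list(features = feats), class = "sbce_schema")
}

#' The canonical 9-feature SBCE schema
#'
#' Nine categorical features describe one capsule-endoscopy reading: area
#' affected (f1), distribution pattern normal/patchy/continuous (f2), mosaic
#' pattern (f3), fissuring (f4), scalloping (f5), villous atrophy (f6),
#' nodularity (f7), ulcers (f8) and percent length of abnormal small-bowel
#' mucosa (f9).  All features are binary absent/present except f2, which has
#' three levels; level code 1 always denotes the normal/absent condition.
#'
#' @return An `sbce_schema` object (see [read_schema()]).
#' @examples
#' sch <- sbce_schema()
#' vapply(sch$features, `[[`, integer(1), "K")  # 2 3 2 2 2 2 2 2 2
#' @export
sbce_schema <- function() {
  if (is.null(.sbce_env$schema)) {
    path <- system.file("extdata", "sbce_schema.yaml", package = "sbceBayes",
                        mustWork = TRUE)
    .sbce_env$schema <- read_schema(path)
  }
  .sbce_env$schema
}

schema_columns <- function(schema) {
  vapply(schema$features, `[[`, character(1), "column")
}

schema_K <- function(schema) {
  vapply(schema$features, `[[`, integer(1), "K")
}

n_features <- function(schema) length(schema$features)

#' @export
print.sbce_schema <- function(x, ...) {
  cat("SBCE feature schema:", n_features(x), "categorical features\n")
  for (f in x$features) {
    cat(sprintf("  %-3s %-34s K=%d  [%s]\n", f$column, f$name, f$K,
                paste(f$levels, collapse = " | ")))
  }
  invisible(x)
}

#' Map Marsh categories to the two-class severity code
#'
#' Marsh 0, 1 and 2 form the mild group (class 1); Marsh 3a, 3b and 3c — the
#' grades with villous atrophy — form the severe group (class 2).
#'
#' @param marsh Character vector of Marsh categories (see [marsh_levels()]).
#' @return Integer vector of class codes (1 = mild, 2 = severe).
#' @examples
#' marsh_to_severity(c("0", "2", "3a", "3c"))  # 1 1 2 2
#' @export
marsh_to_severity <- function(marsh) {
  marsh <- as.character(marsh)
  bad <- !is.na(marsh) & !(marsh %in% marsh_levels())
  if (any(bad)) {
    stop("unknown Marsh category: ",
         paste(sQuote(unique(marsh[bad])), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(marsh)) {
    stop("missing Marsh category at position ",
         paste(which(is.na(marsh)), collapse = ", "), call. = FALSE)
  }
  ifelse(marsh %in% c("0", "1", "2"), 1L, 2L)
}
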
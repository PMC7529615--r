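#' Seeded 81-reading reference cohort
#'
#' Builds a deterministic synthetic stand-in for the 81-reading / 72-patient
#' SBCE cohort the analysis is designed around (the clinical per-reading
#' feature matrix was never deposited).  Its label structure is exact:
#'
#' * 72 patients, with Marsh categories distributed 9 / 15 / 3 / 8 / 19 / 18
#'   over 0 / 1 / 2 / 3a / 3b / 3c;
#' * 9 patients (4 mild, 5 severe) carry a second, independently re-annotated
#'   reading under a second reader id, giving 81 readings;
#' * severity reading counts (31 mild, 50 severe) and disease reading counts
#'   (18 SNVA, 63 CD) exactly; the 18 SNVA readings come from 18
#'   single-reading patients.
#'
#' Joint feature values are synthetic: each reading's nine level codes are
#' drawn independently from the severity-task class-conditional distributions
#' of [default_config()], conditional on the reading's severity class.
#' Duplicated readings share the patient's labels but are re-drawn
#' feature-wise, modelling reader disagreement as independent annotation
#' noise.
#'
#' @param seed Integer seed; the cohort is a pure function of it.
#' @return A validated tibble of 81 readings with columns `f1`..`f9`,
#'   `marsh`, `disease`, `patient_id`, `reader_id`.
#' @examples
#' d <- reference_cohort(seed = 0)
#' nrow(d)                                  # 81
#' length(unique(d$patient_id))             # 72
#' class_counts(d, "severity")              # 31 50
#' class_counts(d, "disease")               # 18 63
#' @export
reference_cohort <- function(seed = 0L) {
  schema <- sbce_schema()
  marsh_patient_counts <- c("0" = 9L, "1" = 15L, "2" = 3L,
                            "3a" = 8L, "3b" = 19L, "3c" = 18L)
  lambda <- default_lambda("severity")

  withr::with_seed(as.integer(seed), {
    marsh <- sample(rep(names(marsh_patient_counts), marsh_patient_counts))
    severity <- marsh_to_severity(marsh)

    # 31 mild readings from 27 mild patients, 50 severe from 45: duplicate
    # 4 mild and 5 severe patients with a second reader.
    dup <- c(sample(which(severity == 1L), 4L),
             sample(which(severity == 2L), 5L))
    snva <- sample(setdiff(seq_along(marsh), dup), 18L)
    disease <- ifelse(seq_along(marsh) %in% snva, "SNVA", "CD")

    patient_id <- sprintf("P%02d", seq_along(marsh))
    idx <- c(seq_along(marsh), dup)                 # 72 primaries + 9 repeats
    reader <- c(rep("R1", length(marsh)), rep("R2", length(dup)))

    feats <- draw_features(severity[idx], lambda, schema)
    out <- tibble::as_tibble(feats)
    out$marsh <- marsh[idx]
    out$disease <- disease[idx]
    out$patient_id <- patient_id[idx]
    out$reader_id <- reader
    validate_readings(out, schema)
  })
}

## Draw one reading per element of `classes` (integer 1/2), feature-wise from
## the per-class categorical parameters; returns an integer matrix with
## schema columns.
draw_features <- function(classes, lambda, schema = sbce_schema()) {
  n <- length(classes)
  cols <- schema_columns(schema)
  m <- matrix(NA_integer_, nrow = n, ncol = length(cols),
              dimnames = list(NULL, cols))
  for (j in seq_along(cols)) {
    K <- schema$features[[j]]$K
    for (cl in 1:2) {
      rows <- which(classes == cl)
      if (length(rows) > 0L) {
        m[rows, j] <- sample.int(K, length(rows), replace = TRUE,
                                 prob = lambda[[cl]][[j]])
      }
    }
  }
  m
}
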
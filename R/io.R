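## Plain-text serialization: a comma-separated long-format longitudinal
## table (subject_id, time, marker) plus a per-subject survival table
## (subject_id, time, status, covariates...).  Times are in years with a
## '.' decimal separator; headers are mandatory.

#' Read a dataset from a CSV pair
#'
#' Validates the long-format invariants on load: every longitudinal
#' subject must appear in the survival table, event indicators must be
#' 0/1, and no measurement may postdate the subject's observed time;
#' violations raise row-addressed errors.
#'
#' @param longitudinal_path CSV with columns `subject_id`, `time`,
#'   `marker`; may contain zero data rows (survival-only datasets).
#' @param survival_path CSV with columns `subject_id`, `time`, `status`
#'   and optional covariate columns.
#' @return a [jlcm_data()] object.
#' @export
read_jlcm_data <- function(longitudinal_path, survival_path) {
  for (pth in c(longitudinal_path, survival_path))
    if (!file.exists(pth)) stop("file not found: ", pth)
  long <- utils::read.csv(longitudinal_path, stringsAsFactors = FALSE)
  surv <- utils::read.csv(survival_path, stringsAsFactors = FALSE)
  long$subject_id <- as.character(long$subject_id)
  surv$subject_id <- as.character(surv$subject_id)
  long$time <- as.numeric(long$time)
  long$marker <- as.numeric(long$marker)
  jlcm_data(long, surv)
}

#' Write a dataset to a CSV pair
#'
#' Inverse of [read_jlcm_data()]: the write-then-read round trip
#' reproduces the dataset content (true classes and metadata are
#' in-memory provenance and are not serialized).
#'
#' @param data a [jlcm_data()] object.
#' @param longitudinal_path,survival_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_jlcm_data <- function(data, longitudinal_path, survival_path) {
  stopifnot(inherits(data, "jlcm_data"))
  utils::write.csv(data$longitudinal, longitudinal_path, row.names = FALSE)
  utils::write.csv(data$survival, survival_path, row.names = FALSE)
  invisible(c(longitudinal_path, survival_path))
}
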
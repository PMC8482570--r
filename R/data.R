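#' Assemble a longitudinal + survival dataset
#'
#' A `jlcm_data` object pairs a long-format table of marker measurements
#' (one row per measurement) with a per-subject survival table.  Every
#' subject of the longitudinal table must appear in the survival table;
#' the converse is not required, so subjects may contribute survival
#' information only.  Measurements taken after the observed time are
#' invalid: the model describes the marker up to the event or censoring
#' time, so rows with `time > observed_time` are rejected.
#'
#' @param longitudinal data frame with columns `subject_id`, `time`,
#'   `marker` (times in years, non-negative).
#' @param survival data frame with columns `subject_id`, `time` (observed
#'   time T = min(event, censoring), > 0), `status` (1 = event,
#'   0 = censored), plus any time-fixed covariate columns.
#' @param true_class optional integer vector of simulated true class
#'   memberships, aligned with the rows of `survival`.
#' @param meta optional list of provenance metadata (scenario, seed,
#'   target censoring rate, ...).
#' @return an object of class `jlcm_data`.
#' @export
jlcm_data <- function(longitudinal, survival, true_class = NULL, meta = list()) {
  longitudinal <- as.data.frame(longitudinal)
  survival <- as.data.frame(survival)
  need_l <- c("subject_id", "time", "marker")
  need_s <- c("subject_id", "time", "status")
  if (!all(need_l %in% names(longitudinal)))
    stop("longitudinal table needs columns: ", paste(need_l, collapse = ", "))
  if (!all(need_s %in% names(survival)))
    stop("survival table needs columns: ", paste(need_s, collapse = ", "))
  if (anyDuplicated(survival$subject_id))
    stop("duplicated subject_id in survival table: ",
         survival$subject_id[anyDuplicated(survival$subject_id)])
  if (!all(survival$status %in% c(0, 1))) {
    bad <- which(!survival$status %in% c(0, 1))[1]
    stop("non-binary event indicator for subject '",
         survival$subject_id[bad], "' (row ", bad, ")")
  }
  if (any(survival$time <= 0))
    stop("observed times must be positive")
  miss <- setdiff(longitudinal$subject_id, survival$subject_id)
  if (length(miss))
    stop("subjects in longitudinal table missing from survival table: ",
         paste(utils::head(miss, 5), collapse = ", "))
  if (any(longitudinal$time < 0))
    stop("measurement times must be non-negative")
  Tmap <- survival$time[match(longitudinal$subject_id, survival$subject_id)]
  late <- which(longitudinal$time > Tmap + 1e-12)
  if (length(late))
    stop("measurement after the observed time for subject '",
         longitudinal$subject_id[late[1]], "' (longitudinal row ", late[1], ")")
  if (!is.null(true_class)) {
    true_class <- as.integer(true_class)
    if (length(true_class) != nrow(survival))
      stop("'true_class' must align with the survival table rows")
  }
  structure(list(longitudinal = longitudinal, survival = survival,
                 true_class = true_class, meta = meta),
            class = "jlcm_data")
}

#' @export
print.jlcm_data <- function(x, ...) {
  cat("JLCM dataset: ", nrow(x$survival), " subjects, ",
      nrow(x$longitudinal), " marker measurements, ",
      sum(x$survival$status == 1), " events (censoring rate ",
      round(mean(x$survival$status == 0), 3), ")\n", sep = "")
  if (!is.null(x$true_class))
    cat("  true class sizes:",
        paste(tabulate(x$true_class), collapse = " / "), "\n")
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta),
                         vapply(x$meta, function(v) paste(format(v), collapse = ","),
                                character(1)),
                         sep = "=", collapse = "; "), "\n")
  invisible(x)
}

#' Number of subjects in a dataset
#' @param data a [jlcm_data()] object.
#' @return integer count of subjects.
#' @export
n_subjects <- function(data) nrow(data$survival)

#' Extract one subject's record
#'
#' Returns a single-subject view (times, marker values, observed time,
#' event indicator, covariates) used by the per-subject likelihood
#' functions.
#'
#' @param data a [jlcm_data()] object.
#' @param i subject position in the survival table, or a subject id.
#' @return a list of class `jlcm_subject` with elements `subject_id`,
#'   `times`, `y`, `covariates`, `T`, `delta`, `true_class`.
#' @export
subject_record <- function(data, i) {
  sv <- data$survival
  if (is.character(i)) i <- match(i, sv$subject_id)
  if (is.na(i) || i < 1 || i > nrow(sv)) stop("unknown subject")
  id <- sv$subject_id[i]
  rows <- data$longitudinal$subject_id == id
  ord <- order(data$longitudinal$time[rows])
  covnames <- setdiff(names(sv), c("subject_id", "time", "status"))
  structure(list(
    subject_id = id,
    times = data$longitudinal$time[rows][ord],
    y = data$longitudinal$marker[rows][ord],
    covariates = as.list(sv[i, covnames, drop = FALSE]),
    T = sv$time[i], delta = sv$status[i],
    true_class = if (!is.null(data$true_class)) data$true_class[i] else NA_integer_),
    class = "jlcm_subject")
}
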
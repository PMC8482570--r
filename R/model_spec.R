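#' Describe the structure of a joint latent class model
#'
#' A `jlcm_spec` records everything structural about a JLCM: the number of
#' latent classes and, for each of the three sub-models, which terms enter
#' with effects common to all classes and which enter with class-specific
#' effects.  Time polynomial terms are denoted `"time"` and `"time2"`
#' (time squared); any other name refers to a time-fixed covariate column
#' of the survival table.
#'
#' The longitudinal sub-model always contains a class-specific intercept;
#' `longit_class_covariates` lists the further class-specific terms
#' (default a linear time trend).  Common and class-specific longitudinal
#' covariate sets must be disjoint.  The random-effects design always
#' contains the intercept.
#'
#' @param n_classes number of latent classes G (>= 1).
#' @param logistic_covariates names of time-fixed covariates in the
#'   multinomial logistic class-membership sub-model.
#' @param longit_common_covariates terms with a single effect shared by
#'   all classes in the mixed sub-model.
#' @param longit_class_covariates terms with class-specific effects in the
#'   mixed sub-model (class intercepts are implicit).
#' @param random_effects subset of `c("intercept", "time", "time2")`.
#' @param surv_common_covariates covariates with a shared log-hazard
#'   effect in the survival sub-model.
#' @param surv_class_covariates covariates with class-specific log-hazard
#'   effects.
#' @param weibull_parameterization `"scale_time"` for
#'   S(t) = exp(-(t/zeta1)^zeta2) (the default) or `"rate"` for
#'   S(t) = exp(-(zeta1 t)^zeta2).  See [weibull_convert()].
#' @return an object of class `jlcm_spec`.
#' @examples
#' jlcm_spec(2)
#' jlcm_spec(3, logistic_covariates = "age", longit_class_covariates = c("time", "time2"))
#' @export
jlcm_spec <- function(n_classes,
                      logistic_covariates = character(),
                      longit_common_covariates = character(),
                      longit_class_covariates = "time",
                      random_effects = "intercept",
                      surv_common_covariates = character(),
                      surv_class_covariates = character(),
                      weibull_parameterization = c("scale_time", "rate")) {
  n_classes <- as.integer(n_classes)
  if (length(n_classes) != 1L || is.na(n_classes) || n_classes < 1L)
    stop("'n_classes' must be a single integer >= 1")
  weibull_parameterization <- match.arg(weibull_parameterization)
  if (length(intersect(longit_common_covariates, longit_class_covariates)))
    stop("common and class-specific longitudinal covariates must be disjoint: ",
         paste(intersect(longit_common_covariates, longit_class_covariates),
               collapse = ", "))
  if (!length(random_effects) || !"intercept" %in% random_effects)
    stop("'random_effects' must be non-empty and contain \"intercept\"")
  if (!all(random_effects %in% c("intercept", "time", "time2")))
    stop("'random_effects' must be a subset of intercept, time, time2")
  structure(
    list(n_classes = n_classes,
         logistic_covariates = as.character(logistic_covariates),
         longit_common_covariates = as.character(longit_common_covariates),
         longit_class_covariates = as.character(longit_class_covariates),
         random_effects = unique(as.character(random_effects)),
         surv_common_covariates = as.character(surv_common_covariates),
         surv_class_covariates = as.character(surv_class_covariates),
         weibull_parameterization = weibull_parameterization),
    class = "jlcm_spec")
}

#' @export
print.jlcm_spec <- function(x, ...) {
  cat("Joint latent class model specification\n")
  cat("  classes:", x$n_classes, "\n")
  fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "(none)"
  cat("  logistic covariates:  ", fmt(x$logistic_covariates), "\n")
  cat("  longitudinal common:  ", fmt(x$longit_common_covariates), "\n")
  cat("  longitudinal by class: intercept",
      if (length(x$longit_class_covariates))
        paste0(", ", paste(x$longit_class_covariates, collapse = ", ")), "\n",
      sep = "")
  cat("  random effects:       ", fmt(x$random_effects), "\n")
  cat("  survival common:      ", fmt(x$surv_common_covariates), "\n")
  cat("  survival by class:    ", fmt(x$surv_class_covariates), "\n")
  cat("  Weibull parameterization:", x$weibull_parameterization, "\n")
  invisible(x)
}

## number of random effects columns
n_ranef <- function(spec) length(spec$random_effects)

## columns of the class-specific longitudinal design (incl. intercept)
longit_class_terms <- function(spec) c("(Intercept)", spec$longit_class_covariates)

#' Convert Weibull parameters between parameterizations
#'
#' The package's canonical Weibull form is `scale_time`,
#' S(t) = exp(-(t/zeta1)^zeta2), where `zeta1` is a scale in time units.
#' The `rate` form writes S(t) = exp(-(zeta1 t)^zeta2) so that its first
#' parameter is the reciprocal of the time scale.  The shape parameter is
#' identical in both forms.
#'
#' @param zeta1 first Weibull parameter (scale or rate).
#' @param from,to parameterization names.
#' @return `zeta1` expressed in the target parameterization.
#' @examples
#' weibull_convert(4.5, from = "scale_time", to = "rate")  # 1/4.5
#' @export
weibull_convert <- function(zeta1, from = c("scale_time", "rate"),
                            to = c("rate", "scale_time")) {
  from <- match.arg(from)
  to <- match.arg(to)
  stopifnot(all(zeta1 > 0))
  if (from == to) zeta1 else 1 / zeta1
}
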
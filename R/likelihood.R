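## Joint observed-data likelihood of the JLCM.
##
## Given the latent class, the marker vector Y_i and the event time are
## independent; the random effects are integrated out of the mixed
## sub-model in closed form, so each subject contributes
##   log sum_g  pi_ig * f(Y_i | g) * alpha(T_i | g)^delta_i * S(T_i | g),
## evaluated in log space throughout.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## row-wise log-sum-exp of a matrix
row_logsumexp <- function(M) {
  m <- apply(M, 1, max)
  m + log(rowSums(exp(M - m)))
}

#' Prior class-membership probabilities
#'
#' Evaluates the multinomial logistic sub-model for one subject:
#' pi_g = exp(xi0_g + x' xi1_g) / sum_l exp(xi0_l + x' xi1_l), with the
#' reference class G carrying zero coefficients.  With no logistic
#' covariates this is the marginal class probability vector.
#'
#' @param params a [jlcm_params()] object.
#' @param spec the matching [jlcm_spec()].
#' @param covariates named list (or vector) with a value for every name
#'   in `spec$logistic_covariates`.
#' @return numeric probability vector of length G summing to 1.
#' @examples
#' sp <- jlcm_spec(2)
#' pm <- jlcm_params(sp, xi0 = -0.84, beta = rbind(c(1, 0), c(0, 0)),
#'                   B = 1, sigma_eps = 1, zeta1 = c(1, 1), zeta2 = c(1, 1))
#' class_prior_probs(pm, sp)  # ~ (0.302, 0.698)
#' @export
class_prior_probs <- function(params, spec, covariates = list()) {
  G <- spec$n_classes
  q <- length(spec$logistic_covariates)
  lp <- c(params$xi0, 0)
  if (q > 0) {
    miss <- setdiff(spec$logistic_covariates, names(covariates))
    if (length(miss))
      stop("missing logistic covariate(s): ", paste(miss, collapse = ", "))
    x <- unlist(covariates[spec$logistic_covariates])
    lp <- lp + c(drop(params$xi1 %*% x), 0)
  }
  p <- exp(lp - logsumexp(lp))
  p / sum(p)
}

#' Weibull log-survival function with proportional-hazards shift
#'
#' Under the canonical `scale_time` parameterization
#' log S(t) = -(t/zeta1)^zeta2 * exp(linpred); under `rate` the first
#' parameter is a rate, log S(t) = -(zeta1 t)^zeta2 * exp(linpred).
#'
#' @param t non-negative time(s).
#' @param zeta1,zeta2 Weibull scale (or rate) and shape, both > 0.
#' @param linpred proportional-hazards linear predictor (log hazard ratio).
#' @param parameterization `"scale_time"` or `"rate"`.
#' @return log S(t); 0 at t = 0, non-increasing in t.
#' @export
weibull_log_survival <- function(t, zeta1, zeta2, linpred = 0,
                                 parameterization = c("scale_time", "rate")) {
  parameterization <- match.arg(parameterization)
  if (any(t < 0)) stop("'t' must be non-negative")
  if (any(zeta1 <= 0) || any(zeta2 <= 0))
    stop("Weibull scale and shape must be strictly positive")
  sc <- if (parameterization == "rate") 1 / zeta1 else zeta1
  -(t / sc)^zeta2 * exp(linpred)
}

#' Weibull log-hazard with proportional-hazards shift
#'
#' log alpha(t) = log(zeta2/zeta1) + (zeta2 - 1) log(t/zeta1) + linpred in
#' the `scale_time` form; it is the derivative of -log S(t) from
#' [weibull_log_survival()].  The hazard is undefined at t = 0 (it
#' diverges for shape < 1), so strictly positive times are required.
#'
#' @inheritParams weibull_log_survival
#' @param t strictly positive time(s).
#' @return log alpha(t).
#' @export
weibull_log_hazard <- function(t, zeta1, zeta2, linpred = 0,
                               parameterization = c("scale_time", "rate")) {
  parameterization <- match.arg(parameterization)
  if (any(t <= 0)) stop("'t' must be strictly positive")
  if (any(zeta1 <= 0) || any(zeta2 <= 0))
    stop("Weibull scale and shape must be strictly positive")
  sc <- if (parameterization == "rate") 1 / zeta1 else zeta1
  log(zeta2 / sc) + (zeta2 - 1) * log(t / sc) + linpred
}

## value of a design term at the subject's measurement times
term_column <- function(term, times, covariates) {
  switch(term,
         "(Intercept)" = rep(1, length(times)),
         "time" = times,
         "time2" = times^2,
         {
           if (is.null(covariates[[term]]))
             stop("missing covariate: ", term)
           rep(as.numeric(covariates[[term]]), length(times))
         })
}

subject_designs <- function(subject, spec) {
  tt <- subject$times
  X1 <- if (length(spec$longit_common_covariates))
    vapply(spec$longit_common_covariates, term_column, numeric(length(tt)),
           times = tt, covariates = subject$covariates)
  else matrix(0, length(tt), 0)
  X2 <- vapply(longit_class_terms(spec), term_column, numeric(length(tt)),
               times = tt, covariates = subject$covariates)
  Z <- vapply(ifelse(spec$random_effects == "intercept", "(Intercept)",
                     spec$random_effects),
              term_column, numeric(length(tt)),
              times = tt, covariates = subject$covariates)
  list(X1 = matrix(X1, length(tt)), X2 = matrix(X2, length(tt)),
       Z = matrix(Z, length(tt)))
}

## time-fixed survival linear predictor for one subject and class g
surv_linpred <- function(subject, g, params, spec) {
  lp <- 0
  if (length(spec$surv_common_covariates))
    lp <- lp + sum(params$vartheta *
                   unlist(subject$covariates[spec$surv_common_covariates]))
  if (length(spec$surv_class_covariates))
    lp <- lp + sum(params$eta[g, ] *
                   unlist(subject$covariates[spec$surv_class_covariates]))
  lp
}

#' Marginal log-density of a subject's marker vector given a class
#'
#' With the random effects integrated out, Y_i | (c_i = g) is multivariate
#' Gaussian with mean X1 gamma + X2 beta_g and covariance
#' Z B Z' + sigma_eps^2 I.  A subject without measurements contributes a
#' log-density of 0.
#'
#' @param subject a [subject_record()].
#' @param class_index latent class g.
#' @param params a [jlcm_params()] object.
#' @param spec the matching [jlcm_spec()].
#' @return the Gaussian log-density.
#' @export
longit_marginal_log_density <- function(subject, class_index, params, spec) {
  ni <- length(subject$times)
  if (ni != length(subject$y)) stop("times and y lengths differ")
  if (ni == 0L) return(0)
  d <- subject_designs(subject, spec)
  mu <- drop(d$X2 %*% params$beta[class_index, ])
  if (ncol(d$X1)) mu <- mu + drop(d$X1 %*% params$gamma)
  V <- d$Z %*% as.matrix(params$B) %*% t(d$Z) + diag(params$sigma_eps^2, ni)
  R <- tryCatch(chol(V), error = function(e)
    stop("singular longitudinal covariance matrix"))
  z <- backsolve(R, subject$y - mu, transpose = TRUE)
  -0.5 * (ni * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2))
}

#' Per-subject joint log-likelihood contribution
#'
#' log sum_g pi_ig f(Y_i|g) alpha(T_i|g)^delta_i S(T_i|g), computed with
#' log-sum-exp stabilization.
#'
#' @inheritParams longit_marginal_log_density
#' @return scalar log-likelihood contribution.
#' @export
subject_log_likelihood <- function(subject, params, spec) {
  G <- spec$n_classes
  pp <- class_prior_probs(params, spec, subject$covariates)
  lg <- vapply(seq_len(G), function(g) {
    lp <- surv_linpred(subject, g, params, spec)
    log(pp[g]) +
      longit_marginal_log_density(subject, g, params, spec) +
      subject$delta * weibull_log_hazard(subject$T, params$zeta1[g],
                                         params$zeta2[g], lp,
                                         spec$weibull_parameterization) +
      weibull_log_survival(subject$T, params$zeta1[g], params$zeta2[g], lp,
                           spec$weibull_parameterization)
  }, numeric(1))
  logsumexp(lg)
}

#' Posterior class-membership probabilities
#'
#' Bayes-rule combination of the prior membership probabilities with the
#' class-conditional longitudinal-and-survival likelihood.  When all
#' classes share identical parameters the posterior equals the prior.
#'
#' @inheritParams longit_marginal_log_density
#' @return probability vector of length G summing to 1.
#' @export
posterior_class_probs <- function(subject, params, spec) {
  G <- spec$n_classes
  pp <- class_prior_probs(params, spec, subject$covariates)
  lg <- vapply(seq_len(G), function(g) {
    lp <- surv_linpred(subject, g, params, spec)
    log(pp[g]) +
      longit_marginal_log_density(subject, g, params, spec) +
      subject$delta * weibull_log_hazard(subject$T, params$zeta1[g],
                                         params$zeta2[g], lp,
                                         spec$weibull_parameterization) +
      weibull_log_survival(subject$T, params$zeta1[g], params$zeta2[g], lp,
                           spec$weibull_parameterization)
  }, numeric(1))
  w <- exp(lg - logsumexp(lg))
  w / sum(w)
}

## ---- vectorized dataset engine ------------------------------------------

## Precompute everything the log-likelihood needs from a dataset.  The
## random-intercept model with class design (1, t) admits a closed form
## built from per-subject sufficient statistics (Sherman-Morrison on
## sigma_b^2 J + sigma_eps^2 I), which keeps optimization fast at large n;
## other designs fall back to a per-subject loop.
prepare_data <- function(data, spec) {
  stopifnot(inherits(data, "jlcm_data"), inherits(spec, "jlcm_spec"))
  sv <- data$survival
  n <- nrow(sv)
  covnames <- setdiff(names(sv), c("subject_id", "time", "status"))
  idx <- match(data$longitudinal$subject_id, sv$subject_id)
  f <- factor(idx, levels = seq_len(n))
  y <- data$longitudinal$marker
  tt <- data$longitudinal$time
  fast <- identical(spec$random_effects, "intercept") &&
    identical(spec$longit_class_covariates, "time") &&
    length(spec$longit_common_covariates) == 0L
  out <- list(n = n, Tobs = sv$time, delta = sv$status,
              cov = sv[covnames], fast = fast, spec = spec)
  if (fast) {
    agg <- function(v) {
      if (!length(v)) return(numeric(n))
      r <- rowsum(as.numeric(v), f)
      z <- numeric(n); z[as.integer(rownames(r))] <- r; z
    }
    out$ni <- as.numeric(table(f))
    out$Sy <- agg(y); out$St <- agg(tt)
    out$Syy <- agg(y^2); out$Stt <- agg(tt^2); out$Syt <- agg(y * tt)
  } else {
    out$subjects <- lapply(seq_len(n), function(i) subject_record(data, i))
  }
  # logistic design
  q <- length(spec$logistic_covariates)
  out$Xl <- if (q) as.matrix(sv[spec$logistic_covariates]) else matrix(0, n, 0)
  out$Xs1 <- if (length(spec$surv_common_covariates))
    as.matrix(sv[spec$surv_common_covariates]) else matrix(0, n, 0)
  out$Xs2 <- if (length(spec$surv_class_covariates))
    as.matrix(sv[spec$surv_class_covariates]) else matrix(0, n, 0)
  out
}

## n x G matrix of log pi_ig + log f(Y_i|g) + delta log alpha + log S
loglik_matrix <- function(pd, params) {
  spec <- pd$spec
  G <- spec$n_classes
  n <- pd$n
  # prior log-probabilities
  lpri <- matrix(c(params$xi0, 0), n, G, byrow = TRUE)
  if (ncol(pd$Xl))
    lpri <- lpri + cbind(pd$Xl %*% t(params$xi1), 0)
  lpri <- lpri - row_logsumexp(lpri)
  L <- matrix(0, n, G)
  rate_par <- spec$weibull_parameterization == "rate"
  for (g in seq_len(G)) {
    if (pd$fast) {
      a <- params$beta[g, 1]; b <- params$beta[g, 2]
      s2e <- params$sigma_eps^2; s2b <- params$B[1, 1]
      Sr <- pd$Sy - pd$ni * a - b * pd$St
      Srr <- pd$Syy + a^2 * pd$ni + b^2 * pd$Stt -
        2 * a * pd$Sy - 2 * b * pd$Syt + 2 * a * b * pd$St
      den <- s2e + pd$ni * s2b
      logdet <- pmax(pd$ni - 1, 0) * log(s2e) + ifelse(pd$ni > 0, log(den), 0)
      quad <- (Srr - s2b / den * Sr^2) / s2e
      lfy <- -0.5 * (pd$ni * log(2 * pi) + logdet + ifelse(pd$ni > 0, quad, 0))
    } else {
      lfy <- vapply(pd$subjects, longit_marginal_log_density, numeric(1),
                    class_index = g, params = params, spec = spec)
    }
    lp <- numeric(n)
    if (ncol(pd$Xs1)) lp <- lp + drop(pd$Xs1 %*% params$vartheta)
    if (ncol(pd$Xs2)) lp <- lp + drop(pd$Xs2 %*% params$eta[g, ])
    sc <- if (rate_par) 1 / params$zeta1[g] else params$zeta1[g]
    sh <- params$zeta2[g]
    lS <- -(pd$Tobs / sc)^sh * exp(lp)
    lh <- log(sh / sc) + (sh - 1) * log(pd$Tobs / sc) + lp
    L[, g] <- lpri[, g] + lfy + pd$delta * lh + lS
  }
  L
}

#' Total joint log-likelihood of a dataset
#'
#' Sum of the per-subject mixture contributions; invariant under any
#' consistent permutation of class labels.
#'
#' @param data a [jlcm_data()] object.
#' @param params a [jlcm_params()] object.
#' @param spec the matching [jlcm_spec()].
#' @return scalar log-likelihood.
#' @export
total_log_likelihood <- function(data, params, spec) {
  if (!n_subjects(data)) stop("empty dataset")
  pd <- prepare_data(data, spec)
  sum(row_logsumexp(loglik_matrix(pd, params)))
}

## posterior matrix for a whole (prepared) dataset
posterior_matrix <- function(pd, params) {
  L <- loglik_matrix(pd, params)
  exp(L - row_logsumexp(L))
}

#' Maximum-a-posteriori class assignment
#'
#' Assigns every subject to the class with the largest posterior
#' probability; ties break deterministically to the lowest class index.
#'
#' @inheritParams total_log_likelihood
#' @return integer vector of class labels in 1..G.
#' @export
assign_classes <- function(data, params, spec) {
  pd <- prepare_data(data, spec)
  W <- posterior_matrix(pd, params)
  apply(W, 1, which.max)  # which.max breaks ties at the lowest index
}

#' Bayesian information criterion
#'
#' BIC = -2 loglik + n_params log(n_subjects); the candidate number of
#' latent classes with the smallest BIC is preferred.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of free parameters.
#' @param n_subjects number of statistical units (subjects).
#' @return scalar BIC.
#' @export
bic <- function(loglik, n_params, n_subjects) {
  stopifnot(n_subjects >= 1)
  -2 * loglik + n_params * log(n_subjects)
}
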
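# Shared fixtures and independent oracle implementations.

# independent log-sum-exp for the oracles
.o_lse <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

# independent design builder: columns for "(Intercept)"/"time"/"time2"
# and time-fixed covariates, written without the package's helpers
.o_design <- function(terms, times, covs) {
  cols <- lapply(terms, function(tm) {
    if (tm == "(Intercept)") rep(1, length(times))
    else if (tm == "time") times
    else if (tm == "time2") times^2
    else rep(as.numeric(covs[[tm]]), length(times))
  })
  do.call(cbind, cols)
}

# brute-force per-subject joint log-likelihood (direct summation):
# Gaussian density via solve()/det(), Weibull terms via dweibull/pweibull
oracle_subject_ll <- function(subject, params, spec) {
  G <- spec$n_classes
  lp0 <- c(params$xi0, 0)
  if (length(spec$logistic_covariates))
    lp0 <- lp0 + c(params$xi1 %*%
                     unlist(subject$covariates[spec$logistic_covariates]), 0)
  pri <- exp(lp0) / sum(exp(lp0))
  comp <- numeric(G)
  for (g in seq_len(G)) {
    ni <- length(subject$times)
    if (ni > 0) {
      X2 <- .o_design(c("(Intercept)", spec$longit_class_covariates),
                      subject$times, subject$covariates)
      mu <- drop(X2 %*% params$beta[g, ])
      if (length(spec$longit_common_covariates)) {
        X1 <- .o_design(spec$longit_common_covariates,
                        subject$times, subject$covariates)
        mu <- mu + drop(X1 %*% params$gamma)
      }
      Zt <- ifelse(spec$random_effects == "intercept", "(Intercept)",
                   spec$random_effects)
      Z <- .o_design(Zt, subject$times, subject$covariates)
      V <- Z %*% as.matrix(params$B) %*% t(Z) + params$sigma_eps^2 * diag(ni)
      r <- subject$y - mu
      lfy <- -0.5 * (ni * log(2 * pi) + log(det(V)) +
                       drop(t(r) %*% solve(V, r)))
    } else lfy <- 0
    lpred <- 0
    if (length(spec$surv_common_covariates))
      lpred <- lpred + sum(params$vartheta *
                             unlist(subject$covariates[spec$surv_common_covariates]))
    if (length(spec$surv_class_covariates))
      lpred <- lpred + sum(params$eta[g, ] *
                             unlist(subject$covariates[spec$surv_class_covariates]))
    sc <- if (spec$weibull_parameterization == "rate")
      1 / params$zeta1[g] else params$zeta1[g]
    sh <- params$zeta2[g]
    lS0 <- pweibull(subject$T, sh, sc, lower.tail = FALSE, log.p = TRUE)
    lh0 <- dweibull(subject$T, sh, sc, log = TRUE) - lS0
    comp[g] <- log(pri[g]) + lfy +
      subject$delta * (lh0 + lpred) + exp(lpred) * lS0
  }
  .o_lse(comp)
}

# random valid parameter set for property tests
random_params <- function(spec, seed) {
  set.seed(seed)
  G <- spec$n_classes
  p <- length(c("(Intercept)", spec$longit_class_covariates))
  r <- length(spec$random_effects)
  q <- length(spec$logistic_covariates)
  A <- matrix(rnorm(r * r, 0, 0.5), r, r)
  jlcm_params(
    spec,
    xi0 = rnorm(max(G - 1, 0), 0, 1),
    xi1 = if (q) matrix(rnorm((G - 1) * q, 0, 0.5), G - 1, q) else NULL,
    gamma = rnorm(length(spec$longit_common_covariates), 0, 1),
    beta = matrix(rnorm(G * p, c(5, rep(0, p - 1)), 3), G, p),
    B = A %*% t(A) + diag(0.5, r),
    sigma_eps = exp(rnorm(1, 0, 0.3)),
    zeta1 = exp(rnorm(G, 1, 0.4)),
    zeta2 = exp(rnorm(G, 0.2, 0.3)),
    vartheta = rnorm(length(spec$surv_common_covariates), 0, 0.3),
    eta = if (length(spec$surv_class_covariates))
      matrix(rnorm(G * length(spec$surv_class_covariates), 0, 0.3),
             G, length(spec$surv_class_covariates)) else NULL)
}

# one-subject record built directly (no dataset machinery)
make_subject <- function(times, y, T, delta, covariates = list()) {
  structure(list(subject_id = "s1", times = times, y = y,
                 covariates = covariates, T = T, delta = delta,
                 true_class = NA_integer_),
            class = "jlcm_subject")
}

# small simulated dataset shortcut
sim_small <- function(n, scenario = "high_separation", tau = 0.1, seed = 1,
                      censor_scale = NULL) {
  simulate_dataset(scenario_config(scenario, n_subjects = n, target_tau = tau,
                                   censor_scale = censor_scale, seed = seed))
}
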
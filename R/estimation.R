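## Maximum-likelihood estimation of the JLCM.
##
## Optimization is quasi-Newton (BFGS) on an unconstrained scale:
## positive parameters (sigma_eps, Weibull scale/shape, the diagonal of
## the Cholesky factor of B) are log-transformed.  Several starting
## points are used because the mixture likelihood has local maxima,
## especially when classes are weakly separated.

#' Optimizer settings for [fit_jlcm()]
#'
#' @param n_starts number of starting points (the first is data-driven,
#'   the rest are seeded random perturbations of it).
#' @param max_iter maximum BFGS iterations per start.
#' @param rel_tol relative log-likelihood convergence tolerance.
#' @param gradient_tol relative gradient tolerance: convergence requires
#'   max |gradient| <= gradient_tol * (1 + |loglik|).
#' @param seed seed for the random start perturbations.
#' @return a list of class `jlcm_control`.
#' @export
jlcm_control <- function(n_starts = 5, max_iter = 500, rel_tol = 1e-8,
                         gradient_tol = 1e-4, seed = 1) {
  stopifnot(n_starts >= 1, rel_tol > 0, gradient_tol > 0)
  structure(list(n_starts = as.integer(n_starts),
                 max_iter = as.integer(max_iter),
                 rel_tol = rel_tol, gradient_tol = gradient_tol,
                 seed = as.integer(seed)),
            class = "jlcm_control")
}

## layout of the packed (unconstrained) parameter vector:
## name, transform ("identity" or "exp" meaning natural = exp(packed))
param_layout <- function(spec) {
  G <- spec$n_classes
  r <- n_ranef(spec)
  nm <- character(0); tr <- character(0)
  add <- function(names, trans) {
    nm <<- c(nm, names); tr <<- c(tr, rep(trans, length(names)))
  }
  if (G > 1) add(paste0("xi0_", seq_len(G - 1)), "identity")
  for (g in seq_len(G - 1))
    if (length(spec$logistic_covariates))
      add(paste0("xi1_", spec$logistic_covariates, "_", g), "identity")
  if (length(spec$longit_common_covariates))
    add(paste0("gamma_", spec$longit_common_covariates), "identity")
  bname <- function(term) switch(term, "(Intercept)" = "beta0",
                                 "time" = "beta1", "time2" = "beta2",
                                 paste0("beta_", term))
  for (g in seq_len(G))
    add(paste0(vapply(longit_class_terms(spec), bname, ""), "_", g),
        "identity")
  if (r == 1) add("sd_b", "exp")
  else for (i in seq_len(r)) for (j in seq_len(i))
    add(paste0("Bchol_", i, "_", j), if (i == j) "exp" else "identity")
  add("sigma_eps", "exp")
  for (g in seq_len(G)) add(c(paste0("zeta1_", g), paste0("zeta2_", g)), "exp")
  if (length(spec$surv_common_covariates))
    add(paste0("vartheta_", spec$surv_common_covariates), "identity")
  for (g in seq_len(G))
    if (length(spec$surv_class_covariates))
      add(paste0("eta_", spec$surv_class_covariates, "_", g), "identity")
  data.frame(name = nm, transform = tr, stringsAsFactors = FALSE)
}

#' Number of free parameters of a model structure
#' @param spec a [jlcm_spec()].
#' @return integer parameter count.
#' @export
n_free_params <- function(spec) nrow(param_layout(spec))

#' Map a parameter set to/from the unconstrained optimization scale
#'
#' `pack_parameters` log-transforms the positive parameters and
#' represents B by its lower Cholesky factor with log-diagonal, giving an
#' unconstrained vector; `unpack_parameters` inverts the map exactly.
#'
#' @param params a [jlcm_params()] object.
#' @param spec the matching [jlcm_spec()].
#' @return `pack_parameters`: a named numeric vector;
#'   `unpack_parameters`: a [jlcm_params()] object.
#' @export
pack_parameters <- function(params, spec) {
  G <- spec$n_classes
  r <- n_ranef(spec)
  L <- tryCatch(t(chol(as.matrix(params$B) + diag(0, r))),
                error = function(e) stop("'B' must be positive definite to pack"))
  v <- c(if (G > 1) params$xi0,
         if (G > 1 && length(spec$logistic_covariates)) as.vector(t(params$xi1)),
         params$gamma,
         as.vector(t(params$beta)),
         if (r == 1) log(L[1, 1]) else {
           out <- c()
           for (i in seq_len(r)) for (j in seq_len(i))
             out <- c(out, if (i == j) log(L[i, j]) else L[i, j])
           out
         },
         log(params$sigma_eps),
         as.vector(rbind(log(params$zeta1), log(params$zeta2))),
         params$vartheta,
         as.vector(t(params$eta)))
  names(v) <- param_layout(spec)$name
  v
}

#' @rdname pack_parameters
#' @param vec a packed parameter vector.
#' @export
unpack_parameters <- function(vec, spec) {
  G <- spec$n_classes
  q <- length(spec$logistic_covariates)
  p <- length(longit_class_terms(spec))
  r <- n_ranef(spec)
  s1 <- length(spec$surv_common_covariates)
  s2 <- length(spec$surv_class_covariates)
  pos <- 0L
  take <- function(k) {
    out <- vec[pos + seq_len(k)]; pos <<- pos + k; out
  }
  xi0 <- if (G > 1) take(G - 1) else numeric(0)
  xi1 <- if (G > 1 && q) matrix(take((G - 1) * q), G - 1, q, byrow = TRUE)
         else matrix(0, max(G - 1, 0), q)
  gamma <- take(length(spec$longit_common_covariates))
  beta <- matrix(take(G * p), G, p, byrow = TRUE)
  if (r == 1) {
    B <- matrix(exp(take(1))^2, 1, 1)
  } else {
    L <- matrix(0, r, r)
    for (i in seq_len(r)) for (j in seq_len(i)) {
      x <- take(1)
      L[i, j] <- if (i == j) exp(x) else x
    }
    B <- L %*% t(L)
  }
  sigma_eps <- exp(take(1))
  zz <- exp(take(2 * G))
  zeta1 <- zz[seq(1, 2 * G, by = 2)]
  zeta2 <- zz[seq(2, 2 * G, by = 2)]
  vartheta <- take(s1)
  eta <- if (s2) matrix(take(G * s2), G, s2, byrow = TRUE) else matrix(0, G, s2)
  jlcm_params(spec, xi0 = xi0, xi1 = xi1, gamma = gamma, beta = beta, B = B,
              sigma_eps = sigma_eps, zeta1 = zeta1, zeta2 = zeta2,
              vartheta = vartheta, eta = eta)
}

## natural-scale values of a packed vector
natural_coef <- function(packed, spec) {
  lay <- param_layout(spec)
  out <- ifelse(lay$transform == "exp", exp(packed), packed)
  names(out) <- lay$name
  out
}

## central-difference gradient with parameter-scaled steps
num_gradient <- function(fn, x, h_rel = 1e-6) {
  vapply(seq_along(x), function(j) {
    h <- h_rel * (1 + abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, numeric(1))
}

## censored-Weibull moment/likelihood starting values for one group
weibull_group_start <- function(Tobs, delta) {
  fit <- tryCatch(
    survival::survreg(survival::Surv(Tobs, delta) ~ 1, dist = "weibull"),
    error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(fit) && is.finite(fit$scale) && fit$scale > 0) {
    c(scale = unname(exp(stats::coef(fit)[1])), shape = 1 / fit$scale)
  } else {
    c(scale = sum(Tobs) / max(sum(delta), 0.5), shape = 1)
  }
}

#' Starting values for the JLCM optimizer
#'
#' The first start is data-driven: per-subject ordinary least-squares
#' (intercept, slope) summaries are clustered into G groups with k-means,
#' the class fixed effects are seeded from group-wise pooled regressions,
#' the variance components from a within/between decomposition of the
#' residuals, the Weibull parameters from censored-Weibull fits per
#' provisional group, and the logistic intercepts from group frequencies.
#' The remaining starts perturb the first on the unconstrained scale
#' (multiplicative on positive parameters, additive on the rest).
#'
#' @param data a [jlcm_data()] object.
#' @param spec a [jlcm_spec()].
#' @param config a [jlcm_control()].
#' @return list of [jlcm_params()] starting points.
#' @export
initialize_starts <- function(data, spec, config = jlcm_control()) {
  G <- spec$n_classes
  n <- n_subjects(data)
  if (n < G) stop("fewer subjects than classes")
  sv <- data$survival
  p <- length(longit_class_terms(spec))
  r <- n_ranef(spec)

  ## per-subject OLS (intercept, slope)
  idx <- match(data$longitudinal$subject_id, sv$subject_id)
  ols <- matrix(NA_real_, n, 2)
  res_ss <- 0; res_df <- 0
  for (i in seq_len(n)) {
    ti <- data$longitudinal$time[idx == i]
    yi <- data$longitudinal$marker[idx == i]
    ni <- length(ti)
    if (ni >= 2 && stats::var(ti) > 0) {
      b <- stats::cov(ti, yi) / stats::var(ti)
      a <- mean(yi) - b * mean(ti)
      ols[i, ] <- c(a, b)
      if (ni >= 3) {
        res_ss <- res_ss + sum((yi - a - b * ti)^2)
        res_df <- res_df + ni - 2
      }
    } else if (ni >= 1) {
      ols[i, ] <- c(mean(yi), NA)
    }
  }
  med_slope <- stats::median(ols[, 2], na.rm = TRUE)
  if (!is.finite(med_slope)) med_slope <- 0
  ols[is.na(ols[, 2]), 2] <- med_slope
  usable <- which(is.finite(ols[, 1]))

  ## provisional grouping
  grp <- rep(1L, n)
  if (G > 1) {
    if (length(usable) < G) stop("not enough subjects with measurements for ", G, " classes")
    feats <- scale(ols[usable, , drop = FALSE])
    feats[!is.finite(feats)] <- 0
    set.seed(config$seed)
    km <- stats::kmeans(feats, centers = G, nstart = 5)
    ## order provisional classes by decreasing slope for a stable labeling
    ord <- order(vapply(seq_len(G), function(g)
      mean(ols[usable, 2][km$cluster == g]), numeric(1)), decreasing = TRUE)
    relab <- match(seq_len(G), ord)
    grp[usable] <- relab[km$cluster]
    grp[-usable] <- which.max(tabulate(grp[usable], G))
  }

  ## class fixed effects from group-wise regressions of y on time terms
  beta <- matrix(0, G, p)
  for (g in seq_len(G)) {
    rows <- idx %in% which(grp == g)
    ti <- data$longitudinal$time[rows]
    yi <- data$longitudinal$marker[rows]
    if (length(yi) > p) {
      ## covariate terms are seeded at zero; only time terms enter here
      X <- vapply(longit_class_terms(spec), function(tm)
        if (tm %in% c("(Intercept)", "time", "time2"))
          term_column(tm, ti, list()) else rep(0, length(ti)),
        numeric(length(ti)))
      cf <- tryCatch(stats::lm.fit(matrix(X, length(ti)), yi)$coefficients,
                     error = function(e) rep(NA_real_, p))
      cf[is.na(cf)] <- 0
      beta[g, ] <- cf
    } else {
      beta[g, ] <- c(mean(yi, na.rm = TRUE), rep(0, p - 1))
    }
  }
  beta[is.na(beta)] <- 0

  ## variance components: within-subject residual variance and
  ## between-subject spread of the OLS intercepts
  sigma2_eps <- if (res_df > 0) res_ss / res_df else stats::var(data$longitudinal$marker)
  sigma2_eps <- max(sigma2_eps, 1e-6)
  v_int <- stats::var(ols[usable, 1] - beta[grp[usable], 1])
  sigma2_b <- max(v_int - sigma2_eps / 2, 0.1 * sigma2_eps)
  B <- diag(c(sigma2_b, rep(0.05 * sigma2_b, r - 1)), r)

  ## Weibull starts per provisional group
  zeta1 <- numeric(G); zeta2 <- numeric(G)
  for (g in seq_len(G)) {
    sel <- grp == g
    w <- weibull_group_start(sv$time[sel], sv$status[sel])
    zeta1[g] <- max(w["scale"], 1e-3); zeta2[g] <- min(max(w["shape"], 0.05), 50)
  }
  if (spec$weibull_parameterization == "rate") zeta1 <- 1 / zeta1

  freq <- pmax(tabulate(grp, G), 0.5)
  xi0 <- if (G > 1) log(freq[-G] / freq[G]) else numeric(0)

  base <- jlcm_params(spec, xi0 = xi0, beta = beta, B = B,
                      sigma_eps = sqrt(sigma2_eps),
                      zeta1 = zeta1, zeta2 = zeta2)
  starts <- list(base)
  if (config$n_starts > 1) {
    v0 <- pack_parameters(base, spec)
    for (k in seq_len(config$n_starts - 1)) {
      set.seed(config$seed + 1000L * k)
      vk <- v0 + stats::rnorm(length(v0), 0, 0.2 * abs(v0) + 0.1)
      starts[[k + 1]] <- unpack_parameters(vk, spec)
    }
  }
  starts
}

## build the final fit object from a packed optimum
finalize_fit <- function(par, vcov, loglik, spec, converged,
                         n_starts_used, best_start_index, n, permutation) {
  lay <- param_layout(spec)
  est <- natural_coef(par, spec)
  se <- ci <- NULL
  if (!is.null(vcov)) {
    sd_packed <- sqrt(pmax(diag(vcov), 0))
    se <- ifelse(lay$transform == "exp", est * sd_packed, sd_packed)
    names(se) <- lay$name
    z <- stats::qnorm(0.975)
    lo <- par - z * sd_packed
    hi <- par + z * sd_packed
    ci <- cbind(lower = ifelse(lay$transform == "exp", exp(lo), lo),
                upper = ifelse(lay$transform == "exp", exp(hi), hi))
    rownames(ci) <- lay$name
    dimnames(vcov) <- list(lay$name, lay$name)
  }
  structure(list(
    params_hat = unpack_parameters(par, spec),
    par_packed = stats::setNames(par, lay$name),
    loglik = loglik, vcov = vcov, se = se, ci95 = ci,
    coefficients = est, converged = converged,
    n_starts_used = n_starts_used, best_start_index = best_start_index,
    n_params = nrow(lay), n_subjects = n,
    bic = bic(loglik, nrow(lay), n),
    permutation = permutation, spec = spec),
    class = "jlcm_fit")
}

#' Fit a joint latent class model by maximum likelihood
#'
#' Maximizes the joint observed-data log-likelihood with multi-start BFGS
#' on the unconstrained parameter scale and returns the best local
#' optimum.  The fit is declared converged only when the optimizer
#' reports success, the scaled gradient norm is below tolerance and the
#' observed information matrix at the optimum is positive definite;
#' otherwise a non-converged result (never an error) is returned, which
#' feeds the Monte-Carlo convergence-failure accounting.
#'
#' @param data a [jlcm_data()] object.
#' @param spec a [jlcm_spec()].
#' @param config a [jlcm_control()].
#' @param starts optional list of [jlcm_params()] starting points
#'   (defaults to [initialize_starts()]).
#' @return an object of class `jlcm_fit` with components `params_hat`,
#'   `loglik`, `vcov` (unconstrained scale), `se` and `ci95` (natural
#'   scale), `converged`, `bic`, `permutation` and bookkeeping fields.
#' @export
fit_jlcm <- function(data, spec, config = jlcm_control(), starts = NULL) {
  pd <- prepare_data(data, spec)
  n <- pd$n
  nll <- function(v) {
    val <- tryCatch(-sum(row_logsumexp(loglik_matrix(pd, unpack_parameters(v, spec)))),
                    error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
  if (is.null(starts)) starts <- initialize_starts(data, spec, config)
  p <- n_free_params(spec)
  ctl <- list(maxit = config$max_iter, reltol = config$rel_tol,
              ndeps = rep(1e-6, p))
  ## a single BFGS call can stop short of its local optimum; restart from
  ## the last iterate until the value stabilizes so that the comparison
  ## between starts is between fully converged local optima
  run_start <- function(par0) {
    opt <- tryCatch(stats::optim(par0, nll, method = "BFGS", control = ctl),
                    error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e9) return(NULL)
    for (round in 1:4) {
      nxt <- tryCatch(stats::optim(opt$par, nll, method = "BFGS", control = ctl),
                      error = function(e) NULL)
      if (is.null(nxt) || !is.finite(nxt$value) || nxt$value > opt$value) break
      improved <- opt$value - nxt$value
      nxt$convergence <- min(nxt$convergence, opt$convergence)
      opt <- nxt
      if (improved <= config$rel_tol * (abs(opt$value) + 1)) break
    }
    opt
  }
  best <- NULL; best_idx <- NA_integer_
  for (k in seq_along(starts)) {
    opt <- run_start(pack_parameters(starts[[k]], spec))
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) {
      best <- opt; best_idx <- k
    }
  }
  if (is.null(best)) {
    ## every start failed: report the data-driven start, unconverged
    par0 <- pack_parameters(starts[[1]], spec)
    return(finalize_fit(par0, NULL, -nll(par0), spec, FALSE,
                        length(starts), NA_integer_, n, seq_len(spec$n_classes)))
  }
  ## final tight polish so the gradient check reflects a true optimum
  tctl <- list(maxit = config$max_iter, reltol = min(config$rel_tol, 1e-13),
               ndeps = rep(1e-6, p))
  tp <- tryCatch(stats::optim(best$par, nll, method = "BFGS", control = tctl),
                 error = function(e) NULL)
  if (!is.null(tp) && is.finite(tp$value) && tp$value <= best$value) {
    tp$convergence <- min(tp$convergence, best$convergence)
    best <- tp
  }
  grad <- num_gradient(nll, best$par)
  ## coarser, scale-aware steps: second differences amplify roundoff
  hctl <- list(ndeps = pmax(1e-4, 1e-4 * abs(best$par)))
  H <- tryCatch(stats::optimHess(best$par, nll, control = hctl),
                error = function(e) NULL)
  ok_grad <- max(abs(grad)) <= config$gradient_tol * (1 + abs(best$value))
  vcov <- NULL; pd_ok <- FALSE
  if (!is.null(H)) {
    H <- (H + t(H)) / 2
    ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) -1)
    if (min(ev) > 0) {
      vcov <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
      pd_ok <- !is.null(vcov)
    }
  }
  converged <- (best$convergence == 0) && ok_grad && pd_ok
  finalize_fit(best$par, vcov, -best$value, spec, converged,
               length(starts), best_idx, n, seq_len(spec$n_classes))
}

#' @export
print.jlcm_fit <- function(x, ...) {
  cat("Joint latent class model fit (", x$spec$n_classes, " classes)\n", sep = "")
  cat("  log-likelihood:", format(x$loglik, digits = 8),
      "  BIC:", format(x$bic, digits = 8), "\n")
  cat("  converged:", x$converged,
      " (start ", x$best_start_index, " of ", x$n_starts_used, ")\n", sep = "")
  tab <- data.frame(estimate = x$coefficients)
  if (!is.null(x$se)) {
    tab$se <- x$se
    tab$lower <- x$ci95[, "lower"]; tab$upper <- x$ci95[, "upper"]
  }
  print(round(tab, 4))
  invisible(x)
}

#' @export
coef.jlcm_fit <- function(object, ...) object$coefficients

#' @export
logLik.jlcm_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, class = "logLik")
}

#' Wald confidence intervals on the natural parameter scale
#'
#' Intervals are built as estimate +/- z * SE on the unconstrained scale
#' and mapped through the monotone transform back to the natural scale,
#' so intervals for positive parameters stay positive.
#'
#' @param fit a converged [fit_jlcm()] result.
#' @param level confidence level.
#' @return matrix with columns `lower`, `upper`, one row per parameter.
#' @export
wald_confidence_intervals <- function(fit, level = 0.95) {
  if (is.null(fit$vcov)) stop("no variance-covariance matrix available")
  lay <- param_layout(fit$spec)
  z <- stats::qnorm(1 - (1 - level) / 2)
  sd_packed <- sqrt(pmax(diag(fit$vcov), 0))
  lo <- fit$par_packed - z * sd_packed
  hi <- fit$par_packed + z * sd_packed
  out <- cbind(lower = ifelse(lay$transform == "exp", exp(lo), lo),
               upper = ifelse(lay$transform == "exp", exp(hi), hi))
  rownames(out) <- lay$name
  out
}

## all permutations of 1..k
all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    sub <- all_perms(k - 1L)
    for (s in sub) out[[length(out) + 1L]] <- c(i, ifelse(s >= i, s + 1L, s))
  }
  out
}

## linear map on the packed scale implementing a class relabeling
packed_perm_matrix <- function(spec, perm) {
  G <- spec$n_classes
  lay <- param_layout(spec)
  p <- nrow(lay)
  A <- diag(p)
  nm <- lay$name
  ## xi block: new xi0_i = xi0_full[perm[i]] - xi0_full[perm[G]]
  if (G > 1) {
    M <- matrix(0, G - 1, G - 1)
    for (i in seq_len(G - 1)) {
      if (perm[i] < G) M[i, perm[i]] <- M[i, perm[i]] + 1
      if (perm[G] < G) M[i, perm[G]] <- M[i, perm[G]] - 1
    }
    ix <- match(paste0("xi0_", seq_len(G - 1)), nm)
    A[ix, ix] <- M
    for (cv in spec$logistic_covariates) {
      ix <- match(paste0("xi1_", cv, "_", seq_len(G - 1)), nm)
      A[ix, ix] <- M
    }
  }
  swap_block <- function(pattern_fun) {
    for (tag in pattern_fun()) {
      ix_new <- match(paste0(tag, "_", seq_len(G)), nm)
      ix_old <- match(paste0(tag, "_", perm), nm)
      A[ix_new, ] <<- 0
      A[cbind(ix_new, ix_old)] <<- 1
    }
  }
  bname <- function(term) switch(term, "(Intercept)" = "beta0",
                                 "time" = "beta1", "time2" = "beta2",
                                 paste0("beta_", term))
  swap_block(function() vapply(longit_class_terms(spec), bname, ""))
  swap_block(function() c("zeta1", "zeta2"))
  if (length(spec$surv_class_covariates))
    swap_block(function() paste0("eta_", spec$surv_class_covariates))
  A
}

#' Align the fitted classes with a reference truth
#'
#' Mixture likelihoods are invariant to class relabeling, so per-class
#' estimates must be aligned before they can be compared with the
#' generating values.  The permutation minimizing the sum of squared
#' differences between estimated and true class intercepts and slopes of
#' the longitudinal sub-model is applied to every class-indexed block
#' (including the logistic block, re-expressed against the new reference
#' class, with the covariance matrix transformed accordingly).
#'
#' @param fit a [fit_jlcm()] result.
#' @param truth the generating [jlcm_params()].
#' @return the fit with classes permuted; `$permutation` records the map
#'   (new class g was fitted class `permutation[g]`).
#' @export
align_to_truth <- function(fit, truth) {
  spec <- fit$spec
  G <- spec$n_classes
  if (G == 1) return(fit)
  ncol_use <- min(2L, ncol(fit$params_hat$beta))
  bhat <- fit$params_hat$beta[, seq_len(ncol_use), drop = FALSE]
  btru <- truth$beta[, seq_len(ncol_use), drop = FALSE]
  perms <- all_perms(G)
  cost <- vapply(perms, function(pm)
    sum((bhat[pm, , drop = FALSE] - btru)^2), numeric(1))
  pm <- perms[[which.min(cost)]]
  if (all(pm == seq_len(G))) {
    fit$permutation <- pm
    return(fit)
  }
  A <- packed_perm_matrix(spec, pm)
  par2 <- drop(A %*% fit$par_packed)
  vcov2 <- if (!is.null(fit$vcov)) A %*% fit$vcov %*% t(A) else NULL
  out <- finalize_fit(par2, vcov2, fit$loglik, spec, fit$converged,
                      fit$n_starts_used, fit$best_start_index,
                      fit$n_subjects, pm)
  out
}

#' Select the number of latent classes by BIC
#'
#' Fits the model for G = 1..`g_max` and reports log-likelihood, BIC and
#' the smallest posterior class size per candidate; the G with minimal
#' BIC (among converged fits when any converged) is preferred.
#'
#' @param data a [jlcm_data()] object.
#' @param spec_template a [jlcm_spec()] whose structure is reused for
#'   every candidate G.
#' @param g_max largest number of classes to try.
#' @param config a [jlcm_control()].
#' @return list with `table` (one row per G) and `best_g`.
#' @export
select_n_classes <- function(data, spec_template, g_max, config = jlcm_control()) {
  stopifnot(g_max >= 1)
  rows <- list(); fits <- list()
  for (G in seq_len(g_max)) {
    sp <- spec_template
    sp$n_classes <- as.integer(G)
    fit <- tryCatch(fit_jlcm(data, sp, config), error = function(e) NULL)
    if (is.null(fit)) {
      rows[[G]] <- data.frame(G = G, loglik = NA, n_params = n_free_params(sp),
                              bic = NA, converged = FALSE, min_class_size = NA)
      next
    }
    cls <- assign_classes(data, fit$params_hat, sp)
    rows[[G]] <- data.frame(G = G, loglik = fit$loglik,
                            n_params = fit$n_params, bic = fit$bic,
                            converged = fit$converged,
                            min_class_size = min(tabulate(cls, G)))
    fits[[G]] <- fit
  }
  tab <- do.call(rbind, rows)
  cand <- if (any(tab$converged, na.rm = TRUE)) which(tab$converged) else which(!is.na(tab$bic))
  best_g <- cand[which.min(tab$bic[cand])]
  list(table = tab, best_g = best_g, fits = fits)
}
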
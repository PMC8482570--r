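## Monte-Carlo harness for the finite-sample property study: grids over
## sample size x censoring rate x class separation, replicate management
## with convergence exclusion, and summaries of relative bias, coverage,
## normality and class-identification accuracy.

#' Grid specification for the Monte-Carlo study
#'
#' Defaults mirror the full study design: n in {100, 500, 1000, 5000},
#' censoring rates {0.05, 0.10, 0.15, 0.25, 0.50}, both separation
#' scenarios, and up to 120 generated replicates per cell to obtain at
#' least 100 converged ones.  Reduced grids (fewer cells, 20-30
#' replicates) are the intended desk-scale usage; summaries carry
#' Monte-Carlo standard errors so they remain comparable.
#'
#' @param n_values subject counts.
#' @param tau_values target censoring rates.
#' @param scenarios subset of `c("high_separation", "low_separation")`.
#' @param n_target_converged converged replicates wanted per cell.
#' @param n_generated_max generation cap per cell.
#' @param base_seed seed offset; replicate k of a cell uses
#'   `base_seed + k`.
#' @param control a [jlcm_control()] used for every fit.
#' @return a list of class `jlcm_grid`.
#' @export
grid_spec <- function(n_values = c(100, 500, 1000, 5000),
                      tau_values = c(0.05, 0.10, 0.15, 0.25, 0.50),
                      scenarios = c("high_separation", "low_separation"),
                      n_target_converged = 100, n_generated_max = 120,
                      base_seed = 1, control = jlcm_control()) {
  stopifnot(n_target_converged <= n_generated_max,
            all(scenarios %in% c("high_separation", "low_separation")))
  structure(list(n_values = n_values, tau_values = tau_values,
                 scenarios = scenarios,
                 n_target_converged = as.integer(n_target_converged),
                 n_generated_max = as.integer(n_generated_max),
                 base_seed = as.integer(base_seed), control = control),
            class = "jlcm_grid")
}

#' Absolute relative bias of a set of estimates
#'
#' |mean(estimates) - theta| / |theta|; multiplied by 100 when quoted as
#' a percentage.  Undefined for a true value of zero.
#'
#' @param estimates numeric vector of replicate estimates.
#' @param theta_true the generating value (non-zero).
#' @return relative bias as a fraction.
#' @export
relative_bias <- function(estimates, theta_true) {
  if (!length(estimates)) stop("no estimates")
  if (theta_true == 0) stop("relative bias is undefined for a true value of 0")
  abs(mean(estimates) - theta_true) / abs(theta_true)
}

#' Empirical coverage of confidence intervals
#'
#' Fraction of (closed) intervals containing the true value.
#'
#' @param lower,upper interval endpoints per replicate.
#' @param theta_true the generating value.
#' @return coverage fraction in [0, 1].
#' @export
coverage_rate <- function(lower, upper, theta_true) {
  stopifnot(length(lower) == length(upper), length(lower) > 0)
  mean(lower <= theta_true & theta_true <= upper)
}

#' Fraction of correctly identified class memberships
#'
#' @param assigned predicted labels (already aligned with the truth's
#'   class order).
#' @param truth true labels.
#' @return accuracy in [0, 1].
#' @export
class_accuracy <- function(assigned, truth) {
  if (length(assigned) != length(truth)) stop("label vectors differ in length")
  mean(assigned == truth)
}

#' Numerical normal quantile-quantile diagnostics
#'
#' Returns the sorted standardized estimates paired with normal order
#' statistic medians (Filliben's approximation) and their correlation.
#' No hypothesis test is run: outliers from occasional hard replicates
#' would dominate a formal test, while the correlation summarizes how
#' straight the QQ line is.
#'
#' @param estimates at least 10 replicate estimates.
#' @return list with `sample` (sorted standardized values),
#'   `theoretical` (normal quantiles of the order-statistic medians) and
#'   `correlation`.
#' @export
normality_diagnostics <- function(estimates) {
  k <- length(estimates)
  if (k < 10) stop("at least 10 estimates are required")
  x <- sort((estimates - mean(estimates)) / stats::sd(estimates))
  m <- (seq_len(k) - 0.3175) / (k + 0.365)
  m[1] <- 1 - 0.5^(1 / k)
  m[k] <- 0.5^(1 / k)
  q <- stats::qnorm(m)
  list(sample = x, theoretical = q, correlation = stats::cor(x, q))
}

#' Run one simulation-and-estimation replicate
#'
#' Simulates a dataset for the cell, fits the two-class model, aligns
#' the fitted classes with the truth, and records the aligned estimates,
#' confidence intervals and class-identification accuracy.  Estimation
#' failure is recorded as `converged = FALSE`, never raised.
#'
#' @param n,tau,scenario cell coordinates.
#' @param seed replicate seed.
#' @param censor_scale pre-calibrated censoring scale for (scenario,
#'   tau); calibrated on the fly when `NULL`.
#' @param control a [jlcm_control()].
#' @return list of class `jlcm_replicate` with fields `seed`,
#'   `converged`, `estimates`, `lower`, `upper`, `accuracy`, `loglik`.
#' @export
run_replicate <- function(n, tau, scenario, seed, censor_scale = NULL,
                          control = jlcm_control()) {
  cfg <- scenario_config(scenario, n_subjects = n, target_tau = tau,
                         censor_scale = censor_scale, seed = seed)
  data <- simulate_dataset(cfg)
  spec <- simulation_spec()
  ctl <- control
  ctl$seed <- as.integer(seed)
  fit <- fit_jlcm(data, spec, ctl)
  if (!fit$converged || is.null(fit$vcov)) {
    return(structure(list(seed = seed, converged = FALSE, estimates = NULL,
                          lower = NULL, upper = NULL, accuracy = NA_real_,
                          loglik = fit$loglik),
                     class = "jlcm_replicate"))
  }
  fit <- align_to_truth(fit, cfg$truth)
  lab <- assign_classes(data, fit$params_hat, spec)
  structure(list(seed = seed, converged = TRUE,
                 estimates = coef(fit),
                 lower = fit$ci95[, "lower"], upper = fit$ci95[, "upper"],
                 accuracy = class_accuracy(lab, data$true_class),
                 loglik = fit$loglik),
            class = "jlcm_replicate")
}

## the parameters summarized in the study tables, with their true values
truth_vector <- function(truth) {
  c(xi0_1 = unname(truth$xi0[1]),
    beta0_1 = unname(truth$beta[1, 1]), beta1_1 = unname(truth$beta[1, 2]),
    beta0_2 = unname(truth$beta[2, 1]), beta1_2 = unname(truth$beta[2, 2]),
    sd_b = sqrt(truth$B[1, 1]), sigma_eps = truth$sigma_eps,
    zeta1_1 = truth$zeta1[1], zeta2_1 = truth$zeta2[1],
    zeta1_2 = truth$zeta1[2], zeta2_2 = truth$zeta2[2])
}

#' Run all replicates of one grid cell and summarize
#'
#' Generates replicates with sequential seeds until either
#' `n_target_converged` converged fits are obtained or
#' `n_generated_max` datasets have been generated; all summaries are
#' computed over converged replicates only, with the generated and
#' converged counts reported.
#'
#' @param n,tau,scenario cell coordinates.
#' @param grid a [grid_spec()].
#' @param verbose print one line per replicate.
#' @return list of class `jlcm_cell_summary`: per-parameter relative
#'   bias and coverage (with Monte-Carlo standard errors), mean accuracy,
#'   normality diagnostics, counts and the raw replicate records.
#' @export
run_cell <- function(n, tau, scenario, grid = grid_spec(), verbose = FALSE) {
  truth <- preset_truth(scenario)
  cs <- calibrate_censoring_scale(truth, tau)
  reps <- list(); n_conv <- 0L; k <- 0L
  while (n_conv < grid$n_target_converged && k < grid$n_generated_max) {
    k <- k + 1L
    rep_seed <- grid$base_seed + k
    r <- run_replicate(n, tau, scenario, rep_seed, censor_scale = cs,
                       control = grid$control)
    if (verbose)
      message(sprintf("cell n=%d tau=%.2f %s seed=%d converged=%s loglik=%.2f",
                      n, tau, scenario, rep_seed, r$converged, r$loglik))
    reps[[k]] <- r
    if (r$converged) n_conv <- n_conv + 1L
  }
  conv <- Filter(function(r) r$converged, reps)
  tv <- truth_vector(truth)
  if (n_conv == 0L)
    return(structure(list(n = n, tau = tau, scenario = scenario,
                          n_generated = k, n_converged = 0L,
                          warning = "no converged replicates",
                          replicates = reps),
                     class = "jlcm_cell_summary"))
  est <- do.call(rbind, lapply(conv, function(r) r$estimates[names(tv)]))
  lo <- do.call(rbind, lapply(conv, function(r) r$lower[names(tv)]))
  hi <- do.call(rbind, lapply(conv, function(r) r$upper[names(tv)]))
  rb <- vapply(names(tv), function(p) relative_bias(est[, p], tv[p]), numeric(1))
  rb_se <- vapply(names(tv), function(p)
    stats::sd(est[, p]) / sqrt(n_conv) / abs(tv[p]), numeric(1))
  cov <- vapply(names(tv), function(p)
    coverage_rate(lo[, p], hi[, p], tv[p]), numeric(1))
  cov_se <- sqrt(cov * (1 - cov) / n_conv)
  acc <- vapply(conv, function(r) r$accuracy, numeric(1))
  nd <- if (n_conv >= 10)
    lapply(stats::setNames(colnames(est), colnames(est)),
           function(p) normality_diagnostics(est[, p]))
  else NULL
  structure(list(
    n = n, tau = tau, scenario = scenario,
    n_generated = k, n_converged = n_conv,
    warning = if (n_conv < grid$n_target_converged)
      "fewer converged replicates than targeted" else NULL,
    truth = tv, estimates = est,
    relative_bias = rb, relative_bias_se = rb_se,
    coverage = cov, coverage_se = cov_se,
    accuracy = mean(acc), accuracy_se = stats::sd(acc) / sqrt(n_conv),
    normality = nd, replicates = reps),
    class = "jlcm_cell_summary")
}

#' @export
print.jlcm_cell_summary <- function(x, ...) {
  cat(sprintf("MC cell: %s, n=%d, tau=%.2f  (%d/%d converged)\n",
              x$scenario, x$n, x$tau, x$n_converged, x$n_generated))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  if (x$n_converged > 0) {
    cat(sprintf("  mean accuracy: %.4f (se %.4f)\n", x$accuracy, x$accuracy_se))
    tab <- data.frame(rel_bias_pct = round(100 * x$relative_bias, 2),
                      coverage = round(x$coverage, 4))
    print(tab)
  }
  invisible(x)
}

#' Run a full grid and emit study tables
#'
#' Computes every (n, tau, scenario) cell of the grid and writes the
#' table analogs as delimited text: per-scenario relative-bias tables
#' (percent), per-scenario coverage tables, and an accuracy table with
#' the low-minus-high difference column.  Missing/failed cells are
#' flagged and the remaining tables are still written.
#'
#' @param grid a [grid_spec()].
#' @param output_dir directory for the CSV tables; `NULL` skips writing.
#' @param verbose print per-replicate progress.
#' @return list with `cells` (all summaries) and `tables` (data frames
#'   `rb_<scenario>`, `coverage_<scenario>`, `accuracy`).
#' @export
summarize_grid <- function(grid = grid_spec(), output_dir = NULL,
                           verbose = FALSE) {
  cells <- list()
  for (sc in grid$scenarios) for (n in grid$n_values) for (tau in grid$tau_values) {
    key <- sprintf("%s_n%d_tau%g", sc, n, tau)
    cells[[key]] <- tryCatch(
      run_cell(n, tau, sc, grid, verbose = verbose),
      error = function(e) {
        warning("cell ", key, " failed: ", conditionMessage(e))
        NULL
      })
  }
  tables <- list()
  pnames <- names(truth_vector(preset_truth("high_separation")))
  for (sc in grid$scenarios) {
    sub <- Filter(function(x) !is.null(x) && x$scenario == sc &&
                    x$n_converged > 0, cells)
    if (!length(sub)) next
    base <- data.frame(n = vapply(sub, `[[`, 0, "n"),
                       tau = vapply(sub, `[[`, 0, "tau"),
                       n_generated = vapply(sub, `[[`, 0L, "n_generated"),
                       n_converged = vapply(sub, `[[`, 0L, "n_converged"))
    rb <- cbind(base, t(vapply(sub, function(x)
      100 * x$relative_bias, numeric(length(pnames)))))
    cv <- cbind(base, t(vapply(sub, function(x)
      x$coverage, numeric(length(pnames)))))
    rownames(rb) <- rownames(cv) <- NULL
    tables[[paste0("rb_", sc)]] <- rb
    tables[[paste0("coverage_", sc)]] <- cv
  }
  ## accuracy table with difference column when both scenarios present
  acc_rows <- list()
  for (n in grid$n_values) for (tau in grid$tau_values) {
    hi <- cells[[sprintf("high_separation_n%d_tau%g", n, tau)]]
    lo <- cells[[sprintf("low_separation_n%d_tau%g", n, tau)]]
    a_hi <- if (!is.null(hi) && hi$n_converged > 0) hi$accuracy else NA_real_
    a_lo <- if (!is.null(lo) && lo$n_converged > 0) lo$accuracy else NA_real_
    acc_rows[[length(acc_rows) + 1L]] <-
      data.frame(n = n, tau = tau, high_separation = a_hi,
                 low_separation = a_lo, difference = a_lo - a_hi)
  }
  tables$accuracy <- do.call(rbind, acc_rows)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(tables))
      utils::write.csv(tables[[nm]], file.path(output_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  list(cells = cells, tables = tables)
}
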
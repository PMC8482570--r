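test_that("packing to the unconstrained scale is a bijection", {
  sp <- simulation_spec()
  tr <- preset_truth("high_separation")
  v <- pack_parameters(tr, sp)
  expect_length(v, 11)  # the two-class random-intercept model
  expect_equal(n_free_params(sp), 11L)
  back <- unpack_parameters(v, sp)
  expect_equal(back$beta, tr$beta, tolerance = 1e-12)
  expect_equal(back$B, tr$B, tolerance = 1e-12)
  expect_equal(back$zeta1, tr$zeta1, tolerance = 1e-12)
  # sigma_eps = 1 maps to 0
  pm1 <- jlcm_params(jlcm_spec(1), beta = matrix(0, 1, 2), B = 1,
                     sigma_eps = 1, zeta1 = 1, zeta2 = 1)
  expect_equal(unname(pack_parameters(pm1, jlcm_spec(1))["sigma_eps"]), 0)
  # property: round trip on random parameter sets, several structures
  specs <- list(simulation_spec(),
                jlcm_spec(3, logistic_covariates = "x",
                          longit_class_covariates = c("time", "time2"),
                          random_effects = c("intercept", "time"),
                          surv_common_covariates = "x",
                          surv_class_covariates = "w"))
  for (spk in specs) for (k in 1:50) {
    pm <- random_params(spk, 2000 + k)
    v <- pack_parameters(pm, spk)
    back <- unpack_parameters(v, spk)
    expect_equal(pack_parameters(back, spk), v, tolerance = 1e-12)
  }
})

test_that("starting values are reproducible and recover the partition", {
  sp <- simulation_spec()
  d <- sim_small(300, "high_separation", tau = 0.1, seed = 17)
  s1 <- initialize_starts(d, sp, jlcm_control(n_starts = 3, seed = 9))
  s2 <- initialize_starts(d, sp, jlcm_control(n_starts = 3, seed = 9))
  expect_length(s1, 3)
  expect_equal(pack_parameters(s1[[2]], sp), pack_parameters(s2[[2]], sp))
  # data-driven start classifies most subjects correctly (high separation)
  lab <- assign_classes(d, s1[[1]], sp)
  acc <- max(mean(lab == d$true_class), mean(3 - lab == d$true_class))
  expect_gt(acc, 0.8)
  # G=1 start comes from pooled closed-form summaries
  st1 <- initialize_starts(d, jlcm_spec(1), jlcm_control(n_starts = 1))
  expect_length(st1, 1)
  fitl <- lm(marker ~ time, data = d$longitudinal)
  expect_equal(unname(st1[[1]]$beta[1, ]), unname(coef(fitl)), tolerance = 1e-6)
  expect_error(initialize_starts(jlcm_data(d$longitudinal[0, ],
                                           d$survival[1, ]), sp),
               "fewer subjects")
})

test_that("single-class fits agree with independent mixed-model and Weibull fits", {
  skip_if_not_installed("lme4")
  sp1 <- jlcm_spec(1)
  tr <- preset_truth("high_separation")
  tr$beta <- rbind(c(150, 40), c(150, 40))
  d <- simulate_dataset(scenario_config("custom", truth = tr, n_subjects = 200,
                                        target_tau = 0.2, seed = 5))
  fit <- fit_jlcm(d, sp1, jlcm_control(n_starts = 1, rel_tol = 1e-12))
  expect_true(fit$converged)
  lmm <- lme4::lmer(marker ~ time + (1 | subject_id), data = d$longitudinal,
                    REML = FALSE)
  sr <- survival::survreg(survival::Surv(time, status) ~ 1,
                          data = d$survival, dist = "weibull")
  est <- coef(fit)
  ref <- c(beta0_1 = unname(lme4::fixef(lmm)[1]),
           beta1_1 = unname(lme4::fixef(lmm)[2]),
           sd_b = unname(attr(lme4::VarCorr(lmm)[[1]], "stddev")),
           sigma_eps = stats::sigma(lmm),
           zeta1_1 = unname(exp(coef(sr))),
           zeta2_1 = 1 / sr$scale)
  expect_equal(est[names(ref)], ref, tolerance = 1e-4)
  # joint log-likelihood splits into the two independent pieces
  expect_equal(fit$loglik,
               as.numeric(logLik(lmm)) + as.numeric(logLik(sr)),
               tolerance = 1e-6)
})

test_that("the fitted optimum is stable under relabeled starting points", {
  sp <- simulation_spec()
  d <- sim_small(120, "high_separation", tau = 0.1, seed = 31)
  st <- initialize_starts(d, sp, jlcm_control(n_starts = 1, seed = 4))
  f1 <- fit_jlcm(d, sp, jlcm_control(n_starts = 1, seed = 4), starts = st)
  st_sw <- list(jointlcm:::permute_params(st[[1]], c(2, 1)))
  f2 <- fit_jlcm(d, sp, jlcm_control(n_starts = 1, seed = 4), starts = st_sw)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  # multi-start never does worse than its own prefix
  f3 <- fit_jlcm(d, sp, jlcm_control(n_starts = 3, seed = 4))
  expect_gte(f3$loglik, f1$loglik - 1e-6)
})

test_that("Wald intervals transform monotonically and behave sanely", {
  sp <- simulation_spec()
  d <- sim_small(250, "high_separation", tau = 0.1, seed = 23)
  fit <- fit_jlcm(d, sp, jlcm_control(n_starts = 2, seed = 23))
  expect_true(fit$converged)
  ci <- wald_confidence_intervals(fit, 0.95)
  expect_true(all(ci[, "lower"] < ci[, "upper"]))
  # untransformed parameters: symmetric about the estimate
  expect_equal(unname(ci["beta0_1", "upper"] - coef(fit)["beta0_1"]),
               unname(coef(fit)["beta0_1"] - ci["beta0_1", "lower"]),
               tolerance = 1e-8)
  # positive parameters stay positive even at wide levels
  ci99 <- wald_confidence_intervals(fit, 0.999)
  expect_true(all(ci99[c("sd_b", "sigma_eps", "zeta1_1", "zeta2_2"), "lower"] > 0))
  # narrower level, narrower interval
  ci80 <- wald_confidence_intervals(fit, 0.80)
  expect_true(all(ci80[, "upper"] - ci80[, "lower"] <
                    ci[, "upper"] - ci[, "lower"]))
})

test_that("confidence intervals for the exponential scale calibrate near 95%", {
  # single-class, shape-1 survival: a fast sub-case exercising the whole
  # Wald machinery; 100 seeded replicates at n = 150
  sp1 <- jlcm_spec(1)
  tr <- preset_truth("high_separation")
  tr$beta <- rbind(c(120, 10), c(120, 10))
  tr$zeta1 <- c(8, 8); tr$zeta2 <- c(1, 1)
  cs <- calibrate_censoring_scale(tr, 0.2)
  hits <- logical(100)
  ok <- logical(100)
  for (k in 1:100) {
    d <- simulate_dataset(scenario_config("custom", truth = tr,
                                          n_subjects = 150, target_tau = 0.2,
                                          censor_scale = cs, seed = 5000 + k))
    f <- fit_jlcm(d, sp1, jlcm_control(n_starts = 1, seed = k))
    ok[k] <- f$converged
    if (f$converged)
      hits[k] <- f$ci95["zeta1_1", "lower"] <= 8 && 8 <= f$ci95["zeta1_1", "upper"]
  }
  expect_gt(mean(ok), 0.95)
  cov <- mean(hits[ok])
  expect_gte(cov, 0.90)
  expect_lte(cov, 0.99)
})

test_that("class alignment recovers the generating permutation", {
  sp <- simulation_spec()
  tr <- preset_truth("high_separation")
  d <- sim_small(150, "high_separation", tau = 0.1, seed = 41)
  fit <- fit_jlcm(d, sp, jlcm_control(n_starts = 2, seed = 41))
  al <- align_to_truth(fit, tr)
  expect_equal(al$loglik, fit$loglik)
  expect_true(all(abs(al$params_hat$beta[, 1] - tr$beta[, 1]) < 25))
  # deliberately swapped fit: swap recovered, covariance transformed
  A <- jointlcm:::packed_perm_matrix(sp, c(2, 1))
  sw <- jointlcm:::finalize_fit(drop(A %*% fit$par_packed),
                                A %*% fit$vcov %*% t(A), fit$loglik, sp,
                                fit$converged, fit$n_starts_used,
                                fit$best_start_index, fit$n_subjects, c(2, 1))
  al2 <- align_to_truth(sw, tr)
  expect_equal(al2$permutation, c(2L, 1L))
  expect_equal(coef(al2), coef(al), tolerance = 1e-10)
  expect_equal(al2$se, al$se, tolerance = 1e-8)
  # G=3: every permutation is undone exactly (brute-force check)
  sp3 <- jlcm_spec(3)
  pm3 <- random_params(sp3, 77)
  pm3$beta <- matrix(c(10, 50, 90, 1, 2, 3), 3, 2)
  fake <- jointlcm:::finalize_fit(pack_parameters(pm3, sp3),
                                  diag(n_free_params(sp3)), -1, sp3, TRUE,
                                  1, 1, 10, 1:3)
  for (pm in jointlcm:::all_perms(3)) {
    A3 <- jointlcm:::packed_perm_matrix(sp3, pm)
    shuffled <- jointlcm:::finalize_fit(drop(A3 %*% fake$par_packed),
                                        diag(n_free_params(sp3)), -1, sp3,
                                        TRUE, 1, 1, 10, pm)
    back <- align_to_truth(shuffled, pm3)
    expect_equal(back$params_hat$beta, pm3$beta, tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("BIC model selection distinguishes one from two classes", {
  sp <- simulation_spec()
  d2 <- sim_small(150, "high_separation", tau = 0.1, seed = 61)
  sel2 <- select_n_classes(d2, jlcm_spec(1), 2, jlcm_control(n_starts = 2, seed = 61))
  expect_equal(sel2$best_g, 2)
  expect_equal(sel2$table$bic,
               bic(sel2$table$loglik, sel2$table$n_params, 150),
               tolerance = 1e-10)
  # one-class data: no support for a second class
  tr1 <- preset_truth("high_separation")
  tr1$beta[1, ] <- tr1$beta[2, ]
  tr1$zeta1[1] <- tr1$zeta1[2]; tr1$zeta2[1] <- tr1$zeta2[2]
  d1 <- simulate_dataset(scenario_config("custom", truth = tr1,
                                         n_subjects = 150, target_tau = 0.1,
                                         seed = 62))
  sel1 <- select_n_classes(d1, jlcm_spec(1), 2, jlcm_control(n_starts = 2, seed = 62))
  expect_equal(sel1$best_g, 1)
})
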
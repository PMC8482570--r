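test_that("prior class probabilities follow the logistic sub-model", {
  sp2 <- jlcm_spec(2)
  pm <- jlcm_params(sp2, xi0 = -0.84, beta = rbind(c(1, 0), c(0, 0)),
                    B = 1, sigma_eps = 1, zeta1 = c(1, 1), zeta2 = c(1, 1))
  p <- class_prior_probs(pm, sp2)
  expect_equal(p[1], exp(-0.84) / (1 + exp(-0.84)), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  sp3 <- jlcm_spec(3)
  pm3 <- jlcm_params(sp3, xi0 = c(0, 0), beta = matrix(0, 3, 2), B = 1,
                     sigma_eps = 1, zeta1 = rep(1, 3), zeta2 = rep(1, 3))
  expect_equal(class_prior_probs(pm3, sp3), rep(1 / 3, 3), tolerance = 1e-12)

  spx <- jlcm_spec(2, logistic_covariates = "x")
  pmx <- jlcm_params(spx, xi0 = 1, xi1 = matrix(0.5, 1, 1),
                     beta = matrix(0, 2, 2), B = 1, sigma_eps = 1,
                     zeta1 = c(1, 1), zeta2 = c(1, 1))
  p <- class_prior_probs(pmx, spx, covariates = list(x = 2))
  expect_equal(p[1], exp(2) / (1 + exp(2)), tolerance = 1e-12)
  expect_error(class_prior_probs(pmx, spx, covariates = list(z = 1)),
               "missing logistic covariate")

  # normalization holds for random parameters, including extreme ones
  for (s in 1:25) {
    sp <- jlcm_spec(sample(2:4, 1))
    pm <- random_params(sp, s)
    pm$xi0 <- pm$xi0 * 50  # push towards saturation
    p <- class_prior_probs(pm, sp)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
  }
})

test_that("Weibull log-survival and log-hazard are mutually consistent", {
  expect_equal(weibull_log_survival(0, 4.5, 2), 0)
  expect_equal(weibull_log_survival(4.5, 4.5, 2), -1)
  expect_equal(weibull_log_hazard(4.5, 4.5, 2), log(2 / 4.5), tolerance = 1e-12)
  # shape 1: constant hazard 1/scale
  expect_equal(weibull_log_hazard(c(0.5, 3, 17), 4, 1), rep(log(1 / 4), 3))
  # median of a near-exponential survival recovered by root finding
  med <- uniroot(function(t) weibull_log_survival(t, 50, 1.01) - log(0.5),
                 c(1, 200), tol = 1e-12)$root
  expect_equal(med, 50 * log(2)^(1 / 1.01), tolerance = 1e-8)

  expect_error(weibull_log_survival(-1, 1, 1), "non-negative")
  expect_error(weibull_log_hazard(0, 1, 0.5), "strictly positive")
  expect_error(weibull_log_hazard(1, -1, 1), "positive")

  # rate parameterization: S(t) = exp(-(zeta1 t)^zeta2)
  expect_equal(weibull_log_survival(2, 0.25, 1.5, parameterization = "rate"),
               weibull_log_survival(2, 4, 1.5))
  expect_equal(weibull_convert(4.5, "scale_time", "rate"), 1 / 4.5)

  # hazard equals -d/dt log S on a grid (finite differences)
  h <- 1e-6
  for (z1 in c(0.8, 4.5, 50)) for (z2 in c(0.7, 1.01, 2, 3)) {
    for (t in c(0.3, 1, 2.7)) {
      num <- -(weibull_log_survival(t + h, z1, z2, 0.3) -
                 weibull_log_survival(t - h, z1, z2, 0.3)) / (2 * h)
      expect_equal(num, exp(weibull_log_hazard(t, z1, z2, 0.3)),
                   tolerance = 1e-6)
    }
  }
})

test_that("marginal longitudinal log-density integrates the random effects exactly", {
  sp <- jlcm_spec(1)
  pm <- jlcm_params(sp, beta = matrix(c(0, 0), 1, 2), B = 0.5^2,
                    sigma_eps = 1, zeta1 = 1, zeta2 = 1)
  # no measurements contribute nothing
  s0 <- make_subject(numeric(0), numeric(0), T = 1, delta = 1)
  expect_identical(longit_marginal_log_density(s0, 1, pm, sp), 0)
  # one observation at the mode of a standard normal (B = 0 is singular
  # only jointly with sigma_eps = 0, so use a tiny B)
  pm1 <- jlcm_params(sp, beta = matrix(c(0, 0), 1, 2), B = 1e-12,
                     sigma_eps = 1, zeta1 = 1, zeta2 = 1)
  s1 <- make_subject(0, 0, T = 1, delta = 1)
  expect_equal(longit_marginal_log_density(s1, 1, pm1, sp),
               -0.5 * log(2 * pi), tolerance = 1e-9)
  # two zero residuals under covariance [[110, 50], [50, 110]]
  pm2 <- jlcm_params(sp, beta = matrix(c(0, 0), 1, 2), B = 50,
                     sigma_eps = sqrt(60), zeta1 = 1, zeta2 = 1)
  s2 <- make_subject(c(0, 0.5), c(0, 0), T = 1, delta = 1)
  V <- matrix(c(110, 50, 50, 110), 2)
  direct <- -0.5 * (2 * log(2 * pi) + log(det(V)))
  expect_equal(longit_marginal_log_density(s2, 1, pm2, sp), direct,
               tolerance = 1e-10)
  # random-slope structure against the brute-force oracle
  spg <- jlcm_spec(1, longit_class_covariates = c("time", "time2"),
                   random_effects = c("intercept", "time"))
  pmg <- random_params(spg, 7)
  sg <- make_subject(c(0.2, 0.7, 1.3), c(1.0, -0.4, 2.2), T = 2, delta = 0)
  expect_equal(subject_log_likelihood(sg, pmg, spg),
               oracle_subject_ll(sg, pmg, spg), tolerance = 1e-10)
})

test_that("subject likelihood matches a direct-summation oracle", {
  sp <- simulation_spec()
  tr <- preset_truth("high_separation")
  d <- sim_small(30, seed = 11)
  for (i in seq_len(10)) {
    s <- subject_record(d, i)
    expect_equal(subject_log_likelihood(s, tr, sp),
                 oracle_subject_ll(s, tr, sp), tolerance = 1e-10)
  }
  # random parameters and random subjects, 100 instances
  for (k in 1:100) {
    pm <- random_params(sp, 1000 + k)
    pm$beta <- pm$beta + matrix(c(150, 100, 40, 1), 2, 2)
    pm$sigma_eps <- pm$sigma_eps * 20
    pm$B <- pm$B * 100
    i <- (k %% 30) + 1
    s <- subject_record(d, i)
    expect_equal(subject_log_likelihood(s, pm, sp),
                 oracle_subject_ll(s, pm, sp), tolerance = 1e-8)
  }
  # covariate-bearing structure
  spc <- jlcm_spec(2, logistic_covariates = "x",
                   longit_common_covariates = "x",
                   surv_common_covariates = "x", surv_class_covariates = "w")
  pmc <- random_params(spc, 5)
  sc <- make_subject(c(0.1, 0.6), c(2.5, 1.0), T = 1.4, delta = 1,
                     covariates = list(x = 0.8, w = -1.2))
  expect_equal(subject_log_likelihood(sc, pmc, spc),
               oracle_subject_ll(sc, pmc, spc), tolerance = 1e-10)
})

test_that("single-class reduction and degenerate mixtures collapse correctly", {
  sp1 <- jlcm_spec(1)
  sp2 <- simulation_spec()
  pm1 <- jlcm_params(sp1, beta = matrix(c(100, 5), 1, 2), B = 49,
                     sigma_eps = 7, zeta1 = 5, zeta2 = 1.3)
  pm2 <- jlcm_params(sp2, xi0 = 0.37, beta = rbind(c(100, 5), c(100, 5)),
                     B = 49, sigma_eps = 7, zeta1 = c(5, 5), zeta2 = c(1.3, 1.3))
  s <- make_subject(c(0.1, 0.5, 1), c(96, 104, 99), T = 1.2, delta = 1)
  # G=1: longitudinal + survival pieces add up
  expect_equal(subject_log_likelihood(s, pm1, sp1),
               longit_marginal_log_density(s, 1, pm1, sp1) +
                 weibull_log_hazard(1.2, 5, 1.3) +
                 weibull_log_survival(1.2, 5, 1.3), tolerance = 1e-12)
  # two identical classes equal the single-class value
  expect_equal(subject_log_likelihood(s, pm2, sp2),
               subject_log_likelihood(s, pm1, sp1), tolerance = 1e-12)
})

test_that("total likelihood is additive and label-permutation invariant", {
  sp <- simulation_spec()
  tr <- preset_truth("low_separation")
  d <- sim_small(40, "low_separation", seed = 3)
  ll <- total_log_likelihood(d, tr, sp)
  # additivity over subjects
  persub <- sum(vapply(seq_len(40), function(i)
    subject_log_likelihood(subject_record(d, i), tr, sp), numeric(1)))
  expect_equal(ll, persub, tolerance = 1e-9)
  # one-subject dataset equals the subject contribution
  d1 <- jlcm_data(d$longitudinal[d$longitudinal$subject_id ==
                                   d$survival$subject_id[1], ],
                  d$survival[1, ])
  expect_equal(total_log_likelihood(d1, tr, sp),
               subject_log_likelihood(subject_record(d, 1), tr, sp),
               tolerance = 1e-12)
  # swapping class labels leaves the mixture likelihood unchanged
  swapped <- jointlcm:::permute_params(tr, c(2, 1))
  expect_equal(total_log_likelihood(d, swapped, sp), ll, tolerance = 1e-10)
  expect_equal(swapped$xi0, -tr$xi0)
})

test_that("posterior probabilities follow Bayes rule and normalize", {
  sp <- simulation_spec()
  tr <- preset_truth("high_separation")
  # identical class parameters: posterior equals the prior
  pm_eq <- tr
  pm_eq$beta[2, ] <- pm_eq$beta[1, ]
  pm_eq$zeta1[2] <- pm_eq$zeta1[1]; pm_eq$zeta2[2] <- pm_eq$zeta2[1]
  s <- make_subject(c(0.25, 1), c(150, 180), T = 1.5, delta = 0)
  expect_equal(posterior_class_probs(s, pm_eq, sp),
               class_prior_probs(pm_eq, sp), tolerance = 1e-12)
  # prior (0.3, 0.7) with likelihood ratio 7:3 balances to (0.5, 0.5):
  # survival-only subject whose log-survival terms differ by log(7/3)
  lr <- log(7 / 3)
  pm_b <- jlcm_params(sp, xi0 = log(0.3 / 0.7),
                      beta = rbind(c(0, 0), c(0, 0)), B = 1, sigma_eps = 1,
                      zeta1 = c(1, 1 / (1 + lr)), zeta2 = c(1, 1))
  sb <- make_subject(numeric(0), numeric(0), T = 1, delta = 0)
  # class 1: log S = -1; class 2: log S = -(1 + lr), difference = lr
  expect_equal(posterior_class_probs(sb, pm_b, sp), c(0.5, 0.5),
               tolerance = 1e-12)
  # normalization for random inputs
  d <- sim_small(15, seed = 21)
  for (k in 1:20) {
    pm <- random_params(sp, 400 + k)
    w <- posterior_class_probs(subject_record(d, (k %% 15) + 1), pm, sp)
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("class assignment takes the posterior argmax with low-index ties", {
  sp <- simulation_spec()
  tr <- preset_truth("high_separation")
  d <- sim_small(60, seed = 8, tau = 0.05)
  lab <- assign_classes(d, tr, sp)
  W <- t(vapply(seq_len(60), function(i)
    posterior_class_probs(subject_record(d, i), tr, sp), numeric(2)))
  expect_equal(lab, apply(W, 1, which.max))
  # high separation at the truth: labels nearly all correct
  expect_gt(mean(lab == d$true_class), 0.9)
  # exact ties break to the lowest index
  expect_equal(which.max(c(0.5, 0.5)), 1L)
  pm_eq <- tr
  pm_eq$xi0 <- 0
  pm_eq$beta[2, ] <- pm_eq$beta[1, ]
  pm_eq$zeta1[2] <- pm_eq$zeta1[1]; pm_eq$zeta2[2] <- pm_eq$zeta2[1]
  expect_true(all(assign_classes(d, pm_eq, sp) == 1L))
})

test_that("BIC penalizes parameters and matches its definition", {
  expect_equal(bic(0, 0, 10), 0)
  expect_equal(bic(-7450, 11, 500), 14900 + 11 * log(500))
  expect_gt(bic(-100, 12, 50), bic(-100, 11, 50))
})
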
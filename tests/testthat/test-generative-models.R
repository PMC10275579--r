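test_that("covariance assembles as D R D", {
  expect_equal(build_covariance(1, 1, 0), diag(2))
  S <- build_covariance(2, 3, 0.5)
  expect_equal(S[1, 2], 3.0)
  expect_equal(S[2, 1], 3.0)
  expect_equal(diag(S), c(4, 9))
  # near-unit correlations are retained (jitter is the sampler's concern)
  S2 <- build_covariance(1, 1, 0.999999)
  expect_true(all(eigen(S2)$values > 0))
  expect_error(build_covariance(1, 1, 1), "< 1")
  expect_error(build_covariance(-1, 1, 0))
  expect_error(build_covariance(1, 1, matrix(c(1, 0.2, 0.3, 1), 2, 2)),
               "symmetric")
})

test_that("reference configurations yield the full-scale draw counts", {
  expect_equal(retained_draws(sampler_defaults("m2")), 3200)
  expect_equal(retained_draws(sampler_defaults("m3")), 4000)
  expect_equal(retained_draws(sampler_defaults("m4")), 24000)
})

test_that("retained-draw accounting holds in a real run", {
  k <- matrix(c(70, 65, 40, 45, 55, 50, 62, 58), ncol = 2, byrow = TRUE)
  cohort <- count_cohort(k, 100)
  cfg <- sampler_config(60, 30, 2, thin = 1, seed = 5)
  fit <- fit_model2(cohort, cfg)
  expect_equal(nrow(as_draws_matrix(fit)), retained_draws(cfg))
  expect_equal(nrow(as_draws_matrix(fit)), 2 * (60 - 30))
})

test_that("LKJ(1) makes the correlation uniform a priori", {
  r <- prior_predictive_retest(50000, seed = 8)
  expect_true(all(r > -1 & r < 1))
  expect_lt(abs(mean(r)), 0.02)
  ks <- suppressWarnings(ks.test(r, "punif", -1, 1))
  expect_lt(unname(ks$statistic), 0.02)
  # non-uniform shape concentrates toward zero
  r4 <- prior_predictive_retest(50000, eta = 4, seed = 9)
  expect_lt(sd(r4), sd(r))
})

m2_retest_fit <- function() {
  cached("m2_retest", {
    # probit-scale truth with retest correlation 0.9
    set.seed(21)
    n <- 60
    rho <- 0.9
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    raw <- cbind(0.2 + 0.5 * z1, 0.2 + 0.5 * z2)
    k <- matrix(rbinom(2 * n, 100, pnorm(raw)), ncol = 2)
    cohort <- count_cohort(k, 100)
    list(fit = fit_model2(cohort, sampler_config(800, 400, 4, thin = 2,
                                                 seed = 77)),
         cohort = cohort, k = k)
  })
}

test_that("the joint binomial model recovers a strong theta correlation", {
  env <- m2_retest_fit()
  est <- extract_retest(env$fit, "theta")
  expect_gte(est$r, 0.6)
  expect_lte(est$r, 1.0)
  expect_equal(est$kind, "credible")
  expect_true(env$fit$converged)
})

test_that("theta posterior means track observed summary scores", {
  env <- m2_retest_fit()
  pm <- person_means(env$fit) |>
    dplyr::filter(.data$session == 1) |>
    dplyr::arrange(.data$subject)
  expect_gt(cor(pm$estimate, env$k[, 1] / 100), 0.95)
})

test_that("model 2 requires the two-session structure", {
  k <- matrix(c(70, 0, 50, 0, 60, 0), ncol = 2, byrow = TRUE)
  cohort <- count_cohort(k, 100, has2 = c(FALSE, FALSE, FALSE))
  expect_error(fit_model2(cohort), "two-session")
})

small_m4_fit <- function() {
  cached("m4_small", {
    bundle <- generate_cohort(
      scenario_config(n = 10, n_trials = 80, missing_session2 = 2),
      seed = 14)
    list(bundle = bundle,
         fit = fit_model4(bundle$cohort,
                          sampler_config(500, 250, 4, thin = 3, seed = 40)))
  })
}

test_that("missing sessions are imputed with wider posteriors", {
  env <- small_m4_fit()
  pooled <- as_draws_matrix(env$fit)
  miss_idx <- match(env$bundle$truth$missing_session2, env$fit$subjects)
  pres_idx <- setdiff(seq_along(env$fit$subjects), miss_idx)
  i <- miss_idx[1]
  # no session-2 data => the imputed session-2 posteriors are wider than the
  # data-constrained ones of observed subjects (on average across the five
  # parameters; single parameters can tie when the between-session
  # correlation makes the imputation precise)
  ratios <- vapply(c("A_rew", "A_pun", "K_prime", "beta_f", "beta_p"),
                   function(p) {
    sd_missing <- sd(pooled[, sprintf("%s[%d,2]", p, i)])
    sd_present <- median(vapply(pres_idx, function(j)
      sd(pooled[, sprintf("%s[%d,2]", p, j)]), numeric(1)))
    sd_missing / sd_present
  }, numeric(1))
  expect_gt(exp(mean(log(ratios))), 1)
  expect_gt(max(ratios), 1)
  # draws exist for both sessions of the missing subject
  expect_true(all(is.finite(pooled[, sprintf("A_pun[%d,2]", i)])))
})

test_that("retest extraction is restricted to the joint models", {
  env <- small_m4_fit()
  est <- extract_retest(env$fit, "beta_p")
  expect_true(est$lo >= -1 && est$hi <= 1 && est$lo <= est$r)
  expect_equal(length(attr(est, "draws")),
               retained_draws(env$fit$config))
  expect_error(extract_retest(env$fit, "nonesuch"), "no correlation draws")
  m3 <- fit_model3(env$bundle$cohort, 1,
                   sampler_config(150, 80, 2, thin = 1, seed = 3))
  expect_error(extract_retest(m3, "A_rew"), "two_step_retest")
})

test_that("tidy and glance summarize fits", {
  env <- small_m4_fit()
  td <- tidy(env$fit, pars = c("r[A_rew]", "mu[beta_p,1]"))
  expect_equal(td$parameter, c("r[A_rew]", "mu[beta_p,1]"))
  expect_true(all(td$lo <= td$mean & td$mean <= td$hi))
  gl <- glance(env$fit)
  expect_equal(gl$retained, 4 * 250)
  expect_equal(gl$model, "m4")
})

test_that("per-session ORL fits are stable across sampler seeds", {
  env <- small_m4_fit()
  cohort <- env$bundle$cohort
  cfg_a <- sampler_config(500, 300, 3, thin = 3, seed = 1)
  cfg_b <- sampler_config(500, 300, 3, thin = 3, seed = 1001)
  fa <- fit_model3(cohort, 1, cfg_a)
  fb <- fit_model3(cohort, 1, cfg_b)
  ma <- person_means(fa) |> dplyr::arrange(.data$subject, .data$parameter)
  mb <- person_means(fb) |> dplyr::arrange(.data$subject, .data$parameter)
  # only Monte Carlo noise distinguishes the runs: posterior means agree
  # to a fraction of the posterior spread
  pooled <- as_draws_matrix(fa)
  psd <- vapply(seq_len(nrow(ma)), function(k) {
    i <- match(ma$subject[k], fa$subjects)
    sd(pooled[, sprintf("%s[%d]", ma$parameter[k], i)])
  }, numeric(1))
  expect_gt(cor(ma$estimate, mb$estimate), 0.98)
  expect_lt(max(abs(ma$estimate - mb$estimate) / psd), 1)
})

test_that("hierarchical fits pool person-level estimates", {
  # shrinkage signature: the spread of person-level posterior means is
  # smaller than the estimated population spread (checked on the identity
  # scale beta weights, where the two are directly comparable)
  env <- small_m4_fit()
  m3 <- fit_model3(env$bundle$cohort, 1,
                   sampler_config(400, 250, 2, thin = 2, seed = 6))
  for (p in c("beta_f", "beta_p")) {
    s3 <- person_means(m3) |> dplyr::filter(.data$parameter == p)
    expect_lt(sd(s3$estimate),
              tidy(m3, pars = sprintf("sigma[%s]", p))$mean)
    s4 <- person_means(env$fit) |>
      dplyr::filter(.data$parameter == p, .data$session == 1)
    expect_lt(sd(s4$estimate),
              tidy(env$fit, pars = sprintf("sigma[%s,1]", p))$mean)
  }
})

test_that("posterior predictive checks cover self-generated data", {
  env <- small_m4_fit()
  ppc <- posterior_predictive_check(env$fit, env$bundle$cohort, n_rep = 60,
                                    seed = 2)
  expect_true(all(ppc$lo <= ppc$pred_mean & ppc$pred_mean <= ppc$hi))
  expect_gte(mean(ppc$covered), 0.8)
  expect_warning(
    posterior_predictive_check(env$fit, env$bundle$cohort, n_rep = 1,
                               seed = 2),
    "degenerate")
})

test_that("binomial PPC tracks an all-good-deck cohort", {
  k <- matrix(100, nrow = 5, ncol = 2)
  cohort <- count_cohort(k, 100)
  fit <- fit_model2(cohort, sampler_config(300, 150, 2, thin = 1, seed = 4))
  ppc <- posterior_predictive_check(fit, cohort, n_rep = 50, seed = 9)
  expect_true(all(ppc$pred_mean > 0.9))
})
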
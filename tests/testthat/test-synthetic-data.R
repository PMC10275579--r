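test_that("identical config and seed give byte-identical bundles", {
  cfg <- scenario_config(n = 6, n_trials = 30, missing_session2 = 1)
  a <- generate_cohort(cfg, seed = 77)
  b <- generate_cohort(cfg, seed = 77)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$truth$parameters, b$truth$parameters)
  c <- generate_cohort(cfg, seed = 78)
  expect_false(identical(a$cohort, c$cohort))
})

test_that("the benchmark scenario mirrors the study's shape", {
  sc <- benchmark_scenario()
  expect_equal(sc$n, 50L)
  expect_equal(sc$n_trials, 100L)
  expect_equal(sc$missing_session2, 4L)
  expect_equal(sc$r[["beta_p"]], 0.82)
  expect_equal(sc$r[["A_rew"]], 0.73)
  bundle <- generate_cohort(sc, seed = 1)
  records <- dplyr::distinct(bundle$cohort, .data$subject, .data$session)
  expect_equal(nrow(records), 96)  # 50 at session 1 + 46 at session 2
  expect_equal(length(bundle$truth$missing_session2), 4)
})

test_that("near-unit correlation pins the two sessions together", {
  cfg <- scenario_config(n = 30, n_trials = 5,
                         mu = c(A_rew = 0, A_pun = 0, K_prime = 0,
                                beta_f = 0, beta_p = 0),
                         sigma = c(A_rew = 0.1, A_pun = 0.1, K_prime = 0.1,
                                   beta_f = 0.1, beta_p = 0.1),
                         r = setNames(rep(1 - 1e-9, 5),
                                      c("A_rew", "A_pun", "K_prime",
                                        "beta_f", "beta_p")))
  bundle <- generate_cohort(cfg, seed = 10)
  wide <- bundle$truth$parameters |>
    tidyr::pivot_wider(id_cols = c("subject", "parameter"),
                       names_from = "session", values_from = "raw",
                       names_prefix = "s")
  expect_lt(max(abs(wide$s1 - wide$s2)), 1e-3)
})

test_that("generated raw values reproduce the configured correlations", {
  cfg <- scenario_config(n = 8000, n_trials = 1,
                         r = c(A_rew = 0.3, A_pun = 0.5, K_prime = 0.7,
                               beta_f = -0.4, beta_p = 0.82))
  bundle <- generate_cohort(cfg, seed = 5)
  emp <- bundle$truth$parameters |>
    tidyr::pivot_wider(id_cols = c("subject", "parameter"),
                       names_from = "session", values_from = "raw",
                       names_prefix = "s") |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(r = cor(.data$s1, .data$s2), .groups = "drop")
  for (p in names(cfg$r))
    expect_lt(abs(emp$r[emp$parameter == p] - cfg$r[[p]]), 0.03)
})

test_that("covariate loadings propagate to empirical correlations", {
  cfg <- scenario_config(n = 2000, n_trials = 1)
  bundle <- generate_cohort(cfg, seed = 6)
  spec <- tibble::tibble(
    covariate = c("pure", "null", "partial"),
    parameter = c("A_pun", "A_pun", "A_pun"),
    session = 1L,
    loading = c(1, 0, 0.4),
    noise_sd = c(0, 1, sqrt(1 - 0.4^2)))
  covs <- generate_covariates(bundle$truth, spec, seed = 8)
  truth <- bundle$truth$parameters |>
    dplyr::filter(.data$parameter == "A_pun", .data$session == 1) |>
    dplyr::arrange(match(.data$subject, covs$subject))
  expect_equal(cor(covs$pure, truth$raw, method = "spearman"), 1)
  expect_lt(abs(cor(covs$null, truth$raw)), 0.06)
  expect_equal(cor(covs$partial, truth$raw), 0.4, tolerance = 0.05)
  expect_error(
    generate_covariates(bundle$truth,
                        tibble::tibble(covariate = "x", parameter = "zzz",
                                       session = 1L, loading = 1,
                                       noise_sd = 0)),
    "unknown target")
})

test_that("synthetic covariates with known loading are detected end-to-end", {
  cfg <- scenario_config(n = 200, n_trials = 1)
  bundle <- generate_cohort(cfg, seed = 16)
  spec <- tibble::tibble(covariate = c("load6", "indep"),
                         parameter = "A_pun", session = 1L,
                         loading = c(0.6, 0), noise_sd = c(0.8, 1))
  covs <- generate_covariates(bundle$truth, spec, seed = 20)
  truth_wide <- bundle$truth$parameters |>
    dplyr::filter(.data$parameter == "A_pun", .data$session == 1) |>
    dplyr::transmute(subject = .data$subject, A_pun = .data$raw)
  out <- covariate_correlations(truth_wide, covs, B = 800, seed = 4)
  l6 <- out[out$covariate == "load6", ]
  expect_gt(l6$r, 0)
  expect_true(l6$excludes_zero)
  ind <- out[out$covariate == "indep", ]
  expect_false(ind$excludes_zero)
})

test_that("two-step summary correlations are attenuated toward zero", {
  cfg <- scenario_config(n = 60, n_trials = 100, missing_session2 = 0)
  truth_r <- calibrate_score_retest(cfg, n_subjects = 250, reps = 8,
                                    seed = 30)
  expect_gt(truth_r, 0.3)  # the scenario induces real score stability
  m1 <- vapply(1:4, function(k) {
    bundle <- generate_cohort(cfg, seed = 100 + k)
    fit_model1(bundle$cohort, B = 500, seed = k)$r
  }, numeric(1))
  expect_lt(mean(m1), truth_r)
})

test_that("bundles persist as plain-text artifacts and reload", {
  cfg <- scenario_config(n = 4, n_trials = 10, missing_session2 = 1)
  bundle <- generate_cohort(cfg, seed = 12)
  bundle$covariates <- generate_covariates(
    bundle$truth,
    tibble::tibble(covariate = "c1", parameter = "beta_p", session = 1L,
                   loading = 0.5, noise_sd = 0.5),
    seed = 2)
  dir <- withr::local_tempdir()
  write_cohort_bundle(bundle, dir)
  expect_true(all(file.exists(file.path(dir, c("cohort.csv", "truth.json",
                                               "covariates.csv")))))
  back <- read_cohort_bundle(dir)
  expect_equal(back$cohort, bundle$cohort)
  expect_equal(back$truth$parameters$raw, bundle$truth$parameters$raw)
  expect_equal(back$truth$config$r, bundle$truth$config$r)
  expect_equal(back$covariates$c1, bundle$covariates$c1)
})
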
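#' Run the four-model test-retest comparison
#'
#' Orchestrates the full analysis on one cohort: the two-step summary-score
#' correlation (model 1), the joint good-deck probability model (model 2),
#' per-session hierarchical ORL fits with two-step correlations of posterior
#' means (model 3), and the full joint generative ORL model (model 4). The
#' report pairs, for each of the six metrics (theta/summary score plus the
#' five ORL parameters), the two-step estimate with its generative
#' counterpart, records convergence, and flags whether the two-step point
#' falls inside the generative 95% HDI.
#'
#' @param cohort a cohort tibble.
#' @param profile sampler profile (`"desk"` or `"reference"`), used when
#'   `configs` is not given.
#' @param configs optional named list of [sampler_config()]s
#'   (`m2`, `m3`, `m4`).
#' @param priors an [hb_priors()].
#' @param control an [orl_control()].
#' @param B bootstrap replicates for the two-step intervals.
#' @param seed integer seed (drives samplers and bootstraps).
#' @param allow_nonconverged keep going when a fit's max split R-hat is
#'   `>= 1.1` (default `FALSE`: fail loudly, naming the model).
#' @return A `comparison_report`: tibble with one row per metric
#'   (`two_step_*` and `generative_*` estimates, `max_rhat`, `converged`,
#'   `overlap`), with the fits attached as attributes `fits` and
#'   `person_means`.
#' @export
run_comparison <- function(cohort, profile = "desk", configs = NULL,
                           priors = hb_priors(), control = orl_control(),
                           B = 2000, seed = 1234,
                           allow_nonconverged = FALSE) {
  cohort <- validate_cohort(cohort)
  configs <- configs %||% list(
    m2 = sampler_defaults("m2", profile, seed = seed),
    m3 = sampler_defaults("m3", profile, seed = seed + 101L),
    m4 = sampler_defaults("m4", profile, seed = seed + 202L))

  check <- function(fit, tag) {
    if (!fit$converged && !allow_nonconverged)
      abort(sprintf("%s did not converge (max split R-hat %.3f >= 1.1)",
                    tag, fit$max_rhat))
    fit
  }

  m1 <- fit_model1(cohort, B = B, seed = seed)
  m2 <- check(fit_model2(cohort, configs$m2, priors), "model 2")
  m3_s1 <- check(fit_model3(cohort, 1, configs$m3, priors, control),
                 "model 3 (session 1)")
  cfg3b <- configs$m3
  cfg3b$seed <- cfg3b$seed + 1L
  m3_s2 <- check(fit_model3(cohort, 2, cfg3b, priors, control),
                 "model 3 (session 2)")
  m4 <- check(fit_model4(cohort, configs$m4, priors, control), "model 4")

  rows <- list()
  gen_theta <- extract_retest(m2, "theta")
  rows[["theta"]] <- tibble::tibble(
    metric = "summary_score",
    two_step_r = m1$r, two_step_lo = m1$lo, two_step_hi = m1$hi,
    generative_r = gen_theta$r, generative_lo = gen_theta$lo,
    generative_hi = gen_theta$hi,
    max_rhat = m2$max_rhat, converged = m2$converged,
    overlap = m1$r >= gen_theta$lo & m1$r <= gen_theta$hi)
  for (p in orl_param_names()) {
    ts <- two_step_retest(m3_s1, m3_s2, p, B = B, seed = seed + 7L)
    gen <- extract_retest(m4, p)
    rows[[p]] <- tibble::tibble(
      metric = p,
      two_step_r = ts$r, two_step_lo = ts$lo, two_step_hi = ts$hi,
      generative_r = gen$r, generative_lo = gen$lo, generative_hi = gen$hi,
      max_rhat = m4$max_rhat, converged = m4$converged,
      overlap = ts$r >= gen$lo & ts$r <= gen$hi)
  }
  report <- dplyr::bind_rows(rows)
  class(report) <- c("comparison_report", class(report))
  attr(report, "fits") <- list(m2 = m2, m3_s1 = m3_s1, m3_s2 = m3_s2,
                               m4 = m4)
  attr(report, "person_means") <- list(
    m3_s1 = person_means(m3_s1), m3_s2 = person_means(m3_s2),
    m4 = person_means(m4))
  attr(report, "seed") <- seed
  report
}

#' Save / load a comparison report
#'
#' The report table (plus seed) round-trips losslessly through JSON; the
#' attached fit objects are not persisted.
#'
#' @param report a `comparison_report`.
#' @param path JSON file path.
#' @export
save_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  jsonlite::write_json(
    list(seed = attr(report, "seed"),
         report = as.data.frame(report)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_report
#' @export
load_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  report <- tibble::as_tibble(obj$report)
  class(report) <- c("comparison_report", class(report))
  attr(report, "seed") <- obj$seed
  report
}

#' Parameter-recovery experiment
#'
#' For each replicate: generate a cohort from the scenario, fit the
#' per-session hierarchical ORL model (session 1) and the joint generative
#' model, and score (a) the correlation between true and posterior-mean
#' person-level parameters and (b) the error of the group-level test-retest
#' estimates against the generating correlations.
#'
#' @param scenario a [scenario_config()].
#' @param n_replicates number of replicate cohorts.
#' @param seed integer seed (replicate `k` uses `seed + k`).
#' @param profile sampler profile for the fits.
#' @param configs optional named list of [sampler_config()]s (`m3`, `m4`).
#' @param priors an [hb_priors()].
#' @param B bootstrap replicates for two-step intervals.
#' @return A `recovery_report`: tibble with one row per (replicate,
#'   parameter): `recovery_m3`, `recovery_m4` (true vs posterior-mean
#'   correlations, session 1), `r_true`, `r_m4` (posterior mean),
#'   `r_two_step` (model 3 two-step), and `max_rhat_m4`.
#' @export
run_recovery <- function(scenario = benchmark_scenario(),
                         n_replicates = 1, seed = 1, profile = "desk",
                         configs = NULL, priors = hb_priors(), B = 1000) {
  stopifnot(n_replicates >= 1)
  configs <- configs %||% list(
    m3 = sampler_defaults("m3", profile, seed = seed + 11L),
    m4 = sampler_defaults("m4", profile, seed = seed + 22L))
  control <- scenario$control

  one <- function(k) {
    bundle <- generate_cohort(scenario, seed = seed + k)
    truth1 <- bundle$truth$parameters |>
      dplyr::filter(.data$session == 1) |>
      dplyr::select("subject", "parameter", truth = "natural")

    m3_s1 <- fit_model3(bundle$cohort, 1, configs$m3, priors, control)
    cfg3b <- configs$m3
    cfg3b$seed <- cfg3b$seed + 1L
    m3_s2 <- fit_model3(bundle$cohort, 2, cfg3b, priors, control)
    m4 <- fit_model4(bundle$cohort, configs$m4, priors, control)

    est3 <- person_means(m3_s1) |> dplyr::rename(est_m3 = "estimate")
    est4 <- person_means(m4) |>
      dplyr::filter(.data$session == 1) |>
      dplyr::rename(est_m4 = "estimate")

    purrr::map_dfr(orl_param_names(), function(p) {
      tr <- dplyr::filter(truth1, .data$parameter == p)
      e3 <- dplyr::filter(est3, .data$parameter == p)
      e4 <- dplyr::filter(est4, .data$parameter == p)
      j <- dplyr::inner_join(tr, e3, by = "subject") |>
        dplyr::inner_join(e4, by = "subject")
      ts <- two_step_retest(m3_s1, m3_s2, p, B = B, seed = seed + 5L)
      tibble::tibble(
        replicate = k, parameter = p,
        recovery_m3 = cor(j$truth, j$est_m3),
        recovery_m4 = cor(j$truth, j$est_m4),
        r_true = scenario$r[[p]],
        r_m4 = extract_retest(m4, p)$r,
        r_two_step = ts$r,
        max_rhat_m4 = m4$max_rhat)
    })
  }

  report <- purrr::map_dfr(seq_len(n_replicates), one)
  class(report) <- c("recovery_report", class(report))
  attr(report, "seed") <- seed
  report
}

#' @export
glance.recovery_report <- function(x, ...) {
  x |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      n_replicates = dplyr::n(),
      recovery_m3 = mean(.data$recovery_m3),
      recovery_m4 = mean(.data$recovery_m4),
      r_true = mean(.data$r_true),
      bias_m4 = mean(.data$r_m4 - .data$r_true),
      rmse_m4 = sqrt(mean((.data$r_m4 - .data$r_true)^2)),
      bias_two_step = mean(.data$r_two_step - .data$r_true),
      .groups = "drop")
}
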
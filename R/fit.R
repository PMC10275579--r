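#' Sampler configuration
#'
#' Iteration accounting follows the usual MCMC convention: each chain runs
#' `iterations` iterations of which the first `warmup` are discarded, so a
#' fit retains `chains * (iterations - warmup)` draws per parameter.
#' `thin` multiplies the number of post-warmup sweeps per retained draw
#' (useful for the random-walk sampler) without changing the accounting.
#'
#' @param iterations iterations per chain (including warmup).
#' @param warmup warmup iterations discarded from each chain.
#' @param chains number of chains.
#' @param thin sweeps per retained draw after warmup (default 1).
#' @param seed integer seed; chain `c` runs under `seed + c - 1`.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(iterations, warmup, chains, thin = 1,
                           seed = 1234) {
  stopifnot(iterations > warmup, warmup >= 1, chains >= 1, thin >= 1)
  structure(list(iterations = as.integer(iterations),
                 warmup = as.integer(warmup),
                 chains = as.integer(chains),
                 thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "sampler_config")
}

#' Default sampler configurations per model
#'
#' `profile = "reference"` is the full-scale analysis configuration
#' (model 2: 4 chains x 1000 iterations / 200 warmup = 3200 retained draws;
#' model 3: 4 x 1500/500 = 4000; model 4: 6 x 5000/1000 = 24000).
#' `profile = "desk"` is a reduced profile for interactive work and tests.
#'
#' @param model `"m2"`, `"m3"` or `"m4"`.
#' @param profile `"reference"` or `"desk"`.
#' @param seed integer seed.
#' @return A [sampler_config()].
#' @export
sampler_defaults <- function(model = c("m2", "m3", "m4"),
                             profile = c("reference", "desk"), seed = 1234) {
  model <- match.arg(model)
  profile <- match.arg(profile)
  if (profile == "reference") {
    switch(model,
           m2 = sampler_config(1000, 200, 4, thin = 1, seed = seed),
           m3 = sampler_config(1500, 500, 4, thin = 2, seed = seed),
           m4 = sampler_config(5000, 1000, 6, thin = 2, seed = seed))
  } else {
    switch(model,
           m2 = sampler_config(700, 300, 4, thin = 2, seed = seed),
           m3 = sampler_config(700, 300, 4, thin = 3, seed = seed),
           m4 = sampler_config(900, 400, 4, thin = 4, seed = seed))
  }
}

#' Retained posterior draws implied by a configuration
#'
#' @param config a [sampler_config()].
#' @return `chains * (iterations - warmup)`.
#' @export
retained_draws <- function(config) {
  stopifnot(inherits(config, "sampler_config"))
  config$chains * (config$iterations - config$warmup)
}

#' Hierarchical model priors
#'
#' Group-level means have Normal(0, `mu_sd`) priors on the raw scale. Group
#' SDs of the probit-scaled parameters (`A_rew`, `A_pun`, `K_prime`) have
#' half-normal(`sigma_probit_scale`) priors; SDs of the unbounded weights
#' (`beta_f`, `beta_p`) have half-Cauchy(`sigma_beta_scale`) priors; the
#' good-deck probability model uses Uniform(0, `sigma_theta_upper`) SDs. The
#' 2x2 between-session correlation matrices have LKJ(1) priors, i.e. a
#' uniform marginal on the correlation.
#'
#' @param mu_sd SD of the group-mean prior (default 1).
#' @param sigma_probit_scale half-normal scale for probit-parameter SDs
#'   (default 0.4).
#' @param sigma_beta_scale half-Cauchy scale for beta-weight SDs (default 1).
#' @param sigma_theta_upper uniform upper bound for the theta-model SDs
#'   (default 1.5).
#' @return An `hb_priors` list.
#' @export
hb_priors <- function(mu_sd = 1, sigma_probit_scale = 0.4,
                      sigma_beta_scale = 1, sigma_theta_upper = 1.5) {
  stopifnot(mu_sd > 0, sigma_probit_scale > 0, sigma_beta_scale > 0,
            sigma_theta_upper > 0)
  structure(list(mu_sd = mu_sd, sigma_probit_scale = sigma_probit_scale,
                 sigma_beta_scale = sigma_beta_scale,
                 sigma_theta_upper = sigma_theta_upper),
            class = "hb_priors")
}

#' ORL likelihood controls
#'
#' @param scale monetary scaling of net outcomes before learning updates
#'   (default 100, i.e. outcomes enter in hundreds of dollars).
#' @param K_prime_max upper bound of the raw decay parameter (default 5).
#' @return An `orl_control` list.
#' @export
orl_control <- function(scale = 100, K_prime_max = 5) {
  stopifnot(scale > 0, K_prime_max > 0)
  structure(list(scale = scale, K_prime_max = K_prime_max),
            class = "orl_control")
}

# --- fitted-model container ---------------------------------------------

new_hb_fit <- function(model, draws, config, priors, control, data_info,
                       subjects) {
  rhats <- vapply(colnames(draws[[1]]), function(p) {
    split_rhat(lapply(draws, function(m) m[, p]))
  }, numeric(1))
  rhat_tbl <- tibble::tibble(parameter = colnames(draws[[1]]), rhat = rhats)
  structure(list(model = model, draws = draws, config = config,
                 priors = priors, control = control, data_info = data_info,
                 subjects = subjects, rhat = rhat_tbl,
                 max_rhat = max(rhats),
                 converged = all(is.finite(rhats)) && max(rhats) < 1.1),
            class = "hb_fit")
}

#' Pooled draw matrix of a fit
#'
#' @param fit an `hb_fit`.
#' @return Matrix (retained draws x parameters) pooling all chains.
#' @export
as_draws_matrix <- function(fit) {
  stopifnot(inherits(fit, "hb_fit"))
  do.call(rbind, fit$draws)
}

#' @export
print.hb_fit <- function(x, ...) {
  cat("<hb_fit>", x$model, "-", length(x$subjects), "subjects,",
      x$config$chains, "chains x",
      x$config$iterations - x$config$warmup, "retained draws\n")
  cat(sprintf("max split R-hat: %.3f (%s)\n", x$max_rhat,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
tidy.hb_fit <- function(x, pars = NULL, level = 0.95, ...) {
  pooled <- as_draws_matrix(x)
  keep <- pars %||% colnames(pooled)
  missing_pars <- setdiff(keep, colnames(pooled))
  if (length(missing_pars) > 0)
    abort(paste0("unknown parameters: ", paste(missing_pars, collapse = ", ")))
  purrr::map_dfr(keep, function(p) {
    d <- pooled[, p]
    h <- hdi(d, level)
    tibble::tibble(parameter = p, mean = mean(d), sd = sd(d),
                   lo = h$lo, hi = h$hi,
                   rhat = x$rhat$rhat[x$rhat$parameter == p])
  })
}

#' @export
glance.hb_fit <- function(x, ...) {
  tibble::tibble(model = x$model, n_subjects = length(x$subjects),
                 chains = x$config$chains,
                 retained = retained_draws(x$config),
                 max_rhat = x$max_rhat, converged = x$converged)
}

#' Per-subject posterior means of person-level parameters
#'
#' @param fit an `hb_fit`.
#' @return Tibble `subject`, `session`, `parameter`, `estimate` with the
#'   posterior mean of each person-level parameter on its natural scale.
#' @export
person_means <- function(fit) {
  stopifnot(inherits(fit, "hb_fit"))
  pooled <- as_draws_matrix(fit)
  pars <- if (fit$model == "m2") "theta" else orl_param_names()
  info <- fit$data_info
  if (fit$model %in% c("m2", "m4")) {
    grid <- tidyr::expand_grid(
      index = seq_along(fit$subjects), session = 1:2,
      parameter = pars)
  } else {
    grid <- tidyr::expand_grid(
      index = seq_along(fit$subjects), session = fit$session,
      parameter = pars)
  }
  grid |>
    dplyr::mutate(
      subject = fit$subjects[.data$index],
      estimate = purrr::pmap_dbl(
        list(.data$parameter, .data$index, .data$session),
        function(p, i, s) {
          col <- if (fit$model == "m3") sprintf("%s[%d]", p, i)
                 else sprintf("%s[%d,%d]", p, i, s)
          mean(pooled[, col])
        })) |>
    dplyr::select("subject", "session", "parameter", "estimate")
}
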
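#' Model 1: two-step test-retest correlation of the summary score
#'
#' The traditional analysis: computes each subject's observed good-deck
#' proportion per session and, over complete session pairs, the Pearson
#' correlation between session-1 and session-2 scores with a BCa bootstrap
#' interval.
#'
#' @param cohort a cohort tibble.
#' @param good_decks decks counted as good.
#' @param B bootstrap replicates.
#' @param seed optional integer seed for the bootstrap.
#' @param level confidence level.
#' @return A one-row `retest_estimate` tibble: `parameter`, `method`, `r`,
#'   `lo`, `hi`, `kind`, `n`.
#' @export
fit_model1 <- function(cohort, good_decks = c("C", "D"), B = 10000,
                       seed = NULL, level = 0.95) {
  scores <- summary_scores(cohort, good_decks)
  pairs <- retest_pairs(scores)
  if (nrow(pairs) < 3) abort("need >= 3 subjects with both sessions")
  ci <- bca_ci(pairs$s1, pairs$s2, B = B, seed = seed, level = level)
  tibble::tibble(parameter = "summary_score", method = "two_step",
                 r = ci$statistic, lo = ci$lo, hi = ci$hi, kind = ci$kind,
                 n = nrow(pairs))
}

# order cohort into per-subject session lists for the samplers
cohort_sessions <- function(cohort) {
  cohort <- validate_cohort(cohort)
  subjects <- unique(cohort$subject)
  by_key <- split(cohort, paste(cohort$subject, cohort$session, sep = "\r"))
  get <- function(sub, ses) by_key[[paste(sub, ses, sep = "\r")]]
  list(cohort = cohort, subjects = subjects, get = get,
       has2 = vapply(subjects, function(s) !is.null(get(s, 2L)), logical(1)))
}

chain_seeds <- function(config) config$seed + seq_len(config$chains) - 1L

m4_param_cols <- function(n) {
  pn <- orl_param_names()
  c(sprintf("mu[%s,1]", pn), sprintf("mu[%s,2]", pn),
    sprintf("sigma[%s,1]", pn), sprintf("sigma[%s,2]", pn),
    sprintf("r[%s]", pn),
    as.vector(vapply(seq_len(n), function(i)
      as.vector(vapply(1:2, function(s) sprintf("%s[%d,%d]", pn, i, s),
                       character(5))), character(10))))
}

#' Model 2: joint hierarchical binomial model of good-deck choice
#'
#' Generative analogue of the summary score: each subject-session's count of
#' good-deck choices is Binomial(T, Phi(raw)) with session-linked raw values
#' drawn per subject from a bivariate normal whose correlation (LKJ(1)
#' prior, uniform on (-1, 1)) is the test-retest reliability of theta.
#' Subjects missing session 2 contribute no session-2 likelihood but receive
#' posterior theta draws through the joint prior.
#'
#' @param cohort a cohort tibble (at least one subject needs both sessions).
#' @param config a [sampler_config()].
#' @param priors an [hb_priors()].
#' @param good_decks decks counted as good.
#' @return An `hb_fit` with draws of `mu[theta,s]`, `sigma[theta,s]`,
#'   `r[theta]` and per-subject `theta[i,s]`.
#' @export
fit_model2 <- function(cohort, config = sampler_defaults("m2"),
                       priors = hb_priors(), good_decks = c("C", "D")) {
  cs <- cohort_sessions(cohort)
  if (!any(cs$has2))
    abort("model 2 requires the two-session structure: no subject has session 2")
  good <- deck_index(good_decks)
  n <- length(cs$subjects)
  counts <- function(ses) {
    k <- integer(n); Tn <- integer(n)
    for (i in seq_len(n)) {
      d <- cs$get(cs$subjects[i], ses)
      if (!is.null(d)) {
        k[i] <- sum(d$deck %in% good)
        Tn[i] <- nrow(d)
      }
    }
    list(k = k, Tn = Tn)
  }
  s1 <- counts(1L); s2 <- counts(2L)

  n_keep <- config$iterations - config$warmup
  warm_sweeps <- config$warmup * config$thin
  draws <- purrr::map(chain_seeds(config), function(s) {
    set.seed(s)
    m <- fit_m2_chain_cpp(s1$k, s1$Tn, s2$k, s2$Tn, cs$has2,
                          n_keep, warm_sweeps, config$thin,
                          priors$mu_sd, priors$sigma_theta_upper)$draws
    colnames(m) <- c("mu[theta,1]", "mu[theta,2]", "sigma[theta,1]",
                     "sigma[theta,2]", "r[theta]",
                     as.vector(vapply(seq_len(n), function(i)
                       sprintf("theta[%d,%d]", i, 1:2), character(2))))
    m
  })
  info <- tidyr::expand_grid(index = seq_len(n), session = 1:2) |>
    dplyr::mutate(subject = cs$subjects[.data$index],
                  n_trials = purrr::map2_int(.data$index, .data$session,
                    function(i, s) if (s == 1) s1$Tn[i] else s2$Tn[i])) |>
    dplyr::filter(.data$n_trials > 0)
  new_hb_fit("m2", draws, config, priors, orl_control(), info, cs$subjects)
}

#' Model 3: per-session hierarchical ORL model
#'
#' Fits the trial-level ORL model to one session with independent normal
#' group distributions on the raw parameter scale (probit for the learning
#' rates and decay, identity for the beta weights). Test-retest reliability
#' is then assessed in a second step by correlating per-subject posterior
#' means across two such fits ([two_step_retest()]).
#'
#' @param cohort a cohort tibble.
#' @param session which session to fit (1 or 2).
#' @param config a [sampler_config()].
#' @param priors an [hb_priors()].
#' @param control an [orl_control()].
#' @return An `hb_fit` with draws of `mu[p]`, `sigma[p]` and per-subject
#'   natural-scale parameters `p[i]`.
#' @export
fit_model3 <- function(cohort, session = 1, config = sampler_defaults("m3"),
                       priors = hb_priors(), control = orl_control()) {
  cs <- cohort_sessions(cohort)
  session <- as.integer(session)
  stopifnot(session %in% c(1L, 2L))
  present <- vapply(cs$subjects, function(s) !is.null(cs$get(s, session)),
                    logical(1))
  subjects <- cs$subjects[present]
  if (length(subjects) < 2) abort("need >= 2 subjects with that session")
  deck <- purrr::map(subjects, function(s) cs$get(s, session)$deck)
  x <- purrr::map(subjects, function(s) {
    d <- cs$get(s, session)
    (d$gain + d$loss) / control$scale
  })
  pn <- orl_param_names()
  sg_scale <- c(rep(priors$sigma_probit_scale, 3),
                rep(priors$sigma_beta_scale, 2))
  sg_type <- c(0L, 0L, 0L, 1L, 1L)
  n <- length(subjects)
  n_keep <- config$iterations - config$warmup
  warm_sweeps <- config$warmup * config$thin
  draws <- purrr::map(chain_seeds(config), function(s) {
    set.seed(s)
    m <- fit_m3_chain_cpp(deck, x, control$K_prime_max,
                          n_keep, warm_sweeps, config$thin,
                          priors$mu_sd, sg_scale, sg_type)$draws
    colnames(m) <- c(sprintf("mu[%s]", pn), sprintf("sigma[%s]", pn),
                     as.vector(vapply(seq_len(n), function(i)
                       sprintf("%s[%d]", pn, i), character(5))))
    m
  })
  info <- tibble::tibble(index = seq_len(n), session = session,
                         subject = subjects,
                         n_trials = lengths(deck))
  fit <- new_hb_fit("m3", draws, config, priors, control, info, subjects)
  fit$session <- session
  fit
}

#' Model 4: full joint generative ORL model across sessions
#'
#' The full generative model: trial-level ORL likelihoods for every observed
#' subject-session, with each of the five person-level parameters following
#' its own session-linked bivariate normal group distribution on the raw
#' scale. The 2x2 correlation matrix of each parameter carries an LKJ(1)
#' prior, so its free off-diagonal element -- the parameter's test-retest
#' correlation -- is a priori uniform on (-1, 1) and is estimated jointly
#' with everything else. Subjects missing session 2 are imputed structurally
#' through the joint prior (no likelihood term), informed by their session-1
#' play and the group-level structure.
#'
#' @inheritParams fit_model3
#' @return An `hb_fit` with draws of `mu[p,s]`, `sigma[p,s]`, the five
#'   test-retest correlations `r[p]`, and per-subject natural-scale
#'   parameters `p[i,s]` for both sessions.
#' @export
fit_model4 <- function(cohort, config = sampler_defaults("m4"),
                       priors = hb_priors(), control = orl_control()) {
  cs <- cohort_sessions(cohort)
  subjects <- cs$subjects
  n <- length(subjects)
  if (n < 2) abort("need >= 2 subjects")
  empty_i <- integer(0); empty_d <- numeric(0)
  get_deck <- function(s, ses) {
    d <- cs$get(s, ses)
    if (is.null(d)) empty_i else d$deck
  }
  get_x <- function(s, ses) {
    d <- cs$get(s, ses)
    if (is.null(d)) empty_d else (d$gain + d$loss) / control$scale
  }
  deck1 <- purrr::map(subjects, get_deck, ses = 1L)
  x1 <- purrr::map(subjects, get_x, ses = 1L)
  deck2 <- purrr::map(subjects, get_deck, ses = 2L)
  x2 <- purrr::map(subjects, get_x, ses = 2L)
  sg_scale <- c(rep(priors$sigma_probit_scale, 3),
                rep(priors$sigma_beta_scale, 2))
  sg_type <- c(0L, 0L, 0L, 1L, 1L)
  n_keep <- config$iterations - config$warmup
  warm_sweeps <- config$warmup * config$thin
  draws <- purrr::map(chain_seeds(config), function(s) {
    set.seed(s)
    m <- fit_m4_chain_cpp(deck1, x1, deck2, x2, cs$has2,
                          control$K_prime_max,
                          n_keep, warm_sweeps, config$thin,
                          priors$mu_sd, sg_scale, sg_type)$draws
    colnames(m) <- m4_param_cols(n)
    m
  })
  info <- tidyr::expand_grid(index = seq_len(n), session = 1:2) |>
    dplyr::mutate(subject = subjects[.data$index],
                  n_trials = purrr::map2_int(.data$index, .data$session,
                    function(i, s) length(if (s == 1) deck1[[i]]
                                          else deck2[[i]]))) |>
    dplyr::filter(.data$n_trials > 0)
  new_hb_fit("m4", draws, config, priors, control, info, subjects)
}

#' Between-session covariance from SDs and a correlation
#'
#' `S = D R D` with `D = diag(sigma1, sigma2)`; the off-diagonal of the 2x2
#' correlation matrix `R` is the test-retest correlation.
#'
#' @param sigma1,sigma2 positive session SDs.
#' @param R a 2x2 correlation matrix, or the scalar correlation.
#' @return Symmetric positive-definite 2x2 covariance matrix.
#' @export
build_covariance <- function(sigma1, sigma2, R) {
  stopifnot(sigma1 > 0, sigma2 > 0)
  if (is.matrix(R)) {
    if (!all(dim(R) == c(2, 2)) || any(diag(R) != 1) || R[1, 2] != R[2, 1])
      abort("R must be a symmetric 2x2 correlation matrix with unit diagonal")
    r <- R[1, 2]
  } else {
    r <- R
    R <- matrix(c(1, r, r, 1), 2, 2)
  }
  if (abs(r) >= 1) abort("|r| must be < 1")
  D <- diag(c(sigma1, sigma2))
  D %*% R %*% D
}

#' Generative test-retest estimate from a joint fit
#'
#' Extracts the posterior draws of a parameter's test-retest correlation
#' from a joint generative fit (model 2 or 4), with posterior mean and 95%
#' highest density interval.
#'
#' @param fit an `hb_fit` from [fit_model2()] or [fit_model4()].
#' @param parameter `"theta"` for model 2; one of `A_rew`, `A_pun`,
#'   `K_prime`, `beta_f`, `beta_p` for model 4.
#' @param level credible mass for the HDI.
#' @return A one-row `retest_estimate` tibble (`parameter`, `method`, `r`,
#'   `lo`, `hi`, `kind`, `n`) with the posterior draws of r as the
#'   `"draws"` attribute.
#' @export
extract_retest <- function(fit, parameter, level = 0.95) {
  stopifnot(inherits(fit, "hb_fit"))
  if (!fit$model %in% c("m2", "m4"))
    abort("test-retest draws exist only in the joint models (m2, m4); use two_step_retest() for per-session fits")
  col <- sprintf("r[%s]", parameter)
  pooled <- as_draws_matrix(fit)
  if (!col %in% colnames(pooled))
    abort(paste0("no correlation draws for parameter '", parameter, "'"))
  d <- pooled[, col]
  h <- hdi(d, level)
  out <- tibble::tibble(parameter = parameter, method = "generative",
                        r = mean(d), lo = h$lo, hi = h$hi, kind = "credible",
                        n = length(fit$subjects))
  attr(out, "draws") <- d
  out
}

#' Two-step test-retest correlation from two per-session fits
#'
#' Correlates per-subject posterior means across two independent per-session
#' fits (complete pairs), with a BCa interval -- the two-step counterpart of
#' [extract_retest()].
#'
#' @param fit_s1,fit_s2 `hb_fit`s of sessions 1 and 2 (model 3).
#' @param parameter person-level parameter name.
#' @param B,seed,level bootstrap settings.
#' @param exclude_outliers optional subject ids to drop before correlating.
#' @return A one-row `retest_estimate` tibble.
#' @export
two_step_retest <- function(fit_s1, fit_s2, parameter, B = 10000,
                            seed = NULL, level = 0.95,
                            exclude_outliers = NULL) {
  est <- function(fit) {
    person_means(fit) |>
      dplyr::filter(.data$parameter == !!parameter) |>
      dplyr::select("subject", "estimate")
  }
  pairs <- dplyr::inner_join(est(fit_s1), est(fit_s2), by = "subject",
                             suffix = c("_1", "_2"))
  if (!is.null(exclude_outliers))
    pairs <- dplyr::filter(pairs, !.data$subject %in% exclude_outliers)
  if (nrow(pairs) < 3) abort("need >= 3 subjects with both sessions")
  ci <- bca_ci(pairs$estimate_1, pairs$estimate_2, B = B, seed = seed,
               level = level)
  tibble::tibble(parameter = parameter, method = "two_step",
                 r = ci$statistic, lo = ci$lo, hi = ci$hi, kind = ci$kind,
                 n = nrow(pairs))
}

#' Prior-predictive draws of the test-retest correlation
#'
#' Samples from the prior the joint models place on each 2x2 correlation
#' matrix. Under LKJ(eta) the off-diagonal r satisfies
#' `(r + 1)/2 ~ Beta(eta, eta)`, so the default `eta = 1` makes every
#' correlation in (-1, 1) equally likely a priori.
#'
#' @param n_draws number of draws.
#' @param eta LKJ shape (default 1).
#' @param seed optional integer seed.
#' @return Numeric vector of correlations in (-1, 1).
#' @export
prior_predictive_retest <- function(n_draws, eta = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  2 * rbeta(n_draws, eta, eta) - 1
}
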
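#' Scenario configuration for synthetic cohorts
#'
#' Describes the generating group-level structure of a two-session synthetic
#' cohort: per ORL parameter, raw-scale group means and SDs per session and
#' the true between-session correlation; plus cohort size, trials per
#' session, and how many randomly chosen subjects miss session 2.
#'
#' @param n number of subjects.
#' @param n_trials trials per session.
#' @param mu 5x2 matrix of raw-scale group means (rows `A_rew`, `A_pun`,
#'   `K_prime`, `beta_f`, `beta_p`; columns sessions), or a length-5 named
#'   vector reused for both sessions.
#' @param sigma 5x2 matrix (or length-5 vector) of raw-scale group SDs.
#' @param r named length-5 vector of true test-retest correlations.
#' @param missing_session2 number of subjects who lack session 2.
#' @param control an [orl_control()] used when simulating play.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n = 50, n_trials = 100,
                            mu = c(A_rew = -1, A_pun = -1, K_prime = -1,
                                   beta_f = 1, beta_p = 0.5),
                            sigma = c(A_rew = 0.5, A_pun = 0.5,
                                      K_prime = 0.5, beta_f = 1,
                                      beta_p = 1),
                            r = c(A_rew = 0.7, A_pun = 0.7, K_prime = 0.7,
                                  beta_f = 0.7, beta_p = 0.7),
                            missing_session2 = 0,
                            control = orl_control()) {
  pn <- orl_param_names()
  expand <- function(v) {
    if (is.matrix(v)) {
      stopifnot(nrow(v) == 5, ncol(v) == 2)
      rownames(v) <- pn
      v
    } else {
      matrix(v[pn], 5, 2, dimnames = list(pn, NULL))
    }
  }
  mu <- expand(mu)
  sigma <- expand(sigma)
  r <- r[pn]
  stopifnot(n >= 2, n_trials >= 1, missing_session2 < n,
            all(sigma > 0), all(abs(r) < 1))
  structure(list(n = as.integer(n), n_trials = as.integer(n_trials),
                 mu = mu, sigma = sigma, r = r,
                 missing_session2 = as.integer(missing_session2),
                 control = control),
            class = "scenario_config")
}

#' The benchmark scenario at the study's scale
#'
#' A 50-subject, 100-trial, two-session cohort with 4 subjects missing
#' session 2, generating test-retest correlations set to the joint-model
#' posterior means reported for the five ORL parameters (A_rew .73,
#' A_pun .67, K .78, beta_f .64, beta_p .82) -- used as generative truth for
#' recovery experiments, not as a recovery claim.
#'
#' @return A [scenario_config()].
#' @export
benchmark_scenario <- function() {
  scenario_config(
    n = 50, n_trials = 100,
    r = c(A_rew = 0.73, A_pun = 0.67, K_prime = 0.78, beta_f = 0.64,
          beta_p = 0.82),
    missing_session2 = 4)
}

#' Generate a synthetic two-session cohort with known truth
#'
#' For each subject and ORL parameter, draws session-linked raw values from
#' the scenario's bivariate normal (via the non-centered construction
#' `raw1 = mu1 + sigma1 z1`, `raw2 = mu2 + sigma2 (r z1 + sqrt(1-r^2) z2)`),
#' maps them to the natural scale, and simulates each present session
#' trial-by-trial on the canonical payoff schedule. The configured number of
#' randomly chosen subjects lose session 2. Identical `(config, seed)` give
#' byte-identical bundles.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @param schedule a [payoff_schedule].
#' @return A `cohort_bundle`: list with `cohort` (trial tibble), `truth`
#'   (generating config, per-subject raw and natural parameters, seed), and
#'   `covariates` (`NULL` until [generate_covariates()] is used).
#' @export
generate_cohort <- function(config = scenario_config(), seed = 1,
                            schedule = default_schedule()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  pn <- orl_param_names()
  n <- config$n
  kmax <- config$control$K_prime_max

  z1 <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, pn))
  z2 <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, pn))
  raw1 <- raw2 <- matrix(NA_real_, n, 5, dimnames = list(NULL, pn))
  for (p in pn) {
    w <- sqrt(1 - config$r[[p]]^2)
    raw1[, p] <- config$mu[p, 1] + config$sigma[p, 1] * z1[, p]
    raw2[, p] <- config$mu[p, 2] +
      config$sigma[p, 2] * (config$r[[p]] * z1[, p] + w * z2[, p])
  }

  missing <- if (config$missing_session2 > 0)
    sort(sample.int(n, config$missing_session2)) else integer(0)
  subjects <- sprintf("S%03d", seq_len(n))

  nat_mat <- function(raw) {
    cbind(A_rew = stats::pnorm(raw[, "A_rew"]),
          A_pun = stats::pnorm(raw[, "A_pun"]),
          K_prime = kmax * stats::pnorm(raw[, "K_prime"]),
          beta_f = raw[, "beta_f"], beta_p = raw[, "beta_p"])
  }
  nat1 <- nat_mat(raw1)
  nat2 <- nat_mat(raw2)
  truth_tbl <- tibble::tibble(
    subject = rep(subjects, each = 10L),
    session = rep(rep(1:2, each = 5L), times = n),
    parameter = rep(pn, times = 2L * n),
    raw = as.vector(t(cbind(raw1, raw2))),
    natural = as.vector(t(cbind(nat1, nat2))))

  n_tr <- config$n_trials
  rec_subj <- integer(0); rec_ses <- integer(0)
  for (i in seq_len(n)) {
    ses <- if (i %in% missing) 1L else 1:2
    rec_subj <- c(rec_subj, rep(i, length(ses)))
    rec_ses <- c(rec_ses, ses)
  }
  n_rec <- length(rec_subj)
  deck <- integer(n_rec * n_tr)
  gain <- numeric(n_rec * n_tr)
  loss <- numeric(n_rec * n_tr)
  for (j in seq_len(n_rec)) {
    i <- rec_subj[j]
    nat <- if (rec_ses[j] == 1L) nat1[i, ] else nat2[i, ]
    sim <- orl_simulate_session_cpp(
      schedule$gain, schedule$loss, n_tr,
      nat[["A_rew"]], nat[["A_pun"]], 3^nat[["K_prime"]] - 1,
      nat[["beta_f"]], nat[["beta_p"]], config$control$scale)
    at <- (j - 1L) * n_tr + seq_len(n_tr)
    deck[at] <- sim$deck
    gain[at] <- sim$gain
    loss[at] <- sim$loss
  }
  cohort <- tibble::tibble(
    subject = rep(subjects[rec_subj], each = n_tr),
    session = rep(rec_ses, each = n_tr),
    trial = rep(seq_len(n_tr), times = n_rec),
    deck = deck, gain = gain, loss = loss)

  truth <- structure(
    list(config = config, subjects = subjects,
         missing_session2 = subjects[missing],
         parameters = truth_tbl, seed = as.integer(seed)),
    class = "synthetic_truth")
  structure(list(cohort = validate_cohort(cohort), truth = truth,
                 covariates = NULL),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>", length(x$truth$subjects), "subjects,",
      x$truth$config$n_trials, "trials/session,",
      length(x$truth$missing_session2), "missing session 2\n")
  invisible(x)
}

#' Synthetic covariates linearly loaded on true parameters
#'
#' Emulates the self-report layer for validity testing: each covariate is
#' `loading * standardize(true raw parameter) + Normal(0, noise_sd)`,
#' standardized to mean 0 and SD 1. With `noise_sd = sqrt(1 - loading^2)`
#' the population correlation with the true parameter equals `loading`.
#'
#' @param truth a `synthetic_truth` (from [generate_cohort()]).
#' @param spec tibble with columns `covariate`, `parameter`, `session`,
#'   `loading`, `noise_sd`.
#' @param seed optional integer seed.
#' @return Tibble with `subject` plus one column per covariate; also stored
#'   when called through a bundle.
#' @export
generate_covariates <- function(truth, spec, seed = NULL) {
  if (inherits(truth, "cohort_bundle")) truth <- truth$truth
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.null(seed)) set.seed(seed)
  out <- tibble::tibble(subject = truth$subjects)
  for (j in seq_len(nrow(spec))) {
    sel <- truth$parameters |>
      dplyr::filter(.data$parameter == spec$parameter[j],
                    .data$session == spec$session[j]) |>
      dplyr::arrange(match(.data$subject, truth$subjects))
    if (nrow(sel) == 0)
      abort(paste0("unknown target parameter: ", spec$parameter[j]))
    base <- as.numeric(scale(sel$raw))
    v <- spec$loading[j] * base + rnorm(length(base), 0, spec$noise_sd[j])
    out[[spec$covariate[j]]] <- as.numeric(scale(v))
  }
  out
}

#' Empirical summary-score retest correlation implied by a scenario
#'
#' The "theta-scale" truth for the summary score is the correlation of the
#' subjects' expected good-deck proportions across sessions. It has no
#' closed form under the ORL, so it is calibrated empirically: each
#' subject-session's expected score is approximated by averaging over `reps`
#' independent play-throughs at the true parameters.
#'
#' @param config a [scenario_config()].
#' @param n_subjects calibration cohort size.
#' @param reps play-throughs averaged per subject-session.
#' @param seed integer seed.
#' @param good_decks decks counted as good.
#' @return The calibrated correlation (a single number).
#' @export
calibrate_score_retest <- function(config = scenario_config(),
                                   n_subjects = 300, reps = 10, seed = 1,
                                   good_decks = c("C", "D")) {
  cfg <- config
  cfg$n <- as.integer(n_subjects)
  cfg$missing_session2 <- 0L
  set.seed(seed)
  pn <- orl_param_names()
  good <- deck_index(good_decks)
  sched <- default_schedule()
  kmax <- cfg$control$K_prime_max
  scores <- matrix(NA_real_, n_subjects, 2)
  for (i in seq_len(n_subjects)) {
    z1 <- rnorm(5); z2 <- rnorm(5)
    for (s in 1:2) {
      raw <- vapply(seq_along(pn), function(p) {
        w <- sqrt(1 - cfg$r[[p]]^2)
        if (s == 1) cfg$mu[p, 1] + cfg$sigma[p, 1] * z1[p]
        else cfg$mu[p, 2] + cfg$sigma[p, 2] * (cfg$r[[p]] * z1[p] + w * z2[p])
      }, numeric(1))
      names(raw) <- pn
      nat <- raw_to_natural(raw, kmax)
      par <- orl_parameters(A_rew = nat[["A_rew"]], A_pun = nat[["A_pun"]],
                            K_prime = nat[["K_prime"]],
                            beta_f = nat[["beta_f"]],
                            beta_p = nat[["beta_p"]], K_prime_max = kmax)
      scores[i, s] <- mean(vapply(seq_len(reps), function(rp) {
        sim <- simulate_session(par, sched, n_trials = cfg$n_trials,
                                scale = cfg$control$scale)
        mean(sim$deck %in% good)
      }, numeric(1)))
    }
  }
  cor(scores[, 1], scores[, 2])
}

#' Persist / load a cohort bundle as plain-text artifacts
#'
#' Writes `cohort.csv` (the trial-level dialect of [write_cohort()]),
#' `truth.json` (generating configuration and per-subject truths) and, when
#' present, `covariates.csv`.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return `write_cohort_bundle()` returns `dir`; `read_cohort_bundle()`
#'   the re-assembled bundle.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(bundle$cohort, file.path(dir, "cohort.csv"))
  tr <- bundle$truth
  truth_json <- list(
    seed = tr$seed,
    n = tr$config$n, n_trials = tr$config$n_trials,
    missing_session2 = tr$missing_session2,
    note = "synthetic cohort; generating values are package conventions, not study estimates",
    mu = list(s1 = as.list(tr$config$mu[, 1]),
              s2 = as.list(tr$config$mu[, 2])),
    sigma = list(s1 = as.list(tr$config$sigma[, 1]),
                 s2 = as.list(tr$config$sigma[, 2])),
    r = as.list(tr$config$r),
    control = unclass(tr$config$control),
    parameters = tr$parameters)
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  if (!is.null(bundle$covariates))
    readr::write_csv(bundle$covariates, file.path(dir, "covariates.csv"))
  invisible(dir)
}

#' @rdname write_cohort_bundle
#' @export
read_cohort_bundle <- function(dir) {
  cohort <- read_cohort(file.path(dir, "cohort.csv"))
  tj <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  pn <- orl_param_names()
  config <- scenario_config(
    n = tj$n, n_trials = tj$n_trials,
    mu = matrix(c(unlist(tj$mu$s1[pn]), unlist(tj$mu$s2[pn])), 5, 2,
                dimnames = list(pn, NULL)),
    sigma = matrix(c(unlist(tj$sigma$s1[pn]), unlist(tj$sigma$s2[pn])), 5, 2,
                   dimnames = list(pn, NULL)),
    r = unlist(tj$r),
    missing_session2 = length(tj$missing_session2),
    control = orl_control(scale = tj$control$scale,
                          K_prime_max = tj$control$K_prime_max))
  params <- tibble::as_tibble(tj$parameters)
  truth <- structure(
    list(config = config, subjects = unique(params$subject),
         missing_session2 = as.character(tj$missing_session2),
         parameters = params, seed = tj$seed),
    class = "synthetic_truth")
  cov_path <- file.path(dir, "covariates.csv")
  covariates <- if (file.exists(cov_path))
    readr::read_csv(cov_path, show_col_types = FALSE) else NULL
  structure(list(cohort = cohort, truth = truth, covariates = covariates),
            class = "cohort_bundle")
}
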
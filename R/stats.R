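#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (>= 3), both non-constant.
#' @return The correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input: correlation undefined")
  cor(x, y)
}

new_interval_estimate <- function(statistic, lo, hi, level, kind,
                                  B = NA_integer_, seed = NA_integer_) {
  tibble::tibble(statistic = statistic, lo = lo, hi = hi, level = level,
                 kind = kind, B = B, seed = seed)
}

#' BCa bootstrap confidence interval for a paired statistic
#'
#' Bias-corrected and accelerated bootstrap interval. The bias correction is
#' `z0 = qnorm(#{stat* < stat_obs} / B)` (ties broken by strict `<` by
#' default; set `ties = "leq"` for `<=`), the acceleration `a` comes from the
#' jackknife skewness of leave-one-out statistics, and the endpoints are the
#' bootstrap quantiles at the adjusted levels
#' `pnorm(z0 + (z0 + z_alpha) / (1 - a * (z0 + z_alpha)))`. If the bootstrap
#' distribution is degenerate (all replicates equal) or the bias correction
#' is unbounded, the interval falls back to plain percentile endpoints with a
#' warning.
#'
#' @param x,y paired numeric vectors.
#' @param stat function of `(x, y)` returning a scalar (default [pearson()]).
#' @param B number of bootstrap replicates (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed for the resampling.
#' @param ties `"strict"` (default) or `"leq"`: how replicates equal to the
#'   observed statistic enter the bias-correction count.
#' @return A one-row tibble: `statistic`, `lo`, `hi`, `level`, `kind`
#'   (`"BCa"`, or `"percentile"` after a degenerate fallback), `B`, `seed`.
#' @export
bca_ci <- function(x, y, stat = pearson, B = 10000, level = 0.95,
                   seed = NULL, ties = c("strict", "leq")) {
  ties <- match.arg(ties)
  n <- length(x)
  if (length(y) != n) abort("x and y must have equal length")
  if (B < 100) abort("B must be >= 100")
  if (!is.null(seed)) set.seed(seed)

  obs <- stat(x, y)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  th <- vapply(seq_len(B), function(b) {
    i <- idx[b, ]
    tryCatch(stat(x[i], y[i]), error = function(e) NA_real_)
  }, numeric(1))
  th <- th[is.finite(th)]
  if (length(th) < B * 0.5)
    abort("too many degenerate bootstrap replicates")

  alpha <- (1 - level) / 2
  if (max(th) - min(th) < 1e-12) {
    warn("degenerate bootstrap distribution; falling back to percentile")
    q <- quantile(th, c(alpha, 1 - alpha), names = FALSE, type = 6)
    return(new_interval_estimate(obs, q[1], q[2], level, "percentile",
                                 length(th), seed %||% NA_integer_))
  }

  prop <- if (ties == "strict") mean(th < obs) else mean(th <= obs)
  z0 <- qnorm(prop)
  if (!is.finite(z0)) {
    warn("unbounded bias correction; falling back to percentile")
    q <- quantile(th, c(alpha, 1 - alpha), names = FALSE, type = 6)
    return(new_interval_estimate(obs, q[1], q[2], level, "percentile",
                                 length(th), seed %||% NA_integer_))
  }

  # jackknife acceleration
  jk <- vapply(seq_len(n), function(i) stat(x[-i], y[-i]), numeric(1))
  d <- mean(jk) - jk
  denom <- sum(d^2)^1.5
  a <- if (denom == 0) 0 else sum(d^3) / (6 * denom)

  zq <- qnorm(c(alpha, 1 - alpha))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  q <- quantile(th, adj, names = FALSE, type = 6)
  new_interval_estimate(obs, q[1], q[2], level, "BCa", length(th),
                        seed %||% NA_integer_)
}

#' Highest density interval of a sample
#'
#' Shortest contiguous interval containing `ceiling(mass * N)` of the sorted
#' draws: every point inside is at least as probable as every point outside
#' (for a unimodal posterior).
#'
#' @param draws numeric vector of posterior draws (>= 100 for `mass < 1`).
#' @param mass probability mass to cover (default 0.95).
#' @return A one-row tibble: `statistic` (the sample mean), `lo`, `hi`,
#'   `level`, `kind = "HDI"`, `B` (the draw count).
#' @export
hdi <- function(draws, mass = 0.95) {
  draws <- sort(draws[is.finite(draws)])
  n <- length(draws)
  if (n == 0) abort("no finite draws")
  k <- min(n, ceiling(mass * n))
  if (k == n) {
    lo <- draws[1]; hi <- draws[n]
  } else {
    width <- draws[k:n] - draws[1:(n - k + 1)]
    i <- which.min(width)
    lo <- draws[i]; hi <- draws[i + k - 1]
  }
  new_interval_estimate(mean(draws), lo, hi, mass, "HDI", n)
}

#' Split R-hat convergence diagnostic
#'
#' Rank-normalized split R-hat: chains are halved, pooled draws are replaced
#' by their normal scores `qnorm((rank - 3/8) / (N + 1/4))`, and the classic
#' between/within variance ratio is computed on the half-chains. The legacy
#' (non rank-normalized) variant is available via `method = "classic"`.
#' Values near 1 indicate mixing; fits are conventionally flagged at 1.1.
#'
#' @param draws matrix of draws (iterations x chains), or a list of equal
#'   length numeric vectors, one per chain.
#' @param method `"rank"` (default) or `"classic"`.
#' @return R-hat (a single number; `Inf` if a split chain is constant while
#'   others are not).
#' @export
split_rhat <- function(draws, method = c("rank", "classic")) {
  method <- match.arg(method)
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  n <- nrow(draws)
  if (ncol(draws) < 2) abort("need >= 2 chains")
  if (n < 4) abort("need >= 4 iterations per chain")
  half <- n %/% 2L
  split <- cbind(draws[seq_len(half), , drop = FALSE],
                 draws[(n - half + 1):n, , drop = FALSE])
  if (all(split == split[1])) return(1)  # all-constant: nothing to diagnose
  if (method == "rank") {
    r <- rank(split, ties.method = "average")
    z <- qnorm((r - 3 / 8) / (length(split) + 1 / 4))
    split <- matrix(z, nrow = half)
  }
  m <- ncol(split)
  means <- colMeans(split)
  vars <- apply(split, 2, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W == 0) return(Inf)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Posterior predictive check of good-deck choice
#'
#' For `n_rep` posterior draws, simulates complete replicated datasets from
#' the fitted model (trial-level ORL play-throughs for the hierarchical ORL
#' fits; binomial counts for the good-deck probability model) and compares
#' block-wise observed good-deck proportions with their posterior predictive
#' distribution.
#'
#' @param fit an [hb_fit] (model 2, 3 or 4).
#' @param cohort the observed cohort the fit was estimated from.
#' @param n_rep number of posterior draws to simulate (default 100).
#' @param seed optional integer seed.
#' @param block_size trials per block (default 10).
#' @param level predictive interval level (default 0.95).
#' @param good_decks decks counted as good.
#' @param schedule payoff schedule for replicated play-throughs.
#' @return A `ppc_report` tibble: per (session, block) the observed good-deck
#'   proportion, predictive mean and interval, and a coverage flag. With
#'   `n_rep = 1` the zero-width intervals are flagged with a warning.
#' @export
posterior_predictive_check <- function(fit, cohort, n_rep = 100, seed = NULL,
                                       block_size = 10, level = 0.95,
                                       good_decks = c("C", "D"),
                                       schedule = default_schedule()) {
  stopifnot(inherits(fit, "hb_fit"))
  cohort <- validate_cohort(cohort)
  if (!is.null(seed)) set.seed(seed)
  if (n_rep < 1) abort("n_rep must be >= 1")
  good <- deck_index(good_decks)
  alpha <- (1 - level) / 2

  obs <- cohort |>
    dplyr::mutate(block = (.data$trial - 1) %/% block_size + 1) |>
    dplyr::group_by(.data$session, .data$block) |>
    dplyr::summarise(observed = mean(.data$deck %in% good), .groups = "drop")

  pooled <- as_draws_matrix(fit)
  take <- sample.int(nrow(pooled), n_rep, replace = n_rep > nrow(pooled))

  info <- fit$data_info
  sim_one <- function(draw) {
    sims <- purrr::map_dfr(seq_len(nrow(info)), function(j) {
      sub <- info$subject[j]; ses <- info$session[j]
      n_tr <- info$n_trials[j]
      if (fit$model == "m2") {
        theta <- draw[[sprintf("theta[%d,%d]", info$index[j], ses)]]
        k <- stats::rbinom(n_tr, 1, theta)
        tibble::tibble(session = ses,
                       trial = seq_len(n_tr),
                       good = k)
      } else {
        par <- orl_parameters(
          A_rew = draw[[sprintf("A_rew[%d,%d]", info$index[j], ses)]],
          A_pun = draw[[sprintf("A_pun[%d,%d]", info$index[j], ses)]],
          K_prime = draw[[sprintf("K_prime[%d,%d]", info$index[j], ses)]],
          beta_f = draw[[sprintf("beta_f[%d,%d]", info$index[j], ses)]],
          beta_p = draw[[sprintf("beta_p[%d,%d]", info$index[j], ses)]],
          K_prime_max = fit$control$K_prime_max)
        s <- simulate_session(par, schedule, n_trials = n_tr,
                              scale = fit$control$scale)
        tibble::tibble(session = ses, trial = s$trial,
                       good = as.integer(s$deck %in% good))
      }
    })
    sims |>
      dplyr::mutate(block = (.data$trial - 1) %/% block_size + 1) |>
      dplyr::group_by(.data$session, .data$block) |>
      dplyr::summarise(p = mean(.data$good), .groups = "drop")
  }

  reps <- purrr::map_dfr(take, function(d) {
    sim_one(as.list(pooled[d, ])) |> dplyr::mutate(rep = d)
  })
  pred <- reps |>
    dplyr::group_by(.data$session, .data$block) |>
    dplyr::summarise(pred_mean = mean(.data$p),
                     lo = quantile(.data$p, alpha, names = FALSE),
                     hi = quantile(.data$p, 1 - alpha, names = FALSE),
                     .groups = "drop")
  out <- dplyr::inner_join(obs, pred, by = c("session", "block")) |>
    dplyr::mutate(covered = .data$observed >= .data$lo &
                    .data$observed <= .data$hi)
  if (n_rep == 1)
    warn("n_rep = 1: predictive intervals are degenerate (zero width)")
  class(out) <- c("ppc_report", class(out))
  attr(out, "n_rep") <- n_rep
  out
}

#' Two-step correlations between person-level estimates and covariates
#'
#' Construct-validity machinery: Pearson correlations with BCa intervals
#' between per-subject behavioral estimates and external covariates (e.g.
#' self-report scores), using pairwise-complete observations joined on
#' `subject`.
#'
#' @param person_estimates tibble with a `subject` column and one numeric
#'   column per behavioral estimate.
#' @param covariates tibble with a `subject` column and one numeric column
#'   per covariate.
#' @param B bootstrap replicates for the BCa intervals.
#' @param seed optional integer seed.
#' @param level confidence level.
#' @return Tibble with one row per (estimate, covariate) pair: `n`, `r`,
#'   `lo`, `hi`, `kind`, and `excludes_zero`. Pairs with fewer than 8
#'   complete observations are kept but flagged with a warning.
#' @export
covariate_correlations <- function(person_estimates, covariates, B = 2000,
                                   seed = NULL, level = 0.95) {
  if (!is.null(seed)) set.seed(seed)
  est_cols <- setdiff(names(person_estimates), "subject")
  cov_cols <- setdiff(names(covariates), "subject")
  joined <- dplyr::inner_join(person_estimates, covariates, by = "subject")
  purrr::map_dfr(est_cols, function(e) {
    purrr::map_dfr(cov_cols, function(cv) {
      ok <- stats::complete.cases(joined[[e]], joined[[cv]])
      n <- sum(ok)
      if (n < 8) {
        warn(paste0("fewer than 8 complete pairs for (", e, ", ", cv, ")"))
        return(tibble::tibble(estimate = e, covariate = cv, n = n,
                              r = NA_real_, lo = NA_real_, hi = NA_real_,
                              kind = NA_character_, excludes_zero = NA))
      }
      ci <- bca_ci(joined[[e]][ok], joined[[cv]][ok], B = B, level = level)
      tibble::tibble(estimate = e, covariate = cv, n = n,
                     r = ci$statistic, lo = ci$lo, hi = ci$hi, kind = ci$kind,
                     excludes_zero = ci$lo > 0 | ci$hi < 0)
    })
  })
}
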
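#' ORL person-level parameters
#'
#' The Outcome-Representation Learning model has five free parameters:
#' reward and punishment learning rates `A_rew`, `A_pun` in \[0, 1\], the
#' memory-decay parameter `K = 3^K_prime - 1 >= 0` (with `K_prime` in
#' \[0, K_prime_max\]), and the unbounded win-frequency and perseveration
#' weights `beta_f`, `beta_p`. Learning rates and `K_prime` live on a probit
#' ("raw") scale in the hierarchical models; `raw_to_natural()` and
#' `natural_to_raw()` map between the two scales.
#'
#' @param A_rew,A_pun learning rates in \[0, 1\].
#' @param K_prime raw decay in \[0, K_prime_max\] (supply this or `K`).
#' @param K decay `>= 0`; converted to `K_prime` via `log3(K + 1)`.
#' @param beta_f,beta_p win-frequency and perseveration weights.
#' @param K_prime_max upper bound of `K_prime` (default 5, so `K <= 242`).
#' @return An `orl_parameters` list with both `K` and `K_prime`.
#' @examples
#' orl_parameters(A_rew = 0.3, A_pun = 0.1, K_prime = 0.5,
#'                beta_f = 1.5, beta_p = 0.8)
#' @export
orl_parameters <- function(A_rew, A_pun, K_prime = NULL, beta_f, beta_p,
                           K = NULL, K_prime_max = 5) {
  if (is.null(K_prime) && is.null(K))
    abort("supply K_prime or K")
  if (is.null(K_prime)) K_prime <- log(K + 1, base = 3)
  K <- 3^K_prime - 1
  if (A_rew < 0 || A_rew > 1 || A_pun < 0 || A_pun > 1)
    abort("learning rates must lie in [0, 1]")
  if (K_prime < 0 || K_prime > K_prime_max)
    abort(paste0("K_prime must lie in [0, ", K_prime_max, "]"))
  structure(list(A_rew = A_rew, A_pun = A_pun, K_prime = K_prime, K = K,
                 beta_f = beta_f, beta_p = beta_p,
                 K_prime_max = K_prime_max),
            class = "orl_parameters")
}

as_orl_parameters <- function(params, K_prime_max = 5) {
  if (inherits(params, "orl_parameters")) return(params)
  p <- as.list(params)
  orl_parameters(A_rew = p$A_rew, A_pun = p$A_pun, K_prime = p$K_prime,
                 K = p$K, beta_f = p$beta_f, beta_p = p$beta_p,
                 K_prime_max = K_prime_max)
}

#' @export
print.orl_parameters <- function(x, ...) {
  cat(sprintf(
    "<orl_parameters> A_rew=%.3f A_pun=%.3f K=%.3f (K'=%.3f) beta_f=%.3f beta_p=%.3f\n",
    x$A_rew, x$A_pun, x$K, x$K_prime, x$beta_f, x$beta_p))
  invisible(x)
}

#' Map ORL parameters between raw (unconstrained) and natural scale
#'
#' Learning rates map through the standard normal CDF (`A = pnorm(raw)`),
#' `K_prime` through `K_prime_max * pnorm(raw)`, and the beta weights are
#' identical on both scales.
#'
#' @param raw,natural named numeric vector with elements `A_rew`, `A_pun`,
#'   `K_prime`, `beta_f`, `beta_p`.
#' @param K_prime_max upper bound for `K_prime`.
#' @return Named numeric vector on the other scale.
#' @export
raw_to_natural <- function(raw, K_prime_max = 5) {
  raw <- raw[orl_param_names()]
  c(A_rew = stats::pnorm(raw[["A_rew"]]),
    A_pun = stats::pnorm(raw[["A_pun"]]),
    K_prime = K_prime_max * stats::pnorm(raw[["K_prime"]]),
    beta_f = raw[["beta_f"]], beta_p = raw[["beta_p"]])
}

#' @rdname raw_to_natural
#' @export
natural_to_raw <- function(natural, K_prime_max = 5) {
  natural <- natural[orl_param_names()]
  c(A_rew = stats::qnorm(natural[["A_rew"]]),
    A_pun = stats::qnorm(natural[["A_pun"]]),
    K_prime = stats::qnorm(natural[["K_prime"]] / K_prime_max),
    beta_f = natural[["beta_f"]], beta_p = natural[["beta_p"]])
}

#' ORL learning-state bookkeeping
#'
#' `initial_state()` returns the pre-task state (all expected values,
#' expected win frequencies and perseverance weights zero).
#' `update_state()` advances it after one outcome, and `integrate_values()`
#' combines it into deck values `V = EV + EF * beta_f + PS * beta_p` and
#' softmax choice probabilities.
#'
#' On the chosen deck, `EV` and `EF` move toward the scaled net outcome and
#' its sign at rate `A_rew` on gain trials (`x >= 0`, which includes `x = 0`)
#' and `A_pun` on loss trials. On unchosen decks `EF` moves toward
#' `-sgn(x)/3` with the rates swapped. The chosen deck's perseverance weight
#' is set to `1/(1+K)` and the others decay by the same factor.
#'
#' @return `initial_state()`/`update_state()`: an `orl_state` list with
#'   4-vectors `EV`, `EF`, `PS`; `integrate_values()`: list with deck values
#'   `V` and choice probabilities `P` (strictly positive, summing to 1).
#' @export
initial_state <- function() {
  structure(list(EV = rep(0, 4), EF = rep(0, 4), PS = rep(0, 4)),
            class = "orl_state")
}

#' @param state an `orl_state`.
#' @param chosen chosen deck (1-4 or letter).
#' @param x scaled net outcome of the trial.
#' @param params [orl_parameters()] (or coercible named list).
#' @rdname initial_state
#' @export
update_state <- function(state, chosen, x, params) {
  params <- as_orl_parameters(params)
  out <- orl_state_step_cpp(state$EV, state$EF, state$PS, deck_index(chosen),
                            x, params$A_rew, params$A_pun, params$K)
  structure(out, class = "orl_state")
}

#' @rdname initial_state
#' @export
integrate_values <- function(state, params) {
  params <- as_orl_parameters(params)
  V <- state$EV + state$EF * params$beta_f + state$PS * params$beta_p
  e <- exp(V - max(V))
  list(V = V, P = e / sum(e))
}

#' ORL log-likelihood of one session
#'
#' Sequential log probability of the observed choice sequence: trial `t`
#' contributes the log softmax probability of the chosen deck given the state
#' built from trials `1..t-1` (so the first trial contributes `log(1/4)`),
#' and the state then advances on the scaled net outcome
#' `x = (gain + loss) / scale`.
#'
#' @param params [orl_parameters()] (or coercible named list).
#' @param session trials of one subject-session: tibble with columns `deck`,
#'   `gain`, `loss`.
#' @param scale monetary scaling of outcomes before they enter the learning
#'   equations (default 100).
#' @return Log-likelihood (a single non-positive number).
#' @export
session_log_likelihood <- function(params, session, scale = 100) {
  params <- as_orl_parameters(params)
  if (nrow(session) == 0) abort("empty session: no trials")
  if (scale <= 0) abort("scale must be > 0")
  x <- (session$gain + session$loss) / scale
  ll <- orl_session_loglik_cpp(deck_index(session$deck), x,
                               params$A_rew, params$A_pun, params$K,
                               params$beta_f, params$beta_p)
  if (!is.finite(ll)) {
    # locate the offending trial for the error message
    state <- initial_state()
    for (t in seq_len(nrow(session))) {
      p <- integrate_values(state, params)$P[deck_index(session$deck[t])]
      if (!is.finite(log(p)))
        abort(paste0("non-finite log-likelihood at trial ", t))
      state <- update_state(state, session$deck[t], x[t], params)
    }
    abort("non-finite log-likelihood")
  }
  ll
}

#' Simulate one IGT session from ORL parameters
#'
#' Plays `n_trials` through the task: each trial samples a deck from the
#' current softmax policy, deals the next card of that deck from the fixed
#' schedule (per-deck draw counts, cycling), and updates the learning state
#' on the scaled net outcome.
#'
#' @inheritParams session_log_likelihood
#' @param schedule a [payoff_schedule] (default the canonical task).
#' @param n_trials number of trials (default 100).
#' @param seed optional integer; if given, `set.seed()` is called first so
#'   the session is reproducible.
#' @return Tibble with columns `trial`, `deck`, `gain`, `loss`.
#' @export
simulate_session <- function(params, schedule = default_schedule(),
                             n_trials = 100, scale = 100, seed = NULL) {
  params <- as_orl_parameters(params)
  stopifnot(inherits(schedule, "payoff_schedule"), n_trials >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- orl_simulate_session_cpp(schedule$gain, schedule$loss,
                                  as.integer(n_trials),
                                  params$A_rew, params$A_pun, params$K,
                                  params$beta_f, params$beta_p, scale)
  tibble::tibble(trial = seq_len(n_trials), deck = out$deck,
                 gain = out$gain, loss = out$loss)
}
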
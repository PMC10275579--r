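# Independent straight-line implementations used as oracles. These are kept
# deliberately naive (explicit loops, no shared code with the package) so a
# defect in the package cannot hide in the oracle.

oracle_orl_loglik <- function(deck, gain, loss, A_rew, A_pun, K,
                              beta_f, beta_p, scale = 100) {
  EV <- rep(0, 4); EF <- rep(0, 4); PS <- rep(0, 4)
  ll <- 0
  for (t in seq_along(deck)) {
    V <- EV + beta_f * EF + beta_p * PS
    P <- exp(V) / sum(exp(V))
    ll <- ll + log(P[deck[t]])
    x <- (gain[t] + loss[t]) / scale
    s <- sign(x)
    if (x >= 0) { A_ch <- A_rew; A_un <- A_pun }
    else { A_ch <- A_pun; A_un <- A_rew }
    d <- deck[t]
    EV[d] <- EV[d] + A_ch * (x - EV[d])
    EF[d] <- EF[d] + A_ch * (s - EF[d])
    for (j in (1:4)[-d]) EF[j] <- EF[j] + A_un * (-s / 3 - EF[j])
    PS <- PS / (1 + K)
    PS[d] <- 1 / (1 + K)
  }
  ll
}

# Brute-force BCa endpoints. Draws the same resampling plan as bca_ci (an
# n x B index matrix from one sample.int call) so that, under a shared seed,
# endpoints are comparable to 3 decimals; the statistics (bias correction,
# jackknife acceleration, adjusted quantiles) are computed independently.
oracle_bca <- function(x, y, B, level = 0.95, seed) {
  set.seed(seed)
  n <- length(x)
  obs <- cor(x, y)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = B)
  th <- numeric(B)
  for (b in 1:B) th[b] <- cor(x[idx[b, ]], y[idx[b, ]])
  z0 <- qnorm(sum(th < obs) / B)
  jk <- numeric(n)
  for (i in 1:n) jk[i] <- cor(x[-i], y[-i])
  d <- mean(jk) - jk
  a <- sum(d^3) / (6 * sum(d^2)^1.5)
  alpha <- (1 - level) / 2
  zq <- qnorm(c(alpha, 1 - alpha))
  adj <- pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  quantile(th, adj, type = 6, names = FALSE)
}

random_orl_params <- function() {
  orl_parameters(A_rew = runif(1), A_pun = runif(1),
                 K_prime = runif(1, 0, 3),
                 beta_f = rnorm(1, 0, 2), beta_p = rnorm(1, 0, 2))
}

make_session <- function(deck, gain, loss) {
  tibble::tibble(trial = seq_along(deck), deck = deck, gain = gain,
                 loss = loss)
}

# cohort with exact per-subject-session good-deck counts (k out of n_trials),
# for exercising the binomial model against known theta structure
count_cohort <- function(k, n_trials, has2 = rep(TRUE, nrow(k))) {
  rows <- list()
  for (i in seq_len(nrow(k))) {
    for (s in 1:2) {
      if (s == 2 && !has2[i]) next
      good <- k[i, s]
      deck <- c(rep(3L, good), rep(1L, n_trials - good))
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject = sprintf("S%03d", i), session = s,
        trial = seq_len(n_trials), deck = deck,
        gain = 50, loss = 0)
    }
  }
  dplyr::bind_rows(rows)
}

# fits reused across test files
.fit_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (is.null(.fit_cache[[name]])) .fit_cache[[name]] <- force(expr)
  .fit_cache[[name]]
}
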
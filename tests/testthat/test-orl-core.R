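params_basic <- orl_parameters(A_rew = 0.5, A_pun = 0.3, K_prime = 0,
                               beta_f = 1, beta_p = 1)

test_that("initial state is zero and yields a uniform policy", {
  st <- initial_state()
  expect_equal(st$EV, rep(0, 4))
  expect_equal(st$EF, rep(0, 4))
  expect_equal(st$PS, rep(0, 4))
  pol <- integrate_values(st, params_basic)
  expect_equal(pol$P, rep(0.25, 4))
  expect_equal(pol$V, rep(0, 4))
  # zeros annihilate the weights regardless of the betas
  big <- orl_parameters(A_rew = 0.5, A_pun = 0.3, K_prime = 0,
                        beta_f = 50, beta_p = -50)
  expect_equal(integrate_values(st, big)$V, rep(0, 4))
})

test_that("state updates follow the learning equations", {
  st <- initial_state()
  # EV: chosen deck only, reward rate on the gain branch
  up <- update_state(st, 1, 1.0, params_basic)
  expect_equal(up$EV, c(0.5, 0, 0, 0))
  # EF: chosen toward sgn(x) at A_rew; unchosen toward -sgn(x)/3 at A_pun
  expect_equal(up$EF, c(0.5, -0.1, -0.1, -0.1))
  # loss branch swaps the rates
  dn <- update_state(st, 1, -1.0, params_basic)
  expect_equal(dn$EV, c(-0.3, 0, 0, 0))
  expect_equal(dn$EF[1], 0.3 * (-1 - 0))
  expect_equal(dn$EF[2], 0.5 * (1 / 3 - 0))
})

test_that("perseveration resets the chosen deck and decays the rest", {
  st <- initial_state()
  st$PS <- c(0.2, 0.8, 0, 0)
  k0 <- orl_parameters(A_rew = 0.5, A_pun = 0.3, K = 0, beta_f = 0,
                       beta_p = 0)
  expect_equal(update_state(st, 2, 1, k0)$PS, c(0.2, 1, 0, 0))
  k2 <- orl_parameters(A_rew = 0.5, A_pun = 0.3, K = 2, beta_f = 0,
                       beta_p = 0)
  expect_equal(update_state(st, 2, 1, k2)$PS, c(0.2 / 3, 1 / 3, 0, 0))
  # large K: all perseveration memory vanishes within one step
  kbig <- orl_parameters(A_rew = 0.5, A_pun = 0.3, K = 1e8, beta_f = 0,
                         beta_p = 0, K_prime_max = 20)
  expect_lt(max(update_state(st, 2, 1, kbig)$PS), 1e-7)
})

test_that("x = 0 takes the gain branch", {
  st <- initial_state()
  st$EF <- c(0.4, 0, 0, 0)
  # sgn(0) = 0, so EF of the chosen deck decays toward 0 at rate A_rew
  up <- update_state(st, 1, 0, params_basic)
  expect_equal(up$EF[1], 0.4 + 0.5 * (0 - 0.4))
  expect_equal(up$EV, rep(0, 4))
})

test_that("value integration is the stated linear combination", {
  st <- initial_state()
  st$EV <- c(1, 0, 0, 0)
  expect_equal(integrate_values(st, params_basic)$V, c(1, 0, 0, 0))
  st2 <- initial_state()
  st2$EF <- c(0.5, -0.1, -0.1, -0.1)
  p2 <- orl_parameters(A_rew = 0.5, A_pun = 0.3, K_prime = 0, beta_f = 2,
                       beta_p = 0)
  pol <- integrate_values(st2, p2)
  expect_equal(pol$V, c(1, -0.2, -0.2, -0.2))
  expect_equal(sum(pol$P), 1)
  expect_true(all(pol$P > 0))
  # beta_f = beta_p = 0 reduces V to expected value alone
  ev_only <- orl_parameters(A_rew = 0.5, A_pun = 0.3, K_prime = 1,
                            beta_f = 0, beta_p = 0)
  st3 <- initial_state()
  st3$EV <- c(0.3, -0.2, 0.1, 0)
  st3$EF <- c(0.9, 0.9, 0.9, 0.9)
  st3$PS <- c(1, 0, 0, 0)
  expect_equal(integrate_values(st3, ev_only)$V, st3$EV)
})

test_that("session log-likelihood has the right fixed points", {
  s1 <- make_session(2L, 100, 0)
  expect_equal(session_log_likelihood(params_basic, s1), log(0.25))
  inert <- orl_parameters(A_rew = 0, A_pun = 0, K_prime = 0, beta_f = 0,
                          beta_p = 0)
  s20 <- make_session(rep(c(1L, 3L), 10), rep(100, 20), rep(-50, 20))
  expect_equal(session_log_likelihood(inert, s20), 20 * log(0.25))
  expect_lte(session_log_likelihood(params_basic, s20), 0)
})

test_that("session log-likelihood matches the straight-line oracle", {
  set.seed(42)
  sched <- default_schedule()
  for (case in 1:100) {
    p <- random_orl_params()
    Tn <- sample(5:40, 1)
    s <- simulate_session(p, sched, n_trials = Tn)
    expect_equal(session_log_likelihood(p, s),
                 oracle_orl_loglik(s$deck, s$gain, s$loss, p$A_rew, p$A_pun,
                                   p$K, p$beta_f, p$beta_p),
                 tolerance = 1e-10)
  }
})

test_that("EF entries stay within [-1, 1]", {
  set.seed(7)
  for (rep in 1:20) {
    p <- random_orl_params()
    st <- initial_state()
    for (t in 1:50) {
      st <- update_state(st, sample(1:4, 1), rnorm(1, 0, 3), p)
      expect_true(all(st$EF >= -1 & st$EF <= 1))
      expect_true(all(st$PS >= 0 & st$PS <= 1))
    }
  }
})

test_that("perseveration weight drives stay/switch behavior in simulation", {
  sched <- default_schedule()
  stay <- orl_parameters(A_rew = 0, A_pun = 0, K_prime = 0, beta_f = 0,
                         beta_p = 10)
  s <- simulate_session(stay, sched, n_trials = 100, seed = 11)
  switch_rate <- mean(diff(s$deck[10:100]) != 0)
  expect_lt(switch_rate, 0.05)
  # with forgetting (K' = 1) a strongly negative beta_p avoids recent decks
  leave <- orl_parameters(A_rew = 0, A_pun = 0, K_prime = 1, beta_f = 0,
                          beta_p = -10)
  s2 <- simulate_session(leave, sched, n_trials = 100, seed = 11)
  expect_gt(mean(diff(s2$deck[10:100]) != 0), 0.95)
})

test_that("an inert agent chooses uniformly", {
  inert <- orl_parameters(A_rew = 0, A_pun = 0, K_prime = 0, beta_f = 0,
                          beta_p = 0)
  s <- simulate_session(inert, n_trials = 10000, seed = 3)
  gof <- chisq.test(table(factor(s$deck, levels = 1:4)))
  expect_gt(gof$p.value, 0.001)
})

test_that("simulation is reproducible given a seed", {
  p <- random_orl_params()
  expect_identical(simulate_session(p, n_trials = 50, seed = 99),
                   simulate_session(p, n_trials = 50, seed = 99))
})

test_that("simulated data is most likely near its generating parameters", {
  # self-consistency: over seeds, the generating parameters beat a
  # perturbation on average
  sched <- default_schedule()
  p <- orl_parameters(A_rew = 0.25, A_pun = 0.1, K_prime = 0.3,
                      beta_f = 1.5, beta_p = 1)
  pert <- orl_parameters(A_rew = 0.55, A_pun = 0.35, K_prime = 1.2,
                         beta_f = 0.2, beta_p = -0.5)
  diffs <- vapply(1:20, function(seed) {
    s <- simulate_session(p, sched, n_trials = 300, seed = seed)
    session_log_likelihood(p, s) - session_log_likelihood(pert, s)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("parameter scale mappings invert each other", {
  raw <- c(A_rew = -0.7, A_pun = 0.3, K_prime = -1.2, beta_f = 1.4,
           beta_p = -0.2)
  nat <- raw_to_natural(raw)
  expect_equal(natural_to_raw(nat), raw)
  expect_true(nat[["A_rew"]] > 0 && nat[["A_rew"]] < 1)
  expect_true(nat[["K_prime"]] >= 0 && nat[["K_prime"]] <= 5)
})
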
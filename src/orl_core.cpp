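#include <Rcpp.h>
using namespace Rcpp;

// Outcome-Representation Learning (ORL) trial-level model.
//
// State per deck j: EV (expected value), EF (expected win frequency),
// PS (perseverance weight). After observing scaled net outcome x on chosen
// deck d:
//   EV_d += A * (x - EV_d)            with A = A_rew if x >= 0 else A_pun
//   EF_d += A * (sgn(x) - EF_d)       same rate as EV
//   EF_j += A' * (-sgn(x)/3 - EF_j)   unchosen j, with the *other* rate
//                                     (A' = A_pun if x >= 0 else A_rew)
//   PS_d  = 1/(1+K); PS_j *= 1/(1+K)  for unchosen j
// Deck value V_j = EV_j + EF_j * beta_f + PS_j * beta_p, choice by softmax
// (no inverse temperature). x = 0 falls in the gain branch.

static inline double sgn0(double x) { return (x > 0) - (x < 0); }

static inline void orl_update(double *EV, double *EF, double *PS,
                              int d, double x,
                              double A_rew, double A_pun, double decay) {
  const double A_ch = (x >= 0.0) ? A_rew : A_pun;
  const double A_un = (x >= 0.0) ? A_pun : A_rew;
  const double s = sgn0(x);
  EV[d] += A_ch * (x - EV[d]);
  EF[d] += A_ch * (s - EF[d]);
  for (int j = 0; j < 4; ++j) {
    if (j == d) continue;
    EF[j] += A_un * (-s / 3.0 - EF[j]);
    PS[j] *= decay;
  }
  PS[d] = decay;
}

static inline void orl_values(const double *EV, const double *EF,
                              const double *PS, double beta_f, double beta_p,
                              double *V) {
  for (int j = 0; j < 4; ++j) V[j] = EV[j] + EF[j] * beta_f + PS[j] * beta_p;
}

// log-likelihood of one session's choice sequence; x is the scaled net outcome
double orl_loglik_raw(const int *deck, const double *x, int T,
                      double A_rew, double A_pun, double K,
                      double beta_f, double beta_p) {
  double EV[4] = {0, 0, 0, 0}, EF[4] = {0, 0, 0, 0}, PS[4] = {0, 0, 0, 0};
  double V[4];
  const double decay = 1.0 / (1.0 + K);
  double ll = 0.0;
  for (int t = 0; t < T; ++t) {
    orl_values(EV, EF, PS, beta_f, beta_p, V);
    double vmax = V[0];
    for (int j = 1; j < 4; ++j) if (V[j] > vmax) vmax = V[j];
    double se = 0.0;
    for (int j = 0; j < 4; ++j) se += std::exp(V[j] - vmax);
    const int d = deck[t] - 1;
    ll += V[d] - vmax - std::log(se);
    orl_update(EV, EF, PS, d, x[t], A_rew, A_pun, decay);
  }
  return ll;
}

// [[Rcpp::export]]
double orl_session_loglik_cpp(IntegerVector deck, NumericVector x,
                              double A_rew, double A_pun, double K,
                              double beta_f, double beta_p) {
  if (deck.size() != x.size()) stop("deck and x must have equal length");
  return orl_loglik_raw(deck.begin(), x.begin(), deck.size(),
                        A_rew, A_pun, K, beta_f, beta_p);
}

// Trial-by-trial bookkeeping used by the pure-R oracle-facing surface:
// returns EV/EF/PS/V/P trajectories so update_state()/integrate_values()
// can be exposed without duplicating the recursion in R.
// [[Rcpp::export]]
List orl_state_step_cpp(NumericVector EV, NumericVector EF, NumericVector PS,
                        int chosen, double x,
                        double A_rew, double A_pun, double K) {
  if (chosen < 1 || chosen > 4) stop("chosen deck must be in 1..4");
  double ev[4], ef[4], ps[4];
  for (int j = 0; j < 4; ++j) { ev[j] = EV[j]; ef[j] = EF[j]; ps[j] = PS[j]; }
  orl_update(ev, ef, ps, chosen - 1, x, A_rew, A_pun, 1.0 / (1.0 + K));
  return List::create(_["EV"] = NumericVector(ev, ev + 4),
                      _["EF"] = NumericVector(ef, ef + 4),
                      _["PS"] = NumericVector(ps, ps + 4));
}

// Forward simulation of one session on a fixed payoff schedule.
// gains/losses: (cards x 4) matrices; draws cycle modulo the deck length.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List orl_simulate_session_cpp(NumericMatrix gains, NumericMatrix losses,
                              int T, double A_rew, double A_pun, double K,
                              double beta_f, double beta_p, double scale) {
  const int len = gains.nrow();
  if (losses.nrow() != len || gains.ncol() != 4 || losses.ncol() != 4)
    stop("schedule matrices must be (cards x 4)");
  IntegerVector deck(T);
  NumericVector gain(T), loss(T);
  double EV[4] = {0, 0, 0, 0}, EF[4] = {0, 0, 0, 0}, PS[4] = {0, 0, 0, 0};
  double V[4], P[4];
  int count[4] = {0, 0, 0, 0};
  const double decay = 1.0 / (1.0 + K);
  for (int t = 0; t < T; ++t) {
    orl_values(EV, EF, PS, beta_f, beta_p, V);
    double vmax = V[0];
    for (int j = 1; j < 4; ++j) if (V[j] > vmax) vmax = V[j];
    double se = 0.0;
    for (int j = 0; j < 4; ++j) { P[j] = std::exp(V[j] - vmax); se += P[j]; }
    // inverse-CDF draw over ordered deck indices
    double u = unif_rand() * se, acc = 0.0;
    int d = 3;
    for (int j = 0; j < 4; ++j) {
      acc += P[j];
      if (u <= acc) { d = j; break; }
    }
    const int card = count[d] % len;
    count[d] += 1;
    deck[t] = d + 1;
    gain[t] = gains(card, d);
    loss[t] = losses(card, d);
    orl_update(EV, EF, PS, d, (gain[t] + loss[t]) / scale, A_rew, A_pun, decay);
  }
  return List::create(_["deck"] = deck, _["gain"] = gain, _["loss"] = loss);
}
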
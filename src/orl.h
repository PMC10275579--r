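#ifndef IGTRETEST_ORL_H
#define IGTRETEST_ORL_H

double orl_loglik_raw(const int *deck, const double *x, int T,
                      double A_rew, double A_pun, double K,
                      double beta_f, double beta_p);

#endif
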
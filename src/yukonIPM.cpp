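// Joint negative log posterior of the integrated life-cycle model.
// Mirrors the R-side process model (simulate_population), observation model
// (joint_loglik), priors (log_prior) and transform Jacobians exactly; the
// R test suite asserts that decomposition.
#define TMB_LIB_INIT R_init_yukonIPM
#include <TMB.hpp>

template <class Type>
Type invlogit_(Type x) { return Type(1) / (Type(1) + exp(-x)); }

template <class Type>
Type objective_function<Type>::operator()()
{
  // ---- data ----------------------------------------------------------
  DATA_VECTOR(J);      DATA_IVECTOR(fJ);
  DATA_VECTOR(E);      DATA_IVECTOR(fE);
  DATA_VECTOR(C);      DATA_IVECTOR(fC);
  DATA_VECTOR(b);      DATA_IVECTOR(fb);
  DATA_MATRIX(cntE);   DATA_IVECTOR(fqE);   // counts over ages 4-7
  DATA_MATRIX(cntC);   DATA_IVECTOR(fqC);
  DATA_MATRIX(cntB);   DATA_IVECTOR(fqB);   // counts over ages 3-6
  DATA_MATRIX(gx);     DATA_MATRIX(gn);     // genetic assignments / samples
  DATA_SCALAR(sigma_J); DATA_SCALAR(sigma_E);
  DATA_SCALAR(sigma_C); DATA_SCALAR(sigma_b);
  DATA_VECTOR(mu_N0);  DATA_VECTOR(mu_R0);  DATA_SCALAR(sd_init);
  DATA_SCALAR(S_ref);  // reference spawner level for the Ricker rotation

  // ---- parameters (unconstrained; order mirrors pack_parameters) -----
  PARAMETER(u_prod);          // log juveniles-per-spawner at S_ref
  PARAMETER(u_beta);
  PARAMETER(log_sigma_R);
  PARAMETER(log_sigma_M);
  PARAMETER(log_sigma_B);
  PARAMETER(log_sigma_T);
  PARAMETER(log_sigma_lam);
  PARAMETER_VECTOR(u_sB);     // 4, ages 3-6
  PARAMETER_VECTOR(u_v);      // 4, ages 4-7
  PARAMETER_VECTOR(u_sT);     // 4, ages 4-7
  PARAMETER(u_lam_init);
  // centred random-walk states: the mortality/harvest series are strongly
  // data-informed, so their log levels are parameters and the walk enters
  // as a difference prior (unit Jacobian vs the init+innovation form)
  PARAMETER_VECTOR(lM);       // T, log natural mortality
  PARAMETER_VECTOR(lFB);      // T, log bycatch mortality
  PARAMETER_VECTOR(lFT);      // T, log harvest mortality
  PARAMETER_VECTOR(z_lam);    // ncoh-1 (weakly informed: non-centred)
  PARAMETER_VECTOR(eps_R);    // T-2 recruitment errors (centred)
  PARAMETER_VECTOR(log_N0);   // 5, ages 2-6 of virtual year 0
  PARAMETER_VECTOR(log_R_init); // 2
  PARAMETER_VECTOR(muG);      // 4, ages 3-6
  PARAMETER_VECTOR(log_sigmaG);
  PARAMETER_VECTOR(lv_G);     // 4*T logit stock proportions, age-major

  int T = J.size();
  int ncoh = z_lam.size() + 1;
  Type nll = 0;
  const Type half = Type(0.5);

  // ---- transforms + Jacobian adjustments -----------------------------
  // (u_prod, u_beta) -> (log_alpha, beta) is triangular with det = beta:
  // the log-productivity axis is rotated to the data-informed direction
  Type beta = exp(u_beta);
  Type log_alpha = u_prod + beta * S_ref;
  Type sigma_R = exp(log_sigma_R), sigma_M = exp(log_sigma_M);
  Type sigma_B = exp(log_sigma_B), sigma_T = exp(log_sigma_T);
  Type sigma_lam = exp(log_sigma_lam);
  nll -= u_beta + log_sigma_R + log_sigma_M + log_sigma_B + log_sigma_T +
         log_sigma_lam;

  vector<Type> sB(4), v4(4), sT(4), sigmaG(4);
  for (int i = 0; i < 4; i++) {
    sB(i) = invlogit_(u_sB(i));
    nll -= log(sB(i)) + log(Type(1) - sB(i));
    Type pv = invlogit_(u_v(i));
    v4(i) = half + half * pv;
    nll -= log(half) + log(pv) + log(Type(1) - pv);
    sT(i) = invlogit_(u_sT(i));
    nll -= log(sT(i)) + log(Type(1) - sT(i));
    sigmaG(i) = exp(log_sigmaG(i));
    nll -= log_sigmaG(i);
  }
  Type log_lam1 = exp(u_lam_init);
  nll -= u_lam_init;

  // ---- priors (natural scale, truncation constants included) ---------
  Type LOG2 = log(Type(2));
  Type c01 = -log(pnorm(Type(1)) - pnorm(Type(0)));   // N(0,1) on [0,1]
  Type cV  = -log(pnorm(Type(1)) - pnorm(half));      // N(0,1) on [0.5,1]
  Type cLam = -log(pnorm(Type(1)));                   // N(1,1) on [0,inf)
  nll -= dnorm(log_alpha, Type(0), Type(12.5), true);
  nll -= dnorm(beta, Type(0), Type(5), true) + LOG2;
  nll -= dnorm(sigma_R, Type(0), Type(5), true) + LOG2;
  nll -= dnorm(sigma_M, Type(0), Type(5), true) + LOG2;
  nll -= dnorm(sigma_B, Type(0), Type(5), true) + LOG2;
  nll -= dnorm(sigma_T, Type(0), Type(5), true) + LOG2;
  nll -= dnorm(sigma_lam, Type(0), Type(5), true) + LOG2;
  for (int i = 0; i < 4; i++) {
    nll -= dnorm(sB(i), Type(0), Type(1), true) + c01;
    nll -= dnorm(v4(i), Type(0), Type(1), true) + cV;
    nll -= dnorm(sT(i), Type(0), Type(1), true) + c01;
    nll -= dnorm(muG(i), Type(0), Type(5), true);
    nll -= dnorm(sigmaG(i), Type(0), Type(5), true) + LOG2;
  }
  nll -= dnorm(lM(0), Type(0), Type(5), true);
  nll -= dnorm(lFB(0), Type(0), Type(7.5), true);
  nll -= dnorm(lFT(0), Type(0), Type(5), true);
  for (int y = 1; y < T; y++) {
    nll -= dnorm(lM(y) - lM(y - 1), Type(0), sigma_M, true);
    nll -= dnorm(lFB(y) - lFB(y - 1), Type(0), sigma_B, true);
    nll -= dnorm(lFT(y) - lFT(y - 1), Type(0), sigma_T, true);
  }
  nll -= dnorm(log_lam1, Type(1), Type(1), true) + cLam;
  nll -= dnorm(z_lam, Type(0), Type(1), true).sum();
  nll -= dnorm(eps_R, Type(0), sigma_R, true).sum();
  for (int i = 0; i < 5; i++)
    nll -= dnorm(log_N0(i), mu_N0(i), sd_init, true);
  for (int i = 0; i < 2; i++)
    nll -= dnorm(log_R_init(i), mu_R0(i), sd_init, true);

  // ---- random-walk rate series ---------------------------------------
  vector<Type> M = exp(lM), FB = exp(lFB), FT = exp(lFT);
  vector<Type> lam(ncoh);
  lam(0) = exp(log_lam1);
  for (int c = 1; c < ncoh; c++)
    lam(c) = exp(log(lam(c - 1)) + sigma_lam * z_lam(c - 1));

  // stock-composition proportions (centred: the assignment data are
  // typically strong, so the logits are parameters and the among-year
  // hierarchy enters as their prior-like density)
  matrix<Type> vt(T, 4);
  for (int a = 0; a < 4; a++)
    for (int y = 0; y < T; y++) {
      nll -= dnorm(lv_G(a * T + y), muG(a), sigmaG(a), true);
      vt(y, a) = invlogit_(lv_G(a * T + y));
    }

  // ---- population dynamics -------------------------------------------
  vector<Type> sB6(6);  // ages 2..7
  sB6(0) = 0; sB6(5) = 0;
  for (int i = 0; i < 4; i++) sB6(i + 1) = sB(i);
  vector<Type> v5(5);   // ages 3..7
  v5(0) = 1;
  for (int i = 0; i < 4; i++) v5(i + 1) = v4(i);

  matrix<Type> N(T, 6), A(T, 4), H(T, 4), S(T, 4), B(T, 4), BA(T, 4);
  vector<Type> S_total(T), Hsum(T), BAsum(T), run_size(T);
  vector<Type> N0e = exp(log_N0);
  Type k7 = log(Type(1) / Type(0.99) - Type(1));

  for (int y = 0; y < T; y++) {
    if (y < 2) {
      N(y, 0) = exp(log_R_init(y));
    } else {
      N(y, 0) = S_total(y - 2) *
        exp(log_alpha - beta * S_total(y - 2) + eps_R(y - 2));
    }
    for (int a = 3; a <= 7; a++) {
      int col = a - 2;
      Type Nprev = (y == 0) ? N0e(a - 3) : N(y - 1, col - 1);
      Type FBs = FB(y) * sB6(col);
      Type Z = FBs + M(y) * v5(a - 3);
      Type surv = Nprev * exp(-Z);
      Type theta = Type(0);
      if (a >= 4) {
        int c = y - (a - 2);
        if (c < 0) c = 0;
        if (c > ncoh - 1) c = ncoh - 1;
        theta = Type(1) / (Type(1) + exp(lam(c) * Type(7 - a) + k7));
        A(y, a - 4) = surv * theta;
      }
      N(y, col) = surv * (Type(1) - theta);
      if (a <= 6)
        B(y, a - 3) = (FBs / Z) * Nprev * (Type(1) - exp(-Z));
    }
    S_total(y) = 0; Hsum(y) = 0; BAsum(y) = 0; run_size(y) = 0;
    for (int i = 0; i < 4; i++) {
      H(y, i) = A(y, i) * (Type(1) - exp(-FT(y) * sT(i)));
      S(y, i) = A(y, i) - H(y, i);
      S_total(y) += S(y, i);
      Hsum(y) += H(y, i);
      run_size(y) += A(y, i);
      BA(y, i) = B(y, i) / vt(y, i);
      BAsum(y) += BA(y, i);
    }
  }

  // ---- observation likelihoods ---------------------------------------
  for (int y = 0; y < T; y++) {
    if (fJ(y))
      nll -= dnorm(log(J(y)), log(N(y, 0)), sigma_J, true) - log(J(y));
    if (fE(y))
      nll -= dnorm(log(E(y)), log(S_total(y)), sigma_E, true) - log(E(y));
    if (fC(y))
      nll -= dnorm(log(C(y)), log(Hsum(y)), sigma_C, true) - log(C(y));
    if (fb(y))
      nll -= dnorm(log(b(y)), log(BAsum(y)), sigma_b, true) - log(b(y));
    if (fqE(y)) {
      Type tot = 0, ll = 0;
      for (int i = 0; i < 4; i++) {
        Type cnt = cntE(y, i);
        tot += cnt;
        ll -= lgamma(cnt + 1);
        if (asDouble(cnt) > 0) ll += cnt * log(S(y, i) / S_total(y));
      }
      nll -= ll + lgamma(tot + 1);
    }
    if (fqC(y)) {
      Type tot = 0, ll = 0;
      for (int i = 0; i < 4; i++) {
        Type cnt = cntC(y, i);
        tot += cnt;
        ll -= lgamma(cnt + 1);
        if (asDouble(cnt) > 0) ll += cnt * log(H(y, i) / Hsum(y));
      }
      nll -= ll + lgamma(tot + 1);
    }
    if (fqB(y)) {
      Type tot = 0, ll = 0;
      for (int i = 0; i < 4; i++) {
        Type cnt = cntB(y, i);
        tot += cnt;
        ll -= lgamma(cnt + 1);
        if (asDouble(cnt) > 0) ll += cnt * log(BA(y, i) / BAsum(y));
      }
      nll -= ll + lgamma(tot + 1);
    }
    for (int i = 0; i < 4; i++) {
      if (asDouble(gn(y, i)) > 0)
        nll -= dbinom(gx(y, i), gn(y, i), vt(y, i), true);
    }
  }

  // ---- reports --------------------------------------------------------
  REPORT(N); REPORT(A); REPORT(H); REPORT(S); REPORT(B); REPORT(BA);
  REPORT(M); REPORT(FB); REPORT(FT); REPORT(lam); REPORT(vt);
  REPORT(S_total); REPORT(run_size);
  return nll;
}
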
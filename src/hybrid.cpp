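#include <Rcpp.h>
using namespace Rcpp;

// Hot loops for the two-stage task HYBRID learner family.
//
// State indexing (fixed topology: 1 stage-1 state, 4 stage-2 states, two
// actions and two successors everywhere):
//   state 0      = stage-1 state
//   states 1..4  = stage-2 states, in the order of the task's stage2 vector
// Actions and successor slots are 0-based here; R passes 1-based and the
// wrappers subtract 1.
//
// Value tables are flat doubles:
//   qs[s + 5*a]            SARSA state-action values     (10)
//   qf[s + 5*a]            FORWARD state-action values   (10); initialized
//                          by the caller (0 for a fresh agent) and
//                          recomputed from th after each trial's update
//   th[s + 5*a + 10*k]     estimated transition prob to successor slot k (20)
// Stage-2 layout arrays (s2 = 0..3 indexes stage-2 states):
//   er[s2 + 4*a + 8*k]     scaled reward of the outcome reached from
//                          (stage-2 state s2, action a, slot k)
//   s1succ(a, k)           stage-2 index (0..3) reached from (stage-1, a, k)

// recompute the full FORWARD table qf (layout as qs) from th
static inline void forward_sweep(const double *th, const IntegerMatrix &s1succ,
                                 const double *er, double *qf) {
  double v2[4];
  for (int s = 0; s < 4; ++s) {
    double best = R_NegInf;
    for (int a = 0; a < 2; ++a) {
      double q = th[(s + 1) + 5 * a] * er[s + 4 * a] +
                 th[(s + 1) + 5 * a + 10] * er[s + 4 * a + 8];
      qf[(s + 1) + 5 * a] = q;
      if (q > best) best = q;
    }
    v2[s] = best;
  }
  for (int a = 0; a < 2; ++a)
    qf[5 * a] = th[5 * a] * v2[s1succ(a, 0)] + th[5 * a + 10] * v2[s1succ(a, 1)];
}

// log softmax probability of choosing index `pick` among two values
static inline double log_softmax2(double q0, double q1, double beta, int pick) {
  double x0 = beta * q0, x1 = beta * q1;
  double m = x0 > x1 ? x0 : x1;
  double z = m + std::log(std::exp(x0 - m) + std::exp(x1 - m));
  return (pick == 0 ? x0 : x1) - z;
}

static inline void t_update(double *th, int s, int a, int slot, double eta) {
  int i0 = s + 5 * a, i1 = s + 5 * a + 10;
  if (slot == 0) {
    th[i0] += eta * (1.0 - th[i0]);
    th[i1] *= (1.0 - eta);
  } else {
    th[i1] += eta * (1.0 - th[i1]);
    th[i0] *= (1.0 - eta);
  }
}

// Teacher-forced negative log-likelihood of one trial sequence under the
// HYBRID learner (SARSA = w 0, FORWARD = w 1). Emission happens before the
// trial's updates; SARSA stage-1 update bootstraps on the chosen stage-2
// action's value prior to the stage-2 update (on-policy order).
// [[Rcpp::export]]
List nll_hybrid_cpp(NumericVector par, IntegerVector a1, IntegerVector s2,
                    IntegerVector slot1, IntegerVector a2, IntegerVector slot2,
                    NumericVector rsc, IntegerMatrix s1succ, NumericVector er,
                    NumericVector qs0, NumericVector qf0, NumericVector th0,
                    bool per_trial = false) {
  const double alpha = par[0], eta = par[1], beta = par[2], w = par[3];
  const int n = a1.size();
  double qs[10], qf[10], th[20];
  for (int i = 0; i < 10; ++i) { qs[i] = qs0[i]; qf[i] = qf0[i]; }
  for (int i = 0; i < 20; ++i) th[i] = th0[i];
  const double *erp = er.begin();

  NumericVector lp1(per_trial ? n : 0), lp2(per_trial ? n : 0);
  double nll = 0.0;

  for (int t = 0; t < n; ++t) {
    int A1 = a1[t], S2 = s2[t], K1 = slot1[t], A2 = a2[t], K2 = slot2[t];
    double qh0 = w * qf[0] + (1.0 - w) * qs[0];
    double qh1 = w * qf[5] + (1.0 - w) * qs[5];
    double l1 = log_softmax2(qh0, qh1, beta, A1);

    double q20 = w * qf[S2 + 1] + (1.0 - w) * qs[(S2 + 1)];
    double q21 = w * qf[(S2 + 1) + 5] + (1.0 - w) * qs[(S2 + 1) + 5];
    double l2 = log_softmax2(q20, q21, beta, A2);

    nll -= l1 + l2;
    if (per_trial) { lp1[t] = l1; lp2[t] = l2; }

    // transition-model updates (state prediction errors), then a full
    // FORWARD recomputation
    t_update(th, 0, A1, K1, eta);
    t_update(th, S2 + 1, A2, K2, eta);
    forward_sweep(th, s1succ, erp, qf);

    // SARSA updates: stage 1 (r = 0, bootstrap on chosen a2), then stage 2
    double d1 = qs[(S2 + 1) + 5 * A2] - qs[5 * A1];
    qs[5 * A1] += alpha * d1;
    double d2 = rsc[t] - qs[(S2 + 1) + 5 * A2];
    qs[(S2 + 1) + 5 * A2] += alpha * d2;
  }

  NumericVector qs_end(10), qf_end(10), th_end(20);
  for (int i = 0; i < 10; ++i) { qs_end[i] = qs[i]; qf_end[i] = qf[i]; }
  for (int i = 0; i < 20; ++i) th_end[i] = th[i];
  List out = List::create(_["nll"] = nll, _["qs"] = qs_end,
                          _["qf"] = qf_end, _["th"] = th_end);
  if (per_trial) { out["lp1"] = lp1; out["lp2"] = lp2; }
  return out;
}

// Generative HYBRID agent. Parameters are per-trial vectors so blockwise
// schedules (w, or all four parameters) cost nothing. Uses R's RNG.
// [[Rcpp::export]]
List sim_hybrid_cpp(NumericVector alpha_t, NumericVector eta_t,
                    NumericVector beta_t, NumericVector w_t,
                    IntegerMatrix s1succ, NumericMatrix s1prob,
                    NumericVector er, NumericVector s2prob,
                    IntegerVector outidx, NumericVector qs0,
                    NumericVector qf0, NumericVector th0) {
  const int n = alpha_t.size();
  double qs[10], qf[10], th[20];
  for (int i = 0; i < 10; ++i) { qs[i] = qs0[i]; qf[i] = qf0[i]; }
  for (int i = 0; i < 20; ++i) th[i] = th0[i];
  const double *erp = er.begin();

  IntegerVector A1(n), S2(n), K1(n), A2(n), K2(n), OUT(n);
  NumericVector RSC(n), Q1L(n), Q1R(n), SURP(n);

  for (int t = 0; t < n; ++t) {
    double alpha = alpha_t[t], eta = eta_t[t], beta = beta_t[t], w = w_t[t];
    double qh0 = w * qf[0] + (1.0 - w) * qs[0];
    double qh1 = w * qf[5] + (1.0 - w) * qs[5];
    Q1L[t] = qh0; Q1R[t] = qh1;
    double p1 = std::exp(log_softmax2(qh0, qh1, beta, 0));
    int a1 = (unif_rand() < p1) ? 0 : 1;
    int k1 = (unif_rand() < s1prob(a1, 0)) ? 0 : 1;
    int s2 = s1succ(a1, k1);
    SURP[t] = 1.0 - th[5 * a1 + 10 * k1];

    double q20 = w * qf[s2 + 1] + (1.0 - w) * qs[(s2 + 1)];
    double q21 = w * qf[(s2 + 1) + 5] + (1.0 - w) * qs[(s2 + 1) + 5];
    double p2 = std::exp(log_softmax2(q20, q21, beta, 0));
    int a2 = (unif_rand() < p2) ? 0 : 1;
    int k2 = (unif_rand() < s2prob[s2 + 4 * a2]) ? 0 : 1;
    double r = erp[s2 + 4 * a2 + 8 * k2];

    A1[t] = a1; S2[t] = s2; K1[t] = k1; A2[t] = a2; K2[t] = k2;
    OUT[t] = outidx[s2 + 4 * a2 + 8 * k2];
    RSC[t] = r;

    t_update(th, 0, a1, k1, eta);
    t_update(th, s2 + 1, a2, k2, eta);
    forward_sweep(th, s1succ, erp, qf);
    double d1 = qs[(s2 + 1) + 5 * a2] - qs[5 * a1];
    qs[5 * a1] += alpha * d1;
    double d2 = r - qs[(s2 + 1) + 5 * a2];
    qs[(s2 + 1) + 5 * a2] += alpha * d2;
  }

  NumericVector qs_end(10), qf_end(10), th_end(20);
  for (int i = 0; i < 10; ++i) { qs_end[i] = qs[i]; qf_end[i] = qf[i]; }
  for (int i = 0; i < 20; ++i) th_end[i] = th[i];
  return List::create(_["a1"] = A1, _["s2"] = S2, _["slot1"] = K1,
                      _["a2"] = A2, _["slot2"] = K2, _["out"] = OUT,
                      _["rsc"] = RSC, _["q1l"] = Q1L, _["q1r"] = Q1R,
                      _["surprise1"] = SURP, _["qs"] = qs_end,
                      _["qf"] = qf_end, _["th"] = th_end);
}
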
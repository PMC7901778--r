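#include <Rcpp.h>
using namespace Rcpp;

// Single per-trial engine for the three Go/NoGo learning models.
// The same loop serves likelihood evaluation (actions/outcomes given) and
// forward simulation (actions sampled from the current policy, outcomes from
// the task contingency), so a model's likelihood on its own simulated data
// reproduces the simulation trace exactly.
//
// Model codes: 0 = rl, 1 = fixed Bayesian, 2 = adaptive Bayesian.
// Action codes: 1 = go, 0 = nogo. Outcomes are in {-1, 0, +1}.

namespace {

const double P_FLOOR = 1e-12;   // per-trial probability floor inside the log
const double MAG_CLIP = 1e-4;   // clip |theta-hat| away from {0,1} in Eq-8 logs

inline double logistic(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Event-probability magnitude of a value estimate backed by eta effective
// observations. A Beta-Bernoulli predictor with eta observations cannot
// justify a predictive probability outside [1/(eta+1), eta/(eta+1)] (rule of
// succession), so magnitudes are clipped to those bounds (plus an absolute
// guard) before entering the log-odds update.
inline double clip_mag(double v, double eta) {
  double m = std::fabs(v);
  const double lo = std::max(1.0 / (eta + 1.0), MAG_CLIP);
  const double hi = std::min(eta / (eta + 1.0), 1.0 - MAG_CLIP);
  if (m < lo) m = lo;
  if (m > hi) m = hi;
  return m;
}

} // namespace

// [[Rcpp::export]]
List engine_run(int model, NumericVector params, IntegerVector stimulus,
                IntegerVector required_go, IntegerVector valence,
                double p_optimal, bool simulate,
                IntegerVector action_in, NumericVector outcome_in) {
  const int T = stimulus.size();
  int S = 0;
  for (int t = 0; t < T; ++t) {
    if (stimulus[t] < 1) stop("stimulus ids must be positive integers");
    if (stimulus[t] > S) S = stimulus[t];
  }

  // unpack parameters
  double alpha = 0, rho = 0, pi_w = 0, b = 0, xi = 0;           // rl
  double beta = 0, v0_pav = 0, eta0_pav = 1, eta0_inst = 1;     // bayes
  double w_fixed = 0.5;
  if (model == 0) {
    alpha = params[0]; rho = params[1]; pi_w = params[2];
    b = params[3]; xi = params[4];
  } else {
    beta = params[0]; v0_pav = params[1];
    eta0_pav = params[2]; eta0_inst = params[3];
    if (model == 1) w_fixed = params[4];
  }

  // latent state: values and effective counts per stimulus (and action)
  // Bayesian instrumental estimates start at the uniform-Beta prior
  // predictive 0.5 (shared by both actions, so no initial go/nogo
  // preference); a prior event probability of 0 is incompatible with a Beta
  // prior and would make the log-odds update unbounded at the start.
  std::vector<double> vp(S, model == 0 ? 0.0 : v0_pav);
  std::vector<double> eta_p(S, eta0_pav);
  std::vector<double> vi(2 * S, model == 0 ? 0.0 : 0.5);  // [a + 2*s], a: 0=nogo, 1=go
  std::vector<double> eta_i(2 * S, eta0_inst);
  double L = 0.0;                            // log-odds for the uncontrollable env

  IntegerVector action(T), outcome(T);
  NumericVector p_go(T), loglik(T);
  NumericVector tr_vi_go(T), tr_vi_nogo(T), tr_vp(T), tr_w(T),
      tr_V_go(T), tr_V_nogo(T), tr_L(T);

  for (int t = 0; t < T; ++t) {
    const int s = stimulus[t] - 1;
    double Vg, Vn, pg, w = NA_REAL;

    if (model == 0) {
      Vg = vi[1 + 2 * s] + pi_w * vp[s] + b;
      Vn = vi[0 + 2 * s];
      pg = logistic(Vg - Vn) * (1.0 - xi) + xi / 2.0;
    } else {
      w = (model == 1) ? w_fixed : logistic(L);
      Vg = (1.0 - w) * vi[1 + 2 * s] + w * vp[s];  // V_P(s, NoGo) = 0
      Vn = (1.0 - w) * vi[0 + 2 * s];
      pg = logistic(beta * (Vg - Vn));
    }

    int a;
    double r;
    if (simulate) {
      a = (unif_rand() < pg) ? 1 : 0;
      const bool optimal = (a == required_go[t]);
      const double p_pos = optimal ? p_optimal : 1.0 - p_optimal;
      const bool pos = (unif_rand() < p_pos);
      r = (valence[t] > 0) ? (pos ? 1.0 : 0.0) : (pos ? 0.0 : -1.0);
    } else {
      a = action_in[t];
      r = outcome_in[t];
    }

    const double pa = (a == 1) ? pg : 1.0 - pg;
    loglik[t] = std::log(std::max(pa, P_FLOOR));

    // trace records pre-choice quantities (the state in force at selection)
    action[t] = a;
    outcome[t] = (int)r;
    p_go[t] = pg;
    tr_vi_go[t] = vi[1 + 2 * s];
    tr_vi_nogo[t] = vi[0 + 2 * s];
    tr_vp[t] = vp[s];
    tr_w[t] = w;
    tr_V_go[t] = Vg;
    tr_V_nogo[t] = Vn;
    tr_L[t] = (model == 2) ? L : NA_REAL;

    // state update
    if (model == 0) {
      vp[s] += alpha * (rho * r - vp[s]);
      vi[a + 2 * s] += alpha * (rho * r - vi[a + 2 * s]);
    } else {
      if (model == 2) {
        // log-odds update uses pre-update estimates of the taken action
        const double e = std::fabs(r);
        const double ms = clip_mag(vp[s], eta_p[s]);
        const double msa = clip_mag(vi[a + 2 * s], eta_i[a + 2 * s]);
        L += e * std::log(ms / msa) +
             (1.0 - e) * std::log((1.0 - ms) / (1.0 - msa));
      }
      // decaying learning rate alpha = 1/eta with the post-increment count
      eta_p[s] += 1.0;
      vp[s] += (r - vp[s]) / eta_p[s];
      eta_i[a + 2 * s] += 1.0;
      vi[a + 2 * s] += (r - vi[a + 2 * s]) / eta_i[a + 2 * s];
    }
  }

  return List::create(
      _["action"] = action, _["outcome"] = outcome, _["p_go"] = p_go,
      _["loglik"] = loglik, _["v_inst_go"] = tr_vi_go,
      _["v_inst_nogo"] = tr_vi_nogo, _["v_pav"] = tr_vp, _["w"] = tr_w,
      _["V_go"] = tr_V_go, _["V_nogo"] = tr_V_nogo, _["L"] = tr_L);
}
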
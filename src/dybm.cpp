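// Compiled kernels for DyBM training, generation and scoring.
//
// The R level owns the documented single-step semantics (train_step,
// advance_state, compute_gradients); these loops reproduce them
// step-for-step for period-scale runs.  Conventions (all 0-based here):
//   hist[i + N*p]        value of neuron i, p+1 steps in the past
//                        (p = 0 is the queue tail, p = d-2 the head)
//   alpha[i + N*j + N*N*k]  synaptic trace, updated as
//                        lambda_k * (alpha + value arriving at (i,j))
//   gamma[j + N*l]       neural trace, mu_l * (gamma + x_j)
//   beta[i + N*j + N*N*l] = sum_{p=0}^{d-2} mu_l^{d-1-p} hist[i + N*p]
//                        (weight = mu^(steps until the queued spike
//                        arrives); computed via prefix sums of
//                        mu^{-(p+1)} hist, rescaled by mu^d per synapse)
// Spike probability: p_j = sigmoid(delta_j), delta_j = b_j
//   + sum u.alpha - sum v.beta - sum_{i,l} v[j,i,l] gamma[i,l].
// AdaGrad: an update with gradient g adds g^2 to the parameter's
// accumulator and steps by eta0 * g / sqrt(accum + eps), the accumulator
// including g itself (every step bounded by eta0).  The two LTD gradient
// components keep separate accumulators and are applied sequentially.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double softplus(double z) {
  if (z > 35.0) return z;
  if (z < -35.0) return std::exp(z);
  return std::log1p(std::exp(z));
}

struct Dybm {
  int N, K, L, Dm1;
  std::vector<int> d;                    // N*N
  std::vector<double> lam, mu;
  std::vector<double> b, u, v;
  std::vector<double> hist, alpha, gam;
  int clk;
  std::vector<double> ab, au, ava, avb;
  double eta0, eps;
  bool hasAda;
  std::vector<double> beta, cumB, prob, delta, powneg, powd, xbuf;

  void loadModel(const List& m) {
    N = as<int>(m["n"]); K = as<int>(m["K"]); L = as<int>(m["L"]);
    IntegerMatrix dm = m["delays"];
    d.assign(dm.begin(), dm.end());
    lam = as<std::vector<double> >(m["lambda"]);
    mu = as<std::vector<double> >(m["mu"]);
    b = as<std::vector<double> >(m["b"]);
    u = as<std::vector<double> >(m["u"]);
    v = as<std::vector<double> >(m["v"]);
    int dmax = 1;
    for (size_t q = 0; q < d.size(); q++) if (d[q] > dmax) dmax = d[q];
    Dm1 = dmax - 1;
    beta.assign((size_t) N * N * L, 0.0);
    cumB.assign((size_t) N * L * (Dm1 > 0 ? Dm1 : 1), 0.0);
    prob.assign(N, 0.0); delta.assign(N, 0.0); xbuf.assign(N, 0.0);
    powneg.assign((size_t) L * (Dm1 > 0 ? Dm1 : 1), 0.0);
    for (int l = 0; l < L; l++)
      for (int p = 0; p < Dm1; p++)
        powneg[l * Dm1 + p] = mu[l] > 0.0 ? std::pow(mu[l], -(p + 1)) : 0.0;
    powd.assign((size_t) L * (Dm1 + 2), 0.0);
    for (int l = 0; l < L; l++)
      for (int dd = 0; dd <= Dm1 + 1; dd++)
        powd[l * (Dm1 + 2) + dd] = std::pow(mu[l], dd);
  }
  void loadState(const List& s) {
    hist = as<std::vector<double> >(s["hist"]);
    alpha = as<std::vector<double> >(s["alpha"]);
    gam = as<std::vector<double> >(s["gamma"]);
    clk = as<int>(s["clock"]);
  }
  void loadAda(const List& a) {
    ab = as<std::vector<double> >(a["ab"]);
    au = as<std::vector<double> >(a["au"]);
    ava = as<std::vector<double> >(a["ava"]);
    avb = as<std::vector<double> >(a["avb"]);
    eta0 = as<double>(a["eta0"]); eps = as<double>(a["eps"]);
    hasAda = true;
  }
  List dumpModel() const {
    return List::create(_["b"] = b, _["u"] = u, _["v"] = v);
  }
  List dumpState() const {
    return List::create(_["hist"] = hist, _["alpha"] = alpha,
                        _["gamma"] = gam, _["clock"] = clk);
  }
  List dumpAda() const {
    return List::create(_["ab"] = ab, _["au"] = au, _["ava"] = ava,
                        _["avb"] = avb, _["eta0"] = eta0, _["eps"] = eps);
  }

  // AdaGrad move: accumulate g^2, then step eta0*g/sqrt(accum+eps)
  inline void move(double& param, double& accum, double g) const {
    accum += g * g;
    if (accum > 0.0) param += eta0 * g / std::sqrt(accum + eps);
  }

  void computeProbs() {
    for (int l = 0; l < L; l++)
      for (int i = 0; i < N; i++) {
        double c = 0.0;
        for (int p = 0; p < Dm1; p++) {
          c += powneg[l * Dm1 + p] * hist[i + N * p];
          cumB[(i * L + l) * Dm1 + p] = c;
        }
      }
    for (int j = 0; j < N; j++) {
      double s = b[j];
      for (int k = 0; k < K; k++) {
        const double* uu = &u[(size_t) N * N * k + (size_t) N * j];
        const double* aa = &alpha[(size_t) N * N * k + (size_t) N * j];
        for (int i = 0; i < N; i++) s += uu[i] * aa[i];
      }
      for (int l = 0; l < L; l++) {
        double* bb = &beta[(size_t) N * N * l + (size_t) N * j];
        const double* vv = &v[(size_t) N * N * l + (size_t) N * j];
        for (int i = 0; i < N; i++) {
          int dd = d[i + N * j];
          double bv = dd > 1
            ? powd[l * (Dm1 + 2) + dd] * cumB[(i * L + l) * Dm1 + dd - 2]
            : 0.0;
          bb[i] = bv;
          s -= vv[i] * bv;
        }
        for (int i = 0; i < N; i++)
          s -= v[j + N * i + (size_t) N * N * l] * gam[i + N * l];
      }
      delta[j] = s;
      prob[j] = s >= 0 ? 1.0 / (1.0 + std::exp(-s))
                       : std::exp(s) / (1.0 + std::exp(s));
    }
  }

  double loglikRow(const int* x) const {
    double s = 0.0;
    for (int j = 0; j < N; j++)
      s -= softplus(x[j] ? -delta[j] : delta[j]);
    return s;
  }

  void advance(const double* x) {
    for (int k = 0; k < K; k++)
      for (int j = 0; j < N; j++)
        for (int i = 0; i < N; i++) {
          int dd = d[i + N * j];
          double arr = dd == 1 ? x[i] : hist[i + N * (dd - 2)];
          size_t idx = (size_t) i + N * j + (size_t) N * N * k;
          alpha[idx] = lam[k] * (alpha[idx] + arr);
        }
    for (int p = Dm1 - 1; p > 0; p--)
      for (int i = 0; i < N; i++) hist[i + N * p] = hist[i + N * (p - 1)];
    if (Dm1 > 0) for (int i = 0; i < N; i++) hist[i] = x[i];
    for (int l = 0; l < L; l++)
      for (int j = 0; j < N; j++)
        gam[j + N * l] = mu[l] * (gam[j + N * l] + x[j]);
    clk++;
  }

  // one online training step on an observed row; returns its log-likelihood
  double trainStep(const int* x) {
    computeProbs();
    double ll = loglikRow(x);
    for (int j = 0; j < N; j++)
      move(b[j], ab[j], x[j] - prob[j]);
    for (int k = 0; k < K; k++)
      for (int j = 0; j < N; j++) {
        double r = x[j] - prob[j];
        size_t off = (size_t) N * j + (size_t) N * N * k;
        for (int i = 0; i < N; i++)
          move(u[off + i], au[off + i], r * alpha[off + i]);
      }
    for (int l = 0; l < L; l++)
      for (int j = 0; j < N; j++) {
        double rj = prob[j] - x[j];
        size_t off = (size_t) N * j + (size_t) N * N * l;
        for (int i = 0; i < N; i++) {
          move(v[off + i], ava[off + i], rj * beta[off + i]);
          move(v[off + i], avb[off + i],
               (prob[i] - x[i]) * gam[j + N * l]);
        }
      }
    for (int j = 0; j < N; j++) xbuf[j] = x[j];
    advance(&xbuf[0]);
    return ll;
  }

  double trainPeriod(const IntegerMatrix& X) {
    double s = 0.0;
    std::vector<int> row(N);
    for (int t = 0; t < X.nrow(); t++) {
      for (int j = 0; j < N; j++) row[j] = X(t, j);
      s += trainStep(&row[0]);
    }
    return s;
  }

  struct Saved { std::vector<double> hist, alpha, gam; int clk; };
  Saved save() const { Saved s; s.hist = hist; s.alpha = alpha;
                       s.gam = gam; s.clk = clk; return s; }
  void restore(const Saved& s) { hist = s.hist; alpha = s.alpha;
                                 gam = s.gam; clk = s.clk; }
  void zeroState() {
    std::fill(hist.begin(), hist.end(), 0.0);
    std::fill(alpha.begin(), alpha.end(), 0.0);
    std::fill(gam.begin(), gam.end(), 0.0);
    clk = 0;
  }

  // closed-loop deterministic generation, comparing against the target
  // tiled from phase `phase`; state is left advanced
  bool generateMatches(const IntegerMatrix& X, int n_steps, int phase) {
    int T = X.nrow();
    bool ok = true;
    for (int t = 0; t < n_steps; t++) {
      computeProbs();
      int tt = (phase + t) % T;
      for (int j = 0; j < N; j++) {
        xbuf[j] = delta[j] > 0.0 ? 1.0 : 0.0;  // ties emit 0
        if ((int) xbuf[j] != X(tt, j)) ok = false;
      }
      if (!ok) return false;
      advance(&xbuf[0]);
    }
    return ok;
  }

  // memorisation check: from a clone of the live state, deterministically
  // generate `reps` periods and require a bit-exact match
  bool memorized(const IntegerMatrix& X, int reps) {
    Saved s = save();
    bool ok = generateMatches(X, reps * X.nrow(), 0);
    restore(s);
    return ok;
  }

  // cue check: zero state, present cue, generate one period, compare with
  // the target continuation after the cue; live state untouched
  bool cueRetrieves(const IntegerMatrix& X, const IntegerMatrix& cue) {
    Saved s = save();
    zeroState();
    for (int t = 0; t < cue.nrow(); t++) {
      for (int j = 0; j < N; j++) xbuf[j] = cue(t, j);
      advance(&xbuf[0]);
    }
    bool ok = generateMatches(X, X.nrow(), cue.nrow() % X.nrow());
    restore(s);
    return ok;
  }
};

// [[Rcpp::export]]
List cpp_advance_seq(List m, List s, IntegerMatrix X, bool want_ll) {
  Dybm dy; dy.loadModel(m); dy.loadState(s);
  int T = X.nrow();
  NumericVector ll(want_ll ? T : 0);
  std::vector<int> row(dy.N);
  for (int t = 0; t < T; t++) {
    for (int j = 0; j < dy.N; j++) row[j] = X(t, j);
    if (want_ll) {
      dy.computeProbs();
      ll[t] = dy.loglikRow(&row[0]);
    }
    for (int j = 0; j < dy.N; j++) dy.xbuf[j] = row[j];
    dy.advance(&dy.xbuf[0]);
  }
  return List::create(_["state"] = dy.dumpState(), _["loglik"] = ll);
}

// [[Rcpp::export]]
List cpp_generate(List m, List s, int n_steps) {
  Dybm dy; dy.loadModel(m); dy.loadState(s);
  IntegerMatrix out(n_steps, dy.N);
  for (int t = 0; t < n_steps; t++) {
    dy.computeProbs();
    for (int j = 0; j < dy.N; j++) {
      dy.xbuf[j] = dy.delta[j] > 0.0 ? 1.0 : 0.0;
      out(t, j) = (int) dy.xbuf[j];
    }
    dy.advance(&dy.xbuf[0]);
  }
  return List::create(_["x"] = out, _["state"] = dy.dumpState());
}

// [[Rcpp::export]]
List cpp_train_seq(List m, List s, List a, IntegerMatrix X, int n_reps) {
  Dybm dy; dy.loadModel(m); dy.loadState(s); dy.loadAda(a);
  NumericVector ll(n_reps);
  for (int r = 0; r < n_reps; r++) ll[r] = dy.trainPeriod(X);
  return List::create(_["model"] = dy.dumpModel(), _["state"] = dy.dumpState(),
                      _["ada"] = dy.dumpAda(), _["loglik"] = ll);
}

// [[Rcpp::export]]
List cpp_train_until_memorized(List m, List s, List a, IntegerMatrix X,
                               int max_periods, int check_every) {
  Dybm dy; dy.loadModel(m); dy.loadState(s); dy.loadAda(a);
  if (check_every < 1) check_every = 1;
  std::vector<double> ll;
  ll.reserve(1024);
  int periods = 0;
  bool conv = dy.memorized(X, 2);
  while (!conv && periods < max_periods) {
    int todo = std::min(check_every, max_periods - periods);
    for (int r = 0; r < todo; r++) {
      ll.push_back(dy.trainPeriod(X));
      periods++;
    }
    conv = dy.memorized(X, 2);
    if (periods % 10000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["model"] = dy.dumpModel(), _["state"] = dy.dumpState(),
                      _["ada"] = dy.dumpAda(), _["loglik"] = wrap(ll),
                      _["periods_used"] = periods, _["converged"] = conv);
}

// [[Rcpp::export]]
List cpp_train_alternating(List m, List s, List a,
                           IntegerMatrix A, IntegerMatrix B,
                           IntegerMatrix cueA, IntegerMatrix cueB,
                           int max_iterations, int max_periods, int check_every) {
  Dybm dy; dy.loadModel(m); dy.loadState(s); dy.loadAda(a);
  if (check_every < 1) check_every = 1;
  std::vector<int> ppi;
  bool converged = false;
  for (int it = 1; it <= max_iterations; it++) {
    const IntegerMatrix& X = (it % 2 == 1) ? A : B;
    const IntegerMatrix& cue = (it % 2 == 1) ? cueA : cueB;
    int per = 0;
    bool got = dy.cueRetrieves(X, cue);
    while (!got && per < max_periods) {
      int todo = std::min(check_every, max_periods - per);
      for (int r = 0; r < todo; r++) {
        dy.trainPeriod(X);
        per++;
      }
      got = dy.cueRetrieves(X, cue);
      if (per % 10000 == 0) Rcpp::checkUserInterrupt();
    }
    ppi.push_back(per);
    if (!got) break;                       // per-iteration budget exhausted
    if (dy.cueRetrieves(A, cueA) && dy.cueRetrieves(B, cueB)) {
      converged = true;
      break;
    }
  }
  return List::create(_["model"] = dy.dumpModel(), _["state"] = dy.dumpState(),
                      _["ada"] = dy.dumpAda(),
                      _["periods_per_iteration"] = wrap(ppi),
                      _["iterations_used"] = (int) ppi.size(),
                      _["converged"] = converged);
}
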
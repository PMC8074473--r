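// RJMCMC core for the four NH-DBN piecewise regression variants.
//
// Variant coding: 1 = uncoupled, 2 = fully coupled, 3 = partially
// segment-wise coupled (binary indicators delta_h), 4 = generalized
// coupled (segment-specific lambda_h).  All marginal-likelihood algebra
// acts on the (k+1)x(k+1) inner matrix (Woodbury / determinant lemma);
// the T_h x T_h covariance C_h = I + X_h Sigma_h X_h' is never formed.
//
// Randomness comes from R's RNG stream (R::*), so set.seed() on the R
// side makes every entry point reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct Hyper {
  double a_sig, b_sig, a_u, b_u, a_c, b_c, a_beta, b_beta, p_cp;
  int fan_in;
};

static Hyper read_hyper(const List& h) {
  Hyper hy;
  hy.a_sig = as<double>(h["alpha_sigma"]);
  hy.b_sig = as<double>(h["beta_sigma"]);
  hy.a_u = as<double>(h["alpha_u"]);
  hy.b_u = as<double>(h["beta_u"]);
  hy.a_c = as<double>(h["alpha_c"]);
  hy.b_c = as<double>(h["beta_c"]);
  hy.a_beta = as<double>(h["a"]);
  hy.b_beta = as<double>(h["b"]);
  hy.p_cp = as<double>(h["p_cp"]);
  hy.fan_in = as<int>(h["fan_in"]);
  return hy;
}

struct Problem {
  arma::vec y;             // responses, length Tall
  arma::mat Xc;            // covariates, Tall x n
  std::vector<bool> valid; // lag pair t valid?
  int Tall, n;
};

struct Seg {
  arma::mat X; // Th x (k+1), leading intercept column
  arma::vec y;
};

struct State {
  std::vector<int> pi;       // 0-based covariate indices, sorted
  std::vector<int> tau;      // sorted changepoints in 1..Tall-1
  double lam_u, lam_c;
  std::vector<double> lam_h; // M4, segments 2..H
  std::vector<int> delta;    // M3, segments 2..H
};

// valid-observation counts per segment of a changepoint set
static std::vector<int> seg_counts(const Problem& P,
                                   const std::vector<int>& tau) {
  std::vector<int> bounds;
  bounds.push_back(0);
  for (int t : tau) bounds.push_back(t);
  bounds.push_back(P.Tall);
  std::vector<int> cnt(bounds.size() - 1, 0);
  for (size_t h = 0; h + 1 < bounds.size(); ++h)
    for (int t = bounds[h] + 1; t <= bounds[h + 1]; ++t)
      if (P.valid[t - 1]) cnt[h]++;
  return cnt;
}

static std::vector<Seg> build_segments(const Problem& P,
                                       const std::vector<int>& pi,
                                       const std::vector<int>& tau) {
  std::vector<int> bounds;
  bounds.push_back(0);
  for (int t : tau) bounds.push_back(t);
  bounds.push_back(P.Tall);
  int k1 = (int)pi.size() + 1;
  std::vector<Seg> segs(bounds.size() - 1);
  for (size_t h = 0; h + 1 < bounds.size(); ++h) {
    std::vector<int> idx;
    for (int t = bounds[h] + 1; t <= bounds[h + 1]; ++t)
      if (P.valid[t - 1]) idx.push_back(t - 1);
    arma::mat X(idx.size(), k1);
    arma::vec y(idx.size());
    for (size_t i = 0; i < idx.size(); ++i) {
      X(i, 0) = 1.0;
      for (size_t j = 0; j < pi.size(); ++j) X(i, j + 1) = P.Xc(idx[i], pi[j]);
      y(i) = P.y(idx[i]);
    }
    segs[h].X = std::move(X);
    segs[h].y = std::move(y);
  }
  return segs;
}

// per-segment prior scalar: lambda and coupled flag
static inline void seg_lambda(int variant, const State& s, int h /*0-based*/,
                              double& lam, bool& coupled) {
  if (h == 0) { lam = s.lam_u; coupled = false; return; }
  switch (variant) {
  case 1: lam = s.lam_u; coupled = false; break;
  case 2: lam = s.lam_c; coupled = true; break;
  case 3:
    if (s.delta[h - 1]) { lam = s.lam_c; coupled = true; }
    else { lam = s.lam_u; coupled = false; }
    break;
  default: lam = s.lam_h[h - 1]; coupled = true; break;
  }
}

struct Eval {
  double logml = 0.0, d2 = 0.0;
  int Ttot = 0;
  std::vector<arma::vec> wtilde;    // w~_1..w~_H
  std::vector<arma::vec> postmean;  // full-conditional means of w_h
  std::vector<arma::mat> cholA;     // upper Cholesky of Sigma^-1 + X'X
};

static Eval eval_model(const std::vector<Seg>& segs, int variant,
                       const State& s, const Hyper& hy,
                       bool keep_extras) {
  int H = (int)segs.size();
  int k1 = (int)segs[0].X.n_cols;
  Eval ev;
  if (keep_extras) {
    ev.wtilde.resize(H);
    ev.postmean.resize(H);
    ev.cholA.resize(H);
  }
  arma::vec w_prev(k1, arma::fill::zeros);
  double ldC = 0.0;
  for (int h = 0; h < H; ++h) {
    double lam; bool coupled;
    seg_lambda(variant, s, h, lam, coupled);
    arma::vec mu = coupled ? w_prev : arma::vec(k1, arma::fill::zeros);
    arma::mat A = segs[h].X.t() * segs[h].X;
    A.diag() += 1.0 / lam;
    arma::mat R = arma::chol(A); // upper
    ldC += k1 * std::log(lam) + 2.0 * arma::sum(arma::log(R.diag()));
    arma::vec rhs = mu / lam + segs[h].X.t() * segs[h].y;
    arma::vec pm = arma::solve(arma::trimatu(R),
                               arma::solve(arma::trimatl(R.t()), rhs));
    arma::vec r = segs[h].y - segs[h].X * mu;
    arma::vec b = segs[h].X.t() * r;
    arma::vec Ainvb = arma::solve(arma::trimatu(R),
                                  arma::solve(arma::trimatl(R.t()), b));
    double quad = arma::dot(r, r) - arma::dot(b, Ainvb);
    if (quad < 0.0) quad = 0.0;
    ev.d2 += quad;
    ev.Ttot += (int)segs[h].y.n_elem;
    if (keep_extras) {
      ev.wtilde[h] = pm;
      ev.postmean[h] = pm;
      ev.cholA[h] = R;
    }
    w_prev = pm;
  }
  double Td = (double)ev.Ttot;
  ev.logml = std::lgamma(Td / 2.0 + hy.a_sig) - std::lgamma(hy.a_sig) -
             (Td / 2.0) * std::log(M_PI) +
             hy.a_sig * std::log(2.0 * hy.b_sig) - 0.5 * ldC -
             (Td / 2.0 + hy.a_sig) * std::log(2.0 * hy.b_sig + ev.d2);
  return ev;
}

static double log_delta_prior_c(const std::vector<int>& delta, double a,
                                double b) {
  int m = (int)delta.size(), s = 0;
  for (int d : delta) s += d;
  return std::lgamma(a + b) - std::lgamma(a) - std::lgamma(b) +
         std::lgamma(a + s) + std::lgamma(b + m - s) -
         std::lgamma(a + b + m);
}

static inline double log_tau_prior(int ntau, int Tall, double p) {
  return ntau * std::log(p) + ((Tall - 1) - ntau) * std::log1p(-p);
}

static inline double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// ---------------------------------------------------------------------
// Gibbs sweep: sigma^2 (collapsed), w_h, lambda's, and for M3 each
// delta_k by collapsed Gibbs.  `segs`/`ev` are the cached segments and
// evaluation for the current (pi, tau); ev is refreshed on exit.
static void gibbs_sweep(const Problem& P, State& s, int variant,
                        const Hyper& hy, std::vector<Seg>& segs, Eval& ev) {
  int H = (int)segs.size();
  int k1 = (int)segs[0].X.n_cols;
  double Td = (double)ev.Ttot;
  double sig2 = rinvgamma(hy.a_sig + Td / 2.0, hy.b_sig + ev.d2 / 2.0);

  // draw w_h ~ N(postmean, sig2 * A^-1), A = R'R
  std::vector<arma::vec> w(H);
  for (int h = 0; h < H; ++h) {
    arma::vec z(k1);
    for (int j = 0; j < k1; ++j) z(j) = R::norm_rand();
    w[h] = ev.postmean[h] +
           std::sqrt(sig2) * arma::solve(arma::trimatu(ev.cholA[h]), z);
  }

  // lambda updates from the variant's full conditionals
  auto sq = [](const arma::vec& v) { return arma::dot(v, v); };
  if (variant == 1) {
    double D2 = 0.0;
    for (int h = 0; h < H; ++h) D2 += sq(w[h]);
    s.lam_u = rinvgamma(hy.a_u + H * k1 / 2.0, hy.b_u + D2 / (2.0 * sig2));
  } else {
    double Du2 = sq(w[0]), Dc2 = 0.0;
    int Hu = 1, Hc = 0;
    for (int h = 1; h < H; ++h) {
      double lam; bool coupled;
      seg_lambda(variant, s, h, lam, coupled);
      arma::vec diff = w[h] - ev.wtilde[h - 1];
      if (variant == 4) {
        s.lam_h[h - 1] = rinvgamma(hy.a_c + k1 / 2.0,
                                   hy.b_c + sq(diff) / (2.0 * sig2));
      } else if (coupled) {
        Dc2 += sq(diff);
        Hc++;
      } else {
        Du2 += sq(w[h]);
        Hu++;
      }
    }
    s.lam_u = rinvgamma(hy.a_u + Hu * k1 / 2.0, hy.b_u + Du2 / (2.0 * sig2));
    if (variant == 2 || variant == 3) {
      if (variant == 2) { Hc = H - 1; } // all h >= 2 coupled
      s.lam_c = rinvgamma(hy.a_c + Hc * k1 / 2.0,
                          hy.b_c + Dc2 / (2.0 * sig2));
    }
  }

  if (variant == 3 && H > 1) {
    // collapsed Gibbs over the coupling indicators, in index order;
    // each candidate re-derives the full w~ recursion
    for (int k = 2; k <= H; ++k) {
      State s0 = s, s1 = s;
      s0.delta[k - 2] = 0;
      s1.delta[k - 2] = 1;
      Eval e0 = eval_model(segs, variant, s0, hy, true);
      Eval e1 = eval_model(segs, variant, s1, hy, true);
      double lp0 = e0.logml + log_delta_prior_c(s0.delta, hy.a_beta, hy.b_beta);
      double lp1 = e1.logml + log_delta_prior_c(s1.delta, hy.a_beta, hy.b_beta);
      double p1 = 1.0 / (1.0 + std::exp(lp0 - lp1));
      if (R::unif_rand() < p1) { s = s1; ev = e1; }
      else { s = s0; ev = e0; }
    }
  } else {
    ev = eval_model(segs, variant, s, hy, true);
  }
}

// ---------------------------------------------------------------------
// Metropolis-Hastings move on the parent set (addition / removal /
// exchange).  Unavailable draws count as rejections.
static bool parent_move(const Problem& P, State& s, int variant,
                        const Hyper& hy, std::vector<Seg>& segs, Eval& ev) {
  int n = P.n;
  int sz = (int)s.pi.size();
  int mt = (int)std::floor(R::unif_rand() * 3.0); // 0=A, 1=R, 2=E
  if (mt == 3) mt = 2;
  std::vector<int> pi_star = s.pi;
  double logHR;
  std::vector<int> out; // non-members
  out.reserve(n);
  {
    std::vector<bool> inpi(n, false);
    for (int j : s.pi) inpi[j] = true;
    for (int j = 0; j < n; ++j)
      if (!inpi[j]) out.push_back(j);
  }
  if (mt == 0) { // addition
    if ((int)out.size() == 0) return false;
    int add = out[(int)std::floor(R::unif_rand() * out.size())];
    pi_star.push_back(add);
    std::sort(pi_star.begin(), pi_star.end());
    logHR = std::log((double)(n - sz)) - std::log((double)(sz + 1));
  } else if (mt == 1) { // removal
    if (sz == 0) return false;
    int rem = (int)std::floor(R::unif_rand() * sz);
    pi_star.erase(pi_star.begin() + rem);
    logHR = std::log((double)sz) - std::log((double)(n - sz + 1));
  } else { // exchange
    if (sz == 0 || (int)out.size() == 0) return false;
    int rem = (int)std::floor(R::unif_rand() * sz);
    int add = out[(int)std::floor(R::unif_rand() * out.size())];
    pi_star[rem] = add;
    std::sort(pi_star.begin(), pi_star.end());
    logHR = 0.0;
  }
  if ((int)pi_star.size() > hy.fan_in) return false; // zero prior
  std::vector<Seg> segs_star = build_segments(P, pi_star, s.tau);
  Eval ev_star = eval_model(segs_star, variant, s, hy, true);
  double logA = (ev_star.logml - ev.logml) + logHR; // flat prior over sizes
  if (std::log(R::unif_rand()) < logA) {
    s.pi = pi_star;
    segs = std::move(segs_star);
    ev = ev_star;
    return true;
  }
  return false;
}

// ---------------------------------------------------------------------
// Reversible-jump move on the changepoint set (birth / death /
// re-allocation).  For M3 the coupling indicators of newly created
// segments are proposed by fair coin flips (factor c_tau = 2, 1/2, 1);
// for M4 the coupling strengths of new segments are redrawn from their
// prior, whose density cancels against the prior ratio.
static bool cp_move(const Problem& P, State& s, int variant, const Hyper& hy,
                    int min_seg_len, std::vector<Seg>& segs, Eval& ev) {
  int Tall = P.Tall;
  int ntau = (int)s.tau.size();
  int npos = Tall - 1;
  int mt = (int)std::floor(R::unif_rand() * 3.0); // 0=B, 1=D, 2=R
  if (mt == 3) mt = 2;

  std::vector<int> tau_star = s.tau;
  double logHR = 0.0, log_c = 0.0;
  // new-segment bookkeeping: for each new segment index (0-based) the
  // source in the old segmentation, or -1 for "new"
  std::vector<int> src;

  if (mt == 0) { // birth
    if (ntau >= npos) return false;
    std::vector<bool> occ(npos + 1, false);
    for (int t : s.tau) occ[t] = true;
    int free_cnt = npos - ntau;
    int pick = (int)std::floor(R::unif_rand() * free_cnt);
    int pos = 0;
    for (int t = 1; t <= npos; ++t) {
      if (!occ[t]) {
        if (pick == 0) { pos = t; break; }
        pick--;
      }
    }
    int j = 0;
    while (j < ntau && s.tau[j] < pos) j++;
    tau_star.insert(tau_star.begin() + j, pos);
    logHR = std::log((double)free_cnt) - std::log((double)(ntau + 1));
    log_c = std::log(2.0);
    int Hs = ntau + 2;
    src.assign(Hs, 0);
    for (int sgi = 0; sgi < Hs; ++sgi)
      src[sgi] = (sgi < j) ? sgi : (sgi == j || sgi == j + 1) ? -1 : sgi - 1;
  } else if (mt == 1) { // death
    if (ntau == 0) return false;
    int j = (int)std::floor(R::unif_rand() * ntau);
    tau_star.erase(tau_star.begin() + j);
    logHR = std::log((double)ntau) - std::log((double)(npos - ntau + 1));
    log_c = -std::log(2.0);
    int Hs = ntau; // = (ntau - 1) + 1 segments
    src.assign(Hs, 0);
    for (int sgi = 0; sgi < Hs; ++sgi)
      src[sgi] = (sgi < j) ? sgi : (sgi == j) ? -1 : sgi + 1;
  } else { // re-allocation
    if (ntau == 0) return false;
    int j = (int)std::floor(R::unif_rand() * ntau);
    int lo = (j == 0) ? 0 : s.tau[j - 1];
    int hi = (j == ntau - 1) ? Tall : s.tau[j + 1];
    int cand_cnt = (hi - lo - 1) - 1; // interior positions minus current
    if (cand_cnt <= 0) return false;
    int pick = (int)std::floor(R::unif_rand() * cand_cnt);
    int pos = lo + 1 + pick;
    if (pos >= s.tau[j]) pos++; // skip current location
    tau_star[j] = pos;
    logHR = 0.0;
    log_c = 0.0;
    int Hs = ntau + 1;
    src.assign(Hs, 0);
    for (int sgi = 0; sgi < Hs; ++sgi)
      src[sgi] = (sgi == j || sgi == j + 1) ? -1 : sgi;
  }

  // min_seg_len screen on valid-observation counts
  std::vector<int> cnt = seg_counts(P, tau_star);
  for (int c : cnt)
    if (c < min_seg_len) return false;

  State s_star = s;
  s_star.tau = tau_star;
  int Hs = (int)tau_star.size() + 1;
  if (variant == 3) {
    s_star.delta.assign(std::max(Hs - 1, 0), 0);
    for (int sgi = 1; sgi < Hs; ++sgi) {
      s_star.delta[sgi - 1] =
          (src[sgi] < 0) ? (R::unif_rand() < 0.5 ? 1 : 0)
                         : s.delta[src[sgi] - 1];
    }
  } else if (variant == 4) {
    s_star.lam_h.assign(std::max(Hs - 1, 0), 1.0);
    for (int sgi = 1; sgi < Hs; ++sgi) {
      s_star.lam_h[sgi - 1] = (src[sgi] < 0)
                                  ? rinvgamma(hy.a_c, hy.b_c)
                                  : s.lam_h[src[sgi] - 1];
    }
  }

  std::vector<Seg> segs_star = build_segments(P, s.pi, tau_star);
  Eval ev_star = eval_model(segs_star, variant, s_star, hy, true);
  double logA = (ev_star.logml - ev.logml) +
                log_tau_prior((int)tau_star.size(), Tall, hy.p_cp) -
                log_tau_prior(ntau, Tall, hy.p_cp) + logHR;
  if (variant == 3) {
    logA += log_delta_prior_c(s_star.delta, hy.a_beta, hy.b_beta) -
            log_delta_prior_c(s.delta, hy.a_beta, hy.b_beta) + log_c;
  }
  // variant 4: lambda prior ratio cancels against the proposal density
  if (std::log(R::unif_rand()) < logA) {
    s = s_star;
    segs = std::move(segs_star);
    ev = ev_star;
    return true;
  }
  return false;
}

static void do_iteration(const Problem& P, State& s, int variant,
                         const Hyper& hy, int min_seg_len, bool fix_tau,
                         bool move_parents, std::vector<Seg>& segs, Eval& ev,
                         int* acc) {
  gibbs_sweep(P, s, variant, hy, segs, ev);
  if (move_parents) {
    acc[1]++;
    if (parent_move(P, s, variant, hy, segs, ev)) acc[0]++;
  }
  if (!fix_tau) {
    acc[3]++;
    if (cp_move(P, s, variant, hy, min_seg_len, segs, ev)) acc[2]++;
  }
}

static Problem make_problem(const NumericVector& y, const NumericMatrix& Xc,
                            const LogicalVector& valid) {
  Problem P;
  P.Tall = y.size();
  P.n = Xc.ncol();
  P.y = arma::vec(y.begin(), y.size());
  P.Xc = arma::mat(Xc.begin(), Xc.nrow(), Xc.ncol());
  P.valid.assign(P.Tall, true);
  for (int t = 0; t < P.Tall; ++t) P.valid[t] = valid[t];
  return P;
}

static State init_state(const Problem& P, int variant, const Hyper& hy,
                        const std::vector<int>& tau0) {
  State s;
  s.tau = tau0;
  s.lam_u = rinvgamma(hy.a_u, hy.b_u);
  s.lam_c = rinvgamma(hy.a_c, hy.b_c);
  int H = (int)tau0.size() + 1;
  if (variant == 3) {
    s.delta.assign(H - 1, 0);
    for (int i = 0; i < H - 1; ++i) s.delta[i] = (R::unif_rand() < 0.5);
  }
  if (variant == 4) {
    s.lam_h.assign(H - 1, 1.0);
    for (int i = 0; i < H - 1; ++i) s.lam_h[i] = rinvgamma(hy.a_c, hy.b_c);
  }
  return s;
}

// [[Rcpp::export]]
List cpp_run_chain(NumericVector y, NumericMatrix Xc, LogicalVector valid,
                   int variant, List hyper, int V, double burn_in_frac,
                   int thinning, bool fix_tau, IntegerVector init_tau,
                   int min_seg_len, bool move_parents) {
  Hyper hy = read_hyper(hyper);
  Problem P = make_problem(y, Xc, valid);
  std::vector<int> tau0(init_tau.begin(), init_tau.end());
  State s = init_state(P, variant, hy, tau0);
  std::vector<Seg> segs = build_segments(P, s.pi, s.tau);
  Eval ev = eval_model(segs, variant, s, hy, true);

  int burn = (int)std::floor(burn_in_frac * V);
  int W = (V - burn) / thinning;
  if (W < 0) W = 0;
  List out_pi(W), out_tau(W), out_delta(W), out_lamh(W);
  NumericVector out_lamu(W), out_lamc(W), out_logml(W);
  int acc[4] = {0, 0, 0, 0}; // parent acc/att, cp acc/att
  int w = 0;
  for (int v = 1; v <= V; ++v) {
    do_iteration(P, s, variant, hy, min_seg_len, fix_tau, move_parents,
                 segs, ev, acc);
    if (v > burn && (v - burn) % thinning == 0 && w < W) {
      IntegerVector pi1(s.pi.size());
      for (size_t i = 0; i < s.pi.size(); ++i) pi1[i] = s.pi[i] + 1;
      out_pi[w] = pi1;
      out_tau[w] = IntegerVector(s.tau.begin(), s.tau.end());
      out_delta[w] = IntegerVector(s.delta.begin(), s.delta.end());
      out_lamh[w] = NumericVector(s.lam_h.begin(), s.lam_h.end());
      out_lamu[w] = s.lam_u;
      out_lamc[w] = s.lam_c;
      out_logml[w] = ev.logml;
      w++;
    }
  }
  return List::create(
      _["pi"] = out_pi, _["tau"] = out_tau, _["delta"] = out_delta,
      _["lambda_h"] = out_lamh, _["lambda_u"] = out_lamu,
      _["lambda_c"] = out_lamc, _["log_marginal"] = out_logml,
      _["accept"] = List::create(
          _["parent_accepted"] = acc[0], _["parent_attempted"] = acc[1],
          _["changepoint_accepted"] = acc[2],
          _["changepoint_attempted"] = acc[3]));
}

// Closed-form log marginal likelihood for a fixed state; used to
// cross-check the C++ path against the R reference implementation.
// [[Rcpp::export]]
double cpp_log_marginal(NumericVector y, NumericMatrix Xc,
                        LogicalVector valid, IntegerVector pi,
                        IntegerVector tau, int variant, double lambda_u,
                        double lambda_c, NumericVector lambda_h,
                        IntegerVector delta, List hyper) {
  Hyper hy = read_hyper(hyper);
  Problem P = make_problem(y, Xc, valid);
  State s;
  for (int j : pi) s.pi.push_back(j - 1);
  std::sort(s.pi.begin(), s.pi.end());
  s.tau.assign(tau.begin(), tau.end());
  s.lam_u = lambda_u;
  s.lam_c = lambda_c;
  s.lam_h.assign(lambda_h.begin(), lambda_h.end());
  s.delta.assign(delta.begin(), delta.end());
  std::vector<Seg> segs = build_segments(P, s.pi, s.tau);
  return eval_model(segs, variant, s, hy, false).logml;
}

// ---------------------------------------------------------------------
// Geweke successive-conditional simulator: alternates (a) drawing a
// response vector from the model given the current (pi, tau, theta) --
// with w_h and sigma^2 drawn from their priors and marginalized by
// discarding -- and (b) one full MCMC iteration on (pi, tau, theta).
// If every update is correct, the marginals of (pi, tau, theta) equal
// their priors.  Returns a trace matrix with columns
// inv_lambda_u, inv_lambda_c, pi_size, H, delta_mean.
// [[Rcpp::export]]
NumericMatrix cpp_geweke(NumericMatrix Xc, int Tall, int variant, List hyper,
                         int nsweep, int min_seg_len, bool fix_tau,
                         IntegerVector init_tau) {
  Hyper hy = read_hyper(hyper);
  Problem P;
  P.Tall = Tall;
  P.n = Xc.ncol();
  P.Xc = arma::mat(Xc.begin(), Xc.nrow(), Xc.ncol());
  P.y = arma::vec(Tall, arma::fill::zeros);
  P.valid.assign(Tall, true);

  // initial structure from the prior
  std::vector<int> tau0(init_tau.begin(), init_tau.end());
  if (!fix_tau) {
    tau0.clear();
    for (int t = 1; t <= Tall - 1; ++t)
      if (R::unif_rand() < hy.p_cp) tau0.push_back(t);
  }
  State s = init_state(P, variant, hy, tau0);
  {
    // parent set: uniform over all sets of size <= fan_in
    int n = P.n, F = std::min(hy.fan_in, n);
    std::vector<double> cum;
    double tot = 0.0;
    for (int j = 0; j <= F; ++j) {
      tot += R::choose(n, j);
      cum.push_back(tot);
    }
    double u = R::unif_rand() * tot;
    int size = 0;
    while (size < F && u > cum[size]) size++;
    std::vector<int> perm(n);
    for (int j = 0; j < n; ++j) perm[j] = j;
    for (int j = 0; j < size; ++j) {
      int pick = j + (int)std::floor(R::unif_rand() * (n - j));
      std::swap(perm[j], perm[pick]);
      s.pi.push_back(perm[j]);
    }
    std::sort(s.pi.begin(), s.pi.end());
  }

  NumericMatrix trace(nsweep, 5);
  colnames(trace) = CharacterVector::create("inv_lambda_u", "inv_lambda_c",
                                            "pi_size", "H", "delta_mean");
  int acc[4] = {0, 0, 0, 0};
  for (int it = 0; it < nsweep; ++it) {
    // (a) regenerate the response from the generative model
    std::vector<Seg> segs = build_segments(P, s.pi, s.tau);
    int H = (int)segs.size();
    int k1 = (int)segs[0].X.n_cols;
    double sig2 = rinvgamma(hy.a_sig, hy.b_sig);
    std::vector<int> bounds;
    bounds.push_back(0);
    for (int t : s.tau) bounds.push_back(t);
    bounds.push_back(Tall);
    arma::vec w_prev(k1, arma::fill::zeros);
    for (int h = 0; h < H; ++h) {
      double lam; bool coupled;
      seg_lambda(variant, s, h, lam, coupled);
      arma::vec mu = coupled ? w_prev : arma::vec(k1, arma::fill::zeros);
      arma::vec wh(k1);
      for (int j = 0; j < k1; ++j)
        wh(j) = mu(j) + std::sqrt(sig2 * lam) * R::norm_rand();
      arma::vec yh = segs[h].X * wh;
      int i = 0;
      for (int t = bounds[h] + 1; t <= bounds[h + 1]; ++t) {
        P.y(t - 1) = yh(i) + std::sqrt(sig2) * R::norm_rand();
        segs[h].y(i) = P.y(t - 1);
        i++;
      }
      // posterior mean on the freshly generated data feeds the next
      // segment's coupled prior mean
      arma::mat A = segs[h].X.t() * segs[h].X;
      A.diag() += 1.0 / lam;
      arma::vec rhs = mu / lam + segs[h].X.t() * segs[h].y;
      w_prev = arma::solve(A, rhs);
    }
    // (b) one MCMC iteration on (pi, tau, theta)
    Eval ev = eval_model(segs, variant, s, hy, true);
    do_iteration(P, s, variant, hy, min_seg_len, fix_tau, true, segs, ev,
                 acc);
    trace(it, 0) = 1.0 / s.lam_u;
    trace(it, 1) = 1.0 / s.lam_c;
    trace(it, 2) = (double)s.pi.size();
    trace(it, 3) = (double)(s.tau.size() + 1);
    double dm = 0.0;
    if (!s.delta.empty()) {
      for (int d : s.delta) dm += d;
      dm /= s.delta.size();
    }
    trace(it, 4) = dm;
  }
  return trace;
}
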
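#include <Rcpp.h>
using namespace Rcpp;

// Three latent states: Initial (entered at first capture), Resident, Dead.
// Transition over one interval with survival phi and residence psi:
//   Initial  -> (0, phi*psi, 1 - phi*psi)
//   Resident -> (0, phi,     1 - phi)
//   Dead     -> (0, 0,       1)
// Observation: only Residents can be detected (prob p); Initial and Dead never.
//
// hist_ll: exact marginal log probability of the detections after first
// capture, by a scaled forward recursion over the latent states. phi_row has
// one entry per interval t -> t+1 (index t-1, 0-based t-2), p_row one entry
// per recapture occasion 2..T (index t-2). Conditioning: state Initial with
// probability 1 at occasion f.
static double hist_ll(const int *det, int T, int f,
                      const double *phi_row, const double *p_row, double psi) {
  if (f >= T) return 0.0;
  double aI = 1.0, aR = 0.0, aD = 0.0, ll = 0.0;
  for (int t = f + 1; t <= T; ++t) {
    double ph = phi_row[t - 2];
    double nR = aI * ph * psi + aR * ph;
    double nD = aI * (1.0 - ph * psi) + aR * (1.0 - ph) + aD;
    double p = p_row[t - 2];
    if (det[t - 1]) {
      aR = nR * p; aD = 0.0;
    } else {
      aR = nR * (1.0 - p); aD = nD;
    }
    aI = 0.0;
    double c = aR + aD;
    if (c <= 0.0) return R_NegInf;
    ll += std::log(c);
    aR /= c; aD /= c;
  }
  return ll;
}

// [[Rcpp::export]]
double hist_loglik_cpp(IntegerVector det, int f, NumericVector phi,
                       NumericVector p, double psi) {
  return hist_ll(det.begin(), det.size(), f, phi.begin(), p.begin(), psi);
}

static double site_ll_c(const IntegerMatrix &pat, const IntegerVector &cnt,
                        const IntegerVector &first, int T,
                        const double *phi_row, const double *p_row,
                        double psi, std::vector<int> &buf) {
  double ll = 0.0;
  int n = pat.nrow();
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < T; ++t) buf[t] = pat(i, t);
    double li = hist_ll(buf.data(), T, first[i], phi_row, p_row, psi);
    if (li == R_NegInf) return R_NegInf;
    ll += cnt[i] * li;
  }
  return ll;
}

// [[Rcpp::export]]
double site_loglik_cpp(IntegerMatrix patterns, IntegerVector counts,
                       IntegerVector first, NumericVector phi,
                       NumericVector p, double psi) {
  int T = patterns.ncol();
  std::vector<int> buf(T);
  return site_ll_c(patterns, counts, first, T, phi.begin(), p.begin(), psi, buf);
}

// [[Rcpp::export]]
double total_loglik_cpp(List site_data, NumericMatrix phi_st,
                        NumericMatrix p_st, NumericVector psi) {
  int S = site_data.size();
  double ll = 0.0;
  for (int s = 0; s < S; ++s) {
    List sd = site_data[s];
    IntegerMatrix pat = sd["patterns"];
    IntegerVector cnt = sd["counts"];
    IntegerVector first = sd["first"];
    int T = pat.ncol();
    std::vector<int> buf(T);
    NumericMatrix::Row phr = phi_st(s, _);
    NumericMatrix::Row pr = p_st(s, _);
    std::vector<double> phv(phr.begin(), phr.end()), pv(pr.begin(), pr.end());
    double ls = site_ll_c(pat, cnt, first, T, phv.data(), pv.data(), psi[s], buf);
    if (ls == R_NegInf) return R_NegInf;
    ll += ls;
  }
  return ll;
}

static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Adaptive random-walk Metropolis-within-Gibbs over the full parameter
// vector. Scalar updates; sigmas proposed on the log scale, psi on the
// logit scale, everything else on its natural (logit-linear) scale.
// Proposal scales adapt toward target_accept during burn-in only.
//
// Parameter layout (0-based):
//   0 mu, 1 beta, [2, 2+S) eta, [2+S, 2+S+K) eps,
//   [2+S+K, 2+S+K+S*K) gamma (site-major), then sigma_space, sigma_time,
//   sigma_gamma, then [., .+S) psi.   K = T - 1.
// [[Rcpp::export]]
List run_chain_cpp(List site_data, int T, NumericVector init,
                   LogicalVector update, List settings) {
  int S = site_data.size();
  int K = T - 1;
  int P = init.size();
  int i_eta = 2, i_eps = 2 + S, i_gam = 2 + S + K;
  int i_sig = i_gam + S * K;           // sigma_space, +1 time, +2 gamma
  int i_psi = i_sig + 3;
  if (P != i_psi + S) stop("parameter vector length mismatch");

  int iterations = as<int>(settings["iterations"]);
  int burn_in = as<int>(settings["burn_in"]);
  int thinning = as<int>(settings["thinning"]);
  double target = as<double>(settings["target_accept"]);
  int window = as<int>(settings["adapt_window"]);
  double logit_bound = as<double>(settings["logit_bound"]);
  double sd_upper = as<double>(settings["sd_upper"]);

  std::vector<double> th(init.begin(), init.end());

  // per-site data views
  std::vector<IntegerMatrix> pats(S);
  std::vector<IntegerVector> cnts(S), firsts(S);
  for (int s = 0; s < S; ++s) {
    List sd = site_data[s];
    pats[s] = as<IntegerMatrix>(sd["patterns"]);
    cnts[s] = as<IntegerVector>(sd["counts"]);
    firsts[s] = as<IntegerVector>(sd["first"]);
  }
  std::vector<int> buf(T);

  // linked detection probabilities
  std::vector<std::vector<double> > phi(S, std::vector<double>(K)),
      pm(S, std::vector<double>(K));
  std::vector<double> sll(S);
  auto refresh_phi_row = [&](int s) {
    for (int k = 0; k < K; ++k)
      phi[s][k] = invlogit(th[0] + th[i_eta + s] + th[i_eps + k]);
  };
  auto refresh_p_row = [&](int s) {
    for (int k = 0; k < K; ++k)
      pm[s][k] = invlogit(th[1] + th[i_gam + s * K + k]);
  };
  auto site_ll = [&](int s) {
    return site_ll_c(pats[s], cnts[s], firsts[s], T, phi[s].data(),
                     pm[s].data(), th[i_psi + s], buf);
  };
  for (int s = 0; s < S; ++s) { refresh_phi_row(s); refresh_p_row(s); sll[s] = site_ll(s); }

  std::vector<double> step(P, 0.3), lstep(P, std::log(0.3));
  std::vector<int> acc_win(P, 0), acc_post(P, 0), n_post(P, 0);
  int win_count = 0, win_index = 0;

  int nret = 0;
  for (int it = burn_in + 1; it <= iterations; ++it)
    if ((it - burn_in) % thinning == 0) ++nret;
  NumericMatrix draws(nret, P);
  int row = 0;

  RNGScope scope;
  for (int it = 1; it <= iterations; ++it) {
    bool post = it > burn_in;

    // -- mu and beta: flat prior on (-logit_bound, logit_bound)
    for (int j = 0; j <= 1; ++j) {
      if (!update[j]) continue;
      double cur = th[j], prop = cur + norm_rand() * step[j];
      bool ok = false;
      if (std::fabs(prop) < logit_bound) {
        double tot_cur = 0.0, tot_new = 0.0;
        th[j] = prop;
        std::vector<std::vector<double> > keep = (j == 0) ? phi : pm;
        std::vector<double> sll_new(S);
        for (int s = 0; s < S; ++s) {
          tot_cur += sll[s];
          if (j == 0) refresh_phi_row(s); else refresh_p_row(s);
          sll_new[s] = site_ll(s);
          tot_new += sll_new[s];
        }
        if (tot_new > R_NegInf &&
            std::log(unif_rand()) < tot_new - tot_cur) {
          sll = sll_new; ok = true;
        } else {
          th[j] = cur;
          if (j == 0) phi = keep; else pm = keep;
        }
      }
      if (ok) { ++acc_win[j]; if (post) ++acc_post[j]; }
      if (post) ++n_post[j];
    }

    // -- eta_s: N(0, sigma_space) prior, site-local likelihood
    double sig_sp = th[i_sig], sig_ti = th[i_sig + 1], sig_ga = th[i_sig + 2];
    for (int s = 0; s < S; ++s) {
      int j = i_eta + s;
      if (!update[j]) continue;
      double cur = th[j], prop = cur + norm_rand() * step[j];
      th[j] = prop;
      std::vector<double> keep = phi[s];
      refresh_phi_row(s);
      double ll_new = site_ll(s);
      double dpr = -0.5 * (prop * prop - cur * cur) / (sig_sp * sig_sp);
      bool ok = ll_new > R_NegInf &&
                std::log(unif_rand()) < ll_new - sll[s] + dpr;
      if (ok) sll[s] = ll_new;
      else { th[j] = cur; phi[s] = keep; }
      if (ok) { ++acc_win[j]; if (post) ++acc_post[j]; }
      if (post) ++n_post[j];
    }

    // -- eps_k: N(0, sigma_time) prior, global likelihood
    for (int k = 0; k < K; ++k) {
      int j = i_eps + k;
      if (!update[j]) continue;
      double cur = th[j], prop = cur + norm_rand() * step[j];
      th[j] = prop;
      double tot_cur = 0.0, tot_new = 0.0;
      std::vector<double> keep(S), sll_new(S);
      for (int s = 0; s < S; ++s) {
        keep[s] = phi[s][k];
        phi[s][k] = invlogit(th[0] + th[i_eta + s] + prop);
        tot_cur += sll[s];
        sll_new[s] = site_ll(s);
        tot_new += sll_new[s];
      }
      double dpr = -0.5 * (prop * prop - cur * cur) / (sig_ti * sig_ti);
      bool ok = tot_new > R_NegInf &&
                std::log(unif_rand()) < tot_new - tot_cur + dpr;
      if (ok) sll = sll_new;
      else { th[j] = cur; for (int s = 0; s < S; ++s) phi[s][k] = keep[s]; }
      if (ok) { ++acc_win[j]; if (post) ++acc_post[j]; }
      if (post) ++n_post[j];
    }

    // -- gamma_{s,k}: N(0, sigma_gamma) prior, site-local likelihood
    for (int s = 0; s < S; ++s) {
      for (int k = 0; k < K; ++k) {
        int j = i_gam + s * K + k;
        if (!update[j]) continue;
        double cur = th[j], prop = cur + norm_rand() * step[j];
        th[j] = prop;
        double keep = pm[s][k];
        pm[s][k] = invlogit(th[1] + prop);
        double ll_new = site_ll(s);
        double dpr = -0.5 * (prop * prop - cur * cur) / (sig_ga * sig_ga);
        bool ok = ll_new > R_NegInf &&
                  std::log(unif_rand()) < ll_new - sll[s] + dpr;
        if (ok) sll[s] = ll_new;
        else { th[j] = cur; pm[s][k] = keep; }
        if (ok) { ++acc_win[j]; if (post) ++acc_post[j]; }
        if (post) ++n_post[j];
      }
    }

    // -- sigmas: U(0, sd_upper) prior, random walk on log sigma
    //    (Jacobian exp(x); likelihood unchanged)
    for (int m = 0; m < 3; ++m) {
      int j = i_sig + m;
      if (!update[j]) continue;
      double cur = th[j];
      double x = std::log(cur), xp = x + norm_rand() * step[j];
      double prop = std::exp(xp);
      bool ok = false;
      if (prop < sd_upper) {
        int n_eff = (m == 0) ? S : (m == 1 ? K : S * K);
        int base = (m == 0) ? i_eta : (m == 1 ? i_eps : i_gam);
        double ssq = 0.0;
        for (int q = 0; q < n_eff; ++q) ssq += th[base + q] * th[base + q];
        double dlp = -0.5 * ssq * (1.0 / (prop * prop) - 1.0 / (cur * cur)) -
                     n_eff * (xp - x) + (xp - x);
        if (std::log(unif_rand()) < dlp) { th[j] = prop; ok = true; }
      }
      if (ok) { ++acc_win[j]; if (post) ++acc_post[j]; }
      if (post) ++n_post[j];
    }

    // -- psi_s: U(0,1) prior, random walk on logit psi (Jacobian psi(1-psi))
    for (int s = 0; s < S; ++s) {
      int j = i_psi + s;
      if (!update[j]) continue;
      double cur = th[j];
      double y = std::log(cur / (1.0 - cur)), yp = y + norm_rand() * step[j];
      double prop = invlogit(yp);
      th[j] = prop;
      double ll_new = site_ll(s);
      double djac = std::log(prop) + std::log(1.0 - prop) -
                    std::log(cur) - std::log(1.0 - cur);
      bool ok = ll_new > R_NegInf &&
                std::log(unif_rand()) < ll_new - sll[s] + djac;
      if (ok) sll[s] = ll_new;
      else th[j] = cur;
      if (ok) { ++acc_win[j]; if (post) ++acc_post[j]; }
      if (post) ++n_post[j];
    }

    // -- adaptation (burn-in only), Roberts-Rosenthal log-scale batches
    if (!post && ++win_count == window) {
      ++win_index;
      double delta = std::min(0.05, 1.0 / std::sqrt((double)win_index));
      for (int j = 0; j < P; ++j) {
        if (!update[j]) continue;
        double rate = (double)acc_win[j] / window;
        lstep[j] += (rate > target) ? delta : -delta;
        step[j] = std::exp(lstep[j]);
        acc_win[j] = 0;
      }
      win_count = 0;
    }

    if (post && (it - burn_in) % thinning == 0) {
      for (int j = 0; j < P; ++j) draws(row, j) = th[j];
      ++row;
    }
  }

  NumericVector acc_rate(P), steps(P);
  for (int j = 0; j < P; ++j) {
    acc_rate[j] = n_post[j] > 0 ? (double)acc_post[j] / n_post[j] : NA_REAL;
    steps[j] = step[j];
  }
  return List::create(_["draws"] = draws, _["accept_rate"] = acc_rate,
                      _["proposal_sd"] = steps);
}
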
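// Metropolis-Hastings core for the joint prior on node ages, with an optional
// JC69 pruning likelihood. Ages are in Ma before present, tips fixed at 0.
//
// Internal nodes are indexed 1..M on the R side; everything here is 0-based.
// Calibration rows: fam (0 none, 1 uniform soft-bound, 2 truncated Cauchy),
// tL, tU, tailL, tailR, p, c.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------- densities

struct Cal {
  int fam;
  double tL, tU, tailL, tailR, p, c;
};

static double cal_logpdf(const Cal &cal, double t) {
  if (cal.fam == 0) return 0.0;
  if (cal.fam == 1) {
    // uniform between bounds; exponential tails matched for continuity at
    // the bounds, carrying masses tailL / tailR
    double span = cal.tU - cal.tL;
    double core = 1.0 - cal.tailL - cal.tailR;
    double h = core / span;
    if (t < cal.tL) {
      if (cal.tailL <= 0.0) return NEG_INF;
      double lamL = h / cal.tailL;
      return std::log(h) - lamL * (cal.tL - t);
    } else if (t <= cal.tU) {
      return std::log(h);
    } else {
      if (cal.tailR <= 0.0) return NEG_INF;
      double lamR = h / cal.tailR;
      return std::log(h) - lamR * (t - cal.tU);
    }
  }
  // truncated Cauchy: location tL(1+p), scale c*tL, renormalised on [tL, Inf)
  if (t < cal.tL) return NEG_INF;
  double A = cal.tL * (1.0 + cal.p);
  double s = cal.c * cal.tL;
  double z = (t - A) / s;
  double mass = 0.5 + std::atan(cal.p / cal.c) / M_PI;
  return -std::log(M_PI * s * (1.0 + z * z)) - std::log(mass);
}

// Conditional birth-death node-age kernel on (0, t_root): density of interior
// node ages given the root age under a birth-death process with sampling
// fraction rho. Unnormalised form k(t) = r^2 e^{rt} / (a + b e^{rt})^2 with
// r = mu - lambda, a = rho*lambda, b = lambda(1-rho) - mu; closed-form
// normaliser on (0, t_root). r -> 0 collapses to the uniform kernel.
static double bd_kernel_logpdf_c(double t, double troot, int kern,
                                 double lambda, double mu, double rho) {
  if (!(t > 0.0) || !(t < troot)) return NEG_INF;
  if (kern == 0) return -std::log(troot);
  double r = mu - lambda;
  double a = rho * lambda;
  double b = lambda * (1.0 - rho) - mu;
  if (std::fabs(r) * troot < 1e-12) return -std::log(troot);
  double num = 2.0 * std::log(std::fabs(r)) + r * t -
               2.0 * std::log(a + b * std::exp(r * t));
  double Z;
  if (std::fabs(b) < 1e-12) {
    Z = r * (std::exp(r * troot) - 1.0) / (a * a);
  } else {
    Z = (r / b) * (1.0 / (a + b) - 1.0 / (a + b * std::exp(r * troot)));
  }
  return num - std::log(Z);
}

// [[Rcpp::export]]
double bd_kernel_logpdf_cpp(double t, double troot, int kern, double lambda,
                            double mu, double rho) {
  return bd_kernel_logpdf_c(t, troot, kern, lambda, mu, rho);
}

// ---------------------------------------------------------------- topology

struct Topo {
  int M, root;
  std::vector<int> parent;                // -1 at root
  std::vector<std::vector<int>> chint;    // internal children
  std::vector<std::vector<int>> chtip;    // tip children (0-based tip rows)
  std::vector<int> postorder;
};

static Topo make_topo(const IntegerVector &parent1, const List &ch_int,
                      const List &ch_tip, int root1) {
  Topo tp;
  tp.M = parent1.size();
  tp.root = root1 - 1;
  tp.parent.resize(tp.M);
  tp.chint.resize(tp.M);
  tp.chtip.resize(tp.M);
  for (int i = 0; i < tp.M; ++i) {
    tp.parent[i] = parent1[i] - 1;  // 0 on R side -> -1
    IntegerVector ci = ch_int[i], ct = ch_tip[i];
    for (int j = 0; j < ci.size(); ++j) tp.chint[i].push_back(ci[j] - 1);
    for (int j = 0; j < ct.size(); ++j) tp.chtip[i].push_back(ct[j] - 1);
  }
  // iterative postorder
  std::vector<int> stack, order;
  stack.push_back(tp.root);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    order.push_back(v);
    for (int c : tp.chint[v]) stack.push_back(c);
  }
  tp.postorder.assign(order.rbegin(), order.rend());
  return tp;
}

static double child_floor(const Topo &tp, const std::vector<double> &age,
                          int i) {
  double lo = 0.0;
  for (int c : tp.chint[i]) lo = std::max(lo, age[c]);
  return lo;
}

// ---------------------------------------------------------------- likelihood

struct LikData {
  bool use;
  int P;
  std::vector<std::vector<int>> tip;  // [tip][pattern], -1 = ambiguous
  std::vector<double> w;
};

static void node_partial(int i, const std::vector<double> &age, double rate,
                         const Topo &tp, const LikData &ld,
                         std::vector<std::vector<double>> &part) {
  int P = ld.P;
  std::vector<double> &out = part[i];
  std::fill(out.begin(), out.end(), 1.0);
  for (int j : tp.chint[i]) {
    double v = rate * (age[i] - age[j]);
    double e = std::exp(-4.0 * v / 3.0);
    double ps = 0.25 + 0.75 * e, pd = 0.25 - 0.25 * e;
    const std::vector<double> &L = part[j];
    for (int q = 0; q < P; ++q) {
      double sum = L[4 * q] + L[4 * q + 1] + L[4 * q + 2] + L[4 * q + 3];
      for (int x = 0; x < 4; ++x) {
        double lx = L[4 * q + x];
        out[4 * q + x] *= ps * lx + pd * (sum - lx);
      }
    }
  }
  for (int tj : tp.chtip[i]) {
    double v = rate * age[i];
    double e = std::exp(-4.0 * v / 3.0);
    double ps = 0.25 + 0.75 * e, pd = 0.25 - 0.25 * e;
    const std::vector<int> &st = ld.tip[tj];
    for (int q = 0; q < P; ++q) {
      int s = st[q];
      if (s < 0) continue;
      for (int x = 0; x < 4; ++x) out[4 * q + x] *= (x == s ? ps : pd);
    }
  }
}

static double root_loglik(const Topo &tp, const LikData &ld,
                          const std::vector<std::vector<double>> &part) {
  const std::vector<double> &L = part[tp.root];
  double ll = 0.0;
  for (int q = 0; q < ld.P; ++q) {
    double s =
        0.25 * (L[4 * q] + L[4 * q + 1] + L[4 * q + 2] + L[4 * q + 3]);
    ll += ld.w[q] * std::log(s);
  }
  return ll;
}

static LikData make_lik(bool use_lik, const IntegerMatrix &patterns,
                        const NumericVector &pat_w) {
  LikData ld;
  ld.use = use_lik;
  ld.P = use_lik ? patterns.ncol() : 0;
  if (use_lik) {
    int ntip = patterns.nrow();
    ld.tip.resize(ntip);
    for (int t = 0; t < ntip; ++t) {
      ld.tip[t].resize(ld.P);
      for (int q = 0; q < ld.P; ++q) ld.tip[t][q] = patterns(t, q);
    }
    ld.w.assign(pat_w.begin(), pat_w.end());
  }
  return ld;
}

// [[Rcpp::export]]
double jc69_loglik_cpp(IntegerVector parent, List ch_int, List ch_tip,
                       int root, NumericVector ages, double rate,
                       IntegerMatrix patterns, NumericVector pat_w) {
  Topo tp = make_topo(parent, ch_int, ch_tip, root);
  LikData ld = make_lik(true, patterns, pat_w);
  std::vector<double> age(ages.begin(), ages.end());
  std::vector<std::vector<double>> part(tp.M,
                                        std::vector<double>(4 * ld.P));
  for (int v : tp.postorder) node_partial(v, age, rate, tp, ld, part);
  return root_loglik(tp, ld, part);
}

// ---------------------------------------------------------------- joint prior

static std::vector<Cal> make_cals(const NumericMatrix &calmat) {
  std::vector<Cal> cals(calmat.nrow());
  for (int i = 0; i < calmat.nrow(); ++i) {
    cals[i].fam = (int)calmat(i, 0);
    cals[i].tL = calmat(i, 1);
    cals[i].tU = calmat(i, 2);
    cals[i].tailL = calmat(i, 3);
    cals[i].tailR = calmat(i, 4);
    cals[i].p = calmat(i, 5);
    cals[i].c = calmat(i, 6);
  }
  return cals;
}

// kernel-counted nodes: non-root nodes that receive the tree-prior kernel
// factor. Conditional construction: uncalibrated nodes only; multiplicative:
// all non-root nodes.
static std::vector<bool> counted_nodes(const Topo &tp,
                                       const std::vector<Cal> &cals,
                                       int construction) {
  std::vector<bool> cnt(tp.M, false);
  for (int i = 0; i < tp.M; ++i) {
    if (i == tp.root) continue;
    cnt[i] = (construction == 1) || (cals[i].fam == 0);
  }
  return cnt;
}

static double joint_logprior(const Topo &tp, const std::vector<Cal> &cals,
                             const std::vector<bool> &cnt, int kern,
                             double lambda, double mu, double rho,
                             const std::vector<double> &age) {
  double troot = age[tp.root];
  double lp = 0.0;
  for (int i = 0; i < tp.M; ++i) {
    if (!(age[i] > 0.0)) return NEG_INF;
    if (tp.parent[i] >= 0 && !(age[tp.parent[i]] > age[i])) return NEG_INF;
    if (cals[i].fam != 0) lp += cal_logpdf(cals[i], age[i]);
    if (cnt[i]) lp += bd_kernel_logpdf_c(age[i], troot, kern, lambda, mu, rho);
    if (!std::isfinite(lp)) return NEG_INF;
  }
  return lp;
}

// [[Rcpp::export]]
double joint_logprior_cpp(NumericVector ages, IntegerVector parent,
                          List ch_int, List ch_tip, int root,
                          NumericMatrix calmat, int construction, int kern,
                          double lambda, double mu, double rho) {
  Topo tp = make_topo(parent, ch_int, ch_tip, root);
  std::vector<Cal> cals = make_cals(calmat);
  std::vector<bool> cnt = counted_nodes(tp, cals, construction);
  std::vector<double> age(ages.begin(), ages.end());
  return joint_logprior(tp, cals, cnt, kern, lambda, mu, rho, age);
}

// ---------------------------------------------------------------- MH chain

// [[Rcpp::export]]
List mh_chain_cpp(IntegerVector parent, List ch_int, List ch_tip, int root,
                  NumericMatrix calmat, int construction, int kern,
                  double lambda, double mu, double rho,
                  NumericVector init_ages, int n_iter, int burn_in, int thin,
                  bool use_lik, IntegerMatrix patterns, NumericVector pat_w,
                  double init_rate, double rate_shape, double rate_rate,
                  double root_step, double rate_step, bool tune) {
  Topo tp = make_topo(parent, ch_int, ch_tip, root);
  std::vector<Cal> cals = make_cals(calmat);
  std::vector<bool> cnt = counted_nodes(tp, cals, construction);
  LikData ld = make_lik(use_lik, patterns, pat_w);

  std::vector<double> age(init_ages.begin(), init_ages.end());
  double rate = init_rate;

  double lp = joint_logprior(tp, cals, cnt, kern, lambda, mu, rho, age);
  if (!std::isfinite(lp)) stop("initial state has zero prior density");

  std::vector<std::vector<double>> part;
  double ll = 0.0;
  if (ld.use) {
    part.assign(tp.M, std::vector<double>(4 * ld.P));
    for (int v : tp.postorder) node_partial(v, age, rate, tp, ld, part);
    ll = root_loglik(tp, ld, part);
  }

  // ancestor path (node -> root) per node, precomputed
  std::vector<std::vector<int>> path(tp.M);
  for (int i = 0; i < tp.M; ++i)
    for (int v = i; v >= 0; v = tp.parent[v]) path[i].push_back(v);

  int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix draws(std::max(n_keep, 0), tp.M);
  NumericVector rate_draws(ld.use ? std::max(n_keep, 0) : 0);
  int kept = 0;

  long n_slide = 0, a_slide = 0;
  long n_root = 0, a_root = 0, n_rate = 0, a_rate = 0;
  long w_root = 0, wa_root = 0, w_rate = 0, wa_rate = 0;  // tuning windows

  std::vector<std::vector<double>> backup;  // partial backups along a path
  backup.reserve(32);

  for (int it = 0; it < n_iter; ++it) {
    // ---- per-node uniform slide within (oldest child, parent age)
    for (int i = 0; i < tp.M; ++i) {
      if (i == tp.root) continue;
      double lo = child_floor(tp, age, i);
      double hi = age[tp.parent[i]];
      if (!(hi > lo)) continue;
      double told = age[i];
      double tnew = lo + (hi - lo) * unif_rand();
      ++n_slide;
      double delta = 0.0;
      if (cals[i].fam != 0)
        delta += cal_logpdf(cals[i], tnew) - cal_logpdf(cals[i], told);
      if (cnt[i] && kern == 1) {
        double troot = age[tp.root];
        delta += bd_kernel_logpdf_c(tnew, troot, kern, lambda, mu, rho) -
                 bd_kernel_logpdf_c(told, troot, kern, lambda, mu, rho);
      }
      double ll_new = ll;
      if (ld.use) {
        backup.clear();
        for (int v : path[i]) backup.push_back(part[v]);
        age[i] = tnew;
        for (int v : path[i]) node_partial(v, age, rate, tp, ld, part);
        ll_new = root_loglik(tp, ld, part);
        age[i] = told;
        delta += ll_new - ll;
      }
      if (std::isfinite(delta) && std::log(unif_rand()) < delta) {
        age[i] = tnew;
        lp += delta - (ld.use ? ll_new - ll : 0.0);
        if (ld.use) ll = ll_new;
        ++a_slide;
      } else if (ld.use) {
        for (size_t k = 0; k < path[i].size(); ++k)
          part[path[i][k]] = backup[k];
      }
    }

    // ---- root multiplier move
    {
      double told = age[tp.root];
      double m = std::exp(root_step * (unif_rand() - 0.5));
      double tnew = told * m;
      ++n_root;
      ++w_root;
      double lo = child_floor(tp, age, tp.root);
      if (tnew > lo) {
        double delta = std::log(m);  // Jacobian
        if (cals[tp.root].fam != 0)
          delta += cal_logpdf(cals[tp.root], tnew) -
                   cal_logpdf(cals[tp.root], told);
        for (int i = 0; i < tp.M; ++i) {
          if (!cnt[i]) continue;
          delta += bd_kernel_logpdf_c(age[i], tnew, kern, lambda, mu, rho) -
                   bd_kernel_logpdf_c(age[i], told, kern, lambda, mu, rho);
        }
        double ll_new = ll;
        if (ld.use) {
          backup.clear();
          backup.push_back(part[tp.root]);
          age[tp.root] = tnew;
          node_partial(tp.root, age, rate, tp, ld, part);
          ll_new = root_loglik(tp, ld, part);
          age[tp.root] = told;
          delta += ll_new - ll;
        }
        if (std::isfinite(delta) && std::log(unif_rand()) < delta) {
          age[tp.root] = tnew;
          lp += delta - std::log(m) - (ld.use ? ll_new - ll : 0.0);
          if (ld.use) ll = ll_new;
          ++a_root;
          ++wa_root;
        } else if (ld.use) {
          part[tp.root] = backup[0];
        }
      }
    }

    // ---- clock-rate multiplier move
    if (ld.use) {
      double rold = rate;
      double m = std::exp(rate_step * (unif_rand() - 0.5));
      double rnew = rold * m;
      ++n_rate;
      ++w_rate;
      double delta = std::log(m) +
                     (rate_shape - 1.0) * std::log(rnew / rold) -
                     rate_rate * (rnew - rold);
      std::vector<std::vector<double>> part_new = part;
      for (int v : tp.postorder) node_partial(v, age, rnew, tp, ld, part_new);
      double ll_new = root_loglik(tp, ld, part_new);
      delta += ll_new - ll;
      if (std::isfinite(delta) && std::log(unif_rand()) < delta) {
        rate = rnew;
        part.swap(part_new);
        ll = ll_new;
        ++a_rate;
        ++wa_rate;
      }
    }

    // ---- step-width tuning, burn-in only
    if (tune && it < burn_in && (it + 1) % 200 == 0) {
      if (w_root > 0) {
        double ar = (double)wa_root / w_root;
        if (ar > 0.45) root_step = std::min(root_step * 1.3, 5.0);
        if (ar < 0.15) root_step = std::max(root_step * 0.7, 1e-4);
      }
      if (ld.use && w_rate > 0) {
        double ar = (double)wa_rate / w_rate;
        if (ar > 0.45) rate_step = std::min(rate_step * 1.3, 5.0);
        if (ar < 0.15) rate_step = std::max(rate_step * 0.7, 1e-4);
      }
      w_root = wa_root = w_rate = wa_rate = 0;
    }

    if (it >= burn_in && ((it - burn_in + 1) % thin == 0) && kept < n_keep) {
      for (int i = 0; i < tp.M; ++i) draws(kept, i) = age[i];
      if (ld.use) rate_draws[kept] = rate;
      ++kept;
    }
    if ((it + 1) % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["draws"] = draws, _["rate_draws"] = rate_draws,
      _["accept"] = List::create(
          _["slide"] = n_slide ? (double)a_slide / n_slide : NA_REAL,
          _["root"] = n_root ? (double)a_root / n_root : NA_REAL,
          _["rate"] = n_rate ? (double)a_rate / n_rate : NA_REAL),
      _["steps"] = List::create(_["root_step"] = root_step,
                                _["rate_step"] = rate_step),
      _["final_logprior"] = lp, _["final_loglik"] = ll);
}
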
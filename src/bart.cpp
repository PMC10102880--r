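// Sum-of-trees (BART) sampler with optional sparse Dirichlet splitting prior
// (DART), for continuous outcomes (Gaussian errors, conjugate leaf/variance
// updates) and binary outcomes (probit link via truncated-normal data
// augmentation). Trees are updated one at a time by Metropolis-Hastings
// GROW/PRUNE moves on the Bayesian CART prior; kept posterior draws are
// serialised as flat node tables so that draw-indexed mean functions can be
// evaluated later on arbitrary feature matrices (the sequential imputation in
// the PPCM estimator feeds each draw's own simulated histories back in, so
// test-set predictions cannot be precomputed inside the sampler).
//
// Randomness comes exclusively from R's RNG, so set.seed() in R makes fits
// bit-reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int var;      // split variable, -1 for leaf
  double cut;   // split value: go left iff x[var] <= cut
  int left, right, parent;
  double mu;    // leaf parameter (only used when var == -1)
};

typedef std::vector<Node> Tree;

int leaf_of(const Tree &tr, const double *xrow, int n, int p) {
  (void)n; (void)p;
  int id = 0;
  while (tr[id].var >= 0)
    id = (xrow[tr[id].var] <= tr[id].cut) ? tr[id].left : tr[id].right;
  return id;
}

// depth by walking parents
int depth_of(const Tree &tr, int id) {
  int d = 0;
  while (tr[id].parent >= 0) { id = tr[id].parent; ++d; }
  return d;
}

void collect_leaves(const Tree &tr, std::vector<int> &out) {
  out.clear();
  for (size_t i = 0; i < tr.size(); ++i)
    if (tr[i].var < 0 && tr[i].parent != -2) out.push_back((int)i);
}

// "nog" = internal node with two leaf children (prunable)
void collect_nogs(const Tree &tr, std::vector<int> &out) {
  out.clear();
  for (size_t i = 0; i < tr.size(); ++i) {
    if (tr[i].var >= 0 && tr[i].parent != -2 &&
        tr[tr[i].left].var < 0 && tr[tr[i].right].var < 0)
      out.push_back((int)i);
  }
}

// log marginal likelihood contribution of one leaf holding residual sum s
// over n observations, leaf prior N(0, tau2), noise variance sig2
double leaf_lml(double n, double s, double sig2, double tau2) {
  double v = sig2 + n * tau2;
  return 0.5 * std::log(sig2 / v) + 0.5 * tau2 * s * s / (sig2 * v);
}

int sample_index(int n) { return (int)std::floor(unif_rand() * n) % n; }

int sample_var(const std::vector<double> &probs) {
  double u = unif_rand(), c = 0.0;
  for (size_t v = 0; v < probs.size(); ++v) {
    c += probs[v];
    if (u <= c) return (int)v;
  }
  return (int)probs.size() - 1;
}

struct Sampler {
  int n, p, ntree, numcut, minobs;
  double alpha, beta, tau2, sig2, nu, lambda;
  bool dart, probit;
  const double *X;          // n x p, column major
  std::vector<double> y;    // working response (centred/scaled, or latent z)
  std::vector<Tree> trees;
  std::vector<std::vector<double> > treefit; // per-tree fitted values on train
  std::vector<double> fhat;
  std::vector<std::vector<double> > cuts;    // per-var cutpoint grids
  std::vector<double> svar;                  // splitting probabilities
  double dart_a;

  std::vector<int> leaf_id;   // scratch: leaf index per row for one tree
  std::vector<double> resid;  // scratch

  void init(int n_, int p_, const double *X_, int ntree_, double alpha_,
            double beta_, double tau2_, int numcut_, int minobs_, bool dart_) {
    n = n_; p = p_; X = X_; ntree = ntree_;
    alpha = alpha_; beta = beta_; tau2 = tau2_;
    numcut = numcut_; minobs = minobs_; dart = dart_;
    trees.assign(ntree, Tree());
    Node root; root.var = -1; root.cut = 0; root.left = root.right = -1;
    root.parent = -1; root.mu = 0;
    for (int k = 0; k < ntree; ++k) trees[k].push_back(root);
    treefit.assign(ntree, std::vector<double>(n, 0.0));
    fhat.assign(n, 0.0);
    cuts.assign(p, std::vector<double>());
    for (int v = 0; v < p; ++v) {
      double lo = R_PosInf, hi = R_NegInf;
      for (int i = 0; i < n; ++i) {
        double x = X[(size_t)v * n + i];
        if (x < lo) lo = x;
        if (x > hi) hi = x;
      }
      if (!(hi > lo)) { lo -= 0.5; hi += 0.5; }
      cuts[v].resize(numcut);
      for (int j = 0; j < numcut; ++j)
        cuts[v][j] = lo + (hi - lo) * (j + 1.0) / (numcut + 1.0);
    }
    svar.assign(p, 1.0 / p);
    dart_a = (double)p; // a = p gives near-uniform start
    leaf_id.resize(n);
    resid.resize(n);
  }

  // assign training rows of a tree to leaves
  void assign_rows(const Tree &tr) {
    for (int i = 0; i < n; ++i) {
      int id = 0;
      while (tr[id].var >= 0)
        id = (X[(size_t)tr[id].var * n + i] <= tr[id].cut) ? tr[id].left
                                                           : tr[id].right;
      leaf_id[i] = id;
    }
  }

  void update_tree(int k) {
    Tree &tr = trees[k];
    for (int i = 0; i < n; ++i) resid[i] = y[i] - fhat[i] + treefit[k][i];

    std::vector<int> leaves, nogs;
    collect_leaves(tr, leaves);
    collect_nogs(tr, nogs);
    bool root_only = (leaves.size() == 1);
    double p_grow = root_only ? 1.0 : 0.5;
    bool try_grow = root_only || (unif_rand() < 0.5);

    assign_rows(tr);

    if (try_grow) {
      int L = leaves[sample_index((int)leaves.size())];
      int v = dart ? sample_var(svar) : sample_index(p);
      double c = cuts[v][sample_index(numcut)];
      double nl = 0, nr = 0, sl = 0, sr = 0;
      for (int i = 0; i < n; ++i) {
        if (leaf_id[i] != L) continue;
        if (X[(size_t)v * n + i] <= c) { nl += 1; sl += resid[i]; }
        else { nr += 1; sr += resid[i]; }
      }
      if (nl < minobs || nr < minobs) return; // invalid proposal
      double d = depth_of(tr, L);
      double pd = alpha * std::pow(1.0 + d, -beta);
      double pd1 = alpha * std::pow(2.0 + d, -beta);
      double log_prior = std::log(pd) + 2.0 * std::log(1.0 - pd1) -
                         std::log(1.0 - pd);
      double log_lik = leaf_lml(nl, sl, sig2, tau2) +
                       leaf_lml(nr, sr, sig2, tau2) -
                       leaf_lml(nl + nr, sl + sr, sig2, tau2);
      // nog count after the grow
      int nnog_new = (int)nogs.size() + 1;
      int par = tr[L].parent;
      if (par >= 0 && tr[tr[par].left].var < 0 && tr[tr[par].right].var < 0)
        nnog_new -= 1; // L's parent was a nog and no longer is
      double log_prop = std::log(0.5) - std::log((double)nnog_new) -
                        (std::log(p_grow) - std::log((double)leaves.size()));
      if (std::log(unif_rand()) < log_prior + log_lik + log_prop) {
        Node cl, cr;
        cl.var = cr.var = -1; cl.cut = cr.cut = 0;
        cl.left = cl.right = cr.left = cr.right = -1;
        cl.parent = cr.parent = L; cl.mu = cr.mu = 0;
        tr.push_back(cl); int il = (int)tr.size() - 1;
        tr.push_back(cr); int ir = (int)tr.size() - 1;
        tr[L].var = v; tr[L].cut = c; tr[L].left = il; tr[L].right = ir;
      }
    } else {
      if (nogs.empty()) return;
      int G = nogs[sample_index((int)nogs.size())];
      int il = tr[G].left, ir = tr[G].right;
      double nl = 0, nr = 0, sl = 0, sr = 0;
      for (int i = 0; i < n; ++i) {
        if (leaf_id[i] == il) { nl += 1; sl += resid[i]; }
        else if (leaf_id[i] == ir) { nr += 1; sr += resid[i]; }
      }
      double d = depth_of(tr, G);
      double pd = alpha * std::pow(1.0 + d, -beta);
      double pd1 = alpha * std::pow(2.0 + d, -beta);
      double log_prior = -(std::log(pd) + 2.0 * std::log(1.0 - pd1) -
                           std::log(1.0 - pd));
      double log_lik = leaf_lml(nl + nr, sl + sr, sig2, tau2) -
                       leaf_lml(nl, sl, sig2, tau2) -
                       leaf_lml(nr, sr, sig2, tau2);
      int nleaf_new = 0;
      for (size_t i = 0; i < tr.size(); ++i)
        if (tr[i].var < 0 && tr[i].parent != -2) ++nleaf_new;
      nleaf_new -= 1; // two leaves collapse into one
      double p_grow_new = (nleaf_new == 1) ? 1.0 : 0.5;
      double log_prop = std::log(p_grow_new) - std::log((double)nleaf_new) -
                        (std::log(0.5) - std::log((double)nogs.size()));
      if (std::log(unif_rand()) < log_prior + log_lik + log_prop) {
        tr[il].parent = -2; // mark dead (kept in the array, never linked)
        tr[ir].parent = -2;
        tr[G].var = -1; tr[G].left = tr[G].right = -1; tr[G].mu = 0;
      }
    }

    // draw leaf parameters and refresh the tree's fitted values
    assign_rows(tr);
    std::vector<double> cnt(tr.size(), 0.0), sum(tr.size(), 0.0);
    for (int i = 0; i < n; ++i) {
      cnt[leaf_id[i]] += 1;
      sum[leaf_id[i]] += resid[i];
    }
    for (size_t j = 0; j < tr.size(); ++j) {
      if (tr[j].var >= 0 || tr[j].parent == -2) continue;
      double v = 1.0 / (cnt[j] / sig2 + 1.0 / tau2);
      double m = v * sum[j] / sig2;
      tr[j].mu = m + std::sqrt(v) * norm_rand();
    }
    for (int i = 0; i < n; ++i) {
      double newfit = tr[leaf_id[i]].mu;
      fhat[i] += newfit - treefit[k][i];
      treefit[k][i] = newfit;
    }
  }

  void update_sigma() {
    double ssr = 0;
    for (int i = 0; i < n; ++i) {
      double e = y[i] - fhat[i];
      ssr += e * e;
    }
    sig2 = (nu * lambda + ssr) / R::rchisq(nu + n);
  }

  void update_dart() {
    // variable split counts across the ensemble
    std::vector<double> cnt(p, 0.0);
    double total = 0;
    for (int k = 0; k < ntree; ++k)
      for (size_t j = 0; j < trees[k].size(); ++j)
        if (trees[k][j].var >= 0 && trees[k][j].parent != -2) {
          cnt[trees[k][j].var] += 1; total += 1;
        }
    // s | counts ~ Dirichlet(a/p + counts)
    double norm = 0;
    for (int v = 0; v < p; ++v) {
      svar[v] = R::rgamma(dart_a / p + cnt[v], 1.0);
      if (svar[v] < 1e-300) svar[v] = 1e-300;
      norm += svar[v];
    }
    double slog = 0;
    for (int v = 0; v < p; ++v) { svar[v] /= norm; slog += std::log(svar[v]); }
    // a | s on a grid; a = p * lam / (1 - lam), lam ~ Beta(0.5, 1)
    const int ng = 60;
    std::vector<double> lp(ng);
    double mx = R_NegInf;
    for (int g = 0; g < ng; ++g) {
      double lam = (g + 1.0) / (ng + 1.0);
      double a = p * lam / (1.0 - lam);
      lp[g] = ::lgamma(a) - p * ::lgamma(a / p) + (a / p) * slog +
              (0.5 - 1.0) * std::log(lam); // Beta(0.5,1) log kernel
      if (lp[g] > mx) mx = lp[g];
    }
    double tot = 0;
    for (int g = 0; g < ng; ++g) { lp[g] = std::exp(lp[g] - mx); tot += lp[g]; }
    double u = unif_rand() * tot, c = 0;
    int pick = ng - 1;
    for (int g = 0; g < ng; ++g) { c += lp[g]; if (u <= c) { pick = g; break; } }
    double lam = (pick + 1.0) / (ng + 1.0);
    dart_a = p * lam / (1.0 - lam);
  }

  // serialise all live nodes of all trees into one matrix with local indices
  NumericMatrix serialise() const {
    int total = 0;
    for (int k = 0; k < ntree; ++k) {
      for (size_t j = 0; j < trees[k].size(); ++j)
        if (trees[k][j].parent != -2) ++total;
    }
    NumericMatrix out(total, 6); // tree, var, cut, left, right, mu
    int row = 0;
    for (int k = 0; k < ntree; ++k) {
      const Tree &tr = trees[k];
      std::vector<int> newid(tr.size(), -1);
      int local = 0;
      for (size_t j = 0; j < tr.size(); ++j)
        if (tr[j].parent != -2) newid[j] = local++;
      for (size_t j = 0; j < tr.size(); ++j) {
        if (tr[j].parent == -2) continue;
        out(row, 0) = k;
        out(row, 1) = tr[j].var;
        out(row, 2) = tr[j].cut;
        out(row, 3) = tr[j].var >= 0 ? newid[tr[j].left] : -1;
        out(row, 4) = tr[j].var >= 0 ? newid[tr[j].right] : -1;
        out(row, 5) = tr[j].mu;
        ++row;
      }
    }
    return out;
  }
};

double trunc_norm(double mean, bool positive) {
  // inverse-CDF truncated normal with unit variance
  double u = unif_rand();
  double z;
  if (positive) {
    double plo = R::pnorm(0.0, mean, 1.0, 1, 0);
    z = R::qnorm(plo + u * (1.0 - plo), mean, 1.0, 1, 0);
    if (z <= 0 || !R_FINITE(z)) z = 1e-8;
  } else {
    double phi = R::pnorm(0.0, mean, 1.0, 1, 0);
    z = R::qnorm(u * phi, mean, 1.0, 1, 0);
    if (z >= 0 || !R_FINITE(z)) z = -1e-8;
  }
  return z;
}

} // namespace

// [[Rcpp::export(name = ".bart_mcmc")]]
List bart_mcmc(NumericMatrix X, NumericVector y, int ntree, int burn,
               int ndraw, double k_scale, double power, double base,
               double nu, double q, int numcut, int minobs, bool dart,
               bool probit, double binary_offset) {
  RNGScope scope;
  int n = X.nrow(), p = X.ncol();

  Sampler s;
  double ymid = 0, ysc = 1;
  std::vector<double> yw(n);
  if (probit) {
    // latent representation: z ~ N(f + offset, 1), y = 1{z > 0}
    for (int i = 0; i < n; ++i) yw[i] = 0.0; // latents initialised below
  } else {
    double ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      if (y[i] < ymin) ymin = y[i];
      if (y[i] > ymax) ymax = y[i];
    }
    ymid = 0.5 * (ymin + ymax);
    ysc = (ymax > ymin) ? (ymax - ymin) : 1.0;
    for (int i = 0; i < n; ++i) yw[i] = (y[i] - ymid) / ysc;
  }

  double tau2;
  if (probit) {
    double tau = 3.0 / (k_scale * std::sqrt((double)ntree));
    tau2 = tau * tau;
  } else {
    double tau = 0.5 / (k_scale * std::sqrt((double)ntree));
    tau2 = tau * tau;
  }

  s.init(n, p, REAL(X), ntree, base, power, tau2, numcut, minobs, dart);
  s.probit = probit;
  s.nu = nu;

  if (probit) {
    s.sig2 = 1.0;
    s.lambda = 1.0;
    for (int i = 0; i < n; ++i)
      s.y.push_back(trunc_norm(0.0, y[i] > 0.5) - binary_offset);
  } else {
    // calibrate lambda so that P(sigma < sd(yw)) = q under nu*lambda/chisq_nu
    double mean = 0, ss = 0;
    for (int i = 0; i < n; ++i) mean += yw[i];
    mean /= n;
    for (int i = 0; i < n; ++i) ss += (yw[i] - mean) * (yw[i] - mean);
    double sdy = std::sqrt(ss / std::max(1, n - 1));
    if (sdy <= 0) sdy = 1e-3;
    double chi_q = R::qchisq(1.0 - q, nu, 1, 0);
    s.lambda = sdy * sdy * chi_q / nu;
    s.sig2 = sdy * sdy;
    s.y = yw;
  }

  List draws(ndraw);
  NumericVector sigma_draws(ndraw);
  NumericMatrix varcount(ndraw, p);

  int total = burn + ndraw;
  for (int it = 0; it < total; ++it) {
    if (probit) {
      for (int i = 0; i < n; ++i)
        s.y[i] = trunc_norm(s.fhat[i] + binary_offset, y[i] > 0.5) -
                 binary_offset;
    }
    for (int k = 0; k < ntree; ++k) s.update_tree(k);
    if (!probit) s.update_sigma();
    if (dart && it >= burn / 2) s.update_dart();
    if (it >= burn) {
      int j = it - burn;
      draws[j] = s.serialise();
      sigma_draws[j] = std::sqrt(s.sig2) * (probit ? 1.0 : ysc);
      std::vector<double> cnt(p, 0.0);
      for (int k = 0; k < ntree; ++k)
        for (size_t jj = 0; jj < s.trees[k].size(); ++jj)
          if (s.trees[k][jj].var >= 0 && s.trees[k][jj].parent != -2)
            cnt[s.trees[k][jj].var] += 1;
      for (int v = 0; v < p; ++v) varcount(j, v) = cnt[v];
    }
  }

  return List::create(_["draws"] = draws, _["sigma"] = sigma_draws,
                      _["ymid"] = ymid, _["yscale"] = ysc,
                      _["ntree"] = ntree, _["probit"] = probit,
                      _["offset"] = binary_offset,
                      _["varcount"] = varcount);
}

// [[Rcpp::export(name = ".bart_eval")]]
NumericVector bart_eval(NumericMatrix nodes, NumericMatrix X, int ntree) {
  int n = X.nrow(), nn = nodes.nrow();
  NumericVector out(n);
  const double *tre = REAL(nodes), *var = tre + nn, *cut = var + nn,
               *lft = cut + nn, *rgt = lft + nn, *mu = rgt + nn;
  const double *x = REAL(X);
  // locate block start of each tree
  std::vector<int> start(ntree + 1, nn);
  int cur = -1;
  for (int r = 0; r < nn; ++r) {
    int k = (int)tre[r];
    if (k != cur) { start[k] = r; cur = k; }
  }
  for (int k = ntree - 1; k >= 0; --k)
    if (start[k] == nn) start[k] = start[k + 1];
  double *o = REAL(out);
  for (int k = 0; k < ntree; ++k) {
    int b = start[k];
    if (b >= nn || b >= start[k + 1]) continue;
    if (var[b] < 0) { // single-leaf tree: constant shift
      double m = mu[b];
      for (int i = 0; i < n; ++i) o[i] += m;
      continue;
    }
    for (int i = 0; i < n; ++i) {
      int id = 0;
      while (var[b + id] >= 0) {
        int v = (int)var[b + id];
        id = (x[(size_t)v * n + i] <= cut[b + id]) ? (int)lft[b + id]
                                                   : (int)rgt[b + id];
      }
      o[i] += mu[b + id];
    }
  }
  return out;
}
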
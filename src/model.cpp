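// Expression-model machinery: Zellner g-prior evidence with rank-revealing
// (pseudo-solve) handling of collinear SNPs, within-block Gibbs sweeps,
// hierarchical LD-block Metropolis-Hastings moves, Rao-Blackwellized
// conditional inclusion probabilities, and the outer coupled driver that
// alternates expression-model and regulatory-model updates.

#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

double pg_draw1(double z_in); // pg.cpp

static const double COLLINEAR_TOL = 1e-9;

// log evidence of a model with R^2 and rank k, up to the gamma-independent
// constant: ((n-1-k)/2) log(1+g) - ((n-1)/2) log(1 + g (1-R^2))
static inline double log_ev(double R2, int k, double n, double g) {
  return 0.5 * (n - 1.0 - k) * std::log1p(g) -
         0.5 * (n - 1.0) * std::log1p(g * (1.0 - R2));
}

// Rank-revealing incremental Cholesky fit of an active SNP set.
// kept: columns that entered the factor (collinear columns are dropped, so
// the evidence uses the design's rank, making it invariant to duplicated
// columns). z = L^{-1} Xty[kept]; R2 = |z|^2 / yty.
struct AFit {
  arma::mat L;
  arma::vec z;
  std::vector<int> kept;
  double R2 = 0.0;
  int rank = 0;
};

static void fit_active(const arma::mat& G, const arma::vec& Xty, double yty,
                       const std::vector<int>& act, AFit& f) {
  const int k = (int)act.size();
  f.kept.clear();
  f.rank = 0;
  f.R2 = 0.0;
  if (k == 0) return;
  f.L.zeros(k, k);
  f.z.set_size(k);
  for (int idx = 0; idx < k; ++idx) {
    const int s = act[idx];
    const int r = f.rank;
    double wTw = 0.0, wTz = 0.0;
    // forward solve L w = G[kept, s], accumulating w in row r of L
    for (int i = 0; i < r; ++i) {
      double acc = G(f.kept[i], s);
      for (int m = 0; m < i; ++m) acc -= f.L(i, m) * f.L(r, m);
      double wi = acc / f.L(i, i);
      f.L(r, i) = wi;
      wTw += wi * wi;
      wTz += wi * f.z[i];
    }
    double d = G(s, s) - wTw;
    if (d <= COLLINEAR_TOL * std::max(1.0, G(s, s))) {
      for (int i = 0; i < r; ++i) f.L(r, i) = 0.0;
      continue; // collinear with columns already in: contributes nothing
    }
    double l = std::sqrt(d);
    f.L(r, r) = l;
    f.z[r] = (Xty[s] - wTz) / l;
    f.kept.push_back(s);
    f.rank++;
  }
  double ss = 0.0;
  for (int i = 0; i < f.rank; ++i) ss += f.z[i] * f.z[i];
  f.R2 = ss / yty;
  if (f.R2 > 1.0 - 1e-12) f.R2 = 1.0 - 1e-12;
}

// log Bayes factor for adding SNP s to the fitted active set
static double add_lbf(const AFit& f, int s, const arma::mat& G,
                      const arma::vec& Xty, double yty, double n, double g) {
  const int r = f.rank;
  double wTw = 0.0, wTz = 0.0;
  std::vector<double> w(r);
  for (int i = 0; i < r; ++i) {
    double acc = G(f.kept[i], s);
    for (int m = 0; m < i; ++m) acc -= f.L(i, m) * w[m];
    w[i] = acc / f.L(i, i);
    wTw += w[i] * w[i];
    wTz += w[i] * f.z[i];
  }
  double d = G(s, s) - wTw;
  if (d <= COLLINEAR_TOL * std::max(1.0, G(s, s))) return 0.0;
  double num = Xty[s] - wTz;
  double R2new = f.R2 + num * num / (d * yty);
  if (R2new > 1.0 - 1e-12) R2new = 1.0 - 1e-12;
  return log_ev(R2new, r + 1, n, g) - log_ev(f.R2, r, n, g);
}

static inline bool in_set(const std::vector<int>& v, int s) {
  return std::find(v.begin(), v.end(), s) != v.end();
}

static std::vector<int> without(const std::vector<int>& v, int s) {
  std::vector<int> out;
  out.reserve(v.size());
  for (int x : v)
    if (x != s) out.push_back(x);
  return out;
}

// One Gibbs sweep over `sweep` SNPs in random order; exact conditional
// flips. When `blk` is supplied (active-block sweeps inside the
// hierarchical sampler), a SNP that is the only included member of its
// block is skipped: emptying a block would change which coordinates the
// sweep selects (inactive blocks are never swept), an adaptive selection
// that breaks detailed balance — block deactivation belongs to the MH
// block moves, which carry the proposal correction.
static void gibbs_sweep_core(const arma::mat& G, const arma::vec& Xty,
                             double yty, double n, double g,
                             std::vector<int>& act, const arma::vec& lpo,
                             std::vector<int> sweep, int kmax,
                             const std::vector<int>* blk = nullptr) {
  // Fisher-Yates shuffle using R's RNG
  for (int i = (int)sweep.size() - 1; i > 0; --i) {
    int j = (int)(R::unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(sweep[i], sweep[j]);
  }
  AFit f;
  for (int s : sweep) {
    bool cur = in_set(act, s);
    if (cur && blk != nullptr) {
      bool last = true;
      for (int t : act)
        if (t != s && (*blk)[t] == (*blk)[s]) { last = false; break; }
      if (last) continue;
    }
    std::vector<int> base = cur ? without(act, s) : act;
    fit_active(G, Xty, yty, base, f);
    double pin;
    if (!cur && f.rank >= kmax) {
      pin = 0.0;
    } else {
      double lbf = add_lbf(f, s, G, Xty, yty, n, g);
      pin = 1.0 / (1.0 + std::exp(-(lpo[s] + lbf)));
    }
    bool newin = (R::unif_rand() < pin);
    if (newin && !cur) act.push_back(s);
    if (!newin && cur) act = without(act, s);
  }
}

// Rao-Blackwellized conditional inclusion probabilities for all p SNPs
static void rb_probs_core(const arma::mat& G, const arma::vec& Xty, double yty,
                          double n, double g, const std::vector<int>& act,
                          const arma::vec& lpo, int kmax, double* out) {
  const int p = G.n_rows;
  AFit ffull, fb;
  fit_active(G, Xty, yty, act, ffull);
  for (int s = 0; s < p; ++s) {
    double pin;
    if (in_set(act, s)) {
      std::vector<int> base = without(act, s);
      fit_active(G, Xty, yty, base, fb);
      double lbf = add_lbf(fb, s, G, Xty, yty, n, g);
      pin = 1.0 / (1.0 + std::exp(-(lpo[s] + lbf)));
    } else if (ffull.rank >= kmax) {
      pin = 0.0;
    } else {
      double lbf = add_lbf(ffull, s, G, Xty, yty, n, g);
      pin = 1.0 / (1.0 + std::exp(-(lpo[s] + lbf)));
    }
    out[s] = pin;
  }
}

// hierarchical block-level MH proposals: activate a block through its single
// best SNP, deactivate a block by dropping all its SNPs, or swap two blocks.
// Moves whose deterministic reverse proposal could not reconstruct the
// current state are auto-rejected, so every kernel leaves the target
// invariant.
static void block_moves_core(const arma::mat& G, const arma::vec& Xty,
                             double yty, double n, double g,
                             std::vector<int>& act, const arma::vec& lpo,
                             const std::vector<std::vector<int>>& bsnps,
                             const std::vector<int>& block, int n_moves,
                             int kmax) {
  const int nb = (int)bsnps.size();
  AFit f;
  for (int mv = 0; mv < n_moves; ++mv) {
    std::vector<char> bact(nb, 0);
    for (int s : act) bact[block[s]] = 1;
    std::vector<int> actB, inB;
    for (int b = 0; b < nb; ++b) (bact[b] ? actB : inB).push_back(b);
    double u = R::unif_rand();
    if (u < 0.4) { // activate
      if (inB.empty()) continue;
      int B = inB[std::min((int)(R::unif_rand() * inB.size()),
                           (int)inB.size() - 1)];
      fit_active(G, Xty, yty, act, f);
      if (f.rank >= kmax) continue;
      double bestv = -std::numeric_limits<double>::infinity();
      int bests = -1;
      for (int s : bsnps[B]) {
        double v = add_lbf(f, s, G, Xty, yty, n, g) + lpo[s];
        if (v > bestv) { bestv = v; bests = s; }
      }
      if (bests < 0) continue;
      double logacc = bestv + std::log((double)inB.size()) -
                      std::log((double)actB.size() + 1.0);
      if (std::log(R::unif_rand()) < logacc) act.push_back(bests);
    } else if (u < 0.8) { // deactivate
      if (actB.empty()) continue;
      int A = actB[std::min((int)(R::unif_rand() * actB.size()),
                            (int)actB.size() - 1)];
      std::vector<int> S, base;
      for (int s : act) (block[s] == A ? S : base).push_back(s);
      if (S.size() != 1) continue; // reverse (best-single-SNP add) infeasible
      fit_active(G, Xty, yty, base, f);
      double bestv = -std::numeric_limits<double>::infinity();
      int bests = -1;
      for (int s : bsnps[A]) {
        double v = add_lbf(f, s, G, Xty, yty, n, g) + lpo[s];
        if (v > bestv) { bestv = v; bests = s; }
      }
      if (bests != S[0]) continue;
      double logacc = -bestv + std::log((double)actB.size()) -
                      std::log((double)inB.size() + 1.0);
      if (std::log(R::unif_rand()) < logacc) act = base;
    } else { // swap
      if (actB.empty() || inB.empty()) continue;
      int A = actB[std::min((int)(R::unif_rand() * actB.size()),
                            (int)actB.size() - 1)];
      int B = inB[std::min((int)(R::unif_rand() * inB.size()),
                           (int)inB.size() - 1)];
      std::vector<int> S, base;
      for (int s : act) (block[s] == A ? S : base).push_back(s);
      if (S.size() != 1) continue;
      fit_active(G, Xty, yty, base, f);
      double bestvA = -std::numeric_limits<double>::infinity();
      int bestsA = -1;
      for (int s : bsnps[A]) {
        double v = add_lbf(f, s, G, Xty, yty, n, g) + lpo[s];
        if (v > bestvA) { bestvA = v; bestsA = s; }
      }
      if (bestsA != S[0]) continue;
      double bestvB = -std::numeric_limits<double>::infinity();
      int bestsB = -1;
      for (int s : bsnps[B]) {
        double v = add_lbf(f, s, G, Xty, yty, n, g) + lpo[s];
        if (v > bestvB) { bestvB = v; bestsB = s; }
      }
      if (bestsB < 0) continue;
      double logacc = bestvB - bestvA; // proposal counts cancel
      if (std::log(R::unif_rand()) < logacc) {
        base.push_back(bestsB);
        act = base;
      }
    }
  }
}

static std::vector<int> gamma_to_act(const IntegerVector& gamma) {
  std::vector<int> act;
  for (int s = 0; s < gamma.size(); ++s)
    if (gamma[s] == 1) act.push_back(s);
  return act;
}

static IntegerVector act_to_gamma(const std::vector<int>& act, int p) {
  IntegerVector gamma(p);
  for (int s : act) gamma[s] = 1;
  return gamma;
}

// [[Rcpp::export(name = "cpp_log_marginal")]]
List cpp_log_marginal(const arma::mat& G, const arma::vec& Xty, double yty,
                      double n, double g, IntegerVector active) {
  std::vector<int> act(active.begin(), active.end());
  AFit f;
  fit_active(G, Xty, yty, act, f);
  return List::create(_["logev"] = log_ev(f.R2, f.rank, n, g),
                      _["rank"] = f.rank, _["r2"] = f.R2);
}

// [[Rcpp::export(name = "cpp_gibbs_sweep")]]
IntegerVector cpp_gibbs_sweep(const arma::mat& G, const arma::vec& Xty,
                              double yty, double n, double g,
                              IntegerVector gamma, const arma::vec& lpo,
                              IntegerVector sweep_idx, int kmax,
                              IntegerVector block) {
  std::vector<int> act = gamma_to_act(gamma);
  std::vector<int> sweep(sweep_idx.begin(), sweep_idx.end());
  if (block.size() == gamma.size()) {
    std::vector<int> blk(block.begin(), block.end());
    gibbs_sweep_core(G, Xty, yty, n, g, act, lpo, sweep, kmax, &blk);
  } else {
    gibbs_sweep_core(G, Xty, yty, n, g, act, lpo, sweep, kmax);
  }
  return act_to_gamma(act, gamma.size());
}

// [[Rcpp::export(name = "cpp_rb_probs")]]
NumericVector cpp_rb_probs(const arma::mat& G, const arma::vec& Xty,
                           double yty, double n, double g, IntegerVector gamma,
                           const arma::vec& lpo, int kmax) {
  std::vector<int> act = gamma_to_act(gamma);
  NumericVector out(gamma.size());
  rb_probs_core(G, Xty, yty, n, g, act, lpo, kmax, REAL(out));
  return out;
}

// [[Rcpp::export(name = "cpp_block_moves")]]
IntegerVector cpp_block_moves(const arma::mat& G, const arma::vec& Xty,
                              double yty, double n, double g,
                              IntegerVector gamma, const arma::vec& lpo,
                              IntegerVector block, int n_moves, int kmax) {
  const int p = gamma.size();
  int nb = 0;
  for (int s = 0; s < p; ++s) nb = std::max(nb, block[s] + 1);
  std::vector<std::vector<int>> bsnps(nb);
  std::vector<int> blk(p);
  for (int s = 0; s < p; ++s) {
    blk[s] = block[s];
    bsnps[block[s]].push_back(s);
  }
  std::vector<int> act = gamma_to_act(gamma);
  block_moves_core(G, Xty, yty, n, g, act, lpo, bsnps, blk, n_moves, kmax);
  return act_to_gamma(act, p);
}

// The outer coupled sampler. `genes` entries carry gram (p_j x p_j), xty,
// yty, block (0-based block index per SNP), offset (0-based row offset into
// the global pair arrays). F is the global pair feature matrix (bias column
// included). Returns Rao-Blackwellized summaries plus chain diagnostics.
// [[Rcpp::export(name = "cpp_fit_coupled")]]
List cpp_fit_coupled(List genes, const arma::mat& F, const arma::vec& bprior,
                     const arma::vec& prior_prec, double nsamp, double g,
                     const arma::vec& pig, double rho, int burn_in, int n_iter,
                     int thin, int n_block_moves, int kmax, bool fix_alpha,
                     int alpha_sweeps, int store_draw_thin) {
  const int G = genes.size();
  const int N = F.n_rows, d = F.n_cols;

  std::vector<arma::mat> gram(G);
  std::vector<arma::vec> xty(G);
  std::vector<double> yty(G);
  std::vector<std::vector<int>> blk(G);
  std::vector<std::vector<std::vector<int>>> bsnps(G);
  std::vector<int> offset(G), psize(G);
  for (int j = 0; j < G; ++j) {
    List gj = genes[j];
    NumericMatrix gm = gj["gram"];
    gram[j] = arma::mat(gm.begin(), gm.nrow(), gm.ncol(), false, true);
    xty[j] = as<arma::vec>(gj["xty"]);
    yty[j] = as<double>(gj["yty"]);
    IntegerVector bb = gj["block"];
    offset[j] = as<int>(gj["offset"]);
    psize[j] = gm.nrow();
    blk[j].assign(bb.begin(), bb.end());
    int nb = 0;
    for (int s = 0; s < (int)blk[j].size(); ++s)
      nb = std::max(nb, blk[j][s] + 1);
    bsnps[j].assign(nb, {});
    for (int s = 0; s < (int)blk[j].size(); ++s)
      bsnps[j][blk[j][s]].push_back(s);
  }

  std::vector<std::vector<int>> act(G); // start: gamma all zero
  arma::vec alpha = bprior;             // start: alpha at prior mean
  arma::vec theta(N, arma::fill::zeros);
  arma::vec kappa_prior = prior_prec % bprior;

  const int n_kept = (n_iter + thin - 1) / thin;
  arma::vec pip_sum(N, arma::fill::zeros), pip1(N, arma::fill::zeros),
      pip2(N, arma::fill::zeros), th_sum(N, arma::fill::zeros),
      beta_sum(N, arma::fill::zeros), freq_sum(N, arma::fill::zeros);
  arma::vec r2_sum(G, arma::fill::zeros);
  arma::mat trace(n_kept, G, arma::fill::zeros);
  arma::mat alpha_draws(n_kept, d, arma::fill::zeros);
  std::vector<int> bd_draw, bd_pair;
  std::vector<double> bd_val;
  int n_h1 = 0, n_h2 = 0, kidx = 0;
  const double shrink = g / (1.0 + g);

  arma::vec rbbuf;
  AFit f;
  for (int it = 0; it < burn_in + n_iter; ++it) {
    bool kept = (it >= burn_in) && ((it - burn_in) % thin == 0);
    bool half2 = kept && (kidx >= n_kept / 2);
    if (kept) { if (half2) ++n_h2; else ++n_h1; }

    arma::vec eta = F * alpha;
    arma::vec q = 1.0 / (1.0 + arma::exp(-eta));

    for (int j = 0; j < G; ++j) {
      const int p = psize[j];
      const double pi1 = pig[j], pi0 = pig[j] / rho;
      arma::vec lpo(p);
      double prior_base = 0.0;
      for (int s = 0; s < p; ++s) {
        double qq = q[offset[j] + s];
        double phibar = qq * pi1 + (1.0 - qq) * pi0;
        lpo[s] = std::log(phibar) - std::log1p(-phibar);
        prior_base += -std::log1p(std::exp(lpo[s])); // log(1 - phibar)... via -log1pexp
      }

      block_moves_core(gram[j], xty[j], yty[j], nsamp, g, act[j], lpo,
                       bsnps[j], blk[j], n_block_moves, kmax);
      { // sweep SNPs of currently active blocks
        std::vector<char> bact(bsnps[j].size(), 0);
        for (int s : act[j]) bact[blk[j][s]] = 1;
        std::vector<int> sweep;
        for (size_t b = 0; b < bsnps[j].size(); ++b)
          if (bact[b])
            sweep.insert(sweep.end(), bsnps[j][b].begin(), bsnps[j][b].end());
        gibbs_sweep_core(gram[j], xty[j], yty[j], nsamp, g, act[j], lpo,
                         sweep, kmax, &blk[j]);
      }

      if (kept) {
        if ((int)rbbuf.n_elem < p) rbbuf.set_size(p);
        rb_probs_core(gram[j], xty[j], yty[j], nsamp, g, act[j], lpo, kmax,
                      rbbuf.memptr());
        for (int s = 0; s < p; ++s) {
          pip_sum[offset[j] + s] += rbbuf[s];
          (half2 ? pip2 : pip1)[offset[j] + s] += rbbuf[s];
        }
        for (int s : act[j]) freq_sum[offset[j] + s] += 1.0;

        fit_active(gram[j], xty[j], yty[j], act[j], f);
        r2_sum[j] += f.R2;
        // E[beta | gamma] = shrink * LS solution on kept columns
        arma::vec bhat(f.rank);
        for (int i = f.rank - 1; i >= 0; --i) {
          double acc = f.z[i];
          for (int m = i + 1; m < f.rank; ++m) acc -= f.L(m, i) * bhat[m];
          bhat[i] = acc / f.L(i, i);
        }
        for (int i = 0; i < f.rank; ++i)
          beta_sum[offset[j] + f.kept[i]] += shrink * bhat[i];
        double lprior = prior_base;
        for (int s : act[j]) lprior += lpo[s];
        trace(kidx, j) = log_ev(f.R2, f.rank, nsamp, g) -
                         0.5 * (nsamp - 1.0) * std::log(yty[j]) + lprior;

        if (store_draw_thin > 0 && kidx % store_draw_thin == 0 &&
            f.rank > 0) {
          double Q = yty[j] * (1.0 - shrink * f.R2);
          double sig2 = (Q / 2.0) / R::rgamma((nsamp - 1.0) / 2.0, 1.0);
          arma::vec zr(f.rank);
          for (int i = 0; i < f.rank; ++i) zr[i] = R::norm_rand();
          // solve L' u = zr for the N(0, S^{-1}) part
          arma::vec u(f.rank);
          for (int i = f.rank - 1; i >= 0; --i) {
            double acc = zr[i];
            for (int m = i + 1; m < f.rank; ++m) acc -= f.L(m, i) * u[m];
            u[i] = acc / f.L(i, i);
          }
          double sd = std::sqrt(sig2 * shrink);
          for (int i = 0; i < f.rank; ++i) {
            bd_draw.push_back(kidx);
            bd_pair.push_back(offset[j] + f.kept[i]);
            bd_val.push_back(shrink * bhat[i] + sd * u[i]);
          }
        }
      }

      // theta: exact conditional given gamma and alpha, then Bernoulli draw
      for (int s = 0; s < p; ++s) {
        double qq = q[offset[j] + s];
        int gam = in_set(act[j], s) ? 1 : 0;
        double lik1 = gam ? pi1 : (1.0 - pi1);
        double lik0 = gam ? pi0 : (1.0 - pi0);
        double tpost = qq * lik1 / (qq * lik1 + (1.0 - qq) * lik0);
        if (kept) th_sum[offset[j] + s] += tpost;
        theta[offset[j] + s] = (R::unif_rand() < tpost) ? 1.0 : 0.0;
      }
    }

    if (!fix_alpha) {
      for (int sw = 0; sw < alpha_sweeps; ++sw) {
        arma::vec psi = F * alpha;
        arma::vec om(N);
        for (int i = 0; i < N; ++i) om[i] = pg_draw1(psi[i]);
        arma::mat P = F.t() * (F.each_col() % om);
        P.diag() += prior_prec;
        arma::mat L = arma::chol(P, "lower");
        arma::vec rhs = F.t() * (theta - 0.5) + kappa_prior;
        arma::vec mu = arma::solve(arma::trimatu(L.t()),
                                   arma::solve(arma::trimatl(L), rhs));
        arma::vec zr(d);
        for (int i = 0; i < d; ++i) zr[i] = R::norm_rand();
        alpha = mu + arma::solve(arma::trimatu(L.t()), zr);
      }
    }
    if (kept) {
      alpha_draws.row(kidx) = alpha.t();
      ++kidx;
    }
  }

  arma::vec pip = pip_sum / std::max(1, kidx);
  arma::vec th = th_sum / std::max(1, kidx);
  arma::vec bm = beta_sum / std::max(1, kidx);
  arma::vec fr = freq_sum / std::max(1, kidx);
  arma::vec r2 = r2_sum / std::max(1, kidx);
  if (n_h1 > 0) pip1 /= n_h1;
  if (n_h2 > 0) pip2 /= n_h2;

  List gfin(G);
  for (int j = 0; j < G; ++j) gfin[j] = act_to_gamma(act[j], psize[j]);

  return List::create(
      _["pip"] = pip, _["pip_half1"] = pip1, _["pip_half2"] = pip2,
      _["theta_hat"] = th, _["beta_mean"] = bm, _["incl_freq"] = fr,
      _["r2"] = r2, _["trace"] = trace, _["alpha_draws"] = alpha_draws,
      _["beta_draw_iter"] = wrap(bd_draw), _["beta_draw_pair"] = wrap(bd_pair),
      _["beta_draw_value"] = wrap(bd_val), _["gamma_final"] = gfin,
      _["n_kept"] = kidx);
}
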
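// Core likelihood computations: Felsenstein pruning with per-node scaling,
// outside ("up") partials, and round-robin branch-length optimisation by
// golden-section search of per-edge likelihood profiles.
//
// The R layer prepares, per partition: tip partial matrices (pattern x 20),
// pattern weights, the eigendecomposition of the rate matrix, category
// rates and mixture weights, and the invariant-class site log-likelihoods.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Part {
  std::vector<mat> tip;   // ntip matrices, npat x 20
  vec invlog;             // log invariant-class likelihood per pattern
  vec wts;                // pattern weights
  vec evals;              // eigenvalues of the symmetrised generator
  mat U, Uinv;            // Q = U diag(evals) Uinv
  vec freqs;              // stationary frequencies
  vec rates;              // category rates
  double logwcat;         // log((1 - p_inv)/ncat)
  double logpinv;         // log(p_inv), -inf when p_inv = 0
  int npat, ncat;
};

Part part_from_list(const Rcpp::List& pl) {
  Part p;
  Rcpp::List tips = pl["tip_part"];
  for (int i = 0; i < tips.size(); ++i) {
    p.tip.push_back(Rcpp::as<mat>(tips[i]));
  }
  p.invlog = Rcpp::as<vec>(pl["inv_loglik"]);
  p.wts = Rcpp::as<vec>(pl["weights"]);
  p.evals = Rcpp::as<vec>(pl["eig_values"]);
  p.U = Rcpp::as<mat>(pl["eig_u"]);
  p.Uinv = Rcpp::as<mat>(pl["eig_uinv"]);
  p.freqs = Rcpp::as<vec>(pl["freqs"]);
  p.rates = Rcpp::as<vec>(pl["rates"]);
  p.logwcat = Rcpp::as<double>(pl["log_wcat"]);
  p.logpinv = Rcpp::as<double>(pl["log_pinv"]);
  p.npat = p.invlog.n_elem;
  p.ncat = p.rates.n_elem;
  return p;
}

// P(t) for category c: U diag(exp(evals * r_c * t)) Uinv, clamped at 0.
mat pmat(const Part& p, int c, double t) {
  mat out = p.U * diagmat(exp(p.evals * (p.rates[c] * t))) * p.Uinv;
  out.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return out;
}

struct Pass {
  // per category, per node: inside partials and log-scale vectors
  std::vector<std::vector<mat>> down;
  std::vector<std::vector<vec>> dscale;
  std::vector<std::vector<mat>> Tm;      // per category, per edge
  std::vector<std::vector<mat>> H;       // outside partials (per node)
  std::vector<std::vector<vec>> Hscale;
};

void rescale(mat& m, vec& s) {
  vec mx = max(m, 1);
  mx.transform([](double x) { return x == 0.0 ? 1.0 : x; });
  m.each_col() /= mx;
  s += log(mx);
}

// Postorder inside pass; edges are 0-based (parent, child) rows ordered so
// children precede parents.
void down_pass(const Part& p, const imat& edge, int ntip,
               const vec& lengths, Pass& ps) {
  int nn = ntip + (int)edge.n_rows / 1;  // upper bound; resized below
  nn = ntip * 2;                         // binary trees: ntip + nnode <= 2*ntip
  int E = edge.n_rows;
  int maxnode = edge.max() + 1;
  ps.down.assign(p.ncat, std::vector<mat>(maxnode));
  ps.dscale.assign(p.ncat, std::vector<vec>(maxnode));
  ps.Tm.assign(p.ncat, std::vector<mat>(E));
  (void)nn;
  for (int c = 0; c < p.ncat; ++c) {
    for (int i = 0; i < ntip; ++i) {
      ps.down[c][i] = p.tip[i];
      ps.dscale[c][i] = zeros<vec>(p.npat);
    }
    for (int r = 0; r < E; ++r) {
      int par = edge(r, 0), chd = edge(r, 1);
      mat P = pmat(p, c, lengths[r]);
      mat T = ps.down[c][chd] * P.t();
      ps.Tm[c][r] = T;
      if (ps.down[c][par].n_elem == 0) {
        ps.down[c][par] = T;
        ps.dscale[c][par] = ps.dscale[c][chd];
      } else {
        ps.down[c][par] %= T;
        ps.dscale[c][par] += ps.dscale[c][chd];
      }
      rescale(ps.down[c][par], ps.dscale[c][par]);
    }
  }
}

double root_loglik(const Part& p, const Pass& ps, int root) {
  vec total(p.npat);
  mat cols(p.npat, p.ncat + 1);
  for (int c = 0; c < p.ncat; ++c) {
    vec lik = ps.down[c][root] * p.freqs;
    lik.transform([](double x) { return x <= 0.0 ? 1e-300 : x; });
    cols.col(c) = p.logwcat + ps.dscale[c][root] + log(lik);
  }
  cols.col(p.ncat) = p.logpinv + p.invlog;
  vec mx = max(cols, 1);
  double out = 0.0;
  for (int i = 0; i < p.npat; ++i) {
    double s = 0.0;
    for (int c = 0; c <= p.ncat; ++c) {
      double d = cols(i, c) - mx[i];
      if (std::isfinite(d)) s += std::exp(d);
    }
    out += p.wts[i] * (mx[i] + std::log(s));
  }
  return out;
}

// Preorder outside pass: H[v] is the outside partial over the states of
// v's parent, excluding v's subtree.
void up_pass(const Part& p, const imat& edge, int ntip,
             const vec& lengths, Pass& ps) {
  int E = edge.n_rows;
  int maxnode = edge.max() + 1;
  int root = ntip;  // 0-based: root is node ntip
  ps.H.assign(p.ncat, std::vector<mat>(maxnode));
  ps.Hscale.assign(p.ncat, std::vector<vec>(maxnode));
  // children rows per parent
  std::vector<std::vector<int>> kids(maxnode);
  for (int r = 0; r < E; ++r) kids[edge(r, 0)].push_back(r);
  for (int c = 0; c < p.ncat; ++c) {
    std::vector<mat> G(maxnode);
    std::vector<vec> Gs(maxnode);
    G[root] = repmat(p.freqs.t(), p.npat, 1);
    Gs[root] = zeros<vec>(p.npat);
    // parents top-down: first backward-scan encounter of a parent comes
    // after the edge above it, so G[u] is always ready by then
    std::vector<char> done(maxnode, 0);
    for (int r = E - 1; r >= 0; --r) {
      int u = edge(r, 0);
      if (done[u] || G[u].n_elem == 0) continue;
      done[u] = 1;
      for (int rc : kids[u]) {
        int v = edge(rc, 1);
        mat h = G[u];
        vec s = Gs[u];
        for (int r2 : kids[u]) {
          if (r2 == rc) continue;
          h %= ps.Tm[c][r2];
          s += ps.dscale[c][edge(r2, 1)];
        }
        rescale(h, s);
        ps.H[c][v] = h;
        ps.Hscale[c][v] = s;
        if (v >= ntip) {
          G[v] = h * pmat(p, c, lengths[rc]);
          Gs[v] = s;
        }
      }
    }
  }
}

// Per-edge profile data, scale-adjusted so the objective is cheap:
// obj(t) = sum_p w_p (smax_p + log( sum_c adj_c[p] * lik_c[p](t) + inv_p )).
struct EdgeProfile {
  std::vector<mat> h, d;   // per category
  std::vector<vec> adj;    // wcat * exp(s_c - smax)
  vec smax, invterm, wts;
  const Part* part;
};

EdgeProfile edge_profile(const Part& p, const Pass& ps, const imat& edge,
                         int r) {
  EdgeProfile ep;
  ep.part = &p;
  int v = edge(r, 1);
  mat scales(p.npat, p.ncat);
  for (int c = 0; c < p.ncat; ++c) {
    scales.col(c) = ps.Hscale[c][v] + ps.dscale[c][v];
  }
  ep.smax = max(scales, 1);
  for (int c = 0; c < p.ncat; ++c) {
    ep.h.push_back(ps.H[c][v]);
    ep.d.push_back(ps.down[c][v]);
    ep.adj.push_back(exp(p.logwcat + scales.col(c) - ep.smax));
  }
  ep.invterm = exp(p.logpinv + p.invlog - ep.smax);
  ep.invterm.transform([](double x) { return std::isfinite(x) ? x : 0.0; });
  ep.wts = p.wts;
  return ep;
}

double edge_obj(const std::vector<EdgeProfile>& eps, double t) {
  double out = 0.0;
  for (const EdgeProfile& ep : eps) {
    const Part& p = *ep.part;
    vec tot = ep.invterm;
    for (int c = 0; c < p.ncat; ++c) {
      mat P = pmat(p, c, t);
      tot += ep.adj[c] % sum((ep.h[c] * P) % ep.d[c], 1);
    }
    for (int i = 0; i < p.npat; ++i) {
      out += ep.wts[i] * (ep.smax[i] + std::log(std::max(tot[i], 1e-300)));
    }
  }
  return out;
}

// Golden-section maximisation on [lo, hi].
double golden_max(const std::vector<EdgeProfile>& eps, double lo, double hi,
                  double tol, double* fbest) {
  const double gr = 0.61803398874989484;
  double a = lo, b = hi;
  double c1 = b - gr * (b - a), c2 = a + gr * (b - a);
  double f1 = edge_obj(eps, c1), f2 = edge_obj(eps, c2);
  while (b - a > tol) {
    if (f1 < f2) {
      a = c1; c1 = c2; f1 = f2;
      c2 = a + gr * (b - a);
      f2 = edge_obj(eps, c2);
    } else {
      b = c2; c2 = c1; f2 = f1;
      c1 = b - gr * (b - a);
      f1 = edge_obj(eps, c1);
    }
  }
  double x = (a + b) / 2;
  *fbest = std::max(f1, f2);
  return x;
}

double total_loglik(const std::vector<Part>& parts, const imat& edge,
                    int ntip, const vec& lengths) {
  double ll = 0.0;
  for (const Part& p : parts) {
    Pass ps;
    down_pass(p, edge, ntip, lengths, ps);
    ll += root_loglik(p, ps, ntip);
  }
  return ll;
}

std::vector<Part> parts_from_r(const Rcpp::List& parts_r) {
  std::vector<Part> parts;
  for (int i = 0; i < parts_r.size(); ++i) {
    parts.push_back(part_from_list(parts_r[i]));
  }
  return parts;
}

}  // namespace

// [[Rcpp::export]]
double cpp_tree_loglik(Rcpp::List parts_r, arma::imat edge, int ntip,
                       arma::vec lengths) {
  return total_loglik(parts_from_r(parts_r), edge, ntip, lengths);
}

// [[Rcpp::export]]
Rcpp::List cpp_optimize_lengths(Rcpp::List parts_r, arma::imat edge, int ntip,
                                arma::vec lengths, int max_sweeps, double tol,
                                double min_len, double max_len,
                                double opt_tol) {
  std::vector<Part> parts = parts_from_r(parts_r);
  int E = edge.n_rows;
  double ll = total_loglik(parts, edge, ntip, lengths);
  std::vector<double> traj{ll};

  auto sweep = [&](vec lens, bool refresh_each) {
    std::vector<Pass> passes(parts.size());
    auto build = [&]() {
      for (size_t i = 0; i < parts.size(); ++i) {
        down_pass(parts[i], edge, ntip, lens, passes[i]);
        up_pass(parts[i], edge, ntip, lens, passes[i]);
      }
    };
    build();
    for (int r = 0; r < E; ++r) {
      if (refresh_each && r > 0) build();
      std::vector<EdgeProfile> eps;
      for (size_t i = 0; i < parts.size(); ++i) {
        eps.push_back(edge_profile(parts[i], passes[i], edge, r));
      }
      double cur = edge_obj(eps, lens[r]);
      // search a bracket around the current value, expanding on boundary hits
      double lo = std::max(min_len, lens[r] / 10.0);
      double hi = std::min(max_len, std::max(lens[r] * 10.0, 0.5));
      double fbest = cur, x = lens[r];
      for (int tries = 0; tries < 4; ++tries) {
        x = golden_max(eps, lo, hi, opt_tol, &fbest);
        bool at_hi = (hi - x) < 2 * opt_tol && hi < max_len;
        bool at_lo = (x - lo) < 2 * opt_tol && lo > min_len;
        if (at_hi) {
          lo = hi * 0.5;
          hi = std::min(max_len, hi * 20.0);
        } else if (at_lo) {
          hi = lo * 2.0;
          lo = min_len;
        } else break;
      }
      if (fbest > cur) lens[r] = x;
    }
    return lens;
  };

  for (int s = 0; s < max_sweeps; ++s) {
    vec cand = sweep(lengths, false);
    double ll_new = total_loglik(parts, edge, ntip, cand);
    if (ll_new < ll) {
      cand = sweep(lengths, true);
      ll_new = total_loglik(parts, edge, ntip, cand);
    }
    if (ll_new >= ll) lengths = cand; else ll_new = ll;
    traj.push_back(ll_new);
    bool done = (ll_new - ll) < tol;
    ll = std::max(ll, ll_new);
    if (done) break;
  }
  return Rcpp::List::create(Rcpp::Named("lengths") = lengths,
                            Rcpp::Named("logL") = ll,
                            Rcpp::Named("trajectory") = traj);
}
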
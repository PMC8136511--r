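// Felsenstein pruning for amino-acid alignments with discrete-gamma rate
// categories, node-wise rescaling, and coordinate-wise branch-length
// optimisation.  Trees arrive as ape postorder edge matrices (1-based node
// ids, tips 1..ntip).  Site patterns are pre-compressed on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

const double LOG_FLOOR = -745.0;  // smallest finite double log-likelihood per site

struct Engine {
  arma::imat edge;      // nedge x 2 (parent, child), postorder
  int ntip, nnode, nedge, npat, ncat, root;
  arma::imat states;    // ntip x npat, 0..19 or -1 (ambiguous)
  arma::vec weights;    // pattern weights
  arma::mat E, Einv;    // Q = E diag(lambda) Einv
  arma::vec lambda, freq, rates;
  std::vector<std::vector<int> > child_edges;  // per node (0-based), edge idx
  std::vector<int> parent_edge;                // per node, -1 at root

  Engine(const arma::imat& edge_, int ntip_,
         const arma::imat& states_, const arma::vec& weights_,
         const arma::mat& E_, const arma::mat& Einv_,
         const arma::vec& lambda_, const arma::vec& freq_,
         const arma::vec& rates_)
      : edge(edge_), ntip(ntip_), states(states_), weights(weights_),
        E(E_), Einv(Einv_), lambda(lambda_), freq(freq_), rates(rates_) {
    nedge = edge.n_rows;
    nnode = edge.max();
    npat = states.n_cols;
    ncat = rates.n_elem;
    root = edge(nedge - 1, 0) - 1;  // postorder: last edge's parent
    child_edges.assign(nnode, std::vector<int>());
    parent_edge.assign(nnode, -1);
    for (int e = 0; e < nedge; ++e) {
      child_edges[edge(e, 0) - 1].push_back(e);
      parent_edge[edge(e, 1) - 1] = e;
    }
  }

  // P(t) = E diag(exp(lambda t)) Einv, clipped to [0, 1]
  arma::mat pmat(double t) const {
    arma::mat P = E * arma::diagmat(arma::exp(lambda * t)) * Einv;
    P.clamp(0.0, 1.0);
    return P;
  }

  // Postorder partial likelihoods for one rate category.
  // D: 20 x npat per node; sc: accumulated log-scalers per node x pattern.
  void downpass(const arma::vec& len, double rate,
                arma::cube& D, arma::mat& sc) const {
    D.set_size(20, npat, nnode);
    sc.zeros(nnode, npat);
    for (int tip = 0; tip < ntip; ++tip) {
      arma::mat L(20, npat, arma::fill::zeros);
      for (int p = 0; p < npat; ++p) {
        int s = states(tip, p);
        if (s < 0) L.col(p).ones(); else L(s, p) = 1.0;
      }
      D.slice(tip) = L;
    }
    for (int v = ntip; v < nnode; ++v) D.slice(v).ones();
    for (int e = 0; e < nedge; ++e) {
      int u = edge(e, 0) - 1, v = edge(e, 1) - 1;
      arma::mat P = pmat(len(e) * rate);
      D.slice(u) %= P * D.slice(v);
      sc.row(u) += sc.row(v);
      if (u >= ntip) {  // rescale after last child merged is fine; do per merge
        // rescale per pattern to guard underflow
        arma::rowvec m = arma::max(D.slice(u), 0);
        for (int p = 0; p < npat; ++p) {
          double mp = m(p);
          if (mp > 0 && mp < 1e-80) {
            D.slice(u).col(p) /= mp;
            sc(u, p) += std::log(mp);
          }
        }
      }
    }
  }

  // Preorder "outer" partials per edge for one rate category: for edge
  // e = (u,v), O.slice(e) is the likelihood of all data outside subtree(v)
  // as a function of the state at u, including the root prior.
  void uppass(const arma::vec& len, double rate,
              const arma::cube& D, const arma::mat& dsc,
              arma::cube& O, arma::mat& osc) const {
    O.set_size(20, npat, nedge);
    osc.zeros(nedge, npat);
    for (int e = nedge - 1; e >= 0; --e) {  // reverse postorder = preorder
      int u = edge(e, 0) - 1, v = edge(e, 1) - 1;
      arma::mat out(20, npat);
      arma::rowvec s(npat, arma::fill::zeros);
      if (u == root) {
        out.each_col() = freq;
      } else {
        int pe = parent_edge[u];
        arma::mat P = pmat(len(pe) * rate);
        out = P.t() * O.slice(pe);
        s = osc.row(pe);
      }
      for (size_t k = 0; k < child_edges[u].size(); ++k) {
        int se = child_edges[u][k];
        if (se == e) continue;
        int w = edge(se, 1) - 1;
        arma::mat P = pmat(len(se) * rate);
        out %= P * D.slice(w);
        s += dsc.row(w);
      }
      arma::rowvec m = arma::max(out, 0);
      for (int p = 0; p < npat; ++p) {
        double mp = m(p);
        if (mp > 0 && mp < 1e-80) {
          out.col(p) /= mp;
          s(p) += std::log(mp);
        }
      }
      O.slice(e) = out;
      osc.row(e) = s;
    }
  }

  // Per-pattern log-likelihoods given branch lengths.
  arma::vec site_loglik(const arma::vec& len, int* n_floored = NULL) const {
    arma::mat lognum(ncat, npat);
    arma::cube D; arma::mat sc;
    for (int c = 0; c < ncat; ++c) {
      downpass(len, rates(c), D, sc);
      arma::rowvec lik = freq.t() * D.slice(root);
      for (int p = 0; p < npat; ++p)
        lognum(c, p) = (lik(p) > 0 ? std::log(lik(p)) : -arma::datum::inf) +
                       sc(root, p);
      }
    return mix_categories(lognum, n_floored);
  }

  arma::vec mix_categories(const arma::mat& lognum, int* n_floored) const {
    arma::vec out(npat);
    int fl = 0;
    for (int p = 0; p < npat; ++p) {
      double m = lognum.col(p).max();
      double s = 0.0;
      if (std::isfinite(m)) {
        for (int c = 0; c < ncat; ++c) s += std::exp(lognum(c, p) - m);
        out(p) = m + std::log(s / ncat);
      } else {
        out(p) = -arma::datum::inf;
      }
      if (out(p) < LOG_FLOOR) { out(p) = LOG_FLOOR; ++fl; }
    }
    if (n_floored) *n_floored = fl;
    return out;
  }

  double total_loglik(const arma::vec& len, int* n_floored = NULL) const {
    return arma::dot(weights, site_loglik(len, n_floored));
  }

  // Profile of one edge: site likelihood as a function of its length t is
  //   lik_cp(t) = sum_k coef[c](k, p) * exp(lambda_k * rate_c * t)
  // (times exp(logsc[c](p))), built from cached outer/inner partials.
  struct EdgeProfile {
    std::vector<arma::mat> coef;   // per category: 20 x npat
    arma::mat logsc;               // ncat x npat
  };

  EdgeProfile edge_profile(int e,
                           const std::vector<arma::cube>& D,
                           const std::vector<arma::mat>& dsc,
                           const std::vector<arma::cube>& O,
                           const std::vector<arma::mat>& osc) const {
    EdgeProfile pr;
    pr.coef.resize(ncat);
    pr.logsc.set_size(ncat, npat);
    int v = edge(e, 1) - 1;
    for (int c = 0; c < ncat; ++c) {
      pr.coef[c] = (E.t() * O[c].slice(e)) % (Einv * D[c].slice(v));
      pr.logsc.row(c) = osc[c].row(e) + dsc[c].row(v);
    }
    return pr;
  }

  double profile_loglik(const EdgeProfile& pr, double t) const {
    arma::mat lognum(ncat, npat);
    for (int c = 0; c < ncat; ++c) {
      arma::vec ex = arma::exp(lambda * (rates(c) * t));
      arma::rowvec lik = ex.t() * pr.coef[c];
      for (int p = 0; p < npat; ++p)
        lognum(c, p) = (lik(p) > 0 ? std::log(lik(p)) : -arma::datum::inf) +
                       pr.logsc(c, p);
    }
    arma::vec sl = mix_categories(lognum, NULL);
    return arma::dot(weights, sl);
  }

  // Golden-section maximisation of the single-edge profile likelihood.
  double optimise_edge(const EdgeProfile& pr, double lo, double hi) const {
    const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
    double a = lo, b = hi;
    double c = b - gr * (b - a), d = a + gr * (b - a);
    double fc = profile_loglik(pr, c), fd = profile_loglik(pr, d);
    for (int it = 0; it < 80 && (b - a) > 1e-9 + 1e-7 * a; ++it) {
      if (fc > fd) { b = d; d = c; fd = fc; c = b - gr * (b - a); fc = profile_loglik(pr, c); }
      else         { a = c; c = d; fc = fd; d = a + gr * (b - a); fd = profile_loglik(pr, d); }
    }
    double t = (fc > fd) ? c : d;
    // snap to bounds when the optimum sits at an endpoint
    double fb = std::max(fc, fd);
    if (profile_loglik(pr, lo) >= fb) return lo;
    if (profile_loglik(pr, hi) >= fb) return hi;
    return t;
  }

  void all_partials(const arma::vec& len,
                    std::vector<arma::cube>& D, std::vector<arma::mat>& dsc,
                    std::vector<arma::cube>& O, std::vector<arma::mat>& osc) const {
    D.resize(ncat); dsc.resize(ncat); O.resize(ncat); osc.resize(ncat);
    for (int c = 0; c < ncat; ++c) {
      downpass(len, rates(c), D[c], dsc[c]);
      uppass(len, rates(c), D[c], dsc[c], O[c], osc[c]);
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_tree_loglik(const arma::imat& edge, int ntip,
                     const arma::imat& states, const arma::vec& weights,
                     const arma::mat& E, const arma::mat& Einv,
                     const arma::vec& lambda, const arma::vec& freq,
                     const arma::vec& rates, const arma::vec& lengths) {
  Engine eng(edge, ntip, states, weights, E, Einv, lambda, freq, rates);
  int fl = 0;
  arma::vec sl = eng.site_loglik(lengths, &fl);
  return List::create(_["loglik"] = arma::dot(weights, sl),
                      _["site_loglik"] = sl,
                      _["n_floored"] = fl);
}

// Coordinate-wise branch-length optimisation.  Each sweep first tries a
// fast pass that optimises every edge against partials cached at the sweep
// start (Jacobi); if the joint update fails to improve the log-likelihood,
// the sweep is redone edge by edge with fresh partials (Gauss-Seidel), which
// is an exact coordinate ascent and cannot decrease the objective.
// [[Rcpp::export]]
List cpp_optimize_bl(const arma::imat& edge, int ntip,
                     const arma::imat& states, const arma::vec& weights,
                     const arma::mat& E, const arma::mat& Einv,
                     const arma::vec& lambda, const arma::vec& freq,
                     const arma::vec& rates, const arma::vec& lengths0,
                     double min_len, double max_len,
                     int max_sweeps, double tol) {
  Engine eng(edge, ntip, states, weights, E, Einv, lambda, freq, rates);
  arma::vec len = arma::clamp(lengths0, min_len, max_len);
  double cur = eng.total_loglik(len);
  int sweeps = 0;
  bool converged = false;
  std::vector<arma::cube> D, O;
  std::vector<arma::mat> dsc, osc;
  for (sweeps = 1; sweeps <= max_sweeps; ++sweeps) {
    arma::vec prev_len = len;
    eng.all_partials(len, D, dsc, O, osc);
    arma::vec cand = len;
    for (int e = 0; e < eng.nedge; ++e) {
      Engine::EdgeProfile pr = eng.edge_profile(e, D, dsc, O, osc);
      cand(e) = eng.optimise_edge(pr, min_len, max_len);
    }
    double cand_ll = eng.total_loglik(cand);
    if (cand_ll >= cur) {
      len = cand;
    } else {
      // exact coordinate ascent fallback
      for (int e = 0; e < eng.nedge; ++e) {
        eng.all_partials(len, D, dsc, O, osc);
        Engine::EdgeProfile pr = eng.edge_profile(e, D, dsc, O, osc);
        len(e) = eng.optimise_edge(pr, min_len, max_len);
      }
      cand_ll = eng.total_loglik(len);
      if (cand_ll < cur) { len = prev_len; cand_ll = cur; }  // numerical guard
    }
    double gain = cand_ll - cur;
    cur = cand_ll;
    if (gain < tol) { converged = true; break; }
  }
  int fl = 0;
  arma::vec sl = eng.site_loglik(len, &fl);
  return List::create(_["lengths"] = len,
                      _["loglik"] = arma::dot(weights, sl),
                      _["site_loglik"] = sl,
                      _["sweeps"] = sweeps,
                      _["converged"] = converged,
                      _["n_floored"] = fl);
}

// Fitch parsimony score over bitmask-encoded site patterns.  The tree must
// be binary with a binary root; edges in ape postorder.
// [[Rcpp::export]]
double cpp_fitch_score(const arma::imat& edge, int ntip,
                       const arma::imat& masks, const arma::vec& weights) {
  int nedge = edge.n_rows, nnode = edge.max(), npat = masks.n_cols;
  arma::imat S(nnode, npat, arma::fill::zeros);
  S.rows(0, ntip - 1) = masks;
  std::vector<bool> touched(nnode, false);
  arma::vec score(npat, arma::fill::zeros);
  for (int e = 0; e < nedge; ++e) {
    int u = edge(e, 0) - 1, v = edge(e, 1) - 1;
    if (!touched[u]) {
      S.row(u) = S.row(v);
      touched[u] = true;
    } else {
      for (int p = 0; p < npat; ++p) {
        int x = S(u, p) & S(v, p);
        if (x == 0) { x = S(u, p) | S(v, p); score(p) += 1.0; }
        S(u, p) = x;
      }
    }
  }
  return arma::dot(score, weights);
}
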
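// Phylogenetic likelihood kernel: Felsenstein pruning over compressed site
// patterns with per-node underflow scaling, discrete-Gamma mixture over
// equal-weight categories, branch-length optimization by Brent's method on
// cached directional partials, and Fitch parsimony scoring.
//
// Conventions shared with the R layer:
//  * nodes are ape 1-based ids (tips 1..ntip, internals ntip+1..), converted
//    to 0-based here; the root is the node that never appears as a child;
//  * the edge matrix is in postorder (every child edge precedes its parent's
//    edge), as produced by ape::reorder.phylo(x, "postorder");
//  * leaf states are IUPAC bitmasks over (A=1, C=2, G=4, T=8); 15 = unknown;
//  * the rate matrix arrives eigendecomposed (Q = U diag(lambda) Uinv) so a
//    single decomposition serves every branch and rate category;
//  * time-reversibility implies pi_i P_ij(t) = pi_j P_ji(t), so the same P
//    propagates partials both rootward and tipward.
//
// Performance notes: tip edges use a 16-state lookup of P-transformed
// indicator vectors instead of a per-pattern matrix-vector product, and the
// branch optimizer computes outside partials for all edges in one preorder
// pass per smoothing sweep.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double SCALE_THRESHOLD = 1e-240;

struct TreeIdx {
  int ntip, nnode, nedge, root;
  std::vector<int> par, chi;        // 0-based, postorder
  std::vector<double> len;
  std::vector<int> nchild;          // children per node
  std::vector<int> parent_edge;     // edge whose child is this node, -1 at root
};

static TreeIdx index_tree(const IntegerMatrix& edge, const NumericVector& edge_len,
                          int ntip) {
  TreeIdx tr;
  tr.nedge = edge.nrow();
  tr.ntip = ntip;
  int maxnode = 0;
  for (int e = 0; e < tr.nedge; e++)
    maxnode = std::max(maxnode, std::max(edge(e, 0), edge(e, 1)));
  tr.nnode = maxnode;
  tr.par.resize(tr.nedge);
  tr.chi.resize(tr.nedge);
  tr.len.resize(tr.nedge);
  tr.nchild.assign(tr.nnode, 0);
  tr.parent_edge.assign(tr.nnode, -1);
  std::vector<bool> is_child(tr.nnode, false);
  for (int e = 0; e < tr.nedge; e++) {
    tr.par[e] = edge(e, 0) - 1;
    tr.chi[e] = edge(e, 1) - 1;
    tr.len[e] = edge_len[e];
    tr.nchild[tr.par[e]]++;
    tr.parent_edge[tr.chi[e]] = e;
    is_child[tr.chi[e]] = true;
  }
  tr.root = -1;
  for (int n = 0; n < tr.nnode; n++)
    if (!is_child[n] && tr.nchild[n] > 0) { tr.root = n; break; }
  if (tr.root < 0) stop("invalid edge matrix: no root found");
  return tr;
}

// P(t) = U diag(exp(lambda * rt)) Uinv, row-major, negatives clipped.
static inline void build_p(const double* U, const double* Uinv,
                           const double* lambda, double rt, double* P) {
  double e[4];
  for (int l = 0; l < 4; l++) e[l] = std::exp(lambda[l] * rt);
  for (int i = 0; i < 4; i++) {
    for (int j = 0; j < 4; j++) {
      double s = 0.0;
      for (int l = 0; l < 4; l++) s += U[i + 4 * l] * e[l] * Uinv[l + 4 * j];
      P[4 * i + j] = (s > 0.0) ? s : 0.0;
    }
  }
}

// tipvec[m][i] = sum_j P[i][j] * indicator_j(mask m), for all 16 masks
static inline void build_tipvec(const double* P, double* tv) {
  for (int m = 0; m < 16; m++) {
    for (int i = 0; i < 4; i++) {
      double s = 0.0;
      if (m & 1) s += P[4 * i + 0];
      if (m & 2) s += P[4 * i + 1];
      if (m & 4) s += P[4 * i + 2];
      if (m & 8) s += P[4 * i + 3];
      tv[4 * m + i] = s;
    }
  }
}

// Workspace for one (tree, alignment, model) likelihood evaluation; buffers
// are reused across categories and sweeps.
struct Work {
  int npat, ncat;
  std::vector<double> part;   // nnode*npat*4, inner partials (one category)
  std::vector<double> scal;   // nnode*npat, cumulative log-scalers
  std::vector<double> D;      // nedge*npat*4, per-edge child contribution
  std::vector<double> E;      // nnode*npat*4, outside partial at parent of node
  std::vector<double> scE;    // nnode*npat
  std::vector<double> R;      // nnode*npat*4, outside partial at node itself
  std::vector<double> scR;    // nnode*npat
  std::vector<double> sitecat;  // ncat*npat

  void alloc(const TreeIdx& tr, int npat_, int ncat_, bool branch_opt) {
    npat = npat_; ncat = ncat_;
    part.resize((size_t)tr.nnode * npat * 4);
    scal.resize((size_t)tr.nnode * npat);
    sitecat.resize((size_t)ncat * npat);
    if (branch_opt) {
      D.resize((size_t)tr.nedge * npat * 4);
      E.resize((size_t)tr.nnode * npat * 4);
      scE.resize((size_t)tr.nnode * npat);
      R.resize((size_t)tr.nnode * npat * 4);
      scR.resize((size_t)tr.nnode * npat);
    }
  }
};

// One postorder pass for a single rate category. When keepD is true the
// per-edge child contributions D_e(i) = sum_j P_e(i,j) part_child(j) are
// stored for the later outside pass.
static void down_pass(const IntegerMatrix& masks, const TreeIdx& tr,
                      const double* U, const double* Uinv, const double* lam,
                      double rcat, Work& w, bool keepD) {
  const int npat = w.npat;
  std::fill(w.part.begin() + (size_t)tr.ntip * npat * 4, w.part.end(), 1.0);
  std::fill(w.scal.begin(), w.scal.end(), 0.0);

  std::vector<int> remaining(tr.nchild);
  double P[16], tv[64];
  for (int e = 0; e < tr.nedge; e++) {
    const int chi = tr.chi[e], par = tr.par[e];
    build_p(U, Uinv, lam, tr.len[e] * rcat, P);
    double* pp = &w.part[(size_t)par * npat * 4];
    double* sp = &w.scal[(size_t)par * npat];
    double* De = keepD ? &w.D[(size_t)e * npat * 4] : nullptr;
    if (chi < tr.ntip) {
      build_tipvec(P, tv);
      for (int s = 0; s < npat; s++) {
        const double* t = tv + 4 * masks(chi, s);
        double* p = pp + 4 * s;
        p[0] *= t[0]; p[1] *= t[1]; p[2] *= t[2]; p[3] *= t[3];
        if (keepD) {
          double* d = De + 4 * s;
          d[0] = t[0]; d[1] = t[1]; d[2] = t[2]; d[3] = t[3];
        }
      }
    } else {
      const double* pc = &w.part[(size_t)chi * npat * 4];
      const double* sc = &w.scal[(size_t)chi * npat];
      for (int s = 0; s < npat; s++) {
        const double* c = pc + 4 * s;
        double* p = pp + 4 * s;
        double v0 = P[0]  * c[0] + P[1]  * c[1] + P[2]  * c[2] + P[3]  * c[3];
        double v1 = P[4]  * c[0] + P[5]  * c[1] + P[6]  * c[2] + P[7]  * c[3];
        double v2 = P[8]  * c[0] + P[9]  * c[1] + P[10] * c[2] + P[11] * c[3];
        double v3 = P[12] * c[0] + P[13] * c[1] + P[14] * c[2] + P[15] * c[3];
        p[0] *= v0; p[1] *= v1; p[2] *= v2; p[3] *= v3;
        sp[s] += sc[s];
        if (keepD) {
          double* d = De + 4 * s;
          d[0] = v0; d[1] = v1; d[2] = v2; d[3] = v3;
        }
      }
    }
    if (--remaining[par] == 0) {
      for (int s = 0; s < npat; s++) {
        double* p = pp + 4 * s;
        double m = std::max(std::max(p[0], p[1]), std::max(p[2], p[3]));
        if (m > 0.0 && m < SCALE_THRESHOLD) {
          double inv = 1.0 / m;
          p[0] *= inv; p[1] *= inv; p[2] *= inv; p[3] *= inv;
          sp[s] += std::log(m);
        }
      }
    }
  }
}

// One preorder pass computing, for every node v with parent u, the outside
// partial E[v](i) = Pr(all data outside subtree(v) | state i at u), and
// R[v](i) = Pr(same | state i at v). Uses the stored D contributions and the
// down-pass scalers; by reversibility R[v] = P_uv E[v] row-wise.
static void up_pass(const TreeIdx& tr,
                    const double* U, const double* Uinv, const double* lam,
                    double rcat, Work& w) {
  const int npat = w.npat;
  double* Rr = &w.R[(size_t)tr.root * npat * 4];
  std::fill(Rr, Rr + (size_t)npat * 4, 1.0);
  std::fill(&w.scR[(size_t)tr.root * npat],
            &w.scR[(size_t)tr.root * npat] + npat, 0.0);
  double P[16];
  // reverse postorder = parents before children
  for (int e = tr.nedge - 1; e >= 0; e--) {
    const int u = tr.par[e], v = tr.chi[e];
    double* Ev = &w.E[(size_t)v * npat * 4];
    double* sEv = &w.scE[(size_t)v * npat];
    const double* Ru = &w.R[(size_t)u * npat * 4];
    const double* sRu = &w.scR[(size_t)u * npat];
    std::copy(Ru, Ru + (size_t)npat * 4, Ev);
    std::copy(sRu, sRu + npat, sEv);
    // fold in the sibling contributions at u
    for (int e2 = 0; e2 < tr.nedge; e2++) {
      if (tr.par[e2] != u || e2 == e) continue;
      const double* De2 = &w.D[(size_t)e2 * npat * 4];
      const int c2 = tr.chi[e2];
      const double* sc2 = (c2 < tr.ntip) ? nullptr
                                         : &w.scal[(size_t)c2 * npat];
      for (int s = 0; s < npat; s++) {
        const double* d = De2 + 4 * s;
        double* ev = Ev + 4 * s;
        ev[0] *= d[0]; ev[1] *= d[1]; ev[2] *= d[2]; ev[3] *= d[3];
        if (sc2) sEv[s] += sc2[s];
      }
    }
    for (int s = 0; s < npat; s++) {  // guard against outside-partial underflow
      double* ev = Ev + 4 * s;
      double m = std::max(std::max(ev[0], ev[1]), std::max(ev[2], ev[3]));
      if (m > 0.0 && m < SCALE_THRESHOLD) {
        double inv = 1.0 / m;
        ev[0] *= inv; ev[1] *= inv; ev[2] *= inv; ev[3] *= inv;
        sEv[s] += std::log(m);
      }
    }
    if (v >= tr.ntip) {               // R only needed at internal nodes
      build_p(U, Uinv, lam, tr.len[e] * rcat, P);
      double* Rv = &w.R[(size_t)v * npat * 4];
      double* sRv = &w.scR[(size_t)v * npat];
      for (int s = 0; s < npat; s++) {
        const double* ev = Ev + 4 * s;
        double* r = Rv + 4 * s;
        r[0] = P[0]  * ev[0] + P[1]  * ev[1] + P[2]  * ev[2] + P[3]  * ev[3];
        r[1] = P[4]  * ev[0] + P[5]  * ev[1] + P[6]  * ev[2] + P[7]  * ev[3];
        r[2] = P[8]  * ev[0] + P[9]  * ev[1] + P[10] * ev[2] + P[11] * ev[3];
        r[3] = P[12] * ev[0] + P[13] * ev[1] + P[14] * ev[2] + P[15] * ev[3];
        sRv[s] = sEv[s];
      }
    }
  }
}

// Mix raw per-category site likelihoods (with per-category log-scalers) into
// the alignment lnL. The common case -- all categories share one scaler,
// typically 0 on shallow trees -- needs a single log per pattern; otherwise a
// log-sum-exp over categories handles heterogeneous scalers.
static double mix_sites(const double* Lraw, const double* const* scalers,
                        const NumericVector& weights, int npat, int ncat) {
  double lnl = 0.0;
  for (int s = 0; s < npat; s++) {
    double k0 = scalers ? scalers[0][s] : 0.0;
    bool same = true;
    if (scalers)
      for (int c = 1; c < ncat; c++)
        if (scalers[c][s] != k0) { same = false; break; }
    if (same) {
      double acc = 0.0;
      for (int c = 0; c < ncat; c++) acc += Lraw[(size_t)c * npat + s];
      if (!(acc > 0.0)) return -std::numeric_limits<double>::infinity();
      lnl += weights[s] * (std::log(acc / ncat) + k0);
    } else {
      double mx = -std::numeric_limits<double>::infinity();
      for (int c = 0; c < ncat; c++) {
        double L = Lraw[(size_t)c * npat + s];
        if (L > 0.0)
          mx = std::max(mx, std::log(L) + scalers[c][s]);
      }
      if (!std::isfinite(mx)) return -std::numeric_limits<double>::infinity();
      double acc = 0.0;
      for (int c = 0; c < ncat; c++) {
        double L = Lraw[(size_t)c * npat + s];
        acc += (L > 0.0) ? std::exp(std::log(L) + scalers[c][s] - mx) : 0.0;
      }
      lnl += weights[s] * (mx + std::log(acc / ncat));
    }
  }
  return lnl;
}

static double loglik_core(const IntegerMatrix& masks, const NumericVector& weights,
                          const TreeIdx& tr, const double* U, const double* Uinv,
                          const double* lam, const double* pi,
                          const NumericVector& cat_rates, Work& w) {
  const int npat = w.npat, ncat = w.ncat;
  std::vector<double> rootsc((size_t)ncat * npat);
  std::vector<const double*> scp(ncat);
  for (int c = 0; c < ncat; c++) {
    down_pass(masks, tr, U, Uinv, lam, cat_rates[c], w, false);
    const double* pr = &w.part[(size_t)tr.root * npat * 4];
    const double* sr = &w.scal[(size_t)tr.root * npat];
    for (int s = 0; s < npat; s++) {
      w.sitecat[(size_t)c * npat + s] =
          pi[0] * pr[4 * s] + pi[1] * pr[4 * s + 1] +
          pi[2] * pr[4 * s + 2] + pi[3] * pr[4 * s + 3];
    }
    std::copy(sr, sr + npat, &rootsc[(size_t)c * npat]);
    scp[c] = &rootsc[(size_t)c * npat];
  }
  return mix_sites(w.sitecat.data(), scp.data(), weights, npat, ncat);
}

// [[Rcpp::export(name = ".cpp_loglik")]]
double cpp_loglik(IntegerMatrix masks, NumericVector weights,
                  IntegerMatrix edge, NumericVector edge_len, int ntip,
                  NumericMatrix U, NumericMatrix Uinv, NumericVector lambda,
                  NumericVector pi, NumericVector cat_rates) {
  TreeIdx tr = index_tree(edge, edge_len, ntip);
  Work w;
  w.alloc(tr, masks.ncol(), cat_rates.size(), false);
  return loglik_core(masks, weights, tr, U.begin(), Uinv.begin(),
                     lambda.begin(), pi.begin(), cat_rates, w);
}

// Brent's method for a univariate minimum on [a, b].
template <typename F>
static double brent_min(F f, double a, double b, double tol, int maxit,
                        double* fout) {
  const double gold = 0.3819660112501051;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int it = 0; it < maxit; it++) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-8;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool parab = false;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etmp = e; e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etmp) &&
          p > q * (a - x) && p < q * (b - x)) {
        parab = true;
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
      }
    }
    if (!parab) {
      e = (x >= xm) ? a - x : b - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d >= 0) ? tol1 : -tol1);
    double fu = f(u);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = w; w = x; x = u; fv = fw; fw = fx; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; w = u; fv = fw; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  *fout = fx;
  return x;
}

// [[Rcpp::export(name = ".cpp_optimize_branches")]]
List cpp_optimize_branches(IntegerMatrix masks, NumericVector weights,
                           IntegerMatrix edge, NumericVector edge_len, int ntip,
                           NumericMatrix U, NumericMatrix Uinv,
                           NumericVector lambda, NumericVector pi,
                           NumericVector cat_rates,
                           int nsweeps, double tol,
                           double min_bl, double max_bl,
                           double brent_tol = 1e-4) {
  TreeIdx tr = index_tree(edge, edge_len, ntip);
  const int npat = masks.ncol();
  const int ncat = cat_rates.size();
  Work w;
  w.alloc(tr, npat, ncat, true);

  // per-category caches for the sweep: G = pi-premultiplied outside partial
  // at the child of each edge, B = inner partial of the child (indicator
  // masks for tips), K = combined log-scaler of both sides
  std::vector<std::vector<double> > Gc(ncat), Bc(ncat), Kc(ncat);

  double cur = loglik_core(masks, weights, tr, U.begin(), Uinv.begin(),
                           lambda.begin(), pi.begin(), cat_rates, w);
  double P[16], tv[64];
  std::vector<double> sitecat((size_t)ncat * npat);

  for (int sweep = 0; sweep < nsweeps; sweep++) {
    // one cache refresh per sweep; each edge is then optimized against the
    // sweep-start partials (simultaneous smoothing). The sweep is accepted
    // only if the exact lnL improves, so lnL is monotone across sweeps.
    std::vector<double> prev_len(tr.len);
    for (int c = 0; c < ncat; c++) {
      down_pass(masks, tr, U.begin(), Uinv.begin(), lambda.begin(),
                cat_rates[c], w, true);
      up_pass(tr, U.begin(), Uinv.begin(), lambda.begin(), cat_rates[c], w);
      if (sweep == 0) {
        Gc[c].resize((size_t)tr.nedge * npat * 4);
        Bc[c].resize((size_t)tr.nedge * npat * 4);
        Kc[c].resize((size_t)tr.nedge * npat);
      }
      for (int e = 0; e < tr.nedge; e++) {
        const int v = tr.chi[e];
        const double* Ev = &w.E[(size_t)v * npat * 4];
        double* G = &Gc[c][(size_t)e * npat * 4];
        for (int s = 0; s < npat; s++) {
          G[4 * s + 0] = pi[0] * Ev[4 * s + 0];
          G[4 * s + 1] = pi[1] * Ev[4 * s + 1];
          G[4 * s + 2] = pi[2] * Ev[4 * s + 2];
          G[4 * s + 3] = pi[3] * Ev[4 * s + 3];
        }
        double* B = &Bc[c][(size_t)e * npat * 4];
        double* K = &Kc[c][(size_t)e * npat];
        std::copy(&w.scE[(size_t)v * npat], &w.scE[(size_t)v * npat] + npat, K);
        if (v < tr.ntip) {
          for (int s = 0; s < npat; s++) {
            int m = masks(v, s);
            B[4 * s + 0] = (m & 1) ? 1.0 : 0.0;
            B[4 * s + 1] = (m & 2) ? 1.0 : 0.0;
            B[4 * s + 2] = (m & 4) ? 1.0 : 0.0;
            B[4 * s + 3] = (m & 8) ? 1.0 : 0.0;
          }
        } else {
          std::copy(&w.part[(size_t)v * npat * 4],
                    &w.part[(size_t)v * npat * 4] + (size_t)npat * 4, B);
          const double* sv = &w.scal[(size_t)v * npat];
          for (int s = 0; s < npat; s++) K[s] += sv[s];
        }
      }
    }

    std::vector<const double*> scp(ncat);
    for (int e = 0; e < tr.nedge; e++) {
      for (int c = 0; c < ncat; c++) scp[c] = &Kc[c][(size_t)e * npat];
      auto neg = [&](double t) {
        for (int c = 0; c < ncat; c++) {
          build_p(U.begin(), Uinv.begin(), lambda.begin(), t * cat_rates[c], P);
          build_tipvec(P, tv);
          const double* G = &Gc[c][(size_t)e * npat * 4];
          const double* B = &Bc[c][(size_t)e * npat * 4];
          const bool tip = tr.chi[e] < tr.ntip;
          double* out = &sitecat[(size_t)c * npat];
          for (int s = 0; s < npat; s++) {
            double L;
            const double* g = G + 4 * s;
            if (tip) {
              const double* t4 = tv + 4 * masks(tr.chi[e], s);
              L = g[0] * t4[0] + g[1] * t4[1] + g[2] * t4[2] + g[3] * t4[3];
            } else {
              const double* b = B + 4 * s;
              double v0 = P[0]*b[0] + P[1]*b[1] + P[2]*b[2] + P[3]*b[3];
              double v1 = P[4]*b[0] + P[5]*b[1] + P[6]*b[2] + P[7]*b[3];
              double v2 = P[8]*b[0] + P[9]*b[1] + P[10]*b[2] + P[11]*b[3];
              double v3 = P[12]*b[0] + P[13]*b[1] + P[14]*b[2] + P[15]*b[3];
              L = g[0]*v0 + g[1]*v1 + g[2]*v2 + g[3]*v3;
            }
            out[s] = L;
          }
        }
        return -mix_sites(sitecat.data(), scp.data(), weights, npat, ncat);
      };
      // optimize inside a window around the current length first; fall back
      // to the full range when the optimum presses against the window
      double saved = tr.len[e];
      double fsaved = neg(saved);
      double a = std::max(min_bl, saved / 8.0);
      double b = std::min(max_bl, std::max(saved * 8.0, 0.05));
      double fbest;
      double tbest = brent_min(neg, a, b, brent_tol, 25, &fbest);
      bool at_lo = (a > min_bl) && (tbest - a < 2.0 * (brent_tol * a + 1e-8));
      bool at_hi = (b < max_bl) && (b - tbest < 2.0 * (brent_tol * b + 1e-8));
      if (at_lo || at_hi)
        tbest = brent_min(neg, min_bl, max_bl, brent_tol, 30, &fbest);
      tr.len[e] = (fbest < fsaved) ? tbest : saved;
    }
    double lnl = loglik_core(masks, weights, tr, U.begin(), Uinv.begin(),
                             lambda.begin(), pi.begin(), cat_rates, w);
    if (lnl < cur) {            // simultaneous update overshot: revert
      tr.len = prev_len;
      break;
    }
    double gain = lnl - cur;
    cur = lnl;
    if (gain < tol) break;
  }
  return List::create(_["edge_length"] = NumericVector(tr.len.begin(), tr.len.end()),
                      _["loglik"] = cur);
}

// [[Rcpp::export(name = ".cpp_fitch")]]
double cpp_fitch(IntegerMatrix masks, NumericVector weights,
                 IntegerMatrix edge, int ntip) {
  NumericVector dummy_len(edge.nrow());
  TreeIdx tr = index_tree(edge, dummy_len, ntip);
  const int npat = masks.ncol();
  std::vector<int> state((size_t)tr.nnode * npat, 0);
  for (int t = 0; t < ntip; t++)
    for (int s = 0; s < npat; s++)
      state[(size_t)t * npat + s] = masks(t, s) & 15;
  std::vector<char> touched(tr.nnode, 0);
  double score = 0.0;
  for (int e = 0; e < tr.nedge; e++) {
    int p = tr.par[e], c = tr.chi[e];
    int* sp = &state[(size_t)p * npat];
    const int* sc = &state[(size_t)c * npat];
    if (!touched[p]) {
      std::copy(sc, sc + npat, sp);
      touched[p] = 1;
    } else {
      for (int s = 0; s < npat; s++) {
        int inter = sp[s] & sc[s];
        if (inter) sp[s] = inter;
        else { sp[s] |= sc[s]; score += weights[s]; }
      }
    }
  }
  return score;
}
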
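// Loopy belief propagation on the factor-graph approximation of the
// lineage- and context-dependent substitution model.
//
// Variables: one per (internal node, site), domain {A,C,G,T}.
// Factors:
//   * root chain: P(r_j | r_{j-2}, r_{j-1}) (second-order Markov root),
//     plus a joint factor over the first two root sites;
//   * branch factors: per (edge, site), coupling the child site with the
//     parent site and its two flanks in the parent (context read from the
//     ancestor); at block boundaries the missing flank is marginalized out;
//   * observed leaves enter as reduced branch factors (the child index is
//     clamped); a masked leaf observation drops its factor (its rate table
//     row-sums to 1, so it carries no information).
//
// Table layout everywhere: idx = a + 4*p + 16*b + 64*c with a = 5' flank,
// p = parent base, b = 3' flank, c = child base (0-based codes A,C,G,T).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Factor {
  int arity;
  int vars[4];
  const double* table;
  int type;      // 0 rootInit, 1 rootChain, 2 edgeInt, 3 edgeLeaf,
                 // 4 edgeInt left boundary, 5 edgeInt right boundary,
                 // 6/7 leaf boundaries (boundaries contribute no counts)
  int who;       // internal child index (edgeInt) or leaf index (edgeLeaf)
  int site;
  int obs;       // observed child code for edgeLeaf, else -1
};

inline void normalize4(double* m) {
  double s = m[0] + m[1] + m[2] + m[3];
  if (s <= 0 || !std::isfinite(s)) { m[0] = m[1] = m[2] = m[3] = 0.25; return; }
  m[0] /= s; m[1] /= s; m[2] /= s; m[3] /= s;
}

} // namespace

// [[Rcpp::export]]
List bp_block(IntegerMatrix obs, IntegerVector leaf_parent,
              IntegerVector int_parent, NumericMatrix rate_leaf,
              NumericMatrix rate_int, NumericVector root_trans,
              NumericVector root_init, IntegerVector col_masked,
              int count_from, int count_to,
              double tol, int max_iter, double damping,
              bool want_counts) {
  const int nLeaf = obs.nrow();
  const int L = obs.ncol();
  const int nInt = int_parent.size();
  if (L < 3) stop("block length must be >= 3");
  int root = -1;
  for (int v = 0; v < nInt; ++v) if (int_parent[v] < 0) root = v;
  if (root < 0) stop("no root among internal nodes");

  // ---- precompute flank-averaged boundary tables ----
  // edgeInt left (j=0): t(p,b,c) = mean_a rate(a,p,b,c), idx p+4b+16c
  // edgeInt right (j=L-1): t(a,p,c) = mean_b rate(a,p,b,c), idx a+4p+16c
  std::vector<double> intL((size_t)nInt * 64, 0.0), intR((size_t)nInt * 64, 0.0);
  for (int v = 0; v < nInt; ++v) {
    if (int_parent[v] < 0) continue;
    for (int c = 0; c < 4; ++c)
      for (int b = 0; b < 4; ++b)
        for (int p = 0; p < 4; ++p)
          for (int a = 0; a < 4; ++a) {
            double r = rate_int(a + 4 * p + 16 * b + 64 * c, v);
            intL[(size_t)v * 64 + p + 4 * b + 16 * c] += 0.25 * r;
            intR[(size_t)v * 64 + a + 4 * p + 16 * c] += 0.25 * r;
          }
  }
  std::vector<double> leafL((size_t)nLeaf * 64, 0.0), leafR((size_t)nLeaf * 64, 0.0);
  for (int w = 0; w < nLeaf; ++w) {
    for (int c = 0; c < 4; ++c)
      for (int b = 0; b < 4; ++b)
        for (int p = 0; p < 4; ++p)
          for (int a = 0; a < 4; ++a) {
            double r = rate_leaf(a + 4 * p + 16 * b + 64 * c, w);
            // slices at fixed c: left idx p+4b (+16c), right idx a+4p (+16c)
            leafL[(size_t)w * 64 + p + 4 * b + 16 * c] += 0.25 * r;
            leafR[(size_t)w * 64 + a + 4 * p + 16 * c] += 0.25 * r;
          }
  }

  // ---- build factor list ----
  std::vector<Factor> fs;
  fs.reserve((size_t)L * (nInt + nLeaf));
  const int nVar = nInt * L;
  auto vid = [L](int v, int j) { return v * L + j; };

  { // root sequence model
    Factor f; f.arity = 2; f.vars[0] = vid(root, 0); f.vars[1] = vid(root, 1);
    f.table = &root_init[0]; f.type = 0; f.who = root; f.site = 0; f.obs = -1;
    fs.push_back(f);
    for (int j = 2; j < L; ++j) {
      Factor g; g.arity = 3;
      g.vars[0] = vid(root, j - 2); g.vars[1] = vid(root, j - 1);
      g.vars[2] = vid(root, j);
      g.table = &root_trans[0]; g.type = 1; g.who = root; g.site = j; g.obs = -1;
      fs.push_back(g);
    }
  }
  for (int v = 0; v < nInt; ++v) { // internal branches
    int u = int_parent[v];
    if (u < 0) continue;
    for (int j = 0; j < L; ++j) {
      Factor f; f.who = v; f.site = j; f.obs = -1;
      if (j == 0) {
        f.arity = 3; f.type = 4;
        f.vars[0] = vid(u, 0); f.vars[1] = vid(u, 1); f.vars[2] = vid(v, 0);
        f.table = &intL[(size_t)v * 64];
      } else if (j == L - 1) {
        f.arity = 3; f.type = 5;
        f.vars[0] = vid(u, j - 1); f.vars[1] = vid(u, j); f.vars[2] = vid(v, j);
        f.table = &intR[(size_t)v * 64];
      } else {
        f.arity = 4; f.type = 2;
        f.vars[0] = vid(u, j - 1); f.vars[1] = vid(u, j);
        f.vars[2] = vid(u, j + 1); f.vars[3] = vid(v, j);
        f.table = &rate_int(0, v);
      }
      fs.push_back(f);
    }
  }
  for (int w = 0; w < nLeaf; ++w) { // leaf branches (child clamped)
    int u = leaf_parent[w];
    for (int j = 0; j < L; ++j) {
      int c = obs(w, j);
      if (c < 0) continue;               // masked: factor carries no evidence
      Factor f; f.who = w; f.site = j; f.obs = c;
      if (j == 0) {
        f.arity = 2; f.type = 6;
        f.vars[0] = vid(u, 0); f.vars[1] = vid(u, 1);
        f.table = &leafL[(size_t)w * 64 + 16 * c];
      } else if (j == L - 1) {
        f.arity = 2; f.type = 7;
        f.vars[0] = vid(u, j - 1); f.vars[1] = vid(u, j);
        f.table = &leafR[(size_t)w * 64 + 16 * c];
      } else {
        f.arity = 3; f.type = 3;
        f.vars[0] = vid(u, j - 1); f.vars[1] = vid(u, j); f.vars[2] = vid(u, j + 1);
        f.table = &rate_leaf(0, w) + 64 * c;
      }
      fs.push_back(f);
    }
  }
  const int nF = (int)fs.size();

  // ---- variable incidence lists ----
  std::vector<int> deg(nVar, 0);
  for (int f = 0; f < nF; ++f)
    for (int k = 0; k < fs[f].arity; ++k) ++deg[fs[f].vars[k]];
  std::vector<int> voff(nVar + 1, 0);
  for (int v = 0; v < nVar; ++v) voff[v + 1] = voff[v] + deg[v];
  std::vector<int> incF(voff[nVar]), incSlot(voff[nVar]);
  {
    std::vector<int> cur(voff.begin(), voff.end() - 1);
    for (int f = 0; f < nF; ++f)
      for (int k = 0; k < fs[f].arity; ++k) {
        int v = fs[f].vars[k];
        incF[cur[v]] = f; incSlot[cur[v]] = k; ++cur[v];
      }
  }

  // message offsets: factor f slot k -> foff[f] + 4*k
  std::vector<int> foff(nF + 1, 0);
  for (int f = 0; f < nF; ++f) foff[f + 1] = foff[f] + 4 * fs[f].arity;
  std::vector<double> msg(foff[nF], 0.25);   // factor -> variable

  // per-variable product of incoming messages (kept incrementally updated,
  // recomputed exactly at every sweep start)
  std::vector<double> vprod((size_t)nVar * 4, 1.0);
  auto recompute_vprod = [&]() {
    std::fill(vprod.begin(), vprod.end(), 1.0);
    for (int f = 0; f < nF; ++f)
      for (int k = 0; k < fs[f].arity; ++k) {
        double* P = &vprod[(size_t)fs[f].vars[k] * 4];
        const double* m = &msg[foff[f] + 4 * k];
        for (int x = 0; x < 4; ++x) P[x] *= m[x];
      }
    for (int v = 0; v < nVar; ++v) normalize4(&vprod[(size_t)v * 4]);
  };

  const double MEPS = 1e-12;
  // variable -> factor messages for one factor, via division
  double inbuf[4][4];
  auto gather_in = [&](int f) {
    for (int k = 0; k < fs[f].arity; ++k) {
      const double* P = &vprod[(size_t)fs[f].vars[k] * 4];
      const double* m = &msg[foff[f] + 4 * k];
      double* in = inbuf[k];
      for (int x = 0; x < 4; ++x) in[x] = P[x] / m[x];
      normalize4(in);
    }
  };

  auto factor_out = [&](int f, double out[4][4]) {
    const Factor& F = fs[f];
    const double* T = F.table;
    for (int k = 0; k < F.arity; ++k)
      for (int x = 0; x < 4; ++x) out[k][x] = 0.0;
    const double* m1 = inbuf[0];
    if (F.arity == 2) {
      const double* m2 = inbuf[1];
      for (int y = 0; y < 4; ++y) {
        double w2 = m2[y];
        const double* Ty = T + 4 * y;
        for (int x = 0; x < 4; ++x) {
          double t = Ty[x];
          out[0][x] += t * w2;
          out[1][y] += t * m1[x];
        }
      }
    } else if (F.arity == 3) {
      const double* m2 = inbuf[1]; const double* m3 = inbuf[2];
      for (int z = 0; z < 4; ++z) {
        double w3 = m3[z];
        for (int y = 0; y < 4; ++y) {
          double w2 = m2[y], w23 = w2 * w3;
          const double* Tyz = T + 4 * y + 16 * z;
          double acc2 = 0.0;
          for (int x = 0; x < 4; ++x) {
            double t = Tyz[x];
            out[0][x] += t * w23;
            acc2 += t * m1[x];
          }
          out[1][y] += acc2 * w3;
          out[2][z] += acc2 * w2;
        }
      }
    } else {
      const double* m2 = inbuf[1]; const double* m3 = inbuf[2];
      const double* m4 = inbuf[3];
      for (int cc = 0; cc < 4; ++cc) {
        double w4 = m4[cc];
        for (int b = 0; b < 4; ++b) {
          double w3 = m3[b], w34 = w3 * w4;
          for (int p = 0; p < 4; ++p) {
            double w2 = m2[p], w234 = w2 * w34;
            const double* Tpbc = T + 4 * p + 16 * b + 64 * cc;
            double acc1 = 0.0;
            for (int a = 0; a < 4; ++a) {
              double t = Tpbc[a];
              out[0][a] += t * w234;
              acc1 += t * m1[a];
            }
            out[1][p] += acc1 * w34;
            out[2][b] += acc1 * w2 * w4;
            out[3][cc] += acc1 * w2 * w3;
          }
        }
      }
    }
  };

  // ---- iterate: sequential (bidirectional) factor sweeps ----
  NumericVector trace(max_iter);
  bool converged = false;
  int iters = 0;
  double out[4][4];
  for (int it = 0; it < max_iter; ++it) {
    recompute_vprod();
    double delta = 0.0;
    bool fwd = (it % 2 == 0);
    for (int fi = 0; fi < nF; ++fi) {
      int f = fwd ? fi : (nF - 1 - fi);
      gather_in(f);
      factor_out(f, out);
      for (int k = 0; k < fs[f].arity; ++k) {
        for (int x = 0; x < 4; ++x) if (out[k][x] < MEPS) out[k][x] = MEPS;
        normalize4(out[k]);
        double* m = &msg[foff[f] + 4 * k];
        double* P = &vprod[(size_t)fs[f].vars[k] * 4];
        for (int x = 0; x < 4; ++x) {
          double nv = damping * m[x] + (1.0 - damping) * out[k][x];
          double d = std::fabs(nv - m[x]);
          if (d > delta) delta = d;
          P[x] *= nv / m[x];
          m[x] = nv;
        }
        normalize4(P);
      }
    }
    trace[it] = delta;
    iters = it + 1;
    if (delta < tol) { converged = true; break; }
    if (it % 16 == 0) Rcpp::checkUserInterrupt();
  }
  recompute_vprod();

  // ---- beliefs ----
  NumericMatrix node_marg(nVar, 4);
  for (int v = 0; v < nVar; ++v) {
    double b[4];
    for (int x = 0; x < 4; ++x) b[x] = vprod[(size_t)v * 4 + x];
    normalize4(b);
    for (int x = 0; x < 4; ++x) node_marg(v, x) = b[x];
  }

  List pair_int(nInt), pair_leaf(nLeaf);
  std::vector<NumericMatrix> pi_mats(nInt), pl_mats(nLeaf);
  for (int v = 0; v < nInt; ++v) {
    pi_mats[v] = NumericMatrix(L, 16);
    std::fill(pi_mats[v].begin(), pi_mats[v].end(), NA_REAL);
  }
  for (int w = 0; w < nLeaf; ++w) {
    pl_mats[w] = NumericMatrix(L, 16);
    std::fill(pl_mats[w].begin(), pl_mats[w].end(), NA_REAL);
  }

  NumericMatrix counts_int(256, nInt), counts_leaf(256, nLeaf);
  NumericVector counts_root(64), counts_root_init(16);
  std::vector<double> bel(256);

  for (int f = 0; f < nF; ++f) {
    const Factor& F = fs[f];
    int sz = 1 << (2 * F.arity);
    gather_in(f);
    const double* m1 = inbuf[0]; const double* m2 = inbuf[1];
    const double* m3 = inbuf[2]; const double* m4 = inbuf[3];
    double s = 0.0;
    for (int idx = 0; idx < sz; ++idx) {
      int x1 = idx & 3, x2 = (idx >> 2) & 3, x3 = (idx >> 4) & 3, x4 = (idx >> 6) & 3;
      double t = F.table[idx] * m1[x1];
      if (F.arity > 1) t *= m2[x2];
      if (F.arity > 2) t *= m3[x3];
      if (F.arity > 3) t *= m4[x4];
      bel[idx] = t; s += t;
    }
    if (s <= 0) continue;
    for (int idx = 0; idx < sz; ++idx) bel[idx] /= s;

    bool in_range = F.site >= count_from && F.site <= count_to &&
      !col_masked[F.site];
    if (F.type == 0 && want_counts && in_range) {
      for (int idx = 0; idx < 16; ++idx) counts_root_init[idx] += bel[idx];
    } else if (F.type == 1 && want_counts && in_range) {
      for (int idx = 0; idx < 64; ++idx) counts_root[idx] += bel[idx];
    } else if (F.type == 2) {
      if (want_counts && in_range)
        for (int idx = 0; idx < 256; ++idx) counts_int(idx, F.who) += bel[idx];
      // pair marginal over (p, c)
      double pm[16] = {0};
      for (int idx = 0; idx < 256; ++idx) {
        int p = (idx >> 2) & 3, c = (idx >> 6) & 3;
        pm[p + 4 * c] += bel[idx];
      }
      for (int z = 0; z < 16; ++z) pi_mats[F.who](F.site, z) = pm[z];
    } else if (F.type == 3) {
      if (want_counts && in_range)
        for (int idx = 0; idx < 64; ++idx)
          counts_leaf(idx + 64 * F.obs, F.who) += bel[idx];
      double pm[4] = {0};
      for (int idx = 0; idx < 64; ++idx) pm[(idx >> 2) & 3] += bel[idx];
      for (int z = 0; z < 16; ++z) pl_mats[F.who](F.site, z) = 0.0;
      for (int p = 0; p < 4; ++p) pl_mats[F.who](F.site, p + 4 * F.obs) = pm[p];
    } else if (F.type == 4 || F.type == 5) {
      // boundary internal-edge factor: vars (.., parent, child)
      double pm[16] = {0};
      for (int idx = 0; idx < 64; ++idx) {
        int p = (F.type == 4) ? (idx & 3) : ((idx >> 2) & 3);
        int c = (idx >> 4) & 3;
        pm[p + 4 * c] += bel[idx];
      }
      for (int z = 0; z < 16; ++z) pi_mats[F.who](F.site, z) = pm[z];
    }
  }
  // boundary-site pair marginals for leaf edges from parent marginals
  for (int w = 0; w < nLeaf; ++w) {
    int u = leaf_parent[w];
    for (int jb : {0, L - 1}) {
      int c = obs(w, jb);
      if (c < 0) continue;
      for (int z = 0; z < 16; ++z) pl_mats[w](jb, z) = 0.0;
      for (int p = 0; p < 4; ++p)
        pl_mats[w](jb, p + 4 * c) = node_marg(vid(u, jb), p);
    }
  }
  for (int v = 0; v < nInt; ++v) pair_int[v] = pi_mats[v];
  for (int w = 0; w < nLeaf; ++w) pair_leaf[w] = pl_mats[w];

  return List::create(
    _["node_marg"] = node_marg, _["pair_int"] = pair_int,
    _["pair_leaf"] = pair_leaf, _["counts_int"] = counts_int,
    _["counts_leaf"] = counts_leaf, _["counts_root"] = counts_root,
    _["counts_root_init"] = counts_root_init,
    _["converged"] = converged, _["iters"] = iters,
    _["trace"] = trace[Range(0, std::max(0, iters - 1))]);
}
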
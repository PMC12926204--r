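// HKY85 pruning likelihood, per-branch optimisation and sequence simulation
// for small (4-6 taxon) trees.  Used by the per-window topology scan, where
// hundreds of thousands of quartet fits must run in minutes.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

const double T_MIN = 1e-9;
const double LIK_FLOOR = 1e-300;

// HKY85 P(t) decomposes entrywise as A + B exp(-beta t) + C exp(-beta c_j t)
// with c_j = 1 + Pi_J (kappa - 1); the coefficients are cached so that P
// and its first two time-derivatives are cheap.
struct Hky {
  double pi[4];
  double kappa;
  double beta;  // rate normalisation so branch lengths are subs/site
  double cA[16], cB[16], cC[16];  // row-major coefficient matrices
  double cfac[4];                 // c_j per target state

  void init(const double *f, double k) {
    for (int i = 0; i < 4; ++i) pi[i] = f[i];
    kappa = k;
    // states A=0, C=1, G=2, T=3; transitions A<->G, C<->T
    double tv = pi[0] * pi[1] + pi[0] * pi[3] + pi[1] * pi[2] + pi[2] * pi[3];
    double ts = pi[0] * pi[2] + pi[1] * pi[3];
    beta = 1.0 / (2.0 * (tv + kappa * ts));
    double piR = pi[0] + pi[2], piY = pi[1] + pi[3];
    for (int j = 0; j < 4; ++j) {
      bool jR = (j == 0 || j == 2);
      cfac[j] = 1.0 + (jR ? piR : piY) * (kappa - 1.0);
    }
    for (int i = 0; i < 4; ++i) {
      bool iR = (i == 0 || i == 2);
      for (int j = 0; j < 4; ++j) {
        bool jR = (j == 0 || j == 2);
        double PJ = jR ? piR : piY;
        int e = i * 4 + j;
        if (i == j) {
          cA[e] = pi[j];
          cB[e] = pi[j] * (1.0 / PJ - 1.0);
          cC[e] = (PJ - pi[j]) / PJ;
        } else if (iR == jR) {
          cA[e] = pi[j];
          cB[e] = pi[j] * (1.0 / PJ - 1.0);
          cC[e] = -pi[j] / PJ;
        } else {
          cA[e] = pi[j];
          cB[e] = -pi[j];
          cC[e] = 0.0;
        }
      }
    }
  }

  // row-major P[i*4+j] = P(j at child | i at parent, t)
  void pmat(double t, double *P) const {
    if (t < 0) t = 0;
    double e2 = std::exp(-beta * t);
    double e3[4];
    for (int j = 0; j < 4; ++j) e3[j] = std::exp(-beta * cfac[j] * t);
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) {
        int e = i * 4 + j;
        double v = cA[e] + cB[e] * e2 + cC[e] * e3[j];
        P[e] = v > 0 ? v : 0.0;
      }
  }

  // P, dP/dt and d2P/dt2 in one pass
  void pmat_d2(double t, double *P, double *D1, double *D2) const {
    if (t < 0) t = 0;
    double e2 = std::exp(-beta * t);
    double e3[4];
    for (int j = 0; j < 4; ++j) e3[j] = std::exp(-beta * cfac[j] * t);
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) {
        int e = i * 4 + j;
        double b2 = beta, b3 = beta * cfac[j];
        double v = cA[e] + cB[e] * e2 + cC[e] * e3[j];
        P[e] = v > 0 ? v : 0.0;
        D1[e] = -b2 * cB[e] * e2 - b3 * cC[e] * e3[j];
        D2[e] = b2 * b2 * cB[e] * e2 + b3 * b3 * cC[e] * e3[j];
      }
  }
};

// Site-pattern compressed alignment for one window.
struct Patterns {
  int nleaf, npat;
  std::vector<int> state;    // nleaf x npat, column-major by pattern; -1 = missing
  std::vector<double> w;     // pattern weights
};

void compress(const int *aln, int nleaf, int L, Patterns &pat) {
  // key = sum (state+1) * 5^row, state in {-1..3}
  int span = 1;
  for (int i = 0; i < nleaf; ++i) span *= 5;
  std::vector<int> slot(span, -1);
  pat.nleaf = nleaf;
  pat.npat = 0;
  pat.state.clear();
  pat.w.clear();
  for (int s = 0; s < L; ++s) {
    int key = 0, mul = 1;
    for (int i = 0; i < nleaf; ++i) {
      int v = aln[i + s * nleaf];
      key += (v + 1) * mul;
      mul *= 5;
    }
    if (slot[key] < 0) {
      slot[key] = pat.npat++;
      for (int i = 0; i < nleaf; ++i) pat.state.push_back(aln[i + s * nleaf]);
      pat.w.push_back(1.0);
    } else {
      pat.w[slot[key]] += 1.0;
    }
  }
}

int count_informative(const int *aln, int nleaf, int L) {
  int n = 0;
  for (int s = 0; s < L; ++s) {
    int cnt[4] = {0, 0, 0, 0};
    for (int i = 0; i < nleaf; ++i) {
      int v = aln[i + s * nleaf];
      if (v >= 0) cnt[v]++;
    }
    int k = 0;
    for (int j = 0; j < 4; ++j)
      if (cnt[j] >= 2) k++;
    if (k >= 2) n++;
  }
  return n;
}

// Small rooted tree (root may be multifurcating, encodes unrooted trees).
// parent[0] == -1, parent[i] < i for i > 0. leafrow[i] >= 0 gives the
// alignment row of leaf i, -1 for internal nodes.
struct Engine {
  int nnode, ncat;
  std::vector<int> parent, leafrow;
  std::vector<std::vector<int>> kids;
  std::vector<double> rates;
  Hky model;
  Patterns *pat;

  // per node: ncat * npat * 4, conditional likelihood of data below node
  std::vector<std::vector<double>> down, msg, up;
  std::vector<double> Pbuf, Pd, D1d, D2d;

  void set_tree(const IntegerVector &par, const IntegerVector &lr) {
    nnode = par.size();
    parent.assign(par.begin(), par.end());
    leafrow.assign(lr.begin(), lr.end());
    kids.assign(nnode, {});
    for (int i = 1; i < nnode; ++i) kids[parent[i]].push_back(i);
  }

  void alloc() {
    int sz = ncat * pat->npat * 4;
    down.assign(nnode, std::vector<double>(sz));
    msg.assign(nnode, std::vector<double>(sz));
    up.assign(nnode, std::vector<double>(sz));
    Pbuf.assign(16 * ncat, 0.0);
    Pd.assign(16 * ncat, 0.0);
    D1d.assign(16 * ncat, 0.0);
    D2d.assign(16 * ncat, 0.0);
  }

  inline double *at(std::vector<double> &v, int cat, int p) {
    return &v[(cat * pat->npat + p) * 4];
  }

  void leaf_init(int i) {
    int row = leafrow[i];
    for (int c = 0; c < ncat; ++c)
      for (int p = 0; p < pat->npat; ++p) {
        double *d = at(down[i], c, p);
        int st = pat->state[row + p * pat->nleaf];
        if (st < 0) { d[0] = d[1] = d[2] = d[3] = 1.0; }
        else { d[0] = d[1] = d[2] = d[3] = 0.0; d[st] = 1.0; }
      }
  }

  // full post-order pass with current edge lengths t
  void pass_down(const std::vector<double> &t) {
    for (int i = nnode - 1; i >= 0; --i) {
      if (leafrow[i] >= 0) leaf_init(i);
      else {
        for (int c = 0; c < ncat; ++c)
          for (int p = 0; p < pat->npat; ++p) {
            double *d = at(down[i], c, p);
            d[0] = d[1] = d[2] = d[3] = 1.0;
          }
        for (int k : kids[i])
          for (int c = 0; c < ncat; ++c)
            for (int p = 0; p < pat->npat; ++p) {
              double *d = at(down[i], c, p);
              const double *m = at(msg[k], c, p);
              for (int s = 0; s < 4; ++s) d[s] *= m[s];
            }
      }
      if (i > 0) {
        for (int c = 0; c < ncat; ++c) model.pmat(t[i] * rates[c], &Pbuf[16 * c]);
        for (int c = 0; c < ncat; ++c) {
          const double *P = &Pbuf[16 * c];
          for (int p = 0; p < pat->npat; ++p) {
            const double *d = at(down[i], c, p);
            double *m = at(msg[i], c, p);
            for (int j = 0; j < 4; ++j)
              m[j] = P[j * 4 + 0] * d[0] + P[j * 4 + 1] * d[1] +
                     P[j * 4 + 2] * d[2] + P[j * 4 + 3] * d[3];
          }
        }
      }
    }
  }

  // pre-order pass: up[i][s] = L(data outside subtree i | state s at node i),
  // with the stationary prior folded in at the root.
  void pass_up(const std::vector<double> &t) {
    for (int c = 0; c < ncat; ++c)
      for (int p = 0; p < pat->npat; ++p) {
        double *u = at(up[0], c, p);
        for (int s = 0; s < 4; ++s) u[s] = model.pi[s];
      }
    for (int i = 1; i < nnode; ++i) {
      int u0 = parent[i];
      for (int c = 0; c < ncat; ++c) model.pmat(t[i] * rates[c], &Pbuf[16 * c]);
      for (int c = 0; c < ncat; ++c) {
        const double *P = &Pbuf[16 * c];
        for (int p = 0; p < pat->npat; ++p) {
          const double *uu = at(up[u0], c, p);
          double V[4];
          for (int s = 0; s < 4; ++s) V[s] = uu[s];
          for (int k : kids[u0]) {
            if (k == i) continue;
            const double *m = at(msg[k], c, p);
            for (int s = 0; s < 4; ++s) V[s] *= m[s];
          }
          double *u = at(up[i], c, p);
          for (int j = 0; j < 4; ++j)
            u[j] = V[0] * P[0 * 4 + j] + V[1] * P[1 * 4 + j] +
                   V[2] * P[2 * 4 + j] + V[3] * P[3 * 4 + j];
        }
      }
    }
  }

  double root_lnl() {
    double lnl = 0.0;
    for (int p = 0; p < pat->npat; ++p) {
      double L = 0.0;
      for (int c = 0; c < ncat; ++c) {
        const double *d = at(down[0], c, p);
        for (int s = 0; s < 4; ++s) L += model.pi[s] * d[s];
      }
      L /= ncat;
      lnl += pat->w[p] * std::log(L > LIK_FLOOR ? L : LIK_FLOOR);
    }
    return lnl;
  }

  // likelihood as a function of the length of the edge above node i,
  // given cached V (outer side, prior folded) and down[i]
  double edge_lnl(int i, double t, const std::vector<double> &V) {
    for (int c = 0; c < ncat; ++c) model.pmat(t * rates[c], &Pbuf[16 * c]);
    double lnl = 0.0;
    for (int p = 0; p < pat->npat; ++p) {
      double L = 0.0;
      for (int c = 0; c < ncat; ++c) {
        const double *P = &Pbuf[16 * c];
        const double *vv = &V[(c * pat->npat + p) * 4];
        const double *d = at(down[i], c, p);
        for (int a = 0; a < 4; ++a) {
          double inner = P[a * 4 + 0] * d[0] + P[a * 4 + 1] * d[1] +
                         P[a * 4 + 2] * d[2] + P[a * 4 + 3] * d[3];
          L += vv[a] * inner;
        }
      }
      L /= ncat;
      lnl += pat->w[p] * std::log(L > LIK_FLOOR ? L : LIK_FLOOR);
    }
    return lnl;
  }

  // first and second derivatives of lnL w.r.t. the edge length above i
  void edge_deriv(int i, double t, const std::vector<double> &V,
                  double &g1, double &g2) {
    std::vector<double> &P = Pd, &D1 = D1d, &D2 = D2d;
    for (int c = 0; c < ncat; ++c) {
      model.pmat_d2(t * rates[c], &P[16 * c], &D1[16 * c], &D2[16 * c]);
      // chain rule for the per-category rate scaling
      for (int e = 0; e < 16; ++e) {
        D1[16 * c + e] *= rates[c];
        D2[16 * c + e] *= rates[c] * rates[c];
      }
    }
    g1 = g2 = 0.0;
    for (int p = 0; p < pat->npat; ++p) {
      double num = 0.0, num1 = 0.0, num2 = 0.0;
      for (int c = 0; c < ncat; ++c) {
        const double *vv = &V[(c * pat->npat + p) * 4];
        const double *d = at(down[i], c, p);
        const double *Pc = &P[16 * c], *D1c = &D1[16 * c],
                     *D2c = &D2[16 * c];
        for (int a = 0; a < 4; ++a) {
          double s0 = 0, s1 = 0, s2 = 0;
          for (int b = 0; b < 4; ++b) {
            s0 += Pc[a * 4 + b] * d[b];
            s1 += D1c[a * 4 + b] * d[b];
            s2 += D2c[a * 4 + b] * d[b];
          }
          num += vv[a] * s0;
          num1 += vv[a] * s1;
          num2 += vv[a] * s2;
        }
      }
      if (num < LIK_FLOOR) num = LIK_FLOOR;
      double r1 = num1 / num;
      g1 += pat->w[p] * r1;
      g2 += pat->w[p] * (num2 / num - r1 * r1);
    }
  }

  // safeguarded Newton maximisation of the edge likelihood over
  // [T_MIN, tmax]: bisection on the derivative sign with Newton steps
  // where the curvature allows them
  double optimise_edge(int i, const std::vector<double> &V, double tmax,
                       double tol, double t0) {
    double g1, g2;
    double lo = T_MIN, hi = tmax;
    edge_deriv(i, lo, V, g1, g2);
    if (g1 <= 0) return lo;
    edge_deriv(i, hi, V, g1, g2);
    if (g1 >= 0) return hi;
    double t = std::min(std::max(t0, lo + tol), hi - tol);
    for (int iter = 0; iter < 60; ++iter) {
      edge_deriv(i, t, V, g1, g2);
      if (g1 > 0) lo = t; else hi = t;
      double tn;
      if (g2 < 0) {
        tn = t - g1 / g2;
        if (!(tn > lo && tn < hi)) tn = 0.5 * (lo + hi);
      } else {
        tn = 0.5 * (lo + hi);
      }
      double moved = std::fabs(tn - t);
      t = tn;
      if (moved < tol || hi - lo < tol) break;
    }
    return t;
  }

  // coordinate-wise branch-length optimisation; returns maximised lnL
  double fit(std::vector<double> &t, int nsweeps, double tol, double tmax) {
    std::vector<double> V(ncat * pat->npat * 4);
    double last = -INFINITY;
    for (int sweep = 0; sweep < nsweeps; ++sweep) {
      for (int i = 1; i < nnode; ++i) {
        pass_down(t);
        pass_up(t);
        int u0 = parent[i];
        for (int c = 0; c < ncat; ++c)
          for (int p = 0; p < pat->npat; ++p) {
            const double *uu = at(up[u0], c, p);
            double *vv = &V[(c * pat->npat + p) * 4];
            for (int s = 0; s < 4; ++s) vv[s] = uu[s];
            for (int k : kids[u0]) {
              if (k == i) continue;
              const double *m = at(msg[k], c, p);
              for (int s = 0; s < 4; ++s) vv[s] *= m[s];
            }
          }
        t[i] = optimise_edge(i, V, tmax, tol, t[i]);
      }
      pass_down(t);
      double lnl = root_lnl();
      if (lnl - last < 1e-6 && sweep > 0) { last = lnl; break; }
      last = lnl;
    }
    pass_down(t);
    return root_lnl();
  }
};

}  // namespace

//' @noRd
// [[Rcpp::export]]
List cpp_hky_ml_batch(List alns, List cand_parent, List cand_leafrow,
                      NumericMatrix freqs, double kappa, NumericVector rates,
                      int nsweeps, double tol, double tmax, double t_init) {
  int nwin = alns.size(), ncand = cand_parent.size();
  NumericMatrix lnl(nwin, ncand);
  IntegerVector ninf(nwin);
  Patterns pat;
  std::vector<Engine> eng(ncand);
  for (int c = 0; c < ncand; ++c) {
    eng[c].set_tree(cand_parent[c], cand_leafrow[c]);
    eng[c].ncat = rates.size();
    eng[c].rates.assign(rates.begin(), rates.end());
    eng[c].pat = &pat;
  }
  for (int w = 0; w < nwin; ++w) {
    IntegerMatrix a = alns[w];
    int nleaf = a.nrow(), L = a.ncol();
    compress(&a[0], nleaf, L, pat);
    ninf[w] = count_informative(&a[0], nleaf, L);
    double f[4];
    for (int s = 0; s < 4; ++s) f[s] = freqs(s, w);
    for (int c = 0; c < ncand; ++c) {
      eng[c].model.init(f, kappa);
      eng[c].alloc();
      std::vector<double> t(eng[c].nnode, t_init);
      lnl(w, c) = eng[c].fit(t, nsweeps, tol, tmax);
    }
  }
  return List::create(_["lnl"] = lnl, _["n_informative"] = ninf);
}

//' @noRd
// [[Rcpp::export]]
List cpp_hky_fit(IntegerMatrix aln, IntegerVector parent, IntegerVector leafrow,
                 NumericVector freqs, double kappa, NumericVector rates,
                 int nsweeps, double tol, double tmax, double t_init) {
  Patterns pat;
  compress(&aln[0], aln.nrow(), aln.ncol(), pat);
  Engine eng;
  eng.set_tree(parent, leafrow);
  eng.ncat = rates.size();
  eng.rates.assign(rates.begin(), rates.end());
  eng.pat = &pat;
  eng.model.init(&freqs[0], kappa);
  eng.alloc();
  std::vector<double> t(eng.nnode, t_init);
  double lnl = eng.fit(t, nsweeps, tol, tmax);
  return List::create(_["lnl"] = lnl,
                      _["edge_lengths"] = NumericVector(t.begin(), t.end()));
}

//' @noRd
// [[Rcpp::export]]
double cpp_hky_lnl(IntegerMatrix aln, IntegerVector parent,
                   IntegerVector leafrow, NumericVector edge_len,
                   NumericVector freqs, double kappa, NumericVector rates) {
  Patterns pat;
  compress(&aln[0], aln.nrow(), aln.ncol(), pat);
  Engine eng;
  eng.set_tree(parent, leafrow);
  eng.ncat = rates.size();
  eng.rates.assign(rates.begin(), rates.end());
  eng.pat = &pat;
  eng.model.init(&freqs[0], kappa);
  eng.alloc();
  std::vector<double> t(edge_len.begin(), edge_len.end());
  eng.pass_down(t);
  return eng.root_lnl();
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_hky_pmat(double t, NumericVector freqs, double kappa) {
  Hky m;
  m.init(&freqs[0], kappa);
  double P[16];
  m.pmat(t, P);
  NumericMatrix out(4, 4);
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = P[i * 4 + j];
  return out;
}

// Simulate sequences on per-window trees under HKY.  parent/elen are
// nnode x nwin; leaf_node maps taxon row -> node index (0-based) per window.
// Uses R's RNG so results are reproducible under set.seed().
//' @noRd
// [[Rcpp::export]]
List cpp_sim_hky_batch(IntegerMatrix parent, NumericMatrix elen,
                       IntegerMatrix leaf_node, int L, NumericVector freqs,
                       double kappa, Nullable<NumericVector> site_rates_) {
  int nnode = parent.nrow(), nwin = parent.ncol(), nleaf = leaf_node.nrow();
  Hky m;
  m.init(&freqs[0], kappa);
  bool het = site_rates_.isNotNull();
  NumericVector site_rates;
  if (het) {
    site_rates = site_rates_.get();
    if (site_rates.size() != L) stop("site_rates must have one rate per site");
  }
  double cpi[4];
  cpi[0] = freqs[0];
  for (int s = 1; s < 4; ++s) cpi[s] = cpi[s - 1] + freqs[s];
  List out(nwin);
  std::vector<double> Pcum(16 * nnode);
  std::vector<int> states(nnode);
  for (int w = 0; w < nwin; ++w) {
    IntegerMatrix seqs(nleaf, L);
    if (!het) {
      for (int i = 1; i < nnode; ++i) {
        double P[16];
        m.pmat(elen(i, w), P);
        for (int a = 0; a < 4; ++a) {
          double c = 0;
          for (int b = 0; b < 4; ++b) {
            c += P[a * 4 + b];
            Pcum[i * 16 + a * 4 + b] = c;
          }
        }
      }
    }
    for (int s = 0; s < L; ++s) {
      if (het) {
        double r = site_rates[s];
        for (int i = 1; i < nnode; ++i) {
          double P[16];
          m.pmat(elen(i, w) * r, P);
          for (int a = 0; a < 4; ++a) {
            double c = 0;
            for (int b = 0; b < 4; ++b) {
              c += P[a * 4 + b];
              Pcum[i * 16 + a * 4 + b] = c;
            }
          }
        }
      }
      double u = unif_rand();
      int st = 0;
      while (st < 3 && u > cpi[st]) ++st;
      states[0] = st;
      for (int i = 1; i < nnode; ++i) {
        int pa = states[parent(i, w)];
        double v = unif_rand();
        const double *row = &Pcum[i * 16 + pa * 4];
        int b = 0;
        while (b < 3 && v > row[b]) ++b;
        states[i] = b;
      }
      for (int i = 0; i < nleaf; ++i) seqs(i, s) = states[leaf_node(i, w)];
    }
    out[w] = seqs;
  }
  return out;
}
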
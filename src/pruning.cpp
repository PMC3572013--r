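#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning under GTR + discrete gamma.
//
// Trees arrive as a postorder edge matrix (1-based node ids, tips 1..ntip,
// root = parent of the last postorder edge). Each partition is a list with
//   tip   : ntip x npat integer matrix, 0 = missing (gap/?/N), 1..4 = ACGT
//   w     : pattern weights
//   pi    : base frequencies (root prior, stationary distribution)
//   U,Uinv: eigenvectors of the rate matrix and their inverse (4 x 4)
//   lam   : eigenvalues
//   rates : discrete gamma category rates (mean 1)
// Branch lengths are shared across partitions; substitution models are not.
//
// The likelihood of a site is the equal-weight mixture over categories of
// the per-category pruning likelihood, with the same category applying to
// the whole tree at that site.

static inline void pmat(const double* U, const double* Uinv, const double* lam,
                        double t, double* P) {
  double e[4];
  for (int k = 0; k < 4; k++) e[k] = std::exp(lam[k] * t);
  for (int j = 0; j < 4; j++)
    for (int i = 0; i < 4; i++) {
      double s = 0.0;
      for (int k = 0; k < 4; k++) s += U[i + 4 * k] * e[k] * Uinv[k + 4 * j];
      P[i + 4 * j] = (s > 1e-300) ? s : 1e-300; // guard rounding negatives
    }
}

struct Part {
  const int* tip; int ntip, npat, ncat;
  const double *w, *pi, *U, *Uinv, *lam, *rates;
};

static Part get_part(List part, int ntip) {
  Part p;
  IntegerMatrix tip = part["tip"];
  NumericVector w = part["w"], pi = part["pi"], lam = part["lam"],
                rates = part["rates"];
  NumericMatrix U = part["U"], Uinv = part["Uinv"];
  p.tip = INTEGER(tip); p.ntip = ntip; p.npat = tip.ncol();
  p.ncat = rates.size();
  p.w = REAL(w); p.pi = REAL(pi); p.U = REAL(U); p.Uinv = REAL(Uinv);
  p.lam = REAL(lam); p.rates = REAL(rates);
  return p;
}

// message along edge (p, c): out[a, pat] = sum_b P[a,b] * partial_c[b, pat]
static void edge_message(const Part& pp, const double* P, int child,
                         const double* Dchild, double* out) {
  const int npat = pp.npat;
  if (child <= pp.ntip) {
    for (int s = 0; s < npat; s++) {
      int st = pp.tip[(child - 1) + pp.ntip * s];
      if (st == 0) {
        for (int a = 0; a < 4; a++) out[a + 4 * s] = 1.0;
      } else {
        for (int a = 0; a < 4; a++) out[a + 4 * s] = P[a + 4 * (st - 1)];
      }
    }
  } else {
    for (int s = 0; s < npat; s++) {
      const double* d = Dchild + 4 * s;
      for (int a = 0; a < 4; a++) {
        double acc = 0.0;
        for (int b = 0; b < 4; b++) acc += P[a + 4 * b] * d[b];
        out[a + 4 * s] = acc;
      }
    }
  }
}

// per-pattern log-likelihood for one partition (mixture over categories)
static void part_site_lnl(const IntegerMatrix& edge, const double* el,
                          int ntip, const Part& pp, double* out) {
  const int nedge = edge.nrow(), npat = pp.npat, ncat = pp.ncat;
  int nnode = 0;
  for (int e = 0; e < nedge; e++) {
    if (edge(e, 0) > nnode) nnode = edge(e, 0);
    if (edge(e, 1) > nnode) nnode = edge(e, 1);
  }
  int root = edge(nedge - 1, 0);
  std::vector<double> D((size_t)(nnode + 1) * 4 * npat);
  std::vector<double> msg((size_t)4 * npat);
  std::vector<double> acc(npat, 0.0);
  double P[16];
  for (int c = 0; c < ncat; c++) {
    // reset internal partials to 1
    for (int v = ntip + 1; v <= nnode; v++) {
      double* d = &D[(size_t)v * 4 * npat];
      for (int k = 0; k < 4 * npat; k++) d[k] = 1.0;
    }
    for (int e = 0; e < nedge; e++) {
      int par = edge(e, 0), ch = edge(e, 1);
      pmat(pp.U, pp.Uinv, pp.lam, el[e] * pp.rates[c], P);
      edge_message(pp, P, ch, &D[(size_t)ch * 4 * npat], msg.data());
      double* d = &D[(size_t)par * 4 * npat];
      for (int k = 0; k < 4 * npat; k++) d[k] *= msg[k];
    }
    const double* r = &D[(size_t)root * 4 * npat];
    for (int s = 0; s < npat; s++) {
      double L = 0.0;
      for (int a = 0; a < 4; a++) L += pp.pi[a] * r[a + 4 * s];
      acc[s] += L / ncat;
    }
  }
  for (int s = 0; s < npat; s++) out[s] = std::log(acc[s]);
}

// [[Rcpp::export]]
List C_persite_lnl(IntegerMatrix edge, NumericVector el, int ntip, List parts) {
  List out(parts.size());
  for (int i = 0; i < parts.size(); i++) {
    Part pp = get_part(parts[i], ntip);
    NumericVector v(pp.npat);
    part_site_lnl(edge, REAL(el), ntip, pp, REAL(v));
    out[i] = v;
  }
  return out;
}

// [[Rcpp::export]]
double C_total_lnl(IntegerMatrix edge, NumericVector el, int ntip, List parts) {
  double tot = 0.0;
  for (int i = 0; i < parts.size(); i++) {
    Part pp = get_part(parts[i], ntip);
    std::vector<double> v(pp.npat);
    part_site_lnl(edge, REAL(el), ntip, pp, v.data());
    for (int s = 0; s < pp.npat; s++) tot += pp.w[s] * v[s];
  }
  return tot;
}

// Cached quantities for one partition x category during a branch sweep:
// D[node]  : downward conditional likelihoods
// O[e]     : outward partial for edge e = (p, c): prior-weighted likelihood of
//            all data outside the subtree of c, as a function of the state at
//            p (pi is absorbed at the root), so that
//            L_site(t_e) = sum_a O[e][a] * (P(t_e) D[c])[a]
struct Cache {
  std::vector<double> D; // (nnode+1) x 4 x npat
  std::vector<double> O; // nedge x 4 x npat
};

static void build_cache(const IntegerMatrix& edge, const double* el, int ntip,
                        const Part& pp, int cat, Cache& ca) {
  const int nedge = edge.nrow(), npat = pp.npat;
  int nnode = 0;
  for (int e = 0; e < nedge; e++) {
    if (edge(e, 0) > nnode) nnode = edge(e, 0);
    if (edge(e, 1) > nnode) nnode = edge(e, 1);
  }
  int root = edge(nedge - 1, 0);
  ca.D.assign((size_t)(nnode + 1) * 4 * npat, 1.0);
  ca.O.assign((size_t)nedge * 4 * npat, 1.0);
  std::vector<double> X((size_t)nedge * 4 * npat); // per-edge messages
  std::vector<double> H((size_t)(nnode + 1) * 4 * npat, 0.0);
  double P[16];
  const double r = pp.rates[cat];
  // down pass
  for (int v = ntip + 1; v <= nnode; v++) {
    double* d = &ca.D[(size_t)v * 4 * npat];
    for (int k = 0; k < 4 * npat; k++) d[k] = 1.0;
  }
  for (int e = 0; e < nedge; e++) {
    int par = edge(e, 0), ch = edge(e, 1);
    pmat(pp.U, pp.Uinv, pp.lam, el[e] * r, P);
    edge_message(pp, P, ch, &ca.D[(size_t)ch * 4 * npat], &X[(size_t)e * 4 * npat]);
    double* d = &ca.D[(size_t)par * 4 * npat];
    const double* x = &X[(size_t)e * 4 * npat];
    for (int k = 0; k < 4 * npat; k++) d[k] *= x[k];
  }
  // up pass: H[root] = pi, then reverse postorder
  {
    double* h = &H[(size_t)root * 4 * npat];
    for (int s = 0; s < npat; s++)
      for (int a = 0; a < 4; a++) h[a + 4 * s] = pp.pi[a];
  }
  // group edges by parent for sibling products
  for (int e = nedge - 1; e >= 0; e--) {
    int par = edge(e, 0), ch = edge(e, 1);
    double* o = &ca.O[(size_t)e * 4 * npat];
    const double* h = &H[(size_t)par * 4 * npat];
    for (int k = 0; k < 4 * npat; k++) o[k] = h[k];
    for (int f = 0; f < nedge; f++) {
      if (f == e || edge(f, 0) != par) continue;
      const double* x = &X[(size_t)f * 4 * npat];
      for (int k = 0; k < 4 * npat; k++) o[k] *= x[k];
    }
    if (ch > ntip) {
      // H[ch][b] = sum_a P_e[a, b] O[e][a]
      pmat(pp.U, pp.Uinv, pp.lam, el[e] * r, P);
      double* hc = &H[(size_t)ch * 4 * npat];
      for (int s = 0; s < npat; s++) {
        const double* os = o + 4 * s;
        for (int b = 0; b < 4; b++) {
          double acc = 0.0;
          for (int a = 0; a < 4; a++) acc += P[a + 4 * b] * os[a];
          hc[b + 4 * s] = acc;
        }
      }
    }
  }
}

// lnL as a function of the length of edge e, from cached partials
static double edge_lnl(const IntegerMatrix& edge, int ntip,
                       const std::vector<Part>& pps,
                       const std::vector<std::vector<Cache> >& caches,
                       int e, double t) {
  double tot = 0.0;
  int ch = edge(e, 1);
  for (size_t ip = 0; ip < pps.size(); ip++) {
    const Part& pp = pps[ip];
    const int npat = pp.npat, ncat = pp.ncat;
    std::vector<double> site(npat, 0.0);
    std::vector<double> msg((size_t)4 * npat);
    double P[16];
    for (int c = 0; c < ncat; c++) {
      const Cache& ca = caches[ip][c];
      pmat(pp.U, pp.Uinv, pp.lam, t * pp.rates[c], P);
      edge_message(pp, P, ch, &ca.D[(size_t)ch * 4 * npat], msg.data());
      const double* o = &ca.O[(size_t)e * 4 * npat];
      for (int s = 0; s < npat; s++) {
        double L = 0.0;
        for (int a = 0; a < 4; a++) L += o[a + 4 * s] * msg[a + 4 * s];
        site[s] += L / ncat;
      }
    }
    for (int s = 0; s < npat; s++) tot += pp.w[s] * std::log(site[s]);
  }
  return tot;
}

// Golden-section maximization of edge_lnl over log branch length.
static double golden_branch(const IntegerMatrix& edge, int ntip,
                            const std::vector<Part>& pps,
                            const std::vector<std::vector<Cache> >& caches,
                            int e, double lo, double hi, int iters) {
  const double gr = 0.6180339887498949;
  double a = std::log(lo), b = std::log(hi);
  double x1 = b - gr * (b - a), x2 = a + gr * (b - a);
  double f1 = edge_lnl(edge, ntip, pps, caches, e, std::exp(x1));
  double f2 = edge_lnl(edge, ntip, pps, caches, e, std::exp(x2));
  for (int it = 0; it < iters; it++) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + gr * (b - a);
      f2 = edge_lnl(edge, ntip, pps, caches, e, std::exp(x2));
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - gr * (b - a);
      f1 = edge_lnl(edge, ntip, pps, caches, e, std::exp(x1));
    }
  }
  return (f1 > f2) ? std::exp(x1) : std::exp(x2);
}

// Sweeps of per-branch golden-section optimization. Within a sweep the
// cached partials are held fixed (Jacobi-style updates); caches are rebuilt
// between sweeps. The caller is responsible for rejecting a result whose
// exact likelihood is worse than the input (which the Jacobi approximation
// permits in principle, though it is not observed in practice).
// [[Rcpp::export]]
List C_optimize_bl(IntegerMatrix edge, NumericVector el, int ntip, List parts,
                   int nsweeps, double min_bl, double max_bl, int iters) {
  const int nedge = edge.nrow();
  std::vector<Part> pps;
  for (int i = 0; i < parts.size(); i++) pps.push_back(get_part(parts[i], ntip));
  NumericVector cur = clone(el);
  std::vector<std::vector<Cache> > caches(pps.size());
  for (int sw = 0; sw < nsweeps; sw++) {
    for (size_t ip = 0; ip < pps.size(); ip++) {
      caches[ip].assign(pps[ip].ncat, Cache());
      for (int c = 0; c < pps[ip].ncat; c++)
        build_cache(edge, REAL(cur), ntip, pps[ip], c, caches[ip][c]);
    }
    for (int e = 0; e < nedge; e++)
      cur[e] = golden_branch(edge, ntip, pps, caches, e, min_bl, max_bl, iters);
  }
  double lnl = C_total_lnl(edge, cur, ntip, parts);
  return List::create(_["el"] = cur, _["lnl"] = lnl);
}
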
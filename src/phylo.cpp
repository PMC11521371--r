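#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Two-state reversible CTMC on a tree, Felsenstein pruning over many
// presence/absence patterns at once, ascertainment-corrected likelihood
// (conditioning on patterns being neither all-absent nor singleton-presence)
// and a coordinate-ascent fitter (golden-section line searches).
//
// Model: stationary frequencies (pi0, pi1); rates scaled so branch lengths
// are expected state changes per character: P(t) = Pi + exp(-t/beta)(I - Pi)
// with beta = 2 * pi0 * pi1.

struct TreeData {
  int nNode;
  int nTip;
  int root;
  std::vector<int> parent;  // per edge, postorder
  std::vector<int> child;
};

static TreeData makeTree(const IntegerMatrix& edge, int nTip) {
  TreeData td;
  td.nTip = nTip;
  int maxNode = 0;
  const int ne = edge.nrow();
  td.parent.resize(ne);
  td.child.resize(ne);
  for (int i = 0; i < ne; ++i) {
    td.parent[i] = edge(i, 0) - 1;
    td.child[i] = edge(i, 1) - 1;
    maxNode = std::max(maxNode, std::max(edge(i, 0), edge(i, 1)));
  }
  td.nNode = maxNode;
  td.root = nTip;  // ape convention: root is node nTip + 1 (0-based nTip)
  return td;
}

static inline void transMat(double t, double pi1, double P[2][2]) {
  const double pi0 = 1.0 - pi1;
  const double beta = 2.0 * pi0 * pi1;
  const double e = std::exp(-t / beta);
  P[0][0] = pi0 + e * pi1;
  P[0][1] = pi1 - e * pi1;
  P[1][0] = pi0 - e * pi0;
  P[1][1] = pi1 + e * pi0;
}

// per-pattern log probability; patterns may contain any 0/1 leaf tuple
static void patternLogProbs(const TreeData& td, const std::vector<double>& bl,
                            double pi1, const IntegerMatrix& patterns,
                            std::vector<double>& out) {
  const int nPat = patterns.nrow();
  const int ne = (int)td.parent.size();
  std::vector<double> P00(ne), P01(ne), P10(ne), P11(ne);
  for (int i = 0; i < ne; ++i) {
    double P[2][2];
    transMat(bl[i], pi1, P);
    P00[i] = P[0][0]; P01[i] = P[0][1]; P10[i] = P[1][0]; P11[i] = P[1][1];
  }
  std::vector<double> L0(td.nNode), L1(td.nNode);
  const double pi0 = 1.0 - pi1;
  for (int p = 0; p < nPat; ++p) {
    for (int v = 0; v < td.nNode; ++v) { L0[v] = 1.0; L1[v] = 1.0; }
    for (int t = 0; t < td.nTip; ++t) {
      if (patterns(p, t) == 1) L0[t] = 0.0; else L1[t] = 0.0;
    }
    for (int i = 0; i < ne; ++i) {
      const int pa = td.parent[i], ch = td.child[i];
      const double c0 = P00[i] * L0[ch] + P01[i] * L1[ch];
      const double c1 = P10[i] * L0[ch] + P11[i] * L1[ch];
      L0[pa] *= c0;
      L1[pa] *= c1;
    }
    out[p] = std::log(pi0 * L0[td.root] + pi1 * L1[td.root]);
  }
}

// [[Rcpp::export(name = ".patternLogProb")]]
NumericVector patternLogProbCpp(IntegerMatrix edge, NumericVector blen,
                                int nTip, double pi1,
                                IntegerMatrix patterns) {
  if (pi1 <= 0.0 || pi1 >= 1.0) stop("pi1 must be in (0, 1)");
  for (int i = 0; i < blen.size(); ++i)
    if (blen[i] < 0) stop("branch lengths must be >= 0");
  TreeData td = makeTree(edge, nTip);
  std::vector<double> bl(blen.begin(), blen.end());
  std::vector<double> out(patterns.nrow());
  patternLogProbs(td, bl, pi1, patterns, out);
  return wrap(out);
}

// log(1 - P(all absent) - sum_i P(only taxon i present)); the correction
// denominator of the conditional likelihood
static double logDenominator(const TreeData& td, const std::vector<double>& bl,
                             double pi1) {
  const int n = td.nTip;
  IntegerMatrix aux(n + 1, n);
  for (int j = 0; j < n; ++j) aux(0, j) = 0;        // all absent
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) aux(i + 1, j) = (i == j) ? 1 : 0;
  std::vector<double> lp(n + 1);
  patternLogProbs(td, bl, pi1, aux, lp);
  double bad = 0.0;
  for (int i = 0; i <= n; ++i) bad += std::exp(lp[i]);
  const double denom = 1.0 - bad;
  if (denom <= 0.0) stop("ascertainment-correction denominator <= 0");
  return std::log(denom);
}

static double correctedLL(const TreeData& td, const std::vector<double>& bl,
                          double pi1, const IntegerMatrix& patterns,
                          const NumericVector& counts) {
  std::vector<double> lp(patterns.nrow());
  patternLogProbs(td, bl, pi1, patterns, lp);
  const double logDen = logDenominator(td, bl, pi1);
  double total = 0.0, nTot = 0.0;
  for (int p = 0; p < patterns.nrow(); ++p) {
    total += counts[p] * lp[p];
    nTot += counts[p];
  }
  return total - nTot * logDen;
}

// [[Rcpp::export(name = ".correctedLogLik")]]
double correctedLogLikCpp(IntegerMatrix edge, NumericVector blen, int nTip,
                          double pi1, IntegerMatrix patterns,
                          NumericVector counts) {
  if (pi1 <= 0.0 || pi1 >= 1.0) stop("pi1 must be in (0, 1)");
  TreeData td = makeTree(edge, nTip);
  std::vector<double> bl(blen.begin(), blen.end());
  return correctedLL(td, bl, pi1, patterns, counts);
}

template <class F>
static double goldenMax(F f, double lo, double hi, double tol, double* xbest) {
  const double invphi = 0.6180339887498949;
  double a = lo, b = hi;
  double x1 = b - invphi * (b - a);
  double x2 = a + invphi * (b - a);
  double f1 = f(x1), f2 = f(x2);
  while (b - a > tol) {
    if (f1 < f2) {
      a = x1; x1 = x2; f1 = f2;
      x2 = a + invphi * (b - a); f2 = f(x2);
    } else {
      b = x2; x2 = x1; f2 = f1;
      x1 = b - invphi * (b - a); f1 = f(x1);
    }
  }
  double xm = (f1 > f2) ? x1 : x2;
  double fm = (f1 > f2) ? f1 : f2;
  *xbest = xm;
  return fm;
}

// [[Rcpp::export(name = ".fitBinaryModel")]]
List fitBinaryModelCpp(IntegerMatrix edge, NumericVector blen0, int nTip,
                       IntegerMatrix patterns, NumericVector counts,
                       double pi10, double relTol, int maxSweeps,
                       double maxBl) {
  TreeData td = makeTree(edge, nTip);
  std::vector<double> bl(blen0.begin(), blen0.end());
  double pi1 = std::min(std::max(pi10, 1e-4), 1.0 - 1e-4);
  const double piLo = 1e-6, piHi = 1.0 - 1e-6;
  double ll = correctedLL(td, bl, pi1, patterns, counts);
  int sweep = 0;
  bool converged = false;
  for (sweep = 1; sweep <= maxSweeps; ++sweep) {
    const double prev = ll;
    double x, cand;
    // every move is accepted only if it does not lower the incumbent
    // likelihood: golden section never probes the current point itself, so
    // an unguarded update can oscillate just above the convergence threshold
    cand = goldenMax([&](double v) {
      return correctedLL(td, bl, v, patterns, counts);
    }, piLo, piHi, 1e-9, &x);
    if (cand >= ll) { ll = cand; pi1 = x; }
    for (size_t i = 0; i < bl.size(); ++i) {
      const double keep = bl[i];
      cand = goldenMax([&](double v) {
        bl[i] = v;
        double r = correctedLL(td, bl, pi1, patterns, counts);
        bl[i] = keep;
        return r;
      }, 1e-9, maxBl, 1e-8, &x);
      if (cand >= ll) { ll = cand; bl[i] = x; } else bl[i] = keep;
    }
    // global rescaling of all branches: pi1 and the overall tree scale are
    // strongly correlated (the rate scaling beta depends on pi1), so plain
    // per-branch updates zigzag along a ridge; this move walks the ridge
    double blMax = 0.0;
    for (size_t i = 0; i < bl.size(); ++i) blMax = std::max(blMax, bl[i]);
    const double cHi = blMax > 0.0 ? std::min(5.0, maxBl / blMax) : 1.0;
    std::vector<double> base(bl);
    cand = goldenMax([&](double c) {
      for (size_t i = 0; i < bl.size(); ++i) bl[i] = std::max(base[i] * c, 1e-9);
      return correctedLL(td, bl, pi1, patterns, counts);
    }, 0.2, cHi, 1e-7, &x);
    if (cand >= ll) {
      ll = cand;
      for (size_t i = 0; i < bl.size(); ++i) bl[i] = std::max(base[i] * x, 1e-9);
    } else {
      bl = base;
    }
    // pi1 move with compensating rescale keeping t/beta fixed: this is the
    // exact ridge direction along which only the stationary part changes
    base = bl;
    const double beta0 = 2.0 * (1.0 - pi1) * pi1;
    cand = goldenMax([&](double v) {
      const double c = (2.0 * (1.0 - v) * v) / beta0;
      for (size_t i = 0; i < bl.size(); ++i)
        bl[i] = std::min(std::max(base[i] * c, 1e-9), maxBl);
      return correctedLL(td, bl, v, patterns, counts);
    }, piLo, piHi, 1e-9, &x);
    if (cand >= ll) {
      ll = cand;
      const double c = (2.0 * (1.0 - x) * x) / beta0;
      for (size_t i = 0; i < bl.size(); ++i)
        bl[i] = std::min(std::max(base[i] * c, 1e-9), maxBl);
      pi1 = x;
    } else {
      bl = base;
    }
    if (std::fabs(ll - prev) < relTol * (std::fabs(prev) + 1.0)) {
      converged = true;
      break;
    }
  }
  return List::create(_["pi1"] = pi1, _["blen"] = wrap(bl),
                      _["loglik"] = ll, _["sweeps"] = sweep,
                      _["converged"] = converged);
}
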
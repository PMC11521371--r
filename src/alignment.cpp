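#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh).
// Scoring: match +2, mismatch -1; a gap of length k costs open + k * ext
// (open = 5, ext = 1), i.e. the first gapped position costs -(open + ext).

static const int MATCH = 2;
static const int MISMATCH = -1;
static const int GAP_OPEN = 5;  // positive costs
static const int GAP_EXT = 1;

static inline std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (int)(unsigned char)s[i];
  return v;
}

// H: best local score; E: gap-in-b (horizontal, scalar per row);
// F: gap-in-a (vertical, one cell per column carried across rows)
static int sw_score(const std::vector<int>& a, const std::vector<int>& b) {
  const int n = (int)a.size(), m = (int)b.size();
  const int NEG = -1000000000;
  std::vector<int> Hv(m + 1, 0), Fv(m + 1, NEG);
  int* H = Hv.data();
  int* F = Fv.data();
  const int* bp = b.data();
  int best = 0;
  for (int i = 0; i < n; ++i) {
    const int ai = a[i];
    int diag = 0;   // H[i-1][j-1]
    int E = NEG;    // horizontal gap state, current row
    for (int j = 1; j <= m; ++j) {
      const int hLeft = H[j - 1];             // H[i][j-1], already updated
      E = std::max(E, hLeft - GAP_OPEN) - GAP_EXT;
      const int hUp = H[j];                   // H[i-1][j]
      const int f = std::max(F[j], hUp - GAP_OPEN) - GAP_EXT;
      F[j] = f;
      int h = diag + (ai == bp[j - 1] ? MATCH : MISMATCH);
      if (E > h) h = E;
      if (f > h) h = f;
      if (h < 0) h = 0;
      diag = hUp;
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".swScore")]]
int swScoreCpp(std::string a, std::string b) {
  if (a.empty() || b.empty()) stop("empty sequence");
  std::vector<int> ea = encode(a), eb = encode(b);
  return sw_score(ea, eb);
}

// All-pairs local alignment scores: rows = queries, cols = targets.
// [[Rcpp::export(name = ".swScoreMatrix")]]
IntegerMatrix swScoreMatrixCpp(CharacterVector queries,
                               CharacterVector targets) {
  const int nq = queries.size(), nt = targets.size();
  std::vector<std::vector<int> > eq(nq), et(nt);
  for (int i = 0; i < nq; ++i) {
    std::string s = as<std::string>(queries[i]);
    if (s.empty()) stop("empty sequence");
    eq[i] = encode(s);
  }
  for (int j = 0; j < nt; ++j) {
    std::string s = as<std::string>(targets[j]);
    if (s.empty()) stop("empty sequence");
    et[j] = encode(s);
  }
  IntegerMatrix out(nq, nt);
  for (int i = 0; i < nq; ++i) {
    Rcpp::checkUserInterrupt();
    for (int j = 0; j < nt; ++j) out(i, j) = sw_score(eq[i], et[j]);
  }
  return out;
}
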
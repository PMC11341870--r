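#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
#include <cctype>
using namespace Rcpp;

// Banded global affine-gap (Gotoh) alignment with full traceback.
//
// Scoring: substitution from `submat` (single-letter dimnames); a gap of
// length L costs gap_open + L * gap_extend (both arguments negative).
// Tie-breaks, in order of preference at equal score:
//   diagonal (match/mismatch) > gap in b (b carries '-') > gap in a;
// within a gap state, extending an existing gap beats opening a new one.
// The band constrains j to [i - band, i + band]; band >= max(len a, len b)
// is an exact full DP.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List align_affine_cpp(std::string a, std::string b, NumericMatrix submat,
                      double gap_open, double gap_extend, int band) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  if (band < std::abs(n - m))
    stop("band (%d) narrower than the length difference (%d)", band, std::abs(n - m));

  // char -> submat index lookup
  std::vector<int> lut(256, -1);
  CharacterVector rn = rownames(submat);
  for (int r = 0; r < rn.size(); ++r) {
    std::string s = as<std::string>(rn[r]);
    if (s.size() != 1) stop("substitution matrix dimnames must be single characters");
    lut[(unsigned char)std::toupper(s[0])] = r;
    lut[(unsigned char)std::tolower(s[0])] = r;
  }
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = lut[(unsigned char)a[i]];
    if (ai[i] < 0) stop("character '%c' in sequence a not in substitution matrix", a[i]);
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = lut[(unsigned char)b[j]];
    if (bi[j] < 0) stop("character '%c' in sequence b not in substitution matrix", b[j]);
  }

  const int W = std::min(m, 2 * band) + 1;      // band-compressed row width
  auto lo = [&](int i) { return std::max(0, i - band); };
  auto hi = [&](int i) { return std::min(m, i + band); };

  const size_t sz = (size_t)(n + 1) * W;
  std::vector<double> H(sz, NEG_INF), E(sz, NEG_INF), F(sz, NEG_INF);
  // traceback: tbH 0=diag 1=F(vertical) 2=E(horizontal); tbE/tbF 0=open 1=extend
  std::vector<unsigned char> tbH(sz, 0), tbE(sz, 0), tbF(sz, 0);
  auto at = [&](int i, int j) { return (size_t)i * W + (j - lo(i)); };

  H[at(0, 0)] = 0.0;
  for (int j = 1; j <= hi(0); ++j) {            // leading gap in a
    size_t c = at(0, j);
    E[c] = gap_open + j * gap_extend;
    tbE[c] = (j == 1) ? 0 : 1;
    H[c] = E[c]; tbH[c] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    const int jl = lo(i), jh = hi(i), pl = lo(i - 1), ph = hi(i - 1);
    if (jl == 0) {                              // leading gap in b
      size_t c = at(i, 0);
      F[c] = gap_open + i * gap_extend;
      tbF[c] = (i == 1) ? 0 : 1;
      H[c] = F[c]; tbH[c] = 1;
    }
    for (int j = std::max(1, jl); j <= jh; ++j) {
      const size_t c = at(i, j);
      // E: gap in a (horizontal), from (i, j-1)
      if (j - 1 >= jl) {
        const size_t w = at(i, j - 1);
        double ext = E[w] + gap_extend, opn = H[w] + gap_open + gap_extend;
        if (ext >= opn && E[w] > NEG_INF) { E[c] = ext; tbE[c] = 1; }
        else if (opn > NEG_INF)           { E[c] = opn; tbE[c] = 0; }
      }
      // F: gap in b (vertical), from (i-1, j)
      if (j >= pl && j <= ph) {
        const size_t u = at(i - 1, j);
        double ext = F[u] + gap_extend, opn = H[u] + gap_open + gap_extend;
        if (ext >= opn && F[u] > NEG_INF) { F[c] = ext; tbF[c] = 1; }
        else if (opn > NEG_INF)           { F[c] = opn; tbF[c] = 0; }
      }
      // H: best of diag / F / E with the fixed preference order
      double diag = NEG_INF;
      if (j - 1 >= pl && j - 1 <= ph) {
        double prev = H[at(i - 1, j - 1)];
        if (prev > NEG_INF) diag = prev + submat(ai[i - 1], bi[j - 1]);
      }
      double best = diag; unsigned char ptr = 0;
      if (F[c] > best) { best = F[c]; ptr = 1; }
      if (E[c] > best) { best = E[c]; ptr = 2; }
      H[c] = best; tbH[c] = ptr;
    }
  }

  const double score = H[at(n, m)];
  if (score == NEG_INF) stop("no alignment within the band");

  // traceback
  std::string oa, ob;
  oa.reserve(n + m); ob.reserve(n + m);
  int i = n, j = m, state = 0;                  // 0=H 1=F 2=E
  while (i > 0 || j > 0) {
    const size_t c = at(i, j);
    if (state == 0) {
      if (tbH[c] == 0) { oa.push_back(a[i - 1]); ob.push_back(b[j - 1]); --i; --j; }
      else state = tbH[c];                      // defer to gap state
    } else if (state == 1) {                    // F: a char over '-'
      oa.push_back(a[i - 1]); ob.push_back('-');
      state = (tbF[c] == 0) ? 0 : 1; --i;
    } else {                                    // E: '-' over b char
      oa.push_back('-'); ob.push_back(b[j - 1]);
      state = (tbE[c] == 0) ? 0 : 2; --j;
    }
  }
  std::reverse(oa.begin(), oa.end());
  std::reverse(ob.begin(), ob.end());

  return List::create(_["score"] = score,
                      _["aligned_a"] = oa,
                      _["aligned_b"] = ob);
}
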
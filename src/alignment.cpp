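// Global alignment of near-identical nucleotide sequences.
//
// Scoring: match +1, mismatch -1, gap open -2, gap extend -1 (a gap of
// length L scores -(2 + L)).  Transcript alphabet: M match, X mismatch,
// I base present in the query only (insertion relative to the target),
// D base present in the target only (deletion from the query).
//
// Tie-breaking is identical in the banded and the full aligner: on equal
// score the diagonal state is preferred over D, and D over I, both when
// filling the matrices and during traceback, so that both routes produce
// the same transcript whenever the band contains the optimum.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static const int NEG_INF = -1000000000;
static const int MATCH = 1, MISMATCH = -1, GAP_OPEN = 2, GAP_EXT = 1;

// state codes used in traceback matrices
enum { ST_M = 0, ST_D = 1, ST_I = 2 };

// [[Rcpp::export]]
List cpp_banded_align(std::string a, std::string b, int band) {
  // a = query, b = target
  int n = (int)a.size(), m = (int)b.size();
  if (n == 0 && m == 0)
    return List::create(_["score"] = 0, _["transcript"] = "");
  if (n == 0)
    return List::create(_["score"] = -(GAP_OPEN + GAP_EXT * m),
                        _["transcript"] = std::string(m, 'D'));
  if (m == 0)
    return List::create(_["score"] = -(GAP_OPEN + GAP_EXT * n),
                        _["transcript"] = std::string(n, 'I'));

  int diff = std::abs(n - m);
  if (band < diff + 1) band = diff + 1;
  if (band > std::max(n, m)) band = std::max(n, m);
  int W = 2 * band + 1;

  // row-offset banded storage: row i covers target columns [i-band, i+band]
  std::vector<int> Mrow((size_t)(n + 1) * W, NEG_INF);
  std::vector<int> Drow((size_t)(n + 1) * W, NEG_INF);
  std::vector<int> Irow((size_t)(n + 1) * W, NEG_INF);
  // traceback: predecessor state for each of the three states
  std::vector<uint8_t> tbM((size_t)(n + 1) * W, 0);
  std::vector<uint8_t> tbD((size_t)(n + 1) * W, 0);
  std::vector<uint8_t> tbI((size_t)(n + 1) * W, 0);

  auto idx = [&](int i, int j) { return (size_t)i * W + (j - (i - band)); };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= m && j >= i - band && j <= i + band;
  };

  Mrow[idx(0, 0)] = 0;
  for (int j = 1; j <= m && j <= band; ++j) {
    Drow[idx(0, j)] = -(GAP_OPEN + GAP_EXT * j);
    tbD[idx(0, j)] = (j == 1) ? ST_M : ST_D;
  }
  for (int i = 1; i <= n; ++i) {
    int lo = std::max(0, i - band), hi = std::min(m, i + band);
    for (int j = lo; j <= hi; ++j) {
      size_t c = idx(i, j);
      // I: consume a[i-1] only (gap in target)
      if (inband(i - 1, j)) {
        size_t up = idx(i - 1, j);
        int fromM = (Mrow[up] == NEG_INF) ? NEG_INF : Mrow[up] - GAP_OPEN - GAP_EXT;
        int fromD = (Drow[up] == NEG_INF) ? NEG_INF : Drow[up] - GAP_OPEN - GAP_EXT;
        int fromI = (Irow[up] == NEG_INF) ? NEG_INF : Irow[up] - GAP_EXT;
        int best = fromM; uint8_t st = ST_M;
        if (fromD > best) { best = fromD; st = ST_D; }
        if (fromI > best) { best = fromI; st = ST_I; }
        Irow[c] = best; tbI[c] = st;
      }
      // D: consume b[j-1] only (gap in query)
      if (j > 0 && inband(i, j - 1)) {
        size_t lf = idx(i, j - 1);
        int fromM = (Mrow[lf] == NEG_INF) ? NEG_INF : Mrow[lf] - GAP_OPEN - GAP_EXT;
        int fromI = (Irow[lf] == NEG_INF) ? NEG_INF : Irow[lf] - GAP_OPEN - GAP_EXT;
        int fromD = (Drow[lf] == NEG_INF) ? NEG_INF : Drow[lf] - GAP_EXT;
        int best = fromM; uint8_t st = ST_M;
        if (fromD > best) { best = fromD; st = ST_D; }
        if (fromI > best) { best = fromI; st = ST_I; }
        Drow[c] = best; tbD[c] = st;
      }
      // M: consume both
      if (i > 0 && j > 0 && inband(i - 1, j - 1)) {
        size_t dg = idx(i - 1, j - 1);
        int s = (a[(size_t)i - 1] == b[(size_t)j - 1]) ? MATCH : MISMATCH;
        int fromM = (Mrow[dg] == NEG_INF) ? NEG_INF : Mrow[dg] + s;
        int fromD = (Drow[dg] == NEG_INF) ? NEG_INF : Drow[dg] + s;
        int fromI = (Irow[dg] == NEG_INF) ? NEG_INF : Irow[dg] + s;
        int best = fromM; uint8_t st = ST_M;
        if (fromD > best) { best = fromD; st = ST_D; }
        if (fromI > best) { best = fromI; st = ST_I; }
        Mrow[c] = best; tbM[c] = st;
      }
    }
  }

  size_t endc = idx(n, m);
  int score = Mrow[endc]; uint8_t state = ST_M;
  if (Drow[endc] > score) { score = Drow[endc]; state = ST_D; }
  if (Irow[endc] > score) { score = Irow[endc]; state = ST_I; }
  if (score <= NEG_INF / 2)
    stop("banded alignment: band too narrow for the optimum path");

  std::string tr;
  tr.reserve((size_t)n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    size_t c = idx(i, j);
    if (state == ST_M) {
      uint8_t prev = tbM[c];
      tr.push_back(a[(size_t)i - 1] == b[(size_t)j - 1] ? 'M' : 'X');
      --i; --j; state = prev;
    } else if (state == ST_D) {
      uint8_t prev = tbD[c];
      tr.push_back('D');
      --j; state = prev;
    } else {
      uint8_t prev = tbI[c];
      tr.push_back('I');
      --i; state = prev;
    }
  }
  std::reverse(tr.begin(), tr.end());
  return List::create(_["score"] = score, _["transcript"] = tr);
}

// Full-matrix (unbanded) Gotoh aligner: the reference implementation used as
// an oracle against the anchored/banded route.  Kept deliberately simple and
// independent of the banded code path.

// [[Rcpp::export]]
List cpp_full_align(std::string a, std::string b) {
  int n = (int)a.size(), m = (int)b.size();
  if ((double)(n + 1) * (m + 1) > 6.5e7)
    stop("full alignment restricted to small sequence pairs");
  size_t W = (size_t)m + 1;
  std::vector<int> M((size_t)(n + 1) * W, NEG_INF);
  std::vector<int> D((size_t)(n + 1) * W, NEG_INF);
  std::vector<int> I((size_t)(n + 1) * W, NEG_INF);
  std::vector<uint8_t> tM((size_t)(n + 1) * W, 0), tD((size_t)(n + 1) * W, 0),
      tI((size_t)(n + 1) * W, 0);
  M[0] = 0;
  for (int j = 1; j <= m; ++j) {
    D[(size_t)j] = -(GAP_OPEN + GAP_EXT * j);
    tD[(size_t)j] = (j == 1) ? ST_M : ST_D;
  }
  for (int i = 1; i <= n; ++i) {
    I[(size_t)i * W] = -(GAP_OPEN + GAP_EXT * i);
    tI[(size_t)i * W] = (i == 1) ? ST_M : ST_I;
    for (int j = 1; j <= m; ++j) {
      size_t c = (size_t)i * W + j, up = c - W, lf = c - 1, dg = up - 1;
      {
        int fM = (M[up] == NEG_INF) ? NEG_INF : M[up] - GAP_OPEN - GAP_EXT;
        int fD = (D[up] == NEG_INF) ? NEG_INF : D[up] - GAP_OPEN - GAP_EXT;
        int fI = (I[up] == NEG_INF) ? NEG_INF : I[up] - GAP_EXT;
        int best = fM; uint8_t st = ST_M;
        if (fD > best) { best = fD; st = ST_D; }
        if (fI > best) { best = fI; st = ST_I; }
        I[c] = best; tI[c] = st;
      }
      {
        int fM = (M[lf] == NEG_INF) ? NEG_INF : M[lf] - GAP_OPEN - GAP_EXT;
        int fD = (D[lf] == NEG_INF) ? NEG_INF : D[lf] - GAP_EXT;
        int fI = (I[lf] == NEG_INF) ? NEG_INF : I[lf] - GAP_OPEN - GAP_EXT;
        int best = fM; uint8_t st = ST_M;
        if (fD > best) { best = fD; st = ST_D; }
        if (fI > best) { best = fI; st = ST_I; }
        D[c] = best; tD[c] = st;
      }
      {
        int s = (a[(size_t)i - 1] == b[(size_t)j - 1]) ? MATCH : MISMATCH;
        int fM = (M[dg] == NEG_INF) ? NEG_INF : M[dg] + s;
        int fD = (D[dg] == NEG_INF) ? NEG_INF : D[dg] + s;
        int fI = (I[dg] == NEG_INF) ? NEG_INF : I[dg] + s;
        int best = fM; uint8_t st = ST_M;
        if (fD > best) { best = fD; st = ST_D; }
        if (fI > best) { best = fI; st = ST_I; }
        M[c] = best; tM[c] = st;
      }
    }
  }
  size_t endc = (size_t)n * W + m;
  int score = M[endc]; uint8_t state = ST_M;
  if (D[endc] > score) { score = D[endc]; state = ST_D; }
  if (I[endc] > score) { score = I[endc]; state = ST_I; }
  std::string tr;
  tr.reserve((size_t)n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    size_t c = (size_t)i * W + j;
    if (state == ST_M) {
      uint8_t prev = tM[c];
      tr.push_back(a[(size_t)i - 1] == b[(size_t)j - 1] ? 'M' : 'X');
      --i; --j; state = prev;
    } else if (state == ST_D) {
      uint8_t prev = tD[c];
      tr.push_back('D'); --j; state = prev;
    } else {
      uint8_t prev = tI[c];
      tr.push_back('I'); --i; state = prev;
    }
  }
  std::reverse(tr.begin(), tr.end());
  return List::create(_["score"] = score, _["transcript"] = tr);
}
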
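// Unique-k-mer anchor finding for near-identical genome pairs.
//
// A k-mer that occurs exactly once in each of two sequences is an anchor
// candidate; consecutive candidates on the same diagonal are merged into
// maximal exact matches.  k is limited to 31 so a k-mer fits in 64 bits
// (2-bit alphabet); windows containing non-ACGT characters are skipped.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
using namespace Rcpp;

struct KmerEntry { uint32_t count; uint32_t pos; };
typedef std::unordered_map<uint64_t, KmerEntry> KmerMap;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static void build_kmer_map(const std::string& s, int k, KmerMap& map) {
  int n = (int)s.size();
  if (n < k) return;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t key = 0;
  int valid = 0;  // number of consecutive valid bases ending at i
  for (int i = 0; i < n; ++i) {
    int c = base_code(s[(size_t)i]);
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++valid >= k) {
      auto it = map.find(key);
      if (it == map.end()) map[key] = {1u, (uint32_t)(i - k + 1)};
      else it->second.count++;
    }
  }
}

// collect (qpos, tpos) pairs for k-mers unique in both sequences, in query
// order, then merge same-diagonal runs into maximal exact matches
static IntegerMatrix match_unique(const std::string& q, const KmerMap& qmap,
                                  const KmerMap& tmap, int k) {
  std::vector<int> qp, tp;
  int n = (int)q.size();
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t key = 0;
  int valid = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(q[(size_t)i]);
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++valid >= k) {
      auto qi = qmap.find(key);
      if (qi == qmap.end() || qi->second.count != 1) continue;
      auto ti = tmap.find(key);
      if (ti == tmap.end() || ti->second.count != 1) continue;
      qp.push_back(i - k + 1);
      tp.push_back((int)ti->second.pos);
    }
  }
  // merge same-diagonal runs: hits whose starts advance equally in both
  // coordinates by at most k still cover one contiguous exact match (a
  // skipped window is a k-mer that is non-unique elsewhere, not a
  // sequence difference)
  std::vector<int> qs, ts, len;
  size_t nn = qp.size();
  for (size_t i = 0; i < nn;) {
    size_t j = i + 1;
    while (j < nn && qp[j] - qp[j - 1] == tp[j] - tp[j - 1] &&
           qp[j] > qp[j - 1] && qp[j] - qp[j - 1] <= k) ++j;
    qs.push_back(qp[i]);
    ts.push_back(tp[i]);
    len.push_back(qp[j - 1] - qp[i] + k);
    i = j;
  }
  IntegerMatrix out((int)qs.size(), 3);
  for (int i = 0; i < (int)qs.size(); ++i) {
    out(i, 0) = qs[(size_t)i];
    out(i, 1) = ts[(size_t)i];
    out(i, 2) = len[(size_t)i];
  }
  colnames(out) = CharacterVector::create("qstart", "tstart", "length");
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_find_anchors(std::string q, std::string t, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  KmerMap qmap, tmap;
  build_kmer_map(q, k, qmap);
  build_kmer_map(t, k, tmap);
  return match_unique(q, qmap, tmap, k);
}

// Batch anchor finding of many short fragments against one target: the
// target map is built once.  Uniqueness is required within each fragment
// and within the target.

// [[Rcpp::export]]
List cpp_fragment_anchors(CharacterVector fragments, std::string t, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  KmerMap tmap;
  build_kmer_map(t, k, tmap);
  int nf = fragments.size();
  List out(nf);
  for (int f = 0; f < nf; ++f) {
    std::string frag = as<std::string>(fragments[f]);
    KmerMap fmap;
    build_kmer_map(frag, k, fmap);
    out[f] = match_unique(frag, fmap, tmap, k);
  }
  return out;
}
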
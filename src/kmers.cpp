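// k-mer anchor discovery and banded edit distance.
// Anchors are k-mers occurring exactly once in each genome, counted
// strand-canonically; they are the raw material for synteny chaining.
#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <climits>
#include <cstdlib>
#include <algorithm>
using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

struct Occ {
  int count;
  int chrom;   // 0-based chromosome index
  int pos;     // 0-based start on the forward strand
  bool fwd;    // canonical form read on forward strand?
};

// Scan one genome, filling a canonical-kmer -> occurrence map.
static void scan_genome(const std::vector<std::string>& seqs, int k,
                        std::unordered_map<std::string, Occ>& map) {
  std::string fwd(k, 'N'), rc(k, 'N');
  for (size_t ci = 0; ci < seqs.size(); ++ci) {
    const std::string& s = seqs[ci];
    if ((int)s.size() < k) continue;
    // next_valid[i]: leftmost j >= i with no N in s[j..j+k)
    int n = (int)s.size();
    int bad_until = -1; // rightmost N seen at or before current window end
    for (int i = 0; i + k <= n; ++i) {
      if (i == 0) {
        for (int j = 0; j < k; ++j) if (s[j] == 'N') bad_until = j;
      } else {
        if (s[i + k - 1] == 'N') bad_until = i + k - 1;
      }
      if (bad_until >= i) continue;
      for (int j = 0; j < k; ++j) {
        fwd[j] = s[i + j];
        rc[k - 1 - j] = comp(s[i + j]);
      }
      bool is_fwd = fwd <= rc;  // k odd: no palindromes, ties impossible
      const std::string& canon = is_fwd ? fwd : rc;
      auto it = map.find(canon);
      if (it == map.end()) {
        map.emplace(canon, Occ{1, (int)ci, i, is_fwd});
      } else {
        it->second.count++;
      }
    }
  }
}

// 2-bit packed scan for k <= 31: canonical code is the numeric min of the
// forward and reverse-complement encodings, maintained by rolling update.
static void scan_genome_packed(const std::vector<std::string>& seqs, int k,
                               std::unordered_map<uint64_t, Occ>& map) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  for (size_t ci = 0; ci < seqs.size(); ++ci) {
    const std::string& s = seqs[ci];
    int n = (int)s.size();
    if (n < k) continue;
    uint64_t fwd = 0, rc = 0;
    int valid = 0;  // consecutive non-N bases ending at current position
    for (int i = 0; i < n; ++i) {
      int code;
      switch (s[i]) {
      case 'A': code = 0; break;
      case 'C': code = 1; break;
      case 'G': code = 2; break;
      case 'T': code = 3; break;
      default:  code = -1;
      }
      if (code < 0) { valid = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)code) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - code) << shift);
      if (++valid < k) continue;
      bool is_fwd = fwd <= rc;
      uint64_t canon = is_fwd ? fwd : rc;
      int pos = i - k + 1;
      auto it = map.find(canon);
      if (it == map.end())
        map.emplace(canon, Occ{1, (int)ci, pos, is_fwd});
      else
        it->second.count++;
    }
  }
}

template <typename MapT, typename ScanF>
static DataFrame anchors_from(const std::vector<std::string>& ref,
                              const std::vector<std::string>& qry, int k,
                              ScanF scan) {
  MapT mref, mqry;
  size_t tot = 0;
  for (auto& s : ref) tot += s.size();
  mref.reserve(tot * 13 / 10);
  scan(ref, k, mref);
  tot = 0;
  for (auto& s : qry) tot += s.size();
  mqry.reserve(tot * 13 / 10);
  scan(qry, k, mqry);

  std::vector<int> rchrom, rpos, qchrom, qpos;
  std::vector<bool> forward;
  for (auto& kv : mref) {
    if (kv.second.count != 1) continue;
    auto it = mqry.find(kv.first);
    if (it == mqry.end() || it->second.count != 1) continue;
    rchrom.push_back(kv.second.chrom + 1);
    rpos.push_back(kv.second.pos);
    qchrom.push_back(it->second.chrom + 1);
    qpos.push_back(it->second.pos);
    forward.push_back(kv.second.fwd == it->second.fwd);
  }
  return DataFrame::create(_["ref_chrom_i"] = rchrom, _["ref_pos"] = rpos,
                           _["qry_chrom_i"] = qchrom, _["qry_pos"] = qpos,
                           _["forward"] = forward);
}

// [[Rcpp::export]]
DataFrame kmer_anchors_cpp(List ref_seqs, List qry_seqs, int k) {
  std::vector<std::string> ref, qry;
  for (int i = 0; i < ref_seqs.size(); ++i)
    ref.push_back(as<std::string>(ref_seqs[i]));
  for (int i = 0; i < qry_seqs.size(); ++i)
    qry.push_back(as<std::string>(qry_seqs[i]));
  if (k <= 31)
    return anchors_from<std::unordered_map<uint64_t, Occ>>(
      ref, qry, k, scan_genome_packed);
  return anchors_from<std::unordered_map<std::string, Occ>>(
    ref, qry, k, scan_genome);
}

// Banded global edit distance (Levenshtein). The band must cover the
// length difference; cells outside the band are treated as infinite.
// [[Rcpp::export]]
int banded_edit_distance_cpp(std::string a, std::string b, int band) {
  int n = (int)a.size(), m = (int)b.size();
  if (band < std::abs(n - m)) band = std::abs(n - m);
  const int INF = INT_MAX / 4;
  std::vector<int> prev(2 * band + 1, INF), cur(2 * band + 1, INF);
  // prev[d] = D(i-1, j) where j = (i-1) + (d - band)
  for (int d = band; d <= 2 * band && d - band <= m; ++d)
    prev[d] = d - band; // row i = 0: D(0, j) = j
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    for (int d = 0; d <= 2 * band; ++d) {
      int j = i + d - band;
      if (j < 0 || j > m) continue;
      int best = INF;
      if (j == 0) {
        best = i;
      } else {
        // substitution / match: D(i-1, j-1), same d
        if (prev[d] < INF) {
          int c = prev[d] + (a[i - 1] == b[j - 1] ? 0 : 1);
          if (c < best) best = c;
        }
        // deletion from a: D(i-1, j), d + 1 in prev indexing
        if (d < 2 * band && prev[d + 1] < INF && prev[d + 1] + 1 < best)
          best = prev[d + 1] + 1;
        // insertion into a: D(i, j-1), d - 1 in cur indexing
        if (d > 0 && cur[d - 1] < INF && cur[d - 1] + 1 < best)
          best = cur[d - 1] + 1;
      }
      cur[d] = best;
    }
    std::swap(prev, cur);
  }
  int d = m - n + band;
  if (d < 0 || d > 2 * band) return INF;
  return prev[d];
}
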
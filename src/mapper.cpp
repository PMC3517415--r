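// Minimal seeded, ungapped read-to-reference mapper: a k-mer index over the
// reference plus ungapped extension at each seeded diagonal. Deliberately
// simple — only best-hit resolution and thresholding are scientific rules;
// this provides self-contained hit records so tests need no external aligner.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// [[Rcpp::export(name = ".map_reads_cpp")]]
DataFrame map_reads_cpp(CharacterVector reads, CharacterVector refs,
                        int k = 15, double min_identity = 0.95,
                        int min_overlap = 50, int stride = 5,
                        int max_kmer_occ = 100) {
  if (refs.size() == 0) stop("empty reference");
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  if (stride < 1) stride = 1;

  std::vector<std::string> ref(refs.size());
  for (int i = 0; i < refs.size(); ++i) ref[i] = as<std::string>(refs[i]);

  // k-mer index: hash -> packed (ref_index << 32 | position)
  std::unordered_map<uint64_t, std::vector<uint64_t> > index;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t r = 0; r < ref.size(); ++r) {
    const std::string &s = ref[r];
    if ((int)s.size() < k) continue;
    uint64_t h = 0;
    int run = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int b = base2bits(s[p]);
      if (b < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & mask;
      if (++run >= k)
        index[h].push_back(((uint64_t)r << 32) | (uint64_t)(p - k + 1));
    }
  }

  std::vector<int> out_read, out_ref, out_match, out_mm, out_ovl;

  for (int i = 0; i < reads.size(); ++i) {
    const std::string q = as<std::string>(reads[i]);
    const int n = (int)q.size();
    if (n < k) continue;

    // candidate diagonals: (ref, offset) with offset = ref_pos - read_pos
    std::unordered_map<int64_t, char> seen;
    std::vector<std::pair<int, int> > cand;
    std::vector<int> seedpos;
    for (int p = 0; p <= n - k; p += stride) seedpos.push_back(p);
    if (seedpos.back() != n - k) seedpos.push_back(n - k);
    for (int p : seedpos) {
      uint64_t h = 0;
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        int b = base2bits(q[p + j]);
        if (b < 0) { ok = false; break; }
        h = (h << 2) | (uint64_t)b;
      }
      if (!ok) continue;
      auto it = index.find(h & mask);
      if (it == index.end() || (int)it->second.size() > max_kmer_occ)
        continue;
      for (uint64_t packed : it->second) {
        int r = (int)(packed >> 32);
        int rp = (int)(packed & 0xffffffffULL);
        int64_t key = ((int64_t)r << 24) + (rp - p + (1 << 22));
        if (seen.emplace(key, 1).second)
          cand.push_back(std::make_pair(r, rp - p));
      }
    }

    // evaluate each diagonal; keep the best per reference
    std::unordered_map<int, std::array<int, 3> > best; // ref -> match, mm, ovl
    for (auto &c : cand) {
      const std::string &s = ref[c.first];
      int off = c.second;
      int qs = off < 0 ? -off : 0;            // first read base used
      int rs = off < 0 ? 0 : off;             // first ref base used
      int len = std::min(n - qs, (int)s.size() - rs);
      if (len < min_overlap) continue;
      int match = 0;
      for (int j = 0; j < len; ++j)
        if (q[qs + j] == s[rs + j]) ++match;
      int mm = len - match;
      if ((double)match / len < min_identity) continue;
      auto it = best.find(c.first);
      if (it == best.end() || match - mm > it->second[0] - it->second[1])
        best[c.first] = std::array<int, 3>{{match, mm, len}};
    }

    for (auto &b : best) {
      out_read.push_back(i + 1);
      out_ref.push_back(b.first + 1);
      out_match.push_back(b.second[0]);
      out_mm.push_back(b.second[1]);
      out_ovl.push_back(b.second[2]);
    }
  }

  return DataFrame::create(_["read"] = out_read, _["ref"] = out_ref,
                           _["matches"] = out_match,
                           _["mismatches"] = out_mm,
                           _["overlap"] = out_ovl);
}
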
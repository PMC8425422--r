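#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// 2-bit code; anything outside ACGT (incl. N) is -1 and never matches.
static inline int code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

static inline bool valid_read_char(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T' || c == 'N';
}

// Hamming distance with early exit; N on either side counts as a mismatch.
static inline int hamming_capped(const char* a, const char* b, int L, int cap) {
  int mm = 0;
  for (int i = 0; i < L; ++i) {
    if (a[i] != b[i] || code(a[i]) < 0) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

static std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[s.size() - 1 - i]) {
      case 'A': r[i] = 'T'; break; case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break; case 'T': r[i] = 'A'; break;
      default:  r[i] = 'N';
    }
  }
  return r;
}

struct KmerIndex {
  int k;
  // packed k-mer -> (ref index, start) for every exact occurrence
  std::unordered_map<uint64_t, std::vector<std::pair<int, int> > > pos;
};

static void build_index(const std::vector<std::string>& refs, int k, KmerIndex& idx) {
  idx.k = k;
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int i = 0; i < (int)refs.size(); ++i) {
    const std::string& s = refs[i];
    const int n = (int)s.size();
    uint64_t key = 0;
    int run = 0; // length of current valid-base run
    for (int p = 0; p < n; ++p) {
      const int c = code(s[p]);
      if (c < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)c) & mask;
      if (++run >= k) idx.pos[key].push_back(std::make_pair(i, p - k + 1));
    }
  }
}

// Search one read orientation. Guarantee: finds every reference with an
// end-to-end occurrence of `rd` at <= max_mm substitutions.
//
// Pigeonhole: split the read into max_mm+1 contiguous pieces; if an
// alignment has <= max_mm mismatches, at least one piece is mismatch-free,
// hence its first k bases occur exactly in the reference and are found via
// the k-mer index. A piece whose seed contains N can never be the clean
// piece (N always mismatches), so skipping such seeds stays exact. Reads
// too short to give k-base seeds fall back to a full window scan.
static void search_oriented(const std::string& rd,
                            const std::vector<std::string>& refs,
                            const KmerIndex& idx, int max_mm,
                            std::vector<char>& seen, std::vector<int>& out) {
  const int L = (int)rd.size();
  const int k = idx.k;
  const int pieces = max_mm + 1;
  const int s = L / pieces;

  if (s < k) { // brute-force fallback for very short reads
    for (int i = 0; i < (int)refs.size(); ++i) {
      if (seen[i]) continue;
      const std::string& R = refs[i];
      const int n = (int)R.size();
      for (int st = 0; st + L <= n; ++st) {
        if (hamming_capped(rd.c_str(), R.c_str() + st, L, max_mm) <= max_mm) {
          seen[i] = 1; out.push_back(i); break;
        }
      }
    }
    return;
  }

  for (int j = 0; j < pieces; ++j) {
    const int o = j * s;
    uint64_t key = 0;
    bool ok = true;
    for (int t = 0; t < k; ++t) {
      const int c = code(rd[o + t]);
      if (c < 0) { ok = false; break; }
      key = (key << 2) | (uint64_t)c;
    }
    if (!ok) continue;
    std::unordered_map<uint64_t, std::vector<std::pair<int, int> > >::const_iterator
      it = idx.pos.find(key);
    if (it == idx.pos.end()) continue;
    const std::vector<std::pair<int, int> >& cand = it->second;
    for (size_t q = 0; q < cand.size(); ++q) {
      const int i = cand[q].first;
      if (seen[i]) continue;
      const int st = cand[q].second - o;
      const std::string& R = refs[i];
      if (st < 0 || st + L > (int)R.size()) continue;
      if (hamming_capped(rd.c_str(), R.c_str() + st, L, max_mm) <= max_mm) {
        seen[i] = 1; out.push_back(i);
      }
    }
  }
}

// [[Rcpp::export]]
List align_reads_cpp(CharacterVector reads, CharacterVector refs,
                     int max_mm, int k) {
  const int nref = refs.size();
  std::vector<std::string> R(nref);
  for (int i = 0; i < nref; ++i) R[i] = as<std::string>(refs[i]);

  KmerIndex idx;
  build_index(R, k, idx);

  std::vector<int> out_read, out_allele;
  LogicalVector skipped(reads.size());
  std::vector<char> seen(nref, 0);

  for (int r = 0; r < reads.size(); ++r) {
    const std::string rd = as<std::string>(reads[r]);
    bool bad = rd.empty();
    for (size_t t = 0; t < rd.size() && !bad; ++t)
      if (!valid_read_char(rd[t])) bad = true;
    if (bad) { skipped[r] = true; continue; }

    std::fill(seen.begin(), seen.end(), 0);
    std::vector<int> hits;
    search_oriented(rd, R, idx, max_mm, seen, hits);
    const std::string rc = revcomp(rd);
    search_oriented(rc, R, idx, max_mm, seen, hits);
    std::sort(hits.begin(), hits.end());
    for (size_t h = 0; h < hits.size(); ++h) {
      out_read.push_back(r + 1);
      out_allele.push_back(hits[h] + 1);
    }
  }
  return List::create(_["read"] = wrap(out_read),
                      _["allele"] = wrap(out_allele),
                      _["skipped"] = skipped);
}

// Apply point substitutions to reads (1-based read index and position).
// RNG-free: positions and replacement bases are drawn in R so that the
// simulation is reproducible from the R seed alone.
// [[Rcpp::export]]
CharacterVector substitute_bases_cpp(CharacterVector reads,
                                     IntegerVector read_idx,
                                     IntegerVector pos,
                                     CharacterVector newbase) {
  CharacterVector out = clone(reads);
  std::unordered_map<int, std::string> touched;
  for (int i = 0; i < read_idx.size(); ++i) {
    const int r = read_idx[i] - 1;
    if (r < 0 || r >= out.size()) stop("read index out of range");
    std::unordered_map<int, std::string>::iterator it = touched.find(r);
    if (it == touched.end())
      it = touched.insert(std::make_pair(r, as<std::string>(out[r]))).first;
    const int p = pos[i] - 1;
    if (p < 0 || p >= (int)it->second.size()) stop("position out of range");
    it->second[p] = CHAR(STRING_ELT(newbase, i))[0];
  }
  for (std::unordered_map<int, std::string>::iterator it = touched.begin();
       it != touched.end(); ++it)
    out[it->first] = it->second;
  return out;
}
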
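#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit packed canonical k-mer machinery, k <= 32.
// A=0, C=1, G=2, T=3; big-endian packing so integer order == lexicographic order.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static std::string decode_kmer(uint64_t code, int k) {
  static const char bases[] = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = bases[code & 3ULL];
    code >>= 2;
  }
  return s;
}

// Rolling scan over one sequence; calls f(canonical_code) per N-free window.
template <typename F>
static void scan_canonical(const char* s, size_t n, int k, F f) {
  if ((int)n < k) return;
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t fwd = 0, rc = 0;
  int shift_rc = 2 * (k - 1);
  int valid = 0; // number of consecutive valid bases ending at i
  for (size_t i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    if (b < 0) { valid = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << shift_rc);
    if (++valid >= k) f(fwd < rc ? fwd : rc);
  }
}

// [[Rcpp::export]]
CharacterVector cpp_canonical_kmers(std::string seq, int k) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  std::vector<std::string> out;
  scan_canonical(seq.c_str(), seq.size(), k, [&](uint64_t code) {
    out.push_back(decode_kmer(code, k));
  });
  return wrap(out);
}

static void tally_seqs(const CharacterVector& seqs, int k,
                       std::unordered_map<uint64_t, int>& counts) {
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    scan_canonical(s, strlen(s), k, [&](uint64_t code) { counts[code]++; });
  }
}

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector seqs, int k) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  std::unordered_map<uint64_t, int> counts;
  tally_seqs(seqs, k, counts);
  std::vector<std::pair<uint64_t, int>> items(counts.begin(), counts.end());
  std::sort(items.begin(), items.end());
  R_xlen_t m = items.size();
  CharacterVector kmers(m);
  IntegerVector cnt(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    kmers[i] = decode_kmer(items[i].first, k);
    cnt[i] = items[i].second;
  }
  return List::create(_["kmer"] = kmers, _["count"] = cnt);
}

// Per-window counts for each query read, looked up in a table built from ref_seqs.
// Windows containing non-ACGT are skipped; absent k-mers count 0.
// [[Rcpp::export]]
List cpp_window_counts(CharacterVector query_seqs, CharacterVector ref_seqs, int k) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  std::unordered_map<uint64_t, int> counts;
  tally_seqs(ref_seqs, k, counts);
  R_xlen_t nq = query_seqs.size();
  List out(nq);
  for (R_xlen_t i = 0; i < nq; ++i) {
    const char* s = CHAR(STRING_ELT(query_seqs, i));
    std::vector<int> w;
    scan_canonical(s, strlen(s), k, [&](uint64_t code) {
      auto it = counts.find(code);
      w.push_back(it == counts.end() ? 0 : it->second);
    });
    out[i] = wrap(w);
  }
  return out;
}
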
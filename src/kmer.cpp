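#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Canonical k-mer counting with 2-bit packing (k <= 32). K-mers containing
// any non-ACGT character are skipped; counting restarts after them.

// [[Rcpp::export(name = ".kmer_hist_cpp")]]
DataFrame kmer_hist_cpp(CharacterVector seqs, int k) {
  if (k < 1 || k > 32) stop("k must be in 1..32");
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift = 2 * (k - 1);
  std::unordered_map<uint64_t, uint32_t> counts;
  counts.reserve(1 << 20);

  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *p = CHAR(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (; *p; ++p) {
      int code;
      switch (*p) {
        case 'A': case 'a': code = 0; break;
        case 'C': case 'c': code = 1; break;
        case 'G': case 'g': code = 2; break;
        case 'T': case 't': code = 3; break;
        default: code = -1;
      }
      if (code < 0) { run = 0; fwd = rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)code) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - code) << shift);
      if (++run >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        ++counts[canon];
      }
    }
  }

  std::unordered_map<uint32_t, double> hist;
  for (const auto &kv : counts) ++hist[kv.second];
  std::vector<uint32_t> depths;
  depths.reserve(hist.size());
  for (const auto &kv : hist) depths.push_back(kv.first);
  std::sort(depths.begin(), depths.end());
  IntegerVector depth(depths.size());
  NumericVector count(depths.size());
  for (size_t i = 0; i < depths.size(); ++i) {
    depth[i] = (int)depths[i];
    count[i] = hist[depths[i]];
  }
  return DataFrame::create(_["depth"] = depth, _["count"] = count);
}
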
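#include <Rcpp.h>
#include <set>
#include <cstdint>

using namespace Rcpp;

// FNV-1a over the canonical k-mer bytes, then a splitmix64 finalizer.
// The result is truncated to 53 bits so every hash is exactly representable
// as an R double.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// [[Rcpp::export(name = ".minhash_sketch_cpp")]]
NumericVector minhash_sketch_cpp(CharacterVector seqs, int k, int sketch_size,
                                 double seed) {
  if (k < 1) stop("kmer_size must be >= 1");
  if (sketch_size < 1) stop("sketch_size must be >= 1");
  const uint64_t seed64 = (uint64_t)seed;
  std::set<uint64_t> bottom;  // sorted ascending; bottom-s sketch

  std::vector<int8_t> code(256, -1);
  code['A'] = 0; code['C'] = 1; code['G'] = 2; code['T'] = 3;
  code['a'] = 0; code['c'] = 1; code['g'] = 2; code['t'] = 3;

  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *str = CHAR(STRING_ELT(seqs, s));
    const int n = LENGTH(STRING_ELT(seqs, s));
    if (n < k) continue;
    std::vector<int8_t> c(n);
    for (int i = 0; i < n; ++i) c[i] = code[(unsigned char)str[i]];

    for (int i = 0; i + k <= n; ++i) {
      bool valid = true;
      for (int j = 0; j < k; ++j) {
        if (c[i + j] < 0) { valid = false; break; }
      }
      if (!valid) continue;
      // canonical orientation: lexicographic min of k-mer and its
      // reverse complement (complement of base b is 3 - b in 2-bit code)
      bool use_rc = false;
      for (int j = 0; j < k; ++j) {
        int8_t f = c[i + j];
        int8_t r = (int8_t)(3 - c[i + k - 1 - j]);
        if (f != r) { use_rc = r < f; break; }
      }
      uint64_t h = 1469598103934665603ULL ^ seed64;
      for (int j = 0; j < k; ++j) {
        uint64_t b = use_rc ? (uint64_t)(3 - c[i + k - 1 - j])
                            : (uint64_t)c[i + j];
        h = (h ^ (b + 1)) * 1099511628211ULL;
      }
      h = splitmix64(h) >> 11;  // 53-bit value

      if ((int)bottom.size() < sketch_size) {
        bottom.insert(h);
      } else if (h < *bottom.rbegin()) {
        if (bottom.insert(h).second) {
          bottom.erase(std::prev(bottom.end()));
        }
      }
    }
  }

  NumericVector out(bottom.size());
  R_xlen_t i = 0;
  for (uint64_t v : bottom) out[i++] = (double)v;
  return out;
}
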
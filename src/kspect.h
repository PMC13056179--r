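#ifndef KSPECT_H
#define KSPECT_H

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <algorithm>

static inline uint64_t rotl64(uint64_t x, int r) {
  r &= 63;
  return r ? (x << r) | (x >> (64 - r)) : x;
}

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// base codes: A=0, C=1, G=2, T=3 (case-insensitive), 0xFF otherwise
extern const uint8_t BASE_CODE[256];
// per-base 64-bit constants for the rolling polynomial
extern const uint64_t BASE_HASH[4];

static inline int base_code(char ch) { return BASE_CODE[(uint8_t)ch]; }
static inline char code_base(int c) { return "ACGT"[c & 3]; }
static inline int comp_code(int c) { return 3 - c; }

// --- spaced-seed mask -------------------------------------------------------
struct SeedMask {
  int k;
  int weight;
  bool plain;                 // all-ones mask
  std::vector<int> care;      // 0-based care positions
  std::string mask;
  SeedMask() : k(0), weight(0), plain(true) {}
  explicit SeedMask(const std::string &m) : mask(m) {
    k = (int)m.size();
    weight = 0;
    for (int i = 0; i < k; ++i) {
      if (m[i] == '1') { care.push_back(i); ++weight; }
      else if (m[i] != '0') Rcpp::stop("mask must be a string over {0,1}");
    }
    if (k < 1) Rcpp::stop("mask length must be >= 1");
    if (weight == 0) Rcpp::stop("mask must have at least one care (1) position");
    plain = (weight == k);
  }
};

// --- hashing ----------------------------------------------------------------
// Plain k-mer: ntHash-style rolling polynomial over forward and reverse
// complement strands; canonical base value = min(fwd, rev), then mixed.
// Spaced seed: canonical care-string (lexicographic min of masked forward vs
// its reverse complement) hashed by the same polynomial from scratch.

struct RollState {
  uint64_t f, r;
  int k;
};

static inline void roll_init(RollState &st, const int *codes, int k) {
  st.k = k;
  st.f = 0;
  st.r = 0;
  for (int i = 0; i < k; ++i) {
    st.f = rotl64(st.f, 1) ^ BASE_HASH[codes[i]];
    st.r ^= rotl64(BASE_HASH[comp_code(codes[i])], i);
  }
}

static inline void roll_step(RollState &st, int out_code, int in_code) {
  st.f = rotl64(st.f, 1) ^ rotl64(BASE_HASH[out_code], st.k) ^ BASE_HASH[in_code];
  st.r = (st.r ^ BASE_HASH[comp_code(out_code)]) >> 1
       | (st.r ^ BASE_HASH[comp_code(out_code)]) << 63;
  st.r ^= rotl64(BASE_HASH[comp_code(in_code)], st.k - 1);
}

static inline uint64_t roll_canonical(const RollState &st) {
  uint64_t u = st.f < st.r ? st.f : st.r;
  return splitmix64(u ^ (0xA24BAED4963EE407ULL + (uint64_t)st.k));
}

// polynomial hash of an explicit code string (used for spaced seeds)
static inline uint64_t string_hash(const int *codes, int n) {
  uint64_t u = 0;
  for (int i = 0; i < n; ++i) u = rotl64(u, 1) ^ BASE_HASH[codes[i]];
  return splitmix64(u ^ (0x9FB21C651E98DF25ULL + (uint64_t)n));
}

// canonical base hash of one window (codes, length k) under a mask
static inline uint64_t window_canonical_hash(const int *codes, const SeedMask &sm) {
  if (sm.plain) {
    RollState st;
    roll_init(st, codes, sm.k);
    return roll_canonical(st);
  }
  const int w = sm.weight;
  std::vector<int> fwd(w), rev(w);
  for (int i = 0; i < w; ++i) fwd[i] = codes[sm.care[i]];
  for (int i = 0; i < w; ++i) rev[i] = comp_code(fwd[w - 1 - i]);
  // lexicographically smaller of care string and its reverse complement
  const int *canon = fwd.data();
  for (int i = 0; i < w; ++i) {
    if (rev[i] < fwd[i]) { canon = rev.data(); break; }
    if (rev[i] > fwd[i]) break;
  }
  return string_hash(canon, w);
}

// derive h hash values from one base value (double hashing)
static inline void derive_hashes(uint64_t base, int h, uint64_t *out) {
  uint64_t step = splitmix64(base ^ 0xD6E8FEB86659FD93ULL) | 1ULL;
  uint64_t v = base;
  for (int i = 0; i < h; ++i) {
    out[i] = v;
    v += step;
  }
}

// iterate valid windows of a sequence, calling fn(pos, base_hash)
template <typename F>
static inline void for_each_window(const char *s, int n, const SeedMask &sm, F fn) {
  const int k = sm.k;
  if (n < k) return;
  std::vector<int> codes(n);
  int last_bad = -1;
  for (int i = 0; i < n; ++i) {
    codes[i] = base_code(s[i]);
    if (codes[i] == 0xFF) last_bad = i;
  }
  if (sm.plain) {
    RollState st;
    bool live = false;
    for (int i = 0; i + k <= n; ++i) {
      // window [i, i+k) valid iff last bad base < i
      bool valid = true;
      if (last_bad >= i) {
        // recheck within window
        for (int j = i; j < i + k; ++j)
          if (codes[j] == 0xFF) { valid = false; break; }
      }
      if (!valid) { live = false; continue; }
      if (!live) {
        roll_init(st, codes.data() + i, k);
        live = true;
      } else {
        roll_step(st, codes[i - 1], codes[i + k - 1]);
      }
      fn(i, roll_canonical(st));
    }
  } else {
    for (int i = 0; i + k <= n; ++i) {
      bool valid = true;
      for (int j = i; j < i + k; ++j)
        if (codes[j] == 0xFF) { valid = false; break; }
      if (!valid) continue;
      fn(i, window_canonical_hash(codes.data() + i, sm));
    }
  }
}

// --- 2-bit canonical codes (plain k-mers, k <= 32) --------------------------
static inline bool kmer_codes_supported(int k) { return k >= 1 && k <= 32; }

// canonical 2-bit code of window; returns false if any non-ACGT base
static inline bool window_code(const char *s, int k, uint64_t &out) {
  uint64_t f = 0, r = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c == 0xFF) return false;
    f = (f << 2) | (uint64_t)c;
    r |= ((uint64_t)(3 - c)) << (2 * i);
  }
  out = f < r ? f : r;
  return true;
}

static inline std::string code_to_string(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = code_base((int)(code & 3ULL));
    code >>= 2;
  }
  return s;
}

// collect canonical codes of all valid windows of a set of sequences
void collect_codes(const Rcpp::CharacterVector &seqs, int k,
                   std::vector<uint64_t> &out);

// --- Bloom structures -------------------------------------------------------
struct BloomF {
  uint64_t m;                  // number of bit positions (multiple of 64)
  int h;
  uint64_t n_inserted;
  std::vector<uint64_t> bits;
  BloomF(uint64_t m_, int h_) : h(h_), n_inserted(0) {
    m = ((m_ + 63) / 64) * 64;
    if (m == 0) Rcpp::stop("Bloom filter size must be positive");
    bits.assign(m / 64, 0ULL);
  }
  inline bool getbit(uint64_t i) const {
    return (bits[i >> 6] >> (i & 63)) & 1ULL;
  }
  inline void setbit(uint64_t i) { bits[i >> 6] |= 1ULL << (i & 63); }
  inline bool contains(const uint64_t *hv) const {
    for (int i = 0; i < h; ++i)
      if (!getbit(hv[i] % m)) return false;
    return true;
  }
  inline void insert(const uint64_t *hv) {
    for (int i = 0; i < h; ++i) setbit(hv[i] % m);
    ++n_inserted;
  }
  // insert, returning whether the element was (apparently) present before
  inline bool contains_insert(const uint64_t *hv) {
    bool all = true;
    for (int i = 0; i < h; ++i) {
      uint64_t idx = hv[i] % m;
      if (!getbit(idx)) { all = false; setbit(idx); }
    }
    ++n_inserted;
    return all;
  }
  void clear() { std::fill(bits.begin(), bits.end(), 0ULL); n_inserted = 0; }
};

struct CountingBF {
  uint64_t m;
  int h;
  int width;                   // counter width in bits (<= 32)
  uint64_t cap;                // 2^width - 1
  uint64_t n_inserted;
  std::vector<uint8_t> c8;     // used when width <= 8
  std::vector<uint32_t> c32;   // used when width > 8
  bool narrow;
  CountingBF(uint64_t m_, int h_, int width_)
      : h(h_), width(width_), n_inserted(0) {
    m = ((m_ + 63) / 64) * 64;
    if (m == 0) Rcpp::stop("counting Bloom filter size must be positive");
    if (width < 1 || width > 32) Rcpp::stop("counter width must be in [1, 32]");
    cap = (width == 64) ? ~0ULL : ((1ULL << width) - 1);
    narrow = width <= 8;
    if (narrow) c8.assign(m, 0); else c32.assign(m, 0);
  }
  inline uint64_t get(uint64_t i) const { return narrow ? c8[i] : c32[i]; }
  inline void set(uint64_t i, uint64_t v) {
    if (narrow) c8[i] = (uint8_t)v; else c32[i] = (uint32_t)v;
  }
  inline uint64_t count(const uint64_t *hv) const {
    uint64_t mn = ~0ULL;
    for (int i = 0; i < h; ++i) {
      uint64_t v = get(hv[i] % m);
      if (v < mn) mn = v;
    }
    return mn;
  }
  // minimal-increase rule: bump only the counters currently at the minimum
  inline void increment(const uint64_t *hv) {
    uint64_t mn = count(hv);
    ++n_inserted;
    if (mn >= cap) return;
    for (int i = 0; i < h; ++i) {
      uint64_t idx = hv[i] % m;
      if (get(idx) == mn) set(idx, mn + 1);
    }
  }
  inline void decrement(const uint64_t *hv, uint64_t amount) {
    for (int i = 0; i < h; ++i) {
      uint64_t idx = hv[i] % m;
      uint64_t v = get(idx);
      set(idx, v > amount ? v - amount : 0);
    }
  }
};

// smallest m with (1 - exp(-h n / m))^h <= fpr
static inline double bf_size_bits(double n, double fpr, int h) {
  double p1 = std::pow(fpr, 1.0 / h);
  return std::ceil(-(double)h * n / std::log1p(-p1));
}

#endif
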
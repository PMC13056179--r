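#include "kspect.h"
using namespace Rcpp;

#define B 0xFF
const uint8_t BASE_CODE[256] = {
  B,B,B,B,B,B,B,B,B,B,B,B,B,B,B,B, B,B,B,B,B,B,B,B,B,B,B,B,B,B,B,B,
  B,B,B,B,B,B,B,B,B,B,B,B,B,B,B,B, B,B,B,B,B,B,B,B,B,B,B,B,B,B,B,B,
  /* @ A B C D E F G */ B,0,B,1,B,B,B,2, B,B,B,B,B,B,B,B,
  /* P..T */            B,B,B,B,3,B,B,B, B,B,B,B,B,B,B,B,
  /* ` a b c d e f g */ B,0,B,1,B,B,B,2, B,B,B,B,B,B,B,B,
  /* p..t */            B,B,B,B,3,B,B,B, B,B,B,B,B,B,B,B,
  B,B,B,B,B,B,B,B,B,B,B,B,B,B,B,B, B,B,B,B,B,B,B,B,B,B,B,B,B,B,B,B,
  B,B,B,B,B,B,B,B,B,B,B,B,B,B,B,B, B,B,B,B,B,B,B,B,B,B,B,B,B,B,B,B,
  B,B,B,B,B,B,B,B,B,B,B,B,B,B,B,B, B,B,B,B,B,B,B,B,B,B,B,B,B,B,B,B
};
#undef B

// arbitrary well-mixed constants; not the ntHash2 seed set
const uint64_t BASE_HASH[4] = {
  0x8F3F73B5CF1C9ADEULL,  // A
  0x3193C18562A02B4CULL,  // C
  0x20323ED082572324ULL,  // G
  0x295549F54BE24456ULL   // T
};

static std::string hash_hex(uint64_t v) {
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)v);
  return std::string(buf);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t j = 0; j < x.size(); ++j) {
    std::string s = as<std::string>(x[j]);
    std::string r(s.rbegin(), s.rend());
    for (char &ch : r) {
      int c = base_code(ch);
      r[&ch - &r[0]] = (c == 0xFF) ? 'N' : code_base(comp_code(c));
    }
    out[j] = r;
  }
  return out;
}

// canonical form: lexicographically smaller of the masked care string and its
// reverse complement
// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector x, std::string mask) {
  SeedMask sm(mask);
  CharacterVector out(x.size());
  for (R_xlen_t j = 0; j < x.size(); ++j) {
    std::string s = as<std::string>(x[j]);
    if ((int)s.size() != sm.k)
      stop("k-mer length (%d) does not match mask length (%d)",
           (int)s.size(), sm.k);
    std::string fwd(sm.weight, 'N'), rev(sm.weight, 'N');
    bool ok = true;
    for (int i = 0; i < sm.weight; ++i) {
      int c = base_code(s[sm.care[i]]);
      if (c == 0xFF) { ok = false; break; }
      fwd[i] = code_base(c);
      rev[sm.weight - 1 - i] = code_base(comp_code(c));
    }
    if (!ok) { out[j] = NA_STRING; continue; }
    out[j] = rev < fwd ? rev : fwd;
  }
  return out;
}

// hash one window from scratch (no rolling): h hex-encoded 64-bit values
// [[Rcpp::export]]
CharacterVector cpp_hash_kmer(std::string window, std::string mask, int h) {
  SeedMask sm(mask);
  if ((int)window.size() != sm.k)
    stop("window length (%d) does not match mask length (%d)",
         (int)window.size(), sm.k);
  std::vector<int> codes(sm.k);
  for (int i = 0; i < sm.k; ++i) {
    codes[i] = base_code(window[i]);
    if (codes[i] == 0xFF) stop("window contains a non-ACGT base");
  }
  uint64_t base = window_canonical_hash(codes.data(), sm);
  std::vector<uint64_t> hv(h);
  derive_hashes(base, h, hv.data());
  CharacterVector out(h);
  for (int i = 0; i < h; ++i) out[i] = hash_hex(hv[i]);
  return out;
}

// hash all valid windows of a sequence via the rolling engine;
// returns 0-based window starts and an (n_windows x h) matrix of hex values
// [[Rcpp::export]]
List cpp_hash_windows(std::string seq, std::string mask, int h) {
  SeedMask sm(mask);
  std::vector<int> pos;
  std::vector<uint64_t> bases;
  for_each_window(seq.c_str(), (int)seq.size(), sm,
                  [&](int i, uint64_t u) { pos.push_back(i); bases.push_back(u); });
  int n = (int)pos.size();
  CharacterMatrix hx(n, h);
  std::vector<uint64_t> hv(h);
  for (int j = 0; j < n; ++j) {
    derive_hashes(bases[j], h, hv.data());
    for (int i = 0; i < h; ++i) hx(j, i) = hash_hex(hv[i]);
  }
  return List::create(_["pos"] = wrap(pos), _["hashes"] = hx);
}

// 64-bit base hashes (hex) of all valid windows; used for collision checks
// [[Rcpp::export]]
CharacterVector cpp_base_hashes(CharacterVector kmers, std::string mask) {
  SeedMask sm(mask);
  CharacterVector out(kmers.size());
  for (R_xlen_t j = 0; j < kmers.size(); ++j) {
    std::string s = as<std::string>(kmers[j]);
    if ((int)s.size() != sm.k) stop("k-mer/mask length mismatch");
    std::vector<int> codes(sm.k);
    bool ok = true;
    for (int i = 0; i < sm.k; ++i) {
      codes[i] = base_code(s[i]);
      if (codes[i] == 0xFF) { ok = false; break; }
    }
    if (!ok) { out[j] = NA_STRING; continue; }
    out[j] = hash_hex(window_canonical_hash(codes.data(), sm));
  }
  return out;
}

void collect_codes(const CharacterVector &seqs, int k,
                   std::vector<uint64_t> &out) {
  for (R_xlen_t j = 0; j < seqs.size(); ++j) {
    const char *s = CHAR(STRING_ELT(seqs, j));
    int n = (int)std::strlen(s);
    if (n < k) continue;
    // rolling 2-bit encoding with validity tracking
    uint64_t f = 0, r = 0;
    uint64_t maskbits = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    int valid = 0;
    for (int i = 0; i < n; ++i) {
      int c = base_code(s[i]);
      if (c == 0xFF) { valid = 0; f = 0; r = 0; continue; }
      f = ((f << 2) | (uint64_t)c) & maskbits;
      r = (r >> 2) | (((uint64_t)(3 - c)) << (2 * (k - 1)));
      if (++valid >= k) out.push_back(f < r ? f : r);
    }
  }
}
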
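#include "kspect.h"
#include <unordered_map>
#include <unordered_set>
using namespace Rcpp;

// Layered counting pipeline: global BF (distinct k-mers) -> intermediate CBF
// (occurrences 2..c_min-1) -> output CBF/BF holding occurrences from the
// c_min-th onward (reported count = stored + c_min - 1), with k-mers crossing
// c_max removed by decrement and optionally recorded in a secondary BF.
// A per-read scratch BF deduplicates k-mers so the depth CBF counts reads.
struct Cascade {
  SeedMask sm;
  int h;
  uint64_t cmin, cmax, cap;
  bool counts_out, depth_on, secondary_on;
  BloomF *global = nullptr, *outbf = nullptr, *secondary = nullptr;
  CountingBF *inter = nullptr, *outcbf = nullptr, *depth = nullptr;
  double read_fpr = 1e-6;
  // tallies
  double reads_total = 0, reads_short = 0, windows_total = 0,
         windows_skipped = 0, removed_over_cmax = 0;
  ~Cascade() {
    delete global; delete outbf; delete secondary;
    delete inter; delete outcbf; delete depth;
  }

  inline uint64_t stored_count(const uint64_t *hv) const {
    if (counts_out) return outcbf->count(hv);
    return outbf->contains(hv) ? 1 : 0;
  }

  inline uint64_t reported(const uint64_t *hv) const {
    if (secondary_on && secondary->contains(hv)) return 0;
    uint64_t s = stored_count(hv);
    return s == 0 ? 0 : s + cmin - 1;
  }

  inline void output_insert(const uint64_t *hv) {
    if (secondary_on && secondary->contains(hv)) return;
    if (counts_out) {
      outcbf->increment(hv);
      uint64_t rep = outcbf->count(hv) + cmin - 1;
      if (rep > cmax) {
        if (secondary_on) secondary->insert(hv);
        outcbf->decrement(hv, rep);
        removed_over_cmax += 1;
      }
    } else {
      outbf->insert(hv);
    }
  }

  inline void occurrence(const uint64_t *hv) {
    if (cmin == 1) { output_insert(hv); return; }
    if (!global->contains_insert(hv)) return;   // first occurrence
    if (cmin == 2) { output_insert(hv); return; }
    uint64_t t = inter->count(hv);
    if (t < cmin - 2) inter->increment(hv);
    else output_insert(hv);
  }

  void process_read(const char *s, int n) {
    reads_total += 1;
    if (n < sm.k) { reads_short += 1; return; }
    int expect = n - sm.k + 1;
    int seen = 0;
    BloomF *readbf = nullptr;
    if (depth_on)
      readbf = new BloomF((uint64_t)bf_size_bits(expect, read_fpr, h), h);
    std::vector<uint64_t> hv(h);
    for_each_window(s, n, sm, [&](int, uint64_t u) {
      derive_hashes(u, h, hv.data());
      occurrence(hv.data());
      if (depth_on && !readbf->contains_insert(hv.data()))
        depth->increment(hv.data());
      ++seen;
    });
    delete readbf;
    windows_total += seen;
    windows_skipped += expect - seen;
  }
};

// [[Rcpp::export]]
SEXP cpp_cascade_new(std::string mask, int h, double cmin, double cmax,
                     int width, bool counts_out, bool depth_on,
                     bool secondary_on, List sizes, double read_fpr) {
  Cascade *cs = new Cascade();
  cs->read_fpr = read_fpr;
  cs->sm = SeedMask(mask);
  cs->h = h;
  cs->cmin = (uint64_t)cmin;
  cs->cmax = (uint64_t)cmax;
  cs->cap = (width >= 64) ? ~0ULL : ((1ULL << width) - 1);
  cs->counts_out = counts_out;
  cs->depth_on = depth_on;
  cs->secondary_on = secondary_on;
  if (cs->cmin >= 2)
    cs->global = new BloomF((uint64_t)as<double>(sizes["global"]), h);
  if (cs->cmin >= 3)
    cs->inter = new CountingBF((uint64_t)as<double>(sizes["intermediate"]), h, width);
  if (counts_out)
    cs->outcbf = new CountingBF((uint64_t)as<double>(sizes["output"]), h, width);
  else
    cs->outbf = new BloomF((uint64_t)as<double>(sizes["output"]), h);
  if (secondary_on)
    cs->secondary = new BloomF((uint64_t)as<double>(sizes["secondary"]), h);
  if (depth_on)
    cs->depth = new CountingBF((uint64_t)as<double>(sizes["depth"]), h, width);
  return XPtr<Cascade>(cs, true);
}

// [[Rcpp::export]]
void cpp_cascade_process(SEXP ptr, CharacterVector reads) {
  XPtr<Cascade> cs(ptr);
  for (R_xlen_t j = 0; j < reads.size(); ++j) {
    const char *s = CHAR(STRING_ELT(reads, j));
    cs->process_read(s, (int)std::strlen(s));
  }
}

template <typename F>
static void cascade_tuples(Cascade *cs, const CharacterVector &kmers, F fn) {
  std::vector<uint64_t> hv(cs->h);
  std::vector<int> codes(cs->sm.k);
  for (R_xlen_t j = 0; j < kmers.size(); ++j) {
    const char *s = CHAR(STRING_ELT(kmers, j));
    if ((int)std::strlen(s) != cs->sm.k)
      stop("element %d: k-mer length does not match k", (int)j + 1);
    bool ok = true;
    for (int i = 0; i < cs->sm.k; ++i) {
      codes[i] = base_code(s[i]);
      if (codes[i] == 0xFF) { ok = false; break; }
    }
    if (!ok) { fn(j, nullptr); continue; }
    derive_hashes(window_canonical_hash(codes.data(), cs->sm), cs->h, hv.data());
    fn(j, hv.data());
  }
}

// [[Rcpp::export]]
NumericVector cpp_cascade_count(SEXP ptr, CharacterVector kmers) {
  XPtr<Cascade> cs(ptr);
  NumericVector out(kmers.size());
  cascade_tuples(cs, kmers, [&](R_xlen_t j, const uint64_t *hv) {
    out[j] = hv ? (double)cs->reported(hv) : NA_REAL;
  });
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_cascade_depth(SEXP ptr, CharacterVector kmers) {
  XPtr<Cascade> cs(ptr);
  if (!cs->depth_on) stop("depth extraction was not enabled for this store");
  NumericVector out(kmers.size());
  cascade_tuples(cs, kmers, [&](R_xlen_t j, const uint64_t *hv) {
    out[j] = hv ? (double)cs->depth->count(hv) : NA_REAL;
  });
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_cascade_secondary(SEXP ptr, CharacterVector kmers) {
  XPtr<Cascade> cs(ptr);
  if (!cs->secondary_on) stop("no secondary filter in this store");
  LogicalVector out(kmers.size());
  cascade_tuples(cs, kmers, [&](R_xlen_t j, const uint64_t *hv) {
    out[j] = hv ? cs->secondary->contains(hv) : NA_LOGICAL;
  });
  return out;
}

// [[Rcpp::export]]
List cpp_cascade_log(SEXP ptr) {
  XPtr<Cascade> cs(ptr);
  auto bfm = [](BloomF *f) { return f ? (double)f->m : NA_REAL; };
  auto cbfm = [](CountingBF *f) { return f ? (double)f->m : NA_REAL; };
  return List::create(
      _["reads_total"] = cs->reads_total, _["reads_short"] = cs->reads_short,
      _["windows_total"] = cs->windows_total,
      _["windows_skipped"] = cs->windows_skipped,
      _["removed_over_cmax"] = cs->removed_over_cmax,
      _["m_global"] = bfm(cs->global), _["m_intermediate"] = cbfm(cs->inter),
      _["m_output"] = cs->counts_out ? cbfm(cs->outcbf) : bfm(cs->outbf),
      _["m_secondary"] = bfm(cs->secondary), _["m_depth"] = cbfm(cs->depth));
}

// Compare cascade counts against an exact counter over every distinct
// canonical k-mer of `reads`. Plain masks with k <= 32 use 2-bit codes.
// [[Rcpp::export]]
List cpp_cascade_compare(SEXP ptr, CharacterVector reads) {
  XPtr<Cascade> cs(ptr);
  if (!(cs->sm.plain && kmer_codes_supported(cs->sm.k)))
    stop("exact comparison requires a plain mask with k <= 32");
  int k = cs->sm.k;
  std::vector<uint64_t> codes;
  collect_codes(reads, k, codes);
  std::sort(codes.begin(), codes.end());
  // run-length over sorted codes = exact counts
  size_t n = codes.size(), i = 0, nd = 0;
  while (i < n) {
    size_t j = i + 1;
    while (j < n && codes[j] == codes[i]) ++j;
    ++nd;
    i = j;
  }
  NumericVector true_count(nd), rep_count(nd);
  std::vector<uint64_t> hv(cs->h);
  std::vector<int> wc(k);
  i = 0; size_t d = 0;
  while (i < n) {
    size_t j = i + 1;
    while (j < n && codes[j] == codes[i]) ++j;
    std::string s = code_to_string(codes[i], k);
    for (int t = 0; t < k; ++t) wc[t] = base_code(s[t]);
    derive_hashes(window_canonical_hash(wc.data(), cs->sm), cs->h, hv.data());
    true_count[d] = (double)(j - i);
    rep_count[d] = (double)cs->reported(hv.data());
    ++d;
    i = j;
  }
  return List::create(_["true_count"] = true_count,
                      _["reported_count"] = rep_count);
}

// enumerate distinct canonical k-mers of `reads` (string form) with reported
// counts (> 0) and depths; intended for modest inputs
// [[Rcpp::export]]
List cpp_cascade_export(SEXP ptr, CharacterVector reads) {
  XPtr<Cascade> cs(ptr);
  std::unordered_set<std::string> seen;
  std::vector<std::string> kms;
  std::vector<double> cnts, dpts;
  std::vector<uint64_t> hv(cs->h);
  for (R_xlen_t j = 0; j < reads.size(); ++j) {
    std::string rd = as<std::string>(reads[j]);
    int n = (int)rd.size();
    const int k = cs->sm.k;
    if (n < k) continue;
    for (int i = 0; i + k <= n; ++i) {
      std::string canon;
      if (cs->sm.plain && kmer_codes_supported(k)) {
        uint64_t code;
        if (!window_code(rd.c_str() + i, k, code)) continue;
        canon = code_to_string(code, k);
      } else {
        // canonical care string
        std::string fwd(cs->sm.weight, 'N'), rev(cs->sm.weight, 'N');
        bool ok = true;
        for (int t = 0; t < cs->sm.weight; ++t) {
          int c = base_code(rd[i + cs->sm.care[t]]);
          if (c == 0xFF) { ok = false; break; }
          fwd[t] = code_base(c);
          rev[cs->sm.weight - 1 - t] = code_base(comp_code(c));
        }
        if (!ok) continue;
        canon = rev < fwd ? rev : fwd;
      }
      if (!seen.insert(canon).second) continue;
      std::vector<int> wc(cs->sm.weight);
      for (int t = 0; t < cs->sm.weight; ++t) wc[t] = base_code(canon[t]);
      // canonical care string hashed as a plain (all-ones) weight-length word
      // equals the cascade's hash only for plain masks; for gapped masks hash
      // via string_hash to match window_canonical_hash
      uint64_t base;
      if (cs->sm.plain) {
        base = window_canonical_hash(wc.data(), cs->sm);
      } else {
        base = string_hash(wc.data(), cs->sm.weight);
      }
      derive_hashes(base, cs->h, hv.data());
      uint64_t rep = cs->reported(hv.data());
      if (rep == 0) continue;
      kms.push_back(canon);
      cnts.push_back((double)rep);
      dpts.push_back(cs->depth_on ? (double)cs->depth->count(hv.data()) : NA_REAL);
    }
  }
  return List::create(_["kmer"] = wrap(kms), _["count"] = wrap(cnts),
                      _["depth"] = wrap(dpts));
}
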
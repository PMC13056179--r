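#include "kspect.h"
#include <unordered_map>
#include <unordered_set>
using namespace Rcpp;

// exact counts-of-counts histogram via sorted 2-bit canonical codes
// [[Rcpp::export]]
List cpp_exact_histogram(CharacterVector reads, int k) {
  if (!kmer_codes_supported(k)) stop("exact histogram requires k <= 32");
  std::vector<uint64_t> codes;
  collect_codes(reads, k, codes);
  if (codes.empty()) stop("no valid k-mers in input");
  std::sort(codes.begin(), codes.end());
  std::vector<double> h;
  size_t n = codes.size(), i = 0;
  double nd = 0;
  while (i < n) {
    size_t j = i + 1;
    while (j < n && codes[j] == codes[i]) ++j;
    size_t c = j - i;
    if (h.size() < c) h.resize(c, 0.0);
    h[c - 1] += 1;
    nd += 1;
    i = j;
  }
  return List::create(_["h"] = wrap(h), _["total_distinct"] = nd,
                      _["total_occurrences"] = (double)n);
}

static void hap_codeset(const CharacterVector &seqs, int k,
                        std::vector<uint64_t> &out) {
  collect_codes(seqs, k, out);
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
}

static inline bool in_set(const std::vector<uint64_t> &v, uint64_t x) {
  return std::binary_search(v.begin(), v.end(), x);
}

// label every distinct read k-mer by haplotype membership and aggregate
// [[Rcpp::export]]
List cpp_label_kmers(CharacterVector reads, CharacterVector hapA,
                     CharacterVector hapB, int k, int keep_max) {
  if (!kmer_codes_supported(k)) stop("k-mer labelling requires k <= 32");
  std::vector<uint64_t> setA, setB;
  hap_codeset(hapA, k, setA);
  hap_codeset(hapB, k, setB);
  std::vector<uint64_t> codes;
  collect_codes(reads, k, codes);
  std::sort(codes.begin(), codes.end());
  double d_rob = 0, d_het = 0, d_err = 0, d_both = 0;
  double o_rob = 0, o_het = 0, o_err = 0;
  std::vector<std::string> kept_kmer;
  std::vector<double> kept_count;
  std::vector<int> kept_label;   // 1 error, 2 heterozygous, 3 homozygous
  size_t n = codes.size(), i = 0;
  while (i < n) {
    size_t j = i + 1;
    while (j < n && codes[j] == codes[i]) ++j;
    double cnt = (double)(j - i);
    bool a = in_set(setA, codes[i]), b = in_set(setB, codes[i]);
    int lab;
    if (!a && !b) { d_err += 1; o_err += cnt; lab = 1; }
    else if (a != b) { d_het += 1; d_rob += 1; o_het += cnt; o_rob += cnt; lab = 2; }
    else { d_both += 1; d_rob += 1; o_rob += cnt; lab = 3; }
    if ((int)kept_kmer.size() < keep_max) {
      kept_kmer.push_back(code_to_string(codes[i], k));
      kept_count.push_back(cnt);
      kept_label.push_back(lab);
    }
    i = j;
  }
  List out = List::create(
      _["distinct_robust"] = d_rob, _["distinct_heterozygous"] = d_het,
      _["distinct_error"] = d_err, _["distinct_both"] = d_both,
      _["occ_robust"] = o_rob, _["occ_heterozygous"] = o_het,
      _["occ_error"] = o_err, _["occ_total"] = (double)n,
      _["distinct_total"] = d_rob + d_err,
      _["distinct_hapA"] = (double)setA.size(),
      _["distinct_hapB"] = (double)setB.size());
  if (keep_max > 0)
    out["table"] = List::create(_["kmer"] = wrap(kept_kmer),
                                _["count"] = wrap(kept_count),
                                _["label"] = wrap(kept_label));
  return out;
}

// exact dictionary counter (string keyed, supports spaced seeds) with
// per-read depth; the independent oracle for the Bloom cascade
// [[Rcpp::export]]
List cpp_count_kmers_exact(CharacterVector reads, std::string mask) {
  SeedMask sm(mask);
  struct CD { double count = 0, depth = 0; };
  std::unordered_map<std::string, CD> tab;
  std::unordered_set<std::string> in_read;
  for (R_xlen_t j = 0; j < reads.size(); ++j) {
    std::string rd = as<std::string>(reads[j]);
    int n = (int)rd.size();
    in_read.clear();
    if (n < sm.k) continue;
    for (int i = 0; i + sm.k <= n; ++i) {
      std::string fwd(sm.weight, 'N'), rev(sm.weight, 'N');
      bool ok = true;
      for (int t = 0; t < sm.weight; ++t) {
        int c = base_code(rd[i + sm.care[t]]);
        if (c == 0xFF) { ok = false; break; }
        fwd[t] = code_base(c);
        rev[sm.weight - 1 - t] = code_base(comp_code(c));
      }
      if (!ok) continue;
      const std::string &canon = rev < fwd ? rev : fwd;
      CD &cd = tab[canon];
      cd.count += 1;
      if (in_read.insert(canon).second) cd.depth += 1;
    }
  }
  std::vector<std::string> kms;
  std::vector<double> cnts, dpts;
  kms.reserve(tab.size());
  for (auto &kv : tab) {
    kms.push_back(kv.first);
    cnts.push_back(kv.second.count);
    dpts.push_back(kv.second.depth);
  }
  return List::create(_["kmer"] = wrap(kms), _["count"] = wrap(cnts),
                      _["depth"] = wrap(dpts));
}
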
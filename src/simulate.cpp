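#include "kspect.h"
#include <random>
using namespace Rcpp;

// Draw reads uniformly from two haplotypes until the target number of bases
// is reached. Substitution errors are iid at `error_rate`; optional iid short
// indels (long-read mode). Qualities are the constant Phred encoding of the
// configured per-base error probability.
// len_mean/len_sd parameterize a lognormal read length (sd 0 = fixed length).
// [[Rcpp::export]]
List cpp_simulate_reads(CharacterVector haps, double target_bases,
                        double len_mean, double len_sd, int len_min,
                        double error_rate, double indel_rate, int seed) {
  if (haps.size() < 1) stop("at least one haplotype required");
  std::mt19937_64 rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 1);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<std::string> hap;
  for (R_xlen_t i = 0; i < haps.size(); ++i)
    hap.push_back(as<std::string>(haps[i]));
  double sdlog = len_sd > 0 ? std::sqrt(std::log1p((len_sd * len_sd) /
                                                   (len_mean * len_mean)))
                            : 0.0;
  double meanlog = std::log(len_mean) - 0.5 * sdlog * sdlog;
  std::lognormal_distribution<double> lnorm(meanlog, sdlog > 0 ? sdlog : 1e-12);
  int qchar = 'I';   // Q40 when error_rate == 0
  if (error_rate > 0) {
    int q = (int)std::lround(-10.0 * std::log10(error_rate));
    if (q > 41) q = 41;
    if (q < 0) q = 0;
    qchar = 33 + q;
  }
  std::vector<std::string> seqs, quals;
  std::vector<int> hap_idx, starts;
  double bases = 0;
  while (bases < target_bases) {
    int hi = (int)(unif(rng) * hap.size());
    if (hi >= (int)hap.size()) hi = (int)hap.size() - 1;
    const std::string &H = hap[hi];
    int L = (int)H.size();
    int len = len_sd > 0 ? (int)std::lround(lnorm(rng)) : (int)len_mean;
    if (len < len_min) len = len_min;
    if (len > L) len = L;
    int start = (int)(unif(rng) * (L - len + 1));
    if (start > L - len) start = L - len;
    std::string rd;
    rd.reserve(len + 16);
    for (int i = 0; i < len; ++i) {
      char ch = H[start + i];
      if (indel_rate > 0) {
        double u = unif(rng);
        if (u < indel_rate / 2) continue;                    // deletion
        if (u < indel_rate) rd.push_back(code_base((int)(unif(rng) * 4)));
      }
      int c = base_code(ch);
      if (c != 0xFF && error_rate > 0 && unif(rng) < error_rate) {
        int sub = (c + 1 + (int)(unif(rng) * 3)) & 3;        // a different base
        ch = code_base(sub);
      }
      rd.push_back(ch);
    }
    if ((int)rd.size() < 1) continue;
    bases += rd.size();
    quals.push_back(std::string(rd.size(), (char)qchar));
    seqs.push_back(std::move(rd));
    hap_idx.push_back(hi + 1);
    starts.push_back(start);
  }
  return List::create(_["seq"] = wrap(seqs), _["qual"] = wrap(quals),
                      _["haplotype"] = wrap(hap_idx), _["start"] = wrap(starts));
}

// minimum base quality within each k-length window of a quality string
// (Phred+33); windows indexed from the read start
// [[Rcpp::export]]
IntegerVector cpp_min_window_qual(std::string qual, int k) {
  int n = (int)qual.size();
  if (n < k) return IntegerVector(0);
  IntegerVector out(n - k + 1);
  for (int i = 0; i + k <= n; ++i) {
    int mn = 255;
    for (int j = i; j < i + k; ++j) mn = std::min(mn, (int)qual[j] - 33);
    out[i] = mn;
  }
  return out;
}
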
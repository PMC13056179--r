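#include "kspect.h"
using namespace Rcpp;

// hash a vector of k-mer strings into per-k-mer tuples, calling fn(hv)
template <typename F>
static void with_tuples(const CharacterVector &kmers, const SeedMask &sm,
                        int h, F fn) {
  std::vector<uint64_t> hv(h);
  std::vector<int> codes(sm.k);
  for (R_xlen_t j = 0; j < kmers.size(); ++j) {
    const char *s = CHAR(STRING_ELT(kmers, j));
    if ((int)std::strlen(s) != sm.k)
      stop("element %d: k-mer length does not match mask length", (int)j + 1);
    for (int i = 0; i < sm.k; ++i) {
      codes[i] = base_code(s[i]);
      if (codes[i] == 0xFF)
        stop("element %d: non-ACGT base in k-mer", (int)j + 1);
    }
    derive_hashes(window_canonical_hash(codes.data(), sm), h, hv.data());
    fn(hv.data());
  }
}

// [[Rcpp::export]]
SEXP cpp_bf_new(double m, int h) {
  return XPtr<BloomF>(new BloomF((uint64_t)m, h), true);
}

// [[Rcpp::export]]
void cpp_bf_insert(SEXP ptr, CharacterVector kmers, std::string mask, int h) {
  XPtr<BloomF> bf(ptr);
  SeedMask sm(mask);
  with_tuples(kmers, sm, h, [&](const uint64_t *hv) { bf->insert(hv); });
}

// [[Rcpp::export]]
LogicalVector cpp_bf_contains(SEXP ptr, CharacterVector kmers,
                              std::string mask, int h) {
  XPtr<BloomF> bf(ptr);
  SeedMask sm(mask);
  LogicalVector out(kmers.size());
  R_xlen_t j = 0;
  with_tuples(kmers, sm, h, [&](const uint64_t *hv) {
    out[j++] = bf->contains(hv);
  });
  return out;
}

// [[Rcpp::export]]
List cpp_bf_info(SEXP ptr) {
  XPtr<BloomF> bf(ptr);
  return List::create(_["m"] = (double)bf->m, _["h"] = bf->h,
                      _["n_inserted"] = (double)bf->n_inserted);
}

// [[Rcpp::export]]
RawVector cpp_bf_payload(SEXP ptr) {
  XPtr<BloomF> bf(ptr);
  RawVector out(bf->m / 8);
  std::memcpy(RAW(out), bf->bits.data(), bf->m / 8);
  return out;
}

// [[Rcpp::export]]
SEXP cpp_bf_from_payload(RawVector payload, double m, int h, double n_inserted) {
  XPtr<BloomF> bf(new BloomF((uint64_t)m, h), true);
  if ((uint64_t)payload.size() != bf->m / 8)
    stop("payload size does not match filter size");
  std::memcpy(bf->bits.data(), RAW(payload), payload.size());
  bf->n_inserted = (uint64_t)n_inserted;
  return bf;
}

// [[Rcpp::export]]
SEXP cpp_cbf_new(double m, int h, int width) {
  return XPtr<CountingBF>(new CountingBF((uint64_t)m, h, width), true);
}

// [[Rcpp::export]]
void cpp_cbf_increment(SEXP ptr, CharacterVector kmers, std::string mask, int h) {
  XPtr<CountingBF> cbf(ptr);
  SeedMask sm(mask);
  with_tuples(kmers, sm, h, [&](const uint64_t *hv) { cbf->increment(hv); });
}

// [[Rcpp::export]]
void cpp_cbf_decrement(SEXP ptr, CharacterVector kmers, std::string mask,
                       int h, double amount) {
  XPtr<CountingBF> cbf(ptr);
  SeedMask sm(mask);
  with_tuples(kmers, sm, h, [&](const uint64_t *hv) {
    cbf->decrement(hv, (uint64_t)amount);
  });
}

// [[Rcpp::export]]
NumericVector cpp_cbf_count(SEXP ptr, CharacterVector kmers, std::string mask,
                            int h) {
  XPtr<CountingBF> cbf(ptr);
  SeedMask sm(mask);
  NumericVector out(kmers.size());
  R_xlen_t j = 0;
  with_tuples(kmers, sm, h, [&](const uint64_t *hv) {
    out[j++] = (double)cbf->count(hv);
  });
  return out;
}

// [[Rcpp::export]]
List cpp_cbf_info(SEXP ptr) {
  XPtr<CountingBF> cbf(ptr);
  return List::create(_["m"] = (double)cbf->m, _["h"] = cbf->h,
                      _["width"] = cbf->width, _["cap"] = (double)cbf->cap,
                      _["n_inserted"] = (double)cbf->n_inserted);
}

// [[Rcpp::export]]
double cpp_cbf_max_counter(SEXP ptr) {
  XPtr<CountingBF> cbf(ptr);
  uint64_t mx = 0;
  for (uint64_t i = 0; i < cbf->m; ++i) mx = std::max(mx, cbf->get(i));
  return (double)mx;
}

// CBF payload: one byte per counter at the default 8-bit width,
// 4 bytes (little-endian) per counter for wider counters
// [[Rcpp::export]]
RawVector cpp_cbf_payload(SEXP ptr) {
  XPtr<CountingBF> cbf(ptr);
  if (cbf->narrow) {
    RawVector out(cbf->m);
    std::memcpy(RAW(out), cbf->c8.data(), cbf->m);
    return out;
  }
  RawVector out(cbf->m * 4);
  std::memcpy(RAW(out), cbf->c32.data(), cbf->m * 4);
  return out;
}

// [[Rcpp::export]]
SEXP cpp_cbf_from_payload(RawVector payload, double m, int h, int width,
                          double n_inserted) {
  XPtr<CountingBF> cbf(new CountingBF((uint64_t)m, h, width), true);
  uint64_t expect = cbf->narrow ? cbf->m : cbf->m * 4;
  if ((uint64_t)payload.size() != expect)
    stop("payload size does not match filter size");
  if (cbf->narrow) std::memcpy(cbf->c8.data(), RAW(payload), payload.size());
  else std::memcpy(cbf->c32.data(), RAW(payload), payload.size());
  cbf->n_inserted = (uint64_t)n_inserted;
  return cbf;
}

// [[Rcpp::export]]
double cpp_bf_size_for(double n, double fpr, int h) {
  return bf_size_bits(n, fpr, h);
}
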
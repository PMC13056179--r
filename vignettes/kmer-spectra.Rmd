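---
title: "Counting k-mers with Bloom filter cascades and modelling their count spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting k-mers with Bloom filter cascades and modelling their count spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kspect)
```

## What this package does

`kspect` addresses two connected tasks in the analysis of raw sequencing
reads:

1. **Counting**: obtain the multiplicity (count) of every k-mer — and its
   *depth*, the number of distinct reads containing it — without storing the
   k-mers themselves, while filtering on minimum/maximum occurrence
   thresholds. This uses a cascade of Bloom filters and counting Bloom
   filters.
2. **Spectrum analysis**: fit a mixture model to the k-mer count histogram
   (h_1, ..., h_c, where h_i is the number of distinct k-mers seen exactly
   i times) and derive genome-level summaries — k-mer coverage,
   heterozygosity, the fraction of error-generated k-mers, genome size — and
   per-k-mer posterior classifications.

Everything is testable offline: a synthetic diploid genome and read
simulator generates fixtures with exact ground truth.

## The counting cascade

A Bloom filter (BF) stores set membership in `m` bits addressed by `h`
hashed positions per element; queries have no false negatives and a
false-positive rate of about `(1 - exp(-h n / m))^h` after `n` insertions.
A counting Bloom filter (CBF) replaces bits with fixed-width counters
(8 bits by default, saturating at 255) and reports the **minimum** of the
addressed counters. Increments follow the *minimal-increase* rule — only
counters currently at the minimum are bumped — which keeps the one-sided
error property (reported count ≥ true count) while reducing overestimation.

The cascade layers these structures so that cheap filters absorb the bulk
of the data:

* a **global BF** records every distinct k-mer (first occurrences);
* an **intermediate CBF** counts occurrences 2 .. c_min−1;
* the **output CBF** (or a BF, 8× smaller, when only membership is needed)
  is touched only from the c_min-th occurrence onward, so its counter plus
  `c_min − 1` is the reported count;
* a k-mer whose reported count would exceed `c_max` is *removed* by
  decrementing its own reported value from its counters, and optionally
  remembered in a **secondary BF** so later occurrences are ignored.

Most k-mers in shotgun data occur once (sequencing errors), so the global
BF absorbs most traffic and the larger-per-element counting structures stay
small. Layers that the thresholds make redundant are never allocated: with
`c_min = 1` and `c_max = 255` the output CBF is the only structure built.

Filter sizes come from inverting the false-positive formula at a target
error rate `e` (default 0.001) with a fixed `h = 7` hash functions, given
the expected number of distinct insertions per layer — read from a count
histogram (`exact_histogram()` in-package, or an ntCard-style profile).

**Error direction.** Absent `c_max` removals, every layer errs on the side
of overcounting: BF false positives can promote a k-mer one layer early,
and CBF collisions can inflate minima, but nothing decrements. Reported
count ≥ true count is therefore an invariant, and the measured exact-match
rate at the default `e` is above 99.5% on the desk-scale fixture (the
acceptance suite recomputes this).

**Depth.** While scanning a read, each k-mer is first probed against a
per-read scratch BF; only unseen ones increment the global depth CBF, so
that CBF counts *reads containing the k-mer*, not occurrences. The scratch
filter is sized for `L − k + 1` insertions at a false-positive rate of
`min(1e-4, e/1000)` — scratch false positives silently drop depth
increments, so this rate is kept far below the store's target error rate
rather than fixed. Depth ≤ count always; the count-to-depth ratio is the
package's analogue of term frequency over document frequency: a ratio above
1 flags k-mers recurring *within* single reads, i.e. repeats at spacings
shorter than a read length.

**Determinism.** Processing is single-threaded in input order. The original
motivation for atomic counters is parallel throughput, which is out of
scope here; determinism makes every pipeline reproducible and testable.

## Hashing

K-mers are hashed in canonical (strand-collapsed) form with an ntHash-style
rolling polynomial: per-base 64-bit constants combined by rotate-and-XOR,
updated in O(1) per shifted window, computed independently for the forward
and reverse-complement strands, canonicalized by taking the minimum, and
passed through a 64-bit finalizing mixer. The `h` values per k-mer are
derived from that one hash by double hashing (`v + i * step` with an odd
`step`). The bit-level constants are this package's own — any
strand-invariant, uniform 64-bit rolling hash satisfies the contract the
filters need.

Spaced seeds (masks over `{0,1}`; 0 = ignore the position) hash the
*care-string*: the canonical form is the lexicographically smaller of the
masked forward string and its reverse complement, which makes a window and
its reverse complement (under the reversed mask) collide by construction,
and makes k-mers differing only at don't-care positions identical. Gapped
windows are hashed from scratch per window; plain windows use the O(1)
rolling update. Windows containing non-ACGT bases are skipped and tallied,
never fatal.

## The count-spectrum mixture model

The histogram of k-mer counts is modelled as

    F(x) = w_err f_err(x) + sum_{j=1..p} w_j f_j(x),   x = 1..c,

with an error component (exponential or gamma) for k-mers created by
sequencing errors and `p` genomic components — for a diploid genome
(`p = 2`) the *heterozygous* and *homozygous* coverage peaks. Component
densities are evaluated at the integer support 1..c and renormalized, so F
is a proper probability mass function. The fit minimizes

    Err(F) = sum_{x=1..c} | F(x) - h_x / sum_j h_j |,

the L1 distance to the normalized histogram: non-negative, zero only for a
perfect fit, invariant to rescaling the histogram.

### Families are selected, not assumed

No single family is imposed: the error component is exponential or gamma;
the genomic peaks are normal, skew normal, Poisson or negative binomial
(mean/dispersion parameterization). Family choices are categorical genes in
the optimizer's candidate encoding, so the data select the shapes. Typical
read data at moderate coverage select the negative binomial or Poisson; at
high coverage the peaks become indistinguishable from discrete normals
(a negative binomial with large shape converges to one — the test suite
verifies this limit numerically).

### Identifiability: one peak family, coupled peaks

Two structural constraints are deliberate design choices:

* **One family is shared by all genomic peaks.** The peaks arise from one
  coverage process sampled at different haplotype multiplicities; fitted
  spectra essentially always select a single family for both peaks, and
  allowing mixed families admits degenerate solutions in which one
  flexible "peak" slides under the error component.
* **Peaks are coupled.** A k-mer present on j of the p haplotypes receives
  j/p of the total coverage, so peak j's mean is `ratio_j * lambda` with
  `ratio_j` confined to `[j/p − 0.05, j/p + 0.05]`, all peaks share one
  dispersion gene (`sd_j = r * sqrt(mean_j)`, `r = 1` being Poisson-like,
  bounded in `[0.5, 2]`) and one skewness gene.

The coupling exists because the unconstrained objective is nearly flat
along a direction that trades heterozygous *weight* against homozygous
*width*: on simulated diploid data, solutions differing by many points of
heterozygosity fit the histogram almost equally well, and the unconstrained
L1 optimum systematically underweights the heterozygous peak. Coupling
removes that degeneracy while leaving weight, location, dispersion and skew
free; it also enforces the component ordering (error, then peaks by
increasing mean) structurally. The residual uncertainty of the
heterozygosity estimate on a realized fixture is of the order of one to two
percentage points — a property of the objective on a finite histogram, not
of the optimizer (independent re-optimizations land on the same solution).

### Differential Evolution, then BFGS

The candidate genome is: two family genes (floored at evaluation), `p + 1`
weight logits (softmax-normalized), two error-component parameters, the
top-peak mean in `[2, c]`, the shared dispersion and skew genes, and the
`p − 1` peak ratios. Differential Evolution (rand/1/bin) runs with
population 16, a mutation factor drawn uniformly from `[0.5, 1]` each
generation, and crossover rate 0.8; greedy selection makes the
per-generation best error non-increasing, which the tests assert. The
initial population covers all eight family combinations, three of them at
moment-based starting points (error decay from `h_1/h_2`, the main peak
from the smoothed histogram beyond the error valley). The run stops after
50 consecutive generations with improvement below 1e-6, or at 500
generations (with a warning).

The winner's continuous genes are then refined with BFGS in a
logit-transformed unconstrained space (plain box-clipping flattens the
gradient at the bounds). Because families are not differentiable, the
refinement is repeated once per family combination from the winner's
continuous genes; a refined solution replaces the DE winner only if it
strictly improves Err, so refinement can never worsen the fit. All
randomness flows from the single seed in `de_config()`; the caller's RNG
state is saved and restored.

### Summary statistics

From a fitted model (`summary()` on the fit):

* **k-mer coverage** — mean of the homozygous (highest-mean) component over
  the discrete support;
* **heterozygosity** — `100 w_het / (w_het + w_hom)`, the share of distinct
  genomic k-mers on a single haplotype; an occurrence-weighted variant
  (weights replaced by the components' expected counts) is also reported
  because either convention appears in practice;
* **error fraction / robust rate** — occurrence-weighted:
  `sum_x x w_err f_err(x) / sum_x x F(x)` and its complement; "robust"
  means present in at least one haplotype, i.e. not an error artifact;
* **genome size** — total occurrences × robust rate / coverage, the
  haploid k-mer count of the genome (≈ its length for k ≪ genome size);
* with `k` supplied, the error fraction inverts to a per-base error
  probability `1 − (1 − err)^(1/k)` and a Phred score; with a read length
  L, the base-level coverage `coverage · L / (L − k + 1)` corrects for the
  k − 1 bases each read end contributes to no window.

If the fitted genomic mass is numerically zero, heterozygosity is reported
as not applicable rather than a 0/0.

### Per-k-mer characterization

The posterior that a k-mer with count x belongs to component c is
`w_c f_c(x) / F(x)`; where `F(x) = 0` it is undefined and reported `NA`
(`classify_kmers()` labels such counts "unclassified"). Classification is
the posterior argmax with ties broken toward the lower-mean component.
`P(error | x)` decreases in x for exponential-error fits, so it can proxy
a quality score: with `P = 10^(-Q/10)`, `phred_from_prob()` converts both
ways, and `min_phred_per_kmer()` extracts the corresponding per-window
minimum base quality from FASTQ reads (one bad base corrupts the whole
window, so the minimum is the representative score).

## The synthetic world

`make_diploid()` draws a uniform random sequence and mutates a copy at a
stated SNV rate (optionally with 1–3 bp indels); every variant is recorded.
`simulate_reads()` draws reads uniformly from both haplotypes — fixed
150 bp in short mode, lognormal lengths with mean 10 kb and sd 6 kb
(minimum 200 bp) in long mode, which is a typical nanopore length scale —
applies iid substitution errors (plus optional iid indels), and writes
constant base qualities encoding the configured error rate.
`label_kmers()` provides exact ground truth: a read k-mer is *robust* if
present in at least one haplotype, *heterozygous* if in exactly one,
*error* if in neither. (The alternative convention, robust = present in
both, is computed as `distinct_both` but not used by the statistics.)

Defaults mirror the conditions the analyses are specified at: 30-fold
coverage; 0.1% base error for short reads and 2% for the long-read mode;
SNV rates of 0.1–1% spanning low to high heterozygosity.

What the generator deliberately does **not** emulate: coverage biases (GC,
mappability), platform-specific error profiles and quality models,
structural variation beyond short indels, chimeric or duplicate reads. A
green test therefore establishes correctness of the algorithms under the
stated statistical structure (an error component plus coverage peaks at
1×/2× haplotype coverage), not robustness to real-platform artifacts. Two
real-data features the simple world *does* reproduce and the model must
cope with: the dominance of singleton error k-mers (h_1 is by far the
largest bin at realistic error rates) and read-end coverage attenuation,
which slightly overdisperses the peaks.

## Numerical and interface choices

* Counter width is 8 bits by default (cap 255, the largest admissible
  `c_max`); widths up to 32 are supported, serialized at 4 bytes per
  counter beyond 8 bits.
* Bit-array sizes round up to multiples of 64 (block storage), so a BF
  payload is exactly m/8 bytes and a default CBF payload m bytes — the 8×
  size ratio is exact.
* `bf_size_for()` returns the smallest m satisfying the FPR formula via the
  closed-form inversion `ceil(-h n / log(1 − fpr^(1/h)))`; a bisection
  oracle in the tests confirms minimality.
* Hash indices are `value mod m`; the 64-bit hash space makes modulo bias
  negligible at any realistic m.
* Filters have reference semantics (external pointers); serialization uses
  a self-describing little-endian header (magic, version, k, h, width, m,
  insert count, mask) and fails loudly on bad magic, version or truncation.
* Histogram tail bins are used exactly as parsed; counts beyond the last
  bin are not folded in.
* Degenerate inputs: histograms with fewer than two non-empty bins are
  rejected; an optimizer run that hits the generation cap returns
  best-so-far with a warning; decrementing an absent k-mer floors at zero.
* The exact dictionary counter (`count_kmers_exact()`, string-keyed, with
  per-read depth) and the code-based comparator (`compare_with_oracle()`)
  are reference implementations kept deliberately independent of the
  Bloom-filter path; they exist for validation and ground truth, not
  production counting.

## Known limitations

* Counts cap at the counter width's maximum (255 by default): highly
  repetitive k-mers saturate unless a wider counter is chosen.
* `c_max` removal decrements shared counters, so colliding k-mers can be
  undercounted afterwards; the collateral is bounded by the target error
  rate.
* TSV export needs a second pass over a k-mer source — Bloom filters
  cannot enumerate their contents.
* Ploidy is a free parameter but the coupled-peak design has only been
  exercised at p = 1 and p = 2; polyploid spectra with repeat structure
  would likely need additional components.
* The heterozygosity estimate inherits an irreducible one-to-two point
  uncertainty from the flat direction of the L1 objective discussed above;
  coverage and robust-rate estimates are substantially more stable.
* Spectrum fitting assumes the histogram comes from roughly uniform
  whole-genome shotgun data; amplicon or RNA-seq count spectra violate the
  coverage-peak structure.
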
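#' Dataset-level statistics from a fitted mixture
#'
#' Derives genome and dataset summaries from the relative areas (weights)
#' and shapes of the fitted components:
#' \itemize{
#' \item k-mer coverage: mean of the homozygous (highest-mean genomic)
#'   component;
#' \item heterozygosity: `100 * w_het / (w_het + w_hom)` over distinct
#'   k-mers, plus an occurrence-weighted variant using the components'
#'   expected counts;
#' \item error k-mer fraction (occurrence-weighted):
#'   `sum_x x w_err f_err(x) / sum_x x F(x)`; the robust k-mer rate is its
#'   complement;
#' \item genome size: robust occurrences (total occurrences times the robust
#'   rate) divided by the k-mer coverage;
#' \item with `k` given, an implied per-base error probability
#'   (`1 - (1 - err)^(1/k)`) and its Phred score; with `read_length` L also
#'   given, the base-level coverage `coverage * L / (L - k + 1)`.
#' }
#'
#' @param object A `kmix` fit.
#' @param k K-mer length used to build the histogram (optional).
#' @param read_length Typical read length L (optional).
#' @param ... Unused.
#' @return Object of class `summary.kmix` (a list of the statistics above).
#' @export
summary.kmix <- function(object, k = NULL, read_length = NULL, ...) {
  hist <- object$hist
  cmax <- hist$c
  mat <- mixture_matrix(object$model, cmax)   # c x (p+1), weighted masses
  comps <- object$model$components
  w <- vapply(comps, function(cc) cc$weight, 1.0)
  means <- vapply(comps, component_mean, 1.0, c = cmax)
  x <- seq_len(cmax)
  occ <- colSums(x * mat)                      # expected count mass per comp
  p <- object$model$p
  # component order: error, then genomic by increasing mean (het ... hom)
  coverage <- means[p + 1L]
  err_frac <- occ[1] / sum(occ)
  robust_rate <- 100 * (1 - err_frac)
  w_gen <- w[-1]
  het_distinct <- het_occ <- NA_real_
  if (p >= 2 && sum(w_gen) > 1e-12) {
    het_distinct <- 100 * w[2L] / sum(w_gen)
    het_occ <- 100 * occ[2L] / sum(occ[-1])
  }
  genome_size <- hist$total_occurrences * (1 - err_frac) / coverage
  base_err <- base_phred <- base_coverage <- NULL
  if (!is.null(k)) {
    base_err <- 1 - (1 - err_frac)^(1 / k)
    base_phred <- phred_from_prob(max(base_err, 1e-12))
    if (!is.null(read_length))
      base_coverage <- coverage * read_length / (read_length - k + 1)
  }
  structure(list(err = object$err, weights = w, component_means = means,
                 coverage = coverage, heterozygosity = het_distinct,
                 heterozygosity_occ = het_occ,
                 error_fraction = 100 * err_frac, robust_rate = robust_rate,
                 genome_size = genome_size, base_error_prob = base_err,
                 base_quality_phred = base_phred,
                 base_coverage = base_coverage,
                 k = k, read_length = read_length),
            class = "summary.kmix")
}

#' @export
print.summary.kmix <- function(x, ...) {
  cat("k-mer spectrum summary\n")
  cat(sprintf("  model error (Err)         : %.6g\n", x$err))
  cat(sprintf("  k-mer coverage            : %.2fx\n", x$coverage))
  if (is.na(x$heterozygosity)) {
    cat("  heterozygosity            : not applicable (no genomic mass)\n")
  } else {
    cat(sprintf("  heterozygosity (distinct) : %.2f%%\n", x$heterozygosity))
    cat(sprintf("  heterozygosity (occurr.)  : %.2f%%\n", x$heterozygosity_occ))
  }
  cat(sprintf("  error k-mers (occurr.)    : %.2f%%\n", x$error_fraction))
  cat(sprintf("  robust k-mer rate         : %.2f%%\n", x$robust_rate))
  cat(sprintf("  genome size estimate      : %.4g\n", x$genome_size))
  if (!is.null(x$base_quality_phred))
    cat(sprintf("  implied base quality      : Q%.1f\n", x$base_quality_phred))
  if (!is.null(x$base_coverage))
    cat(sprintf("  base-level coverage       : %.2fx\n", x$base_coverage))
  invisible(x)
}
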
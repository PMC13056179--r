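#' Synthetic diploid genome
#'
#' Generates a random haploid sequence and a second haplotype copy carrying
#' single-nucleotide variants (and optionally short 1-3 bp indels) at the
#' stated per-base rates, recording every variant. This emulates the
#' construction of simulated heterozygous genomes: k-mers overlapping a
#' variant exist in exactly one haplotype and are the ground-truth
#' heterozygous k-mers.
#'
#' @param length Haplotype length in bp (>= 1000).
#' @param snv_rate Per-base substitution rate for the second copy (<= 0.05).
#' @param indel_rate Per-base short-indel rate for the second copy.
#' @param seed RNG seed; the genome is reproducible from it.
#' @return Object of class `diploid_genome`: `hapA`, `hapB` (strings),
#'   `variants` (data frame of position/type), `length`, rates and `seed`.
#' @examples
#' g <- make_diploid(20000, snv_rate = 0.01, seed = 7)
#' nrow(g$variants)
#' @export
make_diploid <- function(length, snv_rate = 0.001, indel_rate = 0, seed = 1) {
  stopifnot(length >= 1000, snv_rate >= 0, snv_rate <= 0.05,
            indel_rate >= 0, indel_rate <= 0.05)
  with_seed(seed, {
    codes <- sample.int(4L, length, replace = TRUE)
    snv_pos <- which(runif(length) < snv_rate)
    ind_pos <- which(runif(length) < indel_rate)
    ind_pos <- setdiff(ind_pos, snv_pos)
    b_codes <- codes
    if (length(snv_pos) > 0)
      b_codes[snv_pos] <- 1L + (b_codes[snv_pos] - 1L +
                                sample.int(3L, length(snv_pos), TRUE)) %% 4L
    variants <- data.frame(pos = snv_pos,
                           type = rep("snv", length(snv_pos)),
                           len = rep(1L, length(snv_pos)))
    hapB <- b_codes
    if (length(ind_pos) > 0) {
      is_del <- runif(length(ind_pos)) < 0.5
      lens <- ifelse(is_del, 1L, sample.int(3L, length(ind_pos), TRUE))
      segs <- list()
      prev <- 1L
      for (i in order(ind_pos)) {
        p <- ind_pos[i]
        if (p > prev) segs[[length(segs) + 1L]] <- b_codes[prev:(p - 1L)]
        if (!is_del[i])  # insertion after the kept base; deletion drops it
          segs[[length(segs) + 1L]] <- c(b_codes[p],
                                         sample.int(4L, lens[i], TRUE))
        prev <- p + 1L
      }
      if (prev <= length) segs[[length(segs) + 1L]] <- b_codes[prev:length]
      hapB <- unlist(segs)
      variants <- rbind(variants,
                        data.frame(pos = ind_pos,
                                   type = ifelse(is_del, "del", "ins"),
                                   len = lens))
      variants <- variants[order(variants$pos), , drop = FALSE]
    }
    bases <- c("A", "C", "G", "T")
    structure(list(hapA = paste(bases[codes], collapse = ""),
                   hapB = paste(bases[hapB], collapse = ""),
                   variants = variants, length = length,
                   snv_rate = snv_rate, indel_rate = indel_rate, seed = seed),
              class = "diploid_genome")
  })
}

#' @export
print.diploid_genome <- function(x, ...) {
  cat(sprintf(
    "diploid genome: %d bp, %d variants (snv rate %g, indel rate %g), seed %d\n",
    x$length, nrow(x$variants), x$snv_rate, x$indel_rate, x$seed))
  invisible(x)
}

#' Simulate error-bearing reads from a diploid genome
#'
#' Reads are drawn uniformly from both haplotypes (uniform start positions)
#' until the target coverage is reached. Substitution errors are iid at
#' `error_rate`; the long-read mode uses lognormal read lengths and can add
#' iid short indels. Base qualities encode the configured per-base error
#' probability (constant Phred score). This generator reproduces the
#' statistical structure a count-histogram model assumes (an error
#' component plus heterozygous and homozygous peaks), not any platform's
#' detailed error profile.
#'
#' @param genome A [make_diploid()] genome (or a character vector of one or
#'   two haplotype sequences).
#' @param coverage Total fold-coverage across both haplotypes (default 30).
#' @param mode `"short"` (fixed 150 bp reads) or `"long"` (lognormal lengths,
#'   mean 10 kb, sd 6 kb, minimum 200 bp).
#' @param read_length,length_sd,min_length Override the mode's length model
#'   (`length_sd = 0` gives fixed-length reads).
#' @param error_rate Per-base substitution error rate.
#' @param indel_rate Per-base read indel rate (long-read mode noise).
#' @param seed RNG seed; simulation is fully deterministic given it.
#' @return Data frame with `id`, `seq`, `qual`, `haplotype` (1/2), `start`
#'   (0-based).
#' @export
simulate_reads <- function(genome, coverage = 30,
                           mode = c("short", "long"),
                           read_length = NULL, length_sd = NULL,
                           min_length = NULL, error_rate = 0.001,
                           indel_rate = NULL, seed = 1) {
  mode <- match.arg(mode)
  haps <- if (inherits(genome, "diploid_genome")) c(genome$hapA, genome$hapB)
          else as.character(genome)
  stopifnot(coverage > 0, error_rate >= 0, error_rate < 0.5)
  defaults <- if (mode == "short") list(len = 150, sd = 0, min = 50, ind = 0)
              else list(len = 10000, sd = 6000, min = 200, ind = 0)
  read_length <- if (is.null(read_length)) defaults$len else read_length
  length_sd <- if (is.null(length_sd)) defaults$sd else length_sd
  min_length <- if (is.null(min_length)) defaults$min else min_length
  indel_rate <- if (is.null(indel_rate)) defaults$ind else indel_rate
  target <- coverage * mean(nchar(haps))
  res <- cpp_simulate_reads(haps, target, read_length, length_sd,
                            as.integer(min_length), error_rate, indel_rate,
                            as.integer(seed))
  data.frame(id = sprintf("read%06d", seq_along(res$seq)), seq = res$seq,
             qual = res$qual, haplotype = res$haplotype, start = res$start)
}

#' Ground-truth k-mer labels from a diploid fixture
#'
#' Labels every distinct canonical k-mer of the reads by its presence in the
#' source haplotypes: `robust` if present in at least one haplotype,
#' `heterozygous` if in exactly one, `error` if in neither (a sequencing
#' artifact). Both robustness conventions are reported: `distinct_robust`
#' (present in >= 1 haplotype, the convention the summary statistics bind
#' to) and `distinct_both` (present in both).
#'
#' @param reads Read set (data frame, character vector, or file path).
#' @param genome The [make_diploid()] genome the reads came from (or a
#'   character vector of haplotypes).
#' @param k K-mer length (<= 32).
#' @param keep Number of per-k-mer rows to keep in `$table` (0 = aggregates
#'   only).
#' @return List of aggregate counts (distinct and occurrence totals per
#'   label) plus derived ground-truth rates: `het_pct` (heterozygous /
#'   robust distinct k-mers, %), `robust_rate` (robust occurrences / total
#'   occurrences, %), `robust_coverage` (robust occurrences / distinct
#'   k-mers of haplotype A), and optionally `table` with per-k-mer labels.
#' @export
label_kmers <- function(reads, genome, k, keep = 0) {
  haps <- if (inherits(genome, "diploid_genome")) c(genome$hapA, genome$hapB)
          else as.character(genome)
  if (length(haps) == 1L) haps <- c(haps, haps)
  reads <- as_read_seqs(reads)
  res <- cpp_label_kmers(reads, haps[1], haps[2], as.integer(k),
                         as.integer(keep))
  res$het_pct <- 100 * res$distinct_heterozygous / max(res$distinct_robust, 1)
  res$robust_rate <- 100 * res$occ_robust / max(res$occ_total, 1)
  res$robust_coverage <- res$occ_robust / max(res$distinct_hapA, 1)
  if (!is.null(res$table)) {
    res$table <- data.frame(
      kmer = res$table$kmer, count = res$table$count,
      label = factor(c("error", "heterozygous", "homozygous")[res$table$label],
                     levels = c("error", "heterozygous", "homozygous")))
  }
  res
}
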
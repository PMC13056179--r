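test_that("diploid genomes are reproducible with binomially many variants", {
  g1 <- make_diploid(1e5, snv_rate = 0.001, seed = 3)
  g2 <- make_diploid(1e5, snv_rate = 0.001, seed = 3)
  expect_identical(g1$hapA, g2$hapA)
  expect_identical(g1$hapB, g2$hapB)
  # realized SNV count within 5 sigma of rate * length
  n_snv <- sum(g1$variants$type == "snv")
  expect_lt(abs(n_snv - 100), 5 * sqrt(100))
  # the recorded variants are real: haplotypes differ at SNV positions
  a <- strsplit(g1$hapA, "")[[1]]
  b <- strsplit(g1$hapB, "")[[1]]
  expect_true(all(a[g1$variants$pos] != b[g1$variants$pos]))
  expect_true(all(a[-g1$variants$pos] == b[-g1$variants$pos]))
  # zero rates give identical haplotypes and no heterozygous k-mers
  g0 <- make_diploid(50000, snv_rate = 0, seed = 4)
  expect_identical(g0$hapA, g0$hapB)
  rd0 <- simulate_reads(g0, coverage = 5, error_rate = 0, seed = 5)
  lab0 <- label_kmers(rd0, g0, k = 21)
  expect_equal(lab0$distinct_heterozygous, 0)
  expect_equal(lab0$distinct_error, 0)
  # indels shift coordinates but stay recorded
  gi <- make_diploid(50000, snv_rate = 0, indel_rate = 0.001, seed = 6)
  expect_gt(nrow(gi$variants), 0)
  expect_false(nchar(gi$hapB) == nchar(gi$hapA))
})

test_that("read simulation hits coverage, error rate and determinism", {
  g <- make_diploid(1e5, snv_rate = 0.002, seed = 7)
  rd <- simulate_reads(g, coverage = 30, mode = "short", error_rate = 0.01,
                       seed = 8)
  expect_identical(rd, simulate_reads(g, coverage = 30, mode = "short",
                                      error_rate = 0.01, seed = 8))
  total <- sum(nchar(rd$seq))
  expect_lt(abs(total - 30 * 1e5) / (30 * 1e5), 0.05)
  # qualities encode the configured error probability
  expect_equal(unique(unlist(strsplit(rd$qual, ""))),
               rawToChar(as.raw(33 + 20)))
  # realized mismatch rate vs the source haplotype within binomial noise
  haps <- c(g$hapA, g$hapB)
  mism <- 0
  for (i in seq_len(nrow(rd))) {
    src <- substr(haps[rd$haplotype[i]], rd$start[i] + 1,
                  rd$start[i] + nchar(rd$seq[i]))
    mism <- mism + sum(strsplit(src, "")[[1]] != strsplit(rd$seq[i], "")[[1]])
  }
  rate <- mism / total
  expect_lt(abs(rate - 0.01), 5 * sqrt(0.01 / total))
  # error-free reads are exact substrings of a haplotype
  rd0 <- simulate_reads(g, coverage = 2, error_rate = 0, seed = 9)
  for (i in sample(nrow(rd0), 10)) {
    expect_true(grepl(rd0$seq[i], g$hapA, fixed = TRUE) ||
                grepl(rd0$seq[i], g$hapB, fixed = TRUE))
  }
})

test_that("ground-truth labels match a brute-force membership oracle", {
  g <- make_diploid(3000, snv_rate = 0.01, seed = 10)
  rd <- simulate_reads(g, coverage = 8, mode = "short", read_length = 100,
                       error_rate = 0.01, seed = 11)
  k <- 11
  lab <- label_kmers(rd, g, k = k, keep = 1e6)
  # R oracle over canonical k-mer sets
  kset <- function(s) unique(canon_r(substring(s, 1:(nchar(s) - k + 1),
                                               k:nchar(s))))
  setA <- kset(g$hapA)
  setB <- kset(g$hapB)
  oracle <- oracle_counts_r(rd$seq, k)
  in_a <- oracle$kmer %in% setA
  in_b <- oracle$kmer %in% setB
  expect_equal(lab$distinct_error, sum(!in_a & !in_b))
  expect_equal(lab$distinct_heterozygous, sum(xor(in_a, in_b)))
  expect_equal(lab$distinct_robust, sum(in_a | in_b))
  expect_equal(lab$distinct_both, sum(in_a & in_b))
  expect_equal(lab$occ_total, sum(oracle$count))
  expect_equal(lab$occ_robust, sum(oracle$count[in_a | in_b]))
  expect_equal(lab$distinct_hapA, length(setA))
  # per-k-mer table agrees
  merged <- merge(lab$table, oracle, by = "kmer")
  expect_equal(merged$count.x, merged$count.y)
  # heterozygous k-mers are a subset of robust ones
  expect_lte(lab$distinct_heterozygous, lab$distinct_robust)
})

test_that("error-labelled k-mers grow with the base error rate", {
  g <- make_diploid(50000, snv_rate = 0.001, seed = 12)
  fracs <- vapply(c(0.002, 0.01, 0.03), function(e) {
    rd <- simulate_reads(g, coverage = 10, error_rate = e, seed = 13)
    lab <- label_kmers(rd, g, k = 25)
    lab$distinct_error / lab$distinct_total
  }, 1.0)
  expect_true(all(diff(fracs) > 0))
})

test_that("an error-free spectrum peaks near the k-mer coverage", {
  g <- make_diploid(2e5, snv_rate = 0, seed = 14)
  rd <- simulate_reads(g, coverage = 30, mode = "short", error_rate = 0,
                       seed = 15)
  k <- 25
  h <- exact_histogram(rd, k = k)
  mode_bin <- which.max(h$h)
  expect_lt(abs(mode_bin - 30 * (150 - k + 1) / 150), 3)
  # end-to-end: cascade counts equal the dictionary oracle at tight FPR
  cfg <- cascade_config(k = k, c_min = 1, c_max = 255, e = 1e-6)
  st <- count_reads(rd, cfg, histogram = h)
  cmp <- compare_with_oracle(st, rd)
  expect_equal(cmp$n_match, cmp$n_distinct)
})
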
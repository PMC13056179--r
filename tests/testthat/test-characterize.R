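test_that("posteriors follow w_c f_c(x) / F(x) exactly", {
  m <- mixture_model(list(
    list(family = "exponential", weight = 0.6, params = 1.0),
    list(family = "poisson", weight = 0.1, params = 6),
    list(family = "poisson", weight = 0.3, params = 14)))
  cmax <- 40
  post <- posterior_probs(m, 5, c = cmax)
  # direct arithmetic oracle
  f_err <- dexp(1:cmax, 1); f_err <- f_err / sum(f_err)
  f_het <- dpois(1:cmax, 6); f_het <- f_het / sum(f_het)
  f_hom <- dpois(1:cmax, 14); f_hom <- f_hom / sum(f_hom)
  Fx <- 0.6 * f_err[5] + 0.1 * f_het[5] + 0.3 * f_hom[5]
  expect_equal(as.numeric(post),
               c(0.6 * f_err[5], 0.1 * f_het[5], 0.3 * f_hom[5]) / Fx,
               tolerance = 1e-12)
  # normalization across the whole support
  all_post <- posterior_probs(m, 1:cmax, c = cmax)
  expect_equal(unname(rowSums(all_post)), rep(1, cmax), tolerance = 1e-12)
  # where the error mass is numerically zero the posterior excludes it
  expect_lt(posterior_probs(m, 35, c = cmax)[, "error"], 1e-8)
  expect_error(posterior_probs(m, 0, c = cmax), ">= 1")
})

test_that("classification is argmax with low-mean tie-breaking", {
  m <- mixture_model(list(
    list(family = "exponential", weight = 0.6, params = 1.5),
    list(family = "poisson", weight = 0.1, params = 7),
    list(family = "poisson", weight = 0.3, params = 15)))
  expect_equal(as.character(classify_kmers(m, 1, c = 40)), "error")
  expect_equal(as.character(classify_kmers(m, 15, c = 40)), "homozygous")
  # engineered tie: identical genomic components with equal weights
  tie <- mixture_model(list(
    list(family = "exponential", weight = 0.4, params = 20),
    list(family = "poisson", weight = 0.3, params = 10),
    list(family = "poisson", weight = 0.3, params = 10)))
  # at any x > 1 the error mass is ~0 and the two peaks tie exactly
  expect_equal(as.character(classify_kmers(tie, 10, c = 30)), "heterozygous")
  # P(error | x) is non-increasing beyond the error mode for exponential error
  perr <- posterior_probs(m, 1:40, c = 40)[, "error"]
  expect_true(all(diff(perr) <= 1e-12))
})

test_that("Phred conversions match Q = -10 log10(P)", {
  expect_equal(phred_from_prob(0.1), 10)
  expect_equal(phred_from_prob(1), 0)
  expect_equal(prob_from_phred(20), 0.01)
  p <- c(0.5, 0.01, 3e-7)
  expect_equal(prob_from_phred(phred_from_prob(p)), p, tolerance = 1e-12)
  expect_error(phred_from_prob(0), "probabilities")
  expect_error(prob_from_phred(-1), ">= 0")
})

test_that("count/depth profiles give the TF-IDF-style ratio", {
  x <- "ACGTCGGTACC"
  cfg <- cascade_config(k = 11, c_min = 1, depth = TRUE)
  # once per read in 5 reads: ratio 1
  st <- count_reads(rep(x, 5), cfg, n_distinct = 100)
  prof <- count_depth_profile(st, x)
  expect_equal(prof$count, 5)
  expect_equal(prof$depth, 5)
  expect_equal(prof$ratio, 1)
  # three times in each of two reads: count 6, depth 2, ratio 3
  triple <- paste0(x, "TTTTTTTTTTT", x, "GGAGGAGGAGG", x)
  st2 <- count_reads(rep(triple, 2), cfg, n_distinct = 1000)
  prof2 <- count_depth_profile(st2, x)
  expect_equal(prof2$count, 6)
  expect_equal(prof2$depth, 2)
  expect_equal(prof2$ratio, 3)
  expect_true(!is.null(attr(prof2, "density")))
  expect_error(count_depth_profile(count_reads(x, cascade_config(k = 11),
                                               n_distinct = 10), x),
               "depth")
})

test_that("close-proximity repeats have higher count-to-depth ratios", {
  # motifs recurring within a read length apart collapse into one read's
  # window set, so tighter spacing means higher count/depth
  set.seed(21)
  k <- 15
  motifs <- random_kmers(6, k)
  spacing <- c(40, 100, 250, 600, 1500, 4000)
  genome <- random_dna(2000)
  for (i in seq_along(motifs)) {
    block <- paste0(paste(rep(paste0(motifs[i], random_dna(spacing[i])), 4),
                          collapse = ""), random_dna(500))
    genome <- paste0(genome, block)
  }
  rds <- simulate_reads(genome, coverage = 12, mode = "long",
                        read_length = 2000, length_sd = 0, min_length = 2000,
                        error_rate = 0, seed = 22)
  cfg <- cascade_config(k = k, c_min = 1, depth = TRUE, e = 1e-6)
  st <- count_reads(rds, cfg, n_distinct = 1e5)
  prof <- count_depth_profile(st, motifs)
  ok <- prof$depth > 0
  expect_lt(cor(spacing[ok], prof$ratio[ok], method = "spearman"), 0)
})

test_that("window quality is the minimum base quality", {
  qual <- rawToChar(as.raw(33 + c(30, 30, 2, 30, 30, 40)))
  mins <- min_phred_per_kmer(qual, k = 3)[[1]]
  expect_equal(mins, c(2, 2, 2, 30))
  expect_length(min_phred_per_kmer("II", k = 3)[[1]], 0)
})
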
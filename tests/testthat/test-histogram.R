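test_that("ntCard-style histogram files parse and round-trip", {
  path <- tempfile()
  writeLines(c("F1\t30", "1\t6", "2\t3", "3\t1"), path)
  h <- read_histogram(path)
  expect_equal(h$h, c(6, 3, 1))
  expect_equal(h$total_distinct, 10)
  expect_equal(h$total_occurrences, 15)
  expect_equal(h$F1, 30)
  # round trip
  path2 <- tempfile()
  write_histogram(h, path2)
  h2 <- read_histogram(path2)
  expect_equal(h2$h, h$h)
  expect_equal(h2$F1, h$F1)
  # metadata-only files are a format error
  writeLines(c("F0\t10", "F1\t30"), path)
  expect_error(read_histogram(path), "no count rows")
  writeLines(c("1\t5", "junk\t2", "2\t1"), path)
  expect_warning(read_histogram(path), "junk")
  writeLines(c("1\t-5"), path)
  expect_error(read_histogram(path), "negative")
  expect_error(kmer_histogram(numeric(0)), "at least one bin")
})

test_that("the fit error is the L1 distance to the normalized histogram", {
  hist <- kmer_histogram(c(6, 3, 1))
  model <- toy_model(w = c(0.5, 0.2, 0.3), rate = 1.2, means = c(2, 3))
  # independent oracle: renormalized densities computed directly
  f_err <- dexp(1:3, 1.2); f_err <- f_err / sum(f_err)
  f1 <- dnbinom(1:3, mu = 2, size = 1e5); f1 <- f1 / sum(f1)
  f2 <- dnbinom(1:3, mu = 3, size = 1e5); f2 <- f2 / sum(f2)
  F <- 0.5 * f_err + 0.2 * f1 + 0.3 * f2
  expected <- sum(abs(F - c(0.6, 0.3, 0.1)))
  expect_equal(model_error(model, hist), expected, tolerance = 1e-12)
  # perfect fit has zero error
  perfect <- kmer_histogram(mixture_pmf(model, 3) * 1e6)
  expect_lt(model_error(model, perfect), 1e-12)
  # scale invariance in h
  expect_equal(model_error(model, kmer_histogram(c(6, 3, 1) * 7)),
               model_error(model, hist))
})

test_that("component pmfs match closed forms and limits", {
  # Poisson against its closed form
  pm <- component_pmf("poisson", 5, 60)
  oracle <- dpois(1:60, 5) / sum(dpois(1:60, 5))
  expect_equal(pm, oracle, tolerance = 1e-12)
  expect_equal(sum(pm), 1)
  # exponential with tiny rate is near-uniform over the support
  pe <- component_pmf("exponential", 1e-6, 50)
  expect_lt(max(pe) - min(pe), 1e-4)
  # negative binomial converges to Poisson as dispersion -> infinity
  pnb <- component_pmf("nbinom", c(8, 1e7), 60)
  ppo <- component_pmf("poisson", 8, 60)
  expect_lt(max(abs(pnb - ppo)), 1e-5)
  # ... and to a discrete normal for a large shape and mean (central limit)
  pnb2 <- component_pmf("nbinom", c(200, 1e7), 320)
  pno <- component_pmf("normal", c(200, sqrt(200)), 320)
  expect_lt(max(abs(pnb2 - pno)), 1e-3)
  # skew normal with zero shape reduces to the normal
  psk <- component_pmf("skew_normal", c(10, 2, 0), 40)
  pno2 <- component_pmf("normal", c(10, 2), 40)
  expect_equal(psk, pno2, tolerance = 1e-12)
  expect_error(component_pmf("normal", c(5, -1), 10), "bounds")
  expect_error(component_pmf("poisson", c(5, 2), 10), "parameter")
  expect_error(component_pmf("cauchy", 5, 10), "unknown")
})

test_that("mixture models validate their components", {
  expect_error(mixture_model(list(
    list(family = "exponential", weight = 0.5, params = 1),
    list(family = "poisson", weight = 0.4, params = 5))), "sum to 1")
  expect_error(mixture_model(list(
    list(family = "poisson", weight = 0.5, params = 1),
    list(family = "poisson", weight = 0.5, params = 5))), "error family")
  expect_error(mixture_model(list(
    list(family = "exponential", weight = 0.5, params = 1),
    list(family = "gamma", weight = 0.5, params = c(1, 1)))), "genomic")
  m <- toy_model()
  expect_named(m$components, c("error", "heterozygous", "homozygous"))
  expect_equal(sum(mixture_pmf(m, 60)), 1, tolerance = 1e-12)
})

test_that("Jensen-Shannon similarity behaves as a similarity", {
  a <- kmer_histogram(c(5, 3, 2))
  expect_equal(histogram_similarity(a, a), 1)
  expect_equal(histogram_similarity(a, kmer_histogram(c(10, 6, 4))), 1)
  # disjoint supports give zero
  expect_equal(histogram_similarity(c(1, 0, 0), c(0, 1, 1)), 0)
  # 3-bin worked example against the direct formula
  p <- c(0.6, 0.3, 0.1)
  q <- c(0.2, 0.5, 0.3)
  m <- (p + q) / 2
  jsd <- 0.5 * sum(p * log2(p / m)) + 0.5 * sum(q * log2(q / m))
  got <- histogram_similarity(kmer_histogram(p * 100), kmer_histogram(q * 100))
  expect_equal(got, 1 - jsd, tolerance = 1e-12)
  # symmetry
  expect_equal(histogram_similarity(kmer_histogram(q * 100),
                                    kmer_histogram(p * 100)), got)
})
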
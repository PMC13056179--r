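test_that("the optimizer is elitist, deterministic and refinement-safe", {
  h <- sampled_histogram(toy_model(), n_kmers = 2e5, seed = 3)
  de <- de_config(max_gen = 80, seed = 9)
  fit <- suppressWarnings(fit_kmer_mixture(h, de = de))
  # per-generation best error never increases
  expect_true(all(diff(fit$trace) <= 1e-12))
  # BFGS refinement never worsens the DE solution
  raw <- suppressWarnings(fit_kmer_mixture(h, de = de, refine = FALSE))
  expect_lte(fit$err, raw$err + 1e-12)
  expect_equal(fit$err, model_error(fit, h), tolerance = 1e-12)
  # identical seeds give identical results
  fit2 <- suppressWarnings(fit_kmer_mixture(h, de = de))
  expect_identical(coef(fit), coef(fit2))
  expect_identical(fit$trace, fit2$trace)
  expect_identical(fit$err, fit2$err)
  # a different seed may differ but stays a valid model
  fit3 <- suppressWarnings(fit_kmer_mixture(h, de = de_config(max_gen = 80,
                                                              seed = 10)))
  expect_s3_class(fit3$model, "kmer_mixture")
})

test_that("known mixtures are recovered from sampled histograms", {
  truth <- toy_model(w = c(0.70, 0.09, 0.21), rate = 1.2, means = c(10, 20))
  h <- sampled_histogram(truth, n_kmers = 1e6, c = 60, seed = 5)
  fit <- fit_kmer_mixture(h)
  w_hat <- vapply(fit$model$components, function(cc) cc$weight, 1.0)
  expect_lt(max(abs(w_hat - c(0.70, 0.09, 0.21))), 0.02)
  s <- summary(fit)
  expect_lt(abs(s$coverage - 20), 1)
  expect_lt(abs(s$heterozygosity - 100 * 0.09 / 0.30), 2)
})

test_that("degenerate histograms are rejected and caps warn", {
  expect_error(fit_kmer_mixture(kmer_histogram(c(0, 5))), "degenerate")
  h <- sampled_histogram(toy_model(), n_kmers = 1e4, seed = 6)
  expect_warning(fit_kmer_mixture(h, de = de_config(max_gen = 3, seed = 1)),
                 "generation cap")
})

test_that("fit methods expose the model consistently", {
  h <- sampled_histogram(toy_model(), n_kmers = 3e5, seed = 7)
  fit <- suppressWarnings(fit_kmer_mixture(h, de = de_config(max_gen = 60,
                                                             seed = 2)))
  # predict: mixture sums to 1 over the support, components sum to F
  f <- predict(fit)
  expect_equal(sum(f), 1, tolerance = 1e-12)
  comps <- predict(fit, type = "components")
  expect_equal(rowSums(comps), f, tolerance = 1e-12)
  post <- predict(fit, x = c(2, 10), type = "posterior")
  expect_equal(unname(rowSums(post)), c(1, 1), tolerance = 1e-12)
  # residuals are the normalized histogram minus F
  expect_equal(residuals(fit), h$h / sum(h$h) - f, tolerance = 1e-12)
  # simulate returns histogram replicates, deterministic under a seed
  sim1 <- simulate(fit, nsim = 2, seed = 4)
  sim2 <- simulate(fit, nsim = 2, seed = 4)
  expect_equal(sim1[[1]]$h, sim2[[1]]$h)
  expect_s3_class(sim1[[2]], "kmer_histogram")
  expect_equal(sim1[[1]]$total_distinct, h$total_distinct)
  # coefficients carry weights and parameters
  expect_true(all(c("w_error", "w_heterozygous", "w_homozygous") %in%
                  names(coef(fit))))
  # plotting works headless
  png(tempfile(fileext = ".png"))
  expect_silent(plot(fit))
  dev.off()
})

test_that("animation frames cover every recorded generation", {
  h <- sampled_histogram(toy_model(), n_kmers = 1e5, seed = 8)
  fit <- suppressWarnings(fit_kmer_mixture(h, de = de_config(max_gen = 12,
                                                             seed = 3)))
  dir <- tempfile()
  frames <- plot_fit_frames(fit, dir)
  expect_length(frames, fit$generations)
  expect_length(frames, nrow(fit$trace_genomes))
  expect_true(all(file.exists(frames)))
})
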
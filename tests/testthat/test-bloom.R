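test_that("Bloom filters have no false negatives and controlled FPR", {
  bf <- bloom_filter(k = 21, n = 1e4, fpr = 0.01)
  set.seed(1)
  ins <- unique(random_kmers(11000, 21))
  ins <- ins[seq_len(1e4)]
  bf_insert(bf, ins)
  expect_true(all(bf_contains(bf, ins)))
  # canonical duplicates of inserted k-mers also hit
  expect_true(all(bf_contains(bf, rc_r(ins[1:50]))))
  # fresh queries: empirical FPR within [0, 2x target]
  fresh <- setdiff(unique(canon_r(random_kmers(120000, 21))), canon_r(ins))
  fresh <- fresh[seq_len(1e5)]
  fpr <- mean(bf_contains(bf, fresh))
  expect_gte(fpr, 0)
  expect_lte(fpr, 0.02)
})

test_that("an empty filter reports nothing present", {
  bf <- bloom_filter(k = 7, m = 2048)
  expect_false(any(bf_contains(bf, random_kmers(100, 7, seed = 2))))
})

test_that("bf_size_for inverts the false-positive rate formula", {
  # optimal load: fpr = 0.5^h gives m ~ n h / ln 2
  m <- bf_size_for(1000, 0.5^7, h = 7)
  expect_lt(abs(m - 1000 * 7 / log(2)), 2)
  # bisection oracle for the smallest m with (1 - exp(-hn/m))^h <= fpr
  fpr_of <- function(m, n, h) (1 - exp(-h * n / m))^h
  bisect <- function(n, fpr, h) {
    lo <- 1; hi <- 1e12
    while (hi - lo > 0.5) {
      mid <- (lo + hi) / 2
      if (fpr_of(mid, n, h) <= fpr) hi <- mid else lo <- mid
    }
    ceiling(hi)
  }
  for (case in list(c(1e6, 0.001, 7), c(5e4, 0.01, 7), c(1e3, 0.2, 3))) {
    m <- bf_size_for(case[1], case[2], h = case[3])
    expect_lte(abs(m - bisect(case[1], case[2], case[3])), 1)
    expect_lte(fpr_of(m, case[1], case[3]), case[2])
    expect_gt(fpr_of(m - 2, case[1], case[3]), case[2])
  }
  # homogeneous in n/m: doubling n doubles m
  expect_lt(abs(bf_size_for(2e5, 0.001) - 2 * bf_size_for(1e5, 0.001)), 2)
  expect_error(bf_size_for(100, 1.5), "fpr")
  expect_error(bf_size_for(100, 0), "fpr")
})

test_that("counting filters count by minimum selection and saturate", {
  cbf <- counting_bloom_filter(k = 9, n = 1000, fpr = 1e-6)
  x <- "ACGTACGTA"
  cbf_increment(cbf, rep(x, 3))
  expect_equal(cbf_count(cbf, x), 3)
  expect_equal(cbf_count(cbf, rc_r(x)), 3)
  # 8-bit counters cap at 255 and never wrap
  cbf_increment(cbf, rep(x, 297))
  expect_equal(cbf_count(cbf, x), 255)
  expect_lte(kspect:::cpp_cbf_max_counter(cbf$ptr), 255)
  # decrement floors at zero
  y <- "TTTTTCCCC"
  cbf_increment(cbf, rep(y, 5))
  cbf_decrement(cbf, y, 5)
  expect_equal(cbf_count(cbf, y), 0)
  empty <- counting_bloom_filter(k = 9, m = 4096)
  cbf_decrement(empty, y, 10)
  expect_equal(cbf_count(empty, y), 0)
  expect_equal(kspect:::cpp_cbf_max_counter(empty$ptr), 0)
})

test_that("counts never fall below true multiplicity without decrements", {
  set.seed(33)
  pool <- unique(random_kmers(600, 11))[1:500]
  mult <- sample(1:6, 500, replace = TRUE)
  occurrences <- sample(rep(pool, mult))
  truth <- tapply(mult, canon_r(pool), sum)[canon_r(pool)]
  # deliberately small filter: overcounts allowed, undercounts never
  small <- counting_bloom_filter(k = 11, m = 2048, h = 3)
  cbf_increment(small, occurrences)
  expect_true(all(cbf_count(small, pool) >= as.numeric(truth)))
  # generously sized: exact with overwhelming probability
  big <- counting_bloom_filter(k = 11, n = 500, fpr = 1e-6)
  cbf_increment(big, occurrences)
  expect_equal(cbf_count(big, pool), as.numeric(truth), ignore_attr = TRUE)
})

test_that("filters round-trip through serialization", {
  path_bf <- tempfile(fileext = ".bf")
  path_cbf <- tempfile(fileext = ".cbf")
  bf <- bloom_filter(k = 15, m = 8192)
  cbf <- counting_bloom_filter(k = 15, m = 8192)
  km <- random_kmers(400, 15, seed = 4)
  bf_insert(bf, km[1:200])
  cbf_increment(cbf, sample(rep(km[1:200], 3)))
  save_filter(bf, path_bf)
  save_filter(cbf, path_cbf)
  bf2 <- load_filter(path_bf)
  cbf2 <- load_filter(path_cbf)
  expect_identical(bf_contains(bf2, km), bf_contains(bf, km))
  expect_identical(cbf_count(cbf2, km), cbf_count(cbf, km))
  expect_identical(filter_info(bf2), filter_info(bf))
  # CBF payload is exactly 8x the BF payload for equal m
  hdr <- 4 + 4 * 4 + 8 * 2 + 4 + 15
  expect_identical(file.size(path_cbf) - hdr, 8 * (file.size(path_bf) - hdr))
})

test_that("corrupt filter files fail loudly", {
  path <- tempfile()
  bf <- bloom_filter(k = 5, m = 1024)
  save_filter(bf, path)
  # truncation
  raw <- readBin(path, "raw", file.size(path))
  writeBin(raw[1:(length(raw) - 16)], path)
  expect_error(load_filter(path), "truncated")
  # bad magic
  writeBin(as.raw(c(1, 2, 3, 4, raw[-(1:4)])), path)
  expect_error(load_filter(path), "magic")
})
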
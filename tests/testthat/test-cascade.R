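test_that("plan_sizes allocates only the layers the thresholds require", {
  h <- kmer_histogram(c(900, 90, 10))
  # unbounded counts: the output structure is the only one created
  s1 <- plan_sizes(cascade_config(k = 25, c_min = 1, c_max = 255), h)
  expect_false(is.na(s1[["output"]]))
  expect_true(is.na(s1[["global"]]))
  expect_true(is.na(s1[["intermediate"]]))
  # c_min = 2: intermediate CBF omitted, global kept
  s2 <- plan_sizes(cascade_config(k = 25, c_min = 2), h)
  expect_false(is.na(s2[["global"]]))
  expect_true(is.na(s2[["intermediate"]]))
  # c_min = 3 partial sums: global 1000, intermediate 100, output 10
  s3 <- plan_sizes(cascade_config(k = 25, c_min = 3), h)
  n <- attr(s3, "n")
  expect_equal(n[["global"]], 1000)
  expect_equal(n[["intermediate"]], 100)
  expect_equal(n[["output"]], 10)
  expect_equal(s3[["output"]], bf_size_for(10, 0.001, 7))
  expect_error(plan_sizes(cascade_config(k = 25)), "histogram")
})

test_that("a single read counts duplicates but depth collapses them", {
  cfg <- cascade_config(k = 3, c_min = 1, depth = TRUE)
  st <- count_reads("AAAAA", cfg, n_distinct = 100)
  expect_equal(get_count(st, "AAA"), 3)
  expect_equal(get_depth(st, "AAA"), 1)
  expect_equal(get_count(st, "GGG"), 0)
  lg <- store_log(st)
  expect_equal(lg$reads_total, 1)
  expect_equal(lg$windows_total, 3)
})

test_that("cascade counts match the exact oracle above c_min", {
  set.seed(11)
  reads <- vapply(1:200, function(i) random_dna(100), "")
  k <- 21
  oracle <- count_kmers_exact(reads, k = k)
  cfg <- cascade_config(k = k, c_min = 2, c_max = 255, e = 1e-6, depth = TRUE)
  st <- count_reads(reads, cfg, n_distinct = nrow(oracle))
  rep2 <- get_count(st, oracle$kmer)
  expect_true(all(rep2[oracle$count >= 2] == oracle$count[oracle$count >= 2]))
  expect_true(all(rep2[oracle$count < 2] == 0))
  # depth matches the per-read-membership oracle and never exceeds count
  dep <- get_depth(st, oracle$kmer)
  keep <- oracle$count >= 2
  expect_equal(dep[keep], oracle$depth[keep])
  expect_true(all(dep <= oracle$count))     # depth never exceeds occurrences
})

test_that("k-mers crossing c_max are removed and remembered", {
  cfg <- cascade_config(k = 5, c_min = 1, c_max = 3, secondary = TRUE)
  st <- count_reads(rep("ACGTC", 5), cfg, n_distinct = 1000)
  expect_equal(get_count(st, "ACGTC"), 0)
  expect_true(kspect:::cpp_cascade_secondary(st$ptr, "ACGTC"))
  # later occurrences do not resurrect it
  kspect:::cpp_cascade_process(st$ptr, rep("ACGTC", 3))
  expect_equal(get_count(st, "ACGTC"), 0)
  # a k-mer below the threshold is reported normally
  st2 <- count_reads(c(rep("ACGTC", 3), "GGGTA"), cfg, n_distinct = 1000)
  expect_equal(get_count(st2, "ACGTC"), 3)
  expect_equal(get_count(st2, "GGGTA"), 1)
})

test_that("reported counts never undercount without c_max removals", {
  set.seed(12)
  reads <- vapply(1:60, function(i) random_dna(80), "")
  oracle <- count_kmers_exact(reads, k = 15)
  # deliberately undersized filters: errors are overcounts only
  cfg <- cascade_config(k = 15, c_min = 1, c_max = 255)
  st <- count_reads(reads, cfg, sizes = list(output = 4096))
  rep_counts <- get_count(st, oracle$kmer)
  expect_true(all(rep_counts >= oracle$count))
})

test_that("depth counts reads, not occurrences", {
  x <- "ACGTCGGTACC"                 # k = 11 k-mer of interest
  spacer <- "TTTTTTTTTTT"
  cfg <- cascade_config(k = 11, c_min = 1, depth = TRUE)
  # twice in one read, once in three others: count 5, depth 4
  reads <- c(paste0(x, spacer, x), x, x, x)
  st <- count_reads(reads, cfg, n_distinct = 1000)
  expect_equal(get_count(st, x), 5)
  expect_equal(get_depth(st, x), 4)
  expect_error(get_depth(count_reads(x, cascade_config(k = 11),
                                     n_distinct = 10), x),
               "depth")
})

test_that("TSV export enumerates thresholded k-mers via a second pass", {
  set.seed(13)
  # repeated reads guarantee multiplicities on both sides of c_min
  reads <- c(rep(vapply(1:10, function(i) random_dna(60), ""), each = 3),
             vapply(1:5, function(i) random_dna(60), ""))
  k <- 13
  oracle <- count_kmers_exact(reads, k = k)
  cfg <- cascade_config(k = k, c_min = 2, c_max = 255, e = 1e-6, depth = TRUE)
  st <- count_reads(reads, cfg, n_distinct = nrow(oracle))
  path <- tempfile(fileext = ".tsv")
  df <- export_kmer_counts(st, reads, path = path)
  back <- read.delim(path)
  expect_equal(nrow(back), sum(oracle$count >= 2))
  merged <- merge(back, oracle, by = "kmer")
  expect_equal(merged$count.x, merged$count.y)
  expect_equal(merged$depth.x, merged$depth.y)
  # a store with nothing past threshold exports a header-only file
  st0 <- count_reads("ACGTACGTACGTAC", cascade_config(k = 13, c_min = 5),
                     n_distinct = 100)
  export_kmer_counts(st0, "ACGTACGTACGTAC", path = path)
  expect_equal(nrow(read.delim(path)), 0)
})

test_that("reads shorter than k and non-ACGT windows are tallied, not fatal", {
  cfg <- cascade_config(k = 9)
  st <- count_reads(c("ACG", "ACGTNACGTACGTACGTA"), cfg, n_distinct = 100)
  lg <- store_log(st)
  expect_equal(lg$reads_short, 1)
  expect_equal(lg$windows_total, 5)  # only the post-N stretch yields windows
  expect_equal(lg$windows_skipped, 5)
  expect_true(is.na(get_count(st, "ACGTNACGT")))
})

test_that("configuration contracts are enforced", {
  expect_error(cascade_config(k = 5, c_min = 0), "c_min")
  expect_error(cascade_config(k = 5, c_min = 5, c_max = 4), "c_min")
  expect_error(cascade_config(k = 5, c_max = 300), "cap")
  expect_error(cascade_config(k = 5, e = 0), "error rate")
  expect_error(cascade_config(k = 5, c_max = 100, output = "membership"),
               "membership")
  # membership output stores presence of k-mers that crossed c_min
  cfg <- cascade_config(k = 3, c_min = 2, output = "membership")
  st <- count_reads(c("AAAA", "CCCC"), cfg, n_distinct = 10)
  expect_true(store_contains(st, "AAA"))   # 2 occurrences within one read
  expect_true(store_contains(st, "CCC"))
  expect_false(store_contains(st, "GAG"))
})
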
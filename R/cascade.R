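#' Configuration for the counting cascade
#'
#' The cascade counts canonical k-mers (or spaced seeds) while filtering on
#' occurrence thresholds: a k-mer is retained only once observed at least
#' `c_min` times, and is removed again (optionally remembered in a secondary
#' filter) once its reported count would exceed `c_max`. Filter sizes derive
#' from the Bloom filter false-positive rate formula at target error rate `e`
#' with a fixed `h = 7` hash functions per k-mer.
#'
#' @param k K-mer length.
#' @param mask Optional spaced-seed mask (string or [spaced_seed()]).
#' @param c_min Minimum occurrence threshold (default 1).
#' @param c_max Maximum occurrence threshold (default 255, the counter cap at
#'   the default 8-bit width).
#' @param e Target false-positive (error) rate used for sizing, default 0.001.
#' @param output `"counts"` for a counting Bloom filter holding counts, or
#'   `"membership"` for a plain Bloom filter (8x smaller) recording only
#'   which k-mers passed `c_min`. Membership output requires an unbounded
#'   `c_max` (the counter cap), since crossings cannot be detected.
#' @param depth If `TRUE`, simultaneously track each k-mer's depth: the
#'   number of reads containing it at least once.
#' @param secondary If `TRUE`, k-mers crossing `c_max` are recorded in a
#'   secondary Bloom filter so later occurrences are ignored.
#' @param width Counter width in bits (default 8; caps counters at 255).
#' @return An object of class `cascade_config`.
#' @export
cascade_config <- function(k = NULL, mask = NULL, c_min = 1, c_max = NULL,
                           e = 0.001, output = c("counts", "membership"),
                           depth = FALSE, secondary = FALSE, width = 8L) {
  sm <- as_seed(k, mask)
  output <- match.arg(output)
  cap <- 2^width - 1
  if (is.null(c_max)) c_max <- cap
  if (c_min < 1 || c_min > c_max)
    stop("thresholds must satisfy 1 <= c_min <= c_max")
  if (c_max > cap)
    stop("c_max must not exceed the counter cap 2^width - 1 = ", cap)
  if (e <= 0 || e >= 1) stop("error rate e must be in (0, 1)")
  if (output == "membership" && c_max < cap)
    stop("membership output cannot enforce a finite c_max; use output = 'counts'")
  structure(list(k = sm$k, mask = sm$mask, seed = sm, c_min = c_min,
                 c_max = c_max, e = e, h = 7L, output = output, depth = depth,
                 secondary = secondary, width = width),
            class = "cascade_config")
}

#' @export
print.cascade_config <- function(x, ...) {
  cat(sprintf(
    "cascade config: k = %d, c_min = %g, c_max = %g, e = %g, output = %s%s\n",
    x$k, x$c_min, x$c_max, x$e, x$output,
    if (x$depth) " (+depth)" else ""))
  if (!x$seed$plain) cat("  mask:", x$mask, "\n")
  invisible(x)
}

#' Plan cascade filter sizes from a k-mer count histogram
#'
#' Each layer is sized for the number of distinct k-mers expected to reach
#' it: the global Bloom filter for all distinct k-mers (sum of h_i), the
#' intermediate counting filter for those seen at least twice, the output
#' structure for those reaching `c_min`, and the secondary filter for those
#' crossing `c_max`. Sizes come from [bf_size_for()] at the configured error
#' rate with 7 hash functions. Layers the thresholds make redundant are not
#' allocated: no global filter when `c_min == 1`, no intermediate filter when
#' `c_min <= 2`, so with unbounded counts the output structure is the only
#' one created.
#'
#' @param config A [cascade_config()].
#' @param histogram A [kmer_histogram()] (or `NULL` if `n_distinct` given).
#' @param n_distinct Alternative to a histogram: a single number of distinct
#'   k-mers used for every layer (conservative), or a named vector with any
#'   of `global`, `intermediate`, `output`, `secondary`, `depth`.
#' @return Named list of filter sizes in bits/counters (`NA` for layers not
#'   allocated), with the expected insertions as attribute `"n"`.
#' @export
plan_sizes <- function(config, histogram = NULL, n_distinct = NULL) {
  stopifnot(inherits(config, "cascade_config"))
  layers <- c("global", "intermediate", "output", "secondary", "depth")
  if (!is.null(histogram)) {
    stopifnot(inherits(histogram, "kmer_histogram"))
    h <- histogram$h
    idx <- seq_along(h)
    n <- c(global = sum(h),
           intermediate = sum(h[idx >= 2]),
           output = sum(h[idx >= config$c_min]),
           secondary = sum(h[idx > config$c_max]),
           depth = sum(h))
  } else if (!is.null(n_distinct)) {
    if (is.null(names(n_distinct))) {
      stopifnot(length(n_distinct) == 1L)
      n <- setNames(rep(as.numeric(n_distinct), 5L), layers)
    } else {
      n <- setNames(rep(NA_real_, 5L), layers)
      n[names(n_distinct)] <- n_distinct
    }
  } else {
    stop("supply a histogram or explicit n_distinct estimates ",
         "so that filter sizes can be derived")
  }
  need <- c(global = config$c_min >= 2,
            intermediate = config$c_min >= 3,
            output = TRUE,
            secondary = config$secondary,
            depth = config$depth)
  sizes <- setNames(rep(NA_real_, 5L), layers)
  for (nm in layers) {
    if (!need[[nm]]) next
    if (is.na(n[[nm]]))
      stop("no size estimate available for the '", nm, "' layer")
    sizes[[nm]] <- bf_size_for(max(n[[nm]], 1), config$e, config$h)
  }
  attr(sizes, "n") <- n
  sizes
}

#' Count k-mers through the Bloom filter cascade
#'
#' Streams reads through the layered filters: the first occurrence of a
#' k-mer sets the global Bloom filter, occurrences 2..c_min-1 increment the
#' intermediate counting filter, and from the c_min-th occurrence onward the
#' output structure is incremented, so the reported count is the output
#' counter plus c_min - 1. A k-mer whose reported count would exceed `c_max`
#' is removed by decrementing its own reported value from its counters
#' (and remembered in the secondary filter when enabled). With depth
#' enabled, a per-read scratch Bloom filter (sized for L - k + 1 insertions
#' at false-positive rate 1e-4) deduplicates within-read occurrences so a
#' global counting filter accumulates each k-mer's read count.
#'
#' Processing is single-threaded and in input order, hence deterministic.
#' Reads shorter than k and windows containing non-ACGT bases are skipped
#' and tallied in the store's log.
#'
#' @param reads Character vector of read sequences, a data frame with a
#'   `seq` column (as returned by [read_sequences()]), or a path to a
#'   FASTA/FASTQ file (optionally gzipped).
#' @param config A [cascade_config()].
#' @param histogram,n_distinct Sizing inputs passed to [plan_sizes()].
#' @param sizes Explicit sizes (named list/vector), bypassing [plan_sizes()].
#' @return An object of class `count_store`.
#' @examples
#' cfg <- cascade_config(k = 3)
#' st <- count_reads("AAAAA", cfg, n_distinct = 100)
#' get_count(st, "AAA")  # 3
#' @export
count_reads <- function(reads, config, histogram = NULL, n_distinct = NULL,
                        sizes = NULL) {
  stopifnot(inherits(config, "cascade_config"))
  reads <- as_read_seqs(reads)
  if (is.null(sizes)) sizes <- plan_sizes(config, histogram, n_distinct)
  sizes <- as.list(sizes)
  # per-read scratch filter: well below the store's target error rate so
  # depth extraction stays exact for practical purposes
  read_fpr <- min(1e-4, config$e * 1e-3)
  ptr <- cpp_cascade_new(config$mask, config$h, config$c_min, config$c_max,
                         config$width, config$output == "counts",
                         config$depth, config$secondary, sizes, read_fpr)
  cpp_cascade_process(ptr, reads)
  structure(list(ptr = ptr, config = config, sizes = sizes),
            class = "count_store")
}

#' @export
print.count_store <- function(x, ...) {
  lg <- store_log(x)
  cat(sprintf("count store: k = %d, c_min = %g, c_max = %g, e = %g\n",
              x$config$k, x$config$c_min, x$config$c_max, x$config$e))
  cat(sprintf("  reads: %.0f (%.0f shorter than k), k-mers: %.0f (%.0f skipped)\n",
              lg$reads_total, lg$reads_short, lg$windows_total,
              lg$windows_skipped))
  if (x$config$depth) cat("  depth extraction enabled\n")
  invisible(x)
}

#' Query reported counts, depths and run metadata
#'
#' `get_count()` reports 0 for k-mers below `c_min` or filtered above
#' `c_max`, otherwise the output counter plus c_min - 1. `get_depth()`
#' reports the number of reads containing the k-mer (requires counting with
#' `depth = TRUE`). `store_log()` returns filter sizes and skip tallies.
#'
#' @param store A `count_store` from [count_reads()].
#' @param kmers Character vector of k-mers; windows with non-ACGT bases give
#'   `NA`.
#' @return Numeric vector of counts/depths, or a list of log entries.
#' @export
get_count <- function(store, kmers) {
  stopifnot(inherits(store, "count_store"))
  if (store$config$output != "counts")
    stop("this store holds membership only; use store_contains()")
  cpp_cascade_count(store$ptr, as.character(kmers))
}

#' @rdname get_count
#' @export
get_depth <- function(store, kmers) {
  stopifnot(inherits(store, "count_store"))
  if (!store$config$depth)
    stop("depth extraction was not enabled; rerun count_reads() with depth = TRUE")
  cpp_cascade_depth(store$ptr, as.character(kmers))
}

#' @rdname get_count
#' @export
store_contains <- function(store, kmers) {
  stopifnot(inherits(store, "count_store"))
  if (store$config$output == "counts")
    return(get_count(store, kmers) > 0)
  cpp_cascade_count(store$ptr, as.character(kmers)) > 0
}

#' @rdname get_count
#' @export
store_log <- function(store) {
  stopifnot(inherits(store, "count_store"))
  c(cpp_cascade_log(store$ptr),
    list(e = store$config$e, h = store$config$h))
}

#' Export k-mer counts as TSV
#'
#' Bloom filters cannot enumerate their contents, so export takes a second
#' pass over a k-mer source (typically the very reads that were counted),
#' emitting one row per distinct canonical k-mer whose reported count passes
#' the thresholds. Intended for modest inputs; counts for large runs should
#' be queried directly.
#'
#' @param store A `count_store`.
#' @param reads K-mer source (same forms as in [count_reads()]).
#' @param path Optional file path; when given, a tab-separated file with a
#'   header row is written.
#' @return Data frame with columns `kmer`, `count` and, when depth was
#'   enabled, `depth` (invisibly when `path` is given).
#' @export
export_kmer_counts <- function(store, reads, path = NULL) {
  stopifnot(inherits(store, "count_store"))
  reads <- as_read_seqs(reads)
  res <- cpp_cascade_export(store$ptr, reads)
  df <- data.frame(kmer = res$kmer, count = res$count)
  if (store$config$depth) df$depth <- res$depth
  df <- df[order(df$kmer), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Exact dictionary k-mer counter
#'
#' A reference counter that tracks every distinct canonical k-mer (and its
#' depth) in an exact hash map: the independent oracle against which the
#' probabilistic cascade is validated. Memory grows with the number of
#' distinct k-mers, so this is for validation, not production counting.
#'
#' @inheritParams count_reads
#' @param k K-mer length.
#' @param mask Optional spaced-seed mask.
#' @return Data frame with `kmer` (canonical care string), `count`, `depth`.
#' @export
count_kmers_exact <- function(reads, k = NULL, mask = NULL) {
  sm <- as_seed(k, mask)
  reads <- as_read_seqs(reads)
  res <- cpp_count_kmers_exact(reads, sm$mask)
  df <- data.frame(kmer = res$kmer, count = res$count, depth = res$depth)
  df <- df[order(df$kmer), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Compare cascade counts with the exact oracle
#'
#' Enumerates every distinct canonical k-mer of `reads`, computes its exact
#' count, queries the store, and summarizes agreement.
#'
#' @param store A `count_store` built from these reads.
#' @param reads The same read set (character vector, data frame, or path).
#' @return List with `n_distinct`, `n_match`, `accuracy` (fraction of
#'   distinct k-mers whose reported count is exact), and the paired
#'   `true_count` / `reported_count` vectors.
#' @export
compare_with_oracle <- function(store, reads) {
  stopifnot(inherits(store, "count_store"))
  reads <- as_read_seqs(reads)
  res <- cpp_cascade_compare(store$ptr, reads)
  n <- length(res$true_count)
  match <- sum(res$true_count == res$reported_count)
  list(n_distinct = n, n_match = match, accuracy = match / n,
       true_count = res$true_count, reported_count = res$reported_count)
}

# accept a character vector, read data frame, or file path
as_read_seqs <- function(reads) {
  if (is.data.frame(reads)) {
    if (!"seq" %in% names(reads)) stop("read data frame must have a 'seq' column")
    return(as.character(reads$seq))
  }
  if (is.character(reads) && length(reads) == 1L && file.exists(reads) &&
      !grepl("^[ACGTNacgtn]+$", reads))
    return(read_sequences(reads)$seq)
  as.character(reads)
}
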
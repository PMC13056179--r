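#' Bloom filter size for a target false-positive rate
#'
#' Returns the smallest bit-array size m such that the Bloom filter
#' false-positive rate formula \eqn{(1 - e^{-hn/m})^h} does not exceed `fpr`
#' after `n` insertions with `h` hash functions.
#'
#' @param n Expected number of inserted elements (>= 1).
#' @param fpr Target false-positive rate, in (0, 1).
#' @param h Number of hash functions (default 7).
#' @return Size in bits (numeric; may exceed `.Machine$integer.max`).
#' @examples
#' bf_size_for(1e6, 0.001)
#' @export
bf_size_for <- function(n, fpr, h = 7L) {
  stopifnot(n >= 1)
  if (!is.numeric(fpr) || fpr <= 0 || fpr >= 1)
    stop("fpr must be in (0, 1)")
  cpp_bf_size_for(as.numeric(n), fpr, as.integer(h))
}

new_filter <- function(ptr, type, k, mask, h, width = NULL) {
  structure(list(ptr = ptr, type = type, k = k, mask = mask, h = h,
                 width = width),
            class = c(paste0(type, "_filter"), "kmer_filter"))
}

resolve_m <- function(m, n, fpr, h) {
  if (is.null(m)) {
    if (is.null(n) || is.null(fpr))
      stop("supply either m, or n and fpr for automatic sizing")
    m <- bf_size_for(n, fpr, h)
  }
  m
}

#' Bloom filter over canonical k-mers
#'
#' A plain Bloom filter: a bit array of m positions addressed by h hash
#' values per element. Queries have no false negatives; false positives occur
#' at a rate governed by the sizing formula (see [bf_size_for()]). Filters
#' have reference semantics: `bf_insert()` modifies the filter in place and
#' returns it invisibly.
#'
#' @param k K-mer length (or `NULL` when `mask` is given).
#' @param m Number of bit positions (rounded up to a multiple of 64).
#'   Alternatively give `n` and `fpr` for automatic sizing.
#' @param n,fpr Expected insertions and target false-positive rate.
#' @param h Number of hash functions (default 7).
#' @param mask Optional spaced-seed mask.
#' @return An object of class `bloom_filter`.
#' @examples
#' bf <- bloom_filter(k = 5, n = 100, fpr = 0.01)
#' bf_insert(bf, c("ACGTG", "TTTTT"))
#' bf_contains(bf, c("ACGTG", "CACGT", "AAAAA"))
#' @export
bloom_filter <- function(k = NULL, m = NULL, n = NULL, fpr = NULL, h = 7L,
                         mask = NULL) {
  sm <- as_seed(k, mask)
  m <- resolve_m(m, n, fpr, h)
  new_filter(cpp_bf_new(as.numeric(m), as.integer(h)), "bloom",
             sm$k, sm$mask, as.integer(h))
}

#' @param bf A [bloom_filter()].
#' @param kmers Character vector of k-mers (length k each).
#' @rdname bloom_filter
#' @export
bf_insert <- function(bf, kmers) {
  stopifnot(inherits(bf, "bloom_filter"))
  cpp_bf_insert(bf$ptr, as.character(kmers), bf$mask, bf$h)
  invisible(bf)
}

#' @rdname bloom_filter
#' @export
bf_contains <- function(bf, kmers) {
  stopifnot(inherits(bf, "bloom_filter"))
  cpp_bf_contains(bf$ptr, as.character(kmers), bf$mask, bf$h)
}

#' Counting Bloom filter with minimum-selection queries
#'
#' Stores fixed-width unsigned counters (default 8 bits, so counters saturate
#' at 255 and never wrap). A query reports the minimum of the h addressed
#' counters. Increments follow the minimal-increase rule: only the counters
#' currently at that minimum are bumped, which reduces overestimation.
#' Decrements clamp at zero. Without decrements the reported count is always
#' greater than or equal to the true multiplicity.
#'
#' @inheritParams bloom_filter
#' @param width Counter width in bits (default 8).
#' @return An object of class `counting_filter`.
#' @examples
#' cbf <- counting_bloom_filter(k = 5, n = 100, fpr = 0.01)
#' cbf_increment(cbf, rep("ACGTG", 3))
#' cbf_count(cbf, "ACGTG")
#' @export
counting_bloom_filter <- function(k = NULL, m = NULL, n = NULL, fpr = NULL,
                                  h = 7L, width = 8L, mask = NULL) {
  sm <- as_seed(k, mask)
  m <- resolve_m(m, n, fpr, h)
  new_filter(cpp_cbf_new(as.numeric(m), as.integer(h), as.integer(width)),
             "counting", sm$k, sm$mask, as.integer(h), as.integer(width))
}

#' @param cbf A [counting_bloom_filter()].
#' @param kmers Character vector of k-mer occurrences (repeats allowed).
#' @rdname counting_bloom_filter
#' @export
cbf_increment <- function(cbf, kmers) {
  stopifnot(inherits(cbf, "counting_filter"))
  cpp_cbf_increment(cbf$ptr, as.character(kmers), cbf$mask, cbf$h)
  invisible(cbf)
}

#' @param amount Positive integer subtracted from each addressed counter
#'   (clamped at zero).
#' @rdname counting_bloom_filter
#' @export
cbf_decrement <- function(cbf, kmers, amount = 1) {
  stopifnot(inherits(cbf, "counting_filter"), amount >= 1)
  cpp_cbf_decrement(cbf$ptr, as.character(kmers), cbf$mask, cbf$h,
                    as.numeric(amount))
  invisible(cbf)
}

#' @rdname counting_bloom_filter
#' @export
cbf_count <- function(cbf, kmers) {
  stopifnot(inherits(cbf, "counting_filter"))
  cpp_cbf_count(cbf$ptr, as.character(kmers), cbf$mask, cbf$h)
}

#' @export
print.kmer_filter <- function(x, ...) {
  info <- filter_info(x)
  cat(sprintf("%s filter: m = %.0f, h = %d, k = %d%s, inserts = %.0f\n",
              x$type, info$m, info$h, x$k,
              if (!is.null(x$width)) sprintf(", width = %d bits", x$width) else "",
              info$n_inserted))
  if (x$mask != strrep("1", x$k)) cat("  mask:", x$mask, "\n")
  invisible(x)
}

#' Filter metadata
#'
#' @param x A `bloom_filter` or `counting_filter`.
#' @return List with `m`, `h`, `n_inserted` and, for counting filters,
#'   `width` and `cap`.
#' @export
filter_info <- function(x) {
  stopifnot(inherits(x, "kmer_filter"))
  if (x$type == "bloom") cpp_bf_info(x$ptr) else cpp_cbf_info(x$ptr)
}

FILTER_MAGIC <- c(bloom = "KSPB", counting = "KSPC")
FILTER_VERSION <- 1L

#' Serialize filters to disk
#'
#' The file layout is: 4-byte magic (`KSPB` for Bloom filters, `KSPC` for
#' counting filters), int32 format version, int32 k, int32 h, int32 counter
#' width (0 for plain filters), double m, double insert count, int32 mask
#' length, the mask characters, then the payload: packed bits (1 bit per
#' position) for a Bloom filter, one byte per counter for the default 8-bit
#' counting filter. All integers little-endian.
#'
#' @param x A `bloom_filter` or `counting_filter`.
#' @param path File path.
#' @return `save_filter()` returns `path` invisibly; `load_filter()` returns
#'   the reconstructed filter.
#' @export
save_filter <- function(x, path) {
  stopifnot(inherits(x, "kmer_filter"))
  info <- filter_info(x)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(FILTER_MAGIC[[x$type]]), con)
  writeBin(c(FILTER_VERSION, x$k, x$h,
             if (x$type == "counting") x$width else 0L), con,
           size = 4L, endian = "little")
  writeBin(c(info$m, info$n_inserted), con, endian = "little")
  writeBin(nchar(x$mask), con, size = 4L, endian = "little")
  writeBin(charToRaw(x$mask), con)
  payload <- if (x$type == "bloom") cpp_bf_payload(x$ptr)
             else cpp_cbf_payload(x$ptr)
  writeBin(payload, con)
  invisible(path)
}

#' @rdname save_filter
#' @export
load_filter <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!magic %in% FILTER_MAGIC)
    stop("not a kspect filter file (bad magic): ", path)
  type <- names(FILTER_MAGIC)[match(magic, FILTER_MAGIC)]
  hdr <- readBin(con, "integer", 4L, size = 4L, endian = "little")
  if (length(hdr) < 4L) stop("truncated filter file: ", path)
  if (hdr[1] != FILTER_VERSION)
    stop("unsupported filter format version: ", hdr[1])
  k <- hdr[2]; h <- hdr[3]; width <- hdr[4]
  dbl <- readBin(con, "double", 2L, endian = "little")
  masklen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (length(dbl) < 2L || length(masklen) < 1L)
    stop("truncated filter file: ", path)
  mask <- rawToChar(readBin(con, "raw", masklen))
  m <- dbl[1]; n_ins <- dbl[2]
  expect <- if (type == "bloom") m / 8 else if (width <= 8) m else m * 4
  payload <- readBin(con, "raw", expect)
  if (length(payload) != expect) stop("truncated filter file: ", path)
  if (type == "bloom")
    new_filter(cpp_bf_from_payload(payload, m, h, n_ins), "bloom", k, mask, h)
  else
    new_filter(cpp_cbf_from_payload(payload, m, h, width, n_ins), "counting",
               k, mask, h, width)
}
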
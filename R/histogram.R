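#' K-mer count histograms
#'
#' A counts-of-counts histogram (h_1, ..., h_c): h_i is the number of
#' distinct k-mers occurring exactly i times in the data, and c is the
#' largest count present.
#'
#' @param h Numeric vector of non-negative bin values; element i is h_i.
#'   A named vector with integer names is densified onto 1..max(i).
#' @param F0,F1 Optional metadata carried by ntCard-style profiles: the
#'   number of distinct k-mers (F0) and total k-mer occurrences (F1). When
#'   omitted they are computed from `h`.
#' @return Object of class `kmer_histogram` with fields `h`, `c`,
#'   `total_distinct`, `total_occurrences`, `F0`, `F1`.
#' @examples
#' kmer_histogram(c(6, 3, 1))
#' @export
kmer_histogram <- function(h, F0 = NULL, F1 = NULL) {
  if (!is.null(names(h))) {
    idx <- suppressWarnings(as.integer(names(h)))
    if (anyNA(idx) || any(idx < 1)) stop("histogram names must be counts >= 1")
    dense <- numeric(max(idx))
    dense[idx] <- as.numeric(h)
    h <- dense
  }
  h <- as.numeric(h)
  if (length(h) < 1) stop("histogram must have at least one bin")
  if (any(h < 0) || anyNA(h)) stop("histogram bins must be non-negative")
  # drop trailing empty bins so c is the maximum observed count
  cmax <- max(c(1L, which(h > 0)))
  h <- h[seq_len(cmax)]
  structure(list(h = h, c = cmax,
                 total_distinct = sum(h),
                 total_occurrences = sum(seq_along(h) * h),
                 F0 = if (is.null(F0)) sum(h) else as.numeric(F0),
                 F1 = if (is.null(F1)) sum(seq_along(h) * h) else as.numeric(F1)),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf(
    "k-mer count histogram: c = %d, %.5g distinct k-mers, %.5g occurrences\n",
    x$c, x$total_distinct, x$total_occurrences))
  invisible(x)
}

#' Read and write ntCard-style histogram files
#'
#' The dialect is two whitespace-separated columns: rows whose first token
#' is a positive integer i carry h_i; rows keyed `F0`/`F1` carry metadata;
#' other keys are skipped with a warning.
#'
#' @param path Path to a histogram text file.
#' @return A [kmer_histogram()].
#' @export
read_histogram <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty histogram file: ", path)
  parts <- strsplit(trimws(lines), "[ \t]+")
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) stop("malformed histogram line: ", lines[which(bad)[1]])
  key <- vapply(parts, `[[`, "", 1L)
  val <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(val)) stop("non-numeric histogram value in: ", path)
  idx <- suppressWarnings(as.integer(key))
  is_bin <- !is.na(idx) & idx >= 1
  meta <- key %in% c("F0", "F1")
  unknown <- !is_bin & !meta
  if (any(unknown))
    warning("skipping unrecognized histogram rows: ",
            paste(unique(key[unknown]), collapse = ", "))
  if (!any(is_bin)) stop("no count rows (integer first column) in: ", path)
  if (any(val[is_bin] < 0)) stop("negative histogram values in: ", path)
  kmer_histogram(setNames(val[is_bin], idx[is_bin]),
                 F0 = if ("F0" %in% key) val[key == "F0"][1],
                 F1 = if ("F1" %in% key) val[key == "F1"][1])
}

#' @param hist A [kmer_histogram()].
#' @rdname read_histogram
#' @export
write_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "kmer_histogram"))
  lines <- c(sprintf("F0\t%.10g", hist$F0),
             sprintf("F1\t%.10g", hist$F1),
             sprintf("%d\t%.10g", seq_along(hist$h), hist$h))
  writeLines(lines, path)
  invisible(path)
}

#' Histogram from exact counts
#'
#' `histogram_from_counts()` tabulates a vector of per-k-mer counts;
#' `exact_histogram()` computes the exact histogram of a read set directly
#' (k <= 32), the in-package stand-in for an ntCard profile.
#'
#' @param counts Integer vector of per-k-mer multiplicities (>= 1).
#' @return A [kmer_histogram()].
#' @export
histogram_from_counts <- function(counts) {
  counts <- counts[!is.na(counts) & counts >= 1]
  if (length(counts) == 0) stop("no positive counts supplied")
  kmer_histogram(tabulate(as.integer(counts)))
}

#' @inheritParams count_reads
#' @param k K-mer length (at most 32).
#' @rdname histogram_from_counts
#' @export
exact_histogram <- function(reads, k) {
  reads <- as_read_seqs(reads)
  res <- cpp_exact_histogram(reads, as.integer(k))
  kmer_histogram(res$h)
}

#' Jensen-Shannon similarity between histograms
#'
#' Histograms are normalized to probability distributions over the union of
#' their supports; the similarity is 1 minus the Jensen-Shannon divergence
#' (base-2 logarithm, so the divergence lies in \[0, 1\]). Identical
#' normalized histograms give 1; histograms with disjoint support give 0.
#'
#' @param a,b [kmer_histogram()] objects (or plain numeric bin vectors).
#' @return Similarity in \[0, 1\]; symmetric in its arguments.
#' @export
histogram_similarity <- function(a, b) {
  ha <- if (inherits(a, "kmer_histogram")) a$h else as.numeric(a)
  hb <- if (inherits(b, "kmer_histogram")) b$h else as.numeric(b)
  if (sum(ha) <= 0 || sum(hb) <= 0) stop("histograms must be non-empty")
  n <- max(length(ha), length(hb))
  p <- c(ha, numeric(n - length(ha))) / sum(ha)
  q <- c(hb, numeric(n - length(hb))) / sum(hb)
  m <- (p + q) / 2
  kl <- function(x, y) {
    i <- x > 0
    sum(x[i] * log2(x[i] / y[i]))
  }
  jsd <- 0.5 * kl(p, m) + 0.5 * kl(q, m)
  1 - max(0, min(1, jsd))
}
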
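#' Spaced-seed pattern
#'
#' A spaced seed (gapped k-mer) is a binary mask over a length-k window:
#' positions marked `1` ("care") contribute to hashing, positions marked `0`
#' are ignored. The all-ones mask is an ordinary k-mer.
#'
#' @param mask A string over `{0,1}`, e.g. `"1110111"`. Alternatively an
#'   integer `k`, which is expanded to the all-ones mask of that length.
#' @return An object of class `spaced_seed` with fields `mask`, `k` (mask
#'   length) and `weight` (number of care positions).
#' @examples
#' spaced_seed("1101011")
#' spaced_seed(25)  # plain 25-mer
#' @export
spaced_seed <- function(mask) {
  if (is.numeric(mask)) {
    k <- as.integer(mask)
    stopifnot(k >= 1)
    mask <- strrep("1", k)
  }
  stopifnot(is.character(mask), length(mask) == 1L, nchar(mask) >= 1L)
  chars <- strsplit(mask, "")[[1]]
  if (!all(chars %in% c("0", "1")))
    stop("mask must be a string over {0,1}")
  w <- sum(chars == "1")
  if (w == 0L) stop("mask must have at least one care (1) position")
  structure(list(mask = mask, k = nchar(mask), weight = w,
                 plain = w == nchar(mask)),
            class = "spaced_seed")
}

#' @export
print.spaced_seed <- function(x, ...) {
  cat(sprintf("spaced seed: %s (k = %d, weight = %d%s)\n", x$mask, x$k,
              x$weight, if (x$plain) ", plain k-mer" else ""))
  invisible(x)
}

as_seed <- function(k, mask = NULL) {
  if (inherits(mask, "spaced_seed")) {
    if (!is.null(k) && k != mask$k)
      stop("k (", k, ") does not match the mask length (", mask$k, ")")
    return(mask)
  }
  if (!is.null(mask)) {
    s <- spaced_seed(mask)
    if (!is.null(k) && k != s$k)
      stop("k (", k, ") does not match the mask length (", s$k, ")")
    return(s)
  }
  if (is.null(k)) stop("supply k or a spaced-seed mask")
  spaced_seed(k)
}

#' Reverse complement
#'
#' @param x Character vector of DNA strings (non-ACGT bases become `N`).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) cpp_revcomp(as.character(x))

#' Canonical form of k-mers
#'
#' The canonical form is the lexicographically smaller of the care-position
#' string and its reverse complement, so a k-mer and its reverse complement
#' (with the reversed mask) collapse to the same representative.
#'
#' @param x Character vector of k-mers, all of the mask's length.
#' @param k K-mer length (used when `mask` is `NULL`).
#' @param mask Optional spaced-seed mask (string or [spaced_seed()]).
#' @return Character vector of canonical (care-position) strings; `NA` for
#'   windows containing non-ACGT bases.
#' @export
canonical_kmer <- function(x, k = NULL, mask = NULL) {
  sm <- as_seed(if (is.null(k) && is.null(mask)) nchar(x[1]) else k, mask)
  cpp_canonical(as.character(x), sm$mask)
}

#' Multi-valued canonical hashes of k-mer windows
#'
#' `hash_kmer()` hashes a single window from scratch; `kmer_hashes()` slides
#' across a sequence with the rolling engine, emitting the same values for
#' every valid (ACGT-only) window. Hash values are strand-invariant: a window
#' and its reverse complement produce identical tuples. The h values per
#' window are derived from one 64-bit canonical hash by double hashing.
#'
#' Values are returned as 16-character lowercase hex strings (64-bit values
#' do not fit R integers); filter structures consume the native values
#' internally.
#'
#' @param window,seq DNA string (a single window of the mask's length, or a
#'   longer sequence to slide over).
#' @param k K-mer length, when no mask is given.
#' @param mask Optional spaced-seed mask.
#' @param h Number of hash values per k-mer (default 7).
#' @return `hash_kmer()`: character vector of `h` hex values.
#'   `kmer_hashes()`: list with `pos` (0-based window starts) and `hashes`
#'   (matrix, one row per valid window).
#' @examples
#' hash_kmer("ACGT", k = 4)
#' kmer_hashes("ACGTACGTAC", k = 4)
#' @export
hash_kmer <- function(window, k = NULL, mask = NULL, h = 7L) {
  sm <- as_seed(if (is.null(k) && is.null(mask)) nchar(window) else k, mask)
  cpp_hash_kmer(window, sm$mask, as.integer(h))
}

#' @rdname hash_kmer
#' @export
kmer_hashes <- function(seq, k = NULL, mask = NULL, h = 7L) {
  sm <- as_seed(k, mask)
  cpp_hash_windows(seq, sm$mask, as.integer(h))
}

# 64-bit base hash (hex) per k-mer; internal, used by collision tests
base_hashes <- function(kmers, k = NULL, mask = NULL) {
  sm <- as_seed(if (is.null(k) && is.null(mask)) nchar(kmers[1]) else k, mask)
  cpp_base_hashes(as.character(kmers), sm$mask)
}
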
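# shared fixture builders; everything is generated in code under fixed seeds

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

random_kmers <- function(n, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) paste(sample(BASES, k, TRUE), collapse = ""),
         "")
}

# plain-R reverse complement, independent of the package's C++ path
rc_r <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, "", USE.NAMES = FALSE)
}

canon_r <- function(x) pmin(x, rc_r(x))

# brute-force dictionary counter in base R (counts + depths per canonical
# k-mer), the slow oracle used against both C++ counters
oracle_counts_r <- function(reads, k) {
  tab <- new.env(parent = emptyenv())
  dep <- new.env(parent = emptyenv())
  for (rd in reads) {
    if (nchar(rd) < k) next
    wins <- substring(rd, 1:(nchar(rd) - k + 1), k:nchar(rd))
    wins <- wins[!grepl("[^ACGT]", wins)]
    if (length(wins) == 0) next
    wins <- canon_r(wins)
    for (w in wins) assign(w, (if (exists(w, tab)) get(w, tab) else 0) + 1, tab)
    for (w in unique(wins))
      assign(w, (if (exists(w, dep)) get(w, dep) else 0) + 1, dep)
  }
  kms <- sort(ls(tab))
  data.frame(kmer = kms,
             count = vapply(kms, get, 1.0, envir = tab),
             depth = vapply(kms, get, 1.0, envir = dep),
             row.names = NULL)
}

# a small mixture with known components (error + two coupled peaks)
toy_model <- function(w = c(0.7, 0.09, 0.21), rate = 1.2,
                      means = c(10, 20), size = 1e5) {
  mixture_model(list(
    list(family = "exponential", weight = w[1], params = rate),
    list(family = "nbinom", weight = w[2], params = c(means[1], size)),
    list(family = "nbinom", weight = w[3], params = c(means[2], size))))
}

# histogram sampled from a model (multinomial over 1..c)
sampled_histogram <- function(model, n_kmers, c = 60, seed = 1) {
  f <- mixture_pmf(model, c)
  set.seed(seed)
  kmer_histogram(as.numeric(rmultinom(1, n_kmers, f)))
}
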
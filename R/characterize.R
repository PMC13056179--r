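#' Posterior component probabilities for k-mer counts
#'
#' For a count x, the posterior probability that a k-mer with that count
#' came from component c is `w_c f_c(x) / F(x)`. Where F(x) = 0 the
#' posterior is undefined and `NA` is returned.
#'
#' @param model A `kmix` fit or [mixture_model()].
#' @param x Integer counts (>= 1).
#' @param c Support bound; defaults to the fitted histogram's maximum count
#'   (or `max(x)` for a bare model).
#' @return Matrix with one row per count and one column per component;
#'   rows sum to 1 wherever F(x) > 0.
#' @export
posterior_probs <- function(model, x, c = NULL) {
  if (is.null(c))
    c <- if (inherits(model, "kmix")) model$hist$c else max(x)
  c <- max(c, x)
  if (any(x < 1)) stop("counts must be >= 1")
  m <- as_mixture(model)
  mat <- mixture_matrix(m, c)
  f <- rowSums(mat)
  post <- mat / ifelse(f > 0, f, NA_real_)
  out <- post[x, , drop = FALSE]
  rownames(out) <- x
  out
}

#' Classify k-mer counts by maximum posterior
#'
#' Assigns each count the component with the highest posterior probability;
#' ties go to the lower-mean component (error before heterozygous before
#' homozygous). Counts where the posterior is undefined (F(x) = 0) are
#' labelled `unclassified`.
#'
#' @inheritParams posterior_probs
#' @return Factor with the component labels plus `"unclassified"`.
#' @export
classify_kmers <- function(model, x, c = NULL) {
  post <- posterior_probs(model, x, c)
  labs <- colnames(post)
  pick <- apply(post, 1, function(p) {
    if (anyNA(p)) return("unclassified")
    labs[which.max(p)]     # which.max takes the first (lower-mean) on ties
  })
  factor(pick, levels = c(labs, "unclassified"))
}

#' Phred score conversions
#'
#' `phred_from_prob()` maps an error probability to a Phred score
#' Q = -10 log10(P); `prob_from_phred()` inverts it (P = 10^(-Q/10)).
#'
#' @param p Error probabilities in (0, 1].
#' @param q Phred scores (>= 0).
#' @return Numeric vector.
#' @examples
#' phred_from_prob(0.1)  # 10
#' @export
phred_from_prob <- function(p) {
  if (any(p <= 0) || any(p > 1)) stop("probabilities must be in (0, 1]")
  -10 * log10(p)
}

#' @rdname phred_from_prob
#' @export
prob_from_phred <- function(q) {
  if (any(q < 0)) stop("Phred scores must be >= 0")
  10^(-q / 10)
}

#' Count/depth profiles of individual k-mers
#'
#' Combines a store's counts and depths into per-k-mer profiles with the
#' count-to-depth ratio — the genomic analogue of term frequency over
#' document frequency: ratios above 1 flag k-mers that recur within single
#' reads (e.g. across tandem repeats). The aggregate (count, depth) density
#' table used for heatmaps is attached as attribute `"density"`.
#'
#' @param store A `count_store` built with `depth = TRUE`.
#' @param kmers Character vector of k-mers to profile.
#' @param model Optional `kmix` fit; when given, posterior probabilities and
#'   the maximum-posterior label are appended.
#' @return Data frame with `kmer`, `count`, `depth`, `ratio` and optionally
#'   `p_error`/`p_heterozygous`/`p_homozygous`/`label`.
#' @export
count_depth_profile <- function(store, kmers, model = NULL) {
  stopifnot(inherits(store, "count_store"))
  if (!store$config$depth)
    stop("depth extraction was not enabled; rerun count_reads() with depth = TRUE")
  cnt <- get_count(store, kmers)
  dep <- get_depth(store, kmers)
  df <- data.frame(kmer = as.character(kmers), count = cnt, depth = dep,
                   ratio = ifelse(dep > 0, cnt / dep, NA_real_))
  if (!is.null(model)) {
    ok <- !is.na(cnt) & cnt >= 1
    post <- matrix(NA_real_, nrow(df), ncol = model$model$p + 1)
    if (any(ok))
      post[ok, ] <- posterior_probs(model, cnt[ok], c = max(model$hist$c, cnt[ok]))
    colnames(post) <- paste0("p_", names(model$model$components))
    df <- cbind(df, post)
    df$label <- factor(rep("unclassified", nrow(df)),
                       levels = c(names(model$model$components), "unclassified"))
    if (any(ok)) df$label[ok] <- classify_kmers(model, cnt[ok],
                                                c = max(model$hist$c, cnt[ok]))
  }
  ok2 <- !is.na(df$count) & !is.na(df$depth)
  attr(df, "density") <- table(count = df$count[ok2], depth = df$depth[ok2])
  df
}

#' Minimum base quality per k-mer window
#'
#' A single base error corrupts every k-mer covering it, so the minimum
#' Phred score inside a window is a representative quality for that k-mer.
#'
#' @param quals Character vector of Phred+33 quality strings (one per read).
#' @param k Window length.
#' @return List of integer vectors, one per read, with the minimum quality
#'   of each window (empty for reads shorter than k).
#' @export
min_phred_per_kmer <- function(quals, k) {
  lapply(as.character(quals), cpp_min_window_qual, k = as.integer(k))
}
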
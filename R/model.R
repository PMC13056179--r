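ERROR_FAMILIES <- c("exponential", "gamma")
GENOMIC_FAMILIES <- c("normal", "skew_normal", "poisson", "nbinom")

#' Component probability mass over the histogram support
#'
#' Evaluates a component family on the integer support 1..c and renormalizes
#' so the masses sum to 1 (continuous families are evaluated at the integer
#' points). Families and parameters:
#' \describe{
#'   \item{exponential}{`c(rate)` — error component}
#'   \item{gamma}{`c(shape, rate)` — error component}
#'   \item{normal}{`c(mean, sd)`}
#'   \item{skew_normal}{`c(location, scale, shape)`}
#'   \item{poisson}{`c(lambda)`}
#'   \item{nbinom}{`c(mu, size)` — mean/dispersion parameterization}
#' }
#'
#' @param family Family name (see above).
#' @param params Numeric parameter vector for the family.
#' @param c Support bound (maximum count in the histogram).
#' @return Numeric vector of length `c`, non-negative, summing to 1.
#' @examples
#' component_pmf("poisson", 5, 30)
#' @export
component_pmf <- function(family, params, c) {
  x <- seq_len(c)
  d <- switch(family,
    exponential = {
      check_params(params, 1, lower = c(1e-8))
      dexp(x, rate = params[1])
    },
    gamma = {
      check_params(params, 2, lower = c(1e-8, 1e-8))
      dgamma(x, shape = params[1], rate = params[2])
    },
    normal = {
      check_params(params, 2, lower = c(-Inf, 1e-8))
      dnorm(x, mean = params[1], sd = params[2])
    },
    skew_normal = {
      check_params(params, 3, lower = c(-Inf, 1e-8, -Inf))
      z <- (x - params[1]) / params[2]
      2 / params[2] * dnorm(z) * pnorm(params[3] * z)
    },
    poisson = {
      check_params(params, 1, lower = c(1e-8))
      dpois(x, lambda = params[1])
    },
    nbinom = {
      check_params(params, 2, lower = c(1e-8, 1e-8))
      dnbinom(x, mu = params[1], size = params[2])
    },
    stop("unknown component family: ", family)
  )
  s <- sum(d)
  if (!is.finite(s) || s <= 0) rep(1 / c, c) else d / s
}

check_params <- function(params, n, lower) {
  if (length(params) != n)
    stop("expected ", n, " parameter(s), got ", length(params))
  if (anyNA(params) || any(params < lower))
    stop("parameters out of bounds: ", paste(signif(params, 4), collapse = ", "))
  invisible(params)
}

#' Mixture model over a k-mer count histogram
#'
#' F(x) = sum_i w_i f_i(x): an error component (exponential or gamma) plus p
#' genomic components (normal, skew normal, Poisson or negative binomial)
#' ordered by increasing mean — for a diploid genome (p = 2) these are the
#' heterozygous and homozygous peaks.
#'
#' @param components List of components, each a list with `family`, `weight`
#'   and `params` (see [component_pmf()]). The first must use an error
#'   family; the rest genomic families. Weights must sum to 1.
#' @return Object of class `kmer_mixture`.
#' @examples
#' m <- mixture_model(list(
#'   list(family = "exponential", weight = 0.6, params = 1),
#'   list(family = "poisson", weight = 0.1, params = 8),
#'   list(family = "poisson", weight = 0.3, params = 16)))
#' @export
mixture_model <- function(components) {
  stopifnot(is.list(components), length(components) >= 2L)
  w <- vapply(components, function(cc) cc$weight, 1.0)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-6)
    stop("component weights must be non-negative and sum to 1")
  if (!components[[1]]$family %in% ERROR_FAMILIES)
    stop("first component must be an error family (",
         paste(ERROR_FAMILIES, collapse = ", "), ")")
  for (cc in components[-1])
    if (!cc$family %in% GENOMIC_FAMILIES)
      stop("genomic components must be one of ",
           paste(GENOMIC_FAMILIES, collapse = ", "))
  p <- length(components) - 1L
  names(components) <- if (p == 2) c("error", "heterozygous", "homozygous")
                       else c("error", paste0("genomic", seq_len(p)))
  structure(list(components = components, p = p), class = "kmer_mixture")
}

#' @export
print.kmer_mixture <- function(x, ...) {
  cat("k-mer count mixture model (", x$p, " genomic components)\n", sep = "")
  for (nm in names(x$components)) {
    cc <- x$components[[nm]]
    cat(sprintf("  %-13s %-12s w = %.4f  params = [%s]\n", nm, cc$family,
                cc$weight, paste(signif(cc$params, 5), collapse = ", ")))
  }
  invisible(x)
}

# per-component weighted masses over 1..c: matrix c x (p+1)
mixture_matrix <- function(model, c) {
  vapply(model$components,
         function(cc) cc$weight * component_pmf(cc$family, cc$params, c),
         numeric(c))
}

#' Evaluate the mixture F(x) over 1..c
#'
#' @param model A [mixture_model()] or fitted model object.
#' @param c Support bound.
#' @return Numeric vector F(1..c), summing to 1.
#' @export
mixture_pmf <- function(model, c) {
  model <- as_mixture(model)
  rowSums(mixture_matrix(model, c))
}

as_mixture <- function(model) {
  if (inherits(model, "kmix")) return(model$model)
  if (inherits(model, "kmer_mixture")) return(model)
  stop("expected a mixture model or fit object")
}

# mean of a component's discretized pmf
component_mean <- function(cc, c) {
  sum(seq_len(c) * component_pmf(cc$family, cc$params, c))
}

#' Mixture model fit error
#'
#' The sum of absolute differences between the model mass F(x) and the
#' normalized histogram, over the full support x = 1..c:
#' \deqn{Err(F) = \sum_{x=1}^{c} | F(x) - h_x / \sum_j h_j |.}
#' It is zero iff the fit is perfect and is invariant to rescaling all h_i.
#'
#' @param model A [mixture_model()] or fit object.
#' @param hist A [kmer_histogram()].
#' @return Non-negative error value.
#' @export
model_error <- function(model, hist) {
  stopifnot(inherits(hist, "kmer_histogram"))
  model <- as_mixture(model)
  sum(abs(mixture_pmf(model, hist$c) - hist$h / sum(hist$h)))
}
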
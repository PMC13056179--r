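#' Differential Evolution settings
#'
#' Defaults follow the optimizer's stated operating point: population size
#' 16, mutation factor resampled uniformly in \[0.5, 1\] each generation,
#' recombination (crossover) rate 0.8. The run stops when the best error has
#' improved by less than `tol` for `patience` consecutive generations, or at
#' `max_gen` generations.
#'
#' @param pop_size Population size (>= 4), default 16.
#' @param f_range Range the mutation factor is drawn from each generation.
#' @param cr Crossover rate in \[0, 1\], default 0.8.
#' @param max_gen Hard cap on generations, default 500.
#' @param tol Improvement below which a generation counts as stalled.
#' @param patience Consecutive stalled generations before stopping.
#' @param seed RNG seed; fits are reproducible given the same seed.
#' @return Object of class `de_config`.
#' @export
de_config <- function(pop_size = 16L, f_range = c(0.5, 1.0), cr = 0.8,
                      max_gen = 500L, tol = 1e-6, patience = 50L,
                      seed = 42L) {
  stopifnot(pop_size >= 4, length(f_range) == 2, f_range[1] <= f_range[2],
            f_range[1] >= 0, cr >= 0, cr <= 1, max_gen >= 1, patience >= 1)
  structure(list(pop_size = as.integer(pop_size), f_range = f_range, cr = cr,
                 max_gen = as.integer(max_gen), tol = tol,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "de_config")
}

# --- genome encoding --------------------------------------------------------
# [err_family | peak family (shared) | weight logits (p+1) | err params (2) |
#  top-peak mean | dispersion ratio | skew shape | peak-mean ratios (p-1)]
#
# The genomic peaks are coupled for identifiability: a k-mer on j of the p
# haplotypes draws j/p of the total coverage, so peak j sits at a mean
# ratio_j * lambda with ratio_j confined to a narrow band around j/p, and
# all peaks share one family, one dispersion ratio r (sd_j = r * sqrt(mean_j),
# r = 1 being Poisson-like) and one skew gene. Without the coupling the
# objective has a near-flat valley trading heterozygous weight against
# homozygous width, and the weight split — hence the heterozygosity
# estimate — is not identified.
# Categorical family genes are continuous and floored at evaluation; weights
# are softmax-normalized.

gene_layout <- function(p, c) {
  j <- seq_len(max(p - 1, 0))
  lb <- c(0, 0, rep(-6, p + 1), 0.01, 0.01, 2, 0.5, -10, j / p - 0.05)
  ub <- c(2 - 1e-9, 4 - 1e-9, rep(6, p + 1), 10, 5, c, 2, 10, j / p + 0.05)
  list(lb = lb, ub = ub, n = length(lb), p = p,
       i_fam = 1:2,
       i_w = 2L + seq_len(p + 1),
       i_err = (p + 3) + 1:2,
       i_top = p + 6L, i_disp = p + 7L, i_shape = p + 8L,
       i_rho = if (p > 1) (p + 8L) + seq_len(p - 1) else integer(0))
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

nb_size_from_sd <- function(mu, sd) {
  v <- sd * sd
  if (v > mu * 1.0001) min(mu * mu / (v - mu), 1e6) else 1e6
}

decode_genome <- function(g, layout, c) {
  p <- layout$p
  fam_err <- ERROR_FAMILIES[pmin(floor(g[1]) + 1, length(ERROR_FAMILIES))]
  fam_pk <- GENOMIC_FAMILIES[pmin(floor(g[2]) + 1, length(GENOMIC_FAMILIES))]
  w <- softmax(g[layout$i_w])
  ep <- g[layout$i_err]
  err <- list(family = fam_err, weight = w[1],
              params = if (fam_err == "exponential") ep[1] else ep)
  top <- g[layout$i_top]
  r <- g[layout$i_disp]
  shape <- g[layout$i_shape]
  means <- c(g[layout$i_rho], 1) * top   # increasing: het peaks, then hom
  peaks <- vector("list", p)
  for (j in seq_len(p)) {
    m <- max(means[j], 1)
    s <- r * sqrt(m)
    params <- switch(fam_pk,
      normal = c(m, s),
      skew_normal = c(m, s, shape),
      poisson = m,
      nbinom = c(m, nb_size_from_sd(m, s)))
    peaks[[j]] <- list(family = fam_pk, weight = w[j + 1], params = params)
  }
  mixture_model(c(list(err), peaks))
}

genome_objective <- function(g, layout, hist, hnorm) {
  model <- decode_genome(g, layout, hist$c)
  sum(abs(mixture_pmf(model, hist$c) - hnorm))
}

# moment-based starting points: error decay from h1/h2, main peak from the
# smoothed histogram beyond the error valley
heuristic_genomes <- function(hist, layout) {
  h <- hist$h
  c <- hist$c
  nh <- h / sum(h)
  lam <- log(max(h[1], 1) / max(h[min(2, c)], 1))
  lam <- min(max(lam, 0.2), 5)
  sm <- if (c >= 3) stats::filter(nh, rep(1 / 3, 3), sides = 2) else nh
  sm[is.na(sm)] <- nh[is.na(sm)]
  lo <- min(4, c)
  peak <- if (c > lo) lo - 1 + which.max(sm[lo:c]) else c
  valley <- if (peak > 2) which.min(sm[1:(peak - 1)]) else 1
  w_err <- min(max(sum(nh[1:valley]), 0.05), 0.98)
  w_rest <- 1 - w_err
  jp <- seq_len(layout$p)
  logits <- log(pmax(c(w_err, w_rest * jp / sum(jp)), 1e-4))
  logits <- pmin(pmax(logits - mean(logits), -6), 6)
  mk <- function(fam_err, fam_pk) {
    g <- numeric(layout$n)
    g[1] <- fam_err
    g[2] <- fam_pk
    g[layout$i_w] <- logits
    g[layout$i_err] <- c(lam, 1)
    g[layout$i_top] <- peak
    g[layout$i_disp] <- 1.1
    g[layout$i_shape] <- 0
    g[layout$i_rho] <- seq_len(layout$p - 1) / layout$p
    pmin(pmax(g, layout$lb), layout$ub)
  }
  # one member per (error family, peak family) combination so every basin of
  # the categorical genes is represented in the initial population
  out <- list()
  for (fe in c(0.5, 1.5)) for (fp in c(0.5, 1.5, 2.5, 3.5))
    out[[length(out) + 1L]] <- mk(fe, fp)
  out
}

#' Fit a mixture model to a k-mer count histogram
#'
#' Searches over component families (error: exponential or gamma; genomic
#' peaks: one family shared by all peaks, from normal, skew normal, Poisson
#' or negative binomial), weights and parameters by Differential Evolution (rand/1/bin with greedy selection,
#' so the best error is non-increasing across generations), then refines the
#' best candidate's continuous parameters with BFGS, keeping the refined
#' solution only if it improves the error. The objective is the sum of
#' absolute differences between the model and the normalized histogram
#' (see [model_error()]).
#'
#' @param hist A [kmer_histogram()] with at least two non-empty bins.
#' @param ploidy Number of genomic components p (default 2: heterozygous and
#'   homozygous peaks).
#' @param de A [de_config()].
#' @param refine Run the BFGS local search after DE (default `TRUE`).
#' @param init `"auto"` seeds three population members at moment-based
#'   starting points; `"random"` uses a fully random population.
#' @return Object of class `kmix`: the fitted model (`$model`), its error
#'   (`$err`), the per-generation best-error trace (`$trace`), generation
#'   count and convergence flag. Methods: `print`, `summary`, `coef`,
#'   `predict`, `plot`, `simulate`, `residuals`.
#' @examples
#' h <- kmer_histogram(c(900, 200, 80, 40, 60, 90, 60, 25, 8))
#' fit <- fit_kmer_mixture(h, de = de_config(max_gen = 60, seed = 1))
#' fit
#' @export
fit_kmer_mixture <- function(hist, ploidy = 2L, de = de_config(),
                             refine = TRUE, init = c("auto", "random")) {
  stopifnot(inherits(hist, "kmer_histogram"), inherits(de, "de_config"))
  init <- match.arg(init)
  if (sum(hist$h > 0) < 2)
    stop("histogram is degenerate (fewer than 2 non-empty bins); ",
         "a mixture fit needs more support")
  p <- as.integer(ploidy)
  stopifnot(p >= 1)
  layout <- gene_layout(p, hist$c)
  hnorm <- hist$h / sum(hist$h)
  obj <- function(g) genome_objective(g, layout, hist, hnorm)

  res <- with_seed(de$seed, {
    np <- de$pop_size
    pop <- matrix(runif(np * layout$n, layout$lb, layout$ub),
                  nrow = np, byrow = TRUE)
    if (init == "auto") {
      hg <- heuristic_genomes(hist, layout)
      for (i in seq_along(hg)) if (i <= np) pop[i, ] <- hg[[i]]
    }
    err <- apply(pop, 1, obj)
    best_i <- which.min(err)
    trace <- numeric(0)
    trace_genomes <- list()
    stall <- 0L
    gen <- 0L
    while (gen < de$max_gen) {
      gen <- gen + 1L
      f <- runif(1, de$f_range[1], de$f_range[2])
      prev_best <- min(err)
      for (i in seq_len(np)) {
        r <- sample(setdiff(seq_len(np), i), 3L)
        # rand/1 mutation keeps population diversity across family basins
        v <- pop[r[1], ] + f * (pop[r[2], ] - pop[r[3], ])
        v <- pmin(pmax(v, layout$lb), layout$ub)
        cross <- runif(layout$n) < de$cr
        cross[sample.int(layout$n, 1L)] <- TRUE
        trial <- ifelse(cross, v, pop[i, ])
        e_trial <- obj(trial)
        if (e_trial <= err[i]) {
          pop[i, ] <- trial
          err[i] <- e_trial
        }
      }
      best_i <- which.min(err)
      trace <- c(trace, err[best_i])
      trace_genomes[[gen]] <- pop[best_i, ]
      stall <- if (prev_best - err[best_i] < de$tol) stall + 1L else 0L
      if (stall >= de$patience) break
    }
    list(best = pop[best_i, ], err = err[best_i], trace = trace,
         trace_genomes = do.call(rbind, trace_genomes), gen = gen,
         converged = stall >= de$patience)
  })

  best <- res$best
  best_err <- res$err
  refined <- FALSE
  if (refine) {
    # BFGS local search on the continuous genes, in a logit-transformed
    # unconstrained space so bounds do not kill gradients. The search is run
    # once per family combination (the categorical genes are not BFGS-able),
    # starting from the DE winner's continuous genes, and the refined
    # solution is kept only if it improves the error.
    icont <- setdiff(seq_len(layout$n), layout$i_fam)
    lb <- layout$lb[icont]
    ub <- layout$ub[icont]
    to_z <- function(g) {
      t <- pmin(pmax((g - lb) / (ub - lb), 1e-6), 1 - 1e-6)
      log(t / (1 - t))
    }
    from_z <- function(z) lb + (ub - lb) / (1 + exp(-pmin(pmax(z, -30), 30)))
    res_ref <- with_seed(de$seed + 1L, {
      out <- list(value = best_err, genome = best)
      z_de <- to_z(best[icont])
      for (fe in seq_along(ERROR_FAMILIES) - 0.5) {
        for (fp in seq_along(GENOMIC_FAMILIES) - 0.5) {
          g_fam <- best
          g_fam[layout$i_fam] <- c(fe, fp)
          cont_obj <- function(z) {
            g <- g_fam
            g[icont] <- from_z(z)
            obj(g)
          }
          local_best <- Inf
          cur <- z_de
          repeat {   # iterate BFGS restarts until improvement stops
            opt <- tryCatch(
              optim(cur, cont_obj, method = "BFGS",
                    control = list(maxit = 300)),
              error = function(e) NULL)
            if (is.null(opt) || opt$value >= local_best - de$tol) break
            local_best <- opt$value
            cur <- opt$par
            if (opt$value < out$value) {
              g_fam[icont] <- from_z(opt$par)
              out <- list(value = opt$value, genome = g_fam)
            }
          }
        }
      }
      out
    })
    if (res_ref$value < best_err) {
      best <- res_ref$genome
      best_err <- res_ref$value
      refined <- TRUE
    }
  }
  if (!res$converged && res$gen >= de$max_gen)
    warning("optimizer hit the generation cap without converging; ",
            "returning the best solution found")

  structure(list(model = decode_genome(best, layout, hist$c),
                 err = best_err, genome = best, layout = layout,
                 trace = res$trace, trace_genomes = res$trace_genomes,
                 generations = res$gen, converged = res$converged,
                 refined = refined, de = de, ploidy = p, hist = hist,
                 call = match.call()),
            class = "kmix")
}

#' @export
print.kmix <- function(x, ...) {
  cat(sprintf(
    "k-mer spectrum mixture fit (Err = %.6g, %d generations%s%s)\n",
    x$err, x$generations,
    if (x$converged) ", converged" else "",
    if (x$refined) ", BFGS-refined" else ""))
  print(x$model)
  invisible(x)
}

#' @export
coef.kmix <- function(object, ...) {
  out <- c()
  for (nm in names(object$model$components)) {
    cc <- object$model$components[[nm]]
    out[paste0("w_", nm)] <- cc$weight
    pn <- switch(cc$family,
                 exponential = "rate", gamma = c("shape", "rate"),
                 normal = c("mean", "sd"),
                 skew_normal = c("location", "scale", "shape"),
                 poisson = "lambda", nbinom = c("mu", "size"))
    out[paste0(nm, "_", pn)] <- cc$params
  }
  out
}

#' Model predictions over the count support
#'
#' @param object A `kmix` fit.
#' @param x Integer counts to evaluate at (default the full support 1..c).
#' @param type `"mixture"` returns F(x); `"components"` the weighted
#'   per-component masses w_i f_i(x); `"posterior"` the posterior component
#'   probabilities P(component | x).
#' @param ... Unused.
#' @return Numeric vector (`"mixture"`) or matrix with one column per
#'   component.
#' @export
predict.kmix <- function(object, x = NULL,
                         type = c("mixture", "components", "posterior"), ...) {
  type <- match.arg(type)
  cmax <- object$hist$c
  if (is.null(x)) x <- seq_len(cmax)
  if (any(x < 1)) stop("counts must be >= 1")
  cmax <- max(cmax, max(x))
  mat <- mixture_matrix(object$model, cmax)
  if (type == "mixture") return(rowSums(mat)[x])
  if (type == "components") return(mat[x, , drop = FALSE])
  posterior_probs(object, x)
}

#' @export
residuals.kmix <- function(object, ...) {
  object$hist$h / sum(object$hist$h) - mixture_pmf(object$model, object$hist$c)
}

#' Simulate histograms from a fitted mixture
#'
#' Draws `n_kmers` distinct k-mer counts from the fitted F(x) and tabulates
#' them, yielding histogram replicates under the model.
#'
#' @param object A `kmix` fit.
#' @param nsim Number of replicates.
#' @param seed RNG seed.
#' @param n_kmers Distinct k-mers per replicate (default: as in the fitted
#'   histogram).
#' @param ... Unused.
#' @return List of [kmer_histogram()] objects (length `nsim`).
#' @export
simulate.kmix <- function(object, nsim = 1, seed = 1, n_kmers = NULL, ...) {
  n <- if (is.null(n_kmers)) object$hist$total_distinct else n_kmers
  f <- mixture_pmf(object$model, object$hist$c)
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      kmer_histogram(as.numeric(rmultinom(1, size = n, prob = f)))
    })
  })
}
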
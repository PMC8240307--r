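#' Configuration of the hierarchical variable-selection sampler
#'
#' Priors and run length for [fit_hierarchical_selection()]. The gene-level
#' baseline inclusion probability pi_k has a Beta(a, b) prior with b
#' defaulting to the number of SDPs (expected model size of about one
#' predictor per gene); the locus propensity rho_j has a Gamma prior with
#' mean 1, so a locus only inflates inclusion odds when many genes select
#' it; effect sizes carry a Zellner g-prior with g defaulting to the number
#' of lines.
#'
#' @param a,b Beta hyperparameters of pi_k; `b = NULL` means "number of
#'   SDPs".
#' @param rho_shape,rho_rate Gamma hyperparameters of rho_j (default 1, 1).
#' @param g g-prior constant; `NULL` means "number of lines".
#' @param iters,burnin Total and discarded MCMC iterations (defaults 5000,
#'   1000).
#' @param rw_sd Random-walk sd for the log-rho Metropolis step.
#' @param seed Integer seed.
#' @return A `hotspot_model_config` list.
#' @export
hotspot_model_config <- function(a = 1, b = NULL, rho_shape = 1, rho_rate = 1,
                                 g = NULL, iters = 5000L, burnin = 1000L,
                                 rw_sd = 0.35, seed = 1L) {
  stopifnot(a > 0, is.null(b) || b > 0, rho_shape > 0, rho_rate > 0,
            is.null(g) || g > 0, iters > burnin, burnin >= 0)
  structure(list(a = a, b = b, rho_shape = rho_shape, rho_rate = rho_rate,
                 g = g, iters = as.integer(iters), burnin = as.integer(burnin),
                 rw_sd = rw_sd, seed = as.integer(seed)),
            class = "hotspot_model_config")
}

#' Hierarchical Bayesian variable selection across genes and loci
#'
#' Fits, per gene, a spike-and-slab linear model of the (standardized) trait
#' on all SDP genotypes, with the multiplicative inclusion prior
#' `pi_kj = min(pi_k * rho_j, 1)`: the locus propensity rho_j lets a single
#' SDP raise its inclusion odds across many genes simultaneously, which is
#' what gives the model power to detect master-regulatory hotspots. Effects
#' and error variance are marginalized under a g-prior, so the sampler only
#' tracks inclusion indicators. The marginal posterior inclusion probability
#' gamma_hat of a (gene, SDP) pair is its selection frequency over retained
#' states.
#'
#' @param traits Trait matrix (genes x lines), e.g. TE residuals; each gene
#'   is standardized internally.
#' @param map An `sdp_map` or 0/1 genotype matrix (SDPs x lines).
#' @param config A [hotspot_model_config()].
#' @return A `posterior_inclusion` object: `gamma_hat` (genes x SDPs),
#'   gene-level `pi_k`, locus propensities `rho_j`, the Metropolis
#'   acceptance rate, and a split-half convergence correlation (a warning is
#'   raised below 0.9).
#' @export
fit_hierarchical_selection <- function(traits, map,
                                       config = hotspot_model_config()) {
  stopifnot(inherits(config, "hotspot_model_config"))
  geno <- if (inherits(map, "sdp_map")) map$patterns else map
  lines <- intersect(colnames(traits), colnames(geno))
  if (length(lines) < 4L) stop("traits and genotypes share fewer than 4 lines")
  y <- traits[, lines, drop = FALSE]
  x <- geno[, lines, drop = FALSE]
  keep <- rowSums(x) > 0L & rowSums(x) < ncol(x)
  x <- x[keep, , drop = FALSE]
  n <- length(lines)

  Y <- t(scale(t(y)))
  Y[!is.finite(Y)] <- 0
  X <- scale(t(x), scale = FALSE)

  b <- if (is.null(config$b)) nrow(x) else config$b
  g <- if (is.null(config$g)) n else config$g

  set.seed(config$seed)
  res <- multiplicative_ss_sampler(t(Y), X, config$a, b, config$rho_shape,
                      config$rho_rate, g, config$iters, config$burnin,
                      config$rw_sd)
  gamma_hat <- res$gamma_hat
  dimnames(gamma_hat) <- list(rownames(y), rownames(x))
  h1 <- as.vector(res$gamma_half1)
  h2 <- as.vector(res$gamma_half2)
  conv <- if (length(h1) > 1 && sd(h1) > 0 && sd(h2) > 0) {
    cor(h1, h2)
  } else NA_real_
  if (!is.na(conv) && conv < 0.9) {
    warning("split-half selection-frequency correlation ", signif(conv, 3),
            " < 0.9; consider more iterations")
  }
  structure(list(gamma_hat = gamma_hat,
                 pi_k = setNames(res$pi_k, rownames(y)),
                 rho_j = setNames(res$rho_j, rownames(x)),
                 mh_accept = res$mh_accept,
                 split_half_cor = conv,
                 config = config),
            class = "posterior_inclusion")
}

#' @export
print.posterior_inclusion <- function(x, ...) {
  cat("posterior_inclusion:", nrow(x$gamma_hat), "genes x",
      ncol(x$gamma_hat), "SDPs\n")
  cat("  max gamma_hat:", signif(max(x$gamma_hat), 3),
      "| split-half cor:", signif(x$split_half_cor, 3), "\n")
  invisible(x)
}

beta_weighted_mle <- function(s1, s2, lower, upper, init) {
  nll <- function(par) -( (par[1] - 1) * s1 + (par[2] - 1) * s2 -
                            lbeta(par[1], par[2]) )
  init <- pmin(pmax(init, lower), upper)
  fit <- try(optim(init, nll, method = "L-BFGS-B", lower = lower,
                   upper = upper), silent = TRUE)
  if (inherits(fit, "try-error")) init else fit$par
}

#' Two-component beta-mixture fit of posterior inclusion probabilities
#'
#' Models the gamma_hat values as `w0 * Beta(a0, b0) + w1 * Beta(a1, b1)`
#' by EM, with the null component constrained to be decreasing near 0
#' (a0 <= 1 <= b0) and the alternative increasing near 1 (a1 >= 2 >= 1 >= b1).
#' Values are clamped to `(eps, 1 - eps)` first. Converged when the
#' log-likelihood change drops below `tol` or after `max_iter` iterations.
#' If the data are degenerate (all values equal), a single-component
#' fallback with `w1 = 0` is returned.
#'
#' Selection frequencies from a finite sampler pile up at exactly zero
#' (pairs never selected) while chance trait-genotype correlations in a
#' small panel produce a long polynomial tail of moderate frequencies. An
#' unconstrained null component collapses onto the zero mass and abandons
#' that tail to the alternative, which wrecks the FDR estimate; the null
#' concentration cap (`null_shape2_max`, default 5) keeps the null
#' responsible for the whole no-association distribution, and the
#' alternative floor (`alt_shape1_min`, default 2) keeps the signal
#' component genuinely concentrated near 1.
#'
#' @param gamma_hat Numeric vector or matrix of inclusion probabilities.
#' @param eps Clamping constant (default 1e-6).
#' @param max_iter,tol EM controls (defaults 500, 1e-8).
#' @param null_shape2_max Upper bound on the null component's second shape
#'   parameter (default 5).
#' @param alt_shape1_min Lower bound on the alternative component's first
#'   shape parameter (default 2).
#' @return A `beta_mixture_fit`: weights `w0`/`w1`, component parameters,
#'   log-likelihood trace length, and convergence flag.
#' @export
fit_beta_mixture_em <- function(gamma_hat, eps = 1e-6, max_iter = 500L,
                                tol = 1e-8, null_shape2_max = 5,
                                alt_shape1_min = 2) {
  x <- pmin(pmax(as.vector(gamma_hat), eps), 1 - eps)
  n <- length(x)
  if (length(unique(x)) == 1L) {
    return(structure(list(w0 = 1, w1 = 0, null = c(shape1 = 1, shape2 = 1),
                          alt = c(shape1 = 1, shape2 = 1), loglik = NA_real_,
                          iterations = 0L, converged = TRUE,
                          degenerate = TRUE),
                     class = "beta_mixture_fit"))
  }
  lx <- log(x); l1x <- log1p(-x)
  w1 <- 0.1
  null_par <- c(0.5, min(8, null_shape2_max))
  alt_par <- c(8, 0.8)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    ld0 <- (null_par[1] - 1) * lx + (null_par[2] - 1) * l1x -
      lbeta(null_par[1], null_par[2])
    ld1 <- (alt_par[1] - 1) * lx + (alt_par[2] - 1) * l1x -
      lbeta(alt_par[1], alt_par[2])
    m <- pmax(ld0 + log(1 - w1), ld1 + log(w1))
    denom <- m + log(exp(ld0 + log(1 - w1) - m) + exp(ld1 + log(w1) - m))
    r1 <- exp(ld1 + log(w1) - denom)
    ll <- sum(denom)
    w1 <- mean(r1)
    if (w1 > 1e-12 && w1 < 1 - 1e-12) {
      sw0 <- sum(1 - r1); sw1 <- sum(r1)
      null_par <- beta_weighted_mle(sum((1 - r1) * lx) / sw0,
                                    sum((1 - r1) * l1x) / sw0,
                                    lower = c(1e-3, 1),
                                    upper = c(1, null_shape2_max),
                                    init = null_par)
      alt_par <- beta_weighted_mle(sum(r1 * lx) / sw1,
                                   sum(r1 * l1x) / sw1,
                                   lower = c(alt_shape1_min, 1e-3),
                                   upper = c(1e4, 1),
                                   init = alt_par)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * max(1, abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  structure(list(w0 = 1 - w1, w1 = w1,
                 null = c(shape1 = null_par[1], shape2 = null_par[2]),
                 alt = c(shape1 = alt_par[1], shape2 = alt_par[2]),
                 loglik = ll, iterations = it, converged = converged,
                 degenerate = FALSE),
            class = "beta_mixture_fit")
}

#' @export
print.beta_mixture_fit <- function(x, ...) {
  cat("beta_mixture_fit: w1 =", signif(x$w1, 3),
      "| null Beta(", signif(x$null[1], 3), ",", signif(x$null[2], 3),
      ") | alt Beta(", signif(x$alt[1], 3), ",", signif(x$alt[2], 3), ")\n")
  invisible(x)
}

#' FDR cutoff on posterior inclusion probabilities
#'
#' Using the fitted mixture, the estimated FDR at a cutoff t is the null
#' fraction of calls above t:
#' `FDR(t) = w0 S0(t) / (w0 S0(t) + w1 S1(t))` with S the component
#' survival functions. The chosen cutoff is the smallest observed gamma_hat
#' value with estimated FDR at or below `target_fdr`; if none qualifies the
#' significant set is empty (`t = Inf`).
#'
#' @param fit A `beta_mixture_fit`.
#' @param gamma_hat The observed values (vector or matrix).
#' @param target_fdr Target FDR (default 0.05).
#' @return A list: `cutoff`, `fdr_at_cutoff`, and the logical
#'   `significant` vector/matrix.
#' @export
fdr_cutoff <- function(fit, gamma_hat, target_fdr = 0.05) {
  stopifnot(inherits(fit, "beta_mixture_fit"))
  vals <- as.vector(gamma_hat)
  grid <- sort(unique(vals))
  if (fit$w1 <= 0) {
    return(list(cutoff = Inf, fdr_at_cutoff = NA_real_,
                significant = gamma_hat > Inf))
  }
  if (fit$w0 <= 0) {
    return(list(cutoff = grid[1L], fdr_at_cutoff = 0,
                significant = gamma_hat >= grid[1L]))
  }
  s0 <- pbeta(grid, fit$null[1], fit$null[2], lower.tail = FALSE)
  s1 <- pbeta(grid, fit$alt[1], fit$alt[2], lower.tail = FALSE)
  fdr <- fit$w0 * s0 / pmax(fit$w0 * s0 + fit$w1 * s1, .Machine$double.xmin)
  ok <- which(fdr <= target_fdr)
  if (!length(ok)) {
    return(list(cutoff = Inf, fdr_at_cutoff = NA_real_,
                significant = gamma_hat > Inf))
  }
  t_star <- grid[min(ok)]
  list(cutoff = t_star, fdr_at_cutoff = fdr[min(ok)],
       significant = gamma_hat >= t_star)
}

#' Significant gene-SDP pairs from a selection fit
#'
#' Convenience wrapper: beta-mixture FDR on the fit's gamma_hat and
#' extraction of the significant pairs.
#'
#' @param fit A `posterior_inclusion`.
#' @param target_fdr Target FDR (default 0.05).
#' @return Data frame of significant pairs (gene, sdp, gamma_hat), with the
#'   mixture fit and cutoff as attributes.
#' @export
significant_pairs <- function(fit, target_fdr = 0.05) {
  stopifnot(inherits(fit, "posterior_inclusion"))
  mix <- fit_beta_mixture_em(fit$gamma_hat)
  cut <- fdr_cutoff(mix, fit$gamma_hat, target_fdr)
  idx <- which(cut$significant, arr.ind = TRUE)
  out <- data.frame(gene = rownames(fit$gamma_hat)[idx[, 1L]],
                    sdp = colnames(fit$gamma_hat)[idx[, 2L]],
                    gamma_hat = fit$gamma_hat[idx])
  attr(out, "mixture") <- mix
  attr(out, "cutoff") <- cut$cutoff
  out
}

#' Call distant master-regulatory hotspots
#'
#' An SDP is a hotspot when it is significantly associated with at least
#' `min_genes` genes located on chromosomes other than every location of
#' the SDP (distant associations), and those genes span at least
#' `min_chromosomes` chromosomes. Hotspots are ordered by gene count, with
#' a proportion-of-genes score (significant genes / genes tested).
#'
#' @param pairs Data frame of significant (gene, sdp) pairs, e.g. from
#'   [significant_pairs()].
#' @param annotation Gene annotation (gene, chrom).
#' @param map An `sdp_map`.
#' @param n_genes_tested Total genes in the fit (for the proportion score);
#'   default: number of distinct genes in `annotation`.
#' @param min_genes Minimum distant gene count (default 5).
#' @param min_chromosomes Minimum chromosomes spanned by the gene set
#'   (default 2).
#' @return Data frame of hotspots: sdp, n_genes, chromosomes spanned,
#'   proportion score, and the member gene list (comma-separated).
#' @export
call_hotspots <- function(pairs, annotation, map,
                          n_genes_tested = length(unique(annotation$gene)),
                          min_genes = 5L, min_chromosomes = 2L) {
  if (!nrow(pairs)) {
    return(data.frame(sdp = character(), n_genes = integer(),
                      n_chromosomes = integer(), proportion = numeric(),
                      genes = character()))
  }
  g_chrom <- setNames(annotation$chrom, annotation$gene)
  loc <- map$locations
  out <- lapply(split(pairs, pairs$sdp), function(df) {
    sdp_chroms <- unique(loc$chrom[loc$sdp == df$sdp[1L]])
    distant <- !(g_chrom[df$gene] %in% sdp_chroms)
    genes <- unique(df$gene[distant])
    chroms <- unique(g_chrom[genes])
    data.frame(sdp = df$sdp[1L], n_genes = length(genes),
               n_chromosomes = length(chroms),
               proportion = length(genes) / n_genes_tested,
               genes = paste(sort(genes), collapse = ","))
  })
  out <- do.call(rbind, out)
  out <- out[out$n_genes >= min_genes & out$n_chromosomes >= min_chromosomes, ,
             drop = FALSE]
  out <- out[order(-out$n_genes), , drop = FALSE]
  rownames(out) <- NULL
  out
}
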
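# Small fixtures for sampler behavior: genes x lines traits with a known
# driver SDP.
driver_fixture <- function(n_genes = 30, n_driven = 10, r2 = 0.5, seed = 1,
                           map = small_panel()) {
  set.seed(seed)
  lines <- map$lines
  sdp <- rownames(map$patterns)[7]
  dose <- map$patterns[sdp, lines]
  beta <- sqrt(r2 / (1 - r2)) / stats::sd(dose)
  traits <- matrix(rnorm(n_genes * length(lines)), n_genes,
                   dimnames = list(sprintf("G%02d", seq_len(n_genes)), lines))
  if (n_driven > 0) {
    traits[seq_len(n_driven), ] <- traits[seq_len(n_driven), ] +
      outer(rep(beta, n_driven), dose)
  }
  list(traits = traits, sdp = sdp, driven = rownames(traits)[seq_len(n_driven)])
}

test_that("the selection sampler is deterministic under a fixed seed", {
  fx <- driver_fixture(n_genes = 15, n_driven = 3)
  cfg <- hotspot_model_config(iters = 400, burnin = 100, seed = 9)
  f1 <- suppressWarnings(fit_hierarchical_selection(fx$traits,
                                                    small_panel(), cfg))
  f2 <- suppressWarnings(fit_hierarchical_selection(fx$traits,
                                                    small_panel(), cfg))
  expect_identical(f1$gamma_hat, f2$gamma_hat)
  expect_identical(f1$rho_j, f2$rho_j)
})

test_that("a driver SDP's target pairs attain the top posterior inclusion", {
  fx <- driver_fixture(n_genes = 40, n_driven = 10, r2 = 0.5, seed = 2)
  fit <- suppressWarnings(fit_hierarchical_selection(
    fx$traits, small_panel(),
    hotspot_model_config(iters = 2000, burnin = 500, seed = 3)))
  g <- fit$gamma_hat
  top10 <- order(g, decreasing = TRUE)[1:10]
  top_pairs <- paste(rownames(g)[row(g)[top10]], colnames(g)[col(g)[top10]])
  expect_setequal(top_pairs, paste(fx$driven, fx$sdp))
  # the driver locus carries the largest propensity
  expect_identical(names(which.max(fit$rho_j)), fx$sdp)
})

test_that("pure-noise traits stay below 0.5 posterior inclusion", {
  # at 30 lines, chance trait-genotype correlations grow with the number of
  # pairs scanned; the per-pair guarantee is tested at modest dimensionality
  # and the tail is bounded in aggregate at the larger scale
  small_map <- build_sdp_map(simulate_genotypes(panel_config(
    chromosomes = data.frame(name = "chr1", length = 5e7, n_markers = 40L),
    seed = 17)))
  below <- vapply(1:6, function(s) {
    set.seed(300 + s)
    traits <- matrix(rnorm(20 * 30), 20,
                     dimnames = list(sprintf("G%02d", 1:20),
                                     colnames(small_map$patterns)))
    fit <- suppressWarnings(fit_hierarchical_selection(
      traits, small_map,
      hotspot_model_config(iters = 1500, burnin = 400, seed = s)))
    max(fit$gamma_hat) < 0.5
  }, logical(1))
  expect_gte(sum(below), 5L)

  tail_frac <- vapply(1:3, function(s) {
    fx <- driver_fixture(n_genes = 40, n_driven = 0, seed = 10 + s)
    fit <- suppressWarnings(fit_hierarchical_selection(
      fx$traits, small_panel(),
      hotspot_model_config(iters = 1500, burnin = 400, seed = s)))
    mean(fit$gamma_hat >= 0.5)
  }, numeric(1))
  expect_lte(mean(tail_frac), 2e-3)
})

test_that("single-predictor posterior inclusion matches the conjugate closed form", {
  map <- small_panel()
  lines <- map$lines
  n <- length(lines)
  sdp <- rownames(map$patterns)[3]
  dose <- map$patterns[sdp, lines]
  set.seed(6)
  y <- 0.8 * (dose - mean(dose)) / stats::sd(dose) + rnorm(n)
  traits <- matrix(y, 1, dimnames = list("G1", lines))
  geno <- map$patterns[sdp, , drop = FALSE]

  fit <- fit_hierarchical_selection(
    traits, geno, hotspot_model_config(iters = 30000, burnin = 5000,
                                       seed = 4))

  # closed form: P(gamma=1 | y) = BF q / (BF q + 1 - q) with the g-prior
  # Bayes factor and q the prior inclusion marginalized over
  # pi ~ Beta(1, 1) and rho ~ Gamma(1, 1) under the min(pi rho, 1) link
  ys <- as.vector(scale(y)); xs <- dose - mean(dose)
  r2 <- sum(xs * ys)^2 / (sum(xs^2) * sum(ys^2))
  g <- n
  log_bf <- -0.5 * log1p(g) - (n - 1) / 2 * log(1 - g / (1 + g) * r2)
  q_bar <- stats::integrate(function(rho) {
    inner <- ifelse(rho <= 1, rho / 2, 1 - 1 / (2 * rho))
    inner * exp(-rho)
  }, 0, Inf)$value
  post <- exp(log_bf) * q_bar / (exp(log_bf) * q_bar + 1 - q_bar)
  expect_lt(abs(fit$gamma_hat[1, 1] - post), 0.05)
})

test_that("planted effect strength monotonically raises target inclusion", {
  map <- small_panel()
  mean_ppi <- vapply(c(0.2, 0.5, 0.9), function(r2) {
    ppis <- vapply(1:3, function(s) {
      fx <- driver_fixture(n_genes = 25, n_driven = 5, r2 = r2, seed = 50 + s)
      fit <- suppressWarnings(fit_hierarchical_selection(
        fx$traits, map, hotspot_model_config(iters = 1200, burnin = 300,
                                             seed = s)))
      mean(fit$gamma_hat[fx$driven, fx$sdp])
    }, numeric(1))
    mean(ppis)
  }, numeric(1))
  expect_true(all(diff(mean_ppi) > 0))
})

test_that("the beta-mixture EM recovers planted mixtures and degenerate cases", {
  set.seed(42)
  # 0.9 Beta(1,20) + 0.1 Beta(20,1)
  v <- c(rbeta(4500, 1, 20), rbeta(500, 20, 1))
  fit <- fit_beta_mixture_em(v)
  expect_lt(abs(fit$w1 - 0.1), 0.03)

  # all values tiny: no signal component
  expect_lte(fit_beta_mixture_em(runif(2000, 0, 0.01))$w1, 0.01)

  # symmetric mirrored mixture
  v3 <- c(rbeta(2500, 1, 9), rbeta(2500, 9, 1))
  expect_lt(abs(fit_beta_mixture_em(v3)$w1 - 0.5), 0.05)

  # degenerate data: single-component fallback
  fd <- fit_beta_mixture_em(rep(0.2, 50))
  expect_identical(fd$w1, 0)
  expect_true(fd$degenerate)
})

test_that("FDR cutoffs behave at the boundaries of the mixture", {
  set.seed(2)
  vals <- c(rbeta(900, 1, 30), rbeta(100, 30, 1))
  fit <- fit_beta_mixture_em(vals)

  # w0 = 0: everything significant at any target
  all_alt <- fit; all_alt$w0 <- 0; all_alt$w1 <- 1
  cut0 <- fdr_cutoff(all_alt, vals, target_fdr = 0.01)
  expect_equal(cut0$cutoff, min(vals))
  expect_true(all(cut0$significant))

  # target 0 with w0 > 0: empty significant set
  cut1 <- fdr_cutoff(fit, vals, target_fdr = 0)
  expect_identical(cut1$cutoff, Inf)
  expect_false(any(cut1$significant))

  # w1 = 0: nothing significant
  none <- fit; none$w0 <- 1; none$w1 <- 0
  expect_false(any(fdr_cutoff(none, vals, 0.05)$significant))

  # FDR is non-increasing in t on the evaluated grid
  grid <- sort(unique(vals))
  s0 <- pbeta(grid, fit$null[1], fit$null[2], lower.tail = FALSE)
  s1 <- pbeta(grid, fit$alt[1], fit$alt[2], lower.tail = FALSE)
  fdr <- fit$w0 * s0 / (fit$w0 * s0 + fit$w1 * s1)
  expect_true(all(diff(fdr) < 1e-8))
})

test_that("hotspot calling enforces the gene-count and chromosome-span rules", {
  map <- small_panel()
  sdp <- rownames(map$patterns)[2]
  sdp_chr <- map$locations$chrom[map$locations$sdp == sdp][1]
  other_chr <- setdiff(c("chr1", "chr2", "chr3"), sdp_chr)
  ann <- data.frame(gene = sprintf("G%02d", 1:12),
                    chrom = c(rep(other_chr[1], 6), rep(other_chr[2], 6)))

  pairs <- function(genes) data.frame(gene = genes, sdp = sdp,
                                      gamma_hat = 0.99)
  # 4 distant genes: below the floor
  expect_identical(nrow(call_hotspots(pairs(ann$gene[1:4]), ann, map)), 0L)
  # 6 genes all on one chromosome: fails the spanning rule
  expect_identical(nrow(call_hotspots(pairs(ann$gene[1:6]), ann, map)), 0L)
  expect_identical(nrow(call_hotspots(pairs(ann$gene[1:6]), ann, map,
                                      min_chromosomes = 1L)), 1L)
  # 6 genes over two chromosomes: called, with its score
  hs <- call_hotspots(pairs(ann$gene[4:9]), ann, map,
                      n_genes_tested = nrow(ann))
  expect_identical(nrow(hs), 1L)
  expect_identical(hs$n_genes, 6L)
  expect_equal(hs$proportion, 6 / 12)
  # genes on the SDP's own chromosome do not count as distant
  ann2 <- ann; ann2$chrom[1:5] <- sdp_chr
  expect_identical(nrow(call_hotspots(pairs(ann2$gene[1:9]), ann2, map)), 0L)
})
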
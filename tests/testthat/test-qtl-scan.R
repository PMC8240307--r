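make_scan_fixture <- function(seed = 1, n_genes = 20, n_lines = 16) {
  set.seed(seed)
  lines <- sprintf("L%02d", seq_len(n_lines))
  traits <- matrix(rnorm(n_genes * n_lines), n_genes, n_lines,
                   dimnames = list(sprintf("G%02d", seq_len(n_genes)), lines))
  geno <- matrix(rbinom(8 * n_lines, 1, 0.5), 8, n_lines,
                 dimnames = list(sprintf("SDP%02d", 1:8), lines))
  geno[rowSums(geno) == 0 | rowSums(geno) == n_lines, 1] <- 1L
  list(traits = traits, geno = geno)
}

test_that("the scan equals per-pair OLS to 1e-10 relative tolerance", {
  fx <- make_scan_fixture()
  assoc <- scan_associations(fx$traits, fx$geno)
  for (i in sample.int(nrow(assoc), 100)) {
    y <- fx$traits[assoc$gene[i], ]
    x <- fx$geno[assoc$sdp[i], ]
    fit <- summary(stats::lm(y ~ x))$coefficients
    expect_equal(assoc$slope[i], fit["x", "Estimate"], tolerance = 1e-10)
    expect_equal(assoc$t[i], fit["x", "t value"], tolerance = 1e-10)
    expect_equal(assoc$p[i], fit["x", "Pr(>|t|)"], tolerance = 1e-10)
  }
})

test_that("degenerate and perfect associations behave as expected", {
  lines <- paste0("L", 1:10)
  g <- matrix(rep(c(0L, 1L), each = 5), 1, dimnames = list("S1", lines))
  # equal group means with within-group variance: slope 0, p ~ 1
  y0 <- matrix(c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1), 1,
               dimnames = list("G1", lines))
  a0 <- scan_associations(y0, g)
  expect_equal(a0$slope, 0, tolerance = 1e-12)
  expect_gt(a0$p, 0.999)
  # trait = genotype: slope 1, p at machine floor
  a1 <- scan_associations(matrix(as.numeric(g), 1,
                                 dimnames = list("G1", lines)), g)
  expect_equal(a1$slope, 1, tolerance = 1e-12)
  expect_lt(a1$p, 1e-12)
  # monomorphic SDP skipped with a log entry
  gm <- rbind(g, S2 = rep(0L, 10))
  a2 <- scan_associations(y0, gm)
  expect_identical(attr(a2, "skipped"), "S2")
  expect_identical(unique(a2$sdp), "S1")
})

test_that("relabeling the founder alleles flips slopes but not significance", {
  fx <- make_scan_fixture(seed = 3)
  a <- scan_associations(fx$traits, fx$geno)
  b <- scan_associations(fx$traits, 1L - fx$geno)
  expect_equal(a$slope, -b$slope, tolerance = 1e-12)
  expect_equal(abs(a$t), abs(b$t), tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("local/distant classification follows gene overlap with SDP locations", {
  map <- build_sdp_map(gt_from_patterns(
    rbind(c(0, 0, 1, 1), c(0, 1, 1, 0), c(1, 0, 1, 0)),
    chrom = c("chr1", "chr1", "chr2"), pos = c(1e6, 5e6, 3e6)), filter = FALSE)
  traits <- matrix(rnorm(12), 3, 4,
                   dimnames = list(c("Gin", "Gfar", "Gother"),
                                   sprintf("L%02d", 1:4)))
  ann <- data.frame(gene = c("Gin", "Gfar", "Gother"),
                    chrom = c("chr1", "chr1", "chr2"),
                    start = c(9e5, 9e6, 1e6), end = c(1.1e6, 9.1e6, 1.2e6))
  assoc <- classify_local_distant(scan_associations(traits, map), ann, map)
  get <- function(g, s) assoc$class[assoc$gene == g & assoc$sdp == s]
  expect_identical(get("Gin", "SDP0001"), "local")       # inside interval
  expect_identical(get("Gother", "SDP0001"), "distant")  # other chromosome
  expect_identical(get("Gfar", "SDP0001"), "same-chromosome-other")
})

test_that("stratified BH matches a reference step-up within each stratum", {
  set.seed(9)
  assoc <- data.frame(gene = sprintf("G%02d", 1:40), sdp = "S1",
                      p = runif(40),
                      class = rep(c("local", "distant"), 20))
  out <- bh_stratified(assoc)
  step_up <- function(p) {  # textbook BH
    n <- length(p); o <- order(p)
    adj <- rev(cummin(rev(p[o] * n / seq_len(n))))
    pmin(adj, 1)[order(o)]
  }
  for (cl in c("local", "distant")) {
    i <- assoc$class == cl
    expect_equal(out$p_bh[i], step_up(assoc$p[i]), tolerance = 1e-14)
  }
  # single test: adjusted equals nominal; ties stay at the common value
  one <- bh_stratified(data.frame(p = 0.03, class = "local", gene = "g",
                                  sdp = "s"))
  expect_equal(one$p_bh, 0.03)
  ties <- bh_stratified(data.frame(p = rep(0.01, 5), class = "distant",
                                   gene = letters[1:5], sdp = "s"))
  expect_equal(ties$p_bh, rep(0.01, 5))
})

test_that("empirical p values follow the k/n convention at the paper threshold", {
  expect_identical(empirical_pvalue(15, 10000), 0.0015)
  expect_identical(empirical_pvalue(0, 500), 0)
  expect_identical(empirical_pvalue(500, 500), 1)
  expect_equal(empirical_pvalue(15, 10000, "add_one"), 16 / 10001)
})

test_that("permutation nulls flag planted effects and respect determinism", {
  map <- small_panel()
  set.seed(5)
  lines <- map$lines
  traits <- matrix(rnorm(30 * length(lines)), 30,
                   dimnames = list(sprintf("G%02d", 1:30), lines))
  sdp <- rownames(map$patterns)[8]
  traits[1, ] <- map$patterns[sdp, lines] * 4 + rnorm(length(lines), 0, 0.5)
  expect_warning(permutation_empirical_p(traits, map, n_perm = 100, seed = 1),
                 "cannot resolve")
  emp <- permutation_empirical_p(traits, map, n_perm = 400, seed = 1,
                                 threshold = 1 / 400)
  expect_identical(emp, permutation_empirical_p(traits, map, n_perm = 400,
                                                seed = 1, threshold = 1 / 400))
  expect_equal(emp["G01", sdp], 0)  # stronger than every permutation
  expect_error(permutation_empirical_p(traits, map, n_perm = 50), ">= 100")

  assoc <- add_empirical_p(scan_associations(traits, map), emp)
  expect_true(assoc$significant[assoc$gene == "G01" & assoc$sdp == sdp])
  expect_true(all(assoc$p_emp >= 0 & assoc$p_emp <= 1))
})

test_that("multi-location SDP associations are assigned by flanking support", {
  # chr1: S1 S2 S1(dup) ; chr2: S2(dup location of the S2 pattern) is absent,
  # instead build: chr1 [A, B], chr2 [A, C] so A has two locations
  A <- c(0, 0, 1, 1); B <- c(0, 1, 1, 0); C <- c(1, 1, 0, 0)
  map <- build_sdp_map(gt_from_patterns(
    do.call(rbind, list(A, B, A, C)),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    pos = c(1e6, 2e6, 1e6, 2e6)), filter = FALSE)
  a_id <- map$locations$sdp[map$locations$chrom == "chr1" &
                              map$locations$start == 1e6]
  expect_identical(sum(map$locations$sdp == a_id), 2L)

  lines <- sprintf("L%02d", 1:4)
  # trait correlated with pattern B (the chr1 flank of A) but not C
  traits <- matrix(c(0.1, 0.9, 1.1, -0.2), 1,
                   dimnames = list("G1", lines))
  assoc <- assign_sdp_location(scan_associations(traits, map), map)
  row <- assoc[assoc$sdp == a_id, ]
  expect_identical(row$loc_chrom, "chr1")
  expect_false(row$loc_ambiguous)
  # single-location SDPs keep their own location
  b_id <- setdiff(unique(assoc$sdp), a_id)
  expect_true(all(assoc$loc_chrom[assoc$sdp %in% b_id] ==
                    map$locations$chrom[match(assoc$sdp[assoc$sdp %in% b_id],
                                              map$locations$sdp)]))
})

test_that("k-mer cross-mappability detects shared 29-mers within 2 mismatches", {
  set.seed(4)
  core <- paste(sample(c("A", "C", "G", "T"), 29, replace = TRUE),
                collapse = "")
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  s1 <- paste0(pad(40), core, pad(40))
  expect_true(kmer_cross_mappable(s1, paste0(pad(25), core, pad(10))))

  flip <- function(s, i, to) { substr(s, i, i) <- to; s }
  mm <- core
  for (i in c(2, 15, 28)) {
    mm <- flip(mm, i, setdiff(c("A", "C", "G", "T"),
                              substr(mm, i, i))[1])
  }
  expect_false(kmer_cross_mappable(paste0(strrep("A", 35), core),
                                   paste0(strrep("T", 35), mm)))
  expect_false(kmer_cross_mappable(strrep("AC", 40), strrep("GT", 40)))
  expect_warning(expect_false(kmer_cross_mappable("ACGT", core)),
                 "shorter than k")
})

test_that("cross-mappable distant associations are removed with a log", {
  map <- small_panel()
  lines <- map$lines
  loc <- map$locations[map$locations$unique &
                         map$locations$chrom == "chr1", ][1, ]
  ann <- data.frame(gene = c("Gtrans", "Gcis"),
                    chrom = c("chr3", loc$chrom),
                    start = c(1e6, loc$start), end = c(1.01e6, loc$start + 10))
  set.seed(8)
  traits <- matrix(rnorm(2 * length(lines)), 2,
                   dimnames = list(ann$gene, lines))
  assoc <- classify_local_distant(scan_associations(traits, map), ann, map)
  assoc <- assign_sdp_location(assoc, map)
  shared <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                  collapse = "")
  seqs <- c(Gtrans = shared, Gcis = shared)
  out <- cross_mappability_filter(assoc, seqs, ann)
  removed <- attr(out, "cross_map_removed")
  expect_true(all(c("Gtrans", loc$sdp) %in%
                    c(removed$gene, removed$sdp)))
  expect_false(any(out$gene == "Gtrans" & out$sdp == loc$sdp))
})

test_that("heritability follows 0.5 Va / (0.5 Va + Ve) on replicated strains", {
  h <- heritability(c(0, 2, 4, 6), c("s1", "s1", "s2", "s2"))
  expect_equal(h$V_A, 8)
  expect_equal(h$V_E, 2)
  expect_equal(h$h2, 2 / 3)
  # limits
  expect_equal(heritability(c(1, 1, 5, 5), rep(c("a", "b"), each = 2))$h2, 1)
  expect_equal(heritability(c(1, 3, 1, 3), rep(c("a", "b"), each = 2))$h2, 0)
  expect_error(heritability(1:4, rep("a", 4)), ">= 2 strains")
})

test_that("the fixation index matches hand-computed heterozygosity deficits", {
  expect_equal(fixation_index(c(0.3, 0.3, 0.3))$fst, 0)
  f <- fixation_index(c(0, 1))
  expect_equal(f$Hs, 0); expect_equal(f$Ht, 0.5); expect_equal(f$fst, 1)
  f2 <- fixation_index(c(0.2, 0.8))
  expect_equal(f2$Hs, 0.32); expect_equal(f2$Ht, 0.5)
  expect_equal(f2$fst, 1 - 0.32 / 0.5)
  # weighting and multi-locus averaging
  f3 <- fixation_index(rbind(c(0.2, 0.8), c(0.5, 0.5)))
  expect_equal(f3$fst, mean(c(0.36, 0)))
  expect_error(fixation_index(c(-0.1, 0.5)), "frequencies")
})

test_that("standardized effect sizes recover the planted variance fraction", {
  g <- rep(c(0, 1), each = 20)
  expect_equal(standardized_effect_size(g * 2, g), 1)
  set.seed(12)
  expect_lt(standardized_effect_size(rnorm(40), g), 0.2)

  # planted decomposition: delta at balanced groups explains
  # delta^2/4 / (delta^2/4 + sigma^2) of the variance, up to sampling noise
  delta <- 2; sigma <- 1
  expected <- (delta^2 / 4) / (delta^2 / 4 + sigma^2)
  est <- replicate(100, {
    standardized_effect_size(g * delta + rnorm(40, 0, sigma), g)
  })
  se <- stats::sd(est) / 10
  expect_lt(abs(mean(est) - expected), 3 * se + 0.02)
})

test_that("power is non-decreasing in planted effect size", {
  map <- small_panel()
  lines <- map$lines
  sdp <- rownames(map$patterns)[4]
  dose <- map$patterns[sdp, lines]
  set.seed(33)
  power_at <- vapply(c(0, 0.5, 1, 2, 4), function(eff) {
    traits <- matrix(rnorm(50 * length(lines)), 50,
                     dimnames = list(sprintf("G%02d", 1:50), lines))
    traits <- traits + outer(rep(eff, 50), dose)
    a <- scan_associations(traits, map$patterns[sdp, , drop = FALSE])
    mean(a$p < 0.01)
  }, numeric(1))
  expect_true(all(diff(power_at) >= -0.02))
  expect_lt(power_at[1], 0.1)
  expect_gt(power_at[5], 0.9)
})
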
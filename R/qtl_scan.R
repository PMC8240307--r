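#' Association scan of traits against SDP genotypes
#'
#' For every (gene, SDP) pair, simple linear regression of the trait across
#' lines on the SDP genotype coded 0/1: slope, t statistic (n - 2 df), and
#' two-sided p value. Computed in closed form via trait-genotype
#' correlations, equivalent to per-pair OLS. SDPs that are monomorphic over
#' the available lines are skipped (logged in the `"skipped"` attribute).
#'
#' @param traits Numeric matrix, genes x lines (e.g. normalized mRNA counts,
#'   normalized Ribo counts, or the residual matrix of a `te_matrix`).
#' @param map An `sdp_map` (or a 0/1 genotype matrix SDPs x lines).
#' @param trait_type Label stored in the result: `"eQTL"`, `"riboQTL"`, or
#'   `"teQTL"`.
#' @return An `association_table` data frame: gene, sdp, trait, slope, t, p.
#' @export
scan_associations <- function(traits, map,
                              trait_type = c("teQTL", "eQTL", "riboQTL")) {
  trait_type <- match.arg(trait_type)
  geno <- if (inherits(map, "sdp_map")) map$patterns else map
  lines <- intersect(colnames(traits), colnames(geno))
  if (length(lines) < 4L) stop("traits and genotypes share fewer than 4 lines")
  y <- traits[, lines, drop = FALSE]
  x <- geno[, lines, drop = FALSE]
  keep <- rowSums(x) > 0L & rowSums(x) < ncol(x)
  skipped <- rownames(x)[!keep]
  x <- x[keep, , drop = FALSE]
  n <- length(lines)

  ys <- y - rowMeans(y)
  sy <- sqrt(rowSums(ys^2))
  xs <- x - rowMeans(x)
  sx <- sqrt(rowSums(xs^2))
  r <- (ys %*% t(xs)) / (sy %o% sx)
  r[!is.finite(r)] <- 0  # zero-variance traits carry no association
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.xmin))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  slope <- r * (sy %o% (1 / sx))

  out <- data.frame(
    gene = rep(rownames(y), times = nrow(x)),
    sdp = rep(rownames(x), each = nrow(y)),
    trait = trait_type,
    slope = as.vector(slope),
    t = as.vector(tstat),
    p = as.vector(p)
  )
  class(out) <- c("association_table", "data.frame")
  attr(out, "n_lines") <- n
  attr(out, "skipped") <- skipped
  out
}

#' Classify associations as local, distant, or same-chromosome-other
#'
#' A QTL is local when any of the SDP's genomic locations overlaps the gene
#' span, and distant when every location lies on a chromosome different from
#' the gene's. Associations on the gene's chromosome but outside its SDP
#' block form the `same-chromosome-other` class: they enter neither
#' multiple-testing stratum but are retained in the output.
#'
#' @param assoc An `association_table`.
#' @param annotation Data frame with `gene`, `chrom`, `start`, `end`.
#' @param map An `sdp_map`.
#' @return The table with a `class` column added.
#' @export
classify_local_distant <- function(assoc, annotation, map) {
  loc <- map$locations
  g <- match(assoc$gene, annotation$gene)
  if (anyNA(g)) stop("annotation missing genes present in the scan")
  ## per (gene, sdp): any overlapping location / all on other chromosomes
  pairs <- merge(
    data.frame(row = seq_len(nrow(assoc)), gene = assoc$gene, sdp = assoc$sdp,
               g_chrom = annotation$chrom[g], g_start = annotation$start[g],
               g_end = annotation$end[g]),
    loc[c("sdp", "chrom", "start", "end")],
    by = "sdp")
  pairs$local <- pairs$chrom == pairs$g_chrom &
    pairs$start <= pairs$g_end & pairs$end >= pairs$g_start
  pairs$other_chrom <- pairs$chrom != pairs$g_chrom
  any_local <- tapply(pairs$local, pairs$row, any)
  all_other <- tapply(pairs$other_chrom, pairs$row, all)
  cls <- ifelse(any_local, "local",
                ifelse(all_other, "distant", "same-chromosome-other"))
  assoc$class <- unname(cls[as.character(seq_len(nrow(assoc)))])
  assoc
}

#' Benjamini-Hochberg correction, stratified by local/distant class
#'
#' BH step-up within the local stratum and within the distant stratum
#' independently; `same-chromosome-other` associations get `NA`.
#'
#' @param assoc A classified `association_table`.
#' @return The table with a `p_bh` column added.
#' @export
bh_stratified <- function(assoc) {
  if (is.null(assoc$class)) stop("run classify_local_distant() first")
  assoc$p_bh <- NA_real_
  for (cl in c("local", "distant")) {
    i <- assoc$class == cl
    if (any(i)) assoc$p_bh[i] <- p.adjust(assoc$p[i], method = "BH")
  }
  assoc
}

#' Empirical p value from permutation counts
#'
#' Converts "k permuted statistics at least as extreme out of n_perm runs"
#' into an empirical p value. The default convention is `k / n_perm`
#' (allowing 0), matching the significance threshold arithmetic of
#' 15 more-extreme statistics among 10,000 permutations = 0.0015. The
#' add-one convention `(k + 1) / (n_perm + 1)` is available.
#'
#' @param k Count(s) of permuted statistics with `|t|` at least the observed.
#' @param n_perm Number of permutation runs.
#' @param convention `"k_over_n"` (default) or `"add_one"`.
#' @return Empirical p value(s).
#' @export
empirical_pvalue <- function(k, n_perm, convention = c("k_over_n", "add_one")) {
  convention <- match.arg(convention)
  if (convention == "k_over_n") k / n_perm else (k + 1) / (n_perm + 1)
}

#' Permutation-based empirical significance for an association scan
#'
#' Derives the empirical null of the scan statistics by randomizing the
#' sample labels of the whole trait matrix: each run applies one random
#' permutation of the line labels, shared across genes (preserving
#' inter-gene correlation), recomputes the full scan against the fixed
#' genotypes, and counts, per (gene, SDP) pair, how often the permuted |t|
#' reaches the observed |t|.
#'
#' @param traits Trait matrix (genes x lines).
#' @param map `sdp_map` or genotype matrix.
#' @param n_perm Number of permutation runs (>= 100; the paper-scale run
#'   uses 10,000).
#' @param seed Integer seed.
#' @param threshold Empirical significance threshold (default 0.0015,
#'   i.e. 15/10,000).
#' @param convention Passed to [empirical_pvalue()].
#' @return Numeric matrix (genes x SDPs) of empirical p values, with the
#'   threshold in the `"threshold"` attribute.
#' @export
permutation_empirical_p <- function(traits, map, n_perm = 1000L, seed = 1L,
                                    threshold = 0.0015,
                                    convention = c("k_over_n", "add_one")) {
  convention <- match.arg(convention)
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (n_perm < 1 / threshold) {
    warning("n_perm = ", n_perm, " cannot resolve the threshold ", threshold,
            " under the k/n convention")
  }
  geno <- if (inherits(map, "sdp_map")) map$patterns else map
  lines <- intersect(colnames(traits), colnames(geno))
  y <- traits[, lines, drop = FALSE]
  x <- geno[, lines, drop = FALSE]
  keep <- rowSums(x) > 0L & rowSums(x) < ncol(x)
  x <- x[keep, , drop = FALSE]
  n <- length(lines)

  scale_rows <- function(m) {
    mc <- m - rowMeans(m)
    s <- sqrt(rowSums(mc^2))
    s[s == 0] <- 1
    mc / s
  }
  ys <- scale_rows(y)
  xs <- t(scale_rows(x))
  ## |r| ordering equals |t| ordering at fixed n, so count on |r|
  obs <- abs(ys %*% xs)
  set.seed(seed)
  k <- matrix(0L, nrow(obs), ncol(obs))
  for (b in seq_len(n_perm)) {
    perm <- sample.int(n)
    k <- k + (abs(ys[, perm, drop = FALSE] %*% xs) >= obs)
  }
  emp <- empirical_pvalue(k, n_perm, convention)
  dimnames(emp) <- dimnames(obs)
  attr(emp, "threshold") <- threshold
  emp
}

#' Attach empirical p values to an association table
#'
#' @param assoc An `association_table`.
#' @param emp Matrix from [permutation_empirical_p()].
#' @return The table with `p_emp` and logical `significant` columns
#'   (`p_emp <= threshold`).
#' @export
add_empirical_p <- function(assoc, emp) {
  idx <- cbind(match(assoc$gene, rownames(emp)), match(assoc$sdp, colnames(emp)))
  assoc$p_emp <- emp[idx]
  assoc$significant <- !is.na(assoc$p_emp) &
    assoc$p_emp <= attr(emp, "threshold")
  assoc
}

#' Resolve the genomic location of multi-location SDP associations
#'
#' A repeated SDP occurs at several genomic locations; a significant
#' association must be attributed to one of them. True associations are
#' expected to echo in the neighboring SDPs (genotype changes between
#' neighbors are gradual), so each candidate location is scored by the
#' summed -log10 nominal p of the same gene's associations to the
#' immediately flanking SDP locations (one on each side). The top-scoring
#' location is assigned; ties (including chromosome ends with no flanks
#' anywhere) fall back to the first genomic location with an ambiguity flag.
#'
#' @param assoc An `association_table` with nominal p values.
#' @param map An `sdp_map`.
#' @return The table with `loc_chrom`, `loc_start`, `loc_end`, and
#'   `loc_ambiguous` columns.
#' @export
assign_sdp_location <- function(assoc, map) {
  loc <- map$locations
  loc <- loc[order(loc$chrom, loc$start), , drop = FALSE]
  loc$loc_id <- seq_len(nrow(loc))
  ## flanking SDP of each location (previous/next location on the chromosome)
  loc$prev_sdp <- NA_character_
  loc$next_sdp <- NA_character_
  for (chr in unique(loc$chrom)) {
    i <- which(loc$chrom == chr)
    if (length(i) > 1L) {
      loc$prev_sdp[i[-1L]] <- loc$sdp[i[-length(i)]]
      loc$next_sdp[i[-length(i)]] <- loc$sdp[i[-1L]]
    }
  }

  first_loc <- loc[!duplicated(loc$sdp), , drop = FALSE]
  fi <- match(assoc$sdp, first_loc$sdp)
  assoc$loc_chrom <- first_loc$chrom[fi]
  assoc$loc_start <- first_loc$start[fi]
  assoc$loc_end <- first_loc$end[fi]
  assoc$loc_ambiguous <- FALSE

  multi <- names(which(table(loc$sdp) > 1L))
  if (!length(multi)) return(assoc)

  p_lookup <- setNames(assoc$p, paste(assoc$gene, assoc$sdp))
  score_of <- function(gene, flank) {
    if (is.na(flank)) return(0)
    p <- p_lookup[paste(gene, flank)]
    if (is.na(p)) 0 else -log10(pmax(p, .Machine$double.xmin))
  }
  rows <- which(assoc$sdp %in% multi)
  for (ri in rows) {
    cand <- loc[loc$sdp == assoc$sdp[ri], , drop = FALSE]
    sc <- vapply(seq_len(nrow(cand)), function(j) {
      score_of(assoc$gene[ri], cand$prev_sdp[j]) +
        score_of(assoc$gene[ri], cand$next_sdp[j])
    }, numeric(1))
    best <- which(sc == max(sc))
    pick <- cand[best[1L], ]
    assoc$loc_chrom[ri] <- pick$chrom
    assoc$loc_start[ri] <- pick$start
    assoc$loc_end[ri] <- pick$end
    assoc$loc_ambiguous[ri] <- length(best) > 1L || max(sc) == 0
  }
  assoc
}

#' Cross-mappability filter for distant associations
#'
#' Gene pairs whose coding sequences share any k-mer within a Hamming
#' distance of `max_mm` mismatches are susceptible to read cross-mapping,
#' which can fabricate distant QTLs. A distant association is removed when
#' its gene is cross-mappable with any gene residing inside the associated
#' SDP's (assigned) location interval. The k-mer search is exact brute force
#' over all k-mer pairs.
#'
#' @param assoc A classified `association_table` (with assigned locations if
#'   multi-location SDPs are present).
#' @param sequences Named character vector of gene CDS sequences (A/C/G/T).
#' @param annotation Data frame with `gene`, `chrom`, `start`, `end`.
#' @param k K-mer length (default 29, the trimmed read length).
#' @param max_mm Maximum mismatches (default 2).
#' @return The filtered table; removed rows are recorded in the
#'   `"cross_map_removed"` attribute.
#' @export
cross_mappability_filter <- function(assoc, sequences, annotation, k = 29L,
                                     max_mm = 2L) {
  if (is.null(assoc$class)) stop("run classify_local_distant() first")
  if (is.null(assoc$loc_chrom)) {
    stop("run assign_sdp_location() first (location intervals needed)")
  }
  distant <- which(assoc$class == "distant")
  removed <- integer()
  for (ri in distant) {
    g <- assoc$gene[ri]
    if (is.na(match(g, names(sequences)))) next
    in_block <- annotation$chrom == assoc$loc_chrom[ri] &
      annotation$start <= assoc$loc_end[ri] &
      annotation$end >= assoc$loc_start[ri] &
      annotation$gene != g
    for (other in intersect(annotation$gene[in_block], names(sequences))) {
      if (kmer_cross_mappable(sequences[[g]], sequences[[other]], k, max_mm)) {
        removed <- c(removed, ri)
        break
      }
    }
  }
  out <- if (length(removed)) assoc[-removed, , drop = FALSE] else assoc
  attr(out, "cross_map_removed") <- assoc[removed, c("gene", "sdp"),
                                          drop = FALSE]
  out
}

#' Test two sequences for shared k-mers within a mismatch tolerance
#'
#' Exact all-pairs scan: every k-mer of `seq1` is compared against every
#' k-mer of `seq2`; `TRUE` as soon as one pair has at most `max_mm`
#' mismatching positions. Sequences shorter than `k` yield `FALSE` (skipped,
#' with a warning).
#'
#' @param seq1,seq2 DNA sequences as single strings.
#' @param k K-mer length.
#' @param max_mm Maximum Hamming mismatches.
#' @return Logical.
#' @export
kmer_cross_mappable <- function(seq1, seq2, k = 29L, max_mm = 2L) {
  r1 <- utf8ToInt(toupper(seq1))
  r2 <- utf8ToInt(toupper(seq2))
  if (length(r1) < k || length(r2) < k) {
    warning("sequence shorter than k = ", k, "; skipped")
    return(FALSE)
  }
  m1 <- embed(r1, k)[, k:1, drop = FALSE]
  m2 <- embed(r2, k)[, k:1, drop = FALSE]
  for (i in seq_len(nrow(m1))) {
    mm <- rowSums(m2 != matrix(m1[i, ], nrow(m2), k, byrow = TRUE))
    if (any(mm <= max_mm)) return(TRUE)
  }
  FALSE
}

#' Narrow-sense heritability from replicated lines
#'
#' `h2 = 0.5 * V_A / (0.5 * V_A + V_E)`, where `V_A` is the variance of the
#' strain means (additive genetic component) and `V_E` the mean within-strain
#' variance (environmental component). The 0.5 reflects the doubled additive
#' variance among fully inbred strains.
#'
#' @param values Numeric trait values over replicated animals.
#' @param strain Factor/character of strain membership, parallel to `values`.
#' @return A list with `V_A`, `V_E`, and `h2`.
#' @export
heritability <- function(values, strain) {
  strain <- as.factor(strain)
  if (nlevels(strain) < 2L) stop("need >= 2 strains")
  if (any(table(strain) < 2L)) stop("every strain needs >= 2 replicates")
  means <- tapply(values, strain, mean)
  v_a <- var(as.vector(means))
  v_e <- mean(tapply(values, strain, var))
  list(V_A = v_a, V_E = v_e, h2 = 0.5 * v_a / (0.5 * v_a + v_e))
}

#' Fixation index from subpopulation allele frequencies
#'
#' `Fst = 1 - Hs / Ht` per locus, averaged over loci: `Hs` is the (size-
#' weighted) mean expected heterozygosity `2p(1-p)` within subpopulations
#' and `Ht` the expected heterozygosity at the pooled frequency. 0 means no
#' differentiation between subpopulations, 1 complete differentiation.
#'
#' @param freqs Matrix of allele frequencies, loci x subpopulations (a
#'   vector is treated as one locus).
#' @param sizes Subpopulation sizes (weights); default equal.
#' @return A list with per-locus averages `Hs`, `Ht`, and `fst`.
#' @export
fixation_index <- function(freqs, sizes = NULL) {
  if (is.vector(freqs)) freqs <- matrix(freqs, nrow = 1L)
  if (any(freqs < 0 | freqs > 1)) stop("frequencies must be in [0, 1]")
  if (is.null(sizes)) sizes <- rep(1, ncol(freqs))
  w <- sizes / sum(sizes)
  hs <- as.vector((2 * freqs * (1 - freqs)) %*% w)
  pbar <- as.vector(freqs %*% w)
  ht <- 2 * pbar * (1 - pbar)
  ok <- ht > 0
  fst <- 1 - hs[ok] / ht[ok]
  list(Hs = mean(hs), Ht = mean(ht), fst = mean(fst))
}

#' Standardized effect size of a biallelic genotype on a trait
#'
#' The difference in genotype-class means expressed as the proportion of
#' total trait variance explained by the genotype factor: between-group sum
#' of squares over total sum of squares.
#'
#' @param trait Numeric vector.
#' @param genotype 0/1 (or two-level) vector, parallel to `trait`.
#' @return Proportion in [0, 1].
#' @export
standardized_effect_size <- function(trait, genotype) {
  g <- as.factor(genotype)
  if (nlevels(g) != 2L) stop("both genotype classes must be present")
  total <- sum((trait - mean(trait))^2)
  if (total == 0) return(0)
  means <- tapply(trait, g, mean)
  ns <- table(g)
  between <- sum(ns * (means - mean(trait))^2)
  as.numeric(between / total)
}

#' Full QTL mapping of a trait matrix
#'
#' One-call wrapper: scan, local/distant classification, stratified BH, and
#' permutation empirical p values.
#'
#' @inheritParams scan_associations
#' @inheritParams permutation_empirical_p
#' @param annotation Gene annotation (gene, chrom, start, end).
#' @return A complete `association_table`.
#' @export
map_qtl <- function(traits, map, annotation,
                    trait_type = c("teQTL", "eQTL", "riboQTL"),
                    n_perm = 1000L, seed = 1L, threshold = 0.0015) {
  assoc <- scan_associations(traits, map, trait_type)
  assoc <- classify_local_distant(assoc, annotation, map)
  assoc <- bh_stratified(assoc)
  emp <- permutation_empirical_p(traits, map, n_perm = n_perm, seed = seed,
                                 threshold = threshold)
  assoc <- add_empirical_p(assoc, emp)
  assign_sdp_location(assoc, map)
}
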
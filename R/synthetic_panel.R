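#' Configuration for a simulated recombinant inbred panel
#'
#' Defines the genome and breeding structure of a two-founder RI panel:
#' 30 homozygous lines, each a mosaic of the two founder genomes, so that any
#' locus is carried by about half the lines per founder allele (~15/30 at the
#' default balance of 0.5).
#'
#' @param n_lines Number of RI lines (default 30; at least 4).
#' @param chromosomes Data frame with columns `name`, `length` (bp), and
#'   `n_markers`. Default: 5 chromosomes of 100 Mb with 200 markers each.
#' @param recomb_rate Expected crossovers per chromosome per line (homogeneous
#'   Poisson; default 1.7, giving ~40 pattern blocks per chromosome at 30
#'   lines).
#' @param allele_balance Target frequency of the second founder allele per
#'   locus, in (0, 1). Default 0.5.
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @return A `panel_config` list.
#' @export
panel_config <- function(n_lines = 30L,
                         chromosomes = default_chromosomes(),
                         recomb_rate = 1.7,
                         allele_balance = 0.5,
                         seed = 1L) {
  if (n_lines < 4L) stop("n_lines must be >= 4 (downstream regression undefined)")
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length", "n_markers") %in% names(chromosomes)),
            all(chromosomes$n_markers >= 1L),
            allele_balance > 0, allele_balance < 1,
            recomb_rate >= 0)
  structure(list(n_lines = as.integer(n_lines), chromosomes = chromosomes,
                 recomb_rate = recomb_rate, allele_balance = allele_balance,
                 seed = as.integer(seed)),
            class = "panel_config")
}

#' @rdname panel_config
#' @export
default_chromosomes <- function() {
  data.frame(name = paste0("chr", 1:5), length = 1e8, n_markers = 200L)
}

#' Simulate RI-panel founder-allele genotypes
#'
#' Each line's chromosome is a founder mosaic: the allele at the chromosome
#' start is Bernoulli(`allele_balance`), crossover counts are Poisson with
#' mean `recomb_rate`, and crossover positions are uniform. Marker positions
#' are drawn uniformly per chromosome and sorted.
#'
#' @param config A [panel_config()].
#' @return A [genotype_table()] with founder calls `"BN"` / `"SHR"`.
#' @export
simulate_genotypes <- function(config = panel_config()) {
  stopifnot(inherits(config, "panel_config"))
  set.seed(config$seed)
  alleles <- c("BN", "SHR")
  lines <- sprintf("L%02d", seq_len(config$n_lines))
  calls <- NULL
  info <- NULL
  for (i in seq_len(nrow(config$chromosomes))) {
    chr <- config$chromosomes$name[i]
    len <- config$chromosomes$length[i]
    nm <- config$chromosomes$n_markers[i]
    pos <- sort(sample.int(len, nm))
    chr_calls <- matrix("", nm, config$n_lines)
    for (l in seq_len(config$n_lines)) {
      start_allele <- rbinom(1L, 1L, config$allele_balance)
      n_xo <- rpois(1L, config$recomb_rate)
      xo <- sort(runif(n_xo, 1, len))
      # allele index flips at each crossover point
      segment <- findInterval(pos, xo)
      chr_calls[, l] <- alleles[1L + (start_allele + segment) %% 2L]
    }
    calls <- rbind(calls, chr_calls)
    info <- rbind(info, data.frame(
      marker = sprintf("%s_M%04d", chr, seq_len(nm)),
      chrom = chr, pos = pos, near_indel = FALSE))
  }
  colnames(calls) <- lines
  rownames(calls) <- info$marker
  genotype_table(calls, info, alleles = alleles)
}

#' Configuration for simulated paired expression data
#'
#' Describes the generative model for paired mRNA-seq / Ribo-seq gene-level
#' counts over the panel: per-gene log-normal baseline means, negative
#' binomial sampling with a shared dispersion, per-sample log-normal library
#' size factors, and planted genetic effects. Local (cis) effects act on the
#' mRNA mean and propagate to the Ribo mean, optionally with an extra
#' Ribo-only component (a cis teQTL). A trans hotspot multiplies Ribo means
#' only, with a per-gene log2 effect that is linear in log10 CDS length.
#'
#' @param n_genes Number of genes.
#' @param nb_dispersion Negative binomial dispersion (1/size); default 0.05.
#' @param mean_log Named vector `c(meanlog=, sdlog=)` of the log-normal
#'   distribution of baseline gene means. Default meanlog = log(250),
#'   sdlog = 1.
#' @param cds_log Named vector `c(meanlog=, sdlog=)` for the log-normal CDS
#'   length distribution; default median 1.5 kb (meanlog = log(1500)),
#'   sdlog = 0.8.
#' @param lib_size_sdlog Log-normal sd of per-sample size factors
#'   (default 0.2), exercising the joint normalization.
#' @param cis_effects `NULL` or a data frame with columns `gene` (index or
#'   id), `sdp` (SDP id, or `NA` to use the gene's own local SDP),
#'   `log2_mrna` (effect on the mRNA mean), and `log2_ribo_extra` (additional
#'   Ribo-only effect; a cis teQTL when nonzero).
#' @param hotspot `NULL` or a [hotspot_config()].
#' @param replicate_lines Character vector of line ids to duplicate with
#'   independent counting noise (for heritability estimation), or `NULL`.
#' @param filament `NULL` or a [filament_spec()]; when given, the first five
#'   genes are renamed to the filament subunits, get the spec's CDS lengths,
#'   and their Ribo means are set proportional to
#'   stoichiometry x CDS length / turnover so that turnover- and
#'   length-corrected footprint output matches composition stoichiometry.
#' @param seed Integer seed.
#' @return An `expression_sim_config` list.
#' @export
expression_sim_config <- function(n_genes = 1000L,
                                  nb_dispersion = 0.05,
                                  mean_log = c(meanlog = log(250), sdlog = 1),
                                  cds_log = c(meanlog = log(1500), sdlog = 0.8),
                                  lib_size_sdlog = 0.2,
                                  cis_effects = NULL,
                                  hotspot = NULL,
                                  replicate_lines = NULL,
                                  filament = NULL,
                                  seed = 1L) {
  stopifnot(n_genes >= 1L, nb_dispersion > 0)
  if (!is.null(hotspot)) stopifnot(inherits(hotspot, "hotspot_config"))
  structure(list(n_genes = as.integer(n_genes), nb_dispersion = nb_dispersion,
                 mean_log = mean_log, cds_log = cds_log,
                 lib_size_sdlog = lib_size_sdlog, cis_effects = cis_effects,
                 hotspot = hotspot, replicate_lines = replicate_lines,
                 filament = filament, seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Planted trans hotspot for the expression simulator
#'
#' The hotspot shifts translational efficiency as a linear function of log10
#' CDS length: for a target gene g, the log2 Ribo-only effect in lines
#' carrying the second founder allele is
#' `intercept + slope * (log10(cds_g) - median(log10 cds))`. A negative slope
#' reproduces the hypertrophic-heart phenotype: long CDSs translated less,
#' short CDSs more. The default slope (-0.22) is calibrated so that, with the
#' default count model, the panel-wide squared SMA correlation between log10
#' CDS length and Ribo-seq fold change is about 0.26.
#'
#' @param sdp SDP id of the hotspot locus, or `NA` to pick (reproducibly) a
#'   balanced SDP at simulation time.
#' @param n_targets Number of affected genes, or `NULL` for a
#'   translatome-wide effect (every gene is a target).
#' @param slope Log2 TE effect per decade of CDS length.
#' @param intercept Log2 TE effect at the panel median CDS length.
#' @return A `hotspot_config` list.
#' @export
hotspot_config <- function(sdp = NA, n_targets = NULL, slope = -0.22,
                           intercept = 0) {
  structure(list(sdp = sdp, n_targets = n_targets, slope = slope,
                 intercept = intercept),
            class = "hotspot_config")
}

#' Simulate paired mRNA-seq / Ribo-seq counts with planted effects
#'
#' @param genotypes A [genotype_table()] or `sdp_map`; a genotype table is
#'   collapsed to SDPs internally. Planted effects reference SDP ids.
#' @param config An [expression_sim_config()].
#' @return A list with `mrna` and `ribo` count matrices (genes x samples;
#'   replicate lines appear as extra columns suffixed `_r2`, ...), a gene
#'   `annotation` data frame (chrom, start, end, strand, lengths), and
#'   `truth`: the planted cis effects, hotspot locus/targets/effects, and
#'   true size factors.
#' @export
simulate_expression <- function(genotypes, config = expression_sim_config()) {
  stopifnot(inherits(config, "expression_sim_config"))
  map <- if (inherits(genotypes, "genotype_table")) {
    build_sdp_map(genotypes, filter = FALSE)
  } else genotypes
  stopifnot(inherits(map, "sdp_map"))
  set.seed(config$seed)

  n_genes <- config$n_genes
  lines <- map$lines
  n <- length(lines)
  genes <- sprintf("G%04d", seq_len(n_genes))

  ## gene annotation: uniform placement over the map's chromosomes
  chroms <- unique(map$locations$chrom)
  chr_len <- vapply(chroms, function(ch) {
    max(map$locations$end[map$locations$chrom == ch])
  }, numeric(1))
  g_chr <- sample(chroms, n_genes, replace = TRUE)
  cds_len <- pmax(100, round(rlnorm(n_genes, config$cds_log[["meanlog"]],
                                    config$cds_log[["sdlog"]])))
  utr5 <- pmax(10, round(rlnorm(n_genes, log(150), 0.6)))
  utr3 <- pmax(20, round(rlnorm(n_genes, log(800), 0.7)))
  g_start <- floor(runif(n_genes, 1, chr_len[g_chr] * 0.98))
  annotation <- data.frame(
    gene = genes, chrom = g_chr, start = g_start,
    end = g_start + cds_len + utr5 + utr3 - 1,
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    cds_length = cds_len, utr5_length = utr5, utr3_length = utr3,
    transcript_length = cds_len + utr5 + utr3
  )

  spec <- config$filament
  if (!is.null(spec)) {
    if (n_genes < length(spec$genes)) stop("too few genes for filament spec")
    idx <- seq_along(spec$genes)
    annotation$gene[idx] <- spec$genes
    annotation$cds_length[idx] <- spec$cds_length
    genes <- annotation$gene
  }

  ## sample layout (replicated lines get independent noise, same genotype)
  rep_lines <- config$replicate_lines
  if (!is.null(rep_lines) && !all(rep_lines %in% lines)) {
    stop("replicate_lines must reference existing lines")
  }
  samples <- lines
  sample_line <- lines
  if (!is.null(rep_lines)) {
    extra <- unlist(lapply(rep_lines, function(l) paste0(l, "_r", 2:3)))
    samples <- c(samples, extra)
    sample_line <- c(sample_line, rep(rep_lines, each = 2L))
  }
  n_samp <- length(samples)

  ## genotype dosage per (sdp, sample)
  geno <- map$patterns[, sample_line, drop = FALSE]
  colnames(geno) <- samples

  ## baseline means and planted effect matrices (log2 scale)
  base <- rlnorm(n_genes, config$mean_log[["meanlog"]],
                 config$mean_log[["sdlog"]])
  log2_mrna <- matrix(0, n_genes, n_samp, dimnames = list(genes, samples))
  log2_ribo <- matrix(0, n_genes, n_samp, dimnames = list(genes, samples))

  cis <- config$cis_effects
  if (!is.null(cis)) {
    cis$gene_id <- if (is.numeric(cis$gene)) genes[cis$gene] else cis$gene
    for (i in seq_len(nrow(cis))) {
      g <- cis$gene_id[i]
      sdp <- cis$sdp[i]
      if (is.na(sdp)) sdp <- local_sdp(annotation[annotation$gene == g, ], map)
      if (!sdp %in% rownames(geno)) stop("unknown SDP in cis_effects: ", sdp)
      dose <- geno[sdp, ]
      log2_mrna[g, ] <- log2_mrna[g, ] + cis$log2_mrna[i] * dose
      log2_ribo[g, ] <- log2_ribo[g, ] +
        (cis$log2_mrna[i] + cis$log2_ribo_extra[i]) * dose
      cis$sdp[i] <- sdp
    }
  }

  hs <- config$hotspot
  hs_truth <- NULL
  if (!is.null(hs)) {
    hs_sdp <- hs$sdp
    if (is.na(hs_sdp)) {
      ac <- rowSums(map$patterns)
      balanced <- which(ac >= floor(n / 3) & ac <= ceiling(2 * n / 3))
      hs_sdp <- rownames(map$patterns)[sample(balanced, 1L)]
    }
    targets <- if (is.null(hs$n_targets)) genes else {
      sample(genes, hs$n_targets)
    }
    if (anyNA(annotation$cds_length[match(targets, annotation$gene)])) {
      stop("hotspot target genes must have a CDS length")
    }
    med <- median(log10(annotation$cds_length))
    eff <- hs$intercept + hs$slope *
      (log10(annotation$cds_length[match(targets, annotation$gene)]) - med)
    dose <- geno[hs_sdp, ]
    log2_ribo[targets, ] <- log2_ribo[targets, ] + outer(eff, dose)
    hs_truth <- list(sdp = hs_sdp, targets = targets, log2_effect = eff,
                     slope = hs$slope, intercept = hs$intercept)
  }

  ## per-sample library size factors (shared layout, independent per assay)
  sf_mrna <- rlnorm(n_samp, 0, config$lib_size_sdlog)
  sf_ribo <- rlnorm(n_samp, 0, config$lib_size_sdlog)

  mu_mrna <- (base * 2^log2_mrna) %*% diag(sf_mrna)
  ribo_base <- base
  if (!is.null(spec)) {
    idx <- seq_along(spec$genes)
    ribo_base[idx] <- mean(base) * spec$stoichiometry * spec$cds_length /
      spec$turnover_days /
      mean(spec$stoichiometry * spec$cds_length / spec$turnover_days)
  }
  mu_ribo <- (ribo_base * 2^log2_ribo) %*% diag(sf_ribo)

  size <- 1 / config$nb_dispersion
  mrna <- matrix(rnbinom(length(mu_mrna), mu = mu_mrna, size = size),
                 n_genes, n_samp, dimnames = list(genes, samples))
  ribo <- matrix(rnbinom(length(mu_ribo), mu = mu_ribo, size = size),
                 n_genes, n_samp, dimnames = list(genes, samples))

  truth <- list(cis_effects = cis, hotspot = hs_truth,
                size_factors = data.frame(sample = samples,
                                          mrna = sf_mrna, ribo = sf_ribo),
                base_mean = setNames(base, genes),
                sample_line = setNames(sample_line, samples))
  list(mrna = mrna, ribo = ribo, annotation = annotation, truth = truth,
       map = map)
}

#' Local SDP of a gene
#'
#' The SDP whose location overlaps the gene span on the gene's chromosome;
#' if none overlaps, the nearest location on that chromosome.
#'
#' @param gene_row One-row data frame with `chrom`, `start`, `end`.
#' @param map An `sdp_map`.
#' @return An SDP id (or `NA` if the chromosome has no SDP).
#' @export
local_sdp <- function(gene_row, map) {
  loc <- map$locations[map$locations$chrom == gene_row$chrom, , drop = FALSE]
  if (!nrow(loc)) return(NA_character_)
  hit <- loc$start <= gene_row$end & loc$end >= gene_row$start
  if (any(hit)) return(loc$sdp[which(hit)[1L]])
  d <- pmax(loc$start - gene_row$end, gene_row$start - loc$end)
  loc$sdp[which.min(d)]
}

#' Write simulated panel outputs as tab-separated files
#'
#' @param sim Result of [simulate_expression()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes `mrna_counts.tsv`, `ribo_counts.tsv`,
#'   `annotation.tsv`, and a YAML `truth.yml` sidecar with the planted
#'   effects.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$mrna, file.path(dir, "mrna_counts.tsv"))
  write_counts(sim$ribo, file.path(dir, "ribo_counts.tsv"))
  write.table(sim$annotation, file.path(dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$base_mean <- NULL
  yaml::write_yaml(truth, file.path(dir, "truth.yml"))
  invisible(dir)
}
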
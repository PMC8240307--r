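#' Read / write gene-by-sample count matrices
#'
#' Plain tab-separated text: first column `gene`, remaining columns one per
#' sample.
#'
#' @param path File path.
#' @return `read_counts()` returns an integer matrix with gene row names.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  m <- as.matrix(df[-1L])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_counts
#' @param counts Matrix of counts, genes in rows.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Joint median-of-ratios normalization of paired count matrices
#'
#' Pools the columns of the mRNA-seq and Ribo-seq matrices and estimates one
#' size factor per sample by the median-of-ratios method on the pooled
#' matrix: per-gene geometric means over all pooled samples form the
#' reference (genes with any zero count are excluded), and each sample's
#' factor is the median ratio of its counts to the reference. Normalizing
#' both assays against a common reference is what makes Ribo and mRNA levels
#' comparable for translational-efficiency computation. Estimation is
#' delegated to DESeq2's `estimateSizeFactorsForMatrix()`.
#'
#' @param mrna,ribo Count matrices (genes x lines) over the same gene
#'   universe and line set.
#' @return A `normalized_expression` object: raw counts, per-assay size
#'   factors, and normalized matrices (`count / size factor`).
#' @export
joint_size_factors <- function(mrna, ribo) {
  stopifnot(is.matrix(mrna), is.matrix(ribo))
  if (!identical(rownames(mrna), rownames(ribo))) {
    common <- intersect(rownames(mrna), rownames(ribo))
    if (!length(common)) stop("mrna and ribo share no genes")
    mrna <- mrna[common, , drop = FALSE]
    ribo <- ribo[common, , drop = FALSE]
  }
  if (any(mrna < 0) || any(ribo < 0)) stop("negative counts")
  pooled <- cbind(mrna, ribo)
  if (!any(rowSums(pooled == 0) == 0L)) {
    stop("no reference genes: every gene has a zero count in some sample")
  }
  sf <- DESeq2::estimateSizeFactorsForMatrix(pooled)
  n1 <- ncol(mrna)
  sf_mrna <- sf[seq_len(n1)]
  sf_ribo <- sf[-seq_len(n1)]
  structure(
    list(mrna = mrna, ribo = ribo,
         size_factors = data.frame(
           sample = c(colnames(mrna), colnames(ribo)),
           assay = rep(c("mRNA", "Ribo"), c(n1, ncol(ribo))),
           factor = unname(sf)),
         mrna_norm = sweep(mrna, 2L, sf_mrna, "/"),
         ribo_norm = sweep(ribo, 2L, sf_ribo, "/")),
    class = "normalized_expression"
  )
}

#' @export
print.normalized_expression <- function(x, ...) {
  cat("normalized_expression:", nrow(x$mrna), "genes x", ncol(x$mrna),
      "lines (mRNA + Ribo)\n")
  cat("  size factor range:",
      paste(signif(range(x$size_factors$factor), 3), collapse = " - "), "\n")
  invisible(x)
}

#' Per-gene translational efficiency as mRNA-regressed Ribo residuals
#'
#' For each gene, ordinary least squares of normalized Ribo-seq counts on
#' normalized mRNA-seq counts across lines; the residual vector is the
#' gene's TE trait, retaining a quantitative per-line range suitable for QTL
#' mapping (unlike ratio-based TE). Genes whose mRNA predictor has zero
#' variance get centered Ribo values as residuals and are flagged. Genes
#' with zero counts in more than half the lines (either assay) are excluded.
#'
#' @param norm A `normalized_expression` from [joint_size_factors()].
#' @param log_scale Regress on `log2(normalized count + 0.5)` instead of the
#'   normalized-count scale. Default `FALSE` (the count-scale model).
#' @return A `te_matrix`: residual matrix (genes x lines), per-gene `fits`
#'   data frame (slope, intercept, flags), and the scale used.
#' @export
compute_te <- function(norm, log_scale = FALSE) {
  stopifnot(inherits(norm, "normalized_expression"))
  n <- ncol(norm$mrna_norm)
  if (n < 4L) stop("need >= 4 lines for TE regression")
  zeros <- rowMeans(norm$mrna == 0) > 0.5 | rowMeans(norm$ribo == 0) > 0.5
  x <- norm$mrna_norm[!zeros, , drop = FALSE]
  y <- norm$ribo_norm[!zeros, , drop = FALSE]
  if (log_scale) {
    x <- log2(x + 0.5)
    y <- log2(y + 0.5)
  }
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  sxx <- rowSums(xc^2)
  degenerate <- sxx < .Machine$double.eps * pmax(1, rowSums(x^2))
  slope <- ifelse(degenerate, 0, rowSums(xc * yc) / ifelse(sxx == 0, 1, sxx))
  resid <- yc - slope * xc
  fits <- data.frame(gene = rownames(x), slope = slope,
                     intercept = rowMeans(y) - slope * rowMeans(x),
                     degenerate_predictor = degenerate,
                     row.names = NULL)
  structure(list(te = resid, fits = fits, log_scale = log_scale,
                 excluded = rownames(norm$mrna)[zeros]),
            class = "te_matrix")
}

#' @export
print.te_matrix <- function(x, ...) {
  cat("te_matrix:", nrow(x$te), "genes x", ncol(x$te), "lines",
      if (x$log_scale) "(log scale)" else "(count scale)", "\n")
  if (length(x$excluded)) cat("  excluded (sparse):", length(x$excluded), "\n")
  invisible(x)
}

#' Expression and length filters for downstream analyses
#'
#' Returns the gene sets passing (a) the length-analysis filter -- CDS of at
#' least 100 nt and a mean normalized count strictly greater than
#' `min_mean_count` -- and (b) the expression filter on length-normalized
#' abundance (mean normalized count per kb of CDS at least `min_rpk`).
#'
#' @param norm A `normalized_expression`.
#' @param annotation Data frame with `gene` and `cds_length`.
#' @param min_cds Minimum CDS length in nt (default 100).
#' @param min_mean_count Mean normalized count must exceed this (strict;
#'   default 10).
#' @param min_rpk Minimum mean normalized count per kb of CDS (default 1).
#' @param assay Which assay's normalized counts to average (default mRNA).
#' @return A list with character vectors `length_analysis` and `expressed`.
#' @export
filter_expressed <- function(norm, annotation, min_cds = 100,
                             min_mean_count = 10, min_rpk = 1,
                             assay = c("mRNA", "Ribo")) {
  assay <- match.arg(assay)
  m <- if (assay == "mRNA") norm$mrna_norm else norm$ribo_norm
  cds <- annotation$cds_length[match(rownames(m), annotation$gene)]
  mean_count <- rowMeans(m)
  list(
    length_analysis = rownames(m)[!is.na(cds) & cds >= min_cds &
                                    mean_count > min_mean_count],
    expressed = rownames(m)[!is.na(cds) & mean_count / (cds / 1000) >= min_rpk]
  )
}

#' Per-gene log2 fold change between two line groups
#'
#' `log2(mean(group2) / mean(group1))` on normalized counts, with a
#' pseudo-count of 0.5 substituted for zero group means. Splitting the panel
#' by local genotype at a locus (first founder allele = group 1, second =
#' group 2) gives the fold change attributable to that locus.
#'
#' @param norm_mat Normalized count matrix (genes x lines), e.g.
#'   `norm$ribo_norm`.
#' @param group1,group2 Character vectors of line ids (both non-empty).
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
group_fold_change <- function(norm_mat, group1, group2) {
  stopifnot(length(group1) > 0, length(group2) > 0,
            all(c(group1, group2) %in% colnames(norm_mat)))
  m1 <- rowMeans(norm_mat[, group1, drop = FALSE])
  m2 <- rowMeans(norm_mat[, group2, drop = FALSE])
  m1[m1 == 0] <- 0.5
  m2[m2 == 0] <- 0.5
  log2(m2 / m1)
}

#' Fold change between genotype classes at an SDP
#'
#' Convenience wrapper around [group_fold_change()]: lines carrying the
#' second founder allele at `sdp` form group 2.
#'
#' @param norm_mat Normalized count matrix (genes x lines).
#' @param map An `sdp_map`.
#' @param sdp SDP id.
#' @return Named numeric vector of per-gene log2 fold changes
#'   (second vs first founder allele).
#' @export
sdp_fold_change <- function(norm_mat, map, sdp) {
  pat <- map$patterns[sdp, ]
  lines <- intersect(colnames(norm_mat), names(pat))
  group_fold_change(norm_mat, lines[pat[lines] == 0L], lines[pat[lines] == 1L])
}
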
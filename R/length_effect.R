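#' Standardized major axis fit of fold change against a length covariate
#'
#' Symmetric line fit for the relationship between a log-scale length
#' covariate and per-gene expression fold changes: the SMA slope is
#' `sign(r) * sd(y) / sd(x)` with intercept through the means, and the
#' strength of the relationship is the squared Pearson correlation. The p
#' value is the test of the correlation coefficient against zero.
#'
#' @param x Covariate values, typically `log10(CDS length)`.
#' @param y Log2 fold changes, parallel to `x`.
#' @param covariate Label stored in the result (e.g. `"cds_length"`).
#' @return A `length_effect_result` list: `r`, `r2`, `sma_slope`,
#'   `sma_intercept`, `n`, `p`, `covariate`, and the `direction` class from
#'   [classify_direction()].
#' @export
sma_fit <- function(x, y, covariate = "cds_length") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete observations")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y: SMA undefined")
  r <- cor(x, y)
  slope <- sign(r) * sd(y) / sd(x)
  if (r == 0) slope <- sd(y) / sd(x)  # sign convention for exact zero
  p <- cor.test(x, y)$p.value
  structure(list(r = r, r2 = r^2, sma_slope = slope,
                 sma_intercept = mean(y) - slope * mean(x), n = n, p = p,
                 covariate = covariate, direction = classify_direction(r)),
            class = "length_effect_result")
}

#' @export
print.length_effect_result <- function(x, ...) {
  cat("SMA fit (", x$covariate, "): r2 =", signif(x$r2, 3),
      "slope =", signif(x$sma_slope, 3), "n =", x$n,
      "p =", format(x$p, digits = 3), "[", x$direction, "]\n")
  invisible(x)
}

#' Fisher r-to-z comparison of two correlation coefficients
#'
#' `Z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided normal p value. Used to test whether a length effect differs
#' between two conditions.
#'
#' @param r1,r2 Correlations (|r| < 1).
#' @param n1,n2 Sample sizes (both > 3).
#' @return A list with `Z` and `p`.
#' @export
fisher_r_to_z <- function(r1, n1, r2, n2) {
  stopifnot(abs(r1) < 1, abs(r2) < 1, n1 > 3, n2 > 3)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(Z = z, p = 2 * pnorm(-abs(z)))
}

#' Binned fold-change profile over increasing length
#'
#' Genes are sorted by length and split into `n_bins` equal-count bins (any
#' remainder spread over the first bins); the per-bin mean fold change is
#' z-scaled across bins, giving the row profile used in length-effect
#' heatmaps.
#'
#' @param fc Per-gene fold changes.
#' @param lengths Per-gene lengths, parallel to `fc`.
#' @param n_bins Number of bins (default 20; requires `length(fc) >= n_bins`).
#' @return Data frame: bin index, gene count, mean and median length,
#'   mean fold change, and the z-scaled profile value.
#' @export
bin_fold_changes <- function(fc, lengths, n_bins = 20L) {
  ok <- is.finite(fc) & is.finite(lengths)
  fc <- fc[ok]; lengths <- lengths[ok]
  n <- length(fc)
  if (n < n_bins) stop("need at least n_bins genes")
  n_bins <- as.integer(n_bins)
  ord <- order(lengths)
  sizes <- rep(n %/% n_bins, n_bins)
  rem <- n %% n_bins
  if (rem) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  sizes <- as.integer(sizes)
  bin <- rep(seq_len(n_bins), times = sizes)
  mean_fc <- tapply(fc[ord], bin, mean)
  data.frame(bin = seq_len(n_bins),
             n = as.vector(sizes),
             mean_length = as.vector(tapply(lengths[ord], bin, mean)),
             mean_fc = as.vector(mean_fc),
             scaled_fc = as.vector(scale(mean_fc)))
}

#' Direction class of a length correlation
#'
#' `"negative"` when r < -0.1, `"positive"` when r > 0.1, `"none"`
#' otherwise (boundaries excluded).
#'
#' @param r Correlation coefficient(s).
#' @param threshold Classification boundary (default 0.1).
#' @return Character vector of classes.
#' @export
classify_direction <- function(r, threshold = 0.1) {
  ifelse(r < -threshold, "negative", ifelse(r > threshold, "positive", "none"))
}

#' Flag datasets with an RNA-seq length artifact
#'
#' A correlation between mRNA-level fold change and length that is absent
#' from the Ribo-seq data points to a technical length bias (e.g. length
#' normalization of degraded poly(A) RNA) rather than a translational
#' effect. The dataset is flagged when the mRNA correlation exceeds
#' `threshold` in absolute value while the Ribo correlation does not.
#'
#' @param mrna_fc,ribo_fc Per-gene fold changes in each assay.
#' @param lengths Per-gene lengths (same order).
#' @param threshold Flagging threshold on |r| (default 0.15).
#' @return A list: `flag`, `r_mrna`, `r_ribo`.
#' @export
flag_rna_length_artifact <- function(mrna_fc, ribo_fc, lengths,
                                     threshold = 0.15) {
  lx <- log10(lengths)
  ok <- is.finite(lx)
  r_mrna <- cor(lx[ok], mrna_fc[ok])
  r_ribo <- cor(lx[ok], ribo_fc[ok])
  list(flag = abs(r_mrna) > threshold & abs(r_ribo) <= threshold,
       r_mrna = r_mrna, r_ribo = r_ribo)
}

#' Length-effect analysis of a fold-change table
#'
#' Applies the length-analysis filter (CDS >= `min_cds`, mean normalized
#' count strictly greater than `min_mean_count`) and fits the SMA
#' relationship between the chosen log10 length covariate and the fold
#' change.
#'
#' @param table Data frame with columns `gene`, `fc`, `mean_count`, and the
#'   length columns `cds_length`, `transcript_length`, `utr5_length`,
#'   `utr3_length` (only the chosen one is required).
#' @param covariate Which length to use (default CDS).
#' @param min_cds,min_mean_count Filter parameters (defaults 100 nt, 10).
#' @param log10_length Use log10 of the length (default `TRUE`).
#' @return A `length_effect_result` (see [sma_fit()]); the filtered gene
#'   count is the result's `n`.
#' @export
length_effect <- function(table,
                          covariate = c("cds_length", "transcript_length",
                                        "utr5_length", "utr3_length"),
                          min_cds = 100, min_mean_count = 10,
                          log10_length = TRUE) {
  covariate <- match.arg(covariate)
  keep <- table$cds_length >= min_cds & table$mean_count > min_mean_count
  df <- table[keep, , drop = FALSE]
  x <- df[[covariate]]
  if (log10_length) x <- log10(x)
  sma_fit(x, df$fc, covariate = covariate)
}
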
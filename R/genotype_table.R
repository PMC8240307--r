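#' Genotype table for a recombinant inbred panel
#'
#' A `genotype_table` holds founder-allele calls for biallelic markers across
#' inbred lines, together with the genomic position of every marker. Calls are
#' restricted to four states: the two founder alleles, heterozygous (`"HET"`),
#' and missing (`NA`). Markers are kept sorted by chromosome and position.
#'
#' @param calls Character matrix of allele calls, markers in rows and lines in
#'   columns. Row names are marker ids, column names line ids.
#' @param info Data frame with one row per marker and columns `marker`,
#'   `chrom`, `pos` (1-based bp), and optionally `near_indel` (logical; markers
#'   within 13 bp of an indel, defaults to `FALSE`).
#' @param alleles Length-2 character vector naming the two founder alleles,
#'   in the order (reference founder, alternative founder). Default
#'   `c("BN", "SHR")`, matching the HXB/BXH panel founders.
#'
#' @return An object of class `genotype_table`: a list with elements `calls`,
#'   `info` (with an added `call_rate` column), and `alleles`.
#' @export
genotype_table <- function(calls, info, alleles = c("BN", "SHR")) {
  stopifnot(is.matrix(calls), nrow(calls) == nrow(info))
  if (length(alleles) != 2L || anyDuplicated(alleles)) {
    stop("`alleles` must name two distinct founder alleles")
  }
  required <- c("marker", "chrom", "pos")
  if (!all(required %in% names(info))) {
    stop("`info` must have columns marker, chrom, pos")
  }
  if (is.null(info$near_indel)) info$near_indel <- FALSE
  if (is.null(rownames(calls))) rownames(calls) <- info$marker
  bad <- !(calls %in% c(alleles, "HET")) & !is.na(calls)
  if (any(bad)) {
    stop("allele calls outside {", paste(alleles, collapse = ", "),
         ", HET, NA}: e.g. ", calls[which(bad)[1L]])
  }
  ord <- order(info$chrom, info$pos)
  info <- info[ord, , drop = FALSE]
  calls <- calls[ord, , drop = FALSE]
  if (any(duplicated(info[c("chrom", "pos")]))) {
    stop("duplicate marker positions within a chromosome")
  }
  info$call_rate <- rowMeans(!is.na(calls))
  rownames(info) <- NULL
  structure(
    list(calls = calls, info = info, alleles = alleles),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", nrow(x$calls), "markers x", ncol(x$calls), "lines\n")
  cat("  founders:", paste(x$alleles, collapse = " / "), "\n")
  cat("  chromosomes:", paste(unique(x$info$chrom), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$calls)

#' Read / write genotype tables as tab-separated text
#'
#' The on-disk dialect has one row per marker with columns `marker`, `chrom`,
#' `pos`, `near_indel`, followed by one column per line carrying the allele
#' calls (missing calls as `NA`).
#'
#' @param path File path.
#' @param alleles Founder allele alphabet, as in [genotype_table()].
#' @return `read_genotypes()` returns a `genotype_table`;
#'   `write_genotypes()` returns `path` invisibly.
#' @export
read_genotypes <- function(path, alleles = c("BN", "SHR")) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("marker", "chrom", "pos", "near_indel")
  lines <- setdiff(names(df), meta)
  calls <- as.matrix(df[lines])
  mode(calls) <- "character"
  rownames(calls) <- df$marker
  genotype_table(calls, df[intersect(meta, names(df))], alleles = alleles)
}

#' @rdname read_genotypes
#' @param gt A `genotype_table`.
#' @export
write_genotypes <- function(gt, path) {
  df <- cbind(gt$info[c("marker", "chrom", "pos", "near_indel")],
              as.data.frame(gt$calls, stringsAsFactors = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
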
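#' Marker filtering for QTL-ready genotype tables
#'
#' Removes markers that cannot serve as informative, reliable test units:
#' (i) markers within 13 bp of an indel (flagged in the input), (ii) markers
#' with any missing or heterozygous call, (iii) monomorphic markers, and
#' (iv) markers with a call rate below `min_call_rate`. Rules are applied in
#' this order and a per-rule removal count is attached as the `"filter_log"`
#' attribute.
#'
#' @param gt A [genotype_table()].
#' @param min_call_rate Minimum fraction of non-missing calls (default 0.99).
#' @return The filtered `genotype_table` (marker order preserved), with a
#'   `filter_log` attribute: a data frame of per-rule removal counts.
#' @export
filter_markers <- function(gt, min_call_rate = 0.99) {
  stopifnot(inherits(gt, "genotype_table"))
  calls <- gt$calls
  keep <- rep(TRUE, nrow(calls))
  log <- data.frame(rule = c("near_indel", "missing_or_het", "monomorphic",
                             "call_rate"),
                    removed = 0L)

  drop <- keep & gt$info$near_indel
  log$removed[1L] <- sum(drop); keep <- keep & !drop

  has_bad <- apply(calls, 1L, function(z) anyNA(z) || any(z == "HET"))
  drop <- keep & has_bad
  log$removed[2L] <- sum(drop); keep <- keep & !drop

  mono <- apply(calls, 1L, function(z) length(unique(z[!is.na(z)])) < 2L)
  drop <- keep & mono
  log$removed[3L] <- sum(drop); keep <- keep & !drop

  drop <- keep & gt$info$call_rate < min_call_rate
  log$removed[4L] <- sum(drop); keep <- keep & !drop

  if (!any(keep)) stop("no informative markers remain after filtering")
  out <- genotype_table(calls[keep, , drop = FALSE],
                        gt$info[keep, c("marker", "chrom", "pos", "near_indel")],
                        alleles = gt$alleles)
  attr(out, "filter_log") <- log
  out
}

new_sdp_map <- function(patterns, locations, markers, lines, alleles) {
  locations <- locations[order(locations$chrom, locations$start), , drop = FALSE]
  rownames(locations) <- NULL
  n_loc <- table(locations$sdp)
  locations$unique <- as.vector(n_loc[locations$sdp] == 1L)
  structure(
    list(patterns = patterns, locations = locations, markers = markers,
         lines = lines, alleles = alleles),
    class = "sdp_map"
  )
}

#' @export
print.sdp_map <- function(x, ...) {
  cat("sdp_map:", nrow(x$patterns), "SDPs over", nrow(x$locations),
      "genomic locations (", length(x$lines), "lines )\n")
  cat("  multi-location SDPs:",
      sum(!x$locations$unique[!duplicated(x$locations$sdp)]), "\n")
  invisible(x)
}

#' Collapse filtered markers into strain distribution pattern blocks
#'
#' Scans each chromosome in position order and opens a new SDP block whenever
#' the across-line allele pattern changes; consecutive markers sharing the
#' identical pattern belong to one block. Each block spans its first to last
#' member marker. Input markers must be fully called and biallelic (run
#' [filter_markers()] first).
#'
#' @param gt A filtered [genotype_table()].
#' @return An `sdp_map`: SDP patterns (0 = first founder allele, 1 = second),
#'   one genomic location per block, and the marker-to-SDP assignment.
#' @export
collapse_to_sdps <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  calls <- gt$calls
  if (anyNA(calls) || any(calls == "HET")) {
    stop("collapse_to_sdps() requires fully called biallelic markers; ",
         "run filter_markers() first")
  }
  num <- matrix(match(calls, gt$alleles) - 1L, nrow = nrow(calls),
                dimnames = dimnames(calls))
  key <- apply(num, 1L, paste, collapse = "")
  info <- gt$info

  blocks <- list(); pat_keys <- character()
  for (chr in unique(info$chrom)) {
    idx <- which(info$chrom == chr)
    r <- rle(key[idx])
    stops <- cumsum(r$lengths)
    starts <- c(1L, head(stops, -1L) + 1L)
    for (b in seq_along(r$values)) {
      m_idx <- idx[starts[b]:stops[b]]
      blocks[[length(blocks) + 1L]] <- list(
        chrom = chr,
        start = info$pos[m_idx[1L]],
        end = info$pos[m_idx[length(m_idx)]],
        markers = info$marker[m_idx],
        key = r$values[b]
      )
      pat_keys <- c(pat_keys, r$values[b])
    }
  }

  ids <- sprintf("SDP%04d", seq_along(blocks))
  patterns <- do.call(rbind, lapply(blocks, function(b) {
    as.integer(strsplit(b$key, "")[[1L]])
  }))
  dimnames(patterns) <- list(ids, colnames(calls))
  locations <- data.frame(
    sdp = ids,
    chrom = vapply(blocks, `[[`, character(1), "chrom"),
    start = vapply(blocks, function(b) as.numeric(b$start), numeric(1)),
    end = vapply(blocks, function(b) as.numeric(b$end), numeric(1)),
    n_markers = vapply(blocks, function(b) length(b$markers), integer(1))
  )
  markers <- data.frame(
    marker = unlist(lapply(blocks, `[[`, "markers")),
    sdp = rep(ids, locations$n_markers[match(ids, locations$sdp)])
  )
  markers$chrom <- info$chrom[match(markers$marker, info$marker)]
  markers$pos <- info$pos[match(markers$marker, info$marker)]
  new_sdp_map(patterns, locations, markers, colnames(calls), gt$alleles)
}

pattern_key <- function(patterns) apply(patterns, 1L, paste, collapse = "")

#' Merge genomically repeated SDPs into single multi-location entities
#'
#' Blocks anywhere in the genome that share an identical across-line pattern
#' become one SDP carrying multiple genomic locations, so each distinct
#' pattern is tested once. Positional information is preserved: every member
#' location is retained and flagged non-unique.
#'
#' @param map An `sdp_map` from [collapse_to_sdps()].
#' @return The merged `sdp_map`.
#' @export
merge_duplicate_sdps <- function(map) {
  stopifnot(inherits(map, "sdp_map"))
  keys <- pattern_key(map$patterns)
  canon <- rownames(map$patterns)[match(keys, keys)]  # first occurrence wins
  relabel <- setNames(canon, rownames(map$patterns))
  loc <- map$locations
  loc$sdp <- unname(relabel[loc$sdp])
  mk <- map$markers
  mk$sdp <- unname(relabel[mk$sdp])
  keep <- !duplicated(keys)
  new_sdp_map(map$patterns[keep, , drop = FALSE], loc, mk, map$lines,
              map$alleles)
}

#' Merge identical SDP locations separated by a single alternating block
#'
#' Along each chromosome, when two locations of the same SDP are separated by
#' exactly one location of a different SDP (e.g. a genotyping-error block),
#' they are merged into one spanning location. The intervening block is kept
#' as its own SDP. Adjacent same-SDP locations arising during merging are
#' unified, and the rule is applied iteratively until a fixed point.
#'
#' @param map An `sdp_map`, typically after [merge_duplicate_sdps()].
#' @return The `sdp_map` with interrupted locations merged.
#' @export
merge_interrupted_sdps <- function(map) {
  stopifnot(inherits(map, "sdp_map"))
  loc <- map$locations
  merged <- TRUE
  while (merged) {
    merged <- FALSE
    loc <- loc[order(loc$chrom, loc$start), , drop = FALSE]
    for (chr in unique(loc$chrom)) {
      idx <- which(loc$chrom == chr)
      if (length(idx) < 2L) next
      s <- loc$sdp[idx]
      # unify adjacent locations of the same SDP
      j <- which(s[-1L] == s[-length(s)])
      if (length(j)) {
        a <- idx[j[1L]]; b <- idx[j[1L] + 1L]
        loc$end[a] <- max(loc$end[a], loc$end[b])
        loc$start[a] <- min(loc$start[a], loc$start[b])
        loc$n_markers[a] <- loc$n_markers[a] + loc$n_markers[b]
        loc <- loc[-b, , drop = FALSE]
        merged <- TRUE
        break
      }
      # merge locations i and i+2 sharing an SDP across a single other block
      if (length(idx) < 3L) next
      j <- which(s[seq_len(length(s) - 2L)] == s[-(1:2)])
      if (length(j)) {
        a <- idx[j[1L]]; b <- idx[j[1L] + 2L]
        loc$end[a] <- max(loc$end[a], loc$end[b])
        loc$start[a] <- min(loc$start[a], loc$start[b])
        loc$n_markers[a] <- loc$n_markers[a] + loc$n_markers[b]
        loc <- loc[-b, , drop = FALSE]
        merged <- TRUE
        break
      }
    }
  }
  new_sdp_map(map$patterns, loc, map$markers, map$lines, map$alleles)
}

#' Build the full SDP map from a raw genotype table
#'
#' Convenience pipeline: [filter_markers()] then [collapse_to_sdps()],
#' [merge_duplicate_sdps()], and [merge_interrupted_sdps()].
#'
#' @param gt A [genotype_table()].
#' @param filter Apply marker filtering first (default `TRUE`).
#' @return An `sdp_map` ready for association testing.
#' @export
build_sdp_map <- function(gt, filter = TRUE) {
  if (filter) gt <- filter_markers(gt)
  merge_interrupted_sdps(merge_duplicate_sdps(collapse_to_sdps(gt)))
}

#' Summarize an SDP map
#'
#' @param map An `sdp_map`.
#' @return A list: number of SDPs (distinct patterns), number of genomic
#'   locations, count of multi-location SDPs, and mean / median location span
#'   in bp.
#' @export
summarize_map <- function(map) {
  stopifnot(inherits(map, "sdp_map"))
  span <- map$locations$end - map$locations$start
  multi <- sum(table(map$locations$sdp) > 1L)
  list(
    n_sdps = nrow(map$patterns),
    n_locations = nrow(map$locations),
    n_multi_location = multi,
    mean_span = mean(span),
    median_span = median(span)
  )
}

#' Export SDP locations as tab-separated text or BED
#'
#' The TSV has one row per (SDP, location) with the 1-based inclusive
#' interval, marker count, uniqueness flag, and the across-line pattern as a
#' string of 0/1 founder codes. The BED export uses 0-based half-open
#' coordinates.
#'
#' @param map An `sdp_map`.
#' @param path Output file.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_sdp_map <- function(map, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  loc <- map$locations
  if (format == "bed") {
    bed <- data.frame(chrom = loc$chrom, start = loc$start - 1L, end = loc$end,
                      name = loc$sdp)
    write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  } else {
    loc$pattern <- pattern_key(map$patterns)[match(loc$sdp, rownames(map$patterns))]
    write.table(loc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Genotype codes of SDPs across lines
#'
#' @param map An `sdp_map`.
#' @return Integer matrix (SDPs x lines) with 0 for the first founder allele
#'   and 1 for the second.
#' @export
sdp_genotypes <- function(map) {
  stopifnot(inherits(map, "sdp_map"))
  map$patterns
}
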
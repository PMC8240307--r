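# Shared fixture builders and independent oracles.

# Genotype table from a pattern matrix (markers x lines of 0/1/NA/"H"),
# positioned 1 Mb apart on one chromosome unless chrom/pos given.
gt_from_patterns <- function(pat, chrom = NULL, pos = NULL,
                             near_indel = NULL) {
  n_m <- nrow(pat)
  calls <- matrix(NA_character_, n_m, ncol(pat))
  calls[pat == 0] <- "BN"
  calls[pat == 1] <- "SHR"
  calls[!is.na(pat) & pat == 2] <- "HET"
  colnames(calls) <- sprintf("L%02d", seq_len(ncol(pat)))
  rownames(calls) <- sprintf("M%03d", seq_len(n_m))
  genotype_table(
    calls,
    data.frame(marker = rownames(calls),
               chrom = if (is.null(chrom)) rep("chr1", n_m) else chrom,
               pos = if (is.null(pos)) seq_len(n_m) * 1e6 else pos,
               near_indel = if (is.null(near_indel)) FALSE else near_indel)
  )
}

# Independent brute-force SDP construction: plain loops, all-pairs pattern
# comparison for duplicates, and repeated sequence rewriting for the
# interrupted-block rule. Returns, per chromosome, the final list of
# (pattern key, start, end) locations plus the set of distinct patterns.
brute_sdp <- function(pat, chrom, pos) {
  key <- apply(pat, 1L, paste, collapse = "")
  per_chr <- list()
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    i <- i[order(pos[i])]
    blocks <- list()
    for (m in i) {
      nb <- length(blocks)
      if (nb > 0 && blocks[[nb]]$key == key[m]) {
        blocks[[nb]]$end <- pos[m]
        blocks[[nb]]$n <- blocks[[nb]]$n + 1L
      } else {
        blocks[[nb + 1L]] <- list(key = key[m], start = pos[m], end = pos[m],
                                  n = 1L)
      }
    }
    # interrupted-rule closure: unify adjacent same-key blocks and
    # same-key blocks separated by exactly one block, until stable
    repeat {
      changed <- FALSE
      nb <- length(blocks)
      if (nb >= 2) {
        for (b in seq_len(nb - 1L)) {
          if (blocks[[b]]$key == blocks[[b + 1L]]$key) {
            blocks[[b]]$end <- max(blocks[[b]]$end, blocks[[b + 1L]]$end)
            blocks[[b]]$start <- min(blocks[[b]]$start, blocks[[b + 1L]]$start)
            blocks[[b]]$n <- blocks[[b]]$n + blocks[[b + 1L]]$n
            blocks[[b + 1L]] <- NULL
            changed <- TRUE
            break
          }
        }
      }
      if (!changed && nb >= 3) {
        for (b in seq_len(nb - 2L)) {
          if (blocks[[b]]$key == blocks[[b + 2L]]$key &&
              blocks[[b]]$key != blocks[[b + 1L]]$key) {
            blocks[[b]]$end <- max(blocks[[b]]$end, blocks[[b + 2L]]$end)
            blocks[[b]]$start <- min(blocks[[b]]$start, blocks[[b + 2L]]$start)
            blocks[[b]]$n <- blocks[[b]]$n + blocks[[b + 2L]]$n
            blocks[[b + 2L]] <- NULL
            changed <- TRUE
            break
          }
        }
      }
      if (!changed) break
      # re-sort by start after merges
      blocks <- blocks[order(vapply(blocks, `[[`, numeric(1), "start"))]
    }
    per_chr[[ch]] <- blocks
  }
  all_blocks <- do.call(rbind, lapply(names(per_chr), function(ch) {
    do.call(rbind, lapply(per_chr[[ch]], function(b) {
      data.frame(chrom = ch, key = b$key, start = b$start, end = b$end,
                 n_markers = b$n)
    }))
  }))
  list(locations = all_blocks[order(all_blocks$chrom, all_blocks$start), ],
       patterns = unique(key))
}

# Random complete biallelic genotype table (monomorphic markers possible).
random_gt <- function(n_markers, n_lines, n_chrom = 2L, seed = 1L) {
  set.seed(seed)
  # few distinct patterns so collapsing and duplication both occur
  pool <- matrix(rbinom(8L * n_lines, 1L, 0.5), 8L)
  pat <- pool[sample.int(8L, n_markers, replace = TRUE), , drop = FALSE]
  chrom <- sort(sample(paste0("chr", seq_len(n_chrom)), n_markers,
                       replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n_markers), chrom), function(i) {
    sort(sample.int(1e8, length(i)))
  }))
  gt_from_patterns(pat, chrom = chrom, pos = pos)
}

# Small simulated panel shared by several tests (cached per session).
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gt <- simulate_genotypes(panel_config(
        chromosomes = data.frame(name = paste0("chr", 1:3), length = 5e7,
                                 n_markers = 60L),
        seed = 42L))
      cache <<- build_sdp_map(gt)
    }
    cache
  }
})
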
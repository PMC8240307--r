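#' Cardiac thin-filament specification
#'
#' The thin filament is built from five subunits at a fixed molar
#' composition of 7:1:1:1:1 (actin : tropomyosin : the three troponins).
#' Comparing translational output against this composition requires each
#' subunit's CDS length (synthesis per footprint scales with message
#' length) and protein turnover time (longer-lived proteins need less
#' synthesis per unit steady-state protein).
#'
#' @param genes Subunit gene ids (default the rat thin filament:
#'   Actc1, Tpm1, Tnnc1, Tnnt2, Tnni3).
#' @param stoichiometry Molar composition vector (default 7:1:1:1:1).
#' @param turnover_days Protein turnover times in days (defaults
#'   10.3, 5.3, 3.2, 3.5, 5.5).
#' @param cds_length CDS lengths in nt (defaults to the rat lengths:
#'   1134, 855, 486, 867, 633).
#' @return A `filament_spec` list.
#' @export
filament_spec <- function(genes = c("Actc1", "Tpm1", "Tnnc1", "Tnnt2",
                                    "Tnni3"),
                          stoichiometry = c(7, 1, 1, 1, 1),
                          turnover_days = c(10.3, 5.3, 3.2, 3.5, 5.5),
                          cds_length = c(1134, 855, 486, 867, 633)) {
  n <- length(genes)
  if (length(stoichiometry) != n || length(turnover_days) != n ||
      length(cds_length) != n) {
    stop("genes, stoichiometry, turnover_days, cds_length must align")
  }
  if (any(stoichiometry <= 0) || any(turnover_days <= 0) ||
      any(cds_length <= 0)) {
    stop("stoichiometry, turnover_days and cds_length must be positive")
  }
  structure(list(genes = genes, stoichiometry = stoichiometry,
                 turnover_days = turnover_days, cds_length = cds_length),
            class = "filament_spec")
}

#' Length- and turnover-corrected production value
#'
#' Converts a normalized count into a relative protein production value:
#' `(count / cds_length) * turnover_days`. Dividing by CDS length converts
#' footprint (or mRNA) counts into a per-message synthesis rate; multiplying
#' by turnover time converts synthesis into steady-state protein, since
#' longer-lived proteins accumulate more per synthesis event.
#'
#' @param count Normalized count (> 0 allowed to be 0 for absent subunits).
#' @param cds_length CDS length in nt (> 0).
#' @param turnover_days Protein turnover time in days (> 0).
#' @return Production value(s).
#' @export
corrected_abundance <- function(count, cds_length, turnover_days) {
  if (any(count < 0)) stop("count must be non-negative")
  if (any(cds_length <= 0)) stop("cds_length must be positive")
  if (any(turnover_days <= 0)) stop("turnover_days must be positive")
  (count / cds_length) * turnover_days
}

#' Thin-filament production proportions per sample
#'
#' Corrects each subunit's normalized counts for CDS length and protein
#' turnover, normalizes to 100% per sample, and reports the deviation from
#' the composition-stoichiometric optimum (e.g. 7/11 of the filament for
#' actin under 7:1:1:1:1).
#'
#' @param spec A [filament_spec()].
#' @param counts Normalized count matrix with the five subunits in rows
#'   (matched by row name) and samples in columns; a named vector is
#'   treated as one sample.
#' @return A list: `proportions` (percent, subunits x samples), `optimal`
#'   (percent), and `deviation` (observed - optimal, percentage points).
#' @export
filament_proportions <- function(spec, counts) {
  stopifnot(inherits(spec, "filament_spec"))
  if (is.vector(counts)) counts <- matrix(counts, ncol = 1L,
                                          dimnames = list(names(counts),
                                                          "sample1"))
  if (!all(spec$genes %in% rownames(counts))) {
    stop("counts must contain all subunits: ",
         paste(setdiff(spec$genes, rownames(counts)), collapse = ", "))
  }
  m <- counts[spec$genes, , drop = FALSE]
  corrected <- corrected_abundance(m, spec$cds_length, spec$turnover_days)
  totals <- colSums(corrected)
  if (any(totals == 0)) stop("all-zero sample: proportions undefined")
  prop <- sweep(corrected, 2L, totals, "/") * 100
  optimal <- 100 * spec$stoichiometry / sum(spec$stoichiometry)
  names(optimal) <- spec$genes
  list(proportions = prop, optimal = optimal,
       deviation = sweep(prop, 1L, optimal, "-"))
}
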
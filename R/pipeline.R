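#' Pipeline run configuration
#'
#' Bundles inputs, stage toggles, thresholds, and a single global seed from
#' which every stage's seed is derived deterministically. Inputs are either
#' file paths (genotypes, counts, annotation) or a synthetic-panel block.
#'
#' @param synthetic `NULL`, or a list with elements `panel`
#'   (a [panel_config()]) and `expression` (an [expression_sim_config()]);
#'   when given, stage 1 simulates the inputs.
#' @param genotype_file,mrna_file,ribo_file,annotation_file Input paths,
#'   used when `synthetic` is `NULL`.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "sdp", "normalize", "scan", "hotspot", "length",
#'   "stoich")`.
#' @param n_perm Permutation runs for the empirical null (default 1000).
#' @param emp_threshold Empirical significance threshold (default 0.0015).
#' @param target_fdr Hotspot FDR target (default 0.05).
#' @param min_hotspot_genes Minimum distant genes per hotspot (default 5).
#' @param hotspot_iters,hotspot_burnin Sampler run length.
#' @param filament `NULL` or a [filament_spec()] for the stoichiometry
#'   stage.
#' @param seed Global seed.
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = NULL, genotype_file = NULL,
                       mrna_file = NULL, ribo_file = NULL,
                       annotation_file = NULL,
                       stages = c("simulate", "sdp", "normalize", "scan",
                                  "hotspot", "length", "stoich"),
                       n_perm = 1000L, emp_threshold = 0.0015,
                       target_fdr = 0.05, min_hotspot_genes = 5L,
                       hotspot_iters = 5000L, hotspot_burnin = 1000L,
                       filament = NULL, seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(synthetic)) {
    stages <- setdiff(stages, "simulate")
    needed <- list(genotype = genotype_file, mrna = mrna_file,
                   ribo = ribo_file)
    missing_in <- names(needed)[vapply(needed, function(p) {
      is.null(p) || !file.exists(p)
    }, logical(1))]
    if (length(missing_in)) {
      stop("missing pipeline inputs: ", paste(missing_in, collapse = ", "))
    }
    if (("length" %in% stages) && (is.null(annotation_file) ||
                                   !file.exists(annotation_file))) {
      stop("length stage enabled but annotation input is missing")
    }
  }
  structure(list(synthetic = synthetic, genotype_file = genotype_file,
                 mrna_file = mrna_file, ribo_file = ribo_file,
                 annotation_file = annotation_file, stages = stages,
                 n_perm = as.integer(n_perm), emp_threshold = emp_threshold,
                 target_fdr = target_fdr,
                 min_hotspot_genes = as.integer(min_hotspot_genes),
                 hotspot_iters = as.integer(hotspot_iters),
                 hotspot_burnin = as.integer(hotspot_burnin),
                 filament = filament, seed = as.integer(seed)),
            class = "run_config")
}

stage_seed <- function(config, stage) {
  offsets <- c(simulate = 101L, sdp = 211L, normalize = 307L, scan = 401L,
               hotspot = 503L, length = 601L, stoich = 701L)
  (config$seed * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order -- simulate (optional), SDP map,
#' joint normalization + TE, QTL scan of mRNA/Ribo/TE traits, hotspot
#' detection, length-effect analysis, and thin-filament stoichiometry
#' (optional) -- writing each stage's tabular output and a machine-readable
#' JSON manifest (stage row counts, config hash, seed) into `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return A list with the main in-memory results (invisible elements:
#'   `map`, `norm`, `te`, `assoc`, `hotspots`, `length_fit`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_for_hash <- config
  cfg_for_hash$filament <- unclass(config$filament)
  config_hash <- rlang::hash(cfg_for_hash)
  manifest <- list(package_version = as.character(utils::packageVersion("teqtl")),
                   config_hash = config_hash, seed = config$seed,
                   stages = list())
  note <- function(stage, rows) {
    manifest$stages[[stage]] <<- list(rows = rows)
    message("[teqtl] stage ", stage, ": ", rows, " rows")
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## inputs
  if ("simulate" %in% config$stages) {
    sim <- run_stage("simulate", {
      panel <- config$synthetic$panel
      panel$seed <- stage_seed(config, "simulate")
      gt <- simulate_genotypes(panel)
      expr_cfg <- config$synthetic$expression
      expr_cfg$seed <- stage_seed(config, "simulate") + 1L
      simulate_expression(gt, expr_cfg)
    })
    genotypes <- NULL
    map <- sim$map
    mrna <- sim$mrna; ribo <- sim$ribo
    annotation <- sim$annotation
    write_simulation(sim, file.path(out_dir, "simulated"))
    note("simulate", nrow(mrna))
  } else {
    genotypes <- run_stage("input", read_genotypes(config$genotype_file))
    mrna <- read_counts(config$mrna_file)
    ribo <- read_counts(config$ribo_file)
    annotation <- if (!is.null(config$annotation_file)) {
      read.delim(config$annotation_file)
    } else NULL
    sim <- NULL
    map <- NULL
  }

  ## genotype map
  if ("sdp" %in% config$stages && is.null(map)) {
    map <- run_stage("sdp", build_sdp_map(genotypes))
  }
  if (!is.null(map)) {
    write_sdp_map(map, file.path(out_dir, "sdp_map.tsv"))
    note("sdp", nrow(map$locations))
  }

  ## normalization + TE
  norm <- te <- NULL
  if ("normalize" %in% config$stages) {
    ## QTL traits are per line: collapse replicate columns to their line
    base_cols <- colnames(mrna)[colnames(mrna) %in% map$lines]
    norm <- run_stage("normalize", joint_size_factors(
      mrna[, base_cols, drop = FALSE], ribo[, base_cols, drop = FALSE]))
    te <- compute_te(norm)
    write_counts(round(norm$mrna_norm, 3),
                 file.path(out_dir, "mrna_normalized.tsv"))
    write_counts(round(norm$ribo_norm, 3),
                 file.path(out_dir, "ribo_normalized.tsv"))
    write_counts(round(te$te, 4), file.path(out_dir, "te_residuals.tsv"))
    note("normalize", nrow(te$te))
  }

  ## QTL scan (all three trait types)
  assoc <- NULL
  if ("scan" %in% config$stages) {
    assoc <- run_stage("scan", {
      seeds <- stage_seed(config, "scan") + 0:2
      rbind(
        map_qtl(norm$mrna_norm, map, annotation, "eQTL",
                n_perm = config$n_perm, seed = seeds[1L],
                threshold = config$emp_threshold),
        map_qtl(norm$ribo_norm, map, annotation, "riboQTL",
                n_perm = config$n_perm, seed = seeds[2L],
                threshold = config$emp_threshold),
        map_qtl(te$te, map, annotation, "teQTL",
                n_perm = config$n_perm, seed = seeds[3L],
                threshold = config$emp_threshold))
    })
    sig <- assoc[assoc$significant, , drop = FALSE]
    write.table(sig, file.path(out_dir, "associations_significant.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    note("scan", nrow(assoc))
  }

  ## hotspot detection on TE traits
  hotspots <- sel_fit <- NULL
  if ("hotspot" %in% config$stages) {
    sel_fit <- run_stage("hotspot", fit_hierarchical_selection(
      te$te, map,
      hotspot_model_config(iters = config$hotspot_iters,
                           burnin = config$hotspot_burnin,
                           seed = stage_seed(config, "hotspot"))))
    hotspots <- run_stage("hotspot", {
      pairs <- significant_pairs(sel_fit, config$target_fdr)
      call_hotspots(pairs, annotation, map, n_genes_tested = nrow(te$te),
                    min_genes = config$min_hotspot_genes)
    })
    write.table(hotspots, file.path(out_dir, "hotspots.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("hotspot", nrow(hotspots))
  }

  ## length effect at the top hotspot (or strongest distant teQTL locus)
  length_fit <- NULL
  if ("length" %in% config$stages) {
    length_fit <- run_stage("length", {
      if (is.null(annotation)) stop("annotation required")
      sdp <- if (!is.null(hotspots) && nrow(hotspots)) hotspots$sdp[1L] else {
        d <- assoc[assoc$class == "distant", ]
        d$sdp[which.min(d$p)]
      }
      fc <- sdp_fold_change(norm$ribo_norm, map, sdp)
      tab <- data.frame(gene = names(fc), fc = fc,
                        mean_count = rowMeans(norm$mrna_norm)[names(fc)])
      tab <- merge(tab, annotation[c("gene", "cds_length",
                                     "transcript_length", "utr5_length",
                                     "utr3_length")], by = "gene")
      fit <- length_effect(tab)
      fit$sdp <- sdp
      fit
    })
    writeLines(c(paste("sdp", length_fit$sdp, sep = "\t"),
                 paste("covariate", length_fit$covariate, sep = "\t"),
                 paste("r", length_fit$r, sep = "\t"),
                 paste("r2", length_fit$r2, sep = "\t"),
                 paste("sma_slope", length_fit$sma_slope, sep = "\t"),
                 paste("n", length_fit$n, sep = "\t"),
                 paste("p", length_fit$p, sep = "\t")),
               file.path(out_dir, "length_effect.tsv"))
    note("length", 1L)
  }

  ## thin-filament stoichiometry
  stoich <- NULL
  if ("stoich" %in% config$stages && !is.null(config$filament)) {
    stoich <- run_stage("stoich", {
      filament_proportions(config$filament, norm$ribo_norm)
    })
    write.table(data.frame(gene = rownames(stoich$proportions),
                           round(stoich$proportions, 3)),
                file.path(out_dir, "filament_proportions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    note("stoich", nrow(stoich$proportions))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(map = map, norm = norm, te = te, assoc = assoc,
                 selection = sel_fit, hotspots = hotspots,
                 length_fit = length_fit, stoich = stoich,
                 manifest = manifest))
}
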
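#' Pipeline configuration
#'
#' Assembles the run configuration for [run_pipeline()]. Threshold
#' defaults are the analysis constants used throughout: fold-change
#' threshold `sqrt(2)` (log2 cut 0.5), p threshold 0.05 for DEP calling,
#' adjusted-p 0.01 for cell-type specificity, ssGSEA exponent 0.25,
#' cluster resolution 0.5 over 20 components, top-20 correlated genes
#' and top-30 bulk marker genes.
#'
#' The synthetic block plants, by default, 20 tumor-up and 30 tumor-down
#' matrisome effects, a 27-protein PCC-NOS-enriched program (proteoglycan
#' heavy, mirroring the biology the pipeline is designed to expose), a
#' fibroblast-dominant cellular origin for that program, and a bulk
#' cohort whose hazard rises with the program score.
#'
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Optional directory for stage artifacts (TSV/JSON).
#' @param cohort Overrides for [cohort_config()] fields (list).
#' @param fc_threshold,p_threshold DEP thresholds.
#' @param adjusted_p_threshold Cell-type specificity threshold.
#' @param ssgsea_alpha Rank-weight exponent.
#' @param resolution,n_components Fibroblast subclustering parameters.
#' @param top_k Correlated genes reported.
#' @param top_n_markers Bulk marker genes selected.
#' @param n_bulk_patients Bulk cohort size.
#' @param hazard_log_ratio Planted log-hazard slope per unit score.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = NULL,
                            cohort = list(),
                            fc_threshold = sqrt(2),
                            p_threshold = 0.05,
                            adjusted_p_threshold = 0.01,
                            ssgsea_alpha = 0.25,
                            resolution = 0.5,
                            n_components = 20,
                            top_k = 20,
                            top_n_markers = 30,
                            n_bulk_patients = 375,
                            hazard_log_ratio = 1) {
  cfg <- list(
    seed = as.integer(seed),
    out_dir = out_dir,
    cohort = cohort,
    fc_threshold = fc_threshold,
    p_threshold = p_threshold,
    adjusted_p_threshold = adjusted_p_threshold,
    ssgsea_alpha = ssgsea_alpha,
    resolution = resolution,
    n_components = n_components,
    top_k = top_k,
    top_n_markers = top_n_markers,
    n_bulk_patients = n_bulk_patients,
    hazard_log_ratio = hazard_log_ratio
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

# default planted truth addressed at the deterministic protein catalog:
# a proteoglycan-heavy 27-protein PCC-NOS program plus tumor effects
default_planted <- function(catalog) {
  pro <- catalog$protein[catalog$category == "PRO"]
  col <- catalog$protein[catalog$category == "COL"]
  gly <- catalog$protein[catalog$category == "GLY"]
  reg <- catalog$protein[catalog$category == "REG"]
  pem <- c(
    head(pro, 18),
    head(col, 3),
    head(gly, 6)
  )
  pem <- head(pem, 27)
  tumor_up <- head(setdiff(c(reg, gly), pem), 20)
  tumor_down <- head(setdiff(c(rev(gly), rev(col), rev(pro)), c(pem, tumor_up)), 30)
  list(
    tumor = setNames(
      c(rep(1.5, length(tumor_up)), rep(-1.5, length(tumor_down))),
      c(tumor_up, tumor_down)
    ),
    pccnos = setNames(rep(2, length(pem)), pem)
  )
}

#' Run the full ECM-centric analysis pipeline
#'
#' Orchestrates every stage on a synthetic bundle: cohort generation,
#' two-stage TMT normalization, matrisome profiling (RPC, category
#' composition, cumulative coverage, top-abundant, clustering, PCA),
#' differential testing (tumor vs NAT and PCC-NOS vs non-PCC-NOS) with
#' PEM definition, single-cell origin assignment and fibroblast scoring,
#' bulk ssGSEA scoring and survival stratification. Returns a
#' machine-readable report; identical seeds give identical reports.
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @return List of class `run_report`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # --- synthetic inputs -------------------------------------------------
  base_cfg <- do.call(cohort_config, modifyList(
    list(seed = config$seed), config$cohort
  ))
  catalog <- protein_catalog(base_cfg)
  planted <- default_planted(catalog)
  cfg <- do.call(cohort_config, modifyList(
    list(
      seed = config$seed,
      planted_tumor_effects = planted$tumor,
      planted_pccnos_effects = planted$pccnos
    ),
    config$cohort
  ))
  cohort <- stage("generate_cohort", generate_cohort(cfg))

  # --- normalization ----------------------------------------------------
  norm <- stage("normalize", normalize_quant(cohort$quant, cohort$design))
  qc <- attr(norm, "qc")

  # --- matrisome profiling ---------------------------------------------
  rpc_tbl <- stage("rpc", rpc(norm, cohort$design))
  sample_of <- cohort$design |>
    filter(.data$role == "sample") |>
    left_join(cohort$samples, by = "sample_id")
  groups <- tibble(sample = sample_of$channel, group = sample_of$tissue)
  comp <- stage(
    "category_composition",
    category_composition(rpc_tbl, cohort$annotation, groups)
  )
  rpc_m <- as_quant_matrix(rpc_tbl)
  coverage <- vapply(split(groups$sample, groups$group), function(ch) {
    cumulative_coverage(rowMeans(rpc_m[, ch, drop = FALSE], na.rm = TRUE))
  }, integer(1))
  mat_rows <- cohort$annotation$gene[cohort$annotation$category != "none"]
  norm_mat <- filter(norm, .data$protein %in% mat_rows)
  norm_mat_samples <- select(
    norm_mat, all_of(c("protein", groups$sample))
  )
  top20 <- lapply(split(groups$sample, groups$group), function(ch) {
    top_abundant(
      select(rpc_tbl, all_of(c("protein", ch))),
      cohort$annotation,
      n = config$top_k
    )
  })
  hc <- stage("hcluster", hcluster_samples(norm_mat_samples))
  pca <- stage("pca", pca_embed(norm_mat_samples))

  # --- differential -----------------------------------------------------
  ch_of <- function(tissues, histologies = NULL) {
    keep <- sample_of$tissue %in% tissues
    if (!is.null(histologies)) keep <- keep & sample_of$histology %in% histologies
    sample_of$channel[keep]
  }
  dep_tumor <- stage("welch_dep_tumor", welch_dep(
    norm, ch_of("TUM"), ch_of("NAT"),
    annotation = cohort$annotation,
    fc_threshold = config$fc_threshold, p_threshold = config$p_threshold
  ))
  dep_pccnos <- stage("welch_dep_pccnos", welch_dep(
    norm, ch_of("TUM", "PCC-NOS"), ch_of("TUM", "non-PCC-NOS"),
    annotation = cohort$annotation,
    fc_threshold = config$fc_threshold, p_threshold = config$p_threshold
  ))
  pem <- define_pem(dep_pccnos)

  pair_tbl <- sample_of |>
    filter(.data$tissue %in% c("TUM", "NAT")) |>
    select(all_of(c("patient", "tissue", "channel"))) |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "channel") |>
    filter(!is.na(.data$TUM) & !is.na(.data$NAT)) |>
    rename(tum = "TUM", nat = "NAT")
  paired <- stage("paired_log2fc", paired_log2fc(
    norm, pair_tbl,
    proteins = dep_tumor$protein[dep_tumor$dep],
    group_log2fc = setNames(dep_tumor$log2fc, dep_tumor$protein)
  ))

  # --- single-cell integration -----------------------------------------
  # planted origins: fibroblast-dominant with a minority from other types
  n_pem <- length(planted$pccnos)
  origin_pool <- c(
    rep("fibroblast", ceiling(0.8 * n_pem)),
    rep("epithelial", floor(0.1 * n_pem)),
    rep("macrophage", n_pem - ceiling(0.8 * n_pem) - floor(0.1 * n_pem))
  )
  origin_true <- setNames(origin_pool[seq_len(n_pem)], names(planted$pccnos))
  sc <- stage("generate_sc_data", generate_sc_data(
    origin_true = origin_true,
    program_genes = names(planted$pccnos)[origin_true == "fibroblast"],
    seed = config$seed
  ))
  markers <- stage("find_markers", find_markers(sc, alpha = config$adjusted_p_threshold))
  origins <- stage("assign_origin", assign_origin(pem, sc, markers))
  fracs <- if (nrow(origins) > 0) origin_fractions(origins) else NULL

  fibro <- cell_subset(sc, "fibroblast")
  subclusters <- stage("fibroblast_subcluster", fibroblast_subcluster(
    fibro, feature_genes = mat_rows,
    n_components = config$n_components,
    resolution = config$resolution, seed = config$seed
  ))
  pem_cell_scores <- stage("sc_score", sc_score(
    fibro, pem, alpha = config$ssgsea_alpha
  ))
  corr_genes <- stage("correlate_with_score", correlate_with_score(
    fibro, pem_cell_scores, top_k = config$top_k
  ))

  # adipogenic-CAF-like markers: subpopulation vs rest of fibroblasts
  fibro_by_subpop <- fibro
  fibro_by_subpop$cells$cell_type <- ifelse(
    fibro$cells$in_subpop, "subpop", "other"
  )
  subpop_markers <- stage("subpop_markers", find_markers(
    fibro_by_subpop, alpha = config$adjusted_p_threshold
  )) |>
    filter(.data$cell_type == "subpop")
  caf_adi <- select_top_markers(subpop_markers, n = config$top_n_markers)

  # --- bulk scoring and survival ---------------------------------------
  bulk <- stage("generate_bulk_survival", generate_bulk_survival(
    n_patients = config$n_bulk_patients,
    geneset = pem,
    hazard_log_ratio = config$hazard_log_ratio,
    seed = config$seed
  ))
  # bulk matrix carries the program plus background; score both sets on it
  tpm_genes <- bulk$tpm$gene
  caf_in_bulk <- intersect(caf_adi, tpm_genes)
  pem_bulk_scores <- stage("ssgsea_bulk_pem", ssgsea_bulk(
    bulk$tpm, pem, alpha = config$ssgsea_alpha
  ))
  score_corr <- if (length(caf_in_bulk) >= 1) {
    caf_bulk_scores <- ssgsea_bulk(bulk$tpm, caf_in_bulk, alpha = config$ssgsea_alpha)
    score_correlation(pem_bulk_scores, caf_bulk_scores)
  } else {
    NULL
  }
  strata <- dichotomize(pem_bulk_scores, rule = "mean")
  surv <- bulk$survival |>
    mutate(group = strata$group[match(.data$patient, strata$unit)])
  km <- stage("km_estimate", km_estimate(surv))
  lr <- stage("logrank_test", logrank_test(surv))

  report <- list(
    parameters = config[setdiff(names(config), "out_dir")],
    cohort = list(
      n_proteins = nrow(cohort$quant),
      n_channels = ncol(cohort$quant) - 1,
      n_sample_channels = sum(cohort$design$role == "sample"),
      n_matrisome = length(mat_rows)
    ),
    normalization = list(
      n_quantified_all_plexes = qc$n_quantified_all_plexes,
      n_excluded = qc$n_excluded,
      max_median_spread_after = max(qc$median_log2_after) - min(qc$median_log2_after)
    ),
    profile = list(
      coverage_90 = as.list(coverage),
      matrisome_share = comp$group_means |>
        filter(.data$category != "none") |>
        group_by(.data$group) |>
        summarise(share = sum(.data$mean_rpc), .groups = "drop")
    ),
    differential = list(
      n_dep_tumor = sum(dep_tumor$dep),
      n_tumor_enriched = sum(dep_tumor$direction == "A-enriched"),
      n_nat_enriched = sum(dep_tumor$direction == "B-enriched"),
      n_pccnos_enriched = sum(dep_pccnos$direction == "A-enriched"),
      n_nonpccnos_enriched = sum(dep_pccnos$direction == "B-enriched"),
      pem = pem,
      n_paired_concordant = sum(paired$summary$concordant, na.rm = TRUE)
    ),
    single_cell = list(
      origin_fractions = fracs,
      fibroblast_fraction = if (is.null(fracs) ||
        !"fibroblast" %in% fracs$origin) 0 else
        fracs$fraction[fracs$origin == "fibroblast"],
      n_subclusters = length(levels(subclusters$cluster)),
      top_correlated = attr(corr_genes, "top"),
      caf_adi = caf_adi
    ),
    survival = list(
      score_correlation_r = score_corr$r %||% NA_real_,
      logrank_chisq = lr$statistic,
      logrank_p = lr$p,
      n_high = sum(strata$group == "high"),
      n_low = sum(strata$group == "low")
    )
  )
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  class(report) <- "run_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(norm, file.path(config$out_dir, "normalized.tsv"))
    readr::write_tsv(as_tibble(dep_tumor), file.path(config$out_dir, "dep_tumor_nat.tsv"))
    readr::write_tsv(as_tibble(dep_pccnos), file.path(config$out_dir, "dep_pccnos.tsv"))
    writeLines(pem, file.path(config$out_dir, "pem.txt"))
    readr::write_tsv(origins, file.path(config$out_dir, "origins.tsv"))
    readr::write_tsv(pem_bulk_scores, file.path(config$out_dir, "bulk_pem_scores.tsv"))
    r <- report
    r$elapsed_s <- NULL
    jsonlite::write_json(
      r, file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE
    )
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf(
    "  cohort: %d proteins (%d matrisome), %d sample channels\n",
    x$cohort$n_proteins, x$cohort$n_matrisome, x$cohort$n_sample_channels
  ))
  cat(sprintf(
    "  DEPs tumor vs NAT: %d (%d tumor-, %d NAT-enriched); PEMs: %d\n",
    x$differential$n_dep_tumor, x$differential$n_tumor_enriched,
    x$differential$n_nat_enriched, length(x$differential$pem)
  ))
  cat(sprintf(
    "  fibroblast origin fraction: %.2f; score correlation r = %.3f\n",
    x$single_cell$fibroblast_fraction, x$survival$score_correlation_r
  ))
  cat(sprintf(
    "  log-rank chi-squared = %.2f, p = %.3g\n",
    x$survival$logrank_chisq, x$survival$logrank_p
  ))
  invisible(x)
}
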
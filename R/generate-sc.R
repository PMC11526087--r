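#' Generate synthetic labeled single-cell count data
#'
#' Emulates a droplet-style count matrix over a declared set of cell types,
#' with planted cell-type-specific genes (elevated mean in their assigned
#' type, near-baseline elsewhere) and a designated fibroblast
#' subpopulation that over-expresses a planted gene program — the
#' structure the cellular-origin and per-cell scoring stages assume.
#' Counts are negative-binomial around log-normal per-gene baselines.
#'
#' @param n_cells_per_type Cells simulated per cell type.
#' @param cell_types Character vector of type labels; must contain
#'   `subpop_type` if a subpopulation program is planted.
#' @param origin_true Named character: gene -> cell type in which the gene
#'   is specifically expressed (the planted cellular origin).
#' @param program_genes Genes over-expressed by the planted subpopulation
#'   (e.g. a PCC-NOS-like fibroblast program); may overlap `origin_true`.
#' @param subpop_type Cell type that hosts the subpopulation.
#' @param subpop_fraction Fraction of `subpop_type` cells in the
#'   subpopulation.
#' @param n_background_genes Unplanted genes with no type structure.
#' @param origin_log2fc Planted log2 elevation of origin genes in their
#'   type.
#' @param program_log2fc Planted log2 elevation of program genes in the
#'   subpopulation.
#' @param base_mu_log_mean,base_mu_log_sd Log-normal parameters of per-gene
#'   baseline mean counts.
#' @param nb_size Negative-binomial dispersion (size) parameter.
#' @param seed Integer seed.
#'
#' @return A list of class `cell_data`: `counts` (genes x cells integer
#'   matrix), `cells` (tibble: barcode, cell_type, in_subpop).
#' @export
generate_sc_data <- function(n_cells_per_type = 100,
                             cell_types = c(
                               "fibroblast", "epithelial", "macrophage",
                               "endothelial", "T cell", "B cell", "mast cell"
                             ),
                             origin_true = character(),
                             program_genes = character(),
                             subpop_type = "fibroblast",
                             subpop_fraction = 0.3,
                             n_background_genes = 200,
                             origin_log2fc = 3,
                             program_log2fc = 2,
                             base_mu_log_mean = log(0.5),
                             base_mu_log_sd = 0.8,
                             nb_size = 2,
                             seed = 1L) {
  if (length(cell_types) == 0) abort("cell_types must be non-empty")
  bad <- setdiff(unique(unname(origin_true)), cell_types)
  if (length(bad) > 0) {
    abort(paste0("unknown cell type in origin_true: ", paste(bad, collapse = ", ")))
  }
  set.seed(seed)
  genes <- unique(c(
    names(origin_true), program_genes,
    sprintf("BG%04d", seq_len(n_background_genes))
  ))
  n_g <- length(genes)
  cells <- tibble(
    barcode = sprintf("cell%04d", seq_len(n_cells_per_type * length(cell_types))),
    cell_type = rep(cell_types, each = n_cells_per_type)
  )
  host <- cells$cell_type == subpop_type
  cells$in_subpop <- host &
    seq_len(nrow(cells)) %in%
      which(host)[seq_len(round(sum(host) * subpop_fraction))]

  mu0 <- exp(rnorm(n_g, base_mu_log_mean, base_mu_log_sd))
  names(mu0) <- genes
  log2lift <- matrix(0, n_g, nrow(cells), dimnames = list(genes, cells$barcode))
  for (g in names(origin_true)) {
    log2lift[g, cells$cell_type == origin_true[[g]]] <- origin_log2fc
  }
  if (length(program_genes) > 0 && any(cells$in_subpop)) {
    log2lift[program_genes, cells$in_subpop] <-
      log2lift[program_genes, cells$in_subpop] + program_log2fc
  }
  mu <- mu0 * 2^log2lift
  counts <- matrix(
    rnbinom(n_g * nrow(cells), mu = mu, size = nb_size),
    n_g, nrow(cells), dimnames = dimnames(log2lift)
  )
  structure(list(counts = counts, cells = cells), class = "cell_data")
}

#' Normalized expression layers of a `cell_data` object
#'
#' `cell_norm()` scales each cell to 10,000 total counts and applies
#' log1p (the standard library-size normalization used for marker tests
#' and clustering). `cell_tpm()` scales each cell to one million (no
#' length term for droplet counts), the layer used for score
#' correlations.
#'
#' @param cells A `cell_data` object.
#' @return A genes x cells numeric matrix.
#' @export
cell_norm <- function(cells) {
  stopifnot(inherits(cells, "cell_data"))
  tot <- colSums(cells$counts)
  tot[tot == 0] <- 1
  log1p(sweep(cells$counts, 2, tot / 1e4, "/"))
}

#' @rdname cell_norm
#' @export
cell_tpm <- function(cells) {
  stopifnot(inherits(cells, "cell_data"))
  tot <- colSums(cells$counts)
  tot[tot == 0] <- 1
  sweep(cells$counts, 2, tot / 1e6, "/")
}

#' Subset a `cell_data` object
#'
#' @param cells A `cell_data` object.
#' @param keep Logical or integer index over cells, or a cell type name.
#' @return A `cell_data` with the selected cells.
#' @export
cell_subset <- function(cells, keep) {
  stopifnot(inherits(cells, "cell_data"))
  if (is.character(keep) && length(keep) == 1 && keep %in% cells$cells$cell_type) {
    keep <- cells$cells$cell_type == keep
  }
  structure(
    list(
      counts = cells$counts[, keep, drop = FALSE],
      cells = cells$cells[keep, , drop = FALSE]
    ),
    class = "cell_data"
  )
}

#' Generate a synthetic bulk expression cohort with survival
#'
#' Emulates a bulk RNA-seq cohort whose survival depends on a planted
#' gene-set program. Each patient carries a latent standardized program
#' score `z ~ N(0, 1)`; the log2 expression of gene-set members is shifted
#' by `score_loading * z`, columns are scaled to TPM (sum 1e6), and
#' overall-survival times are exponential with log-hazard
#' `log(lambda0) + hazard_log_ratio * z`, with uniform administrative
#' censoring.
#'
#' @param n_patients Cohort size (>= 10).
#' @param geneset Non-empty character vector of program genes.
#' @param hazard_log_ratio Increase in log hazard per unit of the planted
#'   standardized score.
#' @param n_background_genes Genes outside the program.
#' @param score_loading Log2 expression shift of program genes per unit
#'   score.
#' @param baseline_median_months Median survival at score 0, in months.
#' @param censor_range Administrative censoring window (months), sampled
#'   uniformly per patient.
#' @param seed Integer seed.
#'
#' @return List with `tpm` (tibble: `gene` + one column per patient;
#'   columns sum to 1e6) and `survival` (tibble: patient, time, event,
#'   score — the planted standardized score).
#' @export
generate_bulk_survival <- function(n_patients = 375,
                                   geneset,
                                   hazard_log_ratio = 1,
                                   n_background_genes = 500,
                                   score_loading = 1,
                                   baseline_median_months = 24,
                                   censor_range = c(12, 60),
                                   seed = 1L) {
  if (n_patients < 10) abort("n_patients must be at least 10")
  geneset <- unique(as.character(geneset))
  if (length(geneset) == 0) abort("gene set is empty")
  set.seed(seed)
  genes <- unique(c(geneset, sprintf("BLK%04d", seq_len(n_background_genes))))
  n_g <- length(genes)
  patients <- sprintf("PT%04d", seq_len(n_patients))
  z <- rnorm(n_patients)

  base_log2 <- rnorm(n_g, mean = 6, sd = 2)
  expr_log2 <- base_log2 +
    matrix(rnorm(n_g * n_patients, 0, 1), n_g, n_patients)
  in_set <- genes %in% geneset
  expr_log2[in_set, ] <- expr_log2[in_set, ] +
    matrix(score_loading * z, sum(in_set), n_patients, byrow = TRUE)
  raw <- 2^expr_log2
  tpm <- sweep(raw, 2, colSums(raw) / 1e6, "/")
  dimnames(tpm) <- list(genes, patients)

  lambda0 <- log(2) / baseline_median_months
  t_event <- rexp(n_patients, rate = lambda0 * exp(hazard_log_ratio * z))
  t_cens <- runif(n_patients, censor_range[1], censor_range[2])
  list(
    tpm = bind_cols(tibble(gene = genes), as_tibble(tpm)),
    survival = tibble(
      patient = patients,
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      score = z
    )
  )
}
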
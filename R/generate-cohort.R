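#' Generate a synthetic multi-plex TMT cohort
#'
#' Simulates the full input bundle for the pipeline: a protein-by-channel
#' intensity matrix with its plex/channel design, per-sample metadata with
#' patient pairing and histology, a matrisome annotation table, and the
#' planted ground truth used by parameter-recovery tests.
#'
#' Per protein `i`, sample channel `s` in plex `p`, the log2 intensity is
#' `b_i + effect_is + beta_p + e`, with `b_i ~ N(baseline_mean,
#' baseline_sd)`, `beta_p ~ N(0, batch_sd)` a plex-wide batch term, and
#' `e ~ N(0, noise_sd)` independent per measurement. Both reference
#' channels (131N = R1, 131C = R2) of plex `p` carry the pooled linear mean
#' over all sample channels (pre-batch, pre-noise), times the plex batch
#' factor, with independent noise draws — they are exchangeable replicates
#' of a pooled common control.
#'
#' @param config A [cohort_config()].
#' @return A list of class `ecm_cohort` with elements `quant` (tibble:
#'   `protein` + one column per channel), `design` (channel, plex, role,
#'   sample_id), `samples` (sample_id, patient, tissue, histology),
#'   `annotation` (gene, division, category), `truth` (planted ground
#'   truth) and `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(
#'   n_plexes = 2, samples_per_plex = 4,
#'   group_sizes = c(TUM = 4, NAT = 2, LNM = 1, NN = 1),
#'   n_proteins = 50, n_pccnos = 2, seed = 7
#' ))
#' dim(cohort$quant)
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  if (config$samples_per_plex > 9) {
    abort("an 11-plex holds at most 9 tissue samples plus 2 reference channels")
  }
  catalog <- protein_catalog(config)
  if (anyDuplicated(catalog$protein)) abort("duplicate protein ids")
  planted <- c(
    names(config$planted_tumor_effects),
    names(config$planted_pccnos_effects)
  )
  missing_planted <- setdiff(planted, catalog$protein)
  if (length(missing_planted) > 0) {
    abort(paste0(
      "planted effect proteins absent from the catalog: ",
      paste(missing_planted, collapse = ", ")
    ))
  }

  samples <- cohort_sample_table(config)
  design <- cohort_design_table(config, samples)

  set.seed(config$seed)
  p <- config$n_proteins
  n_s <- nrow(samples)
  b <- rnorm(p, config$baseline_mean, config$baseline_sd)

  # planted log2 effects per protein x sample
  eff <- matrix(0, nrow = p, ncol = n_s,
                dimnames = list(catalog$protein, samples$sample_id))
  tum <- samples$tissue == "TUM"
  if (length(config$planted_tumor_effects) > 0) {
    eff[names(config$planted_tumor_effects), tum] <-
      eff[names(config$planted_tumor_effects), tum] +
      config$planted_tumor_effects
  }
  pccnos_tum <- tum & samples$histology == "PCC-NOS"
  if (length(config$planted_pccnos_effects) > 0 && any(pccnos_tum)) {
    eff[names(config$planted_pccnos_effects), pccnos_tum] <-
      eff[names(config$planted_pccnos_effects), pccnos_tum] +
      config$planted_pccnos_effects
  }

  beta <- rnorm(config$n_plexes, 0, config$batch_sd)
  names(beta) <- paste0("plex", seq_len(config$n_plexes))

  # pooled common control: linear mean of all (pre-batch, pre-noise) samples
  pool_log2 <- log2(rowMeans(2^(b + eff)))

  sample_plex <- design$plex[match(samples$sample_id, design$sample_id)]
  log2_samples <- b + eff +
    rep(beta[sample_plex], each = p) +
    matrix(rnorm(p * n_s, 0, config$noise_sd), p, n_s)
  m_samples <- 2^log2_samples
  colnames(m_samples) <- design$channel[match(samples$sample_id, design$sample_id)]

  refs <- design[design$role != "sample", ]
  m_refs <- sapply(seq_len(nrow(refs)), function(k) {
    2^(pool_log2 + beta[[refs$plex[k]]] + rnorm(p, 0, config$noise_sd))
  })
  colnames(m_refs) <- refs$channel

  m <- cbind(m_samples, m_refs)[, design$channel, drop = FALSE]
  rownames(m) <- catalog$protein

  if (config$missing_rate > 0) {
    sample_cols <- design$channel[design$role == "sample"]
    mask <- matrix(
      runif(p * length(sample_cols)) < config$missing_rate,
      p, length(sample_cols)
    )
    m[, sample_cols][mask] <- NA_real_
  }

  truth <- list(
    tumor_up = names(config$planted_tumor_effects)[config$planted_tumor_effects > 0],
    tumor_down = names(config$planted_tumor_effects)[config$planted_tumor_effects < 0],
    pem_true = names(config$planted_pccnos_effects)[config$planted_pccnos_effects > 0],
    tumor_effects = config$planted_tumor_effects,
    pccnos_effects = config$planted_pccnos_effects,
    batch_log2 = beta,
    baseline_log2 = setNames(b, catalog$protein)
  )

  structure(
    list(
      quant = quant_tibble(m),
      design = design,
      samples = samples,
      annotation = dplyr::rename(catalog, gene = "protein"),
      truth = truth,
      config = config
    ),
    class = "ecm_cohort"
  )
}

# deterministic sample bookkeeping: GC patients carry the TUM samples (and
# the NAT/LNM samples for the first so-many), NN patients the normals;
# PCC-NOS histology goes to the first n_pccnos tumor patients
cohort_sample_table <- function(config) {
  gs <- config$group_sizes
  n_gc <- max(gs[["TUM"]], gs[["NAT"]], gs[["LNM"]])
  gc_ids <- sprintf("GC%02d", seq_len(n_gc))
  nn_ids <- sprintf("NN%02d", seq_len(gs[["NN"]]))
  pccnos <- gc_ids[seq_len(config$n_pccnos)]
  rows <- list(
    tibble(
      sample_id = paste0("TUM_", gc_ids[seq_len(gs[["TUM"]])]),
      patient = gc_ids[seq_len(gs[["TUM"]])], tissue = "TUM"
    ),
    tibble(
      sample_id = paste0("NAT_", gc_ids[seq_len(gs[["NAT"]])]),
      patient = gc_ids[seq_len(gs[["NAT"]])], tissue = "NAT"
    ),
    tibble(
      sample_id = paste0("LNM_", gc_ids[seq_len(gs[["LNM"]])]),
      patient = gc_ids[seq_len(gs[["LNM"]])], tissue = "LNM"
    ),
    tibble(
      sample_id = paste0("NN_", nn_ids),
      patient = nn_ids, tissue = "NN"
    )
  )
  out <- bind_rows(rows)
  out$histology <- ifelse(
    out$patient %in% pccnos & out$tissue %in% c("TUM", "LNM"),
    "PCC-NOS",
    ifelse(out$tissue == "TUM", "non-PCC-NOS", NA_character_)
  )
  out
}

cohort_design_table <- function(config, samples) {
  tags <- c("126", "127N", "127C", "128N", "128C",
            "129N", "129C", "130N", "130C")
  # round-robin over the interleaved sample list fills every plex evenly
  plex_of <- ((seq_len(nrow(samples)) - 1L) %% config$n_plexes) + 1L
  design <- purrr::map_dfr(seq_len(config$n_plexes), function(pl) {
    ids <- samples$sample_id[plex_of == pl]
    bind_rows(
      tibble(
        channel = sprintf("plex%d_%s", pl, tags[seq_along(ids)]),
        plex = paste0("plex", pl), role = "sample", sample_id = ids
      ),
      tibble(
        channel = sprintf("plex%d_%s", pl, c("131N", "131C")),
        plex = paste0("plex", pl), role = c("R1", "R2"),
        sample_id = NA_character_
      )
    )
  })
  design
}
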
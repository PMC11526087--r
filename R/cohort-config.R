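#' Configuration for a synthetic multi-plex TMT cohort
#'
#' Builds the configuration object consumed by [generate_cohort()]. The
#' defaults reproduce the design of a 45-sample gastric pdECM study: five
#' TMT 11-plexes, each carrying nine tissue samples plus two pooled
#' reference channels (131N and 131C), with group sizes 19 tumor (TUM),
#' 17 adjacent normal (NAT), 5 lymph-node metastasis (LNM) and 4 normal
#' tissues from non-cancer patients (NN), and a detected proteome of 4838
#' proteins of which 376 are matrisome.
#'
#' Intensities are generated on the log2 scale as
#' `baseline + plex batch + planted effect + Gaussian noise` and
#' exponentiated, i.e. protein intensities are log-normal. Planted tumor
#' effects are added to TUM channels only; planted PCC-NOS effects to TUM
#' channels of PCC-NOS patients only. Reference channels carry, pre-noise,
#' the pooled (arithmetic) mean of all sample channels of their protein,
#' emulating a pooled common control aliquoted into every plex.
#'
#' @param n_plexes Number of TMT plexes.
#' @param samples_per_plex Tissue samples per plex (the two reference
#'   channels are extra).
#' @param group_sizes Named counts per tissue class; must sum to
#'   `n_plexes * samples_per_plex`.
#' @param n_proteins Total proteins in the matrix.
#' @param matrisome_fraction Fraction of proteins annotated as matrisome.
#' @param category_weights Named fractions over the six matrisome
#'   categories (COL, GLY, PRO, REG, AFF, SEC); must sum to 1.
#' @param batch_sd Log2-scale standard deviation of the per-plex
#'   multiplicative batch factor.
#' @param noise_sd Log2-scale residual standard deviation per measurement.
#' @param baseline_mean,baseline_sd Log2-scale mean and sd of per-protein
#'   baseline abundances.
#' @param n_pccnos Number of TUM patients labeled PCC-NOS; the remaining
#'   tumors are lumped as non-PCC-NOS.
#' @param planted_tumor_effects Named numeric: protein id -> log2 effect
#'   added to all TUM channels.
#' @param planted_pccnos_effects Named numeric: protein id -> log2 effect
#'   added to TUM channels of PCC-NOS patients.
#' @param missing_rate Probability that a sample-channel measurement is
#'   missing at random (default 0: complete matrix).
#' @param seed Integer seed; generation is deterministic given the config.
#'
#' @return A list of class `cohort_config`.
#' @seealso [generate_cohort()], [protein_catalog()]
#' @export
cohort_config <- function(n_plexes = 5,
                          samples_per_plex = 9,
                          group_sizes = c(TUM = 19, NAT = 17, LNM = 5, NN = 4),
                          n_proteins = 4838,
                          matrisome_fraction = 376 / 4838,
                          category_weights = prop.table(c(
                            COL = 37, GLY = 102, PRO = 18,
                            REG = 99, AFF = 55, SEC = 63
                          )),
                          batch_sd = 0.5,
                          noise_sd = 0.3,
                          baseline_mean = 18,
                          baseline_sd = 3.5,
                          n_pccnos = 4,
                          planted_tumor_effects = numeric(),
                          planted_pccnos_effects = numeric(),
                          missing_rate = 0,
                          seed = 1L) {
  cfg <- list(
    n_plexes = as.integer(n_plexes),
    samples_per_plex = as.integer(samples_per_plex),
    group_sizes = group_sizes,
    n_proteins = as.integer(n_proteins),
    matrisome_fraction = matrisome_fraction,
    category_weights = category_weights,
    batch_sd = batch_sd,
    noise_sd = noise_sd,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    n_pccnos = as.integer(n_pccnos),
    planted_tumor_effects = planted_tumor_effects,
    planted_pccnos_effects = planted_pccnos_effects,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_plexes < 1 || cfg$samples_per_plex < 1 || cfg$n_proteins < 1) {
    abort("counts in a cohort_config must be positive")
  }
  if (sum(cfg$group_sizes) != cfg$n_plexes * cfg$samples_per_plex) {
    abort(sprintf(
      "group sizes sum to %d but the plex design holds %d samples",
      sum(cfg$group_sizes), cfg$n_plexes * cfg$samples_per_plex
    ))
  }
  cats <- c("COL", "GLY", "PRO", "REG", "AFF", "SEC")
  if (!setequal(names(cfg$category_weights), cats)) {
    abort("category_weights must be named over COL, GLY, PRO, REG, AFF, SEC")
  }
  if (abs(sum(cfg$category_weights) - 1) > 1e-8) {
    abort("category_weights must sum to 1")
  }
  if (cfg$matrisome_fraction < 0 || cfg$matrisome_fraction > 1) {
    abort("matrisome_fraction must lie in [0, 1]")
  }
  if (cfg$batch_sd < 0 || cfg$noise_sd < 0) {
    abort("standard deviations must be non-negative")
  }
  if (cfg$n_pccnos < 0 || cfg$n_pccnos > cfg$group_sizes[["TUM"]]) {
    abort("n_pccnos must lie between 0 and the TUM group size")
  }
  invisible(cfg)
}

#' Deterministic protein catalog for a cohort configuration
#'
#' Enumerates the protein identifiers [generate_cohort()] will emit, with
#' their matrisome division and category, so planted effects can be
#' addressed to specific proteins before generation. Matrisome proteins are
#' named `<CATEGORY><index>` (e.g. `COL001`), the rest `NONM<index>`.
#'
#' @param config A [cohort_config()].
#' @return A tibble with columns `protein`, `division`, `category`.
#' @export
protein_catalog <- function(config) {
  n_mat <- round(config$matrisome_fraction * config$n_proteins)
  cats <- c("COL", "GLY", "PRO", "REG", "AFF", "SEC")
  counts <- floor(config$category_weights[cats] * n_mat)
  # distribute the rounding remainder to the largest fractional parts
  rem <- n_mat - sum(counts)
  if (rem > 0) {
    frac <- config$category_weights[cats] * n_mat - counts
    counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
  }
  division <- c(
    COL = "core matrisome", GLY = "core matrisome", PRO = "core matrisome",
    REG = "matrisome-associated", AFF = "matrisome-associated",
    SEC = "matrisome-associated"
  )
  mat <- purrr::map_dfr(cats, function(cat) {
    k <- counts[[cat]]
    if (k == 0) return(tibble())
    tibble(
      protein = sprintf("%s%03d", cat, seq_len(k)),
      division = division[[cat]],
      category = cat
    )
  })
  n_non <- config$n_proteins - nrow(mat)
  non <- tibble(
    protein = sprintf("NONM%04d", seq_len(n_non)),
    division = "none",
    category = "none"
  )
  bind_rows(mat, non)
}
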
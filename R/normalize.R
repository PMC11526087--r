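#' Stage 1: within-channel median centering on the log2 scale
#'
#' Each channel's log2 intensities are centered on that channel's median,
#' then shifted by the mean of all channel medians so that every channel's
#' log2 median equals the common value, and returned on the linear scale:
#' `out[i, j] = 2^(log2(in[i, j]) - m_j + mean_k(m_k))`. This removes
#' loading and labeling differences between channels while keeping the
#' matrix on its original intensity scale. Missing entries propagate;
#' medians are computed over observed entries.
#'
#' @param quant Tibble with a `protein` column and one numeric column per
#'   channel; intensities must be positive or NA.
#' @return Tibble of the same shape on the linear scale.
#' @export
median_center <- function(quant) {
  m <- as_quant_matrix(quant)
  check_positive_intensities(m)
  med <- log2_col_medians(m)
  target <- mean(med)
  out <- 2^(sweep(log2(m), 2, med - target, "-"))
  quant_tibble(out)
}

#' Stage 2: cross-plex scaling on the internal reference channel
#'
#' Bridges plexes on the second internal reference channel (R2, the
#' pooled common control labeled 131C). For protein `i` and channel `j`
#' in plex `p`: `out[i, j] = in[i, j] / in[i, R2_p] * a_i`, where `a_i`
#' is the arithmetic mean of the protein's R2 intensities over plexes.
#' Consequently every R2 channel of a protein equals `a_i` afterwards,
#' and within-plex intensity ratios are untouched. Proteins whose R2
#' intensity is missing or zero in any plex cannot be bridged; they are
#' set to NA and reported via the `excluded` attribute.
#'
#' @param quant Stage-1 output (tibble, `protein` + channels).
#' @param design Tibble with columns `channel`, `plex`, `role`
#'   (`sample`, `R1`, `R2`); every plex must have exactly one R2 channel.
#' @param r2_mean How the R2 rescaling constant `a_i` is computed:
#'   `"per_protein"` (default; mean of the protein's own R2 values
#'   across plexes, making R2 a cross-plex bridge) or `"grand"` (one
#'   constant, the grand mean of the R2 columns).
#' @return Tibble with attribute `excluded` (protein ids dropped from
#'   cross-plex quantitation).
#' @export
reference_scale <- function(quant, design, r2_mean = c("per_protein", "grand")) {
  r2_mean <- match.arg(r2_mean)
  m <- as_quant_matrix(quant)
  r2 <- design$channel[design$role == "R2"]
  plexes <- design$plex[design$role == "R2"]
  if (length(r2) == 0 || anyDuplicated(plexes) ||
      !setequal(plexes, unique(design$plex))) {
    abort("design must assign exactly one R2 channel to every plex")
  }
  if (!all(design$channel %in% colnames(m))) {
    abort("design lists channels absent from the quant table")
  }
  r2m <- m[, r2, drop = FALSE]
  bad <- rowSums(is.na(r2m) | r2m <= 0) > 0
  if (any(bad)) {
    inform(sprintf(
      "%d protein(s) lack a positive R2 intensity in some plex; excluded from cross-plex quantitation",
      sum(bad)
    ))
  }
  a <- if (r2_mean == "per_protein") {
    rowMeans(r2m)
  } else {
    rep(mean(r2m, na.rm = TRUE), nrow(m))
  }
  out <- m
  for (k in seq_along(r2)) {
    cols <- design$channel[design$plex == plexes[k]]
    out[, cols] <- m[, cols, drop = FALSE] / r2m[, k] * a
  }
  out[bad, ] <- NA_real_
  res <- quant_tibble(out)
  attr(res, "excluded") <- rownames(m)[bad]
  res
}

#' Two-stage TMT normalization pipeline
#'
#' Runs [median_center()] then [reference_scale()] and attaches a QC
#' report: per-channel log2 medians before and after stage 1, the count
#' of proteins quantified (positive R2) in all plexes, and the R1/R2
#' agreement per plex (median log2 ratio of the two reference channels —
#' both carry the same pooled control, so this should sit near 0).
#'
#' @inheritParams reference_scale
#' @return Normalized tibble with attributes `qc` (list) and `excluded`.
#' @export
normalize_quant <- function(quant, design, r2_mean = "per_protein") {
  m0 <- as_quant_matrix(quant)
  med_before <- log2_col_medians(m0)
  stage1 <- median_center(quant)
  med_after <- log2_col_medians(as_quant_matrix(stage1))
  out <- reference_scale(stage1, design, r2_mean = r2_mean)

  s1m <- as_quant_matrix(stage1)
  r1 <- design$channel[design$role == "R1"]
  r2 <- design$channel[design$role == "R2"]
  ref_agreement <- if (length(r1) == length(r2) && length(r1) > 0) {
    setNames(
      vapply(seq_along(r1), function(k) {
        median(log2(s1m[, r1[k]] / s1m[, r2[k]]), na.rm = TRUE)
      }, numeric(1)),
      design$plex[design$role == "R2"]
    )
  } else {
    NULL
  }
  attr(out, "qc") <- list(
    median_log2_before = med_before,
    median_log2_after = med_after,
    n_quantified_all_plexes = nrow(out) - length(attr(out, "excluded")),
    n_excluded = length(attr(out, "excluded")),
    r1_r2_median_log2_ratio = ref_agreement
  )
  out
}
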
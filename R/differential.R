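#' Differential matrisome proteins by Welch's t-test
#'
#' Compares two sample groups protein-by-protein. Fold change is the
#' ratio of linear-scale group means (`mean A / mean B`); the test is
#' Welch's two-sided t-test on log2 intensities with Welch-Satterthwaite
#' degrees of freedom. A protein is flagged as differentially expressed
#' (DEP) when `|log2FC| > log2(fc_threshold)` and `p < p_threshold`; with
#' the default `fc_threshold = sqrt(2)` the log2 cut is 0.5 on both
#' sides. Direction is `A-enriched` (`log2fc > +0.5`), `B-enriched`
#' (`log2fc < -0.5`) or `none`.
#'
#' Note the two deliberate scales: fold changes come from linear means,
#' p-values from log2 intensities. No multiple-testing correction is
#' applied by default (DEP calling uses raw p-values); set
#' `adjust = "BH"` for Benjamini-Hochberg-adjusted flags.
#'
#' @param quant Normalized tibble (`protein` + channel columns).
#' @param group_a,group_b Disjoint character vectors of channel/column
#'   names (each >= 2).
#' @param annotation Optional matrisome annotation; with
#'   `matrisome_only = TRUE` (default when annotation is given) only
#'   matrisome proteins are tested.
#' @param fc_threshold Linear fold-change threshold (default `sqrt(2)`).
#' @param p_threshold P-value threshold (default 0.05).
#' @param matrisome_only Restrict testing to matrisome proteins.
#' @param test_scale Scale for the Welch test: `"log2"` (default) or
#'   `"linear"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble of class `dep_table`: protein, category, mean_a,
#'   mean_b, fc, log2fc, t, df, p (and p_adj if adjusted), dep, direction.
#'   Proteins with fewer than 2 observations in a group are excluded
#'   (count reported via attribute `n_excluded`).
#' @export
welch_dep <- function(quant, group_a, group_b,
                      annotation = NULL,
                      fc_threshold = sqrt(2),
                      p_threshold = 0.05,
                      matrisome_only = !is.null(annotation),
                      test_scale = c("log2", "linear"),
                      adjust = c("none", "BH")) {
  test_scale <- match.arg(test_scale)
  adjust <- match.arg(adjust)
  if (length(intersect(group_a, group_b)) > 0) {
    abort("group_a and group_b overlap")
  }
  m <- as_quant_matrix(quant)
  missing_cols <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing_cols) > 0) {
    abort(paste0("unknown channels: ", paste(missing_cols, collapse = ", ")))
  }
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least 2 samples")
  }
  cat_lab <- rep("none", nrow(m))
  if (!is.null(annotation)) {
    ann <- annotate_matrisome(rownames(m), annotation)
    cat_lab <- ann$category
    if (matrisome_only) {
      keep <- cat_lab != "none"
      m <- m[keep, , drop = FALSE]
      cat_lab <- cat_lab[keep]
    }
  }
  a <- m[, group_a, drop = FALSE]
  b <- m[, group_b, drop = FALSE]
  # zeros are unquantified reporter ions: exclude from the log2 test
  a[!is.na(a) & a <= 0] <- NA
  b[!is.na(b) & b <= 0] <- NA
  ok <- rowSums(!is.na(a)) >= 2 & rowSums(!is.na(b)) >= 2
  n_excluded <- sum(!ok)
  if (n_excluded > 0) {
    inform(sprintf("%d protein(s) with < 2 observations in a group excluded", n_excluded))
  }
  a <- a[ok, , drop = FALSE]
  b <- b[ok, , drop = FALSE]
  cat_lab <- cat_lab[ok]

  w <- if (test_scale == "log2") row_welch(log2(a), log2(b)) else row_welch(a, b)
  mean_a <- rowMeans(a, na.rm = TRUE)
  mean_b <- rowMeans(b, na.rm = TRUE)
  fc <- mean_a / mean_b
  log2fc <- log2(fc)
  p_used <- if (adjust == "BH") p.adjust(w$p, "BH") else w$p
  lfc_cut <- log2(fc_threshold)
  dep <- abs(log2fc) > lfc_cut & p_used < p_threshold
  out <- tibble(
    protein = rownames(a),
    category = cat_lab,
    mean_a = unname(mean_a), mean_b = unname(mean_b),
    fc = unname(fc), log2fc = unname(log2fc),
    t = unname(w$t), df = unname(w$df), p = unname(w$p),
    dep = unname(dep),
    direction = dplyr::case_when(
      dep & log2fc > lfc_cut ~ "A-enriched",
      dep & log2fc < -lfc_cut ~ "B-enriched",
      TRUE ~ "none"
    )
  )
  if (adjust == "BH") out$p_adj <- p_used
  attr(out, "n_excluded") <- n_excluded
  attr(out, "thresholds") <- list(
    fc = fc_threshold, log2fc = lfc_cut, p = p_threshold, adjust = adjust
  )
  class(out) <- c("dep_table", class(out))
  out
}

#' Per-patient paired log2 fold changes
#'
#' For each protein and each patient with both a tumor and an adjacent
#' normal sample, computes `log2(tumor / NAT)`, the per-protein median
#' across patients, and a concordance flag: does the median paired
#' log2FC agree in sign with a supplied group-level log2FC?
#'
#' @param quant Normalized tibble.
#' @param pairs Tibble with columns `patient`, `nat`, `tum` (channel
#'   names); rows with either member missing from the matrix are
#'   dropped.
#' @param proteins Optional protein subset (e.g. the DEPs).
#' @param group_log2fc Optional named numeric of group-level log2FC used
#'   for the concordance flag.
#' @return List with `per_patient` (tibble protein, patient, log2fc) and
#'   `summary` (tibble protein, median_log2fc, n_pairs, n_discordant,
#'   and `concordant` when `group_log2fc` is given).
#' @export
paired_log2fc <- function(quant, pairs, proteins = NULL, group_log2fc = NULL) {
  m <- as_quant_matrix(quant)
  if (!is.null(proteins)) m <- m[rownames(m) %in% proteins, , drop = FALSE]
  ok <- pairs$nat %in% colnames(m) & pairs$tum %in% colnames(m)
  pairs <- pairs[ok, , drop = FALSE]
  if (nrow(pairs) == 0) abort("no complete tumor/NAT pairs")
  per_patient <- purrr::map_dfr(seq_len(nrow(pairs)), function(k) {
    lfc <- log2(m[, pairs$tum[k]] / m[, pairs$nat[k]])
    tibble(protein = rownames(m), patient = pairs$patient[k], log2fc = lfc)
  }) |>
    filter(is.finite(.data$log2fc))
  summary <- per_patient |>
    group_by(.data$protein) |>
    summarise(
      median_log2fc = median(.data$log2fc),
      n_pairs = dplyr::n(),
      n_discordant = sum(sign(.data$log2fc) != sign(median(.data$log2fc))),
      .groups = "drop"
    )
  if (!is.null(group_log2fc)) {
    summary$concordant <-
      sign(summary$median_log2fc) ==
        sign(group_log2fc[summary$protein])
  }
  list(per_patient = per_patient, summary = summary)
}

#' Define the PCC-NOS-enriched matrisome protein (PEM) set
#'
#' From a differential table computed with group A = PCC-NOS tumors and
#' group B = non-PCC-NOS tumors, the PEM set is the proteins flagged DEP
#' on the PCC-NOS-enriched side only (`direction == "A-enriched"`).
#'
#' @param dep A `dep_table` from [welch_dep()] with group A = PCC-NOS.
#' @return Character vector of gene symbols (possibly empty, with a
#'   warning).
#' @export
define_pem <- function(dep) {
  stopifnot(inherits(dep, "dep_table"))
  pem <- dep$protein[dep$direction == "A-enriched"]
  if (length(pem) == 0) warn("no PCC-NOS-enriched proteins; PEM set is empty")
  pem
}
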
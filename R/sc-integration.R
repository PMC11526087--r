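#' One-vs-rest cell-type marker detection
#'
#' For each cell type, tests every gene with a two-sided Wilcoxon
#' rank-sum test (normal approximation with tie and continuity
#' correction) of that type's cells against all other cells, on the
#' library-size-normalized log1p layer. P-values are
#' Benjamini-Hochberg-adjusted across genes within each cell type. A
#' gene is flagged cell-type-specific when the adjusted p is below
#' `alpha` and the effect (log2 ratio of mean normalized expression, with
#' a small pseudocount) is positive. Cell types with fewer than 3 cells
#' are skipped with a warning; genes with zero counts everywhere are not
#' tested.
#'
#' @param cells A `cell_data` object.
#' @param alpha Adjusted-p threshold for specificity (default 0.01).
#' @param pseudocount Added to both means in the effect-size ratio.
#' @return Tibble of class `marker_table`: gene, cell_type, log2fc, p,
#'   p_adj, specific.
#' @export
find_markers <- function(cells, alpha = 0.01, pseudocount = 0.01) {
  stopifnot(inherits(cells, "cell_data"))
  types <- unique(cells$cells$cell_type)
  if (length(types) < 2) abort("need at least 2 cell types")
  sizes <- table(cells$cells$cell_type)
  small <- names(sizes)[sizes < 3]
  if (length(small) > 0) {
    warn(paste0("cell type(s) with < 3 cells skipped: ", paste(small, collapse = ", ")))
    types <- setdiff(types, small)
  }
  norm <- cell_norm(cells)
  expressed <- rowSums(cells$counts) > 0
  x <- norm[expressed, , drop = FALSE]
  # one shared ranking per gene serves every one-vs-rest contrast
  ranks <- t(apply(x, 1, rank))
  tie_terms <- apply(x, 1, function(v) {
    tt <- table(v)
    sum(tt^3 - tt)
  })
  out <- purrr::map_dfr(types, function(ct) {
    in_g <- cells$cells$cell_type == ct
    p <- vapply(seq_len(nrow(x)), function(i) {
      rank_sum_p(ranks[i, ], in_g, tie_terms[i])
    }, numeric(1))
    m_in <- rowMeans(x[, in_g, drop = FALSE])
    m_out <- rowMeans(x[, !in_g, drop = FALSE])
    tibble(
      gene = rownames(x),
      cell_type = ct,
      log2fc = log2((m_in + pseudocount) / (m_out + pseudocount)),
      p = p,
      p_adj = p.adjust(p, "BH")
    )
  })
  out$specific <- !is.na(out$p_adj) & out$p_adj < alpha & out$log2fc > 0
  class(out) <- c("marker_table", class(out))
  out
}

#' Assign cellular origin to genes
#'
#' A gene's cellular origin is the cell type with the highest average
#' normalized expression, assigned only if the gene is statistically
#' cell-type-specific (specific flag in the marker table for at least
#' one type); otherwise the gene is `unassigned`. Genes absent from the
#' matrix are unassigned and reported.
#'
#' @param genes Character vector (e.g. the PEM set).
#' @param cells A `cell_data` object.
#' @param markers A `marker_table` computed on the same cells.
#' @return Tibble (gene, origin, specific_in — comma-separated types the
#'   gene is specific in).
#' @export
assign_origin <- function(genes, cells, markers) {
  stopifnot(inherits(cells, "cell_data"), inherits(markers, "marker_table"))
  norm <- cell_norm(cells)
  types <- unique(cells$cells$cell_type)
  avg <- vapply(types, function(ct) {
    rowMeans(norm[, cells$cells$cell_type == ct, drop = FALSE])
  }, numeric(nrow(norm)))
  absent <- setdiff(genes, rownames(norm))
  if (length(absent) > 0) {
    inform(paste0("gene(s) absent from matrix: ", paste(absent, collapse = ", ")))
  }
  purrr::map_dfr(genes, function(g) {
    if (!g %in% rownames(norm)) {
      return(tibble(gene = g, origin = "unassigned", specific_in = ""))
    }
    spec <- markers$cell_type[markers$gene == g & markers$specific]
    if (length(spec) == 0) {
      return(tibble(gene = g, origin = "unassigned", specific_in = ""))
    }
    tibble(
      gene = g,
      origin = types[which.max(avg[g, ])],
      specific_in = paste(spec, collapse = ",")
    )
  })
}

#' Fraction of a gene set per cellular origin
#'
#' @param origins Output of [assign_origin()].
#' @return Tibble (origin, n, fraction); fractions sum to 1 over assigned
#'   plus unassigned genes.
#' @export
origin_fractions <- function(origins) {
  if (nrow(origins) == 0) abort("empty gene set")
  origins |>
    dplyr::count(.data$origin, name = "n") |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    arrange(desc(.data$fraction))
}

#' Subcluster fibroblasts on matrisome features
#'
#' Z-scores the normalized expression of the feature genes across cells,
#' reduces to principal components, builds a k-nearest-neighbor graph on
#' the component space and partitions it by Leiden modularity
#' optimization at the given resolution. Deterministic under `seed`.
#'
#' @param cells A `cell_data` object (typically the fibroblast subset).
#' @param feature_genes Genes used as features (e.g. all matrisome
#'   genes); at least 2 must be present.
#' @param n_components Principal components kept (default 20).
#' @param resolution Leiden resolution (default 0.5); smaller values
#'   merge clusters.
#' @param k_neighbors Neighbors per cell in the graph (default 20).
#' @param seed Integer seed.
#' @return Tibble (barcode, cluster) with cluster as factor.
#' @export
fibroblast_subcluster <- function(cells, feature_genes,
                                  n_components = 20, resolution = 0.5,
                                  k_neighbors = 20, seed = 1L) {
  stopifnot(inherits(cells, "cell_data"))
  feats <- intersect(feature_genes, rownames(cells$counts))
  if (length(feats) < 2) abort("fewer than 2 feature genes present in the matrix")
  n_cells <- ncol(cells$counts)
  if (n_cells < n_components + 1) {
    n_components <- max(2, n_cells - 1)
    warn(sprintf("reducing n_components to %d for %d cells", n_components, n_cells))
  }
  norm <- cell_norm(cells)[feats, , drop = FALSE]
  sds <- apply(norm, 1, sd)
  norm <- norm[sds > 0, , drop = FALSE]
  z <- t(scale(t(norm)))
  set.seed(seed)
  n_components <- min(n_components, nrow(z) - 1, ncol(z) - 1)
  pcs <- prcomp(t(z), center = TRUE, scale. = FALSE)$x[, seq_len(n_components), drop = FALSE]
  d <- as.matrix(dist(pcs))
  diag(d) <- Inf
  k <- min(k_neighbors, n_cells - 1)
  edges <- purrr::map_dfr(seq_len(n_cells), function(i) {
    nb <- order(d[i, ])[seq_len(k)]
    tibble(from = i, to = nb)
  })
  g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
  g <- igraph::simplify(g)
  part <- igraph::cluster_leiden(
    g,
    objective_function = "modularity",
    resolution = resolution,
    n_iterations = 5
  )
  tibble(
    barcode = cells$cells$barcode,
    cluster = factor(igraph::membership(part))
  )
}

#' Per-cell gene-set score (single-sample rank enrichment)
#'
#' Scores each cell for a gene set with the single-sample GSEA running
#' sum: genes are ranked by expression (average ranks on ties); walking
#' from the highest-expressed gene down, the in-set cumulative
#' distribution accumulates `rank^alpha` weights (normalized over the
#' set) and the out-of-set distribution accumulates uniform weight; the
#' enrichment score is the sum of their differences over all positions.
#' Being rank-based, the score is invariant to any strictly monotone
#' per-cell transformation of expression.
#'
#' @param cells A `cell_data` object (e.g. the fibroblast subset).
#' @param geneset Character vector of set genes; must intersect the
#'   matrix and must not cover all genes.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @return Tibble (barcode, score).
#' @export
sc_score <- function(cells, geneset, alpha = 0.25) {
  stopifnot(inherits(cells, "cell_data"))
  scores <- ssgsea_scores(cell_norm(cells), geneset, alpha = alpha)
  tibble(barcode = names(scores), score = unname(scores))
}

# shared single-sample rank-enrichment scorer used for both cells and
# bulk samples; x is a genes x units matrix
ssgsea_scores <- function(x, geneset, alpha = 0.25) {
  geneset <- unique(as.character(geneset))
  in_set <- rownames(x) %in% geneset
  if (!any(in_set)) abort("gene set does not intersect the matrix")
  if (all(in_set)) abort("gene set covers every gene; complement is empty")
  apply(x, 2, function(v) ssgsea_es(v, in_set, alpha))
}

ssgsea_es <- function(v, in_set, alpha) {
  r <- rank(v, ties.method = "average")
  ord <- order(v, decreasing = TRUE)
  set_ord <- in_set[ord]
  w <- r[ord]^alpha
  w[!set_ord] <- 0
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!set_ord) / sum(!set_ord)
  sum(p_in - p_out)
}

#' Correlate gene expression with a per-cell score
#'
#' Pearson correlation between each gene's TPM-normalized expression and
#' a per-cell score, plus the fraction of cells with a nonzero raw count
#' ("proportion of positive cells"). Zero-variance genes are excluded
#' from the ranking and reported.
#'
#' @param cells A `cell_data` object.
#' @param scores Tibble (barcode, score) aligned with the cells, e.g.
#'   from [sc_score()].
#' @param top_k Genes in the `top` attribute (default 20).
#' @param log_tpm Correlate on log1p(TPM) instead of raw TPM.
#' @return Tibble (gene, r, prop_positive) sorted by descending r, with
#'   attributes `top` (top_k gene symbols) and `n_zero_variance`.
#' @export
correlate_with_score <- function(cells, scores, top_k = 20, log_tpm = FALSE) {
  stopifnot(inherits(cells, "cell_data"))
  if (ncol(cells$counts) < 3) abort("need at least 3 cells")
  s <- scores$score[match(cells$cells$barcode, scores$barcode)]
  if (anyNA(s)) abort("scores do not cover every cell")
  tpm <- cell_tpm(cells)
  if (log_tpm) tpm <- log1p(tpm)
  sds <- apply(tpm, 1, sd)
  n_zv <- sum(sds == 0)
  if (n_zv == nrow(tpm)) abort("all genes have zero variance")
  keep <- sds > 0
  r <- as.vector(cor(t(tpm[keep, , drop = FALSE]), s))
  out <- tibble(
    gene = rownames(tpm)[keep],
    r = r,
    prop_positive = unname(rowMeans(cells$counts[keep, , drop = FALSE] > 0))
  ) |>
    arrange(desc(.data$r))
  attr(out, "top") <- head(out$gene, top_k)
  attr(out, "n_zero_variance") <- n_zv
  out
}
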
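#' Annotate proteins against a matrisome table
#'
#' Labels each protein with its matrisome division (core matrisome /
#' matrisome-associated / none) and category (COL, GLY, PRO, REG, AFF,
#' SEC, none). Matching is by exact gene symbol; unmatched proteins get
#' "none". A summary of category counts is attached as attribute
#' `counts`.
#'
#' @param proteins Character vector of protein/gene symbols, or a tibble
#'   with a `protein` column.
#' @param annotation Tibble with columns `gene`, `division`, `category`.
#' @return Tibble (protein, division, category) with attribute `counts`.
#' @export
annotate_matrisome <- function(proteins, annotation) {
  if (is.data.frame(proteins)) proteins <- proteins$protein
  if (!is.data.frame(annotation) || nrow(annotation) == 0) {
    abort("annotation table is empty")
  }
  idx <- match(proteins, annotation$gene)
  out <- tibble(
    protein = proteins,
    division = ifelse(is.na(idx), "none", annotation$division[idx]),
    category = ifelse(is.na(idx), "none", annotation$category[idx])
  )
  attr(out, "counts") <- table(out$category)
  out
}

#' Relative percent composition (RPC)
#'
#' Expresses each protein's intensity as a percentage of its sample's
#' total intensity: `rpc[i, s] = 100 * x[i, s] / sum_k x[k, s]`. If a
#' design table is supplied, only `role == "sample"` channels are kept.
#' Missing intensities are treated as unobserved (dropped from the
#' denominator and left NA).
#'
#' @param quant Normalized tibble (`protein` + channel columns).
#' @param design Optional design tibble used to keep sample channels only.
#' @return Tibble of the same shape; each column sums to 100.
#' @export
rpc <- function(quant, design = NULL) {
  m <- as_quant_matrix(quant)
  if (!is.null(design)) {
    m <- m[, design$channel[design$role == "sample"], drop = FALSE]
  }
  tot <- colSums(m, na.rm = TRUE)
  if (any(tot == 0)) {
    abort(paste0(
      "sample(s) with zero total intensity: ",
      paste(colnames(m)[tot == 0], collapse = ", ")
    ))
  }
  quant_tibble(sweep(m, 2, tot / 100, "/"))
}

#' Per-group matrisome category composition
#'
#' Sums member-protein RPC into one value per category and sample, then
#' compares groups: per-category group means plus a two-sided Welch
#' t-test per category between each pair of groups. Groups with fewer
#' than 2 samples keep their composition but are skipped in testing
#' (with a warning).
#'
#' @param rpc_tbl Output of [rpc()].
#' @param annotation Matrisome annotation (gene, division, category).
#' @param groups Tibble mapping `sample` (channel/column name) to
#'   `group`.
#' @return List with `per_sample` (sample, category, rpc),
#'   `group_means` (group, category, mean_rpc) and `tests`
#'   (group_a, group_b, category, p).
#' @export
category_composition <- function(rpc_tbl, annotation, groups) {
  m <- as_quant_matrix(rpc_tbl)
  ann <- annotate_matrisome(rownames(m), annotation)
  cats <- sort(unique(ann$category))
  per_cat <- t(vapply(
    cats,
    function(cat) colSums(m[ann$category == cat, , drop = FALSE], na.rm = TRUE),
    numeric(ncol(m))
  ))
  keep <- intersect(colnames(m), groups$sample)
  grp <- groups$group[match(keep, groups$sample)]
  per_sample <- tidyr::pivot_longer(
    bind_cols(tibble(category = cats), as_tibble(per_cat)),
    -"category", names_to = "sample", values_to = "rpc"
  ) |>
    filter(.data$sample %in% keep) |>
    left_join(tibble(sample = keep, group = grp), by = "sample")

  group_means <- per_sample |>
    group_by(.data$group, .data$category) |>
    summarise(mean_rpc = mean(.data$rpc), n = dplyr::n(), .groups = "drop")

  glev <- unique(grp)
  small <- group_means |>
    distinct(.data$group, .data$n) |>
    filter(.data$n < 2)
  if (nrow(small) > 0) {
    warn(paste0(
      "group(s) with < 2 samples skipped in testing: ",
      paste(small$group, collapse = ", ")
    ))
  }
  testable <- setdiff(glev, small$group)
  tests <- NULL
  if (length(testable) >= 2) {
    pairs <- utils::combn(testable, 2, simplify = FALSE)
    tests <- purrr::map_dfr(pairs, function(pr) {
      a <- per_cat[, keep[grp == pr[1]], drop = FALSE]
      b <- per_cat[, keep[grp == pr[2]], drop = FALSE]
      w <- row_welch(a, b)
      tibble(
        group_a = pr[1], group_b = pr[2], category = cats,
        mean_a = unname(w$mean_a), mean_b = unname(w$mean_b),
        t = unname(w$t), p = unname(w$p)
      )
    })
  }
  list(per_sample = per_sample, group_means = group_means, tests = tests)
}

#' Proteins needed to cover a fraction of total intensity
#'
#' Smallest `k` such that the `k` largest values of a mean-RPC vector sum
#' to at least `threshold` of the vector's total (the "how many proteins
#' cover 90% of intensity" count).
#'
#' @param mean_rpc Numeric vector of per-protein mean RPC for one group.
#' @param threshold Coverage fraction in (0, 1].
#' @return Integer count.
#' @export
cumulative_coverage <- function(mean_rpc, threshold = 0.9) {
  mean_rpc <- mean_rpc[!is.na(mean_rpc)]
  if (length(mean_rpc) == 0) abort("empty RPC vector")
  cum <- cumsum(sort(mean_rpc, decreasing = TRUE))
  as.integer(which(cum >= threshold * sum(mean_rpc) - 1e-12)[1])
}

#' Top abundant (matrisome) proteins of a group
#'
#' Ranks proteins by descending mean RPC (ties broken alphabetically by
#' symbol) and attaches every sample's RPC for dispersion display.
#'
#' @param rpc_tbl Output of [rpc()], restricted to one group's samples.
#' @param annotation Matrisome annotation.
#' @param n Number of proteins to return.
#' @param matrisome_only Keep matrisome proteins only (default TRUE).
#' @return Tibble (protein, category, mean_rpc) with list-column
#'   `sample_rpc`.
#' @export
top_abundant <- function(rpc_tbl, annotation, n = 20, matrisome_only = TRUE) {
  stopifnot(n >= 1)
  m <- as_quant_matrix(rpc_tbl)
  ann <- annotate_matrisome(rownames(m), annotation)
  if (matrisome_only) m <- m[ann$category != "none", , drop = FALSE]
  if (nrow(m) < n) {
    warn(sprintf("only %d protein(s) available; returning all", nrow(m)))
    n <- nrow(m)
  }
  means <- rowMeans(m, na.rm = TRUE)
  ord <- order(-means, rownames(m))
  top <- ord[seq_len(n)]
  tibble(
    protein = rownames(m)[top],
    category = ann$category[match(rownames(m)[top], ann$protein)],
    mean_rpc = means[top],
    sample_rpc = lapply(top, function(i) m[i, ])
  )
}

#' Hierarchical clustering of samples on matrisome profiles
#'
#' Protein rows are z-scored across samples (constant rows are dropped
#' with a message), samples are compared by Euclidean distance, and an
#' agglomerative tree is built.
#'
#' @param quant Normalized tibble, typically restricted to matrisome rows.
#' @param method Linkage: one of `average` (default), `single`,
#'   `complete`, `ward` (ward.D2).
#' @param log2 Cluster on log2 intensities (default TRUE).
#' @return An [stats::hclust] object over samples.
#' @export
hcluster_samples <- function(quant, method = c("average", "single", "complete", "ward"),
                             log2 = TRUE) {
  method <- match.arg(method)
  m <- as_quant_matrix(quant)
  if (ncol(m) < 2) abort("need at least 2 samples to cluster")
  if (log2) m <- base::log2(m)
  sds <- apply(m, 1, sd, na.rm = TRUE)
  const <- is.na(sds) | sds == 0
  if (any(const)) {
    inform(sprintf("dropping %d constant protein row(s) before z-scoring", sum(const)))
    m <- m[!const, , drop = FALSE]
  }
  z <- t(scale(t(m)))
  hclust(dist(t(z)), method = if (method == "ward") "ward.D2" else method)
}

#' PCA embedding of samples on matrisome profiles
#'
#' Centers proteins and projects samples onto principal components,
#' ordered by decreasing explained variance. Component signs are fixed by
#' making the loading of largest magnitude positive, so embeddings are
#' reproducible across platforms.
#'
#' @param quant Normalized tibble, typically matrisome rows only.
#' @param n_components Components to keep (reduced with a warning when
#'   more than available).
#' @param log2 Run PCA on log2 intensities (default TRUE; stabilizes
#'   variance).
#' @return List of class `pca_embed`: `coords` (tibble sample, PC1, ...),
#'   `explained_variance` (fraction per component), `loadings` (matrix).
#' @export
pca_embed <- function(quant, n_components = 2, log2 = TRUE) {
  m <- as_quant_matrix(quant)
  if (ncol(m) < 3) abort("need at least 3 samples for PCA")
  if (log2) m <- base::log2(m)
  x <- t(m[complete.cases(m), , drop = FALSE]) # samples x proteins
  max_comp <- min(nrow(x) - 1, ncol(x))
  if (n_components > max_comp) {
    warn(sprintf("reducing components from %d to %d", n_components, max_comp))
    n_components <- max_comp
  }
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  rot <- fit$rotation[, k, drop = FALSE]
  flip <- vapply(k, function(j) {
    sign(rot[which.max(abs(rot[, j])), j])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(fit$x[, k, drop = FALSE], 2, flip, "*")
  rot <- sweep(rot, 2, flip, "*")
  structure(
    list(
      coords = bind_cols(tibble(sample = rownames(scores)), as_tibble(scores)),
      explained_variance = (fit$sdev^2 / sum(fit$sdev^2))[k],
      loadings = rot
    ),
    class = "pca_embed"
  )
}
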
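# shared fixtures and independent oracles

# a small cohort configuration that keeps tests fast
tiny_cohort_config <- function(seed = 1, ...) {
  defaults <- list(
    n_plexes = 2, samples_per_plex = 4,
    group_sizes = c(TUM = 4, NAT = 2, LNM = 1, NN = 1),
    n_proteins = 60, matrisome_fraction = 0.3,
    n_pccnos = 2, seed = seed
  )
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# quant tibble from a named matrix, and back
quant_from_matrix <- function(m) {
  dplyr::bind_cols(tibble::tibble(protein = rownames(m)), tibble::as_tibble(m))
}

quant_mat <- function(q) {
  m <- as.matrix(q[-1])
  rownames(m) <- q$protein
  m
}

# two-group quant fixture: n_planted proteins carry a log2 effect in group A
two_group_quant <- function(n_proteins = 100, n_planted = 20, n_per_group = 10,
                            effect = 1, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  b <- rnorm(n_proteins, 18, 1.5)
  eff <- c(rep(effect, n_planted), rep(0, n_proteins - n_planted))
  a <- 2^(b + eff + matrix(rnorm(n_proteins * n_per_group, 0, noise_sd),
                           n_proteins, n_per_group))
  bb <- 2^(b + matrix(rnorm(n_proteins * n_per_group, 0, noise_sd),
                      n_proteins, n_per_group))
  m <- cbind(a, bb)
  rownames(m) <- sprintf("P%03d", seq_len(n_proteins))
  colnames(m) <- c(sprintf("A%02d", seq_len(n_per_group)),
                   sprintf("B%02d", seq_len(n_per_group)))
  list(
    quant = quant_from_matrix(m),
    group_a = sprintf("A%02d", seq_len(n_per_group)),
    group_b = sprintf("B%02d", seq_len(n_per_group)),
    planted = sprintf("P%03d", seq_len(n_planted))
  )
}

# brute-force single-sample rank-enrichment oracle: explicit walk over the
# ranked gene list, accumulating the two cumulative distributions
ssgsea_oracle <- function(expr, geneset, alpha = 0.25) {
  genes <- names(expr)
  r <- rank(expr, ties.method = "average")
  in_set <- genes %in% geneset
  ord <- order(expr, decreasing = TRUE)
  wsum <- sum(r[in_set]^alpha)
  n_out <- sum(!in_set)
  es <- 0
  p_in <- 0
  p_out <- 0
  for (i in ord) {
    if (in_set[i]) {
      p_in <- p_in + r[i]^alpha / wsum
    } else {
      p_out <- p_out + 1 / n_out
    }
    es <- es + (p_in - p_out)
  }
  as.numeric(es)
}

# all permutations of a vector (tiny n only)
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# cell_data built directly from a counts matrix and labels
cell_data_from_counts <- function(counts, cell_type, in_subpop = FALSE) {
  structure(
    list(
      counts = counts,
      cells = tibble::tibble(
        barcode = colnames(counts),
        cell_type = cell_type,
        in_subpop = in_subpop
      )
    ),
    class = "cell_data"
  )
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
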
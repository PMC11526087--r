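# internal helpers shared across modules

# quant tibbles carry proteins in the first column ("protein") and one
# numeric column per channel; these convert to/from a rownamed matrix.
as_quant_matrix <- function(quant) {
  stopifnot(is.data.frame(quant), "protein" %in% names(quant))
  if (anyDuplicated(quant$protein)) {
    abort("duplicate protein ids in quant table")
  }
  m <- as.matrix(quant[setdiff(names(quant), "protein")])
  if (!is.numeric(m)) abort("non-numeric channel columns in quant table")
  rownames(m) <- quant$protein
  m
}

quant_tibble <- function(m) {
  dplyr::bind_cols(tibble(protein = rownames(m)), as_tibble(m))
}

# column medians of log2 values, NAs ignored
log2_col_medians <- function(m) {
  apply(m, 2, function(x) median(log2(x), na.rm = TRUE))
}

check_positive_intensities <- function(m) {
  bad <- which(!is.na(m) & m <= 0)
  if (length(bad) > 0) {
    abort("non-positive intensities present; mask them as NA before normalizing")
  }
  empty <- colSums(!is.na(m)) == 0
  if (any(empty)) {
    abort(paste0(
      "channel(s) entirely missing: ",
      paste(colnames(m)[empty], collapse = ", ")
    ))
  }
  invisible(m)
}

# vectorized two-sided Welch t-test on rows of two matrices
row_welch <- function(a, b) {
  n1 <- rowSums(!is.na(a))
  n2 <- rowSums(!is.na(b))
  m1 <- rowMeans(a, na.rm = TRUE)
  m2 <- rowMeans(b, na.rm = TRUE)
  v1 <- rowSums((a - m1)^2, na.rm = TRUE) / (n1 - 1)
  v2 <- rowSums((b - m2)^2, na.rm = TRUE) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p, mean_a = m1, mean_b = m2, n_a = n1, n_b = n2)
}

# Mann-Whitney U with normal approximation, tie correction and continuity
# correction; matches wilcox.test(exact = FALSE, correct = TRUE)
rank_sum_p <- function(ranks, in_group, tie_term) {
  n  <- length(ranks)
  n1 <- sum(in_group)
  n2 <- n - n1
  u  <- sum(ranks[in_group]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(NA_real_)
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  2 * pnorm(-z)
}

new_geneset <- function(members, name = "geneset") {
  members <- unique(as.character(members))
  if (length(members) == 0) abort("gene set is empty")
  structure(members, name = name)
}
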
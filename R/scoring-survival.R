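#' Select top marker genes from a ranked table
#'
#' Takes the `n` genes with the largest values of a key column (default
#' the log2 fold change), ties broken alphabetically — e.g. the top 30
#' adipogenic-CAF markers used for bulk scoring.
#'
#' @param marker_table Tibble with a `gene` column and the key column.
#' @param n Genes to keep (default 30; fewer returned with a warning when
#'   the table is short).
#' @param key Column to rank by (default `"log2fc"`).
#' @return Character vector of gene symbols.
#' @export
select_top_markers <- function(marker_table, n = 30, key = "log2fc") {
  if (!key %in% names(marker_table)) {
    abort(sprintf("column '%s' not found in marker table", key))
  }
  if (nrow(marker_table) < n) {
    warn(sprintf("only %d row(s) available; returning all", nrow(marker_table)))
    n <- nrow(marker_table)
  }
  ord <- order(-marker_table[[key]], marker_table$gene)
  marker_table$gene[ord[seq_len(n)]]
}

#' ssGSEA scores of bulk samples
#'
#' Applies the shared single-sample rank-enrichment scorer (see
#' [sc_score()] for the running-sum definition) to each sample column of
#' a bulk TPM matrix.
#'
#' @param tpm Tibble with a `gene` column and one numeric column per
#'   sample, or a genes x samples matrix.
#' @param geneset Character vector of set genes.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @return Tibble (sample, score).
#' @export
ssgsea_bulk <- function(tpm, geneset, alpha = 0.25) {
  m <- if (is.data.frame(tpm)) {
    x <- as.matrix(tpm[setdiff(names(tpm), "gene")])
    rownames(x) <- tpm$gene
    x
  } else {
    tpm
  }
  scores <- ssgsea_scores(m, geneset, alpha = alpha)
  tibble(sample = names(scores), score = unname(scores))
}

#' Pearson correlation of two score vectors
#'
#' @param a,b Aligned numeric vectors (or score tibbles with a `score`
#'   column), n >= 3.
#' @return Tibble (r, p, n); p from the t-distribution with n - 2 df.
#' @export
score_correlation <- function(a, b) {
  if (is.data.frame(a)) a <- a$score
  if (is.data.frame(b)) b <- b$score
  if (length(a) != length(b)) abort("score vectors are not aligned")
  if (length(a) < 3) abort("need at least 3 paired scores")
  if (sd(a) == 0 || sd(b) == 0) abort("zero variance in a score vector")
  ct <- cor.test(a, b, method = "pearson")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Dichotomize scores into high and low groups
#'
#' Splits at the mean (default) or median; a value exactly at the
#' cutpoint is assigned to the high group.
#'
#' @param scores Numeric vector, or tibble with a `score` column (and
#'   optionally a first id column carried through).
#' @param rule `"mean"` or `"median"`.
#' @return Tibble (unit, score, group) with `group` in `{high, low}` and
#'   attribute `cutpoint`.
#' @export
dichotomize <- function(scores, rule = c("mean", "median")) {
  rule <- match.arg(rule)
  if (is.data.frame(scores)) {
    unit <- scores[[1]]
    values <- scores$score
  } else {
    unit <- names(scores) %||% as.character(seq_along(scores))
    values <- unname(scores)
  }
  if (length(values) < 2) abort("need at least 2 values")
  cut <- if (rule == "mean") mean(values) else median(values)
  if (all(values == values[1])) abort("all values equal; degenerate split")
  out <- tibble(
    unit = unit,
    score = values,
    group = ifelse(values >= cut, "high", "low")
  )
  attr(out, "cutpoint") <- cut
  out
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator of the survival function, optionally per
#' group, with censoring handled by risk-set reduction.
#'
#' @param survival Tibble with columns `time` (>= 0), `event` (1 death,
#'   0 censored) and optionally `group`.
#' @return Object of class `km_fit` wrapping a [survival::survfit] fit;
#'   supports `tidy()`, `glance()`, `autoplot()` and `surv_at()`.
#' @export
km_estimate <- function(survival) {
  check_survival_table(survival)
  has_group <- "group" %in% names(survival)
  fit <- if (has_group) {
    survival::survfit(
      survival::Surv(time, event) ~ group,
      data = survival
    )
  } else {
    survival::survfit(survival::Surv(time, event) ~ 1, data = survival)
  }
  structure(list(fit = fit, data = survival), class = "km_fit")
}

#' Survival probability at given times
#'
#' @param km A `km_fit` object (single-group).
#' @param times Numeric times.
#' @return Numeric vector S(times).
#' @export
surv_at <- function(km, times) {
  stopifnot(inherits(km, "km_fit"))
  s <- summary(km$fit, times = times, extend = TRUE)
  s$surv
}

#' Log-rank test between survival groups
#'
#' Standard log-rank test: at each event time the observed events per
#' group are compared with their hypergeometric expectation given the
#' risk sets; the k-group statistic is chi-squared with k - 1 degrees of
#' freedom. Identical groups give a statistic of 0.
#'
#' @param survival Tibble with columns `time`, `event`, `group` (2+
#'   non-empty groups).
#' @return Object of class `logrank_test` (list: statistic, df, p,
#'   observed, expected); supports `glance()`.
#' @export
logrank_test <- function(survival) {
  check_survival_table(survival)
  if (!"group" %in% names(survival)) abort("a 'group' column is required")
  groups <- unique(survival$group)
  if (length(groups) < 2) abort("need at least 2 groups")
  sd_fit <- survival::survdiff(
    survival::Surv(time, event) ~ group,
    data = survival
  )
  structure(
    list(
      statistic = unname(sd_fit$chisq),
      df = length(groups) - 1L,
      p = unname(stats::pchisq(sd_fit$chisq, length(groups) - 1, lower.tail = FALSE)),
      observed = sd_fit$obs,
      expected = sd_fit$exp
    ),
    class = "logrank_test"
  )
}

check_survival_table <- function(survival) {
  if (!all(c("time", "event") %in% names(survival))) {
    abort("survival table needs 'time' and 'event' columns")
  }
  if (any(survival$time < 0)) abort("negative survival times")
  if (!all(survival$event %in% c(0, 1))) abort("event must be 0 (censored) or 1 (death)")
  invisible(survival)
}
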
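#' Tidy a Kaplan-Meier fit
#'
#' @param x A `km_fit` object.
#' @param ... Unused.
#' @return Tibble with time, n.risk, n.event, n.censor, estimate,
#'   std.error, conf.low, conf.high and (for stratified fits) `group`.
#' @export
tidy.km_fit <- function(x, ...) {
  f <- x$fit
  out <- tibble(
    time = f$time,
    n.risk = f$n.risk,
    n.event = f$n.event,
    n.censor = f$n.censor,
    estimate = f$surv,
    std.error = f$std.err,
    conf.low = f$lower,
    conf.high = f$upper
  )
  if (!is.null(f$strata)) {
    out$group <- rep(sub("^group=", "", names(f$strata)), f$strata)
  }
  out
}

#' @rdname tidy.km_fit
#' @export
glance.km_fit <- function(x, ...) {
  f <- x$fit
  med <- summary(f)$table
  if (is.null(dim(med))) med <- matrix(med, nrow = 1, dimnames = list("all", names(med)))
  tibble(
    group = sub("^group=", "", rownames(med)),
    n = med[, "records"],
    events = med[, "events"],
    median_survival = med[, "median"]
  )
}

#' @export
glance.logrank_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p)
}

#' @export
tidy.dep_table <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.dep_table <- function(x, ...) {
  th <- attr(x, "thresholds")
  tibble(
    n_tested = nrow(x),
    n_dep = sum(x$dep),
    n_a_enriched = sum(x$direction == "A-enriched"),
    n_b_enriched = sum(x$direction == "B-enriched"),
    fc_threshold = th$fc,
    p_threshold = th$p
  )
}

#' @export
tidy.pca_embed <- function(x, ...) {
  x$coords
}

#' @export
glance.pca_embed <- function(x, ...) {
  tibble(
    component = paste0("PC", seq_along(x$explained_variance)),
    explained_variance = x$explained_variance
  )
}

#' @export
print.ecm_cohort <- function(x, ...) {
  cat(sprintf(
    "<ecm_cohort> %d proteins x %d channels (%d plexes, %d samples)\n",
    nrow(x$quant), ncol(x$quant) - 1,
    x$config$n_plexes, nrow(x$samples)
  ))
  cat("tissues:", paste(sprintf("%s=%d", names(table(x$samples$tissue)),
                                table(x$samples$tissue)), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf(
    "Log-rank test: chi-squared = %.4g on %d df, p = %.4g\n",
    x$statistic, x$df, x$p
  ))
  invisible(x)
}

#' @export
print.cell_data <- function(x, ...) {
  cat(sprintf(
    "<cell_data> %d genes x %d cells; types: %s\n",
    nrow(x$counts), ncol(x$counts),
    paste(unique(x$cells$cell_type), collapse = ", ")
  ))
  invisible(x)
}
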
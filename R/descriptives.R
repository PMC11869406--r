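#' Survey-weighted prevalence
#'
#' Weighted proportion \eqn{\sum w_i y_i / \sum w_i} of a binary outcome,
#' overall or within the categories of a grouping covariate. Groups with
#' no observations are reported as `NA`, not 0.
#'
#' @param records records data frame with a `weight` column.
#' @param outcome outcome column name (`"y_mcu"` or `"y_shk"`).
#' @param group_by optional covariate column name.
#' @return Named numeric vector (length 1 when ungrouped).
#' @export
weighted_prevalence <- function(records, outcome, group_by = NULL) {
  if (!outcome %in% names(records)) stop("no column '", outcome, "'")
  w <- records$weight
  if (is.null(w)) w <- rep(1, NROW(records))
  if (any(w <= 0)) stop("weights must be positive")
  y <- records[[outcome]]
  if (is.null(group_by)) {
    return(c(overall = sum(w * y) / sum(w)))
  }
  if (!group_by %in% names(records)) stop("no column '", group_by, "'")
  g <- as.character(records[[group_by]])
  levs <- unique(g)
  out <- vapply(levs, function(l) {
    i <- g == l
    if (!any(i)) NA_real_ else sum(w[i] * y[i]) / sum(w[i])
  }, 0)
  out
}

#' Survey-weighted cross-tabulation with chi-square test
#'
#' Weighted cell totals of covariate x outcome, rescaled so the table
#' total equals the unweighted sample size, with a Pearson chi-square test
#' (no continuity or design-effect correction) on the rescaled table.
#' Percentages are normalized within outcome level (column percentages) by
#' default; `percent = "row"` normalizes within covariate category.
#' With unit weights this reproduces the ordinary unweighted chi-square.
#'
#' @param records records data frame with a `weight` column.
#' @param covariate row variable (column name).
#' @param outcome column variable (column name).
#' @param percent `"column"` (default) or `"row"` normalization.
#' @return Object of class `weighted_table`: list with the rescaled
#'   `counts` matrix, `percent` matrix, `statistic`, `df`, `p_value`
#'   (`NA` with a flag when either margin has a single level).
#' @export
weighted_crosstab <- function(records, covariate, outcome,
                              percent = c("column", "row")) {
  percent <- match.arg(percent)
  for (cn in c(covariate, outcome)) {
    if (!cn %in% names(records)) stop("no column '", cn, "'")
  }
  w <- records$weight
  if (is.null(w)) w <- rep(1, NROW(records))
  if (any(w <= 0)) stop("weights must be positive")
  r <- as.character(records[[covariate]])
  c_ <- as.character(records[[outcome]])
  tab <- tapply(w, list(factor(r), factor(c_)), sum, default = 0)
  n <- NROW(records)
  tab <- tab * n / sum(tab)            # rescale weighted totals to n
  pct <- if (percent == "column") {
    sweep(tab, 2, colSums(tab), "/") * 100
  } else {
    sweep(tab, 1, rowSums(tab), "/") * 100
  }
  degenerate <- nrow(tab) < 2L || ncol(tab) < 2L
  if (degenerate) {
    stat <- df <- p <- NA_real_
    warning("chi-square undefined: '", covariate, "' x '", outcome,
            "' has a margin with a single observed level")
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic)
    df <- unname(ct$parameter)
    p <- unname(ct$p.value)
  }
  structure(list(counts = tab, percent = pct, statistic = stat,
                 df = df, p_value = p, n = n,
                 covariate = covariate, outcome = outcome,
                 degenerate = degenerate),
            class = "weighted_table")
}

#' @export
print.weighted_table <- function(x, ...) {
  cat("Weighted cross-tabulation: ", x$covariate, " x ", x$outcome,
      " (n = ", x$n, ")\n", sep = "")
  print(round(x$percent, 1))
  if (x$degenerate) {
    cat("chi-square: undefined (single observed level)\n")
  } else {
    p <- if (x$p_value < 1e-3) "<0.001" else fmt3(x$p_value)
    cat(sprintf("X2 = %.4f, df = %d, p = %s\n", x$statistic,
                as.integer(x$df), p))
  }
  invisible(x)
}
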
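#' Pearson's chi-squared test for a phenotype-by-genotype table
#'
#' Computes `X^2 = sum (O - E)^2 / E` with expected counts
#' `E = row_total * col_total / grand_total`; cells with `E = 0` contribute
#' nothing. Degrees of freedom follow the fixed table dimension,
#' `df = (2 - 1) * (V - 1)` where `V` is the number of genotype columns of
#' the table type (3 univariate, 8 + 1 = 9 bivariate), regardless of empty
#' columns, so that ranking is comparable across pairs. The p-value is the
#' upper chi-squared tail `Q(df/2, X^2/2)`, evaluated in log space so that
#' extreme statistics never underflow to a tied zero.
#'
#' @param tab a `single_table` (2x3) or `pair_table` (2x9), or any 2-row
#'   non-negative count matrix.
#' @return a `pair_stat_result`: list with `statistic`, `p_value`, `log_p`
#'   (natural log) and `df`.
#' @export
chi2_test <- function(tab) {
  m <- unclass(tab)
  storage.mode(m) <- "double"
  if (nrow(m) != 2L) stop("table must have 2 phenotype rows")
  N <- sum(m)
  if (N <= 0) stop("empty table")
  rs <- rowSums(m)
  if (any(rs == 0)) stop("degenerate table: one phenotype class is empty")
  cs <- colSums(m)
  E <- outer(rs, cs) / N
  d <- m - E
  x2 <- sum(ifelse(E > 0, d^2 / E, 0))
  df <- (nrow(m) - 1L) * (ncol(m) - 1L)
  log_p <- stats::pchisq(x2, df = df, lower.tail = FALSE, log.p = TRUE)
  new_stat_result(statistic = x2, log_p = log_p, df = df)
}

new_stat_result <- function(statistic, log_p, df = NA_integer_,
                            converged = TRUE) {
  p <- exp(log_p)
  if (p == 0) p <- .Machine$double.xmin  # p_value stays in (0, 1]
  structure(list(statistic = statistic, p_value = min(p, 1),
                 log_p = min(log_p, 0), df = df, converged = converged),
            class = "pair_stat_result")
}

#' @export
print.pair_stat_result <- function(x, ...) {
  cat(sprintf("statistic = %.6g, df = %s, p = %.4g (log p = %.4g)%s\n",
              x$statistic, ifelse(is.na(x$df), "-", x$df), x$p_value, x$log_p,
              if (isTRUE(x$converged)) "" else " [not converged]"))
  invisible(x)
}
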
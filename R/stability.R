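#' Stratified repeated 2-fold cross-validation plan
#'
#' Each repeat splits the samples into two folds of (near-)equal size,
#' stratified by case/control status so that per-fold class counts differ
#' by at most one. The plan is fully determined by `seed`.
#'
#' @param phen a [phenotype]; both classes must have at least 2 members.
#' @param n_repeats number of random splits (default 10).
#' @param seed RNG seed.
#' @return a `cv_plan`: list with `folds` (samples x repeats matrix of fold
#'   ids 1/2), `n_repeats`, `seed`.
#' @export
make_splits <- function(phen, n_repeats = 10L, seed = 1L) {
  if (n_cases(phen) < 2L || n_controls(phen) < 2L)
    stop("each phenotype class needs at least 2 samples")
  n <- length(phen)
  y <- as.integer(unclass(phen))
  set.seed(seed)
  folds <- matrix(0L, nrow = n, ncol = n_repeats)
  for (r in seq_len(n_repeats)) {
    for (cls in 0:1) {
      idx <- which(y == cls)
      idx <- sample(idx)
      half <- ceiling(length(idx) / 2)
      folds[idx[seq_len(half)], r] <- 1L
      folds[idx[-seq_len(half)], r] <- 2L
    }
  }
  structure(list(folds = folds, n_repeats = as.integer(n_repeats),
                 seed = seed), class = "cv_plan")
}

#' Summarise ZIC values over splits
#'
#' Mean with a Student-t 95% confidence interval,
#' `mean +/- t_{0.975, n-1} * sd / sqrt(n)`. Censored values (no crossing
#' found) are included at their `k_max` with a warning, since dropping
#' them would bias the mean downward.
#'
#' @param zics numeric vector of per-split ZIC values (length >= 2).
#' @param censored optional logical vector flagging censored entries.
#' @return list with `mean`, `lower95`, `upper95`, `n`, `n_censored`.
#' @export
zic_summary <- function(zics, censored = NULL) {
  n <- length(zics)
  if (n < 2L) stop("need at least 2 ZIC values")
  if (!is.null(censored) && any(censored))
    warning(sprintf("%d censored ZIC value(s) included at k_max",
                    sum(censored)))
  m <- mean(zics)
  hw <- stats::qt(0.975, df = n - 1) * stats::sd(zics) / sqrt(n)
  list(mean = m, lower95 = m - hw, upper95 = m + hw, n = n,
       n_censored = if (is.null(censored)) 0L else sum(censored))
}

#' Multiple-testing ranks of a sorted p-value list
#'
#' For T tests at level alpha: the Bonferroni rank is the number of
#' retained p-values at or below `alpha / T`; the Benjamini-Hochberg rank
#' is the largest `j` with `p_(j) <= j * alpha / T`. Both are computed on
#' the retained top list only, so they saturate at the list length (the
#' `saturated` flags mark this, mirroring analyses that keep only the top
#' pairs).
#'
#' @param p numeric vector of p-values sorted ascending (the retained list).
#' @param n_tests total number of tests T (>= `length(p)`).
#' @param alpha significance level.
#' @return an `mtc_ranks`: list with `bonferroni_rank`, `bh_rank`,
#'   `n_tests`, `alpha`, `saturated`.
#' @export
mtc_ranks <- function(p, n_tests, alpha = 0.05) {
  if (is.unsorted(p)) stop("p-values must be sorted ascending")
  if (n_tests < length(p)) stop("n_tests must be >= length(p)")
  bonf <- sum(p <= alpha / n_tests)
  hit <- which(p <= seq_along(p) * alpha / n_tests)
  bh <- if (length(hit)) max(hit) else 0L
  structure(list(bonferroni_rank = as.integer(bonf), bh_rank = as.integer(bh),
                 n_tests = n_tests, alpha = alpha,
                 saturated = bh == length(p) && length(p) > 0L),
            class = "mtc_ranks")
}

#' Cross-validation stability of an exhaustive pair scan
#'
#' The full experimental protocol: for every repeat of the plan, each fold
#' is scanned independently for its top-k pair list; the two lists are
#' compared by the incomplete-list Spearman rho curve, the Jaccard curve,
#' and the Zero Index Crossing; each fold also contributes its
#' univariate-significant SNP set (Bonferroni level `alpha`), the resulting
#' hub counts, and multiple-testing ranks over `T = choose(M, 2)` pair
#' tests. ZIC values are summarised by mean and Student-t 95% CI. A scan on
#' the full data (no split) is included for between-statistic comparisons.
#'
#' @inheritParams exhaustive_scan
#' @param plan a `cv_plan` from [make_splits()].
#' @param tau minimum ZIC prefix size.
#' @param alpha level for the univariate Bonferroni set and the
#'   multiple-testing ranks.
#' @param include_full also scan the complete data set.
#' @param grid prefix-size grid for the rho/Jaccard curves (default
#'   [rho_curve()]'s grid).
#' @return a `stability_report`: list with per-repeat `splits` (fold lists,
#'   curves, `zic`, hub counts, `mtc` ranks), `zic_values`, `zic_censored`,
#'   `summary`, `full_list`, and the configuration.
#' @export
run_stability <- function(x, phen, statistic = c("chi2", "boost", "gss"),
                          k = 10000L, plan = NULL, tau = 100L, alpha = 0.05,
                          include_full = TRUE, grid = NULL) {
  statistic <- match.arg(statistic)
  check_geno_phen(x, phen)
  if (is.null(plan)) plan <- make_splits(phen)
  if (nrow(plan$folds) != length(phen))
    stop("plan does not match the phenotype length")
  M <- ncol(x)
  n_tests <- M * (M - 1) / 2
  y <- as.integer(unclass(phen))

  splits <- vector("list", plan$n_repeats)
  zic_values <- numeric(plan$n_repeats)
  zic_censored <- logical(plan$n_repeats)
  failed <- logical(plan$n_repeats)

  for (r in seq_len(plan$n_repeats)) {
    res <- tryCatch({
      per_fold <- lapply(1:2, function(f) {
        idx <- which(plan$folds[, r] == f)
        xf <- genotype_matrix(unclass(x)[idx, , drop = FALSE],
                              snp_ids = colnames(x),
                              sample_ids = rownames(x)[idx])
        pf <- phenotype(y[idx])
        lst <- exhaustive_scan(xf, pf, statistic = statistic, k = k)
        uni <- univariate_scan(xf, pf)
        sig <- uni$snp_id[uni$p_value <= alpha / M]
        list(list = lst, sig_ids = sig,
             hub = hub_count(lst, sig),
             mtc = mtc_ranks(sort(lst$p_value), n_tests = n_tests,
                             alpha = alpha))
      })
      a <- per_fold[[1L]]$list
      b <- per_fold[[2L]]$list
      z <- zic(a, b, tau = tau)
      rc <- rho_curve(a, b, grid = grid)
      list(fold_a = per_fold[[1L]], fold_b = per_fold[[2L]],
           rho = rc,
           jaccard = data.frame(k = rc$k, jaccard = vapply(rc$k, function(kk)
             jaccard_topk(a, b, kk), numeric(1))),
           zic = z)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("repeat %d failed: %s", r, conditionMessage(res)))
      failed[r] <- TRUE
      next
    }
    splits[[r]] <- res
    zic_values[r] <- res$zic$zic
    zic_censored[r] <- res$zic$censored
  }
  ok <- !failed
  summary <- if (sum(ok) >= 2L)
    zic_summary(zic_values[ok], zic_censored[ok]) else NULL

  full_list <- if (include_full)
    exhaustive_scan(x, phen, statistic = statistic, k = k) else NULL

  structure(list(statistic = statistic, k = k, tau = tau, alpha = alpha,
                 plan = plan, splits = splits, failed_repeats = which(failed),
                 zic_values = zic_values[ok], zic_censored = zic_censored[ok],
                 summary = summary, full_list = full_list),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("stability_report: %s, k = %d, %d/%d repeats\n", x$statistic,
              x$k, length(x$zic_values), x$plan$n_repeats))
  if (!is.null(x$summary))
    cat(sprintf("  ZIC mean %.1f [%.1f, %.1f], %d censored\n",
                x$summary$mean, x$summary$lower95, x$summary$upper95,
                x$summary$n_censored))
  invisible(x)
}

#' Compare the pair sets selected by two statistics
#'
#' Overlap fractions (only A / both / only B, scaled by the union) between
#' the full-data top-k lists of two stability reports built on identical
#' splits, over a grid of prefix sizes, with each statistic's mean ZIC as a
#' marker.
#'
#' @param report_a,report_b `stability_report` objects built with
#'   `include_full = TRUE` on the same plan.
#' @param k_grid prefix sizes; defaults to the rho-curve grid over the
#'   shorter full list.
#' @return list with `overlap` (data frame: k, only_a, both, only_b),
#'   `zic_a`, `zic_b`, `statistic_a`, `statistic_b`.
#' @export
compare_statistics <- function(report_a, report_b, k_grid = NULL) {
  stopifnot(inherits(report_a, "stability_report"),
            inherits(report_b, "stability_report"))
  if (!identical(report_a$plan$folds, report_b$plan$folds))
    stop("reports were not built on identical splits")
  la <- report_a$full_list
  lb <- report_b$full_list
  if (is.null(la) || is.null(lb))
    stop("both reports need a full-data list (include_full = TRUE)")
  k_max <- min(nrow(la), nrow(lb))
  if (is.null(k_grid)) k_grid <- default_k_grid(k_max)
  k_grid <- as.integer(k_grid[k_grid >= 1L & k_grid <= k_max])
  ov <- t(vapply(k_grid, function(k) overlap_fractions(la, lb, k),
                 numeric(3)))
  list(overlap = data.frame(k = k_grid, only_a = ov[, 1L], both = ov[, 2L],
                            only_b = ov[, 3L]),
       zic_a = if (!is.null(report_a$summary)) report_a$summary$mean else NA,
       zic_b = if (!is.null(report_b$summary)) report_b$summary$mean else NA,
       statistic_a = report_a$statistic, statistic_b = report_b$statistic)
}
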
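#' Exhaustive SNP-pair scan with bounded top-k retention
#'
#' Scores every unordered SNP pair `(i < j)` with the chosen statistic and
#' retains the k best in a bounded priority queue: a candidate is admitted
#' only if fewer than k pairs are stored or it beats the current worst
#' entry under the total order (score descending, ties by ascending pair
#' index). The ranking score is the chi-squared or likelihood-ratio
#' statistic, or `-log10 p` for GSS (identical ranking either way at fixed
#' df, but the statistic is kept on each family's native scale).
#'
#' @param x a [genotype_matrix] with at least 2 SNPs.
#' @param phen a [phenotype].
#' @param statistic one of `"chi2"`, `"boost"`, `"gss"`.
#' @param k maximum list length (default 10000; genome-scale analyses
#'   retain on the order of 1e6 pairs, desk-scale runs far fewer).
#' @param screen_threshold optional stage-1 threshold for the BOOST
#'   two-stage procedure: pairs whose Kirkwood screening value falls below
#'   it skip the exact fit and are excluded. `NULL` (default) disables
#'   screening so every pair gets the exact test.
#' @return a [ranked_pair_list] with attributes `statistic`, `k_requested`,
#'   `total_pairs_scanned` and `n_failed` (pairs whose statistic failed,
#'   skipped with a warning).
#' @export
exhaustive_scan <- function(x, phen, statistic = c("chi2", "boost", "gss"),
                            k = 10000L, screen_threshold = NULL) {
  statistic <- match.arg(statistic)
  check_geno_phen(x, phen)
  check_two_classes(phen)
  M <- ncol(x)
  if (M < 2L) stop("need at least 2 SNPs")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  g <- unclass(x)
  y <- as.integer(unclass(phen))
  ids <- colnames(x)
  n_pairs <- M * (M - 1L) / 2L
  cap <- min(k, n_pairs)

  sc <- rep(-Inf, cap)
  pii <- integer(cap)
  pjj <- integer(cap)
  pv <- numeric(cap)
  cnt <- 0L
  worst <- -Inf
  worst_at <- 1L
  n_failed <- 0L
  scanned <- 0L

  stat_fun <- switch(statistic,
    chi2 = function(tab) { r <- chi2_test(tab); c(r$statistic, r$p_value) },
    boost = function(tab) { r <- boost_lrt(tab); c(r$statistic, r$p_value) },
    gss = function(tab) { r <- gss_test(tab); c(r$statistic, r$p_value) })

  for (i in seq_len(M - 1L)) {
    gi <- g[, i]
    for (j in seq.int(i + 1L, M)) {
      scanned <- scanned + 1L
      gj <- g[, j]
      ok <- !is.na(gi) & !is.na(gj)
      counts <- tabulate(2L * (3L * gi[ok] + gj[ok]) + y[ok] + 1L, nbins = 18L)
      tab <- matrix(counts, 2L, 9L)
      if (!is.null(screen_threshold) && statistic == "boost" &&
          ksa_screen(tab) < screen_threshold) next
      res <- tryCatch(stat_fun(tab), error = function(e) NULL)
      if (is.null(res)) { n_failed <- n_failed + 1L; next }
      s <- res[1L]
      if (cnt < cap) {
        cnt <- cnt + 1L
        sc[cnt] <- s; pii[cnt] <- i; pjj[cnt] <- j; pv[cnt] <- res[2L]
        if (cnt == cap) {
          worst_at <- queue_worst(sc, pii, pjj)
          worst <- sc[worst_at]
        }
      } else if (s > worst ||
                 (s == worst && (i < pii[worst_at] ||
                                 (i == pii[worst_at] && j < pjj[worst_at])))) {
        sc[worst_at] <- s; pii[worst_at] <- i; pjj[worst_at] <- j
        pv[worst_at] <- res[2L]
        worst_at <- queue_worst(sc, pii, pjj)
        worst <- sc[worst_at]
      }
    }
  }
  if (n_failed > 0L)
    warning(sprintf("%d pair(s) skipped: statistic failed", n_failed))
  keep <- seq_len(cnt)
  o <- order(-sc[keep], pii[keep], pjj[keep])
  entries <- data.frame(snp_id_1 = ids[pii[keep][o]],
                        snp_id_2 = ids[pjj[keep][o]],
                        score = sc[keep][o], p_value = pv[keep][o],
                        stringsAsFactors = FALSE)
  out <- ranked_pair_list(entries, statistic = statistic, k_requested = k,
                          total_pairs_scanned = scanned)
  attr(out, "n_failed") <- n_failed
  out
}

# worst queue entry under (score desc, pair index asc): lowest score,
# ties resolved towards the largest pair index
queue_worst <- function(sc, pii, pjj) {
  w <- which.min(sc)
  if (sum(sc == sc[w]) > 1L) {
    cand <- which(sc == sc[w])
    w <- cand[order(pii[cand], pjj[cand], decreasing = TRUE)[1L]]
  }
  w
}

#' Univariate chi-squared scan
#'
#' Applies the 2x3 chi-squared test (df = 2) to every SNP.
#'
#' @inheritParams exhaustive_scan
#' @return data frame with columns `snp_id`, `statistic`, `df`, `p_value`,
#'   `log_p`.
#' @export
univariate_scan <- function(x, phen) {
  check_geno_phen(x, phen)
  check_two_classes(phen)
  res <- lapply(seq_len(ncol(x)), function(s)
    chi2_test(build_single_table(x, phen, s)))
  data.frame(snp_id = colnames(x),
             statistic = vapply(res, `[[`, numeric(1), "statistic"),
             df = vapply(res, `[[`, numeric(1), "df"),
             p_value = vapply(res, `[[`, numeric(1), "p_value"),
             log_p = vapply(res, `[[`, numeric(1), "log_p"),
             stringsAsFactors = FALSE)
}

#' Remove univariately significant SNPs at the Bonferroni level
#'
#' Drops every SNP whose univariate chi-squared p-value is at most
#' `alpha / n_snps`. This is the pruning step used to show that hub-driven
#' chi-squared pair lists collapse once their strong-main-effect SNPs are
#' removed, while interaction-targeted statistics are unaffected.
#'
#' @inheritParams exhaustive_scan
#' @param alpha family-wise significance level in (0, 1).
#' @return list with `genotypes` (reduced matrix) and `removed_ids`.
#' @export
prune_univariate <- function(x, phen, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  uni <- univariate_scan(x, phen)
  drop <- uni$p_value <= alpha / ncol(x)
  if (all(drop)) stop("pruning removed every SNP")
  reduced <- unclass(x)[, !drop, drop = FALSE]
  list(genotypes = genotype_matrix(reduced, snp_ids = colnames(x)[!drop],
                                   sample_ids = rownames(x)),
       removed_ids = colnames(x)[drop])
}

#' Count list entries involving given SNPs
#'
#' Number of pairs in a ranked list with at least one member in
#' `significant_ids` — the hub-size diagnostic: a strong-main-effect SNP
#' that pairs promiscuously drives this count up.
#'
#' @param list a [ranked_pair_list].
#' @param significant_ids character vector of SNP ids.
#' @return integer count.
#' @export
hub_count <- function(list, significant_ids) {
  if (length(significant_ids) == 0L) return(0L)
  sum(list$snp_id_1 %in% significant_ids |
        list$snp_id_2 %in% significant_ids)
}
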
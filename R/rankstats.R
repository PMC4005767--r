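#' Extend two top-k lists to fractional rankings over their union
#'
#' Any element of list `b` missing from list `a` must rank beyond the end
#' of `a`; all such absentees share the positions `n_a + 1, ..., m` (where
#' `m` is the union size) and receive their midrank `(n_a + 1 + m) / 2`,
#' preserving consistent fractional ranking. Elements present keep their
#' list position. The mean of each extended rank vector is therefore
#' `(m + 1) / 2`, exactly as for a complete ranking.
#'
#' @param a,b [ranked_pair_list] objects or character key vectors in rank
#'   order.
#' @return list with `union` (element keys), `ranks_a`, `ranks_b`.
#' @export
extend_ranks <- function(a, b) {
  ka <- pair_keys(a)
  kb <- pair_keys(b)
  un <- union(ka, kb)
  m <- length(un)
  ra <- match(un, ka)
  ra[is.na(ra)] <- (length(ka) + 1 + m) / 2
  rb <- match(un, kb)
  rb[is.na(rb)] <- (length(kb) + 1 + m) / 2
  list(union = un, ranks_a = as.numeric(ra), ranks_b = as.numeric(rb))
}

#' Spearman's rho for incomplete top-k lists
#'
#' Pearson correlation of the two extended rank vectors from
#' [extend_ranks()]. When both lists contain the same element set this
#' reduces to the classical tie-aware Spearman correlation. If either
#' extended vector is constant the correlation is undefined; 0 is returned
#' with attribute `undefined = TRUE`.
#'
#' @inheritParams extend_ranks
#' @return a number in `[-1, 1]`.
#' @export
spearman_incomplete <- function(a, b) {
  ka <- pair_keys(a)
  kb <- pair_keys(b)
  if (length(ka) == 0L && length(kb) == 0L) stop("both lists are empty")
  e <- extend_ranks(ka, kb)
  if (stats::sd(e$ranks_a) == 0 || stats::sd(e$ranks_b) == 0)
    return(structure(0, undefined = TRUE))
  stats::cor(e$ranks_a, e$ranks_b)
}

#' Stability curve: rho between top-k prefixes
#'
#' Evaluates [spearman_incomplete()] between the top-k prefixes of two
#' lists for each k in `grid`. The default grid is every k from 2 to 200
#' and then geometric steps (factor 1.1) up to the shorter list length;
#' k = 1 is excluded because two identical singleton prefixes give a
#' constant rank vector (rho undefined by convention).
#'
#' @inheritParams extend_ranks
#' @param grid increasing integer vector of prefix sizes.
#' @return a `rho_curve`: data frame with columns `k` and `rho`.
#' @export
rho_curve <- function(a, b, grid = NULL) {
  ka <- pair_keys(a)
  kb <- pair_keys(b)
  k_max <- min(length(ka), length(kb))
  if (is.null(grid)) grid <- default_k_grid(k_max)
  grid <- as.integer(grid[grid >= 1L & grid <= k_max])
  rho <- vapply(grid, function(k)
    as.numeric(spearman_incomplete(ka[seq_len(k)], kb[seq_len(k)])),
    numeric(1))
  structure(data.frame(k = grid, rho = rho),
            k_max = k_max, class = c("rho_curve", "data.frame"))
}

default_k_grid <- function(k_max) {
  lin <- seq.int(2L, min(200L, k_max))
  if (k_max <= 200L) return(lin)
  geo <- unique(as.integer(floor(200 * 1.1^seq_len(ceiling(
    log(k_max / 200) / log(1.1))))))
  c(lin, pmin(geo, k_max))
}

#' Zero Index Crossing
#'
#' The smallest prefix size `k >= tau` at which the incomplete-list
#' Spearman rho between the two top-k prefixes is `<= 0`. Negative
#' correlations are the expected baseline when two lists select pairs at
#' random from a large universe, so the crossing marks the end of the
#' stable head of the lists. The search walks the exact per-k rho sequence
#' (not a display grid). If no crossing occurs by `k_max` the result is
#' censored at `k_max`.
#'
#' @inheritParams extend_ranks
#' @param tau minimum prefix size considered (the first few ranks are too
#'   noisy to define a crossing; default 100).
#' @param k_max largest prefix examined; defaults to the shorter list.
#' @return a `zic_result`: list with `zic`, `censored`, `tau`, `k_max`.
#' @export
zic <- function(a, b, tau = 100L, k_max = NULL) {
  ka <- pair_keys(a)
  kb <- pair_keys(b)
  tau <- as.integer(tau)
  if (tau < 1L) stop("tau must be >= 1")
  lim <- min(length(ka), length(kb))
  if (is.null(k_max)) k_max <- lim
  k_max <- min(as.integer(k_max), lim)
  if (k_max < tau) stop("k_max is smaller than tau")
  # positions of every potential union element in each full list, computed
  # once; per-k extension is then a vectorised update over the union
  un <- union(ka[seq_len(k_max)], kb[seq_len(k_max)])
  pa <- match(un, ka)
  pb <- match(un, kb)
  for (k in seq.int(tau, k_max)) {
    ina <- !is.na(pa) & pa <= k
    inb <- !is.na(pb) & pb <= k
    inu <- ina | inb
    m <- sum(inu)
    ra <- ifelse(ina[inu], pa[inu], (k + 1 + m) / 2)
    rb <- ifelse(inb[inu], pb[inu], (k + 1 + m) / 2)
    if (stats::sd(ra) == 0 || stats::sd(rb) == 0) r <- 0
    else r <- stats::cor(ra, rb)
    if (!is.na(r) && r <= 0)
      return(structure(list(zic = k, censored = FALSE, tau = tau,
                            k_max = k_max), class = "zic_result"))
  }
  structure(list(zic = k_max, censored = TRUE, tau = tau, k_max = k_max),
            class = "zic_result")
}

#' @export
print.zic_result <- function(x, ...) {
  cat(sprintf("ZIC = %d%s (tau = %d, k_max = %d)\n", x$zic,
              if (x$censored) " [censored]" else "", x$tau, x$k_max))
  invisible(x)
}

#' Jaccard index of two top-k sets
#'
#' `|A_k intersect B_k| / |A_k union B_k|` for the top-k prefixes.
#'
#' @inheritParams extend_ranks
#' @param k prefix size.
#' @return a number in `[0, 1]`.
#' @export
jaccard_topk <- function(a, b, k) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  sa <- utils::head(pair_keys(a), k)
  sb <- utils::head(pair_keys(b), k)
  length(intersect(sa, sb)) / length(union(sa, sb))
}

#' Overlap fractions of two top-k sets
#'
#' Sizes of "only in A", "in both" and "only in B", each scaled by the
#' union size so the three fractions sum to 1. This is the decomposition
#' plotted when comparing the pair sets selected by two statistics.
#'
#' @inheritParams jaccard_topk
#' @return named numeric vector `c(only_a, both, only_b)`.
#' @export
overlap_fractions <- function(a, b, k) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  sa <- utils::head(pair_keys(a), k)
  sb <- utils::head(pair_keys(b), k)
  u <- length(union(sa, sb))
  both <- length(intersect(sa, sb))
  c(only_a = (length(sa) - both) / u, both = both / u,
    only_b = (length(sb) - both) / u)
}
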
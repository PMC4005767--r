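#' Sample prevalence mapping of a contingency table
#'
#' For each genotype column `v`, the prevalence is the fraction of carriers
#' of that genotype (combination) who are cases:
#' `phi_v = cases_v / (cases_v + controls_v)`. Empty columns get `phi = 0`.
#'
#' @param tab a `single_table` or `pair_table` (any 2-row count matrix,
#'   rows control then case).
#' @return numeric vector of per-genotype prevalences.
#' @export
prevalence_map <- function(tab) {
  m <- unclass(tab)
  tot <- colSums(m)
  phi <- ifelse(tot > 0, m[2L, ] / tot, 0)
  names(phi) <- colnames(m)
  phi
}

#' ROC curve of a contingency table under the prevalence ordering
#'
#' Orders genotype columns by descending prevalence (ties broken by
#' ascending control count, then column index; all-empty columns are
#' dropped as they contribute no step) and takes cumulative sums. The
#' vertex after the first `t` genotypes is
#' `(FP_t / n_controls, TP_t / n_cases)`, giving a monotone step curve from
#' (0,0) to (1,1).
#'
#' @param tab 2-row count matrix, both row sums positive.
#' @return a `roc_curve`: list with `points` (vertices, columns fpr/tpr),
#'   `cum_counts` (cumulative control/case counts per vertex), `n_controls`,
#'   `n_cases`.
#' @export
roc_from_table <- function(tab) {
  m <- unclass(tab)
  n0 <- sum(m[1L, ])
  n1 <- sum(m[2L, ])
  if (n0 == 0 || n1 == 0) stop("both classes must be non-empty")
  tot <- colSums(m)
  keep <- which(tot > 0)
  phi <- m[2L, keep] / tot[keep]
  ord <- keep[order(-phi, m[1L, keep], keep)]
  cum0 <- c(0, cumsum(m[1L, ord]))
  cum1 <- c(0, cumsum(m[2L, ord]))
  new_roc_curve(cbind(fpr = cum0 / n0, tpr = cum1 / n1),
                cbind(controls = cum0, cases = cum1), n0, n1)
}

new_roc_curve <- function(points, cum_counts, n_controls, n_cases) {
  structure(list(points = points, cum_counts = cum_counts,
                 n_controls = n_controls, n_cases = n_cases),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d vertices, %d controls / %d cases\n",
              nrow(x$points), x$n_controls, x$n_cases))
  invisible(x)
}

#' Upper convex hull of the union of two ROC curves
#'
#' Returns the concave majorant (in ROC space) of all vertices of both
#' curves plus the corners (0,0) and (1,1). This hull is the GSS null: the
#' best segregation achievable by randomising over thresholds of the two
#' univariate prevalence classifiers.
#'
#' @param r1,r2 `roc_curve` objects sharing `n_cases` / `n_controls`.
#' @return a `roc_curve` whose vertices are the hull vertices in order of
#'   increasing fpr (no cumulative counts).
#' @export
hull_union <- function(r1, r2) {
  if (r1$n_cases != r2$n_cases || r1$n_controls != r2$n_controls)
    stop("curves must share the same case/control totals")
  pts <- rbind(r1$points, r2$points, c(0, 0), c(1, 1))
  h <- upper_hull(pts)
  if (h[1L, 2L] > 0) h <- rbind(c(0, 0), h)  # keep the (0,0) anchor
  new_roc_curve(h, NULL, r1$n_controls, r1$n_cases)
}

# Andrew's monotone chain, upper hull only. Input: 2-column matrix.
upper_hull <- function(pts) {
  colnames(pts) <- c("fpr", "tpr")
  # one point per x: keep the highest, then sort by x
  o <- order(pts[, 1L], -pts[, 2L])
  pts <- pts[o, , drop = FALSE]
  pts <- pts[!duplicated(pts[, 1L]), , drop = FALSE]
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  stack <- integer(n)
  top <- 0L
  for (p in seq_len(n)) {
    while (top >= 2L) {
      o1 <- pts[stack[top - 1L], ]
      o2 <- pts[stack[top], ]
      cr <- (o2[1L] - o1[1L]) * (pts[p, 2L] - o1[2L]) -
            (o2[2L] - o1[2L]) * (pts[p, 1L] - o1[1L])
      if (cr >= 0) top <- top - 1L else break  # pop non-right turns
    }
    top <- top + 1L
    stack[top] <- p
  }
  pts[stack[seq_len(top)], , drop = FALSE]
}

# tpr of the hull at given fpr values (linear interpolation between
# vertices; hull x is strictly increasing apart from a possible (0,0) anchor)
hull_height <- function(hull, fpr) {
  p <- hull$points
  if (nrow(p) >= 2L && p[1L, 1L] == p[2L, 1L]) p <- p[-1L, , drop = FALSE]
  if (nrow(p) == 1L) return(rep(p[1L, 2L], length(fpr)))
  stats::approx(p[, 1L], p[, 2L], xout = fpr, rule = 2L)$y
}

#' Gain in Sensitivity and Specificity (GSS) test
#'
#' Tests whether the ROC curve of a SNP pair rises significantly above the
#' convex hull of the two single-SNP ROC curves (the univariate null). For
#' each pair-curve vertex `t` with cumulative counts `(FP_t, TP_t)`, the
#' probability that sampling from any null operating point `(u, v)` on the
#' hull reaches at least that sensitivity at no more than that
#' false-positive count is
#' `p_t = max_{(u,v) in H} Pr[Bin(n_cases, v) >= TP_t] *
#'   Pr[Bin(n_controls, u) <= FP_t]`,
#' a min-max of two binomial tails: the reported p-value is the minimum of
#' `p_t` over vertices strictly above the hull (vertices on or below it
#' contribute `p_t = 1`). Binomial tails are evaluated in log space. The
#' inner maximum is located on a grid of `edge_points` evenly spaced points
#' per hull edge plus the hull vertices, then sharpened by a local
#' continuous search around the grid optimum.
#'
#' The score of the result is `-log10(p)`, which is the ranking key used by
#' pair scans.
#'
#' @param tab a `pair_table` (2x9 count matrix).
#' @param edge_points number of interior evaluation points per hull edge.
#' @param refine logical; refine the inner maximum continuously.
#' @return a `pair_stat_result` with `statistic = -log10(p_value)` and
#'   `df = NA`.
#' @export
gss_test <- function(tab, edge_points = 64L, refine = TRUE) {
  m <- unclass(tab)
  n0 <- sum(m[1L, ])
  n1 <- sum(m[2L, ])
  if (n0 == 0 || n1 == 0) return(new_stat_result(0, log_p = 0, df = NA_integer_))
  s1 <- pair_margin_counts(m, 1L)
  s2 <- pair_margin_counts(m, 2L)
  hull <- hull_union(roc_from_table(s1), roc_from_table(s2))
  rp <- roc_from_table(m)

  hp <- hull$points
  if (nrow(hp) >= 2L && hp[1L, 1L] == hp[2L, 1L]) hp <- hp[-1L, , drop = FALSE]
  grid <- hull_grid(hp, edge_points)
  base <- hull_height(hull, rp$points[, 1L])

  # coarse pass: grid maximum for every pair-curve vertex above the hull
  nv <- nrow(rp$points)
  above <- which(rp$points[, 2L] > base + 1e-12)  # others contribute p_t = 1
  coarse <- rep(Inf, nv)
  arg <- integer(nv)
  for (t in above) {
    lp <- log_binom_ge(rp$cum_counts[t, 2L], n1, grid$v) +
      log_binom_le(rp$cum_counts[t, 1L], n0, grid$u)
    arg[t] <- which.max(lp)
    coarse[t] <- lp[arg[t]]
  }
  best_log <- if (length(above)) min(coarse) else 0
  if (refine && length(above)) {
    # the continuous max can exceed the grid value by at most a small
    # amount, so only vertices near the coarse minimum can own the final
    # minimum; 2 log units is a generous bound on the grid placement error
    cand <- above[coarse[above] <= min(coarse) + 2]
    best_log <- min(vapply(cand, function(t)
      max(coarse[t], refine_edge(hp, grid, arg[t], rp$cum_counts[t, 2L], n1,
                                 rp$cum_counts[t, 1L], n0)),
      numeric(1)))
  }
  if (!is.finite(best_log) || best_log > 0) best_log <- 0
  new_stat_result(statistic = -best_log / log(10), log_p = best_log,
                  df = NA_integer_)
}

# 2x3 margin counts of a 2x9 pair table (which = 1 keeps g1, 2 keeps g2)
pair_margin_counts <- function(m, which) {
  v <- 0:8
  g <- if (which == 1L) v %/% 3L else v %% 3L
  vapply(0:2, function(k) rowSums(m[, g == k, drop = FALSE]), numeric(2L))
}

# evaluation points along the hull polyline: vertices plus edge_points
# interior points per edge; records the edge and position for refinement
hull_grid <- function(hp, edge_points) {
  ne <- nrow(hp) - 1L
  if (ne < 1L)
    return(list(u = hp[, 1L], v = hp[, 2L], edge = 1L, lambda = 0))
  li <- seq(0, 1, length.out = edge_points + 2L)[-1L]  # (0,1] incl. endpoint
  lambda <- c(0, rep(li, ne))
  edge <- c(1L, rep(seq_len(ne), each = length(li)))
  u <- hp[edge, 1L] + lambda * (hp[edge + 1L, 1L] - hp[edge, 1L])
  v <- hp[edge, 2L] + lambda * (hp[edge + 1L, 2L] - hp[edge, 2L])
  list(u = u, v = v, edge = edge, lambda = lambda)
}

# continuous max over the hull arc neighbouring the grid argmax
refine_edge <- function(hp, grid, i, tp, n1, fp, n0) {
  e <- grid$edge[i]
  h <- 1 / (sum(grid$edge == e) - 1L + 1e-9)  # grid spacing on this edge
  lo <- max(0, grid$lambda[i] - h)
  hi <- min(1, grid$lambda[i] + h)
  if (hi <= lo) return(-Inf)
  f <- function(l) {
    u <- hp[e, 1L] + l * (hp[e + 1L, 1L] - hp[e, 1L])
    v <- hp[e, 2L] + l * (hp[e + 1L, 2L] - hp[e, 2L])
    log_binom_ge(tp, n1, v) + log_binom_le(fp, n0, u)
  }
  stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)$objective
}

# log Pr[Bin(n, p) >= k] and log Pr[Bin(n, p) <= k], vectorised over p.
# At extreme tails pbeta's log series can underflow to -Inf with a warning;
# -Inf is the correct limit here (the point simply loses the inner max),
# so the warning is suppressed.
log_binom_ge <- function(k, n, p) {
  if (k <= 0) return(rep(0, length(p)))
  suppressWarnings(
    stats::pbinom(k - 1, size = n, prob = p, lower.tail = FALSE, log.p = TRUE))
}

log_binom_le <- function(k, n, p) {
  if (k >= n) return(rep(0, length(p)))
  suppressWarnings(stats::pbinom(k, size = n, prob = p, log.p = TRUE))
}
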
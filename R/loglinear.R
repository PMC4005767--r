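#' Fit the homogeneous-association log-linear model
#'
#' Fits the model `[X1X2][X1Y][X2Y]` — all two-way margins, no three-way
#' interaction — to a 3x3x2 genotype-by-genotype-by-phenotype table by
#' iterative proportional fitting (IPF). This is the "main effects"
#' alternative of the BOOST likelihood-ratio test: it captures both SNPs'
#' marginal association with phenotype (and their mutual dependence) while
#' excluding any genuinely bivariate effect.
#'
#' IPF cycles over the three margins until the largest absolute margin
#' discrepancy falls below `tol` or `max_iter` cycles are reached. Zero
#' observed margins propagate zero fitted cells, which is the maximum
#' likelihood solution for those cells.
#'
#' @param tab a `pair_table` (2x9) or a 3x3x2 array (g1, g2, phenotype).
#' @param tol convergence tolerance on the margin discrepancy (counts).
#' @param max_iter maximum number of IPF cycles.
#' @return a `loglinear_fit`: list with `fitted` (3x3x2 expected counts),
#'   `loglik` (sum of `n * log(mu / N)`), `iterations`, `converged` and
#'   `max_discrepancy`.
#' @export
fit_main_effects <- function(tab, tol = 1e-8, max_iter = 200L) {
  n <- as_array3(tab)
  N <- sum(n)
  if (N <= 0) stop("empty table")
  n1 <- n[, , 1L]
  n2 <- n[, , 2L]
  m12 <- n1 + n2
  m13 <- cbind(rowSums(n1), rowSums(n2))
  m23 <- cbind(colSums(n1), colSums(n2))
  mu <- array(N / 18, dim = c(3L, 3L, 2L))
  it <- 0L
  disc <- Inf
  while (it < max_iter) {
    it <- it + 1L
    r12 <- ratio0(m12, mu[, , 1L] + mu[, , 2L])
    mu <- mu * as.vector(r12)  # recycles over the two phenotype slices
    r13 <- ratio0(m13, cbind(rowSums(mu[, , 1L]), rowSums(mu[, , 2L])))
    for (k in 1:2) mu[, , k] <- mu[, , k] * r13[, k]  # recycles down rows
    r23 <- ratio0(m23, cbind(colSums(mu[, , 1L]), colSums(mu[, , 2L])))
    for (k in 1:2) mu[, , k] <- mu[, , k] * rep(r23[, k], each = 3L)
    disc <- max(abs(mu[, , 1L] + mu[, , 2L] - m12),
                abs(cbind(rowSums(mu[, , 1L]), rowSums(mu[, , 2L])) - m13),
                abs(cbind(colSums(mu[, , 1L]), colSums(mu[, , 2L])) - m23))
    if (disc < tol) break
  }
  pos <- n > 0
  ll <- sum(n[pos] * log(pmax(mu[pos], .Machine$double.xmin) / N))
  structure(list(fitted = mu, loglik = ll, iterations = it,
                 converged = disc < tol, max_discrepancy = disc),
            class = "loglinear_fit")
}

ratio0 <- function(target, current) {
  r <- target / current
  r[current <= 0] <- 0
  r
}

#' BOOST-style likelihood-ratio interaction test
#'
#' Likelihood-ratio test of the saturated model against the
#' homogeneous-association log-linear model `[X1X2][X1Y][X2Y]` on the 3x3x2
#' table of a SNP pair: `LRT = 2 * sum n * log(n / mu)` with `mu` from
#' [fit_main_effects()] and the convention `0 * log 0 = 0`. The statistic is
#' clamped at zero and referred to a chi-squared distribution with
#' `df = (3-1)(3-1)(2-1) = 4`. This is the log-linear formulation of
#' comparing logistic "full" and "main effects" models, which are
#' equivalent.
#'
#' A non-converged fit is not an error: the achieved statistic is returned
#' with `converged = FALSE` so the pair can still be ranked, and the caller
#' may log it.
#'
#' @inheritParams fit_main_effects
#' @return a `pair_stat_result` with `df = 4`.
#' @export
boost_lrt <- function(tab, tol = 1e-8, max_iter = 200L) {
  n <- as_array3(tab)
  rs <- apply(n, 3L, sum)
  if (any(rs == 0)) stop("degenerate table: one phenotype class is empty")
  fit <- fit_main_effects(n, tol = tol, max_iter = max_iter)
  pos <- n > 0
  lrt <- 2 * sum(n[pos] * log(n[pos] / pmax(fit$fitted[pos],
                                            .Machine$double.xmin)))
  lrt <- max(lrt, 0)
  log_p <- stats::pchisq(lrt, df = 4L, lower.tail = FALSE, log.p = TRUE)
  new_stat_result(statistic = lrt, log_p = log_p, df = 4L,
                  converged = fit$converged)
}

#' Kirkwood superposition screening statistic
#'
#' Stage-1 screening value of the two-stage BOOST procedure. The Kirkwood
#' superposition approximation to the homogeneous-association fit is
#' `mu_KSA(g1, g2, y) = N * p(g1,g2) p(g1,y) p(g2,y) / (p(g1) p(g2) p(y))`,
#' rescaled to sum to the grand total; the screening value is
#' `2 * sum n * log(n / mu_KSA)`. It upper-bounds the exact LRT on
#' all-positive tables, so pairs whose screening value falls below a
#' threshold can skip the exact iterative fit.
#'
#' @inheritParams fit_main_effects
#' @return the screening statistic (a single number).
#' @export
ksa_screen <- function(tab) {
  n <- as_array3(tab)
  N <- sum(n)
  if (N <= 0) stop("empty table")
  p12 <- apply(n, c(1L, 2L), sum) / N
  p13 <- apply(n, c(1L, 3L), sum) / N
  p23 <- apply(n, c(2L, 3L), sum) / N
  p1 <- apply(n, 1L, sum) / N
  p2 <- apply(n, 2L, sum) / N
  py <- apply(n, 3L, sum) / N
  mu <- array(0, dim = c(3L, 3L, 2L))
  for (a in 1:3) for (b in 1:3) for (k in 1:2) {
    den <- p1[a] * p2[b] * py[k]
    if (den > 0) mu[a, b, k] <- N * p12[a, b] * p13[a, k] * p23[b, k] / den
  }
  s <- sum(mu)
  if (s > 0) mu <- mu * (N / s)
  pos <- n > 0
  2 * sum(n[pos] * log(n[pos] / pmax(mu[pos], .Machine$double.xmin)))
}
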
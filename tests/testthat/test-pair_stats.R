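# Per-table association statistics: chi-squared, log-linear LRT, GSS

test_that("chi-squared statistic, df and p-value match direct evaluation", {
  tab <- matrix(c(10, 30, 20, 20, 30, 10), 2, 3)  # all expected counts 20
  r <- chi2_test(tab)
  expect_equal(r$statistic, 20)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, exp(-10))  # Q(1, x) = e^-x closed form
  # identical rows: O = E
  r0 <- chi2_test(matrix(c(5, 5, 7, 7, 3, 3), 2, 3))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # bivariate df is fixed at 8 whatever the zero pattern
  expect_equal(chi2_test(random_pair_table())$df, 8)
  set.seed(2)
  expect_equal(chi2_test(random_pair_table(lambda = 2))$df, 8)
  expect_error(chi2_test(matrix(c(0, 1, 0, 2, 0, 3), 2, 3)), "degenerate")
})

test_that("IPF fit reproduces tables that already satisfy the model", {
  # product of pairwise factors has no three-way interaction
  set.seed(3)
  a <- runif(3, 0.5, 2); b <- runif(3, 0.5, 2); cc <- runif(2, 0.5, 2)
  d <- matrix(runif(6, 0.5, 2), 3, 2); e <- matrix(runif(6, 0.5, 2), 3, 2)
  n <- array(0, c(3, 3, 2))
  for (i in 1:3) for (j in 1:3) for (k in 1:2)
    n[i, j, k] <- 20 * a[i] * b[j] * cc[k] * d[i, k] * e[j, k]
  fit <- fit_main_effects(n)
  expect_true(fit$converged)
  expect_equal(fit$fitted, n, tolerance = 1e-7)
  expect_lt(boost_lrt(n)$statistic, 1e-6)
  # uniform table satisfies the model trivially
  u <- array(4, c(3, 3, 2))
  expect_equal(fit_main_effects(u)$fitted, u, tolerance = 1e-10)
})

test_that("IPF matches all three observed two-way margins on random tables", {
  set.seed(4)
  for (rep in 1:200) {
    n <- array(rpois(18, 8), c(3, 3, 2))
    if (sum(n) == 0) next
    fit <- fit_main_effects(n)
    mu <- fit$fitted
    expect_equal(mu[, , 1] + mu[, , 2], n[, , 1] + n[, , 2], tolerance = 1e-6)
    expect_equal(cbind(rowSums(mu[, , 1]), rowSums(mu[, , 2])),
                 cbind(rowSums(n[, , 1]), rowSums(n[, , 2])),
                 tolerance = 1e-6)
    expect_equal(cbind(colSums(mu[, , 1]), colSums(mu[, , 2])),
                 cbind(colSums(n[, , 1]), colSums(n[, , 2])),
                 tolerance = 1e-6)
    expect_true(all(mu >= 0))
  }
})

test_that("likelihood-ratio test agrees with an independent IPF oracle", {
  set.seed(6)
  for (rep in 1:150) {
    n <- array(rpois(18, 15) + 1, c(3, 3, 2))
    mine <- boost_lrt(n)
    capture.output(ref <- stats::loglin(n, list(c(1, 2), c(1, 3), c(2, 3)),
                                        fit = TRUE, iter = 60, eps = 1e-10))
    expect_equal(mine$statistic, ref$lrt, tolerance = 1e-6)
    expect_equal(mine$df, 4)
  }
})

test_that("Kirkwood screening value bounds the exact statistic from above", {
  set.seed(8)
  # exact independence: KSA reproduces the factorised table, value ~ 0
  p1 <- c(.2, .5, .3); p2 <- c(.4, .4, .2); py <- c(.6, .4)
  ind <- outer(outer(p1, p2), py) * 1000
  expect_lt(abs(ksa_screen(ind)), 1e-8)
  for (rep in 1:500) {
    n <- array(rpois(18, 10) + 1, c(3, 3, 2))
    expect_gte(ksa_screen(n), boost_lrt(n)$statistic - 1e-9)
  }
})

test_that("disabling the screening threshold reproduces the exact ranking", {
  set.seed(9)
  fx <- random_fixture(n = 60, m = 8, miss = 0)
  plain <- exhaustive_scan(fx$x, fx$phen, "boost", k = 28)
  screened <- exhaustive_scan(fx$x, fx$phen, "boost", k = 28,
                              screen_threshold = -Inf)
  expect_identical(as.data.frame(plain), as.data.frame(screened))
})

test_that("prevalence mapping follows the case fraction per genotype", {
  tab <- matrix(c(1, 3, 4, 0, 0, 0), 2, 3)  # (ctrl,case) per column
  phi <- prevalence_map(tab)
  expect_equal(unname(phi), c(0.75, 0, 0))  # 3/4 cases; all-control; empty
  expect_equal(length(prevalence_map(random_pair_table())), 9L)
})

test_that("ROC construction follows descending prevalence with cumulative sums", {
  # toy: controls (4,2,0), cases (0,2,4); prevalence order g2, g1, g0
  tab <- matrix(c(4, 0, 2, 2, 0, 4), 2, 3)
  rc <- roc_from_table(tab)
  expect_equal(rc$points,
               cbind(fpr = c(0, 0, 1 / 3, 1), tpr = c(0, 2 / 3, 1, 1)),
               ignore_attr = TRUE)
  # single occupied genotype: two endpoints only
  one <- roc_from_table(matrix(c(5, 3, 0, 0, 0, 0), 2, 3))
  expect_equal(nrow(one$points), 2L)
  expect_equal(one$points[2, ], c(fpr = 1, tpr = 1))
  # perfect separator passes through (0, 1)
  sep <- roc_from_table(matrix(c(0, 6, 4, 0, 3, 0), 2, 3))
  expect_true(any(sep$points[, 1] == 0 & sep$points[, 2] == 1))
})

test_that("hull union is idempotent and dominates both inputs", {
  set.seed(10)
  for (rep in 1:50) {
    t1 <- random_pair_table(lambda = 6)
    r1 <- roc_from_table(marginalise_pair_table(t1, 1))
    r2 <- roc_from_table(marginalise_pair_table(t1, 2))
    h <- hull_union(r1, r2)
    hh <- hull_union(h, h)
    expect_equal(hh$points, h$points)
    for (r in list(r1, r2)) {
      ht <- stats::approx(h$points[, 1], h$points[, 2], xout = r$points[, 1],
                          rule = 2, ties = max)$y
      expect_true(all(ht >= r$points[, 2] - 1e-12))
    }
    # concavity: slopes non-increasing
    d <- diff(h$points[, 2]) / pmax(diff(h$points[, 1]), 1e-12)
    expect_true(all(diff(d) <= 1e-9))
  }
  # hand case: both interior points survive on the hull
  ra <- new_roc_curve(rbind(c(0, 0), c(0.2, 0.4), c(1, 1)), NULL, 10, 10)
  rb <- new_roc_curve(rbind(c(0, 0), c(0.5, 0.9), c(1, 1)), NULL, 10, 10)
  h <- hull_union(ra, rb)
  expect_equal(h$points,
               rbind(c(0, 0), c(0.2, 0.4), c(0.5, 0.9), c(1, 1)),
               ignore_attr = TRUE)
})

test_that("GSS returns no gain when the pair adds nothing over one SNP", {
  # second SNP constant: pair curve coincides with SNP1's curve
  pt <- matrix(0, 2, 9)
  pt[1, c(1, 4, 7)] <- c(15, 9, 6)
  pt[2, c(1, 4, 7)] <- c(3, 12, 15)
  expect_equal(gss_test(pt)$p_value, 1)
  expect_equal(gss_test(pt)$statistic, 0)
})

test_that("GSS p-values are probabilities and match the dense-grid oracle", {
  set.seed(12)
  for (rep in 1:300) {
    p <- gss_test(random_pair_table(lambda = 4))$p_value
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
  # XOR-structured toy: cases on odd-sum combinations, flat margins
  xt <- matrix(0, 2, 9)
  xt[2, c(2, 4, 6, 8)] <- 25
  xt[1, c(1, 3, 5, 7, 9)] <- 20
  p <- gss_test(xt)$p_value
  expect_equal(p, gss_dense_oracle(xt), tolerance = 1e-3)
})

test_that("log-space evaluation keeps extreme p-values finite and ranked", {
  # million-sample table with a strong pure interaction
  big <- matrix(0, 2, 9)
  big[1, ] <- c(9, 1, 9, 1, 9, 1, 9, 1, 9) * 6e4
  big[2, ] <- c(1, 9, 1, 9, 1, 9, 1, 9, 1) * 6e4
  for (r in list(chi2_test(big), boost_lrt(big), gss_test(big))) {
    expect_true(is.finite(r$log_p))
    expect_lt(r$log_p, -100)
    expect_gt(r$p_value, 0)
  }
})
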
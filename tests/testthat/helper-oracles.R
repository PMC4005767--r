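# Shared fixtures and independent oracles, built in code at test time.

# random 2x9 pair table; min1 = TRUE forces all cells >= 1
random_pair_table <- function(lambda = 10, min1 = FALSE) {
  repeat {
    tab <- matrix(stats::rpois(18L, lambda) + if (min1) 1L else 0L, 2L, 9L)
    if (all(rowSums(tab) > 0)) break
  }
  structure(tab, class = c("pair_table", class(matrix())))
}

# random genotype fixture with optional missingness
random_fixture <- function(n = 30L, m = 4L, miss = 0.1) {
  g <- matrix(sample(c(0:2, NA_integer_), n * m, replace = TRUE,
                     prob = c(rep((1 - miss) / 3, 3), miss)), n, m)
  y <- c(0L, 1L, sample(0:1, n - 2L, replace = TRUE))  # both classes present
  list(x = genotype_matrix(g), phen = phenotype(y))
}

# naive all-pairs oracle for exhaustive_scan: score every pair directly
# through the per-table statistics and sort
naive_scan <- function(x, phen, statistic, k) {
  M <- ncol(x)
  rows <- list()
  for (i in seq_len(M - 1L)) for (j in seq.int(i + 1L, M)) {
    tab <- build_pair_table(x, phen, i, j)
    r <- switch(statistic, chi2 = chi2_test(tab), boost = boost_lrt(tab),
                gss = gss_test(tab))
    rows[[length(rows) + 1L]] <- data.frame(
      i = i, j = j, snp_id_1 = colnames(x)[i], snp_id_2 = colnames(x)[j],
      score = r$statistic, p_value = r$p_value, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df <- df[order(-df$score, df$i, df$j), ]
  utils::head(df[, c("snp_id_1", "snp_id_2", "score", "p_value")], k)
}

# dense-grid min-max oracle for the GSS p-value: discretises the whole
# null hull polyline by arc length and scans every pair-curve vertex
gss_dense_oracle <- function(tab, npts = 2000L) {
  m <- unclass(tab)
  n0 <- sum(m[1L, ])
  n1 <- sum(m[2L, ])
  marg <- function(w) {
    v <- 0:8
    gg <- if (w == 1L) v %/% 3L else v %% 3L
    vapply(0:2, function(kk) rowSums(m[, gg == kk, drop = FALSE]), numeric(2L))
  }
  H <- hull_union(roc_from_table(marg(1L)), roc_from_table(marg(2L)))
  hp <- H$points
  if (nrow(hp) >= 2L && hp[1L, 1L] == hp[2L, 1L]) hp <- hp[-1L, , drop = FALSE]
  seg <- sqrt(diff(hp[, 1L])^2 + diff(hp[, 2L])^2)
  cum <- c(0, cumsum(seg))
  s <- seq(0, cum[length(cum)], length.out = npts)
  u <- stats::approx(cum, hp[, 1L], s)$y
  v <- stats::approx(cum, hp[, 2L], s)$y
  rp <- roc_from_table(m)
  base <- stats::approx(hp[, 1L], hp[, 2L], xout = rp$points[, 1L],
                        rule = 2L)$y
  best <- 0
  for (t in seq_len(nrow(rp$points))) {
    if (rp$points[t, 2L] <= base[t] + 1e-12) next
    fp <- rp$cum_counts[t, 1L]
    tp <- rp$cum_counts[t, 2L]
    lp <- (if (tp <= 0) 0 else
             stats::pbinom(tp - 1, n1, v, lower.tail = FALSE, log.p = TRUE)) +
      (if (fp >= n0) 0 else stats::pbinom(fp, n0, u, log.p = TRUE))
    best <- min(best, max(lp))
  }
  exp(best)
}

# ranked list from a key vector, scores strictly decreasing
list_from_keys <- function(keys) {
  parts <- strsplit(keys, "\t", fixed = TRUE)
  ranked_pair_list(data.frame(
    snp_id_1 = vapply(parts, `[`, "", 1L),
    snp_id_2 = vapply(parts, `[`, "", 2L),
    score = seq(length(keys), 1L), p_value = rep(0.5, length(keys)),
    stringsAsFactors = FALSE))
}

random_keys <- function(universe_size, k, prefix = "p") {
  paste0(prefix, sample.int(universe_size, k), "\ts")
}
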
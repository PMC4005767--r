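#' Simulation configuration for case-control genotype data
#'
#' Describes a synthetic GWAS cohort: biallelic SNPs in Hardy-Weinberg
#' equilibrium with minor-allele frequencies drawn uniformly from
#' `maf_range`, a logistic disease liability with baseline prevalence
#' `baseline_prevalence`, optional strong-main-effect "hub" SNPs
#' (per-allele odds ratios), and optional planted SNP pairs carrying
#' penetrance offsets on the log-odds scale (so that joint association can
#' exceed the marginals). Individuals are drawn and rejected until the
#' case and control quotas are met exactly.
#'
#' @param n_snps number of SNPs.
#' @param n_cases,n_controls class quotas.
#' @param maf_range MAF sampling range (default 0.05-0.5).
#' @param main_effects list of `list(snp =, or =)` entries: per-allele odds
#'   ratio `or` applied to the allele count of SNP `snp`.
#' @param pairs list of `list(snp_i =, snp_j =, preset =, theta =)` or
#'   `list(snp_i =, snp_j =, offsets = <3x3 matrix>)` entries; presets are
#'   expanded by [preset_penetrance()]. SNPs of an `xor` pair get MAF fixed
#'   at 0.5, which makes their case/control marginal genotype
#'   distributions identical by construction (pure epistasis).
#' @param baseline_prevalence disease probability of the all-reference,
#'   no-effect genotype (default 0.1).
#' @param missing_rate per-entry missing probability (default 0).
#' @param seed RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_snps, n_cases, n_controls,
                       maf_range = c(0.05, 0.5), main_effects = list(),
                       pairs = list(), baseline_prevalence = 0.1,
                       missing_rate = 0, seed = 1L) {
  stopifnot(n_snps >= 1L, n_cases >= 0L, n_controls >= 0L,
            length(maf_range) == 2L, maf_range[1L] > 0,
            maf_range[2L] <= 0.5, maf_range[1L] <= maf_range[2L],
            baseline_prevalence > 0, baseline_prevalence < 1,
            missing_rate >= 0, missing_rate < 1)
  for (me in main_effects) {
    stopifnot(!is.null(me$snp), !is.null(me$or), me$or > 0,
              me$snp >= 1L, me$snp <= n_snps)
  }
  pairs <- lapply(pairs, function(pr) {
    stopifnot(!is.null(pr$snp_i), !is.null(pr$snp_j),
              pr$snp_i != pr$snp_j,
              pr$snp_i >= 1L, pr$snp_i <= n_snps,
              pr$snp_j >= 1L, pr$snp_j <= n_snps)
    if (is.null(pr$offsets)) {
      stopifnot(!is.null(pr$preset), !is.null(pr$theta))
      pr$offsets <- preset_penetrance(pr$preset, pr$theta)
    } else {
      pr$offsets <- as.matrix(pr$offsets)
      stopifnot(all(dim(pr$offsets) == c(3L, 3L)))
      if (is.null(pr$preset)) pr$preset <- "custom"
    }
    pr
  })
  structure(list(n_snps = as.integer(n_snps), n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls), maf_range = maf_range,
                 main_effects = main_effects, pairs = pairs,
                 baseline_prevalence = baseline_prevalence,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Preset penetrance offset tables
#'
#' 3x3 matrices of log-odds offsets indexed by the genotypes of a planted
#' pair:
#' * `xor`: `log(theta)` on the four odd-sum cells (exactly one genotype
#'   equal to 1) and 0 elsewhere; with MAF 0.5 at both SNPs the marginal
#'   genotype distributions of cases and controls coincide, i.e. a pure
#'   interaction.
#' * `threshold`: `log(theta)` wherever both genotypes are >= 1.
#' * `multiplicative`: `g1 * g2 * log(theta)`.
#'
#' @param name one of `"xor"`, `"threshold"`, `"multiplicative"`.
#' @param theta effect size; `theta = 1` gives the null (all-zero offsets).
#' @return 3x3 numeric matrix of log-odds offsets.
#' @export
preset_penetrance <- function(name, theta) {
  stopifnot(is.numeric(theta), theta > 0)
  g <- 0:2
  switch(name,
    xor = outer(g, g, function(a, b) ifelse((a + b) %% 2 == 1, log(theta), 0)),
    threshold = outer(g, g, function(a, b)
      ifelse(a >= 1 & b >= 1, log(theta), 0)),
    multiplicative = outer(g, g, function(a, b) a * b * log(theta)),
    stop("unknown penetrance preset: ", name))
}

#' Simulate a case-control genotype data set
#'
#' Draws individuals with independent HWE genotypes per SNP, assigns
#' disease status from the logistic liability
#' `logit P(case) = logit(baseline) + sum_main g * log(OR) + sum_pairs
#' offsets[g_i, g_j]`, and accumulates accepted individuals until the case
#' and control quotas are filled exactly. Entries are then masked missing
#' at `missing_rate`. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @param max_draws attempt budget (default 500x the cohort size); if the
#'   quotas cannot be reached within it, an error is raised.
#' @return list with `genotypes` ([genotype_matrix]), `phenotype`
#'   ([phenotype]) and `truth` (planted effects, realised MAFs and counts).
#' @export
simulate_gwas <- function(config, max_draws = NULL) {
  stopifnot(inherits(config, "sim_config"))
  M <- config$n_snps
  n_total <- config$n_cases + config$n_controls
  if (n_total == 0L) stop("empty cohort requested")
  if (is.null(max_draws)) max_draws <- 500 * n_total
  set.seed(config$seed)

  maf <- stats::runif(M, config$maf_range[1L], config$maf_range[2L])
  for (pr in config$pairs)
    if (identical(pr$preset, "xor"))
      maf[c(pr$snp_i, pr$snp_j)] <- 0.5  # exact marginal flatness

  base_logit <- stats::qlogis(config$baseline_prevalence)
  need_case <- config$n_cases
  need_ctrl <- config$n_controls
  acc_g <- vector("list", 64L)
  acc_y <- vector("list", 64L)
  n_chunks <- 0L
  drawn <- 0L
  chunk <- max(1024L, min(8192L, n_total))

  while (need_case > 0L || need_ctrl > 0L) {
    if (drawn >= max_draws)
      stop("simulation attempt budget exhausted before quotas were met")
    nb <- min(chunk, max_draws - drawn)
    drawn <- drawn + nb
    G <- matrix(stats::rbinom(nb * M, 2L, rep(maf, each = nb)), nb, M)
    eta <- rep(base_logit, nb)
    for (me in config$main_effects)
      eta <- eta + G[, me$snp] * log(me$or)
    for (pr in config$pairs)
      eta <- eta + pr$offsets[cbind(G[, pr$snp_i] + 1L, G[, pr$snp_j] + 1L)]
    ycand <- stats::rbinom(nb, 1L, stats::plogis(eta))
    take_case <- which(ycand == 1L)[seq_len(min(need_case, sum(ycand == 1L)))]
    take_ctrl <- which(ycand == 0L)[seq_len(min(need_ctrl, sum(ycand == 0L)))]
    take <- sort(c(take_case, take_ctrl))
    if (length(take)) {
      n_chunks <- n_chunks + 1L
      if (n_chunks > length(acc_g)) {
        length(acc_g) <- 2L * n_chunks
        length(acc_y) <- 2L * n_chunks
      }
      acc_g[[n_chunks]] <- G[take, , drop = FALSE]
      acc_y[[n_chunks]] <- ycand[take]
      need_case <- need_case - length(take_case)
      need_ctrl <- need_ctrl - length(take_ctrl)
    }
  }
  G <- do.call(rbind, acc_g[seq_len(n_chunks)])
  y <- unlist(acc_y[seq_len(n_chunks)])

  if (config$missing_rate > 0) {
    mask <- stats::runif(length(G)) < config$missing_rate
    G[mask] <- NA_integer_
  }
  ids <- sprintf("snp%04d", seq_len(M))
  sams <- sprintf("S%05d", seq_len(nrow(G)))
  truth <- list(maf = maf, main_effects = config$main_effects,
                pairs = config$pairs,
                n_cases = sum(y == 1L), n_controls = sum(y == 0L))
  list(genotypes = genotype_matrix(G, snp_ids = ids, sample_ids = sams),
       phenotype = phenotype(stats::setNames(y, sams)),
       truth = truth)
}
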
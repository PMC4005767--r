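#' Phenotype-by-genotype contingency tables
#'
#' `build_single_table()` tallies one SNP into a 2x3 table (rows: control,
#' case; columns: genotype 0, 1, 2). `build_pair_table()` tallies a SNP pair
#' into a 2x9 table whose column index is `v = 3*g_i + g_j` for genotypes
#' `(g_i, g_j)` of the pair `(i, j)` canonicalised so that `i < j`. Samples
#' with a missing genotype at any involved SNP are excluded from that table
#' (pairwise deletion), so the grand total of a pair table is the number of
#' samples non-missing at both SNPs.
#'
#' @param x a [genotype_matrix].
#' @param phen a [phenotype] of matching length.
#' @param snp,i,j SNP column index or SNP id.
#' @return an integer matrix of class `single_table` (2x3) or `pair_table`
#'   (2x9) with the involved SNP id(s) in attributes `snp` / `snp_i`,`snp_j`.
#' @export
build_single_table <- function(x, phen, snp) {
  check_geno_phen(x, phen)
  check_two_classes(phen)
  snp <- resolve_snp(x, snp)
  g <- unclass(x)[, snp]
  y <- as.integer(unclass(phen))
  ok <- !is.na(g)
  counts <- tabulate(2L * g[ok] + y[ok] + 1L, nbins = 6L)
  tab <- matrix(counts, nrow = 2L, ncol = 3L,
                dimnames = list(phenotype = c("control", "case"),
                                genotype = 0:2))
  structure(tab, class = c("single_table", class(matrix())),
            snp = colnames(x)[snp])
}

#' @rdname build_single_table
#' @export
build_pair_table <- function(x, phen, i, j) {
  check_geno_phen(x, phen)
  check_two_classes(phen)
  i <- resolve_snp(x, i)
  j <- resolve_snp(x, j)
  if (i == j) stop("i and j must be distinct SNPs")
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  g1 <- unclass(x)[, i]
  g2 <- unclass(x)[, j]
  y <- as.integer(unclass(phen))
  ok <- !is.na(g1) & !is.na(g2)
  v <- 3L * g1[ok] + g2[ok]
  counts <- tabulate(2L * v + y[ok] + 1L, nbins = 18L)
  tab <- matrix(counts, nrow = 2L, ncol = 9L,
                dimnames = list(phenotype = c("control", "case"),
                                genotype = paste0("v", 0:8)))
  structure(tab, class = c("pair_table", class(matrix())),
            snp_i = colnames(x)[i], snp_j = colnames(x)[j])
}

resolve_snp <- function(x, snp) {
  if (is.character(snp)) {
    idx <- match(snp, colnames(x))
    if (is.na(idx)) stop("unknown SNP id: ", snp)
    return(idx)
  }
  snp <- as.integer(snp)
  if (is.na(snp) || snp < 1L || snp > ncol(x))
    stop("SNP index out of range: ", snp)
  snp
}

#' Marginalise a pair table to one of its SNPs
#'
#' Summing the 2x9 pair table over the other SNP's genotype recovers the
#' 2x3 table of the kept SNP, restricted to samples non-missing at both.
#'
#' @param tab a `pair_table`.
#' @param which 1 to keep the first (lower-index) SNP, 2 the second.
#' @return a `single_table`.
#' @export
marginalise_pair_table <- function(tab, which = 1L) {
  stopifnot(inherits(tab, "pair_table"))
  m <- matrix(0L, 2L, 3L, dimnames = list(phenotype = c("control", "case"),
                                          genotype = 0:2))
  v <- 0:8
  g <- if (which == 1L) v %/% 3L else v %% 3L
  for (k in 0:2) m[, k + 1L] <- rowSums(unclass(tab)[, g == k, drop = FALSE])
  structure(m, class = c("single_table", class(matrix())),
            snp = if (which == 1L) attr(tab, "snp_i") else attr(tab, "snp_j"))
}

# Reshape a 2x9 pair table to the 3x3x2 array (g1, g2, phenotype) used by
# the log-linear machinery. Column v = 3*g1 + g2.
as_array3 <- function(tab) {
  if (is.array(tab) && length(dim(tab)) == 3L) {
    stopifnot(all(dim(tab) == c(3L, 3L, 2L)))
    return(tab)
  }
  stopifnot(nrow(tab) == 2L, ncol(tab) == 9L)
  aperm(array(as.numeric(unclass(tab)), dim = c(2L, 3L, 3L)), c(3L, 2L, 1L))
}
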
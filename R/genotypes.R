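#' Genotype matrix container
#'
#' A `genotype_matrix` is an integer matrix of samples (rows) by SNPs
#' (columns). Genotypes are coded as the count of the second (A2) allele:
#' 0, 1 or 2, with `NA` marking a missing call. Row names are sample ids,
#' column names SNP ids; both must be unique.
#'
#' @param genotypes integer matrix (samples x SNPs) with entries in
#'   `{0, 1, 2, NA}`.
#' @param snp_ids,sample_ids optional character vectors of unique ids;
#'   default to the dimnames of `genotypes` or generated `snp%04d` /
#'   `S%05d` labels.
#' @return an integer matrix of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, snp_ids = NULL, sample_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(snp_ids)) snp_ids <- colnames(genotypes)
  if (is.null(sample_ids)) sample_ids <- rownames(genotypes)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%04d", seq_len(ncol(genotypes)))
  if (is.null(sample_ids)) sample_ids <- sprintf("S%05d", seq_len(nrow(genotypes)))
  snp_ids <- as.character(snp_ids)
  sample_ids <- as.character(sample_ids)
  if (length(snp_ids) != ncol(genotypes))
    stop("length(snp_ids) must equal ncol(genotypes)")
  if (length(sample_ids) != nrow(genotypes))
    stop("length(sample_ids) must equal nrow(genotypes)")
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique")
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  bad <- !(genotypes %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad))
    stop("genotype codes must be 0, 1, 2 or NA; found: ",
         paste(unique(genotypes[bad]), collapse = ", "))
  dimnames(genotypes) <- list(sample_ids, snp_ids)
  class(genotypes) <- c("genotype_matrix", class(matrix()))
  genotypes
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Number of SNPs / samples in a genotype matrix
#' @param x a `genotype_matrix`.
#' @return integer count.
#' @export
n_snps <- function(x) ncol(x)

#' @rdname n_snps
#' @export
n_samples <- function(x) nrow(x)

#' @rdname n_snps
#' @export
snp_ids <- function(x) colnames(x)

#' @rdname n_snps
#' @export
sample_ids <- function(x) rownames(x)

#' Binary phenotype vector
#'
#' Encodes the case/control status of each sample: 0 = control, 1 = case.
#'
#' @param labels integer (or coercible) vector of 0/1 labels, optionally
#'   named by sample id.
#' @return integer vector of class `phenotype` with attributes `n_cases`
#'   and `n_controls`.
#' @export
phenotype <- function(labels) {
  nms <- names(labels)
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("phenotype labels must be 0 (control) or 1 (case)")
  names(labels) <- nms
  structure(labels, class = "phenotype",
            n_cases = sum(labels == 1L), n_controls = sum(labels == 0L))
}

#' @rdname phenotype
#' @param x a `phenotype`.
#' @export
n_cases <- function(x) sum(unclass(x) == 1L)

#' @rdname phenotype
#' @export
n_controls <- function(x) sum(unclass(x) == 0L)

#' @export
print.phenotype <- function(x, ...) {
  cat(sprintf("phenotype: %d cases, %d controls\n", n_cases(x), n_controls(x)))
  invisible(x)
}

# Both classes must be present before any statistic is computed.
check_two_classes <- function(phen) {
  if (n_cases(phen) == 0L || n_controls(phen) == 0L)
    stop("both phenotype classes (cases and controls) must be non-empty")
  invisible(TRUE)
}

check_geno_phen <- function(x, phen) {
  if (nrow(x) != length(phen))
    stop("genotype matrix and phenotype have different numbers of samples")
  invisible(TRUE)
}
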
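#' Read a PLINK 1 binary fileset
#'
#' Decodes a SNP-major `.bed` file (magic bytes `0x6C 0x1B 0x01`) together
#' with its `.bim` and `.fam` companions. Genotypes are coded as the number
#' of A2 alleles: bit pair `00` -> 0, `10` -> 1, `11` -> 2, `01` -> missing
#' (`NA`). Phenotype is taken from column 6 of the `.fam` file with the
#' PLINK convention 1 = control, 2 = case; samples with any other phenotype
#' code are dropped with a warning.
#'
#' @param prefix path prefix; `<prefix>.bed/.bim/.fam` are read. Ignored if
#'   the three explicit paths are given.
#' @param bed,bim,fam explicit file paths (all three or none).
#' @return a list with elements `genotypes` (a [genotype_matrix]) and
#'   `phenotype` (a [phenotype]).
#' @export
read_plink <- function(prefix = NULL, bed = NULL, bim = NULL, fam = NULL) {
  if (!is.null(prefix)) {
    bed <- paste0(prefix, ".bed")
    bim <- paste0(prefix, ".bim")
    fam <- paste0(prefix, ".fam")
  }
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("file not found: ", f)

  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              colClasses = "character")
  if (ncol(bim_df) < 6L) stop(".bim file must have 6 columns")
  snps <- bim_df[[2L]]
  n_snp <- length(snps)

  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE,
                              colClasses = "character")
  if (ncol(fam_df) < 6L) stop(".fam file must have 6 columns")
  samples <- fam_df[[2L]]
  phen_raw <- suppressWarnings(as.numeric(fam_df[[6L]]))
  n_sam <- length(samples)

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L ||
      raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes): ", bed)
  if (raw[3L] != as.raw(0x01))
    stop("only SNP-major .bed files are supported: ", bed)
  bps <- ceiling(n_sam / 4)  # bytes per SNP
  if (length(raw) != 3L + bps * n_snp)
    stop(sprintf(".bed size mismatch: expected %d bytes, found %d",
                 3L + bps * n_snp, length(raw)))

  codes <- plink_byte_lut()[as.integer(raw[-(1:3)]) + 1L, , drop = FALSE]
  # bytes run sample-block-major within each SNP, SNPs consecutive
  geno <- array(t(codes), dim = c(4L * bps, n_snp))[seq_len(n_sam), , drop = FALSE]

  keep <- !is.na(phen_raw) & phen_raw %in% c(1, 2)
  if (!any(keep)) stop("no sample has a valid 1/2 phenotype in ", fam)
  if (!all(keep))
    warning(sprintf("excluding %d sample(s) with phenotype outside {1,2}",
                    sum(!keep)))
  geno <- geno[keep, , drop = FALSE]
  y <- as.integer(phen_raw[keep] == 2)
  names(y) <- samples[keep]
  list(genotypes = genotype_matrix(geno, snp_ids = snps,
                                   sample_ids = samples[keep]),
       phenotype = phenotype(y))
}

# 256 x 4 lookup: byte value -> genotype codes of its four 2-bit fields,
# least-significant pair first (PLINK v1 layout)
plink_byte_lut <- function() {
  lut <- matrix(NA_integer_, 256L, 4L)
  map <- c(0L, NA_integer_, 1L, 2L)  # bit pairs 00,01,10,11
  for (b in 0:255)
    for (s in 0:3)
      lut[b + 1L, s + 1L] <- map[bitwAnd(bitwShiftR(b, 2L * s), 3L) + 1L]
  lut
}

#' Write a PLINK 1 binary fileset
#'
#' Inverse of [read_plink()]: emits a SNP-major `.bed` plus `.bim`/`.fam`
#' files. Phenotype is written as 1 (control) / 2 (case). The `.bed` file is
#' exactly `3 + ceiling(n_samples/4) * n_snps` bytes.
#'
#' @param x a [genotype_matrix].
#' @param phen a [phenotype] of matching length.
#' @param prefix output path prefix.
#' @return the prefix, invisibly.
#' @export
write_plink <- function(x, phen, prefix) {
  check_geno_phen(x, phen)
  n_sam <- nrow(x)
  n_snp <- ncol(x)
  bps <- ceiling(n_sam / 4)

  # genotype code -> bit pair: 0->00, 1->10, 2->11, NA->01; pad bits stay 00
  enc <- matrix(0L, nrow = 4L * bps, ncol = n_snp)
  g <- unclass(x)
  code2bits <- function(v) {
    out <- integer(length(v))
    out[is.na(v)] <- 1L
    out[!is.na(v) & v == 1L] <- 2L
    out[!is.na(v) & v == 2L] <- 3L
    out
  }
  enc[seq_len(n_sam), ] <- code2bits(as.integer(g))
  shift <- rep(c(0L, 2L, 4L, 6L), length.out = 4L * bps)
  shifted <- enc * bitwShiftL(1L, shift)
  dim(shifted) <- c(4L, bps * n_snp)
  bytes <- as.raw(colSums(shifted))

  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)

  bim <- data.frame(chr = 1L, id = colnames(x), cm = 0L,
                    pos = seq_len(n_snp), a1 = "A", a2 = "B")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = rownames(x), iid = rownames(x),
                    pat = 0L, mat = 0L, sex = 0L,
                    phen = as.integer(unclass(phen)) + 1L)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read genotype data from the simple TSV dialect
#'
#' Expected layout: a header row `sample_id<TAB>phenotype<TAB><snp ids...>`,
#' then one row per sample with phenotype in `{0,1}` and genotypes in
#' `{0,1,2,NA}`.
#'
#' @param path file path.
#' @return as [read_plink()].
#' @export
read_genotype_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character",
                          check.names = FALSE, na.strings = NULL)
  if (ncol(df) < 3L)
    stop("TSV must have sample_id, phenotype and at least one SNP column")
  snps <- colnames(df)[-(1:2)]
  if (nrow(df) == 0L)
    return(list(genotypes = genotype_matrix(matrix(integer(), 0L, length(snps)),
                                            snp_ids = snps,
                                            sample_ids = character()),
                phenotype = phenotype(integer())))
  y_tok <- df[[2L]]
  bad <- which(!y_tok %in% c("0", "1"))
  if (length(bad))
    stop(sprintf("bad phenotype token '%s' at data row %d", y_tok[bad[1L]], bad[1L]))
  geno <- matrix(NA_integer_, nrow(df), length(snps))
  for (j in seq_along(snps)) {
    tok <- df[[j + 2L]]
    ok <- tok %in% c("0", "1", "2", "NA")
    if (!all(ok)) {
      r <- which(!ok)[1L]
      stop(sprintf("bad genotype token '%s' at data row %d, column '%s'",
                   tok[r], r, snps[j]))
    }
    col <- rep(NA_integer_, length(tok))
    col[tok != "NA"] <- as.integer(tok[tok != "NA"])
    geno[, j] <- col
  }
  y <- as.integer(y_tok)
  names(y) <- df[[1L]]
  list(genotypes = genotype_matrix(geno, snp_ids = snps, sample_ids = df[[1L]]),
       phenotype = phenotype(y))
}

#' @rdname read_genotype_tsv
#' @param x a [genotype_matrix].
#' @param phen a [phenotype].
#' @export
write_genotype_tsv <- function(x, phen, path) {
  check_geno_phen(x, phen)
  g <- unclass(x)
  out <- data.frame(sample_id = rownames(x),
                    phenotype = as.integer(unclass(phen)),
                    check.names = FALSE)
  gm <- as.data.frame(ifelse(is.na(g), "NA", as.character(g)))
  colnames(gm) <- colnames(x)
  out <- cbind(out, gm)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
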
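# Genotype I/O and contingency-table construction

test_that("hand-encoded PLINK .bed fixture decodes to the intended codes", {
  dir <- withr::local_tempdir()
  # 3 samples, 2 SNPs; SNP1 genotypes (0,1,2), SNP2 (1,NA,2)
  # bit pairs (lowest first): SNP1 00,10,11,pad -> 0x38; SNP2 10,01,11 -> 0x36
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x38, 0x36)),
           file.path(dir, "toy.bed"))
  writeLines(c("1\trs1\t0\t1\tA\tB", "1\trs2\t0\t2\tA\tB"),
             file.path(dir, "toy.bim"))
  writeLines(c("f1\ts1\t0\t0\t0\t1", "f2\ts2\t0\t0\t0\t2",
               "f3\ts3\t0\t0\t0\t2"), file.path(dir, "toy.fam"))
  dat <- read_plink(file.path(dir, "toy"))
  expect_equal(unclass(dat$genotypes),
               matrix(c(0L, 1L, 2L, 1L, NA, 2L), 3, 2,
                      dimnames = list(c("s1", "s2", "s3"), c("rs1", "rs2"))),
               ignore_attr = "class")
  expect_equal(as.integer(unclass(dat$phenotype)), c(0L, 1L, 1L))
})

test_that("PLINK round trip is bit-exact on genotype codes", {
  set.seed(5)
  fx <- random_fixture(n = 13, m = 7, miss = 0.15)
  dir <- withr::local_tempdir()
  write_plink(fx$x, fx$phen, file.path(dir, "rt"))
  expect_equal(file.size(file.path(dir, "rt.bed")),
               3 + ceiling(13 / 4) * 7)  # PLINK layout arithmetic
  back <- read_plink(file.path(dir, "rt"))
  expect_identical(unclass(back$genotypes), unclass(fx$x))
  expect_identical(as.integer(unclass(back$phenotype)),
                   as.integer(unclass(fx$phen)))
  # second write reproduces identical bytes
  write_plink(back$genotypes, back$phenotype, file.path(dir, "rt2"))
  expect_identical(readBin(file.path(dir, "rt.bed"), "raw", 1000),
                   readBin(file.path(dir, "rt2.bed"), "raw", 1000))
})

test_that("bad magic bytes and bad phenotypes are rejected", {
  dir <- withr::local_tempdir()
  writeBin(as.raw(c(0xde, 0xad, 0x01, 0x00)), file.path(dir, "bad.bed"))
  writeLines("1\trs1\t0\t1\tA\tB", file.path(dir, "bad.bim"))
  writeLines("f1\ts1\t0\t0\t0\t1", file.path(dir, "bad.fam"))
  expect_error(read_plink(file.path(dir, "bad")), "magic")
  # all-missing phenotype column
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x00)), file.path(dir, "bad.bed"))
  writeLines("f1\ts1\t0\t0\t0\t-9", file.path(dir, "bad.fam"))
  expect_error(read_plink(file.path(dir, "bad")), "phenotype")
})

test_that("TSV dialect loads identically to the PLINK encoding", {
  set.seed(7)
  fx <- random_fixture(n = 9, m = 5, miss = 0.2)
  dir <- withr::local_tempdir()
  write_plink(fx$x, fx$phen, file.path(dir, "eq"))
  write_genotype_tsv(fx$x, fx$phen, file.path(dir, "eq.tsv"))
  a <- read_plink(file.path(dir, "eq"))
  b <- read_genotype_tsv(file.path(dir, "eq.tsv"))
  expect_identical(unclass(a$genotypes), unclass(b$genotypes))
  expect_identical(as.integer(unclass(a$phenotype)),
                   as.integer(unclass(b$phenotype)))
})

test_that("TSV parser reports bad tokens and handles empty files", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "bad.tsv")
  writeLines(c("sample_id\tphenotype\tsnpA", "s1\t1\t3"), p)
  expect_error(read_genotype_tsv(p), "row 1.*snpA")
  writeLines("sample_id\tphenotype\tsnpA", p)
  empty <- read_genotype_tsv(p)
  expect_equal(nrow(empty$genotypes), 0L)
  expect_error(build_single_table(empty$genotypes, empty$phenotype, 1L))
})

test_that("single and pair tables match hand tallies", {
  # controls with genotypes (0,0,1), cases with (1,2,2)
  x <- genotype_matrix(matrix(c(0L, 0L, 1L, 1L, 2L, 2L,
                                0L, 1L, 1L, 1L, 2L, 2L), 6, 2),
                       snp_ids = c("a", "b"))
  phen <- phenotype(c(0, 0, 0, 1, 1, 1))
  st <- build_single_table(x, phen, "a")
  expect_equal(unclass(st), matrix(c(2L, 0L, 1L, 1L, 0L, 2L), 2, 3),
               ignore_attr = TRUE)
  expect_equal(colSums(st), c(`0` = 2, `1` = 2, `2` = 2))  # conservation
  # pairs (0,0),(0,1),(1,1) controls; (1,1),(2,2),(2,2) cases
  pt <- build_pair_table(x, phen, 1L, 2L)
  expected <- matrix(0L, 2, 9)
  expected[1, c(1, 2, 5)] <- 1L          # ctrl v=0,1,4
  expected[2, 5] <- 1L; expected[2, 9] <- 2L  # case v=4, v=8 twice
  expect_equal(unclass(pt), expected, ignore_attr = TRUE)
})

test_that("pair tables are symmetric in argument order and reject i == j", {
  set.seed(11)
  fx <- random_fixture(n = 40, m = 3, miss = 0.1)
  expect_identical(unclass(build_pair_table(fx$x, fx$phen, 1L, 3L)),
                   unclass(build_pair_table(fx$x, fx$phen, 3L, 1L)))
  expect_error(build_pair_table(fx$x, fx$phen, 2L, 2L), "distinct")
})

test_that("pair-table marginals agree with single tables on random fixtures", {
  set.seed(13)
  for (rep in 1:300) {
    fx <- random_fixture(n = 25, m = 3, miss = 0.2)
    pt <- build_pair_table(fx$x, fx$phen, 1L, 2L)
    # conservation: total = samples non-missing at both SNPs
    both <- !is.na(unclass(fx$x)[, 1]) & !is.na(unclass(fx$x)[, 2])
    expect_equal(sum(pt), sum(both))
    # marginalisation = single table restricted to the common subset
    xr <- genotype_matrix(unclass(fx$x)[both, , drop = FALSE])
    pr <- phenotype(as.integer(unclass(fx$phen))[both])
    if (n_cases(pr) == 0 || n_controls(pr) == 0) next
    expect_equal(unclass(marginalise_pair_table(pt, 1L)),
                 unclass(build_single_table(xr, pr, 1L)),
                 ignore_attr = TRUE)
    expect_equal(unclass(marginalise_pair_table(pt, 2L)),
                 unclass(build_single_table(xr, pr, 2L)),
                 ignore_attr = TRUE)
  }
})

test_that("ranked lists round-trip and reject malformed input", {
  l <- list_from_keys(c("a\tb", "a\tc", "b\tc"))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "l.tsv")
  write_ranked_list(l, p)
  back <- read_ranked_list(p)
  expect_equal(back$snp_id_1, l$snp_id_1)
  expect_equal(back$score, l$score)
  # duplicate pair
  writeLines(c("rank\tsnp_id_1\tsnp_id_2\tscore\tp_value",
               "1\ta\tb\t3\t0.1", "2\ta\tb\t2\t0.2"), p)
  expect_error(read_ranked_list(p), "duplicate")
  # unsorted scores
  writeLines(c("rank\tsnp_id_1\tsnp_id_2\tscore\tp_value",
               "1\ta\tb\t1\t0.1", "2\ta\tc\t2\t0.2"), p)
  expect_error(read_ranked_list(p), "sorted")
  # empty list -> header-only file
  e <- ranked_pair_list(data.frame(snp_id_1 = character(),
                                   snp_id_2 = character(),
                                   score = numeric(), p_value = numeric()))
  write_ranked_list(e, p)
  expect_equal(length(readLines(p)), 1L)
  expect_equal(nrow(read_ranked_list(p)), 0L)
})
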
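test_that("the TSV dialect round-trips a count table", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  snps <- make_counts(c(30, 10, 5), c(20, 10, 5), c(25, 10, 5), c(30, 10, 5),
                      chrom = c("1", "1", "2"), pos = c(100, 200, 50))
  write_snp_counts(snps, tsv)
  expect_equal(read_snp_counts(tsv), snps)
})

test_that("VCF allele depths map onto the count table", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tES\tET",
    "1\t100\t.\tA\tG\t.\t.\t.\tAD\t30,20\t25,30",
    "1\t200\t.\tC\tT,G\t.\t.\t.\tAD\t10,5\t10,5",     # triallelic: dropped
    "1\t300\t.\tG\tA\t.\t.\t.\tAD\t.\t12,13",          # missing AD: dropped
    "2\t50\t.\tT\tC\t.\t.\t.\tAD\t40,41\t42,43"
  ), vcf)
  expect_message(snps <- read_snp_counts(vcf), "dropped 2")
  expect_equal(nrow(snps), 2)
  row1 <- snps[snps$pos == 100, ]
  expect_equal(unlist(row1[, 3:6], use.names = FALSE), c(30, 20, 25, 30))
  # reversed cross: ALT is the parent-1 allele
  snps_alt <- suppressMessages(read_snp_counts(vcf, parent1 = "alt"))
  expect_equal(unlist(snps_alt[snps_alt$pos == 100, 3:6], use.names = FALSE),
               c(20, 30, 30, 25))
})

test_that("unsorted input sorts with a warning and duplicates error", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tn1_ES\tn2_ES\tn1_ET\tn2_ET",
               "1\t200\t1\t2\t3\t4", "1\t100\t5\t6\t7\t8"), tsv)
  expect_warning(snps <- read_snp_counts(tsv), "sort")
  expect_equal(snps$pos, c(100, 200))
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tn1_ES\tn2_ES\tn1_ET\tn2_ET",
               "1\t100\t1\t2\t3\t4", "1\t100\t5\t6\t7\t8"), tsv2)
  expect_error(suppressWarnings(read_snp_counts(tsv2)), "duplicated")
})

test_that("SNP filtering applies the three closed-interval rules", {
  keep_row <- make_counts(30, 20, 25, 30)  # total 105, pools 50/55, f 0.524
  expect_equal(nrow(filter_snps(keep_row, quiet = TRUE)), 1)

  # rule 2 boundaries: totals 100 and 400 pass, 99 and 401 fail
  expect_equal(nrow(filter_snps(make_counts(25, 25, 25, 25), quiet = TRUE)), 1)
  expect_equal(nrow(filter_snps(make_counts(100, 100, 100, 100), quiet = TRUE)), 1)
  expect_equal(nrow(filter_snps(make_counts(25, 25, 25, 24), quiet = TRUE)), 0)
  expect_equal(nrow(filter_snps(make_counts(100, 100, 100, 101), quiet = TRUE)), 0)

  # rule 3: a pool depth of 39 fails, 40 passes
  expect_equal(nrow(filter_snps(make_counts(19, 20, 50, 50), quiet = TRUE)), 0)
  expect_equal(nrow(filter_snps(make_counts(20, 20, 50, 50), quiet = TRUE)), 1)

  # rule 1: overall parent-1 frequency 20% and 80% pass; 19% fails
  expect_equal(nrow(filter_snps(make_counts(20, 80, 20, 80), quiet = TRUE)), 1)
  expect_equal(nrow(filter_snps(make_counts(80, 20, 80, 20), quiet = TRUE)), 1)
  expect_equal(nrow(filter_snps(make_counts(19, 81, 19, 81), quiet = TRUE)), 0)

  # zero total depth rejects under the depth rule, not a crash
  zero <- make_counts(0, 0, 0, 0)
  out <- filter_snps(zero, quiet = TRUE)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "rejections")[["total_depth"]], 1L)
})

test_that("filtering is idempotent and accounts for every rejection", {
  set.seed(5)
  snps <- random_tables(500)
  out <- filter_snps(snps, quiet = TRUE)
  expect_equal(sum(attr(out, "rejections")), nrow(snps) - nrow(out))
  again <- filter_snps(out, quiet = TRUE)
  expect_equal(again, out, ignore_attr = "rejections")
  expect_equal(sum(attr(again, "rejections")), 0L)
  # order independence
  shuf <- filter_snps(snps[sample(nrow(snps)), ], quiet = TRUE)
  expect_equal(shuf, out, ignore_attr = "rejections")
})

test_that("frequency summary reports the overall parent-1 spectrum", {
  expect_equal(frequency_summary(make_counts(c(25, 25), c(25, 25),
                                             c(25, 25), c(25, 25)))$mean, 0.5)
  # two SNPs at f = 0.2 and 0.8 average to 0.5
  two <- make_counts(c(20, 80), c(80, 20), c(20, 80), c(80, 20))
  expect_equal(frequency_summary(two)$mean, 0.5)
  hs <- frequency_summary(two, binwidth = 0.02)$histogram
  expect_equal(sum(hs$count), 2)
  expect_error(frequency_summary(make_counts(numeric(0), numeric(0),
                                             numeric(0), numeric(0))), "empty")
})

test_that("coverage summary computes the accounting identities", {
  ms <- tibble::tibble(raw_reads = 100, kept_reads = 100,
                       uniquely_mapped_reads = 50, total_mapped_length = 5000,
                       covered_length = 400, genome_length = 1000)
  out <- coverage_summary(ms)
  expect_equal(out$kept_pct, 100)
  expect_equal(out$unique_pct, 50)
  expect_equal(out$coverage_rate_pct, 40)
  expect_equal(out$depth, 12.5)
  expect_error(coverage_summary(transform(ms, covered_length = 0)), "covered")
  expect_error(coverage_summary(transform(ms, kept_reads = 101)), "exceeds")
})
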
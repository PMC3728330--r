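# A G' track can be built directly for interval logic: only chrom, pos,
# Gprime are consulted.
toy_track <- function(gprime, pos = seq_along(gprime) * 1e6, chrom = "1") {
  tibble::tibble(chrom = chrom, pos = pos, G = gprime, Gprime = gprime)
}

test_that("full intervals are maximal above-threshold runs with merging", {
  tr <- toy_track(c(1, 20, 25, 20, 1))
  expect_equal(nrow(full_intervals(tr, threshold = 30)), 0)
  iv <- full_intervals(tr, threshold = 12, min_span = 1e6, min_snps = 2)
  expect_equal(nrow(iv), 1)
  expect_equal(c(iv$start, iv$end), c(2e6, 4e6))
  expect_equal(iv$n_snps, 3L)
  # two runs 300 kb apart merge under the default 500-kb gap
  tr2 <- toy_track(c(20, 20, 1, 20, 20),
                   pos = c(1e5, 2e5, 3e5, 5e5, 6e5))
  iv2 <- full_intervals(tr2, threshold = 12, merge_gap = 5e5,
                        min_span = 1e5, min_snps = 2)
  expect_equal(nrow(iv2), 1)
  expect_equal(c(iv2$start, iv2$end), c(1e5, 6e5))
  # a 500-kb gap (not < merge_gap) stays split
  tr3 <- toy_track(c(20, 20, 1, 20, 20),
                   pos = c(1e5, 2e5, 3e5, 7e5, 8e5))
  iv3 <- full_intervals(tr3, threshold = 12, merge_gap = 5e5,
                        min_span = 1e5, min_snps = 2)
  expect_equal(nrow(iv3), 2)
  # short/sparse runs are minor peaks, not QTLs
  iv4 <- full_intervals(tr2, threshold = 12)
  expect_true(all(iv4$type == "minor"))
})

test_that("summits take the leftmost maximal G'", {
  tr <- toy_track(c(20, 25, 20))
  expect_equal(summit(tr, list(chrom = "1", start = 1e6, end = 3e6))$pos, 2e6)
  tie <- toy_track(c(25, 25))
  expect_equal(summit(tie, list(chrom = "1", start = 1e6, end = 2e6))$pos, 1e6)
  expect_error(summit(tr, list(chrom = "2", start = 1, end = 2)), "no SNP")
})

test_that("the probable interval isolates the head of the peak", {
  # triangular peak rising 10..30 by 5: threshold 10, head_fraction 0.75
  # -> level 25: only G' in {25, 30, 25}
  tri <- toy_track(c(10, 15, 20, 25, 30, 25, 20, 15, 10))
  iv <- list(chrom = "1", start = 1e6, end = 9e6)
  pr <- probable_interval(tri, iv, threshold = 10, head_fraction = 0.75)
  expect_equal(c(pr$start, pr$end), c(4e6, 6e6))
  # head_fraction 0 reduces to the full above-threshold run
  pr0 <- probable_interval(tri, iv, threshold = 10, head_fraction = 0)
  expect_equal(c(pr0$start, pr0$end), c(1e6, 9e6))
  # flat top at summit level: probable = full interval
  flat <- toy_track(rep(30, 4))
  prf <- probable_interval(flat, list(chrom = "1", start = 1e6, end = 4e6),
                           threshold = 10, head_fraction = 0.75)
  expect_equal(c(prf$start, prf$end), c(1e6, 4e6))
})

test_that("the allele source follows the sign of the summit NAFD", {
  nafd <- tibble::tibble(chrom = "1", start = c(1, 1e5 + 1), end = c(1e5, 2e5),
                         m = c(5L, 5L), f_ES = c(0.2, 0.5), f_ET = c(0.61, 0.5),
                         nafd = c(0.41, 0))
  expect_equal(allele_source(nafd, "1", 5e4)$source, "parent1")
  neg <- nafd; neg$nafd <- c(-0.35, -0.1)
  expect_equal(allele_source(neg, "1", 5e4)$source, "parent2")
  expect_equal(allele_source(nafd, "1", 1.5e5)$source, "undetermined")
  none <- nafd[0, ]
  expect_equal(allele_source(none, "1", 5e4)$source, "undetermined")
})

test_that("QTL calls are named per chromosome with positional suffixes", {
  g <- c(rep(1, 3), rep(20, 4), rep(1, 10), rep(25, 4), rep(1, 3))
  tr <- toy_track(g, pos = seq_along(g) * 5e5)
  calls <- call_qtls(tr, threshold = 10, trait = "CT", min_span = 5e5,
                     min_snps = 3)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$name, c("qCT-1a", "qCT-1b"))
  expect_true(all(calls$summit_gprime >= 10))
  expect_true(all(calls$probable_start >= calls$full_start &
                    calls$probable_end <= calls$full_end))
  expect_true(all(calls$source_parent == "undetermined"))  # no NAFD given
  single <- call_qtls(toy_track(c(1, 20, 20, 20, 1), pos = 1:5 * 5e5),
                      threshold = 10, trait = "CT", min_span = 5e5,
                      min_snps = 3)
  expect_equal(single$name, "qCT-1")
})

test_that("valley splitting emits two flanking sub-calls when enabled", {
  # M-shaped peak: two summits at 30 with an internal dip to 12 (below the
  # head level) - the analogue of a centromere-divided double QTL
  g <- c(1, 20, 30, 20, 12, 20, 30, 20, 1)
  tr <- toy_track(g, pos = seq_along(g) * 5e5)
  whole <- call_qtls(tr, threshold = 10, min_span = 5e5, min_snps = 3)
  expect_equal(nrow(whole), 1)
  split <- call_qtls(tr, threshold = 10, min_span = 5e5, min_snps = 3,
                     split_valleys = TRUE)
  expect_equal(nrow(split), 2)
  expect_equal(split$full_end[1], split$full_start[2])  # share the valley
  expect_equal(split$summit_gprime, c(30, 30))
})

test_that("reports round-trip through JSON and export BED intervals", {
  g <- c(1, 20, 25, 20, 1)
  tr <- toy_track(g, pos = 1:5 * 5e5)
  nafd <- nafd_scan(make_counts(c(80), c(20), c(20), c(80), pos = 15e5))
  calls <- call_qtls(tr, threshold = 10, nafd_track = nafd, min_span = 5e5,
                     min_snps = 3)
  expect_equal(calls$source_parent, "parent2")  # nafd = -0.6 at the summit
  json <- withr::local_tempfile(fileext = ".json")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_qtl_report(calls, json = json, bed_full = bed)
  back <- read_qtl_report(json)
  expect_equal(back$summit_pos, calls$summit_pos)
  expect_equal(back$name, calls$name)
  bed_tbl <- readr::read_tsv(bed, col_names = c("chrom", "start", "end", "name"),
                             show_col_types = FALSE)
  expect_equal(bed_tbl$start, calls$full_start - 1)   # 0-based half-open
  expect_equal(bed_tbl$end, calls$full_end)
  # empty calls still produce a header-only table
  empty <- call_qtls(tr, threshold = 100)
  expect_equal(nrow(empty), 0)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_qtl_report(empty, tsv = tsv)
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), 0)
})
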
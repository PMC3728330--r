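#' Read a per-SNP allele-count table
#'
#' Loads the two-pool biallelic allele depths that drive the whole
#' analysis. Two formats are supported:
#'
#' * `"tsv"`: the package-standard dialect — a tab-separated table with
#'   header `chrom pos n1_ES n2_ES n1_ET n2_ET` and `#` comment lines,
#'   where `n1` is the parent-1 (reference, e.g. Nipponbare) allele depth.
#' * `"vcf"`: a VCF (4.x) with exactly two samples carrying `FORMAT/AD`
#'   allele depths; the first sample is taken as ES and the second as ET
#'   unless `samples = c(es, et)` names them. Multiallelic records and
#'   records with missing AD are dropped (a message reports how many).
#'
#' Rows are sorted by `(chrom, pos)` (with a warning if the input was
#' unsorted); duplicated positions are an error.
#'
#' @param path Input file.
#' @param format `"tsv"` or `"vcf"` (default guessed from the extension).
#' @param parent1 Which VCF allele is the parent-1 allele: `"ref"`
#'   (default; the reference genome is parent 1) or `"alt"` for reversed
#'   crosses.
#' @param samples Optional length-2 character: VCF sample names for
#'   `c(ES, ET)`.
#' @return Tibble `chrom, pos, n1_ES, n2_ES, n1_ET, n2_ET`.
#' @export
read_snp_counts <- function(path, format = c("auto", "tsv", "vcf"),
                            parent1 = c("ref", "alt"), samples = NULL) {
  format <- match.arg(format)
  parent1 <- match.arg(parent1)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  snps <- if (format == "tsv") {
    readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                    col_types = readr::cols(
                      chrom = readr::col_character(),
                      pos = readr::col_double(),
                      .default = readr::col_double()
                    ))
  } else {
    read_counts_vcf(path, parent1, samples)
  }
  resorted <- dplyr::arrange(snps, .data$chrom, .data$pos)
  if (!identical(resorted$pos, snps$pos) ||
      !identical(resorted$chrom, snps$chrom)) {
    warn("input records were not position-sorted; sorting")
  }
  validate_counts(resorted)
}

read_counts_vcf <- function(path, parent1, samples) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (ncol(ad) != 2 && is.null(samples)) {
    abort("VCF must contain exactly two samples (ES, ET), or name them via `samples`")
  }
  if (!is.null(samples)) {
    if (!all(samples %in% colnames(ad))) abort("`samples` not found in VCF")
    ad <- ad[, samples, drop = FALSE]
  }
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | is.na(alt) | alt == "."
  no_ad <- is.na(ad[, 1]) | is.na(ad[, 2]) |
    !grepl("^\\d+,\\d+$", ad[, 1]) | !grepl("^\\d+,\\d+$", ad[, 2])
  drop <- multi | no_ad
  if (any(drop)) {
    inform(sprintf("dropped %d record(s): %d multiallelic, %d with missing AD",
                   sum(drop), sum(multi), sum(no_ad & !multi)))
  }
  keep <- !drop
  split_ad <- function(x) {
    m <- do.call(rbind, strsplit(x, ",", fixed = TRUE))
    matrix(as.numeric(m), ncol = 2)
  }
  es <- split_ad(ad[keep, 1]); et <- split_ad(ad[keep, 2])
  if (parent1 == "alt") { es <- es[, 2:1, drop = FALSE]; et <- et[, 2:1, drop = FALSE] }
  tibble::tibble(
    chrom = as.character(fix[keep, "CHROM"]),
    pos = as.numeric(fix[keep, "POS"]),
    n1_ES = es[, 1], n2_ES = es[, 2],
    n1_ET = et[, 1], n2_ET = et[, 2]
  )
}

#' Write an allele-count table in the package TSV dialect
#'
#' @param snps Allele-count tibble (see [read_snp_counts()]).
#' @param path Output path.
#' @return `snps`, invisibly.
#' @export
write_snp_counts <- function(snps, path) {
  snps <- validate_counts(snps)
  readr::write_tsv(snps[, c("chrom", "pos", "n1_ES", "n2_ES", "n1_ET", "n2_ET")],
                   path)
  invisible(snps)
}

#' Filter SNPs for pooled QTL analysis
#'
#' Applies the three retention requirements that guard against segregation
#' bias and unstable small-depth tables. A SNP is kept iff
#' 1. the overall parent-1 allele frequency across both pools lies in
#'    `freq_range` (closed interval),
#' 2. its total depth over both pools lies in `total_depth_range` (closed),
#' 3. each pool's depth is at least `min_pool_depth`.
#'
#' Rejections are attributed to the first failing rule in the order 1, 2,
#' 3; a zero-total-depth SNP (undefined frequency) is rejected under
#' rule 2. The filter is idempotent and order-independent.
#'
#' @param snps Allele-count tibble.
#' @param freq_range Closed frequency interval (default `c(0.20, 0.80)`).
#' @param total_depth_range Closed total-depth interval (default
#'   `c(100, 400)`).
#' @param min_pool_depth Minimum per-pool depth (default 40).
#' @param quiet Suppress the rejection summary message.
#' @return The retained rows, with an attribute `"rejections"`: a named
#'   integer vector `c(freq, total_depth, pool_depth)`.
#' @examples
#' snps <- tibble::tibble(chrom = "1", pos = c(100, 200),
#'                        n1_ES = c(30, 10), n2_ES = c(20, 10),
#'                        n1_ET = c(25, 10), n2_ET = c(30, 10))
#' filter_snps(snps)
#' @export
filter_snps <- function(snps, freq_range = c(0.20, 0.80),
                        total_depth_range = c(100, 400),
                        min_pool_depth = 40, quiet = FALSE) {
  snps <- validate_counts(snps)
  d_es <- snps$n1_ES + snps$n2_ES
  d_et <- snps$n1_ET + snps$n2_ET
  total <- d_es + d_et
  freq <- (snps$n1_ES + snps$n1_ET) / total  # NaN when total == 0
  fail1 <- !is.na(freq) & (freq < freq_range[1] | freq > freq_range[2])
  fail2 <- total < total_depth_range[1] | total > total_depth_range[2]
  fail3 <- d_es < min_pool_depth | d_et < min_pool_depth
  first_fail <- dplyr::case_when(fail1 ~ 1L, fail2 ~ 2L, fail3 ~ 3L,
                                 .default = 0L)
  rejections <- c(
    freq = sum(first_fail == 1L),
    total_depth = sum(first_fail == 2L),
    pool_depth = sum(first_fail == 3L)
  )
  out <- snps[first_fail == 0L, , drop = FALSE]
  if (!quiet) {
    inform(sprintf(
      "kept %d / %d SNPs (rejected: %d frequency, %d total depth, %d pool depth)",
      nrow(out), nrow(snps), rejections[["freq"]],
      rejections[["total_depth"]], rejections[["pool_depth"]]))
  }
  attr(out, "rejections") <- rejections
  out
}

#' Summarize the overall parent-1 allele frequency spectrum
#'
#' Per-SNP overall frequency is `(n1_ES + n1_ET) / total depth`. In a
#' well-behaved F3 pooled design the spectrum is approximately symmetric
#' and unimodal around 0.5.
#'
#' @param snps Allele-count tibble (nonempty).
#' @param binwidth Histogram bin width on the frequency axis (default
#'   0.02).
#' @return List with `mean` (scalar) and `histogram`, a tibble of
#'   `bin_start, bin_end, count`.
#' @export
frequency_summary <- function(snps, binwidth = 0.02) {
  snps <- validate_counts(snps)
  if (nrow(snps) == 0) abort("empty SNP table")
  total <- snps$n1_ES + snps$n2_ES + snps$n1_ET + snps$n2_ET
  f <- (snps$n1_ES + snps$n1_ET) / total
  f <- f[!is.na(f)]
  if (length(f) == 0) abort("no SNP has positive depth")
  breaks <- seq(0, 1 + binwidth, by = binwidth)
  h <- hist(f, breaks = breaks, plot = FALSE, right = FALSE)
  list(
    mean = mean(f),
    histogram = tibble::tibble(
      bin_start = head(h$breaks, -1),
      bin_end = tail(h$breaks, -1),
      count = h$counts
    )
  )
}

#' Sequencing and mapping coverage summary
#'
#' Reproduces the standard per-pool accounting of a pooled sequencing run:
#' the percentage of raw reads retained after trimming, the percentage of
#' retained reads mapping uniquely, the fraction of the genome covered,
#' and the mean depth over covered positions.
#'
#' @param ms A data frame (one row per pool) with columns `raw_reads`,
#'   `kept_reads`, `uniquely_mapped_reads`, `total_mapped_length`,
#'   `covered_length`, `genome_length`.
#' @return Tibble with `kept_pct`, `unique_pct`, `coverage_rate_pct`,
#'   `depth` (plus any identifier columns of `ms`).
#' @examples
#' coverage_summary(tibble::tibble(
#'   pool = "ES", raw_reads = 356193956, kept_reads = 353856120,
#'   uniquely_mapped_reads = 244801282, total_mapped_length = 24152244325,
#'   covered_length = 342446650, genome_length = 373245519
#' ))
#' @export
coverage_summary <- function(ms) {
  ms <- tibble::as_tibble(ms)
  need <- c("raw_reads", "kept_reads", "uniquely_mapped_reads",
            "total_mapped_length", "covered_length", "genome_length")
  if (!all(need %in% names(ms))) {
    abort(paste("coverage_summary needs columns:", paste(need, collapse = ", ")))
  }
  if (any(ms$raw_reads <= 0 | ms$kept_reads <= 0 | ms$genome_length <= 0)) {
    abort("read counts and genome length must be positive")
  }
  if (any(ms$covered_length <= 0)) abort("covered_length must be positive")
  if (any(ms$kept_reads > ms$raw_reads)) abort("kept_reads exceeds raw_reads")
  if (any(ms$covered_length > ms$genome_length)) {
    abort("covered_length exceeds genome_length")
  }
  id_cols <- setdiff(names(ms), need)
  dplyr::bind_cols(
    ms[, id_cols, drop = FALSE],
    tibble::tibble(
      kept_pct = 100 * ms$kept_reads / ms$raw_reads,
      unique_pct = 100 * ms$uniquely_mapped_reads / ms$kept_reads,
      coverage_rate_pct = 100 * ms$covered_length / ms$genome_length,
      depth = ms$total_mapped_length / ms$covered_length
    )
  )
}

#' @importFrom graphics hist
NULL
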
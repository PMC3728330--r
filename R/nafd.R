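#' Pooled parent-1 allele frequency of a window
#'
#' Depth-weighted pooled frequency over the `m` SNPs of a window:
#' `f = sum(a_i) / sum(a_i + b_i)` with `a_i`/`b_i` the parent-1/parent-2
#' depths of SNP `i` in the chosen pool. Pooling the counts (rather than
#' averaging per-SNP frequencies) weights each SNP by its depth.
#'
#' @param snps Allele-count rows lying inside the window.
#' @param pool `"ES"` or `"ET"`.
#' @return Scalar frequency in `[0, 1]`; error if the window is empty or
#'   its total depth is zero.
#' @export
window_frequency <- function(snps, pool = c("ES", "ET")) {
  pool <- match.arg(pool)
  if (nrow(snps) == 0) abort("empty window")
  a <- snps[[paste0("n1_", pool)]]
  b <- snps[[paste0("n2_", pool)]]
  tot <- sum(a + b)
  if (tot <= 0) abort("window has zero depth")
  sum(a) / tot
}

#' Sliding-window reference-parent allele-frequency difference profile
#'
#' Moves a fixed-width window along each chromosome in fixed steps
#' (anchored at position 1, closed-open spans `[start, start + window)`),
#' computes the depth-pooled parent-1 allele frequency in each pool
#' ([window_frequency()]), and reports their difference
#' `nafd = f_ET - f_ES`. At a QTL, `nafd > 0` indicates that the parent-1
#' allele increases the selected-for trait (tolerance) and `nafd < 0`
#' that it decreases it. Windows containing no SNP are omitted.
#'
#' @inheritParams expected_counts
#' @param window Window width in bp (default 300,000).
#' @param step Step length in bp (default 10,000).
#' @return A tibble of class `"bsa_nafd"`: `chrom, start, end, m, f_ES,
#'   f_ET, nafd` (`start`/`end` are 1-based inclusive; `m` = SNPs in
#'   window).
#' @export
nafd_scan <- function(snps, window = 3e5, step = 1e4) {
  snps <- validate_counts(snps)
  out <- list()
  for (ch in unique(snps$chrom)) {
    sub <- snps[snps$chrom == ch, ]
    pos <- sub$pos
    ca1 <- cumsum(sub$n1_ES); ct1 <- cumsum(sub$n1_ES + sub$n2_ES)
    ca2 <- cumsum(sub$n1_ET); ct2 <- cumsum(sub$n1_ET + sub$n2_ET)
    starts <- seq(1, max(pos), by = step)
    lo <- findInterval(starts - 0.5, pos) + 1L
    hi <- findInterval(starts + window - 0.5, pos)
    m <- hi - lo + 1L
    keep <- m >= 1L
    lo <- lo[keep]; hi <- hi[keep]
    csum <- function(cs, lo, hi) cs[hi] - ifelse(lo > 1, cs[lo - 1L], 0)
    a1 <- csum(ca1, lo, hi); t1 <- csum(ct1, lo, hi)
    a2 <- csum(ca2, lo, hi); t2 <- csum(ct2, lo, hi)
    f_es <- ifelse(t1 > 0, a1 / t1, NA_real_)
    f_et <- ifelse(t2 > 0, a2 / t2, NA_real_)
    out[[ch]] <- tibble::tibble(
      chrom = ch, start = starts[keep], end = starts[keep] + window - 1,
      m = m[keep], f_ES = f_es, f_ET = f_et, nafd = f_et - f_es
    )
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("bsa_nafd", class(res))
  res
}
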
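#' Expected allele counts under the no-linkage null
#'
#' For each SNP's 2x2 table of (pool x parental allele) read depths, the
#' null expectation preserves both margins:
#' `nhat_i = (row margin) * (column margin) / N`.
#'
#' @param snps Allele-count tibble (`chrom, pos, n1_ES, n2_ES, n1_ET,
#'   n2_ET`); every SNP must have positive total depth.
#' @return Tibble `n1_hat, n2_hat, n3_hat, n4_hat` (same row order;
#'   n1..n4 = parent-1/parent-2 depth in ES, then in ET).
#' @export
expected_counts <- function(snps) {
  d_es <- snps$n1_ES + snps$n2_ES
  d_et <- snps$n1_ET + snps$n2_ET
  p1 <- snps$n1_ES + snps$n1_ET
  p2 <- snps$n2_ES + snps$n2_ET
  N <- d_es + d_et
  if (any(N <= 0)) abort("every SNP must have positive total depth")
  tibble::tibble(
    n1_hat = d_es * p1 / N, n2_hat = d_es * p2 / N,
    n3_hat = d_et * p1 / N, n4_hat = d_et * p2 / N
  )
}

#' Per-SNP likelihood-ratio G statistic
#'
#' `G = 2 * sum_i n_i * ln(n_i / nhat_i)` over the four cells of the
#' (pool x parental allele) table, with the convention `0 * ln 0 = 0`.
#' G is the likelihood-ratio test of identical allele frequencies in the
#' two pools and is nonnegative, equalling zero iff the observed table
#' matches its margin-preserving expectation.
#'
#' @inheritParams expected_counts
#' @return Numeric vector of G values (one per SNP).
#' @examples
#' snps <- tibble::tibble(chrom = "1", pos = 1,
#'                        n1_ES = 60, n2_ES = 40, n1_ET = 40, n2_ET = 60)
#' g_statistic(snps) # 8.054
#' @export
g_statistic <- function(snps) {
  e <- expected_counts(snps)
  obs <- cbind(snps$n1_ES, snps$n2_ES, snps$n1_ET, snps$n2_ET)
  exp_ <- cbind(e$n1_hat, e$n2_hat, e$n3_hat, e$n4_hat)
  term <- ifelse(obs > 0, obs * log(obs / exp_), 0)
  pmax(2 * rowSums(term), 0)  # clamp tiny negative rounding at G ~ 0
}

#' Tricube smoothing weights within a genomic window
#'
#' Standardized distance `D_j = |pos_j - center| / half_width` runs from 0
#' at the window centre to 1 at the edge; raw weights are the tricube
#' kernel `(1 - D_j^3)^3`, normalized to sum to one.
#'
#' @param positions SNP positions (bp) inside the window.
#' @param center Window centre (bp).
#' @param half_width Window half-width (bp).
#' @return Normalized weight vector (nonnegative, sums to 1,
#'   non-increasing in distance).
#' @export
tricube_weights <- function(positions, center, half_width) {
  if (length(positions) == 0) abort("empty window")
  D <- abs(positions - center) / half_width
  if (any(D > 1 + 1e-12)) abort("position outside the window")
  raw <- (1 - pmin(D, 1)^3)^3
  s <- sum(raw)
  if (s <= 0) abort("all weights are zero (only edge SNPs in window)")
  raw / s
}

#' Sliding-window G' genome scan
#'
#' Computes the per-SNP G statistic and, at every SNP, the
#' tricube-weighted average G' of all G values within a fixed-width window
#' centred on that SNP. Windows never span chromosomes and are truncated
#' at chromosome ends. G' smooths read-sampling noise and exploits
#' linkage: QTL regions appear as broad G' peaks.
#'
#' @inheritParams expected_counts
#' @param window Full window width in bp (default 1,000,000 = 1000 kb).
#' @return A tibble of class `"bsa_gprime"`: `chrom, pos, G, Gprime,
#'   n_snps_in_window`.
#' @export
gprime_scan <- function(snps, window = 1e6) {
  snps <- validate_counts(snps)
  if (nrow(snps) == 0) abort("empty SNP table")
  half <- window / 2
  G <- g_statistic(snps)
  out <- vector("list", length(unique(snps$chrom)))
  i <- 0
  for (ch in unique(snps$chrom)) {
    sel <- snps$chrom == ch
    pos <- snps$pos[sel]
    g <- G[sel]
    m <- length(pos)
    gp <- numeric(m); nw <- integer(m)
    for (j in seq_len(m)) {
      lo <- findInterval(pos[j] - half - 1e-9, pos) + 1L
      hi <- findInterval(pos[j] + half + 1e-9, pos)
      D <- abs(pos[lo:hi] - pos[j]) / half
      raw <- (1 - D^3)^3
      s <- sum(raw)
      gp[j] <- if (s > 0) sum(raw * g[lo:hi]) / s else g[j]
      nw[j] <- hi - lo + 1L
    }
    i <- i + 1
    out[[i]] <- tibble::tibble(chrom = ch, pos = pos, G = g, Gprime = gp,
                               n_snps_in_window = nw)
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("bsa_gprime", class(res))
  res
}
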
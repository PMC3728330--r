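#' Run the complete pooled-segregant QTL scan
#'
#' One-call pipeline over a filtered allele-count table: G' genome scan
#' ([gprime_scan()]), robust log-normal null and FDR threshold
#' ([estimate_threshold()]), Bonferroni-corrected Jensen-Shannon
#' differential-SNP scan ([differential_scan()]), windowed
#' allele-frequency-difference profile ([nafd_scan()]), and QTL interval
#' calling ([call_qtls()]).
#'
#' @inheritParams expected_counts
#' @param window G' window width in bp.
#' @param qstar Target FDR for the G' threshold.
#' @param spacing,reps Null-estimation subsampling parameters (see
#'   [estimate_threshold()]).
#' @param alpha Bonferroni family-wise level for the differential scan.
#' @param nafd_window,nafd_step NAFD profile window and step (bp).
#' @param trait,head_fraction,merge_gap,min_span,min_snps,split_valleys
#'   Passed to [call_qtls()].
#' @param seed Seed for the threshold-estimation subsampling.
#' @return Object of class `"bsa_result"`: list with elements `gprime`,
#'   `null`, `jsd`, `nafd`, `qtls`.
#' @examples
#' cfg <- sim_config(chrom_lengths = c(4e7), n_snps = 400, pop_size = 500,
#'                   tail_fraction = 0.2, pool_sizes = c(100, 100),
#'                   qtls = data.frame(chrom = "1", pos = 2e7, effect = 1,
#'                                     source = "parent1"),
#'                   seed = 7)
#' res <- bsa_scan(simulate_bsa(cfg)$counts, reps = 5, seed = 7)
#' res$qtls
#' @export
bsa_scan <- function(snps, window = 1e6, qstar = 0.05, spacing = 2e5,
                     reps = 20, alpha = 0.05, nafd_window = 3e5,
                     nafd_step = 1e4, trait = "QTL", head_fraction = 0.75,
                     merge_gap = 5e5, min_span = 5e5, min_snps = 50,
                     split_valleys = FALSE, seed = NULL) {
  snps <- validate_counts(snps)
  track <- gprime_scan(snps, window = window)
  null <- estimate_threshold(track, spacing = spacing, reps = reps,
                             qstar = qstar, seed = seed)
  jsd <- differential_scan(snps, alpha = alpha)
  nafd <- nafd_scan(snps, window = nafd_window, step = nafd_step)
  qtls <- if (is.finite(null$gprime_threshold)) {
    call_qtls(track, null, nafd_track = nafd, trait = trait,
              head_fraction = head_fraction, merge_gap = merge_gap,
              min_span = min_span, min_snps = min_snps,
              split_valleys = split_valleys)
  } else {
    NULL
  }
  structure(list(gprime = track, null = null, jsd = jsd, nafd = nafd,
                 qtls = qtls), class = "bsa_result")
}

#' @export
print.bsa_result <- function(x, ...) {
  cat("<bsa_result>\n")
  cat(sprintf("  %d SNPs on %d chromosome(s)\n", nrow(x$gprime),
              length(unique(x$gprime$chrom))))
  cat(sprintf("  null lnN(%.4f, %.4f); G' threshold %.4g (q* = %g)\n",
              x$null$mu, x$null$sigma2, x$null$gprime_threshold,
              x$null$qstar))
  cat(sprintf("  %d Bonferroni-significant differential SNP(s)\n",
              sum(x$jsd$significant)))
  if (is.null(x$qtls) || nrow(x$qtls) == 0) {
    cat("  no QTL called\n")
  } else {
    cat(sprintf("  %d QTL(s) called: %s\n", nrow(x$qtls),
                paste(x$qtls$name, collapse = ", ")))
  }
  invisible(x)
}
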
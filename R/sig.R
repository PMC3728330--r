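#' Robust trimming of G' values before null fitting
#'
#' Treats the observed G' distribution as a mixture of a log-normal null
#' (non-QTL regions) and right contaminating components (QTL regions), and
#' discards the contaminated upper tail: with `x = ln(G')`,
#' `z = Median(x) - x` over the lower half (`x <= Median(x)`), values with
#' `x - Median(x) > c * Median(z)` are dropped.
#'
#' @param values Positive G' values (at least 10).
#' @param trim_constant The constant `c` (default 5.2).
#' @return The retained (trimmed) values.
#' @export
trim_gprime <- function(values, trim_constant = 5.2) {
  if (length(values) < 10) abort("need at least 10 G' values to trim")
  if (any(values <= 0)) abort("G' values must be positive")
  x <- log(values)
  mx <- median(x)
  z <- mx - x[x <= mx]
  mz <- median(z)
  if (mz == 0) abort("degenerate G' sample: lower half has zero spread")
  values[x - mx <= trim_constant * mz]
}

#' Mode of a continuous sample
#'
#' Three estimators. `"kde"` (default) takes the argmax of a Gaussian
#' kernel density estimate on the raw scale — lowest bias on large
#' samples. `"logkde"` estimates the density of `log(x)` and maximizes
#' the back-transformed density `f(log x) / x` — slightly more biased but
#' structurally stable on small right-skewed samples (for log-normal data
#' it cannot place the mode above the median). `"hsm"` is the half-sample
#' mode (iterated shortest half), bandwidth-free and highly robust but
#' the most variable of the three.
#'
#' @param x Numeric sample (positive values required for `"logkde"`).
#' @param method `"kde"`, `"logkde"` or `"hsm"`.
#' @return Scalar mode estimate.
#' @export
sample_mode <- function(x, method = c("kde", "logkde", "hsm")) {
  method <- match.arg(method)
  if (length(x) == 0) abort("empty sample")
  if (method == "kde") {
    d <- density(x, n = 2048)
    return(d$x[which.max(d$y)])
  }
  if (method == "logkde") {
    if (any(x <= 0)) abort("logkde mode requires positive values")
    d <- density(log(x), n = 2048)
    return(exp(d$x[which.max(log(d$y) - d$x)]))
  }
  x <- sort(x)
  while (length(x) > 3) {
    n <- length(x); h <- ceiling(n / 2)
    w <- x[h:n] - x[1:(n - h + 1)]
    i <- which.min(w)  # leftmost shortest half
    x <- x[i:(i + h - 1)]
  }
  if (length(x) == 3) {
    if (x[2] - x[1] <= x[3] - x[2]) mean(x[1:2]) else mean(x[2:3])
  } else {
    mean(x)
  }
}

#' Fit the log-normal null from trimmed G' values
#'
#' Method-of-robust-moments fit: `mu = ln(Median(G'))` and
#' `sigma2 = mu - ln(Mode(G'))`, exploiting the log-normal identities
#' Median = e^mu and Mode = e^(mu - sigma2).
#'
#' @param trimmed Trimmed G' values (from [trim_gprime()]).
#' @param mode_method Mode estimator passed to [sample_mode()].
#' @return List with elements `mu` and `sigma2` (`sigma2 > 0`).
#' @export
fit_null <- function(trimmed, mode_method = c("kde", "logkde", "hsm")) {
  if (length(trimmed) == 0) abort("empty trimmed sample")
  mo <- sample_mode(trimmed, match.arg(mode_method))
  mu <- log(median(trimmed))
  sigma2 <- mu - log(mo)
  if (!is.finite(sigma2) || sigma2 <= 0) {
    abort("Mode >= Median: sample is not right-skewed; refusing to fit a log-normal null")
  }
  list(mu = mu, sigma2 = sigma2)
}

#' Upper-tail p-values under the fitted log-normal null
#'
#' @param gprime G' values.
#' @param null List with `mu`, `sigma2` (from [fit_null()]).
#' @return Upper-tail probabilities `P(lnN(mu, sigma2) > G')`.
#' @export
null_pvalues <- function(gprime, null) {
  if (null$sigma2 <= 0) abort("sigma2 must be positive")
  plnorm(gprime, meanlog = null$mu, sdlog = sqrt(null$sigma2),
         lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up selection
#'
#' Sorts the p-values ascending and returns the largest index `k` with
#' `p_(k) <= qstar * k / n`, together with `p_(k)`.
#'
#' @param pvals P-values (nonempty).
#' @param qstar Target FDR (default 0.05).
#' @return List `(k, p_k)`, or `NULL` when no index qualifies.
#' @export
bh_select <- function(pvals, qstar = 0.05) {
  if (length(pvals) == 0) abort("empty p-value vector")
  o <- sort(pvals)
  n <- length(o)
  ok <- which(o <= qstar * seq_len(n) / n)
  if (length(ok) == 0) return(NULL)
  k <- max(ok)
  list(k = k, p_k = o[k])
}

# Flag SNPs lying inside any of the exclusion intervals (1-based, closed).
in_intervals <- function(chrom, pos, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(intervals))) {
    hit <- hit | (chrom == intervals$chrom[i] &
                    pos >= intervals$start[i] & pos <= intervals$end[i])
  }
  hit
}

# Data-driven exclusion regions: SNPs whose preliminary (untrimmed-fit)
# p-value falls below `p_cut`, merged over gaps <= `gap`.
auto_exclude <- function(track, p_cut = 0.001, gap = 1e6,
                         trim_constant = 5.2, mode_method = "kde") {
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric())
  # a genome with no QTL signal can be too weakly right-skewed to fit;
  # then there is nothing to exclude
  prelim <- tryCatch(
    fit_null(trim_gprime(track$Gprime, trim_constant), mode_method),
    error = function(e) NULL)
  if (is.null(prelim)) return(empty)
  p <- null_pvalues(track$Gprime, prelim)
  hot <- p < p_cut
  if (!any(hot)) return(empty)
  track[hot, c("chrom", "pos")] |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(merge_intervals(.data$pos, .data$pos, max_gap = gap)) |>
    dplyr::ungroup()
}

#' Estimate the G' significance threshold (robust log-normal null + FDR)
#'
#' Implements the empirical thresholding procedure for a G' genome scan:
#'
#' 1. Putative QTL regions are excluded (supplied via `exclude`, or
#'    detected automatically as regions whose preliminary fit gives
#'    p < 0.001, merged over 1-Mb gaps).
#' 2. In each of `reps` repetitions, one G' value is drawn uniformly per
#'    `spacing`-bp bin (bins anchored at position 1 per chromosome) from
#'    the non-excluded regions, the draw is robustly trimmed
#'    ([trim_gprime()]) and the log-normal null fitted ([fit_null()]);
#'    the final `(mu, sigma2)` are the means over repetitions.
#' 3. Per repetition, a genome-wide one-per-bin subsample (QTL regions
#'    included) is scored with upper-tail p-values under the averaged
#'    null and the Benjamini-Hochberg rule at `qstar` applied; `p_k` is
#'    averaged over the repetitions that select any index and converted
#'    back to the G' scale by quantile inversion.
#'
#' The resulting threshold applies to all SNPs' G' genome-wide even
#' though it was estimated on the spaced subsample (closely linked G'
#' values are redundant).
#'
#' @param track G' track from [gprime_scan()].
#' @param exclude Optional tibble `chrom, start, end` (1-based, closed) of
#'   regions to exclude from null estimation; `NULL` = detect
#'   automatically.
#' @param spacing Subsampling bin width in bp (default 200,000).
#' @param reps Number of subsampling repetitions (default 20).
#' @param qstar Target FDR (default 0.05).
#' @param trim_constant Trimming constant (default 5.2).
#' @param mode_method Mode estimator (see [sample_mode()]).
#' @param seed Optional seed for the subsampling randomness.
#' @return Object of class `"bsa_null"`: a list with `mu`, `sigma2`,
#'   `qstar`, `p_threshold`, `gprime_threshold`, `trim_constant`,
#'   `spacing`, `reps`, `n_reps_selected`, `exclude`, `seed`.
#' @export
estimate_threshold <- function(track, exclude = NULL, spacing = 2e5,
                               reps = 20, qstar = 0.05, trim_constant = 5.2,
                               mode_method = c("logkde", "kde", "hsm"),
                               seed = NULL) {
  mode_method <- match.arg(mode_method)
  if (nrow(track) == 0) abort("empty G' track")
  with_seed(seed, {
    if (is.null(exclude)) {
      exclude <- auto_exclude(track, trim_constant = trim_constant,
                              mode_method = mode_method)
    }
    excluded <- in_intervals(track$chrom, track$pos, exclude)
    if (all(excluded)) abort("all bins are excluded; cannot estimate the null")
    bin <- paste(track$chrom, (track$pos - 1) %/% spacing)

    null_idx <- which(!excluded)
    mus <- rep(NA_real_, reps); s2s <- rep(NA_real_, reps)
    p_ks <- rep(NA_real_, reps)
    gw_samples <- vector("list", reps)
    for (r in seq_len(reps)) {
      pick <- vapply(split(null_idx, bin[null_idx]),
                     function(ix) if (length(ix) == 1) ix else sample(ix, 1),
                     numeric(1))
      # a repetition whose subsample is too weakly right-skewed to fit is
      # skipped; parameters average over the successful repetitions
      fit <- tryCatch(
        fit_null(trim_gprime(track$Gprime[pick], trim_constant), mode_method),
        error = function(e) NULL)
      if (!is.null(fit)) { mus[r] <- fit$mu; s2s[r] <- fit$sigma2 }
      all_idx <- seq_len(nrow(track))
      gw_samples[[r]] <- vapply(split(all_idx, bin),
                                function(ix) if (length(ix) == 1) ix else sample(ix, 1),
                                numeric(1))
    }
    n_fit <- sum(!is.na(mus))
    if (n_fit == 0) {
      # last resort: fit once on all non-excluded G' values (larger sample,
      # stabler mode)
      fit <- tryCatch(
        fit_null(trim_gprime(track$Gprime[null_idx], trim_constant),
                 mode_method),
        error = function(e) NULL)
      if (is.null(fit)) {
        # the G' distribution is not right-skewed even in aggregate: there
        # is no log-normal null to fit and no evidence of contaminating
        # (QTL) components -- report a no-signal model instead of failing
        warn(paste("G' shows no right skew (no contaminating components);",
                   "returning an infinite threshold (no significant regions)"))
        return(structure(list(
          mu = log(median(track$Gprime[null_idx])), sigma2 = NA_real_,
          qstar = qstar, p_threshold = NA_real_, gprime_threshold = Inf,
          trim_constant = trim_constant, spacing = spacing, reps = reps,
          n_reps_fit = 0L, n_reps_selected = 0L, exclude = exclude,
          seed = seed
        ), class = "bsa_null"))
      }
      warn("all subsampling repetitions were too weakly skewed; null fitted on the full non-QTL track")
      mus[1] <- fit$mu; s2s[1] <- fit$sigma2
      n_fit <- 1L
    }
    mu <- mean(mus, na.rm = TRUE); sigma2 <- mean(s2s, na.rm = TRUE)
    null <- list(mu = mu, sigma2 = sigma2)
    for (r in seq_len(reps)) {
      sel <- bh_select(null_pvalues(track$Gprime[gw_samples[[r]]], null), qstar)
      if (!is.null(sel)) p_ks[r] <- sel$p_k
    }
    n_sel <- sum(!is.na(p_ks))
    if (n_sel == 0) {
      warn("no repetition rejected any G' value: no significant regions (threshold = Inf)")
      p_threshold <- NA_real_
      gprime_threshold <- Inf
    } else {
      p_threshold <- mean(p_ks, na.rm = TRUE)
      gprime_threshold <- qlnorm(p_threshold, mu, sqrt(sigma2),
                                 lower.tail = FALSE)
    }
    structure(list(
      mu = mu, sigma2 = sigma2, qstar = qstar,
      p_threshold = p_threshold, gprime_threshold = gprime_threshold,
      trim_constant = trim_constant, spacing = spacing, reps = reps,
      n_reps_fit = n_fit, n_reps_selected = n_sel, exclude = exclude,
      seed = seed
    ), class = "bsa_null")
  })
}

#' @export
print.bsa_null <- function(x, ...) {
  cat("<bsa_null>\n")
  cat(sprintf("  null: lnN(%.4f, %.4f)  [%d reps, one G' per %g kb]\n",
              x$mu, x$sigma2, x$reps, x$spacing / 1000))
  cat(sprintf("  FDR q* = %g: p-threshold %.3g, G' threshold %.4g\n",
              x$qstar, x$p_threshold, x$gprime_threshold))
  if (!is.null(x$exclude) && nrow(x$exclude) > 0) {
    cat(sprintf("  excluded %d putative QTL region(s) from null estimation\n",
                nrow(x$exclude)))
  }
  invisible(x)
}
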
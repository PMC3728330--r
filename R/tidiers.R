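#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the fitted G' null model
#'
#' @param x A `"bsa_null"` object from [estimate_threshold()].
#' @param ... Unused.
#' @return One row per estimated quantity: `term`, `estimate`.
#' @export
tidy.bsa_null <- function(x, ...) {
  tibble::tibble(
    term = c("mu", "sigma2", "p_threshold", "gprime_threshold"),
    estimate = c(x$mu, x$sigma2, x$p_threshold, x$gprime_threshold)
  )
}

#' @rdname tidy.bsa_null
#' @return `glance()`: a one-row tibble of the model's parameters and
#'   settings.
#' @export
glance.bsa_null <- function(x, ...) {
  tibble::tibble(
    mu = x$mu, sigma2 = x$sigma2, qstar = x$qstar,
    p_threshold = x$p_threshold, gprime_threshold = x$gprime_threshold,
    trim_constant = x$trim_constant, spacing = x$spacing, reps = x$reps,
    n_reps_selected = x$n_reps_selected,
    n_excluded_regions = if (is.null(x$exclude)) 0L else nrow(x$exclude)
  )
}

#' Tidy a full scan result
#'
#' @param x A `"bsa_result"` from [bsa_scan()].
#' @param ... Unused.
#' @return `tidy()`: the QTL call table (zero rows when nothing was
#'   called); `glance()`: a one-row scan summary.
#' @export
tidy.bsa_result <- function(x, ...) {
  if (is.null(x$qtls)) {
    return(tibble::tibble(name = character(), chrom = character()))
  }
  tibble::as_tibble(x$qtls)
}

#' @rdname tidy.bsa_result
#' @export
glance.bsa_result <- function(x, ...) {
  tibble::tibble(
    n_snps = nrow(x$gprime),
    n_chromosomes = length(unique(x$gprime$chrom)),
    mu = x$null$mu, sigma2 = x$null$sigma2,
    gprime_threshold = x$null$gprime_threshold,
    n_differential_snps = sum(x$jsd$significant),
    n_qtls = if (is.null(x$qtls)) 0L else nrow(x$qtls)
  )
}
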
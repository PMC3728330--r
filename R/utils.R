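#' @importFrom rlang %||% abort warn inform
#' @importFrom stats median qlnorm plnorm rnorm runif rbinom rnbinom density
#' @importFrom utils head tail
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Merge 1-based inclusive intervals on one chromosome whose gap is <= max_gap.
merge_intervals <- function(start, end, max_gap = 0) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- numeric(0); out_e <- numeric(0)
  if (length(start) > 1) {
    for (i in 2:length(start)) {
      if (start[i] - me <= max_gap) {
        me <- max(me, end[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  tibble::tibble(start = c(out_s, ms), end = c(out_e, me))
}

# Validate a per-SNP allele-count table (the package-standard layout:
# chrom, pos, n1_ES, n2_ES, n1_ET, n2_ET). Returns the table sorted by
# (chrom, pos); errors on duplicates and negative depths.
validate_counts <- function(snps, call = rlang::caller_env()) {
  need <- c("chrom", "pos", "n1_ES", "n2_ES", "n1_ET", "n2_ET")
  miss <- setdiff(need, names(snps))
  if (length(miss) > 0) {
    abort(paste0("allele-count table lacks column(s): ", paste(miss, collapse = ", ")),
          call = call)
  }
  counts <- as.matrix(snps[, c("n1_ES", "n2_ES", "n1_ET", "n2_ET")])
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("allele depths must be finite and non-negative", call = call)
  }
  if (any(snps$pos < 1)) abort("positions must be >= 1", call = call)
  snps <- dplyr::arrange(snps, .data$chrom, .data$pos)
  if (any(duplicated(snps[, c("chrom", "pos")]))) {
    abort("duplicated (chrom, pos) records", call = call)
  }
  snps
}

#' @importFrom rlang .data
NULL
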
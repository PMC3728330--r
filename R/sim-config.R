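#' Configuration for a simulated pooled extreme-segregant experiment
#'
#' Describes a biparental F3 bulked-segregant design: a large selfed F3
#' population scored for a quantitative trait, opposite phenotypic tails
#' pooled and sequenced as two bulks ("ES" = extremely sensitive, low tail;
#' "ET" = extremely tolerant, high tail). Defaults mirror a rice-scale
#' experiment: 12 chromosomes totalling ~373 Mb, 10,800 F3 individuals,
#' ~4% tails, pools of 430 (ES) and 385 (ET), mean pool depths 70x and 89x.
#'
#' @param chrom_lengths Numeric vector of chromosome lengths in bp. Default:
#'   12 rice-like chromosomes summing to ~373 Mb.
#' @param snp_positions Optional list (one sorted numeric vector per
#'   chromosome) of SNP positions. If `NULL`, `n_snps` positions are drawn
#'   uniformly at random (unevenly spaced, as in real data) proportionally
#'   to chromosome length.
#' @param n_snps Total SNP count used when `snp_positions` is `NULL`.
#' @param qtls Tibble/data.frame with columns `chrom`, `pos`, `effect`
#'   (additive allele-substitution effect, > 0) and `source` (`"parent1"` or
#'   `"parent2"`: which parent carries the tolerance-increasing allele).
#'   `NULL` or zero rows gives a pure-noise trait (null simulations).
#' @param heritability Proportion of phenotypic variance explained jointly by
#'   the QTLs (broad-sense under the additive model). Ignored when
#'   `residual_sd` is given or no QTLs are configured.
#' @param residual_sd Residual (environmental) standard deviation; overrides
#'   `heritability` when non-`NULL`. With no QTLs, defaults to 1.
#' @param pop_size Number of F3 individuals.
#' @param tail_fraction Phenotypic tail proportion eligible for each pool.
#' @param pool_sizes Length-2 integer vector `c(ES, ET)`.
#' @param depth_means Length-2 numeric vector of mean per-SNP sequencing
#'   depths `c(ES, ET)`.
#' @param depth_dispersion Negative-binomial size parameter of the per-SNP
#'   depth distribution (smaller = more overdispersed); depths are truncated
#'   at 1.
#' @param seq_error_rate Symmetric per-read allele-flip probability.
#' @param bp_per_cm Physical-to-genetic map scale in bp per centimorgan
#'   (rice-like default: 200 kb/cM).
#' @param offspring_per_f2 F3 family size: each simulated F2 plant
#'   contributes this many selfed F3 offspring.
#' @param seed Optional integer seed making the whole simulation
#'   reproducible.
#'
#' @return A validated list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(
#'   chrom_lengths = c(3e7, 3e7), n_snps = 500, pop_size = 400,
#'   tail_fraction = 0.25, pool_sizes = c(80, 80), seed = 1
#' )
#' @export
sim_config <- function(chrom_lengths = NULL,
                       snp_positions = NULL,
                       n_snps = 20000,
                       qtls = NULL,
                       heritability = 0.5,
                       residual_sd = NULL,
                       pop_size = 10800,
                       tail_fraction = 0.04,
                       pool_sizes = c(430, 385),
                       depth_means = c(70, 89),
                       depth_dispersion = 10,
                       seq_error_rate = 0,
                       bp_per_cm = 2e5,
                       offspring_per_f2 = 1,
                       seed = NULL) {
  if (is.null(chrom_lengths)) {
    # rice-like karyotype (Mb), total ~373 Mb
    chrom_lengths <- c(43.3, 35.9, 36.4, 35.5, 29.9, 31.2,
                       29.7, 28.4, 23.0, 23.2, 29.0, 27.5) * 1e6
  }
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- as.character(seq_along(chrom_lengths))
  }
  if (any(chrom_lengths <= 0)) abort("chromosome lengths must be positive")

  if (!is.null(snp_positions)) {
    if (length(snp_positions) != length(chrom_lengths)) {
      abort("snp_positions must have one element per chromosome")
    }
    snp_positions <- purrr::map2(snp_positions, chrom_lengths, function(p, L) {
      p <- sort(unique(round(p)))
      if (length(p) > 0 && (min(p) < 1 || max(p) > L)) {
        abort("SNP positions must lie within their chromosome")
      }
      p
    })
  }
  if (!(tail_fraction > 0 && tail_fraction < 0.5)) {
    abort("tail_fraction must lie in (0, 0.5)")
  }
  pool_sizes <- as.integer(pool_sizes)
  if (length(pool_sizes) != 2 || any(pool_sizes < 1)) {
    abort("pool_sizes must be two positive counts c(ES, ET)")
  }
  tail_n <- ceiling(tail_fraction * pop_size)
  if (any(pool_sizes > tail_n)) {
    abort(sprintf("pool sizes must not exceed the tail size (%d individuals)", tail_n))
  }
  if (length(depth_means) != 2 || any(depth_means <= 0)) {
    abort("depth_means must be two positive means c(ES, ET)")
  }
  if (!is.null(qtls) && nrow(qtls) > 0) {
    qtls <- tibble::as_tibble(qtls)
    need <- c("chrom", "pos", "effect", "source")
    if (!all(need %in% names(qtls))) {
      abort("qtls needs columns chrom, pos, effect, source")
    }
    qtls$chrom <- as.character(qtls$chrom)
    if (!all(qtls$chrom %in% names(chrom_lengths))) {
      abort("QTL chromosomes must be declared in chrom_lengths")
    }
    if (any(qtls$pos < 1 | qtls$pos > chrom_lengths[qtls$chrom])) {
      abort("QTL positions must lie on their chromosome")
    }
    if (any(!is.finite(qtls$effect))) abort("QTL effects must be finite")
    if (!all(qtls$source %in% c("parent1", "parent2"))) {
      abort('QTL source must be "parent1" or "parent2"')
    }
  } else {
    qtls <- tibble::tibble(chrom = character(), pos = numeric(),
                           effect = numeric(), source = character())
  }
  if (nrow(qtls) == 0 && is.null(residual_sd)) residual_sd <- 1
  if (!is.null(residual_sd) && residual_sd < 0) abort("residual_sd must be >= 0")
  if (!is.null(heritability) &&
      (heritability <= 0 || heritability >= 1) && nrow(qtls) > 0 &&
      is.null(residual_sd)) {
    abort("heritability must lie in (0, 1)")
  }
  if (seq_error_rate < 0 || seq_error_rate >= 0.5) {
    abort("seq_error_rate must lie in [0, 0.5)")
  }

  structure(list(
    chrom_lengths = chrom_lengths,
    snp_positions = snp_positions,
    n_snps = as.integer(n_snps),
    qtls = qtls,
    heritability = heritability,
    residual_sd = residual_sd,
    pop_size = as.integer(pop_size),
    tail_fraction = tail_fraction,
    pool_sizes = stats::setNames(pool_sizes, c("ES", "ET")),
    depth_means = stats::setNames(as.numeric(depth_means), c("ES", "ET")),
    depth_dispersion = depth_dispersion,
    seq_error_rate = seq_error_rate,
    bp_per_cm = bp_per_cm,
    offspring_per_f2 = as.integer(offspring_per_f2),
    seed = seed
  ), class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [sim_config()]; `qtls` is a list of
#' mappings with keys `chrom`, `pos`, `effect`, `source`.
#'
#' @param path Path to a YAML file.
#' @param seed Optional seed overriding the file's `seed` field.
#' @return A `"sim_config"` object.
#' @export
read_sim_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$qtls)) y$qtls <- dplyr::bind_rows(y$qtls)
  if (!is.null(y$chrom_lengths)) y$chrom_lengths <- unlist(y$chrom_lengths)
  if (!is.null(seed)) y$seed <- seed
  do.call(sim_config, y)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d chromosome(s), %.1f Mb total; ~%d SNPs\n",
              length(x$chrom_lengths), sum(x$chrom_lengths) / 1e6,
              if (is.null(x$snp_positions)) x$n_snps
              else sum(lengths(x$snp_positions))))
  cat(sprintf("  F3 population %d; tails %.1f%%; pools ES=%d ET=%d\n",
              x$pop_size, 100 * x$tail_fraction,
              x$pool_sizes[["ES"]], x$pool_sizes[["ET"]]))
  cat(sprintf("  depths ES=%.0fx ET=%.0fx (NB size %.3g); %d QTL(s)\n",
              x$depth_means[["ES"]], x$depth_means[["ET"]],
              x$depth_dispersion, nrow(x$qtls)))
  invisible(x)
}
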
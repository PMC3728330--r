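#' @title Simulation of pooled extreme-segregant sequencing experiments
#' @description Internal machinery plus exported stage functions for the
#'   synthetic-data generator: F3 meiosis with crossover, additive
#'   phenotypes, truncation selection of opposite tails, and pooled
#'   short-read sequencing of the two bulks.
#' @name simdata
NULL

# Column-wise cumulative sum of an m x n numeric matrix without apply().
col_cumsum <- function(M) {
  m <- nrow(M); n <- ncol(M)
  cs <- matrix(cumsum(as.numeric(M)), m, n)
  if (n > 1) cs <- cs - rep(c(0, cs[m, -n]), each = m)
  cs
}

# Haldane recombination fractions between adjacent positions (bp).
haldane_r <- function(positions, bp_per_cm) {
  d_morgan <- diff(positions) / (bp_per_cm * 100)
  0.5 * (1 - exp(-2 * d_morgan))
}

# Simulate n meiotic phase vectors along `positions`: an m x n 0/1 matrix.
# Crossovers form a Poisson process of rate 1 per Morgan on the genetic map
# (no interference), so adjacent SNPs switch phase with the Haldane
# recombination fraction; the starting haplotype is chosen at random.
crossover_phase <- function(positions, n, bp_per_cm) {
  m <- length(positions)
  start <- runif(n) < 0.5
  if (m == 1) return(matrix(as.integer(start), 1, n))
  gpos <- positions / (bp_per_cm * 100)  # Morgans
  len <- gpos[m] - gpos[1]
  k <- stats::rpois(n, len)
  tot <- sum(k)
  inc <- integer(m * n)
  if (tot > 0) {
    xo <- runif(tot, gpos[1], gpos[m])
    gam <- rep.int(seq_len(n), k)
    iv <- pmin(findInterval(xo, gpos), m - 1L)  # switch takes effect at SNP iv+1
    inc <- tabulate((gam - 1L) * m + iv + 1L, nbins = m * n)
  }
  inc <- matrix(inc, m, n)
  inc[1, ] <- inc[1, ] + start
  col_cumsum(inc) %% 2
}

#' Simulate gametes from an F1 heterozygote
#'
#' Draws `n` independent meioses of an F1 plant (heterozygous at every
#' marker, parental haplotypes intact) along one chromosome, under a
#' Haldane map with a constant physical-to-genetic scale.
#'
#' @param positions Sorted SNP positions in bp.
#' @param n Number of gametes.
#' @param bp_per_cm Map scale (default 200 kb per cM, rice-like).
#' @return An `n` x `length(positions)` 0/1 matrix; 1 = parent-1 allele.
#' @examples
#' g <- simulate_gametes(c(1e6, 1.2e6), 1000)
#' mean(g[, 1] != g[, 2]) # ~ Haldane r for 1 cM
#' @export
simulate_gametes <- function(positions, n, bp_per_cm = 2e5) {
  if (is.unsorted(positions)) abort("positions must be sorted")
  t(crossover_phase(positions, n, bp_per_cm))
}

# Resolve SNP positions for a config; draws them (uniformly per chromosome,
# proportional to length) when not supplied. Consumes RNG when drawing.
resolve_positions <- function(cfg) {
  if (!is.null(cfg$snp_positions)) return(cfg$snp_positions)
  L <- cfg$chrom_lengths
  n_per <- round(cfg$n_snps * L / sum(L))
  purrr::map2(n_per, L, function(n, len) sort(sample.int(len, n)))
}

#' Simulate F3 genotypes from a biparental cross
#'
#' Produces an F3 population by explicit meiosis: each F2 plant is formed
#' from two recombinant F1 gametes and then selfed; crossovers follow a
#' Haldane map with a constant `bp_per_cm` scale and no interference.
#' Marginal F3 genotype frequencies at any locus approach (3/8, 1/4, 3/8)
#' for 2/1/0 copies of the parent-1 allele.
#'
#' @param cfg A [sim_config()].
#' @param use_seed Apply `cfg$seed` before simulating (disabled when called
#'   from [simulate_bsa()], which seeds once for the whole experiment).
#' @return Integer matrix (individuals x SNPs) of parent-1 allele counts
#'   in \{0, 1, 2\}, with a `"map"` attribute: a tibble of `chrom`, `pos`.
#' @export
simulate_f3_genotypes <- function(cfg, use_seed = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(if (use_seed) cfg$seed else NULL, {
    pos_list <- resolve_positions(cfg)
    chroms <- names(cfg$chrom_lengths)
    pop <- cfg$pop_size
    k <- cfg$offspring_per_f2
    n_fam <- ceiling(pop / k)
    fam <- rep(seq_len(n_fam), each = k)[seq_len(pop)]

    blocks <- vector("list", length(chroms))
    maps <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
      p <- pos_list[[ci]]
      if (length(p) == 0) {
        warn(sprintf("chromosome %s carries no SNPs; skipped", chroms[ci]))
        next
      }
      # F2 haplotypes: two independent F1 gametes per family
      h1 <- crossover_phase(p, n_fam, cfg$bp_per_cm)
      h2 <- crossover_phase(p, n_fam, cfg$bp_per_cm)
      # selfing: two gametes drawn from each F2's pair of haplotypes;
      # gamete = H1 + (H2 - H1) * phase, so genotype = 2 H1 + (H2 - H1)(ph_a + ph_b)
      ph_a <- crossover_phase(p, pop, cfg$bp_per_cm)
      ph_b <- crossover_phase(p, pop, cfg$bp_per_cm)
      H1 <- h1[, fam, drop = FALSE]
      D <- h2[, fam, drop = FALSE] - H1
      blocks[[ci]] <- t(2 * H1 + D * (ph_a + ph_b))
      maps[[ci]] <- tibble::tibble(chrom = chroms[ci], pos = p)
    }
    keep <- !vapply(blocks, is.null, logical(1))
    if (!any(keep)) abort("no chromosome carries any SNP")
    G <- do.call(cbind, blocks[keep])
    storage.mode(G) <- "integer"
    attr(G, "map") <- dplyr::bind_rows(maps[keep])
    G
  })
}

#' Assign additive phenotypes to simulated genotypes
#'
#' Phenotype model: `y = sum_q a_q * s_q * (g_q - 1) + e`, where `g_q` is
#' the parent-1 allele count at the SNP nearest each configured QTL,
#' `s_q = +1` when parent 1 carries the tolerance-increasing allele and
#' `-1` otherwise, and `e ~ Normal(0, sigma_e)`. When `cfg$residual_sd` is
#' `NULL`, `sigma_e` is set from the realized genetic variance so that the
#' QTLs jointly explain `cfg$heritability` of the phenotypic variance.
#'
#' @param genos Genotype matrix from [simulate_f3_genotypes()].
#' @param cfg The [sim_config()].
#' @return Numeric phenotype vector (one per individual) with a
#'   `"qtl_map"` attribute giving each QTL's assigned SNP column and
#'   position.
#' @export
assign_phenotypes <- function(genos, cfg) {
  map <- attr(genos, "map")
  if (is.null(map)) abort("genotype matrix lacks its SNP map attribute")
  n <- nrow(genos)
  qtls <- cfg$qtls
  gscore <- numeric(n)
  qtl_map <- tibble::tibble(chrom = character(), pos = numeric(),
                            snp_col = integer(), snp_pos = numeric(),
                            effect = numeric(), source = character())
  if (nrow(qtls) > 0) {
    for (i in seq_len(nrow(qtls))) {
      on_chrom <- which(map$chrom == qtls$chrom[i])
      if (length(on_chrom) == 0) {
        abort(sprintf("no simulated SNP on chromosome %s for QTL %d",
                      qtls$chrom[i], i))
      }
      j <- on_chrom[which.min(abs(map$pos[on_chrom] - qtls$pos[i]))]
      s <- if (qtls$source[i] == "parent1") 1 else -1
      gscore <- gscore + qtls$effect[i] * s * (genos[, j] - 1)
      qtl_map <- dplyr::bind_rows(qtl_map, tibble::tibble(
        chrom = qtls$chrom[i], pos = qtls$pos[i], snp_col = j,
        snp_pos = map$pos[j], effect = qtls$effect[i], source = qtls$source[i]
      ))
    }
  }
  sigma_e <- cfg$residual_sd
  if (is.null(sigma_e)) {
    vg <- stats::var(gscore)
    if (vg == 0) abort("zero genetic variance: set residual_sd for null traits")
    sigma_e <- sqrt(vg * (1 - cfg$heritability) / cfg$heritability)
  }
  y <- gscore + rnorm(n, 0, sigma_e)
  attr(y, "qtl_map") <- qtl_map
  y
}

#' Select the opposite extreme-phenotype pools
#'
#' ES (extremely sensitive) = the `pool_sizes["ES"]` lowest phenotypes; ET
#' (extremely tolerant) = the `pool_sizes["ET"]` highest. Ties at a cut are
#' broken by stable index order (lower index first), so selection is
#' deterministic.
#'
#' @param phenos Phenotype vector.
#' @param cfg The [sim_config()].
#' @return List with sorted integer index vectors `ES` and `ET` (disjoint).
#' @export
select_extreme_pools <- function(phenos, cfg) {
  n_es <- cfg$pool_sizes[["ES"]]; n_et <- cfg$pool_sizes[["ET"]]
  n <- length(phenos)
  if (n_es + n_et > n) abort("pool sizes overlap: tails exceed the population")
  tail_n <- ceiling(cfg$tail_fraction * n)
  if (n_es > tail_n || n_et > tail_n) {
    abort("pool sizes exceed the configured phenotypic tail")
  }
  # stable orders: ties at either cut resolve to the lower index
  list(ES = sort(order(phenos)[seq_len(n_es)]),
       ET = sort(order(-phenos)[seq_len(n_et)]))
}

# Negative-binomial depths truncated at >= 1 (zeros redrawn).
draw_depths <- function(m, mu, size) {
  d <- rnbinom(m, mu = mu, size = size)
  while (any(d == 0)) {
    z <- d == 0
    d[z] <- rnbinom(sum(z), mu = mu, size = size)
  }
  d
}

#' Sequence the two pools at every SNP
#'
#' For each SNP and pool, the true pool allele frequency is the mean
#' genotype of the pooled individuals divided by two; the sequencing depth
#' is negative-binomial around the pool's mean depth (truncated at 1); and
#' the parent-1 read count is binomial at that depth, optionally with a
#' symmetric allele-flip sequencing error.
#'
#' @param genos Genotype matrix from [simulate_f3_genotypes()].
#' @param pools List with index vectors `ES`, `ET` (from
#'   [select_extreme_pools()]).
#' @param cfg The [sim_config()].
#' @return Tibble with columns `chrom, pos, n1_ES, n2_ES, n1_ET, n2_ET`
#'   (n1 = parent-1 allele depth), sorted by position.
#' @export
sequence_pools <- function(genos, pools, cfg) {
  map <- attr(genos, "map")
  if (is.null(map)) abort("genotype matrix lacks its SNP map attribute")
  if (length(pools$ES) == 0 || length(pools$ET) == 0) abort("pools must be nonempty")
  m <- ncol(genos)
  eps <- cfg$seq_error_rate
  out <- list()
  for (pool in c("ES", "ET")) {
    f <- colMeans(genos[pools[[pool]], , drop = FALSE]) / 2
    d <- draw_depths(m, cfg$depth_means[[pool]], cfg$depth_dispersion)
    f_obs <- f * (1 - 2 * eps) + eps
    n1 <- rbinom(m, d, f_obs)
    out[[pool]] <- list(n1 = n1, n2 = d - n1)
  }
  tibble::tibble(
    chrom = map$chrom, pos = map$pos,
    n1_ES = out$ES$n1, n2_ES = out$ES$n2,
    n1_ET = out$ET$n1, n2_ET = out$ET$n2
  )
}

#' Simulate a complete pooled extreme-segregant experiment
#'
#' Runs the full generator: F3 meiosis, additive phenotypes, truncation
#' selection of the opposite tails, and pooled sequencing. All randomness
#' is governed by `cfg$seed` (same seed, bit-identical output).
#'
#' @param cfg A [sim_config()].
#' @param keep_genotypes Retain the (large) genotype matrix in the result.
#' @return An object of class `"bsa_sim"`: a list with `counts` (the
#'   per-SNP allele-depth tibble), `phenotypes`, `pools`, `qtl_truth`
#'   (configured QTLs with their assigned SNP positions), `config`, and
#'   optionally `genotypes`.
#' @examples
#' cfg <- sim_config(chrom_lengths = c(2e7), n_snps = 200, pop_size = 300,
#'                   tail_fraction = 0.2, pool_sizes = c(50, 50), seed = 1)
#' sim <- simulate_bsa(cfg)
#' sim$counts
#' @export
simulate_bsa <- function(cfg, keep_genotypes = FALSE) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    genos <- simulate_f3_genotypes(cfg, use_seed = FALSE)
    phenos <- assign_phenotypes(genos, cfg)
    pools <- select_extreme_pools(phenos, cfg)
    counts <- sequence_pools(genos, pools, cfg)
    res <- list(counts = counts, phenotypes = phenos, pools = pools,
                qtl_truth = attr(phenos, "qtl_map"), config = cfg)
    if (keep_genotypes) res$genotypes <- genos
    structure(res, class = "bsa_sim")
  })
}

#' @export
print.bsa_sim <- function(x, ...) {
  cat("<bsa_sim>\n")
  cat(sprintf("  %d SNPs on %d chromosome(s); pools ES=%d ET=%d; %d QTL(s)\n",
              nrow(x$counts), length(unique(x$counts$chrom)),
              length(x$pools$ES), length(x$pools$ET), nrow(x$qtl_truth)))
  invisible(x)
}
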
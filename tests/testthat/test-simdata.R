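test_that("F3 genotype frequencies match the selfing expectation", {
  cfg <- sim_config(chrom_lengths = c(2e7), n_snps = 40, pop_size = 8000,
                    tail_fraction = 0.1, pool_sizes = c(100, 100), seed = 101)
  g <- simulate_f3_genotypes(cfg)
  freqs <- tabulate(as.vector(g) + 1L, 3) / length(g)  # counts of 0,1,2
  # F2 (1/4, 1/2, 1/4) selfed once -> (3/8, 1/4, 3/8)
  expect_equal(freqs, c(3 / 8, 1 / 4, 3 / 8), tolerance = 0.03)
  # no selection yet: parent-1 allele frequency ~ 0.5 at every locus
  expect_equal(mean(colMeans(g) / 2), 0.5, tolerance = 0.02)
})

test_that("recombinant gamete fraction follows the Haldane map at 200 kb", {
  set.seed(42)
  gam <- simulate_gametes(c(1e6, 1.2e6), 2e5)  # 200 kb = 1 cM
  observed <- mean(gam[, 1] != gam[, 2])
  expected <- 0.5 * (1 - exp(-2 * 0.01))  # ~0.0099
  expect_equal(observed, expected, tolerance = 0.05)
  expect_equal(observed, 0.01, tolerance = 0.08)
})

test_that("phenotype model decomposes variance as configured", {
  base <- list(chrom_lengths = c(2e7), n_snps = 60, pop_size = 4000,
               tail_fraction = 0.1, pool_sizes = c(100, 100))
  # pure-noise trait: variance ~ residual_sd^2
  cfg0 <- do.call(sim_config, c(base, list(residual_sd = 1, seed = 7)))
  g0 <- simulate_f3_genotypes(cfg0)
  y0 <- assign_phenotypes(g0, cfg0)
  expect_equal(stats::var(y0), 1, tolerance = 0.1)
  # one QTL at h2 = 0.5: regression R2 on the QTL genotype ~ 0.5
  qt <- data.frame(chrom = "1", pos = 1e7, effect = 1, source = "parent1")
  cfg1 <- do.call(sim_config, c(base, list(qtls = qt, heritability = 0.5,
                                           seed = 8)))
  g1 <- simulate_f3_genotypes(cfg1)
  y1 <- assign_phenotypes(g1, cfg1)
  j <- attr(y1, "qtl_map")$snp_col
  r2 <- summary(stats::lm(y1 ~ g1[, j]))$r.squared
  expect_equal(r2, 0.5, tolerance = 0.05)
  # flipping the source parent flips the phenotype-genotype correlation
  qt2 <- transform(qt, source = "parent2")
  cfg2 <- do.call(sim_config, c(base, list(qtls = qt2, heritability = 0.5,
                                           seed = 8)))
  y2 <- assign_phenotypes(g1, cfg2)
  expect_lt(stats::cor(y2, g1[, j]), 0)
  expect_gt(stats::cor(y1, g1[, j]), 0)
})

test_that("extreme-pool selection takes the opposite tails deterministically", {
  cfg <- sim_config(chrom_lengths = c(1e6), n_snps = 5, pop_size = 5,
                    tail_fraction = 0.2, pool_sizes = c(1, 1), seed = 1)
  pools <- select_extreme_pools(c(1, 2, 3, 4, 5), cfg)
  expect_equal(pools$ES, 1L)
  expect_equal(pools$ET, 5L)
  # ties at the cut break by stable index order
  pools_tie <- select_extreme_pools(c(2, 1, 1, 5, 5), cfg)
  expect_equal(pools_tie$ES, 2L)
  expect_equal(pools_tie$ET, 4L)
  # overlapping tails error out
  cfg_big <- sim_config(chrom_lengths = c(1e6), n_snps = 5, pop_size = 5,
                        tail_fraction = 0.45, pool_sizes = c(2, 2), seed = 1)
  expect_error(select_extreme_pools(c(1, 2, 3), cfg_big), "overlap")
})

test_that("pool sequencing reflects pool frequencies and the depth model", {
  cfg <- sim_config(chrom_lengths = c(1e7), n_snps = 200, pop_size = 100,
                    tail_fraction = 0.3, pool_sizes = c(20, 20),
                    depth_means = c(100, 100), residual_sd = 1, seed = 5)
  g <- simulate_f3_genotypes(cfg)
  # force monomorphic-parent-2 pool: f = 0 everywhere -> zero parent-1 reads
  g0 <- g; g0[, ] <- 0L; attr(g0, "map") <- attr(g, "map")
  counts0 <- sequence_pools(g0, list(ES = 1:20, ET = 21:40), cfg)
  expect_true(all(counts0$n1_ES == 0) && all(counts0$n1_ET == 0))
  expect_true(all(counts0$n2_ES >= 1))  # depths truncated at 1
  # f = 0.5 at depth ~100: mean parent-1 count ~ 50
  g1 <- g; g1[, ] <- 1L; attr(g1, "map") <- attr(g, "map")
  counts1 <- sequence_pools(g1, list(ES = 1:20, ET = 21:40), cfg)
  expect_equal(mean(counts1$n1_ES), 50, tolerance = 0.1)
})

test_that("same seed gives a bit-identical experiment", {
  cfg <- sim_config(chrom_lengths = c(5e6, 5e6), n_snps = 120, pop_size = 300,
                    tail_fraction = 0.25, pool_sizes = c(60, 50), seed = 77)
  expect_identical(simulate_bsa(cfg)$counts, simulate_bsa(cfg)$counts)
})

test_that("a chromosome without SNPs is skipped with a warning", {
  cfg <- sim_config(chrom_lengths = c(1e6, 1e6),
                    snp_positions = list(c(1e5, 2e5, 3e5), numeric(0)),
                    pop_size = 50, tail_fraction = 0.3, pool_sizes = c(10, 10),
                    seed = 2)
  expect_warning(g <- simulate_f3_genotypes(cfg), "no SNPs")
  expect_equal(ncol(g), 3)
})

test_that("selection shifts the QTL allele toward the configured parent", {
  # sign of (f_ET - f_ES) at the QTL matches the tolerance-allele source
  # in nearly all seeded replicates
  hits <- vapply(1:100, function(s) {
    cfg <- sim_config(chrom_lengths = c(2e7), n_snps = 50, pop_size = 400,
                      tail_fraction = 0.2, pool_sizes = c(80, 80),
                      qtls = data.frame(chrom = "1", pos = 1e7, effect = 1,
                                        source = "parent1"),
                      heritability = 0.35, seed = 1000 + s)
    sim <- simulate_bsa(cfg)
    j <- which.min(abs(sim$counts$pos - sim$qtl_truth$snp_pos))
    row <- sim$counts[j, ]
    f_es <- row$n1_ES / (row$n1_ES + row$n2_ES)
    f_et <- row$n1_ET / (row$n1_ET + row$n2_ET)
    (f_et - f_es) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(tail_fraction = 0.6), "tail_fraction")
  expect_error(sim_config(pop_size = 100, pool_sizes = c(50, 50)), "tail")
  expect_error(
    sim_config(chrom_lengths = c(1e6),
               qtls = data.frame(chrom = "2", pos = 1, effect = 1,
                                 source = "parent1")),
    "declared")
  expect_error(
    sim_config(chrom_lengths = c(1e6), n_snps = 10, pop_size = 1000,
               pool_sizes = c(40, 40),
               qtls = data.frame(chrom = "1", pos = 10, effect = Inf,
                                 source = "parent1")),
    "finite")
})

test_that("a YAML configuration round-trips through read_sim_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "chrom_lengths: [10000000, 20000000]",
    "n_snps: 100",
    "pop_size: 200",
    "tail_fraction: 0.3",
    "pool_sizes: [40, 40]",
    "qtls:",
    "  - {chrom: '2', pos: 5000000, effect: 1.0, source: parent2}",
    "seed: 4"
  ), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$pool_sizes, c(ES = 40L, ET = 40L))
  expect_equal(cfg$qtls$source, "parent2")
  cfg2 <- read_sim_config(path, seed = 99)
  expect_equal(cfg2$seed, 99)
})
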
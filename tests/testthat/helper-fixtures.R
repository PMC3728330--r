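# Shared fixtures and independent oracles used across the suite.

# One-row (or n-row) allele-count table from n1..n4 vectors
# (n1/n2 = parent-1/parent-2 depth in ES; n3/n4 the same in ET).
make_counts <- function(n1, n2, n3, n4, chrom = "1", pos = NULL) {
  n <- length(n1)
  tibble::tibble(
    chrom = rep_len(chrom, n),
    pos = if (is.null(pos)) seq_len(n) * 1000 else pos,
    n1_ES = n1, n2_ES = n2, n1_ET = n3, n2_ET = n4
  )
}

# Random strictly-positive-margin 2x2 tables for identity/property tests.
random_tables <- function(n, max_depth = 200) {
  tibble::tibble(
    chrom = "1", pos = seq_len(n) * 100,
    n1_ES = sample.int(max_depth, n, replace = TRUE),
    n2_ES = sample.int(max_depth, n, replace = TRUE),
    n1_ET = sample.int(max_depth, n, replace = TRUE),
    n2_ET = sample.int(max_depth, n, replace = TRUE)
  )
}

# Exhaustive maximum-sum-substring oracle for the Mott trimmer: enumerates
# every (i, j), using the same prefix sums and the same leftmost-longest
# tie rule, so any disagreement is a defect of the linear-scan algorithm.
mott_oracle <- function(bases, quals, limit = 0.05) {
  b <- strsplit(toupper(bases), "")[[1]]
  p <- 10^(-quals / 10)
  p[b == "N"] <- 0.75
  s <- limit - p
  n <- length(s)
  if (n == 0) return(integer(0))
  P <- c(0, cumsum(s))
  tol <- 1e-12
  best <- -Inf; bi <- 0L; bj <- -1L
  for (i in seq_len(n)) {
    for (j in i:n) {
      v <- P[j + 1] - P[i]
      if (v > best + tol ||
          (v >= best - tol && (i < bi || (i == bi && j > bj)))) {
        if (v > best + tol) best <- v
        bi <- i; bj <- j
      }
    }
  }
  if (best <= tol) return(integer(0))
  c(bi, bj)
}

# Direct step-up oracle for BH selection: checks every index.
bh_oracle <- function(p, qstar) {
  o <- sort(p)
  n <- length(o)
  k <- 0L
  for (i in seq_len(n)) if (o[i] <= qstar * i / n) k <- i
  if (k == 0L) NULL else list(k = k, p_k = o[k])
}

# Random read with occasional N bases.
random_read <- function(len, n_prob = 0.05) {
  bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  bases[runif(len) < n_prob] <- "N"
  quals <- sample(0:41, len, replace = TRUE)
  list(bases = paste(bases, collapse = ""), quals = quals)
}
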
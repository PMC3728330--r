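#' Convert a PHRED quality score to an error probability
#'
#' @param q Integer PHRED score(s), >= 0.
#' @return `10^(-q/10)`, in (0, 1].
#' @examples
#' phred_to_error(c(0, 10, 20, 30))
#' @export
phred_to_error <- function(q) {
  if (any(q < 0)) abort("PHRED scores must be >= 0")
  10^(-q / 10)
}

# Per-base Mott scores: limit minus error probability; N bases are treated
# as uninformative (p = 0.75) regardless of their stated quality, so they
# can never rescue a segment.
mott_scores <- function(bases, quals, limit) {
  p <- phred_to_error(quals)
  p[bases == "N"] <- 0.75
  limit - p
}

parse_qual <- function(qual) {
  if (is.character(qual)) {
    q <- utf8ToInt(qual) - 33L
    if (any(q < 0)) abort("quality string is not Sanger/PHRED+33 encoded")
    q
  } else {
    as.integer(qual)
  }
}

#' Modified-Mott quality trimming of one read
#'
#' Scores each base as `limit - p_i` (`p_i` = PHRED error probability,
#' 0.75 for `N` bases) and retains the contiguous segment with the maximum
#' score sum. The empty segment is returned when every score is negative.
#' Ties among equal-sum segments resolve to the leftmost, then longest,
#' segment, so trimming is deterministic; trimming a trimmed read returns
#' it unchanged.
#'
#' @param bases Read sequence: a single string over `A,C,G,T,N`.
#' @param qual Per-base qualities: an integer vector of PHRED scores or a
#'   Sanger/PHRED+33-encoded string of the same length.
#' @param limit Error-probability limit (default 0.05).
#' @return Integer vector `c(start, end)` of the retained 1-based interval,
#'   or `integer(0)` for an empty result.
#' @examples
#' mott_trim("ACGTA", rep(30L, 5))        # full read
#' mott_trim("ACGTA", rep(2L, 5))         # empty
#' @export
mott_trim <- function(bases, qual, limit = 0.05) {
  b <- strsplit(toupper(bases), "")[[1]]
  q <- parse_qual(qual)
  if (length(b) != length(q)) abort("bases and qualities differ in length")
  if (length(b) == 0) return(integer(0))
  s <- mott_scores(b, q, limit)
  # prefix-scan maximum-sum segment; ties resolve leftmost then longest
  P <- c(0, cumsum(s))
  tol <- 1e-12
  best_sum <- -Inf; best_start <- 0L; best_end <- -1L
  min_p <- P[1]; min_start <- 1L
  for (j in seq_along(s)) {
    if (P[j] < min_p) { min_p <- P[j]; min_start <- j }  # earliest prefix min
    cand <- P[j + 1] - min_p
    if (cand > best_sum + tol) {
      best_sum <- cand; best_start <- min_start; best_end <- j
    } else if (cand >= best_sum - tol &&
               (min_start < best_start ||
                (min_start == best_start && j > best_end))) {
      best_start <- min_start; best_end <- j
    }
  }
  if (best_sum <= tol) return(integer(0))
  c(best_start, best_end)
}

#' Post-trimming read filter
#'
#' Keeps a (trimmed) read iff it is at least `min_len` bases long and
#' contains at most `max_ambiguous` ambiguous (`N`) bases.
#'
#' @param bases Read sequence string (already trimmed).
#' @param max_ambiguous Maximum `N` count (default 2).
#' @param min_len Minimum retained length in bp (default 25).
#' @return Logical: keep (`TRUE`) or discard.
#' @export
filter_read <- function(bases, max_ambiguous = 2, min_len = 25) {
  b <- toupper(bases)
  nchar(b) >= min_len &
    vapply(strsplit(b, ""), function(x) sum(x == "N"), integer(1)) <= max_ambiguous
}

#' Trim and filter a FASTQ file
#'
#' Applies [mott_trim()] and [filter_read()] to every read of a FASTQ file
#' (plain or gzipped; Sanger/PHRED+33 qualities only) and writes the
#' retained reads. Requires the Biostrings package.
#'
#' @param infile,outfile Input and output FASTQ paths (`outfile = NULL`
#'   skips writing).
#' @param limit Mott error-probability limit.
#' @param max_ambiguous,min_len Passed to [filter_read()].
#' @return A one-row tibble: `raw` and `kept` read counts, `kept_pct`, and
#'   `mean_length` of the kept reads.
#' @export
trim_fastq <- function(infile, outfile = NULL, limit = 0.05,
                       max_ambiguous = 2, min_len = 25) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("trim_fastq() requires the Biostrings package")
  }
  reads <- Biostrings::readDNAStringSet(infile, format = "fastq",
                                        with.qualities = TRUE)
  quals <- as.character(S4Vectors::mcols(reads)$qualities)
  seqs <- as.character(reads)
  ids <- names(reads)
  n <- length(seqs)
  out_seq <- character(n); out_qual <- character(n); keep <- logical(n)
  for (i in seq_len(n)) {
    iv <- mott_trim(seqs[i], quals[i], limit)
    if (length(iv) == 0) next
    s <- substr(seqs[i], iv[1], iv[2])
    if (!filter_read(s, max_ambiguous, min_len)) next
    keep[i] <- TRUE
    out_seq[i] <- s
    out_qual[i] <- substr(quals[i], iv[1], iv[2])
  }
  kept <- sum(keep)
  if (!is.null(outfile)) {
    x <- Biostrings::DNAStringSet(out_seq[keep])
    names(x) <- ids[keep]
    Biostrings::writeXStringSet(
      x, outfile, format = "fastq",
      qualities = Biostrings::BStringSet(out_qual[keep])
    )
  }
  tibble::tibble(
    raw = n, kept = kept,
    kept_pct = if (n > 0) 100 * kept / n else NA_real_,
    mean_length = if (kept > 0) mean(nchar(out_seq[keep])) else NA_real_
  )
}
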
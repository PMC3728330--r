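#' Delineate G' peak intervals above the significance threshold
#'
#' Finds, per chromosome, maximal runs of consecutive SNPs with
#' `G' >= threshold`; runs separated by less than `merge_gap` bp are
#' merged into one interval. Intervals spanning less than `min_span` bp or
#' containing fewer than `min_snps` above-threshold SNPs are classified as
#' `"minor"` peaks (reported, but not called as QTLs); the rest are
#' `"major"`.
#'
#' @param track G' track from [gprime_scan()].
#' @param threshold Finite G' significance threshold (or a `"bsa_null"`
#'   object, whose `gprime_threshold` is used).
#' @param merge_gap Runs closer than this are merged (default 500 kb).
#' @param min_span Minimum bp extent of a major peak (default 500 kb).
#' @param min_snps Minimum above-threshold SNP count of a major peak
#'   (default 50).
#' @return Tibble `chrom, start, end, n_snps, span, type` (positions of
#'   the bounding SNPs, 1-based inclusive).
#' @export
full_intervals <- function(track, threshold, merge_gap = 5e5,
                           min_span = 5e5, min_snps = 50) {
  if (inherits(threshold, "bsa_null")) threshold <- threshold$gprime_threshold
  if (!is.finite(threshold)) abort("threshold must be finite")
  if (nrow(track) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_snps = integer(),
                          span = numeric(), type = character()))
  }
  out <- list()
  for (ch in unique(track$chrom)) {
    sub <- track[track$chrom == ch, ]
    above <- sub$Gprime >= threshold
    if (!any(above)) next
    r <- rle(above)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    runs <- which(r$values)
    iv <- merge_intervals(sub$pos[starts_i[runs]], sub$pos[ends_i[runs]],
                          max_gap = merge_gap - 1)
    iv$chrom <- ch
    iv$n_snps <- vapply(seq_len(nrow(iv)), function(i) {
      sum(above & sub$pos >= iv$start[i] & sub$pos <= iv$end[i])
    }, integer(1))
    out[[ch]] <- iv
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_snps = integer(),
                          span = numeric(), type = character()))
  }
  res <- dplyr::bind_rows(out)
  res$span <- res$end - res$start
  res$type <- ifelse(res$span >= min_span & res$n_snps >= min_snps,
                     "major", "minor")
  res[, c("chrom", "start", "end", "n_snps", "span", "type")]
}

#' Summit of a G' peak
#'
#' The SNP with maximal G' inside an interval; ties resolve to the
#' leftmost SNP.
#'
#' @param track G' track.
#' @param interval List or one-row data frame with `chrom`, `start`,
#'   `end`.
#' @return List `(pos, gprime)`.
#' @export
summit <- function(track, interval) {
  sub <- track[track$chrom == interval$chrom &
                 track$pos >= interval$start & track$pos <= interval$end, ]
  if (nrow(sub) == 0) abort("interval contains no SNP")
  i <- which.max(sub$Gprime)  # first maximum = leftmost tie
  list(pos = sub$pos[i], gprime = sub$Gprime[i])
}

#' Most-probable ("head") interval of a G' peak
#'
#' Operationalizes the visual "shoulder" of a major G' peak: the maximal
#' contiguous region around the summit where
#' `G' >= threshold + head_fraction * (summit G' - threshold)`.
#' `head_fraction = 0` reduces to the full run at the threshold; larger
#' values isolate the top of the peak. Always contained in the full
#' interval.
#'
#' @inheritParams summit
#' @param threshold G' significance threshold.
#' @param head_fraction Fraction of the summit rise defining the shoulder
#'   level (default 0.75).
#' @return List `(start, end)` of bounding SNP positions.
#' @export
probable_interval <- function(track, interval, threshold,
                              head_fraction = 0.75) {
  sub <- track[track$chrom == interval$chrom &
                 track$pos >= interval$start & track$pos <= interval$end, ]
  if (nrow(sub) == 0) abort("interval contains no SNP")
  s <- which.max(sub$Gprime)
  level <- threshold + head_fraction * (sub$Gprime[s] - threshold)
  ok <- sub$Gprime >= level - 1e-12
  lo <- s; hi <- s
  while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  while (hi < nrow(sub) && ok[hi + 1]) hi <- hi + 1
  list(start = sub$pos[lo], end = sub$pos[hi])
}

#' Resistant-allele source from the NAFD profile
#'
#' Looks up the NAFD window whose centre lies nearest the summit: a
#' positive value means the parent-1 (reference) allele increases the
#' selected trait, a negative value the parent-2 allele; exactly zero or
#' no NAFD coverage yields `"undetermined"`.
#'
#' @param nafd_track Windowed profile from [nafd_scan()].
#' @param chrom,summit_pos Chromosome and summit position of the call.
#' @return List `(source, nafd)` with source one of `"parent1"`,
#'   `"parent2"`, `"undetermined"`.
#' @export
allele_source <- function(nafd_track, chrom, summit_pos) {
  sub <- nafd_track[nafd_track$chrom == chrom & !is.na(nafd_track$nafd), ]
  if (nrow(sub) == 0) return(list(source = "undetermined", nafd = NA_real_))
  centers <- (sub$start + sub$end) / 2
  v <- sub$nafd[which.min(abs(centers - summit_pos))]
  src <- if (v > 0) "parent1" else if (v < 0) "parent2" else "undetermined"
  list(source = src, nafd = v)
}

# Split a major interval at an internal valley dipping below the head
# level, provided both sides retain a peak >= threshold. Returns a list of
# one (no split) or two interval lists.
split_valley <- function(sub, interval, threshold, head_fraction) {
  s <- which.max(sub$Gprime)
  level <- threshold + head_fraction * (sub$Gprime[s] - threshold)
  n <- nrow(sub)
  if (n < 3) return(list(interval))
  best <- NULL
  for (m in 2:(n - 1)) {
    if (sub$Gprime[m] < level &&
        max(sub$Gprime[1:(m - 1)]) >= threshold &&
        max(sub$Gprime[(m + 1):n]) >= threshold) {
      if (is.null(best) || sub$Gprime[m] < sub$Gprime[best]) best <- m
    }
  }
  if (is.null(best)) return(list(interval))
  vpos <- sub$pos[best]
  list(
    list(chrom = interval$chrom, start = interval$start, end = vpos),
    list(chrom = interval$chrom, start = vpos, end = interval$end)
  )
}

#' Call QTLs from a thresholded G' track
#'
#' End-stage of the scan: delineates major G' peaks
#' ([full_intervals()]), finds each peak's summit, its most-probable
#' "head" interval ([probable_interval()]), and — when an NAFD profile is
#' supplied — the parent contributing the trait-increasing allele at the
#' summit. Calls are named `q<trait>-<chrom>`, with `a`, `b`, ... suffixes
#' when one chromosome yields several calls.
#'
#' @param track G' track from [gprime_scan()].
#' @param threshold G' threshold or a `"bsa_null"` object.
#' @param nafd_track Optional profile from [nafd_scan()].
#' @param trait Trait tag used in QTL names (default `"QTL"`, giving
#'   names like `qQTL-3`).
#' @param head_fraction Shoulder rule for the probable interval.
#' @param merge_gap,min_span,min_snps Passed to [full_intervals()].
#' @param split_valleys Also split major peaks at internal valleys that
#'   dip below the head level between two above-threshold shoulders
#'   (off by default; such splits are speculative).
#' @return A tibble of class `"bsa_qtl"` with one row per called QTL:
#'   `name, chrom, full_start, full_end, probable_start, probable_end,
#'   summit_pos, summit_gprime, summit_nafd, source_parent`; minor peaks
#'   are attached as attribute `"minor_peaks"`.
#' @export
call_qtls <- function(track, threshold, nafd_track = NULL, trait = "QTL",
                      head_fraction = 0.75, merge_gap = 5e5, min_span = 5e5,
                      min_snps = 50, split_valleys = FALSE) {
  if (inherits(threshold, "bsa_null")) threshold <- threshold$gprime_threshold
  iv <- full_intervals(track, threshold, merge_gap, min_span, min_snps)
  minors <- iv[iv$type == "minor", ]
  majors <- iv[iv$type == "major", ]
  rows <- list()
  for (i in seq_len(nrow(majors))) {
    base <- list(chrom = majors$chrom[i], start = majors$start[i],
                 end = majors$end[i])
    sub <- track[track$chrom == base$chrom & track$pos >= base$start &
                   track$pos <= base$end, ]
    parts <- if (split_valleys) {
      split_valley(sub, base, threshold, head_fraction)
    } else {
      list(base)
    }
    for (p in parts) {
      s <- summit(track, p)
      pr <- probable_interval(track, p, threshold, head_fraction)
      src <- if (is.null(nafd_track)) {
        list(source = "undetermined", nafd = NA_real_)
      } else {
        allele_source(nafd_track, p$chrom, s$pos)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = p$chrom, full_start = p$start, full_end = p$end,
        probable_start = pr$start, probable_end = pr$end,
        summit_pos = s$pos, summit_gprime = s$gprime,
        summit_nafd = src$nafd, source_parent = src$source
      )
    }
  }
  calls <- if (length(rows) > 0) dplyr::bind_rows(rows) else tibble::tibble(
    chrom = character(), full_start = numeric(), full_end = numeric(),
    probable_start = numeric(), probable_end = numeric(),
    summit_pos = numeric(), summit_gprime = numeric(),
    summit_nafd = numeric(), source_parent = character()
  )
  calls <- dplyr::arrange(calls, .data$chrom, .data$full_start)
  calls <- calls |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      name = paste0("q", trait, "-", .data$chrom,
                    if (dplyr::n() > 1) letters[dplyr::row_number()] else "")
    ) |>
    dplyr::ungroup() |>
    dplyr::relocate("name")
  attr(calls, "minor_peaks") <- minors
  attr(calls, "threshold") <- threshold
  class(calls) <- c("bsa_qtl", class(calls))
  calls
}

#' Write (and read back) a QTL call report
#'
#' Exports the calls as a TSV table, a JSON document, and/or BED tracks of
#' the full and most-probable intervals (BED uses 0-based half-open
#' coordinates).
#'
#' @param calls `"bsa_qtl"` tibble from [call_qtls()].
#' @param tsv,json,bed_full,bed_probable Optional output paths.
#' @return `calls`, invisibly.
#' @export
write_qtl_report <- function(calls, tsv = NULL, json = NULL,
                             bed_full = NULL, bed_probable = NULL) {
  tbl <- tibble::as_tibble(calls)
  if (!is.null(tsv)) readr::write_tsv(tbl, tsv)
  if (!is.null(json)) {
    jsonlite::write_json(tbl, json, digits = NA, na = "null")
  }
  write_bed <- function(path, s, e) {
    readr::write_tsv(
      tibble::tibble(chrom = tbl$chrom, start = as.integer(s - 1),
                     end = as.integer(e), name = tbl$name),
      path, col_names = FALSE)
  }
  if (!is.null(bed_full)) write_bed(bed_full, tbl$full_start, tbl$full_end)
  if (!is.null(bed_probable)) {
    write_bed(bed_probable, tbl$probable_start, tbl$probable_end)
  }
  invisible(calls)
}

#' @rdname write_qtl_report
#' @param path JSON report path.
#' @export
read_qtl_report <- function(path) {
  tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
}
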
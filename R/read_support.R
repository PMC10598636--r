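#' Ends-free pairwise alignment
#'
#' Overlap alignment with linear gap costs: the prefix and suffix of either
#' sequence may dangle unaligned at no cost. Used to place long reads on
#' conformation templates and available directly for diagnostics. An
#' optional diagonal band (centred on `band_offset`) restricts the dynamic
#' programme for speed.
#'
#' @param pattern,subject DNA strings.
#' @param match,mismatch,gap Scores (gap per base, linear).
#' @param band_offset,band_width Band centre diagonal (subject position minus
#'   pattern position) and half-width; `band_width = 0` disables banding.
#' @return List with `score` and 1-based `p_start`, `p_end`, `s_start`,
#'   `s_end` of the aligned blocks.
#' @export
align_overlap <- function(pattern, subject, match = 1L, mismatch = -1L,
                          gap = -1L, band_offset = 0L, band_width = 0L) {
  align_overlap_cpp(toupper(pattern), toupper(subject),
                    as.integer(match), as.integer(mismatch), as.integer(gap),
                    as.integer(band_offset), as.integer(band_width),
                    band_width > 0L)
}

#' Classify long reads against the four conformations of a repeat
#'
#' Each read (and its reverse complement) is aligned ends-free to the four
#' conformation templates. A read is *usable* (informative) when its best
#' alignment covers the entire repeat copy plus at least `min_anchor` bases
#' of unique flank on both sides; it is assigned to the conformation with
#' the highest score when that score beats the runner-up conformation by at
#' least `min_margin`, and is `ambiguous` otherwise (ties are always
#' ambiguous). Reads shorter than repeat + 2 x `min_anchor` are rejected
#' with reason `too_short` without alignment.
#'
#' @param reads Character vector of read sequences (or a data.frame with a
#'   `seq` column as produced by [simulate_reads()]).
#' @param cs A `ConformationSet` from [build_local_conformations()].
#' @param min_anchor Minimum flank coverage beyond the repeat, bp.
#' @param min_margin Minimum score margin over the runner-up conformation.
#' @param match,mismatch,gap Alignment scores.
#' @param band_width DP band half-width around a seeded diagonal; 0 for full
#'   dynamic programming.
#' @return data.frame, one row per read: `read_id`, `best` (`c1`..`c4`,
#'   `ambiguous`, or `NA` when unusable), `strand`, `score_best`,
#'   `score_second`, `anchor_left`, `anchor_right`, `usable`, `reason`.
#' @export
classify_reads <- function(reads, cs, min_anchor = 100L, min_margin = 20L,
                           match = 1L, mismatch = -1L, gap = -1L,
                           band_width = 100L) {
  stopifnot(inherits(cs, "ConformationSet"))
  if (is.data.frame(reads)) {
    ids <- if ("read_id" %in% names(reads)) reads$read_id
           else sprintf("read%04d", seq_len(nrow(reads)))
    seqs <- reads$seq
  } else {
    seqs <- unname(reads)
    ids <- if (!is.null(names(reads))) names(reads)
           else sprintf("read%04d", seq_along(seqs))
  }
  res <- classify_reads_cpp(toupper(seqs),
                            c(cs$c1, cs$c2, cs$c3, cs$c4),
                            as.integer(cs$rep_start), as.integer(cs$rep_end),
                            as.integer(min_anchor), as.integer(min_margin),
                            as.integer(match), as.integer(mismatch),
                            as.integer(gap), as.integer(band_width), 15L)
  cbind(data.frame(read_id = ids, stringsAsFactors = FALSE), res)
}

#' @rdname classify_reads
#' @param read A single read sequence.
#' @export
classify_read <- function(read, cs, min_anchor = 100L, min_margin = 20L, ...) {
  classify_reads(read, cs, min_anchor = min_anchor,
                 min_margin = min_margin, ...)
}

#' Recombination frequency from conformation-assigned read counts
#'
#' RF is the fraction of informative spanning reads supporting the
#' recombinant (minor) conformations: `(n3 + n4) / (n1 + n2 + n3 + n4)`.
#'
#' @param n1,n2,n3,n4 Spanning-read counts for conformations c1..c4.
#' @return Fraction in `[0, 1]`.
#' @export
recombination_frequency <- function(n1, n2, n3, n4) {
  tot <- n1 + n2 + n3 + n4
  if (tot <= 0) stop("no informative reads")
  (n3 + n4) / tot
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials (> 0).
#' @param conf Confidence level.
#' @return Numeric vector `c(lo, hi)`.
#' @export
wilson_interval <- function(k, n, conf = 0.95) {
  if (n <= 0) stop("n must be positive")
  stopifnot(k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

#' Is the minor (recombinant) conformation supported by reads?
#'
#' The presence criterion: a conformation is considered present when at
#' least `min_reads` spanning reads map to it.
#'
#' @param report A recombination report (see [recombination_report()]) or a
#'   list with counts `n3`, `n4`.
#' @param min_reads Minimum spanning reads on either minor conformation.
#' @return Logical.
#' @export
call_supported <- function(report, min_reads = 1L) {
  report$n3 >= min_reads || report$n4 >= min_reads
}

#' Summarise read assignments into a recombination report
#'
#' @param assignments data.frame from [classify_reads()].
#' @param hsp_id Repeat identifier for the report.
#' @param conf Confidence level for the Wilson interval on RF.
#' @param min_reads Support threshold passed to [call_supported()].
#' @return One-row data.frame: `hsp_id`, `n1`..`n4`, `n_ambiguous`,
#'   `n_unusable`, `rf`, `ci_low`, `ci_high`, `supported_minor`. `rf` is
#'   `NA` when no read is informative.
#' @export
recombination_report <- function(assignments, hsp_id = "R1", conf = 0.95,
                                 min_reads = 1L) {
  a <- assignments
  counts <- vapply(c("c1", "c2", "c3", "c4"), function(lbl) {
    sum(a$usable & !is.na(a$best) & a$best == lbl)
  }, 0L)
  n_amb <- sum(a$usable & !is.na(a$best) & a$best == "ambiguous")
  n_un <- sum(!a$usable)
  tot <- sum(counts)
  if (tot > 0) {
    rf <- recombination_frequency(counts[1], counts[2], counts[3], counts[4])
    ci <- wilson_interval(counts[3] + counts[4], tot, conf)
  } else {
    rf <- NA_real_
    ci <- c(lo = NA_real_, hi = NA_real_)
  }
  rep <- data.frame(hsp_id = hsp_id, n1 = counts[1], n2 = counts[2],
                    n3 = counts[3], n4 = counts[4], n_ambiguous = n_amb,
                    n_unusable = n_un, rf = rf, ci_low = ci[["lo"]],
                    ci_high = ci[["hi"]], row.names = NULL,
                    stringsAsFactors = FALSE)
  rep$supported_minor <- call_supported(rep, min_reads)
  rep
}
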
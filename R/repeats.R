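#' Alignment parameters for homology searches
#'
#' Defaults are the classic `blastn` (non-megablast) nucleotide scoring:
#' match +2, mismatch -3, gap open 5, gap extend 2, word size 11, with an
#' E-value cutoff of 1e-5. `karlin_k` and `lambda` are the Karlin-Altschul
#' statistics for this scoring system, used by [expect_value()].
#'
#' @param match,mismatch,gap_open,gap_extend,word_size Scoring parameters.
#' @param min_evalue E-value cutoff for reported hits.
#' @param karlin_k,lambda Karlin-Altschul parameters.
#' @return An object of class `AlignParams`.
#' @export
align_params <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                         gap_extend = 2L, word_size = 11L,
                         min_evalue = 1e-5, karlin_k = 0.621,
                         lambda = 1.33) {
  stopifnot(match > 0, mismatch < 0, word_size >= 7)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, word_size = word_size,
                 min_evalue = min_evalue, karlin_k = karlin_k,
                 lambda = lambda),
            class = "AlignParams")
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * score)`: the expected number of local
#' alignments scoring at least `score` between random sequences of lengths
#' `m` and `n`.
#'
#' @param score Raw alignment score (> 0).
#' @param m,n Sequence (search space) lengths in bp.
#' @param params [align_params()] supplying `karlin_k` and `lambda`.
#' @return Expectation value.
#' @export
expect_value <- function(score, m, n, params = align_params()) {
  stopifnot(score > 0, m > 0, n > 0)
  params$karlin_k * m * n * exp(-params$lambda * score)
}

blast_available <- function() {
  nzchar(Sys.which("blastn"))
}

# Run blastn between two FASTA files (bl2seq mode, no database build) and
# parse tabular output. Strand is encoded by sstart > send as usual.
run_blastn <- function(query_path, subject_path, params = align_params(),
                       task = "blastn") {
  if (!blast_available())
    stop("blastn not found on PATH; install NCBI BLAST+")
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  out <- system2("blastn",
                 c("-task", task,
                   "-query", shQuote(query_path),
                   "-subject", shQuote(subject_path),
                   "-reward", params$match, "-penalty", params$mismatch,
                   "-gapopen", params$gap_open,
                   "-gapextend", params$gap_extend,
                   "-word_size", params$word_size,
                   "-evalue", format(params$min_evalue, scientific = TRUE),
                   "-dust", "no",
                   "-outfmt", shQuote(paste("6", paste(cols, collapse = " ")))),
                 stdout = TRUE, stderr = FALSE)
  if (length(out) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                        stringsAsFactors = FALSE)
    for (nm in setdiff(cols, c("qseqid", "sseqid"))) df[[nm]] <- numeric(0)
    return(df)
  }
  df <- utils::read.delim(text = out, header = FALSE, col.names = cols,
                          stringsAsFactors = FALSE)
  df
}

# Map an interval on the extended (circularly unwrapped) sequence back onto
# [1, L]; start > end encodes wraparound through the origin.
map_back <- function(start, end, L) {
  if (start > L && end > L) c(start - L, end - L)
  else if (end > L) c(start, end - L)
  else c(start, end)
}

# Do two 1-based inclusive intervals (possibly wrapping on a circle of
# length L) share any base?
intervals_overlap <- function(a1, a2, b1, b2, L) {
  expand <- function(s, e) {
    if (s <= e) list(c(s, e)) else list(c(s, L), c(1L, e))
  }
  for (x in expand(a1, a2)) for (y in expand(b1, b2)) {
    if (x[1] <= y[2] && y[1] <= x[2]) return(TRUE)
  }
  FALSE
}

#' Find dispersed repeat pairs by genome self-alignment
#'
#' The genome is compared against itself with `blastn`; each resulting
#' high-scoring pair (HSP) is a candidate dispersed repeat that could
#' mediate homologous recombination. Circular molecules are unwrapped by
#' appending the first `circular_ext` bases so origin-spanning repeats are
#' caught; coordinates are mapped back modulo the molecule length.
#'
#' The trivial self-identity hit of each molecule is removed, mirrored
#' duplicates (a, b) / (b, a) are collapsed to a canonical order (lower
#' molecule/start first), and pairs whose two loci overlap (tandem rather
#' than dispersed repeats) are dropped unless `keep_overlapping = TRUE`.
#' HSP ids `R1, R2, ...` are assigned in descending bitscore order (ties
#' broken by coordinates); absolute numbering is implementation-defined.
#'
#' @param genome List of `Molecule`s.
#' @param params [align_params()].
#' @param min_length Minimum alignment length (bp) to report.
#' @param circular_ext Unwrap length for circular molecules (bp).
#' @param keep_overlapping Keep pairs with overlapping loci.
#' @return data.frame: `hsp_id`, `mol_a`, `start_a`, `end_a`, `mol_b`,
#'   `start_b`, `end_b`, `orientation` (`direct`/`inverted`), `length`,
#'   `identity` (fraction), `bitscore`, `evalue`.
#' @export
self_align <- function(genome, params = align_params(), min_length = 50L,
                       circular_ext = 5000L, keep_overlapping = FALSE) {
  genome <- as_genome(genome)
  lens <- vapply(genome, `[[`, 0L, "length")
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa), add = TRUE)
  writeLines(unlist(lapply(genome, function(m) {
    e <- if (m$topology == "circular")
      min(m$length - 1L, as.integer(circular_ext)) else 0L
    s <- if (e > 0L) paste0(m$seq, substr(m$seq, 1L, e)) else m$seq
    c(paste0(">", m$id), s)
  })), fa)
  hits <- run_blastn(fa, fa, params)
  pairs_from_hits(hits, lens, min_length, params$min_evalue,
                  keep_overlapping)
}

# Shared post-processing: map back to circular coordinates, canonicalize,
# deduplicate and number HSPs.
pairs_from_hits <- function(hits, lens, min_length, max_evalue,
                            keep_overlapping) {
  empty <- data.frame(hsp_id = character(), mol_a = character(),
                      start_a = integer(), end_a = integer(),
                      mol_b = character(), start_b = integer(),
                      end_b = integer(), orientation = character(),
                      length = integer(), identity = numeric(),
                      bitscore = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  rows <- list()
  seen <- character(0)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    La <- lens[[h$qseqid]]; Lb <- lens[[h$sseqid]]
    orientation <- if (h$sstart <= h$send) "direct" else "inverted"
    a <- map_back(h$qstart, h$qend, La)
    b <- map_back(min(h$sstart, h$send), max(h$sstart, h$send), Lb)
    if (h$length < min_length || h$evalue > max_evalue) next
    # identical locus aligned to itself (incl. via the circular extension)
    if (h$qseqid == h$sseqid && a[1] == b[1] && a[2] == b[2]) next
    # canonical order: lower (molecule, start) first
    if (h$qseqid > h$sseqid ||
        (h$qseqid == h$sseqid && (b[1] < a[1] ||
                                  (b[1] == a[1] && b[2] < a[2])))) {
      tmp <- a; a <- b; b <- tmp
      mol_a <- h$sseqid; mol_b <- h$qseqid
    } else {
      mol_a <- h$qseqid; mol_b <- h$sseqid
    }
    if (!keep_overlapping && mol_a == mol_b &&
        intervals_overlap(a[1], a[2], b[1], b[2], lens[[mol_a]])) next
    key <- paste(mol_a, a[1], a[2], mol_b, b[1], b[2], orientation)
    if (key %in% seen) next
    seen <- c(seen, key)
    rows[[length(rows) + 1L]] <- data.frame(
      hsp_id = NA_character_, mol_a = mol_a, start_a = a[1], end_a = a[2],
      mol_b = mol_b, start_b = b[1], end_b = b[2],
      orientation = orientation, length = as.integer(h$length),
      identity = h$pident / 100, bitscore = h$bitscore, evalue = h$evalue,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- drop_contained_pairs(out, lens)
  out <- out[order(-out$bitscore, out$mol_a, out$start_a, out$mol_b,
                   out$start_b), , drop = FALSE]
  out$hsp_id <- paste0("R", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

# is circular interval (s1, e1) contained in (s2, e2) on a circle of size L?
circ_contains <- function(s2, e2, s1, e1, L) {
  len2 <- if (s2 <= e2) e2 - s2 + 1L else L - s2 + 1L + e2
  len1 <- if (s1 <= e1) e1 - s1 + 1L else L - s1 + 1L + e1
  off <- (s1 - s2) %% L
  off + len1 <= len2
}

# Remove pairs whose both loci lie inside another pair's loci (partial
# echoes of the same repeat produced by the circular unwrapping).
drop_contained_pairs <- function(out, lens) {
  n <- nrow(out)
  if (n <= 1L) return(out)
  drop <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || drop[j]) next
      if (out$mol_a[i] != out$mol_a[j] || out$mol_b[i] != out$mol_b[j] ||
          out$orientation[i] != out$orientation[j]) next
      if (out$length[i] > out$length[j]) next
      if (out$length[i] == out$length[j] && i < j) next
      La <- lens[[out$mol_a[i]]]; Lb <- lens[[out$mol_b[i]]]
      straight <-
        circ_contains(out$start_a[j], out$end_a[j],
                      out$start_a[i], out$end_a[i], La) &&
        circ_contains(out$start_b[j], out$end_b[j],
                      out$start_b[i], out$end_b[i], Lb)
      crossed <- out$mol_a[i] == out$mol_b[i] &&
        circ_contains(out$start_b[j], out$end_b[j],
                      out$start_a[i], out$end_a[i], La) &&
        circ_contains(out$start_a[j], out$end_a[j],
                      out$start_b[i], out$end_b[i], Lb)
      if (straight || crossed) { drop[i] <- TRUE; break }
    }
  }
  out[!drop, , drop = FALSE]
}

#' Select repeats of interest by length rank
#'
#' Picks repeat pairs for downstream reporting, e.g. "the pair longer than
#' 5 kb". Ties in length are broken by ascending coordinates so the
#' selection is deterministic.
#'
#' @param pairs data.frame from [self_align()].
#' @param min_length Keep pairs with alignment length >= this (bp).
#' @param top_n Keep at most the `top_n` longest pairs.
#' @return Subset of `pairs` ordered by decreasing length. Warns when empty.
#' @export
match_named_repeats <- function(pairs, min_length = NULL, top_n = NULL) {
  sel <- pairs[order(-pairs$length, pairs$mol_a, pairs$start_a,
                     pairs$mol_b, pairs$start_b), , drop = FALSE]
  if (!is.null(min_length)) sel <- sel[sel$length >= min_length, , drop = FALSE]
  if (!is.null(top_n)) sel <- utils::head(sel, top_n)
  if (nrow(sel) == 0L) warning("no repeat pair matches the criterion")
  rownames(sel) <- NULL
  sel
}
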
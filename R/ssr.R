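#' SSR detection thresholds
#'
#' Minimum copy numbers per motif unit size (1-6 bp) and the maximum
#' interruption allowed when merging adjacent loci into compound SSRs.
#'
#' Two presets are shipped. `"relaxed"` (the default: mono >= 10, di >= 5,
#' tri >= 4, tetra/penta/hexa >= 3) reproduces a result profile in which
#' tetramer loci are the most abundant class, as reported for the coffee
#' mitogenome; `"misa-web"` is the stricter historic MISA web-server set
#' (10/6/5/5/5/5).
#'
#' @param preset `"relaxed"` or `"misa-web"`.
#' @param min_copies Optional named/positional integer vector of length 6
#'   overriding the preset.
#' @param max_interruption Maximum gap (bp) between loci merged into a
#'   compound SSR.
#' @return An object of class `SSRThresholds`.
#' @export
ssr_thresholds <- function(preset = c("relaxed", "misa-web"), min_copies = NULL,
                           max_interruption = 100L) {
  preset <- match.arg(preset)
  mc <- if (!is.null(min_copies)) as.integer(min_copies)
        else if (preset == "relaxed") c(10L, 5L, 4L, 3L, 3L, 3L)
        else c(10L, 6L, 5L, 5L, 5L, 5L)
  stopifnot(length(mc) == 6L, all(mc >= 2L))
  structure(list(min_copies = mc,
                 max_interruption = as.integer(max_interruption),
                 preset = preset),
            class = "SSRThresholds")
}

# Smallest period of a motif that yields an exact repetition of a
# sub-unit; k if the motif is primitive.
motif_period <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0L && strrep(substr(motif, 1L, d), k %/% d) == motif)
      return(d)
  }
  k
}

# Scan one unit size over a character vector of bases. Regions are the
# maximal runs of period-k agreement; within a unit size, loci consume the
# sequence left to right (no same-size overlap), matching greedy
# regular-expression semantics. Loci whose motif has a smaller period are
# recorded for consumption but flagged for removal (they belong to the
# smaller unit size).
scan_unit_size <- function(chars, k, min_copies) {
  L <- length(chars)
  out <- list()
  if (L < k * min_copies) return(out)
  a <- chars[seq_len(L - k)]
  b <- chars[(k + 1):L]
  eq <- a == b & a != "N"
  r <- rle(eq)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  keep <- r$values & r$lengths >= k * (min_copies - 1L)
  next_free <- 1L
  for (i in which(keep)) {
    region_start <- run_start[i]
    region_end <- run_end[i] + k  # in base coordinates
    j <- max(region_start, next_free)
    copies <- (region_end - j + 1L) %/% k
    if (copies < min_copies) next
    motif <- paste(chars[j:(j + k - 1L)], collapse = "")
    locus_end <- j + copies * k - 1L
    out[[length(out) + 1L]] <- list(start = j, end = locus_end, motif = motif,
                                    copies = copies,
                                    primitive = motif_period(motif) == k)
    next_free <- locus_end + 1L
  }
  out
}

#' Find perfect microsatellites (SSRs) in a molecule
#'
#' MISA-compatible scan for maximal perfect tandem repeats with unit sizes
#' 1-6 bp. A locus is reported when its integer copy number reaches the
#' per-unit-size minimum in `thr`. Loci whose motif is itself a repetition
#' of a shorter unit are reported at the shorter unit size only. The motif
#' is reported as it appears at the locus start (no canonical rotation).
#' Circular molecules are scanned linearly, so an SSR spanning the origin is
#' not detected; this mirrors how web-based scanners see a FASTA record.
#'
#' @param mol A `Molecule`.
#' @param thr [ssr_thresholds()].
#' @return data.frame sorted by `start` with columns `molecule`, `start`,
#'   `end`, `unit_size`, `motif`, `copies`, `kind` (`"perfect"`).
#' @export
find_ssrs <- function(mol, thr = ssr_thresholds()) {
  stopifnot(inherits(mol, "Molecule"), inherits(thr, "SSRThresholds"))
  chars <- strsplit(mol$seq, "", fixed = TRUE)[[1]]
  rows <- list()
  for (k in 1:6) {
    loci <- scan_unit_size(chars, k, thr$min_copies[k])
    for (lc in loci) {
      if (!lc$primitive) next
      rows[[length(rows) + 1L]] <- data.frame(
        molecule = mol$id, start = lc$start, end = lc$end,
        unit_size = k, motif = lc$motif, copies = lc$copies,
        kind = "perfect", stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(molecule = character(), start = integer(),
                      end = integer(), unit_size = integer(),
                      motif = character(), copies = integer(),
                      kind = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$unit_size), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a whole genome for SSRs
#'
#' @param genome List of `Molecule`s.
#' @inheritParams find_ssrs
#' @return Combined data.frame as in [find_ssrs()].
#' @export
find_ssrs_genome <- function(genome, thr = ssr_thresholds()) {
  genome <- as_genome(genome)
  do.call(rbind, c(lapply(genome, find_ssrs, thr = thr),
                   make.row.names = FALSE))
}

#' Merge nearby SSR loci into compound SSRs
#'
#' Adjacent loci on the same molecule separated by at most
#' `thr$max_interruption` bp (MISA convention; overlapping loci always
#' merge) are collapsed into a single locus of kind `"compound"`. Component
#' motifs are retained in the `components` column, `;`-separated.
#'
#' @param ssrs data.frame from [find_ssrs()] (sorted by start).
#' @param thr [ssr_thresholds()].
#' @return data.frame with `kind` in `{perfect, compound}` and a
#'   `components` column.
#' @export
merge_compound <- function(ssrs, thr = ssr_thresholds()) {
  if (nrow(ssrs) == 0L) {
    ssrs$components <- character(0)
    return(ssrs)
  }
  ssrs <- ssrs[order(ssrs$molecule, ssrs$start), , drop = FALSE]
  gap_prev <- c(Inf, ssrs$start[-1L] - ssrs$end[-nrow(ssrs)] - 1L)
  same_mol <- c(FALSE, ssrs$molecule[-1L] == ssrs$molecule[-nrow(ssrs)])
  new_group <- !(same_mol & gap_prev <= thr$max_interruption)
  grp <- cumsum(new_group)
  rows <- lapply(split(seq_len(nrow(ssrs)), grp), function(idx) {
    s <- ssrs[idx, , drop = FALSE]
    if (nrow(s) == 1L) {
      s$components <- s$motif
      return(s)
    }
    data.frame(molecule = s$molecule[1L], start = min(s$start),
               end = max(s$end), unit_size = NA_integer_,
               motif = paste0("(", s$motif, ")", s$copies, collapse = ""),
               copies = NA_integer_, kind = "compound",
               components = paste(s$motif, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out[order(out$molecule, out$start), , drop = FALSE]
}

#' Summarise an SSR table
#'
#' @param ssrs data.frame from [find_ssrs()] or [merge_compound()].
#' @param count_compound_as `"one"` counts each compound locus once (as its
#'   own class); `"components"` counts its perfect components individually
#'   (requires an unmerged table or the `components` column).
#' @return List with `total`, `by_unit` (unit size 1-6 plus `compound`:
#'   count and share of total) and `by_molecule` counts.
#' @export
ssr_summary <- function(ssrs, count_compound_as = c("one", "components")) {
  count_compound_as <- match.arg(count_compound_as)
  # one class label per counted unit: "1".."6" for perfect loci, and either
  # "compound" (counted once) or the component unit sizes
  cls <- character(0)
  mol <- character(0)
  perfect <- ssrs$kind != "compound"
  cls <- c(cls, as.character(ssrs$unit_size[perfect]))
  mol <- c(mol, ssrs$molecule[perfect])
  if (any(!perfect)) {
    comp <- ssrs[!perfect, , drop = FALSE]
    if (count_compound_as == "one") {
      cls <- c(cls, rep("compound", nrow(comp)))
      mol <- c(mol, comp$molecule)
    } else {
      for (i in seq_len(nrow(comp))) {
        units <- nchar(strsplit(comp$components[i], ";", fixed = TRUE)[[1]])
        cls <- c(cls, as.character(units))
        mol <- c(mol, rep(comp$molecule[i], length(units)))
      }
    }
  }
  classes <- c(as.character(1:6), "compound")
  counts <- vapply(classes, function(cl) sum(cls == cl), 0L)
  total <- length(cls)
  by_unit <- data.frame(class = classes, count = counts,
                        share = if (total > 0) counts / total
                                else rep(0, length(classes)),
                        row.names = NULL, stringsAsFactors = FALSE)
  by_mol <- if (length(mol)) {
    x <- as.data.frame(table(mol), stringsAsFactors = FALSE)
    stats::setNames(x, c("molecule", "count"))
  } else {
    data.frame(molecule = character(), count = integer(),
               stringsAsFactors = FALSE)
  }
  list(total = total, by_unit = by_unit, by_molecule = by_mol)
}
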
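translate_codon <- function(codon_dna) {
  codon_dna <- chartr("U", "T", toupper(codon_dna))
  if (grepl("[^ACGT]", codon_dna)) return(NA_character_)
  unname(Biostrings::GENETIC_CODE[codon_dna])
}

#' Codon effect of a single C-to-U edit
#'
#' Replaces the C at `codon_pos` by U, translates both codons with the
#' standard genetic code (plant mitochondria use the standard code) and
#' classifies the change.
#'
#' @param ref_codon Triplet (DNA or RNA alphabet) containing C at
#'   `codon_pos`.
#' @param codon_pos Position within the codon (1, 2 or 3).
#' @return List: `edited_codon` (RNA), `ref_codon` (RNA), `aa_ref`,
#'   `aa_alt` (single letters, `"*"` for stop), `effect` (one of
#'   `synonymous`, `nonsynonymous`, `stop_gain`, `stop_loss`).
#' @export
classify_effect <- function(ref_codon, codon_pos) {
  stopifnot(nchar(ref_codon) == 3L, codon_pos %in% 1:3)
  rna <- chartr("T", "U", toupper(ref_codon))
  if (substr(rna, codon_pos, codon_pos) != "C")
    stop("no C at codon position ", codon_pos, " in ", ref_codon)
  edited <- rna
  substr(edited, codon_pos, codon_pos) <- "U"
  aa_ref <- translate_codon(rna)
  aa_alt <- translate_codon(edited)
  effect <- if (is.na(aa_ref) || is.na(aa_alt)) NA_character_
    else if (aa_ref == aa_alt) "synonymous"
    else if (aa_alt == "*") "stop_gain"
    else if (aa_ref == "*") "stop_loss"
    else "nonsynonymous"
  list(ref_codon = rna, edited_codon = edited, aa_ref = aa_ref,
       aa_alt = aa_alt, effect = effect)
}

empty_events <- function() {
  data.frame(gene_id = character(), cds_pos = integer(),
             codon_index = integer(), codon_pos = integer(),
             ref_codon = character(), edited_codon = character(),
             aa_ref = character(), aa_alt = character(),
             effect = character(), name = character(),
             stringsAsFactors = FALSE)
}

#' Call C-to-U RNA-editing sites from paired gDNA and cDNA sequences
#'
#' The cDNA amplicon is aligned within the genomic CDS with free end gaps
#' (the amplicon may cover any sub-interval; its offset is inferred). Both
#' the given frame and its reverse complement are tried and the better-
#' scoring frame is used, so a gene sequenced on the opposite strand - where
#' C-to-U edits appear as G-to-A - is normalized automatically. Positions
#' where the gDNA has `C` and the cDNA has `T` are editing events; every
#' other mismatch or indel is logged as a discrepancy, never as an edit.
#'
#' @param gdna_cds Genomic CDS sequence (sense strand, frame 1).
#' @param cdna cDNA amplicon sequence.
#' @param gene_id Gene name used in event names (`gene-cds_pos`).
#' @param min_identity Identity floor below which the amplicon is rejected.
#' @return Object of class `editing_calls`: `gene_id`, `frame`
#'   (`forward`/`reverse`), `identity`, `events` (one row per edit with
#'   codon annotation from [classify_effect()]) and `discrepancies`.
#' @export
call_edits <- function(gdna_cds, cdna, gene_id, min_identity = 0.90) {
  gdna_cds <- toupper(gdna_cds)
  cdna <- chartr("U", "T", toupper(cdna))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln_of <- function(query) {
    Biostrings::pairwiseAlignment(pattern = query, subject = gdna_cds,
                                  substitutionMatrix = mat,
                                  gapOpening = 2, gapExtension = 1,
                                  type = "global-local")
  }
  fwd <- aln_of(cdna)
  rev <- aln_of(reverse_complement(cdna))
  use_rev <- Biostrings::score(rev) > Biostrings::score(fwd)
  aln <- if (use_rev) rev else fwd
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ident <- sum(p == s & p != "-") / length(p)
  if (ident < min_identity)
    stop("unalignable amplicon for gene ", gene_id,
         sprintf(" (identity %.2f < %.2f)", ident, min_identity))

  subj_pos <- Biostrings::start(Biostrings::subject(aln)) - 1L
  ev <- list(); disc <- list()
  for (i in seq_along(p)) {
    if (s[i] != "-") subj_pos <- subj_pos + 1L
    if (p[i] == s[i]) next
    if (p[i] == "-") {
      disc[[length(disc) + 1L]] <- data.frame(
        cds_pos = subj_pos, type = "deletion", ref = s[i], alt = "-",
        stringsAsFactors = FALSE)
    } else if (s[i] == "-") {
      disc[[length(disc) + 1L]] <- data.frame(
        cds_pos = subj_pos, type = "insertion", ref = "-", alt = p[i],
        stringsAsFactors = FALSE)
    } else if (s[i] == "C" && p[i] == "T") {
      ev[[length(ev) + 1L]] <- subj_pos
    } else {
      disc[[length(disc) + 1L]] <- data.frame(
        cds_pos = subj_pos, type = "substitution", ref = s[i], alt = p[i],
        stringsAsFactors = FALSE)
    }
  }
  events <- empty_events()
  for (pos in ev) {
    ci <- (pos - 1L) %/% 3L + 1L
    cp <- (pos - 1L) %% 3L + 1L
    codon_start <- (ci - 1L) * 3L + 1L
    if (codon_start + 2L > nchar(gdna_cds)) {
      warning(gene_id, ": edit at cds position ", pos,
              " falls in an incomplete terminal codon; skipped")
      next
    }
    codon <- substr(gdna_cds, codon_start, codon_start + 2L)
    fx <- classify_effect(codon, cp)
    events <- rbind(events, data.frame(
      gene_id = gene_id, cds_pos = pos, codon_index = ci, codon_pos = cp,
      ref_codon = fx$ref_codon, edited_codon = fx$edited_codon,
      aa_ref = fx$aa_ref, aa_alt = fx$aa_alt, effect = fx$effect,
      name = paste0(gene_id, "-", pos), stringsAsFactors = FALSE))
  }
  disc <- if (length(disc)) do.call(rbind, disc)
          else data.frame(cds_pos = integer(), type = character(),
                          ref = character(), alt = character(),
                          stringsAsFactors = FALSE)
  structure(list(gene_id = gene_id,
                 frame = if (use_rev) "reverse" else "forward",
                 identity = ident, events = events, discrepancies = disc),
            class = "editing_calls")
}

#' @export
print.editing_calls <- function(x, ...) {
  cat(sprintf("<editing_calls> %s: %d C-to-U events, %d discrepancies (%s frame, %.1f%% identity)\n",
              x$gene_id, nrow(x$events), nrow(x$discrepancies), x$frame,
              100 * x$identity))
  invisible(x)
}

#' Summarise editing events
#'
#' @param events data.frame of events (rbind of `editing_calls$events`
#'   tables, or a single one; a list of `editing_calls` is also accepted).
#' @return List of count tables: `by_effect`, `by_gene`, `by_conversion`
#'   (amino-acid change, e.g. `S>L`), `by_codon_pos`, plus `total`.
#' @export
editing_spectrum <- function(events) {
  if (is.list(events) && !is.data.frame(events) &&
      all(vapply(events, inherits, TRUE, "editing_calls"))) {
    events <- do.call(rbind, lapply(events, `[[`, "events"))
  }
  if (is.null(events) || nrow(events) == 0L) {
    zero <- stats::setNames(integer(4), c("synonymous", "nonsynonymous",
                                          "stop_gain", "stop_loss"))
    return(list(total = 0L, by_effect = zero,
                by_gene = integer(0), by_conversion = integer(0),
                by_codon_pos = stats::setNames(integer(3), 1:3)))
  }
  by_effect <- vapply(c("synonymous", "nonsynonymous", "stop_gain",
                        "stop_loss"),
                      function(e) sum(events$effect == e), 0L)
  by_gene <- vapply(split(events, events$gene_id), nrow, 0L)
  conv <- paste0(events$aa_ref, ">", events$aa_alt)
  by_conversion <- vapply(split(conv, conv), length, 0L)
  by_codon_pos <- vapply(as.character(1:3),
                         function(p) sum(events$codon_pos == as.integer(p)),
                         0L)
  list(total = nrow(events), by_effect = by_effect, by_gene = by_gene,
       by_conversion = by_conversion, by_codon_pos = by_codon_pos)
}
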
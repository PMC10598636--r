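#' Detect plastid-derived fragments (MTPTs) in a mitochondrial genome
#'
#' Reciprocal homology search between mitogenome and plastome with `blastn`
#' (`-evalue 1e-5`-style cutoff): the mitogenome is searched against the
#' plastome and the roles are then reversed. Hits from both directions are
#' unioned on mitochondrial coordinates and overlapping intervals are merged
#' (the provenance of the best-identity hit is kept per merged fragment).
#'
#' @param mitogenome,plastome Lists of `Molecule`s.
#' @param evalue_cutoff Expectation-value cutoff.
#' @param params [align_params()] scoring set.
#' @param min_length Minimum hit length (bp).
#' @return data.frame, one row per merged fragment: `mito_molecule`,
#'   `mito_start`, `mito_end`, `length`, `plastid_molecule`,
#'   `plastid_start`, `plastid_end`, `strand`, `identity`, `evalue`,
#'   `n_hits`.
#' @export
find_mtpts <- function(mitogenome, plastome, evalue_cutoff = 1e-5,
                       params = align_params(), min_length = 30L) {
  mitogenome <- as_genome(mitogenome)
  plastome <- as_genome(plastome)
  params$min_evalue <- evalue_cutoff
  fa_m <- tempfile(fileext = ".fa"); fa_p <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fa_m, fa_p)), add = TRUE)
  write_fasta(mitogenome, fa_m)
  write_fasta(plastome, fa_p)

  fwd <- run_blastn(fa_m, fa_p, params)    # mito query, plastid subject
  rev <- run_blastn(fa_p, fa_m, params)    # roles reversed

  std <- function(h, mito_is_query) {
    if (nrow(h) == 0L) return(NULL)
    if (mito_is_query) {
      data.frame(mito_molecule = h$qseqid, mito_start = h$qstart,
                 mito_end = h$qend,
                 plastid_molecule = h$sseqid,
                 plastid_start = pmin(h$sstart, h$send),
                 plastid_end = pmax(h$sstart, h$send),
                 strand = ifelse(h$sstart <= h$send, "+", "-"),
                 length = h$length, identity = h$pident / 100,
                 evalue = h$evalue, stringsAsFactors = FALSE)
    } else {
      data.frame(mito_molecule = h$sseqid,
                 mito_start = pmin(h$sstart, h$send),
                 mito_end = pmax(h$sstart, h$send),
                 plastid_molecule = h$qseqid, plastid_start = h$qstart,
                 plastid_end = h$qend,
                 strand = ifelse(h$sstart <= h$send, "+", "-"),
                 length = h$length, identity = h$pident / 100,
                 evalue = h$evalue, stringsAsFactors = FALSE)
    }
  }
  hits <- rbind(std(fwd, TRUE), std(rev, FALSE))
  empty <- data.frame(mito_molecule = character(), mito_start = integer(),
                      mito_end = integer(), length = integer(),
                      plastid_molecule = character(),
                      plastid_start = integer(), plastid_end = integer(),
                      strand = character(), identity = numeric(),
                      evalue = numeric(), n_hits = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  hits <- hits[hits$length >= min_length & hits$evalue <= evalue_cutoff, ,
               drop = FALSE]
  if (nrow(hits) == 0L) return(empty)

  out <- lapply(split(hits, hits$mito_molecule), function(h) {
    ir <- IRanges::IRanges(start = h$mito_start, end = h$mito_end)
    merged <- IRanges::reduce(ir)
    ov <- IRanges::findOverlaps(merged, ir)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    do.call(rbind, lapply(seq_along(merged), function(i) {
      members <- sh[qh == i]
      best <- members[which.max(h$identity[members])]
      data.frame(mito_molecule = h$mito_molecule[1],
                 mito_start = IRanges::start(merged)[i],
                 mito_end = IRanges::end(merged)[i],
                 length = IRanges::width(merged)[i],
                 plastid_molecule = h$plastid_molecule[best],
                 plastid_start = h$plastid_start[best],
                 plastid_end = h$plastid_end[best],
                 strand = h$strand[best],
                 identity = h$identity[best],
                 evalue = h$evalue[best],
                 n_hits = length(unique(paste(h$mito_start[members],
                                              h$mito_end[members]))),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, c(out, make.row.names = FALSE))
  out <- out[order(out$mito_molecule, out$mito_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plastid genes fully contained in MTPT fragments
#'
#' A gene is contained when every one of its exons lies entirely within the
#' fragment's plastid-side interval; a gene overhanging a fragment edge by
#' even 1 bp is not contained.
#'
#' @param fragments data.frame from [find_mtpts()].
#' @param plastid_annotation List of gene models ([read_gff_genes()]) on
#'   plastome coordinates.
#' @return `fragments` with an added `genes_contained` column
#'   (`;`-separated gene ids, `""` when none).
#' @export
genes_in_fragments <- function(fragments, plastid_annotation) {
  plastid_mols <- unique(fragments$plastid_molecule)
  for (gm in plastid_annotation) {
    if (!gm$molecule_id %in% plastid_mols && nrow(fragments) > 0L)
      stop("annotation on unknown molecule: ", gm$molecule_id)
  }
  fragments$genes_contained <- vapply(seq_len(nrow(fragments)), function(i) {
    fr <- fragments[i, ]
    inside <- vapply(plastid_annotation, function(gm) {
      gm$molecule_id == fr$plastid_molecule &&
        all(gm$exons$start >= fr$plastid_start &
              gm$exons$end <= fr$plastid_end)
    }, TRUE)
    paste(vapply(plastid_annotation[inside], `[[`, "", "gene_id"),
          collapse = ";")
  }, "")
  fragments
}

#' Summarise MTPT content
#'
#' @param fragments data.frame from [find_mtpts()].
#' @param mitogenome List of `Molecule`s the fragments live on.
#' @return List: `count_per_molecule`, `total_bp`, `fraction` of the summed
#'   mitogenome length, and `pct` (the fraction in percent, two decimals).
#' @export
mtpt_summary <- function(fragments, mitogenome) {
  mitogenome <- as_genome(mitogenome)
  genome_bp <- sum(vapply(mitogenome, `[[`, 0L, "length"))
  total_bp <- if (nrow(fragments) > 0L)
    sum(fragments$mito_end - fragments$mito_start + 1L) else 0L
  counts <- vapply(names(mitogenome), function(id) {
    sum(fragments$mito_molecule == id)
  }, 0L)
  frac <- total_bp / genome_bp
  list(count_per_molecule = counts, total_bp = as.integer(total_bp),
       fraction = frac, pct = round(100 * frac, 2))
}
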
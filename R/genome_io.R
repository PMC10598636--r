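#' Construct a Molecule
#'
#' A `Molecule` is one genome sequence together with its topology. Plant
#' mitochondrial and plastid chromosomes are typically circular, so every
#' coordinate operation in the package understands origin wraparound.
#'
#' @param id Character scalar, unique sequence identifier.
#' @param seq Character scalar over `A`,`C`,`G`,`T`,`N`. Lowercase input is
#'   uppercased and `U` is mapped to `T`; other IUPAC ambiguity codes are
#'   mapped to `N` with a warning.
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `Molecule`: a list with elements `id`, `seq`,
#'   `topology` and `length`.
#' @export
molecule <- function(id, seq, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  seq <- toupper(seq)
  seq <- chartr("U", "T", seq)
  if (grepl("[^ACGTN]", seq)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", seq), "")[[1]])
    warning(sprintf("molecule '%s': ambiguity codes [%s] mapped to N",
                    id, paste(bad, collapse = "")))
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  n <- nchar(seq)
  if (n == 0L) stop("molecule '", id, "': empty sequence")
  structure(list(id = id, seq = seq, topology = topology, length = n),
            class = "Molecule")
}

#' @export
print.Molecule <- function(x, ...) {
  cat(sprintf("<Molecule> %s: %s bp, %s\n", x$id,
              format(x$length, big.mark = ","), x$topology))
  invisible(x)
}

#' Read a genome FASTA into a list of Molecules
#'
#' Topology is taken from a `circular` token in the record description
#' (e.g. `>m1 circular`), falling back to `default_topology`.
#'
#' @param path FASTA file.
#' @param default_topology Topology for records without a header token.
#' @return Named list of [molecule()] objects.
#' @export
read_fasta <- function(path, default_topology = c("circular", "linear")) {
  default_topology <- match.arg(default_topology)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate record ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  topo <- ifelse(grepl("(^|\\s)circular(\\s|$)", headers, ignore.case = TRUE),
                 "circular",
                 ifelse(grepl("(^|\\s)linear(\\s|$)", headers,
                              ignore.case = TRUE),
                        "linear", default_topology))
  mols <- lapply(seq_along(set), function(i) {
    molecule(ids[i], as.character(set[[i]]), topo[i])
  })
  names(mols) <- ids
  mols
}

#' Write Molecules to FASTA
#'
#' The topology is recorded as a `circular`/`linear` token in the header so
#' that [read_fasta()] round-trips it.
#'
#' @param genome A `Molecule` or list of them.
#' @param path Output file.
#' @param width Line width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  genome <- as_genome(genome)
  set <- Biostrings::DNAStringSet(vapply(genome, `[[`, "", "seq"))
  names(set) <- vapply(genome, function(m) paste(m$id, m$topology), "")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Normalize a Molecule or list of Molecules to a named list.
as_genome <- function(genome) {
  if (inherits(genome, "Molecule")) genome <- list(genome)
  stopifnot(all(vapply(genome, inherits, TRUE, "Molecule")))
  names(genome) <- vapply(genome, `[[`, "", "id")
  genome
}

#' GC content of a molecule
#'
#' Fraction (G + C) / (A + C + G + T); `N` bases are excluded from the
#' denominator. Reported GC percentages in genome reports use one decimal,
#' the convention of organelle-genome tables.
#'
#' @param mol A `Molecule` or plain DNA string.
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(mol) {
  seq <- if (inherits(mol, "Molecule")) mol$seq else toupper(mol)
  f <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq))
  acgt <- sum(f[c("A", "C", "G", "T")])
  if (acgt == 0) stop("gc_content undefined: no unambiguous bases")
  unname((f["G"] + f["C"]) / acgt)
}

#' Reverse complement of a DNA string
#'
#' `N` maps to `N`. Works on plain character strings (vectorised).
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector.
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    rc_cpp(toupper(s))
  }, "", USE.NAMES = FALSE)
}

# Map a raw (possibly out-of-range) coordinate onto [1, L] for a circle.
circ_norm <- function(pos, len) ((pos - 1L) %% len) + 1L

# Extract by raw offsets that may fall outside [1, L]; circular molecules
# wrap, linear molecules clamp is an error.
subseq_raw <- function(mol, start, end) {
  L <- mol$length
  if (mol$topology == "linear") {
    if (start < 1L || end > L || start > end)
      stop("coordinates [", start, ",", end, "] outside linear molecule ",
           mol$id)
    return(substr(mol$seq, start, end))
  }
  n <- end - start + 1L
  if (n <= 0L) stop("empty raw extraction")
  if (n > L) stop("extraction longer than circular molecule ", mol$id)
  s <- circ_norm(start, L)
  e <- circ_norm(end, L)
  if (s <= e) substr(mol$seq, s, e)
  else paste0(substr(mol$seq, s, L), substr(mol$seq, 1L, e))
}

#' Extract a subsequence, honouring circular topology
#'
#' Coordinates are 1-based inclusive. On a circular molecule `start > end`
#' encodes wraparound through the origin. `strand = "-"` returns the reverse
#' complement of the extracted segment.
#'
#' @param mol A `Molecule`.
#' @param start,end Integer coordinates in `[1, length]`.
#' @param strand `"+"` or `"-"`.
#' @return Character scalar.
#' @export
subsequence <- function(mol, start, end, strand = "+") {
  stopifnot(inherits(mol, "Molecule"))
  L <- mol$length
  if (start < 1L || start > L || end < 1L || end > L)
    stop("coordinates outside [1, ", L, "] for molecule ", mol$id)
  if (start > end && mol$topology == "linear")
    stop("wraparound extraction on linear molecule ", mol$id)
  s <- if (start <= end) substr(mol$seq, start, end)
       else paste0(substr(mol$seq, start, L), substr(mol$seq, 1L, end))
  if (strand == "-") reverse_complement(s) else s
}

#' Length of a 1-based inclusive interval on a molecule
#'
#' For circular molecules `start > end` counts through the origin.
#' @param mol A `Molecule`.
#' @param start,end Coordinates.
#' @return Integer length in bp.
#' @export
interval_length <- function(mol, start, end) {
  if (start <= end) end - start + 1L else mol$length - start + 1L + end
}

#' Rotate a circular molecule so that `new_origin` becomes position 1
#'
#' @param mol A circular `Molecule`.
#' @param new_origin Position that becomes base 1.
#' @return A rotated `Molecule` (same id).
#' @export
rotate_molecule <- function(mol, new_origin) {
  stopifnot(inherits(mol, "Molecule"), mol$topology == "circular")
  o <- circ_norm(new_origin, mol$length)
  if (o == 1L) return(mol)
  molecule(mol$id,
           paste0(substr(mol$seq, o, mol$length), substr(mol$seq, 1L, o - 1L)),
           "circular")
}

#' Per-molecule length and GC summary
#'
#' @param genome List of `Molecule`s.
#' @return data.frame with columns `molecule`, `length_bp`, `gc_pct`
#'   (one decimal), `topology`.
#' @export
genome_stats <- function(genome) {
  genome <- as_genome(genome)
  data.frame(
    molecule = vapply(genome, `[[`, "", "id"),
    length_bp = vapply(genome, `[[`, 0L, "length"),
    gc_pct = round(100 * vapply(genome, gc_content, 0), 1),
    topology = vapply(genome, `[[`, "", "topology"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Read CDS gene models from a GFF3 file
#'
#' CDS features are grouped into gene models by their `Parent` (or, failing
#' that, `ID`/`gene_id`) attribute. Exons are ordered 5' to 3' on the coding
#' strand.
#'
#' @param path GFF3 file.
#' @return Named list of gene models: each a list with `gene_id`,
#'   `molecule_id`, `strand` and an `exons` data.frame (`start`, `end`).
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(list())
  f <- utils::read.delim(text = lines, header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("seqid", "source", "type", "start",
                                       "end", "score", "strand", "phase",
                                       "attributes"))
  f <- f[f$type == "CDS", , drop = FALSE]
  if (nrow(f) == 0L) return(list())
  get_attr <- function(a, key) {
    m <- regmatches(a, regexpr(paste0("(?:^|;)", key, "=([^;]+)"), a,
                               perl = TRUE))
    if (length(m) == 0L) return(NA_character_)
    sub(paste0("^;?", key, "="), "", m)
  }
  gene <- vapply(f$attributes, function(a) {
    g <- get_attr(a, "Parent")
    if (is.na(g)) g <- get_attr(a, "gene_id")
    if (is.na(g)) g <- get_attr(a, "ID")
    if (is.na(g)) stop("CDS feature without Parent/gene_id/ID attribute")
    g
  }, "", USE.NAMES = FALSE)
  models <- lapply(split(seq_len(nrow(f)), gene), function(idx) {
    rows <- f[idx, , drop = FALSE]
    if (length(unique(rows$seqid)) != 1L || length(unique(rows$strand)) != 1L)
      stop("gene ", gene[idx[1]], ": CDS rows disagree on molecule/strand")
    ord <- order(rows$start)
    if (rows$strand[1] == "-") ord <- rev(ord)
    list(gene_id = gene[idx[1]],
         molecule_id = rows$seqid[1],
         strand = rows$strand[1],
         exons = data.frame(start = rows$start[ord], end = rows$end[ord]))
  })
  models
}

#' Spliced CDS sequence of a gene model
#'
#' @param genome List of `Molecule`s.
#' @param gm Gene model from [read_gff_genes()].
#' @return Character scalar, the coding-strand CDS sequence.
#' @export
cds_sequence <- function(genome, gm) {
  genome <- as_genome(genome)
  mol <- genome[[gm$molecule_id]]
  if (is.null(mol)) stop("gene ", gm$gene_id, ": molecule ", gm$molecule_id,
                         " not in genome")
  parts <- vapply(seq_len(nrow(gm$exons)), function(i) {
    subsequence(mol, gm$exons$start[i], gm$exons$end[i], gm$strand)
  }, "")
  paste(parts, collapse = "")
}
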
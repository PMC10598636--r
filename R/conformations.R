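# Normalize a repeat-pair row (from self_align or a plain list) to the
# fields used by the conformation builders.
as_repeat_pair <- function(rp) {
  if (is.data.frame(rp)) {
    stopifnot(nrow(rp) == 1L)
    rp <- as.list(rp)
  }
  need <- c("mol_a", "start_a", "end_a", "mol_b", "start_b", "end_b",
            "orientation")
  if (!all(need %in% names(rp)))
    stop("repeat pair must carry fields: ", paste(need, collapse = ", "))
  if (is.null(rp$hsp_id)) rp$hsp_id <- "R?"
  rp
}

# Arc length (bp) strictly between two positions going forward on a circle.
forward_gap <- function(from_end, to_start, L) (to_start - from_end - 1L) %% L

#' Build the four local conformations around a dispersed repeat
#'
#' Around a repeat pair (copies A and B) the two assembled arrangements are
#' `c1 = aU + R + aD` and `c2 = bU + R + bD` (upstream flank + repeat +
#' downstream flank). Homologous recombination between the copies exchanges
#' the downstream context, giving the recombinant arrangements
#' `c3 = aU + R + bD` and `c4 = bU + R + aD`. For an inverted pair, copy
#' B's context is read on the reverse strand so that both copies present the
#' repeat in the same reading direction.
#'
#' When two copies lie closer together than `flank`, the colliding flanks
#' are truncated at the midpoint of the intervening arc (with a warning), so
#' that every conformation keeps a unique anchor on both sides.
#'
#' @param genome List of `Molecule`s.
#' @param rp A single repeat pair (one row of [self_align()] output or an
#'   equivalent list).
#' @param flank Flank length in bp (default 1000).
#' @return An object of class `ConformationSet`: sequences `c1`..`c4`,
#'   per-conformation repeat coordinates `rep_start`/`rep_end`, the flank
#'   lengths used, and a `provenance` data.frame mapping every segment back
#'   to genome coordinates.
#' @export
build_local_conformations <- function(genome, rp, flank = 1000L) {
  genome <- as_genome(genome)
  rp <- as_repeat_pair(rp)
  molA <- genome[[rp$mol_a]]
  molB <- genome[[rp$mol_b]]
  if (is.null(molA) || is.null(molB))
    stop("repeat pair refers to molecules not in the genome")
  flank <- as.integer(flank)
  a1 <- rp$start_a; a2 <- rp$end_a
  b1 <- rp$start_b; b2 <- rp$end_b
  inverted <- rp$orientation == "inverted"
  R <- subsequence(molA, a1, a2, "+")
  replen <- nchar(R)

  intra <- rp$mol_a == rp$mol_b
  if (intra) {
    L <- molA$length
    gapAB <- forward_gap(a2, b1, L)
    gapBA <- forward_gap(b2, a1, L)
    if (inverted) {
      f_aD <- f_bD <- min(flank, gapAB %/% 2L)
      f_aU <- f_bU <- min(flank, gapBA %/% 2L)
    } else {
      f_aD <- f_bU <- min(flank, gapAB %/% 2L)
      f_aU <- f_bD <- min(flank, gapBA %/% 2L)
    }
  } else {
    cap <- function(mol, s, e, up) {
      if (mol$topology == "circular")
        min(flank, (mol$length - interval_length(mol, s, e)) %/% 2L)
      else if (up) min(flank, s - 1L) else min(flank, mol$length - e)
    }
    f_aU <- cap(molA, a1, a2, TRUE); f_aD <- cap(molA, a1, a2, FALSE)
    f_bU <- cap(molB, b1, b2, TRUE); f_bD <- cap(molB, b1, b2, FALSE)
  }
  if (any(c(f_aU, f_aD, f_bU, f_bD) < flank))
    warning(sprintf("%s: flanks truncated to fit between repeat copies (%d/%d/%d/%d bp)",
                    rp$hsp_id, f_aU, f_aD, f_bU, f_bD))

  seg <- function(mol, s, e) if (e >= s) subseq_raw(mol, s, e) else ""
  aU <- seg(molA, a1 - f_aU, a1 - 1L)
  aD <- seg(molA, a2 + 1L, a2 + f_aD)
  if (inverted) {
    bU <- if (f_bU > 0L) reverse_complement(seg(molB, b2 + 1L, b2 + f_bU)) else ""
    bD <- if (f_bD > 0L) reverse_complement(seg(molB, b1 - f_bD, b1 - 1L)) else ""
  } else {
    bU <- seg(molB, b1 - f_bU, b1 - 1L)
    bD <- seg(molB, b2 + 1L, b2 + f_bD)
  }

  conf <- c(c1 = paste0(aU, R, aD), c2 = paste0(bU, R, bD),
            c3 = paste0(aU, R, bD), c4 = paste0(bU, R, aD))
  left_len <- c(f_aU, f_bU, f_aU, f_bU)
  right_len <- c(f_aD, f_bD, f_bD, f_aD)

  norm <- function(mol, s, e) c(circ_norm(s, mol$length), circ_norm(e, mol$length))
  pa_u <- norm(molA, a1 - f_aU, a1 - 1L)
  pa_d <- norm(molA, a2 + 1L, a2 + f_aD)
  if (inverted) {
    pb_u <- norm(molB, b2 + 1L, b2 + f_bU)
    pb_d <- norm(molB, b1 - f_bD, b1 - 1L)
    sb <- "-"
  } else {
    pb_u <- norm(molB, b1 - f_bU, b1 - 1L)
    pb_d <- norm(molB, b2 + 1L, b2 + f_bD)
    sb <- "+"
  }
  prov <- data.frame(
    conformation = rep(c("c1", "c2", "c3", "c4"), each = 3L),
    part = rep(c("left", "repeat", "right"), 4L),
    molecule = c(rp$mol_a, rp$mol_a, rp$mol_a,
                 rp$mol_b, rp$mol_a, rp$mol_b,
                 rp$mol_a, rp$mol_a, rp$mol_b,
                 rp$mol_b, rp$mol_a, rp$mol_a),
    start = c(pa_u[1], a1, pa_d[1],
              pb_u[1], a1, pb_d[1],
              pa_u[1], a1, pb_d[1],
              pb_u[1], a1, pa_d[1]),
    end = c(pa_u[2], a2, pa_d[2],
            pb_u[2], a2, pb_d[2],
            pa_u[2], a2, pb_d[2],
            pb_u[2], a2, pa_d[2]),
    strand = c("+", "+", "+",
               sb, "+", sb,
               "+", "+", sb,
               sb, "+", "+"),
    stringsAsFactors = FALSE)

  structure(list(repeat_pair = rp, flank = flank,
                 c1 = conf[["c1"]], c2 = conf[["c2"]],
                 c3 = conf[["c3"]], c4 = conf[["c4"]],
                 rep_start = left_len + 1L,
                 rep_end = left_len + replen,
                 flank_left = left_len, flank_right = right_len,
                 repeat_length = replen,
                 provenance = prov),
            class = "ConformationSet")
}

#' @export
print.ConformationSet <- function(x, ...) {
  cat(sprintf("<ConformationSet> %s (%s, %d bp repeat, flank %d)\n",
              x$repeat_pair$hsp_id, x$repeat_pair$orientation,
              x$repeat_length, x$flank))
  for (lbl in c("c1", "c2", "c3", "c4"))
    cat(sprintf("  %s: %d bp\n", lbl, nchar(x[[lbl]])))
  invisible(x)
}

#' Whole-molecule recombination products of a repeat pair
#'
#' Recombination between the two copies of a dispersed repeat rearranges
#' whole chromosomes:
#' \itemize{
#'   \item intra-molecular \emph{inverted} pair: the segment between the
#'     copies is inverted (one product molecule, same length);
#'   \item intra-molecular \emph{direct} pair: the circle splits into two
#'     smaller circles, each retaining one repeat copy;
#'   \item inter-molecular \emph{direct} pair: the two circles fuse into
#'     one, retaining both copies;
#'   \item inter-molecular \emph{inverted} pair: also a single fused circle,
#'     with one parent flipped (flagged in `note`).
#' }
#'
#' @param genome List of circular `Molecule`s.
#' @param rp A single repeat pair (see [build_local_conformations()]).
#' @return An object of class `RecombProduct`: `kind`
#'   (`inversion`/`split`/`fusion`), `molecules` (list of `Molecule`),
#'   `mediated_by`, `note`.
#' @export
build_genome_products <- function(genome, rp) {
  genome <- as_genome(genome)
  rp <- as_repeat_pair(rp)
  molA <- genome[[rp$mol_a]]
  molB <- genome[[rp$mol_b]]
  if (molA$topology != "circular" || molB$topology != "circular")
    stop("recombination products are defined for circular molecules")
  intra <- rp$mol_a == rp$mol_b
  inverted <- rp$orientation == "inverted"
  note <- NA_character_

  if (intra) {
    L <- molA$length
    # rotate so copy A starts at position 1; copy B then lies fully ahead
    rot <- rotate_molecule(molA, rp$start_a)
    shift <- function(x) circ_norm(x - rp$start_a + 1L, L)
    a2 <- shift(rp$end_a); b1 <- shift(rp$start_b); b2 <- shift(rp$end_b)
    if (b1 <= a2 || b2 < b1)
      stop("repeat copies overlap; cannot build products")
    if (inverted) {
      kind <- "inversion"
      mid <- if (b1 - a2 > 1L)
        reverse_complement(substr(rot$seq, a2 + 1L, b1 - 1L)) else ""
      seqs <- list(paste0(substr(rot$seq, 1L, a2), mid,
                          substr(rot$seq, b1, L)))
      ids <- paste0(molA$id, "_inv_", rp$hsp_id)
    } else {
      kind <- "split"
      seqs <- list(substr(rot$seq, 1L, b1 - 1L), substr(rot$seq, b1, L))
      ids <- paste0(molA$id, c("_splitA_", "_splitB_"), rp$hsp_id)
    }
  } else {
    kind <- "fusion"
    if (inverted) {
      molB <- molecule(molB$id, reverse_complement(molB$seq), "circular")
      LB <- molB$length
      nb1 <- LB - rp$end_b + 1L
      nb2 <- LB - rp$start_b + 1L
      note <- "orientation_flipped"
    } else {
      nb1 <- rp$start_b; nb2 <- rp$end_b
    }
    rA <- rotate_molecule(molA, rp$start_a)
    rB <- rotate_molecule(molB, nb1)
    lenA <- interval_length(molA, rp$start_a, rp$end_a)
    lenB <- interval_length(molB, nb1, nb2)
    # copyA + arcB + copyB + arcA: both recombinant junctions present
    seqs <- list(paste0(substr(rA$seq, 1L, lenA),
                        substr(rB$seq, lenB + 1L, rB$length),
                        substr(rB$seq, 1L, lenB),
                        substr(rA$seq, lenA + 1L, rA$length)))
    ids <- paste0(molA$id, "_", molB$id, "_fused_", rp$hsp_id)
  }
  mols <- lapply(seq_along(seqs), function(i) molecule(ids[i], seqs[[i]],
                                                       "circular"))
  structure(list(kind = kind, molecules = mols, mediated_by = rp$hsp_id,
                 note = note),
            class = "RecombProduct")
}

#' @export
print.RecombProduct <- function(x, ...) {
  cat(sprintf("<RecombProduct> %s mediated by %s\n", x$kind, x$mediated_by))
  for (m in x$molecules) print(m)
  invisible(x)
}

#' Write a ConformationSet to FASTA
#'
#' @param cs A `ConformationSet`.
#' @param path Output FASTA.
#' @export
write_conformations <- function(cs, path) {
  stopifnot(inherits(cs, "ConformationSet"))
  id <- cs$repeat_pair$hsp_id
  lines <- unlist(lapply(c("c1", "c2", "c3", "c4"), function(lbl) {
    c(paste0(">", id, "_", lbl, " linear"), cs[[lbl]])
  }))
  writeLines(lines, path)
  invisible(path)
}
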
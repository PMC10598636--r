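# Evaluate code under a given RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  code
}

#' Random DNA sequence at a target GC content
#'
#' Bases are i.i.d. with P(G) = P(C) = gc/2. Uses the current RNG stream.
#'
#' @param n Length in bp.
#' @param gc Target GC fraction.
#' @return Character scalar.
#' @export
random_dna <- function(n, gc = 0.445) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate a two-chromosome circular plant mitogenome at 44.5% GC
#' (desk scale: 50 kb + 20 kb chromosomes standing in for the study-sized
#' 868 kb + 154 kb ones) plus an optional plastome for MTPT planting.
#'
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @param molecules List of `list(id, length, topology)` mitochondrial
#'   chromosomes.
#' @param gc GC fraction of the random background.
#' @param repeats List of planted repeat pairs:
#'   `list(length, identity, orientation, mol_a, pos_a, mol_b, pos_b)`.
#'   Copy B is copied from copy A (reverse-complemented when `orientation =
#'   "inverted"`) and degraded to the requested identity by interior
#'   substitutions.
#' @param ssr_plants List of `list(molecule, motif, copies, pos)` perfect
#'   SSRs written over the background.
#' @param plastome `list(id, length, topology)` or `NULL`.
#' @param mtpt_plants List of
#'   `list(mito_molecule, mito_pos, plastid_start, plastid_end)` plastome
#'   segments copied into the mitogenome.
#' @param boundary_pad Number of bases flanking each planted repeat/MTPT
#'   copy that are forced to differ from the partner copy's context, so the
#'   planted coordinates are the true maximal homology boundaries and
#'   planted-truth recovery is exact. The default (20) makes a local
#'   alignment extension across the pad score about -60 under typical
#'   nucleotide scoring, which chance similarity beyond the pad cannot
#'   repay.
#' @return List of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       molecules = list(
                         list(id = "MC1", length = 50000L,
                              topology = "circular"),
                         list(id = "MC2", length = 20000L,
                              topology = "circular")),
                       gc = 0.445,
                       repeats = list(),
                       ssr_plants = list(),
                       plastome = NULL,
                       mtpt_plants = list(),
                       boundary_pad = 20L) {
  stopifnot(gc > 0, gc < 1)
  structure(list(seed = as.integer(seed), molecules = molecules, gc = gc,
                 repeats = repeats, ssr_plants = ssr_plants,
                 plastome = plastome, mtpt_plants = mtpt_plants,
                 boundary_pad = as.integer(boundary_pad)),
            class = "SimConfig")
}

# set chars[idx] (1-based, already wrapped) to a random base != forbidden
mutate_away <- function(chars, idx, forbidden) {
  bases <- c("A", "C", "G", "T")
  for (j in seq_along(idx)) {
    choices <- setdiff(bases, forbidden[j])
    chars[idx[j]] <- choices[sample.int(3L, 1L)]
  }
  chars
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

#' Generate a synthetic genome with planted features and a truth manifest
#'
#' Background bases are i.i.d. at the configured GC. Repeat pairs are
#' planted by copying (and, for `identity < 1`, degrading by substitutions
#' confined to the copy interior so the end points stay the optimal local-
#' alignment boundaries); perfect SSRs and plastome segments are written
#' over the background with 1-base guards / divergent pads so the planted
#' coordinates are exactly maximal. Planted features must not overlap;
#' infeasible placements raise an error before any output.
#'
#' @param cfg A [sim_config()].
#' @return List: `genome` (mito `Molecule`s), `plastome` (`Molecule` or
#'   `NULL`), and `manifest` with data.frames `repeats`, `ssrs`, `mtpts`.
#' @export
make_genome <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_seed(cfg$seed, make_genome_impl(cfg))
}

make_genome_impl <- function(cfg) {
  pad <- cfg$boundary_pad
  lens <- stats::setNames(
    vapply(cfg$molecules, function(m) as.integer(m$length), 0L),
    vapply(cfg$molecules, `[[`, "", "id"))

  # ---- feasibility: collect footprints (feature +/- pad) per molecule ----
  claims <- list()
  claim <- function(mol, s, e, what) {
    claims[[length(claims) + 1L]] <<- list(mol = mol, s = s, e = e,
                                           what = what)
  }
  for (rp in cfg$repeats) {
    len <- rp$length
    claim(rp$mol_a, rp$pos_a - pad, rp$pos_a + len - 1L + pad, "repeat")
    claim(rp$mol_b, rp$pos_b - pad, rp$pos_b + len - 1L + pad, "repeat")
  }
  for (sp in cfg$ssr_plants)
    claim(sp$molecule, sp$pos - 1L,
          sp$pos + nchar(sp$motif) * sp$copies, "ssr")
  for (mp in cfg$mtpt_plants)
    claim(mp$mito_molecule, mp$mito_pos - pad,
          mp$mito_pos + (mp$plastid_end - mp$plastid_start) + pad, "mtpt")
  for (mol_id in unique(vapply(claims, `[[`, "", "mol"))) {
    if (!mol_id %in% names(lens))
      stop("planted feature on unknown molecule ", mol_id)
    L <- lens[[mol_id]]
    cl <- Filter(function(x) x$mol == mol_id, claims)
    iv <- do.call(rbind, lapply(cl, function(x) {
      if (x$e - x$s + 1L > L) stop("feature longer than molecule ", mol_id)
      c(circ_norm(x$s, L), x$e - x$s + 1L)
    }))
    # unwrap onto a doubled axis: two copies L apart detect circular overlap
    starts <- iv[, 1]; ends <- iv[, 1] + iv[, 2] - 1L
    ir <- IRanges::IRanges(start = c(starts, starts + L),
                           end = c(ends, ends + L))
    if (any(IRanges::countOverlaps(ir) > 1L))
      stop("planted features overlap on molecule ", mol_id,
           " (pads included); adjust placements")
  }

  # ---- background ----
  seqs <- lapply(cfg$molecules, function(m) {
    strsplit(random_dna(m$length, cfg$gc), "", fixed = TRUE)[[1]]
  })
  names(seqs) <- names(lens)
  plast <- NULL
  if (!is.null(cfg$plastome)) {
    plast <- strsplit(random_dna(cfg$plastome$length, cfg$gc),
                      "", fixed = TRUE)[[1]]
  }

  # ---- repeats ----
  rep_rows <- list()
  for (rp in cfg$repeats) {
    len <- as.integer(rp$length)
    identity <- if (is.null(rp$identity)) 1 else rp$identity
    inv <- rp$orientation == "inverted"
    La <- lens[[rp$mol_a]]; Lb <- lens[[rp$mol_b]]
    ia <- circ_norm(rp$pos_a + 0:(len - 1L), La)
    ib <- circ_norm(rp$pos_b + 0:(len - 1L), Lb)
    src <- seqs[[rp$mol_a]][ia]
    cp <- if (inv) rev(comp_base(src)) else src
    nmut <- round((1 - identity) * len)
    if (nmut > 0) {
      # keep a clean margin at both copy ends so the planted interval stays
      # the optimal local-alignment block (ends never trim away)
      margin <- 10L
      if (len - 2L * margin < nmut) margin <- max(1L, (len - nmut) %/% 3L)
      if (len - 2L * margin < nmut)
        stop("repeat too short for requested identity")
      at <- sample((margin + 1L):(len - margin), nmut)
      cp <- mutate_away(cp, at, cp[at])
    }
    seqs[[rp$mol_b]][ib] <- cp
    # Divergent context pads: the `pad` bases flanking copy A are drawn
    # from {A, C} and those flanking copy B from the alphabet that is
    # disjoint after strand normalization ({G, T} for direct pairs, {A, C}
    # for inverted ones, whose subject strand is read as the complement).
    # Every alignment column crossing the pads then mismatches, whatever
    # gaps the aligner inserts, so the planted ends are the true maximal
    # local-alignment boundaries.
    if (pad > 0L) {
      ctx_a <- circ_norm(c(rp$pos_a - seq_len(pad),
                           rp$pos_a + len - 1L + seq_len(pad)), La)
      ctx_b <- circ_norm(c(rp$pos_b - seq_len(pad),
                           rp$pos_b + len - 1L + seq_len(pad)), Lb)
      alpha_b <- if (inv) c("A", "C") else c("G", "T")
      seqs[[rp$mol_a]][ctx_a] <- sample(c("A", "C"), 2L * pad,
                                        replace = TRUE)
      seqs[[rp$mol_b]][ctx_b] <- sample(alpha_b, 2L * pad, replace = TRUE)
    }
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      mol_a = rp$mol_a, start_a = circ_norm(rp$pos_a, La),
      end_a = circ_norm(rp$pos_a + len - 1L, La),
      mol_b = rp$mol_b, start_b = circ_norm(rp$pos_b, Lb),
      end_b = circ_norm(rp$pos_b + len - 1L, Lb),
      orientation = rp$orientation, length = len, identity = identity,
      stringsAsFactors = FALSE)
  }

  # ---- SSRs ----
  ssr_rows <- list()
  for (sp in cfg$ssr_plants) {
    k <- nchar(sp$motif)
    if (motif_period(sp$motif) != k)
      stop("planted SSR motif ", sp$motif, " is not primitive")
    L <- lens[[sp$molecule]]
    len <- k * sp$copies
    idx <- circ_norm(sp$pos + 0:(len - 1L), L)
    seqs[[sp$molecule]][idx] <-
      strsplit(strrep(sp$motif, sp$copies), "", fixed = TRUE)[[1]]
    # guards: the base before must not extend the period, nor the base after
    before <- circ_norm(sp$pos - 1L, L)
    after <- circ_norm(sp$pos + len, L)
    seqs[[sp$molecule]] <- mutate_away(seqs[[sp$molecule]], before,
                                       substr(sp$motif, k, k))
    seqs[[sp$molecule]] <- mutate_away(seqs[[sp$molecule]], after,
                                       substr(sp$motif, 1L, 1L))
    ssr_rows[[length(ssr_rows) + 1L]] <- data.frame(
      molecule = sp$molecule, start = circ_norm(sp$pos, L),
      end = circ_norm(sp$pos + len - 1L, L), unit_size = k,
      motif = sp$motif, copies = sp$copies, stringsAsFactors = FALSE)
  }

  # ---- MTPTs ----
  mtpt_rows <- list()
  for (mp in cfg$mtpt_plants) {
    if (is.null(plast)) stop("mtpt_plants given but no plastome configured")
    Lp <- length(plast)
    L <- lens[[mp$mito_molecule]]
    pidx <- circ_norm(mp$plastid_start:mp$plastid_end, Lp)
    len <- length(pidx)
    midx <- circ_norm(mp$mito_pos + 0:(len - 1L), L)
    seqs[[mp$mito_molecule]][midx] <- plast[pidx]
    # disjoint-alphabet pads, as for planted repeats: mito context {G, T},
    # plastid context {A, C}
    if (pad > 0L) {
      ctx_m <- circ_norm(c(mp$mito_pos - seq_len(pad),
                           mp$mito_pos + len - 1L + seq_len(pad)), L)
      ctx_p <- circ_norm(c(mp$plastid_start - seq_len(pad),
                           mp$plastid_end + seq_len(pad)), Lp)
      seqs[[mp$mito_molecule]][ctx_m] <- sample(c("G", "T"), 2L * pad,
                                                replace = TRUE)
      plast[ctx_p] <- sample(c("A", "C"), 2L * pad, replace = TRUE)
    }
    mtpt_rows[[length(mtpt_rows) + 1L]] <- data.frame(
      mito_molecule = mp$mito_molecule, mito_start = circ_norm(mp$mito_pos, L),
      mito_end = circ_norm(mp$mito_pos + len - 1L, L),
      plastid_start = mp$plastid_start, plastid_end = mp$plastid_end,
      length = len, stringsAsFactors = FALSE)
  }

  bind_or_empty <- function(rows, proto) {
    if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
    else proto
  }
  genome <- lapply(cfg$molecules, function(m) {
    molecule(m$id, paste(seqs[[m$id]], collapse = ""),
             if (is.null(m$topology)) "circular" else m$topology)
  })
  names(genome) <- names(lens)
  plast_mol <- if (!is.null(plast))
    molecule(cfg$plastome$id, paste(plast, collapse = ""),
             if (is.null(cfg$plastome$topology)) "circular"
             else cfg$plastome$topology)
  list(genome = genome, plastome = plast_mol,
       manifest = list(
         repeats = bind_or_empty(rep_rows, data.frame()),
         ssrs = bind_or_empty(ssr_rows, data.frame()),
         mtpts = bind_or_empty(mtpt_rows, data.frame()),
         config = cfg))
}

#' Conformational mixture at a true recombination frequency
#'
#' Builds the weighted population of molecules a long-read library would
#' sample from when a fraction `rf_true` of genome copies carry the
#' recombinant arrangement at repeat `rp`.
#'
#' With `level = "local"` the population is the four local conformation
#' templates around the repeat, weighted `(1 - rf)/2, (1 - rf)/2, rf/2,
#' rf/2`; with `level = "genome"` it is the parent molecule(s) at weight
#' `1 - rf` and the whole-molecule recombination product(s) at weight `rf`
#' (weight split within a state in proportion to molecule length).
#'
#' @param genome List of `Molecule`s.
#' @param rp A repeat pair row.
#' @param rf_true True recombination frequency in `[0, 1]`.
#' @param level `"local"` or `"genome"`.
#' @param flank Flank length for local templates.
#' @return Object of class `conformation_mixture`: `molecules`, `weights`,
#'   and (local level) the `ConformationSet`.
#' @export
make_mixture <- function(genome, rp, rf_true, level = c("local", "genome"),
                         flank = 1000L) {
  level <- match.arg(level)
  stopifnot(rf_true >= 0, rf_true <= 1)
  genome <- as_genome(genome)
  if (level == "local") {
    cs <- build_local_conformations(genome, rp, flank)
    mols <- lapply(c("c1", "c2", "c3", "c4"), function(lbl) {
      molecule(lbl, cs[[lbl]], "linear")
    })
    w <- c((1 - rf_true) / 2, (1 - rf_true) / 2, rf_true / 2, rf_true / 2)
    structure(list(molecules = mols, weights = w, conformations = cs,
                   rf_true = rf_true, level = level),
              class = "conformation_mixture")
  } else {
    rp <- as_repeat_pair(rp)
    prod <- build_genome_products(genome, rp)
    parents <- unique(c(rp$mol_a, rp$mol_b))
    pmols <- genome[parents]
    split_w <- function(mols, total) {
      lens <- vapply(mols, `[[`, 0L, "length")
      total * lens / sum(lens)
    }
    mols <- c(pmols, prod$molecules)
    w <- c(split_w(pmols, 1 - rf_true), split_w(prod$molecules, rf_true))
    structure(list(molecules = unname(mols), weights = unname(w),
                   product = prod, rf_true = rf_true, level = level),
              class = "conformation_mixture")
  }
}

# substitution/insertion/deletion noise on a character vector of bases;
# returns list(seq, n_sub, n_ins, n_del)
apply_errors <- function(chars, sub, ins, del) {
  L <- length(chars)
  if (sub + ins + del <= 0) {
    return(list(seq = paste(chars, collapse = ""), n_sub = 0L, n_ins = 0L,
                n_del = 0L))
  }
  u <- stats::runif(L)
  i_sub <- which(u < sub)
  i_ins <- which(u >= sub & u < sub + ins)
  i_del <- which(u >= sub + ins & u < sub + ins + del)
  out <- chars
  if (length(i_sub)) out <- mutate_away(out, i_sub, chars[i_sub])
  if (length(i_ins)) {
    bases <- c("A", "C", "G", "T")
    out[i_ins] <- paste0(out[i_ins],
                         bases[sample.int(4L, length(i_ins),
                                          replace = TRUE)])
  }
  if (length(i_del)) out[i_del] <- ""
  list(seq = paste(out, collapse = ""), n_sub = length(i_sub),
       n_ins = length(i_ins), n_del = length(i_del))
}

#' Simulate long reads from a molecule population
#'
#' Each read picks a molecule by weight, a uniform start (uniform over the
#' circle for circular molecules), a uniform strand, and a lognormal length
#' truncated at the molecule length; substitution/insertion/deletion errors
#' are applied at the configured per-base rates. Truth labels live in a
#' sidecar table, not in the read ids.
#'
#' @param population A `conformation_mixture`, or a list of `Molecule`s
#'   (uniform weights).
#' @param n Number of reads.
#' @param seed Integer seed.
#' @param meanlog,sdlog Lognormal read-length parameters (defaults give a
#'   median around 8 kb, echoing a Nanopore long-read library).
#' @param sub,ins,del Per-base error rates (each in `[0, 0.2]`).
#' @param min_length Shortest read emitted.
#' @return List: `reads` (data.frame `read_id`, `seq`) and `truth`
#'   (data.frame `read_id`, `molecule`, `start`, `length`, `strand`,
#'   `n_sub`, `n_ins`, `n_del`).
#' @export
simulate_reads <- function(population, n, seed = 1L,
                           meanlog = log(8000), sdlog = 0.5,
                           sub = 0.05, ins = 0.025, del = 0.025,
                           min_length = 50L) {
  stopifnot(sub >= 0, ins >= 0, del >= 0, sub <= 0.2, ins <= 0.2, del <= 0.2)
  if (inherits(population, "conformation_mixture")) {
    mols <- population$molecules
    w <- population$weights
  } else {
    mols <- as_genome(population)
    w <- rep(1, length(mols))
  }
  w <- w / sum(w)
  with_seed(seed, {
    idx <- sample.int(length(mols), n, replace = TRUE, prob = w)
    lens <- pmax(min_length, round(stats::rlnorm(n, meanlog, sdlog)))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    reads <- character(n)
    truth <- data.frame(read_id = sprintf("read%05d", seq_len(n)),
                        molecule = character(n), start = integer(n),
                        length = integer(n), strand = strands,
                        n_sub = integer(n), n_ins = integer(n),
                        n_del = integer(n), stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      m <- mols[[idx[i]]]
      L <- m$length
      len <- min(lens[i], L)
      start <- if (m$topology == "circular") sample.int(L, 1L)
               else sample.int(L - len + 1L, 1L)
      raw <- subseq_raw(m, start, start + len - 1L)
      if (strands[i] == "-") raw <- reverse_complement(raw)
      err <- apply_errors(strsplit(raw, "", fixed = TRUE)[[1]], sub, ins, del)
      reads[i] <- err$seq
      truth$molecule[i] <- m$id
      truth$start[i] <- start
      truth$length[i] <- len
      truth$n_sub[i] <- err$n_sub
      truth$n_ins[i] <- err$n_ins
      truth$n_del[i] <- err$n_del
    }
    list(reads = data.frame(read_id = truth$read_id, seq = reads,
                            stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Write simulated reads to FASTQ
#'
#' @param reads data.frame with `read_id` and `seq` (from
#'   [simulate_reads()]).
#' @param path Output FASTQ.
#' @param quality_char Constant per-base quality character.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  lines <- unlist(lapply(seq_len(nrow(reads)), function(i) {
    c(paste0("@", reads$read_id[i]), reads$seq[i], "+",
      strrep(quality_char, nchar(reads$seq[i])))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read FASTQ/FASTA reads into a data.frame
#'
#' @param path Reads file (FASTQ or FASTA, plain text).
#' @return data.frame with `read_id` and `seq`.
#' @export
read_reads <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) {
    return(data.frame(read_id = character(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  if (startsWith(first, "@")) {
    set <- Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    set <- Biostrings::readDNAStringSet(path, format = "fasta")
  }
  data.frame(read_id = sub("\\s.*$", "", names(set)),
             seq = as.character(set), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Simulate an edited cDNA from a CDS
#'
#' Applies C-to-T conversions at the given CDS positions (the DNA image of
#' C-to-U editing) and, optionally, low-rate random substitution noise at
#' non-edit positions emulating Sanger read errors.
#'
#' @param cds Genomic CDS sequence.
#' @param edit_positions Integer positions (1-based); each must hold `C`.
#' @param seed Seed for the noise (ignored when `noise = 0`).
#' @param noise Per-base substitution probability at non-edit positions.
#' @return Character scalar, the cDNA sequence.
#' @export
simulate_cdna <- function(cds, edit_positions, seed = 1L, noise = 0) {
  cds <- toupper(cds)
  chars <- strsplit(cds, "", fixed = TRUE)[[1]]
  if (length(edit_positions)) {
    bad <- edit_positions[chars[edit_positions] != "C"]
    if (length(bad))
      stop("no C at CDS position(s): ", paste(bad, collapse = ", "))
    chars[edit_positions] <- "T"
  }
  if (noise > 0) {
    with_seed(seed, {
      cand <- setdiff(which(stats::runif(length(chars)) < noise),
                      edit_positions)
      if (length(cand)) chars <- mutate_away(chars, cand, chars[cand])
    })
  }
  paste(chars, collapse = "")
}
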
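# Independent oracles and small fixture builders shared across tests.

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# smallest period of a motif (independent reimplementation for the oracle)
oracle_period <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0L && strrep(substr(motif, 1, d), k / d) == motif)
      return(d)
  }
  k
}

# Brute-force SSR scan: greedy backreference regex per unit size (leftmost,
# non-overlapping, integer copies), then drop motifs with a smaller period.
oracle_ssrs <- function(seq, thr) {
  rows <- list()
  for (k in 1:6) {
    m <- thr$min_copies[k]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, m - 1L)
    g <- gregexpr(pat, seq, perl = TRUE)[[1]]
    if (g[1] == -1L) next
    lens <- attr(g, "match.length")
    for (i in seq_along(g)) {
      motif <- substr(seq, g[i], g[i] + k - 1L)
      if (oracle_period(motif) != k) next
      copies <- lens[i] %/% k
      rows[[length(rows) + 1L]] <- data.frame(
        start = as.integer(g[i]), end = as.integer(g[i] + copies * k - 1L),
        unit_size = k, motif = motif, copies = copies,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(),
                      unit_size = integer(), motif = character(),
                      copies = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$unit_size), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# simple character-level reverse complement used as an oracle
oracle_revcomp <- function(s) {
  paste(rev(chartr("ACGTN", "TGCAN", strsplit(s, "")[[1]])), collapse = "")
}

# toy circle with an exact direct/inverted repeat planted at given positions
toy_repeat_genome <- function(L, rep_len, pos_a, pos_b,
                              orientation = "direct", seed = 1) {
  set.seed(seed)
  chars <- strsplit(rand_dna(L), "")[[1]]
  src <- chars[pos_a:(pos_a + rep_len - 1)]
  cp <- if (orientation == "inverted")
    rev(chartr("ACGT", "TGCA", src)) else src
  chars[pos_b:(pos_b + rep_len - 1)] <- cp
  mol <- molecule("toy", paste(chars, collapse = ""), "circular")
  rp <- list(hsp_id = "R1", mol_a = "toy", start_a = pos_a,
             end_a = pos_a + rep_len - 1, mol_b = "toy", start_b = pos_b,
             end_b = pos_b + rep_len - 1, orientation = orientation)
  list(mol = mol, rp = rp)
}
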
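---
title: "Methods: repeat-mediated recombination, SSR, MTPT and RNA-editing analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeat-mediated recombination, SSR, MTPT and RNA-editing analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoforma)
```

# Scope and model

Plant mitochondrial genomes recombine across dispersed repeats. The
assembled sequence is the *major* conformation; in the same DNA preparation
a fraction of molecules carries the recombined arrangement. `mitoforma`
treats each dispersed repeat pair independently and asks two questions:

1. **Which arrangements exist?** A conformation is *present* when at least
   one long read spans the entire repeat copy plus unique flank on both
   sides of it (the read could only derive from a molecule with that
   arrangement).
2. **At what frequency?** The recombination frequency at a repeat is the
   fraction of informative spanning reads assigned to the recombinant
   arrangements:
   RF = (n3 + n4) / (n1 + n2 + n3 + n4).

The per-repeat independence assumption matters: recombination events at
different repeats may be correlated on the same molecule, and the package
deliberately does not enumerate combined conformations across repeats —
each repeat is reported on its own. Reads are also counted at most once per
repeat, and a read spanning two repeats contributes to both reports
independently.

# Coordinates and circularity

All coordinates are 1-based inclusive, matching GenBank, BLAST and MISA
conventions. Circularity is *declared* (a `circular` token in the FASTA
header, or the default topology for mitochondrial input), never inferred.
On a circular molecule an interval with `start > end` wraps through the
origin; every extraction (`subsequence()`), flank computation and product
construction understands this. Self-alignment unwraps each circular
molecule by appending its first `circular_ext` (default 5000) bases, maps
hits back modulo the length, and removes the artefacts this creates
(self-identity hits, mirrored duplicates, partial echoes contained in a
longer hit).

# Repeat discovery

`self_align()` delegates the local alignment itself to BLASTN (word size
11, match +2, mismatch −3, gap open 5, gap extend 2, E ≤ 1e-5 — classic
`-task blastn` scoring, the standard choice when no scoring set is
prescribed); all of these are exposed in `align_params()`. HSP identifiers `R1, R2, ...` are assigned in descending
bitscore, ties broken by coordinates. The numbering is
implementation-defined: a different aligner build may split or merge HSPs
differently, so downstream selections should use coordinates or length
criteria (`match_named_repeats()`), not ids. Pairs whose two loci overlap
are tandem, not dispersed, repeats and are excluded from recombination
candidates by default. `expect_value()` implements the Karlin–Altschul
expectation E = K·m·n·exp(−λ·score) for diagnostic use.

# Conformation construction

With copy A read on the plus strand and copy B strand-normalized so both
copies present the repeat in the same reading direction:

* c1 = aU + R + aD and c2 = bU + R + bD (reference),
* c3 = aU + R + bD and c4 = bU + R + aD (recombinant).

`R` is copy A's sequence; for imperfect repeats the copies differ at interior
positions, which penalizes all four templates equally and therefore does not
bias classification. The flank default is 1000 bp. When two copies lie
closer than the flank length, the colliding flanks are truncated at the
midpoint of the intervening arc rather than skipping the repeat — the
classifier needs *some* unique anchor, and `min_anchor` later decides
whether the remaining anchor suffices. This truncation rule is a design
choice the upstream procedure leaves open.

Whole-molecule products follow the standard geometry: an intra-molecular
inverted pair inverts the segment between the copies (an involution); a
direct intra-molecular pair splits the circle into two circles whose
lengths sum to the parent's (each retains one copy); a direct
inter-molecular pair fuses two circles (both copies retained, both
recombinant junctions present). An inverted inter-molecular pair also
fuses, with one parent flipped; the product is flagged
(`note = "orientation_flipped"`). Note that an inversion conserves length
but *not* the single-strand base multiset — the inverted segment is
complement-swapped; tests assert the structural identity, not naive
composition.

# Read classification and RF

Each read and its reverse complement are aligned to c1–c4 with an ends-free
(overlap) dynamic programme in C++: match +1, mismatch −1, gap −1 per base.
Linear gap costs suffice because the templates are short (≤ 2·flank +
repeat) and only score *differences* between near-identical templates
matter. The DP is restricted to a diagonal band (half-width `band_width`,
default 100 — generous for ≤ 1 kb reads at ~10% indel rates) centred on a
seed diagonal found by looking up non-overlapping read 15-mers in a
per-template k-mer index and taking the modal offset. A (template, strand)
combination that shares no 15-mer with the read cannot plausibly be its
source and is skipped; if no combination has a seed the read is rejected
with reason `no_seed`. Setting `band_width = 0` forces full (unbanded,
seedless) DP.

Usability and assignment rules, in order:

* reads shorter than repeat + 2·`min_anchor` are rejected (`too_short`)
  without alignment;
* the best alignment must cover the entire repeat plus ≥ `min_anchor`
  (default 100 bp) of flank on both sides, else `no_span`;
* the best conformation must beat the runner-up conformation by
  ≥ `min_margin` (default 20 score points), else the read is `ambiguous`;
  exact ties are always ambiguous — never broken arbitrarily.

`min_anchor` = 100 and `min_margin` = 20 are package choices (the upstream
method states neither): 100 bp of unique anchor tolerates long-read error
rates while excluding repeat-only reads, and a margin of 20 under ±1
scoring requires ~20 bases of net evidence, far above noise on a 100 bp
anchor. Ambiguous and unusable reads are excluded from both the numerator
and denominator of RF. Uncertainty is summarized by the Wilson score
interval, which behaves sensibly at the boundaries (n3 + n4 = 0 gives a
lower bound of exactly 0).

# SSR scanning

`find_ssrs()` reports maximal perfect tandem repeats with unit sizes 1–6
and integer copy numbers, scanning each unit size left to right with greedy
non-overlapping consumption — deliberately the semantics of a
backreference regular expression, which is also the independent oracle used
by the test suite. A locus whose motif has a smaller period is reported at
the smaller unit size only; the motif is reported as written at the locus
start (no canonical rotation). `N` runs never form SSRs. Circular
molecules are scanned linearly, so an origin-spanning SSR is invisible —
exactly as a web scanner sees the same FASTA.

Two threshold presets are shipped because "MISA with defaults" is ambiguous
across MISA versions and front-ends: `"relaxed"` (mono ≥ 10, di ≥ 5, tri ≥ 4,
tetra/penta/hexa ≥ 3) — the setting under which tetramer loci can dominate
the count, as reported for the coffee mitogenome — and the historic MISA
web set `"misa-web"`
(10/6/5/5/5/5), under which tetramer and longer loci are much rarer. The
acceptance check against the deposited genome states which preset it uses;
on synthetic data both presets are tested against the oracle.

# MTPT detection

`find_mtpts()` performs the reciprocal search (mitogenome as query against
the plastome, then the roles reversed) with the same aligner and scoring as
repeat discovery, unions the two directions on mitochondrial coordinates
and merges intervals overlapping by ≥ 1 bp (`IRanges::reduce`). Merging is
forced by taking the union of two search directions; fragment *counts* are
therefore merge-dependent and secondary to total transferred bp, which is
the robust quantity. A gene is contained in a fragment only if every exon
lies entirely within the fragment's plastid interval — a 1 bp overhang
disqualifies.

# RNA-editing calling

The cDNA amplicon is aligned inside the genomic CDS with free end gaps
(`Biostrings::pairwiseAlignment`, type `"global-local"`); the amplicon's
offset is inferred, not supplied. Both frames are tried; when the reverse
complement aligns better, the normalization turns genome-strand G-to-A
mismatches into the canonical C-to-U representation automatically. An
amplicon below 90% identity is rejected (`unalignable amplicon`) rather
than force-called — mirroring how Sanger fragments contaminated by
homologous sequences cannot be resolved. Only C→U mismatches are edits;
every other substitution and all indels are logged as discrepancies.
Effects use the standard genetic code (plant mitochondria use it):
`stop_gain` when the edited codon is a stop, `synonymous` when the amino
acid is unchanged, else `nonsynonymous` (`stop_loss` is unreachable for
C→U since no stop codon contains C, but the class is kept for symmetry).
Site names follow the `gene-cds_pos` convention (e.g. `cox2-278`).

# The synthetic-data generator

`make_genome()` emulates the statistical structure the analysis assumes:
i.i.d. bases at configurable GC (default 0.445, the organellar value the
package targets), circular multichromosomal molecules, planted repeat
pairs (copied, optionally reverse-complemented, degraded to a target
identity by interior substitutions), perfect SSRs and plastome-derived
insertions, each recorded in a truth manifest sufficient to recompute every
expected output. Determinism is absolute: the same `SimConfig` yields
byte-identical output, and the generator's RNG use is isolated from the
caller's stream.

Three details make *exact* planted-truth recovery well-defined:

* **Disjoint-alphabet boundary pads.** The `boundary_pad` (20 bp) of
  context flanking one repeat copy is drawn from {A, C} and that flanking
  the partner copy from the alphabet disjoint after strand normalization.
  Any local-alignment column crossing the pads mismatches *regardless of
  gap placement*, so no chance similarity beyond the boundary can extend
  the optimal alignment and the planted interval is the unique maximal
  alignment block. (Per-base forced mismatches alone do not give this
  guarantee: a gap can shift the register into a lucky run.)
* **Interior-only degradation.** Identity-reducing substitutions avoid the
  outer 10 bp of the copy, so trimmed ends never outscore the planted ends.
* **SSR guards.** The base before a planted SSR differs from the motif's
  last base and the base after from its first, so the planted locus is
  exactly maximal.

Reads draw a molecule by weight, a uniform (circular) start, a uniform
strand and a lognormal length (default median ~8 kb, echoing a long-read
library; truncated at molecule length), then apply substitution, insertion
and deletion noise at configured per-base rates (defaults 5%/2.5%/2.5%).
Truth labels live in a sidecar table so the pipeline cannot read them.

What the generator does **not** emulate — and hence what green tests do not
show about real data: k-mer composition structure, homopolymer-biased
long-read errors, chimeric reads, coverage bias, heteroplasmy gradients
along molecules, and nuclear copies of organellar DNA (NUMTs). Results on
real libraries can be noisier than the synthetic benchmarks in exactly
those directions.

# Problem sizes and numerical choices

The test and acceptance workloads use desk-scale stand-ins chosen to keep
every statistic meaningful: 10–30 kb chromosomes (in place of the ~868 kb +
154 kb study genome), repeats of 100–1500 bp at identities 0.9–1.0, RF
experiments with 1,000 reads per replicate and 100 seeded replicates at
true RF ∈ {0.05, 0.2, 0.5}, 200 random sequences (≤ 5 kb) for the SSR
oracle comparison, and 100 random split/fusion geometries. The RF scenarios
at true values 0.54 and 0.20 mirror the two regimes reported for the study
genome (one high-frequency repeat at 0.54; all others ≤ 0.22).

Degenerate inputs are handled explicitly: empty read sets yield a "no
informative reads" report rather than an error; an all-N sequence has
undefined GC and raises; zero informative reads make RF undefined (`NA`)
while the per-class counts are still reported; `rf_true` outside [0, 1] and
infeasible planted placements abort before any output is written.

# Known limitations

* RF reproduction on real libraries depends on the mapper, anchor and
  ambiguity rules of the original analysis, which are unstated; agreement
  is expected within tolerance, not bit-exactly.
* HSP numbering is not reproducible across aligner builds; select repeats
  by coordinates or length.
* Multi-repeat haplotypes (one read phasing several repeats) are out of
  scope, as are assembly, annotation transfer, tandem-repeat (TRF-style)
  detection and machine-learned editing prediction.
* The SSR preset behind a web server's "default parameters" is ambiguous;
  both plausible presets are shipped and tested.
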
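---
title: "Methods: cryptic splice-site discovery and mRNA re-splicing"
author: "crypticsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cryptic splice-site discovery and mRNA re-splicing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions, parameters and design
choices behind `crypticsplice`, and what the package's tests do and do not
establish about real data.

## Coordinates and junction representation

All internal coordinates are 0-based, half-open; GTF input (1-based,
inclusive) is converted once at the boundary. A junction is stored as its
intron interval `[start, end)` on the plus strand, together with a strand.
"Donor" and "acceptor" always refer to transcriptional orientation and are
represented as *cut points*: the donor boundary is `start` on the plus
strand and `end` on the minus strand, the acceptor the other end. This
convention removes every ±1 ambiguity from junction arithmetic: the donor
cut of a plus-strand intron `[100, 200)` is 100, its first intronic base is
genomic position 100; on the minus strand the donor cut is 200 and the
first intronic base (in sense) is genomic 199. Windows around boundaries
(`extract_window()`) take `up`/`down` in sense space and return sequence in
sense orientation, so `up = 2, down = 0` at an acceptor always reads the
intron-terminal `AG` regardless of strand.

## Split-read quantification

A qualifying read is primary, mapped, not duplicate-flagged, and carries
`NM ≤ max_mismatches` (default 0; reads without an NM tag are excluded and
counted). Each CIGAR `N` operation on a qualifying read increments its
junction once, provided the shorter of the two aligned blocks flanking the
gap is at least `min_overhang` (default 8) nt. "No mismatches" is enforced
as `NM = 0`, which also excludes indel-bearing reads — the strictest
reading. Only primary alignments are counted, with no additional MAPQ
threshold, because that is the minimal deterministic rule. The overhang is
measured on aligned blocks (after soft-clipping), not on the raw read.
Library size is the number of qualifying primary mapped reads; normalized
counts are counts-per-million of that figure.

Junction strand comes from the `XS` tag when present, otherwise from the
intron-terminal dinucleotides (`GT..AG` forward implies plus, `CT..AC`
implies minus), otherwise the junction is stored unstranded and can only be
resolved against the annotation.

## PSI

The local percent-selected-index of junction *j* in sample *s* is

    PSI(j, s) = raw(j, s) / sum over k sharing j's donor or acceptor of raw(k, s)

including *j* itself. This is a deterministic local-splice-variant proxy
computable from counts alone; it deliberately diverges from Bayesian PSI
quantifiers, whose posteriors are not reproducible from a count table. PSI
is undefined (NA, never 0) when the denominator is zero.

## The filter cascade

Unannotated junctions (novelty is keyed on the full chromosome / strand /
donor / acceptor quadruple, so known sites in novel combinations count as
novel) pass three gates in order:

1. aggregate raw reads over all libraries ≥ `min_aggregate_reads` (5);
2. `(CPM_kd + 1) / (CPM_ctrl + 1) > 2` in at least `min_concordant_kd` (2)
   knockdown conditions;
3. `(PSI_kd + 0.01) / (PSI_ctrl + 0.01) > 2` in at least 2 knockdown
   conditions, with undefined PSI entering as 0.

All inequalities are strict. The pseudocounts (1 CPM for counts, 0.01 for
PSI) bound the ratios when control expression is zero — the typical case
for a cryptic junction — and are exposed in `pipeline_config()`. Fold
changes use normalized counts; the aggregate floor uses raw counts.

Raising any threshold can only shrink the emitted set (tested as a
property). A caveat the count-level noise study makes explicit: with a
single control library, one downward-fluctuating control draw inflates all
knockdown ratios at once, so at low baseline expression (~5 expected reads
per library) the cascade's false-call fraction is near 0.10 and its
sensitivity near 0.92 under negative-binomial noise with dispersion 0.1;
both improve steeply as baseline counts grow. These are properties of the
published filter under these conditions, not of the implementation.

## Classification and metagene positioning

Exactly one class per call: both ends annotated but the pair novel gives
`novel_alternative`; one annotated end with the novel end in annotated
exonic sequence gives `exonic_5ss` / `exonic_3ss` (novel donor / acceptor),
in intronic sequence `intronic_5ss` / `intronic_3ss`; anything else is
`unclassified` (a value, not an error). Point queries take the union over
transcripts; where overlapping transcripts disagree, exon takes precedence
over intron, because exonic de-repression is the conservative call for a
site that is exonic in any expressed isoform. The host gene is the gene of
the transcript carrying the annotated end; ties (shared sites across
overlapping genes) are broken by longest transcript, then lexicographic
gene id — a fixed, recorded convention for an attribution that annotation
data leave genuinely ambiguous.

Metagene distances are measured on the mature mRNA of the host transcript
(not the genome), because EJC deposition ~24 nt upstream of junctions is an
mRNA-space geometry; the sign is negative upstream. The
`within_ejc_footprint` flag marks sites within ±10 nt of −24; the 10-nt
half-width is a package choice exposed in the configuration.

## Splice-site and branchpoint models

Donor windows cover 3 exonic + 6 intronic nt (the AG|GTRAGT context),
acceptor windows 14 intronic + 3 exonic nt (polypyrimidine tract, terminal
AG, two exonic bases). Position weight matrices are per-column frequencies
with pseudocount 1, log2-odds against the pooled base frequencies of the
training windows, and min-max normalization: the column-wise consensus
scores exactly 1, the anti-consensus exactly 0. Normalized scores are
invariant to per-column affine shifts of the log-odds. Windows containing N
or clipped at a sequence end score as *missing*, never as 0.

The scorer is a deliberate stand-in for neural-network splice-site scores:
thresholds such as 0.75 ("strong site") are structurally analogous but not
numerically comparable to published network scores, which are treated as
qualitative weak/strong labels only.

The branchpoint model is derived from the 31-nt windows lying 15–45 nt
upstream of annotated acceptors (introns shorter than the window plus motif
width are skipped and counted), from up to 10,000 randomly sampled introns.
A one-occurrence-per-sequence EM finder fits a motif of width 7 (default;
the width is a configuration choice): the E-step computes the posterior
over motif start positions against a 0-order background, the M-step updates
frequencies from expected counts with Dirichlet pseudocount 1; 5 random
restarts, at most 200 iterations, convergence when the objective gains less
than 1e-6. The monitored objective is the pseudocount-penalized (MAP)
log-likelihood — the quantity EM provably never decreases; the raw
likelihood can dip by the prior term's magnitude, the penalized one cannot.
After the restarts, a phase-shift refinement re-seeds EM from ±1 and ±2
column shifts of the best motif and keeps improvements; without it,
one-occurrence EM converges to a shifted register in roughly a fifth of
planted-motif runs. "75% PWM match" for branchpoint scanning is read as
min-max normalized score ≥ 0.75, the common interpretation of
percent-PWM-match.

## Re-splicing scan

Exon-exon junction *i* of a transcript sits at the cumulative length of its
first *i* exons on the mRNA. A regenerated 5' SS requires `GT` as the first
two bases downstream of the junction, a regenerated 3' SS an `AG`
immediately upstream. Compatibility of a cryptic call requires only the
invariant dinucleotide at the partner junction: PWM scores are attached but
never thresholded, because experimentally functional regenerated sites span
the full score range down to zero — score does not predict function here.
The deletion runs from the cryptic cut to the partner junction cut; events
whose span touches a transcript end are dropped and counted; spans crossing
intermediate junctions keep only the terminal-junction partner and list the
intermediate cut points as metadata. Events computed on multiple host
transcripts are de-duplicated by identical mRNA sequence context.

Frame consequences intersect the deletion with the CDS in mRNA space:
fully inside and divisible by 3 is an in-frame deletion whose removed
amino-acid count comes from translating the reference and deleted CDS and
diffing; not divisible by 3 is a frameshift; crossing the CDS start or end
is flagged separately; UTR-only deletions and transcripts without CDS are
noncoding.

## The synthetic-data generator

The generator emulates the four-library knockdown design the pipeline
targets: one control (lacZ) and three core-EJC knockdowns (eIF4AIII, mago,
tsu). Defaults: 30 genes, 3–6 exons of 150–300 nt, introns of 70–140 nt,
canonical splice sites built on the GTAAGT / polypyrimidine–CAG consensus
with per-position fidelity 0.9 (invariant GT/AG always), a planted
CTAAT-like branchpoint 20–35 nt upstream of each acceptor, and splice-site
remnants written into exon termini with probabilities 0.54 (GT downstream)
and 0.57 (AG upstream) — the transcriptome-wide rates observed for such
remnants. Planted cryptic junctions (two per class by default) carry 2
control reads and an 8-fold increase in 2 or 3 knockdowns; responsiveness
in 2-or-3 rather than always-2 knockdowns reflects that the three core
factors are mutually required, so a truly suppressed junction tends to
respond to every depletion. Cryptic site sequence is rejection-sampled into
a target strength band against PWMs trained on the simulated annotation
itself. Reads are single-end 100-mers with `aM nN bM` CIGARs, uniform
overhangs of at least 8 nt on both sides, NM tags and XS strand tags, so
the quantifier's filters are exercised literally; counts are exact in
noise-free mode and negative-binomial (dispersion parameter, `size =
1/dispersion`) otherwise. The genome background is i.i.d. uniform ACGT; GC
structure, sequencing errors, paired ends and intron retention are out of
scope. Every draw derives from the seed, and a fixed seed reproduces all
output files byte for byte.

What passing tests therefore show: the pipeline's arithmetic, coordinate
handling, filters, classification and re-splice logic are correct on data
whose truth is known, across both strands. What they do not show: behavior
under alignment artifacts, non-uniform coverage, GC or mappability bias,
overlapping gene models, or annotation incompleteness in real libraries.

The noisy recovery study runs at the count layer
(`simulate_count_study()`): the negative-binomial noise model acts on
counts, and the read-level round trip is already verified exhaustively in
noise-free mode, so re-materializing reads for every noise replicate would
add runtime without adding evidence.

## Problem sizes and determinism

The shipped tests use 5–14 simulated genes for unit fixtures, a 100-gene
fixture for end-to-end recovery, 20 seeds of a 100-junction count study for
noise calibration, 50 runs of 200 windows for motif recovery, 10^5
permutations for the hypergeometric comparison and 500 × 2000 permutations
for the null-uniformity check, and 1,000 random transcripts for the
coordinate round-trip. All stochastic components take explicit seeds; the
permutation p-value uses the add-one correction and never returns zero.

## Known limitations

* PSI is a local proxy; junctions embedded in complex splicing graphs
  shared across many sites receive a denominator pooled over both ends.
* The splice-site scorer ranks sites consistently but its absolute scale is
  not comparable to published neural-network scores.
* With a single control library the filter cascade's error rates at low
  baseline expression are materially worse than with replicated controls;
  the package averages samples within a condition when replicates exist.
* Junction-to-gene attribution for sites shared by overlapping genes uses a
  fixed precedence (longest transcript, then gene id) and is recorded, but
  other conventions are defensible.
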
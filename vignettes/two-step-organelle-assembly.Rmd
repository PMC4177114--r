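---
title: "Two-step assembly of plastid and mitochondrial genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-step assembly of plastid and mitochondrial genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsapipe)
```

## The problem

Plant total-DNA libraries mix three genome compartments at wildly
different copy numbers: plastid DNA can be present at thousands of copies
per nuclear genome copy, mitochondrial DNA at tens of copies, and the
nuclear genome at one. A single mixed-organelle library therefore carries
both organelle genomes at assembly-grade depth while the nuclear genome
is barely covered — provided the assembly strategy exploits that depth
stratification and copes with the extensive sequence homology between the
plastid and mitochondrial genomes. `tsapipe` implements that strategy end
to end: qPCR-based purity quantification and dataset sizing, depth-aware
de Bruijn assembly, exact-match removal of plastid read pairs, reference-
guided draft construction, and strict iterative gap closure.

## Copy-fold quantification from qPCR

One marker amplicon per compartment (a plastid gene, a mitochondrial
gene, a nuclear gene) is cloned into a single control vector, so the
three amplicons are equimolar in the control. Each amplicon's relative
quantity in a DNA sample is the efficiency-corrected ratio

$$ Q = (1 + E)^{\,CT_\text{control} - CT_\text{sample}}, $$

where $E$ is the amplicon's own amplification efficiency ($E = 1$ is
perfect doubling) and $CT$ the cycle threshold. The organelle/nuclear
copy fold is the ratio of two such quantities. `copy_fold()` rounds the
two quantities to 4 decimals before taking the ratio: that is the
precision at which such tables are printed, and the integer folds quoted
alongside them are only reproducible from the rounded intermediates. An
`exact = TRUE` flag skips the intermediate rounding for scientific use
(the unrounded ratio is the better estimator, but its integer rounding
need not match a printed table). Integer folds use round-half-away-from-
zero. Copy folds double as expected sequencing depths: when a dataset
covers the nuclear genome once, each organelle is covered `copy_fold`
layers, so `required_bases()` sizes a dataset for a target organelle
depth (50 layers is a customary floor for a clean de novo assembly).

```{r}
nuc <- qpcr_measurement("actin", "nuclear", 1.124, 17.79, 23.70)
mit <- qpcr_measurement("ccmB", "mitochondrial", 1.060, 17.64, 17.87)
c(relative_quantity(mit), copy_fold(mit, nuc))
```

## What the simulator emulates — and what it does not

`make_genomes()` builds the three compartments with the two structural
features that drive the pipeline's hard cases:

* a **quadripartite plastid** — LSC + IRa + SSC + IRb, with IRb the exact
  reverse complement of IRa. The IR is the canonical large repeat that a
  unitig assembler must collapse;
* a **plastid-homologous tract** in the mitochondrion, copied verbatim
  from the plastid single-copy region. This is the homology trap: exact
  removal of plastid-matching read pairs deletes the tract's coverage and
  leaves a gap that only iterative anchored closure can repair.

`sample_read_pairs()` draws fragments multinomially with weights
`copy_fold × genome length`, samples circular molecules across the
origin, sequences both fragment ends inward (mate 1 forward, mate 2
reverse-complemented), and attaches truth labels in a sidecar table that
never leaks into the FASTQ. Insert sizes are normal, rounded to integers
and truncated at `[2 × read length, genome length]` — the source data are
described only as "approximately 500 bp", so a truncated normal is a
deliberate, minimal commitment. Defaults (100 nt reads, 500 ± 50 insert)
mirror the study library design.

Simplifications to keep in mind when interpreting green tests: simulated
nuclear sequence is i.i.d. uniform (no repeat families, so nuclear
contamination of organelle contigs is rarer than in real data); errors
are substitutions only (no indel errors, no quality decay along the
read); the mitochondrial tract is an *exact* plastid copy, whereas real
homologous tracts have diverged — near-exact homology makes the
plastid-removal step *less* destructive than our worst case, not more.
Passing tests therefore demonstrate the pipeline's mechanics (depth
stratification, pair removal, gap repair), not robustness to repeat-rich
nuclear genomes or high error rates.

## Assembly by depth stratification

`assemble_contigs()` builds a canonical (strand-symmetric) de Bruijn
graph: kmers below `min_kmer_freq` and edges whose (k+1)-mer support is
below `min_edge_cov` are dropped, and maximal non-branching paths
(unitigs) are emitted. There is deliberately no bubble popping, tip
clipping or repeat threading: the two thresholds are the whole cleaning
model, which keeps the depth-stratification mechanism auditable. With
plastid depth ~20× the mitochondrial depth and ~2000× the nuclear depth,
a high frequency floor (step 1 default 100) retains only plastid kmers;
after plastid-pair removal, the standard floor (41/20/20) assembles the
mitochondrion while nuclear kmers (depth ≈ 1) stay far below threshold.

Numerical conventions: `k` must be odd, so no kmer equals its own reverse
complement and canonical orientation is always well defined; output
contigs are strand-normalised (lexicographic minimum of the two strands)
and ordered by length then sequence, so assembly output is byte-
deterministic; a unitig that closes a cycle is reported circular with the
duplicated `k−1` overlap trimmed. The IR collapses into a single contig
at double depth and the quadripartite plastid assembles into ≥ 2 contigs
— this is expected, and the draft builder recovers the layout.

## Exact placement and pair removal

All of the pipeline's filters are exact-match semantics, so
`map_reads()` is seed-and-verify with non-overlapping seeds: a read with
at most `m` mismatches over `m + 1` blocks must contain one exact block
(pigeonhole), so seeding each block start and verifying candidates by
full-length Hamming comparison misses no placement. `N` matches nothing,
including `N` — a gap base in a draft can never anchor a read. A pair is
removed as plastid when *either* end places on the assembled plastid with
zero mismatches; using the sample's own assembled plastid (rather than a
related reference) is what makes exact matching appropriate.

Depth reporting rounds to the nearest integer, and reads with several
placements count once per placement. For unbiased depth estimates the
pipeline restricts to *unique regions*: positions not covered by runs
(≥ `min_run`, default 100 nt — a documented choice, since "similar
region" has no canonical quantitative definition) shared between the two
organelle genomes, and additionally not covered by within-genome repeats
such as the IR, where per-placement counting would double the apparent
depth.

## Reference-guided drafts

`align_scaffold()` restricts anchors to kmers unique in the reference;
IR-internal sequence therefore never anchors, and an IR-only contig
aligns nowhere (its placement is recovered later by gap closure, from
reads anchored on unique flanks). Chains are the largest colinear anchor
subset per strand, ties broken toward `+`. For circular references the
chain may run across the origin; `build_draft()` then rotates the
reference frame so no scaffold straddles the origin, which is safe
because circular assemblies are compared up to rotation anyway.

Joins prefer exact sequence overlap (≥ `min_overlap`); otherwise the
reference-implied distance is written as Ns, but never fewer than
`gap_floor` (default 100), since the sample's true distance is only
estimated by the reference and the closure step will correct it.
Insertions relative to the reference survive untouched inside scaffolds —
the reference orders scaffolds, it never edits them. Conflicting claims
on one reference interval raise an error listing both scaffolds; the
method's manual ancestor resolved such conflicts by eye, and silent
automatic choices would hide real biology (or real misassembly).

## Strict iterative gap closure

Each cycle maps *all* clean reads to the current draft, keeps pairs with
at least one exactly-mapped end, and positions each kept pair's
unanchored mate over a gap flank using the anchored mate's position, the
insert model (± 3 SD) and inward orientation. Flanks grow base-by-base by
strict majority vote (> 50% of votes and ≥ `min_support`, default 3); a
tie stops extension at that base — a conservative, auditable stand-in for
black-box gap fillers. When the two extensions of a gap share an exact
overlap (≥ `k_check`, default 25) the gap closes and residual Ns vanish.
The loop repeats until nothing extends anywhere (the global reading of
"no longer extended": any extension anywhere continues the loop) or an
iteration cap (20) is reached.

Two wiring details matter. First, the mitochondrial closure maps the
**total** clean reads, not the plastid-depleted subset used for
mitochondrial contig assembly: reads from the homologous tract are
indistinguishable from plastid reads and were removed before assembly,
but once the draft exists they anchor to it exactly and are exactly the
material that fills the homology-trap gap. The two flanks extend toward
each other through the tract and meet in its interior, so neither
extension ever reaches the boundary where plastid-flank votes would
diverge from the true mitochondrial continuation. Second, the plastid
step's closure ("fill with all reads") uses the same anchored machinery:
a pair with no exactly-mapped end carries no placement information, so
restricting to anchored pairs discards nothing a voting extender could
use.

Safety invariants, all tested: non-gap bases are never rewritten; total N
count never increases; with error-free reads every written base matches
the truth; each productive iteration removes at least one N, so the
fixpoint is reached in finitely many iterations.

## Variant classification

`align_genomes()` chains unique shared anchors, compresses runs of
consistent anchors into exact-match blocks, and aligns only the short
inter-block segments globally (unit mismatch cost, affine gaps with open
2 / extend 1 — cheap enough for real indels, expensive enough that a
deletion–insertion pair never masquerades as a substitution run). A
maximal run of adjacent difference columns is one event — the merging
rule that defines the MNP and CV categories, which otherwise have no
standard quantitative definition: equal-length multi-base runs are MNPs,
one-sided events are indels, length-changing two-sided events are complex
variations (CV). Indels are left-aligned through homopolymers for
deterministic coordinates. Rearranged inputs fail loudly rather than
being mis-typed. Coding SNPs are translated strand-aware under the
standard genetic code; synonymy is reported only for SNPs (`NA`
otherwise).

## Problem sizes and verification scale

The package's own test battery runs the complete pipeline on a synthetic
triple chosen to exercise every mechanism at desk scale: a 15 kb
quadripartite plastid (8 kb LSC, 2 kb SSC, 2.5 kb IRs), a 20 kb
mitochondrion carrying a 1 kb plastid tract, a 50 kb nuclear background,
copy folds 100:10:1, and 55,000 error-free 100 nt pairs (≈ 630× plastid,
≈ 63× mitochondrial, ≈ 6× nuclear). These sizes keep a full end-to-end
run in tens of seconds while preserving the ratios that make the method
work: organelle depths above the 50-layer assembly floor, an order of
magnitude between strata, and a homology tract wider than a read but
narrower than the span that anchored mates can bridge in a few cycles.
Both genomes are recovered byte-exactly (up to rotation and strand), and
the homology-induced mitochondrial gap is created and then closed by the
iterative loop.

## Known limitations

* Scaffolding by read pairs is not re-implemented; unitig contigs play
  the scaffold role and the reference supplies their order. A sample
  whose organelle genome is rearranged relative to its reference would
  need manual ordering.
* Exact-match semantics throughout: sequencing errors shrink the usable
  read set rather than being corrected. Real libraries should be
  quality-filtered (the QC rule here discards pairs with adaptor, > 10%
  N, or > 50% sub-Q5 bases — strict inequalities) and benefit from low
  error rates.
* The gap-closure voter pool positions mates by a single insert-size
  model; libraries with mixed insert sizes would need per-library models.
* `align_genomes()` assumes colinearity; structural rearrangements are
  out of scope by design and raise errors instead of calls.
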
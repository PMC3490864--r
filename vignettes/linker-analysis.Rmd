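---
title: "Motif-anchored segmentation and analysis of cellulase linkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif-anchored segmentation and analysis of cellulase linkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellulinker)
```

## The problem

Secreted fungal and bacterial cellulases are frequently multi-modular: a
glycoside hydrolase (GH) catalytic domain, family 6 or 7, joined to a small
carbohydrate-binding module (CBM), family 1 (fungal) or family 2
(bacterial), by an intrinsically disordered linker peptide. Four
architectures are handled here, named N- to C-terminus: GH7/CBM1 and
CBM1/GH6 (eukaryotic), and CBM2/GH6 and GH6/CBM2 (bacterial). Linkers are
too divergent for ordinary alignment-based analysis, yet they carry
conserved *statistical* signatures — characteristic lengths per
architecture, strong serine/threonine/proline bias (S/T residues are
putative O-glycosylation sites), terminal glycine enrichment, and a striking
avoidance of N-glycosylation sequons (N-X-S/T with X ≠ P) in favour of N-P
motifs. `cellulinker` extracts linkers reproducibly and quantifies those
signatures.

## Segmentation model

Domain boundaries are not detected by HMMs or alignments but by short,
structurally motivated anchor motifs with fixed offsets:

* **CBM1/GH6** — signal peptides are trimmed by deleting everything more
  than 6 residues N-terminal to the first `QCGG`; the CBM ends after the
  `(S)QC(L)` motif; the catalytic domain starts 5 residues N-terminal to
  `(G)N(P)(F)`.
* **GH7/CBM1** — the catalytic domain ends 9 residues after the last
  residue of `S/T-N/D-I-K`; the CBM starts 6 residues N-terminal to `QCGG`,
  searched downstream of the GH cut.
* **CBM2/GH6** — the CBM ends 2 residues C-terminal to the last cysteine in
  a leading window (default 140 residues ≈ signal peptide + CBM2); the
  catalytic domain starts at `RVDN`, falling back to `YVD`.
* **GH6/CBM2** — the catalytic domain ends 8 residues after `FVML`; the CBM
  starts at the first C/L/I/F at least `min_linker` (default 10) residues
  downstream of the GH cut.

Parenthesised motif positions are *preferred but not required*: any residue
matches there, and competing matches are scored by how many preferred
residues they carry (`pick = "best"`, ties to the earliest position). This
replaces the original by-eye resolution on an alignment with a reproducible
rule. Several readings of the published rules were genuinely open; the
choices made here are:

* "cut after `(S)QC(L)`" assigns the L-position residue to the CBM (the cut
  falls immediately after the 4-residue match);
* "nine positions after the motif" counts from the motif's **last**
  residue, so the GH segment keeps the motif plus nine residues;
* the "absolutely conserved" CBM2 cysteine is operationalised as the last
  Cys inside a configurable leading window, because CBM2 contains several
  cysteines and the C-terminal one abuts the linker;
* the GH6/CBM2 C/L/I/F rule is guarded by `min_linker` because, read
  literally, it would fire on the first hydrophobic residue of the GH tail.

Coordinates are 1-based inclusive everywhere a user sees them (the
biologists' convention); a linker may legitimately be empty, and any record
whose anchors cannot be found is returned with a `failed` status and a
reason — never silently dropped (`batch_segment()` collects the failures).

## Statistics on linker sets

`length_stats()` reports mean, median, extremes, range and the sample
(n−1) standard deviation; survey-style tables round the mean to an integer
while keeping full precision in `average_exact`. Between-set length
comparisons use the classic pooled-variance two-tailed Student's t at
α = 0.05 (`welch = TRUE` switches to the unequal-variance variant, since
the exact variant used historically for these comparisons is unstated).
No multiple-testing correction is applied across the pairwise tests, by
design.

`positional_profile()` splits each linker into 11 approximately equal bins,
assigning residue *i* (1-based) of a length-*L* linker to bin
`floor((i−1)·11/L) + 1`, so remainder residues land in later bins —
deterministic, and a partition of every sequence. Densities are pooled:
group counts and position counts are summed across the set per bin *before*
dividing, so each bin is (group residues in bin)/(total residues in bin).
Linkers shorter than the bin count are retained (they simply leave some
bins empty for that sequence).

`sequon_scan()` counts N-X-S/T sequons (X ≠ P), N-P motifs, and totals.
All positional matches are counted, including overlapping ones; an N within
two positions of the C-terminus can only contribute to the N total. The two
motif classes are disjoint by construction.

## Alignment and trees

Percent-identity distributions use all-pairs global alignment rather than a
progressive multiple alignment: a three-state affine-gap dynamic program
(compiled) scored with the published Gonnet (1992) matrix, gap opening 10
charged at the first gapped column and 0.05 per additional column, end gaps
penalised. That gap ratio is unusual but is applied verbatim; both
penalties are arguments. Tie-breaking is deterministic (substitution over
gap-in-`a` over gap-in-`b`). Percent identity divides identities by aligned
columns including internal gaps but excluding terminal overhangs — a
configurable, commonly used convention. The move from progressive MSA to
pairwise alignment is a deliberate substitution: it preserves the
linker-vs-structured-domain conservation contrast that the identity
histograms exist to show, without reimplementing a proprietary aligner.

Trees are neighbor joining (via `ape`) on the distance `100 − identity`,
with negative branch lengths clamped to zero. NJ is exact on additive
metrics, which the test suite exercises; here its role is purely to expose
divergent clades (ruminal-fungal and proteobacterial outliers sit on their
own branch), after which `exclude_subset()` removes them from the core
comparisons.

## The synthetic generator: a stated world

`generate_dataset()` emits motif-bearing stub proteins so that every stage
runs, and can be validated, offline. Its defaults *are* the stated world of
the analysis:

* lengths per class are truncated normals with mean/SD/min/max
  30/7/16/47 (GH7_CBM1), 42/8/25/61 (CBM1_GH6), 35/13/16/65 (CBM2_GH6),
  34/17/14/75 (GH6_CBM2), and survey sizes 79/39/25/15;
* eukaryotic composition S = 0.25, T = 0.30, P = 0.15 (S+T ≈ 55%);
  bacterial S = 0.10, T = 0.30, P = 0.35; the ruminal-fungal outlier class
  is 45% N with S+T ≈ 5%, and the proteobacterial outlier class is
  glycine-rich (G = 0.25) with S = 0.30/T = 0.10 as specified — noting that
  the source statements about that class's S/T split are internally
  inconsistent, which is recorded rather than resolved;
* bacterial classes couple the proline fraction to length
  (0.003/residue), eukaryotic classes do not — reproducing the
  proline-vs-length trend contrast.

Positional structure is imposed by composition-preserving *swaps*, not
resampling: terminal-bin S/T residues are exchanged with interior glycines
(probability 0.3), and the residue after an asparagine is exchanged with a
proline from elsewhere in the linker (probability 0.6). Swapping means the
marginal composition stays exactly at its target while terminal glycine
enrichment, terminal S/T depletion, and the N-P sequon-avoidance bias all
appear — so composition recovery and positional-profile tests do not fight
each other.

Linker alphabets exclude C, I, L, F, M, R, V, W, Y and H. That mimics the
hydrophobic/aromatic depletion of real disordered linkers, and it has a
deliberate engineering consequence: no segmentation anchor can fire inside
a generated linker, so exact boundary recovery is a designed invariant of
the generator/segmenter pair, tested at 100% over hundreds of records.
Structured domains are low-entropy filler templates (drawn from an alphabet
that likewise cannot spell any anchor motif) with a 5% per-record mutation
rate; outlier records and the GH7 endoglucanase subfamily use
deterministically diverged template variants, which is what makes
outlier-clade separation and the exo/endo identity split emerge in the
alignment stage. The stubs are *not* biologically realistic domains — a
green test establishes that the pipeline's arithmetic and rules are
correct, not that real GenBank records will always segment cleanly.
Real linker length distributions are also visibly non-normal; the
truncated normal is a stated simplification. Genus labels cycle through
per-class pools sized so that roughly 82% of GH7/CBM1 genera recur in
CBM1/GH6 but only ~60% in the reverse direction, emulating the asymmetric
genus overlap of the real surveys.

## Numerical and degenerate-input choices

* Zero-length linkers count in length statistics but are excluded (with a
  warning) from per-linker composition ratios — there is nothing to divide.
* Two constant, equal samples give t = 0, p = 1; constant unequal samples
  give ±Inf, p = 0, rather than an error.
* `find_motif()` returns `NA` on no match; severity is the caller's
  decision.
* Histogram bins are half-open `[k·w, (k+1)·w)`; the final identity bin
  `[95, 100]` is closed so perfect identity is counted.
* Reruns of `run_full_analysis()` with the same seed and configuration are
  byte-identical; the manifest deliberately contains no timestamps.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(out_dir = "linker_run", seed = 1)
res <- run_full_analysis(cfg)
res$tables$length_stats
res$tables$sequons
```

This writes one TSV per analysis stage (segmentation table, linker FASTA,
length statistics and histograms, t-test matrix, composition, trends,
positional profiles, sequon table, identity histograms), Newick trees for
the two datasets that carry outlier clades, and `manifest.json`.

## Limitations

Segmentation handles exactly the four named architectures; there is no
HMM fallback for records whose anchors have drifted. The generator's
stubs cannot stand in for real structured domains in any structural sense.
Percent identity from pairwise alignment is not numerically identical to
percent identity read off a progressive MSA, so conservation contrasts
should be read qualitatively. EC-based exo/endo splitting uses metadata
only; the secondary criterion based on gaps in catalytic loops is out of
scope.
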
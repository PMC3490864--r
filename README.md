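# cellulinker

Segmentation and sequence analysis of cellulase linker regions.

Multi-modular cellulases couple a glycoside hydrolase (GH) catalytic domain
(family 6 or 7) to a carbohydrate-binding module (CBM, family 1 or 2)
through an intrinsically disordered linker peptide. The linkers are too
divergent to study by ordinary alignment, but they carry conserved
statistical signatures: architecture-specific lengths, heavy
serine/threonine/proline bias (every S/T is a putative *O*-glycosylation
site), glycine enrichment where linkers meet structured domains, and a
strong avoidance of *N*-glycosylation sequons (N-X-S/T, X ≠ P) in favour of
sequon-blocking N-P motifs.

`cellulinker` is for sequence analysts working on cellulases (or other
multidomain carbohydrate-active enzymes) who need those signatures computed
reproducibly. It provides:

* **Motif-anchored segmentation** of the four architectures GH7/CBM1,
  CBM1/GH6, CBM2/GH6 and GH6/CBM2 into CBM, linker and catalytic domain.
  Cuts are anchored on short conserved motifs with fixed offsets — e.g. for
  CBM1/GH6, trim the signal peptide to 6 residues before `QCGG`, end the
  CBM after `(S)QC(L)`, start the GH domain 5 residues before `(G)N(P)(F)`
  — where parenthesised positions are preferred-but-not-required and
  competing matches are scored by preferred residues matched.
* **Linker statistics**: length summaries (mean/median/max/min/range/SD),
  5-residue length histograms, pooled amino-acid composition, pooled-variance
  Student's *t* between sets, OLS trends of residue-group content vs
  length, and genus-overlap percentages.
* **Positional profiles**: each linker split into 11 approximately equal
  bins (residue *i* of length *L* goes to bin `floor((i−1)·11/L)+1`), with
  per-bin density = pooled group counts / pooled positions.
* **Sequon statistics**: overlapping-match counts of N-X-S/T sequons, N-P
  motifs, and N/P/residue totals per set and combined.
* **Alignment & phylogenetics**: exact affine-gap global alignment
  (three-state Gotoh, compiled; Gonnet 1992 scoring; gap open 10 charged at
  the first gapped column, extend 0.05 per additional column), all-pairs
  percent-identity matrices and histograms, EC-number exo/endo splitting,
  and neighbor-joining trees on `100 − identity` for outlier-clade
  detection.
* A **seeded synthetic generator** producing motif-bearing stub proteins
  with per-record truth tables, so the entire pipeline is testable offline.

## Worked example

```r
library(cellulinker)
set.seed(42)

# a CBM1/GH6-architecture dataset: 39 core records plus 5
# ruminal-fungal-like outliers, with truth tables
gen <- generate_dataset("CBM1_GH6", n = 39, n_outliers = 5)
gen$dataset
#> <cellu_dataset> CBM1_GH6: 44 record(s)
#>   subset flags: core=39, ruminal_fungi=5

# segment everything; outliers drag the maximum linker length past 100
batch_segment(gen$dataset)$linkers
#> <linker_set> CBM1_GH6: n=44, lengths 30-128

# drop the divergent clade and summarise the core linkers
core <- exclude_subset(gen$dataset, "ruminal_fungi")
#> exclude_subset: removed 5 record(s) flagged 'ruminal_fungi' from CBM1_GH6
lk <- batch_segment(core)$linkers
length_stats(lk)
#> <length_stats> n=39  average=43  median=42  max=58  min=30  range=28  sd=6.3

# N-glycosylation sequons are rare; N-P motifs are not
aggregate_sequons(lk)
#> <sequon_counts> sequons=15  N-P=43  N=75  P=230  residues=1677

# putative O-glycosylation sites are uniform mid-linker, depleted at the
# termini where glycines take over
positional_profile(lk, c("S", "T"))
#> <positional_profile> residues {S,T}, 11 bins
#>  [1] 0.461 0.558 0.641 0.555 0.583 0.623 0.616 0.568 0.582 0.583 0.336
```

The length summary reads like a survey table row (average 43, median 42,
SD 6 residues for this seed's CBM1/GH6 core set); the sequon counts show
the N-P bias (43 of 75 asparagines immediately precede a proline, only 15
begin a sequon); the 11-bin profile shows S/T density flat across the
linker interior and depressed in the terminal bins.

`run_full_analysis(pipeline_config(out_dir, seed))` chains every stage —
simulate (or read FASTA + metadata TSV), build NJ trees, exclude outlier
subsets, segment, then write length/t-test/composition/trend/profile/
sequon/identity tables, Newick trees, and a `manifest.json` — all
byte-reproducible from the seed.

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch against the
installed package (synthetic four-class bundle at the survey sizes, seeded
from `--seed`), prints the resulting linker length table, and writes the
acceptance JSON to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

* `R/seqio.R` — FASTA and metadata-TSV I/O, dataset assembly, subset
  exclusion
* `R/segmentation.R` — motif matcher and the four cutting schemes
* `R/linkerstats.R` — lengths, histograms, t-tests, trends, genus overlap
* `R/composition.R` — composition, positional profiles, sequon scanning
* `R/alignphylo.R`, `src/align.cpp` — alignment, identity matrices, NJ trees
* `R/synthetic.R` — the generator and its class specifications
* `R/pipeline.R` — end-to-end orchestration and report writing
* `vignettes/linker-analysis.Rmd` — the methods notes: model assumptions,
  parameter choices, generator design, numerical conventions, limitations
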
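# gh57csr

Conserved-sequence-region (CSR) fingerprinting for the α-amylase family
GH57.

Family GH57 proteins — α-amylases, amylopullulanases,
4-α-glucanotransferases, branching enzymes, maltogenic amylases,
α-galactosidases and their relatives — are not alignable over their full
lengths. What they share are five short conserved regions which,
concatenated, form a 36-position fingerprint: CSR-1 (positions 1–5),
CSR-2 (6–11), CSR-3 (12–17), CSR-4 (18–27), CSR-5 (28–36). Position 15
carries the catalytic nucleophile (Glu) and position 20 the proton donor
(Asp); positions 1, 12, 23 and the terminal pair 35–36 are diagnostic of
the enzyme specificity (e.g. K23 in 4-α-glucanotransferases, the YY
terminus of α-amylases, the invariant G35–W36 of α-galactosidases).
"Like" proteins are homologues that have lost one or both catalytic
residues.

The package implements the full in silico workflow around that
fingerprint, for sequence analysts working on amylolytic families:

* **Detection** — per-CSR position-specific scoring profiles and an
  exact dynamic program that places the five windows (ordered,
  non-overlapping, minimum spacer) to maximize total log₂-odds;
  sequences lacking a region are eliminated against a per-CSR score
  floor (0.3 × profile consensus score by default).
* **Classification** — machinery status (`complete` iff E15 and D20),
  nearest-profile specificity assignment, like-group relabeling for
  incomplete machinery, diagnostic-position agreement flags.
* **Logos** — per-position residue frequencies and Shannon information
  content, `IC = log2(20) + Σ p·log2 p` (bits).
* **Phylogeny** — p-distance over the 36 columns, Saitou–Nei neighbor
  joining (deterministic tie-breaks), column bootstrap, and a
  per-group monophyly score.
* **Synthetic data** — a generator that emulates the family's study-set
  structure (14 groups, 1602 members, 383 archaeal / 1219 bacterial,
  group-specific fingerprints and mean lengths, knockout "like" members,
  dropout decoys), so the pipeline is fully testable offline.

## Worked example

```r
library(gh57csr)

cfg <- synthetic_config()              # study-scale defaults, seed 1602
ds  <- generate_dataset(cfg)           # 1634 sequences incl. 32 decoys
pr  <- train_profiles(cfg)

det <- detect_fingerprints(ds$sequences, pr$detect)
table(det$status)
#> accepted eliminated
#>     1580         54

asg <- classify_fingerprints(det, pr$classify)
head(summarize_assignments(asg, setNames(ds$truth$taxonomy, ds$truth$id)))
#>          group   n n_archaea n_bacteria
#> 1         4AGT 106        39         67
#> 2    4AGT-like  61         0         61
#> 3         AAMY 151        97         54
#> 4    AAMY-like 125        60         65
#> 5         AGAL  14        14          0
#> 6 AGAL-related  15         0         15
```

The numbered drivers under `analysis/` run the same workflow end to end
and write their tables under `results/`:

```text
$ Rscript analysis/01_simulate.R   # results/synthetic/{sequences.fasta,truth.tsv}
generated 1634 sequences (32 decoys) into results/synthetic
archaeal 383 / bacterial 1219 among labeled members

$ Rscript analysis/02_detect.R     # results/fingerprints.tsv
detection recall 98.4% (1576/1602 true members accepted)
coordinate exactness 99.1% among accepted
decoys eliminated: 28/32

$ Rscript analysis/03_classify.R   # results/{assignments,summary}.tsv
label accuracy 100.00% on 1576 accepted members
machinery-status accuracy 100.00%
top summary rows: GBE 539, APU 260, NSA 170, AAMY 151, AAMY-like 125

$ Rscript analysis/04_logos.R      # results/logos.json, per-group TSVs
AAMY           n= 151  IC15=4.32 IC20=4.32 bits  pos23=T  pair35-36=YY
GBE-like       n=  59  IC15=1.02 IC20=0.85 bits  pos23=L  pair35-36=FA
...

$ Rscript analysis/05_tree.R       # results/tree.nwk, monophyly.tsv
tree over 195 leaves, 100 bootstrap trials
monophyly fraction: min 1.000 (4AGT), mean 1.000
```

Reading the logo lines: 4.32 bits is `log2 20`, i.e. an invariant column
— enzyme groups keep E15/D20 perfectly, while the like groups' eroded
information content at those positions (here 1.02/0.85 bits) is exactly
the substituted-machinery signature.

`detect_fingerprints()` accepts any protein FASTA via `read_fasta()`, so
real GH57 sequences can be scanned with the same profiles.

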
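---
title: "CSR fingerprinting of the α-amylase family GH57: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CSR fingerprinting of family GH57}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gh57csr)
```

## The problem

Family GH57 is the "second" α-amylase family: a set of archaeal and
bacterial glycoside hydrolases whose catalytic domain is an incomplete
(β/α)~7~ TIM-barrel. Its members are too divergent to align over their full
lengths; what they share are five short conserved sequence regions (CSRs).
Concatenated in order, the CSRs give a 36-position *fingerprint* —
CSR-1 = positions 1–5, CSR-2 = 6–11, CSR-3 = 12–17, CSR-4 = 18–27,
CSR-5 = 28–36 — that carries essentially all of the usable comparative
signal: the catalytic nucleophile (Glu, position 15) and proton donor
(Asp, position 20), and a handful of diagnostic positions (1, 12, 23, 35,
36) whose residues differ systematically between enzyme specificities
(e.g. Lys at 23 for 4-α-glucanotransferases, the terminal Tyr–Tyr pair of
α-amylases, the invariant Gly before Trp in α-galactosidases).

`gh57csr` turns that fingerprint logic into a reproducible pipeline:

1. **detect** the five CSRs in a protein sequence and extract the
   fingerprint, eliminating sequences that lack a region;
2. **classify** each fingerprint into one of nine enzyme-specificity
   groups or their "like"-protein counterparts (homologues that have lost
   one or both catalytic residues);
3. compute **sequence-logo matrices** (per-position residue frequencies
   and Shannon information content);
4. build a **neighbor-joining tree** from fingerprint p-distances with a
   column bootstrap.

A synthetic-data generator reproduces the statistical structure of the
family's study set (14 groups, 1602 members, 383 archaeal / 1219
bacterial) so that every stage can be validated against known truth with
no database access.

## The detection model

CSR location is profile scanning, not multiple alignment. From a training
set of fingerprints we build, per CSR, a position-specific scoring matrix:
frequencies `(count + pseudocount) / (n + 20 · pseudocount)` converted to
log~2~-odds against a uniform background. For a candidate sequence, the
five windows are placed by an exact dynamic program that maximizes total
log-odds subject to ordering and a minimum spacer (default 5 residues)
between consecutive regions; ties break toward the leftmost placement so
results are deterministic. Residues outside the 20-letter alphabet score
0 (the background expectation).

Elimination — the operational form of discarding sequences that
"obviously lack" a CSR — compares each placed window's score against a
floor, by default 0.3 × the profile's own consensus score. Two choices
matter here and both were settled by measurement during design:

* **Per-group scanning.** Scanning runs once per group profile set (all
  14 groups, like-protein sets included with their substituted catalytic
  residues) and keeps the best-scoring placement. A single pooled profile
  was tried first and rejected: pooled columns are mixtures over groups,
  so members of minority groups and like proteins score systematically
  low and the floor eliminates them wholesale. With per-group scanning
  the floor is calibrated against a profile the sequence can actually
  match, and behaves uniformly across groups.
* **Profile smoothing.** Training uses add-one smoothing (pseudocount 1
  on 60 training fingerprints per group). With sharper profiles a single
  mismatched position costs ≈ −2.8 bits, so two or three point
  substitutions inside a 6-residue CSR can push an otherwise perfect
  placement below the floor; add-one bounds the penalty near −2 bits and
  makes elimination a test for the *presence* of a region rather than a
  penalty on point variation.

On the default synthetic study set this yields ≈ 98% detection recall,
≈ 99% coordinate exactness, and ≈ 90% elimination of dropout decoys.
Sequences whose CSR-3 is essentially destroyed by noise are the residual
failure mode; in the original analysis such uncertain CSRs were resolved
by structure modelling, which is deliberately out of scope here.

## Classification

Machinery status is a pure function of the fingerprint: complete iff
position 15 is Glu and position 20 is Asp, otherwise
nucleophile-/donor-/both-substituted. The best base group is the argmax of
total log-odds against the nine enzyme-group profiles (ties break by
count of agreeing diagnostic flags, then group name). A best score below
the threshold (default 0, permissive — the real study set contained
exactly one unclassifiable sequence) yields "unclassified"; an incomplete
machinery assigns the partner like group of the best base group;
otherwise the base group itself. Diagnostic-position disagreement is
recorded as a warning, never a veto: several once-unique features
(tryptophan pairs, the position-23 residues) are no longer strictly
invariant in the family, so hard vetoes would misclassify legitimate
members.

## Logos

Logo matrices use plain counting (no pseudocount — display convention)
and per-column Shannon information content
`IC = log2(20) + Σ p·log2 p`, without the small-sample correction that
WebLogo applies by default. Omitting the correction keeps closed-form
values exact (an invariant column is exactly `log2 20 ≈ 4.322` bits, a
uniform column exactly 0), which is what the tests pin down; for display
purposes alongside WebLogo output the difference is a constant per n.

## The tree

Distances between fingerprints are p-distances (mismatch fraction over
the 36 columns, ambiguous positions excluded pairwise) — the simplest
defensible choice given that only "an alignment of the five CSRs" is
specified upstream; the metric is pluggable. Neighbor joining follows the
Saitou–Nei agglomeration with the standard Q-criterion and branch-length
formulas, ties broken toward the smallest index pair, and negative branch
lengths clamped to zero with the deficit moved to the sibling edge (the
usual practical convention). Support values come from the classical
column bootstrap: resample the 36 fingerprint columns with replacement,
rebuild distances and tree, and score each original internal edge by the
fraction of trials containing the same bipartition. The conventional
default is 1000 trials; desk-scale runs and tests use 100. Trees are
subsampled to ≤ 200 leaves (stratified by label, at least one per group)
to keep the bootstrap inside interactive runtimes; with 36 columns the
within-group edges have low support by construction, so the informative
quantity is the support of group-separating edges.

`monophyly_fraction` quantifies what the published tree asserts visually:
for each labeled group, 1 if some edge isolates exactly that group's
leaves, otherwise the best Jaccard overlap between the group and any
edge-induced leaf set. Terminal edges count, so singleton groups are
trivially 1.

## What the generator emulates — and what it does not

Each group has a 36-residue consensus built in two layers: a family-wide
base consensus (CSRs are, by definition, the best conserved segments of
the *whole* family) from which each enzyme group mutates 6 of the 29
non-diagnostic positions, with redraws until every pair of group consensi
differs at ≥ 8 free positions. Diagnostic positions are set by the rule
table (or inherit the family base where no rule is documented). Like
groups are modelled as lineages beside their partner enzyme: the partner
consensus mutated at 12 free positions, with each emitted member then
losing the nucleophile, the donor, or both (probabilities 0.4/0.4/0.2).
The divergence values are design choices: 6 keeps the family-wide CSR
conservation that makes detection meaningful, and 12 is large enough that
like lineages form their own clusters beside the partner clade — the
qualitative structure the real family tree shows. Members are emitted by
flipping each free consensus position with probability 1 − conservation
(default conservation 0.9, a stand-in — real per-position conservation is
only published as logo graphics), embedding the five CSR blocks in
uniform-composition linker, with total length Normal(group mean,
0.1 × mean) and the non-CSR residues apportioned across the six segments
by a symmetric Dirichlet(2) with a 5-residue minimum spacer.

Known departures from real data: no phylogenetic correlation within
groups (members are i.i.d. around the consensus, so within-group tree
structure is star-like noise); uniform linker composition; length is the
only per-group covariate; and the generator enforces that like members
never retain the full catalytic pair, whereas the real like groups
contain documented exceptions with complete machinery. Consequently,
passing tests demonstrate the *pipeline's* correctness under the family's
statistical structure, not performance on real GH57 sequences; on real
data the detection floor and the classification threshold are the knobs
that would need attention.

## Numerical and degenerate-input conventions

* Fingerprint and full-sequence coordinates are 1-based inclusive.
* "Aromatic" means {F, W, Y, H}; His is included conservatively.
* DP ties → leftmost placement; NJ Q-ties → smallest (i, j); score ties
  in classification → diagnostic-flag count, then lexicographic name.
* Sequences shorter than 36 + 4 × spacer are eliminated as "too short";
  empty fingerprint sets and non-probability logo columns are errors.
* The single unclassifiable sequence of the real study set is modelled by
  the catch-all "unclassified" label, not a fifteenth group; like-group
  members with complete machinery (the documented exceptions) would pass
  through as base-group assignments with a warning flag rather than being
  forced into a like group.
* All randomness flows from one integer seed; derived streams (consensus,
  dataset, training, subsample, bootstrap) are split arithmetically so
  stages can be reproduced in isolation.

## Problem sizes used by the shipped analyses

The `analysis/` drivers and the acceptance script run the full
1602-sequence study-scale dataset through detection and classification,
and a 200-leaf stratified subsample with 100 bootstrap trials through the
tree stage; unit tests use a ~200-sequence configuration with the same
group structure. These sizes were chosen so a complete run stays within a
few minutes on one CPU while every group, including the singleton
maltogenic-amylase-like "group", is exercised.
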
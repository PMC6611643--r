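---
title: "Methods: quantifying the evolution of kinase substrate specificity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the evolution of kinase substrate specificity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinevo)
```

## Overview

Eukaryotic protein kinases phosphorylate serine/threonine acceptors whose
surrounding residues (the substrate motif, e.g. R-x-x-S/T or S/T-P) are
read out by specificity-determining residues (SDRs) in the kinase domain.
`kinevo` provides a tested pipeline for asking how this specificity evolves
across a kinase phylogeny:

1. score, per alignment column, the divergence between a kinase
   family/subfamily and its sister clade from ancestral sequence
   posteriors;
2. aggregate "switch" events across many such comparisons and test their
   enrichment in functional residue categories;
3. compare substrate preferences directly as position weight matrices
   (PWMs) under the Frobenius distance, with a data-derived threshold for
   calling a pair of kinases "specificity-diverged";
4. discover phosphorylation motifs in species phosphoproteomes against
   shuffled-flank backgrounds and test their enrichment with a
   superset-conditioned binomial statistic;
5. date the origin of kinase groups/families/subfamilies on a species tree
   under a two-state Markov model; and
6. relate kinome composition to motif usage with phylogenetic comparative
   statistics.

Every stage consumes plain-text files (FASTA, Newick, TSV) or objects
produced by the built-in synthetic generators, so the whole pipeline is
testable without any external database.

## The divergence score

For a focal clade A (a family or subfamily) and its nearest sister clade B,
each alignment column receives

$$S = RC_A - AC_X \cdot p(AC),$$

where

* **RC** (recent conservation) is the mean substitution-matrix similarity
  over all unordered residue pairs of clade A at that column. The default
  matrix is BLOSUM62 rescaled linearly over its 20×20 standard-residue
  range so that the minimum entry maps to 0 and the maximum (W–W) to 1;
  pairs involving a gap contribute 0 and columns with fewer than two
  residues are skipped. RC is therefore always in [0, 1].
* **AC** is +1 when the predicted ancestral residues of clade A and clade B
  are identical and −1 otherwise. An ancestral gap is treated as a symbol
  that never matches a residue.
* **p(AC)** weights the score by the confidence that AC was assigned
  correctly: the posterior probability of clade B's predicted residue when
  the ancestors match, and the summed posterior of all residues *other*
  than clade A's predicted residue when they differ.

S is bounded in [−1, 2]: a perfectly conserved column with confidently
matching ancestors scores 0, a fixed difference with certain ancestors
scores 2. The statistic looks for the burst-after-duplication signature: a
substitution on the branch separating two sister clades followed by
conservation within the focal clade.

### Clade selection

Comparisons are only scored when they are phylogenetically clean:

* the focal clade is the clade holding the most focal-label sequences
  while keeping spurious (non-focal) leaves strictly below 15% of the
  clade; when no such clade exists, the largest fully pure subclade is
  used instead;
* the sister is the other child subtree of the focal clade's parent (the
  largest one at a polytomy);
* both clades must hold at least 5 sequences, and below the top level the
  two clades' dominant labels must share the parent category (sister
  subfamilies must belong to the same family).

### Switch aggregation

Scores from all comparisons at one level are pooled after collapsing
comparisons that share the same unordered pair of ancestral nodes, so one
evolutionary event is counted once. The switch threshold is the 95th
percentile of the pooled scores, computed with the linear-interpolation
quantile (R's default type 7) and applied with *strict* exceedance; both
choices are fixed so thresholds are reproducible. Per-domain-position
switch counts are mapped through the alignment's column map (domain
positions 1–246 of the protein kinase domain model), and "frequently
switching" positions are those whose count strictly exceeds the 90th
percentile of the 246 counts. Category enrichment uses a one-sided Fisher
exact test (frequently switching × membership of any named functional
category) and a one-tailed Mann–Whitney test (normal approximation with
tie correction, no continuity correction, so identical samples give
exactly p = 0.5).

## Ancestral reconstruction

The package ships a single-rate marginal reconstructor so the score
pipeline can run end to end: Felsenstein pruning for site likelihoods and
the standard inside–outside computation for per-node residue posteriors,
under a reversible model (Poisson by default, LG optionally). Gaps are
fully ambiguous, the root is weighted by the equilibrium frequencies, and
argmax ties break alphabetically (and are flagged). Transition matrices
come from an eigendecomposition of the symmetrised rate matrix; entries
below 1e-12 are clipped and rows renormalised.

Two caveats are deliberate. Rate heterogeneity across sites (gamma
categories) is not implemented: the divergence score consumes posteriors,
not a reconstruction method, and production analyses can supply externally
computed posteriors through the ancestral-state TSV contract instead.
Consequently numerical equality with external reconstruction tools is not
asserted anywhere; the reconstructor is validated against exhaustive
enumeration over all internal-node assignments on small trees (tolerance
1e-10) and by re-rooting invariance under reversibility.

## Specificity models

PWMs are built from 15-mer target sites (7 residues either side of the S/T
acceptor): per flank position, probabilities are
(count + pseudocount)/(n + 20·pseudocount), with the padding character
`_` excluded from counts position by position and the centre column
excluded from the matrix. The default pseudocount is 0.5 per residue;
whatever value is chosen must be used consistently for every matrix that
enters a comparison, because the pseudocount shrinks all columns toward
uniformity and therefore shifts every distance.

Two models are compared by the Frobenius distance
$d = \sqrt{\sum_{ij} (a_{ij} - b_{ij})^2}$. The threshold separating
"specificity-conserved" from "specificity-diverged" pairs is derived by
subsampling: for each kinase with at least 50 annotated sites, two
independent subsamples of 25 sites (each drawn without replacement) are
turned into PWMs and their distance recorded; the threshold is the maximum
over all kinases and draws — the largest divergence explainable by
sampling noise alone. Whether the two subsamples should be disjoint is an
open choice; we draw them independently, which is slightly conservative
(it allows overlap, making same-kinase distances smaller on average and
the threshold tighter). The curated-data operating point 1.06 ships as the
constant `SPECIFICITY_DIVERGENCE_THRESHOLD`; synthetic pipelines derive
their own with `derive_threshold()`.

Within/between comparisons at the group, family and subfamily levels
always retain the higher-level categorisation: families are compared only
within a group, subfamilies only within a family, and the two distance
samples are contrasted with a two-sided Kolmogorov–Smirnov test.

## Motif discovery and enrichment

Backgrounds are built by shuffling each foreground site's 14 flank
characters 10 times with the centre fixed, so foreground and background
have identical composition — a stricter null than sampling random S/T
windows from the proteome. Discovery is greedy, motif-x style: repeatedly
add the (position, residue) constraint with the smallest binomial p-value
against the current background subset, accepting a constraint only when
p < 1e-6 and at least 20 foreground sites remain; emitted motifs remove
their matching foreground sites and the background shuffles generated from
them before extraction restarts. One numerical choice matters here: deep
constraints can leave the conditional background subset small, where the
observed background frequency is an unstable point estimate of the null
(near-zero cells would admit spurious deep constraints). The step null is
therefore taken as the upper 99.9% Beta-posterior quantile of the
background frequency rather than the raw proportion; with a large
background subset the bound converges to the observed frequency, and with
a small one a constraint is accepted only when its foreground enrichment
exceeds what background-estimation noise could explain. Ties break on smaller p-value, then
smaller absolute position, then alphabetical residue, making discovery
deterministic.

Enrichment of a motif is judged relative to its *most frequent superset
motif*: the motif with one constraint removed, choosing the removal that
maximises background matches (for single-constraint motifs the superset is
the bare S/T centre). With k foreground motif matches among n foreground
superset matches and null probability p0 = background motif matches /
background superset matches, the p-value is the exact upper binomial tail
P(Bin(n, p0) ≥ k). Conditioning on the superset asks "is the added
constraint enriched given the rest of the pattern", which prevents a deep
motif from inheriting significance from its classical core. For motifs
with three or more constraints, the one-constraint-removed superset is our
reading of "most frequent superset"; the alternative (always conditioning
on the classical core) would be less conservative.

Cross-species filtering merges motifs under the synonym classes R/K, D/E
and L/I/V/M (applied at the merge stage, not during discovery), then
retains a motif if it appears in at least a third of the species of some
superphylum, or at least 2 excavate species; motifs exclusive to
single-species superphyla (amoebozoa, heterokonts) are discarded, as are
motifs whose only additions over a classical motif are S/T constraints
(phosphosite misassignment produces exactly these) and motifs adding only
further D/E constraints to the casein-kinase-2 core S/T-D/E-x-D/E.
Phosphoproteome coverage then counts sites matching at least one retained
motif, excluding single-constraint motifs except the classic S/T-P and
R-x-x-S/T signatures.

## Dating kinase-unit origins

Presence/absence of each kinase unit across taxa is modelled with the
equal-rates two-state Markov model: one rate q, fitted by bounded
one-dimensional search of the pruning likelihood, with a flat prior on the
root state. All-present (or all-absent) units return a boundary flag with
the rate at the search floor rather than a spurious estimate. Marginal
presence probabilities at every node come from the same inside–outside
machinery as the sequence reconstructor; polytomies are handled natively
by the pruning recursion. The origin of a unit is the deepest node whose
presence probability strictly exceeds 0.5 while its parent's does not;
multiple candidate origins are resolved to their most recent common
ancestor with a multiple-origin flag (assuming no horizontal transfer or
convergent gain). The 0.5 threshold is a configurable choice — nodes at
exactly the threshold count as absent. Ages are looked up in a
user-supplied divergence-time table, with the uncertainty interval running
from the origin node's age to its parent's (unbounded at the root).

## Comparative statistics

Kinome–phosphoproteome coevolution is tested with phylogenetic independent
contrasts (Felsenstein's recursion via `ape::pic`, polytomies resolved
deterministically into zero-length bifurcations), regressing motif
enrichment contrasts on relative-kinase-frequency contrasts *through the
origin* — the only valid form for contrasts — with a two-sided p-value on
n−1 degrees of freedom for n contrasts. Because the axis quantity "motif
enrichment value" is not uniquely defined, the package takes log10 fold
enrichment (bounded, symmetric around zero) as its default and leaves the
choice to the caller.

Phylogenetic signal is summarised by Blomberg's K (statistic computed by
`phytools::phylosig`; the permutation p-value is computed in-package as
the add-one-corrected fraction of tip-shuffled datasets with K at least
the observed value, so it is never exactly zero and is reproducible under
a seed) and Pagel's λ (ML estimate bounded by positive-definiteness, with
a likelihood-ratio test against λ = 0). Other signal statistics (Abouheif
C, Moran's I, K*) are out of scope.

## The synthetic-data layer

The generators emulate each input at the scale the test surface needs:

* `simulate_family_alignment()` evolves sequences down a tree under a
  single-rate replacement process (uniform exchangeabilities by default —
  the score test needs controlled divergence, not realism) and implants
  switch residues after the branch leading into a named clade, fixing them
  in the whole clade. It returns the *true* ancestral states as point-mass
  posteriors, optionally blurred with a Dirichlet centred on the truth to
  probe the p(AC) weighting.
* `sister_family_battery()` packages the canonical recovery experiment:
  two sister clades of 20 leaves on short internal branches (0.25) with
  unit terminal branches, 500 columns, 10 implanted switches, rate 0.08
  substitutions per site per unit branch. The short internal/long terminal
  geometry keeps genuine ancestor differences rare while leaving enough
  within-clade variation that implanted (fixed) columns dominate the score
  ranking.
* `sample_sites_from_pwm()` and `simulate_phosphoproteome()` draw 15-mer
  sites column-independently from a PWM, or as a mixture of motif-bearing
  and background sites with stated weights (uniform background residue
  frequencies by default; constrained positions drawn uniformly within the
  residue class).
* `simulate_binary_trait()` and `simulate_bm_traits()` provide two-state
  Markov and Brownian-motion traits, the latter as y = slope·x + an
  independent Brownian error so regression recovery has a known truth.

All generators are pure functions of their arguments and a seed, with a
fixed traversal order, and leave the caller's RNG state untouched.

What the generators do *not* emulate — indels, rate heterogeneity across
sites and lineages, compositional bias, phosphosite detection noise,
correlated motif occurrences — bounds what passing tests show: they
demonstrate that the statistics are implemented correctly and behave as
designed under their own model assumptions, not that the biological
conclusions of any particular dataset are robust to violations of those
assumptions.

## Problem sizes and runtime choices

The test suite exercises the stochastic properties at deliberately modest
sizes chosen to give stable pass/fail behaviour: 100 seeded dual-route
score comparisons; 100 enumeration trees of 2–4 leaves; 1,000 random PWM
triples for the metric axioms; 100 threshold-separation seeds (30
subsample draws each); 50 discovery-power seeds at n = 3,000 sites with a
15% implanted mixture and 100 pure-background seeds at n = 1,000; 50
rate-recovery seeds on a 200-leaf tree and 50 single-gain origin seeds on
a 100-leaf tree; 100 slope-recovery and type-I seeds on a 100-leaf tree
and 40 Blomberg-K seeds on a 60-leaf tree. `scripts/acceptance.R`
recomputes the same quantities at similar sizes from a single command-line
seed.

## Known limitations

* The reconstructor is single-rate; supply external posteriors for
  analyses where rate heterogeneity matters.
* The equal-rates dating model cannot express asymmetric gain/loss;
  a unit lost frequently but gained once will bias origins rootward.
* Greedy motif discovery inherits motif-x's local-optimum behaviour:
  overlapping motifs compete for sites, and the emission order can affect
  which of two correlated motifs absorbs shared matches.
* Percentile-based switch thresholds pool only emitted scores; columns
  skipped for insufficient data do not enter the pool.
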
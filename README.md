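# kinevo

Tools for studying how protein-kinase substrate specificity evolves.

Eukaryotic serine/threonine kinases recognise short linear motifs around
the phospho-acceptor (R-x-x-S/T, S/T-P, S/T-D/E-x-D/E, ...), and the
kinase-domain residues that read these motifs out — specificity-determining
residues (SDRs) — change as kinase families duplicate and diverge. `kinevo`
implements the complete analysis chain for this question on a kinase-domain
phylogeny, for molecular evolution researchers who have (or simulate) a
labelled kinase alignment, ancestral sequence posteriors, kinase target
sites and species phosphoproteomes:

* **Divergence scoring.** For a family/subfamily (clade A) versus its
  nearest sister clade (B), each alignment column gets
  `S = RC_A − AC_X · p(AC)`, where RC is the within-clade conservation
  (rescaled BLOSUM62 pair similarity, in [0, 1]), AC is +1/−1 for
  matching/mismatching predicted ancestral residues, and p(AC) is the
  posterior confidence of that call. S ∈ [−1, 2]; a confidently fixed
  difference between sister clades scores 2.
* **Switch aggregation.** Scores above the 95th percentile (per level,
  duplicate ancestor pairs collapsed) are "switches"; per-domain-position
  counts, frequently switching positions (above the 90th percentile of
  counts) and functional-category enrichment (one-sided Fisher exact,
  one-tailed Mann–Whitney).
* **Specificity models.** Position weight matrices over the 14 flank
  positions of 15-mer target sites, compared with the Frobenius distance
  `d = sqrt(Σ (a_ij − b_ij)²)`; within/between comparisons at the
  group/family/subfamily levels; a divergence threshold derived by
  subsampling 25 sites per kinase (≥ 50 annotated targets) and taking the
  maximum same-kinase distance; sequence identity vs specificity distance.
* **Motif analysis.** Shuffled-flank backgrounds (composition-preserving),
  greedy motif-x-style discovery (p < 1e-6, ≥ 20 occurrences), enrichment
  by the superset-conditioned exact binomial `P(Bin(n, p0) ≥ k)` with
  `p0` = background motif matches / background superset-motif matches,
  cross-species filtering with R/K, D/E, L/I/V/M synonym merging, and
  phosphoproteome coverage.
* **Origin dating.** Equal-rates two-state Markov model fitted by maximum
  likelihood on a species tree, marginal presence probabilities at every
  node, origin calling with an MRCA rule for multiple origins, and age
  assignment from a divergence-time table.
* **Comparative statistics.** Phylogenetic independent contrasts with
  regression through the origin, Blomberg's K (permutation test) and
  Pagel's λ (likelihood-ratio test).

A synthetic-data layer (`simulate_family_alignment()`,
`sample_sites_from_pwm()`, `simulate_phosphoproteome()`,
`simulate_binary_trait()`, `simulate_bm_traits()`) generates every input
the pipeline consumes, so the whole chain runs and is tested end to end
without external databases. An in-repo marginal ancestral reconstructor
(Felsenstein pruning, Poisson/LG models) stands in for external
reconstruction tools; production posteriors can be supplied as TSV.

## Worked example

Simulate the canonical burst-after-duplication experiment — two sister
clades of 20 kinases, 500 alignment columns, 10 columns carrying a residue
fixed in clade A after the duplication — then score divergence:

```r
library(kinevo)

bat <- sister_family_battery(seed = 1)
scores <- divergence_scores(bat$comparison, bat$simulation$alignment,
                            bat$simulation$ancestral)
head(scores[order(-scores$S), c("column", "RC", "AC", "p_AC", "S")], 5)
#>  column RC AC p_AC S
#>      46  1 -1    1 2
#>      92  1 -1    1 2
#>     137  1 -1    1 2
#>     182  1 -1    1 2
#>     228  1 -1    1 2
bat$switch_columns
#> [1]  46  92 137 182 228 273 319 364 409 455
```

The top-scoring columns are exactly the implanted ones: RC = 1 (the column
is perfectly conserved within clade A), AC = −1 with p(AC) = 1 (the two
clade ancestors confidently differ), so S = 2, the maximum.

Motif discovery on a simulated phosphoproteome with 15% of 3,000 sites
carrying the CDK-type signature S/T-P-x-K:

```r
cdk <- motif_pattern(list(`1` = "P", `3` = "K"))
pp  <- simulate_phosphoproteome("yeast", 3000, motifs = list(cdk),
                                weights = 0.15, seed = 1)
bg  <- generate_background(pp, shuffles_per_site = 10, seed = 2)
found <- discover_motifs(pp, bg)
format_motif(found[[1]]$motif)
#> [1] "S/T-P-x-K"

superset_binomial(cdk, pp, bg)[c("p0", "k", "n", "fold")]
#> p0 = 0.065, k = 462 of n = 585, fold = 12.1   (p < 1e-300)
```

The motif is recovered exactly, and its enrichment is judged against its
most frequent superset motif (S/T-P): among the 585 foreground sites with
a proline at +1, 462 also carry the +3 lysine, versus a null rate of 6.5%
estimated from the shuffled background — a 12-fold enrichment.

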
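---
title: "Methods: stage-resolved multi-omic peak and expression integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stage-resolved multi-omic peak and expression integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`tempomics` analyzes a three-stage differentiation time course (D0, D15,
D35) profiled with replicate TF peak calls, three histone marks, and
RNA-seq counts for two genotypes (wild type and a heterozygous mutant).
Every stage of the pipeline is a pure function of its inputs plus a single
configuration object, and every stochastic step is seeded, so two runs
from one seed are byte-identical.

# The overlap predicate and consensus rule

All interval comparisons use one reciprocal-fraction predicate, modelled
on `bedtools intersect -f 0.25 -F 0.25 -e`: intervals overlap when the
shared bases cover at least 25% of either interval (either-mode; an
AND-mode is configurable). Reproducible peaks are connected components of
the cross-replicate overlap graph that span at least 2 of 4 replicates.

Three choices here were genuinely open and are package decisions:

- **Consensus coordinates.** The reproducibility rule defines membership,
  not coordinates. We emit the component's coordinate *union* (configurable
  to intersection or median) so that downstream histone-mark overlap is not
  artificially narrowed, and so the invariant "every supporting replicate
  peak is contained in its consensus interval" holds exactly.
- **Component semantics.** "Intersecting in 2 or more replicates" is read
  as "the component spans ≥ k distinct replicates", not "k pairwise
  overlaps": a peak chain r1–r2 counts, two peaks of one replicate do not.
- **Cross-stage linking** for temporal classes reuses the same predicate
  and the same component rule, so a D0–D15–D35 chain without a direct
  D0–D35 overlap is classed as bound at all three stages. The alternative
  (pairwise Venn semantics) leaves chained peaks ill-defined.

Temporal classes live in the 7-subset taxonomy of {D0, D15, D35};
classification operates on consensus peaks (post-merge), since the
upstream definition of "unique" peaks before or after merging is not
fixed by the rule itself.

# Annotation

Peaks are anchored at their midpoint. The nearest gene is the gene whose
TSS minimizes the unsigned midpoint distance (ties broken by the
lexicographically smaller gene id — deterministic and close to common
annotator behavior); distance is signed negative upstream with respect to
gene strand. Categories follow the precedence promoter > exon > intron >
TTS > intergenic with promoter = ±2 kb of any TSS and TTS = ±1 kb of a
transcript end (the TTS window mirrors the common annotator default; UTRs
are collapsed into exon).

# Expression

Counts are CPM-normalized for filtering and DE, RPKM-normalized for
clustering — the two normalizations are deliberately not interchangeable.
Dynamic genes must exceed a strict 1.5-fold change (direction-agnostic,
0.1-RPKM pseudo-count) on a consecutive stage transition; a fold of
exactly 1.5 is excluded. D0-relative profiles divide by the D0 value after
the same pseudo-count, making profiles scale-invariant with first
coordinate exactly 1.

Clustering is k-means at K = 12 with k-means++ initialization, 50
restarts, and a seeded RNG; a within-cluster SSE sweep over K is reported
for elbow diagnostics, but K itself is fixed by configuration. Cluster ids
are arbitrary labels: clusters are interpreted by centroid shape, never by
index.

# The negative-binomial Wald engine

Differential expression and differential binding share one in-repo
engine rather than wrapping an external package: per-feature counts are
modelled as NB(s_j·q_i, α) with median-of-ratios size factors s_j.
Dispersion is estimated by the method of moments on within-group residual
variance, then shrunk toward the dataset median (the average of the two,
floored at a quarter of the median) — a deliberately conservative
stabilizer for n = 3–4 designs that keeps the null calibrated at the cost
of a little power, which the planted 4-fold effects easily absorb. Group
means are NB maximum-likelihood (Newton iterations from the ratio
estimator), and the Wald statistic uses the observed Fisher information
1/I_A + 1/I_B with I_g = Σ μ/(1+αμ). Groups with all-zero counts receive a
half-count continuity correction so fold changes stay finite. Calls
require both the BH-adjusted q-value and the fold-change threshold
(2-fold, FDR 0.05 by default); DEGs additionally require CPM ≥ 1 in at
least half of the compared samples, with the filter applied before
testing so BH operates on the tested set only.

The DBR method in the source analysis is not named; defining it as this
NB test on per-peak counts with the same thresholds is an interpretation,
and both thresholds are independently configurable.

# Chromatin states

Per CHD2 peak and stage, each mark is flagged present iff the peak
overlaps ≥ 1 consensus peak of that mark under the standard predicate —
a set-based (peak-level) definition, matching counting of overlapping
peaks rather than signal quantiles. Bivalent is definitionally
K4me3 ∧ K27me3. The label precedence is bivalent > active_promoter
(K4me3, with or without K27ac) > active (K27ac) > repressed (K27me3) >
none. The combination K27ac ∧ K27me3 without K4me3 is outside the
taxonomy; it resolves to `repressed` with a warning (the more specific of
two conflicting readings of the taxonomy, chosen because an
acetylation-only "active" call over a Polycomb mark would overstate
activity).

# Concordance integration

Each significant DBR is mapped to the nearest TSS of its midpoint and
joined to that gene's DEG direction; concordance requires the same
non-`ns` direction. "Bound in the terminal cell type" is a region-level
test: the DBR overlaps a CHD2 consensus peak whose temporal class
contains D35. Kinetics are `all_stages` (class D0+D15+D35), `later_only`
(D15+D35 or D35 exactly), `other` (any other D35-containing class), or
`unbound`. When several D35-class peaks overlap one DBR the
largest-overlap peak wins (ties: first in sorted order) — multiplicity is
genuinely open here and this rule is deterministic. Each DBR contributes
exactly one record, so the kinetics partition sums to the DBR total.

# Motif enrichment

PWMs are scanned by log2-odds on both strands; any position covering a
non-ACGT base scores −∞. The default hit threshold is the 0.85 relative
quantile of a motif's achievable score range — published per-motif
thresholds for the original tool do not exist, so this is documented as
non-equivalent to it. Enrichment is a one-sided Fisher exact test on
sequences-with-site counts, foreground vs a 2× sampled background matched
on length exactly and on GC in 5 equal-width bins, excluding foreground
overlap, BH-adjusted across motifs.

# The synthetic world

The generator's defaults are the stated world and are not tuned to test
outcomes: a ~4 Mb, 3-chromosome, 41%-GC genome with ~600 genes; ~420
planted TF peaks over the 7 temporal classes with a D0-heavy weight
vector (30% D0-unique, 28% all-stage — the qualitative shape of the real
binding landscape); 4 replicates with Normal(0, 10 bp) coordinate jitter,
10% dropout, and private noise peaks; H3K27ac covering 70% of TF peaks
(coupling) plus a 10% promoter background; H3K4me3 at 80% of promoters;
H3K27me3 at a repressed set plus a bivalency-gaining set that acquires
the mark at D15/D35; RNA counts NB with dispersion 0.05 over 12 archetype
shapes (minimum pairwise separation ~0.5 in D0-relative space); and a
genotype effect of log2FC −2 on a 40-gene cell-cycle-like module and +2
on a 40-gene neuronal-like module at D35, mirrored in per-peak H3K27ac
counts at their promoter peaks. The repressed module's peaks are planted
as bound-throughout and 40% of the activated module's peaks as bound only
later, reproducing the kinetics asymmetry the integration stage measures.
A 10-bp consensus motif is overwritten into 80% of D35-unique peak
sequences.

What the generator does **not** emulate: read-level noise (mapping,
duplicates, fragment models), signal-intensity gradations within peaks,
GC or accessibility biases in counts, correlated replicate structure, and
genome-scale peak numbers. A green planted-truth test therefore
establishes the correctness of the set algebra, the statistics, and the
joins — not performance on real sequencing artifacts.

# Numerical choices

- Pseudo-count 0.1 RPKM before ratios and D0-normalization (config-exposed).
- Strict inequalities at fold-change boundaries (a fold of exactly the
  threshold is not dynamic/changed); overlap fractions use ≥.
- k-means ties and local optima handled by best-of-50 k-means++ restarts
  under a fixed seed.
- Results tables render doubles with 17 significant digits so re-reading
  reproduces records exactly.
- All RNG is locally scoped (`with_seed`), leaving the caller's RNG state
  untouched.

# Known limitations

- The consensus component rule can chain many jittered peaks into one
  wide interval in pathological inputs; union coordinates make this
  visible rather than hiding it.
- The NB engine's moderated dispersion is simpler than modern
  shrinkage-trend estimators; it is calibrated (tested) but not optimal
  in power at very small n.
- Nearest-TSS gene assignment ignores enhancer–gene maps; a DBR between
  two TSSs is assigned deterministically but possibly to the wrong gene.
- Motif thresholds are relative-score quantiles, not information-content
  matched to any reference tool.
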
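---
title: "Methods: integrative detection of convergent selection and maternal transcript deposition under doubly uniparental inheritance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative detection of convergent selection and maternal transcript deposition under doubly uniparental inheritance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

Bivalves with doubly uniparental inheritance (DUI) transmit paternal
mitochondria through the male germline while maternal mitochondria go to
both sexes. In *Mytilus*, egg pools from different females preferentially
produce embryos in which paternal mitochondria are either aggregated
(male-developing) or dispersed (female-developing), and the maternal
transcripts deposited in those eggs are candidates for controlling the
segregation machinery. `duiconverge` implements the full inference chain
that connects that phenotype to molecular evolution:

1. **Sex-bias classification and differential deposition** — operator
   counts of aggregated/dispersed embryos classify egg pools
   (`classifySexBias`); low-signal transcripts are removed by a CPM
   filter, counts are TMM-normalized, and differential deposition between
   male- and female-biased pools is called with an empirical-null (M, D)
   statistic plus a Spearman test against the per-sample offspring sex
   ratio (`expressionStage`).
2. **Convergent rate evolution** — each orthogroup's gene tree is scored
   for convergently slower ("constrained") or faster ("accelerated")
   evolution of the DUI species relative to a reference species tree,
   with permutation significance and a control harness of random and
   phylogenetically matched taggings (`convergenceTest`, `controlScan`).
3. **Branch-model selection** — one-ratio versus two-ratio GY94 codon
   models quantify whether DUI clades evolve under different dN/dS, via
   likelihood-ratio tests and the reported difference
   `deltaOmega = omegaFg - omegaBg` (`branchModelLrt`).
4. **Mito-nuclear rate covariation** — per-species root-to-tip distances
   of each gene tree are regressed (through the origin) on those of a
   mitochondrial concatenate tree after phylogenetic independent
   contrasts, and significant covariation is tested for enrichment among
   the convergently evolving genes (`ercTest`, `enrichment2x2`).
5. **lncRNA genomic hits** — similarity hits of candidate regulatory
   lncRNAs are filtered, assigned to containing genes with a 100-bp
   flank and an antisense flag, and tested for over-representation in
   differentially deposited genes by resampling (`filterHits`,
   `annotateContainment`, `hitEnrichment`).
6. **Network integration** — differentially deposited and convergently
   evolving gene products are placed on a scored interactome; edge-count
   enrichment, connected components, and node metrics (degree, stress
   centrality, neighborhood connectivity) with Wilcoxon/KS group
   contrasts summarize how the two sets interlock (`edgeEnrichment`,
   `nodeMetrics`, `compareGroups`).

Everything runs end to end on synthetic data with planted ground truth
(`runPipeline`), so each stage's operating characteristics are measurable
without any external download.

# The convergence statistic

For a gene tree `G` and the reference species tree `S`, both restricted
to their shared species, the per-species relative rate is

    r_s = log(d_s(G) / d_s(S)) - median_s' log(d_s'(G) / d_s'(S))

where `d_s` is the root-to-tip path length. The median centering removes
the gene-wide rate, so `r_s` captures lineage-specific deviations; the
log scale makes "constrained" and "accelerated" symmetric. The statistic

    T = sum_p w_p (r_fg(p) - r_bg(p)) / sum_p w_p

averages over all foreground x background species pairs `p`. With the
default `mrca_depth` weighting, pairs sharing the same species-tree MRCA
share one unit of weight, which de-emphasizes phylogenetically redundant
comparisons; `uniform` weighting is available. `T < 0` is convergent
constraint, `T > 0` convergent acceleration.

**Permutation null.** Significance uses `p = (1 + #{|T*| >= |T|}) /
(nPerm + 1)`. A naive permutation that re-draws the foreground uniformly
among tips is miscalibrated here: the DUI tips arrive in clades, sibling
tips share most of their root-to-tip path, and positively correlated
`r_s` inflate the variance of `T` for clustered taggings relative to
scattered ones (we measured a 0.19 rejection rate at a nominal 0.05).
The permutations therefore re-tag the gene tree with random disjoint
monophyletic groups matching the observed foreground's clade-size
profile (for the default design: four species pairs plus two singletons),
falling back to uniform draws only when no placement exists. Under this
scheme the null rejection rate is statistically indistinguishable from
the nominal level (the acceptance suite verifies the 95% binomial
interval at 1000 genes x 199 permutations), and taggings of ten
scattered control species reduce to plain uniform draws, so the control
harness remains faithful to the control design of 50 random taggings
of 10 non-DUI species plus one phylogenetically matched tagging.

**Control harness.** `controlScan` reports, per tagging, the fraction of
genes with `p < alpha` split by direction, and the rank of the true
tagging among the random ones. With planted constraint the true tagging
ranks first; under the null its rank is uniform — both behaviors are
exercised in the acceptance suite.

# Codon branch models

`gy94RateMatrix` builds the Goldman–Yang generator over the 61 sense
codons of the standard genetic code: single-position changes at rate
`pi_j * kappa^[transition] * omega^[nonsynonymous]`. Both branch classes
(background and foreground = DUI clades, i.e. branches whose descendant
tips are all foreground, stems included by default) share one scale so
that branch lengths stay in expected substitutions per codon under the
background class. The likelihood is computed by Felsenstein pruning over
compressed site patterns (C++ core), with transition matrices obtained
from the eigensystem of the reversible generator.

`branchModelLrt` maximizes `(kappa, omega, scale)` under the null and
`(kappa, omegaBg, omegaFg, scale)` under the alternative with bounded
L-BFGS (`omega` in `[1e-4, 10]`, `kappa` in `[0.1, 20]`), where `scale`
is one free multiplier of the input branch lengths rather than a full
re-optimization — the trees are inputs here, and a global scalar absorbs
unit mismatches at a fraction of the cost. The null model uses two fixed
starts; the alternative starts from the null optimum (which guarantees
`lnL1 >= lnL0`) plus two perturbed starts. `Lambda = 2(lnL1 - lnL0)` is
referred to chi-square with one degree of freedom; its null distribution
is verified against chi-square(1) by simulation in the acceptance suite.
Codon frequencies default to F1x4 estimated from the alignment
(`uniform` and `F3x4` are available); the choice is recorded in results.

# Rate covariation

`ercTest` intersects the species of the gene tree, the mitochondrial
tree and the reference tree (at least 10 shared species by default),
computes both root-to-tip distance vectors, transforms each with
phylogenetic independent contrasts on the pruned reference tree, and
fits a regression through the origin — the standard form for contrasts,
whose sign symmetry the tests assert. Signed contrasts are the default;
absolute contrasts are available behind a flag. Zero-length terminal
branches receive an epsilon of `1e-8` before the contrast recursion;
contrasts are emitted in a deterministic order keyed by the sorted tip
labels under each internal node. Branch-length units cancel between the
two distance vectors as long as they are consistent within a run, so the
package treats them as opaque.

The 2x2 enrichment of significant covariation (default `p < 0.05`)
among convergently evolving genes uses chi-square without continuity
correction; Fisher's exact test is used
for the DE-versus-CE overlap and whenever a margin degenerates.

# Differential deposition

`deTest` is an empirical-null statistic in the NOISeq family and is the
package's deliberate stand-in for external empirical-noise DE engines —
the one intentional methodological substitution in the chain. It keeps
that family's decision geometry: per feature, `M = log2((xA + c)/(xB + c))`
and `D = |xA - xB|` on TMM-normalized values (pseudo-count `c = 0.5`),
a null cloud of `(M*, D*)` pairs, and a call when the feature's pair
jointly dominates more than `q = 0.95` of the null. Null pairs are built
from randomly drawn features whose values are permuted within bias
groups and contrasted across balanced splits (half of each group on
either side), so genuine group signal cancels. Because the raw `D` scales
with expression, features are compared within abundance strata (ten
quantile bins of the mean normalized value, `nBins`); without the
stratification, recall saturates near 0.63 regardless of effect size
because low-abundance features can never dominate a pooled null. The
`q > 0.95` rule is applied as-is, without multiple-testing adjustment.

TMM normalization is delegated to `edgeR::calcNormFactors` (trim 0.30 on
M, 0.05 on A, precision weights, factors rescaled to geometric mean 1);
the test suite pins it against an independent straight-line
reimplementation of the TMM definition to `1e-6`. The Spearman
correlation against offspring sex ratio uses the exact small-sample null
for `n <= 9` without ties (the 8-sample design), vectorized over
features from a single enumeration of the rank-permutation distribution
and verified against `stats::cor.test`.

# Networks

Edges below the medium-confidence score 0.400 are dropped at load.
Expected edge counts come from resampling uniform node sets of equal
size (a degree-stratified mode exists because hub-rich sets inflate
counts); the analytic expectation printed by interaction databases is
intentionally not reproduced. Stress centrality counts, over unordered
node pairs, every distinct shortest path passing through a node
(Shimbel's convention; ordered-pair counting, which exactly doubles the
values, is available via `pairs = "ordered"`). Neighborhood connectivity
is the mean neighbor degree, undefined for isolated nodes.

# Synthetic data: what it emulates, and what it does not

The generators encode the modeled design: a 36-taxon species tree built
from three monophyletic subclasses with six independently placed DUI
clades (four species pairs and two singletons, ten foreground tips);
gene trees as the species tree with lognormal gene and branch rate
noise, a foreground multiplier (0.3 for constrained genes, its inverse
for accelerated), and uniformly missing taxa re-drawn to respect the
15-species/4-DUI retention rule; codon alignments under branch-specific
omega; a mitochondrial tree sharing per-branch rate deviations with a
configurable subset of genes (the planted covariation signal, biased
toward constrained genes in the default pipeline); 8-sample
negative-binomial counts in a 4-vs-4 bias design with means
`L_s * q_f * 2^(lfc_f * x_s)`, `x_s` the centered offspring sex ratio;
hit tables with placement probability proportional to gene length times
a focal-gene bias; and Erdos-Renyi interactomes with a planted dense
module between the DE-labelled and CE-labelled node sets.

Where the modeled design fixes a value we use it (36 species, six DUI
origins, 8 samples 4-vs-4, 15,826 features, all thresholds); effect
sizes it does not quantify (rate multiplier 0.3, branch noise sd 0.2, gene
rate sd 0.5, planted log2 fold change 2 per unit sex ratio, NB
dispersion 0.1, library sizes 8-12 million) were chosen once as
plausible for a divergent bivalve phylogeny and a moderately dispersed
RNA-seq experiment, and are free parameters of the generators — they are
conditions for calibration and recovery checks, not estimates of the
real system. Passing tests therefore demonstrate that the machinery is
calibrated and recovers planted structure at these settings; they say
nothing about power on real data, where branch-rate noise is not
lognormal-independent, expression is not negative binomial with a single
dispersion, orthology errors and alignment artifacts exist, and
interactomes are transferred across species.

# Numerical choices and degenerate inputs

* Permutation p-values use the `(1 + k)/(n + 1)` convention and never
  return 0.
* `relativeTipRates` errors on a zero species-tree distance and floors
  gene distances at `1e-8` (a fully collapsed lineage).
* Genes with fewer than 2 foreground or background tips, or fewer shared
  species than `minShared`, are skipped with a logged reason rather than
  scored.
* The LRT clamps `Lambda` at 0; `lnL1 >= lnL0` is structural because the
  alternative starts at the null optimum.
* Empty enrichment margins force Fisher's test (p = 1); chi-square
  refuses them.
* All generators and analyses are pure functions of their parameters and
  seeds; `runPipeline` fans one master seed out to per-stage seeds
  through a recorded schedule, and repeated runs are byte-identical.

# Problem sizes

The default pipeline configuration is desk-scale by design: 15,826
features x 8 samples; 120 gene trees on 36 taxa scanned with 199
permutations and 50 random taggings of 10 species; branch-model fits for
10 candidate genes at 200 codons on up to 12 taxa; 999-draw resampling
nulls for hit and edge enrichment. The calibration experiments in the
acceptance suite use 1000 genes x 199 permutations (convergence), 200
replicates of 10-taxon 200-codon alignments (LRT), 500 replicates
(rate covariation), and 200 replicates each for the enrichment nulls.
These sizes were chosen so the whole suite runs on a single CPU in well
under an hour while leaving every check statistically meaningful.

# Known limitations

* Root-to-tip distances of every gene share the reference tree's depth
  structure, and independent contrasts remove phylogenetic covariance,
  not that shared mean component — so a baseline fraction of genes shows
  "significant" covariation with the mitochondrial tree even without any
  planted link, at a level that depends on the tree shape and noise. The
  interpretable quantity is therefore the 2x2 enrichment of significant
  covariation among convergently evolving genes, not the absolute count
  of significant regressions; the synthetic generators damp the shared
  mitochondrial deviations on linked gene trees (`ercDamping`) so the
  planted contrast rides on top of that baseline.

* The convergence statistic is a pair-based relative-rate contrast, not
  a reimplementation of any specific existing tool; its permutation
  scheme conditions on the observed clade-size profile, which is
  conservative when the true foreground structure is informative beyond
  its profile.
* Branch lengths are taken from the input trees up to one free scalar in
  the codon models; genes whose branch-length errors correlate with the
  foreground will bias `deltaOmega`.
* The empirical-null deposition test shares information across features
  within abundance strata; strong global signal (many true positives)
  inflates the null cloud and makes calls conservative.
* Monophyly rescue removes at most two species and recomputes trimmed
  columns instead of realigning; rescued orthogroups are flagged so
  downstream users can drop them.
* The resampling expectation for network edges is not the analytic
  value printed by interaction databases, so expected-edge counts
  reported by those services are not numerically reproducible here.
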
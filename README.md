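# duiconverge

Integrative analysis of **doubly uniparental inheritance (DUI)** of
mitochondria in bivalves. Some mussel females produce egg pools that
mostly develop into males (paternal mitochondria stay aggregated near the
cleavage furrow) or mostly into females (paternal mitochondria disperse).
`duiconverge` connects that maternal egg phenotype to molecular
evolution across the bivalve tree, asking whether the machinery that
segregates paternal mitochondria leaves two converging signatures:
transcripts differentially deposited in sex-biased eggs, and genes whose
protein evolution is convergently constrained across the independent
origins of DUI.

The package implements, as reusable Bioconductor-style components:

* **Sex-bias classification and differential deposition** — median of
  operator-counted aggregated/dispersed embryo ratios with the 70% rule;
  CPM `>= 2` filtering; TMM normalization (via edgeR); an empirical-null
  deposition statistic: per feature `M = log2((x̄_A + c)/(x̄_B + c))`,
  `D = |x̄_A − x̄_B|`, called when `(|M|, D)` jointly dominates a
  fraction `> q = 0.95` of a within-group-permutation null cloud,
  stratified by abundance; exact Spearman correlation of normalized
  values with per-sample offspring sex ratios.
* **Convergent relative evolutionary rates** — per-species
  `r_s = log(d_s(gene)/d_s(species))`, median-centered; the statistic
  `T = Σ w_p (r_fg − r_bg)/Σ w_p` over foreground × background pairs
  with MRCA-redundancy weights; permutation p-values from random
  monophyletic re-taggings matching the foreground's clade-size
  profile; a control harness of 50 random taggings of 10 background
  species plus a phylogenetically matched tagging.
* **GY94 branch models** — one-ratio vs two-ratio codon models
  (`q_ij = π_j κ^[ti] ω^[nonsyn]` over the 61 sense codons), pruning
  likelihood in C++, bounded ML fits, `Λ = 2(lnL1 − lnL0)` against
  χ²(1), and `Δω = ω_fg − ω_bg` (negative = stronger purifying
  selection in DUI lineages).
* **Mito-nuclear rate covariation** — root-to-tip distances,
  phylogenetic independent contrasts on the reference tree, regression
  through the origin, and 2×2 chi-square/Fisher enrichment of
  significant covariation among convergently evolving genes.
* **lncRNA genomic hits** — filters (length > 100 bp, coverage > 0.5,
  identity > 90%), strand-aware containment within genes ± 100 bp with
  antisense flags, and resampling enrichment within differentially
  deposited genes.
* **Interactome integration** — scored edges kept at `w >= 0.400`,
  resampling edge enrichment, connected components, degree, stress
  centrality and neighborhood connectivity with Wilcoxon/KS contrasts.
* **Synthetic-data generators** with planted ground truth for every
  input (species/gene/mito trees, codon alignments, counts, hit tables,
  interactomes), so the whole pipeline is testable offline.

See the methods vignette (`vignettes/duiconverge-methods.Rmd`) for the
statistical details and design rationale.

## Worked example

Score one simulated orthogroup for convergent constraint and foreground
purifying selection:

```r
library(duiconverge)

# a 30-taxon species tree with 6 DUI origins (10 foreground tips)
st <- makeSpeciesTree(30, c(2, 2, 2, 2, 1, 1), seed = 1)

# one convergently constrained gene tree (foreground rates x 0.3)
gt <- simulateGeneTrees(st, 1, constrainedFrac = 1,
                        rateMultiplier = 0.3, seed = 3)$trees[[1]]
convergenceTest(gt, st, nPerm = 999, seed = 1)
#>    statistic   direction     p nForeground nBackground
#> 1 -0.1325849 constrained 0.019           9          20

# a codon alignment evolved with omega 0.1 on DUI branches, 0.5 elsewhere
st10 <- makeSpeciesTree(10, c(2, 1), seed = 2)
aln <- simulateCodonAlignment(st10, 300, omegaBg = 0.5, omegaFg = 0.1,
                              kappa = 2, seed = 1)
branchModelLrt(aln, st10, seed = 1)
#>        lnL0      lnL1   lambda           p   omegaBg    omegaFg deltaOmega    kappa converged
#> 1 -3723.151 -3694.494 57.31435 3.71435e-14 0.4967045 0.07415391 -0.4225506 2.340862      TRUE
```

The convergence statistic is negative — this gene's nine foreground
(DUI) lineages evolve slower than the species tree predicts, with a
permutation p of 0.019 at 999 re-taggings. The branch-model fit recovers
the planted dN/dS contrast almost exactly (`ω` estimates 0.50 and 0.074
against the simulated 0.5 and 0.1, `Δω = −0.42`), and the
likelihood-ratio test rejects the one-ratio model decisively
(`Λ = 57.3`, `p ≈ 4 × 10⁻¹⁴`).

The full synthetic study runs in a few minutes:

```r
report <- runPipeline(defaultConfig(masterSeed = 1))
str(report$summary)
```

and reports, among other quantities, the number of deposition calls and
their planted-truth recall, the constrained/accelerated gene counts, the
true tagging's rank among 50 random taggings, the median `Δω` of the
selection fits, the chi-square p for rate-covariation enrichment among
convergently evolving genes, and the observed vs expected edge counts of
the DE+CE set on the planted interactome.

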
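---
title: "Methods: models, parameters and design choices in paraselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in paraselect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paraselect)
```

# Scope

`paraselect` implements the comparative-evolution toolkit needed to study
how a duplicated gene family — the motivating case is the α/β subunit pair
of plant mitochondrial NAD-dependent malic enzyme, recruited into C4
photosynthesis in some lineages — diverges after duplication. Five stages
cooperate:

1. **Codon alignment preparation** (`backtranslate`, `coverageFilter`,
   `codonPositionExtract`, `translateCodonAlignment`,
   `matureRegionSlice`): the tool consumes existing protein alignments and
   coding sequences; alignment computation and manual curation are
   deliberately out of scope, since they are not reproducible code.
2. **Strict differential-substitution scanning** (`strictDiffSubShared`,
   `strictDiffSubSingle`): given a foreground partition (e.g. sequences of
   C4 species), find alignment columns where the foreground shares one
   amino acid and the entire background shares a single different amino
   acid.
3. **Gene-dosage census** (`classifyRatio`, `buildContingency`,
   `fisherExactTwoSided`, `dosageReport`): per-species β/α copy-number
   ratios, classified against the 1:1 ancestral state and tested with a
   self-contained exact test.
4. **Site-model selection inference** (`buildRateMatrix`,
   `siteLogLikelihood`, `fitSiteModel`, `lrtSiteModels`, `sitePosteriors`,
   `selectedSites`): GY94 codon models with among-site ω mixtures
   (M0–M8a), likelihood-ratio tests and empirical-Bayes site
   identification.
5. **Micro-synteny classification** (`findSyntenicRegions`,
   `classifyContext`, `syntenicDepth`): windowed collinear-anchor search
   that separates genes retained in their ancestral genomic context from
   transposed copies.

A synthetic-data generator (`simulateYuleTree`, `simulateCodonAlignment`,
`plantConvergentSubstitutions`, `simulateDosageTable`,
`simulateWgdGenome`) produces inputs with exactly the statistical
structure each stage assumes, so the whole pipeline is testable without
any external download. The `runAnalysis` orchestrator drives all stages
from one YAML configuration.

# The codon substitution model

The substitution process is the Goldman–Yang codon model. For sense
codons $i \ne j$,

$$
q_{ij} =
\begin{cases}
0 & \text{more than one nucleotide differs, or a stop codon,}\\
\pi_j & \text{synonymous transversion,}\\
\kappa \pi_j & \text{synonymous transition,}\\
\omega \pi_j & \text{nonsynonymous transversion,}\\
\kappa \omega \pi_j & \text{nonsynonymous transition,}
\end{cases}
$$

with rows summing to zero and the matrix rescaled so that
$-\sum_i \pi_i q_{ii} = 1$: branch lengths read as expected substitutions
per codon site. Each ω class of a mixture is normalized separately; the
simulator and the likelihood engine share one implementation of $Q$, so
simulation/inference mismatch cannot confound the recovery studies.

Only the standard genetic code (61 sense codons, lexicographic order over
A < C < G < T) is supported; data codons containing stops are rejected at
load with an explicit error, and gap- or N-containing codons are treated
as missing data in the likelihood.

Transition probabilities $e^{Qt}$ are computed by eigendecomposition of
the reversible matrix in the π-symmetrized basis
($B = \Pi^{1/2} Q \Pi^{-1/2}$ is symmetric), which remains stable for
branch lengths up to 50 and guarantees stochastic rows to ~1e-10.
Negative entries from roundoff are clamped to zero.

## Site-class models

The M-series mixtures assign each codon site one ω drawn from a small set
of classes shared across all branches (the site-model assumption — no
branch heterogeneity, no branch-site models):

* **M0**: one ratio. **M1a**: ω₀ < 1 with weight p₀, ω = 1 otherwise.
  **M2a**: M1a plus a class ω₂ > 1. **M3**: K free (weight, ω) pairs.
* **M7**: ω ~ Beta(p, q). **M8**: beta with weight p₀ plus ωs > 1.
  **M8a**: M8 with ωs fixed at 1.

The beta is discretized into `ncat = 10` equal-probability categories
represented by their within-bin means, computed in closed form from the
incomplete beta function. K = 10 is the convention of the standard
implementation of these models; it is configurable.

## Frequencies

`F3x4` (position-specific nucleotide frequencies multiplied per codon,
stops zeroed, renormalized) is the default; empirical `F61` with a 0.1
pseudocount is available. The choice mirrors the common default of codon
model software.

## Likelihood, optimization, numerical choices

Per-site likelihoods are computed by Felsenstein pruning over 61 states
(compiled with RcppArmadillo), with per-node rescaling against underflow
and site-pattern compression. Free parameters are optimized on log/logit
scales by bounded L-BFGS-B with a memoized forward-difference gradient;
bounds are κ ∈ [0.01, 50], ω ≤ 50, beta shapes ∈ [0.005, 99], mixture
weights on a logit scale clamped to ±30. Convergence tolerances:
`factr = 1e7` (≈ 2e-9 relative on the log-likelihood), parameter
tolerance via the transform scale. Non-convergence is flagged in the
returned object, never silent.

Branch lengths of the fixed input topology are rescaled by a single free
multiplier by default (`optimizeBranches = TRUE` frees every branch); a
single scale keeps desk-scale runtimes while absorbing overall rate
differences between the tree units and the data.

`fitSiteModel` uses three deterministic starts by default.
`fitSiteModelSeries` fits nested hierarchies the way practitioners run
them: each alternative starts from (i) a boundary image of its null's MLE
— which guarantees, by monotonicity of the optimizer, that the fitted
alternative can never fall below its null beyond roundoff — and (ii) an
interior start whose positive-selection class has been pre-optimized
against the null's cached per-site class likelihoods (a cheap
two-parameter profile). This both enforces the nesting inequalities and
roughly halves fitting time.

## LRTs and site identification

`2Δℓ` is compared with χ² on the difference in free-parameter counts
(M1a–M2a: 2; M7–M8: 2; M8a–M8: 1). For M8a–M8 the default χ²₁ reference
is conservative because ωs sits on the boundary under the null; the 50:50
mixture of a point mass and χ²₁ is available via `boundaryMixture`.

`sitePosteriors` reports the posterior probability that a site belongs to
the ω > 1 class. `NEB` plugs the MLEs into Bayes' rule. `BEB` averages
the NEB posteriors over an 8 × 8 grid on (positive-class weight, ωs),
weighting grid points by their data likelihood under a flat prior. This
likelihood-weighted grid average follows the spirit of the published
Bayes-empirical-Bayes construction but is an approximation of its
integrals, so NEB is always reported alongside; on strongly informative
data the two agree at the conventional 0.90 reporting threshold. Sites
above the threshold are mapped to reference-sequence numbering via
`mapToReference` (1-based, full-length precursor numbering by way of the
`offset` argument when scanning mature-protein slices).

# The differential-substitution scanner

A column is a *shared strict* hit when every foreground sequence carries
one amino acid, every background sequence carries one identical different
amino acid, and no gap or `X` occurs among the considered sequences. The
default gap policy is maximally strict because the defining phrase is
"shared in *all* other sequences"; `allowBackgroundGaps` relaxes the
background condition to all non-gap residues agreeing, with a
configurable minimum background coverage (default 0.8), since curated
real alignments contain ragged ends. Sequences that should count neither
as foreground nor background (e.g. the second β paralog of a focal
species) go into `ignore`. `X` never matches anything.

# The dosage census and exact test

Ratios are reduced by gcd, so 3:3 is 1:1 and 4:1 stays 4:1. Species with
zero α copies are classified "1:0" and flagged, never dropped silently.
The default contingency groups species with C4-NAD-ME photosynthesis
against everything else; C3–C4 intermediates count as "other". The
two-sided Fisher p-value enumerates all tables with the observed margins
and sums hypergeometric point probabilities not exceeding the observed
one (+1e-12 slack) — the point-probability rule used by the conventional
implementations. The published census structure (92 species, 7 C4-NAD-ME
of which 5 non-1:1, 86 others of which 16 non-1:1) gives proportions
71.4% and 18.6% and p ≈ 0.0059 under this rule, matching the printed
values, and those proportions are the generator defaults.

# Micro-synteny

Windows are measured in gene ordinals (40 genes by default), not base
pairs. Candidate target regions are seeded by homologs of any windowed
query gene and scored by the longest strictly monotone chain of anchor
pairs, in either orientation (strand is ignored; inversions appear as
descending runs). Homologs of one query gene within 2 ordinals of each
other collapse to a single anchor so tandem arrays cannot inflate counts.
Regions with ≥ 4 chained anchors are reported. The published tool's exact
chaining is not documented, so monotone-run chaining is the simplest
faithful interpretation; desk-scale equivalence with real-genome panels
is replaced by simulation recovery (below). A gene is *syntenic* when
some region contains a homolog of the gene itself, *transposed* when it
has homologs but none in context, *absent* otherwise.

# What the generator emulates — and what it does not

* `simulateYuleTree`: pure-birth trees; topology realism is irrelevant to
  the properties tested, so no birth–death or coalescent variants. The
  default `depthScale = 0.5` yields root-to-tip lengths around one
  substitution per codon site for tens of taxa — plant-order-level
  divergence.
* `simulateCodonAlignment`: gap-free alignments, site ω drawn once per
  site, no indels, no rate variation beyond the ω mixture, no
  recombination. Gaps enter tests only through dedicated fixtures.
* `plantConvergentSubstitutions`: plants a shared foreground amino acid
  on background-conserved, gap-free columns; the replacement codon is the
  lexicographically smallest encoding the target (determinism).
* `simulateDosageTable`: Bernoulli group labels and conditional non-1:1
  indicators; the non-1:1 ratio distribution defaults to mostly 2:1 with
  occasional 3:1, 4:1 and 1:2, mirroring the observed census where
  β-side duplications dominate. The generating process behind the real
  proportions is unknown; these are modelling choices, not estimates.
* `simulateWgdGenome`: whole-chromosome duplication, independent
  per-gene retention (fractionation), and uniform single-gene
  transposition. No segmental rearrangement, inversion or tandem-array
  growth models.

Consequently, passing recovery tests demonstrates internal correctness
and calibration under the stated generative assumptions — clean
alignments, a correct fixed topology, no model misspecification — not
performance on curated real data, where alignment error and among-site
rate heterogeneity beyond the ω mixture matter.

# Study sizes used by the automated checks

The calibration and recovery studies are exercised at sizes chosen to
keep a full check run at desk scale on one CPU; all are arguments of the
exported study functions, so larger runs are one call away:

* scanner-vs-oracle: 1000 random alignments (≤ 12 × 60);
  planted-recovery: 100 seeds.
* Fisher: full enumeration over every table with total ≤ 60 plus 50
  random tables against a 10⁶-draw permutation oracle.
* LRT type-I calibration: 16 replicates of the 12-taxon × 300-codon
  design; LRT power under M8 (ωs = 4, p_s = 0.15, same design): 20
  replicates. Site false-discovery of sites flagged at posterior > 0.90
  is measured at the site-identification design — ωs = 5, p_s = 0.1,
  16 taxa × 400 codons — with 8 replicates, pooling flags across
  replicates. At the weaker power design the
  plug-in posteriors are visibly overconfident (posteriors computed at
  the true generating parameters are well calibrated; the excess false
  discovery is parameter-estimation noise that likelihood-weighted grid
  averaging cannot remove at that information level), which is why the
  FDR statement belongs to the stronger design. Replicate fits use the
  warm-started series with a single default start. Binomial tolerances
  are computed at the replicate counts used.
* M0 recovery: 20 seeds of 16 taxa × 500 codons (script: 12).
* Synteny recovery: 50 simulated WGD genomes of 500 genes (script: 30).

# Known limitations

* BEB is a grid approximation (above), not a port of the published
  integrals; posterior values can differ in the second decimal even when
  the reported site sets agree.
* The M8a–M8 boundary mixture is optional rather than default; the
  default χ²₁ is conservative.
* `F3x4` inherits the known biases of product-of-position estimators.
* The synteny chainer is a deliberately simple stand-in for production
  collinearity tools; it ranks and classifies correctly on simulated
  histories but does not model proximal tandem complexities beyond the
  collapse rule.
* The pipeline runs stages sequentially on one process; no workflow
  engine integration.
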
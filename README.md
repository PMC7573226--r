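# paraselect

Comparative molecular-evolution analysis of duplicated gene families.

## The problem

When a gene family duplicates — for example the α- and β-subunit lineages
of plant mitochondrial NAD-dependent malic enzyme (NAD-ME), whose β
copies were repeatedly duplicated and recruited into C4 photosynthesis —
four questions recur:

1. **Which amino-acid positions changed specifically in an adapted
   lineage?** A *strict differential substitution* is an alignment column
   where every foreground sequence (e.g. the C4 species) shares one amino
   acid while every other sequence shares a single, different amino acid.
2. **Is gene dosage skewed in the adapted group?** Per species, the β/α
   copy-number ratio is classified against the ancestral 1:1 state and the
   groups are compared with a two-sided Fisher exact test
   (point-probability rule, exact enumeration).
3. **Did selection act on coding sequences?** Codon site-class models in
   the GY94 family, with ω = dN/dS mixed over sites: M0, M1a, M2a, M3,
   M7 (ω ~ Beta(p,q)), M8 (beta + a class with ωs > 1) and M8a (ωs = 1).
   Nested models are compared by likelihood-ratio tests
   (2Δℓ ~ χ²; M7–M8: df 2, M8a–M8: df 1), and sites in the ω > 1 class
   are identified by naive and Bayes empirical-Bayes posteriors with the
   conventional 0.90 reporting threshold.
4. **Are duplicate copies in their ancestral genomic context?** A
   windowed micro-synteny search (window 40 genes, ≥ 4 collinear anchors,
   longest strictly monotone anchor chain) classifies each gene as
   *syntenic*, *transposed* or *absent* in a target genome.

`paraselect` implements all four stages plus a synthetic-data generator
(Yule trees, GY94 site-class alignment simulation with the same rate
matrix as the likelihood engine, planted convergent substitutions,
dosage tables, whole-genome-duplication gene orders with fractionation
and transposition) so every stage is testable end to end without
external data, and a pipeline driver (`runAnalysis`) that runs the
stages from one YAML configuration.

The likelihood engine is Felsenstein pruning over the 61 sense codons,
compiled with RcppArmadillo; model fitting is bounded quasi-Newton on
transformed parameters with deterministic multi-starts, and nested model
hierarchies are fitted warm-started (`fitSiteModelSeries`) so the
log-likelihood ordering of nested models holds by construction. See the
methods vignette (`vignettes/paraselect-methods.Rmd`) for the model, the
numerical choices and the generator's assumptions.

## Worked example

Simulate an alignment with 15% of sites under strong positive selection,
then detect that selection and recover the sites:

```r
library(paraselect)

tree <- simulateYuleTree(10, seed = 7)
spec <- codonSubstitutionSpec(
  kappa = 2,
  siteClass = siteClassModel("M8", p0 = 0.85, p = 0.4, q = 2, omegaS = 5))
sim <- simulateCodonAlignment(tree, spec, 300, seed = 8)
sim$alignment
#> CodonAlignment: 10 sequences x 300 codons (900 nt)

fits <- fitSiteModelSeries(sim$alignment, tree, c("M7", "M8"), nstarts = 1)
fits$M8
#> CodonSiteFit [M8]  lnL = -4129.1251  (6 free parameters)
#>   estimates: kappa=1.977  treeScale=1.091  p0=0.8122  p=0.4864  q=2.593  omegaS=49.79

lrtSiteModels(fits$M7, fits$M8)
#> LRT M7 vs M8: 2*dlnL = 26.2874, df = 2, p = 1.958e-06
```

The LRT rejects M7 decisively (the fitted ωs rails at the upper bound
because the selected class is extreme), and the fitted weight of the
beta component, p0 ≈ 0.81, is close to the simulated 0.85. Site-level
identification:

```r
post <- sitePosteriors(fits$M8, method = "BEB")
hits <- selectedSites(post, threshold = 0.90)
nrow(hits)
#> [1] 10
head(hits, 3)
#>   site posterior refPosition
#> 1   82 0.9037603          NA
#> 2  131 0.9510003          NA
#> 3  142 0.9186887          NA
mean(hits$site %in% which(sim$siteOmega > 1))
#> [1] 0.8
```

Ten sites exceed posterior 0.90; eight of them are truly from the
simulated ω = 5 class (80% precision, i.e. an empirical false-discovery
rate of 0.2 at this threshold on one replicate). A dosage census under
the package's default conditions (92 species, a small C4-NAD-ME group
with an elevated probability of non-1:1 β/α dosage):

```r
tab <- simulateDosageTable(seed = 1)
rep <- dosageReport(tab)
rep$proportions
#>    group1    group2
#> 0.8000000 0.1264368
rep$fisherP
#> [1] 0.002198339
```

The C4-NAD-ME group shows 80% non-1:1 species against 13% elsewhere,
and the exact test rejects independence at p ≈ 0.002.

## Command line

A thin wrapper over the package functions is installed at
`inst/scripts/paraselect.R`:

```sh
Rscript inst/scripts/paraselect.R run config.yaml
Rscript inst/scripts/paraselect.R simulate alignment --taxa 12 --codons 300 --seed 1 --out sim
```
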
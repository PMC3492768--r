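---
title: "Methods: neutral structure, dispersal and selection along a rainfall gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neutral structure, dispersal and selection along a rainfall gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

honeypop implements a joint analysis of neutral genetic structure and
adaptive phenotypic divergence for a songbird sampled at six sites spanning
three rainfall categories (low < 32 mm, moderate 32–44 mm, high > 44 mm mean
monthly rainfall). The inputs are multilocus microsatellite genotypes
(Genepop format), a seven-trait morphology table, site rainfall, and a
pairwise overland distance matrix. This vignette describes each model, its
assumptions, the tunable parameters, and the design choices made where the
methodology was genuinely open. Everything shown here is computed by the
package; the numbered scripts under `analysis/` run the same stages on a
simulated study with known truth.

## The synthetic study

Because no genotype or morphology data accompany the study design, every
stage is exercised on data from `sim_config()` / `simulate_dataset()`, whose
defaults are fixed once to mirror the field design:

* **Sites.** Six sites on a 420 km line (positions 0, 100, 220, 300, 360,
  420 km), rainfall 28, 31, 36, 43, 46, 52 mm — two sites per category.
* **Markers.** 10 loci, 12 possible alleles each. Ancestral frequencies are
  symmetric-Dirichlet(1); site 1 is a Balding–Nichols draw around the
  ancestor with differentiation `F_step`, and each subsequent site is drawn
  the same way around its left neighbour (a stepping-stone chain). The
  default `F_step = 0.02` yields a global Weir–Cockerham theta near 0.02 and
  per-locus expected heterozygosities of roughly 0.73–0.89, matching the
  reported panel (6–18 alleles per locus, H_E 0.67–0.91). We chose this
  equilibrium sampling model over forward-time simulation because the
  analyses only require an isolation-by-distance pattern with a controlled
  magnitude, not a demographic history; there is no burn-in and the
  differentiation per chain step is a direct parameter.
  Note a parameterization subtlety: because each site is drawn *around its
  neighbour*, the expected theta between an adjacent pair is `F_step / 2`
  (the between-pair variance is half the drift variance), while
  differentiation keeps accumulating along the chain.
* **Sampling.** 28 birds per site and sex (336 total), close to the 330
  genotyped birds of the field panel; 5.8% of genotype entries are masked at
  random. The field morphology tables contain more birds (357 males, 223
  females) than the genotyped subset; the simulator drives both samples from
  one per-site count and we prioritized the genetic design. Tests that need
  more phenotypic power (e.g. the selection scan at 200 birds per category)
  raise the per-site count explicitly.
* **Dispersal.** Each bird is an immigrant from an adjacent site with
  per-sex probability; defaults `m_male = 0.05`, `m_female = 0.25` encode
  female-biased dispersal with male philopatry. Immigrants come from
  adjacent sites only, consistent with a stepping-stone range.
* **Traits.** Each structural trait is `intercept + slope × rainfall +
  N(0, sd)`. Intercepts and within-site SDs sit at the field values for a
  ~20 g honeyeater; the default slopes encode the reported gradient (longer
  bill-head, shallower bill, shorter tarsus with increasing rainfall: +0.06,
  −0.008 and −0.025 trait units per mm, i.e. about +1.2 mm, −0.2 mm and
  −0.6 mm from the driest to the wettest site).
* **Condition and selection.** Mass is structural plus a condition
  component: `mass = 9.3 + 0.5 × tarsus + c_rain × rainfall + selection term
  + N(0, 1.2)`. The default `c_rain = 0.1` g/mm makes the male
  condition-on-rainfall regression recover an adjusted r² near 0.30, the
  reported male statistic. Selection is injected through condition — not
  through trait means — because the downstream inference reads condition as
  a fitness proxy: with `z` the focal trait's z-score within its sex ×
  rainfall-category stratum, the term is 0 (none), −γz² (stabilizing), ±γz
  (directional), or +γz² (disruptive). The focal trait defaults to bill
  depth, the trait with the detected stabilizing signal in the field study.

What the generator deliberately does **not** model: traits have no genetic
basis (no heritability, no drift-driven trait divergence), there is no
mutation, no overlapping generations, and no spatial structure within sites.
Two consequences matter for interpreting green tests. First, a "neutral"
simulated trait has expected P_ST near 0, so the P_ST-vs-F_ST machinery is
validated against a drift-free baseline rather than a trait drifting with
the genome; the null calibration shows the *verdict* is conservative, not
that P_ST estimates drift correctly for heritable traits. Second, passing
recovery tests show the pipeline detects the signals it injects at field
effect sizes; they cannot show that real rainfall–morphology covariation has
the injected functional form.

## Population-genetic statistics

`allele_stats()` reports N_A, unbiased expected heterozygosity
`2n/(2n−1)(1 − Σp̂²)`, observed heterozygosity and F_IS per locus, by site
and globally. F_IS is the descriptive Nei form `1 − H_O/H_E` (undefined at
monomorphic loci, reported as `NA`, never coerced to zero); the
Weir–Cockerham small-f would be the alternative if an estimator with
sampling theory were needed, but these summaries are descriptive here.

`wc_fst()` implements the Weir & Cockerham (1984) variance components a, b,
c per allele and locus from sample sizes, allele frequencies and
heterozygote frequencies, with per-locus theta `Σa/Σ(a+b+c)` and the
multi-locus ratio-of-sums. Missing genotypes are dropped locus-wise
(complete-case per locus, no imputation). The estimator may legitimately go
negative near zero differentiation; it is reported as computed. Confidence
intervals jackknife over loci: delete-one-locus pseudovalues
`Lθ − (L−1)θ₋ₗ`, interval = pseudovalue mean ± 1.96 SE. At least three
informative loci are required; with identical per-locus components the
interval collapses onto theta.

`hwe_test()` is a conditional exact test in the Guo–Thompson spirit realized
by Monte-Carlo re-pairing: the statistic is the conditional probability of
the genotype table given allele counts, and the null shuffles the 2n allele
copies and re-pairs them. `ld_test()` uses the genotypic G statistic with
genotypes of the second locus permuted across individuals within a site.
Both use the add-one estimator `(1+k)/(1+N)`, which cannot return zero and
keeps the tests valid at any permutation count; defaults are 10,000
permutations with a mandatory seed. Family-wise control uses
`holm_adjust()`, the sequential Bonferroni (Holm/Rice) step-down rule with
stop-at-first-failure, applied at P < 0.01 for the HWE/LD families and
P < 0.05 for trait families (both exposed as configuration).

## Sex-biased dispersal

`assignment_index()` computes AI as the log10 expected frequency of an
individual's multilocus genotype under its own site's allele frequencies
(p² / 2pq per locus, summed over typed loci) and centres it per site (AIc).
Frequencies are leave-one-out, and alleles unseen after removal are floored
at `1/(2n+1)` — the standard assignment-index practice, which avoids log(0);
both behaviours are arguments. `sex_bias_test()` permutes sex labels within
sites and compares, one-sided, either the variance of AIc (as a
male/female variance ratio, matching the randomization framework of the
source method rather than a parametric F test), mean AIc, or per-sex
multi-locus theta. The caller must state the tested direction explicitly:
the field study's reported directions for the two tests are not both the
textbook expectation (the philopatric sex should show higher per-sex F_ST
and lower vAIc), so the package refuses to hard-code either convention.

## Isolation by distance

`linearize_fst()` applies the Rousset transform `θ/(1−θ)` (negative theta
passes through; θ = 1 is flagged and must be excluded), and `mantel_test()`
correlates the upper triangles after a natural-log transform of distance
(the log base only rescales a regression slope, never r or p). Significance
permutes rows and columns of one matrix simultaneously; with six or fewer
sites the test enumerates all n! relabelings exactly (720 at n = 6), which
is both cheaper and exact — the Monte-Carlo path is kept for larger
matrices and is checked against the exact path in the tests. Distances are
consumed as given; any routing decisions (e.g. across a sea divide) belong
to the data provider.

## P_ST versus F_ST

For each trait, sex and site pair, `anova_components()` computes one-way
ANOVA mean squares on just the two sites in the pair (not a pooled
within-variance — the comparisons are strictly pairwise), with the
unbalanced effective group size `n0 = (N − Σn_i²/N)/(k−1)` and the
method-of-moments `σ²_B = max(0, (MS_B − MS_W)/n0)`; negative estimates are
truncated at zero and counted. `pst()` is
`rσ²_B / (rσ²_B + 2σ²_W)` with `r = c/h²` defaulting to 1 (the plain
phenotypic form); r is exposed for sensitivity analysis because P_ST makes
an untestable assumption about the additive share of between- versus
within-population variance. `pairwise_pst()` aggregates the 15 pairwise
values with a ±1 SD interval — deliberately the spread measure used when too
few populations exist for a model-based global interval, and *not* a
nominal-coverage CI (it is not multiplied by 1.96). `compare_pst_fst()`
calls "exceeds" only when the P_ST lower bound clears the jackknife upper
bound of the sex-matched theta — a conservative rule: under the defaults'
mild trait slopes the verdict is usually "overlaps" even though mean P_ST
is several times theta, and the null calibration shows "exceeds" fires in
under 10% of drift-only replicates.

## Condition and the selection scan

`condition_index()` standardizes residuals of mass on tarsus per sex (the
species is sexually dimorphic; pooling is available but not default). The
index is unitless with mean 0 / SD 1 per stratum by construction.
`condition_rainfall_regression()` regresses individual condition on site
rainfall, one-sided for a positive slope; both r² and adjusted r² and the
site-mean variant are reported because individual-level and site-level
versions of this analysis answer slightly different questions.

`bin_traits()` z-scores a trait within its sex × rainfall-category stratum
and bins: |z| ≤ 1 mean, −2 ≤ z < −1 small, 1 < z ≤ 2 large. Values beyond
2 SD fall in none of the three defined ranges and are excluded (counted and
logged). The stratum for the SD was an open choice — within-category was
selected so that "extreme" means extreme for that climate, keeping bins
comparable across categories; it is exposed as configuration through the
stratification of the scan. `selection_scan()` compares mean condition
across the three bins (one-way ANOVA, sequential Bonferroni across the
whole scan — 90 cells at the defaults) and classifies significant cells:
mean bin strictly highest → stabilizing; both extremes above the mean bin →
disruptive; a single extreme highest, or an extreme tied with the mean bin
within ε = 0.05 condition units (configurable), → directional toward that
extreme. Tarsus is barred from the scan because it defines the condition
index; mass is excluded for the same reason. Classification is symmetric:
negating a trait swaps the directional calls and fixes
stabilizing/disruptive.

## Numerical choices and degenerate inputs

* Permutation p-values always use `(1+k)/(1+N)` and compare with a 1e−12
  slack so ties count as hits (conservative).
* Monomorphic loci: H_E = 0 with F_IS undefined; a locus monomorphic across
  the selected sites contributes 0/0 and is excluded from the theta sums.
* `anova_components()` drops groups with fewer than two observations (with a
  warning) and errors when fewer than two usable groups remain.
* Zero tarsus variance or an exact mass–tarsus fit abort the condition
  index rather than standardizing by ~0.
* `rainfall_category()` maps 44 mm into "moderate" (the category bounds are
  low [0, 32), moderate [32, 44], high (44, ∞), so every value has exactly
  one category).
* Seeds: every stochastic routine takes an explicit integer seed; the
  pipeline derives per-test seeds from its master seed so reruns are
  byte-identical.

## Problem sizes used by the test suite

The suite favours many small replicates over few large ones: permutation
calibrations run 200–500 replicates at 1,000 permutations on samples of
30–40; recovery checks run 100 replicates at the generator defaults (IBD,
P_ST) or 100 birds per site and sex (selection scan, giving the 200 per
category the scan design calls for). The P_ST "strong slope" recovery uses
0.15 trait units per mm — about 3.6 within-site SDs across the gradient —
as its definition of strong. The full suite completes in a few minutes on
one core.

## Known limitations

* The sex-biased-dispersal permutation test has limited power at realistic
  differentiation: with theta near 0.02 and ~28 birds per site and sex, the
  per-sex theta contrast detects female-biased dispersal (one-sided
  p < 0.05) in well under half of replicates even though the direction of
  the contrast is right in over 90% — detection there is a long-run
  property, not a per-study guarantee.
* P_ST inherits every caveat of phenotype-only differentiation measures;
  the package reports the scaling ratio used and the truncation count, but
  cannot estimate heritability.
* The Mantel exact mode enumerates permutations up to n = 6 sites;
  larger designs fall back to Monte-Carlo with a seed.
* The Genepop dialect supported is the classic one (2/3-digit codes,
  `Pop` delimiters); extended dialects are out of scope, as are VCF/PLINK
  inputs and GIS distance computation.
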
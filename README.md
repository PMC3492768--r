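# honeypop

Joint analysis of neutral genetic structure and adaptive phenotypic
divergence in songbird populations sampled along a rainfall gradient — the
situation where a nectarivorous bird spans sites from dry (< 32 mm mean
monthly rainfall) to wet (> 44 mm), gene flow is high, and the question is
whether morphology diverges more than drift allows and which mode of
selection is acting. It is written for population and evolutionary
ecologists working with microsatellite panels plus field morphometrics.

The package provides, as plain R functions over a genotype-matrix container
and data frames:

* **Marker statistics** — per-locus N_A, unbiased H_E, H_O, F_IS;
  Hardy–Weinberg and linkage-disequilibrium permutation tests (Monte-Carlo
  exact re-pairing and genotypic G tests) with sequential Bonferroni
  (Holm/Rice) correction.
* **F_ST** — the Weir–Cockerham (1984) variance-component estimator θ
  (global, per sex, pairwise) with jackknife-over-loci 95% CIs.
* **Sex-biased dispersal** — corrected assignment indices (AIc) with
  leave-one-out frequencies, and one-sided within-site label-permutation
  tests on vAIc, mean AIc, or per-sex θ.
* **Isolation by distance** — Rousset linearization θ/(1−θ) against log
  distance with Mantel tests (exact enumeration up to 6 sites, Monte-Carlo
  beyond).
* **P_ST vs F_ST** — pairwise P_ST = σ²_B/(σ²_B + 2σ²_W) per trait and sex
  from two-site ANOVA variance components (optional c/h² scaling), a ±1 SD
  interval across site pairs, and an interval-disjointness verdict against
  the θ jackknife CI.
* **Selection scan** — body condition (standardized mass-on-tarsus
  residuals) as a fitness proxy; one-way ANOVA of condition across
  small/mean/large trait bins (±1–2 SD) within sex × rainfall category, and
  classification into stabilizing / directional / disruptive / none.
* **A simulator with known truth** — stepping-stone Balding–Nichols allele
  frequencies, sex-specific migration, rainfall-driven trait means, and
  selection injected through condition, so every stage is testable.

File formats: Genepop (2- and 3-digit) via `read_genepop()`/`write_genepop()`
and CSV tables via `read_morphology()`, `read_sites()`, `read_distances()`.

## Worked example

The `analysis/` scripts run the whole study on simulated data. In brief:

```r
library(honeypop)

cfg <- sim_config(seed = 20121, selection_mode = "stabilizing",
                  selection_gamma = 0.5)
dat <- simulate_dataset(cfg)

# neutral structure
fst <- wc_fst(dat$genotypes, ci = TRUE)
fst
#> Weir-Cockerham theta = 0.0157 over 10 loci, 6 sites
#>   95% jackknife CI: (0.0102, 0.0213)

# isolation by distance, males
males <- subset_genotypes(dat$genotypes,
                          individuals = dat$genotypes$sex == "male")
lin <- linearize_fst(pairwise_fst(males))
mantel_test(lin, dat$distances, transform_b = "log")[c("r", "p")]
#> $r
#> [1] 0.7716
#> $p
#> [1] 0.002778

# sex-biased dispersal: is male theta larger (males philopatric)?
sex_bias_test(dat$genotypes, "per_sex_FST", n_perm = 999, seed = 20124,
              direction = "male_greater")[c("male", "female", "p")]
#> $male
#> [1] 0.01944
#> $female
#> [1] 0.01314
#> $p
#> [1] 0.035

# selection scan on condition
ci <- condition_index(dat$morphology)
scan <- selection_scan(dat$morphology, ci, dat$sites)
scan[scan$mode != "none", c("trait", "sex", "rainfall_category", "p", "mode")]
#>         trait  sex rainfall_category       p        mode
#> 14 bill_depth male          moderate 0.00012 stabilizing
```

Reading the numbers: multi-locus θ ≈ 0.016 with a CI excluding zero says the
six sites are weakly but detectably differentiated; Mantel r ≈ 0.77 on
linearized θ against log distance is a strong isolation-by-distance signal;
male per-sex θ exceeding female θ with permutation p = 0.035 indicates male
philopatry (females disperse); and the scan recovers the stabilizing signal
injected on bill depth — condition is highest at intermediate bill depths.

Run the full workflow (writes tables under `results/`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_popgen.R
Rscript analysis/03_dispersal_ibd.R
Rscript analysis/04_pst_fst.R
Rscript analysis/05_selection.R
```

## Package layout

```
R/                 implementation (io, simulator, popgen, dispersal/IBD,
                   P_ST, condition/selection, pipeline)
analysis/          numbered workflow scripts over the package
tests/testthat/    unit, property and end-to-end statistical tests
scripts/           acceptance script
vignettes/         methods vignette (models, assumptions, design choices)
```
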
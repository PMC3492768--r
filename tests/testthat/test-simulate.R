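test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 11)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$allele_frequencies, d2$allele_frequencies)
  expect_true(genotypes_equal(d1$genotypes, d2$genotypes))
  expect_identical(d1$morphology, d2$morphology)
})

test_that("allele frequencies are valid simplex vectors at every site", {
  cfg <- sim_config(seed = 3, n_loci = 5)
  fr <- simulate_allele_frequencies(cfg)
  for (f in fr) {
    expect_true(all(f >= 0))
    expect_equal(unname(rowSums(f)), rep(1, cfg$n_sites))
  }
})

test_that("F_step = 0 copies frequencies exactly and theta stays near zero", {
  cfg <- quick_cfg(5, F_step = 0)
  fr <- simulate_allele_frequencies(cfg)
  for (f in fr) expect_equal(max(apply(f, 2, function(x) diff(range(x)))), 0)
  gm <- simulate_genotypes(fr, cfg)
  expect_lt(abs(wc_fst(gm)$theta), 0.01)
})

test_that("adjacent-site theta matches the replicate-average oracle (F/2)", {
  # each site is a Balding-Nichols draw around its left neighbour, so the
  # parent/child pair has E[theta] = F_step / 2; oracle = average WC theta
  # over 200 replicate simulations at F_step = 0.05
  set.seed(80)
  th <- replicate(200, {
    cfg <- quick_cfg(sample.int(1e6, 1), n_sites = 2,
                     site_positions = c(0, 10), F_step = 0.05,
                     alleles_per_locus = 10, n_per_site_per_sex = 50,
                     m_male = 0, m_female = 0,
                     rainfall_per_site = c(30, 50))
    gm <- simulate_genotypes(simulate_allele_frequencies(cfg, seed = FALSE),
                             cfg)
    wc_fst(gm)$theta
  })
  expect_lt(abs(mean(th) - 0.025), 0.01)
})

test_that("no migrants and no masking when both rates are zero", {
  cfg <- quick_cfg(9, m_male = 0, m_female = 0)
  gm <- simulate_genotypes(simulate_allele_frequencies(cfg), cfg)
  expect_equal(missing_summary(gm)$n_missing, 0)
  expect_equal(attr(gm, "true_source_site"), gm$site)
})

test_that("masking rate reproduces the expected missing count", {
  # 330 x 10 design at rate 192/3300: binomial mean 192
  set.seed(12)
  counts <- replicate(20, {
    cfg <- sim_config(seed = sample.int(1e6, 1), n_per_site_per_sex = 28,
                      missing_rate = 192 / 3300)
    gm <- simulate_genotypes(simulate_allele_frequencies(cfg, seed = FALSE),
                             cfg)
    gm <- subset_genotypes(gm, individuals = seq_len(330))
    missing_summary(gm)$n_missing
  })
  expect_lt(abs(mean(counts) - 192), 3 * sqrt(192 * (1 - 192/3300) / 20))
})

test_that("linearized differentiation is non-decreasing in chain distance", {
  set.seed(14)
  rho <- replicate(30, {
    cfg <- quick_cfg(sample.int(1e6, 1), m_male = 0, m_female = 0,
                     n_per_site_per_sex = 15)
    gm <- simulate_genotypes(simulate_allele_frequencies(cfg, seed = FALSE),
                             cfg)
    lin <- linearize_fst(pairwise_fst(gm))
    steps <- abs(outer(seq_len(cfg$n_sites), seq_len(cfg$n_sites), "-"))
    stats::cor(lin[upper.tri(lin)], steps[upper.tri(steps)],
               method = "spearman")
  })
  expect_gt(mean(rho), 0)
  expect_gt(mean(rho > 0), 0.9)
})

test_that("female-biased migration depresses female theta in most replicates", {
  set.seed(15)
  hits <- replicate(100, {
    cfg <- quick_cfg(sample.int(1e6, 1), m_male = 0.05, m_female = 0.25)
    gm <- simulate_genotypes(simulate_allele_frequencies(cfg, seed = FALSE),
                             cfg)
    m <- wc_fst(subset_genotypes(gm, individuals = gm$sex == "male"))$theta
    f <- wc_fst(subset_genotypes(gm, individuals = gm$sex == "female"))$theta
    f < m
  })
  expect_gt(mean(hits), 0.5)
})

test_that("rainfall slopes order site trait means as constructed", {
  cfg <- sim_config(seed = 21, n_per_site_per_sex = 400)
  morph <- simulate_morphology(cfg)
  means <- tapply(morph$bill_head_length, morph$site, mean)
  means <- means[cfg$sites]
  expect_equal(order(means), order(cfg$rainfall_per_site))
  # negative tarsus slope reverses the ordering
  tmeans <- tapply(morph$tarsus_length, morph$site, mean)[cfg$sites]
  expect_equal(order(tmeans), rev(order(cfg$rainfall_per_site)))
})

test_that("null trait model gives flat site means and no selection signal", {
  tm <- default_trait_model()
  tm$slope <- 0
  cfg <- sim_config(seed = 22, trait_model = tm, condition_rain_slope = 0,
                    n_per_site_per_sex = 100)
  morph <- simulate_morphology(cfg)
  a <- anova_components(morph$bill_head_length, morph$site)
  expect_gt(a$p, 0.001)   # no systematic site effect
  truth <- attr(morph, "truth")
  expect_equal(truth$selection_mode, "none")
})

test_that("stabilizing injection peaks condition in the central bin", {
  # oracle: with penalty -gamma * z^2 the expected condition of the central
  # bin (|z| <= 1) exceeds both extreme bins (1 < |z| <= 2) by construction
  cfg <- sim_config(seed = 23, n_per_site_per_sex = 100,
                    selection_mode = "stabilizing", selection_gamma = 0.5)
  morph <- simulate_morphology(cfg)
  ci <- condition_index(morph)
  rows <- morph$sex == "male" &
    as.character(rainfall_category(
      cfg$rainfall_per_site[match(morph$site, cfg$sites)])) == "high"
  bins <- bin_traits(morph$bill_depth[rows])
  v <- ci$CI[match(morph$individual_id[rows], ci$individual_id)]
  mns <- tapply(v, bins, mean)
  expect_gt(mns["mean"], mns["small"])
  expect_gt(mns["mean"], mns["large"])
})

test_that("unknown selection mode is rejected", {
  expect_error(sim_config(selection_mode = "sideways"))
})
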
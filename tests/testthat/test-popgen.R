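test_that("diversity summaries match hand arithmetic", {
  # 10 individuals all Aa: H_O = 1, unbiased H_E = 20/19 * 0.5 = 10/19,
  # F_IS = 1 - 1 / (10/19) = -0.9
  gm <- make_gm1(rep(1, 10), rep(2, 10), rep("s", 10))
  st <- allele_stats(gm, by_site = FALSE)
  expect_equal(st$H_O, 1)
  expect_equal(st$H_E, 10 / 19)
  expect_equal(st$F_IS, 1 - 19 / 10)
  expect_equal(st$N_A, 2)

  # monomorphic: N_A = 1, H_E = 0, F_IS undefined
  gm2 <- make_gm1(rep(1, 8), rep(1, 8), rep("s", 8))
  st2 <- allele_stats(gm2, by_site = FALSE)
  expect_equal(st2$N_A, 1)
  expect_equal(st2$H_E, 0)
  expect_true(is.na(st2$F_IS))
})

test_that("the default synthetic panel sits in the field diversity range", {
  cfg <- sim_config(seed = 42)
  gm <- simulate_genotypes(simulate_allele_frequencies(cfg), cfg)
  st <- allele_stats(gm, by_site = FALSE)
  expect_true(all(st$N_A >= 6 & st$N_A <= 18))
  expect_true(all(st$H_E >= 0.67 & st$H_E <= 0.91))
})

test_that("HWE Monte-Carlo p agrees with exhaustive re-pairing enumeration", {
  a <- c(1, 1, 1, 2, 1)
  b <- c(1, 2, 2, 2, 1)   # n = 5, informative two-allele table
  gm <- make_gm1(a, b, rep("s", 5))
  obs <- table_log_prob(Map(c, pmin(a, b), pmax(a, b)))
  ms <- all_matchings(c(a, b))
  p_exact <- mean(vapply(ms, table_log_prob, 0) <= obs + 1e-12)
  p_mc <- hwe_test(gm, "L1", "s", n_perm = 5000, seed = 7)$p
  expect_lt(abs(p_mc - p_exact), 0.02)
})

test_that("HWE test flags heterozygote excess and accepts modal tables", {
  all_het <- make_gm1(rep(1, 50), rep(2, 50), rep("s", 50))
  expect_lt(hwe_test(all_het, 1, "s", 2000, 1)$p, 0.01)

  hw <- make_gm1(c(rep(1, 25), rep(1, 50), rep(2, 25)),
                 c(rep(1, 25), rep(2, 50), rep(2, 25)), rep("s", 100))
  expect_gt(hwe_test(hw, 1, "s", 2000, 1)$p, 0.5)

  mono <- make_gm1(rep(1, 10), rep(1, 10), rep("s", 10))
  rec <- hwe_test(mono, 1, "s", 100, 1)
  expect_true(rec$skipped)
  expect_match(rec$reason, "monomorphic")
})

test_that("LD test detects a duplicated locus and skips tiny samples", {
  set.seed(31)
  a <- sample(1:3, 40, TRUE); b <- sample(1:3, 40, TRUE)
  gm <- genotype_matrix(sprintf("i%02d", 1:40), rep("s", 40),
                        rep("unknown", 40), cbind(a, a), cbind(b, b),
                        c("L1", "L2"))
  expect_lt(ld_test(gm, "L1", "L2", "s", 1000, 1)$p, 0.01)

  tiny <- genotype_matrix(c("x", "y"), rep("s", 2), rep("unknown", 2),
                          cbind(c(1, 2), c(1, 2)), cbind(c(1, 2), c(1, 2)),
                          c("L1", "L2"))
  rec <- ld_test(tiny, "L1", "L2", "s", 100, 1)
  expect_true(rec$skipped)
})

test_that("theta matches an independent evaluation of the 1984 components", {
  # site1: 5 AA + 5 Aa, site2: 5 Aa + 5 aa; hand-coded per-allele arithmetic
  r <- 2; n1 <- 10; n2 <- 10; nbar <- 10
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  hand <- function(p1, p2, h1, h2) {
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    c(a, a + b + hbar / 2)
  }
  comp <- hand(0.75, 0.25, 0.5, 0.5) + hand(0.25, 0.75, 0.5, 0.5)
  theta_hand <- comp[1] / comp[2]

  gm <- make_gm1(c(rep(1, 10), rep(1, 5), rep(2, 5)),
                 c(rep(1, 5), rep(2, 5), rep(2, 10)),
                 rep(c("s1", "s2"), each = 10))
  expect_lt(abs(wc_fst(gm)$theta - theta_hand), 1e-10)
  expect_equal(theta_hand, 0.377777777777778, tolerance = 1e-12)
})

test_that("theta hits the boundary cases", {
  fixed <- make_gm1(rep(c(1, 2), each = 10), rep(c(1, 2), each = 10),
                    rep(c("s1", "s2"), each = 10))
  expect_equal(wc_fst(fixed)$theta, 1)

  # identical genotype collections in both sites: no between-site variance
  a <- c(rep(1, 5), rep(1, 3), rep(2, 2))
  same <- make_gm1(c(a, a), c(rep(1, 3), rep(2, 7), rep(1, 3), rep(2, 7)),
                   rep(c("s1", "s2"), each = 10))
  expect_lte(wc_fst(same)$theta, 0)

  mono <- make_gm1(rep(1, 20), rep(1, 20), rep(c("s1", "s2"), each = 10))
  expect_true(is.na(wc_fst(mono)$theta))
})

test_that("theta is invariant to allele relabeling and site order", {
  set.seed(33)
  cfg <- quick_cfg(33, n_loci = 4)
  gm <- simulate_genotypes(simulate_allele_frequencies(cfg), cfg)
  base <- wc_fst(gm)$theta

  relab <- sample(100)   # injective recode of allele ids
  gm2 <- genotype_matrix(gm$individual_id, gm$site, gm$sex,
                         matrix(relab[gm$allele_a], nrow(gm$allele_a)),
                         matrix(relab[gm$allele_b], nrow(gm$allele_b)),
                         gm$locus_names)
  expect_equal(wc_fst(gm2)$theta, base, tolerance = 1e-12)

  perm <- sample(n_individuals(gm))
  gm3 <- subset_genotypes(gm)    # copy
  gm3 <- genotype_matrix(gm$individual_id[perm], gm$site[perm], gm$sex[perm],
                         gm$allele_a[perm, ], gm$allele_b[perm, ],
                         gm$locus_names)
  expect_equal(wc_fst(gm3)$theta, base, tolerance = 1e-12)
})

test_that("jackknife interval behaves as a delete-one-locus construction", {
  cfg <- quick_cfg(34)
  gm <- simulate_genotypes(simulate_allele_frequencies(cfg), cfg)
  fst <- wc_fst(gm, ci = TRUE)
  expect_lt(fst$ci[1], fst$theta)
  expect_gt(fst$ci[2], fst$theta)

  # removing a locus reproduces the corresponding pseudosample
  drop1 <- wc_fst(gm, loci = gm$locus_names[-1])$theta
  comp <- fst$components
  expect_equal(drop1, sum(comp[-1, "A"]) / sum(comp[-1, "ABC"]),
               tolerance = 1e-12)

  # identical per-locus components collapse the interval onto theta
  same <- comp
  same[, "A"] <- 0.1; same[, "ABC"] <- 1
  ci <- jackknife_ci(same)
  expect_equal(unname(ci), c(0.1, 0.1))

  expect_warning(jackknife_ci(comp[1:2, , drop = FALSE]), ">= 3")
})

test_that("sequential Bonferroni follows the step-down rule", {
  expect_equal(holm_adjust(numeric(0)), logical(0))
  expect_equal(holm_adjust(0.04, alpha = 0.05), TRUE)     # m = 1: raw test
  expect_equal(holm_adjust(c(0.04, 0.001)), c(TRUE, TRUE))
  expect_equal(holm_adjust(c(0.03, 0.001)), c(TRUE, TRUE))
  expect_equal(holm_adjust(c(0.04, 0.026)), c(FALSE, FALSE)) # first gate fails
  expect_equal(holm_adjust(rep(1, 5)), rep(FALSE, 5))

  # agrees with the standard step-down adjustment on random input
  set.seed(35)
  for (i in 1:20) {
    p <- stats::runif(7)^2
    expect_equal(holm_adjust(p), stats::p.adjust(p, "holm") < 0.05)
  }
})

test_that("sex-ratio chi-square matches hand arithmetic", {
  even <- sex_ratio_test(50, 50)
  expect_equal(even$chisq, 0)
  expect_equal(even$p, 1)
  expect_equal(sex_ratio_test(60, 40)$chisq, 4)
  expect_equal(sex_ratio_test(75, 25)$chisq, 25)
  expect_error(sex_ratio_test(0, 0))
})
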
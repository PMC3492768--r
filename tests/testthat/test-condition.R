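test_that("condition index standardizes within strata", {
  cfg <- sim_config(seed = 71)
  morph <- simulate_morphology(cfg)
  ci <- condition_index(morph)
  for (sx in c("male", "female")) {
    v <- ci$CI[ci$sex == sx]
    expect_lt(abs(mean(v)), 1e-6)
    expect_lt(abs(stats::sd(v) - 1), 1e-6)
  }
})

test_that("a mass outlier receives the largest condition index", {
  tarsus <- seq(20, 24, length.out = 20)
  mass <- 9 + 0.5 * tarsus
  mass[7] <- mass[7] + 3
  morph <- data.frame(individual_id = sprintf("i%02d", 1:20), site = "s",
                      sex = "male", tarsus_length = tarsus, mass = mass)
  ci <- condition_index(morph)
  expect_equal(which.max(ci$CI), 7)
})

test_that("the 5-point toy matches closed-form least squares", {
  morph <- data.frame(individual_id = paste0("i", 1:5), site = "s",
                      sex = "male", tarsus_length = 20:24,
                      mass = c(18, 19, 21, 20, 23))
  # hand fit: slope 11/10, intercept -4, residuals (0,-0.1,0.8,-1.3,0.6),
  # sd = sqrt(2.7/4)
  expected <- c(0, -0.1, 0.8, -1.3, 0.6) / sqrt(2.7 / 4)
  expect_equal(condition_index(morph)$CI, expected, tolerance = 1e-12)
})

test_that("degenerate condition strata are refused", {
  flat <- data.frame(individual_id = paste0("i", 1:5), site = "s",
                     sex = "male", tarsus_length = rep(21, 5),
                     mass = c(18, 19, 21, 20, 23))
  expect_error(condition_index(flat), "tarsus variance")
  exact <- data.frame(individual_id = paste0("i", 1:5), site = "s",
                      sex = "male", tarsus_length = 20:24,
                      mass = 9 + 0.5 * (20:24))
  expect_error(condition_index(exact), "residual variance")
})

test_that("condition-rainfall regression is one-sided for a positive slope", {
  cfg <- sim_config(seed = 72, condition_rain_slope = 0.08)
  morph <- simulate_morphology(cfg)
  ci <- condition_index(morph)
  sites <- sim_site_table(cfg)
  res <- condition_rainfall_regression(ci, sites)
  expect_gt(res$slope, 0)
  expect_lt(res$p_one_sided, 0.05)
  # the one-sided p is half the two-sided p for a positive slope
  fit <- stats::lm(ci$CI ~ sites$rainfall_mm[match(ci$site, sites$site)])
  p2 <- summary(fit)$coefficients[2, 4]
  expect_equal(res$p_one_sided, p2 / 2, tolerance = 1e-12)
  # site-mean mode uses one point per site
  expect_equal(condition_rainfall_regression(ci, sites, "site_mean")$n, 6)
})

test_that("trait binning applies the SD rules and affine invariance", {
  set.seed(73)
  x <- stats::rnorm(200)
  bins <- bin_traits(x)
  z <- (x - mean(x)) / stats::sd(x)
  expect_true(all(bins[abs(z) <= 1] == "mean"))
  expect_true(all(bins[z < -1 & z >= -2] == "small"))
  expect_true(all(bins[z > 1 & z <= 2] == "large"))
  expect_true(all(bins[abs(z) > 2] == "excluded"))
  expect_equal(bin_traits(5 + 2 * x), bins)     # affine invariance
  expect_warning(bin_traits(c(1, 2)), "< 3")
})

test_that("large-sample bin proportions match the normal tails", {
  set.seed(74)
  bins <- bin_traits(stats::rnorm(10000))
  prop <- table(bins) / 10000
  expect_lt(abs(prop[["mean"]] - 0.683), 0.015)
  expect_lt(abs(prop[["small"]] - 0.136), 0.015)
  expect_lt(abs(prop[["large"]] - 0.136), 0.015)
})

test_that("mode classification follows the bin-mean rules", {
  cl <- honeypop:::.classify_mode
  expect_equal(cl(c(small = -0.3, mean = 0.4, large = -0.3)), "stabilizing")
  expect_equal(cl(c(small = -0.4, mean = 0.0, large = 0.5)), "directional_up")
  expect_equal(cl(c(small = 0.5, mean = 0.0, large = -0.4)),
               "directional_down")
  expect_equal(cl(c(small = 0.4, mean = -0.3, large = 0.5)), "disruptive")
  # an extreme tied with the mean bin within eps is directional
  expect_equal(cl(c(small = -0.4, mean = 0.49, large = 0.5)),
               "directional_up")
  # negating the trait swaps the directional calls and fixes the others
  swap <- function(m) c(small = unname(m["large"]), mean = unname(m["mean"]),
                        large = unname(m["small"]))
  for (m in list(c(small = -0.4, mean = 0, large = 0.5),
                 c(small = -0.3, mean = 0.4, large = -0.3),
                 c(small = 0.4, mean = -0.3, large = 0.5))) {
    got <- cl(m); mirrored <- cl(swap(m))
    expect_equal(mirrored,
                 switch(got, directional_up = "directional_down",
                        directional_down = "directional_up", got))
  }
})

test_that("the selection scan recovers an injected stabilizing signal", {
  cfg <- sim_config(seed = 75, n_per_site_per_sex = 100,
                    selection_mode = "stabilizing", selection_gamma = 0.5)
  morph <- simulate_morphology(cfg)
  ci <- condition_index(morph)
  scan <- selection_scan(morph, ci, sim_site_table(cfg))
  focal <- scan[scan$trait == "bill_depth", ]
  expect_gt(mean(focal$mode == "stabilizing"), 0.5)
  # non-significant cells always carry mode "none"
  expect_true(all(scan$mode[!scan$significant] == "none"))
  # bins partition the retained individuals
  expect_true(all(scan$n_small + scan$n_mean + scan$n_large <=
                    sum(morph$sex == "male") + sum(morph$sex == "female")))
  expect_error(selection_scan(morph, ci, sim_site_table(cfg),
                              traits = "tarsus_length"), "tarsus")
})

test_that("site-trait ANOVA flags only the traits with rainfall structure", {
  tm <- default_trait_model()
  tm$slope <- 0
  tm$slope[tm$trait == "bill_depth"] <- -0.03
  cfg <- sim_config(seed = 76, trait_model = tm, n_per_site_per_sex = 80)
  morph <- simulate_morphology(cfg)
  tab <- site_trait_anova_table(morph, "male",
                                traits = setdiff(trait_names(), "mass"))
  expect_true(tab$significant[tab$trait == "bill_depth"])
  null_traits <- setdiff(tab$trait, "bill_depth")
  expect_lte(sum(tab$significant[tab$trait %in% null_traits]), 1)
  expect_error(site_trait_anova(morph[morph$site == "site_1", ],
                                "bill_depth", "male"))
})

test_that("rainfall-on-morphology regression recovers coefficient signs", {
  cfg <- sim_config(seed = 77, n_per_site_per_sex = 150)
  morph <- simulate_morphology(cfg)
  sites <- sim_site_table(cfg)
  res <- rainfall_morphology_regression(morph, sites, "male")
  co <- res$coefficients
  expect_lt(co$estimate[co$trait == "bill_depth"], 0)    # shallower bills wet
  expect_gt(co$estimate[co$trait == "bill_head_length"], 0)
  expect_true(res$r2 >= 0 && res$r2 <= 1)
  tiny <- morph[1:8, ]
  expect_error(rainfall_morphology_regression(tiny, sites, "male"),
               "more observations")
})
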
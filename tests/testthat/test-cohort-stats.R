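test_that("block t-test agrees with the closed form and Student tail", {
  # printed toy vector: t = sqrt(5) * 3 / sqrt(2.5)
  r <- block_ttest(c(1, 2, 3, 4, 5))
  expect_equal(r$t, 3 / (sqrt(2.5) / sqrt(5)), tolerance = 1e-10)
  expect_equal(r$p_raw, 2 * pt(-r$t, 4), tolerance = 1e-10)
  expect_equal(r$p_bonf, 1)  # 105 * 0.0132 caps at 1

  # direct-formula oracle on random small inputs
  set.seed(30)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1), sd = runif(1, 0.1, 2))
    r <- block_ttest(x, m_comparisons = 7)
    t_direct <- mean(x) / (sd(x) / sqrt(length(x)))
    expect_equal(r$t, t_direct, tolerance = 1e-10)
    expect_equal(r$p_raw, 2 * pt(-abs(t_direct), length(x) - 1),
                 tolerance = 1e-10)
    expect_equal(r$p_bonf, min(1, 7 * r$p_raw), tolerance = 1e-10)
  }
})

test_that("block t-test degenerate and error cases", {
  z <- block_ttest(rep(0, 5))
  expect_equal(z$t, 0)
  expect_equal(z$p_raw, 1)
  d <- block_ttest(rep(0.2, 5))
  expect_true(d$degenerate)
  expect_equal(d$p_raw, 0)
  expect_error(block_ttest(1), "at least 2")
})

test_that("sign counts split strictly positive, negative and zero", {
  atlas <- counts_atlas(c(2, 2), labels = c(0, 6))
  younger <- matrix(0.1, 3, 6)
  older <- younger + matrix(rep(c(0.1, -0.2, 0), 6), 3, 6)
  cohort <- manual_cohort(atlas, younger, older,
                          sex = c("M", "M", "F"),
                          age_group = c("young", "old", "old"))
  sc <- sign_counts(cohort, "0-6")
  male <- sc[sc$group == "Male", ]
  expect_equal(male$block_pos, 1)
  expect_equal(male$block_neg, 1)
  expect_equal(male$block_zero, 0)
  fem <- sc[sc$group == "Female", ]
  expect_equal(fem$block_zero, 1)
  # percentages reproduce counts / totals
  expect_equal(sc$block_pos_pct, 100 * sc$block_pos / sc$n)
  expect_equal(sc$total_pos_pct, 100 * sc$total_pos / sc$n)
})

test_that("positive-change fraction matches the Gaussian orthant rate", {
  atlas <- atlas_subset(power264_atlas(), c(0, 6))
  cfg <- synth_config(atlas = atlas, n_subjects = 4000, seed = 31)
  cohort <- generate_fc_cohort(cfg)
  sc <- sign_counts(cohort, "0-6")
  # per-subject block change ~ N(0.03, sigma); sigma combines the block
  # effect with averaged edge noise over the 930 block edges
  sigma <- sqrt(cfg$block_effect_sd^2 +
                  (cfg$change_sd^2 - cfg$block_effect_sd^2) / 930)
  target <- pnorm(0.03 / sigma)
  frac <- sum(sc$block_pos) / sum(sc$n)
  expect_lt(abs(frac - target), 2 * sqrt(target * (1 - target) / 4000))

  # zero-noise positive-shift generator: 100% positive
  cfg0 <- synth_config(atlas = atlas, n_subjects = 20, change_sd = 0,
                       block_effect_sd = 0, subject_sd = 0, edge_sd = 0,
                       seed = 32)
  sc0 <- sign_counts(generate_fc_cohort(cfg0), "0-6")
  expect_equal(sum(sc0$block_pos), sum(sc0$n))
})

test_that("cross-sectional comparison: identical groups give zero diffs", {
  atlas <- counts_atlas(c(2, 3), labels = c(0, 4))
  set.seed(33)
  fc <- matrix(runif(8 * 10, -0.5, 0.5), 8, 10)
  subjects <- data.frame(subject_id = sprintf("s%d", 1:8),
                         age_group = rep(c("young", "old"), each = 4))
  cohort <- fc_cohort(atlas, subjects, fc = rbind(fc[1:4, ], fc[1:4, ]))
  cs <- cross_sectional_compare(cohort)
  expect_equal(cs$blocks$diff, rep(0, nrow(cs$blocks)))
  expect_true(all(abs(cs$edge_diff) < 1e-12))
  expect_equal(cs$blocks$key[nrow(cs$blocks)], "total")
})

test_that("cross-sectional generator recovers signed age effects", {
  atlas <- atlas_subset(power264_atlas(), c(0, 6), per_network = 10)
  cfg <- synth_config(atlas = atlas, n_young = 2000, n_old = 2000, seed = 34)
  cohort <- generate_cross_sectional(cfg)
  cs <- cross_sectional_compare(cohort)
  vv <- cs$blocks[cs$blocks$key == "6-6", ]
  # the configured visual within-network age effect is negative
  expect_lt(vv$diff, 0)
  expect_error(cross_sectional_compare(
    fclong:::cohort_subset(cohort, 1:3)), "age_group|2 subjects")
})

test_that("phenotype correlations behave at the construction extremes", {
  atlas <- counts_atlas(c(3, 3), labels = c(0, 6))
  cfg <- synth_config(atlas = atlas, n_subjects = 2000, seed = 35)
  cohort <- generate_fc_cohort(cfg)
  cohort <- generate_phenotypes(cohort, list(
    list(name = "exact", block = "0-6", r = 1),
    list(name = "weak", block = "0-6", r = 0.1),
    list(name = "null", block = "0-6", r = 0),
    list(name = "flat", block = "0-6", r = 0)), seed = 36)
  cohort$phenotypes$flat <- 1  # constant phenotype
  expect_equal(phenotype_correlation(cohort, "0-6", "exact")$r, 1,
               tolerance = 1e-10)
  weak <- phenotype_correlation(cohort, "0-6", "weak")
  expect_lt(abs(weak$r - 0.1), 2 / sqrt(2000) * 2)
  expect_lt(abs(phenotype_correlation(cohort, "0-6", "null")$r),
            3 / sqrt(2000))
  expect_warning(flat <- phenotype_correlation(cohort, "0-6", "flat"),
                 "constant")
  expect_true(is.na(flat$r))
  expect_error(phenotype_correlation(cohort, "0-6", "nope"), "unknown")
})
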
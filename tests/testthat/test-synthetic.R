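test_that("generated cohorts are bit-for-bit reproducible from (config, seed)", {
  atlas <- counts_atlas(c(4, 4), labels = c(0, 6))
  cfg <- synth_config(atlas = atlas, n_subjects = 30, seed = 37)
  c1 <- generate_fc_cohort(cfg)
  c2 <- generate_fc_cohort(cfg)
  expect_identical(c1$younger, c2$younger)
  expect_identical(c1$older, c2$older)
  expect_identical(c1$subjects, c2$subjects)
  c3 <- generate_fc_cohort(synth_config(atlas = atlas, n_subjects = 30,
                                        seed = 38))
  expect_false(identical(c1$younger, c3$younger))
})

test_that("emitted younger-scan FC satisfies matrix invariants", {
  atlas <- counts_atlas(c(5, 5), labels = c(0, 6))
  cfg <- synth_config(atlas = atlas, n_subjects = 5, seed = 39)
  cohort <- generate_fc_cohort(cfg)
  for (i in 1:5) {
    m <- devectorize_fc(cohort$younger[i, ])
    expect_true(all(abs(m) <= 1))
    expect_equal(unclass(m), t(unclass(m)))
    expect_equal(diag(unclass(m)), rep(1, nrow(atlas)), ignore_attr = TRUE)
  }
  # bounded mode clips the older scan into range as well
  cfgb <- synth_config(atlas = atlas, n_subjects = 5, bounded = TRUE,
                       seed = 39)
  cb <- generate_fc_cohort(cfgb)
  expect_true(all(abs(cb$older) <= 1))
  # PSD repair yields positive-semidefinite unit-diagonal matrices
  cfgp <- synth_config(atlas = atlas, n_subjects = 3, bounded = TRUE,
                       psd_repair = TRUE, seed = 40)
  cp <- generate_fc_cohort(cfgp)
  for (i in 1:3) {
    m <- devectorize_fc(cp$older[i, ])
    ev <- eigen(unclass(m), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
})

test_that("zero-noise, zero-shift generator returns identical scans", {
  atlas <- counts_atlas(c(3, 3), labels = c(0, 6))
  cfg <- synth_config(atlas = atlas, n_subjects = 10, shift = c("0-6" = 0),
                      change_sd = 0, block_effect_sd = 0, subject_sd = 0,
                      edge_sd = 0, seed = 41)
  cohort <- generate_fc_cohort(cfg)
  expect_identical(cohort$older, cohort$younger)
  s <- cohort_change_summary(cohort)
  expect_equal(s$blocks$mu, rep(0, 3))
  expect_equal(s$blocks$sd_subject, rep(0, 3))
})

test_that("config validation rejects impossible calibrations", {
  atlas <- counts_atlas(c(3, 3), labels = c(0, 6))
  expect_error(synth_config(atlas = atlas, baseline_overrides = c("0-6" = 1.2)),
               "inside")
  # baseline + shift escaping (-1, 1) is rejected too
  expect_error(synth_config(atlas = atlas,
                            baseline_overrides = c("0-6" = 0.95),
                            shift = c("0-6" = 0.1)), "inside")
  # a large shift whose sum stays in range is fine
  expect_no_error(synth_config(atlas = atlas, shift = c("0-6" = 0.5),
                               baseline_overrides = c("0-6" = 0.39)))
  expect_error(synth_config(atlas = atlas, block_effect_sd = 0.3,
                            change_sd = 0.26), "exceed")
})

test_that("parameter recovery: configured means, shift and dispersions", {
  atlas <- atlas_subset(power264_atlas(), c(0, 6), per_network = 12)
  cfg <- synth_config(atlas = atlas, n_subjects = 1500, seed = 42)
  cohort <- generate_fc_cohort(cfg)
  p <- cohort$partition
  bs <- fclong:::block_structure(p)
  yb <- fclong:::block_means_rows(cohort$younger, bs)
  # configured baselines: 0.39 cross block, 0.30 within
  expect_lt(abs(mean(yb[, "0-6"]) - 0.39), 2 * sd(yb[, "0-6"]) / sqrt(1500))
  expect_lt(abs(mean(yb[, "0-0"]) - 0.30), 2 * sd(yb[, "0-0"]) / sqrt(1500))
  s <- cohort_change_summary(cohort)
  b <- s$blocks
  r06 <- b[b$key == "0-6", ]
  expect_lt(abs(r06$mu - 0.03), 2 * r06$sd_subject / sqrt(r06$n))
  # unshifted blocks recover zero change
  r00 <- b[b$key == "0-0", ]
  expect_lt(abs(r00$mu), 2 * r00$sd_subject / sqrt(r00$n))
  # marginal per-edge change sd calibrated to 0.26 in every block
  expect_equal(unname(b$sd_edge_mean), rep(0.26, 3), tolerance = 0.01)
  # the three percent-change definitions are mutually consistent
  expect_equal(r06$pct_of_younger, 100 * r06$mu / r06$mu_younger)
  expect_equal(r06$pct_of_older,
               100 * r06$mu / (r06$mu_younger + r06$mu))
  expect_equal(r06$pct_of_younger, 100 * 0.03 / 0.39, tolerance = 0.1)
})

test_that("timeseries factor model realizes target block correlations", {
  atlas <- counts_atlas(c(5, 5), labels = c(0, 6))
  cfg <- synth_config(atlas = atlas, n_subjects = 1, frames = 20000,
                      baseline_within = 0.5,
                      baseline_overrides = c("0-6" = 0.4), seed = 43)
  subj <- generate_timeseries_cohort(cfg)[[1]]
  m <- fc_from_timeseries(subj$younger)
  ba <- block_average(m, network_partition(atlas))
  expect_lt(abs(ba[["0-6"]] - 0.4), 0.02)
  expect_lt(abs(ba[["0-0"]] - 0.5), 0.03)
  # older scan realizes the shifted target
  mo <- fc_from_timeseries(subj$older)
  bo <- block_average(mo, network_partition(atlas))
  expect_lt(abs(bo[["0-6"]] - 0.43), 0.03)
  # infeasible: cross-block target above sqrt(B_aa B_bb)
  bad <- synth_config(atlas = atlas, n_subjects = 1, frames = 200,
                      baseline_within = 0.2,
                      baseline_overrides = c("0-6" = 0.5), seed = 44)
  expect_error(generate_timeseries_cohort(bad), "not realizable")
})

test_that("the full pipeline recovers generator structure end-to-end", {
  atlas <- counts_atlas(c(4, 4), labels = c(0, 6))
  cfg <- synth_config(atlas = atlas, n_subjects = 1, frames = 6000,
                      baseline_within = 0.45,
                      baseline_overrides = c("0-6" = 0.35), seed = 45)
  subj <- generate_timeseries_cohort(cfg)[[1]]
  # extraction -> bandpass -> FC -> block averages
  m <- fc_from_timeseries(bandpass(subj$younger))
  ba <- block_average(m, network_partition(atlas))
  expect_lt(abs(ba[["0-6"]] - 0.35), 0.04)
  expect_lt(abs(ba[["0-0"]] - 0.45), 0.04)
})

test_that("cross-sectional generator applies per-sex age effects", {
  atlas <- atlas_subset(power264_atlas(), c(0, 4), per_network = 8)
  cfg <- synth_config(atlas = atlas, n_young = 1500, n_old = 1500,
                      sex_prop = 1, seed = 46)  # male calibration
  cohort <- generate_cross_sectional(cfg)
  cs <- cross_sectional_compare(cohort)
  row <- cs$blocks[cs$blocks$key == "0-4", ]
  se <- sqrt(row$sd_young^2 / cs$n_young + row$sd_old^2 / cs$n_old)
  expect_lt(abs(row$diff - 0.045), 2 * se)
  # zero age effect -> near-zero difference
  cfg0 <- synth_config(atlas = atlas, n_young = 800, n_old = 800,
                       age_effect_base = c(M = 0, F = 0),
                       age_effect_overrides = list(M = numeric(0),
                                                   F = numeric(0)),
                       seed = 47)
  cs0 <- cross_sectional_compare(generate_cross_sectional(cfg0))
  row0 <- cs0$blocks[cs0$blocks$key == "0-4", ]
  se0 <- sqrt(row0$sd_young^2 / 800 + row0$sd_old^2 / 800)
  expect_lt(abs(row0$diff), 3 * se0)
})
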
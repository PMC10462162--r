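test_that("block averages reduce edges correctly", {
  # 4 ROIs in 2 networks {0,1},{2,3}; cross-block entries set by hand
  atlas <- counts_atlas(c(2, 2))
  p <- network_partition(atlas)
  m <- diag(4)
  m[1, 3] <- m[3, 1] <- 0.1
  m[1, 4] <- m[4, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.3
  m[2, 4] <- m[4, 2] <- 0.4
  m[1, 2] <- m[2, 1] <- 0.7   # within network 0 (single edge)
  m[3, 4] <- m[4, 3] <- -0.5  # within network 1 (single edge)
  ba <- block_average(m, p)
  expect_equal(unname(ba["0-1"]), mean(c(0.1, 0.2, 0.3, 0.4)))
  # single-edge blocks equal that edge's value
  expect_equal(unname(ba["0-0"]), 0.7)
  expect_equal(unname(ba["1-1"]), -0.5)

  # constant off-diagonal: every block mean is that constant
  mc <- matrix(0.5, 4, 4); diag(mc) <- 1
  expect_equal(as.numeric(block_average(mc, p)), rep(0.5, 3))
})

test_that("edge-count-weighted block means conserve the FC-vector mean", {
  atlas <- scaled_atlas14(3)
  p <- network_partition(atlas)
  set.seed(9)
  v <- runif(nrow(atlas) * (nrow(atlas) - 1) / 2, -1, 1)
  ba <- block_average(v, p)
  pairs <- attr(ba, "pairs")
  bs <- fclong:::block_structure(p)
  expect_equal(sum(ba * bs$counts) / sum(bs$counts), mean(v),
               tolerance = 1e-10)
})

test_that("subject block change is the older-minus-younger block mean", {
  atlas <- counts_atlas(c(3, 4), labels = c(0, 6))
  p <- network_partition(atlas)
  set.seed(10)
  e <- nrow(atlas) * (nrow(atlas) - 1) / 2
  younger <- matrix(runif(2 * e, -0.5, 0.5), 2, e)
  older <- younger
  # add 0.03 to every edge of the 0-6 block for subject 1
  bs <- fclong:::block_structure(p)
  key06 <- which(bs$pairs$key == "0-6")
  older[1, bs$edge_block == key06] <- older[1, bs$edge_block == key06] + 0.03
  cohort <- manual_cohort(atlas, younger, older)
  pair <- scan_pair(cohort, 1)
  expect_equal(subject_block_change(pair, "0-6", p), 0.03)
  expect_equal(subject_block_change(scan_pair(cohort, 2), "0-6", p), 0)
  # swapping scans negates the change
  swapped <- list(younger = pair$older, older = pair$younger)
  expect_equal(subject_block_change(swapped, "0-6", p), -0.03)
  # missing edge on one scan -> missing block value
  y2 <- younger; y2[1, which(bs$edge_block == key06)[1]] <- NA
  pair_na <- list(younger = y2[1, ], older = older[1, ])
  expect_true(is.na(subject_block_change(pair_na, "0-6", p)))
})

test_that("cohort change summary matches edge-level maps and handles zeros", {
  atlas <- counts_atlas(c(3, 3), labels = c(0, 6))
  set.seed(11)
  e <- 15
  younger <- matrix(runif(6 * e, -0.5, 0.5), 6, e)
  older <- younger + matrix(rnorm(6 * e, 0.02, 0.1), 6, e)
  cohort <- manual_cohort(atlas, younger, older)
  s <- cohort_change_summary(cohort)
  # exchange of averages: block mean of the edge-level mean map
  p <- network_partition(atlas)
  ba <- block_average(s$edge_mean, p)
  expect_equal(as.numeric(ba), s$blocks$mu, tolerance = 1e-10)
  # zero change everywhere -> mu 0, sd 0, p 1
  z <- cohort_change_summary(manual_cohort(atlas, younger, younger))
  expect_equal(z$blocks$mu, rep(0, 3))
  expect_equal(z$blocks$sd_subject, rep(0, 3))
  expect_equal(z$blocks$p_raw, rep(1, 3))
  expect_error(cohort_change_summary(
    manual_cohort(atlas, younger[1, , drop = FALSE],
                  older[1, , drop = FALSE])), "2 subjects")
})

test_that("subjects with missing block edges are excluded from that block", {
  atlas <- counts_atlas(c(2, 2), labels = c(0, 6))
  younger <- matrix(0.1, 4, 6)
  older <- matrix(0.2, 4, 6)
  bs <- fclong:::block_structure(network_partition(atlas))
  cross <- which(bs$pairs$key == "0-6")
  younger[1, which(bs$edge_block == cross)[1]] <- NA
  s <- cohort_change_summary(manual_cohort(atlas, younger, older))
  b <- s$blocks
  expect_equal(b$n[b$key == "0-6"], 3)
  expect_equal(b$n[b$key == "0-0"], 4)
})

test_that("subgroup summaries recover a common effect in every subgroup", {
  atlas <- atlas_subset(power264_atlas(), c(0, 6), per_network = 10)
  cfg <- synth_config(atlas = atlas, n_subjects = 2000, seed = 12)
  cohort <- generate_fc_cohort(cfg)
  by_sex <- subgroup_summaries(cohort, "sex")
  by_age <- subgroup_summaries(cohort, "age_group")
  expect_named(by_sex, c("F", "M"))
  expect_named(by_age, c("young", "old"))
  for (s in c(by_sex, by_age)) {
    b <- s$blocks
    row <- b[b$key == "0-6", ]
    se <- row$sd_subject / sqrt(row$n)
    expect_lt(abs(row$mu - 0.03), 2 * se)
  }
  # reproducible split
  by_sex2 <- subgroup_summaries(generate_fc_cohort(cfg), "sex")
  expect_identical(by_sex$M$blocks, by_sex2$M$blocks)
  # singleton subgroup skipped with a warning
  c2 <- cohort
  c2$subjects$sex[1] <- "X"
  expect_warning(s2 <- subgroup_summaries(c2, "sex"), "skipped")
  expect_false("X" %in% names(s2))
})
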
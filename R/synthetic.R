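#' Configuration for the synthetic FC cohort generator
#'
#' The generator emulates the statistical structure the longitudinal
#' analysis assumes: paired per-subject FC whose network-block means,
#' longitudinal block shift, per-edge change dispersion and subject-level
#' heterogeneity are set to published effect sizes. Defaults encode the
#' headline calibration: a somatomotor-visual (block 0-6) younger-scan
#' mean of 0.39 shifting by +0.03 at the older scan, a marginal per-edge
#' change standard deviation of 0.26, and a per-subject block-effect
#' standard deviation of 0.11 (chosen so that roughly 60% of subjects
#' show a positive block change, the observed regime; the per-edge
#' residual noise sd is derived internally as
#' `sqrt(change_sd^2 - block_effect_sd^2)`).
#'
#' @param n_subjects longitudinal cohort size (default 2722).
#' @param atlas an `fc_atlas` (default the packaged 264-ROI atlas; pass a
#'   reduced atlas from [atlas_subset()] to scale the simulation down).
#' @param baseline_within,baseline_between default block means for
#'   within-network and between-network blocks of the younger scan.
#' @param baseline_overrides named vector of block-mean overrides, keyed
#'   `"a-b"` (default sets the 0-6 block to 0.39).
#' @param shift named vector of longitudinal block-mean shifts (older
#'   minus younger), default `c("0-6" = 0.03)`, zero elsewhere.
#' @param change_sd marginal per-edge change standard deviation (0.26).
#' @param block_effect_sd per-subject block-effect standard deviation
#'   (0.11); must not exceed `change_sd`.
#' @param subject_sd per-subject baseline offset sd (0.11, matching the
#'   observed dispersion of per-subject block averages).
#' @param edge_sd per-edge baseline noise sd (0.10).
#' @param sex_prop probability of male sex (0.474).
#' @param age_prop probabilities of the young (< 55), middle (55-65) and
#'   old (> 65) age groups, summing to 1.
#' @param n_young,n_old group sizes for cross-sectional generation.
#' @param age_effect_base per-sex default cross-sectional age effect
#'   applied to every block (old-group mean minus young-group mean).
#' @param age_effect_overrides per-sex named vectors of block-specific
#'   age effects (defaults encode the published four-block calibration,
#'   including the negative visual within-network effect).
#' @param frames,tr timeseries-mode frame count and repetition time
#'   (490 frames at 0.735 s, about six minutes of scanning).
#' @param low_hz,high_hz passband used for timeseries-mode noise.
#' @param bounded clip generated older-scan FC into `[-1, 1]`. Off by
#'   default: with the calibrated change dispersion a small fraction of
#'   edge values exceeds 1, and hard clipping would bias the recovered
#'   means and dispersions away from their configured targets.
#' @param psd_repair project each generated FC matrix to the nearest
#'   positive-semidefinite correlation matrix (eigenvalue clipping plus
#'   diagonal renormalization). Off by default for the same reason.
#' @param seed integer seed; every generated cohort is bit-for-bit
#'   reproducible from (config, seed).
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_subjects = 2722,
                         atlas = power264_atlas(),
                         baseline_within = 0.30,
                         baseline_between = 0.10,
                         baseline_overrides = c("0-6" = 0.39),
                         shift = c("0-6" = 0.03),
                         change_sd = 0.26,
                         block_effect_sd = 0.11,
                         subject_sd = 0.11,
                         edge_sd = 0.10,
                         sex_prop = 0.474,
                         age_prop = c(young = 0.168, middle = 0.457,
                                      old = 0.375),
                         n_young = 5000, n_old = 5000,
                         age_effect_base = c(M = 0.035, F = 0.031),
                         age_effect_overrides = list(
                           M = c("0-6" = 0.031, "0-4" = 0.045,
                                 "4-6" = 0.042, "6-6" = -0.014),
                           F = c("0-6" = 0.029, "0-4" = 0.043,
                                 "4-6" = 0.035, "6-6" = -0.009)),
                         frames = 490, tr = 0.735,
                         low_hz = 0.01, high_hz = 0.15,
                         bounded = FALSE, psd_repair = FALSE,
                         seed = 1) {
  stopifnot(inherits(atlas, "fc_atlas"), n_subjects >= 1,
            change_sd >= 0, block_effect_sd >= 0, subject_sd >= 0,
            edge_sd >= 0, frames >= 2, tr > 0)
  if (block_effect_sd > change_sd)
    stop("block_effect_sd cannot exceed the marginal change_sd")
  if (abs(sum(age_prop) - 1) > 1e-8) stop("age_prop must sum to 1")
  cfg <- list(n_subjects = as.integer(n_subjects), atlas = atlas,
              baseline_within = baseline_within,
              baseline_between = baseline_between,
              baseline_overrides = baseline_overrides, shift = shift,
              change_sd = change_sd, block_effect_sd = block_effect_sd,
              subject_sd = subject_sd, edge_sd = edge_sd,
              sex_prop = sex_prop, age_prop = age_prop,
              n_young = as.integer(n_young), n_old = as.integer(n_old),
              age_effect_base = age_effect_base,
              age_effect_overrides = age_effect_overrides,
              frames = as.integer(frames), tr = tr,
              low_hz = low_hz, high_hz = high_hz,
              bounded = bounded, psd_repair = psd_repair,
              seed = as.integer(seed))
  class(cfg) <- "synth_config"
  # validate that configured means stay inside (-1, 1)
  p <- network_partition(atlas)
  base <- block_mean_vector(cfg, p)
  sh <- override_vector(numeric(length(base)) + 0, cfg$shift, names(base))
  if (any(abs(base) >= 1) || any(abs(base + sh) >= 1))
    stop("configured block means (baseline or baseline + shift) must lie ",
         "strictly inside (-1, 1)")
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic cohort config: n = %d, %d ROIs; change sd %.3g ",
    "(block effect %.3g), subject sd %.3g, seed %d\n"),
    x$n_subjects, nrow(x$atlas), x$change_sd, x$block_effect_sd,
    x$subject_sd, x$seed))
  invisible(x)
}

# named per-block mean vector for the partition's block keys
block_mean_vector <- function(cfg, partition) {
  pairs <- block_pairs(partition)
  v <- ifelse(pairs$a == pairs$b, cfg$baseline_within, cfg$baseline_between)
  names(v) <- pairs$key
  override_apply(v, cfg$baseline_overrides)
}

override_apply <- function(v, overrides) {
  if (length(overrides)) {
    keys <- vapply(names(overrides), canonical_key, "")
    hit <- keys %in% names(v)
    v[keys[hit]] <- overrides[hit]
  }
  v
}

override_vector <- function(zero, overrides, keys) {
  names(zero) <- keys
  override_apply(zero, overrides)
}

#' Generate a paired longitudinal FC cohort
#'
#' Younger scan: population block-mean template plus a per-subject scalar
#' baseline offset plus per-edge noise, clipped into `[-1, 1]`. Older
#' scan: younger scan plus a per-subject, per-block effect (mean = the
#' configured shift, sd = `block_effect_sd`) plus per-edge change noise
#' whose sd is derived so that the marginal per-edge change standard
#' deviation equals `change_sd`. The older scan is left unclipped unless
#' `bounded = TRUE` (see [synth_config()]).
#'
#' @param cfg a `synth_config`.
#' @return a longitudinal `fc_cohort` with sex and age-group covariates
#'   and full provenance.
#' @export
generate_fc_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  p <- network_partition(cfg$atlas)
  bs <- block_structure(p)
  n <- cfg$n_subjects
  e <- nrow(bs$ind)
  base <- block_mean_vector(cfg, p)
  shift <- override_vector(numeric(length(base)), cfg$shift, names(base))
  subjects <- draw_subjects(n, cfg)
  younger <- matrix(stats::rnorm(n * e, 0, cfg$edge_sd), n, e)
  younger <- younger + stats::rnorm(n, 0, cfg$subject_sd)
  younger <- sweep(younger, 2, base[bs$edge_block], "+")
  younger[younger > 1] <- 1
  younger[younger < -1] <- -1
  nb <- length(base)
  deff <- matrix(stats::rnorm(n * nb, 0, cfg$block_effect_sd), n, nb)
  deff <- sweep(deff, 2, shift, "+")
  resid_sd <- sqrt(cfg$change_sd^2 - cfg$block_effect_sd^2)
  older <- younger + deff[, bs$edge_block, drop = FALSE] +
    matrix(stats::rnorm(n * e, 0, resid_sd), n, e)
  if (cfg$bounded) {
    older[older > 1] <- 1
    older[older < -1] <- -1
  }
  if (cfg$psd_repair) {
    younger <- t(apply(younger, 1, function(v) vectorize_fc(psd_repair(devectorize_fc(v)))))
    older <- t(apply(older, 1, function(v) vectorize_fc(psd_repair(devectorize_fc(v)))))
  }
  fc_cohort(cfg$atlas, subjects, younger = younger, older = older,
            partition = p,
            provenance = list(generator = "generate_fc_cohort",
                              config = cfg[setdiff(names(cfg), "atlas")],
                              seed = cfg$seed))
}

draw_subjects <- function(n, cfg) {
  data.frame(
    subject_id = sprintf("S%05d", seq_len(n)),
    sex = sample(c("M", "F"), n, replace = TRUE,
                 prob = c(cfg$sex_prop, 1 - cfg$sex_prop)),
    age_group = sample(names(cfg$age_prop), n, replace = TRUE,
                       prob = cfg$age_prop),
    stringsAsFactors = FALSE)
}

#' Generate a cross-sectional FC cohort
#'
#' Single scan per subject. Young-group block means follow the baseline
#' configuration; old-group means add a per-sex age-effect matrix
#' (defaults calibrated to the published four-block cross-sectional
#' effects, including the negative visual within-network effect).
#'
#' @param cfg a `synth_config`; `n_young` / `n_old` set the group sizes.
#' @return a cross-sectional `fc_cohort` with `age_group` and `sex`.
#' @export
generate_cross_sectional <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  p <- network_partition(cfg$atlas)
  bs <- block_structure(p)
  base <- block_mean_vector(cfg, p)
  n <- cfg$n_young + cfg$n_old
  e <- nrow(bs$ind)
  subjects <- data.frame(
    subject_id = sprintf("C%05d", seq_len(n)),
    sex = sample(c("M", "F"), n, replace = TRUE,
                 prob = c(cfg$sex_prop, 1 - cfg$sex_prop)),
    age_group = rep(c("young", "old"), c(cfg$n_young, cfg$n_old)),
    stringsAsFactors = FALSE)
  eff <- lapply(c(M = "M", F = "F"), function(s)
    override_vector(numeric(length(base)) + cfg$age_effect_base[[s]],
                    cfg$age_effect_overrides[[s]], names(base)))
  fc <- matrix(stats::rnorm(n * e, 0, cfg$edge_sd), n, e)
  fc <- fc + stats::rnorm(n, 0, cfg$subject_sd)
  fc <- sweep(fc, 2, base[bs$edge_block], "+")
  old <- subjects$age_group == "old"
  for (s in c("M", "F")) {
    rows <- which(old & subjects$sex == s)
    if (length(rows))
      fc[rows, ] <- sweep(fc[rows, , drop = FALSE], 2,
                          eff[[s]][bs$edge_block], "+")
  }
  fc[fc > 1] <- 1
  fc[fc < -1] <- -1
  fc_cohort(cfg$atlas, subjects, fc = fc, partition = p,
            provenance = list(generator = "generate_cross_sectional",
                              config = cfg[setdiff(names(cfg), "atlas")],
                              seed = cfg$seed))
}

#' Attach synthetic phenotypes correlated with block change
#'
#' Each phenotype is built as `r * z + sqrt(1 - r^2) * noise`, where `z`
#' is the standardized per-subject change of a named block, so its
#' population correlation with that block change equals the target `r`.
#'
#' @param cohort a longitudinal `fc_cohort`.
#' @param specs list of specs, each a list with `name`, `block` (key) and
#'   `r` (target correlation in `[-1, 1]`); optional `missing` rate.
#' @param seed integer seed.
#' @return the cohort with the generated `phenotypes` table attached.
#' @export
generate_phenotypes <- function(cohort, specs, seed = 1) {
  stopifnot(inherits(cohort, "fc_cohort"), cohort$mode == "longitudinal")
  set.seed(seed)
  bs <- block_structure(cohort$partition)
  bm <- block_means_rows(cohort$older - cohort$younger, bs)
  n <- nrow(cohort$subjects)
  tab <- data.frame(subject_id = cohort$subjects$subject_id,
                    stringsAsFactors = FALSE)
  for (sp in specs) {
    if (abs(sp$r) > 1) stop("target correlation must lie in [-1, 1]")
    key <- canonical_key(sp$block)
    z <- bm[, key]
    z <- (z - mean(z, na.rm = TRUE)) / stats::sd(z, na.rm = TRUE)
    v <- sp$r * z + sqrt(1 - sp$r^2) * stats::rnorm(n)
    miss <- if (is.null(sp$missing)) 0 else sp$missing
    if (miss > 0) v[stats::runif(n) < miss] <- NA
    tab[[sp$name]] <- v
  }
  cohort$phenotypes <- tab
  cohort$provenance$phenotype_seed <- seed
  cohort
}

#' Generate paired BOLD timeseries cohorts
#'
#' Latent-factor construction: each network has a band-limited latent
#' signal; network factors are mixed to carry the configured inter-network
#' correlations, and each ROI is its network factor plus independent
#' band-limited noise, with weights solved so expected inter-ROI
#' correlations match the configured block means (`a_k = sqrt(B_kk)`,
#' factor correlation `C_kl = B_kl / (a_k a_l)`). Older-scan factors
#' target the shifted block means. Errors if the implied factor
#' correlation matrix is not realizable (not positive semidefinite or a
#' cross-block entry exceeding `sqrt(B_kk B_ll)`).
#'
#' @param cfg a `synth_config` (small `n_subjects` recommended; this mode
#'   exists to exercise extraction and filtering end-to-end).
#' @return list of subjects, each with `subject_id`, `younger` and
#'   `older` [bold_timeseries()].
#' @export
generate_timeseries_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$frames < 100)
    stop("timeseries mode needs at least 100 frames for usable correlations")
  set.seed(cfg$seed)
  p <- network_partition(cfg$atlas)
  base <- block_target_matrix(block_mean_vector(cfg, p), p)
  shift <- override_vector(numeric(nrow(block_pairs(p))), cfg$shift,
                           block_pairs(p)$key)
  older_t <- block_target_matrix(block_mean_vector(cfg, p) + shift, p)
  lapply(seq_len(cfg$n_subjects), function(i) {
    list(subject_id = sprintf("T%03d", i),
         younger = factor_model_ts(base, p, cfg),
         older = factor_model_ts(older_t, p, cfg))
  })
}

# named block-mean vector -> K x K symmetric target matrix
block_target_matrix <- function(v, partition) {
  labels <- attr(partition, "labels")
  k <- length(labels)
  m <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  for (nm in names(v)) {
    ab <- as.integer(strsplit(nm, "-", fixed = TRUE)[[1]])
    i <- match(ab[1], labels); j <- match(ab[2], labels)
    m[i, j] <- m[j, i] <- v[nm]
  }
  m
}

factor_model_ts <- function(btarget, partition, cfg) {
  labels <- attr(partition, "labels")
  k <- length(labels)
  a <- sqrt(diag(btarget))
  if (any(diag(btarget) < 0) || any(diag(btarget) > 1))
    stop("within-network targets must lie in [0, 1]")
  cmat <- btarget / tcrossprod(pmax(a, 1e-12))
  diag(cmat) <- 1
  bad <- which(abs(cmat) > 1 + 1e-8, arr.ind = TRUE)
  if (nrow(bad))
    stop("block ", labels[bad[1, 1]], "-", labels[bad[1, 2]],
         " target exceeds sqrt(B_aa * B_bb); not realizable")
  ei <- eigen(cmat, symmetric = TRUE)
  if (min(ei$values) < -1e-8)
    stop("factor correlation matrix is not positive semidefinite; ",
         "target block means are not jointly realizable")
  loading <- ei$vectors %*% diag(sqrt(pmax(ei$values, 0)), k)
  frames <- cfg$frames
  w <- band_noise(frames, k, cfg)
  f <- w %*% t(loading)
  n_roi <- attr(partition, "n_roi")
  x <- matrix(NA_real_, frames, n_roi)
  for (ki in seq_len(k)) {
    rois <- partition[[as.character(labels[ki])]] + 1L
    eps <- band_noise(frames, length(rois), cfg)
    x[, rois] <- a[ki] * f[, ki] + sqrt(max(1 - a[ki]^2, 0)) * eps
  }
  bold_timeseries(x, cfg$tr)
}

# band-limited standardized noise columns
band_noise <- function(frames, ncols, cfg) {
  bf <- signal::butter(2, c(cfg$low_hz, cfg$high_hz) / (1 / (2 * cfg$tr)),
                       type = "pass")
  z <- matrix(stats::rnorm(frames * ncols), frames, ncols)
  for (j in seq_len(ncols)) {
    y <- filtfilt_padded(bf, z[, j])
    z[, j] <- (y - mean(y)) / stats::sd(y)
  }
  z
}

#' Project a matrix to the nearest PSD correlation matrix
#'
#' Eigenvalue clipping at zero followed by diagonal renormalization to
#' unit diagonal.
#'
#' @param m symmetric matrix.
#' @return an `fc_matrix`.
#' @export
psd_repair <- function(m) {
  m <- unclass(as.matrix(m))
  ei <- eigen((m + t(m)) / 2, symmetric = TRUE)
  vals <- pmax(ei$values, 0)
  r <- ei$vectors %*% diag(vals, length(vals)) %*% t(ei$vectors)
  d <- sqrt(pmax(diag(r), 1e-12))
  r <- r / tcrossprod(d)
  diag(r) <- 1
  r[r > 1] <- 1
  r[r < -1] <- -1
  fc_matrix(r, check = FALSE)
}
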
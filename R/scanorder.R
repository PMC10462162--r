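#' Scan-order prediction from signed FC differences
#'
#' The experiment: for each subject, take the difference of the two scans'
#' FC with a randomized sign (whether the older scan is subtracted from the
#' younger or vice versa), label the sample by that sign, and train an
#' L2-regularized logistic classifier to recover which scan was older.
#' Features are either the full vectorized FC difference or a single
#' network-block average difference.
#'
#' @name scanorder
NULL

#' Build sign-randomized difference samples
#'
#' Each subject contributes one sample: a sign `s` drawn uniformly from
#' \{-1, +1\}, the feature vector `s * (older - younger)`, and label `s`
#' (+1 means the difference was computed older minus younger). Negating a
#' sample's features and label yields an equivalent sample.
#'
#' @param x a longitudinal `fc_cohort`, or a numeric vector of precomputed
#'   per-subject differences (single-feature mode).
#' @param feature `"full"` for the whole FC-difference vector, or a block
#'   key (`"a-b"` or `c(a, b)`) for that block's average difference.
#'   Ignored when `x` is a numeric vector.
#' @param seed integer seed for the sign draws.
#' @return an `fc_diff_samples` object: list with `x` (n x p feature
#'   matrix), `y` (labels in \{-1, +1\}), `subject_id`, `feature`, `seed`.
#' @export
make_diff_samples <- function(x, feature = "full", seed = NULL) {
  if (inherits(x, "fc_cohort")) {
    if (x$mode != "longitudinal") stop("a longitudinal cohort is required")
    if (nrow(x$subjects) == 0) stop("empty cohort")
    d <- x$older - x$younger
    if (!identical(feature, "full")) {
      key <- canonical_key(feature)
      bs <- block_structure(x$partition)
      bm <- block_means_rows(d, bs)
      if (!key %in% colnames(bm)) stop("unknown block key: ", key)
      d <- bm[, key, drop = FALSE]
      feature <- key
    }
    ids <- x$subjects$subject_id
  } else {
    d <- matrix(as.numeric(x), ncol = 1)
    if (nrow(d) == 0) stop("empty sample set")
    ids <- seq_len(nrow(d))
    feature <- "scalar"
  }
  keep <- !apply(is.na(d), 1, any)
  if (!all(keep)) {
    message(sum(!keep), " subject(s) with missing features dropped")
    d <- d[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  if (!is.null(seed)) set.seed(seed)
  s <- sample(c(-1, 1), nrow(d), replace = TRUE)
  structure(list(x = d * s, y = s, subject_id = ids,
                 feature = feature, seed = seed),
            class = "fc_diff_samples")
}

# L2-penalized logistic regression at inverse regularization strength C:
# minimizes sum(log-loss) + ||w||^2 / (2C), intercept unpenalized.
# glmnet's binomial ridge objective matches with lambda = 1/(n*C); glmnet
# refuses single-column x, so a zero column (ridge coefficient exactly 0)
# is padded on.
ridge_logistic <- function(x, y, C = 1) {
  x <- as.matrix(x)
  pad <- ncol(x) == 1
  if (pad) x <- cbind(x, 0)
  fit <- glmnet::glmnet(x, factor(y, levels = c(-1, 1)), family = "binomial",
                        alpha = 0, lambda = 1 / (nrow(x) * C),
                        standardize = FALSE, thresh = 1e-8, maxit = 1e4)
  beta <- as.numeric(fit$beta)
  if (pad) beta <- beta[1]
  list(intercept = as.numeric(fit$a0), beta = beta)
}

predict_sign <- function(model, x) {
  eta <- model$intercept + as.matrix(x) %*% model$beta
  ifelse(eta >= 0, 1, -1)
}

#' Bootstrap learning curve for scan-order prediction
#'
#' For each training-set size and repetition, draws a random training
#' subset (all remaining samples form the test set), fits the regularized
#' logistic model, and records held-out accuracy. "Bootstrap" follows the
#' repeated-random-split sense (subsampling without replacement) so that
#' test sets are disjoint from training; sampling with replacement is
#' available via `scheme = "resample"`.
#'
#' @param samples an `fc_diff_samples` object.
#' @param train_sizes integer vector of training-set sizes, each at most
#'   `n - 1`.
#' @param reps repetitions per size (default 20).
#' @param C inverse regularization strength (default 1).
#' @param seed integer seed for the splits.
#' @param scheme `"split"` (disjoint train/test, default) or `"resample"`
#'   (training drawn with replacement; test = samples never drawn).
#' @return an `fc_learning_curve`: data frame `runs` (size, rep, n_test,
#'   accuracy) plus `summary` (mean accuracy per size).
#' @export
learning_curve <- function(samples, train_sizes, reps = 20, C = 1,
                           seed = NULL, scheme = c("split", "resample")) {
  stopifnot(inherits(samples, "fc_diff_samples"), length(train_sizes) >= 1,
            reps >= 1, C > 0)
  scheme <- match.arg(scheme)
  n <- length(samples$y)
  if (max(train_sizes) + 1 > n)
    stop("largest training size leaves no test samples")
  if (!is.null(seed)) set.seed(seed)
  runs <- expand.grid(rep = seq_len(reps), size = train_sizes)[, 2:1]
  runs$n_test <- NA_integer_
  runs$accuracy <- NA_real_
  for (r in seq_len(nrow(runs))) {
    sz <- runs$size[r]
    for (attempt in 1:100) {
      tr <- if (scheme == "split") sample.int(n, sz)
            else sample.int(n, sz, replace = TRUE)
      if (length(unique(samples$y[tr])) == 2) break
      if (attempt == 100) stop("could not draw a two-class training set")
      message("single-class training draw redrawn (size ", sz, ")")
    }
    te <- setdiff(seq_len(n), tr)
    model <- ridge_logistic(samples$x[tr, , drop = FALSE], samples$y[tr], C)
    pred <- predict_sign(model, samples$x[te, , drop = FALSE])
    runs$n_test[r] <- length(te)
    runs$accuracy[r] <- mean(pred == samples$y[te])
  }
  smry <- stats::aggregate(accuracy ~ size, data = runs, FUN = mean)
  structure(list(runs = runs, summary = smry, reps = reps, C = C,
                 feature = samples$feature),
            class = "fc_learning_curve")
}

#' @export
print.fc_learning_curve <- function(x, ...) {
  cat(sprintf("Scan-order learning curve (feature: %s, C = %g, %d reps)\n",
              paste(x$feature, collapse = ","), x$C, x$reps))
  print(format(x$summary, digits = 3), row.names = FALSE)
  invisible(x)
}

#' Rank network blocks by single-feature scan-order accuracy
#'
#' For each network block, trains the regularized logistic classifier on
#' that block's sign-randomized average-FC difference alone and records
#' mean held-out accuracy, alongside the Bonferroni-corrected two-sided
#' one-sample t-test p-value of the block's change. Rows are sorted by
#' descending accuracy (ties broken by key order).
#'
#' @param cohort a longitudinal `fc_cohort` (at least 2 networks).
#' @param partition defaults to the cohort's partition.
#' @param train_size training-set size per repetition; defaults to 3/4 of
#'   the cohort (the asymptotic regime of the learning curve).
#' @param reps,C,seed as in [learning_curve()].
#' @return an `fc_block_ranking` data frame: key, networks, accuracy, t,
#'   p_bonf, rank.
#' @export
rank_blocks <- function(cohort, partition = NULL, train_size = NULL,
                        reps = 20, C = 1, seed = NULL) {
  stopifnot(inherits(cohort, "fc_cohort"))
  if (is.null(partition)) partition <- cohort$partition
  if (length(attr(partition, "labels")) < 2)
    stop("ranking needs at least 2 networks")
  n <- nrow(cohort$subjects)
  if (is.null(train_size)) train_size <- max(2L, floor(0.75 * n))
  if (!is.null(seed)) set.seed(seed)
  bs <- block_structure(partition)
  d <- cohort$older - cohort$younger
  bm <- block_means_rows(d, bs)
  # one sign draw per subject, shared across blocks: the randomization is
  # of which scan was subtracted, which flips every feature together
  s <- sample(c(-1, 1), n, replace = TRUE)
  stats <- cohort_change_summary(cohort, partition)$blocks
  acc <- rep(NA_real_, nrow(bs$pairs))
  for (b in seq_len(nrow(bs$pairs))) {
    xb <- bm[, b] * s
    keep <- !is.na(xb)
    if (sum(keep) < train_size + 1) {
      warning("block ", bs$pairs$key[b], " has too few complete subjects; ",
              "excluded from ranking")
      next
    }
    smp <- structure(list(x = matrix(xb[keep], ncol = 1), y = s[keep],
                          subject_id = cohort$subjects$subject_id[keep],
                          feature = bs$pairs$key[b], seed = NULL),
                     class = "fc_diff_samples")
    lc <- learning_curve(smp, train_sizes = train_size, reps = reps, C = C)
    acc[b] <- lc$summary$accuracy[1]
  }
  out <- data.frame(bs$pairs[, c("key", "networks")], accuracy = acc,
                    t = stats$t, p_bonf = stats$p_bonf,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$accuracy), ]
  ord <- order(-out$accuracy, match(out$key, bs$pairs$key))
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("fc_block_ranking", "data.frame"),
            train_size = train_size, reps = reps, C = C)
}

#' @export
print.fc_block_ranking <- function(x, ..., top = 10) {
  cat(sprintf(
    "Block ranking by scan-order accuracy (train %d, %d reps, C = %g)\n",
    attr(x, "train_size"), attr(x, "reps"), attr(x, "C")))
  print(format(utils::head(as.data.frame(x), top), digits = 3),
        row.names = FALSE)
  invisible(x)
}
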
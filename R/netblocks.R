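#' Network-block reduction of FC
#'
#' A "block" is the set of FC edges whose endpoints lie in a given pair of
#' functional networks (within-network blocks use all internal edges); its
#' unweighted mean over the strict upper triangle is one inter-network
#' connectivity. Fourteen networks give 105 blocks.
#'
#' @name netblocks
NULL

# edge -> block bookkeeping for a partition: block table, per-edge block id,
# sparse edge-by-block indicator, per-block edge counts
block_structure <- function(partition) {
  n <- attr(partition, "n_roi")
  pairs <- block_pairs(partition)
  lab <- integer(n)
  for (l in attr(partition, "labels")) lab[partition[[as.character(l)]] + 1L] <- l
  ij <- edge_index(n)
  la <- pmin(lab[ij[, 1]], lab[ij[, 2]])
  lb <- pmax(lab[ij[, 1]], lab[ij[, 2]])
  eb <- match(paste0(la, "-", lb), pairs$key)
  ind <- Matrix::sparseMatrix(i = seq_along(eb), j = eb, x = 1,
                              dims = c(length(eb), nrow(pairs)))
  counts <- as.integer(Matrix::colSums(ind))
  list(pairs = pairs, edge_block = eb, ind = ind, counts = counts)
}

#' Block averages of a single FC matrix
#'
#' @param m an `fc_matrix`, a symmetric matrix, or an FC vector (row-major
#'   strict upper triangle).
#' @param partition an `fc_partition` covering the matrix dimension.
#' @return named numeric vector of block means, keyed `"a-b"`; blocks with
#'   no valid (non-`NA`) edge are `NA`. Attribute `pairs` holds the block
#'   table.
#' @export
block_average <- function(m, partition) {
  v <- if (is.matrix(m)) vectorize_fc(m) else as.numeric(m)
  bs <- block_structure(partition)
  if (length(v) != nrow(bs$ind))
    stop("FC size does not match the partition's ROI count")
  out <- block_means_rows(matrix(v, 1), bs)[1, ]
  names(out) <- bs$pairs$key
  structure(out, pairs = bs$pairs)
}

# row-wise block means of an n x E matrix; a row's block is NA if any edge
# in the block is NA for that row (subjects with missing edges are excluded
# from that block), except rows where the block has zero edges overall
block_means_rows <- function(x, bs, require_complete = TRUE) {
  miss <- is.na(x)
  has_na <- any(miss)
  x0 <- if (has_na) {x[miss] <- 0; x} else x
  s <- as.matrix(x0 %*% bs$ind)
  cnt <- matrix(bs$counts, nrow(x), length(bs$counts), byrow = TRUE)
  if (has_na) {
    nvalid <- as.matrix((!miss) %*% bs$ind)
    if (require_complete) {
      s[nvalid < cnt] <- NA
      out <- s / cnt
    } else {
      out <- s / nvalid
      out[nvalid == 0] <- NA
    }
  } else out <- s / cnt
  colnames(out) <- bs$pairs$key
  out
}

#' Per-subject change in one block's average FC
#'
#' Older-scan block average minus younger-scan block average; swapping the
#' scans negates the result.
#'
#' @param pair a scan pair from [scan_pair()], or any list with `younger`
#'   and `older` FC vectors.
#' @param key block key: `"a-b"` string or integer pair `c(a, b)`.
#' @param partition an `fc_partition`.
#' @return scalar change in block-average correlation (`NA` if the block is
#'   missing on either scan).
#' @export
subject_block_change <- function(pair, key, partition) {
  key <- canonical_key(key)
  yo <- block_average(pair$younger, partition)
  ol <- block_average(pair$older, partition)
  if (!key %in% names(yo)) stop("unknown block key: ", key)
  unname(ol[key] - yo[key])
}

canonical_key <- function(key) {
  if (is.character(key) && length(key) == 1) {
    ab <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
  } else ab <- as.integer(key)
  if (length(ab) != 2 || anyNA(ab)) stop("block key must be two labels")
  paste0(min(ab), "-", max(ab))
}

#' Cohort-level longitudinal change summary
#'
#' For every network block: the cohort mean of per-subject block-average
#' change (older minus younger scan), two dispersion measures, and a
#' Bonferroni-corrected two-sided one-sample t-test of the change against
#' zero. The two dispersions are deliberately distinct: `sd_subject` is the
#' standard deviation across subjects of the per-subject *block-average*
#' change (what the t-test uses), while `sd_edge_mean` is the mean over the
#' block's edges of the per-edge change standard deviation (what an
#' edge-level dispersion map averages to; for the headline somatomotor-
#' visual block this is the ~0.26-scale quantity). Edge-level mean and
#' standard-deviation change maps are returned alongside.
#'
#' @param cohort a longitudinal `fc_cohort` with at least 2 subjects.
#' @param partition defaults to the cohort's partition.
#' @param m_comparisons Bonferroni factor; defaults to the number of blocks
#'   actually tested.
#' @return an `fc_change_summary`: list with `blocks` (data frame: key,
#'   networks, n_edges, n, mu, sd_subject, sd_edge_mean, mu_younger, three
#'   percent-change definitions — `pct_of_younger`, `pct_of_older`,
#'   `pct_subject_mean` (relative change is ambiguous, so all three are
#'   reported) — t, p_raw, p_bonf), `edge_mean` and `edge_sd` (ROI x ROI
#'   matrices, zero diagonal), `n_subjects`, `m_comparisons`.
#' @export
cohort_change_summary <- function(cohort, partition = NULL,
                                  m_comparisons = NULL) {
  stopifnot(inherits(cohort, "fc_cohort"))
  if (cohort$mode != "longitudinal")
    stop("cohort_change_summary needs a longitudinal cohort")
  if (nrow(cohort$subjects) < 2)
    stop("dispersion is undefined for fewer than 2 subjects")
  if (is.null(partition)) partition <- cohort$partition
  bs <- block_structure(partition)
  d <- cohort$older - cohort$younger
  bm <- block_means_rows(d, bs)
  n <- colSums(!is.na(bm))
  mu <- colMeans(bm, na.rm = TRUE)
  sd_subject <- apply(bm, 2, stats::sd, na.rm = TRUE)
  # per-edge change std across subjects, then averaged within block
  edge_mu <- colMeans(d, na.rm = TRUE)
  edge_n <- colSums(!is.na(d))
  edge_var <- (colSums(d * d, na.rm = TRUE) - edge_n * edge_mu^2) /
    pmax(edge_n - 1, 1)
  edge_sd <- sqrt(pmax(edge_var, 0))
  sd_edge_mean <- as.numeric(matrix(edge_sd, 1) %*% bs$ind) / bs$counts
  # relative (percent) change is ambiguous; report all three definitions:
  # cohort change over the younger mean, over the older mean, and the mean
  # of per-subject percent changes (non-finite ratios from near-zero
  # younger baselines are dropped from the third)
  ym <- block_means_rows(cohort$younger, bs)
  mu_younger <- colMeans(ym, na.rm = TRUE)
  ratio <- bm / ym
  ratio[!is.finite(ratio)] <- NA
  pct_subject <- 100 * colMeans(ratio, na.rm = TRUE)
  if (is.null(m_comparisons)) m_comparisons <- nrow(bs$pairs)
  tt <- mu / (sd_subject / sqrt(n))
  p_raw <- 2 * stats::pt(-abs(tt), pmax(n - 1, 1))
  degenerate <- sd_subject == 0 & is.finite(mu)
  p_raw[degenerate & mu != 0] <- 0
  tt[degenerate & mu == 0] <- 0
  p_raw[degenerate & mu == 0] <- 1
  blocks <- data.frame(bs$pairs, n_edges = bs$counts, n = n, mu = mu,
                       sd_subject = sd_subject, sd_edge_mean = sd_edge_mean,
                       mu_younger = mu_younger,
                       pct_of_younger = 100 * mu / mu_younger,
                       pct_of_older = 100 * mu / (mu_younger + mu),
                       pct_subject_mean = pct_subject,
                       t = tt, p_raw = p_raw,
                       p_bonf = pmin(1, m_comparisons * p_raw),
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(blocks = blocks,
                 edge_mean = edge_map(edge_mu, attr(partition, "n_roi")),
                 edge_sd = edge_map(edge_sd, attr(partition, "n_roi")),
                 n_subjects = nrow(cohort$subjects),
                 m_comparisons = m_comparisons),
            class = "fc_change_summary")
}

edge_map <- function(v, n) {
  a <- matrix(0, n, n)
  a[lower.tri(a)] <- v
  a + t(a)
}

#' @export
print.fc_change_summary <- function(x, ..., top = 5) {
  cat(sprintf("Longitudinal FC change over %d blocks (%d subjects)\n",
              nrow(x$blocks), x$n_subjects))
  b <- x$blocks[order(-abs(x$blocks$t)), ]
  cat(sprintf("Top %d blocks by |t| (Bonferroni m = %d):\n",
              min(top, nrow(b)), x$m_comparisons))
  print(format(utils::head(
    b[, c("key", "networks", "mu", "sd_subject", "sd_edge_mean", "t", "p_bonf")],
    top), digits = 3), row.names = FALSE)
  invisible(x)
}

#' Change summaries for cohort subgroups
#'
#' Repeats [cohort_change_summary()] within each level of a grouping
#' variable (genetic sex or age group). Subgroups with fewer than 2
#' subjects are skipped with a warning. For `age_group`, "middle" subjects
#' belong to no subgroup and are not summarized.
#'
#' @param cohort a longitudinal `fc_cohort`.
#' @param by `"sex"` or `"age_group"`.
#' @param ... passed to [cohort_change_summary()].
#' @return named list of `fc_change_summary`, one per subgroup, with the
#'   subgroup sizes in `attr(, "sizes")`.
#' @export
subgroup_summaries <- function(cohort, by = c("sex", "age_group"), ...) {
  by <- match.arg(by)
  g <- cohort$subjects[[by]]
  if (is.null(g)) stop("cohort has no '", by, "' covariate")
  levels <- if (by == "age_group") intersect(c("young", "old"), unique(g))
            else sort(unique(g))
  out <- list()
  sizes <- integer()
  for (lv in levels) {
    idx <- which(g == lv)
    if (length(idx) < 2) {
      warning("subgroup '", lv, "' has fewer than 2 subjects; skipped")
      next
    }
    out[[lv]] <- cohort_change_summary(cohort_subset(cohort, idx), ...)
    sizes[lv] <- length(idx)
  }
  attr(out, "sizes") <- sizes
  out
}
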
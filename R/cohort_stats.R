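#' Bonferroni-corrected one-sample t-test of block change
#'
#' Two-sided one-sample t-test of per-subject block changes against zero,
#' with the p-value multiplied by the number of simultaneous block
#' comparisons (105 for the full 14-network atlas) and capped at 1.
#'
#' @param changes numeric vector of per-subject block-average changes
#'   (length at least 2).
#' @param m_comparisons Bonferroni factor (default 105).
#' @return list with `estimate` (mean change), `t`, `df`, `p_raw`,
#'   `p_bonf`, `n`, and `degenerate` (`TRUE` when the sample variance is
#'   zero, in which case `p_raw` is 0 for a nonzero mean and 1 otherwise).
#' @export
#' @examples
#' block_ttest(c(1, 2, 3, 4, 5))$t  # 4.2426
block_ttest <- function(changes, m_comparisons = 105) {
  changes <- changes[!is.na(changes)]
  n <- length(changes)
  if (n < 2) stop("at least 2 observations are required")
  if (stats::sd(changes) == 0) {
    m <- mean(changes)
    return(list(estimate = m, t = if (m == 0) 0 else sign(m) * Inf,
                df = n - 1, p_raw = if (m == 0) 1 else 0,
                p_bonf = if (m == 0) 1 else 0, n = n, degenerate = TRUE))
  }
  ht <- stats::t.test(changes, mu = 0, alternative = "two.sided")
  p <- ht$p.value
  list(estimate = unname(ht$estimate), t = unname(ht$statistic),
       df = unname(ht$parameter), p_raw = p,
       p_bonf = min(1, m_comparisons * p), n = n, degenerate = FALSE)
}

#' Subjects increasing and decreasing in FC, by subgroup
#'
#' Counts subjects whose block-average FC (and total FC) strictly
#' increased or strictly decreased from younger to older scan within the
#' male, female, young (< 55) and old (> 65) subgroups. Exact zero changes
#' are counted in their own column, never folded into either sign.
#'
#' @param cohort a longitudinal `fc_cohort` with `sex` and/or `age_group`.
#' @param block block key for the named block (default the somatomotor
#'   hand-visual pair `"0-6"`).
#' @return a `data.frame` with one row per subgroup: counts and
#'   percentages of positive/negative block change and total-FC change.
#' @export
sign_counts <- function(cohort, block = "0-6") {
  stopifnot(inherits(cohort, "fc_cohort"), cohort$mode == "longitudinal")
  key <- canonical_key(block)
  bs <- block_structure(cohort$partition)
  d <- cohort$older - cohort$younger
  bch <- block_means_rows(d, bs)[, key]
  tch <- total_fc(cohort, "change")
  groups <- list()
  if (!is.null(cohort$subjects$sex)) {
    groups[["Male"]] <- cohort$subjects$sex == "M"
    groups[["Female"]] <- cohort$subjects$sex == "F"
  }
  if (!is.null(cohort$subjects$age_group)) {
    groups[["< 55 years old"]] <- cohort$subjects$age_group == "young"
    groups[["> 65 years old"]] <- cohort$subjects$age_group == "old"
  }
  if (!length(groups)) groups[["All"]] <- rep(TRUE, nrow(cohort$subjects))
  rows <- lapply(names(groups), function(g) {
    i <- groups[[g]]
    b <- bch[i]; tt <- tch[i]
    total <- sum(i)
    data.frame(group = g,
               block_pos = sum(b > 0, na.rm = TRUE),
               block_neg = sum(b < 0, na.rm = TRUE),
               block_zero = sum(b == 0, na.rm = TRUE),
               block_pos_pct = 100 * sum(b > 0, na.rm = TRUE) / total,
               total_pos = sum(tt > 0, na.rm = TRUE),
               total_neg = sum(tt < 0, na.rm = TRUE),
               total_zero = sum(tt == 0, na.rm = TRUE),
               total_pos_pct = 100 * sum(tt > 0, na.rm = TRUE) / total,
               n = total, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "block") <- key
  out
}

#' Cross-sectional comparison of young and old groups
#'
#' Per network block: difference of group means of per-subject block
#' averages (old minus young), each group's dispersion of those block
#' averages plus the pooled value, and a Welch (unequal-variance)
#' two-sample two-sided p-value. A `Total FC` row (mean over all edges)
#' and an edge-level mean-difference map are included.
#'
#' @param young,old cross-sectional `fc_cohort`s on the same atlas, or a
#'   single cohort in `young` with an `age_group` covariate (split into
#'   "young" and "old" levels, `old` omitted).
#' @param partition defaults to the cohort's partition.
#' @return an `fc_cross_sectional`: list with `blocks` (key, networks,
#'   diff, sd_young, sd_old, sd_pooled, t, p, and a trailing Total FC
#'   row), `edge_diff` matrix, group sizes.
#' @export
cross_sectional_compare <- function(young, old = NULL, partition = NULL) {
  stopifnot(inherits(young, "fc_cohort"))
  if (is.null(old)) {
    ag <- young$subjects$age_group
    if (is.null(ag)) stop("single-cohort form needs an age_group covariate")
    old <- cohort_subset(young, which(ag == "old"))
    young <- cohort_subset(young, which(ag == "young"))
  }
  if (nrow(young$subjects) < 2 || nrow(old$subjects) < 2)
    stop("each group needs at least 2 subjects")
  if (is.null(partition)) partition <- young$partition
  bs <- block_structure(partition)
  fy <- if (young$mode == "longitudinal") young$younger else young$fc
  fo <- if (old$mode == "longitudinal") old$younger else old$fc
  by <- cbind(block_means_rows(fy, bs), `Total FC` = rowMeans(fy, na.rm = TRUE))
  bo <- cbind(block_means_rows(fo, bs), `Total FC` = rowMeans(fo, na.rm = TRUE))
  k <- ncol(by)
  res <- lapply(seq_len(k), function(b) {
    a <- by[, b]; z <- bo[, b]
    ht <- stats::t.test(z, a, alternative = "two.sided", var.equal = FALSE)
    ny <- sum(!is.na(a)); no <- sum(!is.na(z))
    vy <- stats::var(a, na.rm = TRUE); vo <- stats::var(z, na.rm = TRUE)
    data.frame(diff = mean(z, na.rm = TRUE) - mean(a, na.rm = TRUE),
               sd_young = sqrt(vy), sd_old = sqrt(vo),
               sd_pooled = sqrt(((ny - 1) * vy + (no - 1) * vo) / (ny + no - 2)),
               t = unname(ht$statistic), p = ht$p.value)
  })
  blocks <- cbind(
    data.frame(key = c(bs$pairs$key, "total"),
               networks = c(bs$pairs$networks, "Total FC"),
               stringsAsFactors = FALSE),
    do.call(rbind, res))
  edge_diff <- edge_map(colMeans(fo, na.rm = TRUE) - colMeans(fy, na.rm = TRUE),
                        attr(partition, "n_roi"))
  structure(list(blocks = blocks, edge_diff = edge_diff,
                 n_young = nrow(young$subjects), n_old = nrow(old$subjects)),
            class = "fc_cross_sectional")
}

#' @export
print.fc_cross_sectional <- function(x, ..., top = 6) {
  cat(sprintf("Cross-sectional FC comparison: %d young vs %d old subjects\n",
              x$n_young, x$n_old))
  b <- x$blocks[order(x$blocks$p), ]
  print(format(utils::head(b, top), digits = 3), row.names = FALSE)
  invisible(x)
}

#' Correlate a phenotype with per-subject block change
#'
#' Pearson correlation (with two-sided p-value) between a phenotype and
#' the per-subject change in one block's average FC. Missing phenotype
#' values are pairwise-deleted and the effective n reported.
#'
#' @param cohort a longitudinal `fc_cohort` with a `phenotypes` table.
#' @param block block key.
#' @param phenotype phenotype column name.
#' @return list with `phenotype`, `block`, `r`, `p`, `n`.
#' @export
phenotype_correlation <- function(cohort, block, phenotype) {
  stopifnot(inherits(cohort, "fc_cohort"), cohort$mode == "longitudinal")
  if (is.null(cohort$phenotypes) || !phenotype %in% names(cohort$phenotypes))
    stop("unknown phenotype: ", phenotype)
  key <- canonical_key(block)
  bs <- block_structure(cohort$partition)
  ch <- block_means_rows(cohort$older - cohort$younger, bs)[, key]
  ph <- cohort$phenotypes[[phenotype]]
  ok <- !is.na(ch) & !is.na(ph)
  if (sum(ok) < 3) stop("fewer than 3 subjects with phenotype and block data")
  if (stats::sd(ph[ok]) == 0) {
    warning("constant phenotype; correlation undefined")
    return(list(phenotype = phenotype, block = key, r = NA_real_,
                p = NA_real_, n = sum(ok)))
  }
  ht <- stats::cor.test(ch[ok], ph[ok], method = "pearson")
  list(phenotype = phenotype, block = key, r = unname(ht$estimate),
       p = ht$p.value, n = sum(ok))
}
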
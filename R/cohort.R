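#' FC cohort container
#'
#' Holds per-subject vectorized FC (row-major strict upper triangle, one row
#' per subject) together with the atlas, network partition, covariates and
#' optional phenotypes. Longitudinal cohorts carry paired `younger` and
#' `older` scan matrices; cross-sectional cohorts carry a single `fc`
#' matrix plus an `age_group` covariate.
#'
#' @param atlas an `fc_atlas`.
#' @param subjects data frame with at least `subject_id` (unique); usually
#'   also `sex` ("M"/"F") and `age_group` ("young", "middle", "old" —
#'   young means < 55 years, old means > 65 years; subjects in between
#'   belong to neither subgroup but stay in whole-cohort statistics).
#' @param younger,older subjects x edges matrices of vectorized FC for the
#'   chronologically first and second scan (longitudinal mode).
#' @param fc subjects x edges matrix for single-scan (cross-sectional) mode.
#' @param phenotypes optional data frame of per-subject phenotypes.
#' @param partition an `fc_partition`; derived from `atlas` if omitted.
#' @param provenance list recording how the cohort was made (config, seed).
#' @return an `fc_cohort`.
#' @export
fc_cohort <- function(atlas, subjects, younger = NULL, older = NULL,
                      fc = NULL, phenotypes = NULL, partition = NULL,
                      provenance = list()) {
  stopifnot(inherits(atlas, "fc_atlas"))
  if (anyDuplicated(subjects$subject_id)) stop("duplicate subject_id")
  n <- nrow(subjects)
  n_roi <- nrow(atlas)
  n_edge <- n_roi * (n_roi - 1L) / 2L
  longitudinal <- !is.null(younger)
  if (longitudinal) {
    if (is.null(older)) stop("longitudinal cohort needs both scans")
    if (!all(dim(younger) == c(n, n_edge), dim(older) == c(n, n_edge)))
      stop("scan matrices must be subjects x edges (", n, " x ", n_edge, ")")
  } else {
    if (is.null(fc)) stop("provide either younger/older or fc")
    if (!all(dim(fc) == c(n, n_edge)))
      stop("fc must be subjects x edges (", n, " x ", n_edge, ")")
  }
  if (is.null(partition)) partition <- network_partition(atlas)
  structure(list(atlas = atlas, partition = partition, subjects = subjects,
                 younger = younger, older = older, fc = fc,
                 phenotypes = phenotypes, provenance = provenance,
                 mode = if (longitudinal) "longitudinal" else "cross-sectional"),
            class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat(sprintf("FC cohort (%s): %d subjects, %d ROIs / %d networks, %d edges\n",
              x$mode, nrow(x$subjects), nrow(x$atlas),
              length(attr(x$partition, "labels")),
              nrow(x$atlas) * (nrow(x$atlas) - 1) / 2))
  if (!is.null(x$subjects$sex))
    cat("  sex:", paste(names(table(x$subjects$sex)),
                        table(x$subjects$sex), collapse = ", "), "\n")
  if (!is.null(x$subjects$age_group))
    cat("  age groups:", paste(names(table(x$subjects$age_group)),
                               table(x$subjects$age_group), collapse = ", "), "\n")
  if (!is.null(x$phenotypes))
    cat("  phenotypes:", paste(setdiff(names(x$phenotypes), "subject_id"),
                               collapse = ", "), "\n")
  invisible(x)
}

#' Extract one subject's scan pair
#'
#' @param cohort a longitudinal `fc_cohort`.
#' @param i subject row index or subject id.
#' @return a list with `subject_id`, `younger` and `older` FC vectors,
#'   `sex`, and `age_group`.
#' @export
scan_pair <- function(cohort, i) {
  stopifnot(inherits(cohort, "fc_cohort"), cohort$mode == "longitudinal")
  if (is.character(i)) i <- match(i, cohort$subjects$subject_id)
  if (is.na(i) || i < 1 || i > nrow(cohort$subjects)) stop("unknown subject")
  list(subject_id = cohort$subjects$subject_id[i],
       younger = cohort$younger[i, ],
       older = cohort$older[i, ],
       sex = cohort$subjects$sex[i],
       age_group = cohort$subjects$age_group[i])
}

# subset a cohort's subjects (internal)
cohort_subset <- function(cohort, idx) {
  out <- cohort
  out$subjects <- cohort$subjects[idx, , drop = FALSE]
  for (f in c("younger", "older", "fc"))
    if (!is.null(cohort[[f]])) out[[f]] <- cohort[[f]][idx, , drop = FALSE]
  if (!is.null(cohort$phenotypes))
    out$phenotypes <- cohort$phenotypes[idx, , drop = FALSE]
  out
}

#' Mean FC over all edges ("total FC") per subject
#'
#' @param x an `fc_cohort` or a subjects x edges matrix.
#' @param scan for longitudinal cohorts: `"change"` (older minus younger,
#'   the default), `"younger"` or `"older"`.
#' @return numeric vector, one value per subject.
#' @export
total_fc <- function(x, scan = c("change", "younger", "older")) {
  scan <- match.arg(scan)
  m <- if (inherits(x, "fc_cohort")) {
    if (x$mode == "longitudinal") {
      switch(scan, change = x$older - x$younger,
             younger = x$younger, older = x$older)
    } else x$fc
  } else x
  rowMeans(m, na.rm = TRUE)
}
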
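#' Read a cohort manifest
#'
#' A manifest is a CSV with one row per subject: `subject_id` (unique),
#' `scan1` and `scan2` (paths or ids of the chronologically first and
#' second scan; `scan1` may be empty for subjects who only have the second
#' scan, which cross-sectional analyses accept but longitudinal analyses
#' reject), and optional `sex`, `age_group` and phenotype columns.
#'
#' @param path CSV path.
#' @param mode `"any"` (keep all rows), `"longitudinal"` (reject rows
#'   without both scans) or `"cross-sectional"` (require at least one
#'   scan).
#' @return validated manifest data frame; rejected rows are dropped with a
#'   message naming their row numbers.
#' @export
read_manifest <- function(path, mode = c("any", "longitudinal",
                                         "cross-sectional")) {
  mode <- match.arg(mode)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"subject_id" %in% names(df))
    stop("manifest must have a subject_id column")
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in manifest: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "))
  blank <- function(x) if (is.null(x)) rep(TRUE, nrow(df)) else
    is.na(x) | !nzchar(trimws(x))
  no1 <- blank(df$scan1)
  no2 <- blank(df$scan2)
  bad <- if (mode == "longitudinal") no1 | no2 else no1 & no2
  if (mode == "any") bad <- no1 & no2
  if (any(bad)) {
    message("rejecting row(s) ", paste(which(bad), collapse = ", "),
            " (missing required scan fields for mode '", mode, "')")
    df <- df[!bad, , drop = FALSE]
  }
  if (!nrow(df)) stop("manifest has no usable rows for mode '", mode, "'")
  rownames(df) <- NULL
  df
}

fc_meta_lines <- function(n_roi, extra = character()) {
  c("# fclong FC matrix",
    "# edge_order: row-major strict upper triangle (i < j)",
    paste0("# n_roi: ", n_roi),
    extra)
}

#' Write / read an FC matrix as TSV
#'
#' Full-precision TSV with `#`-prefixed metadata lines (edge ordering,
#' matrix size); a written matrix reads back bit-identical.
#'
#' @param m matrix (`fc_matrix` or plain numeric).
#' @param path output path.
#' @param extra_meta optional additional `# ...` metadata lines.
#' @export
write_fc_matrix <- function(m, path, extra_meta = character()) {
  m <- unclass(as.matrix(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(fc_meta_lines(nrow(m), extra_meta), con)
  utils::write.table(format(m, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' @rdname write_fc_matrix
#' @export
read_fc_matrix <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", comment.char = "#",
                              colClasses = "numeric"))
}

# run provenance embedded in every output directory; content-only (no
# timestamps) so repeated runs are byte-identical
run_record <- function(seed = NULL, config = NULL, exclusions = list()) {
  list(package = "fclong",
       version = as.character(utils::packageVersion("fclong")),
       seed = seed,
       config = config,
       edge_order = "row-major strict upper triangle (i < j)",
       exclusions = exclusions)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

#' Run the longitudinal change analysis and write a report bundle
#'
#' Computes the whole-cohort block change summary, subgroup summaries,
#' and sign-count table, optionally writing a deterministic report
#' directory: `block_change.tsv`, `edge_mean.tsv` / `edge_sd.tsv`
#' (ROI x ROI change maps), `sign_counts.tsv`, `summary.json` (block
#' statistics keyed `"a-b"`), and `run_record.json`. Given the same
#' cohort the outputs are byte-identical across runs.
#'
#' @param cohort a longitudinal `fc_cohort`.
#' @param out_dir optional output directory (created if needed).
#' @param block headline block for the sign-count table.
#' @return invisibly, a list with `summary`, `by_sex`, `by_age`,
#'   `sign_counts`.
#' @export
analyze_longitudinal <- function(cohort, out_dir = NULL, block = "0-6") {
  smry <- cohort_change_summary(cohort)
  by_sex <- if (!is.null(cohort$subjects$sex))
    subgroup_summaries(cohort, "sex") else NULL
  by_age <- if (!is.null(cohort$subjects$age_group))
    subgroup_summaries(cohort, "age_group") else NULL
  sc <- tryCatch(sign_counts(cohort, block), error = function(e) NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    b <- smry$blocks
    utils::write.table(format(b, digits = 17, trim = TRUE), file.path(
      out_dir, "block_change.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_fc_matrix(smry$edge_mean, file.path(out_dir, "edge_mean.tsv"))
    write_fc_matrix(smry$edge_sd, file.path(out_dir, "edge_sd.tsv"))
    if (!is.null(sc))
      utils::write.table(sc, file.path(out_dir, "sign_counts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    js <- stats::setNames(lapply(seq_len(nrow(b)), function(i)
      as.list(b[i, setdiff(names(b), c("key", "networks"))])), b$key)
    write_json_file(js, file.path(out_dir, "summary.json"))
    write_json_file(run_record(seed = cohort$provenance$seed,
                               config = cohort$provenance$config[
                                 c("n_subjects", "change_sd",
                                   "block_effect_sd", "subject_sd",
                                   "edge_sd")],
                               exclusions = list()),
                    file.path(out_dir, "run_record.json"))
  }
  invisible(list(summary = smry, by_sex = by_sex, by_age = by_age,
                 sign_counts = sc))
}

#' Build FC files from imaging inputs listed in a manifest
#'
#' For each manifest row and scan column, reads the NIfTI volume (or a
#' frames x ROIs timeseries TSV), extracts ROI means where needed,
#' bandpass filters, computes the Pearson FC matrix and writes it as TSV
#' next to an edge-ordering manifest. Per-subject failures are isolated,
#' tallied and reported; the run continues.
#'
#' @param manifest data frame from [read_manifest()].
#' @param atlas an `fc_atlas`.
#' @param out_dir output directory.
#' @param tr repetition time override (seconds).
#' @param low_hz,high_hz passband.
#' @return invisibly, a data frame of written files and per-subject
#'   status.
#' @export
build_fc <- function(manifest, atlas, out_dir, tr = NULL,
                     low_hz = 0.01, high_hz = 0.15) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    for (scan in intersect(c("scan1", "scan2"), names(manifest))) {
      src <- manifest[[scan]][i]
      if (is.na(src) || !nzchar(trimws(src))) next
      id <- manifest$subject_id[i]
      out <- file.path(out_dir, paste0(id, "_", scan, "_fc.tsv"))
      status <- tryCatch({
        ts <- if (grepl("\\.tsv$", src)) {
          bold_timeseries(as.matrix(utils::read.delim(src, comment.char = "#")),
                          tr = if (is.null(tr)) 0.735 else tr)
        } else extract_roi_timeseries(src, atlas, tr = tr)
        m <- fc_from_timeseries(bandpass(ts, low_hz, high_hz))
        write_fc_matrix(m, out)
        "ok"
      }, error = function(e) conditionMessage(e))
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, scan = scan, file = out, status = status,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  failed <- res$status != "ok"
  if (any(failed))
    message(sum(failed), " scan(s) failed and were excluded: ",
            paste(unique(res$subject_id[failed]), collapse = ", "))
  write_json_file(run_record(exclusions = as.list(
    stats::setNames(res$status[failed],
                    paste(res$subject_id[failed], res$scan[failed])))),
    file.path(out_dir, "run_record.json"))
  invisible(res)
}
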
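# In-code fixtures shared across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write an atlas TSV and load it; centers is an n x 3 matrix (MNI mm).
local_atlas <- function(centers, labels, radius = 5,
                        env = parent.frame()) {
  centers <- matrix(centers, ncol = 3)
  n <- nrow(centers)
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  df <- data.frame(roi_id = seq_len(n) - 1L,
                   x_mm = centers[, 1], y_mm = centers[, 2],
                   z_mm = centers[, 3], radius_mm = radius,
                   network_label = as.integer(labels),
                   network_name = paste0("net", labels))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_atlas(path)
}

# Atlas with `counts[k]` ROIs in network labels[k]; placeholder centers.
counts_atlas <- function(counts, labels = seq_along(counts) - 1L,
                         env = parent.frame()) {
  n <- sum(counts)
  local_atlas(cbind(12 * seq_len(n), 0, 0), rep(labels, counts), env = env)
}

# 1/4-scale 14-network atlas (all 105 blocks present, 56 ROIs).
scaled_atlas14 <- function(per_network = 4) {
  atlas_subset(power264_atlas(), 0:13, per_network = per_network)
}

# Build a longitudinal cohort directly from scan matrices.
manual_cohort <- function(atlas, younger, older, sex = NULL,
                          age_group = NULL) {
  n <- nrow(younger)
  subjects <- data.frame(subject_id = sprintf("M%03d", seq_len(n)),
                         stringsAsFactors = FALSE)
  if (!is.null(sex)) subjects$sex <- sex
  if (!is.null(age_group)) subjects$age_group <- age_group
  fc_cohort(atlas, subjects, younger = younger, older = older)
}
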
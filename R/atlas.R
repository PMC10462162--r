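#' Sphere-based brain atlases and network partitions
#'
#' An `fc_atlas` is a data frame with one row per region of interest (ROI):
#' a 0-based `roi_id`, an MNI-millimetre sphere centre (`x_mm`, `y_mm`,
#' `z_mm`), a sphere `radius_mm`, and an integer `network_label` in 0..13
#' with a human-readable `network_name`. The packaged default follows the
#' published 264-ROI / 14-network grouping (somatomotor hand and mouth,
#' cinguloopercular, auditory, default mode, memory, visual, frontoparietal,
#' salience, subcortical, ventral and dorsal attention, cerebellar,
#' uncertain); its sphere centres are synthetic placeholders on a 12 mm
#' grid, since only the label structure matters for block-level statistics.
#' Any user atlas in the same tabular format is accepted.
#'
#' @name atlas
NULL

# label -> abbreviation for the 14-network grouping
NETWORK_ABBREV <- c("SMT", "SMT", "CNG", "AUD", "DMN", "MEM", "VIS", "FRNT",
                    "SAL", "SUB", "VTRL", "DRSL", "CB", "UNK")

new_atlas <- function(df) {
  required <- c("roi_id", "x_mm", "y_mm", "z_mm", "radius_mm",
                "network_label", "network_name")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("atlas is missing column(s): ", paste(missing, collapse = ", "))
  df$roi_id <- as.integer(df$roi_id)
  df$network_label <- as.integer(df$network_label)
  n <- nrow(df)
  if (n < 1L) stop("atlas has no ROIs")
  if (anyNA(df$roi_id) || anyDuplicated(df$roi_id))
    stop("atlas roi_id values must be unique and non-missing")
  if (!identical(sort(df$roi_id), 0:(n - 1L)))
    stop("atlas roi_id values must be contiguous 0..N-1")
  if (any(df$radius_mm <= 0)) stop("atlas radius_mm must be positive")
  if (any(df$network_label < 0L | df$network_label > 13L))
    stop("atlas network_label must lie in 0..13")
  nm <- tapply(df$network_name, df$network_label, function(x) length(unique(x)))
  if (any(nm != 1L))
    stop("network_name must be constant within each network_label")
  structure(df[order(df$roi_id), , drop = FALSE],
            class = c("fc_atlas", "data.frame"), row.names = seq_len(n))
}

#' Load an atlas from a tab-separated file
#'
#' @param path path to a TSV with header columns `roi_id`, `x_mm`, `y_mm`,
#'   `z_mm`, `radius_mm`, `network_label`, `network_name`; one row per ROI,
#'   0-based contiguous `roi_id`, labels in 0..13. Row order is preserved as
#'   the ROI order.
#' @return an `fc_atlas` data frame.
#' @export
#' @examples
#' atlas <- power264_atlas()
#' nrow(atlas)  # 264
load_atlas <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  new_atlas(df)
}

#' The packaged 264-ROI / 14-network atlas
#'
#' Network labels and ROI ranges follow the published 14-network grouping
#' (label 0 = somatomotor hand ROIs 0-29, ..., label 6 = visual ROIs
#' 125-155, ..., label 13 = uncertain ROIs 236-263). Sphere centres are
#' synthetic placeholders and must not be used for real voxel extraction.
#'
#' @return an `fc_atlas` with 264 ROIs in 14 networks.
#' @export
power264_atlas <- function() {
  load_atlas(system.file("extdata", "power264_synthetic.tsv",
                         package = "fclong", mustWork = TRUE))
}

#' Restrict an atlas to a subset of networks
#'
#' Keeps the ROIs of the selected network labels and renumbers `roi_id`
#' contiguously (preserving order); network labels and names are unchanged.
#' Useful for running block-level analyses on a reduced parcellation.
#'
#' @param atlas an `fc_atlas`.
#' @param labels integer network labels to keep.
#' @param per_network optionally keep only the first `per_network` ROIs of
#'   each retained network (scales the atlas down).
#' @return an `fc_atlas`.
#' @export
atlas_subset <- function(atlas, labels = sort(unique(atlas$network_label)),
                         per_network = NULL) {
  keep <- atlas$network_label %in% as.integer(labels)
  df <- atlas[keep, , drop = FALSE]
  if (!is.null(per_network)) {
    idx <- unlist(lapply(split(seq_len(nrow(df)), df$network_label),
                         utils::head, n = per_network), use.names = FALSE)
    df <- df[sort(idx), , drop = FALSE]
  }
  if (!nrow(df)) stop("atlas_subset: no ROIs left")
  df$roi_id <- seq_len(nrow(df)) - 1L
  new_atlas(df)
}

#' Partition atlas ROIs into functional networks
#'
#' @param atlas an `fc_atlas`.
#' @param merge_somatomotor if `TRUE`, merge the somatomotor mouth network
#'   (label 1) into the somatomotor hand network (label 0), giving a single
#'   SMT network. Off by default: the headline SMT-VIS block is the
#'   hand-visual pair (labels 0 and 6).
#' @return an `fc_partition`: a list mapping network label (as character)
#'   to the 0-based `roi_id`s in that network, with attributes `labels`
#'   (sorted integer labels present), `abbrev`, `network_names`, and
#'   `n_roi`.
#' @export
network_partition <- function(atlas, merge_somatomotor = FALSE) {
  stopifnot(inherits(atlas, "fc_atlas"))
  lab <- atlas$network_label
  if (merge_somatomotor) lab[lab == 1L] <- 0L
  labels <- sort(unique(lab))
  rois <- lapply(labels, function(l) atlas$roi_id[lab == l])
  names(rois) <- as.character(labels)
  nm <- vapply(labels, function(l) atlas$network_name[lab == l][1], "")
  structure(rois,
            labels = labels,
            abbrev = NETWORK_ABBREV[labels + 1L],
            network_names = nm,
            n_roi = nrow(atlas),
            class = "fc_partition")
}

#' Enumerate canonical network-pair blocks
#'
#' All unordered pairs of network labels (within-network pairs included),
#' canonicalized `a <= b` and listed in lexicographic order; K networks
#' give K(K+1)/2 blocks (105 for the 14-network atlas).
#'
#' @param partition an `fc_partition`.
#' @return a data frame with integer columns `a`, `b`, a `key` string
#'   `"a-b"`, and a `networks` string such as `"SMT-VIS"`.
#' @export
#' @examples
#' p <- network_partition(power264_atlas())
#' nrow(block_pairs(p))  # 105
block_pairs <- function(partition) {
  stopifnot(inherits(partition, "fc_partition"))
  labels <- attr(partition, "labels")
  ab <- attr(partition, "abbrev")
  k <- length(labels)
  a <- rep(labels, times = rev(seq_len(k)))
  b <- unlist(lapply(seq_len(k), function(i) labels[i:k]), use.names = FALSE)
  ia <- match(a, labels); ib <- match(b, labels)
  data.frame(a = a, b = b,
             key = paste0(a, "-", b),
             networks = paste0(ab[ia], "-", ab[ib]),
             stringsAsFactors = FALSE)
}

#' @export
print.fc_partition <- function(x, ...) {
  labels <- attr(x, "labels")
  cat("Network partition:", attr(x, "n_roi"), "ROIs in", length(labels),
      "networks\n")
  sizes <- lengths(x)
  for (i in seq_along(labels))
    cat(sprintf("  %2d %-5s %-22s %3d ROIs\n", labels[i],
                attr(x, "abbrev")[i], attr(x, "network_names")[i], sizes[i]))
  invisible(x)
}

#' Voxel mask of an ROI sphere
#'
#' Returns the voxels of a 3D grid whose centres lie within the ROI's
#' sphere (Euclidean distance `<= radius_mm` of the centre, so membership
#' is deterministic and grid-resolution independent). Voxel centres are
#' mapped to millimetre space by the grid's affine, applied to 0-based
#' voxel indices as in the NIfTI convention. Spheres may overlap; each mask
#' is computed independently.
#'
#' @param atlas an `fc_atlas`.
#' @param roi_id 0-based ROI id.
#' @param dim integer length-3 grid dimensions.
#' @param affine 4x4 voxel-to-mm affine matrix.
#' @return integer vector of 1-based linear indices into an array of
#'   dimension `dim`; attribute `ijk` holds the 1-based voxel coordinates.
#'   Empty (with a warning) when the sphere misses the grid.
#' @export
roi_sphere_mask <- function(atlas, roi_id, dim, affine) {
  stopifnot(inherits(atlas, "fc_atlas"), length(dim) == 3)
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine[1:3, 1:3])) < 1e-12)
    stop("affine must be an invertible 4x4 voxel-to-mm transform")
  row <- match(as.integer(roi_id), atlas$roi_id)
  if (is.na(row)) stop("unknown roi_id: ", roi_id)
  ctr <- as.numeric(atlas[row, c("x_mm", "y_mm", "z_mm")])
  r <- atlas$radius_mm[row]
  # bounding box in voxel space to avoid scanning the whole grid
  inv <- solve(affine)
  vc <- inv %*% c(ctr, 1)
  # conservative per-axis voxel extent of the sphere
  step <- sqrt(colSums(affine[1:3, 1:3]^2))
  lo <- pmax(1L, floor(vc[1:3] + 1 - r / step - 1))
  hi <- pmin(dim, ceiling(vc[1:3] + 1 + r / step + 1))
  if (any(lo > hi)) {
    warning("ROI ", roi_id, " sphere lies outside the grid; empty mask")
    return(structure(integer(0), ijk = matrix(integer(0), 0, 3)))
  }
  g <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  mm <- cbind(g - 1, 1) %*% t(affine[1:3, , drop = FALSE])
  d2 <- (mm[, 1] - ctr[1])^2 + (mm[, 2] - ctr[2])^2 + (mm[, 3] - ctr[3])^2
  sel <- d2 <= r^2
  if (!any(sel)) {
    warning("ROI ", roi_id, " sphere contains no voxel centre; empty mask")
    return(structure(integer(0), ijk = matrix(integer(0), 0, 3)))
  }
  ijk <- g[sel, , drop = FALSE]
  idx <- ijk[, 1] + dim[1] * (ijk[, 2] - 1L) + dim[1] * dim[2] * (ijk[, 3] - 1L)
  structure(as.integer(idx), ijk = ijk)
}
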
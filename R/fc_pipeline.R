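#' BOLD timeseries container
#'
#' @param data numeric matrix, frames x ROIs.
#' @param tr repetition time in seconds (sampling interval between frames).
#' @param valid logical per-ROI flags; ROIs flagged `FALSE` (e.g. empty
#'   sphere masks, zero variance) propagate as missing rows/columns of the
#'   FC matrix rather than silent zeros.
#' @return a `bold_timeseries` object.
#' @export
bold_timeseries <- function(data, tr, valid = rep(TRUE, ncol(data))) {
  data <- as.matrix(data)
  if (!is.numeric(tr) || length(tr) != 1 || tr <= 0) stop("tr must be > 0")
  if (nrow(data) < 2) stop("timeseries needs at least 2 frames")
  if (length(valid) != ncol(data)) stop("valid flags must match ROI count")
  if (any(!is.finite(data[, valid, drop = FALSE])))
    stop("non-finite values in valid ROI timeseries")
  structure(list(data = data, tr = tr, valid = as.logical(valid)),
            class = "bold_timeseries")
}

#' @export
print.bold_timeseries <- function(x, ...) {
  cat(sprintf("BOLD timeseries: %d frames x %d ROIs, TR = %g s (%d valid)\n",
              nrow(x$data), ncol(x$data), x$tr, sum(x$valid)))
  invisible(x)
}

#' Extract mean ROI timeseries from a 4D volume
#'
#' Entry (t, r) is the mean over ROI r's sphere-mask voxels of frame t.
#' ROIs with empty masks are flagged invalid and carried as `NA` columns.
#'
#' @param volume a 4D numeric array, a `niftiImage`, or a path to a NIfTI
#'   file readable by \pkg{RNifti}.
#' @param atlas an `fc_atlas` giving sphere centres and radii.
#' @param tr repetition time in seconds; taken from the NIfTI header when
#'   the volume is a file or `niftiImage` and `tr` is `NULL`.
#' @param affine 4x4 voxel-to-mm affine; taken from the NIfTI header when
#'   available.
#' @return a `bold_timeseries` (frames x ROIs).
#' @export
extract_roi_timeseries <- function(volume, atlas, tr = NULL, affine = NULL) {
  if (is.character(volume)) volume <- RNifti::readNifti(volume)
  if (inherits(volume, "niftiImage")) {
    if (is.null(affine)) affine <- structure(RNifti::xform(volume), code = NULL)
    if (is.null(tr)) {
      pd <- RNifti::pixdim(volume)
      if (length(pd) >= 4 && pd[4] > 0) tr <- pd[4]
    }
    volume <- as.array(volume)
  }
  if (length(dim(volume)) != 4) stop("volume must be 4D (x, y, z, frames)")
  if (is.null(affine)) stop("an affine is required to place ROI spheres")
  if (is.null(tr)) stop("tr is required (not present in the input header)")
  d <- dim(volume)
  if (d[4] < 2) stop("volume must have at least 2 frames")
  nvox <- prod(d[1:3])
  vmat <- matrix(volume, nvox, d[4])
  n_roi <- nrow(atlas)
  out <- matrix(NA_real_, d[4], n_roi)
  valid <- logical(n_roi)
  for (r in seq_len(n_roi)) {
    mask <- suppressWarnings(
      roi_sphere_mask(atlas, atlas$roi_id[r], d[1:3], affine))
    if (length(mask)) {
      out[, r] <- colMeans(vmat[mask, , drop = FALSE])
      valid[r] <- TRUE
    }
  }
  if (!any(valid)) stop("extraction failed: every ROI mask is empty")
  if (any(!valid))
    message(sum(!valid), " ROI(s) with empty masks flagged invalid")
  colnames(out) <- atlas$roi_id
  bold_timeseries(out, tr, valid)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Applies a forward-backward (zero-phase) Butterworth bandpass to every
#' ROI column, the standard band for resting-state BOLD being
#' 0.01-0.15 Hz. Zero phase avoids introducing inter-ROI lags that would
#' bias Pearson correlations. Each series is demeaned and odd-reflection
#' padded before filtering to suppress edge transients; DC is removed
#' entirely (it is below the passband).
#'
#' @param ts a `bold_timeseries`.
#' @param low_hz,high_hz passband edges in Hz; must satisfy
#'   `0 <= low_hz < high_hz < 1/(2 tr)` (the Nyquist frequency).
#' @param order Butterworth order of the underlying design (the effective
#'   attenuation is doubled by the forward-backward pass).
#' @return a filtered `bold_timeseries` of the same shape.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.15, order = 2) {
  stopifnot(inherits(ts, "bold_timeseries"))
  nyq <- 1 / (2 * ts$tr)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyq))
    stop(sprintf(
      "infeasible band [%g, %g] Hz for TR = %g s (Nyquist %.4g Hz)",
      low_hz, high_hz, ts$tr, nyq))
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  out <- ts$data
  for (r in which(ts$valid)) {
    x <- ts$data[, r]
    out[, r] <- filtfilt_padded(bf, x - mean(x))
  }
  bold_timeseries(out, ts$tr, ts$valid)
}

# forward-backward filtering with odd-reflection end padding
# (signal::filtfilt alone leaves large end transients)
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  pad <- min(3L * (max(length(bf$b), length(bf$a)) - 1L) * 10L, n - 1L)
  if (pad < 1L) return(signal::filtfilt(bf, x))
  pre <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(pad + 1L):(pad + n)]
}

#' Pearson FC matrix from ROI timeseries
#'
#' @param ts a `bold_timeseries` with at least 3 frames.
#' @return an `fc_matrix`: a symmetric unit-diagonal ROI x ROI Pearson
#'   correlation matrix; invalid or zero-variance ROIs give `NA`
#'   rows/columns and are flagged in the `valid` attribute.
#' @export
fc_from_timeseries <- function(ts) {
  stopifnot(inherits(ts, "bold_timeseries"))
  if (nrow(ts$data) < 3)
    stop("at least 3 frames are needed for a correlation estimate")
  valid <- ts$valid
  sds <- apply(ts$data, 2, stats::sd)
  zv <- valid & (is.na(sds) | sds == 0)
  if (any(zv)) {
    message(sum(zv), " zero-variance ROI(s) flagged invalid")
    valid <- valid & !zv
  }
  n <- ncol(ts$data)
  m <- matrix(NA_real_, n, n)
  if (any(valid)) {
    m[valid, valid] <- stats::cor(ts$data[, valid, drop = FALSE])
    diag(m)[valid] <- 1
  }
  fc_matrix(m, valid = valid, check = FALSE)
}

#' FC matrix constructor
#'
#' @param m symmetric unit-diagonal matrix of correlations in `[-1, 1]`.
#' @param valid per-ROI validity flags (rows/columns of invalid ROIs are
#'   `NA`).
#' @param check validate the invariants.
#' @return an `fc_matrix`.
#' @export
fc_matrix <- function(m, valid = rep(TRUE, nrow(m)), check = TRUE) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("FC matrix must be square")
  if (check) {
    mm <- m[valid, valid, drop = FALSE]
    if (any(is.na(mm))) stop("NA entries among valid ROIs")
    if (max(abs(mm - t(mm))) > 1e-8) stop("FC matrix must be symmetric")
    if (any(abs(diag(mm) - 1) > 1e-8)) stop("FC diagonal must be 1")
    if (any(mm < -1 - 1e-8 | mm > 1 + 1e-8))
      stop("FC entries must lie in [-1, 1]")
  }
  structure(m, valid = as.logical(valid), class = c("fc_matrix", "matrix"))
}

#' Vectorize the strict upper triangle of an FC matrix
#'
#' Row-major order: (1,2), (1,3), ..., (1,N), (2,3), ... — the edge
#' ordering used by every vectorized output of this package. A 264-ROI
#' matrix gives 34,716 features.
#'
#' @param m a symmetric matrix (`fc_matrix` or plain).
#' @return numeric vector of length N(N-1)/2 with attribute `n` = N.
#' @export
vectorize_fc <- function(m) {
  m <- unclass(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  v <- t(m)[lower.tri(m)]
  structure(v, n = nrow(m))
}

#' Rebuild a symmetric FC matrix from its upper-triangle vector
#'
#' @param v vector of length N(N-1)/2 in row-major strict-upper-triangle
#'   order.
#' @param n matrix dimension; inferred from `length(v)` when omitted.
#' @return an `fc_matrix` with unit diagonal.
#' @export
devectorize_fc <- function(v, n = NULL) {
  if (is.null(n)) {
    n <- (1 + sqrt(1 + 8 * length(v))) / 2
    if (n != round(n))
      stop("length ", length(v), " is not of the form N(N-1)/2")
    n <- as.integer(n)
  } else if (length(v) != n * (n - 1) / 2) {
    stop("vector length does not match n(n-1)/2")
  }
  a <- matrix(0, n, n)
  a[lower.tri(a)] <- v     # column-major lower = mirror of row-major upper
  m <- a + t(a)
  diag(m) <- 1
  fc_matrix(m, valid = !apply(is.na(m), 1, any), check = FALSE)
}

# row-major strict upper-triangle (i, j) pairs, 1-based
edge_index <- function(n) {
  if (n < 2) return(cbind(i = integer(0), j = integer(0)))
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}
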
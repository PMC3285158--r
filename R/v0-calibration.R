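#' High-resolution angiography-like volume
#'
#' A 3-D scalar intensity grid (e.g. a time-of-flight angiogram) assumed
#' already co-registered and grid-aligned with the functional image:
#' registration and reslicing are done upstream, and every high-resolution
#' dimension must be an exact integer multiple of the corresponding
#' functional dimension.
#'
#' @param intensities 3-D numeric array.
#' @param voxel_size Physical voxel dimensions in mm per axis (`> 0`).
#' @param origin Offset of the first voxel in mm (bookkeeping only).
#' @return An object of class `high_res_volume`.
#' @export
high_res_volume <- function(intensities, voxel_size = c(1, 1, 1),
                            origin = c(0, 0, 0)) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3L,
            all(dim(intensities) >= 1L), all(voxel_size > 0),
            length(voxel_size) == 3L, length(origin) == 3L)
  structure(list(intensities = intensities,
                 voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "high_res_volume")
}

# Logical array: does any neighbor (under the connectivity rule) satisfy
# `above`?  Implemented by shifting the array along the offset directions.
neighbor_any <- function(above, connectivity) {
  d <- dim(above)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  if (connectivity == 6L)
    offsets <- offsets[rowSums(abs(offsets)) == 1, , drop = FALSE]
  out <- array(FALSE, d)
  idx <- function(n, o) {
    # target positions receiving the value of position shifted by o
    if (o == 0) list(to = 1:n, from = 1:n)
    else if (o > 0) list(to = (1 + o):n, from = 1:(n - o))
    else list(to = 1:(n + o), from = (1 - o):n)
  }
  for (r in seq_len(nrow(offsets))) {
    ox <- idx(d[1], offsets[r, 1])
    oy <- idx(d[2], offsets[r, 2])
    oz <- idx(d[3], offsets[r, 3])
    if (!length(ox$to) || !length(oy$to) || !length(oz$to)) next
    shifted <- array(FALSE, d)
    shifted[ox$to, oy$to, oz$to] <- above[ox$from, oy$from, oz$from]
    out <- out | shifted
  }
  out
}

#' Segment large vessels by thresholding with isolated-voxel rejection
#'
#' A voxel enters the vessel mask iff its intensity exceeds `threshold`
#' AND at least one neighbor (26-connectivity by default, i.e. any
#' face/edge/corner neighbor; optionally 6-connectivity) also exceeds the
#' threshold.  Above-threshold voxels with no above-threshold neighbor are
#' treated as noise and excluded; their count is reported.
#'
#' @param volume A [high_res_volume()].
#' @param threshold Intensity threshold (strictly-greater comparison).  A
#'   threshold outside the volume's intensity range triggers a warning
#'   (the mask may be empty or cover everything) but not an error.
#' @param connectivity 26 (default) or 6.
#' @return An object of class `vessel_mask`: binary array `mask`, the
#'   `threshold` and `connectivity` used, and `n_removed`, the number of
#'   isolated above-threshold voxels excluded.
#' @export
segment_vessels <- function(volume, threshold, connectivity = 26L) {
  stopifnot(inherits(volume, "high_res_volume"))
  connectivity <- match.arg(as.character(connectivity), c("26", "6"))
  connectivity <- as.integer(connectivity)
  rng <- range(volume$intensities)
  if (threshold < rng[1] || threshold > rng[2])
    warning(sprintf(
      "threshold %g outside intensity range [%g, %g]; mask may be trivial",
      threshold, rng[1], rng[2]))
  above <- volume$intensities > threshold
  keep <- above & neighbor_any(above, connectivity)
  structure(list(mask = array(as.integer(keep), dim(above)),
                 threshold = threshold,
                 connectivity = connectivity,
                 n_removed = sum(above) - sum(keep)),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf(
    "Vessel mask %s: %d vessel voxel(s), %d isolated voxel(s) removed\n",
    paste(dim(x$mask), collapse = "x"), sum(x$mask), x$n_removed))
  cat(sprintf("  threshold %g, %d-connectivity isolation rule\n",
              x$threshold, x$connectivity))
  invisible(x)
}

#' Per-functional-voxel large-vessel fraction by subvoxel counting
#'
#' Partitions the high-resolution mask into blocks of
#' `fx x fy x fz` subvoxels (one block per functional voxel; the block of
#' functional voxel `(i, j, k)`, 1-based, covers the subvoxel index range
#' `((i-1)*fx, i*fx]` etc.) and returns the fraction of vessel subvoxels
#' in each block.  Counting is exact integer arithmetic: the total vessel
#' subvoxel count is conserved.
#'
#' @param mask A [segment_vessels()] result, or a binary 3-D array.
#' @param functional_dim Integer dimensions of the functional grid; each
#'   high-resolution dimension must be an exact integer multiple.
#' @return 3-D array of fractions in `[0, 1]` with dim `functional_dim`;
#'   attribute `factors` records the per-axis downsampling factors and
#'   `n_vessel` the total vessel subvoxel count.
#' @export
vessel_fraction <- function(mask, functional_dim) {
  m <- if (inherits(mask, "vessel_mask")) mask$mask else mask
  stopifnot(is.array(m), length(dim(m)) == 3L,
            length(functional_dim) == 3L)
  functional_dim <- as.integer(functional_dim)
  hd <- dim(m)
  if (any(hd %% functional_dim != 0L))
    stop("high-resolution dimensions (", paste(hd, collapse = "x"),
         ") are not integer multiples of the functional grid (",
         paste(functional_dim, collapse = "x"),
         "); resample the volumes upstream so the grids nest exactly")
  f <- hd %/% functional_dim
  # reshape to (fx, nx, fy, ny, fz, nz), move block axes first, block-sum
  a <- array(as.integer(m != 0),
             c(f[1], functional_dim[1], f[2], functional_dim[2],
               f[3], functional_dim[3]))
  a <- aperm(a, c(1, 3, 5, 2, 4, 6))
  counts <- colSums(matrix(a, nrow = prod(f)))
  lambda <- array(counts / prod(f), functional_dim)
  attr(lambda, "factors") <- f
  attr(lambda, "n_vessel") <- sum(m != 0)
  lambda
}

#' Resting blood volume fraction map from vessel fractions
#'
#' Mixes the large-vessel and tissue blood components per functional
#' voxel: `V0 = lambda * v_blood + (1 - lambda) * v_tissue`.  A voxel with
#' no large vessel (`lambda = 0`) reduces to the tissue value.
#'
#' @param lambda 3-D array of large-vessel fractions in `[0, 1]` (from
#'   [vessel_fraction()]).
#' @param v_tissue Blood volume fraction of vessel-free tissue
#'   (capillaries and small post-capillaries), default 0.02.
#' @param v_blood Blood volume fraction assigned to a pure-vessel subvoxel
#'   (default 1: a segmented vessel subvoxel is all blood).
#' @return An object of class `v0_map`: array `values` on the functional
#'   grid plus the two mixture components.
#' @export
compute_v0_map <- function(lambda, v_tissue = 0.02, v_blood = 1.0) {
  stopifnot(is.array(lambda), all(lambda >= 0), all(lambda <= 1))
  if (v_tissue <= 0 || v_tissue >= v_blood || v_blood > 1)
    stop("require 0 < v_tissue < v_blood <= 1")
  vals <- lambda * v_blood + (1 - lambda) * v_tissue
  structure(list(values = array(as.numeric(vals), dim(lambda)),
                 v_tissue = v_tissue, v_blood = v_blood),
            class = "v0_map")
}

#' @export
print.v0_map <- function(x, ...) {
  cat(sprintf("V0 map %s: range [%.4g, %.4g] (v_tissue %.3g, v_blood %.3g)\n",
              paste(dim(x$values), collapse = "x"),
              min(x$values), max(x$values), x$v_tissue, x$v_blood))
  invisible(x)
}

#' Extract an averaged ROI time series
#'
#' Averages the BOLD time series of the ROI center voxel and its
#' edge-adjacent in-slice neighbors (4-neighborhood in the slice plane;
#' corners excluded).  Neighbors falling outside the volume are dropped.
#'
#' @param bold_4d 4-D numeric array `(x, y, z, time)`.
#' @param roi_center Integer voxel index `c(i, j, k)`, 1-based, inside the
#'   volume.
#' @param include_center Include the center voxel itself (default TRUE).
#' @return List with `series` (data frame `time_index`, `mean_bold`) and
#'   `members` (matrix of member voxel indices, for audit).
#' @export
extract_roi_series <- function(bold_4d, roi_center, include_center = TRUE) {
  stopifnot(is.array(bold_4d), length(dim(bold_4d)) == 4L,
            length(roi_center) == 3L)
  d <- dim(bold_4d)[1:3]
  roi_center <- as.integer(roi_center)
  if (any(roi_center < 1L) || any(roi_center > d))
    stop("roi_center lies outside the volume")
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0))
  if (include_center) offs <- rbind(c(0, 0, 0), offs)
  members <- sweep(offs, 2, roi_center, "+")
  inside <- members[, 1] >= 1 & members[, 1] <= d[1] &
    members[, 2] >= 1 & members[, 2] <= d[2] &
    members[, 3] >= 1 & members[, 3] <= d[3]
  members <- members[inside, , drop = FALSE]
  colnames(members) <- c("i", "j", "k")
  series <- vapply(seq_len(nrow(members)), function(r)
    bold_4d[members[r, 1], members[r, 2], members[r, 3], ],
    numeric(dim(bold_4d)[4]))
  list(series = data.frame(time_index = seq_len(dim(bold_4d)[4]),
                           mean_bold = rowMeans(series)),
       members = members)
}
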
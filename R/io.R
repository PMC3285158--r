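#' Write and read a simulated BOLD series as CSV
#'
#' The CSV carries `time_s`, `bold_noiseless`, `bold_noisy` (or whatever
#' columns the data frame has); a JSON sidecar (same path with `.json`
#' appended) records the generating parameters and seed when present as
#' attributes.
#'
#' @param series Data frame (e.g. from [simulate_bold()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  p <- attr(series, "params")
  meta <- list(noise_sd = attr(series, "noise_sd"),
               seed = attr(series, "seed"))
  if (!is.null(p)) meta$params <- unclass(p)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  utils::read.csv(path)
}

#' Write and read a stimulus train as YAML
#'
#' @param stimulus A [stimulus_train()].
#' @param path Output `.yaml` path.
#' @return `path` invisibly; `read_stimulus_yaml()` returns the
#'   reconstructed [stimulus_train()].
#' @export
write_stimulus_yaml <- function(stimulus, path) {
  stopifnot(inherits(stimulus, "stimulus_train"))
  yaml::write_yaml(list(onsets = stimulus$onsets,
                        durations = stimulus$durations,
                        amplitude = stimulus$amplitude), path)
  invisible(path)
}

#' @rdname write_stimulus_yaml
#' @export
read_stimulus_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  stimulus_train(unlist(x$onsets), unlist(x$durations), x$amplitude)
}

#' NIfTI input/output for volumes and V0 maps
#'
#' Thin wrappers over the RNifti reader/writer.  `write_v0_nifti()` also
#' writes a JSON sidecar recording the mixture components (and, when a
#' [segment_vessels()] mask is passed, the threshold, connectivity rule
#' and removed-voxel count) for reproducibility.
#'
#' @param x A [high_res_volume()], [segment_vessels()] mask, or plain 3-D
#'   array.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path` invisibly; `read_volume_nifti()` returns a
#'   [high_res_volume()].
#' @export
write_volume_nifti <- function(x, path) {
  if (inherits(x, "high_res_volume")) {
    img <- RNifti::asNifti(x$intensities, pixdim = x$voxel_size)
  } else if (inherits(x, "vessel_mask")) {
    img <- RNifti::asNifti(x$mask)
  } else {
    img <- RNifti::asNifti(x)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  high_res_volume(array(as.numeric(img), dim(img)),
                  voxel_size = RNifti::pixdim(img)[1:3])
}

#' @rdname write_volume_nifti
#' @param v0map A [compute_v0_map()] result.
#' @param mask Optional [segment_vessels()] mask whose provenance goes in
#'   the sidecar.
#' @export
write_v0_nifti <- function(v0map, path, mask = NULL) {
  stopifnot(inherits(v0map, "v0_map"))
  RNifti::writeNifti(RNifti::asNifti(v0map$values), path)
  meta <- list(v_tissue = v0map$v_tissue, v_blood = v0map$v_blood)
  if (!is.null(mask) && inherits(mask, "vessel_mask"))
    meta <- c(meta, list(threshold = mask$threshold,
                         connectivity = mask$connectivity,
                         n_removed = mask$n_removed))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
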
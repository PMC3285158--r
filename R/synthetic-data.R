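#' Alternating rest/stimulus block design
#'
#' Builds the boxcar stimulus of a block-design acquisition: `n_blocks`
#' stimulation epochs of `block_s` seconds separated by `rest_s` seconds
#' of rest, starting with rest.
#'
#' @param n_blocks Number of stimulation blocks (`>= 0`).
#' @param block_s Block duration in seconds (default 20).
#' @param rest_s Rest duration in seconds (default 20).
#' @param amplitude Input level during blocks.
#' @return A [stimulus_train()].
#' @examples
#' make_block_design(5, 20, 20)  # spans 220 s
#' @export
make_block_design <- function(n_blocks, block_s = 20, rest_s = 20,
                              amplitude = 1) {
  stopifnot(n_blocks >= 0, block_s > 0, rest_s > 0)
  if (n_blocks == 0)
    return(stimulus_train(numeric(0), numeric(0), amplitude))
  onsets <- rest_s + (seq_len(n_blocks) - 1) * (block_s + rest_s)
  stimulus_train(onsets, rep(block_s, n_blocks), amplitude)
}

#' Synthetic single-region acquisition scenario
#'
#' Ground-truth description of one simulated block-design run: the true
#' hemodynamic parameters (including `V0`), the stimulus, the sampling
#' grid, and the measurement noise.  Defaults emulate an fMRI-typical
#' protocol: TR = 2 s, 200 scans, 20 s on/off blocks.  The default input
#' amplitude 0.25 keeps the true response in the physiological regime
#' (roughly a 40% peak inflow increase and a few-percent BOLD change at a
#' vein-dominated `V0 = 0.1`).  Noise can be given directly (`noise_sd`) or as a target peak
#' signal-to-noise ratio (`snr`, peak of the noiseless response over the
#' noise SD).
#'
#' @param name Scenario label.
#' @param params True [hemodynamic_params()] (its `V0` is the actual
#'   blood volume fraction of the region).
#' @param tr Repetition time in seconds.
#' @param n_scans Number of scans.
#' @param block_s,rest_s,amplitude Block-design geometry.
#' @param noise_sd Measurement noise SD; if `NULL`, derived from `snr`.
#' @param snr Target peak SNR (used only when `noise_sd` is `NULL`).
#' @param seed Integer seed driving the noise draw.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(name = "single_region",
                               params = hemodynamic_params(V0 = 0.1),
                               tr = 2, n_scans = 200, block_s = 20,
                               rest_s = 20, amplitude = 0.25,
                               noise_sd = NULL, snr = 10, seed = 1L) {
  stopifnot(tr > 0, n_scans >= 2, is.null(noise_sd) || noise_sd >= 0,
            snr > 0)
  structure(list(name = name, params = params, tr = tr,
                 n_scans = as.integer(n_scans), block_s = block_s,
                 rest_s = rest_s, amplitude = amplitude,
                 noise_sd = noise_sd, snr = snr, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

scenario_stimulus <- function(scenario) {
  span <- scenario$tr * scenario$n_scans
  cycle <- scenario$block_s + scenario$rest_s
  n_blocks <- max(0L, floor((span - scenario$rest_s) / cycle +
                              1e-9))
  make_block_design(n_blocks, scenario$block_s, scenario$rest_s,
                    scenario$amplitude)
}

#' Generate a single-region dataset from a scenario
#'
#' Runs the forward model for the scenario's ground truth and returns the
#' noisy series together with a truth bundle.  Reproducible: the same
#' scenario (same seed) always yields identical output.
#'
#' @param scenario A [synthetic_scenario()].
#' @return List with `series` (data frame `time_s`, `bold_noiseless`,
#'   `bold_noisy`), `stimulus`, `truth` (true parameters, realized
#'   `noise_sd`, peak amplitude), and the `scenario` itself.
#' @export
make_single_region_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  stim <- scenario_stimulus(scenario)
  times <- scenario$tr * seq_len(scenario$n_scans)
  clean <- simulate_bold(scenario$params, stim, times, noise_sd = 0)
  peak <- max(abs(clean$bold_noiseless))
  noise_sd <- if (is.null(scenario$noise_sd)) peak / scenario$snr
  else scenario$noise_sd
  set.seed(scenario$seed)
  noisy <- clean$bold_noiseless +
    if (noise_sd > 0) stats::rnorm(length(times), 0, noise_sd) else 0
  list(series = data.frame(time_s = times,
                           bold_noiseless = clean$bold_noiseless,
                           bold_noisy = noisy),
       stimulus = stim,
       truth = list(params = scenario$params, noise_sd = noise_sd,
                    peak = peak),
       scenario = scenario)
}

#' Synthetic two-region acquisition scenario
#'
#' Ground truth for a two-node DCM run.  The default emulates the
#' vein-versus-tissue contrast the calibration question turns on: region
#' 1 (primary visual cortex locus, vein-dominated) has `V0 = 0.1`, region
#' 2 (a downstream visual area without large veins) keeps the tissue
#' value `V0 = 0.02`; region 1 is driven directly by the stimulus and
#' drives region 2 through `a21`.
#'
#' @param connectivity True [dcm_connectivity()].  The default is a
#'   balanced bidirectional hierarchy (`a12 = a21 = 0.4` per s) with the
#'   stimulus driving region 1 strongly and region 2 weakly -- couplings
#'   strong enough that their signs are statistically identifiable at the
#'   default scan count and SNR, as a recovery simulation requires.
#' @param v0 Length-2 true resting blood volume fractions.
#' @param epsilon Length-2 true neuronal efficacies.
#' @param tr,n_scans,block_s,rest_s,amplitude Acquisition geometry as in
#'   [synthetic_scenario()].
#' @param snr Target peak SNR per region (applied region-wise).
#' @param seed Integer seed.
#' @return An object of class `dcm_scenario`.
#' @export
dcm_scenario <- function(connectivity = dcm_connectivity(
                           a11 = -1, a12 = 0.4, a21 = 0.4, a22 = -1,
                           c1 = 1, c2 = 0.2),
                         v0 = c(0.1, 0.02), epsilon = c(0.54, 0.54),
                         tr = 2, n_scans = 200, block_s = 20, rest_s = 20,
                         amplitude = 0.25, snr = 10, seed = 1L) {
  stopifnot(length(v0) == 2L, length(epsilon) == 2L)
  structure(list(connectivity = connectivity, v0 = v0, epsilon = epsilon,
                 tr = tr, n_scans = as.integer(n_scans),
                 block_s = block_s, rest_s = rest_s,
                 amplitude = amplitude, snr = snr,
                 seed = as.integer(seed)),
            class = "dcm_scenario")
}

#' Generate a two-region dataset from a DCM scenario
#'
#' @param scenario A [dcm_scenario()].
#' @return List with `series` (two-region noisy + noiseless BOLD),
#'   `stimulus`, `model` (the true [dcm_model()]), `truth` (realized
#'   per-region noise SDs and peaks), and the `scenario`.
#' @export
make_two_region_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "dcm_scenario"))
  base <- synthetic_scenario(tr = scenario$tr, n_scans = scenario$n_scans,
                             block_s = scenario$block_s,
                             rest_s = scenario$rest_s,
                             amplitude = scenario$amplitude)
  stim <- scenario_stimulus(base)
  times <- scenario$tr * seq_len(scenario$n_scans)
  mk_params <- function(i) hemodynamic_params(
    epsilon = scenario$epsilon[i], V0 = scenario$v0[i])
  model <- dcm_model(scenario$connectivity, mk_params(1), mk_params(2))
  clean <- simulate_dcm(model, stim, times, noise_sd = c(0, 0))
  peaks <- c(max(abs(clean$bold1_noiseless)),
             max(abs(clean$bold2_noiseless)))
  noise_sd <- peaks / scenario$snr
  set.seed(scenario$seed)
  n <- length(times)
  series <- data.frame(
    time_s = times,
    bold1_noiseless = clean$bold1_noiseless,
    bold1_noisy = clean$bold1_noiseless + stats::rnorm(n, 0, noise_sd[1]),
    bold2_noiseless = clean$bold2_noiseless,
    bold2_noisy = clean$bold2_noiseless + stats::rnorm(n, 0, noise_sd[2]))
  list(series = series, stimulus = stim, model = model,
       truth = list(connectivity = scenario$connectivity,
                    v0 = scenario$v0, epsilon = scenario$epsilon,
                    noise_sd = noise_sd, peaks = peaks),
       scenario = scenario)
}

#' Specification of a high-resolution vessel phantom
#'
#' Geometry of a synthetic angiography-like volume: straight vessel
#' segments rasterized at high resolution over a low-intensity
#' background, plus a number of isolated above-threshold noise voxels.
#' Each functional voxel corresponds to a `factor^3` block of subvoxels,
#' so the per-voxel vessel fraction is known exactly by construction.
#'
#' @param functional_dim Functional grid dimensions (default `c(6, 6, 4)`).
#' @param factor Per-axis subvoxel factor (default 4: 64 subvoxels per
#'   functional voxel).
#' @param segments List of segments, each a list with `from`, `to`
#'   (subvoxel coordinates, 1-based) and `radius` (in subvoxels; 0 means
#'   the voxelized line only).  `NULL` draws `n_segments` random
#'   segments.
#' @param n_segments Number of random segments when `segments` is `NULL`.
#' @param n_noise Number of isolated noise voxels to inject.
#' @param background_intensity,vessel_intensity,noise_intensity Intensity
#'   levels; vessel and noise voxels get i.i.d. jitter of
#'   `intensity_jitter` around their level so that masks shrink smoothly
#'   as the threshold rises.
#' @param intensity_jitter Half-width of the uniform intensity jitter.
#' @param seed Integer seed.
#' @return An object of class `vessel_phantom_spec`.
#' @export
vessel_phantom_spec <- function(functional_dim = c(6, 6, 4), factor = 4,
                                segments = NULL, n_segments = 3,
                                n_noise = 5, background_intensity = 150,
                                vessel_intensity = 1100,
                                noise_intensity = 1100,
                                intensity_jitter = 280, seed = 1L) {
  stopifnot(length(functional_dim) == 3L, all(functional_dim >= 1),
            factor >= 1, n_noise >= 0,
            background_intensity + intensity_jitter <
              vessel_intensity - intensity_jitter)
  structure(list(functional_dim = as.integer(functional_dim),
                 factor = as.integer(factor), segments = segments,
                 n_segments = n_segments, n_noise = as.integer(n_noise),
                 background_intensity = background_intensity,
                 vessel_intensity = vessel_intensity,
                 noise_intensity = noise_intensity,
                 intensity_jitter = intensity_jitter,
                 seed = as.integer(seed)),
            class = "vessel_phantom_spec")
}

# subvoxel centers within `radius` of the segment from->to (inclusive);
# radius 0 keeps the rounded line raster only
rasterize_segment <- function(from, to, radius, dim3) {
  from <- as.numeric(from); to <- as.numeric(to)
  len <- sqrt(sum((to - from)^2))
  n <- max(2L, as.integer(ceiling(len * 4)) + 1L)
  tseq <- seq(0, 1, length.out = n)
  pts <- unique(round(cbind(from[1] + tseq * (to[1] - from[1]),
                            from[2] + tseq * (to[2] - from[2]),
                            from[3] + tseq * (to[3] - from[3]))))
  if (radius > 0) {
    r <- ceiling(radius)
    offs <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
    offs <- offs[rowSums(offs^2) <= radius^2, , drop = FALSE]
    pts <- unique(do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
      sweep(pts, 2, offs[i, ], "+"))))
  }
  ok <- pts[, 1] >= 1 & pts[, 1] <= dim3[1] &
    pts[, 2] >= 1 & pts[, 2] <= dim3[2] &
    pts[, 3] >= 1 & pts[, 3] <= dim3[3]
  pts[ok, , drop = FALSE]
}

#' Build a vessel phantom with an exactly known fraction table
#'
#' Rasterizes the specified segments into a high-resolution volume,
#' injects isolated noise voxels (each guaranteed to have no
#' above-threshold neighbor, so the segmentation's isolation rule removes
#' exactly these), and returns the analytic per-functional-voxel vessel
#' fraction computed by exact integer subvoxel counting -- the oracle for
#' the calibration pipeline.
#'
#' @param spec A [vessel_phantom_spec()].
#' @return List with `volume` (a [high_res_volume()]), `lambda_true` (the
#'   exact fraction array on the functional grid), `vessel_mask_true`
#'   (binary high-resolution array of vessel subvoxels, noise excluded),
#'   `noise_voxels` (matrix of injected noise coordinates),
#'   `threshold` (a value that separates vessel/noise from background),
#'   and the `spec`.
#' @export
make_vessel_phantom <- function(spec) {
  stopifnot(inherits(spec, "vessel_phantom_spec"))
  set.seed(spec$seed)
  hd <- spec$functional_dim * spec$factor
  segments <- spec$segments
  if (is.null(segments) && spec$n_segments > 0) {
    segments <- lapply(seq_len(spec$n_segments), function(i) {
      axis <- sample(3L, 1L)
      from <- sapply(hd, function(n) sample(n, 1L))
      to <- from
      to[axis] <- sample(hd[axis], 1L)
      list(from = from, to = to, radius = sample(0:2, 1L))
    })
  }
  vessel <- array(FALSE, hd)
  for (seg in segments) {
    pts <- rasterize_segment(seg$from, seg$to, seg$radius, hd)
    if (nrow(pts)) vessel[pts] <- TRUE
  }
  # drop vessel voxels that would themselves be isolated (single-subvoxel
  # rasters), so the geometry survives the segmentation's isolation rule
  if (any(vessel)) {
    keep <- vessel & neighbor_any(vessel, 26L)
    vessel <- keep
  }

  intens <- array(stats::runif(prod(hd), 0, 1) * spec$intensity_jitter +
                    (spec$background_intensity - spec$intensity_jitter / 2),
                  hd)
  nv <- sum(vessel)
  intens[vessel] <- spec$vessel_intensity +
    stats::runif(nv, -spec$intensity_jitter, spec$intensity_jitter)

  # isolated noise voxels: above threshold, but no above-threshold voxel
  # in the 26-neighborhood (adjacency-free placement, re-drawn as needed)
  blocked <- vessel | neighbor_any(vessel, 26L)
  noise_voxels <- matrix(integer(0), 0, 3)
  attempts <- 0L
  while (nrow(noise_voxels) < spec$n_noise && attempts < 10000L) {
    attempts <- attempts + 1L
    cand <- c(sample(hd[1], 1L), sample(hd[2], 1L), sample(hd[3], 1L))
    if (blocked[cand[1], cand[2], cand[3]]) next
    noise_voxels <- rbind(noise_voxels, cand)
    # block the candidate and its whole neighborhood for later draws
    lo <- pmax(cand - 1L, 1L)
    hi <- pmin(cand + 1L, hd)
    blocked[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  }
  if (nrow(noise_voxels) < spec$n_noise)
    stop("could not place the requested number of isolated noise voxels")
  if (nrow(noise_voxels)) {
    intens[noise_voxels] <- spec$noise_intensity +
      stats::runif(nrow(noise_voxels), -spec$intensity_jitter,
                   spec$intensity_jitter)
    rownames(noise_voxels) <- NULL
  }
  threshold <- (spec$background_intensity + spec$intensity_jitter / 2 +
                  spec$vessel_intensity - spec$intensity_jitter) / 2
  # analytic fraction table by direct per-subvoxel block assignment
  # (independent of the reshape-based counting in vessel_fraction)
  counts <- array(0L, spec$functional_dim)
  idx <- which(vessel, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    b <- (idx[r, ] - 1L) %/% spec$factor + 1L
    counts[b[1], b[2], b[3]] <- counts[b[1], b[2], b[3]] + 1L
  }
  lambda_true <- counts / spec$factor^3
  list(volume = high_res_volume(intens),
       lambda_true = lambda_true,
       vessel_mask_true = array(as.integer(vessel), hd),
       noise_voxels = noise_voxels,
       threshold = threshold,
       spec = spec)
}
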
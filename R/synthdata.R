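#' Per-ROI kinetic parameters for the synthetic tracer model
#'
#' The synthetic model drives each ROI with the infusion boxcar convolved
#' with an Erlang (serial linear compartment cascade) impulse response,
#' optionally mixed with a second parallel cascade branch (a fast CSF route
#' plus a slow parenchymal route produces the biphasic curves seen for
#' periventricular regions). The combined response is normalized to unit
#' peak, so `amplitude` is the peak signal change in a.u. An onset `delay`
#' shifts the whole response; the mean transport delay of an ROI is
#' `delay + (1 - mix2) * n_stages / rate_const + mix2 * n_stages2 / rate_const2`.
#'
#' All arguments are recycled to a common length (one entry per ROI).
#'
#' @param n_stages Cascade depth (number of serial compartments), >= 1.
#' @param rate_const Compartment rate constant, 1/min, > 0.
#' @param amplitude Peak signal change, a.u., >= 0.
#' @param delay Onset (transport) delay in minutes, >= 0.
#' @param mix2 Weight in `[0, 1)` of the second cascade branch (0 = none).
#' @param n_stages2,rate_const2 Parameters of the second branch.
#' @param baseline Baseline signal offset, a.u.
#' @param polarity `+1` (uptake brightens) or `-1` (uptake darkens).
#' @param cluster Integer ground-truth cluster label.
#' @param roi_id,roi_name ROI identifiers.
#' @return A `data.frame` of class `kinetic_params`, one row per ROI.
#' @export
kinetic_params <- function(n_stages, rate_const, amplitude = 100,
                           delay = 0, mix2 = 0, n_stages2 = 1,
                           rate_const2 = 1, baseline = 100, polarity = 1,
                           cluster = NA_integer_,
                           roi_id = NULL, roi_name = NULL) {
  n <- max(lengths(list(n_stages, rate_const, amplitude, delay, mix2,
                        n_stages2, rate_const2, baseline, polarity, cluster)))
  if (is.null(roi_id)) roi_id <- seq_len(n)
  if (is.null(roi_name)) roi_name <- sprintf("roi_%02d", roi_id)
  p <- data.frame(
    roi_id = as.integer(rep_len(roi_id, n)),
    roi_name = as.character(rep_len(roi_name, n)),
    n_stages = as.integer(rep_len(n_stages, n)),
    rate_const = as.numeric(rep_len(rate_const, n)),
    amplitude = as.numeric(rep_len(amplitude, n)),
    delay = as.numeric(rep_len(delay, n)),
    mix2 = as.numeric(rep_len(mix2, n)),
    n_stages2 = as.integer(rep_len(n_stages2, n)),
    rate_const2 = as.numeric(rep_len(rate_const2, n)),
    baseline = as.numeric(rep_len(baseline, n)),
    polarity = as.integer(rep_len(polarity, n)),
    cluster = as.integer(rep_len(cluster, n)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(p$roi_id)) stop("duplicate roi_id in kinetic parameters")
  if (any(p$n_stages < 1L) || any(p$n_stages2 < 1L))
    stop("n_stages must be >= 1")
  if (any(p$rate_const <= 0) || any(p$rate_const2 <= 0))
    stop("rate_const must be > 0")
  if (any(p$amplitude < 0)) stop("amplitude must be >= 0")
  if (any(p$delay < 0)) stop("delay must be >= 0")
  if (any(p$mix2 < 0 | p$mix2 >= 1)) stop("mix2 must be in [0, 1)")
  if (!all(p$polarity %in% c(-1L, 1L))) stop("polarity must be +1 or -1")
  class(p) <- c("kinetic_params", "data.frame")
  p
}

#' Mean transport delay of each ROI
#'
#' Onset delay plus the branch-weighted mean of the cascade delays
#' (`n_stages / rate_const` per branch), in minutes. Differences of these
#' values are the ground-truth lag times of a synthetic dataset.
#'
#' @param params A [kinetic_params()] table.
#' @return Numeric vector of delays (min), one per ROI.
#' @export
transport_delay <- function(params) {
  stopifnot(inherits(params, "kinetic_params"))
  params$delay +
    (1 - params$mix2) * params$n_stages / params$rate_const +
    params$mix2 * params$n_stages2 / params$rate_const2
}

#' Ground truth of a synthetic dataset
#'
#' Bundles the kinetic parameters with the derived ground-truth lag matrix
#' (antisymmetric, minutes; `lag[i, j] > 0` means ROI j lags ROI i) and the
#' planted cluster labels.
#'
#' @param params A [kinetic_params()] table.
#' @param seed Optional integer recorded as the generating seed.
#' @return An object of class `synthetic_truth` with fields `params`,
#'   `true_lag_matrix`, `true_clusters`, `seed`.
#' @export
synthetic_truth <- function(params, seed = NULL) {
  stopifnot(inherits(params, "kinetic_params"))
  tau <- transport_delay(params)
  lag <- outer(tau, tau, function(a, b) b - a)
  dimnames(lag) <- list(params$roi_name, params$roi_name)
  clusters <- params$cluster
  names(clusters) <- params$roi_name
  structure(list(params = params, true_lag_matrix = lag,
                 true_clusters = clusters,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic ground truth: %d ROIs, %d cluster(s)\n",
              nrow(x$params),
              length(unique(x$true_clusters[!is.na(x$true_clusters)]))))
  cat(sprintf("  transport delays %.3g-%.3g min\n",
              min(transport_delay(x$params)), max(transport_delay(x$params))))
  invisible(x)
}

# Unit-peak tracer response for one ROI: infusion boxcar convolved with the
# (possibly two-branch) Erlang impulse response, normalized so the global
# peak (which may fall beyond the scan window for slow kinetics) is 1.
tracer_unit_response <- function(time, protocol, n_stages, rate_const,
                                 delay = 0, mix2 = 0, n_stages2 = 1,
                                 rate_const2 = 1) {
  if (protocol$duration <= 0) return(numeric(length(time)))
  t0 <- protocol$start_time + delay
  t1 <- t0 + protocol$duration
  upper <- t1 + max(qgamma(0.999, n_stages, rate_const),
                    if (mix2 > 0) qgamma(0.999, n_stages2, rate_const2) else 0)
  fine <- seq(0, upper, length.out = 4096L)
  comp <- function(t, k, lam) pgamma(t - t0, k, lam) - pgamma(t - t1, k, lam)
  # each branch normalized to unit peak before mixing, so mix2 is the
  # fractional contribution of the slow route to the peak signal
  peak1 <- max(comp(fine, n_stages, rate_const))
  f <- function(t) {
    r <- (1 - mix2) * comp(t, n_stages, rate_const) / peak1
    if (mix2 > 0)
      r <- r + mix2 * comp(t, n_stages2, rate_const2) /
        max(comp(fine, n_stages2, rate_const2))
    r
  }
  peak <- max(f(fine))
  f(time) / peak
}

#' Simulate ROI time courses
#'
#' Generates one signal curve per ROI:
#' `baseline + polarity * amplitude * response(t) + N(0, noise_sd)`,
#' where `response` is the unit-peak infusion-convolved cascade response of
#' [kinetic_params()]. Deterministic for a fixed `seed`.
#'
#' @param truth A [synthetic_truth()].
#' @param protocol An [infusion_protocol()].
#' @param acq An [acquisition_protocol()]; curves are generated at the raw
#'   (single-average) frame times.
#' @param noise_sd Gaussian noise standard deviation, a.u., >= 0.
#' @param seed Optional integer seed for the noise.
#' @return A [roi_curves()] object.
#' @export
simulate_roi_curves <- function(truth, protocol = infusion_protocol(),
                                acq = phantom_acquisition(), noise_sd = 0,
                                seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  p <- truth$params
  time <- frame_times(acq)
  pol <- unique(p$polarity)
  if (length(pol) > 1L)
    stop("all ROIs in one simulated series must share one polarity")
  sig <- vapply(seq_len(nrow(p)), function(i) {
    resp <- tracer_unit_response(time, protocol, p$n_stages[i],
                                 p$rate_const[i], p$delay[i], p$mix2[i],
                                 p$n_stages2[i], p$rate_const2[i])
    p$baseline[i] + pol * p$amplitude[i] * resp
  }, numeric(length(time)))
  if (noise_sd > 0)
    sig <- sig + matrix(rnorm(length(sig), 0, noise_sd), nrow(sig))
  roi_curves(time, sig, roi_id = p$roi_id, roi_name = p$roi_name,
             n_baseline_frames = acq$n_baseline_frames, polarity = pol)
}

#' Simulate a 4D dynamic volume from ground truth
#'
#' Every voxel carrying label k receives ROI k's noise-free curve plus iid
#' Gaussian voxel noise; background voxels (label 0) carry
#' `background_offset` plus noise.
#'
#' @param truth A [synthetic_truth()].
#' @param label_map A [label_map()] whose nonzero labels all appear in
#'   `truth$params$roi_id`.
#' @param protocol An [infusion_protocol()].
#' @param acq An [acquisition_protocol()].
#' @param noise_sd Per-voxel, per-frame Gaussian noise SD (a.u.).
#' @param seed Optional integer seed.
#' @param background_offset Baseline signal of background voxels (a.u.).
#' @return A [dynamic_series()].
#' @export
simulate_dynamic_volume <- function(truth, label_map,
                                    protocol = infusion_protocol(),
                                    acq = phantom_acquisition(),
                                    noise_sd = 0, seed = NULL,
                                    background_offset = 100) {
  stopifnot(inherits(truth, "synthetic_truth"), inherits(label_map, "label_map"))
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  labs <- sort(unique(as.integer(label_map$labels)))
  labs <- labs[labs != 0L]
  missing <- setdiff(labs, truth$params$roi_id)
  if (length(missing))
    stop("label(s) in map with no kinetic parameters: ",
         paste(missing, collapse = ", "))
  curves <- simulate_roi_curves(truth, protocol, acq, noise_sd = 0)
  if (!is.null(seed)) set.seed(seed)
  nt <- length(curves$time)
  dm <- dim(label_map$labels)
  flat <- matrix(background_offset, prod(dm), nt)
  lab_vec <- as.integer(label_map$labels)
  for (k in labs) {
    cur <- curves$signal[, match(k, curves$roi_id)]
    flat[lab_vec == k, ] <- rep(cur, each = sum(lab_vec == k))
  }
  if (noise_sd > 0)
    flat <- flat + matrix(rnorm(length(flat), 0, noise_sd), nrow(flat))
  dynamic_series(array(flat, c(dm, nt)), time = curves$time,
                 n_baseline_frames = acq$n_baseline_frames,
                 polarity = unique(truth$params$polarity),
                 voxel_size = voxel_size(acq))
}

#' Analysis-resolution phantom acquisition
#'
#' The default grid on which synthetic fixtures are generated: the
#' 6-average reconstruction of the 312 x 25 s water protocol, i.e. 52
#' frames spaced 2.5 min (130 min total) with 2 baseline frames. Voxel
#' geometry is a small phantom grid, not the in-vivo matrix.
#'
#' @param dim Spatial dimensions of the phantom grid.
#' @return An [acquisition_protocol()].
#' @export
phantom_acquisition <- function(dim = c(32, 26, 12)) {
  acquisition_protocol(frame_interval = 150, n_frames = 52,
                       n_baseline_frames = 2, n_average = 1,
                       fov = dim * 0.2, matrix = dim)
}

#' Ellipsoid phantom label map
#'
#' Deterministic layout of `n_roi` spherical ROIs on a regular grid inside
#' a small volume, for volume-synthesis round trips.
#'
#' @param n_roi Number of ROIs (<= 20 for the default dimensions).
#' @param dim Volume dimensions in voxels.
#' @param radius Sphere radius in voxels.
#' @param names Optional ROI names (length `n_roi`).
#' @return A [label_map()].
#' @export
ellipsoid_label_map <- function(n_roi = 20, dim = c(32, 26, 12), radius = 2,
                                names = sprintf("roi_%02d", seq_len(n_roi))) {
  nx_pos <- floor((dim[1] - 2) / (2 * radius + 2))
  ny_pos <- floor((dim[2] - 2) / (2 * radius + 2))
  if (nx_pos * ny_pos < n_roi)
    stop("volume too small for ", n_roi, " ROIs")
  lab <- array(0L, dim)
  cz <- ceiling(dim[3] / 2)
  step <- 2 * radius + 2
  k <- 0L
  for (iy in seq_len(ny_pos)) for (ix in seq_len(nx_pos)) {
    if (k >= n_roi) break
    k <- k + 1L
    cx <- 1 + radius + (ix - 1) * step
    cy <- 1 + radius + (iy - 1) * step
    xr <- max(1, cx - radius):min(dim[1], cx + radius)
    yr <- max(1, cy - radius):min(dim[2], cy + radius)
    zr <- max(1, cz - radius):min(dim[3], cz + radius)
    for (x in xr) for (y in yr) for (z in zr)
      if ((x - cx)^2 + (y - cy)^2 + (z - cz)^2 <= radius^2)
        lab[x, y, z] <- k
  }
  stopifnot(length(names) == n_roi)
  label_map(lab, names = stats::setNames(names, seq_len(n_roi)))
}

#' Synthetic phantoms with planted lag and cluster structure
#'
#' Three canonical ground-truth configurations used throughout the tests:
#'
#' * `"four_cluster"`: 20 ROIs in 4 clusters (sizes 6, 5, 5, 4) built from
#'   four kinetic archetypes chosen to be mutually distinguishable under
#'   optimal lag alignment: a fast infusion-site spike (1 stage,
#'   1.5/min), a slow parenchymal ramp (2 stages, 0.008/min), a delayed
#'   deep-brain bump (8 stages, 0.25/min, 45-min onset delay), and a
#'   biphasic CSF/parenchymal mixture (0.3 spike + 0.7 slow plateau).
#'   Per-ROI lognormal rate jitter (sd 0.06) and uniform amplitude spread
#'   (0.7-1.3 x 100 a.u.) individualize the curves; ROI 1 is the
#'   high-amplitude infusion-site reference.
#' * `"delay_line"`: 3 ROIs sharing one cascade shape (2 stages, 0.12/min)
#'   with onset delays 0, 2.5 and 7.5 min, i.e. planted lags of exactly
#'   0, 1 and 3 frames on the 2.5-min grid.
#' * `"two_cluster"`: 8 ROIs, 4 spikes + 4 slow ramps, the well-separated
#'   two-cluster case used for bootstrap calibration.
#'
#' @param type Phantom type.
#' @param seed Integer seed for the per-ROI jitter draws.
#' @return A [synthetic_truth()].
#' @export
phantom_truth <- function(type = c("four_cluster", "delay_line", "two_cluster"),
                          seed = 1L) {
  type <- match.arg(type)
  set.seed(seed)
  if (type == "delay_line") {
    p <- kinetic_params(n_stages = 2, rate_const = 0.12, amplitude = 100,
                        delay = c(0, 2.5, 7.5), cluster = 1L,
                        roi_name = c("lead", "lag1", "lag3"))
    return(synthetic_truth(p, seed = seed))
  }
  if (type == "two_cluster") {
    jit <- exp(rnorm(8, 0, 0.04))
    p <- kinetic_params(
      n_stages = rep(c(1L, 2L), each = 4),
      rate_const = rep(c(1.5, 0.008), each = 4) * jit,
      amplitude = 100 * runif(8, 0.8, 1.2),
      cluster = rep(1:2, each = 4),
      roi_name = sprintf("%s_%d", rep(c("spike", "ramp"), each = 4),
                         rep(1:4, 2)))
    return(synthetic_truth(p, seed = seed))
  }
  # four_cluster
  g <- rep(1:4, c(6, 5, 5, 4))
  n <- length(g)
  jit <- exp(rnorm(n, 0, 0.06))
  # CSF-adjacent (ventral, periventricular) regions enhance most strongly
  amp <- c(110, 100, 90, 130)[g] * runif(n, 0.9, 1.1)
  base_k <- c(1L, 2L, 8L, 1L)[g]
  base_l <- c(1.5, 0.008, 0.25, 1.5)[g]
  base_d <- c(0, 0, 45, 0)[g]
  mix2 <- c(0, 0, 0, 0.7)[g]
  # reference ROI: no jitter, highest amplitude
  jit[1] <- 1
  amp[1] <- 150
  p <- kinetic_params(
    n_stages = base_k, rate_const = base_l * jit, amplitude = amp,
    delay = base_d, mix2 = mix2, n_stages2 = 1L, rate_const2 = 0.008 * jit,
    cluster = g,
    roi_name = c("cisterna_magna",
                 sprintf("ventral_%d", 1:5),
                 sprintf("parenchyma_%d", 1:5),
                 sprintf("deep_%d", 1:5),
                 sprintf("periventricular_%d", 1:4)))
  synthetic_truth(p, seed = seed)
}

#' Agent archetype parameter presets
#'
#' Qualitative 20-ROI parameter sets emulating the three tracer regimes:
#' `"fast_extensive"` (small labelled water: shallow fast cascades
#' everywhere, polarity -1 on T2-weighted images), `"slow_parenchymal"`
#' (small gadolinium chelate: fast along the ventral surface, deep slow
#' cascades in parenchyma), and `"csf_confined"` (large-polymer agent:
#' near-zero amplitude in parenchymal ROIs).
#'
#' @param agent Preset name.
#' @param seed Integer seed for amplitude jitter.
#' @return A [synthetic_truth()].
#' @export
tracer_presets <- function(agent = c("slow_parenchymal", "fast_extensive",
                                     "csf_confined"), seed = 1L) {
  agent <- match.arg(agent)
  set.seed(seed)
  n <- 20L
  region <- rep(1:4, c(6, 5, 5, 4))  # ventral, mid, deep, ventricular
  nm <- c("cisterna_magna", sprintf("ventral_%d", 1:5),
          sprintf("mid_%d", 1:5), sprintf("deep_%d", 1:5),
          sprintf("ventricle_%d", 1:4))
  amp_jit <- runif(n, 0.8, 1.2)
  p <- switch(agent,
    slow_parenchymal = kinetic_params(
      n_stages = c(1L, 3L, 8L, 4L)[region],
      rate_const = c(0.8, 0.15, 0.1, 0.12)[region],
      amplitude = c(120, 100, 35, 15)[region] * amp_jit,
      polarity = 1L, cluster = region, roi_name = nm),
    fast_extensive = kinetic_params(
      n_stages = c(1L, 1L, 3L, 2L)[region],
      rate_const = c(1.5, 0.6, 0.25, 0.1)[region],
      amplitude = c(60, 55, 45, 40)[region] * amp_jit,
      polarity = -1L, cluster = region, roi_name = nm),
    csf_confined = kinetic_params(
      n_stages = c(1L, 2L, 4L, 1L)[region],
      rate_const = c(1.0, 0.3, 0.2, 0.5)[region],
      amplitude = c(120, 90, 2, 80)[region] * amp_jit,
      polarity = 1L, cluster = region, roi_name = nm))
  synthetic_truth(p, seed = seed)
}
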
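#' Intracisternal infusion protocol
#'
#' Describes a constant-rate intrathecal tracer infusion. The default matches
#' the standard mouse cisterna-magna protocol: 10 uL infused at 1 uL/min
#' (10 min total infusion time), started after the baseline frames.
#'
#' @param rate Infusion rate in uL/min. Must be positive.
#' @param volume Total infused volume in uL. Must be non-negative; a zero
#'   volume describes a sham (no-infusion) run.
#' @param start_time Time at which the infusion starts, in minutes from the
#'   start of the dynamic acquisition.
#' @return An object of class `infusion_protocol` with fields `rate`,
#'   `volume`, `start_time` and the derived `duration = volume / rate` (min).
#' @examples
#' p <- infusion_protocol(rate = 1, volume = 10, start_time = 5)
#' p$duration  # 10 min
#' @export
infusion_protocol <- function(rate = 1, volume = 10, start_time = 5) {
  stopifnot(is.numeric(rate), length(rate) == 1L, is.finite(rate),
            is.numeric(volume), length(volume) == 1L, is.finite(volume),
            is.numeric(start_time), length(start_time) == 1L, is.finite(start_time))
  if (rate <= 0) stop("infusion rate must be > 0 (uL/min)")
  if (volume < 0) stop("infusion volume must be >= 0 (uL)")
  structure(
    list(rate = as.numeric(rate), volume = as.numeric(volume),
         start_time = as.numeric(start_time),
         duration = as.numeric(volume) / as.numeric(rate)),
    class = "infusion_protocol")
}

#' @export
print.infusion_protocol <- function(x, ...) {
  cat(sprintf("Infusion protocol: %g uL at %g uL/min (%g min), start t = %g min\n",
              x$volume, x$rate, x$duration, x$start_time))
  invisible(x)
}

#' Dynamic acquisition protocol
#'
#' Describes the timing and geometry of a dynamic MRI acquisition: frames of
#' fixed duration acquired back to back, the first `n_baseline_frames` of
#' which precede the infusion, optionally combined in groups of `n_average`
#' consecutive frames during reconstruction.
#'
#' Frame times are taken at the frame centre, so frame i is at
#' `(i - 1/2) * frame_interval`.
#'
#' @param frame_interval Duration of one acquired frame, in seconds.
#' @param n_frames Total number of acquired frames.
#' @param n_baseline_frames Number of pre-infusion baseline frames (>= 1).
#' @param n_average Number of consecutive frames combined per reconstructed
#'   time point; trailing frames that do not fill a complete group are
#'   dropped.
#' @param fov Field of view, length-3 numeric, in mm.
#' @param matrix Acquisition matrix, length-3 integer.
#' @return An object of class `acquisition_protocol`.
#' @seealso [frame_times()], [voxel_size()], [temporal_average()]
#' @examples
#' # T2-weighted water (H2-17O) protocol: 312 x 25 s frames = 130 min,
#' # 12 baseline frames, reconstructed with 6 averages -> 2.5 min resolution
#' acq <- acquisition_protocol(frame_interval = 25, n_frames = 312,
#'                             n_baseline_frames = 12, n_average = 6)
#' voxel_size(acq)  # 0.2 mm isotropic
#' @export
acquisition_protocol <- function(frame_interval, n_frames,
                                 n_baseline_frames, n_average = 1,
                                 fov = c(20, 16, 14), matrix = c(100, 80, 70)) {
  stopifnot(is.numeric(frame_interval), frame_interval > 0,
            is.numeric(n_frames), n_frames >= 2,
            is.numeric(n_baseline_frames), n_baseline_frames >= 1,
            is.numeric(n_average), n_average >= 1,
            length(fov) == 3L, all(fov > 0),
            length(matrix) == 3L, all(matrix >= 1))
  if (n_baseline_frames >= n_frames)
    stop("n_baseline_frames must be smaller than n_frames")
  if (n_average > n_frames)
    stop("n_average cannot exceed n_frames")
  structure(
    list(frame_interval = as.numeric(frame_interval),
         n_frames = as.integer(n_frames),
         n_baseline_frames = as.integer(n_baseline_frames),
         n_average = as.integer(n_average),
         fov = as.numeric(fov), matrix = as.integer(matrix)),
    class = "acquisition_protocol")
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  cat(sprintf(paste0("Acquisition: %d frames x %g s (%g min total), ",
                     "%d baseline frame(s), %d-average reconstruction\n"),
              x$n_frames, x$frame_interval,
              x$n_frames * x$frame_interval / 60, x$n_baseline_frames,
              x$n_average))
  vs <- voxel_size(x)
  cat(sprintf("  FOV %s mm / matrix %s -> voxel %s mm\n",
              paste(x$fov, collapse = "x"), paste(x$matrix, collapse = "x"),
              paste(signif(vs, 4), collapse = "x")))
  invisible(x)
}

#' Frame-centre times of an acquisition
#'
#' @param acq An [acquisition_protocol()].
#' @param averaged If `TRUE`, return the time axis after `n_average`
#'   reconstruction (block means of the raw frame times, trailing remainder
#'   dropped).
#' @return Numeric vector of frame times in minutes.
#' @export
frame_times <- function(acq, averaged = FALSE) {
  stopifnot(inherits(acq, "acquisition_protocol"))
  t_raw <- (seq_len(acq$n_frames) - 0.5) * acq$frame_interval / 60
  if (!averaged || acq$n_average == 1L) return(t_raw)
  n_blocks <- acq$n_frames %/% acq$n_average
  idx <- rep(seq_len(n_blocks), each = acq$n_average)
  as.numeric(tapply(t_raw[seq_along(idx)], idx, mean))
}

#' Voxel size of an acquisition
#'
#' Element-wise `fov / matrix`, in mm.
#'
#' @param acq An [acquisition_protocol()].
#' @return Length-3 numeric vector (mm).
#' @export
voxel_size <- function(acq) {
  stopifnot(inherits(acq, "acquisition_protocol"))
  acq$fov / acq$matrix
}

#' Infusion input as a rate function on a time axis
#'
#' Evaluates the constant-rate infusion as a boxcar on the given time axis:
#' `rate` for `start_time <= t < start_time + duration`, zero elsewhere.
#' The trapezoid integral of the result over a sufficiently fine axis
#' approximates the infused volume.
#'
#' @param protocol An [infusion_protocol()].
#' @param time Strictly increasing numeric time axis, in minutes.
#' @return Numeric vector of infusion rates (uL/min), same length as `time`.
#' @export
make_infusion_input <- function(protocol, time) {
  stopifnot(inherits(protocol, "infusion_protocol"), is.numeric(time))
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("time axis must be strictly increasing")
  if (protocol$volume == 0) return(numeric(length(time)))
  t0 <- protocol$start_time
  t1 <- t0 + protocol$duration
  ifelse(time >= t0 & time < t1, protocol$rate, 0)
}

#' Built-in acquisition protocols
#'
#' The two dynamic sequences used for CSF tracer transport in mouse:
#' `"t1_gbca"`, a T1-weighted 3D FLASH acquisition for gadolinium-based
#' agents (5-min frames, one baseline frame, 26 frames = 130 min), and
#' `"t2_water"`, a T2-weighted RARE acquisition for isotopically labelled
#' water (25-s frames, 312 frames = 130 min, 12 baseline frames,
#' reconstructed with 6 averages to 2.5-min resolution).
#'
#' @param name One of `"t1_gbca"`, `"t2_water"`.
#' @return An [acquisition_protocol()].
#' @export
default_acquisition <- function(name = c("t2_water", "t1_gbca")) {
  name <- match.arg(name)
  switch(name,
    t2_water = acquisition_protocol(frame_interval = 25, n_frames = 312,
                                    n_baseline_frames = 12, n_average = 6,
                                    fov = c(20, 16, 14),
                                    matrix = c(100, 80, 70)),
    t1_gbca = acquisition_protocol(frame_interval = 300, n_frames = 26,
                                   n_baseline_frames = 1, n_average = 1,
                                   fov = c(20, 16, 14),
                                   matrix = c(100, 80, 70)))
}
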
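#' Generate an auditory oddball event design
#'
#' Builds a stream of \code{n_stimuli} tones at a fixed onset-to-onset
#' interstimulus interval, of which exactly \code{round(n_stimuli *
#' p_target)} are rare deviant targets, pseudorandomly interleaved among
#' standards under the constraint that no two targets are adjacent. Target
#' positions are drawn uniformly among all non-adjacent arrangements (via
#' the standard gap bijection between k non-adjacent picks from n slots and
#' k unconstrained picks from n - k + 1).
#'
#' @param n_stimuli total number of stimuli.
#' @param p_target fraction of targets in [0, 1].
#' @param isi onset-to-onset interstimulus interval in seconds (> 0).
#' @param seed optional integer seed.
#' @return A data.frame of class \code{event_design} with BIDS-events
#'   columns \code{onset} (seconds, \code{(k-1) * isi}), \code{duration}
#'   (stimulus duration, 0.1 s) and \code{trial_type} ("standard"/"target"),
#'   with attributes \code{isi}, \code{n_stimuli}, \code{p_target} and
#'   \code{total_duration} (\code{n_stimuli * isi}).
#' @export
generate_event_design <- function(n_stimuli = 270, p_target = 0.2,
                                  isi = 2.0, seed = NULL) {
  if (p_target < 0 || p_target > 1) stop("'p_target' must be in [0, 1]")
  if (isi <= 0) stop("'isi' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  k <- round(n_stimuli * p_target)
  if (k > 0 && k > floor((n_stimuli + 1) / 2))
    stop("adjacency constraint infeasible: too many targets (p_target > 0.5)")
  type <- rep("standard", n_stimuli)
  if (k > 0) {
    picks <- sort(sample.int(n_stimuli - k + 1L, k))
    pos <- picks + 0:(k - 1L)   # gap bijection: guarantees no adjacency
    type[pos] <- "target"
  }
  out <- data.frame(onset = (seq_len(n_stimuli) - 1) * isi,
                    duration = rep(0.1, n_stimuli),
                    trial_type = type, stringsAsFactors = FALSE)
  attr(out, "isi") <- isi
  attr(out, "n_stimuli") <- n_stimuli
  attr(out, "p_target") <- p_target
  attr(out, "total_duration") <- n_stimuli * isi
  class(out) <- c("event_design", "data.frame")
  out
}

#' Write / read an event design as a BIDS-style events TSV
#' @param design an \code{event_design} data.frame.
#' @param path file path.
#' @return \code{write_events_tsv} returns \code{path} invisibly;
#'   \code{read_events_tsv} returns an \code{event_design} (attributes
#'   reconstructed from the onsets).
#' @export
write_events_tsv <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("onset", "duration", "trial_type") %in% names(out)))
  n <- nrow(out)
  isi <- if (n > 1) stats::median(diff(out$onset)) else NA_real_
  attr(out, "isi") <- isi
  attr(out, "n_stimuli") <- n
  attr(out, "p_target") <- mean(out$trial_type == "target")
  attr(out, "total_duration") <- if (is.na(isi)) max(out$onset) else n * isi
  class(out) <- c("event_design", "data.frame")
  out
}

#' Generate cardiac and respiratory traces
#'
#' Quasi-periodic waveforms: beat/breath times follow the nominal rate with
#' multiplicative Gaussian jitter on each interval, and the waveform is a
#' sharp von Mises-shaped pulse (cardiac) or a sinusoid (respiratory) of the
#' accumulated cycle phase, so peak times are recoverable by peak detection.
#' The first cycle peak sits half a period into the recording.
#'
#' @param duration recording length in seconds (> 0).
#' @param cardiac_hz,resp_hz nominal rates in Hz (> 0).
#' @param fs sampling rate in Hz (must exceed twice the dominant frequency).
#' @param rate_jitter SD of the multiplicative interval jitter (0 = strictly
#'   periodic).
#' @param seed optional integer seed.
#' @return A list of class \code{physio_trace}: \code{cardiac} and
#'   \code{resp}, each with \code{signal}, \code{fs}, \code{peak_times}
#'   (ground-truth cycle peaks), plus \code{duration}.
#' @export
generate_physio <- function(duration, cardiac_hz = 1.0, resp_hz = 0.25,
                            fs = 100, rate_jitter = 0.05, seed = NULL) {
  if (duration <= 0) stop("'duration' must be > 0")
  if (cardiac_hz <= 0 || resp_hz <= 0) stop("rates must be > 0")
  if (fs <= 2 * max(cardiac_hz, resp_hz))
    stop("'fs' must exceed twice the dominant frequency")
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  one <- function(hz, shape) {
    period <- 1 / hz
    peaks <- numeric(0)
    tp <- period / 2
    while (tp < duration) {
      peaks <- c(peaks, tp)
      jit <- if (rate_jitter > 0) max(0.2, 1 + rate_jitter * stats::rnorm(1)) else 1
      tp <- tp + period * jit
    }
    # accumulated phase: 0 at each peak, linear in between
    phase <- phase_from_peaks(peaks, t)
    sig <- if (shape == "pulse") exp(4 * (cos(phase) - 1)) else sin(phase + pi / 2)
    list(signal = sig, fs = fs, peak_times = peaks)
  }
  structure(list(cardiac = one(cardiac_hz, "pulse"),
                 resp = one(resp_hz, "sine"),
                 duration = duration),
            class = "physio_trace")
}

# Unwrapped-then-wrapped cycle phase at times `t` given peak times:
# 2*pi*k at peak k (0-based), linear in between, linearly extrapolated
# outside with the first/last observed period.
phase_from_peaks <- function(peaks, t) {
  K <- length(peaks)
  if (K < 2) stop("need at least 2 detected peaks to define a phase")
  u <- stats::approx(peaks, 2 * pi * (seq_len(K) - 1), xout = t,
                     rule = 2)$y
  before <- t < peaks[1]
  after <- t > peaks[K]
  u[before] <- 2 * pi * (t[before] - peaks[1]) / (peaks[2] - peaks[1])
  u[after] <- 2 * pi * (K - 1) +
    2 * pi * (t[after] - peaks[K]) / (peaks[K] - peaks[K - 1])
  u %% (2 * pi)
}

#' Detect peaks in a quasi-periodic trace
#'
#' Local maxima above the signal midrange, with a minimum separation of
#' half the nominal period (the larger peak wins within a conflict).
#'
#' @param signal sampled waveform.
#' @param fs sampling rate in Hz.
#' @param nominal_hz nominal cycle rate used for the separation constraint.
#' @return Numeric vector of peak times in seconds.
#' @export
detect_peaks <- function(signal, fs, nominal_hz) {
  n <- length(signal)
  thr <- (max(signal) + min(signal)) / 2
  cand <- which(signal > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[signal[cand] > signal[cand - 1] & signal[cand] >= signal[cand + 1]]
  if (length(cand) == 0) return(numeric(0))
  min_gap <- round(fs / nominal_hz / 2)
  keep <- integer(0)
  for (i in cand[order(-signal[cand])]) {
    if (all(abs(i - keep) >= min_gap)) keep <- c(keep, i)
  }
  sort((keep - 1) / fs)
}

#' Generate a head-motion trace
#'
#' Smooth bounded random-walk realignment parameters (3 translations in mm,
#' 3 rotations in degrees) relative to the first volume, scaled so that the
#' maximum excursion stays below the requested bound.
#'
#' @param n_volumes number of BOLD volumes (one row each).
#' @param max_trans_mm,max_rot_deg bounds on the absolute excursion.
#' @param seed optional integer seed.
#' @return A numeric matrix \code{n_volumes x 6} with columns
#'   \code{trans_x/y/z}, \code{rot_pitch/roll/yaw}; first row is zero.
#' @export
generate_motion <- function(n_volumes, max_trans_mm = 1.0, max_rot_deg = 1.0,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  one <- function(bound) {
    w <- cumsum(stats::rnorm(n_volumes))
    w <- w - w[1]
    m <- max(abs(w))
    if (m > 0) w <- w * (bound * stats::runif(1, 0.3, 0.9) / m)
    w
  }
  out <- cbind(trans_x = one(max_trans_mm), trans_y = one(max_trans_mm),
               trans_z = one(max_trans_mm), rot_pitch = one(max_rot_deg),
               rot_roll = one(max_rot_deg), rot_yaw = one(max_rot_deg))
  out
}

#' Functional-grid voxels covered by the LC
#'
#' Maps the ground-truth LC centerlines (world mm) onto a functional grid:
#' a functional voxel belongs to a side if its in-plane footprint overlaps
#' the cylinder cross-section (nearest point of the voxel rectangle within
#' \code{radius_mm} of that side's axis) and its slice overlaps the
#' cylinder's z extent. Overlap (rather than center-in-cylinder) membership
#' guarantees that every structural-space point of the cylinder maps into a
#' member voxel, so nearest-neighbor ROI resampling stays inside the
#' planted support.
#'
#' @param truth ground truth from \code{\link{generate_lc_volume}}.
#' @param dim functional grid dimensions.
#' @param voxel_size functional voxel size in mm.
#' @return Named list (left/right) of integer voxel matrices (x, y, z).
#' @export
functional_lc_voxels <- function(truth, dim, voxel_size) {
  vs <- rep(as.numeric(voxel_size), length.out = 3)
  out <- list()
  for (side in names(truth$sides)) {
    cl <- truth$sides[[side]]$centerline_mm
    ax <- cl[1, "x"]; ay <- cl[1, "y"]
    zr <- range(cl[, "z"])
    xs <- (seq_len(dim[1]) - 0.5) * vs[1]
    ys <- (seq_len(dim[2]) - 0.5) * vs[2]
    zs <- (seq_len(dim[3]) - 0.5) * vs[3]
    dx <- pmax(0, abs(xs - ax) - vs[1] / 2)
    dy <- pmax(0, abs(ys - ay) - vs[2] / 2)
    inpl <- which(outer(dx^2, dy^2, `+`) <= truth$radius_mm^2,
                  arr.ind = TRUE)
    if (nrow(inpl) == 0)
      inpl <- cbind(min(max(round(ax / vs[1] + 0.5), 1), dim[1]),
                    min(max(round(ay / vs[2] + 0.5), 1), dim[2]))
    zi <- which(zs >= zr[1] - vs[3] / 2 & zs <= zr[2] + vs[3] / 2)
    zi <- zi[zi >= 1 & zi <= dim[3]]
    vox <- cbind(inpl[rep(seq_len(nrow(inpl)), length(zi)), , drop = FALSE],
                 rep(zi, each = nrow(inpl)))
    colnames(vox) <- c("x", "y", "z")
    out[[side]] <- vox
  }
  out
}

#' Generate a 4D BOLD series with a known LC response
#'
#' LC voxels carry \code{amplitude} times the HRF-convolved target regressor
#' (peak-normalized, so the first-level GLM coefficient on that regressor
#' equals \code{amplitude} in signal units; with the default baseline of 100
#' this is percent signal change) on top of a constant baseline. All voxels
#' receive, when supplied, a linear drift, motion-coupled components (random
#' per-voxel weights on the 6 realignment parameters), cardiac/respiratory
#' phase-coupled components, and white Gaussian noise.
#'
#' @param design an \code{event_design}.
#' @param truth structural ground truth (for LC voxel placement).
#' @param amplitude response amplitude in signal units (percent signal
#'   change of the 100-unit baseline).
#' @param motion optional motion matrix from \code{\link{generate_motion}}.
#' @param physio optional \code{physio_trace}.
#' @param tr repetition time in seconds.
#' @param noise_sd white-noise SD.
#' @param dim functional grid dimensions.
#' @param voxel_size functional voxel size in mm.
#' @param baseline constant baseline intensity.
#' @param drift_range linear drift amplitude range (units over the run);
#'   0 disables drift.
#' @param motion_scale,physio_scale coupling strengths.
#' @param seed optional integer seed.
#' @return A list with \code{bold} (a \code{bold4d}), \code{lc_voxels}
#'   (per-side functional voxel sets) and \code{task_regressor} (the exact
#'   regressor planted in LC voxels).
#' @export
generate_bold <- function(design, truth, amplitude, motion = NULL,
                          physio = NULL, tr = 2.34, noise_sd = 1,
                          dim = c(20L, 20L, 20L), voxel_size = 1.4,
                          baseline = 100, drift_range = 0,
                          motion_scale = 0, physio_scale = 0, seed = NULL) {
  if (nrow(design) == 0) stop("'design' has no events")
  if (!is.finite(amplitude)) stop("'amplitude' must be finite")
  if (tr <= 0) stop("'tr' must be > 0")
  if (!is.null(seed)) set.seed(seed)
  total <- attr(design, "total_duration")
  nv <- as.integer(ceiling(total / tr))
  vt <- (seq_len(nv) - 1) * tr
  x_task <- task_regressor(design, n_volumes = nv, tr = tr)
  V <- prod(dim)
  Y <- matrix(baseline, nrow = nv, ncol = V)
  if (drift_range > 0) {
    slope <- stats::runif(V, -drift_range, drift_range)
    Y <- Y + outer(seq_len(nv) / nv, slope)
  }
  if (!is.null(motion) && motion_scale > 0) {
    stopifnot(nrow(motion) == nv)
    W <- matrix(stats::rnorm(6 * V, 0, motion_scale), nrow = 6)
    Y <- Y + motion %*% W
  }
  if (!is.null(physio) && physio_scale > 0) {
    cph <- phase_from_peaks(physio$cardiac$peak_times, vt)
    rph <- phase_from_peaks(physio$resp$peak_times, vt)
    P <- cbind(sin(cph), cos(cph), sin(rph), cos(rph))
    Wp <- matrix(stats::rnorm(4 * V, 0, physio_scale), nrow = 4)
    Y <- Y + P %*% Wp
  }
  lcv <- functional_lc_voxels(truth, dim, voxel_size)
  lin <- c(vox_key(lcv$left, dim), vox_key(lcv$right, dim))
  Y[, unique(lin)] <- Y[, unique(lin), drop = FALSE] + amplitude * x_task
  if (noise_sd > 0)
    Y <- Y + matrix(stats::rnorm(nv * V, 0, noise_sd), nrow = nv)
  arr <- array(t(Y), dim = c(dim, nv))
  list(bold = bold4d(arr, voxel_size, tr), lc_voxels = lcv,
       task_regressor = x_task)
}
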
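#' Canonical double-gamma hemodynamic response function
#'
#' The conventional canonical HRF: a gamma-density response peaking near
#' 5 s minus a later gamma undershoot (peak delay 6 s, undershoot delay
#' 16 s, unit dispersions, undershoot ratio 1/6), sampled on [0, 32] s at
#' resolution \code{dt} and normalized to a unit peak. A unit-peak kernel
#' makes the task-regressor coefficient interpretable as the peak response
#' amplitude.
#'
#' @param dt sampling interval in seconds (> 0).
#' @param duration kernel support in seconds (default 32).
#' @return Numeric vector of kernel values at \code{seq(0, duration, by=dt)}.
#' @export
canonical_hrf <- function(dt, duration = 32) {
  if (dt <= 0) stop("'dt' must be > 0")
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

#' Target-event task regressor
#'
#' Convolves the target-onset indicator with the canonical HRF on a fine
#' microtime grid (\code{tr / oversample}) and samples the result at the
#' volume acquisition times \code{(v - 1) * tr}. A single event at t = 0
#' therefore yields the HRF itself sampled at the volume times.
#'
#' @param design an \code{event_design}.
#' @param n_volumes number of BOLD volumes.
#' @param tr repetition time in seconds.
#' @param oversample microtime bins per TR (default 16).
#' @param condition trial type modeled as the event of interest.
#' @return Numeric vector of length \code{n_volumes}.
#' @export
task_regressor <- function(design, n_volumes, tr, oversample = 16L,
                           condition = "target") {
  onsets <- design$onset[design$trial_type == condition]
  if (length(onsets) == 0) return(numeric(n_volumes))
  dt <- tr / oversample
  n_fine <- n_volumes * oversample
  sticks <- numeric(n_fine + 1L)
  bins <- round(onsets / dt) + 1L
  bins <- bins[bins >= 1L & bins <= n_fine]
  for (b in bins) sticks[b] <- sticks[b] + 1
  h <- canonical_hrf(dt)
  conv <- stats::convolve(sticks, rev(h), type = "open")[seq_len(n_fine)]
  conv[seq(1L, by = oversample, length.out = n_volumes)]
}

#' Discrete cosine high-pass basis
#'
#' The drift-removal basis used alongside event-related regressors: cosine
#' functions at all frequencies below \code{1 / cutoff} Hz, i.e.
#' \code{floor(2 * n * tr / cutoff)} columns
#' \code{cos(pi * k * (2v - 1) / (2n))}, k = 1, ..., K.
#'
#' @param n_volumes number of volumes.
#' @param tr repetition time in seconds.
#' @param cutoff high-pass cutoff period in seconds (default 128).
#' @return Matrix with \code{n_volumes} rows and K columns (possibly 0).
#' @export
dct_highpass_basis <- function(n_volumes, tr, cutoff = 128) {
  K <- floor(2 * n_volumes * tr / cutoff)
  v <- seq_len(n_volumes)
  if (K < 1) return(matrix(numeric(0), nrow = n_volumes, ncol = 0))
  out <- sapply(seq_len(K), function(k) cos(pi * k * (2 * v - 1) / (2 * n_volumes)))
  colnames(out) <- paste0("dct_", seq_len(K))
  out
}

#' Summarize a motion trace
#'
#' The overall displacement per realignment parameter is the discrete
#' integral of its absolute value over the run, i.e. the sum over volumes
#' of the absolute parameter (positions are relative to the first volume).
#' Frame-to-frame increments are also summarized for QC.
#'
#' @param trace motion matrix (volumes x 6: translations mm, rotations deg).
#' @return A list: \code{overall} (named per-parameter sums),
#'   \code{mean_translation}, \code{mean_rotation} (means of the three
#'   per-parameter summaries), \code{overall_increment} (sum of absolute
#'   frame-to-frame differences), \code{max_abs} per parameter.
#' @export
summarize_motion <- function(trace) {
  trace <- as.matrix(trace)
  if (nrow(trace) == 0) stop("empty motion trace")
  if (ncol(trace) != 6L) stop("motion trace must have 6 parameters")
  overall <- colSums(abs(trace))
  inc <- if (nrow(trace) > 1) colSums(abs(apply(trace, 2, diff))) else overall * 0
  list(overall = overall,
       mean_translation = mean(overall[1:3]),
       mean_rotation = mean(overall[4:6]),
       overall_increment = inc,
       max_abs = apply(abs(trace), 2, max))
}

#' Motion-based subject exclusion
#'
#' Keeps subjects whose maximal absolute per-volume translation is strictly
#' below \code{max_trans_mm} on every axis and rotation strictly below
#' \code{max_rot_deg}; a subject exactly at the bound is excluded.
#'
#' @param traces named list of motion matrices.
#' @param max_trans_mm,max_rot_deg exclusion limits (default 3 mm / 3 deg).
#' @return Character vector of kept subject names.
#' @export
exclude_by_motion <- function(traces, max_trans_mm = 3, max_rot_deg = 3) {
  keep <- vapply(traces, function(tr) {
    mx <- apply(abs(as.matrix(tr)), 2, max)
    all(mx[1:3] < max_trans_mm) && all(mx[4:6] < max_rot_deg)
  }, logical(1))
  names(traces)[keep]
}

#' Cardiac/respiratory phase at volume times
#'
#' Detects cycle peaks in the recorded trace and assigns each volume the
#' elapsed cycle fraction times 2*pi between the surrounding peaks
#' (linearly extrapolated with the first/last period outside the peak
#' range). The same cycle-fraction rule is used for both modalities.
#'
#' @param physio a \code{physio_trace}.
#' @param volume_times acquisition times in seconds.
#' @param use_truth_peaks if TRUE use the generator's ground-truth peak
#'   times instead of detecting them (for oracle tests).
#' @return A list with \code{cardiac} and \code{resp} phase vectors in
#'   [0, 2*pi).
#' @export
compute_phase <- function(physio, volume_times, use_truth_peaks = FALSE) {
  get_peaks <- function(ch, hz_guess) {
    if (use_truth_peaks) return(ch$peak_times)
    p <- detect_peaks(ch$signal, ch$fs, hz_guess)
    if (length(p) < 2) stop("fewer than 2 peaks detected")
    p
  }
  card_hz <- length(physio$cardiac$peak_times) / physio$duration
  resp_hz <- length(physio$resp$peak_times) / physio$duration
  list(cardiac = phase_from_peaks(get_peaks(physio$cardiac, card_hz),
                                  volume_times),
       resp = phase_from_peaks(get_peaks(physio$resp, resp_hz),
                               volume_times))
}

#' Fourier expansion of a phase signal
#'
#' Nuisance regressors \code{sin(k*phase)}, \code{cos(k*phase)} for
#' k = 1, ..., order, the low-order Fourier basis conventionally used to
#' model cardiac and respiratory signal fluctuations.
#'
#' @param phase per-volume phase in radians.
#' @param order expansion order (>= 1).
#' @param prefix column-name prefix.
#' @return Matrix with \code{2 * order} columns, values in [-1, 1].
#' @export
fourier_expansion <- function(phase, order, prefix = "phys") {
  if (order < 1) stop("'order' must be >= 1")
  cols <- lapply(seq_len(order), function(k)
    cbind(sin(k * phase), cos(k * phase)))
  out <- do.call(cbind, cols)
  colnames(out) <- as.vector(vapply(seq_len(order), function(k)
    paste0(prefix, c("_sin", "_cos"), k), character(2)))
  out
}

#' Build a nuisance regressor set
#'
#' Six realignment parameters plus Fourier expansions of cardiac phase
#' (order 3) and respiratory phase (order 4); physiological columns are
#' omitted when no physio trace is available (the design loses columns,
#' never rows).
#'
#' @param motion motion matrix (volumes x 6) or NULL.
#' @param physio a \code{physio_trace} or NULL.
#' @param volume_times acquisition times in seconds.
#' @param cardiac_order,resp_order Fourier orders (defaults 3 and 4).
#' @param use_truth_peaks see \code{\link{compute_phase}}.
#' @return Numeric matrix with named columns (possibly 0 columns).
#' @export
build_nuisance <- function(motion = NULL, physio = NULL, volume_times,
                           cardiac_order = 3L, resp_order = 4L,
                           use_truth_peaks = FALSE) {
  parts <- list()
  if (!is.null(motion)) {
    m <- as.matrix(motion)
    stopifnot(nrow(m) == length(volume_times))
    colnames(m) <- c("trans_x", "trans_y", "trans_z",
                     "rot_pitch", "rot_roll", "rot_yaw")
    parts$motion <- m
  }
  if (!is.null(physio)) {
    ph <- compute_phase(physio, volume_times, use_truth_peaks)
    parts$cardiac <- fourier_expansion(ph$cardiac, cardiac_order, "card")
    parts$resp <- fourier_expansion(ph$resp, resp_order, "resp")
  }
  if (length(parts) == 0)
    return(matrix(numeric(0), nrow = length(volume_times), ncol = 0))
  do.call(cbind, parts)
}

#' Assemble the first-level design matrix
#'
#' Task regressor (HRF-convolved target onsets) first, then nuisance
#' columns, then the drift model, then the intercept. The drift model is a
#' first-order polynomial (centered linear ramp) plus the discrete-cosine
#' high-pass set below \code{1 / hp_cutoff} Hz, so linear scanner drift is
#' absorbed exactly and slow oscillatory drift up to the cutoff is
#' projected out.
#'
#' @param design an \code{event_design}.
#' @param nuisance nuisance matrix from \code{\link{build_nuisance}} (or
#'   NULL).
#' @param n_volumes,tr run geometry.
#' @param hp_cutoff high-pass cutoff in seconds (default 128; NULL
#'   disables).
#' @return A matrix of class \code{design_matrix} with attribute
#'   \code{task_col = 1}; rank deficiency is flagged with an error.
#' @export
build_design <- function(design, nuisance = NULL, n_volumes, tr,
                         hp_cutoff = 128) {
  x_task <- task_regressor(design, n_volumes, tr)
  X <- cbind(task = x_task)
  if (!is.null(nuisance) && ncol(nuisance) > 0) {
    stopifnot(nrow(nuisance) == n_volumes)
    X <- cbind(X, nuisance)
  }
  if (!is.null(hp_cutoff)) {
    v <- seq_len(n_volumes)
    X <- cbind(X, linear = v - mean(v),
               dct_highpass_basis(n_volumes, tr, hp_cutoff))
  }
  X <- cbind(X, intercept = 1)
  # an identically-zero task column (no events) is a legitimate null design;
  # rank deficiency is flagged among the informative columns
  nonzero <- colSums(X != 0) > 0
  if (qr(X[, nonzero, drop = FALSE])$rank < sum(nonzero))
    stop("design matrix is rank deficient")
  attr(X, "task_col") <- 1L
  class(X) <- c("design_matrix", class(X))
  X
}

#' Fit a voxelwise GLM
#'
#' Ordinary least squares at every voxel with a shared design matrix;
#' returns coefficient maps, the residual variance, the t-map for the task
#' column and the residual degrees of freedom \code{n - rank(X)}.
#'
#' @param bold a \code{bold4d} (or a volumes x voxels matrix with
#'   \code{dim_space} supplied).
#' @param X design matrix from \code{\link{build_design}}.
#' @param dim_space spatial dimensions when \code{bold} is a matrix.
#' @return A list of class \code{glm_fit}: \code{beta} (voxels x columns),
#'   \code{sigma2}, \code{tmap} (3D array for the task column),
#'   \code{beta_map} (3D array for the task column), \code{df},
#'   \code{columns}, \code{dim_space}.
#' @export
fit_glm <- function(bold, X, dim_space = NULL) {
  if (inherits(bold, "bold4d")) {
    d <- dim(bold$data)
    dim_space <- d[1:3]
    Y <- matrix(bold$data, nrow = prod(d[1:3]), ncol = d[4])
    Y <- t(Y)
  } else {
    Y <- as.matrix(bold)
    if (is.null(dim_space)) stop("'dim_space' required for matrix input")
  }
  n <- nrow(Y)
  stopifnot(nrow(X) == n)
  qrX <- qr(X)
  p <- qrX$rank
  if (p < ncol(X)) stop("design matrix is rank deficient")
  df <- n - p
  if (df <= 0) stop("no residual degrees of freedom")
  beta <- qr.coef(qrX, Y)                       # columns x voxels
  res <- Y - X %*% beta
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  tc <- attr(X, "task_col")
  if (is.null(tc)) tc <- 1L
  se <- sqrt(sigma2 * XtXinv[tc, tc])
  tvals <- ifelse(se > 0, beta[tc, ] / se,
                  ifelse(beta[tc, ] == 0, 0, sign(beta[tc, ]) * Inf))
  out <- list(beta = t(beta), sigma2 = sigma2,
              tmap = array(tvals, dim = dim_space),
              beta_map = array(beta[tc, ], dim = dim_space),
              df = df, columns = colnames(X), task_col = tc,
              dim_space = dim_space)
  class(out) <- "glm_fit"
  out
}

#' Extract the LC ROI activity estimate
#'
#' Resamples the skeletonized LC mask (on the upsampled structural grid)
#' into the functional grid by nearest neighbor — each skeleton voxel
#' center, in world mm, maps to the functional voxel containing it — and
#' averages the task-column coefficient over the hit voxels. Per-side and
#' bilateral estimates are returned.
#'
#' @param fit a \code{glm_fit}.
#' @param skeletons list with \code{left}/\code{right} \code{skeleton_lc}
#'   tables.
#' @param struct_voxel_size voxel size of the (upsampled) structural grid.
#' @param func_voxel_size voxel size of the functional grid.
#' @return List: \code{left}, \code{right}, \code{bilateral} mean betas and
#'   \code{voxels} (per-side functional voxel matrices).
#' @export
extract_roi_beta <- function(fit, skeletons, struct_voxel_size,
                             func_voxel_size) {
  svs <- rep(as.numeric(struct_voxel_size), length.out = 3)
  fvs <- rep(as.numeric(func_voxel_size), length.out = 3)
  d <- fit$dim_space
  resample_side <- function(skel) {
    mm <- cbind((skel$x - 0.5) * svs[1], (skel$y - 0.5) * svs[2],
                (skel$z - 0.5) * svs[3])
    vox <- cbind(floor(mm[, 1] / fvs[1]) + 1L, floor(mm[, 2] / fvs[2]) + 1L,
                 floor(mm[, 3] / fvs[3]) + 1L)
    ok <- vox[, 1] >= 1 & vox[, 1] <= d[1] & vox[, 2] >= 1 &
      vox[, 2] <= d[2] & vox[, 3] >= 1 & vox[, 3] <= d[3]
    vox <- unique(vox[ok, , drop = FALSE])
    if (nrow(vox) == 0) stop("resampled LC mask is empty in functional space")
    colnames(vox) <- c("x", "y", "z")
    vox
  }
  vl <- resample_side(skeletons$left)
  vr <- resample_side(skeletons$right)
  bl <- mean(fit$beta_map[vl])
  br <- mean(fit$beta_map[vr])
  list(left = bl, right = br, bilateral = (bl + br) / 2,
       voxels = list(left = vl, right = vr))
}

#' Second-level (group) GLM
#'
#' One-sample group analysis of per-subject coefficient maps with
#' mean-centered covariates (age, sex, BMI by default): per voxel,
#' \code{beta_subject ~ 1 + covariates}; the group t-map tests the
#' intercept (the covariate-adjusted group mean response). With N subjects
#' and 3 covariates the residual degrees of freedom are N - 4.
#'
#' @param beta_maps N x V matrix (or list of 3D arrays) of subject-level
#'   task coefficients.
#' @param covariates data.frame with numeric/dichotomous columns (sex is
#'   coded 0/1 internally).
#' @param dim_space spatial dimensions of the maps.
#' @return A \code{glm_fit}-like list with group \code{tmap},
#'   \code{beta_map} (group mean), \code{df}.
#' @export
second_level <- function(beta_maps, covariates = NULL, dim_space = NULL) {
  if (is.list(beta_maps) && !is.matrix(beta_maps)) {
    if (is.null(dim_space)) dim_space <- dim(beta_maps[[1]])
    beta_maps <- do.call(rbind, lapply(beta_maps, as.vector))
  }
  N <- nrow(beta_maps)
  X <- matrix(1, nrow = N, ncol = 1, dimnames = list(NULL, "group_mean"))
  if (!is.null(covariates) && ncol(covariates) > 0) {
    C <- sapply(covariates, function(col) {
      if (!is.numeric(col)) col <- as.numeric(factor(col)) - 1
      col - mean(col)
    })
    X <- cbind(X, C)
  }
  if (N < ncol(X) + 2) stop("too few subjects for the second-level model")
  if (is.null(dim_space)) dim_space <- c(ncol(beta_maps), 1L, 1L)
  fit <- fit_glm(beta_maps, structure(X, task_col = 1L),
                 dim_space = dim_space)
  fit
}

# 26-connectivity connected components over a logical 3D array.
label_components <- function(mask3d) {
  d <- dim(mask3d)
  lab <- array(0L, dim = d)
  idx <- which(mask3d)
  if (length(idx) == 0) return(list(labels = lab, n = 0L))
  coords <- arrayInd(idx, d)
  inmask <- array(FALSE, d); inmask[idx] <- TRUE
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  cur <- 0L
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue) > 0) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cv <- arrayInd(v, d)
      nb <- sweep(offs, 2, as.integer(cv), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      ni <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      fresh <- ni[inmask[ni] & lab[ni] == 0L]
      if (length(fresh)) {
        lab[fresh] <- cur
        queue <- c(queue, fresh)
      }
    }
  }
  list(labels = lab, n = cur)
}

#' Report supra-threshold clusters
#'
#' Thresholds a t-map, groups surviving voxels into 26-connected
#' components, drops components smaller than \code{min_size}, and reports
#' one row per cluster peak, sorted by peak t descending.
#'
#' @param tmap 3D t-statistic array.
#' @param threshold t threshold (voxels strictly above survive).
#' @param min_size minimum cluster extent in voxels (default 20).
#' @param region label attached to every row.
#' @return A data.frame: \code{region}, \code{cluster_size}, \code{t},
#'   \code{peak_x/y/z}.
#' @export
cluster_report <- function(tmap, threshold, min_size = 20L, region = "LC") {
  stopifnot(is.finite(threshold))
  comp <- label_components(tmap > threshold)
  out <- data.frame(region = character(0), cluster_size = integer(0),
                    t = numeric(0), peak_x = integer(0), peak_y = integer(0),
                    peak_z = integer(0), stringsAsFactors = FALSE)
  if (comp$n == 0L) return(out)
  for (k in seq_len(comp$n)) {
    vox <- which(comp$labels == k)
    if (length(vox) < min_size) next
    tv <- tmap[vox]
    pk <- arrayInd(vox[which.max(tv)], dim(tmap))
    out <- rbind(out, data.frame(region = region,
                                 cluster_size = length(vox),
                                 t = max(tv), peak_x = pk[1], peak_y = pk[2],
                                 peak_z = pk[3], stringsAsFactors = FALSE))
  }
  out[order(-out$t), , drop = FALSE]
}

#' Small-volume correction within an LC template
#'
#' Voxel-level family-wise-error control restricted to a predefined search
#' mask, by Bonferroni over the mask voxels (a deliberately conservative
#' replacement for random-field-theory correction; an optional
#' permutation-style max-t alternative is available via
#' \code{method = "maxt"} given a subject-level data matrix). Significant
#' voxels are grouped into 26-connected clusters and reported peak-first.
#'
#' @param fit a group \code{glm_fit} (needs \code{tmap} and \code{df}).
#' @param mask logical 3D array, or a probabilistic template
#'   \code{volume3d} (support taken as values > \code{template_thresh}).
#' @param alpha corrected significance level (default 0.05).
#' @param template_thresh support threshold for probabilistic templates.
#' @param region label for the report.
#' @return A data.frame: \code{region}, \code{cluster_size}, \code{t},
#'   \code{p_fwe}, \code{peak_x/y/z}, sorted by t descending; zero rows if
#'   nothing survives. Attribute \code{n_search_voxels} records the
#'   correction denominator.
#' @export
small_volume_correct <- function(fit, mask, alpha = 0.05,
                                 template_thresh = 0, region = "LC") {
  if (inherits(mask, "volume3d")) mask <- mask$grid > template_thresh
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  mask <- array(as.logical(mask), dim = dim(mask))
  m <- sum(mask)
  if (m == 0) stop("empty search mask")
  p_unc <- stats::pt(fit$tmap, df = fit$df, lower.tail = FALSE)
  p_fwe <- pmin(1, p_unc * m)
  sig <- mask & (p_fwe < alpha)
  out <- data.frame(region = character(0), cluster_size = integer(0),
                    t = numeric(0), p_fwe = numeric(0), peak_x = integer(0),
                    peak_y = integer(0), peak_z = integer(0),
                    stringsAsFactors = FALSE)
  comp <- label_components(sig)
  if (comp$n > 0L) {
    for (k in seq_len(comp$n)) {
      vox <- which(comp$labels == k)
      tv <- fit$tmap[vox]
      pk <- arrayInd(vox[which.max(tv)], dim(fit$tmap))
      out <- rbind(out, data.frame(region = region,
                                   cluster_size = length(vox), t = max(tv),
                                   p_fwe = min(p_fwe[vox]),
                                   peak_x = pk[1], peak_y = pk[2],
                                   peak_z = pk[3], stringsAsFactors = FALSE))
    }
    out <- out[order(-out$t), , drop = FALSE]
  }
  attr(out, "n_search_voxels") <- m
  out
}
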
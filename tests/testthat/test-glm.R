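test_that("motion summaries are sums of absolute parameter values", {
  z <- matrix(0, 5, 6)
  s0 <- summarize_motion(z)
  expect_true(all(s0$overall == 0) && s0$mean_translation == 0)
  tr <- matrix(0, 3, 6)
  tr[, 1] <- c(0.1, -0.2, 0.3)
  expect_equal(unname(summarize_motion(tr)$overall[1]), 0.6)
  set.seed(2)
  rnd <- matrix(rnorm(60), 10, 6)
  s <- summarize_motion(rnd)
  expect_equal(unname(s$overall), colSums(abs(rnd)))
  expect_equal(s$mean_translation, mean(colSums(abs(rnd))[1:3]))
  expect_error(summarize_motion(matrix(0, 0, 6)), "empty")
})

test_that("motion exclusion applies strict 3 mm / 3 degree limits", {
  ok <- matrix(0.5, 10, 6)
  over <- ok; over[4, 1] <- 3.5
  border <- ok; border[2, 5] <- 3.0
  kept <- exclude_by_motion(list(a = ok, b = over, c = border))
  expect_identical(kept, "a")
  expect_identical(exclude_by_motion(list(x = ok, y = ok)), c("x", "y"))
})

test_that("phase assignment matches the cycle-fraction definition", {
  p <- generate_physio(20, cardiac_hz = 1, fs = 100, rate_jitter = 0,
                       seed = 1)
  # peaks at 0.5, 1.5, ...: a volume mid-beat is at phase pi, at-peak is 0
  ph <- compute_phase(p, c(1.0, 1.5), use_truth_peaks = TRUE)
  expect_equal(ph$cardiac[1], pi, tolerance = 1e-12)
  expect_equal(ph$cardiac[2], 0, tolerance = 1e-12)
  # jittered trace: detected-peak phases match a direct interpolation oracle
  pj <- generate_physio(60, cardiac_hz = 1, fs = 100, rate_jitter = 0.05,
                        seed = 4)
  vt <- seq(2, 55, by = 2.34)
  got <- compute_phase(pj, vt)$cardiac
  peaks <- detect_peaks(pj$cardiac$signal, 100, 1)
  oracle <- vapply(vt, function(t) {
    k <- findInterval(t, peaks)
    k <- min(max(k, 1), length(peaks) - 1)
    (2 * pi * (t - peaks[k]) / (peaks[k + 1] - peaks[k])) %% (2 * pi)
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-9)
  expect_error(compute_phase(list(cardiac = list(signal = c(0, 1, 0), fs = 1,
                                                 peak_times = 1),
                                  resp = pj$resp, duration = 3), 1:2,
                             use_truth_peaks = TRUE),
               "2")
})

test_that("Fourier expansions have the contracted shape and orthogonality", {
  z <- fourier_expansion(rep(0, 7), 2)
  expect_true(all(z[, c(1, 3)] == 0) && all(z[, c(2, 4)] == 1))
  expect_equal(ncol(fourier_expansion(runif(5), 3)), 6L)
  phi <- 2 * pi * (seq_len(4000) - 0.5) / 4000   # uniform phase grid
  Fq <- fourier_expansion(phi, 3)
  G <- crossprod(Fq) / nrow(Fq)
  expect_true(max(abs(G - diag(diag(G)))) < 1e-10)
  expect_true(all(abs(Fq) <= 1))
  expect_error(fourier_expansion(phi, 0), "order")
})

test_that("the canonical HRF has the conventional double-gamma shape", {
  h <- canonical_hrf(0.1)
  expect_equal(length(h), 321L)            # 32 s support + endpoint
  expect_true(all(is.finite(h)))
  expect_equal(max(h), 1)                  # peak-normalized
  tmax <- (which.max(h) - 1) * 0.1
  expect_true(abs(tmax - 5) < 0.3)         # gamma(6,1) mode at 5 s
  # single positive lobe followed by an undershoot
  expect_true(min(h) < 0)
  expect_gt(which.min(h), which.max(h))
  expect_error(canonical_hrf(0), "dt")
})

test_that("discrete-cosine columns match the frequency enumeration", {
  for (case in list(c(243, 2.34), c(100, 2), c(60, 3), c(20, 1))) {
    n <- case[1]; tr <- case[2]
    K <- ncol(dct_highpass_basis(n, tr, 128))
    # direct enumeration: cosine k has frequency k / (2 n tr)
    expect_equal(K, sum(seq_len(2 * n) / (2 * n * tr) < 1 / 128))
    expect_equal(K, floor(2 * n * tr / 128))
  }
})

test_that("design matrices carry task, nuisance, drift and intercept", {
  d <- generate_event_design(50, 0.2, 2.0, seed = 3)
  X <- build_design(d, NULL, 50L, 2.0)
  expect_equal(colnames(X)[1], "task")
  expect_equal(colnames(X)[ncol(X)], "intercept")
  expect_equal(nrow(X), 50L)
  # no events: zero task column
  d0 <- generate_event_design(50, 0, 2.0, seed = 1)
  expect_true(all(build_design(d0, NULL, 50L, 2.0)[, "task"] == 0))
  # single event at t = 0 reproduces the HRF at volume times
  d1 <- d0[1, ]; d1$trial_type <- "target"
  attr(d1, "total_duration") <- 100
  x <- task_regressor(d1, 40L, 2.0)
  h <- canonical_hrf(2.0 / 16)
  idx <- seq(1, length(h), by = 16)     # kernel samples at volume times
  expected <- numeric(40)
  expected[seq_along(idx)] <- h[idx]
  expect_equal(x, expected, tolerance = 1e-12)
  # rank deficiency is flagged
  nuis <- cbind(dup = X[, "task"])
  expect_error(build_design(d, nuis, 50L, 2.0), "rank")
})

test_that("voxelwise OLS matches the normal-equations oracle", {
  set.seed(8)
  n <- 40; V <- 12
  X <- cbind(task = rnorm(n), n1 = rnorm(n), intercept = 1)
  attr(X, "task_col") <- 1L
  Y <- matrix(rnorm(n * V), n, V)
  fit <- fit_glm(Y, X, dim_space = c(V, 1L, 1L))
  XtXi <- solve(t(X) %*% X)
  B <- XtXi %*% t(X) %*% Y
  expect_equal(unname(fit$beta), unname(t(B)), tolerance = 1e-10)
  # t-statistics from the scalar formula
  res <- Y - X %*% B
  s2 <- colSums(res^2) / (n - 3)
  expect_equal(as.vector(fit$tmap), unname(B[1, ] / sqrt(s2 * XtXi[1, 1])),
               tolerance = 1e-10)
  expect_equal(fit$df, n - 3)
  # a nuisance column orthogonal to all columns leaves the task beta fixed
  ortho <- qr.resid(qr(X), rnorm(n))
  X2 <- cbind(X[, 1, drop = FALSE], ortho, X[, 2:3])
  attr(X2, "task_col") <- 1L
  fit2 <- fit_glm(Y, X2, dim_space = c(V, 1L, 1L))
  expect_equal(fit2$beta[, 1], fit$beta[, 1], tolerance = 1e-10)
})

test_that("ROI extraction averages the resampled skeleton voxels", {
  ph <- small_phantom()
  res <- small_contrast_chain(ph)
  dimf <- c(10L, 10L, 10L)
  fit <- list(beta_map = array(2.5, dimf), dim_space = dimf)
  roi <- extract_roi_beta(fit, res$skeletons, ph$volume$voxel_size / 2, 1.8)
  expect_equal(roi$bilateral, 2.5)
  # random map: brute-force mean over the mapped voxel set
  set.seed(3)
  fit$beta_map <- array(rnorm(prod(dimf)), dimf)
  roi2 <- extract_roi_beta(fit, res$skeletons, ph$volume$voxel_size / 2, 1.8)
  svs <- ph$volume$voxel_size / 2
  manual_side <- function(skel) {
    mm <- cbind((skel$x - 0.5) * svs[1], (skel$y - 0.5) * svs[2],
                (skel$z - 0.5) * svs[3])
    vox <- unique(cbind(floor(mm[, 1] / 1.8) + 1, floor(mm[, 2] / 1.8) + 1,
                        floor(mm[, 3] / 1.8) + 1))
    mean(apply(vox, 1, function(v) fit$beta_map[v[1], v[2], v[3]]))
  }
  expect_equal(roi2$left, manual_side(res$skeletons$left), tolerance = 1e-12)
  # mask entirely out of grid errors
  tiny <- list(beta_map = array(0, c(2L, 2L, 2L)), dim_space = c(2L, 2L, 2L))
  expect_error(extract_roi_beta(tiny, res$skeletons,
                                ph$volume$voxel_size / 2, 0.1), "empty")
})

test_that("second-level models have N - 4 df and match scalar regression", {
  set.seed(5)
  N <- 53; V <- 9
  maps <- matrix(rnorm(N * V, mean = 0.3), N, V)
  covs <- data.frame(age = rnorm(N, 40, 15), sex = sample(c("F", "M"), N,
                                                          replace = TRUE),
                     bmi = rnorm(N, 23, 3))
  fit <- second_level(maps, covs, dim_space = c(V, 1L, 1L))
  expect_equal(fit$df, 49)
  # per-voxel lm oracle on the intercept of the mean-centered model
  for (v in c(1, 5)) {
    dfv <- data.frame(y = maps[, v],
                      age = covs$age - mean(covs$age),
                      sex = as.numeric(factor(covs$sex)) - 1,
                      bmi = covs$bmi - mean(covs$bmi))
    dfv$sex <- dfv$sex - mean(dfv$sex)
    ref <- summary(lm(y ~ age + sex + bmi, dfv))$coefficients["(Intercept)", ]
    expect_equal(as.vector(fit$tmap)[v], unname(ref["t value"]),
                 tolerance = 1e-10)
  }
  zero <- second_level(matrix(0, 20, 4), dim_space = c(4L, 1L, 1L))
  expect_true(all(zero$tmap == 0))
  expect_error(second_level(matrix(0, 4, 2), covs[1:4, ],
                            dim_space = c(2L, 1L, 1L)), "few")
})

test_that("small-volume correction is Bonferroni over the mask", {
  dimt <- c(8L, 8L, 8L)
  tmap <- array(0, dimt)
  fit <- list(tmap = tmap, df = 49)
  mask <- array(TRUE, dimt)
  expect_equal(nrow(small_volume_correct(fit, mask)), 0L)
  # single-voxel mask reduces to one uncorrected t-test
  m1 <- array(FALSE, dimt); m1[4, 4, 4] <- TRUE
  fit$tmap[4, 4, 4] <- 3.2
  tab <- small_volume_correct(fit, m1)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$p_fwe, pt(3.2, 49, lower.tail = FALSE))
  # planted 25-voxel blob: one cluster of size 25 (flood-fill oracle)
  fit$tmap <- array(0, dimt)
  blob <- as.matrix(expand.grid(2:6, 3:7, 5))
  fit$tmap[blob] <- 8
  mask_all <- array(TRUE, dimt)
  tab2 <- small_volume_correct(fit, mask_all)
  expect_equal(tab2$cluster_size, 25L)
  expect_equal(oracle_components(fit$tmap > 4), 25L)
  expect_error(small_volume_correct(fit, array(FALSE, dimt)), "empty")
})

test_that("Bonferroni correction controls family-wise error under the null", {
  set.seed(11)
  dimt <- c(6L, 6L, 6L)
  mask <- array(TRUE, dimt)
  df <- 49
  hits <- vapply(1:400, function(i) {
    fit <- list(tmap = array(rt(prod(dimt), df), dimt), df = df)
    nrow(small_volume_correct(fit, mask, alpha = 0.05)) > 0
  }, logical(1))
  # FWE <= alpha: the observed rate must not significantly exceed 0.05
  expect_lt(mean(hits), 0.05 + 1.96 * sqrt(0.05 * 0.95 / 400))
})

test_that("cluster reports drop sub-threshold and small components", {
  set.seed(13)
  dimt <- c(10L, 10L, 6L)
  tmap <- array(rnorm(prod(dimt)), dimt)
  expect_equal(nrow(cluster_report(tmap, max(tmap) + 1, min_size = 1)), 0L)
  # random field: component sizes match the flood-fill oracle
  thr <- 0.2
  rep_all <- cluster_report(tmap, thr, min_size = 1L)
  expect_equal(sort(rep_all$cluster_size, decreasing = TRUE),
               oracle_components(tmap > thr))
  # a 19-voxel component is dropped at the default 20-voxel floor
  t2 <- array(0, c(25L, 4L, 4L))
  t2[cbind(1:19, 1, 1)] <- 5   # 19 voxels in a 26-connected line
  expect_equal(nrow(cluster_report(t2, 1)), 0L)
  t2[20, 1, 1] <- 5
  expect_equal(cluster_report(t2, 1)$cluster_size, 20L)
})

test_that("physio availability changes design columns, never rows", {
  d <- generate_event_design(60, 0.2, 2.0, seed = 2)
  nvol <- 52L
  vt <- (seq_len(nvol) - 1) * 2.34
  motion <- generate_motion(nvol, seed = 1)
  physio <- generate_physio(130, fs = 50, seed = 3)
  with_p <- build_design(d, build_nuisance(motion, physio, vt,
                                           use_truth_peaks = TRUE),
                         nvol, 2.34)
  without <- build_design(d, build_nuisance(motion, NULL, vt), nvol, 2.34)
  expect_equal(nrow(with_p), nrow(without))
  expect_equal(ncol(with_p) - ncol(without), 2 * 3 + 2 * 4)
  # fitting still succeeds without physio columns
  set.seed(4)
  Y <- matrix(rnorm(nvol * 5), nvol, 5)
  expect_silent(fit_glm(Y, without, dim_space = c(5L, 1L, 1L)))
})

test_that("drift in the span of the drift model leaves the task beta fixed", {
  ph <- small_phantom()
  d <- generate_event_design(120, 0.2, 2.0, seed = 6)
  sim <- generate_bold(d, ph$truth, amplitude = 0.6, tr = 2.0, noise_sd = 0,
                       dim = c(8L, 8L, 8L), voxel_size = 2.0, seed = 1)
  nvol <- n_volumes(sim$bold)
  X <- build_design(d, NULL, nvol, 2.0)
  base <- fit_glm(sim$bold, X)
  v <- seq_len(nvol)
  drifts <- list(linear = 5 * v / nvol,
                 slow_cos = 3 * cos(pi * 2 * (2 * v - 1) / (2 * nvol)))
  for (dr in drifts) {
    arr <- sim$bold$data
    for (t in v) arr[, , , t] <- arr[, , , t] + dr[t]
    fit <- fit_glm(bold4d(arr, 2.0, 2.0), X)
    expect_lt(max(abs(fit$beta_map - base$beta_map)), 1e-6)
  }
  # an off-basis slow sine is only approximately projected out: the basis
  # truncation leaves a small residual coupling (measured ~2% here)
  sine <- 3 * sin(2 * pi * (v - 1) * 2.0 / 500)
  arr <- sim$bold$data
  for (t in v) arr[, , , t] <- arr[, , , t] + sine[t]
  fit_s <- fit_glm(bold4d(arr, 2.0, 2.0), X)
  expect_lt(max(abs(fit_s$beta_map - base$beta_map)), 0.05 * 0.6)
})
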
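test_that("mask intersection is the voxelwise AND", {
  d <- c(12L, 12L, 8L)
  m1 <- random_mask(d, 80, seed = 1)
  m2 <- random_mask(d, 80, seed = 2)
  # brute-force array AND oracle
  a1 <- array(FALSE, d); a1[m1$voxels] <- TRUE
  a2 <- array(FALSE, d); a2[m2$voxels] <- TRUE
  expected <- which(a1 & a2, arr.ind = TRUE)
  got <- intersect_masks(m1, m2)$voxels
  expect_setequal(lcpipe:::vox_key(got, d),
                  lcpipe:::vox_key(unname(expected), d))
  # idempotence
  expect_setequal(lcpipe:::vox_key(intersect_masks(m1, m1)$voxels, d),
                  lcpipe:::vox_key(m1$voxels, d))
  # disjoint masks error
  ma <- lc_mask("left", cbind(1, 1, 1), d)
  mb <- lc_mask("left", cbind(2, 2, 2), d)
  expect_error(intersect_masks(ma, mb), "empty")
  expect_error(intersect_masks(ma, lc_mask("right", cbind(1, 1, 1), d)),
               "side")
})

test_that("trilinear upsampling preserves constants, ramps, and identity", {
  v <- volume3d(array(7.5, c(4, 5, 6)), c(1, 1, 1))
  expect_identical(upsample_volume(v, 1L), v)
  up <- upsample_volume(v, 2L)
  expect_equal(dim(up$grid), c(8L, 10L, 12L))
  expect_equal(up$voxel_size, c(0.5, 0.5, 0.5))
  expect_true(all(up$grid == 7.5))
  # linear ramp along x: interior fine voxels interpolate exactly
  g <- array(rep(seq_len(10), times = 4 * 4), c(10, 4, 4))
  up2 <- upsample_volume(volume3d(g, c(1, 1, 1)), 2L)
  at <- (seq_len(20) - 0.5) / 2 + 0.5          # fractional source index
  expected <- pmin(pmax(at, 1), 10)            # clamped linear ramp
  expect_equal(up2$grid[, 1, 1], expected)
  expect_error(upsample_volume(v, 0), "factor")
})

test_that("block mask upsampling preserves membership exactly", {
  d <- c(6L, 6L, 4L)
  m <- random_mask(d, 10, seed = 3)
  up <- upsample_mask(m, 2L)
  expect_equal(nrow(up$voxels), nrow(m$voxels) * 8L)
  # every fine voxel maps back into the source mask
  back <- unique(cbind((up$voxels[, 1] - 1L) %/% 2L + 1L,
                       (up$voxels[, 2] - 1L) %/% 2L + 1L,
                       (up$voxels[, 3] - 1L) %/% 2L + 1L))
  expect_setequal(lcpipe:::vox_key(back, d),
                  lcpipe:::vox_key(m$voxels, d))
})

test_that("skeletonization keeps the per-slice in-mask argmax", {
  d <- c(10L, 10L, 6L)
  set.seed(4)
  vol <- volume3d(array(rnorm(prod(d)), d), c(1, 1, 1))
  m <- random_mask(d, 60, seed = 5)
  sk <- skeletonize(m, vol)
  expect_s3_class(sk, "skeleton_lc")
  # brute-force oracle with the tie-break ordering
  for (z in sort(unique(m$voxels[, 3]))) {
    vz <- m$voxels[m$voxels[, 3] == z, , drop = FALSE]
    vz <- vz[order(vz[, 1], vz[, 2]), , drop = FALSE]
    ints <- vol$grid[vz]
    best <- vz[which.max(ints), ]
    row <- sk[sk$slice == z, ]
    expect_equal(nrow(row), 1L)
    expect_equal(c(row$x, row$y), unname(best[1:2]))
    expect_equal(row$intensity, max(ints))
  }
  # at most one voxel per slice; every skeleton voxel is in the mask
  expect_false(anyDuplicated(sk$slice) > 0)
  expect_true(all(lcpipe:::vox_key(as.matrix(sk[, c("x", "y", "z")]), d) %in%
                    lcpipe:::vox_key(m$voxels, d)))
  # mask with one voxel per slice reproduces itself
  single <- lc_mask("left", cbind(3:5, 3:5, 1:3), d)
  sk1 <- skeletonize(single, vol)
  expect_equal(as.matrix(sk1[, c("x", "y", "z")]),
               matrix(c(3:5, 3:5, 1:3), ncol = 3,
                      dimnames = list(NULL, c("x", "y", "z"))))
  expect_error(skeletonize(lc_mask("left", cbind(1, 1, 1)[0, ], d), vol),
               "empty")
})

test_that("ties in skeletonization break to smallest x, then y", {
  d <- c(5L, 5L, 1L)
  vol <- volume3d(array(1, d), c(1, 1, 1))
  m <- lc_mask("left", cbind(c(4, 2, 2), c(1, 3, 2), c(1, 1, 1)), d)
  sk <- skeletonize(m, vol)
  expect_equal(c(sk$x, sk$y), c(2, 2))
})

test_that("reference regions average exactly 225 voxels at the anchor", {
  d <- c(40L, 40L, 5L)
  vc <- volume3d(array(3.25, d), c(1, 1, 1))
  ref <- place_reference(vc, 1:5, c(20, 20))
  expect_true(all(ref$ref_mean == 3.25))
  set.seed(6)
  vr <- volume3d(array(rnorm(prod(d)), d), c(1, 1, 1))
  ref2 <- place_reference(vr, c(2, 4), c(18, 22))
  for (i in seq_len(nrow(ref2))) {
    z <- ref2$slice[i]
    expect_equal(ref2$ref_mean[i], mean(vr$grid[11:25, 15:29, z]))
  }
  expect_error(place_reference(vc, 1, c(5, 20)), "edge")
  expect_error(place_reference(vc, 99, c(20, 20)), "slice")
})

test_that("the contrast formula and aggregation follow the definition", {
  mk_skel <- function(side, ints) {
    structure(data.frame(side = side, slice = seq_along(ints),
                         x = 1L, y = 1L, z = seq_along(ints),
                         intensity = ints),
              class = c("skeleton_lc", "data.frame"))
  }
  ref <- structure(data.frame(slice = 1:3, x = 5L, y = 5L,
                              ref_mean = c(100, 100, 100)),
                   class = c("reference_region", "data.frame"))
  # null case and forced value
  r0 <- compute_contrast(mk_skel("left", c(100, 100, 100)),
                         mk_skel("right", c(150, 150, 150)), ref)
  expect_equal(r0$left, 0)
  expect_equal(r0$right, 0.5)
  expect_equal(r0$bilateral, 0.25)
  # hand-computed slice mean: (0.1 + 0.2 + 0.3) / 3 = 0.2
  r1 <- compute_contrast(mk_skel("left", c(110, 120, 130)),
                         mk_skel("right", c(110, 120, 130)), ref)
  expect_equal(r1$left, 0.2)
  expect_equal(r1$bilateral, 0.2)
  # degenerate reference
  bad <- ref; bad$ref_mean[2] <- 0
  expect_error(compute_contrast(mk_skel("left", c(1, 1, 1)),
                                mk_skel("right", c(1, 1, 1)), bad),
               "degenerate")
  short <- ref[1:2, ]
  expect_error(compute_contrast(mk_skel("left", c(1, 1, 1)),
                                mk_skel("right", c(1, 1, 1)), short),
               "missing")
})

test_that("noiseless phantoms recover the planted contrast exactly", {
  ph <- small_phantom(contrast_amplitude = 0.3)
  res <- small_contrast_chain(ph)
  expect_equal(res$contrast$bilateral, 0.3, tolerance = 1e-12)
  expect_equal(res$contrast$left, 0.3, tolerance = 1e-12)
  # with a peaked radial profile the skeleton tracks the centerline
  # (a flat plateau ties every interior voxel, so the brightest-voxel rule
  # is only pinned to the axis when intensity falls off radially)
  php <- generate_lc_volume(small_geometry(), profile = "peaked")
  resp <- small_contrast_chain(php)
  sgl <- lcpipe:::support_on_grid(php$truth, "left", 2L)
  sk <- res_skel <- resp$skeletons$left
  ctr <- sgl$centerline[match(sk$slice, sgl$centerline[, "z"]), ,
                        drop = FALSE]
  expect_true(all(abs(sk$x - ctr[, "x"]) <= 1))
  expect_true(all(abs(sk$y - ctr[, "y"]) <= 1))
  # null amplitude: contrast vanishes
  ph0 <- small_phantom(contrast_amplitude = 0)
  expect_equal(small_contrast_chain(ph0)$contrast$bilateral, 0,
               tolerance = 1e-12)
})

test_that("contrast is scale invariant and shift sensitive (closed form)", {
  ph <- small_phantom(noise_sd = 1.5, seed = 9)
  res <- small_contrast_chain(ph, jitter = 0.2, seed = 3)
  for (c_scale in c(0.2, 3.7)) {
    vs <- volume3d(ph$volume$grid * c_scale, ph$volume$voxel_size)
    ml <- simulate_rater_masks(ph$truth, "left", 0.2, seed = 3, factor = 2)
    mr <- simulate_rater_masks(ph$truth, "right", 0.2, seed = 4, factor = 2)
    res_s <- compute_lc_contrast(vs, ml, mr, ph$truth$pons_anchor, 2)
    expect_equal(res_s$contrast$bilateral, res$contrast$bilateral,
                 tolerance = 1e-12)
  }
  # additive shift k: per-slice contrast becomes (LC - ref) / (ref + k)
  k <- 12.5
  vshift <- volume3d(ph$volume$grid + k, ph$volume$voxel_size)
  ml <- simulate_rater_masks(ph$truth, "left", 0.2, seed = 3, factor = 2)
  mr <- simulate_rater_masks(ph$truth, "right", 0.2, seed = 4, factor = 2)
  res_k <- compute_lc_contrast(vshift, ml, mr, ph$truth$pons_anchor, 2)
  ps <- res$contrast$per_slice
  expected <- (ps$lc_intensity - ps$ref_mean) / (ps$ref_mean + k)
  expect_equal(res_k$contrast$per_slice$contrast, expected,
               tolerance = 1e-12)
})

test_that("skeleton is nested in the intersection and both rater masks", {
  ph <- small_phantom(noise_sd = 2, seed = 12)
  ml <- simulate_rater_masks(ph$truth, "left", 0.3, seed = 5, factor = 2)
  inter <- intersect_masks(ml$rater1, ml$rater2)
  volu <- upsample_volume(ph$volume, 2L)
  sk <- skeletonize(inter, volu)
  kk <- lcpipe:::vox_key(as.matrix(sk[, c("x", "y", "z")]), inter$grid_dim)
  ki <- lcpipe:::vox_key(inter$voxels, inter$grid_dim)
  k1 <- lcpipe:::vox_key(ml$rater1$voxels, inter$grid_dim)
  k2 <- lcpipe:::vox_key(ml$rater2$voxels, inter$grid_dim)
  expect_true(all(kk %in% ki))
  expect_true(all(ki %in% k1) && all(ki %in% k2))
})

test_that("measured contrast bias grows with noise (max-statistic selection)", {
  bias_at <- function(noise_sd) {
    vals <- vapply(1:6, function(s) {
      ph <- small_phantom(contrast_amplitude = 0.3, noise_sd = noise_sd,
                          seed = 100 + s)
      small_contrast_chain(ph)$contrast$bilateral
    }, numeric(1))
    mean(vals) - 0.3
  }
  b0 <- bias_at(0); b1 <- bias_at(1.5); b2 <- bias_at(4)
  expect_equal(b0, 0, tolerance = 1e-12)
  expect_true(b1 > 0)
  expect_true(b2 > b1)
})

test_that("probabilistic templates are occupancy fractions", {
  d <- c(8L, 8L, 4L)
  m1 <- random_mask(d, 30, seed = 1)
  tpl_same <- build_probabilistic_template(list(m1, m1, m1))
  inside <- array(FALSE, d); inside[m1$voxels] <- TRUE
  expect_true(all(tpl_same$grid[inside] == 1))
  expect_true(all(tpl_same$grid[!inside] == 0))
  m2 <- random_mask(d, 30, seed = 2)
  tpl <- build_probabilistic_template(list(m1, m2))
  # brute-force count oracle
  a1 <- array(0, d); a1[m1$voxels] <- 1
  a2 <- array(0, d); a2[m2$voxels] <- 1
  expect_equal(tpl$grid, (a1 + a2) / 2)
  expect_true(all(tpl$grid >= 0 & tpl$grid <= 1))
  # template mass equals the mean mask volume
  vox_vol <- prod(c(0.5, 0.5, 0.6))
  tplv <- build_probabilistic_template(list(m1, m2),
                                       voxel_size = c(0.5, 0.5, 0.6))
  expect_equal(sum(tplv$grid) * vox_vol,
               mean(c(nrow(m1$voxels), nrow(m2$voxels))) * vox_vol)
  expect_error(build_probabilistic_template(list()), "no masks")
})
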
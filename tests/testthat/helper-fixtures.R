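# Small-scale fixtures shared across the suites. Everything is generated in
# code; grids are kept small so the default run stays fast.

# compact structural phantom: 40 x 40 x 24 at 0.5/0.5/0.6 mm, 10 mm nuclei
small_geometry <- function(contrast_amplitude = 0.3) {
  lc_geometry(dim = c(40L, 40L, 24L), voxel_size = c(0.5, 0.5, 0.6),
              length_mm = 9.6, radius_mm = 1.25, lateral_offset_mm = 3,
              contrast_amplitude = contrast_amplitude)
}

small_phantom <- function(contrast_amplitude = 0.3, noise_sd = 0,
                          seed = NULL) {
  generate_lc_volume(small_geometry(contrast_amplitude), noise_sd = noise_sd,
                     seed = seed)
}

# run the full structural chain on a phantom with noiseless raters
small_contrast_chain <- function(ph, jitter = 0, factor = 2L, seed = 1L) {
  ml <- simulate_rater_masks(ph$truth, "left", jitter, seed = seed,
                             factor = factor)
  mr <- simulate_rater_masks(ph$truth, "right", jitter, seed = seed + 1L,
                             factor = factor)
  compute_lc_contrast(ph$volume, ml, mr, ph$truth$pons_anchor,
                      factor = factor)
}

# random voxel set on a grid, as an lc_mask
random_mask <- function(d, n, side = "left", seed = 1) {
  set.seed(seed)
  vox <- cbind(sample.int(d[1], n, replace = TRUE),
               sample.int(d[2], n, replace = TRUE),
               sample.int(d[3], n, replace = TRUE))
  lc_mask(side, unique(vox), d)
}

# independent connected-component oracle (igraph, 26-connectivity)
oracle_components <- function(mask3d) {
  d <- dim(mask3d)
  idx <- which(mask3d)
  if (length(idx) == 0) return(integer(0))
  co <- arrayInd(idx, d)
  key <- stats::setNames(seq_along(idx), idx)
  edges <- c()
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (i in seq_along(idx)) {
    nb <- sweep(offs, 2, co[i, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    ni <- nb[, 1] + (nb[, 2] - 1) * d[1] + (nb[, 3] - 1) * d[1] * d[2]
    ni <- ni[as.character(ni) %in% names(key)]
    for (j in key[as.character(ni)])
      if (j > i) edges <- c(edges, i, j)
  }
  g <- igraph::make_graph(edges = as.numeric(edges), n = length(idx),
                          directed = FALSE)
  sort(as.integer(table(igraph::components(g)$membership)), decreasing = TRUE)
}
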
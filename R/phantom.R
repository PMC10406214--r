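#' LC mask on a structural grid
#'
#' A set of voxels belonging to one side of the locus coeruleus (LC), with
#' 1-based (x, y, z) grid coordinates.
#'
#' @param side "left" or "right".
#' @param voxels integer matrix with columns x, y, z (one row per voxel).
#' @param grid_dim dimensions of the grid the coordinates live on.
#' @return Object of class \code{lc_mask}.
#' @export
lc_mask <- function(side, voxels, grid_dim) {
  side <- match.arg(side, c("left", "right"))
  voxels <- matrix(as.integer(voxels), ncol = 3L,
                   dimnames = list(NULL, c("x", "y", "z")))
  if (nrow(voxels) > 0) {
    if (any(voxels < 1L) ||
        any(voxels[, 1] > grid_dim[1]) || any(voxels[, 2] > grid_dim[2]) ||
        any(voxels[, 3] > grid_dim[3]))
      stop("mask voxels outside grid bounds")
  }
  voxels <- unique(voxels)
  structure(list(side = side, voxels = voxels,
                 grid_dim = as.integer(grid_dim)), class = "lc_mask")
}

#' @export
print.lc_mask <- function(x, ...) {
  cat(sprintf("lc_mask (%s): %d voxels on %s grid\n", x$side,
              nrow(x$voxels), paste(x$grid_dim, collapse = " x ")))
  invisible(x)
}

# linear index <-> (x,y,z) helpers
vox_key <- function(v, d) (v[, 3L] - 1L) * d[1L] * d[2L] +
  (v[, 2L] - 1L) * d[1L] + v[, 1L]

#' Default LC phantom geometry
#'
#' The LC is modeled as two parallel cylinders, ~15 mm long and 2.5 mm in
#' diameter, running along the slice (z) axis on either side of the midline,
#' embedded in a constant pons-like plateau. The pons reference anchor is
#' the in-plane point midway between and anterior to the two nuclei.
#'
#' @param dim grid dimensions in voxels (x, y, z).
#' @param voxel_size mm per axis; default emulates a 0.4 x 0.4 x 0.5 mm slab.
#' @param length_mm,radius_mm cylinder length and radius in mm.
#' @param lateral_offset_mm distance of each cylinder axis from the midline.
#' @param contrast_amplitude fractional hyperintensity of the LC above the
#'   pons mean (the quantity the contrast statistic recovers).
#' @param pons_mean background plateau intensity (arbitrary units).
#' @return A list of geometry parameters used by
#'   \code{\link{generate_lc_volume}}.
#' @export
lc_geometry <- function(dim = c(80L, 80L, 60L),
                        voxel_size = c(0.4, 0.4, 0.5),
                        length_mm = 15, radius_mm = 1.25,
                        lateral_offset_mm = 4,
                        contrast_amplitude = 0.3,
                        pons_mean = 100) {
  list(dim = as.integer(dim), voxel_size = as.numeric(voxel_size),
       length_mm = length_mm, radius_mm = radius_mm,
       lateral_offset_mm = lateral_offset_mm,
       contrast_amplitude = contrast_amplitude, pons_mean = pons_mean)
}

#' Generate a structural LC phantom volume
#'
#' Builds a neuromelanin-sensitive-like slab: a constant pons plateau with
#' two hyperintense cylinders (one per side) brightened by
#' \code{contrast_amplitude * pons_mean}, plus optional additive Gaussian
#' noise. The cylinders are hard-edged by default (voxel centers within
#' \code{radius_mm} of the axis), which makes downstream contrast recovery
#' exact on noiseless phantoms; an optional Gaussian radial falloff
#' \code{edge_sigma_mm} softens the boundary.
#'
#' @param geometry a list from \code{\link{lc_geometry}}.
#' @param noise_sd SD of additive Gaussian noise (intensity units, >= 0).
#' @param edge_sigma_mm radial Gaussian falloff beyond the cylinder edge;
#'   0 (default) gives a hard edge.
#' @param profile radial intensity profile inside the cylinder: "flat"
#'   (default; constant plateau, exact contrast oracles) or "peaked"
#'   (Gaussian falloff from the axis with sigma = radius, so the
#'   brightest voxel of each slice sits on the centerline).
#' @param seed optional integer seed.
#' @return A list with \code{volume} (a \code{volume3d}) and \code{truth},
#'   the ground truth: per-side centerline voxel coordinates (matrix x,y,z),
#'   per-side support voxel sets, centerline world coordinates in mm,
#'   radius/length, \code{contrast_amplitude}, \code{pons_mean} and the
#'   in-plane \code{pons_anchor} (x, y) for reference-region placement.
#' @export
generate_lc_volume <- function(geometry = lc_geometry(), noise_sd = 0,
                               edge_sigma_mm = 0,
                               profile = c("flat", "peaked"), seed = NULL) {
  profile <- match.arg(profile)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  d <- geometry$dim; vs <- geometry$voxel_size
  extent <- d * vs
  n_slices <- round(geometry$length_mm / vs[3])
  z0 <- floor((d[3] - n_slices) / 2) + 1L
  zs <- z0:(z0 + n_slices - 1L)
  if (z0 < 1L || max(zs) > d[3])
    stop("cylinder exceeds grid bounds along the slice axis")
  cx <- extent[1] / 2
  cy <- extent[2] / 2
  centers_mm <- list(
    left  = c(cx - geometry$lateral_offset_mm, cy),
    right = c(cx + geometry$lateral_offset_mm, cy)
  )
  xs_mm <- (seq_len(d[1]) - 0.5) * vs[1]
  ys_mm <- (seq_len(d[2]) - 0.5) * vs[2]
  grid <- array(geometry$pons_mean, dim = d)
  bump <- geometry$contrast_amplitude * geometry$pons_mean
  truth <- list(sides = list(), radius_mm = geometry$radius_mm,
                length_mm = geometry$length_mm,
                contrast_amplitude = geometry$contrast_amplitude,
                pons_mean = geometry$pons_mean,
                voxel_size = vs, grid_dim = d)
  for (side in c("left", "right")) {
    cc <- centers_mm[[side]]
    r2 <- outer((xs_mm - cc[1])^2, (ys_mm - cc[2])^2, `+`)
    core <- if (profile == "peaked")
      exp(-0.5 * r2 / geometry$radius_mm^2) else 1
    if (edge_sigma_mm > 0) {
      w <- ifelse(sqrt(r2) <= geometry$radius_mm, core,
                  exp(-0.5 * ((sqrt(r2) - geometry$radius_mm) / edge_sigma_mm)^2) *
                    (if (profile == "peaked") exp(-0.5) else 1))
    } else {
      w <- (sqrt(r2) <= geometry$radius_mm) * core
    }
    inplane <- which(w > 1e-8, arr.ind = TRUE)
    if (nrow(inplane) == 0)
      stop("cylinder radius too small for this grid: no voxel centers inside")
    sup <- cbind(inplane[rep(seq_len(nrow(inplane)), length(zs)), , drop = FALSE],
                 rep(zs, each = nrow(inplane)))
    colnames(sup) <- c("x", "y", "z")
    for (z in zs) grid[, , z] <- grid[, , z] + bump * w
    ctr_vox <- cbind(x = rep(round(cc[1] / vs[1] + 0.5), length(zs)),
                     y = rep(round(cc[2] / vs[2] + 0.5), length(zs)),
                     z = zs)
    hard <- sup[rep(sqrt(r2[inplane]) <= geometry$radius_mm, length(zs)), ,
                drop = FALSE]
    truth$sides[[side]] <- list(
      centerline = ctr_vox,
      centerline_mm = cbind(x = rep(cc[1], length(zs)),
                            y = rep(cc[2], length(zs)),
                            z = (zs - 0.5) * vs[3]),
      support = hard
    )
  }
  if (noise_sd > 0)
    grid <- grid + array(stats::rnorm(prod(d), 0, noise_sd), dim = d)
  # anterior-central pons anchor, clamped so a 15x15 reference patch fits
  # on the native grid (and, a fortiori, on any upsampled grid)
  anchor <- c(x = round(cx / vs[1] + 0.5),
              y = round((cy - 3 * geometry$radius_mm -
                           geometry$lateral_offset_mm) / vs[2] + 0.5))
  anchor <- pmin(pmax(anchor, 8), d[1:2] - 7)
  truth$pons_anchor <- anchor
  list(volume = volume3d(grid, vs), truth = truth)
}

# True cylinder support on the delineation grid (the structural grid
# upsampled by `factor`): in-plane voxel centers within radius_mm of the
# side's axis, axial slice centers within the z range of the painted slice
# centers. On the fine grid this is the fully hyperintense core of the
# interpolated cylinder -- the region an expert delineating the upsampled
# image would mark unambiguously.
support_on_grid <- function(truth, side, factor = 1L) {
  d <- truth$grid_dim * factor
  vs <- truth$voxel_size / factor
  cl <- truth$sides[[side]]$centerline_mm
  ax <- cl[1, "x"]; ay <- cl[1, "y"]
  zr <- range(cl[, "z"])
  xs <- (seq_len(d[1]) - 0.5) * vs[1]
  ys <- (seq_len(d[2]) - 0.5) * vs[2]
  zs_mm <- (seq_len(d[3]) - 0.5) * vs[3]
  inpl <- which(outer((xs - ax)^2, (ys - ay)^2, `+`) <= truth$radius_mm^2,
                arr.ind = TRUE)
  zi <- which(zs_mm >= zr[1] - 1e-9 & zs_mm <= zr[2] + 1e-9)
  sup <- cbind(inpl[rep(seq_len(nrow(inpl)), length(zi)), , drop = FALSE],
               rep(zi, each = nrow(inpl)))
  colnames(sup) <- c("x", "y", "z")
  ctr <- cbind(x = rep(min(max(round(ax / vs[1] + 0.5), 1L), d[1]), length(zi)),
               y = rep(min(max(round(ay / vs[2] + 0.5), 1L), d[2]), length(zi)),
               z = zi)
  list(support = sup, centerline = ctr, grid_dim = d)
}

#' Simulate two rater delineations of the LC
#'
#' Emulates independent manual delineation by two raters on the grid the
#' contrast is computed on (pass \code{factor} matching the upsampling
#' factor: delineation happens on the upsampled image, as in the emulated
#' workflow). Each rater's mask is the true cylinder support with boundary
#' voxels independently flipped (eroded from the mask surface or dilated
#' from the adjacent background) with probability \code{jitter}. Centerline
#' voxels are never removed, so the intersection of the two masks always
#' contains the centerline.
#'
#' @param truth ground truth from \code{\link{generate_lc_volume}}.
#' @param side "left" or "right".
#' @param jitter boundary flip probability in [0, 1]; 0 reproduces the true
#'   support exactly.
#' @param seed optional integer seed.
#' @param factor delineation grid refinement relative to the structural
#'   grid (default 1: the native grid).
#' @return A list of two \code{lc_mask} objects (\code{rater1},
#'   \code{rater2}).
#' @export
simulate_rater_masks <- function(truth, side = c("left", "right"),
                                 jitter = 0.2, seed = NULL, factor = 1L) {
  side <- match.arg(side)
  if (jitter < 0 || jitter > 1) stop("'jitter' must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  sg <- support_on_grid(truth, side, factor)
  d <- sg$grid_dim
  sup <- sg$support
  sup_keys <- vox_key(sup, d)
  ctr_keys <- vox_key(sg$centerline, d)
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  n <- nrow(sup)
  nb <- sup[rep(seq_len(n), each = 6L), , drop = FALSE] +
    offs[rep(1:6, n), , drop = FALSE]
  inb <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
    nb[, 1] <= d[1] & nb[, 2] <= d[2] & nb[, 3] <= d[3]
  nb_in_sup <- logical(6L * n)
  nb_in_sup[inb] <- vox_key(nb[inb, , drop = FALSE], d) %in% sup_keys
  is_boundary <- colSums(matrix(!nb_in_sup, nrow = 6L)) > 0
  outer_ring <- unique(nb[inb & !nb_in_sup, , drop = FALSE])
  one_rater <- function() {
    keep <- rep(TRUE, n)
    flip_out <- is_boundary & stats::runif(n) < jitter &
      !(sup_keys %in% ctr_keys)
    keep[flip_out] <- FALSE
    add_in <- stats::runif(nrow(outer_ring)) < jitter
    vox <- rbind(sup[keep, , drop = FALSE],
                 outer_ring[add_in, , drop = FALSE])
    lc_mask(side, vox, d)
  }
  list(rater1 = one_rater(), rater2 = one_rater())
}

#' Dice overlap between two masks
#' @param m1,m2 \code{lc_mask} objects on the same grid.
#' @return Dice coefficient in [0, 1].
#' @export
dice_overlap <- function(m1, m2) {
  k1 <- vox_key(m1$voxels, m1$grid_dim)
  k2 <- vox_key(m2$voxels, m2$grid_dim)
  2 * length(intersect(k1, k2)) / (length(k1) + length(k2))
}
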
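#' Intersect two rater masks
#'
#' The consensus LC mask is the voxelwise logical AND of the two raters'
#' delineations; an empty intersection signals a delineation failure.
#'
#' @param rater1,rater2 \code{lc_mask} objects on the same grid and side.
#' @return An \code{lc_mask}.
#' @export
intersect_masks <- function(rater1, rater2) {
  stopifnot(inherits(rater1, "lc_mask"), inherits(rater2, "lc_mask"))
  if (rater1$side != rater2$side) stop("masks are from different sides")
  if (!all(rater1$grid_dim == rater2$grid_dim))
    stop("masks are on different grids")
  k1 <- vox_key(rater1$voxels, rater1$grid_dim)
  k2 <- vox_key(rater2$voxels, rater2$grid_dim)
  keep <- rater1$voxels[k1 %in% k2, , drop = FALSE]
  if (nrow(keep) == 0)
    stop("empty mask intersection: rater delineations do not overlap")
  lc_mask(rater1$side, keep, rater1$grid_dim)
}

#' Upsample a mask to match an upsampled volume
#'
#' Each original voxel maps onto its \code{factor^3} block of fine-grid
#' voxels (nearest-neighbor in the block-aligned sense), so mask membership
#' is preserved exactly and skeleton voxels remain inside the mask.
#'
#' @param mask an \code{lc_mask}.
#' @param factor integer upsampling factor.
#' @return An \code{lc_mask} on the fine grid.
#' @export
upsample_mask <- function(mask, factor = 2L) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("'factor' must be >= 1")
  if (factor == 1L) return(mask)
  v <- mask$voxels
  offs <- as.matrix(expand.grid(dx = 0:(factor - 1L), dy = 0:(factor - 1L),
                                dz = 0:(factor - 1L)))
  n <- nrow(v)
  base <- (v - 1L) * factor + 1L
  big <- base[rep(seq_len(n), each = nrow(offs)), , drop = FALSE] +
    offs[rep(seq_len(nrow(offs)), n), ]
  lc_mask(mask$side, big, mask$grid_dim * factor)
}

#' Skeletonize an LC mask
#'
#' Reduces the mask to at most one voxel per axial slice: within each slice
#' that intersects the mask, the in-mask voxel of maximal intensity is kept.
#' Intensity ties are broken deterministically by the smallest x, then
#' smallest y, coordinate.
#'
#' @param mask an \code{lc_mask} (typically the rater intersection, on the
#'   upsampled grid).
#' @param vol the \code{volume3d} the intensities are read from; grids must
#'   match.
#' @return A data.frame of class \code{skeleton_lc}: one row per slice with
#'   \code{side}, \code{slice}, \code{x}, \code{y}, \code{z},
#'   \code{intensity}.
#' @export
skeletonize <- function(mask, vol) {
  stopifnot(inherits(mask, "lc_mask"), inherits(vol, "volume3d"))
  if (!all(mask$grid_dim == dim(vol$grid)))
    stop("mask and volume grids differ")
  v <- mask$voxels
  if (nrow(v) == 0) stop("empty mask")
  rows <- lapply(sort(unique(v[, "z"])), function(z) {
    vz <- v[v[, "z"] == z, , drop = FALSE]
    vz <- vz[order(vz[, "x"], vz[, "y"]), , drop = FALSE]
    ints <- vol$grid[vz]
    i <- which.max(ints)          # first max: smallest x, then y, wins ties
    data.frame(side = mask$side, slice = z, x = vz[i, "x"], y = vz[i, "y"],
               z = z, intensity = ints[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("skeleton_lc", "data.frame")
  out
}

#' Place the slice-wise pons reference region
#'
#' For each requested axial slice, a fixed-size square in-plane patch
#' (default 15 x 15 voxels, anterior-central pons) is centered at the same
#' in-plane anchor, and its mean intensity is recorded as that slice's
#' normalization reference.
#'
#' @param vol a \code{volume3d}.
#' @param slices axial slice indices.
#' @param pons_anchor in-plane (x, y) patch center (1-based voxel indices).
#' @param size patch side length in voxels (odd; default 15).
#' @return A data.frame of class \code{reference_region}: \code{slice},
#'   \code{x}, \code{y} (anchor), \code{ref_mean}.
#' @export
place_reference <- function(vol, slices, pons_anchor, size = 15L) {
  stopifnot(inherits(vol, "volume3d"))
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L) stop("'size' must be a positive odd integer")
  half <- size %/% 2L
  cx <- as.integer(round(pons_anchor[1]))
  cy <- as.integer(round(pons_anchor[2]))
  d <- dim(vol$grid)
  if (cx - half < 1L || cx + half > d[1] || cy - half < 1L || cy + half > d[2])
    stop("reference patch overlaps the grid edge")
  if (any(slices < 1L) || any(slices > d[3]))
    stop("requested slice outside the grid")
  xs <- (cx - half):(cx + half)
  ys <- (cy - half):(cy + half)
  means <- vapply(slices, function(z) mean(vol$grid[xs, ys, z]), numeric(1))
  out <- data.frame(slice = as.integer(slices), x = cx, y = cy,
                    ref_mean = means)
  class(out) <- c("reference_region", "data.frame")
  out
}

#' Compute the LC contrast statistic
#'
#' Per slice i and side, the contrast is
#' \code{(LC_i - ref_mean_i) / ref_mean_i}, where \code{LC_i} is the
#' skeleton (maximal in-mask) intensity on slice i and \code{ref_mean_i}
#' the slice-corresponding pons reference mean. The per-side contrast is
#' the mean over that side's slices, and the bilateral LC contrast is the
#' mean of the left and right per-side contrasts. The statistic is a ratio,
#' hence invariant to global intensity rescaling.
#'
#' @param skel_left,skel_right \code{skeleton_lc} tables.
#' @param ref a \code{reference_region} covering every skeleton slice.
#' @return A list of class \code{contrast_result}: \code{per_slice}
#'   (data.frame side/slice/lc_intensity/ref_mean/contrast), \code{left},
#'   \code{right}, \code{bilateral}.
#' @export
compute_contrast <- function(skel_left, skel_right, ref) {
  one_side <- function(skel) {
    m <- match(skel$slice, ref$slice)
    if (anyNA(m)) stop("reference region missing for some skeleton slices")
    rm_ <- ref$ref_mean[m]
    if (any(rm_ <= 0))
      stop("reference mean <= 0 on some slice: degenerate normalization")
    data.frame(side = skel$side, slice = skel$slice,
               lc_intensity = skel$intensity, ref_mean = rm_,
               contrast = (skel$intensity - rm_) / rm_,
               stringsAsFactors = FALSE)
  }
  left <- one_side(skel_left)
  right <- one_side(skel_right)
  per_slice <- rbind(left, right)
  res <- list(per_slice = per_slice,
              left = mean(left$contrast),
              right = mean(right$contrast),
              bilateral = (mean(left$contrast) + mean(right$contrast)) / 2)
  class(res) <- "contrast_result"
  res
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("LC contrast: left %.4f, right %.4f, bilateral %.4f (%d slices)\n",
              x$left, x$right, x$bilateral, nrow(x$per_slice)))
  invisible(x)
}

#' Full structural LC contrast chain for one subject
#'
#' Runs the native-space pipeline: per-side intersection of the two rater
#' masks, trilinear upsampling of the volume by \code{factor}, slice-wise
#' skeletonization on the upsampled volume, reference-region placement at
#' the (upsampled) pons anchor, and the contrast statistic. Masks
#' delineated on the fine grid (the usual workflow: delineation happens on
#' the upsampled image) are used as-is; masks on the native grid are block
#' upsampled first.
#'
#' @param vol structural \code{volume3d} (native space).
#' @param masks_left,masks_right lists with \code{rater1}/\code{rater2}
#'   \code{lc_mask} objects per side.
#' @param pons_anchor in-plane (x, y) anchor on the original grid.
#' @param factor upsampling factor (default 2).
#' @param ref_size reference patch side length (default 15).
#' @return A list: \code{contrast} (\code{contrast_result}),
#'   \code{skeletons} (left/right), \code{reference}, \code{volume_up}.
#' @export
compute_lc_contrast <- function(vol, masks_left, masks_right, pons_anchor,
                                factor = 2L, ref_size = 15L) {
  inter_l <- intersect_masks(masks_left$rater1, masks_left$rater2)
  inter_r <- intersect_masks(masks_right$rater1, masks_right$rater2)
  vol_up <- upsample_volume(vol, factor)
  fine_dim <- dim(vol$grid) * factor
  to_fine <- function(m) {
    if (all(m$grid_dim == fine_dim)) m
    else if (all(m$grid_dim == dim(vol$grid))) upsample_mask(m, factor)
    else stop("mask grid matches neither the native nor the upsampled volume")
  }
  up_l <- to_fine(inter_l)
  up_r <- to_fine(inter_r)
  skel_l <- skeletonize(up_l, vol_up)
  skel_r <- skeletonize(up_r, vol_up)
  anchor_up <- round((as.numeric(pons_anchor[1:2]) - 0.5) * factor + 0.5)
  slices <- sort(unique(c(skel_l$slice, skel_r$slice)))
  ref <- place_reference(vol_up, slices, anchor_up, size = ref_size)
  ctr <- compute_contrast(skel_l, skel_r, ref)
  list(contrast = ctr, skeletons = list(left = skel_l, right = skel_r),
       reference = ref, volume_up = vol_up)
}

#' Build a probabilistic LC template
#'
#' Voxelwise occupancy fraction over subjects: the sum of all binary masks
#' divided by the number of subjects. Masks must live on a common grid
#' (synthetic subjects share one space, so spatial normalization is the
#' identity; pass pre-transformed masks otherwise).
#'
#' @param masks list of \code{lc_mask} objects (one consensus mask per
#'   subject per side may be combined upstream).
#' @param n_subjects divisor; defaults to \code{length(masks)}.
#' @param voxel_size mm per axis of the common grid.
#' @return A \code{volume3d} of probabilities in [0, 1] with attribute
#'   \code{n_subjects}.
#' @export
build_probabilistic_template <- function(masks, n_subjects = length(masks),
                                         voxel_size = c(1, 1, 1)) {
  if (length(masks) == 0) stop("no masks supplied")
  d <- masks[[1]]$grid_dim
  for (m in masks) if (!all(m$grid_dim == d)) stop("masks on different grids")
  acc <- array(0, dim = d)
  for (m in masks) {
    occ <- array(FALSE, dim = d)
    occ[m$voxels] <- TRUE
    acc <- acc + occ
  }
  out <- volume3d(acc / n_subjects, voxel_size = voxel_size)
  attr(out, "n_subjects") <- n_subjects
  out
}
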
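#' 3D intensity volume
#'
#' A minimal container for a regular 3D voxel grid: an intensity array plus
#' the physical voxel size in mm per axis. The third array axis is the axial
#' (slice) direction throughout the package; voxel indices are 1-based and
#' voxel centers sit at \code{(i - 0.5) * voxel_size} in world mm, so the
#' world origin is the outer corner of voxel (1, 1, 1).
#'
#' @param grid numeric 3D array of intensities.
#' @param voxel_size numeric length-3, mm per axis (x, y, z); all > 0.
#' @return An object of class \code{volume3d}: a list with elements
#'   \code{grid} and \code{voxel_size}.
#' @export
volume3d <- function(grid, voxel_size) {
  if (length(dim(grid)) != 3L)
    stop("'grid' must be a 3D array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive values (mm)")
  structure(list(grid = grid, voxel_size = voxel_size), class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("volume3d: %s voxels @ (%s) mm\n",
              paste(dim(x$grid), collapse = " x "),
              paste(format(x$voxel_size), collapse = ", ")))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$grid)

#' 4D BOLD time series
#'
#' @param data numeric 4D array (x, y, z, volume).
#' @param voxel_size numeric length-3, mm per axis.
#' @param tr repetition time in seconds (> 0).
#' @return Object of class \code{bold4d} with elements \code{data},
#'   \code{voxel_size}, \code{tr}.
#' @export
bold4d <- function(data, voxel_size, tr) {
  if (length(dim(data)) != 4L)
    stop("'data' must be a 4D array")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("'tr' must be a positive scalar (seconds)")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  structure(list(data = data, voxel_size = voxel_size, tr = tr),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("bold4d: %d x %d x %d voxels, %d volumes, TR = %g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' Number of volumes in a BOLD series
#' @param bold a \code{bold4d} object.
#' @return Integer count of time points.
#' @export
n_volumes <- function(bold) dim(bold$data)[4L]

# Linear interpolation of an array along one axis at fractional 1-based
# index positions `at` (clamped to [1, n]: constant extrapolation at edges).
interp_axis <- function(arr, axis, at) {
  n <- dim(arr)[axis]
  at <- pmin(pmax(at, 1), n)
  lo <- pmin(floor(at), n - 1L)
  if (n == 1L) lo <- rep(1L, length(at))
  w <- at - lo
  hi <- pmin(lo + 1L, n)
  take <- function(i) {
    ind <- vector("list", 3L)
    ind[[axis]] <- i
    for (a in setdiff(1:3, axis)) ind[[a]] <- seq_len(dim(arr)[a])
    do.call(`[`, c(list(arr), ind, list(drop = FALSE)))
  }
  a_lo <- take(lo)
  a_hi <- take(hi)
  # broadcast weights along `axis`
  wd <- c(1L, 1L, 1L)
  wd[axis] <- length(at)
  warr <- array(rep(w, each = prod(dim(arr)[seq_len(axis - 1)])),
                dim = replace(dim(a_lo), axis, length(at)))
  a_lo + warr * (a_hi - a_lo)
}

#' Upsample a volume by an integer factor
#'
#' Trilinear interpolation onto a grid with \code{voxel_size / factor}.
#' The world extent of the volume is preserved: new voxel \code{j} is
#' centered at \code{(j - 0.5) * voxel_size / factor} mm and sampled from
#' the original grid at that world position (constant extrapolation within
#' the outer half-voxel margin). Constant regions are reproduced exactly,
#' and \code{factor = 1} is the identity.
#'
#' @param vol a \code{volume3d}.
#' @param factor integer upsampling factor, >= 1.
#' @return A \code{volume3d} with dimensions \code{factor * dim(vol)}.
#' @export
upsample_volume <- function(vol, factor = 2L) {
  stopifnot(inherits(vol, "volume3d"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L)
    stop("'factor' must be an integer >= 1")
  if (factor == 1L) return(vol)
  g <- vol$grid
  for (axis in 1:3) {
    n_new <- dim(vol$grid)[axis] * factor
    # new center (j-0.5)*vs/f mm falls at fractional old index pos/vs + 0.5
    at <- (seq_len(n_new) - 0.5) / factor + 0.5
    g <- interp_axis(g, axis, at)
  }
  volume3d(g, vol$voxel_size / factor)
}

#' Separable Gaussian smoothing of a volume
#'
#' Smooths with a Gaussian kernel specified by its full width at half
#' maximum in mm (the fMRI convention); the kernel is truncated at 3 sigma
#' and renormalized at the edges so constant volumes are preserved.
#'
#' @param vol a \code{volume3d}, or a plain 3D array (then \code{voxel_size}
#'   must be given).
#' @param fwhm_mm full width at half maximum in mm; 0 returns the input.
#' @param voxel_size mm per axis when \code{vol} is a plain array.
#' @return Smoothed object of the same type as the input.
#' @export
smooth_volume <- function(vol, fwhm_mm, voxel_size = NULL) {
  is_v3d <- inherits(vol, "volume3d")
  g <- if (is_v3d) vol$grid else vol
  vs <- if (is_v3d) vol$voxel_size else rep(as.numeric(voxel_size), length.out = 3)
  if (fwhm_mm < 0) stop("'fwhm_mm' must be >= 0")
  if (fwhm_mm == 0) return(vol)
  sigma_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / vs
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    half <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-half):half / s)^2)
    g <- convolve_axis(g, axis, k / sum(k))
  }
  if (is_v3d) volume3d(g, vs) else g
}

# 1D convolution along one array axis with edge renormalization.
convolve_axis <- function(arr, axis, kernel) {
  d <- dim(arr)
  n <- d[axis]
  half <- (length(kernel) - 1L) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  wsum <- numeric(n)
  for (j in seq_along(kernel)) {
    off <- j - half - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + kernel[j] * m[src[ok], , drop = FALSE]
    wsum[ok] <- wsum[ok] + kernel[j]
  }
  out <- out / wsum
  a <- array(out, dim = d[perm])
  aperm(a, order(perm))
}

#' Write / read a volume as NIfTI-1
#'
#' Thin wrappers over \pkg{RNifti} that carry the voxel size in the pixdim
#' header field. BOLD series store TR as the fourth pixdim.
#'
#' @param vol a \code{volume3d} or \code{bold4d}.
#' @param path output file path (".nii" or ".nii.gz").
#' @return \code{write_nifti_volume} returns \code{path} invisibly;
#'   \code{read_nifti_volume} returns a \code{volume3d} or \code{bold4d}.
#' @export
write_nifti_volume <- function(vol, path) {
  if (inherits(vol, "volume3d")) {
    img <- RNifti::asNifti(vol$grid)
    RNifti::pixdim(img) <- vol$voxel_size
  } else if (inherits(vol, "bold4d")) {
    img <- RNifti::asNifti(vol$data)
    RNifti::pixdim(img) <- c(vol$voxel_size, vol$tr)
  } else stop("'vol' must be a volume3d or bold4d")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @param path input file path.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) {
    volume3d(arr, pd[1:3])
  } else if (length(dim(arr)) == 4L) {
    bold4d(arr, pd[1:3], tr = pd[4])
  } else stop("unsupported NIfTI dimensionality")
}
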
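#' Volume geometry
#'
#' Describes the sampling grid of a volume: matrix size, voxel spacing and
#' world origin. Voxel indices are 0-based; world coordinates are RAS
#' millimeters; world position of voxel `(i, j, k)` is
#' `origin + spacing * (i, j, k)` (axis-aligned grids).
#'
#' @param shape integer vector of length 3 (voxels per axis).
#' @param spacing voxel size in mm per axis (scalar or length 3).
#' @param origin world position of voxel (0, 0, 0) in mm.
#' @return An object of class `volume_geometry`.
#' @export
volume_geometry <- function(shape, spacing = 1, origin = 0) {
  shape <- as.integer(rep_len(shape, 3))
  spacing <- rep_len(as.numeric(spacing), 3)
  origin <- rep_len(as.numeric(origin), 3)
  if (any(shape < 1)) stop("shape must be positive")
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "volume_geometry")
}

geom_affine <- function(geom) {
  A <- diag(4)
  diag(A)[1:3] <- geom$spacing
  A[1:3, 4] <- geom$origin
  A
}

#' Resample a volume onto a target grid through a rigid affine
#'
#' Samples the input volume on the target geometry's grid after mapping
#' each target world coordinate through the inverse of `transform`
#' (a 4x4 world-to-world affine, input <- transform . target in the moving
#' image convention: the transform maps target-space points into the
#' input's world frame). Out-of-field voxels are 0. `"nearest"` must be
#' used for label volumes so no new label values are invented.
#'
#' @param vol 3D numeric array.
#' @param geom a [volume_geometry()] for `vol`.
#' @param target a [volume_geometry()] for the output grid.
#' @param transform 4x4 affine matrix (default identity).
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return 3D array with dim `target$shape` and attribute `"geometry"`.
#' @export
resample_volume <- function(vol, geom, target, transform = diag(4),
                            interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(geom, "volume_geometry"),
            inherits(target, "volume_geometry"))
  transform <- as.matrix(transform)
  if (!all(dim(transform) == c(4, 4)) ||
      abs(det(transform)) < 1e-12)
    stop("transform must be an invertible 4x4 affine")
  if (!all(dim(vol) == geom$shape)) stop("volume does not match its geometry")

  tg <- target$shape
  ii <- seq_len(tg[1]) - 1; jj <- seq_len(tg[2]) - 1; kk <- seq_len(tg[3]) - 1
  pts <- cbind(
    rep(ii, times = tg[2] * tg[3]),
    rep(rep(jj, each = tg[1]), times = tg[3]),
    rep(kk, each = tg[1] * tg[2]))
  world <- sweep(sweep(pts, 2, target$spacing, "*"), 2, target$origin, "+")
  moved <- cbind(world, 1) %*% t(transform)
  # continuous voxel coordinates in the input grid (0-based)
  vc <- sweep(sweep(moved[, 1:3, drop = FALSE], 2, geom$origin, "-"),
              2, geom$spacing, "/")

  out <- if (interpolation == "nearest") {
    nn <- round(vc)
    inside <- nn[, 1] >= 0 & nn[, 1] <= geom$shape[1] - 1 &
              nn[, 2] >= 0 & nn[, 2] <= geom$shape[2] - 1 &
              nn[, 3] >= 0 & nn[, 3] <= geom$shape[3] - 1
    v <- numeric(nrow(nn))
    lin <- nn[inside, 1] + geom$shape[1] *
      (nn[inside, 2] + geom$shape[2] * nn[inside, 3])
    v[inside] <- vol[lin + 1]
    v
  } else {
    trilinear_sample(vol, vc)
  }
  out <- array(out, dim = tg)
  attr(out, "geometry") <- target
  out
}

# Vectorized trilinear interpolation at continuous 0-based voxel coords;
# points outside the field of view evaluate to 0 (zero boundary).
trilinear_sample <- function(vol, vc) {
  d <- dim(vol)
  f <- floor(vc)
  w <- vc - f
  acc <- numeric(nrow(vc))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    xi <- f[, 1] + dx; yi <- f[, 2] + dy; zi <- f[, 3] + dz
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    inside <- xi >= 0 & xi <= d[1] - 1 & yi >= 0 & yi <= d[2] - 1 &
              zi >= 0 & zi <= d[3] - 1 & wt > 0
    if (any(inside)) {
      lin <- xi[inside] + d[1] * (yi[inside] + d[2] * zi[inside])
      acc[inside] <- acc[inside] + wt[inside] * vol[lin + 1]
    }
  }
  acc
}

#' Normalize volume intensities to \[0, 1\]
#'
#' Divides by the maximum voxel intensity so the brightest voxel is
#' exactly 1 and relative intensities are preserved; invariant to global
#' positive scaling of the input.
#' @param vol numeric array with at least one positive value.
#' @return array of the same shape.
#' @export
normalize_intensity <- function(vol) {
  m <- max(vol)
  if (!is.finite(m) || m <= 0)
    stop("cannot normalize a volume with non-positive maximum")
  vol / m
}

#' Apply a skull-strip (brain) mask
#'
#' Zeroes every voxel outside the mask.
#' @param vol numeric array.
#' @param mask logical/0-1 array of the same shape.
#' @return masked array.
#' @export
apply_brain_mask <- function(vol, mask) {
  if (!all(dim(vol) == dim(mask)))
    stop("mask geometry does not match the volume")
  vol * (as.numeric(mask) != 0)
}

#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti keeping the qform/sform affine intact.
#' `write_volume` accepts a [volume_geometry()] to set spacing/origin.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol numeric array (3D, or 4D for multi-channel SV volumes).
#' @param geom optional [volume_geometry()].
#' @return `read_volume`: the array with a `"geometry"` attribute.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  pix <- attr(img, "pixdim")
  if (is.null(pix)) pix <- rep(1, 3)
  orig <- RNifti::xform(img)[1:3, 4]
  attr(arr, "geometry") <- volume_geometry(dim(arr)[1:3],
                                           abs(pix[1:3]), orig)
  arr
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path, geom = NULL) {
  a <- as.array(vol)
  attr(a, "geometry") <- NULL
  img <- RNifti::asNifti(a)
  if (!is.null(geom)) {
    # NIfTI xforms are RAS; our axis-aligned geometry maps directly
    RNifti::pixdim(img) <- geom$spacing
    RNifti::qform(img) <- structure(geom_affine(geom), code = 2L)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4x4 affine from a whitespace-delimited text file
#' @param path text file with four rows of four numbers.
#' @return 4x4 numeric matrix.
#' @export
read_affine <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  if (!all(dim(m) == c(4, 4))) stop("affine file must be 4x4")
  m
}
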
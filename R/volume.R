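#' Scalar volumes and binary masks
#'
#' A `scalar_volume` is a 3D numeric grid with a voxel-to-world affine, a
#' units tag and a validity mask. It carries quantitative maps (R1 in s^-1,
#' MD in mm^2/s) or arbitrary-unit images. Invalid voxels (e.g. masked-out
#' ventricles, non-converged relaxometry fits) have `valid = FALSE`; their
#' grid values are not meaningful and are written to file as NaN.
#'
#' @param grid 3D numeric array.
#' @param affine An [affine4x4] mapping 0-based voxel indices to RAS mm.
#' @param units One of `"s^-1"`, `"mm^2/s"`, `"a.u."`.
#' @param valid Logical array of the same shape as `grid`; defaults to
#'   finite entries of `grid`.
#' @return A `scalar_volume` object.
#' @export
scalar_volume <- function(grid, affine, units = "a.u.", valid = NULL) {
  if (length(dim(grid)) != 3L) stop("grid must be a 3D array")
  units <- match.arg(units, c("a.u.", "s^-1", "mm^2/s"))
  if (is.null(valid)) valid <- is.finite(grid)
  if (!identical(dim(valid), dim(grid)))
    stop("grid and valid must have identical shapes")
  valid <- valid & is.finite(grid)
  storage.mode(grid) <- "double"
  structure(
    list(grid = grid, affine = affine4x4(affine), units = units,
         valid = array(as.logical(valid), dim(grid))),
    class = "scalar_volume")
}

#' @rdname scalar_volume
#' @param x Object to test.
#' @export
is_scalar_volume <- function(x) inherits(x, "scalar_volume")

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume> %s, dim %s, %d/%d valid voxels\n",
              x$units, paste(dim(x$grid), collapse = "x"),
              sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Binary mask on a voxel grid
#'
#' @param grid Logical (or 0/1 numeric) 3D array.
#' @param affine An [affine4x4].
#' @return A `binary_mask` object.
#' @export
binary_mask <- function(grid, affine) {
  if (length(dim(grid)) != 3L) stop("mask grid must be a 3D array")
  g <- array(as.logical(grid), dim(grid))
  g[is.na(g)] <- FALSE
  structure(list(grid = g, affine = affine4x4(affine)), class = "binary_mask")
}

#' @rdname binary_mask
#' @param x Object to test.
#' @export
is_binary_mask <- function(x) inherits(x, "binary_mask")

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> dim %s, %d set voxels\n",
              paste(dim(x$grid), collapse = "x"), sum(x$grid)))
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$grid), dim(b$grid)) &&
    max(abs(unclass(a$affine) - unclass(b$affine))) <= tol
}

rnifti_with_affine <- function(data, affine) {
  img <- RNifti::asNifti(data)
  RNifti::`sform<-`(img, structure(unclass(affine), code = 2L))
}

#' Read a NIfTI-1 scalar volume
#'
#' Reads a single 3D image. Voxels stored as NaN become `valid = FALSE`.
#' The sform (falling back to qform) provides the voxel-to-world affine.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param units Units tag to attach (NIfTI does not carry these units).
#' @return A [scalar_volume].
#' @export
read_volume <- function(path, units = "a.u.") {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) != 3L)
    stop(sprintf("expected a 3D image, got %dD: %s", length(dim(a)), path))
  aff <- affine4x4(structure(RNifti::xform(img), dim = c(4, 4)))
  scalar_volume(a, aff, units = units)
}

#' Write a scalar volume to NIfTI-1
#'
#' Invalid voxels are written as NaN so that validity round-trips.
#'
#' @param vol A [scalar_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_scalar_volume(vol))
  g <- vol$grid
  g[!vol$valid] <- NaN
  RNifti::writeNifti(rnifti_with_affine(g, vol$affine), path)
  invisible(path)
}

#' Read / write a binary mask as NIfTI-1
#'
#' Nonzero voxels are set; NaN counts as unset.
#'
#' @param path NIfTI file path.
#' @return A [binary_mask] (`read_mask`), or `path` invisibly (`write_mask`).
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  g <- v$grid != 0 & v$valid
  binary_mask(g, v$affine)
}

#' @rdname read_mask
#' @param mask A [binary_mask].
#' @export
write_mask <- function(mask, path) {
  stopifnot(is_binary_mask(mask))
  RNifti::writeNifti(
    rnifti_with_affine(array(as.numeric(mask$grid), dim(mask$grid)),
                       mask$affine), path)
  invisible(path)
}

#' Read / write a 4D inversion-recovery magnitude series
#'
#' @param path NIfTI file path holding a 4D image (x, y, z, inversion time).
#' @return A list with `data` (4D array) and `affine` (for the spatial axes).
#' @export
read_ir_series <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) != 4L)
    stop(sprintf("expected a 4D series, got %dD: %s", length(dim(a)), path))
  list(data = a, affine = affine4x4(structure(RNifti::xform(img), dim = c(4, 4))))
}

#' @rdname read_ir_series
#' @param data 4D numeric array.
#' @param affine Spatial [affine4x4].
#' @export
write_ir_series <- function(data, affine, path) {
  if (length(dim(data)) != 4L) stop("series must be 4D")
  RNifti::writeNifti(rnifti_with_affine(data, affine), path)
  invisible(path)
}

#' Trilinear interpolation of a scalar volume at world points
#'
#' In `"strict"` missing mode (the default) a sample is missing (NA) when any
#' of the 8 surrounding voxels is invalid or outside the grid: this keeps
#' partial-volume leakage from masked structures (e.g. ventricles) out of
#' tract profiles. In `"lenient"` mode the interpolation weights are
#' renormalised over the valid neighbours, and a sample is missing only when
#' all 8 neighbours are invalid.
#'
#' @param vol A [scalar_volume].
#' @param points n x 3 matrix of RAS-mm coordinates.
#' @param missing Missing-data policy, `"strict"` or `"lenient"`.
#' @return Numeric vector of length n with NA where missing.
#' @export
interp_trilinear <- function(vol, points, missing = c("strict", "lenient")) {
  missing <- match.arg(missing)
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  n <- nrow(p)
  dims <- dim(vol$grid)
  vc <- world_to_voxel(p, vol$affine)
  i0 <- floor(vc)
  fr <- vc - i0
  vals <- numeric(n)
  wsum <- numeric(n)
  bad <- logical(n)
  grid <- vol$grid
  valid <- vol$valid
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ii <- i0[, 1] + dx; jj <- i0[, 2] + dy; kk <- i0[, 3] + dz
    w <- (if (dx == 1) fr[, 1] else 1 - fr[, 1]) *
         (if (dy == 1) fr[, 2] else 1 - fr[, 2]) *
         (if (dz == 1) fr[, 3] else 1 - fr[, 3])
    inside <- ii >= 0 & ii < dims[1] & jj >= 0 & jj < dims[2] &
              kk >= 0 & kk < dims[3]
    lin <- rep(NA_integer_, n)
    lin[inside] <- 1L + ii[inside] + dims[1] * (jj[inside] + dims[2] * kk[inside])
    ok <- inside
    ok[inside] <- valid[lin[inside]]
    contrib <- ok & w > 0
    # a zero-weight neighbour cannot leak values, but in strict mode an
    # invalid neighbour with nonzero weight poisons the sample
    bad <- bad | (!ok & w > 0)
    vals[contrib] <- vals[contrib] + w[contrib] * grid[lin[contrib]]
    wsum[contrib] <- wsum[contrib] + w[contrib]
  }
  out <- ifelse(wsum > 0, vals / wsum, NA_real_)
  if (missing == "strict") out[bad] <- NA_real_
  out
}
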
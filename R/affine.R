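#' 4x4 voxel-to-world affine transforms
#'
#' An affine maps 0-based voxel indices (i, j, k, 1) to RAS millimetre
#' coordinates (x, y, z, 1), following the NIfTI convention: the origin of
#' voxel (0,0,0) is the *centre* of the first voxel. All package-internal
#' world coordinates are RAS mm; in AC-PC aligned data (0,0,0) is the
#' anterior commissure.
#'
#' @param matrix A numeric 4x4 matrix; the bottom row must be (0,0,0,1) and
#'   the matrix must be invertible.
#' @return An object of class `affine4x4` (a plain 4x4 matrix with a class
#'   attribute).
#' @export
affine4x4 <- function(matrix) {
  if (length(matrix) != 16L) stop("affine must be a 4x4 matrix")
  m <- base::matrix(as.double(matrix), 4L, 4L)  # strips stray attributes
  if (!identical(dim(m), c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (!isTRUE(all(m[4, ] == c(0, 0, 0, 1))))
    stop("affine bottom row must be exactly (0, 0, 0, 1)")
  d <- det(m[1:3, 1:3])
  if (!is.finite(d) || abs(d) < .Machine$double.eps * 100)
    stop("affine is singular (non-invertible)")
  structure(m, class = "affine4x4")
}

#' @rdname affine4x4
#' @param x Object to test.
#' @export
is_affine4x4 <- function(x) inherits(x, "affine4x4")

#' Construct a scaling + translation affine
#'
#' Convenience constructor for the common case of axis-aligned voxels.
#'
#' @param voxel_mm Voxel edge lengths in mm (length 1 or 3).
#' @param origin_mm World coordinate of the centre of voxel (0,0,0).
#' @return An `affine4x4`.
#' @export
affine_scale <- function(voxel_mm, origin_mm = c(0, 0, 0)) {
  v <- rep_len(as.numeric(voxel_mm), 3L)
  m <- diag(4)
  m[1, 1] <- v[1]; m[2, 2] <- v[2]; m[3, 3] <- v[3]
  m[1:3, 4] <- as.numeric(origin_mm)
  affine4x4(m)
}

#' Invert an affine
#' @param affine An `affine4x4`.
#' @return The inverse `affine4x4`.
#' @export
affine_inverse <- function(affine) {
  affine4x4(solve(unclass(affine)))
}

#' Apply an affine to points
#'
#' @param affine An `affine4x4`.
#' @param points An n x 3 matrix (or length-3 vector) of coordinates.
#' @return An n x 3 matrix of transformed coordinates.
#' @export
apply_affine <- function(affine, points) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  stopifnot(ncol(p) == 3)
  m <- unclass(affine)
  out <- p %*% t(m[1:3, 1:3]) +
    matrix(m[1:3, 4], nrow(p), 3, byrow = TRUE)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Convert between world (RAS mm) and 0-based voxel coordinates
#'
#' `world_to_voxel` returns continuous 0-based voxel coordinates; a point is
#' inside voxel (i,j,k) iff its rounded continuous coordinate equals (i,j,k),
#' i.e. half-open boxes \[i-0.5, i+0.5) centred on voxel centres.
#'
#' @param points n x 3 matrix of coordinates.
#' @param affine The voxel-to-world `affine4x4`.
#' @return n x 3 matrix.
#' @export
world_to_voxel <- function(points, affine) {
  apply_affine(affine_inverse(affine), points)
}

#' @rdname world_to_voxel
#' @export
voxel_to_world <- function(points, affine) {
  apply_affine(affine, points)
}

#' @export
print.affine4x4 <- function(x, ...) {
  cat("<affine4x4> voxel (0-based) -> RAS mm\n")
  print(unclass(x))
  invisible(x)
}
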
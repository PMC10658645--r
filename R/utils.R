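#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats sd median rnorm fft optim var setNames
#' @importFrom utils head tail read.csv write.csv
NULL

# Shared coordinate convention
# ----------------------------
# Voxel centers on a grid of M_d voxels per axis d sit at FOV-normalized
# positions x~_j = (j - floor(M_d/2)) / M_d, j = 0..M_d-1, so integer k-space
# coordinates are cycles per FOV and the encoding exponential exp(-2i*pi*k*x~)
# reduces to a DFT on integer-k schemes.  Voxel linearization is x fastest,
# then y, then z (column-major order of an array dim = grid_shape).

#' FOV-normalized voxel-center coordinates along one axis
#' @param m number of voxels along the axis
#' @return numeric vector of length `m`, values in \[-1/2, 1/2)
#' @keywords internal
axis_coords <- function(m) {
  (seq_len(m) - 1 - floor(m / 2)) / m
}

#' Voxel-center coordinate table for a grid
#'
#' Returns the FOV-normalized coordinates of every voxel center of a 3D grid,
#' in the package-wide linearization order (x fastest, then y, then z).
#'
#' @param grid_shape integer triple of voxels per axis
#' @return a numeric matrix with `prod(grid_shape)` rows and columns
#'   `x`, `y`, `z` (cycles-per-FOV units)
#' @export
voxel_centers <- function(grid_shape) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  cx <- axis_coords(grid_shape[1])
  cy <- axis_coords(grid_shape[2])
  cz <- axis_coords(grid_shape[3])
  out <- cbind(
    x = rep(cx, times = grid_shape[2] * grid_shape[3]),
    y = rep(rep(cy, each = grid_shape[1]), times = grid_shape[3]),
    z = rep(cz, each = grid_shape[1] * grid_shape[2])
  )
  out
}

#' Moore-Penrose pseudoinverse of a complex matrix
#'
#' SVD-based pseudoinverse with the rank tolerance
#' `max(dim(a)) * .Machine$double.eps * max(singular values)`.
#'
#' @param a complex (or numeric) matrix
#' @param tol optional absolute singular-value cutoff; default as above
#' @return list with elements `pinv` (the pseudoinverse), `rank`, and
#'   `condition` (ratio of largest to smallest retained singular value)
#' @keywords internal
pinv_svd <- function(a, tol = NULL) {
  sv <- svd(a)
  if (is.null(tol)) tol <- max(dim(a)) * .Machine$double.eps * max(sv$d)
  keep <- sv$d > tol
  r <- sum(keep)
  if (r == 0) abort("matrix is numerically zero; pseudoinverse undefined")
  dinv <- 1 / sv$d[keep]
  pinv <- sv$v[, keep, drop = FALSE] %*%
    (dinv * Conj(t(sv$u[, keep, drop = FALSE])))
  list(pinv = pinv, rank = r, condition = max(sv$d[keep]) / min(sv$d[keep]))
}

#' Normalized sinc, sinc(z) = sin(pi z) / (pi z)
#' @keywords internal
sinc <- function(z) {
  out <- rep(1, length(z))
  nz <- z != 0
  out[nz] <- sin(pi * z[nz]) / (pi * z[nz])
  out
}

#' Circular complex white noise
#'
#' Real and imaginary parts are independent N(0, sd^2).
#' @keywords internal
crnorm <- function(n, sd = 1) {
  complex(real = rnorm(n, sd = sd), imaginary = rnorm(n, sd = sd))
}

#' Discrete Fourier transform of time signals to spectra
#'
#' Applies the package-wide spectral convention: `fft()` along the time axis of
#' a C x N matrix (rows are signals), no scaling.
#' @keywords internal
time_to_spectrum <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  t(apply(x, 1, fft))
}

assert_grid_shape <- function(grid_shape, what = "grid_shape") {
  if (length(grid_shape) != 3 || any(grid_shape < 1) ||
      any(grid_shape != round(grid_shape))) {
    abort(sprintf("%s must be a positive integer triple", what))
  }
  as.integer(grid_shape)
}

assert_fov <- function(fov_mm) {
  if (length(fov_mm) != 3 || any(fov_mm <= 0)) {
    abort("fov_mm must be a positive real triple (mm)")
  }
  as.numeric(fov_mm)
}
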
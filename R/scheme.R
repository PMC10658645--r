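# Phase-encode schemes
#
# A scheme is the ordered table of k-space coordinates k_m (cycles per FOV)
# with their repeat counts R_m.  The repeat counts of an acquisition-weighted
# (AW) scheme act as an apodizing window on k-space; data for repeated encodes
# are stored SUMMED over the R_m repeats throughout the package, so R_m
# appears in the encoding operators rather than in the data.

#' Construct a phase-encode scheme
#'
#' A `pe_scheme` is a tibble with one row per recorded phase encode and
#' columns `kx`, `ky`, `kz` (cycles per FOV; integer-valued for Fourier
#' schemes, fractional for fSLAM-optimized schemes) and `repeats` (the number
#' of repeats R_m summed into the stored data).  The full nominal matrix and
#' the field of view travel along as attributes.
#'
#' @param k_coords numeric matrix (M' x 3) or data frame with columns
#'   kx, ky, kz, in cycles per FOV
#' @param repeats positive integer vector of length M'
#' @param fov_mm field of view in mm (length-3)
#' @param matrix_shape nominal full encoding matrix (length-3 integer)
#' @return a `pe_scheme` tibble
#' @export
pe_scheme <- function(k_coords, repeats, fov_mm, matrix_shape) {
  if (is.data.frame(k_coords)) {
    k_coords <- as.matrix(k_coords[, c("kx", "ky", "kz")])
  }
  k_coords <- matrix(as.numeric(k_coords), ncol = 3)
  if (nrow(k_coords) < 1) abort("a scheme needs at least one phase encode")
  if (length(repeats) != nrow(k_coords)) {
    abort("repeats must have one entry per phase encode")
  }
  repeats <- as.integer(repeats)
  if (any(repeats < 1)) abort("all repeat counts R_m must be >= 1")
  if (anyDuplicated(asplit(k_coords, 1))) {
    abort("k-space coordinates must be unique")
  }
  out <- tibble(
    kx = k_coords[, 1], ky = k_coords[, 2], kz = k_coords[, 3],
    repeats = repeats
  )
  attr(out, "fov_mm") <- assert_fov(fov_mm)
  attr(out, "matrix_shape") <- assert_grid_shape(matrix_shape, "matrix_shape")
  class(out) <- c("pe_scheme", class(out))
  out
}

#' @export
print.pe_scheme <- function(x, ...) {
  cat(sprintf(
    "<pe_scheme> %d encodes, %d total readouts, matrix %s, FOV %s mm\n",
    nrow(x), total_readouts(x),
    paste(attr(x, "matrix_shape"), collapse = "x"),
    paste(attr(x, "fov_mm"), collapse = "x")
  ))
  NextMethod()
}

#' Total number of readouts of a scheme
#'
#' The sum of the per-encode repeat counts; with one readout per TR this is
#' proportional to scan time.
#'
#' @param scheme a [pe_scheme()]
#' @return integer scalar
#' @export
total_readouts <- function(scheme) {
  sum(scheme$repeats)
}

scheme_k_matrix <- function(scheme) {
  cbind(scheme$kx, scheme$ky, scheme$kz)
}

scheme_is_integer <- function(scheme, tol = 1e-9) {
  k <- scheme_k_matrix(scheme)
  all(abs(k - round(k)) < tol)
}

# Separable k-space apodization windows, normalized to w(0) = 1.  k is in
# cycles/FOV on a matrix of m points (k in -floor(m/2) .. ceil(m/2)-1).
window_1d <- function(k, m, name) {
  switch(name,
    hamming = if (m == 1) rep(1, length(k)) else
      (0.54 + 0.46 * cos(2 * pi * k / m)),
    hann = if (m == 1) rep(1, length(k)) else
      (0.5 + 0.5 * cos(2 * pi * k / m)),
    uniform = rep(1, length(k)),
    abort(sprintf(
      "unknown weighting '%s'; supported windows: hamming, hann, uniform",
      name
    ))
  )
}

integer_k_axis <- function(m) seq.int(-floor(m / 2), ceiling(m / 2) - 1)

full_integer_grid <- function(matrix_shape) {
  kx <- integer_k_axis(matrix_shape[1])
  ky <- integer_k_axis(matrix_shape[2])
  kz <- integer_k_axis(matrix_shape[3])
  cbind(
    rep(kx, times = length(ky) * length(kz)),
    rep(rep(ky, each = length(kx)), times = length(kz)),
    rep(kz, each = length(kx) * length(ky))
  )
}

#' Acquisition-weighted phase-encode scheme
#'
#' Builds a 3D acquisition-weighted (AW) scheme on the full integer k-space
#' grid of `matrix_shape`, with repeat counts following a separable
#' apodization window scaled so that the k-space center receives
#' `center_averages` repeats: R(k) = round(center_averages * w(k)).
#' With `drop_zero = TRUE` (the default, the hard-threshold variant) encodes
#' whose rounded repeat count is zero are omitted, which confines the readouts
#' to roughly the same scan-time budget as a truncated scheme with the same
#' averaging; with `drop_zero = FALSE` every encode is kept with
#' R(k) = max(1, round(center_averages * w(k))).
#'
#' @param matrix_shape full integer matrix, e.g. `c(8, 16, 8)`
#' @param center_averages repeats at k = (0,0,0) (>= 1)
#' @param weighting window name: `"hamming"` (default), `"hann"`, `"uniform"`
#' @param fov_mm field of view in mm
#' @param drop_zero drop encodes with rounded repeat count 0 (default TRUE)
#' @return a [pe_scheme()]
#' @export
make_aw_scheme <- function(matrix_shape, center_averages = 4,
                           weighting = "hamming",
                           fov_mm = c(240, 240, 200),
                           drop_zero = TRUE) {
  matrix_shape <- assert_grid_shape(matrix_shape, "matrix_shape")
  if (center_averages < 1) abort("center_averages must be >= 1")
  k <- full_integer_grid(matrix_shape)
  w <- window_1d(k[, 1], matrix_shape[1], weighting) *
    window_1d(k[, 2], matrix_shape[2], weighting) *
    window_1d(k[, 3], matrix_shape[3], weighting)
  r <- round(center_averages * w)
  if (drop_zero) {
    keep <- r > 0
    k <- k[keep, , drop = FALSE]
    r <- r[keep]
  } else {
    r <- pmax(1, r)
  }
  pe_scheme(k, r, fov_mm, matrix_shape)
}

#' Central (truncated) phase-encode scheme
#'
#' The `sub_shape` block of integer k-space coordinates nearest the k-space
#' origin of the full `matrix_shape` grid, each acquired with `averages`
#' repeats.  For an even sub-shape s the block is k in \{-s/2, ..., s/2 - 1\}
#' per axis (DFT-consistent).
#'
#' @param matrix_shape full nominal matrix
#' @param sub_shape truncated block, e.g. `c(4, 4, 4)`
#' @param averages repeats at every retained encode
#' @param fov_mm field of view in mm
#' @return a [pe_scheme()]
#' @export
make_central_scheme <- function(matrix_shape, sub_shape = c(4, 4, 4),
                                averages = 6, fov_mm = c(240, 240, 200)) {
  matrix_shape <- assert_grid_shape(matrix_shape, "matrix_shape")
  sub_shape <- assert_grid_shape(sub_shape, "sub_shape")
  if (any(sub_shape > matrix_shape)) {
    abort("sub_shape must not exceed matrix_shape on any axis")
  }
  if (averages < 1) abort("averages must be >= 1")
  kx <- integer_k_axis(sub_shape[1])
  ky <- integer_k_axis(sub_shape[2])
  kz <- integer_k_axis(sub_shape[3])
  k <- cbind(
    rep(kx, times = length(ky) * length(kz)),
    rep(rep(ky, each = length(kx)), times = length(kz)),
    rep(kz, each = length(kx) * length(ky))
  )
  pe_scheme(k, rep(averages, nrow(k)), fov_mm, matrix_shape)
}

#' Write / read a phase-encode scheme as CSV
#'
#' Columns `kx`, `ky`, `kz` (cycles per FOV) and `repeats`; the FOV and
#' nominal matrix are stored in commented header lines.  Round-trip is
#' lossless to 12 significant digits.
#'
#' @param scheme a [pe_scheme()]
#' @param path file path
#' @return `write_scheme_csv` returns `path` invisibly; `read_scheme_csv`
#'   returns a [pe_scheme()]
#' @export
write_scheme_csv <- function(scheme, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# fov_mm: %s", paste(format(attr(scheme, "fov_mm"), digits = 12),
                          collapse = " ")), con)
  writeLines(sprintf(
    "# matrix_shape: %s", paste(attr(scheme, "matrix_shape"),
                                collapse = " ")), con)
  writeLines("kx,ky,kz,repeats", con)
  k <- scheme_k_matrix(scheme)
  writeLines(paste(
    format(k[, 1], digits = 12, trim = TRUE, scientific = FALSE),
    format(k[, 2], digits = 12, trim = TRUE, scientific = FALSE),
    format(k[, 3], digits = 12, trim = TRUE, scientific = FALSE),
    scheme$repeats, sep = ","
  ), con)
  invisible(path)
}

#' @rdname write_scheme_csv
#' @export
read_scheme_csv <- function(path) {
  hdr <- readLines(path, n = 2)
  parse_hdr <- function(lines, key) {
    ln <- grep(paste0("^# ", key, ":"), lines, value = TRUE)
    if (length(ln) != 1) abort(sprintf("scheme CSV missing '%s' header", key))
    as.numeric(strsplit(sub(paste0("^# ", key, ": *"), "", ln), " +")[[1]])
  }
  fov <- parse_hdr(hdr, "fov_mm")
  mat <- parse_hdr(hdr, "matrix_shape")
  tab <- read.csv(path, comment.char = "#")
  pe_scheme(as.matrix(tab[, c("kx", "ky", "kz")]), tab$repeats, fov, mat)
}
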
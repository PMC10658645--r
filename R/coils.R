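# Surface-coil receive sensitivity via the Biot-Savart law
#
# Each coil element is a circular current loop discretized into straight
# segments; the receive sensitivity at a voxel is taken as the magnitude of
# the loop's magnetic field per unit current there.  Lengths are in mm, so
# fields are in units of mu0 * I / mm; only relative sensitivity matters for
# the reconstruction and SRF weighting.

#' Coil geometry of circular loop elements
#'
#' @param loops list of loops, each a list with `center_mm` (length-3),
#'   `normal` (unit length-3), `radius_mm` (> 0) and optionally
#'   `n_segments` (>= 8, default 64)
#' @return a `coil_geometry` object
#' @export
coil_geometry <- function(loops) {
  loops <- lapply(loops, function(lp) {
    if (is.null(lp$n_segments)) lp$n_segments <- 64L
    if (lp$radius_mm <= 0) abort("loop radius_mm must be > 0")
    if (lp$n_segments < 8) abort("loops need n_segments >= 8")
    nrm <- sqrt(sum(lp$normal^2))
    if (abs(nrm - 1) > 1e-9) abort("loop normals must have unit length")
    lp
  })
  structure(list(loops = loops), class = "coil_geometry")
}

#' Two-loop 31P surface coil
#'
#' The default transmit-receive geometry emulated by the package: two 15-cm
#' circular loops, overlapped for decoupling, lying anterior to the chest
#' (low y), both facing the +y direction.
#'
#' @param radius_mm loop radius (default 75)
#' @param y_mm anterior loop-plane position (default -160)
#' @param overlap_mm center-to-center x offset of the two loops (default 110)
#' @return a `coil_geometry` with two loops
#' @export
default_cardiac_coil <- function(radius_mm = 75, y_mm = -160,
                                 overlap_mm = 110) {
  coil_geometry(list(
    list(center_mm = c(-overlap_mm / 2, y_mm, 0), normal = c(0, 1, 0),
         radius_mm = radius_mm),
    list(center_mm = c(overlap_mm / 2, y_mm, 0), normal = c(0, 1, 0),
         radius_mm = radius_mm)
  ))
}

loop_segments <- function(lp) {
  n <- lp$n_segments
  nrm <- lp$normal
  ref <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * nrm) * nrm
  u <- u / sqrt(sum(u^2))
  v <- c(
    nrm[2] * u[3] - nrm[3] * u[2],
    nrm[3] * u[1] - nrm[1] * u[3],
    nrm[1] * u[2] - nrm[2] * u[1]
  )
  th <- 2 * pi * (seq_len(n + 1) - 1) / n
  pts <- outer(cos(th), lp$radius_mm * u) + outer(sin(th), lp$radius_mm * v)
  pts <- sweep(pts, 2, lp$center_mm, `+`)
  list(
    mid = (pts[-1, , drop = FALSE] + pts[-(n + 1), , drop = FALSE]) / 2,
    dl = pts[-1, , drop = FALSE] - pts[-(n + 1), , drop = FALSE]
  )
}

#' Biot-Savart receive-sensitivity maps
#'
#' Returns the magnitude of the magnetic field per unit current of each coil
#' loop at every voxel center, from a segment-wise Biot-Savart sum.  Voxels
#' within `exclusion_mm` of any wire segment midpoint are zeroed (the
#' quasi-static simulation is not valid immediately next to the conductors).
#'
#' @param coils a [coil_geometry()]
#' @param grid_shape reconstruction grid (integer triple)
#' @param fov_mm field of view in mm
#' @param exclusion_mm zeroing radius around wire segments (default 15)
#' @return numeric matrix (voxels x loops), voxel linearization x fastest
#' @export
biot_savart_sensitivity <- function(coils, grid_shape,
                                    fov_mm = c(240, 240, 200),
                                    exclusion_mm = 15) {
  grid_shape <- assert_grid_shape(grid_shape)
  fov_mm <- assert_fov(fov_mm)
  pts <- sweep(voxel_centers(grid_shape), 2, fov_mm, `*`)
  out <- matrix(0, nrow(pts), length(coils$loops))
  mu0_over_4pi <- 1e-7  # mu0/(4 pi) with mu0 = 4e-7 pi; lengths in mm
  for (li in seq_along(coils$loops)) {
    seg <- loop_segments(coils$loops[[li]])
    b <- matrix(0, nrow(pts), 3)
    mind2 <- rep(Inf, nrow(pts))
    for (si in seq_len(nrow(seg$mid))) {
      r <- sweep(pts, 2, seg$mid[si, ], `-`)
      r2 <- rowSums(r^2)
      mind2 <- pmin(mind2, r2)
      inv_r3 <- 1 / (r2 * sqrt(r2))
      dl <- seg$dl[si, ]
      b <- b + inv_r3 * cbind(
        dl[2] * r[, 3] - dl[3] * r[, 2],
        dl[3] * r[, 1] - dl[1] * r[, 3],
        dl[1] * r[, 2] - dl[2] * r[, 1]
      )
    }
    mag <- mu0_over_4pi * sqrt(rowSums(b^2))
    mag[mind2 < exclusion_mm^2] <- 0
    out[, li] <- mag
  }
  out
}
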
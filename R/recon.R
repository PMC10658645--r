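# Compartment and Fourier reconstruction
#
# SLAM: the discrete-Fourier phase-encode matrix, with rows weighted by the
# repeat counts R_m, has its voxel columns summed (per-voxel-mean normalized)
# within each compartment; the compressed M' x C matrix is pseudoinverted and
# applied to the repeat-summed data.  SLIM replaces the compartment column
# sums by continuous-Fourier integrals of the encoding basis over the
# compartment volumes, which for a voxelized mask evaluate in closed form as
# per-axis sinc factors.  FT-MRS is the standard (inverse-DFT) voxel
# reconstruction, in which the acquisition weights act as k-space apodization.

#' Compartment mask
#'
#' @param label_map integer 3D array of per-voxel labels on the
#'   reconstruction grid (voxels outside every compartment may carry a label
#'   not listed in `compartment_ids`, conventionally -1)
#' @param fov_mm field of view in mm
#' @param compartment_ids named integer vector giving the ordered compartment
#'   labels to reconstruct; defaults to all non-negative labels present
#' @return a `compartment_mask` object
#' @export
compartment_mask <- function(label_map, fov_mm, compartment_ids = NULL) {
  if (length(dim(label_map)) != 3) abort("label_map must be a 3D array")
  if (is.null(compartment_ids)) {
    ids <- sort(unique(as.vector(label_map)))
    ids <- ids[ids >= 0]
    compartment_ids <- setNames(as.integer(ids), paste0("comp", ids))
  }
  if (length(compartment_ids) < 1) abort("at least one compartment required")
  for (i in seq_along(compartment_ids)) {
    if (!any(label_map == compartment_ids[i])) {
      abort(sprintf("compartment '%s' (label %d) is empty in the mask",
                    names(compartment_ids)[i], compartment_ids[i]))
    }
  }
  structure(
    list(
      label_map = label_map,
      grid_shape = as.integer(dim(label_map)),
      compartment_ids = compartment_ids,
      fov_mm = assert_fov(fov_mm)
    ),
    class = "compartment_mask"
  )
}

#' Extract the compartment mask of a phantom
#'
#' @param phantom an `mrsi_phantom`
#' @param compartments named integer label vector; default the phantom's
#'   three compartments in the order other, chest_wall, heart
#' @return a [compartment_mask()]
#' @export
as_compartment_mask <- function(phantom, compartments = NULL) {
  if (is.null(compartments)) compartments <- phantom$compartments
  compartment_mask(phantom$label_map, phantom$fov_mm, compartments)
}

#' Build the repeat-weighted phase-encode matrix
#'
#' Entry (m, j) is `R_m * exp(-2i pi k_m . x~_j)` with `x~_j` the
#' FOV-normalized voxel center; rows follow scheme order, columns the
#' package-wide voxel linearization (x fastest).
#'
#' @param scheme a [pe_scheme()]
#' @param grid_shape reconstruction grid (integer triple)
#' @return complex matrix (M' x prod(grid_shape))
#' @export
build_pe_matrix <- function(scheme, grid_shape) {
  grid_shape <- assert_grid_shape(grid_shape)
  k <- scheme_k_matrix(scheme)
  xc <- voxel_centers(grid_shape)
  exp(-2i * pi * tcrossprod(k, xc)) * scheme$repeats
}

new_recon_operator <- function(kind, enc, scheme, mask, sizes,
                               normalization, solution_scale) {
  p <- pinv_svd(enc)
  op <- structure(
    list(
      kind = kind, encoding_matrix = enc, pinv = p$pinv, scheme = scheme,
      mask = mask, compartment_sizes = sizes, condition = p$condition,
      rank = p$rank, normalization = normalization,
      solution_scale = solution_scale
    ),
    class = "recon_operator"
  )
  if (p$rank < ncol(enc) || p$condition > 1e8) {
    warn(sprintf(
      "%s operator is ill-conditioned (rank %d of %d, condition %.3g)",
      kind, p$rank, ncol(enc), p$condition
    ))
  }
  op
}

#' @export
print.recon_operator <- function(x, ...) {
  cat(sprintf(
    "<recon_operator> %s, %d encodes x %d compartments, condition %.3g\n",
    x$kind, nrow(x$encoding_matrix), ncol(x$encoding_matrix), x$condition
  ))
  invisible(x)
}

mask_indices <- function(mask) {
  lab <- as.vector(mask$label_map)
  lapply(mask$compartment_ids, function(id) which(lab == id))
}

#' Compress a phase-encode matrix onto compartments (SLAM operator)
#'
#' Sums (per-voxel-mean normalizes, by default) the voxel columns of the full
#' phase-encode matrix within each compartment and computes the SVD
#' pseudoinverse of the resulting M' x C matrix.  Voxels outside every listed
#' compartment are excluded.
#'
#' @param pe full phase-encode matrix from [build_pe_matrix()] on the mask
#'   grid
#' @param mask a [compartment_mask()]
#' @param scheme the [pe_scheme()] that generated `pe`
#' @param normalization `"per_voxel_mean"` (default; compartment spectra are
#'   mean per-voxel spectra, making metabolite ratios compartment-size
#'   invariant) or `"total"` (plain column sums)
#' @return a `recon_operator` of kind `"SLAM"`
#' @export
compress_compartments <- function(pe, mask, scheme,
                                  normalization = c("per_voxel_mean",
                                                    "total")) {
  normalization <- match.arg(normalization)
  if (ncol(pe) != prod(mask$grid_shape)) {
    abort("PE matrix columns do not match the mask grid")
  }
  idx <- mask_indices(mask)
  sizes <- lengths(idx)
  enc <- vapply(seq_along(idx), function(c) {
    s <- rowSums(pe[, idx[[c]], drop = FALSE])
    if (normalization == "per_voxel_mean") s / sizes[c] else s
  }, complex(nrow(pe)))
  enc <- matrix(enc, nrow = nrow(pe))
  # The data couple to compartment column *sums*, so the raw pseudoinverse
  # solution of the mean-normalized system carries a factor n_c; the
  # solution scale maps it back to per-voxel-mean spectra.
  scale <- if (normalization == "per_voxel_mean") 1 / sizes else
    rep(1, length(sizes))
  new_recon_operator("SLAM", enc, scheme, mask, sizes, normalization, scale)
}

#' Build a SLAM operator from a scheme and mask
#'
#' Convenience wrapper: [build_pe_matrix()] on the mask grid followed by
#' [compress_compartments()].
#'
#' @inheritParams compress_compartments
#' @param scheme a [pe_scheme()]
#' @return a `recon_operator` of kind `"SLAM"`
#' @export
slam_operator <- function(scheme, mask,
                          normalization = c("per_voxel_mean", "total")) {
  pe <- build_pe_matrix(scheme, mask$grid_shape)
  compress_compartments(pe, mask, scheme, match.arg(normalization))
}

#' Build the SLIM encoding matrix operator
#'
#' Entry (m, c) is the continuous-Fourier integral of the encoding basis over
#' compartment c, `R_m * sum_{j in c} integral_voxel_j exp(-2i pi k_m . x~)`,
#' evaluated per voxel in closed form as
#' `prod_d w_d sinc(k_d w_d) exp(-2i pi k_d x~_center_d)` with `w_d` the
#' FOV-normalized voxel width.  With per-voxel-mean normalization the column
#' is divided by the compartment volume, making the SLIM and SLAM compartment
#' spectra directly comparable.
#'
#' @param scheme a [pe_scheme()]
#' @param mask a [compartment_mask()]
#' @param normalization as in [compress_compartments()] (`"total"` leaves the
#'   volume integral unnormalized)
#' @return a `recon_operator` of kind `"SLIM"`
#' @export
build_g_matrix <- function(scheme, mask,
                           normalization = c("per_voxel_mean", "total")) {
  normalization <- match.arg(normalization)
  g <- mask$grid_shape
  w <- 1 / g
  k <- scheme_k_matrix(scheme)
  sincw <- sinc(k[, 1] * w[1]) * sinc(k[, 2] * w[2]) * sinc(k[, 3] * w[3])
  xc <- voxel_centers(g)
  phase <- exp(-2i * pi * tcrossprod(k, xc))  # M' x Nvox
  idx <- mask_indices(mask)
  sizes <- lengths(idx)
  voxvol <- prod(w)
  enc <- vapply(seq_along(idx), function(c) {
    s <- rowSums(phase[, idx[[c]], drop = FALSE]) * sincw * voxvol
    if (normalization == "per_voxel_mean") s / (sizes[c] * voxvol) else s
  }, complex(nrow(k)))
  enc <- matrix(enc, nrow = nrow(k)) * scheme$repeats
  # The gridded data hold per-voxel (not per-unit-volume) signal, so the raw
  # solution of the volume-normalized system carries n_c (or 1/voxvol for
  # the unnormalized integrals); scale back to per-voxel-mean spectra.
  scale <- if (normalization == "per_voxel_mean") 1 / sizes else
    rep(voxvol, length(sizes))
  new_recon_operator("SLIM", enc, scheme, mask, sizes, normalization, scale)
}

#' Compartment spectra container
#'
#' @param compartment_ids named integer vector
#' @param time_signals complex C x N matrix of separated compartment FIDs
#' @param dwell_s dwell time (s)
#' @param normalization normalization tag of the operator that produced it
#' @return a `compartment_spectra` object; `spectra` holds the discrete FT of
#'   `time_signals` along time
#' @export
compartment_spectra <- function(compartment_ids, time_signals, dwell_s,
                                normalization = "per_voxel_mean") {
  structure(
    list(
      compartment_ids = compartment_ids,
      time_signals = time_signals,
      spectra = time_to_spectrum(time_signals),
      dwell_s = dwell_s,
      normalization = normalization
    ),
    class = "compartment_spectra"
  )
}

#' Reconstruct compartment spectra (SLAM or SLIM)
#'
#' Applies the operator's pseudoinverse to the (single-channel,
#' repeat-summed) k-space data: `xi = H d`, then Fourier transforms each
#' separated compartment FID.
#'
#' @param kdata a single-channel `kspace_data` acquired with the operator's
#'   scheme
#' @param op a `recon_operator`
#' @return a [compartment_spectra()]
#' @export
slam_reconstruct <- function(kdata, op) {
  if (op$kind != "SLAM") abort("operator kind must be SLAM")
  reconstruct_with_operator(kdata, op)
}

#' @rdname slam_reconstruct
#' @export
slim_reconstruct <- function(kdata, op) {
  if (op$kind != "SLIM") abort("operator kind must be SLIM")
  reconstruct_with_operator(kdata, op)
}

reconstruct_with_operator <- function(kdata, op) {
  if (kdata$n_channels != 1) {
    abort("kdata must be single channel; combine coils first (wsvd_combine)")
  }
  check_scheme_match(kdata$scheme, op$scheme)
  d <- matrix(kdata$data[1, , ], nrow = nrow(kdata$scheme))
  xi <- (op$pinv %*% d) * op$solution_scale
  if (op$normalization == "total") xi <- xi * op$compartment_sizes
  compartment_spectra(op$mask$compartment_ids, xi, kdata$dwell_s,
                      op$normalization)
}

#' Per-compartment noise gain of a reconstruction operator
#'
#' With repeat-summed data whose per-average noise SD is sigma, the noise SD
#' of compartment c's reconstructed time points is
#' `sigma * ||row_c(H_eff diag(sqrt(R_m)))||_2`, where `H_eff` is the matrix
#' the operator actually applies to the data (pseudoinverse times the
#' per-voxel-mean solution scaling).  This returns the per-compartment gain
#' vector `||row_c(H_eff diag(sqrt(R_m)))||_2`.
#'
#' @param op a `recon_operator`
#' @return numeric vector, one entry per compartment
#' @export
operator_noise_gain <- function(op) {
  h_eff <- op$pinv * op$solution_scale
  if (op$normalization == "total") h_eff <- h_eff * op$compartment_sizes
  w <- sqrt(op$scheme$repeats)
  sqrt(rowSums(Mod(sweep(h_eff, 2, w, `*`))^2))
}

check_scheme_match <- function(a, b, tol = 1e-9) {
  if (nrow(a) != nrow(b) ||
      max(abs(scheme_k_matrix(a) - scheme_k_matrix(b))) > tol ||
      any(a$repeats != b$repeats)) {
    abort("k-space data scheme does not match the operator scheme")
  }
}

#' Fourier (FT-MRS) voxel reconstruction
#'
#' Zero-fills unacquired encodes of the full integer matrix and applies the
#' inverse DFT to the repeat-summed data, so acquisition weights act as
#' apodization (no division by R_m).  The scheme must have integer k on the
#' nominal matrix.
#'
#' @param kdata single-channel `kspace_data` with integer k
#' @param grid_shape reconstruction grid; defaults to the scheme's nominal
#'   matrix
#' @return a `voxel_spectra` object with fields `fids` and `spectra`
#'   (voxels x time, x-fastest linearization), `grid_shape`, `dwell_s`
#' @export
ft_mrs_reconstruct <- function(kdata, grid_shape = NULL) {
  scheme <- kdata$scheme
  if (!scheme_is_integer(scheme)) {
    abort("FT-MRS is undefined for fractional k-space coordinates")
  }
  if (kdata$n_channels != 1) {
    abort("kdata must be single channel; combine coils first (wsvd_combine)")
  }
  if (is.null(grid_shape)) grid_shape <- attr(scheme, "matrix_shape")
  grid_shape <- assert_grid_shape(grid_shape)
  k <- round(scheme_k_matrix(scheme))
  if (any(k < matrix(-floor(grid_shape / 2), nrow(k), 3, byrow = TRUE)) ||
      any(k >= matrix(ceiling(grid_shape / 2), nrow(k), 3, byrow = TRUE))) {
    abort("scheme k-space coordinates fall outside the reconstruction matrix")
  }
  m <- grid_shape
  idx <- cbind(k[, 1] %% m[1], k[, 2] %% m[2], k[, 3] %% m[3]) + 1

  n_time <- kdata$n_time
  nvox <- prod(m)
  fids <- matrix(0 + 0i, nvox, n_time)
  d <- matrix(kdata$data[1, , ], nrow = nrow(scheme))
  lin <- (idx[, 3] - 1) * m[1] * m[2] + (idx[, 2] - 1) * m[1] + idx[, 1]
  # circular shift per axis mapping DFT output index to the centered voxel
  # convention x~_j = (j - floor(M/2))/M
  shift_idx <- function(mm) ((seq_len(mm) - 1 - floor(mm / 2)) %% mm) + 1
  sx <- shift_idx(m[1]); sy <- shift_idx(m[2]); sz <- shift_idx(m[3])
  for (t in seq_len(n_time)) {
    arr <- array(0 + 0i, dim = m)
    arr[lin] <- d[, t]
    f <- fft(arr, inverse = TRUE) / nvox
    fids[, t] <- as.vector(f[sx, sy, sz])
  }
  structure(
    list(
      grid_shape = m, fids = fids, spectra = time_to_spectrum(fids),
      dwell_s = kdata$dwell_s
    ),
    class = "voxel_spectra"
  )
}

#' Extract one voxel's FID and spectrum from a voxel reconstruction
#'
#' @param vs a `voxel_spectra` object
#' @param voxel 1-based integer triple (e.g. the midseptal voxel)
#' @return list with `fid` and `spectrum` complex vectors
#' @export
extract_voxel <- function(vs, voxel) {
  g <- vs$grid_shape
  v <- as.integer(voxel)
  if (length(v) != 3 || any(v < 1) || any(v > g)) {
    abort("voxel index out of range")
  }
  j <- (v[3] - 1) * g[1] * g[2] + (v[2] - 1) * g[1] + v[1]
  list(fid = vs$fids[j, ], spectrum = vs$spectra[j, ])
}

#' Estimate the channel noise covariance from signal-free data
#'
#' Uses the final `fraction` of the readout (after FID decay) across all
#' encodes, with each encode scaled by 1/sqrt(R_m) to a common per-average
#' noise level.
#'
#' @param kdata a `kspace_data`
#' @param fraction tail fraction of time points to use (default 0.25)
#' @return complex Hermitian channels x channels covariance matrix
#' @export
estimate_noise_cov <- function(kdata, fraction = 0.25) {
  n_tail <- max(2, floor(kdata$n_time * fraction))
  tsel <- seq.int(kdata$n_time - n_tail + 1, kdata$n_time)
  nch <- kdata$n_channels
  x <- matrix(0 + 0i, nch, nrow(kdata$scheme) * n_tail)
  for (ch in seq_len(nch)) {
    d <- matrix(kdata$data[ch, , tsel], nrow = nrow(kdata$scheme))
    x[ch, ] <- as.vector(d / sqrt(kdata$scheme$repeats))
  }
  x <- x - rowMeans(x)
  tcrossprod(x, Conj(x)) / (ncol(x) - 1)
}

#' Noise-whitened SVD coil combination
#'
#' Whitens the channels by the inverse square root of the noise covariance,
#' stacks the whitened FIDs as a channels x (encodes * time) matrix, and
#' takes the dominant left-singular-vector projection (the rank-1
#' approximation's combined signal).  The combined data are phased so that
#' the first data point keeps the phase of the dominant channel's first
#' point, and carry the energy of the rank-1 component.
#'
#' @param kdata multi-channel `kspace_data`
#' @param noise_cov Hermitian positive-definite channel covariance; default
#'   estimated with [estimate_noise_cov()]
#' @return single-channel `kspace_data` in whitened units
#' @export
wsvd_combine <- function(kdata, noise_cov = NULL) {
  nch <- kdata$n_channels
  if (nch == 1) return(kdata)
  if (is.null(noise_cov)) noise_cov <- estimate_noise_cov(kdata)
  noise_cov <- (noise_cov + Conj(t(noise_cov))) / 2
  ev <- eigen(noise_cov, symmetric = TRUE)
  if (any(ev$values <= 0)) {
    abort("noise covariance must be positive-definite")
  }
  wmat <- ev$vectors %*% (1 / sqrt(ev$values) * Conj(t(ev$vectors)))

  mprime <- nrow(kdata$scheme)
  x <- matrix(0 + 0i, nch, mprime * kdata$n_time)
  for (ch in seq_len(nch)) {
    x[ch, ] <- as.vector(matrix(kdata$data[ch, , ], nrow = mprime))
  }
  xw <- wmat %*% x
  sv <- svd(xw, nu = nch, nv = 0)
  u1 <- sv$u[, 1]
  combined <- as.vector(Conj(t(u1)) %*% xw)
  dom <- which.max(Mod(u1))
  ph <- Arg(x[dom, 1]) - Arg(combined[1])
  combined <- combined * exp(1i * ph)
  out <- array(0 + 0i, dim = c(1, mprime, kdata$n_time))
  out[1, , ] <- matrix(combined, mprime, kdata$n_time)
  kspace_data(kdata$scheme, out, kdata$dwell_s, 1)
}
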
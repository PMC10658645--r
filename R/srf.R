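# Spatial response functions and point spread functions
#
# The SRF beta_c(x) of a compartment is the spatial weighting with which
# every FOV position contributes to that compartment's reconstructed
# spectrum: beta_c(x) = sum_m h_cm R_m exp(-2i pi k_m . x~), i.e. the
# reconstruction applied to a point source at x.  Its magnitude is the
# worst-case contamination bound (attained when the B0-induced phase aligns
# with the SRF phase), optionally weighted by the receive-B1 map.

new_srf_map <- function(compartment_id, values, eval_grid_shape, fov_mm,
                        variant = "complex") {
  structure(
    list(
      compartment_id = compartment_id,
      values = array(values, dim = eval_grid_shape),
      eval_grid_shape = eval_grid_shape,
      fov_mm = fov_mm,
      variant = variant
    ),
    class = "srf_map"
  )
}

#' @export
print.srf_map <- function(x, ...) {
  cat(sprintf(
    "<srf_map> compartment %s, %s, grid %s\n",
    paste(x$compartment_id, collapse = ""), x$variant,
    paste(x$eval_grid_shape, collapse = "x")
  ))
  invisible(x)
}

#' Compute spatial response functions of a reconstruction operator
#'
#' Evaluates beta_c(x) for every compartment of the operator at every point
#' of the evaluation grid (by performing the reconstruction for a unit point
#' source at each grid position).  An oversampled grid gives smooth maps for
#' display and leakage integrals; the delta-property (compartment mean of
#' beta_c over compartment d equals the Kronecker delta for SLAM) holds on
#' the exact acquisition grid.
#'
#' @param op a `recon_operator`
#' @param oversample integer per-axis oversampling factor of the mask grid
#'   (default 1 = acquisition grid)
#' @param eval_grid_shape explicit evaluation grid, overrides `oversample`
#' @return named list of complex `srf_map` objects, one per compartment
#' @export
compute_srf <- function(op, oversample = 1, eval_grid_shape = NULL) {
  if (is.null(eval_grid_shape)) {
    eval_grid_shape <- op$mask$grid_shape * as.integer(oversample)
  }
  eval_grid_shape <- assert_grid_shape(eval_grid_shape)
  e <- build_pe_matrix(op$scheme, eval_grid_shape)  # rows carry R_m
  beta <- op$pinv %*% e                             # C x Npoints
  out <- lapply(seq_len(nrow(beta)), function(c) {
    new_srf_map(op$mask$compartment_ids[c], beta[c, ], eval_grid_shape,
                op$mask$fov_mm)
  })
  names(out) <- names(op$mask$compartment_ids)
  out
}

#' Worst-case (magnitude) SRF
#'
#' @param srf an `srf_map`
#' @return the magnitude variant, the worst-case contamination bound
#' @export
worst_case_srf <- function(srf) {
  new_srf_map(srf$compartment_id, Mod(srf$values), srf$eval_grid_shape,
              srf$fov_mm, "worst_case")
}

#' B1-weighted worst-case SRF
#'
#' Pointwise product of the magnitude SRF with a receive-sensitivity map
#' (already zeroed inside the coil-exclusion region by
#' [biot_savart_sensitivity()]).
#'
#' @param srf an `srf_map`
#' @param sensitivity per-voxel sensitivity on the same evaluation grid
#'   (vector or array)
#' @return the B1-weighted magnitude variant
#' @export
b1_weighted_srf <- function(srf, sensitivity) {
  s <- array(as.numeric(sensitivity), dim = srf$eval_grid_shape)
  new_srf_map(srf$compartment_id, Mod(srf$values) * s, srf$eval_grid_shape,
              srf$fov_mm, "b1_weighted")
}

#' Point spread function of one FT-MRS voxel
#'
#' PSF(x) = sum_m R_m exp(-2i pi k_m . (x~ - x~_voxel)), normalized to unit
#' maximum magnitude — the Fourier analogue of the SRF for a single voxel of
#' the nominal grid.
#'
#' @param scheme a [pe_scheme()]
#' @param voxel 1-based integer triple on the scheme's nominal matrix
#' @param oversample per-axis oversampling of the nominal matrix (default 1)
#' @param eval_grid_shape explicit evaluation grid, overrides `oversample`
#' @return an `srf_map` (complex variant, unit maximum magnitude)
#' @export
ft_psf <- function(scheme, voxel, oversample = 1, eval_grid_shape = NULL) {
  m <- attr(scheme, "matrix_shape")
  v <- as.integer(voxel)
  if (length(v) != 3 || any(v < 1) || any(v > m)) {
    abort("voxel index out of range for the scheme's nominal matrix")
  }
  if (is.null(eval_grid_shape)) {
    eval_grid_shape <- m * as.integer(oversample)
  }
  eval_grid_shape <- assert_grid_shape(eval_grid_shape)
  xv <- (v - 1 - floor(m / 2)) / m
  k <- scheme_k_matrix(scheme)
  xc <- voxel_centers(eval_grid_shape)
  dx <- sweep(xc, 2, xv, `-`)
  vals <- as.vector(crossprod(
    exp(-2i * pi * tcrossprod(k, dx)), scheme$repeats
  ))
  vals <- vals / max(Mod(vals))
  new_srf_map(NA_integer_, vals, eval_grid_shape, attr(scheme, "fov_mm"))
}

#' Map evaluation-grid points to their nearest acquisition-grid voxel
#'
#' Assigns every point of an oversampled evaluation grid to the voxel of the
#' coarse grid whose center is nearest, periodically (the edge voxel of the
#' centered coordinate convention wraps around the FOV boundary).  Used to
#' carry compartment labels onto oversampled SRF grids for quadrature.
#'
#' @param eval_grid_shape oversampled grid (integer triple)
#' @param grid_shape coarse acquisition grid (integer triple)
#' @return integer vector of linear voxel indices (x-fastest), one per
#'   evaluation point
#' @export
eval_to_voxel_index <- function(eval_grid_shape, grid_shape) {
  idx_axis <- function(ne, m) {
    x <- axis_coords(ne)
    c0 <- axis_coords(m)[1]
    (round((x - c0) * m) %% m) + 1
  }
  ix <- idx_axis(eval_grid_shape[1], grid_shape[1])
  iy <- idx_axis(eval_grid_shape[2], grid_shape[2])
  iz <- idx_axis(eval_grid_shape[3], grid_shape[3])
  nx <- grid_shape[1]
  nxy <- grid_shape[1] * grid_shape[2]
  as.vector(
    outer(
      outer(ix, (iy - 1) * nx, `+`),
      (iz - 1) * nxy, `+`
    )
  )
}

#' Iso-contour mask of a PSF/SRF at a fractional threshold
#'
#' @param srf an `srf_map`
#' @param threshold fraction of the maximum magnitude (default 0.64, the
#'   conventional voxel-extent threshold for AW point spread functions)
#' @return logical array on the evaluation grid
#' @export
psf_contour_mask <- function(srf, threshold = 0.64) {
  m <- Mod(srf$values)
  m >= threshold * max(m)
}

#' Leakage table of SRFs over mask regions
#'
#' For every (source region, target-compartment SRF) pair, integrates the
#' worst-case (optionally B1-weighted) SRF magnitude over the region:
#' `sum_{x in region} |beta_c(x)| w(x) * voxvol`.  The SRF evaluation grid
#' must be an integer oversampling of the mask grid.
#'
#' @param srfs list of `srf_map`s from [compute_srf()]
#' @param mask a [compartment_mask()]
#' @param sensitivity optional per-voxel weight on the evaluation grid
#' @return tibble with columns `target_compartment`, `source_region`,
#'   `leakage`
#' @export
leakage_report <- function(srfs, mask, sensitivity = NULL) {
  eg <- srfs[[1]]$eval_grid_shape
  ov <- eg / mask$grid_shape
  if (any(ov != round(ov))) {
    abort("SRF evaluation grid must be an integer oversampling of the mask")
  }
  lab <- as.vector(mask$label_map)[eval_to_voxel_index(eg, mask$grid_shape)]
  w <- if (is.null(sensitivity)) 1 else as.numeric(sensitivity)
  voxvol <- 1 / prod(eg)
  rows <- list()
  for (ci in seq_along(srfs)) {
    mag <- as.vector(Mod(srfs[[ci]]$values)) * w
    for (di in seq_along(mask$compartment_ids)) {
      sel <- lab == mask$compartment_ids[di]
      rows[[length(rows) + 1]] <- tibble(
        target_compartment = names(srfs)[ci],
        source_region = names(mask$compartment_ids)[di],
        leakage = sum(mag[sel]) * voxvol
      )
    }
  }
  dplyr::bind_rows(rows)
}
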
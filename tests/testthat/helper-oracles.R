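# Shared fixtures and independent oracles for the test suite.

# Field-homogeneous cardiac phantom (no B0 offset, no phase map).
homog_phantom <- function(grid = c(8, 16, 8), extra = list()) {
  cfg <- c(list(grid_shape = grid, b0 = list(peak_hz = 0),
                phase = list(peak_rad = 0)), extra)
  make_cardiac_phantom(cfg)
}

# Replace a phantom's label map (test geometry surgery); density is reset to
# 1 inside the labeled region and 0 outside (-1).
relabel_phantom <- function(ph, label_map) {
  stopifnot(all(dim(label_map) == ph$grid_shape))
  ph$label_map <- label_map
  d <- array(1, dim = ph$grid_shape)
  d[label_map == -1L] <- 0
  ph$density_map <- d
  ph
}

# Independent oracle: the per-voxel-mean compartment FID of a
# field-homogeneous phantom is the compartment's resonance sum, evaluated
# directly from the resonance table (no package FID code involved).
gt_compartment_fids <- function(ph, n_time, dwell_s,
                                comps = c("other", "chest_wall", "heart")) {
  tv <- (seq_len(n_time) - 1) * dwell_s
  t(sapply(comps, function(nm) {
    r <- ph$resonances[[nm]]
    colSums(r$amplitude * exp(1i * r$phase_rad) *
              exp(outer(2i * pi * r$frequency_hz - pi * r$linewidth_hz, tv)))
  }))
}

rel_err_rows <- function(x, gt) {
  sapply(seq_len(nrow(gt)), function(c) {
    sqrt(sum(Mod(x[c, ] - gt[c, ])^2) / sum(Mod(gt[c, ])^2))
  })
}

# 2D (single-slice) mask with three compartments: background, a rectangle
# and a centered ellipse; used for SLIM quadrature checks where a highly
# oversampled evaluation grid is affordable.
flat_mask_2d <- function(n = 16, fov = c(240, 240, 200)) {
  lab <- array(0L, dim = c(n, n, 1))
  lab[, seq_len(round(n / 4)), 1] <- 1L
  xc <- slamslim::voxel_centers(c(n, n, 1))
  inside <- (xc[, 1] / 0.28)^2 + ((xc[, 2] - 0.08) / 0.22)^2 <= 1
  lab[array(inside, dim = c(n, n, 1)) & lab == 0L] <- 2L
  compartment_mask(lab, fov, c(other = 0L, chest_wall = 1L, heart = 2L))
}

# SLIM relative recovery error of the default cardiac geometry at a given
# phantom grid (the scheme stays at the nominal acquisition matrix).
slim_recovery_error <- function(grid, n_time = 32) {
  ph <- homog_phantom(grid)
  mask <- as_compartment_mask(ph)
  s <- make_aw_scheme(c(8, 16, 8), 4)
  kd <- forward_encode(ph, s, n_time = n_time)
  rec <- slim_reconstruct(kd, build_g_matrix(s, mask))
  gt <- gt_compartment_fids(ph, n_time, kd$dwell_s)
  max(rel_err_rows(rec$time_signals, gt))
}
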
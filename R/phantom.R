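# Digital cardiac phantom and forward simulation
#
# The phantom is a voxelized 3D torso section with three tissue compartments
# (heart spheroid, curved chest-wall slab, background "other") on the
# reconstruction grid, per-compartment Lorentzian 31P resonances, smooth
# polynomial B0 offset / phase maps and a relative transmit-B1 map.  The
# forward model evaluates the phase-encoded signal of each voxel's FID with
# the encoding exponential exp(-2i pi k . x~), weighted by the per-encode
# repeat count R_m, with circular complex white noise added per repeat and
# then summed — exactly the convention under which the reconstruction
# operators carry R_m.

# 31P resonance frequencies (Hz offset from PCr) at 7 T, where 1 ppm is about
# 120.3 Hz.  The 2,3-DPG resonance is modeled as a doublet.
default_resonance_freqs <- c(
  "PCr" = 0, "gamma-ATP" = -298, "alpha-ATP" = -905, "beta-ATP" = -1956,
  "2,3-DPG-2" = 630, "2,3-DPG-3" = 750, "PDE" = 350
)

default_resonance_linewidths <- c(
  "PCr" = 25, "gamma-ATP" = 35, "alpha-ATP" = 35, "beta-ATP" = 45,
  "2,3-DPG-2" = 45, "2,3-DPG-3" = 45, "PDE" = 50
)

resonance_tbl <- function(names, amplitudes,
                          freqs = default_resonance_freqs,
                          lws = default_resonance_linewidths,
                          phases = 0) {
  tibble(
    name = names,
    amplitude = as.numeric(amplitudes),
    frequency_hz = unname(freqs[names]),
    linewidth_hz = unname(lws[names]),
    phase_rad = rep_len(phases, length(names))
  )
}

#' Default per-compartment resonance tables
#'
#' Amplitudes are "as acquired": the unsaturated tissue amplitudes are
#' multiplied by the steady-state partial-saturation factor of each metabolite
#' under the supplied correction configuration, and the heart gamma-ATP line
#' additionally carries a blood-pool ATP contribution proportional to the
#' mean 2,3-DPG amplitude, so that the blood- and saturation-corrected
#' myocardial PCr/gamma-ATP ratio of the phantom equals `true_pcr_atp`
#' exactly.
#'
#' @param true_pcr_atp ground-truth corrected myocardial PCr/gamma-ATP ratio
#' @param cfg a [correction_config()]; its blood factor, TR, flip angles and
#'   T1 values define the saturation and blood contributions baked into the
#'   amplitudes
#' @return named list of per-compartment resonance tibbles
#'   (`heart`, `chest_wall`, `other`)
#' @export
default_compartment_resonances <- function(true_pcr_atp = 2.0,
                                           cfg = correction_config()) {
  e <- vapply(
    names(default_resonance_freqs),
    function(nm) saturation_factor(nm, cfg),
    numeric(1)
  )
  dpg_unsat <- 0.5
  heart <- resonance_tbl(
    names(default_resonance_freqs),
    c(
      true_pcr_atp * e[["PCr"]],
      e[["gamma-ATP"]] + cfg$blood_atp_per_dpg * dpg_unsat * e[["2,3-DPG-2"]],
      e[["alpha-ATP"]], e[["beta-ATP"]],
      dpg_unsat * e[["2,3-DPG-2"]], dpg_unsat * e[["2,3-DPG-3"]],
      0.4 * e[["PDE"]]
    )
  )
  cw_names <- c("PCr", "gamma-ATP", "alpha-ATP", "beta-ATP")
  chest_wall <- resonance_tbl(
    cw_names, c(4.0 * e[["PCr"]], e[["gamma-ATP"]], e[["alpha-ATP"]],
                e[["beta-ATP"]])
  )
  other <- resonance_tbl(
    cw_names, 0.15 * c(2.0 * e[["PCr"]], e[["gamma-ATP"]], e[["alpha-ATP"]],
                       e[["beta-ATP"]])
  )
  list(heart = heart, chest_wall = chest_wall, other = other)
}

#' Default phantom configuration
#'
#' @return a named list of configuration entries accepted by
#'   [make_cardiac_phantom()]; override any subset by passing a partial list.
#' @export
phantom_config <- function() {
  list(
    grid_shape = c(8, 16, 8),
    fov_mm = c(240, 240, 200),
    heart = list(center_mm = c(0, -10, 0), semi_axes_mm = c(45, 40, 45)),
    chest_wall = list(y0_mm = -110, thickness_mm = 25, curvature_mm = 15),
    body = list(y_back_mm = 95),
    b0 = list(peak_hz = 30),
    phase = list(peak_rad = 0.3),
    b1_tx = 1,
    density = 1,
    true_pcr_atp = 2.0,
    corrections = correction_config(),
    resonances = NULL,
    trim_base_slices = TRUE,
    excitation = list(enabled = FALSE, center_hz = 266, bandwidth_hz = 2000)
  )
}

merge_config <- function(default, user) {
  for (nm in names(user)) {
    if (is.list(default[[nm]]) && is.list(user[[nm]])) {
      default[[nm]] <- merge_config(default[[nm]], user[[nm]])
    } else {
      default[[nm]] <- user[[nm]]
    }
  }
  default
}

# Compartment label codes used throughout the package.
LBL_OUTSIDE <- -1L
LBL_OTHER <- 0L
LBL_CHEST <- 1L
LBL_HEART <- 2L

#' Generate a digital 3D cardiac phantom
#'
#' Builds the voxelized ground truth for the forward simulations: a label map
#' with a spheroidal heart compartment, a curved chest-wall slab adjacent to
#' the anterior FOV edge and background "other" tissue inside the body
#' (voxels outside the body are marked -1); per-compartment Lorentzian
#' resonance tables; smooth low-order polynomial B0 frequency-offset and
#' phase maps with configurable peak amplitude; and relative transmit-B1 and
#' spin-density maps.
#'
#' @param config partial configuration list; see [phantom_config()] for the
#'   defaults and available entries
#' @return an object of class `mrsi_phantom`
#' @export
make_cardiac_phantom <- function(config = list()) {
  cfg <- merge_config(phantom_config(), config)
  grid_shape <- assert_grid_shape(cfg$grid_shape)
  fov <- assert_fov(cfg$fov_mm)

  ax <- c("x", "y", "z")
  ctr <- cfg$heart$center_mm
  semi <- cfg$heart$semi_axes_mm
  for (d in 1:3) {
    if (any(semi > 0) && (ctr[d] - semi[d] < -fov[d] / 2 ||
                          ctr[d] + semi[d] > fov[d] / 2)) {
      abort(sprintf("heart spheroid exceeds the FOV along the %s axis", ax[d]))
    }
  }

  xc <- voxel_centers(grid_shape)  # FOV-normalized
  xmm <- sweep(xc, 2, fov, `*`)    # voxel centers in mm
  nvox <- nrow(xmm)

  # body: between the curved anterior chest boundary and the posterior edge
  u <- sweep(xc, 2, rep(2, 3), `*`)  # coords scaled to [-1, 1)
  y_front <- cfg$chest_wall$y0_mm +
    cfg$chest_wall$curvature_mm * (u[, 1]^2 + u[, 3]^2)
  in_body <- xmm[, 2] >= y_front & xmm[, 2] <= cfg$body$y_back_mm

  labels <- rep(LBL_OUTSIDE, nvox)
  labels[in_body] <- LBL_OTHER
  in_chest <- in_body & xmm[, 2] < y_front + cfg$chest_wall$thickness_mm
  labels[in_chest] <- LBL_CHEST
  if (all(semi > 0)) {
    r2 <- ((xmm[, 1] - ctr[1]) / semi[1])^2 +
      ((xmm[, 2] - ctr[2]) / semi[2])^2 +
      ((xmm[, 3] - ctr[3]) / semi[3])^2
    labels[in_body & r2 <= 1] <- LBL_HEART
  }

  label_map <- array(as.integer(labels), dim = grid_shape)
  if (isTRUE(cfg$trim_base_slices) && grid_shape[3] >= 2) {
    base <- (grid_shape[3] - 1):grid_shape[3]
    sl <- label_map[, , base]
    sl[sl == LBL_HEART] <- LBL_OTHER
    label_map[, , base] <- sl
  }

  res <- cfg$resonances
  if (is.null(res)) {
    res <- default_compartment_resonances(cfg$true_pcr_atp, cfg$corrections)
  }
  known <- c("other", "chest_wall", "heart")
  bad <- setdiff(names(res), known)
  if (length(bad)) {
    abort(sprintf(
      "unknown compartment name(s) in spectral config: %s (known: %s)",
      paste(bad, collapse = ", "), paste(known, collapse = ", ")
    ))
  }
  for (nm in names(res)) {
    r <- res[[nm]]
    if (any(r$linewidth_hz <= 0) || any(r$amplitude < 0)) {
      abort("resonances need linewidth_hz > 0 and amplitude >= 0")
    }
  }

  if (isTRUE(cfg$excitation$enabled)) {
    prof <- function(f) {
      exp(-((f - cfg$excitation$center_hz) /
              (cfg$excitation$bandwidth_hz / 2))^8)
    }
    res <- lapply(res, function(r) {
      r$amplitude <- r$amplitude * prof(r$frequency_hz)
      r
    })
  }

  poly_map <- function(coef_fun, peak) {
    p <- coef_fun(u)
    m <- max(abs(p))
    if (m == 0 || peak == 0) return(array(0, dim = grid_shape))
    array(p / m * peak, dim = grid_shape)
  }
  delta_f_map <- poly_map(
    function(u) 0.6 * u[, 2] + 0.5 * u[, 1] * u[, 2] + 0.4 * u[, 2]^2 +
      0.3 * u[, 3] + 0.2 * u[, 1]^2,
    cfg$b0$peak_hz
  )
  phase_map <- poly_map(
    function(u) 0.7 * u[, 1] + 0.4 * u[, 2] * u[, 3] + 0.3 * u[, 3]^2,
    cfg$phase$peak_rad
  )

  density_map <- array(rep_len(cfg$density, nvox), dim = grid_shape)
  density_map[label_map == LBL_OUTSIDE] <- 0
  b1_tx_map <- array(rep_len(cfg$b1_tx, nvox), dim = grid_shape)
  if (any(density_map < 0) || any(b1_tx_map < 0)) {
    abort("density and transmit-B1 maps must be non-negative")
  }

  structure(
    list(
      grid_shape = grid_shape, fov_mm = fov,
      label_map = label_map,
      compartments = c(other = LBL_OTHER, chest_wall = LBL_CHEST,
                       heart = LBL_HEART),
      resonances = res,
      delta_f_map = delta_f_map, phase_map = phase_map,
      b1_tx_map = b1_tx_map, density_map = density_map,
      config = cfg
    ),
    class = "mrsi_phantom"
  )
}

#' @export
print.mrsi_phantom <- function(x, ...) {
  counts <- table(factor(x$label_map,
                         levels = c(LBL_OUTSIDE, LBL_OTHER, LBL_CHEST,
                                    LBL_HEART),
                         labels = c("outside", "other", "chest_wall",
                                    "heart")))
  cat(sprintf(
    "<mrsi_phantom> grid %s, FOV %s mm\n",
    paste(x$grid_shape, collapse = "x"), paste(x$fov_mm, collapse = "x")
  ))
  print(counts)
  invisible(x)
}

compartment_base_fid <- function(res, tvec) {
  if (nrow(res) == 0) return(rep(0 + 0i, length(tvec)))
  decay <- exp(outer(tvec, 1i * 2 * pi * res$frequency_hz -
                       pi * res$linewidth_hz))
  as.vector(decay %*% (res$amplitude * exp(1i * res$phase_rad)))
}

label_name <- function(lbl) {
  c("-1" = "outside", "0" = "other", "1" = "chest_wall",
    "2" = "heart")[as.character(lbl)]
}

#' Time-domain FID of a single phantom voxel
#'
#' Evaluates the voxel's complex free induction decay
#' \deqn{\sum_r a_r \rho(x) \Delta B_1(x) e^{i(\phi_r + \phi(x))}
#'   e^{(2\pi i (f_r + \Delta f(x)) - \pi \ell_r) t}}
#' sampled at t = (0, 1, ..., n_time - 1) * dwell_s.  Voxels outside the body
#' return zeros.
#'
#' @param phantom an `mrsi_phantom`
#' @param voxel_index 1-based integer triple
#' @param n_time number of samples
#' @param dwell_s dwell time in seconds
#' @return complex vector of length `n_time`
#' @export
voxel_fid <- function(phantom, voxel_index, n_time, dwell_s) {
  g <- phantom$grid_shape
  v <- as.integer(voxel_index)
  if (length(v) != 3 || any(v < 1) || any(v > g)) {
    abort(sprintf("voxel index (%s) out of range for grid %s",
                  paste(voxel_index, collapse = ","),
                  paste(g, collapse = "x")))
  }
  lbl <- phantom$label_map[v[1], v[2], v[3]]
  if (lbl == LBL_OUTSIDE) return(rep(0 + 0i, n_time))
  res <- phantom$resonances[[label_name(lbl)]]
  tvec <- (seq_len(n_time) - 1) * dwell_s
  base <- compartment_base_fid(res, tvec)
  df <- phantom$delta_f_map[v[1], v[2], v[3]]
  ph <- phantom$phase_map[v[1], v[2], v[3]]
  dens <- phantom$density_map[v[1], v[2], v[3]]
  b1 <- phantom$b1_tx_map[v[1], v[2], v[3]]
  dens * b1 * exp(1i * ph) * exp(1i * 2 * pi * df * tvec) * base
}

# All-voxel FID matrix (Nvox x N), linearized x fastest.
phantom_fid_matrix <- function(phantom, n_time, dwell_s) {
  g <- phantom$grid_shape
  nvox <- prod(g)
  tvec <- (seq_len(n_time) - 1) * dwell_s
  out <- matrix(0 + 0i, nvox, n_time)
  lab <- as.vector(phantom$label_map)
  df <- as.vector(phantom$delta_f_map)
  ph <- as.vector(phantom$phase_map)
  amp <- as.vector(phantom$density_map) * as.vector(phantom$b1_tx_map)
  for (lbl in c(LBL_OTHER, LBL_CHEST, LBL_HEART)) {
    idx <- which(lab == lbl)
    if (!length(idx)) next
    base <- compartment_base_fid(phantom$resonances[[label_name(lbl)]], tvec)
    shift <- exp(outer(1i * (2 * pi * df[idx]), tvec) + 1i * ph[idx])
    out[idx, ] <- (amp[idx] * shift) *
      matrix(base, length(idx), n_time, byrow = TRUE)
  }
  out
}

#' Simulate phase-encoded multi-coil k-space data
#'
#' Evaluates the forward model on the phantom grid: for each coil channel and
#' phase encode m, the stored (repeat-summed) signal is
#' \deqn{d_m(t) = R_m \sum_x s_{ch}(x)\, \mathrm{FID}_x(t)\,
#'   e^{-2\pi i k_m \cdot \tilde x} + \sum_{r=1}^{R_m} n_r(t)}
#' with independent circular complex white noise of per-average standard
#' deviation `noise_sd` drawn per repeat, channel, encode and time point.
#'
#' @param phantom an `mrsi_phantom`
#' @param scheme a [pe_scheme()] sharing the phantom's FOV
#' @param coils `NULL` for a single uniform-sensitivity channel, a
#'   [coil_geometry()] (sensitivities computed by [biot_savart_sensitivity()]
#'   and normalized to unit maximum), or a numeric/complex matrix of
#'   per-voxel sensitivities (Nvox x channels)
#' @param noise_sd per-average noise SD (>= 0)
#' @param seed optional integer seed; seeded runs are bit-reproducible
#' @param n_time readout points N
#' @param dwell_s dwell time (s)
#' @return a `kspace_data` object
#' @export
forward_encode <- function(phantom, scheme, coils = NULL, noise_sd = 0,
                           seed = NULL, n_time = 512, dwell_s = 1 / 6000) {
  if (!isTRUE(all.equal(attr(scheme, "fov_mm"), phantom$fov_mm))) {
    abort("scheme and phantom FOV differ")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  g <- phantom$grid_shape
  nvox <- prod(g)
  sens <- resolve_sensitivity(coils, g, phantom$fov_mm, nvox)
  nch <- ncol(sens)

  fids <- phantom_fid_matrix(phantom, n_time, dwell_s)
  k <- scheme_k_matrix(scheme)
  xc <- voxel_centers(g)
  enc <- exp(-2i * pi * tcrossprod(k, xc)) * scheme$repeats  # M' x Nvox

  mprime <- nrow(scheme)
  data <- array(0 + 0i, dim = c(nch, mprime, n_time))
  for (ch in seq_len(nch)) {
    data[ch, , ] <- enc %*% (sens[, ch] * fids)
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    grp <- rep(seq_len(mprime), scheme$repeats)
    for (ch in seq_len(nch)) {
      draws_re <- matrix(rnorm(length(grp) * n_time, sd = noise_sd),
                         length(grp), n_time)
      draws_im <- matrix(rnorm(length(grp) * n_time, sd = noise_sd),
                         length(grp), n_time)
      data[ch, , ] <- data[ch, , ] +
        rowsum(draws_re, grp) + 1i * rowsum(draws_im, grp)
    }
  }
  kspace_data(scheme, data, dwell_s, noise_sd)
}

resolve_sensitivity <- function(coils, grid_shape, fov_mm, nvox) {
  if (is.null(coils)) {
    matrix(1, nvox, 1)
  } else if (inherits(coils, "coil_geometry")) {
    s <- biot_savart_sensitivity(coils, grid_shape, fov_mm)
    s / max(s)
  } else if (is.matrix(coils)) {
    if (nrow(coils) != nvox) {
      abort("sensitivity matrix must have one row per voxel")
    }
    coils
  } else {
    abort("coils must be NULL, a coil_geometry, or a sensitivity matrix")
  }
}

#' Construct a k-space data container
#'
#' Holds the repeat-summed phase-encoded time-domain data as a complex array
#' indexed (channel, encode, time), together with the scheme that produced it.
#'
#' @param scheme the [pe_scheme()] the data were acquired with
#' @param data complex array (channels x encodes x time)
#' @param dwell_s dwell time (s)
#' @param noise_sd_per_average per-average noise SD used/assumed
#' @return a `kspace_data` object
#' @export
kspace_data <- function(scheme, data, dwell_s, noise_sd_per_average = 0) {
  if (length(dim(data)) != 3) abort("data must be a 3D array")
  if (dim(data)[2] != nrow(scheme)) {
    abort("data second axis must match the number of encodes in the scheme")
  }
  if (dwell_s <= 0) abort("dwell_s must be > 0")
  structure(
    list(
      scheme = scheme, n_channels = dim(data)[1], n_time = dim(data)[3],
      dwell_s = dwell_s, data = data,
      noise_sd_per_average = noise_sd_per_average
    ),
    class = "kspace_data"
  )
}

#' @export
print.kspace_data <- function(x, ...) {
  cat(sprintf(
    "<kspace_data> %d channel(s), %d encodes, %d time points, dwell %.3g s\n",
    x$n_channels, nrow(x$scheme), x$n_time, x$dwell_s
  ))
  invisible(x)
}
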
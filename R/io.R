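# External interfaces: NIfTI volumes, YAML run configs, data containers

#' Write a volumetric map as NIfTI
#'
#' @param vol 3D array (label map, field map, SRF magnitude, ...)
#' @param fov_mm field of view in mm (sets the voxel pixdim)
#' @param path output file (.nii or .nii.gz)
#' @return `path` invisibly
#' @export
write_nifti_map <- function(vol, fov_mm, path) {
  if (length(dim(vol)) != 3) abort("vol must be a 3D array")
  img <- RNifti::asNifti(vol * 1.0)
  RNifti::pixdim(img) <- fov_mm / dim(vol)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volumetric NIfTI map
#'
#' @param path NIfTI file
#' @return list with `vol` (3D array) and `fov_mm`
#' @export
read_nifti_map <- function(path) {
  img <- RNifti::readNifti(path)
  vol <- array(as.numeric(img), dim = dim(img))
  list(vol = vol, fov_mm = RNifti::pixdim(img)[1:3] * dim(vol))
}

#' Export phantom volumes as NIfTI files
#'
#' Writes the label, B0 offset, phase, transmit-B1 and density maps as
#' `<prefix>_<map>.nii.gz`.
#'
#' @param phantom an `mrsi_phantom`
#' @param prefix output path prefix
#' @return character vector of paths written, invisibly
#' @export
write_phantom_nifti <- function(phantom, prefix) {
  maps <- list(
    labels = phantom$label_map * 1.0, b0_hz = phantom$delta_f_map,
    phase_rad = phantom$phase_map, b1_tx = phantom$b1_tx_map,
    density = phantom$density_map
  )
  paths <- vapply(names(maps), function(nm) {
    p <- sprintf("%s_%s.nii.gz", prefix, nm)
    write_nifti_map(maps[[nm]], phantom$fov_mm, p)
    p
  }, character(1))
  invisible(paths)
}

#' Save / load k-space data
#'
#' The complex data array is stored in R's native serialization with the
#' scheme table embedded; the scheme is additionally written alongside as
#' CSV (`<path>.scheme.csv`) for interoperability.
#'
#' @param kdata a `kspace_data`
#' @param path output path (.rds)
#' @return `path` invisibly; `read_kspace` returns the `kspace_data`
#' @export
write_kspace <- function(kdata, path) {
  saveRDS(kdata, path)
  write_scheme_csv(kdata$scheme, paste0(path, ".scheme.csv"))
  invisible(path)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "kspace_data")) abort("file does not hold kspace_data")
  x
}

#' Export compartment spectra as CSV
#'
#' Long format: compartment, time index, real and imaginary FID parts, real
#' and imaginary spectrum parts.
#'
#' @param spectra a `compartment_spectra`
#' @param path output CSV path
#' @return `path` invisibly
#' @export
write_spectra_csv <- function(spectra, path) {
  n <- ncol(spectra$time_signals)
  df <- purrr::map_dfr(seq_along(spectra$compartment_ids), function(c) {
    tibble(
      compartment = names(spectra$compartment_ids)[c],
      index = seq_len(n) - 1,
      fid_re = Re(spectra$time_signals[c, ]),
      fid_im = Im(spectra$time_signals[c, ]),
      spec_re = Re(spectra$spectra[c, ]),
      spec_im = Im(spectra$spectra[c, ])
    )
  })
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a YAML run configuration
#'
#' @param path YAML file
#' @return named list
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}
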
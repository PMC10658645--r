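# Reproducibility metrics and the six acquisition-reconstruction techniques
#
# The six techniques pair three phase-encode schemes (acquisition-weighted
# 8x16x8, central 4x4x4 with six averages, fSLAM-optimized fractional
# 4x4x4) with the FT-MRS, SLAM and SLIM reconstructions.  A synthetic
# test-retest study simulates S subjects scanned twice, runs every technique
# on both scans and reports per-technique mean +/- SD of the corrected
# PCr/ATP ratio, PCr SNR, linewidth and amplitude CRLB, together with the
# coefficients of reproducibility (CoR) and variation (CoV).

#' The six acquisition-reconstruction combinations
#'
#' @return tibble with columns `technique`, `acquisition`, `reconstruction`,
#'   `phase_encodes`, `averages`
#' @export
technique_table <- function() {
  tibble(
    technique = c("AW FT-MRS", "AW SLAM", "AW SLIM",
                  "4x4x4 SLAM", "4x4x4 SLIM", "fSLAM"),
    acquisition = c(rep("AW k-space", 3), rep("Central integer k-space", 2),
                    "fSLAM optimized k-space"),
    reconstruction = c("Fourier transform", "SLAM", "SLIM",
                       "SLAM", "SLIM", "SLAM"),
    phase_encodes = c(rep("8x16x8", 3), rep("4x4x4", 3)),
    averages = c(4L, 4L, 4L, 6L, 6L, 6L)
  )
}

#' Coefficient of reproducibility
#'
#' `CoR = 1.96 * SD_intrasubject`, with `SD_intrasubject` the sample SD
#' (n - 1 denominator) of the per-subject signed differences
#' scan1 - scan2.  Excluded subjects are removed from both scans.
#'
#' @param data data frame with columns `ratio_scan1` and `ratio_scan2` (and
#'   optionally a logical `excluded`), or a numeric vector of scan-1 values
#' @param scan2 numeric vector of scan-2 values when `data` is a vector
#' @return numeric scalar
#' @export
coefficient_of_reproducibility <- function(data, scan2 = NULL) {
  p <- paired_values(data, scan2)
  if (length(p$s1) < 2) {
    abort("need at least 2 paired subjects after exclusions")
  }
  1.96 * sd(p$s1 - p$s2)
}

#' Coefficient of variation
#'
#' Pooled-sample SD of both scans' values (stacked, n - 1 denominator)
#' divided by the pooled mean.
#'
#' @inheritParams coefficient_of_reproducibility
#' @return numeric scalar
#' @export
coefficient_of_variation <- function(data, scan2 = NULL) {
  p <- paired_values(data, scan2)
  pooled <- c(p$s1, p$s2)
  m <- mean(pooled)
  if (m <= 0) abort("pooled mean must be > 0 for a coefficient of variation")
  sd(pooled) / m
}

paired_values <- function(data, scan2) {
  if (is.numeric(data) && !is.null(scan2)) {
    if (length(data) != length(scan2)) {
      abort("paired scans must have equal length")
    }
    return(list(s1 = data, s2 = scan2))
  }
  if (!all(c("ratio_scan1", "ratio_scan2") %in% names(data))) {
    abort("data needs columns ratio_scan1 and ratio_scan2")
  }
  keep <- if ("excluded" %in% names(data)) !data$excluded else
    rep(TRUE, nrow(data))
  list(s1 = data$ratio_scan1[keep], s2 = data$ratio_scan2[keep])
}

technique_scheme <- function(technique, phantom, mask = NULL, coils = NULL,
                             fov_mm = NULL) {
  if (is.null(fov_mm)) fov_mm <- phantom$fov_mm
  switch(technique,
    "AW FT-MRS" = , "AW SLAM" = , "AW SLIM" =
      make_aw_scheme(c(8, 16, 8), center_averages = 4, fov_mm = fov_mm),
    "4x4x4 SLAM" = , "4x4x4 SLIM" =
      make_central_scheme(c(8, 16, 8), c(4, 4, 4), averages = 6,
                          fov_mm = fov_mm),
    "fSLAM" = {
      init <- make_central_scheme(c(8, 16, 8), c(4, 4, 4), averages = 6,
                                  fov_mm = fov_mm)
      if (is.null(mask)) mask <- as_compartment_mask(phantom)
      sens <- if (is.null(coils)) NULL else
        rowSums(resolve_sensitivity(coils, phantom$grid_shape,
                                    phantom$fov_mm, prod(phantom$grid_shape)))
      optimize_fslam(init, mask, target = "heart", sensitivity = sens)
    },
    abort(sprintf("unknown technique '%s'", technique))
  )
}

# Heart voxel nearest the heart-compartment centroid: the "midseptal" voxel
# used for single-voxel FT-MRS readouts.
midseptal_voxel <- function(mask) {
  heart_id <- mask$compartment_ids[["heart"]]
  idx <- which(mask$label_map == heart_id, arr.ind = TRUE)
  if (nrow(idx) == 0) abort("mask has no heart voxels")
  ctr <- colMeans(idx)
  idx[which.min(rowSums(sweep(idx, 2, ctr)^2)), ]
}

#' Run one acquisition-reconstruction technique end to end
#'
#' Scheme generation, forward encoding of the phantom, coil combination,
#' reconstruction (compartment or midseptal voxel), time-domain fitting and
#' blood/saturation correction, in one dispatch.
#'
#' @param phantom an `mrsi_phantom`
#' @param technique one of the names in [technique_table()]
#' @param noise_sd per-average noise SD
#' @param seed integer seed for the noise draw
#' @param coils `NULL` (uniform single channel) or a [coil_geometry()]
#' @param n_time,dwell_s readout parameters
#' @param cfg a [correction_config()]
#' @param kdata optional pre-acquired `kspace_data` (multi-channel allowed);
#'   when supplied, the acquisition step is skipped so several
#'   reconstructions can share one dataset
#' @param scheme optional pre-built scheme (e.g. a cached fSLAM
#'   optimization)
#' @return list with elements `technique`, `ratio`, `snr`, `linewidth_hz`,
#'   `crlb_amplitude`, `fit`, `spectra`, `condition`, `scheme`, `seed`
#' @export
run_technique <- function(phantom, technique, noise_sd = 0, seed = 1,
                          coils = NULL, n_time = 256, dwell_s = 1 / 6000,
                          cfg = correction_config(), kdata = NULL,
                          scheme = NULL) {
  mask <- as_compartment_mask(phantom)
  if (is.null(scheme)) {
    scheme <- if (is.null(kdata)) {
      technique_scheme(technique, phantom, mask, coils)
    } else {
      kdata$scheme
    }
  }
  if (is.null(kdata)) {
    kdata <- forward_encode(phantom, scheme, coils = coils,
                            noise_sd = noise_sd, seed = seed,
                            n_time = n_time, dwell_s = dwell_s)
  }
  combined <- if (kdata$n_channels > 1) wsvd_combine(kdata) else kdata

  recon_kind <- technique_table()$reconstruction[
    match(technique, technique_table()$technique)]
  if (is.na(recon_kind)) abort(sprintf("unknown technique '%s'", technique))

  condition <- NA_real_
  if (recon_kind == "Fourier transform") {
    vs <- ft_mrs_reconstruct(combined)
    vox <- midseptal_voxel(mask)
    fid <- extract_voxel(vs, vox)$fid
    spectra <- vs
  } else {
    op <- if (recon_kind == "SLAM") slam_operator(scheme, mask) else
      build_g_matrix(scheme, mask)
    spectra <- reconstruct_with_operator(combined, op)
    condition <- op$condition
    hi <- match("heart", names(mask$compartment_ids))
    fid <- spectra$time_signals[hi, ]
  }

  fit <- fit_time_domain(fid, default_fit_model(combined$dwell_s))
  pcr <- match("PCr", fit$name)
  # a blood correction that wipes out gamma-ATP marks the spectrum for
  # exclusion (never silently), mirroring failed-correction exclusions in
  # test-retest practice
  ratio <- tryCatch(
    suppressWarnings(pcr_atp_ratio(fit, cfg)),
    error = function(e) NA_real_
  )
  exclusion_reason <- if (is.na(ratio)) "blood correction failed" else
    NA_character_
  list(
    technique = technique,
    ratio = ratio,
    excluded = is.na(ratio),
    exclusion_reason = exclusion_reason,
    snr = compute_snr(fit, "PCr"),
    linewidth_hz = fit$linewidth_hz[pcr],
    crlb_amplitude = fit$crlb_amplitude[pcr],
    fit = fit, spectra = spectra, condition = condition,
    scheme = scheme, seed = seed
  )
}

# Randomized per-subject phantom: heart geometry and field amplitude drawn
# from the configured uniform ranges.
subject_phantom <- function(ranges) {
  semi <- stats::runif(3, ranges$heart_semi_axes_mm[1],
                       ranges$heart_semi_axes_mm[2])
  ctr <- c(stats::runif(1, -ranges$heart_shift_mm, ranges$heart_shift_mm),
           -10 + stats::runif(1, -ranges$heart_shift_mm,
                              ranges$heart_shift_mm),
           stats::runif(1, -ranges$heart_shift_mm, ranges$heart_shift_mm))
  b0 <- stats::runif(1, ranges$b0_peak_hz[1], ranges$b0_peak_hz[2])
  make_cardiac_phantom(list(
    heart = list(center_mm = ctr, semi_axes_mm = semi),
    b0 = list(peak_hz = b0)
  ))
}

#' Default study configuration
#'
#' Subject variability ranges and acquisition parameters of the synthetic
#' test-retest study.
#'
#' @return named list: `heart_semi_axes_mm` (uniform range), `heart_shift_mm`
#'   (center jitter half-width), `b0_peak_hz` (uniform range), `n_time`,
#'   `dwell_s`, `use_coils`
#' @export
study_config <- function() {
  list(
    heart_semi_axes_mm = c(38, 50),
    heart_shift_mm = 8,
    b0_peak_hz = c(20, 40),
    n_time = 256,
    dwell_s = 1 / 6000,
    use_coils = TRUE
  )
}

#' Run a synthetic test-retest study
#'
#' Simulates `n_subjects` randomized phantoms, each "scanned" twice (two
#' independent noise realizations of the three acquisitions), reconstructs
#' all six techniques per scan, fits and corrects the spectra, and tabulates
#' per-technique summary statistics, CoR and CoV.
#'
#' @param n_subjects number of synthetic subjects (>= 2)
#' @param noise_sd per-average noise SD (0 gives a noiseless study); the
#'   default 1.0 is calibrated so the single-voxel AW FT-MRS PCr SNR of the
#'   default phantom sits near the low-teens reference level typical of
#'   7 T cardiac 31P single-voxel readouts
#' @param seed master seed governing subject draws and scan noise
#' @param config a [study_config()] list (partial overrides merged)
#' @return list with `results` (one row per subject x scan x technique,
#'   including explicit exclusion flags), `summary` (one row per technique:
#'   mean/SD of ratio, SNR, linewidth, CRLB, plus CoR and CoV over the
#'   non-excluded pairs), `exclusions` (the logged exclusion table) and
#'   `config`
#' @export
run_study <- function(n_subjects = 8, noise_sd = 1.0, seed = 1,
                      config = list()) {
  cfg <- merge_config(study_config(), config)
  if (n_subjects < 2) abort("need at least 2 subjects")
  set.seed(as.integer(seed))
  subject_seeds <- sample.int(2^30, n_subjects)
  coils <- if (isTRUE(cfg$use_coils)) default_cardiac_coil() else NULL

  rows <- list()
  for (s in seq_len(n_subjects)) {
    set.seed(subject_seeds[s])
    phantom <- subject_phantom(cfg)
    mask <- as_compartment_mask(phantom)
    schemes <- list(
      aw = technique_scheme("AW SLAM", phantom),
      central = technique_scheme("4x4x4 SLAM", phantom),
      fslam = technique_scheme("fSLAM", phantom, mask, coils)
    )
    for (scan in 1:2) {
      scan_seed <- (subject_seeds[s] + 7919L * scan) %% 2147483647L
      acq <- list(
        aw = forward_encode(phantom, schemes$aw, coils = coils,
                            noise_sd = noise_sd, seed = scan_seed,
                            n_time = cfg$n_time, dwell_s = cfg$dwell_s),
        central = forward_encode(phantom, schemes$central, coils = coils,
                                 noise_sd = noise_sd, seed = scan_seed + 1L,
                                 n_time = cfg$n_time, dwell_s = cfg$dwell_s),
        fslam = forward_encode(phantom, schemes$fslam, coils = coils,
                               noise_sd = noise_sd, seed = scan_seed + 2L,
                               n_time = cfg$n_time, dwell_s = cfg$dwell_s)
      )
      acq_for <- c("AW FT-MRS" = "aw", "AW SLAM" = "aw", "AW SLIM" = "aw",
                   "4x4x4 SLAM" = "central", "4x4x4 SLIM" = "central",
                   "fSLAM" = "fslam")
      for (tech in names(acq_for)) {
        r <- run_technique(phantom, tech, kdata = acq[[acq_for[tech]]],
                           scheme = schemes[[acq_for[tech]]])
        rows[[length(rows) + 1]] <- tibble(
          subject = s, scan = scan, technique = tech,
          ratio = r$ratio, snr = r$snr, linewidth_hz = r$linewidth_hz,
          crlb_amplitude = r$crlb_amplitude, condition = r$condition,
          excluded = r$excluded,
          exclusion_reason = r$exclusion_reason
        )
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  exclusions <- results[results$excluded,
                        c("subject", "scan", "technique",
                          "exclusion_reason")]

  # paired statistics drop a subject's pair whenever either repeat was
  # excluded
  pair_stat <- function(s1, s2, f) {
    keep <- !is.na(s1) & !is.na(s2)
    if (sum(keep) < 2) return(NA_real_)
    f(s1[keep], s2[keep])
  }

  summary <- results |>
    tidyr::pivot_wider(
      id_cols = c("subject", "technique"),
      names_from = "scan",
      values_from = c("ratio", "snr", "linewidth_hz", "crlb_amplitude"),
      names_sep = "_scan"
    ) |>
    dplyr::group_by(.data$technique) |>
    dplyr::summarise(
      ratio_mean = mean(c(.data$ratio_scan1, .data$ratio_scan2),
                        na.rm = TRUE),
      ratio_sd = sd(c(.data$ratio_scan1, .data$ratio_scan2), na.rm = TRUE),
      snr_mean = mean(c(.data$snr_scan1, .data$snr_scan2)),
      snr_sd = sd(c(.data$snr_scan1, .data$snr_scan2)),
      linewidth_mean = mean(c(.data$linewidth_hz_scan1,
                              .data$linewidth_hz_scan2)),
      crlb_mean = mean(c(.data$crlb_amplitude_scan1,
                         .data$crlb_amplitude_scan2)),
      cor = pair_stat(.data$ratio_scan1, .data$ratio_scan2,
                      coefficient_of_reproducibility),
      cov = pair_stat(.data$ratio_scan1, .data$ratio_scan2,
                      coefficient_of_variation),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$technique, technique_table()$technique))

  list(results = results, summary = summary, exclusions = exclusions,
       config = cfg, seed = seed)
}

#' Wilcoxon signed-rank comparisons against a reference technique
#'
#' Paired two-sided tests of each technique's values (both scans stacked as
#' in the reproducibility analysis) against the reference technique on the
#' same subjects and scans.  Delegated to [stats::wilcox.test()].
#'
#' @param results the `results` tibble of [run_study()]
#' @param value column to compare (default `"snr"`)
#' @param reference reference technique (default `"AW FT-MRS"`)
#' @return tibble of technique, statistic and p value
#' @export
compare_techniques <- function(results, value = "snr",
                               reference = "AW FT-MRS") {
  ref <- results[results$technique == reference, ]
  ref <- ref[order(ref$subject, ref$scan), ][[value]]
  others <- setdiff(unique(results$technique), reference)
  purrr::map_dfr(others, function(tech) {
    x <- results[results$technique == tech, ]
    x <- x[order(x$subject, x$scan), ][[value]]
    wt <- stats::wilcox.test(x, ref, paired = TRUE, exact = FALSE)
    tibble(technique = tech, reference = reference, value = value,
           statistic = unname(wt$statistic), p_value = wt$p.value)
  })
}

#' Format a study summary as a markdown table
#'
#' @param summary the `summary` tibble of [run_study()]
#' @return character vector of markdown lines
#' @export
format_study_markdown <- function(summary) {
  hdr <- paste("| Technique | PCr/ATP ratio | PCr SNR | PCr linewidth (Hz)",
               "| PCr CRLB | CoR | CoV |")
  sep <- paste(c("|", rep(" --- |", 7)), collapse = "")
  rows <- sprintf(
    "| %s | %.2f ± %.2f | %.2f ± %.2f | %.1f | %.3g | %.2f | %.2f |",
    summary$technique, summary$ratio_mean, summary$ratio_sd,
    summary$snr_mean, summary$snr_sd, summary$linewidth_mean,
    summary$crlb_mean, summary$cor, summary$cov
  )
  c(hdr, sep, rows)
}
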
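lorentz_fid <- function(tv, amp, f, lw, ph = 0) {
  as.vector(
    exp(outer(tv, 2i * pi * f - pi * lw) +
          matrix(1i * ph, length(tv), length(f), byrow = TRUE)) %*% amp
  )
}

test_that("noiseless Lorentzian parameters are recovered exactly", {
  dwell <- 1 / 6000
  tv <- (0:255) * dwell
  m1 <- fit_model(
    tibble::tibble(name = "PCr", frequency_hz = 0, frequency_bounds_hz = 40,
                   linewidth_hz = 20, linewidth_min_hz = 5,
                   linewidth_max_hz = 120),
    dwell_s = dwell
  )
  ft <- fit_time_domain(lorentz_fid(tv, 1, 0, 30), m1)
  expect_equal(ft$amplitude, 1, tolerance = 1e-6)
  expect_equal(ft$frequency_hz, 0, tolerance = 1e-4)
  expect_equal(ft$linewidth_hz, 30, tolerance = 1e-5)

  # two resonances with 2:1 amplitudes
  m2 <- fit_model(
    tibble::tibble(name = c("a", "b"), frequency_hz = c(0, -150),
                   frequency_bounds_hz = 40,
                   linewidth_hz = c(25, 25), linewidth_min_hz = 5,
                   linewidth_max_hz = 120),
    dwell_s = dwell
  )
  fid2 <- lorentz_fid(tv, c(2, 1), c(0, -150), c(30, 40))
  ft2 <- fit_time_domain(fid2, m2)
  expect_equal(ft2$amplitude[1] / ft2$amplitude[2], 2, tolerance = 1e-6)
  expect_equal(ft2$linewidth_hz, c(30, 40), tolerance = 1e-5)
})

test_that("randomized noiseless multi-resonance fits recover parameters", {
  set.seed(31)
  dwell <- 1 / 6000
  tv <- (0:255) * dwell
  for (i in 1:5) {
    nr <- sample(2:3, 1)
    f <- sort(runif(nr, -1500, 800))
    if (min(diff(c(f, Inf))) < 150) f <- f + seq(0, by = 200, length.out = nr)
    a <- runif(nr, 0.5, 3)
    lw <- runif(nr, 15, 60)
    ph <- runif(1, -1, 1)
    m <- fit_model(
      tibble::tibble(name = paste0("r", seq_len(nr)),
                     frequency_hz = f + runif(nr, -10, 10),
                     frequency_bounds_hz = 30,
                     linewidth_hz = pmin(pmax(lw + runif(nr, -5, 5), 6), 119),
                     linewidth_min_hz = 5, linewidth_max_hz = 120),
      dwell_s = dwell
    )
    ft <- fit_time_domain(lorentz_fid(tv, a, f, lw, ph), m)
    expect_equal(ft$amplitude, a, tolerance = 1e-5)
    expect_equal(ft$linewidth_hz, lw, tolerance = 1e-4)
    expect_equal(ft$phase_rad[1], ph, tolerance = 1e-5)
  }
})

test_that("CRLBs follow the Fisher-information closed forms", {
  dwell <- 1 / 6000
  n <- 256
  tv <- (0:(n - 1)) * dwell
  m <- fit_model(
    tibble::tibble(name = "x", frequency_hz = 50, frequency_bounds_hz = 30,
                   linewidth_hz = 0, linewidth_min_hz = 0,
                   linewidth_max_hz = 0, fix_linewidth = TRUE),
    dwell_s = dwell
  )
  ft <- fit_time_domain(lorentz_fid(tv, 1, 50, 0), m)

  # undamped single resonance: amplitude CRLB = sigma / sqrt(N)
  crlb1 <- compute_crlb(ft, noise_sd = 0.2)
  expect_equal(crlb1$crlb_amplitude, 0.2 / sqrt(n), tolerance = 1e-2)
  # linear scaling in sigma
  crlb2 <- compute_crlb(ft, noise_sd = 0.4)
  expect_equal(crlb2$crlb_amplitude, 2 * crlb1$crlb_amplitude,
               tolerance = 1e-10)

  # overlapping resonances: CRLBs diverge as the separation halves
  crlb_sep <- sapply(c(40, 20, 10), function(df) {
    msep <- fit_model(
      tibble::tibble(name = c("a", "b"), frequency_hz = c(0, df),
                     frequency_bounds_hz = 5, linewidth_hz = 30,
                     linewidth_min_hz = 5, linewidth_max_hz = 120),
      dwell_s = dwell
    )
    ftsep <- fit_time_domain(lorentz_fid(tv, c(1, 1), c(0, df), c(30, 30)),
                             msep, n_starts = 1)
    compute_crlb(ftsep, noise_sd = 0.1)$crlb_amplitude[1]
  })
  expect_true(all(diff(crlb_sep) > 0))
  expect_gt(crlb_sep[3] / crlb_sep[1], 2)
})

test_that("Monte-Carlo parameter spread approaches the CRLB", {
  set.seed(77)
  dwell <- 1 / 6000
  n <- 256
  tv <- (0:(n - 1)) * dwell
  sigma <- 1 / 15  # SNR 15 at unit amplitude
  m <- fit_model(
    tibble::tibble(name = "PCr", frequency_hz = 0, frequency_bounds_hz = 40,
                   linewidth_hz = 25, linewidth_min_hz = 5,
                   linewidth_max_hz = 120),
    dwell_s = dwell
  )
  clean <- lorentz_fid(tv, 1, 0, 30)
  fits <- sapply(seq_len(120), function(i) {
    noisy <- clean + complex(real = rnorm(n, sd = sigma),
                             imaginary = rnorm(n, sd = sigma))
    ft <- fit_time_domain(noisy, m, n_starts = 1)
    c(ft$amplitude, ft$frequency_hz, ft$linewidth_hz)
  })
  crlb <- compute_crlb(fit_time_domain(clean, m, n_starts = 1),
                       noise_sd = sigma)
  emp <- apply(fits, 1, sd)
  # at this sample size the spread should sit near (and not below ~85% of)
  # the bound
  expect_gt(emp[1], 0.85 * crlb$crlb_amplitude)
  expect_lt(emp[1], 1.4 * crlb$crlb_amplitude)
  expect_gt(emp[2], 0.85 * crlb$crlb_frequency)
  expect_lt(emp[3], 1.4 * crlb$crlb_linewidth)
})

test_that("SNR and its noise estimator are calibrated", {
  set.seed(5)
  dwell <- 1 / 6000
  n <- 256
  tv <- (0:(n - 1)) * dwell
  m <- fit_model(
    tibble::tibble(name = "PCr", frequency_hz = 0, frequency_bounds_hz = 40,
                   linewidth_hz = 25, linewidth_min_hz = 5,
                   linewidth_max_hz = 120),
    dwell_s = dwell
  )
  clean <- lorentz_fid(tv, 5, 0, 40)
  sigma <- 0.25
  sds <- replicate(150, {
    noisy <- clean + complex(real = rnorm(n, sd = sigma),
                             imaginary = rnorm(n, sd = sigma))
    attr(fit_time_domain(noisy, m, n_starts = 1), "noise_sd")
  })
  expect_equal(mean(sds), sigma, tolerance = 0.03)

  noisy <- clean + complex(real = rnorm(n, sd = sigma),
                           imaginary = rnorm(n, sd = sigma))
  ft <- fit_time_domain(noisy, m, n_starts = 1)
  expect_equal(compute_snr(ft, "PCr"),
               ft$amplitude[1] / attr(ft, "noise_sd"))
  ft2 <- fit_time_domain(2 * noisy, m, n_starts = 1)
  expect_equal(compute_snr(ft2, "PCr"), compute_snr(ft, "PCr"),
               tolerance = 1e-6)
  expect_error(compute_snr(ft, "gamma-ATP"), "not in the fit")
})

test_that("blood and saturation corrections follow their closed forms", {
  fake_fit <- tibble::tibble(
    name = c("PCr", "gamma-ATP", "2,3-DPG-2", "2,3-DPG-3"),
    amplitude = c(2, 1, 1.2, 0.8)
  )
  cfg0 <- correction_config(blood_atp_per_dpg = 0)
  expect_equal(blood_correct(fake_fit, cfg0), 1)
  cfg3 <- correction_config(blood_atp_per_dpg = 0.3)
  expect_equal(blood_correct(fake_fit, cfg3), 1 - 0.3 * 1)
  no_dpg <- fake_fit[1:2, ]
  expect_equal(blood_correct(no_dpg, cfg3), 1)
  heavy <- correction_config(blood_atp_per_dpg = 2)
  expect_warning(out <- blood_correct(fake_fit, heavy), "clamped")
  expect_equal(out, 0)

  # TR >> T1 and a 90-degree flip leave amplitudes unchanged
  cfg_relax <- correction_config(tr_s = 1000, flip_deg = 90,
                                 t1_s = c("PCr" = 3))
  expect_equal(saturation_factor("PCr", cfg_relax), 1, tolerance = 1e-10)
  expect_error(
    saturation_factor("PCr", correction_config(flip_deg = 0,
                                               t1_s = c("PCr" = 3))),
    "zero flip"
  )

  # closed form cross-checked by iterating the Bloch steady state
  cfg <- correction_config(tr_s = 1, flip_deg = 30, t1_s = c("PCr" = 3))
  e1 <- exp(-1 / 3)
  expect_equal(saturation_factor("PCr", cfg),
               (1 - e1) * sin(pi / 6) / (1 - cos(pi / 6) * e1),
               tolerance = 1e-12)
  mz <- 1
  for (i in 1:500) mz <- 1 - (1 - mz * cos(pi / 6)) * e1
  expect_equal(saturation_factor("PCr", cfg), mz * sin(pi / 6),
               tolerance = 1e-8)

  # ratio invariances
  fit_eq <- tibble::tibble(name = c("PCr", "gamma-ATP"),
                           amplitude = c(1, 1))
  cfg_id <- correction_config(blood_atp_per_dpg = 0, tr_s = 1000,
                              flip_deg = 90,
                              t1_s = c("PCr" = 3, "gamma-ATP" = 2))
  expect_equal(pcr_atp_ratio(fit_eq, cfg_id), 1)
  fit_sc <- fit_eq
  fit_sc$amplitude <- fit_sc$amplitude * 3.7
  expect_equal(pcr_atp_ratio(fit_sc, cfg_id), 1)
})
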
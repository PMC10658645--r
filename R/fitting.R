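# Time-domain Lorentzian spectral fitting with Cramer-Rao lower bounds
#
# The model is a sum of complex Lorentzian lines,
#   m(t) = sum_r a_r exp(i phi_r) exp((2 pi i f_r - pi lw_r) t),
# fitted to the FID by nonlinear least squares on the stacked real and
# imaginary parts (minpack.lm, analytic Jacobian, multi-start on frequency).
# Prior knowledge is reduced to per-resonance frequency and linewidth
# bounds, an optional shared zeroth-order phase, and a fixed first-order
# phase delay; ATP multiplets are modeled as one Lorentzian per moiety.

#' Specify a time-domain fit model
#'
#' @param resonances tibble/data frame with columns `name`, `frequency_hz`
#'   (initial), `frequency_bounds_hz` (half-width of the search box around
#'   the initial frequency), `linewidth_hz` (initial), `linewidth_min_hz`,
#'   `linewidth_max_hz`, and optionally `amplitude` (initial, default 1) and
#'   `fix_linewidth` (logical, default FALSE)
#' @param dwell_s dwell time (s)
#' @param phase_mode `"shared"` (single zeroth-order phase for all lines,
#'   the default) or `"free"` (per-resonance phase)
#' @param phase0 initial zeroth-order phase (rad)
#' @param first_order_phase_s fixed first-order phase delay tau (s): each
#'   line carries an extra phase 2 pi f_r tau
#' @return a `fit_model` object
#' @export
fit_model <- function(resonances, dwell_s,
                      phase_mode = c("shared", "free"),
                      phase0 = 0, first_order_phase_s = 0) {
  phase_mode <- match.arg(phase_mode)
  res <- as_tibble(resonances)
  if (nrow(res) < 1) abort("the model needs at least one resonance")
  if (!"amplitude" %in% names(res)) res$amplitude <- 1
  if (!"fix_linewidth" %in% names(res)) res$fix_linewidth <- FALSE
  if (!"frequency_bounds_hz" %in% names(res)) res$frequency_bounds_hz <- 30
  needed <- c("name", "frequency_hz", "linewidth_hz", "linewidth_min_hz",
              "linewidth_max_hz")
  if (!all(needed %in% names(res))) {
    abort(sprintf("resonances must provide columns: %s",
                  paste(needed, collapse = ", ")))
  }
  bad <- !res$fix_linewidth &
    (res$linewidth_hz < res$linewidth_min_hz |
       res$linewidth_hz > res$linewidth_max_hz)
  if (any(bad)) abort("initial linewidths must lie inside their bounds")
  structure(
    list(resonances = res, dwell_s = dwell_s, phase_mode = phase_mode,
         phase0 = phase0, first_order_phase_s = first_order_phase_s),
    class = "fit_model"
  )
}

#' Default 31P cardiac fit model
#'
#' One Lorentzian per line of the package's 31P spectrum (PCr, the three ATP
#' moieties, the 2,3-DPG doublet and PDE), shared zeroth-order phase,
#' frequencies bounded +/- 30 Hz around their nominal positions and
#' linewidths in \[5, 150\] Hz.
#'
#' @param dwell_s dwell time (s)
#' @param names subset of line names to include (default all seven)
#' @return a [fit_model()]
#' @export
default_fit_model <- function(dwell_s, names = NULL) {
  if (is.null(names)) names <- names(default_resonance_freqs)
  fit_model(
    tibble(
      name = names,
      frequency_hz = unname(default_resonance_freqs[names]),
      frequency_bounds_hz = 30,
      linewidth_hz = unname(default_resonance_linewidths[names]),
      linewidth_min_hz = 5, linewidth_max_hz = 150,
      amplitude = 1
    ),
    dwell_s = dwell_s
  )
}

# Parameter packing: amplitudes (R), frequencies (R), free linewidths,
# then phase(s).
pack_params <- function(model) {
  res <- model$resonances
  free_lw <- which(!res$fix_linewidth)
  nr <- nrow(res)
  nph <- if (model$phase_mode == "shared") 1L else nr
  list(
    n_res = nr, free_lw = free_lw, n_phase = nph,
    par = c(res$amplitude, res$frequency_hz, res$linewidth_hz[free_lw],
            rep(model$phase0, nph)),
    lower = c(rep(0, nr), res$frequency_hz - res$frequency_bounds_hz,
              res$linewidth_min_hz[free_lw], rep(-pi, nph)),
    upper = c(rep(Inf, nr), res$frequency_hz + res$frequency_bounds_hz,
              res$linewidth_max_hz[free_lw], rep(pi, nph))
  )
}

unpack_params <- function(par, model, pk) {
  res <- model$resonances
  nr <- pk$n_res
  amp <- par[seq_len(nr)]
  freq <- par[nr + seq_len(nr)]
  lw <- res$linewidth_hz
  lw[pk$free_lw] <- par[2 * nr + seq_along(pk$free_lw)]
  ph <- par[2 * nr + length(pk$free_lw) + seq_len(pk$n_phase)]
  phase <- if (model$phase_mode == "shared") rep(ph, nr) else ph
  list(amplitude = amp, frequency_hz = freq, linewidth_hz = lw,
       phase_rad = phase)
}

model_components <- function(p, model, tvec) {
  ph <- p$phase_rad + 2 * pi * p$frequency_hz * model$first_order_phase_s
  exp(outer(tvec, 2i * pi * p$frequency_hz - pi * p$linewidth_hz) +
        matrix(1i * ph, length(tvec), length(ph), byrow = TRUE))
}

model_eval <- function(p, model, tvec) {
  as.vector(model_components(p, model, tvec) %*% p$amplitude)
}

# Jacobian of the complex model wrt the packed free parameters (N x P
# complex), columns ordered as in pack_params.
model_jacobian <- function(p, model, tvec, pk) {
  comp <- model_components(p, model, tvec)        # N x R (unit amplitude)
  scaled <- comp * matrix(p$amplitude, length(tvec), pk$n_res, byrow = TRUE)
  d_amp <- comp
  d_freq <- scaled *
    (2i * pi * (tvec + model$first_order_phase_s))
  d_lw <- (-pi * tvec) * scaled[, pk$free_lw, drop = FALSE]
  d_ph <- if (model$phase_mode == "shared") {
    matrix(1i * rowSums(scaled), ncol = 1)
  } else {
    1i * scaled
  }
  cbind(d_amp, d_freq, d_lw, d_ph)
}

stack_ri <- function(z) c(Re(z), Im(z))

#' Fit a FID in the time domain
#'
#' Constrained nonlinear least squares of the Lorentzian model against the
#' complex FID (real and imaginary parts stacked), with optional multi-start
#' on the line frequencies within their bounds.  The residual noise SD is
#' estimated from the final `noise_fraction` of the residual FID.
#'
#' @param fid complex FID vector
#' @param model a [fit_model()]
#' @param n_starts frequency multi-start count (default 3; the first start
#'   is the model's initial values)
#' @param noise_fraction tail fraction used for the noise-SD estimate
#' @param maxiter per-start Levenberg-Marquardt iteration cap
#' @return an `mrsi_fit`: a tibble with one row per resonance (amplitude,
#'   frequency, linewidth, phase and their CRLBs) carrying the noise SD,
#'   residual norm, fitted curve and model as attributes
#' @export
fit_time_domain <- function(fid, model, n_starts = 3, noise_fraction = 0.25,
                            maxiter = 200) {
  pk <- pack_params(model)
  n <- length(fid)
  if (n < 4 * length(pk$par)) {
    abort("FID too short: need at least 4 points per free parameter")
  }
  tvec <- (seq_len(n) - 1) * model$dwell_s
  target <- stack_ri(fid)

  resid_fn <- function(par) {
    p <- unpack_params(par, model, pk)
    stack_ri(model_eval(p, model, tvec)) - target
  }
  jac_fn <- function(par) {
    p <- unpack_params(par, model, pk)
    j <- model_jacobian(p, model, tvec, pk)
    rbind(Re(j), Im(j))
  }

  nr <- pk$n_res
  offsets <- if (n_starts <= 1) 0 else
    seq(-0.5, 0.5, length.out = n_starts) *
      min(model$resonances$frequency_bounds_hz)
  best <- NULL
  for (off in offsets) {
    par0 <- pk$par
    par0[nr + seq_len(nr)] <- pmin(
      pmax(par0[nr + seq_len(nr)] + off, pk$lower[nr + seq_len(nr)]),
      pk$upper[nr + seq_len(nr)]
    )
    ft <- tryCatch(
      minpack.lm::nls.lm(
        par = par0, lower = pk$lower, upper = pk$upper,
        fn = resid_fn, jac = jac_fn,
        control = minpack.lm::nls.lm.control(maxiter = maxiter)
      ),
      error = function(e) NULL
    )
    if (is.null(ft)) next
    if (is.null(best) || ft$deviance < best$deviance) best <- ft
  }
  if (is.null(best)) {
    abort("time-domain fit failed to converge from every start")
  }

  p <- unpack_params(best$par, model, pk)
  fitted <- model_eval(p, model, tvec)
  residual <- fid - fitted
  n_tail <- max(2, floor(n * noise_fraction))
  tail_r <- residual[seq.int(n - n_tail + 1, n)]
  noise_sd <- sd(c(Re(tail_r), Im(tail_r)))

  crlb <- crlb_from_model(p, model, tvec, pk, noise_sd)
  at_bounds <- best$par <= pk$lower + 1e-9 | best$par >= pk$upper - 1e-9

  out <- tibble(
    name = model$resonances$name,
    amplitude = p$amplitude,
    frequency_hz = p$frequency_hz,
    linewidth_hz = p$linewidth_hz,
    phase_rad = p$phase_rad,
    crlb_amplitude = crlb$amplitude,
    crlb_frequency = crlb$frequency,
    crlb_linewidth = crlb$linewidth,
    crlb_phase = crlb$phase
  )
  structure(out,
    class = c("mrsi_fit", class(out)),
    noise_sd = noise_sd,
    residual_norm = sqrt(best$deviance),
    fid = fid, fitted = fitted, model = model,
    par = best$par, packing = pk,
    dwell_s = model$dwell_s,
    active_bounds = at_bounds,
    info = best$info
  )
}

crlb_from_model <- function(p, model, tvec, pk, noise_sd) {
  j <- model_jacobian(p, model, tvec, pk)
  js <- rbind(Re(j), Im(j))
  fisher <- crossprod(js) / noise_sd^2
  cov <- tryCatch(solve(fisher), error = function(e) {
    matrix(NA_real_, nrow(fisher), ncol(fisher))
  })
  se <- sqrt(pmax(diag(cov), 0))
  nr <- pk$n_res
  lw <- rep(NA_real_, nr)
  lw[pk$free_lw] <- se[2 * nr + seq_along(pk$free_lw)]
  ph_se <- se[2 * nr + length(pk$free_lw) + seq_len(pk$n_phase)]
  list(
    amplitude = se[seq_len(nr)],
    frequency = se[nr + seq_len(nr)],
    linewidth = lw,
    phase = if (model$phase_mode == "shared") rep(ph_se, nr) else ph_se
  )
}

#' Cramer-Rao lower bounds at the fitted point
#'
#' `sqrt(diag((J' J / sigma^2)^-1))` with J the complex model Jacobian
#' stacked real/imaginary, evaluated at the fitted parameters.
#'
#' @param fit an `mrsi_fit`
#' @param noise_sd noise SD; defaults to the fit's tail estimate
#' @return tibble of per-resonance parameter lower-bound SDs
#' @export
compute_crlb <- function(fit, noise_sd = NULL) {
  if (is.null(noise_sd)) noise_sd <- attr(fit, "noise_sd")
  model <- attr(fit, "model")
  pk <- attr(fit, "packing")
  p <- unpack_params(attr(fit, "par"), model, pk)
  n <- length(attr(fit, "fid"))
  tvec <- (seq_len(n) - 1) * model$dwell_s
  crlb <- crlb_from_model(p, model, tvec, pk, noise_sd)
  tibble(
    name = model$resonances$name,
    crlb_amplitude = crlb$amplitude,
    crlb_frequency = crlb$frequency,
    crlb_linewidth = crlb$linewidth,
    crlb_phase = crlb$phase
  )
}

#' Fitted-amplitude SNR of a resonance
#'
#' Fitted amplitude divided by the time-domain noise SD (estimated from the
#' residual tail at fit time).
#'
#' @param fit an `mrsi_fit`
#' @param resonance line name (default `"PCr"`)
#' @return numeric scalar
#' @export
compute_snr <- function(fit, resonance = "PCr") {
  i <- match(resonance, fit$name)
  if (is.na(i)) abort(sprintf("resonance '%s' not in the fit", resonance))
  fit$amplitude[i] / attr(fit, "noise_sd")
}

#' Correction configuration for PCr/ATP quantification
#'
#' Holds the blood-correction factor (fraction of the mean 2,3-DPG doublet
#' amplitude subtracted from gamma-ATP) and the steady-state saturation
#' parameters (TR, per-metabolite effective flip angle and T1).  The
#' shipped defaults are configurable placeholders typical for 7 T cardiac
#' 31P work, not literature constants; set them from your own calibration.
#'
#' @param blood_atp_per_dpg blood ATP per unit mean 2,3-DPG amplitude
#'   (>= 0, default 0.30)
#' @param tr_s repetition time (s), > 0
#' @param flip_deg named per-metabolite effective flip angles (deg); a
#'   scalar is recycled
#' @param t1_s named per-metabolite T1 values (s), > 0
#' @return a `correction_config` list
#' @export
correction_config <- function(blood_atp_per_dpg = 0.30, tr_s = 1,
                              flip_deg = 30,
                              t1_s = c("PCr" = 3.1, "gamma-ATP" = 1.8,
                                       "alpha-ATP" = 1.8, "beta-ATP" = 1.8,
                                       "2,3-DPG-2" = 2.5, "2,3-DPG-3" = 2.5,
                                       "PDE" = 4.0)) {
  if (blood_atp_per_dpg < 0) abort("blood_atp_per_dpg must be >= 0")
  if (tr_s <= 0) abort("tr_s must be > 0")
  if (any(t1_s <= 0)) abort("t1_s must be > 0")
  structure(
    list(blood_atp_per_dpg = blood_atp_per_dpg, tr_s = tr_s,
         flip_deg = flip_deg, t1_s = t1_s),
    class = "correction_config"
  )
}

lookup_metab <- function(x, name, default = NULL) {
  if (length(x) == 1 && is.null(names(x))) return(unname(x))
  if (name %in% names(x)) return(unname(x[[name]]))
  if (!is.null(default)) return(default)
  abort(sprintf("no value for metabolite '%s'", name))
}

#' Steady-state saturation factor of a metabolite
#'
#' `E = (1 - exp(-TR/T1)) sin(alpha) / (1 - cos(alpha) exp(-TR/T1))`, the
#' steady-state signal of a spoiled acquisition relative to a fully relaxed
#' 90-degree acquisition.
#'
#' @param metabolite metabolite name (looked up in the config's flip/T1
#'   tables)
#' @param cfg a [correction_config()]
#' @return saturation factor in (0, 1\]
#' @export
saturation_factor <- function(metabolite, cfg = correction_config()) {
  a <- lookup_metab(cfg$flip_deg, metabolite) * pi / 180
  if (sin(a) == 0) abort("zero flip angle gives no signal to correct")
  t1 <- lookup_metab(cfg$t1_s, metabolite)
  e1 <- exp(-cfg$tr_s / t1)
  (1 - e1) * sin(a) / (1 - cos(a) * e1)
}

#' Blood correction of the gamma-ATP amplitude
#'
#' Subtracts `blood_atp_per_dpg` times the mean fitted 2,3-DPG doublet
#' amplitude from the fitted gamma-ATP amplitude (the 2,3-DPG intensity is
#' proportional to the blood volume in the sensitive region).  A negative
#' corrected amplitude is clamped to zero with a warning, mirroring the
#' failed-blood-correction exclusions of in-vivo practice.
#'
#' @param fit an `mrsi_fit` (or any data frame with `name` and `amplitude`)
#' @param cfg a [correction_config()]
#' @return corrected gamma-ATP amplitude (numeric scalar)
#' @export
blood_correct <- function(fit, cfg = correction_config()) {
  gi <- match("gamma-ATP", fit$name)
  if (is.na(gi)) abort("fit has no gamma-ATP resonance")
  dpg <- grepl("DPG", fit$name)
  dpg_mean <- if (any(dpg)) mean(fit$amplitude[dpg]) else 0
  out <- fit$amplitude[gi] - cfg$blood_atp_per_dpg * dpg_mean
  if (out < 0) {
    warn("blood correction produced a negative gamma-ATP; clamped to 0")
    out <- 0
  }
  out
}

#' Saturation-correct metabolite amplitudes
#'
#' Divides each amplitude by its steady-state saturation factor.
#'
#' @param amplitudes named numeric vector of fitted amplitudes
#' @param cfg a [correction_config()]
#' @return corrected named numeric vector
#' @export
saturation_correct <- function(amplitudes, cfg = correction_config()) {
  vapply(names(amplitudes), function(nm) {
    amplitudes[[nm]] / saturation_factor(nm, cfg)
  }, numeric(1))
}

#' Blood- and saturation-corrected PCr/ATP ratio
#'
#' Saturation-corrected PCr amplitude over the blood- then
#' saturation-corrected gamma-ATP amplitude.
#'
#' @param fit an `mrsi_fit` containing PCr and gamma-ATP lines
#' @param cfg a [correction_config()]
#' @return numeric scalar
#' @export
pcr_atp_ratio <- function(fit, cfg = correction_config()) {
  pi_ <- match("PCr", fit$name)
  if (is.na(pi_)) abort("fit has no PCr resonance")
  pcr <- fit$amplitude[pi_] / saturation_factor("PCr", cfg)
  atp <- blood_correct(fit, cfg) / saturation_factor("gamma-ATP", cfg)
  if (atp == 0) abort("corrected gamma-ATP amplitude is zero")
  pcr / atp
}
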
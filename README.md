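# slamslim

Compartment-based reconstruction of acquisition-weighted 3D ³¹P cardiac
magnetic resonance spectroscopic imaging (MRSI), with a digital phantom for
end-to-end validation.

## The problem

Cardiac ³¹P spectroscopy measures the phosphocreatine-to-ATP ratio
(PCr/ATP), a biomarker of myocardial energetics, but is starved for SNR even
at 7 T. Conventional Fourier (FT-MRS) reconstruction of phase-encoded MRSI
yields one low-SNR spectrum per voxel; a single midseptal voxel is typically
reported. Compartment-based reconstructions instead solve directly for one
spectrum per anatomical compartment (heart, chest wall, other), pooling
signal over the whole organ.

This package implements, for the three-compartment cardiac setting:

* **SLAM** — the discrete-Fourier phase-encode matrix
  `PE[m, j] = R_m exp(-2πi k_m · x̃_j)` has its voxel columns summed within
  each compartment; the compressed M′ × C system
  `S = PE_c ρ` is solved with the Moore–Penrose pseudoinverse `H`. The
  per-encode repeat counts `R_m` of acquisition-weighted (AW) schemes enter
  as row weights, so repeat-summed scanner data are reconstructed directly.
* **SLIM** — the encoding matrix is instead built from continuous-Fourier
  integrals over compartment volumes,
  `g_mc = R_m ∫_c exp(-2πi k_m · x̃) dx̃`, evaluated in closed form per
  voxel as per-axis `w sinc(k w)` factors.
* **fSLAM** — bounded local optimization of the fractional per-axis k-space
  coordinates of a truncated scheme (12 degrees of freedom for 4×4×4),
  minimizing intercompartmental leakage plus intracompartmental
  nonuniformity of the spatial response function (SRF)
  `β_c(x) = Σ_m h_cm R_m exp(-2πi k_m · x̃)`.
* Supporting machinery: AW/central phase-encode scheme generators, FT-MRS
  reconstruction with a point-spread-function helper, Biot–Savart
  surface-coil sensitivity maps, noise-whitened SVD coil combination,
  constrained time-domain Lorentzian fitting with Cramér–Rao lower bounds,
  blood (2,3-DPG-based) and saturation corrections of PCr/ATP, and the
  test–retest metrics CoR (= 1.96 × SD of paired differences) and CoV
  (pooled SD / mean).
* A **digital cardiac phantom** (heart spheroid, curved chest-wall slab,
  background tissue; Lorentzian ³¹P resonances; smooth B0/phase maps) and a
  forward simulator that produce multi-coil phase-encoded k-space data for
  all six acquisition–reconstruction combinations, plus `run_study()`, a
  synthetic test–retest study across randomized "subjects".

## Worked example

```r
library(slamslim)

ph <- make_cardiac_phantom()                      # 8x16x8, FOV 240x240x200 mm
kd <- forward_encode(ph, make_aw_scheme(c(8, 16, 8), 4),
                     coils = default_cardiac_coil(),
                     noise_sd = 1, seed = 7, n_time = 256)

res <- run_technique(ph, "AW SLAM", kdata = kd)   # wSVD combine -> SLAM -> fit
tidy(res$fit)[, 1:6]
#> # A tibble: 7 × 6
#>   name      amplitude frequency_hz linewidth_hz phase_rad crlb_amplitude
#>   <chr>         <dbl>        <dbl>        <dbl>     <dbl>          <dbl>
#> 1 PCr          0.0566       -0.315         25.2    -0.759       0.000458
#> 2 gamma-ATP    0.0409     -299.            35.9    -0.759       0.000541
#> 3 alpha-ATP    0.0345     -906.            34.5    -0.759       0.000528
#> 4 beta-ATP     0.0346    -1956.            45.6    -0.759       0.000602
#> 5 2,3-DPG-2    0.0163      630.            43.3    -0.759       0.000644
#> 6 2,3-DPG-3    0.0162      750.            41.2    -0.759       0.000633
#> 7 PDE          0.0119      350.            52.8    -0.759       0.000657
```

The fit resolves all seven ³¹P lines of the heart-compartment spectrum; the
amplitude scale is arbitrary (whitened units after coil combination), so the
quantities of interest are ratios and SNR:

```r
sprintf("PCr/ATP = %.3f  PCr SNR = %.1f  linewidth = %.1f Hz",
        res$ratio, res$snr, res$linewidth_hz)
#> "PCr/ATP = 1.801  PCr SNR = 28.6  linewidth = 25.2 Hz"

run_technique(ph, "AW FT-MRS", kdata = kd)[c("ratio", "snr")]
#> PCr/ATP = 1.930, SNR = 21.4   (single midseptal voxel, same k-space data)
```

The phantom's ground-truth corrected PCr/ATP is 2.0; both reconstructions
sit near it, and SLAM's heart-compartment SNR exceeds the single-voxel
FT-MRS readout from the *same* acquisition — the central finding the
synthetic study reproduces at scale (`run_study()`).

SRF maps, PSFs, schemes, spectra and fits all have `autoplot()` methods;
`compute_srf()` / `worst_case_srf()` / `b1_weighted_srf()` give the
localization analysis, and `leakage_report()` tabulates intercompartment
contamination.

A command-line front end over these functions is installed at
`inst/scripts/slamslim-cli.R`
(verbs: `phantom-make`, `scheme-make`, `scheme-optimize`, `simulate`,
`recon`, `srf`, `fit`, `study-run`).

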
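---
title: "Compartment-based MRSI reconstruction: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment-based MRSI reconstruction: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements: the
reconstruction models and their assumptions, the conventions every module
shares, the places where the design was genuinely open and what was decided,
and what the synthetic phantom does and does not establish about real data.

## The reconstruction problem

Phase-encoded MRSI acquires, for each k-space position $k_m$, a time-domain
signal that is the Fourier-weighted sum of all spin signal in the FOV. With
repeat-summed averaging ($R_m$ repeats at encode $m$, stored summed), the
discrete model is

$$ s(k_m, t) \;=\; R_m \sum_j \mathrm{FID}_j(t)\, e^{-2\pi i k_m \cdot \tilde x_j}. $$

FT-MRS inverts this with the inverse DFT voxel by voxel. Compartment-based
reconstruction assumes the FID is *common within each of $C$ anatomical
compartments* and solves a far smaller $M' \times C$ system:

* **SLAM** compresses the phase-encode matrix by summing voxel columns within
  compartments and applies the SVD pseudoinverse $H$.
* **SLIM** builds the same-shaped system from continuous-Fourier integrals of
  the encoding basis over compartment volumes.

Both carry $R_m$ in the operator rather than the data, so acquisition-weighted
(AW) data sets are reconstructed without unweighting. The spatial response
function $\beta_c(x) = \sum_m h_{cm} R_m e^{-2\pi i k_m\cdot\tilde x}$ makes
the localization of either operator explicit; its magnitude is the worst-case
contamination bound (attained when B0-induced phase aligns with the SRF
phase), optionally weighted by the receive-B1 map.

The homogeneity assumption is the method's central leap of faith: within-
compartment variation of metabolite content, B0 or B1 is *not* modeled and
surfaces as bias. The forward simulator deliberately violates homogeneity
(polynomial B0/phase maps, coil-profile receive weighting) so that the
synthetic study exercises this failure mode.

## Conventions shared by every module

* **Coordinates.** Voxel centers at $\tilde x_j = (j - \lfloor M_d/2\rfloor)/M_d$,
  $j = 0..M_d-1$ per axis; integer $k$ are cycles per FOV, and the encoding
  exponential is a DFT on integer-$k$ schemes. Voxel linearization is x
  fastest, then y, then z. The first voxel of an even axis sits exactly at
  $-\mathrm{FOV}/2$ and wraps periodically; `eval_to_voxel_index()` honors
  this when carrying labels onto oversampled SRF grids.
* **Repeats are summed, not averaged.** Simulated noise is drawn per repeat
  and summed, so encode $m$ carries noise SD $\sigma\sqrt{R_m}$ per
  component — which is why $W = \mathrm{diag}(\sqrt{R_m})$ appears in the
  closed-form compartment noise SD $\sigma\,\lVert \mathrm{row}_c(H_\text{eff} W)\rVert_2$
  (`operator_noise_gain()`), verified by Monte-Carlo in the tests.
* **Spectra** are the unnormalized `fft()` of the time signals, everywhere.

## Normalization of compartment spectra

The compartment columns of the SLAM operator are *means* of the voxel
columns (division by the voxel count $n_c$), and the SLIM columns are
volume-normalized integrals. A subtlety follows: the data couple to column
*sums*, so the raw pseudoinverse solution of the mean-normalized system is
the compartment **total**, $n_c$ times the per-voxel signal. The operator
therefore stores a `solution_scale` that maps the raw solution back to
**per-voxel-mean spectra**, which is what `slam_reconstruct()` /
`slim_reconstruct()` return under the default `per_voxel_mean` tag.
Per-voxel-mean output makes spectra comparable across compartments of
different size and leaves metabolite *ratios* invariant either way; a
`total` tag is available behind a flag. The SRF delta property is stated for
the mean-normalized operator: the compartment mean of $\beta_c$ over
compartment $d$ is $\delta_{cd}$ (machine precision for SLAM on the
acquisition grid; quadrature-limited for SLIM on an oversampled grid, where
an odd oversampling factor is used so no evaluation point straddles a voxel
boundary).

## The AW scheme and the readout budget

The repeat table of the scanner's AW scheme is vendor-specific and not
derivable from its total readout count alone. The package's default is a
separable Hamming window, $R(k) = \mathrm{round}(A\,w(k))$ with $A$ the
center averages, and the hard-threshold variant (dropping rounded-to-zero
encodes) as default so the scheme stays in the neighborhood of the same
TR-per-readout budget as the 384-readout truncated scheme (the default
8×16×8/4-average Hamming scheme keeps 369 encodes, 568 readouts; `hann` is
sharper if a tighter budget is wanted). Any measured scanner repeat table
can be loaded losslessly from CSV (`read_scheme_csv()`), which is the
recommended route for emulating a specific sequence. For FT-MRS the repeat
counts are *kept* as k-space apodization (no division by $R_m$): this
matches the rationale of acquisition weighting, and it is why SLAM with
singleton-voxel compartments reproduces FT-MRS exactly only for uniform
repeat tables — the pseudoinverse unweights $R_m$, apodization does not.
The reduction-property test uses the uniform full scheme accordingly.

## SLIM's integrals and the voxelized phantom

The SLIM integrals are evaluated in closed form: per voxel and axis,
$w\,\mathrm{sinc}(k w)\,e^{-2\pi i k \tilde x_c}$. For a *continuous*
object this is exact; the digital phantom, however, is a grid of point
sources (the forward model sums voxel centers), and the per-axis
$\mathrm{sinc}(k w)$ factor is precisely the mismatch between the
continuous basis and midpoint quadrature. Consequently the SLIM recovery
error on a noiseless, field-homogeneous phantom is *not* at machine
precision: the acceptance script computes it at about 5% when the phantom
grid equals the 8×16×8 acquisition matrix, falling as $O(w^2)$ under grid
refinement (about 1.2% at 16×32×16, a few tenths of a percent at
32×64×32). This is a property of the phantom's discretization, not of the
operator: the same tests show $HG = I$ to $10^{-8}$ and the SLIM delta
property to the quadrature tolerance. Evaluating the integrals by summation
over the phantom grid instead would collapse SLIM onto SLAM and erase the
distinction between the algorithms, so the closed form was kept.

## The fSLAM cost

The cited description of fractional-coordinate optimization is verbal
(inter- vs intracompartmental leakage); the cost implemented here is this
package's own formulation:

$$ \mathcal{C} = w_1 \sum_{x \notin \text{target}} w(x)\,|\beta_t(x)|^2
   \;+\; w_2\, \mathrm{Var}_{x \in \text{target}}\,\beta_t(x), $$

with $w(x)$ an optional receive-sensitivity weight, $\beta_t$ recomputed by
the SRF module at each candidate, default $w_1 = w_2 = 1$, and the heart as
the target. The twelve free parameters are the per-axis coordinate vectors
of the separable 4×4×4 scheme; the optimizer is bounded L-BFGS-B within ±1
cycle/FOV of the integer starting positions (collisions of coordinates are
fenced with a large penalty, and the best-so-far scheme is returned if the
optimizer aborts). Total readouts are conserved by construction. No
conjugate-symmetry constraint is imposed on the fractional coordinates;
nothing in the formulation requires it, and the bounded box keeps the
coordinates near their integer starts anyway.

## Coil combination and SNR

Multi-channel data are combined by noise-whitened SVD: whiten by the
inverse matrix square root of the channel noise covariance (estimated from
the repeat-normalized FID tails unless supplied), take the dominant
left-singular-vector projection of the stacked whitened FIDs, and phase the
result so the first point keeps the dominant channel's phase. This is the
matched filter in the equal-signal limit (the tests verify the $\sqrt 2$
two-channel SNR gain by Monte-Carlo). Combined data live in whitened units,
so downstream amplitudes are arbitrary and only ratios and SNR are
meaningful.

No SNR definition is standard across sites; the package fixes **fitted PCr
amplitude / time-domain noise SD**, with the noise SD estimated from the
final quarter (configurable) of the residual FID after fit subtraction. The
tests calibrate this estimator to within a few percent.

## Spectral fitting

The fitter is a constrained time-domain least squares over sums of complex
Lorentzians (real and imaginary parts stacked), with analytic Jacobian,
optional frequency multi-start, per-line frequency/linewidth bounds, a
shared zeroth-order phase and a fixed first-order phase delay. This is a
deliberate reduction of full prior-knowledge multiplet fitting: ATP
moieties are single Lorentzians, J-coupling and measured prior amplitudes
are out of scope. CRLBs are
$\sqrt{\mathrm{diag}\,(J^\top J/\sigma^2)^{-1}}$ at the fitted point with
$J$ the stacked real/imaginary Jacobian; the acceptance suite verifies
Monte-Carlo attainment at SNR 15 and the closed-form
$\sigma/\sqrt N$ amplitude bound for an undamped line. Exponential
apodization before fitting is available but defaults to 0 Hz so the
noiseless oracles stay exact.

## Corrections

PCr/ATP is blood- and saturation-corrected. The blood correction subtracts
`blood_atp_per_dpg` times the mean fitted 2,3-DPG doublet amplitude from
γ-ATP (2,3-DPG lives only in blood, so its intensity indexes the blood-pool
ATP contribution); the shipped 0.30 is a configurable placeholder, not a
literature constant — set it from your own calibration. Saturation uses the
steady-state factor $E = (1-e^{-TR/T_1})\sin\alpha/(1-\cos\alpha\,e^{-TR/T_1})$
per metabolite (cross-checked in the tests against an iterated Bloch steady
state). A blood correction that wipes out γ-ATP flags the spectrum for
exclusion — logged, never silent — and the paired test–retest statistics
drop that subject's pair, mirroring in-vivo practice.

## The phantom and what passing tests do (and do not) show

`make_cardiac_phantom()` builds an 8×16×8 grid over a 240×240×200 mm FOV
(30×15×25 mm voxels): a spheroidal heart (default semi-axes 45×40×45 mm), a
25 mm curved chest-wall slab at the anterior edge, background "other"
tissue, and an outside-body marker. Seven ³¹P Lorentzians are placed at 7 T
frequencies (γ/α/β-ATP at −298/−905/−1956 Hz from PCr, the 2,3-DPG doublet
at +630/+750 Hz, PDE at +350 Hz) with tissue-plausible linewidths. The
generator's amplitudes are "as acquired": unsaturated tissue amplitudes
multiplied by the steady-state saturation factors of the default correction
configuration (TR 1 s, 30° effective flip, T1 of 1.8–4 s), with the heart's
γ-ATP carrying a blood contribution proportional to the 2,3-DPG amplitude —
so the blood- and saturation-corrected myocardial PCr/γ-ATP equals the
configured ground truth (2.0) exactly, and the full correction chain is
exercised end-to-end. B0 offset and phase maps are low-order 3D polynomials
(default peaks 30 Hz and 0.3 rad) — smooth, as a shimmed heart is. The
optional shaped-pulse excitation profile (2 kHz band centered +266 Hz) is a
multiplicative amplitude weighting, flat by default. The last two slices of
the heart can be cleared (default on) so the heart SRF does not alias into
the first slice on the 8-voxel slice axis.

The default per-average noise SD of the study (1.0) is calibrated so the
single-voxel AW FT-MRS PCr SNR of the default phantom lands in the low
teens, the reference operating point for 7 T cardiac single-voxel readouts
with a two-loop surface coil; the two 15 cm loops of
`default_cardiac_coil()` sit 160 mm anterior of iso-center, fields by
segment-wise Biot–Savart (64 segments; within 0.1% of the circular-loop
closed forms), zeroed within 15 mm of the wires where the quasi-static
field model is invalid.

What the phantom does *not* emulate: cardiac and respiratory motion (the
dominant in-vivo confounder of compartment methods), realistic torso
electromagnetics, Bloch-level pulse behavior, multiplet structure, baseline
signals, or inter-scan physiological change — the two "scans" of a synthetic
subject differ only in noise. Passing tests therefore establish the
*algorithmic* claims (exactness, noise propagation, CRLB attainment, SNR
ordering of techniques) but say nothing about motion robustness, and the
synthetic CoR is far below in-vivo values because biological test–retest
variation is absent by construction.

## The synthetic test–retest study

`run_study()` simulates S subjects (default 8; heart semi-axes uniform in
38–50 mm, center jitter ±8 mm, B0 peak 20–40 Hz — all drawn from the master
seed), two noise realizations each, all six technique combinations (one AW
acquisition feeding FT-MRS/SLAM/SLIM; truncated and fSLAM-optimized 4×4×4
acquisitions with six averages; the fSLAM scheme optimized per subject on
its own mask, as scanner-side practice requires). Readouts are 256 points
at 6 kHz bandwidth — long enough to resolve the 25–50 Hz lines, short
enough that the full study fits in minutes on one CPU. Outputs are the
per-scan results table (with explicit exclusion flags), the per-technique
summary in the layout of the standard results table (mean ± SD of ratio,
SNR, linewidth, CRLB; CoR; CoV), and Wilcoxon signed-rank comparisons
against AW FT-MRS via `compare_techniques()` (delegated to
`stats::wilcox.test`, reported but not part of the acceptance surface).

## Numerical choices and degenerate inputs

* Pseudoinverses via SVD with rank tolerance
  $\max(M',C)\,\varepsilon\,\sigma_{\max}$; the condition number is always
  stored on the operator and a warning is attached when rank-deficient or
  above $10^8$.
* Empty compartments error immediately, naming the compartment; a heart
  spheroid leaving the FOV errors naming the axis; fractional k in FT-MRS
  errors (the DFT is undefined there).
* Degenerate geometry (zero heart semi-axes) is allowed and yields an empty
  compartment only when the mask requests it.
* Scheme CSV round-trips are exact to 12 significant digits; fractional
  fSLAM coordinates survive serialization.
* Tests and the acceptance script use 8×16×8 grids with 32–256 time points,
  refinements to 16×32×16 (and 2D 128² for the width-limit check), 500-
  to 1000-draw Monte-Carlo loops and an eight-subject study — sizes chosen
  so each property is measured well inside its tolerance while the whole
  suite runs in minutes.

## Known limitations

* The homogeneity assumption is violated by the receive-coil profile even
  in the noiseless study; PCr/ATP is ratio-invariant to this, but absolute
  compartment amplitudes are coil-weighted tissue averages.
* SLIM inherits the voxel-discretization mismatch discussed above whenever
  its continuous basis is compared against gridded data.
* B0-map-aware reconstruction (BSLIM-style) and the alternative SLAM solver
  variant are out of scope, as are motion, gating and DICOM/vendor raw
  formats; k-space containers are R-native (RDS) with CSV scheme tables,
  and volumes are NIfTI.
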
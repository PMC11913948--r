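---
title: "Water-selective T1 mapping with a continuous Look-Locker spiral model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-selective T1 mapping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wt1map)
```

This vignette explains the signal model behind `wt1map`, the numerical
choices made at each pipeline stage, what the synthetic phantom does and
does not emulate, and the limitations a user should keep in mind when
carrying conclusions from simulation to real data.

## The acquisition model

The sequence is a continuous inversion-recovery Look-Locker (CIR-LL)
spoiled gradient echo: an adiabatic slice-selective inversion, then
`n_excitations = 100` excitations of `flip_deg = 5`° every `tr_ms = 15` ms.
Each excitation reads a single spiral arm (readout 9.2 ms), rotated by
360°/N_s per TR, at echo times alternating between `te1_ms = 2.3` and
`te2_ms = 3.3` ms. One slice therefore takes 1.5 s, eight slices fill a
12 s breath-hold, and three stacks with a two-slice (11 mm) overlap cover a
whole organ in 24 acquired / 20 unique slices. These defaults are stored in
`seq_config()` and every one of them is overridable; `sequence_timing()`
derives the protocol arithmetic from them rather than hard-coding it.

Under repeated small-flip excitation the longitudinal magnetization relaxes
toward a reduced steady state with the *apparent* time constant

$$\frac{1}{T_1^*} = \frac{1}{T_1} - \frac{\ln \cos\alpha}{TR},$$

which is what makes a Look-Locker train T1-sensitive at high sampling
efficiency. The matching step absorbs the T1* → T1 correction implicitly,
because the dictionary is simulated with the same sequence model.

## EPG simulation and its two spoiling regimes

`epg_simulate_train()` propagates the standard configuration states
(F⁺ₖ, F⁻ₖ, Zₖ) through RF mixing, relaxation, and one gradient-dephasing
increment per TR. Two regimes are exposed:

* `ideal` — all transverse magnetization is crushed after each echo. This
  is algebraically identical to the closed-form Look-Locker recursion on
  Mz, and the test suite checks that identity to 10⁻⁹ against an
  independently written recursion.
* `gradient_spoiled` (default) — full state evolution with one k-shift per
  TR and no RF spoiling. The test suite validates this against a
  brute-force isochromat (Bloch) simulation with uniform intra-voxel
  dephasing; the two agree to numerical precision.

A point worth stating explicitly: at TR 15 ms and T2 50 ms the transverse
survival factor per TR is exp(−15/50) ≈ 0.74, so coherence feedback is
*not* negligible even at 5°. The gradient-spoiled train deviates from the
ideally spoiled recursion by up to ≈ 4.4% of the peak signal. Because the
dictionary and all forward simulations use the same regime, this deviation
cancels in matching; it matters only if one mixes regimes between
simulation and dictionary.

Truncating the tracked dephasing order is safe because a state of order k
must survive 2k TRs of T2 decay to return to the echo line; orders beyond
`-log(tol) * T2 / (2 TR)` cannot contribute above `tol` and are dropped.

## Slice profile

Small-flip excitation profiles follow the Fourier transform of the RF
envelope. `slice_profile()` discretizes the profile of a Hamming-windowed
sinc (time–bandwidth 4) into 21 sub-slices spanning twice the nominal
thickness; each sub-slice runs the EPG train at its local flip angle and
the slab signal is the complex sum. The adiabatic inversion is assumed to
invert a slab wider than the excitation slice, so its sub-slice scale
defaults to 1. Twenty-one sub-slices reproduce a 201-sub-slice reference to
better than 5% peak-relative error; the profile is pluggable because the
vendor RF pulse shape is not public.

## Dictionary and TE-pair collapse

`build_dictionary()` simulates T1 = 100…3000 ms in 5 ms steps at T2 = 50 ms
and nominal transmit field (the small-flip train encodes neither T2 nor B1
to first order), collapses the interleaved TE pairs, and normalizes each
atom — 581 complex vectors of length 50. The build is deterministic and
hash-stamped with its configuration.

The collapse deserves scrutiny. The default (`collapse = "te1"`) keeps the
TE1-indexed sample of each pair, treating the TE2 sample as redundant. But
the two echoes of a pair come from *consecutive excitations*, with one TR
of recovery between them, and the two-point separation downstream returns
for a pure-water pixel the affine combination

$$\hat W_k = (1+\lambda)\,s_{2k-1} - \lambda\, s_{2k},
\qquad \lambda = \frac{c_F(TE_1)}{c_F(TE_2) - c_F(TE_1)},$$

not the TE1 sample. Matching that series against TE1-collapsed atoms biases
wT1 low by one to four grid steps (10–30 ms over wT1 300–2000 ms, largest
near the inversion null where consecutive samples differ most). We keep
"te1" as the default because it is the conventional construction, and
provide `collapse = "matched"`, which builds atoms with exactly the
separation weights: fat-free recovery then becomes exact to grid rounding.
With fat present a smaller residual (≈ 15 ms at 40% fat fraction) remains
in either variant, because the fat magnetization also evolves between the
two echoes of a pair and its cancellation is imperfect. This is an
intrinsic property of two-point separation applied to sequentially excited
echo pairs, not an implementation artifact, and it is the reason the
noiseless end-to-end recovery is specified in the tests with an explicit
≈ 30 ms envelope rather than at grid precision.

## Water–fat separation

`separate_series()` demodulates each TR pair by the known per-pixel B0
phase (convention: positive off-resonance accrues positive phase,
`exp(+i 2π f TE)`, used consistently by the k-space forward model) and
inverts the 2×2 system `s_k = W + c_F(TE_k) F` exactly. T2* decay between
the two close echoes is neglected, as is standard for a 1 ms echo spacing.
If the two fat phasors coincide (a degenerate fat model), pixels are
flagged and returned as all-water rather than silently inverted. The fat
models shipped — a 7-peak in vivo liver-type spectrum and a 10-peak
peanut-oil spectrum — are *nominal* tables derived from standard
triglyceride proton bookkeeping (chain length / double-bond counts typical
of each material); both are fully overridable, and any quantitative claim
that depends on the exact peak table should use a measured spectrum.

Two PDFF estimators are provided. `pdff_map()` forms |F|/(|W|+|F|) at the
first TR pair, where both species still carry their full inverted
magnetization; it is simple but inherits the pair-mixing leakage (up to
≈ 8% absolute at short T1). `pdff_fit()` instead solves the two-amplitude
least-squares fit of the *entire* composite train at the matched wT1 and is
exact on noiseless model data; it is the estimator to use for quantitative
fat fractions. Later-train magnitude ratios are deliberately not offered:
they are T1-weighted and can misreport a 20% vial as ≈ 78%.

## Spiral trajectory, reconstruction, deblurring

`make_spiral()` builds a uniform-density Archimedean arm that reaches the
Nyquist radius `matrix/(2 FOV)` at the end of the readout, with the turn
count chosen so the full rotated arm set meets the radial Nyquist spacing
1/FOV, and along-arm sampling at 1.2× the Nyquist arc density. Hardware
slew and amplitude limits are intentionally not modeled: this trajectory
parameterizes a simulation, not a waveform export.

The forward model (`forward_sample()`) is an exact non-uniform DFT with
per-sample off-resonance phase `exp(i 2π b0(x) t)` at the true sample time
stamps; there is no NUFFT approximation anywhere, which keeps desk-scale
oracles exact. Reconstruction (`grid_recon()`) offers:

* `adjoint` — density-compensated adjoint with analytic annular-area
  weights (|k|-proportional; the k = 0 sample's disc weight is shared
  across arms since every arm starts there). This mirrors scanner
  gridding and is the fast default. At desk scale, however, the spiral has
  only ~4 turns, and the Riemann-sum weights leave a low-frequency error of
  ≈ 0.5% of the PSF peak — negligible for contrast, but large *relative*
  error on DC-dominated test images.
* `lsq` — conjugate-gradient least-squares inversion of the same operator
  (Tikhonov-stabilized, still linear in the data), which is quantitatively
  exact on fully sampled noiseless data and is what the fidelity tests use.

`mfi_deblur()` implements frequency-segmented conjugate-phase correction:
demodulate at bins spanning the B0 range (bin count from the half-cycle
rule `range · readout / 0.5` cycles, minimum 5), reconstruct per bin, and
interpolate per pixel between the two bracketing bins. It is exact for
constant fields (equivalent to global demodulation) and strictly improves
RMSE on piecewise-constant two-compartment fields in the tests.

In the single-shot regime each of the 100 images is reconstructed from one
arm — an undersampling factor of N_s. The pipeline relies on matching to
tolerate the resulting aliasing, so k-space-mode phantom tests assert
ordering and plausibility of the recovered map, not pixel accuracy.

## The digital phantom and what passing tests mean

`phantom_spec()` defaults to a 12-vial layout in three PDFF rows (0/5/10%)
by four wT1 columns (400–1300 ms) on a 64×64, 128 mm field of view —
the geometry of commercial fat/T1 calibration phantoms; vials are
non-overlapping by construction and every map (wT1, PDFF, B0, masks) is
available as ground truth. `simulate_composite_series()` builds the
composite train per pixel from the same EPG + fat-phasor signal model the
dictionary uses, optionally through the k-space chain, and adds seeded
complex Gaussian noise last (SNR is defined against the settled water
magnitude). Wider ranges used in the test suite (wT1 300–2000 ms,
PDFF 0–40%, B0 ±40 Hz) exercise the claimed validity envelope.

Simulated fat relaxation defaults to T1 = 380 ms, T2 = 50 ms — typical
adipose values at 3 T — and fat experiences the same slice profile as
water. What the phantom does *not* emulate: respiratory motion and
inter-stack displacement, coil arrays and their phase maps, T2* decay
along the readout, B0 map misregistration, partial volume at vial edges
beyond raster resolution, and any anatomy. Passing tests therefore
demonstrate internal consistency of the method under its own signal model,
not robustness to those confounds.

## The composite-T1 bias surface

`simulate_bias_grid()` quantifies why separation matters: composite
(water + fat) trains for wT1 ∈ [600, 1700] ms × PDFF ∈ [5, 40] % are
matched *directly* to the water dictionary, separately for the TE1-only
and TE2-only 50-point series. On the default models the TE1 branch always
underestimates (down to ≈ −41% at 40% fat) because the near-in-phase fat,
with its short T1, accelerates the apparent recovery; the TE2 branch,
near opposed phase, pushes the null later and overestimates by up to
≈ +108% before the 3000 ms dictionary ceiling clips it. Two secondary
effects are worth knowing: even at PDFF 0 the TE2-only branch reads a few
percent low (its train starts one TR later than the TE1-collapsed atoms),
and at 5% fat the TE2 branch can be slightly negative for short wT1 —
the sign structure is guaranteed only at the extremes. The
100·(T1comp − wT1)/wT1 grid is a tidy data frame; `bias_report()` extracts
the extrema and `plot_bias_surface()` renders the two branches.

Grid spacing for this surface (100 ms in wT1, 5% in PDFF) was chosen once
as sufficient to resolve the smooth surface; the extremes sit on the PDFF
boundary, where monotonicity makes finer PDFF sampling unnecessary.

## Numerical and degenerate-input policy

Zero-norm pixels are masked (NA wT1, quality 0) rather than matched;
matching ties resolve to the lower T1; background masking uses 5% of the
95th-percentile mean magnitude, disabled by setting the threshold to 0.
Near-singular separation systems are flagged per pixel. All randomness is
seeded through the phantom spec or function arguments; `sigma = 0` paths
are bit-deterministic and dictionary builds are hash-reproducible. B0 maps
of mismatched shape are bilinearly resampled. NIfTI round trips store
complex series as paired real/imaginary volumes at float32, with slice
spacing encoded as thickness + gap (6 mm center-to-center).

## Problem sizes

The shipped tests and the acceptance script run, by design, at desk scale:
48–64-pixel matrices, 12-vial phantoms, full 581-atom dictionaries, 28-arm
full trajectories at matrix 110 for trajectory geometry checks, and
single-arm (undersampled) k-space pipelines at matrix 24. These sizes were
chosen as the smallest that leave every effect of interest (slice-profile
bias, pair-mixing bias, aliasing, deblurring gains) clearly measurable.

## Known limitations

* The pair-mixing wT1 bias described above is inherent to per-pair
  two-point separation on this sequence; removing it entirely would
  require joint fitting of the full train (as `pdff_fit()` does for
  amplitudes) or a dictionary over both species.
* Matching quantization is half the grid step (2.5 ms at the default 5 ms
  grid).
* The adjoint gridding mode should not be used for quantitative intensity
  comparisons at desk scale; use `method = "lsq"`.
* Fat spectral tables are nominal; absolute bias-surface endpoints shift
  by several percentage points across plausible fat models and fat
  relaxation values.
* Multi-coil combination, motion, and T2* are out of scope.
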
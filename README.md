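# wt1map

Water-selective T1 (wT1) mapping of the whole pancreas — or any abdominal
organ — at 3 T is hard because (i) the organ spans many slices, (ii)
breath-holds must stay short, and (iii) tissue fat biases conventional T1
estimates. `wt1map` implements, end to end and fully in simulation, a
quantification pipeline built around a **continuous inversion-recovery
Look-Locker (CIR-LL) spiral acquisition**: one adiabatic inversion followed
by 100 small-flip (5°) excitations every TR = 15 ms, each reading one
rotating single-shot spiral arm at interleaved echo times
TE₁/TE₂ = 2.3/3.3 ms. One slice takes 1.5 s; eight slices fit a 12 s
breath-hold; three overlapping stacks (24 slices, 2×2×5 mm³, 1 mm gap,
11 mm overlap) cover the whole organ.

The package is aimed at quantitative-MRI researchers who want to study,
stress or extend each stage of such a pipeline on a desk, without scanner
data: every stage has a matching digital-phantom forward model.

## Method

Per pixel the composite signal at excitation *n* is

```
s(n) = W · s_w(n) + c_F(TE_n) · F · s_f(n),       c_F(TE) = Σ_p a_p e^{i 2π f_p TE}
```

where `s_w`, `s_f` are the inversion-prepared spoiled-GRE trains of water
and fat (simulated with the Extended Phase Graph formalism including the
excitation slice profile), `W`/`F` the proton densities, and `c_F` the
multi-peak fat phasor. The pipeline stages are:

1. **Spiral reconstruction + B0 deblurring** — uniform-density Archimedean
   trajectory, exact non-uniform DFT forward model with off-resonance phase
   accrual, density-compensated gridding (plus a CG least-squares mode),
   and frequency-segmented conjugate-phase deblurring from a known B0 map.
2. **Two-point water–fat separation** — per TR pair, demodulate by the B0
   map and solve `s_k = W + c_F(TE_k) F` for the two echoes.
3. **Dictionary matching** — the water series is matched per pixel against
   581 unit-norm complex atoms (T1 = 100…3000 ms in 5 ms steps, T2 = 50 ms,
   EPG with slice-profile modeling, TE pairs collapsed to length 50) by the
   magnitude of the normalized inner product; the arg-max T1 is the wT1.
4. **Assembly and analysis** — interleaved slice ordering, three-stack
   overlap resolution, circular-ROI statistics, and method-comparison
   regression.

The synthetic module generates a 12-vial fat/T1 calibration phantom
(PDFF rows 0/5/10%, columns of increasing wT1) and forward-simulates the
full composite series in image space or through the k-space chain, with
seeded complex Gaussian noise.

## Worked example

```r
library(wt1map)

cfg  <- seq_config()                 # the published protocol is the default
dict <- build_dictionary(cfg)        # 581 atoms of length 50, ~8 s
res  <- wt1_pipeline(phantom_spec(noise_sigma = 0.014, seed = 42),
                     dictionary = dict)
res$roi[, c("label", "mean", "sd", "wt1_true_ms")]
compare_methods(res$roi$wt1_true_ms, res$roi$mean)
```

prints (abridged)

```
     label   mean    sd wt1_true_ms
1   vial_1  385.5 2.248         400
2   vial_2  683.9 2.898         700
3   vial_3  983.9 3.521        1000
4   vial_4 1284.7 4.234        1300
...
<wt1_regression> y = 0.999 x -14.02, R2 = 1.000 (n = 12)
```

Vial means track the true wT1 with an essentially unit slope and a small
negative offset: the two-point separation combines two *consecutive*
excitations of the train as if they were one magnetization state, which
biases wT1 low by roughly one to four dictionary steps (the package
vignette quantifies this and offers a `collapse = "matched"` dictionary
that removes it for fat-free tissue). The per-vial spread at roughly
SNR 30 is a few ms.

The fat bias that motivates the separation step can be mapped directly:

```r
surface <- simulate_bias_grid(dictionary = dict)   # wT1 600..1700, PDFF 5..40%
bias_report(surface)          # min -41.5% (TE1 branch), max +107.9% (TE2 branch)
plot_bias_surface(surface)
```

Matching the composite (unseparated) signal underestimates T1 at TE₁ and
overestimates it at TE₂, by tens of percent at 40% fat fraction.

## Command line

A thin wrapper around the package functions lives at `inst/cli/wt1.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/wt1.R", package = "wt1map"))')" \
    pipeline --config config.yaml --out out/ --mode image_space --noise 0
```

Subcommands: `dict`, `phantom`, `simulate`, `recon`, `separate`, `match`,
`pipeline`, `analyze`. All artifacts are NIfTI / YAML / CSV / JSON with a
JSON sidecar carrying the configuration hash and seed.

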
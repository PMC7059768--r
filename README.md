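# memdeeg

Multivariate empirical mode decomposition (MEMD) preprocessing for EEG
source reconstruction with low-density electrode montages.

EEG source imaging estimates the amplitudes of thousands of cortical
sources from a few tens of electrodes through the linear forward model
`y(t) = M x(t) + e(t)`, where `M` is the lead-field matrix. The problem
is badly ill-posed and degrades quickly as electrodes are removed. This
package implements a pipeline that keeps reconstruction accuracy at low
channel counts (32, 16, 8 electrodes from a 10-10 layout):

1. **MEMD** — joint sifting of all channels against a low-discrepancy
   direction set on the unit sphere, producing the same number of
   *scale-aligned* intrinsic mode functions (IMFs) in every channel:
   `s(t) = sum_m c_m(t) + r(t)`.
2. **Entropy selection** — each IMF is scored with
   `e_i = -sum_k ||c_i(t_k)||^2 log ||c_i(t_k)||^2` and the
   highest-entropy (signal-bearing) modes are kept.
3. **MSP inversion** — a multiple-sparse-priors Bayesian solver:
   sensor covariance `Sigma = lambda_0 I + sum_j lambda_j M C_j M'`
   over smooth cortical patch components, weights fitted by ReML ascent
   on the variational free energy, conditional-mean source estimate.
   Each selected IMF is inverted separately and the maps are summed.
   A Tikhonov minimum-norm baseline is included.
4. **Wasserstein evaluation** — spatial error is the exact
   1-Wasserstein (earth mover's) distance in mm between time-ROI source
   power distributions of the estimate and the ground truth, solved as
   a transportation LP.

A synthetic-data module generates all test inputs: a deterministic
three-shell spherical head model with an idealized 10-10 montage, and
Gaussian-windowed sinusoid sources
(`x_i(t) = exp(-((t-c_i)/sigma)^2/2) sin(2 pi f_i t)`, `sigma = 0.12 s`)
in one/three/five-source scenarios at brain-rhythm frequencies, with
white noise added at an exact broadband SNR.

## Worked example

Simulate the three-source scenario (20/12/4 Hz at t = 1/3/5 s, SNR
10 dB), reduce to 8 electrodes, decompose, select modes, and compare
raw-MSP against MEMD-MSP over 5 noise seeds:

```r
library(memdeeg)

head     <- synth_headmodel(500, montage_labels("full"), seed = 7)
activity <- make_scenario("three", head)
eeg      <- add_noise(forward_project(head, activity), snr_db = 10, seed = 1)
low      <- reduce_montage(eeg, head, montage_labels(8))

dec <- memd(low$signal)
dec
#> <mimf_set> 12 p-variate IMF(s), p = 8, T = 1201, 200 Hz

rank_and_select(dec, k = 4)
#> <imf_selection> kept IMFs: 1, 3, 4, 6
#>  entropies: 0.9222, 0.4333, 1.159, 1.492, 0.3275, 1.11, 0.8525, ...
```

IMFs 3, 4 and 6 carry the 20, 12 and 4 Hz sources (IMF 1 is broadband
noise); the selection keeps all three rhythms. The paired study:

```r
tbl <- run_study(montages = 8, methods = c("raw", "memd"),
                 seeds = 1:5, scenario = "three", snr_db = 10)
cmp <- study_comparison(tbl, 8)
#> mean Wm  raw-MSP: 54.0 mm   MEMD-MSP: 42.6 mm   reduction: 21.1%
cmp$test
#> <paired_comparison> t(4) = 12.431, p = 0.000241 *
```

The Wasserstein error of the 8-electrode reconstruction drops by about
a fifth when MEMD preprocessing is added, and the paired t-test over
shared noise seeds is significant. Lower Wm = mass of the estimated
source power is closer, in mm, to the true source locations.

A command-line front end with `simulate`, `decompose`, `select`,
`invert`, `evaluate` and `pipeline` subcommands is installed at
`inst/cli/memdeeg.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/memdeeg.R", package="memdeeg"))') \
    pipeline --scenario three --montage 8 --snr 10 --seeds 1:5 \
    --decomposition memd --out-dir results/
```

## Package layout

| Area | Functions |
| --- | --- |
| EMD core | `emd`, `find_extrema`, `local_mean`, `instantaneous_frequency`, `hilbert_spectrum` |
| MEMD | `memd`, `hammersley_directions`, `project_signal`, `multivariate_local_mean` |
| Selection | `imf_entropy`, `imf_entropies`, `rank_and_select`, `rebuild` |
| Simulation | `synth_headmodel`, `three_shell_leadfield`, `make_scenario`, `windowed_sinusoid`, `forward_project`, `add_noise`, `reduce_montage`, `montage_labels` |
| Inversion | `build_patches`, `invert_msp`, `invert_mn` |
| Evaluation | `roi_power`, `wasserstein`, `transport_plan`, `percent_reduction`, `compare_conditions` |
| Orchestration | `pipeline_config`, `run_pipeline`, `run_study`, `study_comparison` |
| I/O | `read_eeg`/`write_eeg`, `read_edf`/`write_edf`, `read_imfs`/`write_imfs`, `read_headmodel`/`write_headmodel`, `load_eeg` |

The methods vignette (`vignettes/memd-msp-pipeline.Rmd`) documents the
model assumptions, the tunable parameters and their defaults, the
design decisions, and what the synthetic studies do and do not show
about real recordings.
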
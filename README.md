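# retinovel

Simulation and analysis tools for studying how the classical center-surround
receptive field (RF) of retinal bipolar cells enhances responses to newly
appearing objects. Continuously moving stimuli enter a cell's antagonistic
surround before its center, so surround inhibition is already developed when
the center is engaged; an object that pops out from behind an occluder
engages center and surround together and is answered with a larger, faster
response. `retinovel` implements the computational machinery needed to study
this effect end to end:

- **Stimuli** — flashed and moving bars, occluding masks, apparent-motion
  sequences, and synthetic naturalistic movies (multi-scale 1/f-like
  textures, 8-bit statistics, an emerging "predator" object behind an
  occluder, and pure-flow controls).
- **Outer-retina circuit simulator** — a 1-D array of photoreceptors with
  biphasic kinetics, horizontal cells (HC) with distance-normalised divisive
  feedback, transient/sustained bipolar cells (BC) behind a sigmoidal
  synapse, and an optional feed-forward amacrine circuit.
- **Linear center-surround population** — Gaussian center/surround
  components (half-widths 50/200 µm) low-pass filtered at τ = 20/100 ms,
  combined as `RF_full = RF_center − Factor_Surround × RF_surround`.
- **Metrics** — transiency index, static-edge and emerging-object
  enhancement, direction-selectivity index, RF localisation from opposed
  motion trials, sigmoid/exponential kinetics fits.
- **Information readout** — plug-in entropy and mutual information (MI)
  between stimulus condition (novel object vs continuous scene motion) and
  integer-discretized peak responses; surround-strength sweeps and
  enhancement-versus-distance profiles.
- **Imaging pipeline** — preprocessing (2×2 binning, 20-Hz zero-phase
  low-pass, dF/F), >20 % dF/F pixel selection, farthest-point clustering
  into ROIs, coefficient-of-variation curation, and across-experiment
  hierarchical clustering with c-index model selection — plus a
  ground-truth-labelled synthetic iGluSnFR-style movie generator to exercise
  all of it.

## The models

**Circuit model.** Per 1-ms step and cell *i* (light `VS ≥ 0`, all states
zero at rest):

    drive_i = g · (E_HC · h̄_i + E_VS · VS_i) / (|h̄|_i + VS_i + 1)       (HC feedback, distance-normalised)
    Ph_A += (drive − Ph_A)/60 ;  Ph_B += (drive − Ph_B)/400 ;  Ph = Ph_A − 0.8·Ph_B
    HC∞_i = Σ_j d_ij Ph_j / Σ_j d_ij ;   HC_i += (E_Ph·HC∞/(HC∞+E_Ph) − HC_i)/300
    BC∞_i = Σ_j d_ij [σ(−Ph_j) − σ(0)],  σ(v) = 1/(1+exp(V_slope(V_½ − v)))
    BC_i += (BC∞ − BC_i)/50 ;   Vm_i = E_Ph (E_Ph·BC_i + E_AC·AC_i) / (|BC_i| + |AC_i| + E_Ph)

with `E_Ph = 10`, `E_HC = 2`, `E_VS = −10` mV, transient BCs at
`V_slope = 1.1 mV⁻¹, V_½ = 4 mV`, sustained at `0.1, 1`, and Gaussian
interaction kernels of FWHM 300 µm (HC), 50 µm (BC) and 300 µm (AC).

**Linear RF model.** Each unit's center and surround illumination is the
unit-mass Gaussian-weighted scene luminance; each component relaxes as
`RF_t = (illum − RF_{t−1})/τ + RF_{t−1}`; the full response is
`C − f·ρ·S` with surround factor `f` and integrated surround:center weight
`ρ = 2`, so the difference-of-Gaussians nulls extended scenes at `f = 0.5`.

## Worked example

Simulate the circuit's stimulus battery and measure emerging-motion
enhancement at a cell just beyond the occluder edge:

```r
library(retinovel)
params <- circuit_params()
battery <- opl_battery(params)          # flash/motion x full-field/masked
peaks <- opl_condition_peaks(battery, params,
                             trace = "bc_vm_transient")$peaks
probe <- 35                              # x = 340 um, < 50 um from the mask
round(peaks[probe, ], 3)
#>          flash_full        flash_masked        motion_right
#>               2.309               2.437               2.059
#>         motion_left motion_right_masked  motion_left_masked
#>               2.038               2.549               2.019
emerging_enhancement(peaks[probe, "motion_right_masked"],
                     peaks[probe, "motion_left_masked"])
#> [1] 0.2621595
```

The transient bipolar cell responds ~26 % more strongly to a bar emerging
from the mask than to the same bar moving into it, while its responses to
exiting and continuous motion are indistinguishable — the novel-object
signature. The horizontal-cell mechanism behind it:

```r
sim <- run_opl_simulation(battery$motion_right, params,
                          record = c("ph", "hc"))
hc_lead_time(sim)$max_lead_ms    # HC initiation precedes bar arrival
#> [1] 266
```

For the naturalistic-movie analyses, a (scaled-down) paired ensemble:

```r
ens <- novelty_ensemble(n_trials = 200, factors = c(0, 0.5), seed = 1)
novelty_mi(ens, 0.5)$mean        # center-surround units, bits/trial
novelty_mi(ens, 0)$mean          # center-only units
enhancement_vs_distance(ens, 0.5)$half_max_width_um
```

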
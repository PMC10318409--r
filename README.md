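# flimox

Analysis chain for **oxygen-controlled microfluidic single-cell
cultivation**. Gas-permeable PDMS chips let dissolved oxygen in micrometre-
scale growth chambers be steered between 0% and 100% while bacteria grow as
monolayers under time-lapse microscopy. `flimox` covers the three
computational stages such an experiment needs:

1. **Frequency-domain FLIM** — per-pixel fluorescence lifetimes from
   modulated image stacks. For a pixel series *I\_k* over *K* phase steps the
   first-harmonic phasor is
   *φ* = atan2(*b*, *a*), *m* = √(a² + b²)/c₀ with
   *a* = (2/K) Σ I_k cos(2πk/K), *b* = (2/K) Σ I_k sin(2πk/K);
   after correction against a reference slide of known lifetime
   (τ_ref = 3.75 ns), the lifetime follows from
   τ_φ = tan(φ)/ω or τ_m = √(1/m² − 1)/ω, ω = 2πf (f = 550 kHz).

2. **Stern–Volmer oxygen sensing** — the lifetime of the ruthenium dye RTDP
   is quenched by oxygen as
   **[O₂] = (1/K_q)(τ₀/τ − 1)**,
   calibrated at two points (τ₀ at 0% O₂ and τ at a known oxic level). From
   the resulting oxygen traces the package extracts per-step plateau levels
   (mean over the last hour of each step) and switching times t₈₅/t₉₀/t₉₅
   (time to traverse 85/90/95% of a step's change, located by linear
   interpolation with a sustained-crossing rule).

3. **Single-cell quantification** — given label masks and fluorescence
   frames: border filtering (cells with pixels closer than 0.5 µm to the
   image edge are artifacts), per-cell mean intensities *I*_cell, greedy
   overlap (IoU) tracking into a lineage forest, generation numbers
   (founders are generation 0; both daughters of a division gain one),
   population growth rates µ from log-linear fits of cell counts, intensity
   slopes ΔI_population/Δt and their fold-changes, and
   intensity-versus-generation tables.

A first-class **synthetic-data module** generates every input with known
ground truth — first-order chip oxygen responses, noise-controllable
modulated FLIM stacks through the forward Stern–Volmer model, and
agent-based monolayer colonies of rod-shaped cells whose GFP matures only in
the presence of oxygen — so the whole chain runs and is tested without any
external image data.

Intended users: microbiologists and microfluidics researchers quantifying
growth and gene expression under controlled oxygen, and method developers
who need a fully specified simulator of such experiments.

## Worked example

```r
library(flimox)

# two-point sensor calibration from the 30 degC lifetimes
calib <- fit_stern_volmer(526, 144, o2_ox_fraction = 1, temperature_c = 30)
calib
#> <stern_volmer_calibration> tau0 = 526 ns, tau_ox = 144 ns at 100% O2,
#>   T = 30 degC -> Kq = 2.6528

# chip step-response characterization on a synthetic 28 h step test
sched <- default_step_schedule()          # 0,2,4,6,8,10,15,21,100 % O2
trace <- simulate_o2_response(sched, o2_response_model(37))
head(as.data.frame(switching_times(trace, sched))[, 1:6], 4)
#>   step setpoint_percent plateau_fraction t85_min t90_min t95_min
#> 1    1                0             0.00   0.000   0.000   0.000
#> 2    2                2             0.02  66.157  78.946  98.662
#> 3    3                4             0.04  66.119  78.913  98.634
#> 4    4                6             0.06  66.119  78.912  98.634

# full anaerobic-to-aerobic switch experiment, five synthetic chambers
report <- run_pipeline(pipeline_config(preset = "anaerobic_switch", seed = 1))
report
#> <run_report> preset 'anaerobic_switch', seed 1, Kq = 2.6528
#>   mu = 0.529 +/- 0.008 1/h over 5 chamber(s)
#>   post-switch slope 20.0 vs aerobic 3.1 a.u./h -> 6-fold
```

Reading the numbers: the quenching constant K_q = 2.65 fixes the
lifetime-to-oxygen conversion at 30 °C. In the step test every setpoint
plateaus at its programmed level and the 90% switching time is ~79–85 min,
independent of the step amplitude — diffusion through the chip membrane sets
the timescale, not the concentration difference. In the switch experiment
the five chambers grow at µ ≈ 0.53 h⁻¹ with zero fluorescence while oxygen
is absent; after the 8 h switch the backlog of immature GFP matures and the
population fluorescence rises several-fold faster than under constant
aerobic conditions.

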
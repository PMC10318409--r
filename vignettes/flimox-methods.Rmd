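---
title: "Methods: oxygen-controlled microfluidic cultivation analysis with flimox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oxygen-controlled microfluidic cultivation analysis with flimox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`flimox` implements the computational side of oxygen-controlled microfluidic
single-cell cultivation: frequency-domain fluorescence lifetime imaging
(FLIM) of an oxygen-sensitive dye, Stern–Volmer conversion of lifetimes to
dissolved-oxygen concentrations, characterization of the chip's switching
dynamics, and mask-based quantification of growing monolayer
micro-colonies. This vignette describes the models, the tunable parameters,
the numerical conventions, and — because the package ships its own
synthetic-data generator — exactly what the generator does and does not
emulate, and hence what passing tests do and do not demonstrate about real
data.

## 1. Frequency-domain lifetime estimation

Under sinusoidally modulated excitation at frequency $f$
($\omega = 2\pi f$; default 550 kHz, a typical modulated-camera frequency),
a mono-exponential emitter with lifetime $\tau$ responds with phase shift
$\varphi = \arctan(\omega\tau)$ and demodulation
$m = 1/\sqrt{1 + (\omega\tau)^2}$. `compute_phasor()` estimates both per
pixel from $K$ equally spaced phase-step images (default $K = 8$,
configurable; $K \ge 3$ is required to separate DC, amplitude and phase)
using the discrete first-harmonic sums
$a = \tfrac{2}{K}\sum_k I_k \cos(2\pi k/K)$,
$b = \tfrac{2}{K}\sum_k I_k \sin(2\pi k/K)$,
$\varphi = \operatorname{atan2}(b, a)$, $m = \sqrt{a^2+b^2}/c_0$.
The sign convention makes a pure emission delay positive.

Assumptions: a single exponential decay dominates (true for the sensor dye),
the phase steps evenly cover one modulation period, and photobleaching
within one $K$-step acquisition is negligible. Multi-exponential unmixing is
out of scope.

**Instrument calibration.** Phase offsets and demodulation losses of the
light path are removed with a reference slide of known lifetime
$\tau_\mathrm{ref}$ (default use case 3.75 ns):
`calibrate_instrument()` stores
$\varphi_0 = \langle\varphi\rangle_\mathrm{ROI} - \arctan(\omega\tau_\mathrm{ref})$
and
$M = \langle m \rangle_\mathrm{ROI}\sqrt{1 + (\omega\tau_\mathrm{ref})^2}$,
and `correct_phasor()` applies $\varphi - \varphi_0$ and $m / M$. A
calibration is only valid at the frequency it was measured at; mixing
frequencies is an error.

**Numerical conventions.** Phases are wrapped to $(-\pi, \pi]$. A purely DC
pixel series has an undefined phase; the package reports phase 0 and
modulation 0 there (pixels whose harmonic magnitude is below $10^{-12}$ of
the DC level). Dark pixels ($c_0 = 0$) give `NaN`. In `lifetime_from_phase()`
a phase of exactly 0 maps to $\tau = 0$ while $\varphi < 0$ or
$\varphi \ge \pi/2$ (unphysical for a decay) map to `NaN`; in
`lifetime_from_modulation()` $m \ge 1$ (possible after gain correction under
noise) clips to $\tau = 0$ and $m \le 0$ maps to `NaN`. All flagged-pixel
counts are reported. The **phase lifetime is the default** readout — at
$\omega\tau_0 \approx 1.8$ (anoxic sensor at 550 kHz) it is the more robust
of the two — and the modulation lifetime is retained as an internal
consistency check: on mono-exponential input both must agree, which the test
suite enforces to $10^{-6}$ ns. Whether a vendor camera reports phase,
modulation, or a fusion lifetime is generally undocumented; providing both
sidesteps the question.

Because single lifetime images are noisy at the pixel level, each image is
reduced to an ROI mean (`mean_lifetime()`, arithmetic mean over finite
pixels, exclusion count attached) before conversion to a concentration. ROIs
are axis-aligned rectangles in 0-based, half-open pixel coordinates.

## 2. Stern–Volmer oxygen calibration and conversion

The luminescence lifetime of the ruthenium dye RTDP decreases with dissolved
oxygen by dynamic quenching:
$$[\mathrm{O_2}] = \frac{1}{K_q}\left(\frac{\tau_0}{\tau} - 1\right).$$
`fit_stern_volmer(tau0_ns, tau_ox_ns, o2_ox_fraction, temperature_c)`
implements the two-point calibration: the anoxic lifetime $\tau_0$ and one
oxic lifetime fix $K_q = (\tau_0/\tau_\mathrm{ox} - 1)/[\mathrm{O_2}]_\mathrm{ox}$.

**Unit convention.** Oxygen is a *fraction of the full calibration scale*
internally (1.0 = 100%), making $K_q$ dimensionless; per-cent appears only
at I/O boundaries. This convention is forced by consistency: a calibration
at 100% O$_2$ gives $K_q = \tau_0/\tau_{100\%} - 1$ only on the fractional
scale. Lifetimes are temperature dependent, so a calibration carries a
temperature label and conversion refuses traces labelled with a different
temperature; no cross-temperature correction is attempted (calibrate per
temperature instead).

Noisy conversions may fall slightly below 0 or above 1; they are
deliberately **not clipped** in traces (clipping would bias averages) and
should be clipped only in rendered reports.

## 3. Step-response characterization

A step test drives the gas supply through a programmed schedule
(`default_step_schedule()`: 0, 2, 4, 6, 8, 10, 15, 21, 100% O$_2$; 4 h
initial anoxic hold, 3 h per later step, 5 min sampling). Two summaries are
computed per step:

* **Plateau** (`plateau_values()`): mean of the measured trace over the
  final 60 min of the step (window configurable), the period where a
  first-order response with a ~37 min time constant has essentially
  equilibrated. Samples are attributed to steps by half-open
  `[start, end)` intervals; the trace's last sample belongs to the final
  step; windows longer than a step truncate with a warning.
* **Switching times** (`switching_times()`): with initial value $c_i$ (last
  sample before step onset) and final value $c_f$ (the plateau mean — a
  measured quantity, deliberately not the setpoint, so measured-vs-set
  comparisons remain meaningful), $t_X$ is the first time the trace crosses
  $c_i + X(c_f - c_i)$ toward $c_f$ and, by default, stays beyond it for the
  rest of the step (robust to noise spikes; pure first-crossing is a flag).
  Crossings are located by linear interpolation between samples. A step with
  $c_f = c_i$ is degenerate: all $t_X = 0$, flagged. "$X$% of the final
  concentration" is interpreted as $X$% of the *change* — this yields
  $t_X = 0$ for a null step and makes $t_{90}$ independent of step
  amplitude; for the common case of a first step from zero both
  interpretations coincide.

**A small systematic worth knowing.** For a first-order response with time
constant $T$ and 3 h steps, the 1 h plateau window underestimates the
asymptote by $\approx 1.9\%$ of the step change; referencing the thresholds
to this plateau shifts the apparent $t_{90}$ from $T\ln 10$ (85.2 min at
$T = 37$ min) down to $\approx 79$ min. The effect is identical across all
step amplitudes, so amplitude independence is untouched. With longer steps
(the test suite uses 6 h) the plateau converges to the asymptote and
$t_{90} \to T\ln 10$. Tests assert both regimes against the closed forms.

## 4. Single-cell and population quantification

Inputs are integer label masks (0 = background; labels are frame-local) plus
fluorescence frames; segmentation itself (e.g. by a pre-trained neural
model) is out of scope — this package consumes its output.

* `border_filter(frame, margin_um = 0.5)` removes any cell with a pixel
  center strictly closer than the margin to an image edge (segmentation
  artifacts concentrate there). Pixel centers sit at half-integer positions,
  so a zero margin removes nothing.
* `cell_intensities()` computes the mean fluorescence over each cell's
  pixels, plus centroid (0-based pixel coordinates) and area in µm²
  (default pixel size 0.065 µm, the 100x-objective class). **No background
  subtraction** is applied — the generator adds a known background so its
  effect is measurable rather than hidden.
* `track_cells(frames, min_iou = 0.2)` is a deliberately simple greedy
  intersection-over-union tracker: candidate links sorted by IoU descending
  (ties: target label, then source label ascending — fully deterministic),
  each target gets at most one parent, each source at most two children (two
  = division), unmatched targets become new roots. This stands in for more
  sophisticated published trackers; for short imaging intervals relative to
  the division time it recovers the generator's ground-truth lineage almost
  perfectly (the suite requires ≥ 95% edge recall), and the generator's own
  lineage can be used directly wherever tracking is not under study.
* `assign_generations()`: founders carry generation 0; both daughters of a
  recorded division gain one; a merely tracked cell keeps its generation.
* `growth_rate()` fits $\ln N$ against time (hours) by ordinary least
  squares; replicate chambers are fitted separately and summarized as
  mean ± SD. `intensity_slope()` is the OLS slope of the population-mean
  intensity (unweighted mean over cells — per-cell values are averaged, not
  pixels); `fold_change()` is the ratio of two slopes with a rounded fold.
* `intensity_vs_generation()` pairs each cell alive at a queried time with
  its generation and reports a Spearman rank correlation.

## 5. The synthetic-data generator

The generator produces every input of the chain with known ground truth.
What it emulates, and how:

**Chip oxygen response** (`simulate_o2_response()`): oxygen reaches the
fluid by diffusion through the chip body, lumped into a single first-order
relaxation $c(t) = s + (c_0 - s)e^{-t/T}$ per step, continuous across
boundaries. The default $T = 37$ min is chosen so $t_{90} = T\ln 10 \approx
85$ min lies in the 80–90 min band typical of millimetre-thick chips; $T$
can also be derived from a thickness via $T \approx d^2/D$
($D \approx 10^{-9}\,\mathrm{m^2 s^{-1}}$ for oxygen in PDMS). $T$ is a free
parameter, not a claim about membrane physics. At a step onset the sampled
value is the pre-switch concentration (the physical trace is continuous);
only in the $T \to 0$ limit does the trace become the setpoint staircase
away from the switch instants.

**FLIM stacks** (`simulate_flim_series()`): per frame the forward
Stern–Volmer model gives $\tau$, the mono-exponential closed form gives
phase and modulation, and each pixel's $K$-step series is synthesized with
optional additive Gaussian or Poisson noise. Noise-free, the analysis chain
inverts this exactly (the suite requires $10^{-6}$ over the full 0–100%
range), so any end-to-end discrepancy on real data localizes to effects the
model excludes: multi-exponential decays, stray light, detector
nonlinearity.

**Monolayer colonies** (`simulate_colony()`): rod-shaped cells (width 1 µm —
the chamber height, which enforces the monolayer; birth length 2 µm) grow
exponentially in length and divide into equal halves when they double.
Interdivision times are lognormal with CV `division_cv` (default 0.2, a
typical single-cell interdivision spread); their mean is calibrated by
numerically solving the Euler–Lotka equation $2\,E[e^{-\mu T_d}] = 1$ so the
*population* growth rate equals `target_mu_per_h`. Each cell's elongation
rate is $\ln 2 / T_d$, so fast-dividing cells genuinely grow and dilute
faster. Founder cells start at uniformly random cell-cycle phases to
desynchronize the colony. Overlaps are resolved by pairwise push-apart along
the closest-approach direction of the rod axes; the long chamber walls
(50 × 30 µm chamber, 1.5 pL) confine the colony, and cells drifting past
the open ends — which connect to the fluid supply channels — exit and are
removed (logged), which keeps 9 h simulations below the crowding stop
(packing fraction 0.9).

**GFP kinetics** (`gfp_kinetics()`): two pools per cell. Expression feeds
the immature (dark) pool; maturation converts it to the fluorescent pool at
`maturation_rate_per_h` (default 1.4 h⁻¹, i.e. a ~30 min maturation
half-time) **only while ambient oxygen is at or above `o2_min`**. The
threshold is an abstract value on the simulator's fraction scale (default
$10^{-6}$, effectively "any measurable oxygen"); no conversion from
literature ppm figures to the fraction scale is attempted, since that bound
only marks the regime "maturation needs oxygen". Updates use the exact
linear-kinetics solution per interval, so immature + mature over all cells
(including exited ones) equals cumulative expression to machine precision
when bleaching is off. At division both pools split in proportion to
daughter lengths (deterministic; the biology of partitioning noise is not
modeled). The per-cell expression rate ramps linearly from 0 over
`induction_ramp_h` (default 12 h): expression capacity builds up gradually
after induction. This is what makes the population-mean fluorescence rise
nearly linearly over a 9 h culture — with a constant rate, mean
concentration would reach the expression/dilution steady state within
$\sim 1/\mu$ hours and flatten, which is not what oxygen-reporter cultures
of this kind show. With oxygen absent the mature pool is exactly zero;
after a switch the accumulated immature backlog converts, producing a
fluorescence rise several-fold steeper than under constant aerobic
conditions, and lineages that divided more carry less per-cell fluorescence
(negative generation–intensity rank correlation) — both emergent properties
of the kinetics, not fitted behaviors.

**Rendering** (`render_frames()`): rods are rasterized as rounded rectangles
(pixels whose centers lie within half a width of the axis); the painted
fluorescence value is the cell's mature-GFP concentration (amount per µm²),
optionally blurred with a Gaussian PSF, plus constant background and
Gaussian noise. Conflicting pixels go to the nearer axis, so label masks
never overlap. Fluorescence units are self-consistent arbitrary units; no
attempt is made to match any camera's absolute scale.

**What the generator does *not* emulate** — and therefore what passing
tests do not show about real data: phase-contrast appearance and
segmentation difficulty (masks are perfect by construction), rod mechanics
beyond pairwise push-apart (no torque, no filament buckling), spatial oxygen
gradients inside a chamber (oxygen is uniform per frame), nutrient or
byproduct fields, photobleaching by default, and detector physics beyond
additive/Poisson pixel noise. Tracking accuracy measured here is an upper
bound for real data, where segmentation errors dominate.

**Determinism.** Identical parameters and seed give bit-identical datasets;
all generator randomness flows through one locally seeded RNG that does not
disturb the caller's RNG state. Experiment presets derive chamber sub-seeds
deterministically from the base seed.

## 6. Presets, pipeline and file formats

`make_experiment()` bundles the three study designs: `aerobic` (constant
21% O$_2$, 9 h, target µ = 0.55 h⁻¹), `anaerobic_switch` (0% for 8 h, then
21% through the chip response model, target µ = 0.52 h⁻¹) and `step_test`
(the default 28 h schedule), with five replicate chambers by default.
`run_pipeline()` + `pipeline_config()` orchestrate generation and analysis
with a validated configuration (unknown keys are rejected; the resolved
configuration is written beside the outputs; identical configurations
reproduce byte-identical CSV/JSON). For the switch preset the fold-change
compares the post-switch intensity slope against an aerobic reference run
with the same chamber seeds. A thin command-line wrapper lives at
`inst/cli/flimox.R`; the exported functions are the primary interface.

Stacks travel as multi-page TIFF plus a JSON sidecar (pixel size, frequency,
timestamps). Because the available TIFF writers store integer samples,
real-valued images are encoded as affine-scaled 31-bit integer codes with a
reserved non-finite sentinel and the value range in the sidecar: exact for
16-bit integer data, and lossless to ~5 × 10⁻¹⁰ of the value range (with
exact `NaN` positions) for float data. Times are seconds since experiment
start in files, hours in reports.

## 7. Problem sizes and tolerances in the shipped checks

The test suite and the acceptance script run entirely on synthetic data at
desk scale: colonies start from 2 seed cells and run 9 h at 5-min frames
(~300 cells at the end), growth-rate recovery uses 5 chambers per regime
(and 20 seeds for the distribution-level check, tolerance 0.02 h⁻¹ on the
mean), FLIM round trips use tiny 2 × 2 to 4 × 4 px stacks over a 21-point
oxygen grid at $10^{-6}$ tolerance, and step tests use the default schedule
plus a 6 h-step variant for the asymptotic $t_{90}$ check (tolerance: one
5-min sampling interval). Instrument-scale observations — absolute plateau
accuracy of a physical chip, cell counts of a specific experiment, absolute
$t_{90}$ values of a particular chip thickness — are hardware-dependent and
are represented by these ground-truth-recovery checks rather than by
numeric reproduction.

## 8. Known limitations

* The tracker is greedy and overlap-based; it will fail on large
  displacements or long imaging intervals. It is a documented stand-in, not
  a contribution.
* The mechanical model is 2-D and torque-free; mask geometry is realistic
  enough for tracking/quantification tests, not for mechanics studies.
* Oxygen is spatially uniform per frame; reaction–diffusion fields inside
  chambers are out of scope.
* Growth rate is an input to the simulator, not an emergent property of
  nutrient physiology; equal aerobic/anaerobic growth is a parameter choice,
  not a prediction.
* Temperature enters only as a calibration label; no lifetime–temperature
  model is included.
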
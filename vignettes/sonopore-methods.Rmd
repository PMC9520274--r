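---
title: "Modelling low-frequency microbubble cavitation and sonoporation dose-response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling low-frequency microbubble cavitation and sonoporation dose-response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonopore)
```

## The problem

Sonoporation uses ultrasound-driven microbubbles (MBs) as cavitation
nuclei next to cells: the oscillating bubble transiently pores the cell
membrane and lets otherwise impermeable molecules in. Driving lipid-shelled
MBs far below their resonance frequency (here 250 kHz, an order of
magnitude below the multi-MHz resonance of a 1.5 um bubble) produces very
large radial excursions once the peak negative pressure (PNP) exceeds a
Blake-type threshold, which is what makes large-molecule delivery
possible at clinically modest pressures. `sonopore` models this system
end to end: the radial dynamics and cavitation-regime map of a single
shelled bubble, the ligand budget of an antibody-targeted bubble, the
statistical analysis of uptake/viability dose-response tables, and a
reproducible two-channel image quantification, with synthetic-data
generators standing in for wet-lab measurements.

## Radial dynamics model

The bubble radius $R(t)$ obeys a modified Rayleigh–Plesset equation for
a lipid-shelled bubble (the Marmottant family of models):

$$
\rho\!\left(R\ddot R + \tfrac{3}{2}\dot R^2\right) =
P_{g0}\left(\frac{R_0}{R}\right)^{3\kappa}
\!\left(1 - \frac{3\kappa\dot R}{c}\right) + P_v
- \frac{2\sigma(R)}{R}
- \frac{4\mu\dot R}{R}
- \frac{4\kappa_s\dot R}{R^2}
- P_0 - p_{ac}(t)
$$

with polytropic gas core ($P_{g0} = P_0 + 2\sigma(R_0)/R_0 - P_v$ from
mechanical equilibrium at rest), first-order acoustic radiation damping
through the $\dot R/c$ term, liquid viscosity $\mu$, shell surface
viscosity $\kappa_s$, and the piecewise shell surface tension

$$
\sigma(R) =
\begin{cases}
0 & R \le R_b \quad\text{(buckled)}\\
\chi\!\left(R^2/R_b^2 - 1\right) & R_b < R < R_r \quad\text{(elastic)}\\
\sigma_w & R \ge R_r \quad\text{(ruptured)} .
\end{cases}
$$

$R_b$ is chosen so the elastic branch passes through the configured
resting tension $\sigma(R_0) = \sigma_0$, and $R_r$ so that the branch
meets the clean-interface value $\sigma_w$ continuously. Full thermal
modelling is omitted; the gas is treated quasi-adiabatically with
$\kappa = 1.07$ (perfluorobutane), which is a second-order effect for
the maximum-expansion statistic this package reports.

The drive $p_{ac}(t) = -P\!N\!P\,\sin(2\pi f t)$ is rarefaction-first
(the bubble is pulled outward first), rectangular by default, with an
optional linear amplitude ramp.

**Expansion ratio and regimes.** The expansion ratio (ER) is the maximal
diameter over the resting diameter during the drive window. ERs between
1.1 and 3.5 are classified as stable cavitation, above 3.5 as inertial
cavitation, below 1.1 as negligible; the two regime boundaries on a
PNP sweep are located by linear interpolation at the first upward
crossing of each threshold.

## Parameters, defaults and why

| parameter | symbol | default | unit | rationale |
|---|---|---|---|---|
| resting radius | $R_0$ | 0.75e-6 | m | 1.5 um diameter bubble |
| polytropic exponent | $\kappa$ | 1.07 | – | quasi-adiabatic C4F10 |
| vapor pressure | $P_v$ | 0 | Pa | low-solubility perfluorocarbon core |
| density | $\rho$ | 1000 | kg/m³ | aqueous medium |
| viscosity | $\mu$ | 0.002 | Pa·s | cell-suspension-like medium |
| sound speed | $c$ | 1500 | m/s | water |
| ambient pressure | $P_0$ | 101325 | Pa | 1 atm |
| clean surface tension | $\sigma_w$ | 0.073 | N/m | water |
| shell elastic modulus | $\chi$ | 0.020 | N/m | calibrated (below) |
| shell surface viscosity | $\kappa_s$ | 5.8e-9 | kg/s | calibrated (below) |
| resting surface tension | $\sigma_0$ | 0.050 | N/m | calibrated (below) |
| drive frequency | $f$ | 250e3 | Hz | low-frequency regime of interest |
| drive cycles | – | 50 | – | see drive-window note |
| stable floor / inertial onset | – | 1.1 / 3.5 | ER | field convention |

All defaults live in a versioned YAML config
(`default_bubble_config()`); nothing is hard-coded, and the package
works in strict SI internally with unit-annotated keys at the config
boundary.

**Shell calibration.** Shell parameters of lipid MBs vary with
formulation and are not directly measurable here. `calibrate_shell()`
freezes them by minimizing the joint mean squared relative error of the
simulated curve against anchor expansion ratios of 15, 33 and 50 at
300, 500 and 800 kPa and regime boundaries of 85 and 205 kPa — a single
parameter set for all anchors, fitted by Nelder–Mead on log-transformed
parameters inside a bounded physically plausible box
($\chi \in [0.02, 0.3]$ N/m, $\kappa_s \in [1, 12]\times10^{-9}$ kg/s,
$\sigma_0 \in [0.005, 0.05]$ N/m). The frozen defaults reproduce
ER = 15.4/32.5/49.6 and boundaries 85.4/213.5 kPa. These values are the
package's own calibration, not measured shell constants; the fitted
$\chi$ sits at the lower box edge, which is consistent with the very
soft, easily buckling shells required for a sub-100-kPa response onset
at this frequency.

**Drive window.** Experimental insonations last seconds (millions of
cycles); the maximum-expansion statistic converges within tens of
cycles because the bubble either settles into a periodic stable
oscillation or collapses inertially on the first few cycles. The
default window is therefore 50 cycles (200 us at 250 kHz), exposed as a
config knob.

**Collapse handling.** Inertial collapse makes the equation
arbitrarily stiff. An integration event truncates the trace when
$R < 0.05\,R_0$ and flags it; the expansion ratio uses the pre-collapse
maximum, which is reached before the first collapse. This preserves
the reported statistic while avoiding integrating through the
singularity-like rebound.

**Numerics.** `deSolve::lsodar` (adaptive, stiff-capable, with root
finding) integrates a compiled right-hand side at relative tolerance
1e-8 and absolute radius tolerance 1e-12·R0; the maximum step is capped
at a twentieth of the drive period so the pulse onset is never stepped
over. An R-language right-hand side (`marmottant_rhs()`) is exported
and the two are cross-checked in the tests; the adaptive solution is
additionally verified against an independently written fixed-step RK4
oracle at 1e4 steps per cycle (agreement is at the 1e-8 level in the
stable regime, asserted at 1e-4). Because shell and radiation damping
make the linearized oscillator nearly critically damped (damping ratio
about 0.8), small-amplitude behaviour is validated against the
linearized system's matrix-exponential solution and its driven
steady-state amplitude rather than against a free-oscillation
frequency, which would be unmeasurable at this damping.

**Sweep and boundaries.** The default sweep grid step is 5 kPa;
boundary crossings are linearly interpolated at the first upward
crossing (first crossing wins if there are several). A bisection-based
crossing finder is used inside calibration for speed and agrees with
the sweep estimator to below half a grid step. A closed-form
quasi-static Blake threshold (`blake_threshold_estimate()`) is provided
as a diagnostic pressure scale only; it assumes a clean isothermal
bubble with constant surface tension and plays no role in
classification.

## Ligand budget

The targeted-MB arithmetic follows the standard order-of-magnitude
chain with the $\pi d^2$ spherical-surface convention: lipids per shell
$= \pi d^2 / a$ with $a = 0.6$ nm² per DSPC headgroup; 5 mol%
biotinylated lipid; 1:1 biotin:streptavidin; 2 antibodies per
streptavidin. Counts are real numbers, not integers — these are
order-of-magnitude estimates. An explicit `rounded` flag reproduces
one-significant-figure bookkeeping at every step of the chain
(1e7 lipids → 5e5 biotin → 5e5 streptavidin → 10e5 antibodies); exact
mode (default) keeps full precision (1.178e7 lipids, 5.89e5 biotin).

## Dose-response statistics

Measurements are percentages stored on the `[0, 100]` scale. Fractions
are plain validated ratios: stained/total cell counts (microscopy
counting) or green/phase confluence areas (live-cell imaging).
Viability is the cell count as a percentage of the sham group and may
exceed 100.

**Fold uptake** offers two modes. `mean-ratio` (default) is the ratio
of group mean to sham mean. `replicate` divides replicate-wise and
reports mean ± SD of the ratios. Published fold summaries for this
kind of experiment are sometimes computed replicate-wise, in which case
the reported fold can differ slightly from the ratio of the reported
means (e.g. a reported 2.8-fold where the mean ratio is 2.75); both
modes are therefore provided rather than guessing one, and the default
is the reproducible mean-ratio.

**ANOVA and Tukey.** `one_way_anova()` computes F from the definitional
between/within sums of squares with the upper-tail F p value;
`tukey_hsd()` adjusts all pairwise comparisons through the studentized
range distribution (`ptukey`) with the Tukey–Kramer standard error for
unequal group sizes, two-sided, α = 0.05, with the conventional star
notation (\*, \*\*, \*\*\*, \*\*\*\* at 0.05/0.01/0.001/0.0001). Both
are cross-checked in the tests against `stats::aov` and
`stats::TukeyHSD`, and their error calibration is verified by
simulation: over 1e4 null replicates (5 groups × 3 replicates) the
ANOVA type-I error and the Tukey familywise error rate must land in
[0.04, 0.06] at α = 0.05. No normality pre-tests are added. A
degenerate table in which every group has zero within-group variance is
an error, not a p value.

**Optimum.** `dose_response_summary()` reports per-group mean, SD and
fold, and the optimal PNP as the insonated group with the largest mean,
ties broken toward the lower pressure (the cheaper, safer setting).

## Image quantification

The manual threshold-and-count workflow is replaced by a deterministic
pipeline: global Otsu threshold per channel (a fixed-threshold override
exists), connected-component labeling (8-connectivity default,
4-connectivity available), removal of components below 20 px as
background denoising, and a per-cell staining rule — a nuclear
component is "stained" when its mean reporter-channel intensity exceeds
the reporter threshold. This is the simplest rule consistent with
per-cell counting. With no nuclear component the fraction is reported
as missing, never as zero. Watershed splitting of touching nuclei is
deliberately excluded; the synthetic fixtures are generated
non-overlapping, and real confluent images would need a segmentation
step this package does not claim to provide.

## Synthetic data

`synth_replicates()`/`synth_experiment()` draw replicate percentages
from a normal distribution at the registry's published group mean/SD,
truncated to [0, 100] by rejection sampling, in triplicate by default.
The shipped registry (`uptake_registry()`) stores the published group
summaries verbatim as a read-only versioned YAML file; synthetic
replicates are never presented as raw experimental data. Near the
scale bounds the truncated-normal mean is biased inward (e.g. a
viability group at 100 ± 9 can only be sampled below 100), which is a
property of the stated noise model, not a bug; tests that check
unbiased recovery use groups several SDs inside the bounds.
`synth_frame()` places non-overlapping intensity disks by rejection
sampling with a bounded retry count (erroring with advice rather than
hanging), paints the stained subset into the reporter channel, adds
Gaussian noise and clamps to the 16-bit range, returning exact ground
truth alongside.

What the generators do *not* emulate: realistic cell morphology and
clumping, optical point-spread and illumination fields, replicate
correlation across timepoints, and any distribution shape beyond the
truncated normal. Passing the recovery tests therefore demonstrates
that the quantification and statistics are correct on data satisfying
the stated model, not that they would be unbiased on arbitrary real
microscopy.

## Problem sizes used by the tests

The test suite uses 10-cycle windows for solver-oracle comparisons,
1e4-replicate null simulations for the error-rate checks, 320 px
synthetic frames with 100 cells for quantification recovery across
stained fractions {0, 10, 30, 57.7, 100}% at noise SD 5% of signal, and
two-anchor synthetic-parameter recovery for the calibrator. These sizes
were chosen so each property is measured well inside its tolerance.

## Known limitations

- Single-bubble, free-field model: no transducer field geometry, no
  bubble–cell or bubble–wall coupling, no multi-bubble interactions, no
  thermal dose.
- The shell parameters are a calibration to macroscopic curve anchors,
  not independent measurements; different (χ, κs, σ0) combinations can
  fit almost equally well (the fit is along a soft valley).
- The expansion-ratio statistic is insensitive to the drive window
  beyond a few tens of cycles, but sub-harmonic or chaotic regimes just
  above the inertial threshold can make single-point ER values
  sensitive to solver settings; the regime classification is robust to
  this, individual ER values near the boundary less so.
- Percentages are modelled as independent truncated normals; counts
  are not modelled as Poisson/binomial, matching how such experiments
  are usually summarized (mean ± SD) rather than their microstructure.
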
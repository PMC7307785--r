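---
title: "Modelling activity-dependent chloride and the neuronal input-output function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling activity-dependent chloride and the neuronal input-output function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cldyn)
```

## The scientific problem

Fast synaptic inhibition is carried mostly by GABA~A~ receptors, which are
permeable to chloride and, to a lesser degree, bicarbonate (a 4:1 ratio).
The driving force of an inhibitory synapse therefore depends on the local
intracellular chloride concentration, which is itself moved by the very
currents that inhibition produces.  When synaptic drive is sustained,
chloride accumulates faster than the KCC2 cotransporter can extrude it,
EGABA depolarizes, and inhibition loses its grip on the cell — a form of
short-term *ionic plasticity*.  `cldyn` implements a multi-compartment
conductance-based pyramidal-cell model in which chloride is a dynamic state
variable in every compartment, together with the calibration experiment
that pins down the KCC2 pump strength and the analyses that quantify what
dynamic chloride does to the neuronal input-output function.

## The model

**Morphology.**  A chain of four cylindrical sections: a 500 μm × 0.1 μm
axon, a soma, a short thick "proximal" dendrite (50 μm × 2 μm) and a long
thin "distal" dendrite (500 μm × 0.5 μm unless swept).  Each section is
discretized into cylindrical compartments (10/10/20/10 by default;
convergence is exercised in the test suite).  Because the morphology is an
unbranched chain, the implicit voltage update is a single tridiagonal
solve per time step (backward Euler, default dt = 0.025 ms), with membrane
conductances frozen at the previous step so the update stays linear.

**Membrane mechanisms.**  Every compartment carries ohmic leak channels
for K⁺, Na⁺ and Cl⁻ in the fixed ratio 1 : 0.23 : 0.4, with the common
magnitude tuned so a −10 pA somatic step measures a 365 MΩ input
resistance (`tune_leaks()`).  The axon additionally carries
Hodgkin–Huxley-style Na⁺ and K⁺ channels and a slow M-type K⁺ current
responsible for spike-frequency adaptation.  The delayed-rectifier current
uses a *single-exponent* K⁺ gate, `IK = n gK (Vm − EK)`, by default (`k_exponent = 1`; the classical `n⁴` form is available
behind the same flag).

**KCC2.**  Chloride extrusion follows the thermodynamic rate law

$$V \;=\; P_{\mathrm{KCC2}}\,\bigl([K^+]_i[Cl^-]_i \;-\; [K^+]_o[Cl^-]_o\bigr),$$

zero at the equilibrium concentration
$[Cl^-]_i = [K^+]_o[Cl^-]_o/[K^+]_i \approx 3.86$ mM.  The pump strength
is expressed per membrane area, $P_{\mathrm{KCC2}} = 1.9297\times10^{-5}$
mA·mM⁻²·cm⁻² (equivalently 0.001 mM⁻¹·s⁻¹ for the reference cell of
1.058 pL and 529 × 10⁻⁸ cm²; `convert_pump_strength()` moves between the
two unit systems), so that a single constant serves compartments of every
size.

**Chloride mass balance.**  Per compartment,

$$\frac{d[Cl^-]_i}{dt} \;=\;
  \frac{I_{Cl}}{F\,\mathrm{Vol}} \;-\;
  P_{\mathrm{KCC2}}\bigl([K^+]_i[Cl^-]_i-[K^+]_o[Cl^-]_o\bigr) \;+\;
  D_{Cl}\,\frac{\partial^2 [Cl^-]_i}{\partial x^2},$$

with the sign convention that outward-positive chloride current is anion
influx (raising $[Cl^-]_i$) and a positive KCC2 bracket is extrusion
(lowering it).  Longitudinal diffusion uses a conservative finite-volume
stencil between compartment midpoints with series-resistance coupling at
diameter jumps, so total chloride is conserved to floating-point accuracy
on a sealed cable.  $E_{Cl}$ is recomputed from the Nernst equation every
step and $E_{GABA} = \tfrac45 E_{Cl} + \tfrac15 E_{HCO_3}$ with
$E_{HCO_3}$ held constant.  In the *static chloride* mode every
$[Cl^-]_i$ is frozen at its initial value (EGABA −77.41 mV at defaults),
which is the classical fixed-reversal assumption the dynamic mode is
compared against.

**KCC2 and membrane charge.**  The transporter moves one K⁺ with one Cl⁻
and is electroneutral, so by default it enters only the chloride (and, in
the dynamic-potassium mode, potassium) mass balance, not the membrane
current sum.  This is also what the model's own resting state demands: a
chloride-current-carrying KCC2 would cancel the chloride leak current at
steady state and move the resting potential to the K/Na-only balance near
−64 mV, well away from the −71.35 mV the full three-ion balance produces.
A charge-carrying variant is retained (`kcc2 = list(electrogenic = TRUE)`)
for sensitivity exploration.

**Synapses.**  Event-driven ("f-in") synapses receive independent Poisson
trains at a set mean frequency.  Excitatory synapses are mixed AMPA+NMDA
(dual-exponential kinetics, τ 0.2/1.7 ms and 2.04/75.2 ms, 1 nS, reversal
0 mV) with the NMDA component subject to a sigmoidal magnesium block,
$1/(1 + ([Mg]/3.57)e^{-0.062V})$ at 1 mM Mg²⁺.  Inhibitory synapses are
GABA~A~ receptors following the two-state transmitter-binding scheme
(α = 5 mM⁻¹ms⁻¹, β = 0.18 ms⁻¹, 350 pS) driven by a 1 mM × 1 ms
transmitter pulse per presynaptic event, and their current is split 4:1
between chloride and bicarbonate so the chloride component feeds the mass
balance.  The continuous "gclamp" drive is an Ornstein–Uhlenbeck
conductance (baseline 0.0001 μS per synapse, CV 0.1, correlation time
10 ms, clipped at zero) delivered by a fixed population of 20 synapses per
drive placed evenly along the target section; the *relative conductance*
multiplier scales every synapse's baseline.

## Calibration against the recovery experiment

The perforated-patch experiment loads the cell with chloride (a 15 s
photocurrent) and watches $[Cl^-]_i$ relax back over about a minute.  With
a KCC2-plus-constant-leak single compartment the relaxation is exactly a
single exponential with $\tau = 1/(P\,[K^+]_i)$ (≈ 7.1 s at the reference
pump strength), which is what `generate_recovery()` produces — sparse
samples (every 5 s from 2 s to 90 s by default, a package choice matching the
sparse per-trial sampling such recordings allow), Gaussian measurement noise, ground truth recorded in the output.
`fit_recovery()` mirrors the experimental analysis pipeline rather than
just inverting the time constant: it fits the exponential, differentiates the *fitted*
curve analytically (noise-robust, unlike finite differences of raw
samples), and regresses the extrusion rate on the KCC2 bracket; the slope
is $\hat P$ in mM⁻¹·s⁻¹, converted to current-density units with the
recorded-cell geometry.

```{r calibration}
trace <- generate_recovery(P_true = 0.001, noise_sd = 0.3, seed = 1)
fit <- fit_recovery(trace$time_s, trace$cl_mM)
summary(fit)
```

## Behavioural anchors and the free parameters

Several parameters of the model are not fixed by its reference constant
set and were chosen once, as package defaults, against the model's
behavioural anchors
(resting Vm −71.35 mV and [Cl⁻]ᵢ 4.25 mM, input resistance 365 MΩ, and a
5 Hz output for the reference 250:300 E:I distal configuration driven at
5 Hz):

* soma 13 μm × 13 μm (the soma size is otherwise unconstrained; this
  size makes the tuned chloride-leak density consistent with a 4.25 mM
  resting chloride fixed point at the default pump strength);
* specific capacitance 1 μF/cm², axial resistivity 100 Ω·cm (standard
  cortical-model values);
* squid-derived Na/K rate functions with depolarizing shifts of +8 mV
  (Na) and +45 mV (K).  The large K-gate shift compensates the
  single-exponent K current: with `n¹` the delayed rectifier would
  otherwise be substantially open at rest, hyperpolarizing and shunting
  the axon;
* M-current: first-order gate, V½ −35 mV, slope 10 mV, τ 200 ms, 5 × 10⁻⁴
  S/cm²;
* NMDA:AMPA maximal-conductance ratio 0.22.  With equal 1 nS maxima the
  NMDA component (75 ms decay) alone delivers ~100 nS of unblocked
  conductance at the reference drive and plateau-depolarizes the dendrite;
  0.22 places the reference configuration at the 5 Hz anchor while
  keeping inhibition effective;
* spike detection: upward crossing of −20 mV at the axon tip with a 2 ms
  lockout.

These are calibration decisions, exposed in the configuration, and the
package's results should be read with that freedom in mind: quantities
that depend only on the reference constants (reversal potentials, pump
strength, rest state, input resistance) are parameter-free, whereas
absolute firing rates inherit the uncertainty of the free kinetics.

## The analyses

`io_curve()` maps excitatory drive (synapse counts for the event-driven
drive, relative conductance for the fluctuating drive — two abscissa kinds
that are tagged and never mixed) to the mean output rate over seeded
trials.  `half_max()` extracts $x_{50}$, the abscissa at half-maximal
rate, by piecewise-linear interpolation of the rising limb after a
running-maximum pass; for distally inhibited curves the reference maximum
is the no-inhibition plateau, which distal inhibition does not change.
The **chloride index**

$$\mathrm{index} \;=\; 1 - \frac{a}{b}, \qquad
  a = x_{50,i}^{\Delta Cl} - x_{50,i=0}, \qquad
  b = x_{50,i}^{\overline{Cl}} - x_{50,i=0}$$

measures how much of the static-chloride offset survives when chloride is
dynamic: 0 when dynamics are irrelevant, 1 when the offset is abolished.
The distal EGABA shift attached to an index is the volume-weighted distal
average at the end of the run minus its start, taken from the dynamic run
at the grid point nearest $x_{50}^{\Delta Cl}$, where the offset itself is
measured.  `index_egaba_sweep()` repeats the full protocol over
manipulations that change chloride accumulation — pump strength 25–200 %,
distal diameter 0.5–2 μm, leak scaling, distal-only KCC2 scaling, run
duration, dynamic potassium — and correlates index with EGABA shift
across all points.

The no-inhibition reference curve is computed in the static mode: with no
GABAergic conductance the two modes differ only through the
excitation-driven shift in the chloride *leak* driving force, a
sub-millivolt effect on the curve, and the static reference is common to
both offsets.

## Numerical choices

* Backward-Euler tridiagonal voltage solve; gating advanced by exact
  exponential updates at the new voltage; chloride (and K⁺) advanced
  explicitly after the voltage step (operator splitting).  The splitting
  and dt choices are exercised by a dt-halving convergence test.
* Diffusion is explicit; at dt = 0.025 ms the stability number
  $D\,dt/\Delta x^2$ stays far below ½ for every default compartment.
* The engine is deterministic given (configuration, seed): Poisson trains
  come from per-synapse counter-derived sub-seeds (`subseed()`), and the
  OU noise uses a platform-independent splitmix64 generator inside the
  engine, so adding a recorder never perturbs a stimulus realization.
* Spatial discretization of the 0.1 μm axon matters for spike initiation:
  coarser than ~50 μm compartments the initiation site is under-resolved.
  The default (10 compartments) is the tested configuration.
* Divergence (|Vm| > 200 mV, NaN) and chloride underflow (< 10⁻³ mM) stop
  the run with the offending step and compartment.

## What the synthetic data do and do not establish

The recovery generator emulates the *structure* of the perforated-patch
experiment — exponential recovery from a load, sparse sampling, additive
noise, known ground truth — so it validates the estimator, not the
biology: real recordings add series-resistance and liquid-junction
artefacts, non-stationary baselines and opsin kinetics that are
deliberately out of scope.  Likewise the balanced-drive fixtures
reproduce the reference protocol parameters (250:300 E:I at 5 Hz, etc.),
so passing tests show the pipeline reproduces the model's behaviour under
those conditions, not that the model captures any particular real
neuron.

## Problem sizes used by the shipped analyses

The sweep behind the index–EGABA correlation runs pump strength
{25, 50, 100, 200} % × distal diameter {0.5, 1, 2} μm × inhibition
{2, 4, 8} (36 points, three trials per grid point, 1 s runs on a
17-point excitation grid).  The test suite uses smaller grids and shorter runs of
the same protocols; both sizes are package choices made to keep the
analyses routinely re-runnable, and the sweep correlation is stable well
below the full 292-run design it is scaled down from.

## Limitations

Dendrites are passive (no active dendritic conductances), the morphology
is a four-section chain rather than a reconstructed tree, HCO₃⁻ and — by
default — K⁺ and Na⁺ concentrations are static, there is no NKCC1 import
pathway, no impermeant-anion/osmotic coupling, and no radial (submembrane)
diffusion.  Network-level consequences of the single-cell findings are
out of scope.
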
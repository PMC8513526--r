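---
title: "Models and methods behind napdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind napdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(napdyn)
```

`napdyn` analyses ensemble patch-clamp experiments in which a single
17-pulse cumulative voltage protocol, repeated at 1 Hz, simultaneously
probes three aspects of state-dependent sodium channel inhibition: onset of
inhibition during depolarization (SDO), recovery of availability during
hyperpolarization (RFI), and quasi-steady-state availability as a function
of membrane potential (SSI). This vignette explains the models the package
implements, the reconstruction choices behind the reference protocol, the
synthetic-data generator used for validation, and the numerical decisions
in the fitting machinery — together with what the passing test suite does
and does not demonstrate about real recordings.

## The reference protocol and its reconstruction

The published description of the protocol fixes its logical structure —
17 test pulses; cumulative depolarized times of 2.5, 7.5, 22.5 and 67.5 ms
before SDO pulses #2–#5; hyperpolarized gaps of 64, 1, 2, 4, 8, 16 and
32 ms before RFI pulses #6–#12 plus the 498-ms inter-sweep interval before
pulse #1; 40-ms SSI pre-pulses at −110 to −70 mV before pulses #13–#17
with pulse #12 doubling as the −130 mV point; a 522-ms recorded sweep in a
1000-ms period; and 34 voltage steps — but not every segment duration.
`build_reference_protocol()` reconstructs the missing pieces under three
simultaneous constraints: the recorded durations sum to exactly 522 ms,
the hyperpolarized time before pulse #1 of the next sweep is exactly
498 ms, and exactly 34 potential changes exist.

The unique solution places 10-ms holding margins at both ends of the
recorded sweep (the first and last 10 ms of the 498-ms inter-sweep
hyperpolarization are recorded), which leaves 95/12 ms ≈ 7.92 ms as the
single RFI/SSI test-pulse duration. Because each SSI pre-pulse directly
follows the preceding test pulse, pre-pulse entries coincide with pulse
offset edges, and the 34 potential changes are exactly the 17 onset plus
17 offset edges of the test pulses. Two quantities are design choices
rather than published values: the test-pulse potential (0 mV, standard for
peak inward-current elicitation; only peak amplitudes enter the analysis)
and the holding potential (−130 mV, implied by pulse #12 serving as the
−130 mV SSI point). Both are exposed as overrides. Potentials are stored
as corrected membrane potentials; `apply_junction_offset()` converts to
command-potential space (the reference liquid-junction correction is
8.1 mV, applied by the caller).

Nominal edge times of the reconstructed protocol fall at thirds of a
sample at 20 kHz. Both the trace renderer and the section extractor
therefore quantize edges to the nearest acquisition-clock tick — the
behaviour of an instrument whose stimulus DAC runs on the sampling clock.
Taking instead the first sample at-or-after a between-tick nominal edge
would start sections one tick late, so the rising sodium transient would
contaminate the baseline sample that the offset-removal step subtracts.

## Availability models

Steady-state availability follows the decreasing Boltzmann curve
$I(V_p) = I_{max} / (1 + \exp((V_p - V_{1/2})/k))$ with midpoint
$V_{1/2}$ (mV) and slope factor $k > 0$ (mV). Recovery from inactivation
follows the extended equation

$$I(t_{ip}) = I_{max}\left(A_1\,(1 - e^{-t_{ip}/\tau_1})^{x}
 + A_2\,(1 - e^{-t_{ip}/\tau_2}) + A_3\right)$$

with $A_1 + A_2 + A_3 = 1$, $\tau_1 < \tau_2$ and $x \ge 1$; the plain
bi-exponential is the nested case $A_3 = 0$, $x = 1$. $A_3$ is implemented
as a constant offset — the only reading consistent with the equation's
form — and represents the channel fraction whose recovery is too fast to
resolve at the shortest interval (an "unmodulated" fraction under drug).
The sum constraint makes $I \to I_{max}$ as $t_{ip} \to \infty$; it is not
restated for the extended model in the source description and is flagged
as an assumption. Fit quality is tracked by the RMSE expressed as a
percentage of the same sweep's pulse-#1 amplitude (the per-sweep maximal
current) and by per-point relative errors, which are dominated by the
smallest-amplitude points by construction.

## Constrained fitting

All fits minimise absolute (not relative) squared residuals on raw
amplitudes, using bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with
five deterministic multi-starts spanning the bounds; per-sweep automated
fits are additionally seeded with the previous sweep's parameters, which
keeps the series time-coherent and makes warm starts the common path.
Default bounds: $V_{1/2} \in [-150, -20]$ mV, $k \in (0, 20]$ mV,
$\tau_1 \in (0, \tau_2)$, fractions in $[0, 1]$, $x \in [1, 5]$, and
$I_{max}$ within a factor band of the largest observed amplitude. Two
constraints are enforced by reparameterisation rather than by penalty or
post-hoc repair: the fraction sum, via $A_1 = \varphi(1 - A_3)$ with
$\varphi \in [0,1]$, and the time-constant order, via
$\tau_2 = \tau_1 + \Delta\tau$ with $\Delta\tau > 0$. The
reparameterisation matters for the exponent-free model: swapping the fast
and slow components is not a symmetry of the model when $x \ne 1$, so a
swap-and-refit repair can land on a worse curve, whereas every iterate of
the reparameterised problem is admissible by construction. An initial
guess violating the order enters as its order-respecting projection.

In automated (per-sweep) mode the slow time constant is fixed, because the
8-point RFI design has few points in its range; `fixed_tau2_from_supervised()`
supplies the mean of supervised fits and warns outside the typical
100–400 ms band. `stepwise_extension()` fits the bi-exponential first and
frees $A_3$, then $x$, only while the percentage RMSE exceeds a threshold
(default 2 %, motivated by the observation that routine fits stay below
4 % except where the bi-exponential is structurally inadequate). The fixed
$\tau_2$ is kept through the extension steps; freeing it there lets the
$A_3$ step absorb the exponent effect and defeats the purpose of the
sequence. Each extension is seeded with the previous optimum, so the RMSE
sequence is non-increasing by construction. When $x$ is free the fitted
$\tau_1$ is flagged non-comparable, because the time constant and the
exponent are interdependent.

## The synthetic-experiment generator

No deposited recordings exist, so the generator defines the study
conditions for every test. It is deliberately minimal but reproduces the
statistical structure the analysis assumes:

- **Macro-kinetics.** The aqueous concentration switches instantly between
  perfusion windows (complete solution exchange between sweeps); the
  membrane phase relaxes toward it first-order with separate wash-in and
  wash-out time constants. Multi-step access kinetics (deprotonation,
  partitioning) are not modelled separately.
- **Modulation.** Effective parameters interpolate between control and
  saturating values with the fraction $e = c_m/(c_m + K)$: a
  hyperpolarizing $V_{1/2}$ shift, a fold-increase of $\tau_1$, a
  suppression of $A_1$ (redistribution into $A_2$), an unmodulated
  fraction $A_3$, an exponent $x$, tonic block, and an SDO block with its
  own onset time constant (the SDO section is generated but not fitted).
  The two presets encode the qualitative dichotomy the method is designed
  to resolve: `lidocaine_like_spec()` redistributes $A_1 \to A_2$ at fixed
  $\tau_1$; `riluzole_like_spec()` slows $\tau_1$ up to 8-fold with a
  concentration-dependent $A_3$ and $x$ up to 2.
- **Per-sweep amplitudes.** RFI-role pulses evaluate the extended recovery
  equation at their interval (pulse #12 at its true 32-ms conditioning);
  SSI-role pulses evaluate the Boltzmann curve at their pre-pulse
  potential, scaled by the recovery attainable in the 40-ms pre-pulse
  (about 90 % in control) — which keeps the generated SSI section an
  exactly scaled Boltzmann, so the availability midpoint stays
  identifiable while the ceiling stays physical. Amplitudes are scaled by
  the tonic-block factor and the ensemble amplitude, signed negative.
- **Noise and drift.** Additive Gaussian noise per amplitude (and per
  trace sample) plus a slow multiplicative drift shared by amplitudes and
  seal series. Defaults: 9.5 nA control amplitude and 8.75 MΩ seal
  (reference means), 0.05 nA noise, 3 % drift per experiment.
- **Raw traces.** A difference-of-exponentials sodium transient at each
  test pulse (0.1 ms activation, 0.5 ms inactivation, peak scaled to the
  programmed amplitude), residual capacitive transients at every voltage
  step proportional to the step size (2×10⁻⁴ nA/mV, 0.05 ms decay — a
  well-compensated instrument), ohmic leak $V/R_{seal}$, and Gaussian
  noise at 20 kHz. Single-channel stochasticity, series-resistance error
  and temperature effects are out of scope.

What passing tests show: the chain recovers what the generator programmed
— peaks within 2 % RMS of the control amplitude through the full
render/extract round trip, plateau $V_{1/2}$ shifts within 1 mV,
$\tau_1$ fold-changes within ~10 %, and the stepwise RMSE sequence
strictly decreasing on riluzole-like data. What they do not show: anything
about artifacts the generator omits (imperfect voltage control in leaky
ensembles, series resistance, temperature drift, multi-exponential
wash-out), which on real data appear as elevated RMSE and flagged sweeps
rather than silently wrong parameters.

## Preprocessing choices

For every test pulse a 2-ms section is cut after its onset edge and after
its offset edge; the two are summed elementwise (the residual capacitive
transients at the two edges have opposite polarity and cancel — exactly,
for equal step sizes) and the sum is shifted so its first sample is zero,
which removes the constant ohmic leak. No P/n leak subtraction is used.
The peak is the raw minimum of the corrected segment (the 10-kHz hardware
filter is assumed; an optional software low-pass is off by default), with
its position returned for QC. Two structural approximations are inherited
from the method itself and documented rather than repaired: the offset
section contains tail current, and the SSI pulses' onset and offset steps
differ in size, leaving a small uncancelled residual proportional to the
mismatch. With the well-compensated defaults this residual is ≈0.003 nA —
negligible against nA-scale currents — and the amplitude-recovery
guarantee is therefore stated as an RMS over the 17 peaks relative to the
ensemble's control amplitude, the same anchoring the percentage RMSE uses.

## Quality control

The four exclusion rules are: control amplitude below 2 nA; mean seal
resistance below 5 MΩ; a fitted gradual seal decline exceeding 20 % of the
initial seal (a robust linear trend, so single steps do not masquerade as
drift); and a sudden amplitude drop concurrent with a seal drop,
operationalised as >20 % amplitude loss between consecutive sweeps with
>10 % seal loss within the same 3-sweep window — the published rule names
no magnitudes, so these defaults are explicit, configurable, and recorded
in the QC report header. Ensemble stability is scored as the inverse
coefficient of variation of the seal series (the selection criterion is
stated as seal stability without a formula); `select_top()` picks the six
highest-scoring passing ensembles per zone with a deterministic
tie-break.

## Problem sizes and determinism

The test suite and the acceptance script run entirely on synthetic data at
desk scale: oracle-equivalence on 20 noisy 6- and 8-point datasets against
dense grid searches with the amplitude parameters solved linearly per grid
point; parameter recovery over 200 simulated quantitative fits — each
following the method's own procedure of fitting averages of three
consecutive sweeps — at per-sweep noise of 2 % of $I_{max}$; and one fully
rendered 120-sweep experiment (1.25 million samples) pushed through
render → extract → per-sweep fits → dynamics. A full 1700-sweep reference
experiment simulates in seconds and fits in well under a minute. Every
stochastic step takes an explicit seed; identical seeds give identical
files byte-for-byte.

Recovery-rate criteria deserve one note: at 2 % single-sweep noise the
single-fit estimator of $A_1$ has a standard error of ≈0.027 on this
design, so a ±0.05 band can never contain 95 % of single fits; the
three-sweep averaging that defines the method's quantitative fits is what
makes the 95 % rates attainable, and it is that procedure the recovery
tests simulate. Likewise the 6-point SSI design bounds single-fit
$V_{1/2}$ precision at ≈1.3 mV, so the 1-mV guarantee applies to the
recovery bias and to averaged plateau shifts, not to individual sweeps.

## Known limitations

SDO quantitation is out of scope (the generator produces the section; no
onset model is fitted). Macro-kinetics are fit mono-exponentially with a
free plateau; multi-exponential wash-out is not modelled. The repetition
internal control compares endpoint parameters between the two schedule
repetitions and flags baseline deviations beyond 5 % amplitude or 2 mV
$V_{1/2}$ (configurable); it detects incomplete recovery but does not
correct for it. The native instrument binary format is not parsed — the
CSV export path is the supported interchange, and `read_isd_file()` fails
with a clear message.
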
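---
title: "Modeling bursting and tonic spiking in larval cold-sensing neurons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling bursting and tonic spiking in larval cold-sensing neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`coldburst` simulates a *Drosophila* larva Class III (CIII) multidendritic
sensory neuron, the larva's primary cold nociceptor.  The cell is a single
electrical compartment whose membrane potential obeys

$$C_m \frac{dV_m}{dt} = -\left[I_{Na} + I_K + I_{Ca} + I_{BK} + I_{SK} +
I_L + I_{TRP}\right]$$

with a voltage-gated Na^+^ current ($m^3 h$ kinetics), a delayed-rectifier
K^+^ current ($m^4$), an N-type Ca^2+^ current ($m h$, dynamic Nernst
reversal), big- and small-conductance Ca^2+^-activated K^+^ currents (BK:
instantaneous Hill factor in Ca^2+^ times a slow $m^4$ voltage gate; SK: a
Hill-activated gate with a 40 ms time constant), an ohmic leak, and a lumped
cold-activated thermoTRP current.  Intracellular Ca^2+^ integrates the Ca^2+^
influx through the voltage-gated channel and the TRP conductance's Ca^2+^
component and is cleared first-order at 403 s^-1^ towards a 50 nM floor.
Maximal conductances carry a temperature factor
$\rho(T) = 1.3^{(T - T_0)/10}$ and gating kinetics
$\varphi(T) = 3^{(T - T_0)/10}$ with $T_0$ = 298.15 K, so cooling weakens
every conductance (except the TRP current, which is not $\rho$-scaled) and
slows every gate.  Units are mV, s, nS, pA, nF, nM, pL and Kelvin
internally; Celsius appears only at user interfaces.

The TRP current exists at two levels of description:

* **Level I** (`trp_parameters("leak", G_LTRP = ...)`): a constant
  nonspecific leak conductance with reversal near 0 mV.  Steady-state
  behavior over the $(G_{LTRP}, T)$ plane is the package's *activity map*.
* **Level II** (`trp_parameters("dynamic")`): the conductance
  $\bar G_{TRP}\, m_{TRP}\, h_{TRP}$ is gated by a temperature-dependent
  activation ($\tau_m$ = 2 ms) and a Ca^2+^-dependent inactivation
  ($\tau_h$ = 10 s).  The activation steady state is a Boltzmann in
  temperature (half-activation $T_h$ = 290.15 K, steepness $A$ = 1 K^-1^,
  scale $B$ = 1) and the inactivation a falling Hill function of Ca^2+^
  ($Ca_h$ = 700 nM, $N$ = 2).  The fast-activation / slow-inactivation
  asymmetry makes the conductance overshoot during rapid cooling, which is
  what turns the cooling *rate* into a pattern cue.

The right-hand side is implemented once in C (integrated by `deSolve`'s
backward-differentiation formulas with temperature supplied as a forcing
function; absolute/relative tolerances 1e-9/1e-8) and once in plain R
(`state_derivatives()`); the test suite holds the two to within machine
precision of each other, and checks the variable-step solution against a
fixed-step Runge-Kutta integration on a spiking excerpt.

## Readings of the published model definition

Three elements of the typeset model description cannot be taken at face
value, and each is exposed as an explicit switch with the corrected reading
as default.  The package treats the model's *reported behavior* — the
curve family of the rate-temperature plots, the regime structure of the
activity map, the 1.3 °C/s bursting threshold — as the authority on what
the equations must have been.

1. **Bell-shaped gating time constants** (`tau_profile = "sech"`).  The
   printed formulas read
   $\tau_{hNa} = (4.5\cosh((V+41.2)/12.6) + 0.75)/1000$ and
   $\tau_{mK} = (5\cosh((V+12)/14) + 0.75)/1000$.  Taken literally, these
   *grow* away from their center voltage, making Na^+^ inactivation
   slower than 1 s at spike peaks; spikes become half-second plateaus, the
   model can fire at no more than ~2 Hz, and never bursts.  Reading the
   formulas as bell curves, $(a/\cosh(\cdot) + 0.75)/1000$ — i.e. the
   standard sech-shaped time constant, fastest away from the half-voltage,
   and the same typographical fraction-bar loss visible elsewhere in the
   typeset equations — restores millisecond spikes and reproduces every
   reported behavior quantitatively.  Both profiles agree at the center
   voltage, where the published closed-form values (5.25 ms, 5.75 ms) hold.
2. **K^+^ half-activation sign** (`Vm_K = -12` by default).  The parameter
   table prints $V_{mK}$ = +12 mV — the only positive half-voltage of any
   gate, and inconsistent with the model's own $\tau_{mK}$ formula, whose
   $\cosh((V_m + 12)/14)$ centers at −12 mV.  With +12 the delayed
   rectifier is effectively absent below 0 mV; a stable depolarized fixed
   point then sits between Na^+^ inactivation and K^+^ activation and the
   cell blocks instead of firing.  With −12 the model reproduces the full
   reported curve family at the printed anchor conductances: peaked
   rate-temperature curve at 0.12 nS, monotonic increase on cooling at
   0.28 nS, saturation at 0.42 nS, and a peak at ~10 °C at 0.88 nS.
3. **Cold orientation of TRP activation**
   (`activation_orientation = "cold"`).  The printed Boltzmann
   $B/(1+e^{-A(T-T_h)})$ increases with *warming*; a cold receptor must
   open on cooling, and the silent-at-room-temperature, active-when-cold
   behavior requires the reflected form $B/(1+e^{A(T-T_h)})$, which is the
   default.  Similarly the TRP reversal potential uses the live Nernst
   Ca^2+^ reversal in its Ca^2+^ term (`etrp_mode = "dynamic_ECa"`),
   because the fixed-calibration form is identically 0 mV by construction
   of the Na^+^ permeability; the literal constants are retained as
   switches.

The cosh-argument centering is also ambiguous in print ("$V_m + V_{hNa}$"
with $V_{hNa}$ = −41.2 mV).  The default `tau_convention = "magnitude"`
reads the printed offsets as magnitudes, $V_m + |V_{half}|$, centering
$\tau_{hNa}$ at −41.2 mV and $\tau_{mK}$ at −12 mV — the only reading that
places both centers at physiological voltages and agrees with the signed
parameter table under the corrected $V_{mK}$.

## Protocols and preparation

Temperature stimuli are piecewise protocols: `make_trapezoid()` (hold /
linear fall / cold hold / linear rise / hold; the reference stimulus holds
24 °C for 30 s, falls to the target, holds 30 s, and returns),
`make_experimental_like()` (the perfusate-switch "fast" stimulus as an
exponential approach with initial slope 2–6 °C/s and a 60 s cold hold,
truncated within 0.05 °C of the target; the in-line-cooler "slow" stimulus
as a ±0.12 °C/s ramp with a 30 s hold), and `load_trace()` for replaying
two-column recorded traces by linear interpolation.
`synth_temperature_trace()` samples the analytic protocols at 100 Hz (the
thermometer's bandwidth scale — temperature is slow compared to the 2 kHz
electrophysiological output grid) and can add seeded low-pass Gaussian
noise of at most 0.1 °C to emulate thermocouple recordings.

Every run starts from a 100 s *pre-integration* at the protocol's starting
(room) temperature, which makes results insensitive to the arbitrary
initial state (V~m~ = −60 mV, gates at steady state, Ca^2+^ at floor).
Activity-map cells settle 60 s at their $(G_{LTRP}, T)$ condition and are
analyzed over the following 40 s.  Because several map cells are bistable
(0.88 nS at 20 °C, for instance, spikes when entered from one quiescent
preparation and stays silent from another), the pre-integration must be
performed with the conductance actually under study: each map column uses
the 100 s room-temperature state of the model with its own $G_{LTRP}$.
A shared state can still be supplied explicitly (`ic =`).

## Spike-train analysis

Spikes are upward 0 mV crossings of the simulated voltage (linearly
interpolated between samples, 1 ms refractory) — a model-side stand-in
for the amplitude threshold applied to extracellular currents in
recordings.  A *burst* is three or more spikes with interspike intervals
(ISIs) of 0.2 s or less; two-spike groups are tallied separately as pairs;
when a short-ISI run exceeds six spikes, interior strict local maxima of
its ISI sequence (with a 1 ns float-noise guard) are treated as breaks,
applied greedily from the largest peak down, refusing any break that would
strand a fragment of fewer than three spikes and resolving ties towards
the earlier peak.  The segmentation is verified against an independent
recursive implementation of the same rule on a thousand seeded random
trains.

Window *pattern labels* are assigned in a fixed order: `silence` (no
spikes); `depol_block` (earlier spikes but a spikeless final 5 s with mean
V~m~ above −30 mV); `plateau` (a depolarized, spikeless stretch longer
than 5 s after the last spike that later repolarizes); `bursting`;
`period2` (no bursts and ISIs alternating between two levels); `tonic`
otherwise.  The −30 mV / 5 s constants operationalize labels that the
experimental literature names without numeric definitions.

The `bursting` label demands more than the raw burst rule: the ISI
adjacent to a burst must be a *pause* (> 0.2 s) at least **twice** the
neighboring intra-burst interval.  This is the interval-bimodality
signature of bursting responses (bursting cells show bimodal ISI
histograms; tonic cells unimodal ones).  It matters during fast cooling:
the model's tonic firing smoothly accelerates through 5 Hz, so ISIs drift
below 0.2 s and the literal rule would call every fall "bursting" from
about 0.5 °C/s upward.  With the contrast requirement the tonic-to-bursting
transition of the trapezoid rate sweep is sharp: at 1.2 °C/s the falling
phase has no pause at all, at 1.3 °C/s the pause/intra contrast jumps to
~7 and the maximal instantaneous frequency jumps from 20 to 33 Hz one grid
step later.  Any contrast factor between about 1.3 and 7 therefore locates
the same transition; the default 2 was fixed beforehand as the natural
factor-of-two.  Observed silence *after* a burst (inside the analysis
window) counts as its terminating pause; silence *before* the first spike
does not, since that is the approach to threshold rather than a pause
between activity.  Bursts belong to the protocol phase containing their
first spike and are completed across a phase boundary before being judged.

## Maps, sweeps, projection, census

`sweep_map()` builds the level-I activity map (reference grid: G from 0 to
1 nS in 0.02 nS steps, temperature 24 to 4 °C in 0.5 °C steps).  Its regime
structure — silence at warm temperatures and low conductance, a bursting
and period-2 peninsula at low conductance near the activity boundary,
tonic spiking elsewhere, with per-cell mean frequency (intra-burst mean
when bursts exist, mean 1/ISI otherwise), spikes per burst and mean
Ca^2+^ — is the backdrop onto which `project_trajectory()` draws the
level-II instantaneous conductance path $(T(t), \bar G m h)$ with each
spike annotated by its instantaneous frequency.  The warmest active
temperature of each column (`activity_threshold()`) is a function of the
conductance, though not a monotone one: intermediate conductances turn on
at colder temperatures than either lower or higher ones, a consequence of
Ca^2+^ load on the SK/BK currents.

`rate_sweep()` and `magnitude_sweep()` drive the level-II model through
trapezoid protocols, varying the ramp rate at fixed 10 °C target
(0.1–5.5 °C/s in 0.1 steps) and the target temperature at fixed 3 °C/s
(20–6 °C in 0.5 steps) respectively.  The first reports the smallest rate
whose falling phase is bursting; the second verifies that cold *magnitude*
does not shape the falling-phase pattern — every target whose fall contains
spikes shows the same bursting label with an identical maximal intra-burst
frequency, because all falls share the same trajectory prefix.  Targets of
19.5 °C and warmer produce no spikes during their short falls at all: the
level-II conductance trajectory only crosses the level-I activity boundary
near 18.6 °C with the reference TRP parameters ($T_h$ = 17 °C), so the
pattern-invariance statement applies to the targets that are active during
the fall.

`phenotype_census()` runs the full model once per row of a TRP-parameter
table under a common stimulus and classifies each response as bursting,
tonic (period-2 folded in), plateau, depolarization block, or
non-responsive (no spikes in the stimulus's first 30 s).
`synth_parameter_table()` provides seeded uniform draws plus four fixed
exemplar parameter sets spanning the published response taxonomy (two
bursting, two tonic-only, one of the latter with a transient
high-frequency peak); the census reproduces those four characters.  The
published census percentages over the several hundred experimentally
fitted parameter sets are *not* reproducible here — those sets live in a
prior study's supplement and the recorded temperature traces are
unpublished — so the census is validated structurally (normalization,
determinism, degenerate rows) and against the exemplars.

## Numerical choices

* Output grid 2 kHz: spikes are milliseconds wide; 0 mV-crossing detection
  is verified stable against 10 kHz resampling.  Internal steps are capped
  at 0.1 s so the solver never strides across a protocol breakpoint.
* Solver `bdf` at 1e-9/1e-8 tolerances; tightening to 1e-10/1e-9 leaves
  every spike count unchanged and moves spike times by under 1 ms on the
  reference fast-protocol run (537 spikes).
* Exponential protocol segments are sampled at 100 Hz for the forcing
  interpolation (curvature error far below 0.01 °C); linear and hold
  segments contribute exact breakpoints.
* Curve-shape rules for rate-temperature curves: a fall-off of more than
  10% from the maximum at the cold end is `peaked_then_decline`; otherwise
  the curve is `saturating` when at least a quarter of the active range
  lies within 10% of the maximum, else `monotonic`.  The four published
  anchor conductances classify correctly under these rules, with wide
  margins (the 0.88 nS curve falls about 19% off its peak by 4 °C; the
  0.28 nS curve is still rising steeply at the cold end).
* Problem sizes in the tests: the full 55-rate sweep and 0.5 °C-resolution
  map columns are exercised as published; exploratory maps in the tests
  use coarser grids (4 x 5 cells) chosen to straddle every regime.

## What the synthetic fixtures do and do not show

`synth_spike_train()` composes trains from declared burst/pair/tonic/gap
segments with jitter bounded so the declared segmentation provably
survives (intervals may not cross the 0.2 s line; long constant-interval
bursts may not acquire spurious peaks), and emits that segmentation as
ground truth — the classifier oracle.  These trains have rectangular
regime boundaries and stationary intervals; real CIII trains drift,
accelerate and mix regimes continuously, which is why the classifier is
additionally property-tested against an independent implementation on
random mixed-interval trains and exercised on simulated voltage.  Passing
all of that shows the *rules* are implemented exactly; it cannot show the
rules themselves capture every judgement a human scorer would make on
borderline biological trains (the rate sweep's 4.9 °C/s fall, where the
terminating pause shrinks to exactly 0.2 s, is a genuinely borderline
case that the rule calls tonic between bursting neighbors).

## Known limitations

* Single compartment; no dendritic morphology, channel noise, or synaptic
  context, and one lumped TRP current rather than the cell's TRP channel
  inventory.
* No bifurcation-theoretic boundary tracing; map regime boundaries are
  empirical at grid resolution, and path-regime assignment is
  nearest-cell.
* The literal typeset readings (`tau_profile = "cosh"`,
  `Vm_K = 12`, warm orientation, constant TRP reversal) are preserved as
  switches for auditing, but no attempt is made to make the model behave
  under them: with those settings it is, demonstrably, nearly inert.
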
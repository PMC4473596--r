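---
title: "Complex pattern learning in memristive recurrent networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complex pattern learning in memristive recurrent networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memforce)
```

`memforce` simulates a neuromorphic learning system in which a recurrent
firing-rate network, whose signed synaptic weights are physically realised
by pairs of iron-oxide memristors, learns to generate spatiotemporal
patterns by online recursive least squares (the FORCE scheme). This
vignette explains each layer of the model, the parameters that matter,
the numerical choices, and what the synthetic benchmarks do and do not
demonstrate.

## The device model

A memristor is represented by a bounded conductance $G \in
[G_{\min}, G_{\max}]$ with a programming threshold $V_{th}$: voltages
below the threshold (reads, default 0.1 V) never move the state, while
supra-threshold pulses move it by a fixed fraction of the remaining
headroom,

$$G \leftarrow G + \eta_{pot}(G_{\max} - G) \quad (\text{LTP pulse}), \qquad
  G \leftarrow G - \eta_{dep}(G - G_{\min}) \quad (\text{LTD pulse}).$$

This bounded-geometric ("soft saturation") update is the simplest form
consistent with measured LTP/LTD staircases: per-pulse steps shrink as the
state approaches either rail, and $n$ identical pulses have the closed
form $G_n = G_{\max} - (G_{\max} - G_0)(1-\eta)^n$. The defaults are
$G_{\min} = 1.5$ mS, $G_{\max} = 4.5$ mS (a resistance ratio of 3),
$\eta_{pot} = \eta_{dep} = 0.18$, chosen so that a standard 15-pulse train
traverses about 95% of the window, matching the measured staircase shape.
$V_{th} = 0.8$ V sits strictly between the 0.1 V read and the 1.6 V write
amplitude; only this ordering matters to the simulation. Pulse width is
carried for bookkeeping but does not affect the update (devices are
programmed at fixed width). `calibrate_from_trace()` refits
$\eta_{pot}, \eta_{dep}$ to a measured staircase by profiled nonlinear
least squares on the headroom decay; with a noiseless model trace it
recovers the rates to $10^{-6}$, and under 1% multiplicative read noise a
31-point trace pins them to about $\pm 0.02$ on average — the
information limit of such a short trace; individual fits can be off by
several hundredths.

Fine programming uses a *differential pulse pair* — one potentiating and
one depressing pulse of unequal effect — whose net action is a fixed
resistance step $\Delta R = 0.6\ \Omega$. At the low-resistance state
($1/G_{\max} \approx 222\ \Omega$) this is a relative step of about
0.27%, below the 0.3% precision budget. The conversion to conductance is
exact, not linearised.

## The differential synapse and crossbar

Two memristors and an inverting amplifier with feedback resistance
$R_f = 330\ \Omega$ form one synapse with effective weight

$$w = -R_f (G_1 - G_2),$$

spanning $[-0.99, +0.99]$ for the default window even though the device
on/off ratio is only 3; the joint conductance $G_1 - G_2$ spans
$[-3, 3]$ mS. The printed formula (with its leading minus sign) is
followed throughout; the prose description of the device roles implies an
additional downstream inversion, and the formula is taken as
authoritative.

Programming follows the four-case scheme: to increase $w$, depress device
1 *or* potentiate device 2; to decrease it, the converse. Exactly one
device changes per modulation stage, which makes the modulation path
unique; the implementation picks the device with more headroom in the
required direction and breaks exact ties toward device 2 (an arbitrary
but fixed rule). `program_to_target()` is a write-verify loop: coarse
full pulses while the weight error exceeds 5% of the full range, then
fine pulse pairs as long as a step still reduces the error. Three
refinements push the residual far below a single fine step: (i) when
the planned device's step overshoots, the complementary device — whose
step size differs with its conductance state — is tried in the next
modulation stage; (ii) when neither single step improves, same-polarity
pairs on *both* devices (two stages) net to the *difference* of the two
step sizes, a much finer increment; (iii) when both devices have
ratcheted into the high-conductance half, the pair is erased toward the
floor and re-programmed (the array is isolated during modulation, so
the transient excursion is unseen), keeping the pair at the
high-resistance end where steps are finest. Together with the canonical
low-conductance weight mapping of `crossbar_from_weights()` this keeps
the one-shot write residual a small fraction of a single fine step,
well inside the default 0.3% tolerance the test suite asserts. The 5% coarse band is an
engineering choice: wide enough that a coarse pulse never overshoots
out of it, narrow enough that fine stepping converges in tens of pairs.
The crossbar enforces the two-stage contract (`processing` vs
`modulation`) and half-select locality: programming one synapse never
perturbs any other, which the test suite checks bit-wise.

## Network dynamics

The rate network integrates the classical leaky equations

$$\tau \dot{x} = -x + g\, W^{NN} r + W^{NI} I(t), \qquad r = \tanh(x),
 \qquad z = W^{ZN} r,$$

by forward Euler — deliberately, since the hardware counterpart solves
the same difference equation with an accumulator. Defaults: $N = 500$,
$g = 1.5$ (chaotic regime, the substrate FORCE needs), $\tau = 10$ ms,
$dt = 1$ ms, full connectivity. Internal weights start i.i.d. Gaussian
with variance $1/(p\,N)$ (spectral radius $\approx 1$, so $g$ alone sets
the regime), inputs uniform on $[-1,1]$, readouts Gaussian with s.d.
$1/\sqrt N$. Sparse connectivity ($p < 1$) applies a fixed Bernoulli
mask; masked synapses stay exactly zero through training.

## RLS / FORCE learning

The readout error $e(t) = z(t) - f(t)$ drives rank-one recursive
least-squares updates with a single shared inverse-correlation matrix
$P$, initialised to $I/\alpha$:

$$P \leftarrow P - \frac{(P r)(P r)^\top}{1 + r^\top P r}, \qquad
  \Delta w = -e \,(P r).$$

The update order within a step is integrate, read out, error, $P$
update, weight update (the standard FORCE ordering). $P$ is maintained
in its upper triangle with symmetric BLAS rank-one updates, so symmetry
is exact by construction; equivalence with the directly inverted
correlation matrix is verified to $10^{-8}$ in the tests.

**How internal rows share the scalar error.** The readout row receives
$-e\,(Pr)^\top$. For the internal matrix three modes are provided. The
default, `feedback`, scales row $i$ by a fixed random factor
$u_i \sim U(-1,1)$: $\Delta W^{NN}_{ij} = -u_i e (Pr)_j$. This is the
absorbed-feedback construction — it is exactly what the internal matrix
accumulates when a conventional feedback loop $u\,z(t)$ is folded into
the recurrent weights — and it entrains the chaotic substrate reliably.
The `identical` mode (every row the same increment) was tried first and
rejected: a uniform row increment only drives the network's common
mode, leaving the chaotic fluctuations unsuppressed. For multi-channel targets the `partition` mode splits the $N$
neurons evenly across channels and drives each subset's rows with its own
channel error; it is the default for the motor task.

`update_every = 1` (weights modified at every time step) is the default
throughout. The experiment drivers default to $\alpha = 10$: with true
per-step crossbar programming the weights can only move on the fine-step
grid, and a damped RLS gain keeps that granularity from dominating the
updates; the dual-pattern experiment runs at $\alpha = 1$ (its
configuration) and converges comfortably there in offline mode. Both are
plain config entries.

**Online training through the crossbar.** In online mode every weight
lives on the crossbar: each step the RLS increments are accumulated on
*continuous target registers* and every synapse is programmed toward its
register value (coarse/fine write-verify at 0.3% tolerance), while the
network dynamics always run on the realised, quantised weights. The
target registers matter: if increments were applied directly to the
quantised weights, any update smaller than half a fine programming step
would be discarded, and the accumulated loss of sub-quantum corrections
stalls learning at a high error floor. Offline
mode runs the same loop on ideal weights and writes the crossbar once at
the end; both the continuous and the post-write network are reported so
quantisation cost is measurable (typically $< 0.05$ NRMSE on the
benchmark tasks).

Keeping the device in the loop has a price the test suite makes
visible: a one-shot write degrades the sinusoid benchmark only
marginally, but *training* through per-step quantised programming
leaves a realisation-dependent floor on the autonomous test error
(phase-aligned NRMSE varying by several-fold across seeds on the
sinusoid task) that ideal-weight training does not have. The granular weight
jumps act as ongoing state noise while the attractor is being carved,
and the resulting limit cycle is slightly detuned from seed to seed.
Damping the RLS gain (larger $\alpha$) helps; eliminating the gap
entirely would require modulating weights continuously, i.e. removing
the device from the loop.

## Benchmark fixtures and the choice of time scales

The generators supply: a unit-amplitude sinusoid; a four-component
harmonic composite (amplitudes 1, 0.5, 0.25, 0.125); a dual-pattern task
(two composites of 5 and 10 Hz with swapped amplitude ratios
1.0/0.5 vs 0.5/1.0, interleaved in alternating two-period segments, each
tagged with one of two static random control vectors held through
training and test); and a synthetic 62-channel motor trajectory
(> 1000 frames, per-joint low-order Fourier series over a common base
frequency plus a shared smooth "jump" envelope).

The experiment fixtures place the target period at 10–20 membrane time
constants (10 Hz sinusoid, 5/10/15/20 Hz composites at $\tau = 10$ ms).
This is the regime of the rate-network pattern-generation literature, and
it matters: we initially used 1 Hz targets (period $100\tau$) and found
the learned solution is then a fine-tuned slow mode so fragile that a
single crossbar write at 0.3% precision destroys the pattern, and *any*
dispersion level fails — inconsistent with the robustness this system
class demonstrably has. A network holds a learned limit cycle robustly
only when the cycle's period is within an order of magnitude of its
intrinsic timescale; the fixtures respect that.

Training defaults are 200 pattern periods with 20 test periods for the
scalar tasks; convergence on the fixtures is reached well within this.
The dual task trains online (the headline scheme) on 8 interleaved
segment pairs and is tested per pattern after one settling period over
a 2-period window — about the span over which reproduction of such a
pattern is judged; the
phase-*aligned* NRMSE (minimum over circular shifts up to one period,
computed per channel via FFT cross-correlation) tolerates the constant
phase offsets this system exhibits, while slow frequency drift still
accumulates error. A pattern counts as "reproduced" below 0.5
phase-aligned NRMSE; both thresholds are configurable.

## Device-variation sweep

`variation_sweep()` multiplies every trained weight by independent
$U(1-d,\,1+d)$ factors ("weight dispersion", modelling device-to-device
and cycle-to-cycle variation), re-tests both patterns of the dual task
under their control inputs, and reports success fractions over 10 random
trials per level at $d \in \{6, 12, 16\}\%$. A Gaussian dispersion
option exists but is off by default. The sweep sits near a bifurcation
by design — small dispersion leaves both attractors intact, large
dispersion collapses the network back toward chaos — so per-seed
success fractions at the intermediate and high levels are genuinely
stochastic; the summary reports the largest level at which both patterns
survive the majority of trials and the smallest at which neither does.

## The motor task

62 readout channels (one per joint angle), $N = 800$, partitioned row
updates, ideal-weight training over 20 repetitions of the > 1000-frame
trajectory, then a frozen two-repetition test scored per channel by
phase-aligned NRMSE. The synthetic trajectory emulates the scale and
smoothness of a motion-capture take (order-one normalised joint angles,
bounded per-frame increments) but not its kinematic structure — no
skeleton constraints, no contact events — so success here demonstrates
capacity and the partitioned multi-readout mechanism, not biomechanics.
An AMC-format reader (`read_amc()`) lets a real capture file replace the
synthetic trajectory.

## Numerical choices and degenerate inputs

* Programming loops carry a 10,000-stage safety bound; exceeding it (or
  targeting an unrepresentable weight) raises a classed error rather than
  looping.
* The RLS denominator $1 + r^\top P r$ is checked positive; divergence of
  the network state (non-finite $x$) aborts with the step index.
* Sub-threshold pulses, zero-length runs, zero training steps, constant
  calibration traces, constant NRMSE targets and stage violations are all
  explicit, tested edge cases.
* All randomness flows through R's RNG: every generator and experiment is
  a pure function of its parameters and the seed.

## Known limitations

* The device model is behavioural: no retention/drift, no electrothermal
  filament physics, no AC characteristics, no pulse-width dependence.
* The crossbar ignores sneak paths, IR drop, amplifier saturation and
  ADC/DAC quantisation of the signals (weight quantisation *is*
  modelled).
* Sparse mode keeps the single shared $N \times N$ inverse-correlation
  matrix with mask-projected increments; a per-neuron reduced-$P$
  formulation would be cheaper in hardware but is not implemented.
* Robustness conclusions from the dispersion sweep are statements about
  this network-and-fixture ensemble, not about any specific physical
  die.
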
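---
title: "Dynamic Boltzmann machines: model, learning rule and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic Boltzmann machines: model, learning rule and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dybm)
```

## The model

A dynamic Boltzmann machine (DyBM) extends the Boltzmann machine from
static patterns to sequences.  `N` binary neurons evolve in discrete
time; the energy of the configuration at time `t` depends on the past
only through a finite summary held in the network itself:

* **FIFO queues.**  Every ordered pair `(i, j)` of neurons — self-pairs
  included — carries a conduction delay `d[i, j] >= 1`; a spike of `i`
  reaches `j` after exactly `d[i, j]` steps, the intervening values
  waiting in a queue of length `d[i, j] - 1`.  Because all queues leaving
  a neuron hold the same recent values, the implementation stores one
  history buffer per neuron; `queue_contents()` exposes the per-synapse
  view.
* **Eligibility traces.**  Neuron `j` keeps `L` neural traces
  `gamma[j, l]`, geometric sums of its own past spikes with decay
  `mu_l`; synapse `(i, j)` keeps `K` synaptic traces `alpha[i, j, k]`,
  geometric sums (decay `lambda_k`) of the spikes that have *already
  arrived* through the queue.  The queued-spike summary `beta[i, j, l]`
  is computed on demand from the queue.

Conditional on the history, neurons are independent, with the per-neuron
energy linear in the candidate value (see `?energy_neuron`): a bias term,
an LTP term coupling `u[i, j, k]` to `alpha`, an LTD term coupling
`v[i, j, l]` to the queued spikes `beta`, and a reverse LTD term coupling
`v[j, i, l]` to the post-synaptic neuron's own trace `gamma[i, l]`.  The
spike probability is the logistic function of the energy gap divided by
the temperature `tau`.

## Trace conventions

The recursions performed by `advance_state()` define the traces exactly;
the package fixes the following conventions, and property tests hold the
recursions to the corresponding closed-form sums:

* `gamma[j, l]` after history `x^[1..t]` equals
  `sum_s mu_l^(t+1-s) x_j^[s]` — the most recent spike carries weight
  `mu_l`, via `gamma <- mu_l * (gamma + x_j)`.
* `alpha[i, j, k]` equals `sum_{s <= t+1-d} lambda_k^(t+2-d-s) x_i^[s]`
  — the most recent *arrival* carries weight `lambda_k`, via
  `alpha <- lambda_k * (alpha + arriving)` with the arriving value read
  from the queue head before the push.
* `beta[i, j, l]` weighs a queued spike emitted `p` steps ago by
  `mu_l^(d - p)` — i.e. by `mu_l` to the power of the number of steps
  until it arrives.  Spikes closer to the queue head therefore weigh
  more, and all weights are bounded by `mu_l`.  An alternative reading
  weights by `mu_l^(-p)`; we rejected it because those weights reach
  `mu^(1-d)` (about 6.5e4 at `mu = 0.25`, `d = 9`), which makes the
  energy of a freshly initialised model explode and training diverge —
  incompatible with the model being trainable under the standard
  initialisation.  The qualitative ordering (head-proximal spikes weigh
  more) is asserted as a regression test.

## Learning rule

Presenting `x^[t]` updates every parameter by the *exact* gradient of the
one-step conditional log-likelihood at `tau = 1` (verified against
central finite differences on randomised instances, relative error at
most `1e-5`): `d b_j = x_j - <X_j>`, `d u[i,j,k] = (x_j - <X_j>)
alpha[i,j,k]`, and `d v[i,j,l]` splits into a queued-spike component
`(<X_j> - x_j) beta[i,j,l]` and a reverse component `(<X_i> - x_i)
gamma[j,l]`.  The expectation subtraction acts as homeostatic
plasticity: training a bias-only model on an i.i.d. Bernoulli stream
drives its spike probability to the stream's rate (tested at rates 0.1,
0.5 and 0.9 within ±0.02).  Every component reads only quantities
available at its own synapse or neuron, which a locality test enforces.

Rates are per-parameter AdaGrad with base rate `eta0 = 1`: an update with
gradient `g` adds `g^2` to that parameter's accumulator and steps by
`eta0 * g / sqrt(epsilon + accumulator)`, the accumulator *including*
`g`.  Including the current gradient bounds every step by `eta0`; the
variant that excludes it makes the step after a near-zero first gradient
arbitrarily large (a gradient of `1e-3` followed by one of `0.3` yields a
step of about 300) and demonstrably diverges, so it was rejected.
`epsilon` (default `1e-12`) only guards the division.  The two LTD
components keep independent accumulators and apply sequentially, and all
gradient components of one step are computed from the same pre-update
parameters before any of them is applied.

## Default parameters

| parameter | default | meaning |
|---|---|---|
| delays `d[i, j]` | i.i.d. uniform integers 1..9 | conduction delay, in time steps |
| `K`, `lambda` | 3; 0.25, 0.5, 0.75 | synaptic trace count and decays per step |
| `L`, `mu` | 3; 0.25, 0.5, 0.75 | neural trace count and decays per step |
| initial `b, u, v` | i.i.d. Normal(0, 0.1) | pre-training parameters |
| `eta0` | 1 | AdaGrad base rate |
| `tau` (training) | 1 | temperature during learning |
| `check_every` | 10 periods | cadence of convergence / retrieval checks |
| `max_periods` | 130,000 | training budget per memorisation run |

The spread of decay rates approximates slow hyperbolic forgetting with a
small bank of geometric traces; the delay range 1..9 is short relative
to the 35-step period, so memorising a sequence requires genuine
interaction of queues and traces rather than a delay line covering the
period.

Generation uses the deterministic zero-temperature limit: a neuron emits
1 iff its spike probability exceeds 0.5 *strictly* (an exact tie emits
0), and the emitted vector feeds back into the traces and queues.
`sample_step()` provides finite-temperature sampling instead.

## Protocols

**Memorisation** (`dybm()`, `train_until_memorized()`): one period of the
target per training period; at period 0 and every `check_every` periods a
clone of the live state generates two periods deterministically, and
training stops at the first bit-exact reproduction.  The traces are not
refreshed for the check, so the presented history itself cues the
generation; the comparison is aligned to the phase after the last
presented step.  Budget exhaustion returns `converged = FALSE` rather
than an error.

**Cue-based retrieval** (`retrieve_with_cue()`): traces and queues are
zeroed (equivalent to a long blank presentation), the cue is presented
without learning, and the continuation is generated deterministically.
For the 35-column sequences the standard cues span 25 columns
("SCIEN", and the mirrored "IENCE" for the reversed sequence), long
enough that the trace transient from the zeroed start is negligible.
For much shorter toy periods this transient matters: a cue spanning a
single short period can leave the traces far from the periodic orbit and
retrieval may fail even though the orbit is stored, which is why the toy
tests use cues spanning two periods.

**Dual-sequence alternation** (`train_alternating()`): odd iterations
train the forward sequence, even iterations the mirrored one, each until
its cue retrieves it exactly (checked before the first period and every
`check_every` periods); the run ends when both cues retrieve their
sequences at the end of an iteration.  Per-iteration period counts are
returned — the relearning-speed curve.  We deliberately check at the
default cadence of 10 periods rather than every period: stopping an
iteration at the earliest transient moment of exact retrieval leaves the
sequence under-trained and empirically prevents the alternation from
ever stabilising, while the small overshoot from coarser checking does
not.  Early iterations overwrite the other sequence — after iteration 1
the reverse cue fails — and convergence of the full-scale 35-column pair
is a long run (checkpointing via `write_dybm()`/`read_dybm()` supports
resuming it); the desk-scale experiments use the 15-column "SCI" pair.

**Anomaly scoring** (`nll_profile()`): each step is scored by
`-log P(x_t | past)` at `tau = 1` before the state advances with the
observed vector; no learning occurs.  The scored stream continues from
the live post-training state, as the caller chooses via `initial_state`.
Peaks mark patterns the model finds surprising.  Note that with delays
up to 9 the columns immediately *after* an anomalous glyph also carry
anomalous context, so for some seeds the profile's global peak falls a
few columns after the glyph itself; the anomalous columns still separate
from ordinary ones by an order of magnitude.

## The bitmap fixtures

Experimental inputs are regenerated from code: a packaged 5x7 block font
(S, C, I, E, N) rendered column-wise, so "SCIENCE" is a 35-step sequence
over 7 neurons, with its mirror image and the anomalous
"SCIENSESCIENCE" (the second "C" of the first word replaced by "S")
derived from it.  The font file is fixture data with two frozen
properties the experiments rely on: the five letters are distinct
bitmaps, and "I" is left-right symmetric.  The original experiments'
exact glyph shapes are not tabulated anywhere, so all bit-level
expectations in this package are defined relative to the packaged font;
sequences from a different font will reproduce the phenomena but not the
same period counts.  These fixtures emulate clean, noiseless, strictly
periodic binary data — they say nothing about robustness to noisy or
aperiodic spike trains, which the model as implemented does not address.

## Numerical choices and degenerate inputs

* Spike probabilities and log-likelihoods are evaluated in logistic /
  log1p form; energies of magnitude `1e4` produce exact 0/1
  probabilities rather than overflow.
* `d[i, j] = 1` means an empty queue: `beta` is identically zero and the
  arriving value is the immediately preceding `x_i`, with no special
  casing anywhere in the API.
* A decay rate of 0 is allowed (traces remember only the newest value;
  queued-spike weights are treated as zero).
* States are values: probability and likelihood evaluation never mutate,
  only `advance_state()` and generation do; the compiled batch loops are
  held equal to the composed R single steps by a consistency test.
* Oracle tolerances: traces against their defining sums at `1e-10`;
  energies against a term-by-term transcription at `1e-12`; gradients
  against finite differences at `1e-5` relative.
* Checkpoints serialise at 17 significant digits, which round-trips
  doubles bit-exactly.

## Problem sizes

The test suite and the acceptance script run entirely at desk scale: the
7-neuron, 35-column memorisation over five seeds (budget 130,000 periods
each, typically converging within a few thousand), the anomaly profile
over 70 columns, the 15-column dual-sequence alternation over five
seeds, and randomised property checks on 2–5 neuron instances with
histories up to 50 steps.  The full-scale dual-sequence alternation of
the 35-column pair — millions of iterations in the original experiment —
is supported through checkpointed long runs but is not part of the test
suite.

## Known limitations

* All neurons are visible; there are no hidden units, real-valued
  inputs, or joint (non-factorised) sampling.
* Deterministic generation can enter limit cycles other than the target
  from states off the training trajectory; retrieval is only guaranteed
  in the sense tested — exact continuation after a sufficiently long
  cue once the alternation protocol has converged.
* Convergence of the alternating protocol is seed-dependent; a minority
  of seeds may stall in an iteration whose cue-conditioned trajectory
  never aligns bit-exactly within the period budget.
* The per-parameter AdaGrad rate decays monotonically, so very long runs
  become increasingly conservative; no rate restarts are provided.
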
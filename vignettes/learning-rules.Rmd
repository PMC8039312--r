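---
title: "Hebbian and spatiotemporal learning rules: model, parameters, and measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hebbian and spatiotemporal learning rules: model, parameters, and measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stlrsim)
```

## The scientific question

Memory systems face two contradictory demands when similar episodes arrive
in sequence: *pattern completion* (map similar inputs onto one common
representation) and *pattern discrimination* (keep similar inputs apart).
`stlrsim` simulates a single-layer feed-forward network of binary threshold
neurons trained under two synaptic plasticity rules that embody these two
demands:

* the **Hebbian rule (HEBLR)** — a synapse from an active input onto a
  *firing* output neuron is potentiated by a fixed increment; if the output
  neuron does not fire, nothing happens;
* the **spatiotemporal learning rule (STLR)** — plasticity is decided
  *without reference to postsynaptic firing*, by a coincidence coefficient
  measuring how strongly each active input cooperates with the other
  coactive inputs converging on the same neuron, compared against two
  thresholds in a BCM-like arrangement (high coincidence: LTP; low: LTD;
  intermediate: no change).

The package's central claim, checked by its test suite, is distributional:
after a short training protocol on similar context sequences, HEBLR produces
a two-peak weight distribution that is insensitive to temporal context,
while STLR produces two dominant peaks (potentiated and depressed subsets)
for a repeated context and a multimodal distribution — one enhancement
cluster per distinct input — for a time-varying context.

## Model

Each of $N$ output neurons $i$ receives all $N$ binary inputs $x_j \in
\{0,1\}$ through real-valued weights $w_{ij}$:

$$ s_i = \sum_{j=1}^{N} w_{ij}\, x_j, \qquad
   y_i = F(s_i - \eta), \qquad
   F(u) = \begin{cases} 1 & u \ge 0 \\ 0 & u < 0.\end{cases} $$

The boundary fires: $s_i = \eta$ gives $y_i = 1$. Dynamics are synchronous —
within a time step all $s_i$ are computed from the same pre-update weights,
then all weight updates are applied at once.

**HEBLR.** If $s_i \ge \eta$ and $x_j = 1$ then
$w_{ij} \leftarrow w_{ij} + \delta w$; otherwise $w_{ij}$ is unchanged.
The per-neuron total change in one step is therefore the closed form
$\Delta W_i = y_i\,(\sum_j x_j)\,\delta w$, an identity the tests verify
against the update itself.

**STLR.** The coincidence coefficient of an active synapse is

$$ I_{ij} = w_{ij} x_j \sum_{m \ne j} w_{im} x_m
   \quad \text{("exact" form)}, $$

and, because $s_i$ dominates any single synaptic drive when the network is
large and input activity is not sparse,

$$ I_{ij} \approx \frac{w_{ij} x_j}{s_i} \quad \text{("approximate" form,
   the default).} $$

The update is

$$ w_{ij} \leftarrow \begin{cases}
   w_{ij} + \delta w & I_{ij} \ge \theta_1 \quad (\text{enhancement})\\
   w_{ij}            & \theta_1 > I_{ij} > \theta_2 \quad (\text{invariance})\\
   w_{ij} - \delta w & I_{ij} \le \theta_2 \quad (\text{attenuation}),
   \end{cases} $$

applied only where $x_j = 1$. Weights are *not* clipped at zero: repeated
attenuation drives them negative, and the negative-region peak of the
trained distribution is part of the rule's signature.

**Unit-sphere geometry.** To compare weight configurations at different
scales the package projects each weight row and the input onto the unit
sphere: $\tilde w_{ij} = w_{ij}/\lVert W_i\rVert$,
$\tilde x_j = x_j/\lVert X\rVert$,
$\tilde s_i = \sum_j \tilde w_{ij}\tilde x_j \in [0,1]$ for nonnegative
weights, and $\tilde I_{ij} = \tilde w_{ij}\,\tilde s_i$ — a straight line
through the origin with slope $\tilde s_i$ in the
$(\tilde w, \tilde I)$ plane. Neurons fall into regions by their slope:
$R_1$ ($\tilde s_i \ge \tilde\theta_1$) can reach all three branches, $R_2$
($\tilde\theta_1 > \tilde s_i > \tilde\theta_2$) only invariance and
attenuation, $R_3$ ($\tilde s_i \le \tilde\theta_2$) only attenuation.
By default the STLR thresholds operate in this normalized space
(`normalized = TRUE`), where they are scale-free; thresholding the raw
$I_{ij}$ is available by configuration. Per-neuron branch fractions
$q_i + r_i + p_i = 1$ (enhancement/invariance/attenuation over active
synapses) are recorded at every step.

Normalization is an *analysis* transform only: training always updates the
raw weights, and no per-step weight renormalization is applied.

## Synthetic inputs

A study condition needs several input frames that are similar to a
controlled, *exact* degree. The generator builds $k$ binary vectors of
length $n$ with exactly `ones_count` ones and every pairwise Hamming
distance exactly `hd`, via a shared-core design: a random core of
`ones_count - hd/2` positions is set in all patterns, and each pattern gets
its own disjoint block of `hd/2` private ones. Any two patterns then differ
exactly in their two private blocks. With the defaults ($n = 120$, $k = 5$,
$hd = 10$, 60 ones) the overlap between any two patterns is 55 of 60 active
positions, i.e. an inter-pattern cosine of $55/60 \approx 0.917$ — similar
enough that discriminating them is nontrivial.

Sequences are five frames long: a *same-context* sequence repeats one
pattern five times; a *different-context* sequence presents the five
patterns in order (canonical mode), or four randomly chosen patterns
followed by a fixed final frame (randomized mode; sampling is without
replacement by default, and the fifth frame defaults to the fifth pattern
so that the canonical and randomized conditions end identically).

What the generator deliberately does **not** emulate: graded (rate-coded)
activity, input noise or jitter, correlated sparseness across frames, and
any temporal-history dependence in the inputs. Passing tests therefore
demonstrate the rules' behaviour under clean, exactly-calibrated similarity
structure, not robustness to noisy biological input.

## Parameters and defaults

| parameter | default | meaning and rationale |
|---|---|---|
| `n` | 120 | network size (inputs = outputs; rectangular allowed) |
| `ones_count` | 60 | active inputs per frame (half of `n`) |
| `hd` | 10 | exact pairwise Hamming distance between patterns |
| `t_len` | 5 | training frames; one weight update per frame, no epochs |
| `w_low`, `w_high` | 0, 1 | initial weights i.i.d. uniform; nonnegative start reflects excitatory feed-forward synapses |
| `dw` | 0.3 | learning increment. Five potentiation events move a synapse by 1.5, one and a half times the width of the initial distribution, so trained and untrained subsets separate cleanly after the 5-step protocol; at 0.05–0.2 the shifted and unshifted uniform blocks still overlap and merge into a single histogram mode |
| `eta` | `"auto"` | firing threshold; default = median internal state at the first frame (half the population fires initially), frozen for the run. A fixed absolute value may be supplied |
| `theta1`, `theta2` | `"auto"` | STLR thresholds; default = 60th/40th percentiles of the normalized coincidence coefficient over active synapses at the first frame, frozen thereafter (`theta_probs = c(0.4, 0.6)`) |
| `coincidence_form` | `"approximate"` | the operative form; `"exact"` available |
| `normalized` | `TRUE` | threshold in unit-sphere space |

On the threshold band: the 40th/60th percentile choice gives a 20%
invariance band at the first step. All three branches are populated, and the
invariance band is deliberately narrow: most active synapses commit to LTP
or LTD, which is what produces the two *dominant* positive/negative peaks
with only a small residual middle cluster in the repeated-context
condition. A wide band (e.g. 30th/70th) leaves a 40% invariance subset
whose members drain gradually into attenuation as row norms grow (their
$\tilde w_{ij}$, and hence $\tilde I_{ij}$, shrink below the frozen
$\tilde\theta_2$); the partially-trained remnants then form
mid-distribution clusters that can rival the fully-trained peaks. The
narrow band is robust: across several disjoint 20-seed windows and
$\delta w \in [0.25, 0.4]$ every grid condition shows its expected mode
structure in ≥ 95% of runs.

Thresholds are resolved **once**, at the first training frame, then frozen;
the resolved numeric values are echoed into the result configuration, and
re-running with those numbers reproduces the run bit-for-bit.

## Measuring the weight distribution

**Surface.** Histograms pool the raw weights of synapses from inputs that
are active at least once in the training sequence (`hist_active_only =
TRUE`, `hist_source = "raw"`). Synapses from never-active inputs cannot
change under either rule; including them (half of all synapses in the
same-context condition) adds a large flat untrained background that
obscures the trained structure. Raw units are used because the rules move
weights by exact multiples of $\delta w$, so subpopulations appear as
uniform blocks offset by $k\,\delta w$ — directly interpretable. Pooling
all synapses, and pooling row-normalized weights, remain available
(`hist_active_only = FALSE`, `hist_source = "normalized"`); on the
normalized surface the potentiated cluster converges to
$1/\sqrt{\texttt{ones\_count}}$, which always lies inside the untrained
rows' band, so modality is *not* well separated there — the reason raw is
the default.

**Mode counting.** "Bimodal" and "multimodal" are made machine-checkable by
a fixed procedure: 50 equal-width bins over the pooled range; centered
moving-average smoothing with a 5-bin window, treating counts outside the
histogram support as zero (the empirical density *is* zero there — without
zero padding, a uniform block touching the support boundary has no
detectable peak); local maxima (plateaus counted once); topographic
prominence of each maximum; keep peaks with prominence at least 10% of the
maximum smoothed count. The procedure is deterministic and invariant to
rescaling all counts. Its resolution limit: clusters closer than roughly
one smoothing window merge, and near-flat histograms with modest sample
counts can show an occasional spurious low-prominence mode — at the study's
pooled sizes (7,200–9,600 weights) the trained structures sit far above
this noise floor.

**Expected structure under the defaults.** With one update per frame:

* *HEBLR, same context* — winner rows' active synapses shift by
  $+5\delta w = +1.5$, everything else keeps its initial value: two uniform
  blocks with a clean gap → 2 modes.
* *HEBLR, different context* — the 55 core positions are active in every
  frame and shift by $+1.5$ for winners; each 5-position private block is
  active once and shifts by $+0.3$, slightly widening the untrained hump:
  still 2 modes, with the trained peak in the same place as the
  same-context run up to the $\delta w$ quantization — the Hebbian outcome
  is context-insensitive.
* *STLR, same context* — enhancement and attenuation subsets shift to
  $\approx +1.5$ and $\approx -1.5$; the small invariance remainder stays
  near its initial values: two dominant peaks flanking zero, plus a small
  middle cluster.
* *STLR, different context* — core synapses accumulate up to $\pm 1.5$
  while each private block is trained once ($\pm 0.3$): enhancement
  clusters appear at several distinct offsets, one per distinct input
  pattern → at least 3 modes.

## Completion versus discrimination

The functional contrast is measured by a paired design: for each rule, five
replicate networks with *shared* initial weights are trained on the five
same-context sequences (one per pattern), and each trained network's binary
output for its own training pattern is recorded. Completion predicts nearly
identical outputs across replicates; discrimination predicts distinct ones.
The statistic is the mean pairwise Hamming distance among the five outputs.

Readout uses the population-median convention applied to the *trained*
state: each network's readout threshold is the median of its final internal
states, so half of its neurons fire. This choice matters. A threshold
frozen at the initial median measures mostly overall excitability drift:
STLR shifts the entire drive distribution (every neuron both potentiates
and depresses synapses), while HEBLR leaves non-winners exactly at their
initial drive, parking half the population on the threshold boundary where
pattern-to-pattern noise dominates the distance. Equalizing excitability at
readout makes the pairwise distances comparable across rules, and the
expected ordering — STLR separates similar sequences more than HEBLR — then
holds in 15–20 of 20 paired runs across every seed window examined
(one-sided sign test, $p < 0.05$).

## Numerical conventions and degenerate inputs

* Branch boundaries are inclusive outward: $I \ge \theta_1$ enhances,
  $I \le \theta_2$ attenuates; $s \ge \eta$ fires; $\tilde s \ge
  \tilde\theta_1$ is $R_1$, $\tilde s \le \tilde\theta_2$ is $R_3$.
* Approximate coincidence with $s_i = 0$ (no drive): the row is defined as
  all zeros and a warning is issued — unreachable with positive initial
  weights and at least one active input, but the function is total.
  Zero-norm weight rows in normalized space are handled the same way.
* Neurons with no active synapse get `NA` branch fractions rather than a
  silent 0/0.
* Infeasible pattern-set parameters (odd `hd`, or core plus $k$ disjoint
  blocks exceeding $n$) raise explicit errors; constraints are never
  silently relaxed.
* Every random choice derives from the configuration seed (patterns:
  `seed`; initial weights: `seed + 1`; randomized sequences: `seed + 2`);
  identical configurations reproduce results byte-identically, and there is
  no fallback to clock seeding.

## Problem sizes used by the tests

The distributional checks run the full 2×2 grid at the study condition
($N = 120$, 5 steps) over 20 seeds, and the discrimination experiment over
20 paired seeds — about seven seconds in total. Loop-oracle equivalence
uses 200 random 8×8 instances, where exhaustive per-synapse reference
implementations are practical. Pattern-set exactness is asserted over 100
seeds.

## Known limitations

* The STLR here omits any temporal-history factor: plasticity at step $t$
  depends only on the current frame and weights. Context sensitivity
  arises purely from *which* synapses each frame trains.
* Mode counts depend on the documented histogram/smoothing parameters;
  they are a measurement procedure, not an intrinsic property of the
  weight matrix. Conclusions are stated at the default procedure.
* The auto thresholds are data-scaled percentile conventions chosen to
  realize the intended operating regime (half the population firing; a
  narrow invariance band); the model gives no unique first-principles
  values for $\eta$, $\theta_1$, $\theta_2$ or $\delta w$, and all can be
  overridden as absolute numbers.
* Exact histogram shapes vary with the seed; only the mode structure and
  the paired discrimination ordering are claimed, and those are asserted
  as rates over seed ensembles, not per-seed certainties.
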
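# stlrsim

Simulation of two biologically grounded synaptic plasticity rules — the
classical **Hebbian learning rule (HEBLR)** and the **spatiotemporal
learning rule (STLR)** — in a single-layer feed-forward network of binary
threshold neurons, trained on similar spatiotemporal context sequences.
The package is for computational neuroscientists studying how a learning
rule's *self-organization mechanism* shapes the trained synaptic weight
distribution, and in particular how the two rules realize the opposing
memory functions of **pattern completion** (HEBLR) and **pattern
discrimination** (STLR).

## The model

Output neuron *i* integrates binary inputs through real-valued weights and
fires by a hard threshold:

    s_i = Σ_j w_ij x_j ,   y_i = F(s_i − η),   F(u) = 1 if u ≥ 0 else 0.

**HEBLR** potentiates active-input synapses of firing neurons:

    w_ij ← w_ij + δw   if s_i ≥ η and x_j = 1.

**STLR** modifies active-input synapses independently of postsynaptic
firing, by a coincidence coefficient I_ij = w_ij x_j / s_i (the cooperative
drive meeting input *j* at neuron *i*) against two thresholds, BCM-style:

    w_ij ← w_ij + δw   if I_ij ≥ θ1        (enhancement / LTP)
    w_ij ← w_ij        if θ1 > I_ij > θ2   (invariance)
    w_ij ← w_ij − δw   if I_ij ≤ θ2        (attenuation / LTD)

with no clipping at zero. By default the thresholds act in unit-sphere
normalized space (Ĩ_ij = w̃_ij·s̃_i). Training inputs are five-frame
sequences of binary patterns of length 120 with exactly 60 ones and exact
pairwise Hamming distance 10 (inter-pattern cosine 55/60 ≈ 0.917): a
*same-context* sequence repeats one pattern, a *different-context* sequence
presents five distinct similar patterns.

The headline result, asserted by the test suite: after five training steps
HEBLR yields a two-peak weight distribution in *both* contexts, while STLR
yields two dominant peaks flanking zero for the repeated context and a
multimodal distribution — one enhancement cluster per distinct input — for
the time-varying context; and STLR maps the five similar sequences to more
distinct outputs than HEBLR does.

## Worked example

```r
library(stlrsim)

ps <- generate_pattern_set(n = 120, k = 5, hd = 10, seed = 1)
ps
#> <pattern_set> 5 patterns of length 120, 60 ones each, pairwise Hamming distance 10
hamming_distance(ps$patterns[1, ], ps$patterns[2, ])
#> [1] 10
cosine_similarity(ps$patterns[1, ], ps$patterns[2, ])
#> [1] 0.9166667

g <- run_grid(experiment_config(seed = 1))
g
#> <experiment_grid>
#>   heblr_same: 2 final mode(s)
#>   stlr_same: 3 final mode(s)
#>   heblr_different: 2 final mode(s)
#>   stlr_different: 4 final mode(s)
g$stlr_different$modes_final
#> <mode_report> 4 mode(s) at -1.3, -0.18, 1.34, 2.06

d <- discrimination_experiment(experiment_config(seed = 1))
d$mean_distance
#> heblr  stlr
#>  13.6  19.2
```

Reading the output: the Hebbian runs end bimodal in both contexts (trained
winners vs untouched synapses — context-insensitive). The STLR same-context
run has two dominant peaks flanking zero (potentiated vs depressed
subsets) plus a small invariant remainder; the different-context run is
multimodal — synapses active in every frame sit near ±1.5 while each
pattern's private positions were trained once (±0.3), giving one cluster
per distinct input. The discrimination experiment trains five replicate
networks (shared initial weights) on the five same-context sequences: the
mean pairwise output Hamming distance is larger under STLR (19.2) than
under HEBLR (13.6) — discrimination vs completion.

`write_experiment_report()` serializes any run or grid to JSON/CSV/text
(`summary.json`, `histogram_t0.csv`, `histogram_tN.csv`, `modes.json`,
`qrp.csv`, `outputs.txt`, `patterns.txt`). A thin command-line driver with
subcommands `generate-patterns`, `run` and `grid` is installed at
`inst/cli/stlrsim.R` (`--seed` is mandatory; there is no clock seeding).

See the vignette (`vignettes/learning-rules.Rmd`) for the full model
description, the parameter defaults and their rationale, and the mode
detection procedure.

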
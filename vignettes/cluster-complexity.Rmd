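---
title: "Macroscopic cluster topology and the complexity of spiking activity: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Macroscopic cluster topology and the complexity of spiking activity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(clustnet)
```

`clustnet` simulates a two-level network — spiking neurons inside groups,
groups on a Watts–Strogatz (WS) scaffold — self-organizes it with STDP, and
quantifies how each group's position in the self-organized *synaptic
network* relates to the complexity of its activity. This vignette is the
package's account of the model, the conventions behind every analysis, the
reduced-scale presets, and what desk-scale runs can and cannot show.

## 1. The model

### Fundamental network

The macroscopic scaffold is an undirected graph on `n_groups` nodes built
by the WS procedure: a ring lattice where each node links to its `k/2`
nearest neighbours on both sides, followed by one pass over the edges in
which each edge, independently with probability `p_ws`, keeps its first
endpoint and moves the other to a uniformly drawn node. A draw that would
create a self-loop or duplicate edge is redrawn (a redraw may restore the
edge it just left — the procedure forbids only immediate collisions). Edge
count `n_groups * k / 2` is therefore invariant in `p_ws`, which is the
point of the WS construction: clustering and path length vary while the
connection budget does not. The fundamental network is undirected;
directionality exists only at the synapse level.

Node indices are 0-free: everything user-facing is 1-based.

### Neuron groups and synapses

Each group holds `n_exc` excitatory and `n_inh` inhibitory Izhikevich
neurons with the standard heterogeneous parameterization (excitatory:
`(a,b) = (0.02, 0.2)`, `c = -65 + 15 r^2`, `d = 8 - 6 r^2`; inhibitory:
`a = 0.02 + 0.08 r`, `b = 0.25 - 0.05 r`, `(c,d) = (-65, 2)`; `r` uniform
per neuron), initialized at `v = -65`, `u = b v`.

Wiring rules:

* every excitatory neuron → `c_intra` distinct neurons of its own group
  (either type, never itself); plastic, weight `w_init_exc`, integer delay
  uniform on `delay_intra_exc`;
* every inhibitory neuron → `c_intra` distinct *excitatory* neurons of its
  own group; fixed weight `w_init_inh < 0`, fixed delay `delay_intra_inh`,
  never plastic;
* for each fundamental edge, in both directions, every excitatory neuron
  of the source group → `c_inter` distinct neurons of the target group
  (either type); plastic, delay uniform on `delay_inter_exc`. Inhibitory
  neurons have no interconnections, and group pairs without a fundamental
  edge have none either, which pins the synaptic network's support to the
  fundamental edge set for the whole run.

Two readings of `c_inter` are possible ("per adjacent group" vs "total,
split across neighbours"); the package defaults to per-adjacent-group and
exposes `inter_per_neighbor = FALSE` for the split reading.

Delay ranges are sampled on integer milliseconds with a floor of 1 ms
(`{1..20}` intra, `{10..30}` inter): the simulation grid is 1 ms, and a
0 ms delay would make delivery instantaneous within a step.

### Integration and delivery

Time advances in 1 ms steps. `v` is integrated with two 0.5 ms forward
Euler half-steps, `u` with one 1 ms step; a neuron with `v >= 30` at the
end of a step emits a spike, is recorded at +30 (the value the LAP sees),
and is reset (`v <- c`, `u <- u + d`). A spike at `t` on a synapse with
delay `d` contributes its weight to the target's input current exactly at
`t + d`; input is the plain sum of arriving weights (current-based, no
synaptic kinetics). Non-finite state aborts with the neuron id and time.

### STDP

Plasticity is additive pair STDP with nearest-spike bookkeeping: each
neuron remembers its last spike time. When a spike *arrives* at a target
that fired `dt` ms earlier, the synapse's derivative decreases by
`a_minus * exp(-dt / tau)`; when a neuron fires, each plastic afferent
whose last spike *arrived* `dt` ms earlier gains `a_plus * exp(-dt / tau)`
(delays enter through arrival times, `dt = 0` counts in full on both
sides). Once per simulated second, for plastic synapses only,
`w <- clip(w + flush_bias + sd, 0, w_upper)` and `sd <- flush_decay * sd`.
Defaults `a_plus = 0.1`, `a_minus = 0.12`, `tau = 20` ms, bias `0.01`,
decay `0.9` follow the classic reference regime for this family of models;
all are configurable. With depression slightly dominant and a small
positive drift at the flush, weights bimodalize toward 0 and `w_upper`,
which is what makes structured, self-sustaining circuits emerge.

### Schedule and inputs

Three nested windows (all in seconds): STDP active on `[0, t_stdp)`, tonic
input on `[0, t_tonic)`, and the input-free remainder `[t_tonic, t_total)`
analyzed as spontaneous activity. The tonic input, which the model family
leaves essentially free, is one uniformly chosen neuron per group per
millisecond receiving a current pulse of 20 (configurable magnitude and
multiplicity); it is a sparse, stationary drive whose only role is to keep
the network active while STDP works.

RNG streams are separated by purpose (topology, heterogeneity, intra
wiring, inter wiring, input), each seeded deterministically from the
configuration seed, so changing e.g. the input seed leaves the frozen
wiring untouched.

## 2. Analyses

**LAP.** The per-millisecond mean membrane potential of a group's
excitatory neurons, with spike samples capped at +30 mV. It is recorded
during simulation (optionally from a start time, to bound memory).

**Multiscale entropy.** Sample entropy uses the asymmetric-range template
counts: `C_m` over the `N - m + 1` length-`m` templates normalised by
`(N-m+1)(N-m)`, `C_{m+1}` over the `N - m` longer ones, Chebyshev distance,
strict `< r`, self-matches excluded, `SampEn = -ln(C_{m+1}/C_m)`. A
consequence worth knowing: perfectly periodic signals give a small positive
value (of order `1/N`), not exactly 0, because the two template families
have different counts. Zero match counts return `NA` ("undefined"), never
an error. The tolerance is `r = 0.15` times the SD of the *raw* signal,
held fixed across scales (the standard convention; recomputing the SD per
scale would mix amplitude shrinkage into the entropy profile). Scale `eps`
coarse-grains by non-overlapping block means, dropping the trailing
partial block. The complexity index is the sum over the configured scales
(1–80 at full scale, 1–40 at desk scale). The production kernel sorts
template starts by first coordinate and compares only within-tolerance
windows; tests pin it to a literal `O(N^2)` double loop to `1e-12`.

**Spectra.** Mean-removed single-sided FFT amplitude spectra at 1 kHz,
scaled so a unit sinusoid peaks at 1. Band peaks take the maximum bin in
half-open bands (default 0–20, 20–40, 40–60 Hz), ties to the lower
frequency. The peak envelope interpolates linearly through local maxima,
endpoints anchored. Spectra use the full analysis window, untapered; for
noisy exploratory work a segment-averaging option would be the natural
extension, deliberately not defaulted.

**Graph metrics.** The synaptic network is the group-by-group matrix of
mean interconnection weights. Clustering is the total directed weighted
coefficient: with `What = (W / max W)^(1/3)`,
`C_i = [(What + What')^3]_ii / (2 (d_tot (d_tot - 1) - 2 d_bi))`, counting
all triangle orientations, normalised into `[0, 1]`; nodes whose
denominator vanishes are `NA`. Path lengths are BFS hop counts on the
binarised digraph (an edge wherever `W > 0`; the threshold is
configurable), averaged over reachable targets, with unreachable counts
reported — hops, not inverse-weight distances, because the quantity of
interest is "number of steps". Degree centrality defaults to the number of
distinct neighbours (in or out), which equals the fundamental degree
whenever every fundamental edge retains weight; in/out variants exist.
Intraconnection summaries are per-group means of plastic intra weights
split by target type (E→E vs E→I).

**Study statistics.** The study orchestrator sweeps `p_ws` with replicate
simulations, joins all per-group measures into a long table, and reports
Spearman rank correlations (per `p_ws` and pooled) between structural and
dynamical columns. The correlation is this package's quantitative surface
for relationships the underlying literature presents as scatter plots; it
is labelled as such, not attributed.

## 3. Reduced-scale presets and the weight-scaling law

Full scale (100 groups × 1000 neurons, 1200 s) is supported through
`desk_config("full")` but is not a workstation target. The `desk` preset
(30 groups × 100 neurons, `c_intra = 20`, 300 s total / 250 s STDP / 280 s
input, entropy scales 1–40) and `smoke` preset (10 × 50, 60 s) keep the
full model's structural ratios: 4:1 E:I, intra fan-out well below group
size, `k = 6`, `c_inter = 3`, nested schedule.

Downscaling cuts each neuron's expected synaptic fan-in (at desk scale,
excitatory afferents drop ~3.1×, inhibitory 5×). Keeping the full-scale
weights then quenches recurrent input so thoroughly that the network
cannot sustain any activity once the tonic input stops — the central
phenomenon (spontaneous activity in the self-organized network, none
without STDP) disappears, which defeats the preset's purpose. Scaling
weights proportionally to the fan-in reduction (mean-preserving, `w ∝ 1/K`)
overshoots in the opposite direction: input *fluctuations* grow as
`sqrt(K) w`, so the static, un-organized network already self-ignites and
the no-STDP control fails to be silent. The presets therefore use the
balanced-network convention, `w ∝ 1/sqrt(K)`: each afferent class's
weights (and the STDP amplitudes and flush bias, which live on the weight
scale) are multiplied by the square root of that class's fan-in reduction,
computed arithmetically in `fanin_weight_scale()`. This preserves the size
of input fluctuations — the quantity that governs ignition and sustainment
of recurrent firing — and empirically restores both regime facts at desk
scale: the self-organized network sustains spontaneous activity after
input-off, the non-plastic control goes silent.

## 4. Numerical choices and degenerate inputs

* Euler half-steps and the `v >= 30` grid test mirror the reference
  implementations of this model family; recorded potentials are capped at
  +30 so spike heights are uniform in the LAP.
* Weight flushes happen at the end of each simulated second within the
  STDP window; bounds `[0, w_upper]` are enforced at the flush (the
  simulator reports the extremes seen at every flush, so tests can assert
  the bound without snapshotting every second).
* Sample entropy: `NA` for zero matches; constant signals short-circuit to
  0 at every scale (their SD-based tolerance would be 0, which is
  invalid); series shorter than `max(scales) * (m + 2)` are rejected.
* Band-peak ties break to the lower frequency; bands are `[lo, hi)`.
* Spearman correlations with a constant column are reported `NA` with the
  pair's sample size, not dropped silently.
* Extreme-group selection breaks ties by group id, making the low/high
  sets deterministic and disjoint.
* The 1/f surrogate shapes white Gaussian noise in the frequency domain
  (amplitude `∝ f^(-1/2)`, folded symmetrically about Nyquist), then
  standardizes; its log–log spectral slope is checked near −1 in the
  tests.

## 5. What desk-scale runs show — and what they do not

The test suite and `scripts/acceptance.R` exercise the full pipeline at
desk scale with lattice (`p_ws = 0`) and random (`p_ws = 1`) topologies, a
handful of replicates each, sized to minutes on one CPU (the problem sizes
are stated in `desk_config()`). At that scale the package reproduces,
within each self-organized network, the headline structure–dynamics
relations as directions of rank correlations: complexity falls with degree
centrality, firing rates rise with degree and clustering, and the
complexity of a group tracks its intraconnection balance (positively with
mean E→E weight, negatively with E→I).

Two caveats delimit what this says about full-scale behaviour. First, the
*across-topology* contrast — mean complexity of all groups higher in the
random than in the lattice network — is weak at reduced scale: at 30 (and
in exploratory runs 60) groups the lattice-vs-random clustering contrast
is several-fold smaller than at 100 groups (a random graph with `k = 6` on
30 nodes still has clustering ≈ 0.2), within-network degree variance
dominates the complexity variance, and the mean shift does not separate
from replicate noise in either direction. The acceptance run reports both
means; they should be read as "not resolved at this scale", not as a
replication or refutation of the full-scale effect. Second, surrogate
signals validate the entropy and spectral stack (white vs 1/f orderings,
band peaks) but do not emulate LAP statistics; the simulator itself is the
only source of LAP-like data, so entropy values quoted for simulations
inherit all of the model's scale choices.

Other known limitations: no conductance-based synapses, no transmission
distances, no laminar structure, no scale-free or rich-club scaffolds; the
tonic input's form is a modelling choice the underlying model family never
pins down, and the inhibitory population's weights are static by
construction.
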
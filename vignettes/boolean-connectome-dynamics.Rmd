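---
title: "Windowed-threshold Boolean dynamics on brain connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed-threshold Boolean dynamics on brain connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolcortex)
```

## The model

A structural connectome is a weighted, undirected graph over parcellated
brain regions; here the 82-node Brodmann parcellation (41 cytoarchitectonic
areas x 2 hemispheres, areas 12-16, 31 and 33 absent), with connection
weights in [0, 1]. boolcortex treats this graph as the wiring of a Boolean
network: each region carries a binary activation state $s_i(t)$, and the
weighted matrix is first reduced to a 0/1 adjacency by a connection
threshold $x$ — an edge survives exactly when its weight is *strictly*
greater than $x$.

The update rule is a totalistic activation window. Writing
$\sigma_i(t) = \sum_j A_{ij} s_j(t)$ for the number of active neighbours of
region $i$ (the node's own state never contributes; the diagonal is zero),

$$s_i(t+1) = \begin{cases} 1 & a \le \sigma_i(t) \le b \\ 0 &
\text{otherwise,} \end{cases}$$

so a region fires next step when its neighbourhood is active enough to
excite it but not so active as to saturate it. Five update schemes order
these updates in time: CRBN (all nodes synchronously — the default and the
scheme used for all reference analyses), ARBN (one random node per step),
DARBN (node $i$ eligible when $q_i = t \bmod p_i$, eligible nodes updated
one by one in ascending index, each seeing in-step changes), GARBN ($g$
random nodes simultaneously) and DGARBN (DARBN eligibility, simultaneous
update). CRBN, DARBN and DGARBN are deterministic; ARBN and GARBN require a
seed and are reproducible from it.

Deterministic trajectories are characterised by their transient and period:
the dynamics are followed with every visited configuration hashed, and the
first revisit at times $(t_1, t_2)$ yields transient $t_1$ and period
$t_2 - t_1$. A run with no revisit within the horizon is classified
*chaotic*; a long cycle (period above 8 by default) is *complex*; a short
cycle is *ordered*. The interesting cognition-like behaviour lives in the
complex band between frozen order and chaos.

## Emergent circuits

After a simulation, regions that never change state over the analysis
window are removed (they carry no signal and make correlations undefined).
The remaining 0/1 time courses are correlated pairwise (Pearson). Given a
correlation threshold $z$, the circuit seeded at region $r$ is $r$ together
with every region whose correlation with $r$ exceeds $z$; candidates with
at least two members are kept and identical member sets are counted once.
Two members of one circuit need *not* correlate above $z$ with each other —
two strong pairs sharing a hub can merge into a three-area circuit whose
third leg is weak. This hub structure is a feature of the seeded rule, not
an artifact, and it is asserted in the test suite.

Circuit families are compared by the intersection ratio
$i_{rs} = |r \cap s| / n_r$, which equals 1 exactly when $r \subseteq s$;
by membership counts per area label; by proper-subset relations; and, for
stability analysis against a reference configuration, by exact member-set
matches, containments (a reference circuit surviving only inside a larger
candidate circuit — partial survival, deliberately not counted as a match)
and a Jaccard score over distinct member sets. Damage spreading — the
Hamming distance over time between a trajectory and a perturbed twin —
probes sensitivity to initial conditions.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| $x$ | connection threshold on weights | 0.9 | reference analyses use $x = 0.9$; below ~0.8 the 82-node graph is so dense that dynamics collapse immediately |
| $a, b$ | activation window (neighbour counts) | 1, 4 | the reference run; $a \ge 2$ mostly kills activity, large $b$ orders it |
| boundary | inclusive / strict window | inclusive | see below |
| $z$ | correlation threshold for circuits | 0.87 | reference value; lower $z$ merges circuits, higher $z$ dissolves them |
| steps | simulation length / recurrence horizon | 500 | standard run length; long enough for the reference transients |
| complex cutoff | ordered/complex period boundary | 8 | separates the short cycles (period $\le 8$) observed at wide windows from medium/high periodicity |

## Numerical and design choices

**Inclusive window by default.** The window rule is sometimes written with
strict inequalities $a < \sigma < b$, but a strict reading makes every
narrow window degenerate: with $a = b$ no $\sigma$ can fire at all, while
narrow-window regimes demonstrably exhibit non-trivial dynamics. The
package therefore defaults to $a \le \sigma \le b$ and exposes
`boundary = "strict"` as a flag; both modes are verified against the
exhaustive state-space oracle.

**Strict inequality at thresholds.** "Above the threshold" is read
strictly at both $x$ and $z$: a weight equal to $x$ gives no edge, a
correlation equal to $z$ gives no membership. The choice is arbitrary on a
measure-zero boundary but is fixed and documented so tests are exact.

**Row-ramp binarization.** The alternative thresholding that raises the
cutoff by 0.01 per row produces an asymmetric rule on an undirected graph.
`ramp_binarize()` symmetrises with AND by default (edge kept only if the
weight clears both endpoints' thresholds — conservative, keeps the graph
undirected); OR is available behind a flag. The global threshold is the
default pathway; the ramp is provided as an explicitly flagged variant.

**Weight synthesis.** Only the first two moments of the reference weight
distribution are known (mean 0.51, sd 0.288 on [0, 1]), so the generator
uses the maximum-structure-free choice: a Beta law with both shape
parameters solved from the moments ($\alpha \approx 1.03$,
$\beta \approx 0.99$ at the defaults — nearly uniform). A rejection-sampled
truncated normal is available; truncation shrinks its realised moments
slightly, which is why Beta is the default. Admissibility requires
$\mathrm{sd}^2 < \mathrm{mean}(1-\mathrm{mean})$.

**Signed correlation.** Circuit membership uses signed Pearson correlation
(membership requires $\mathrm{corr} > z > 0$), since the reference analyses
describe correlations on [0, 1]; whether anti-correlated pairs should ever
be grouped is unsettled, so an absolute-value mode exists behind
`mode = "absolute"` but is not the default.

**Correlation window.** The exact window behind the reference circuit
table is not recorded (full run vs post-transient only), so the window is a
first-class argument everywhere: `trajectory_circuits()` defaults to the
full trajectory and accepts any `(t_start, t_end)` span, e.g. the 250-500
post-transient segment or the 0-50 / 50-100 windows used to study circuit
emergence over time.

**Period detection.** Configurations are hashed as strings; for DARBN and
DGARBN the pair (configuration, $t \bmod \mathrm{lcm}(p)$) is hashed
because the configuration alone does not determine its successor under
phase-dependent eligibility. The default horizon is 500 steps with
recurrence tracking from step 0; `warm_start` lets the search begin after a
burn-in (reported transients stay absolute), since period tables can
equally be read as counting from the end of a 500-step transient.

**Empty windows in sweeps.** A period sweep over an $a \times b$ grid
includes cells with $b < a$. Such a window can never fire, so every state
maps to all-zero in one step; the sweep records these cells directly
(period 1, ordered) rather than constructing a degenerate rule, keeping
the full $7 \times 13 = 91$-cell grid shape of the canonical period table.

**A note on the weight-override reading.** The source material for the
reference configuration contains a remark that node weights were "set at
0.87". Setting all weights to one constant would make every binarization
trivial (complete or empty graph), contradicting the analyses that follow;
the package treats the remark as belonging to the threshold family
(x/z near 0.87-0.9) and implements no weight override.

**Circuit ordering.** Circuit sets are reported sorted by size ascending,
then lexicographically by member ids — the presentation order of the
reference table — and deduplicated by exact member set.

## What the synthetic generator does and does not emulate

`synthetic_connectome()` reproduces the *marginal weight distribution* of
the reference 82-node connectome (its mean and standard deviation, on
[0, 1]) with independent edge weights. It does not reproduce the topology
of a real tractography-derived connectome: no community structure,
small-world organisation, hemispheric symmetry, hubs, or
distance-dependent weight decay. Consequently, tests passing on synthetic
connectomes demonstrate that the *machinery* is correct (thresholding,
dynamics, period detection, circuit extraction, stability scoring), and
that regime structure qualitatively matches (dense graphs die; narrow
windows at $x = 0.9$ produce chaotic-to-complex behaviour; wide windows
order the dynamics). They do not reproduce the specific published
dynamical numbers — particular periods such as 199 or 48, or the identity
of the ten reference circuits — which depend on the exact unpublished
weight matrix. The ten-circuit reference configuration itself is therefore
shipped as a verbatim fixture (`reference_circuits()`) rather than
recomputed.

## Problem sizes used by the test suite

The suite exercises: exhaustive oracle equivalence on *all* labeled
connected graphs with 2-5 nodes (771 graphs), all $2^N$ initial states
each, both boundary modes, against a full state-graph-traversal oracle;
200 randomized instances per brute-force check (constant-node partition,
long-hand Pearson formula, subset relations); 10 replicates of the 82-node
generator for moment recovery; and 82-node, 150-500-step runs for
end-to-end reproducibility. These sizes were chosen to make the
combinatorial checks exhaustive where the state space allows it and
statistically tight elsewhere.

## Known limitations

* Probabilistic Boolean networks, arbitrary per-node truth tables, and
  continuous-state models are out of scope; the windowed threshold rule is
  the only update rule.
* Circuit extraction implements the seeded-grouping rule only — no
  community detection (modularity, Infomap) and no significance testing of
  correlations.
* The four-parameter stability map $(a, b, x, z)$ is explored cell by
  cell; no exhaustive characterisation of the full product space is
  attempted.
* Stochastic schemes (ARBN, GARBN) have no period notion here;
  `detect_period()` rejects them rather than reporting pseudo-periods.
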
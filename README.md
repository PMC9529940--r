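# boolcortex

Threshold Boolean network dynamics on brain connectomes.

## What this is for

How does coordinated activity between brain regions emerge from anatomical
wiring? boolcortex models a structural connectome — a weighted, undirected
graph over 82 Brodmann-parcellated regions — as a Boolean network: each
region carries a binary activation state, the weighted matrix is reduced to
a 0/1 adjacency by a connection threshold *x*, and states evolve by a
windowed threshold rule. Writing σᵢ(t) = Σⱼ Aᵢⱼ sⱼ(t) for the number of
active neighbours of region *i*,

    sᵢ(t+1) = 1  if a ≤ σᵢ(t) ≤ b,   else 0

under synchronous (CRBN) or asynchronous (ARBN, DARBN, GARBN, DGARBN)
update schemes. Deterministic trajectories are summarised by their
transient and period and classified as ordered, complex or chaotic.
Regions whose 0/1 time courses correlate above a threshold *z* are grouped
into emergent **brain circuits** (seeded at each region, deduplicated, with
hub-mediated unions allowed), and circuit families are compared across
parameter settings by intersection ratios i_rs = |r∩s|/n_r, subset
relations and stability reports against a reference configuration. The
package is aimed at computational neuroscientists and complex-systems
researchers studying how cognitive-circuit-like structure emerges from
connectome topology.

Shipped fixtures: the 82-node Brodmann label table (`brodmann_nodes()`),
the 16-region Action-Execution initial activation pattern
(`action_execution_state()`), and the ten-circuit reference configuration
extracted at a = 1, b = 4, x = 0.9, z = 0.87 (`reference_circuits()`).
Because the exact 82×82 weight matrix behind the reference analyses is not
publicly deposited, `synthetic_connectome()` generates surrogate matrices
matching its published weight statistics (mean 0.51, sd 0.288) with a
moment-matched Beta sampler.

## Worked example

```r
library(boolcortex)

s0  <- action_execution_state()          # 16 active regions
cn  <- synthetic_connectome(82, seed = 2, nodes = brodmann_nodes())
adj <- binarize(cn, 0.9)                 # edges where weight > 0.9

detect_period(s0, adj, threshold_rule(1, 4), horizon = 500)
#> <period_result> transient 68, period 29 (horizon 500)
# period 29 > 8, so classify_regime() calls this run "complex"

tr <- simulate_bn(s0, adj, threshold_rule(1, 4), steps = 500)
trajectory_circuits(tr, z = 0.87, window = c(250, 500),
                    labels = brodmann_nodes()$label)
#> <circuit_set> 5 circuits (z = 0.87)
#>    1: {9, 32}  {5L, 21R}
#>    2: {9, 39}  {5L, 25L}
#>    3: {16, 57}  {8R, 36L}
#>    4: {19, 69}  {10L, 42L}
#>    5: {9, 32, 39}  {5L, 21R, 25L}
```

The run settles after a 68-step transient onto a 29-cycle — the "complex"
band between frozen order and chaos where circuit-like structure lives.
Five circuits emerge on the post-transient window; note the hub pattern:
circuits {5L, 21R} and {5L, 25L} are each strongly synchronized pairs, and
their union {5L, 21R, 25L} appears as a third circuit through the shared
hub 5L even though 21R and 25L correlate below z with each other. A period
map over the activation window reproduces the canonical table layout
("NP" = no period within the horizon, i.e. chaotic):

```r
sweep_table(period_sweep(cn, s0, a_range = 1:3, b_range = 1:6, x = 0.9))
#>     b=1 b=2 b=3 b=4 b=5 b=6
#> a=1 "NP" "4"  "16" "29" "2" "4"
#> a=2 "1"  "NP" "NP" "NP" "4" "2"
#> a=3 "1"  "1"  "1"  "NP" "NP" "NP"
```

Circuit-set stability against the shipped reference configuration:

```r
compare_to_reference(trajectory_circuits(tr, 0.87, c(250, 500)),
                     reference_circuits())
#> <stability_report> 5 candidate vs 10 reference circuits
#>   exact matches: 0; containments: 0; jaccard: 0.000
```

(The surrogate matrix shares only the reference connectome's weight
statistics, not its topology, so its circuits differ from the reference —
see the methods vignette.)

## Command line

A thin CLI wraps the same functions (`inst/cli/boolcortex`, available at
`system.file("cli/boolcortex", package = "boolcortex")` after install):

```sh
boolcortex synth --n 82 --mean 0.51 --sd 0.288 --seed 0 -o conn.tsv
boolcortex binarize conn.tsv --x 0.9 -o adj.tsv
boolcortex fixtures --what init -o init.txt
boolcortex simulate adj.tsv --init init.txt --a 1 --b 4 --steps 500 -o traj.tsv
boolcortex circuits traj.tsv --z 0.87 --window 250:500 -o circuits.json
boolcortex stability circuits.json -o report.json
```

All outputs are plain text (TSV/JSON) with a `#` comment header recording
the parameters; runs with fixed seeds are byte-reproducible.

## Documentation

The methods vignette
(`vignettes/boolean-connectome-dynamics.Rmd`) describes the model and its
assumptions, the parameters and defaults, what the synthetic generator
does and does not emulate, and the numerical design choices.
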
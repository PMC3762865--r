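# signedlogic

Logical modelling and steady-state analysis of signed gene/protein
interaction networks in R.

Large curated signalling models — the DNA-damage/p53 interactome is the
archetype — are naturally expressed as signed directed networks: nodes are
genes or proteins plus an environmental input (DNA damage) and phenotypic
outputs (apoptosis, cellular senescence), and each edge is an activation
(`+1`) or an inhibition (`-1`). `signedlogic` provides the complete analysis
stack for such models for systems biologists who want to interrogate a
curated network without kinetic parameters:

* **Structural analytics** — layers around a hub node, connectivity degrees,
  two-step feedback loops, censuses of links touching the input and each
  output.
* **The six-class dependency matrix** — for every ordered node pair `(i, j)`,
  the net influence of `i` on `j` classified from elementary (node-repetition
  free) signed paths. With `pos(i,j)` / `neg(i,j)` denoting the existence of
  a positive- / negative-net-sign path (the sign of a path is the product of
  its edge signs):

  | `pos` | `neg` | negative feedback loop touching a path of that sign | class |
  |-------|-------|------------------------------------------------------|-------|
  | no    | no    | —                                                    | `NO_EFFECT` |
  | yes   | yes   | —                                                    | `AMBIVALENT` |
  | yes   | no    | no                                                   | `STRONG_ACTIVATOR` |
  | yes   | no    | yes                                                  | `WEAK_ACTIVATOR` |
  | no    | yes   | no                                                   | `STRONG_INHIBITOR` |
  | no    | yes   | yes                                                  | `WEAK_INHIBITOR` |

* **In-silico knockouts** — structural node deletion, dependency-matrix
  differencing, and extraction of "major change" predictions (pairs that
  move from `AMBIVALENT`/`NO_EFFECT` to a strong class).
* **Three-valued logical steady states (LSS)** — sum-of-products Boolean
  rules (`target = OR(activators) OR OR(NOT inhibitors)`) with monotone
  Kleene propagation of 0/1/NaN values under input clamps, plus an exhaustive
  enumeration oracle for small networks.
* **Concordance scoring** — discretized model predictions `E_mod ∈ {-1,0,1}`
  versus discretized expression changes `E_exp ∈ {-1,0,1}` from per-gene
  log10 fold changes `Z = log10(M_tgt / M_src)` thresholded at `mean(Z) ± sd(Z)`;
  `|E_mod − E_exp|` of 0/1/2 counts true / small-error / large-error
  predictions, with a one-sided exact binomial test against the random
  baseline of 1/3.
* **Synthetic generators** — seeded random signed networks (uniform and
  hub-skewed) and expression tables with planted up/down signals, so every
  stage is testable without external data.

## Worked example

The built-in 20-node demonstration network wires the DNA damage input
through ATM/ATR/CHEK kinases to p53 and its MDM2/MDM4 regulators, and on to
apoptosis and senescence outputs (also shipped as
`inst/extdata/damage_demo_network.tsv`):

```r
library(signedlogic)
net <- example_damage_network()
net
#> signed_network: 20 nodes (1 input, 2 output), 34 edges (24 activating, 10 inhibiting)

dependency_matrix(net, method = "dfs")
#> dependency_matrix: 20 x 20 (method = dfs, loop_touch = node)
#>        NO_EFFECT       AMBIVALENT   WEAK_ACTIVATOR   WEAK_INHIBITOR
#>              245               34               61               45
#> STRONG_ACTIVATOR STRONG_INHIBITOR
#>               10                5
```

DNA damage is an *ambivalent* factor for the death receptor FAS in the wild
type — a direct activation coexists with negative routes through p53 — but
the knockout screen shows that deleting p53 leaves only the positive path:

```r
scr <- knockout_screen(net, method = "dfs")
scr
#> knockout_screen: 1 candidates
#>   p53             113 changed,   5 major
head(extract_predictions(scr[[1]]), 3)
#> in p53 knockout, ATM strongly activates CHEK2
#> in p53 knockout, DNAdamage strongly activates apoptosis
#> in p53 knockout, DNAdamage strongly activates CHEK2
```

Steady-state analysis shows the stabilizing role of the hub: with DNA damage
on, every node is determined in the wild type, but almost half the network
becomes undetermined (free across multiple steady states) once p53 is
removed:

```r
propagate_lss(net, scenario("wt_damage", clamps = c(DNAdamage = 1)))
#> ternary_state 'wt_damage': 20/20 nodes determined (100.0%)
propagate_lss(net, scenario("ko_damage", clamps = c(DNAdamage = 1), removed = "p53"))
#> ternary_state 'ko_damage': 10/19 nodes determined (52.6%)
```

The numbers above are exactly what the code prints; the vignette
(`vignettes/signed-network-logic.Rmd`) walks through the semantics behind
them and the concordance workflow against expression tables.

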
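---
title: "Methods: logical analysis of signed interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: logical analysis of signed interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signedlogic)
```

# The model

`signedlogic` analyses signed directed networks of regulatory interactions:
each node is a gene/protein, an environmental input (e.g. DNA damage) or a
phenotypic output (e.g. apoptosis, senescence), and each edge is either an
activation (+1) or an inhibition (−1). The representation is a directed
multigraph — the same ordered pair may carry both an activating and an
inhibiting edge, as happens when one regulator acts on a target through two
mechanisms — but exact duplicate edges are rejected. Input nodes receive no
edges and outputs emit none; these are validated invariants, not
conventions.

Three analyses are built on this object, and the assumptions behind each are
worth stating explicitly because they are where published tools differ.

## Signed paths and the dependency matrix

The influence of node $i$ on node $j$ is read off the *elementary* directed
paths $i \to j$ (paths that repeat no node); the sign of a path is the
product of its edge signs. Six classes arise: no path at all (`NO_EFFECT`);
paths of both signs (`AMBIVALENT`); only positive or only negative paths,
graded *strong* when no negative feedback loop interferes with any such path
and *weak* when one does. A negative feedback loop is an elementary cycle
with an odd number of inhibitions; "interferes" defaults to sharing at least
one node with at least one path of the relevant sign (`loop_touch = "node"`),
with edge-sharing (`loop_touch = "edge"`) available as a stricter
alternative — the two differ only in the weak/strong grading, never in the
activator/inhibitor/ambivalent call, which the test suite asserts.

Two assumptions deserve emphasis:

* **Paths, not walks.** If influence were propagated along arbitrary walks,
  any pair connected through a negative cycle would acquire both signs and
  collapse into `AMBIVALENT`, emptying the weak classes of meaning. The
  elementary-path semantics keeps the weak/strong distinction informative.
* **The diagonal is included.** A node's effect on itself is classified from
  the elementary cycles through it; a node on no cycle has `NO_EFFECT` on
  itself.

Deciding whether a positive and a negative simple path exist between a node
pair is NP-hard in general, so the package ships two engines.
`method = "dfs"` enumerates elementary paths exactly and is the reference
semantics; it is used automatically up to `cap = 12` nodes (the default is
deliberately conservative — sparse networks of a few hundred nodes are often
still feasible, and the cap is a user-visible argument, with a
`max_visits` budget guarding against explosion). `method = "closure"` is a
polynomial signed transitive closure computed by boolean matrix squaring
over a product graph that tracks (node, sign, loop-touched) states. The
closure operates on *walks*, of which simple paths are a subset, so it can
only over-approximate: every path the DFS finds, the closure finds too, but
the converse fails on cyclic networks, where a walk around a negative cycle
manufactures the opposite sign. The two engines therefore agree exactly on
acyclic networks and satisfy containment everywhere — both are asserted as
properties in the test suite over seeded random networks — but they are
*not* interchangeable on cyclic networks, and the DFS is the one validated
against an independent brute-force oracle (igraph's `all_simple_paths`) on a
thousand random networks. When the closure must be used on a large cyclic
network, its census should be read as a lower bound on single-sign classes
and an upper bound on ambivalence.

Negative feedback loops themselves are found by exact elementary-cycle
enumeration (a rooted depth-first search reporting each cycle once, with
parallel-edge sign sets resolved per cycle). For networks whose cycle count
explodes, `negative_loop_nodes(method = "scc")` offers a polynomial
over-approximation: a strongly connected component contains a negative cycle
iff its edges cannot be sign-consistently two-coloured, and all nodes of a
failing component are returned, even though individual ones might lie only
on positive cycles.

## Logical rules and three-valued steady states

Rules follow the sum-of-products convention: arcs converging on a node
combine by OR, an inhibitory arc contributing the negation of its source.
So a node whose only regulator is an inhibitor is *active* when that
inhibitor is off — this follows the convention literally rather than
defaulting unexplained nodes to 0. Nodes with no incoming edges have no
rule; unless clamped by the scenario they stay undetermined (`NaN`),
because they are genuinely free across steady states.

`propagate_lss()` computes the nodes whose value is the same in *every*
logical steady state compatible with the clamps, by monotone three-valued
(Kleene) fixpoint iteration: a ruled node becomes 1 once any literal is
known true, 0 once all are known false. The iteration only ever gains
information, so it terminates within one sweep per node and its result is
independent of node order (tested under shuffled declarations). Propagation
is *sound* — the exhaustive oracle `enumerate_lss()` confirms on a thousand
small random networks that every propagated value is unanimous across all
enumerated steady states — but deliberately *not complete*: it reasons one
rule at a time. The shipped demonstration network contains the canonical
counterexample: after the p53 knockout, MDM2's rule degenerates to
`MDM4 OR (NOT MDM4)`, which equals 1 in every steady state, yet propagation
reports `NaN` because MDM4 itself is undetermined. A case-splitting
refinement could close this gap; it is intentionally not the default, so
that the reported "determined" set has the simple one-rule-at-a-time
reading.

Knockouts are *structural deletions* — the node and its incident edges are
removed before rules are built — not clamps to 0. The distinction matters:
clamping an inhibitor to 0 activates its targets, deleting it removes the
literal altogether. Both behaviours are reachable (`scenario(removed = )`
versus `scenario(clamps = )`), deletion being the default reading of a
loss-of-function mutation. A clamp that contradicts a forced rule value
raises an infeasible-scenario error naming the node, and the enumeration
oracle consistently returns zero states for such scenarios.

## Concordance with expression data

The model's predicted change of a gene between two scenarios is encoded as
$E_{mod} \in \{-1, 0, +1\}$ from the two ternary states. Determined pairs
are forced: $0 \to 1$ is $+1$, $1 \to 0$ is $-1$, equal values 0. Pairs
involving `NaN` are a genuine modelling choice with two shipped mappings:
`"conservative"` (default) scores every NaN-involving pair 0 — no confident
prediction — while `"directional"` reads a move into or out of
indeterminacy as a half-step ($1 \to$ `NaN` and `NaN` $\to 0$ are $-1$;
$0 \to$ `NaN` and `NaN` $\to 1$ are $+1$). The conservative default is the
defensible null position; the directional mapping is useful when comparing
a fully determined wild type against a largely undetermined knockout, where
the conservative mapping scores almost everything "unchanged".

Observed changes come from per-gene fold changes $F = M_{tgt}/M_{src}$ of
median intensities, $Z = \log_{10} F$, discretized at thresholds
$\theta_{up,down} = \mu \pm k\sigma$ estimated from the $Z$ distribution
itself (default multiplier $k = 1$, exposed as `multiplier`). Estimating
thresholds from the distribution normalizes away global intensity rescaling
of either condition — a property asserted in the tests. Conventions at the
margins: a $Z$ exactly on a threshold counts as unchanged (conservative);
genes with missing or non-positive medians are excluded and reported; fewer
than three usable genes, or a degenerate distribution ($\sigma = 0$), refuse
to set thresholds rather than silently produce all-zero calls. Probe- and
replicate-level rows are collapsed to genes by median before fold changes.
Gene matching against the network is case-insensitive and expands
merged-node aliases (a node standing for several paralogues matches any of
its constituent symbols); node identifiers themselves are case-sensitive as
declared, normalization happening only at matching time.

$|E_{mod} - E_{exp}|$ scores each gene: 0 true, 1 small error, 2 large
error (opposite directions). Significance of the true-prediction count uses
a one-sided exact binomial tail with null $p_0 = 1/3$ — three equiprobable
outcomes is the natural chance model for a ternary call, and the test's
calibration (≈5% rejections at $\alpha = 0.05$ under the null) is itself a
test-suite property. Other nulls (e.g. class-frequency-matched) are easy to
pass through `p0`.

# Synthetic data: what it emulates and what it does not

`generate_network()` produces seeded random signed networks with role
constraints enforced by construction, either uniformly wired
(`model = "erdos"`) or degree-skewed through preferential attachment
(`model = "hub"`), the latter mimicking the hub-dominated connectivity of
curated interactomes. `generate_expression()` emulates summarized
microarray medians under the same generative model the discretization
assumes: $Z \sim \mathcal{N}(\delta \cdot E_{planted}, \sigma_{noise})$ on
the $\log_{10}$ scale, source medians at a constant baseline.

Two realism limits matter for interpreting green tests. First, random
networks have no biological modularity; passing the oracle-equivalence
suite shows the *algorithms* are correct on arbitrary topologies, not that
any biological conclusion transfers. Second, the expression generator
plants a *sparse* signal by default study condition — in the acceptance
run, 2% of 1,000 genes (10 up, 10 down) — because the $\mu \pm \sigma$
thresholds are estimated from the whole $Z$ distribution: a dense planted
signal inflates $\hat\sigma$ and no threshold rule of this family can then
recover it (with balanced thirds planted, expected recovery is capped
around 74%). Sparse differential signal is also what real two-condition
expression comparisons look like. Recovery is reported as the fraction of
*planted* genes called in the planted direction; at effect size
$\delta = 3\sigma_{noise}$ the expected recovery is ≈96–97%, so the ≥95%
acceptance bar is intrinsically tight and is pinned to a fixed seed in the
test suite. The generator does not attempt probe-level artefacts,
background correction or array normalization — inputs are assumed to be
already-summarized medians.

# Parameters at a glance

| Parameter | Where | Default | Why |
|---|---|---|---|
| `cap` | `signed_reachability` | 12 nodes | switch point from exact DFS to walk closure under `method = "auto"` |
| `loop_touch` | dependency functions | `"node"` | node-sharing loop interference; `"edge"` is stricter, same sign calls |
| `max_cycles`, `max_visits` | cycle/path enumeration | 1e5 / 5e6 | explicit budgets instead of silent hangs |
| `min_degree` | `knockout_screen` | 10 | screen hubs (degree > 10), where deletions change the matrix |
| `include_weak` | `compare_matrices` | `FALSE` | "major" = transition into a strong class only |
| `mapping` | `compute_Emod` | `"conservative"` | NaN pairs score 0; `"directional"` available |
| `multiplier` | `fold_changes` | 1 | thresholds at $\mu \pm 1\sigma$ of $Z$ |
| `p0` | `significance` | 1/3 | ternary chance level |
| `delta`, `sigma_noise` | `generate_expression` | 1, 0.3 | log10-scale effect and noise; acceptance run uses $\delta = 3\sigma_{noise}$ |

# Problem sizes in the shipped verification

The property suites run on seeded random networks of 4–10 nodes (path/cycle
oracles, a thousand networks), 4–10 nodes for steady-state unanimity against
exhaustive enumeration (a thousand networks), and 1,000-gene expression
tables; the demonstration network has 20 nodes. These sizes keep the
brute-force oracles exact and the full suite fast while exercising every
code path, including parallel opposite-sign edges, self-loops and
undetermined regions.

# Known limitations

* No trajectory or attractor-cycle analysis: the steady-state machinery
  answers "which values are forced", not "how the system moves".
* Pairwise arcs only — no AND-hyperarcs. Rules are pure OR combinations.
* The walk-based closure is a coarse upper bound on ambivalence for cyclic
  networks (see above); exact classification of large, densely cyclic
  networks may be infeasible, which is a property of the problem, not of
  the implementation.
* Exhaustive steady-state enumeration is capped (default 20 free nodes) and
  is an oracle, not a production path.

# End-to-end runs

`validate_config()`/`run_all()` drive the whole pipeline from one YAML
configuration (network source, scenarios, scenario comparisons, knockout
screen, concordance comparisons), write per-table TSVs plus a JSON report,
and echo every semantic default (mapping, multiplier, loop-touch mode) into
the report for provenance. `scripts/acceptance.R` is a worked example of the
same flow driven from a single `--seed`.
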
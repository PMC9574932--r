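---
title: "Graph-driven reaction discovery with grds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-driven reaction discovery with grds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grds)
```

## The discrete model of chemical space

`grds` treats a chemical system of $N$ atoms as a *bonding graph*: a
symmetric binary $N \times N$ adjacency matrix $\mathbf{G}$ over an
ordered atom list, with $G_{ij} = 1$ exactly when atoms $i$ and $j$ are
bonded. Bonding is decided geometrically: atoms are bonded when their
distance $r_{ij}$ falls below $\alpha (R_i + R_j)$, where $R_i$ are
per-element covalent radii and $\alpha$ is a dimensionless scaling
factor. This rule discretizes chemical space — every molecular geometry
maps to exactly one graph, and differently bonded species map to
different graphs — at the price of losing all conformational
information (cis and trans isomers of one connectivity share a graph)
and all bond-order information (the adjacency is binary; a double bond
is a single edge).

Three modeling choices are bundled with the rule and deserve scrutiny:

* **Covalent radii.** The package ships a fixed table of
  Pyykkö-style single-bond radii so that results are reproducible;
  every radius can be overridden per element through `atom_spec()`.
* **The cutoff factor $\alpha$.** Values near 1.1–1.2 classify
  ordinary covalent structures robustly; the package default is 1.15,
  the midpoint of that range. Larger values merge van-der-Waals
  contacts into bonds, smaller values break stretched bonds.
* **Valence ranges.** Each element carries an allowed
  coordination-number interval $[v_\min, v_\max]$. The defaults are
  permissive (zero is included for elements that plausibly occur as
  free atoms or radicals, e.g. hydrogen), because the valence filter is
  the *only* chemistry-awareness the searches have; a user who knows,
  say, that bare oxygen atoms should never appear simply sets
  `valence_ranges = list(O = c(1, 2))`.

Species identity is decided by a canonical key: graphs are
canonicalized by BLISS canonical vertex ordering with element labels as
vertex colors (via igraph), and the key string is the canonical element
sequence plus the canonical upper-triangle bond bits. Key equality is
therefore exactly element-labeled graph isomorphism; the test suite
verifies this against a brute-force permutation oracle on all labeled
graphs of up to six atoms.

## Reaction classes and valence rejection

A reaction class is a pair of $k \times k$ bonding patterns
(before/after) on a tuple of $k \in \{2, 3, 4\}$ atoms. Applying a
class to a tuple whose induced sub-adjacency equals the `before`
pattern replaces that block with `after` and touches nothing else.
The built-in library holds five classes:

| class | arity | bond change |
|---|---|---|
| `dissociation` | 2 | i–j breaks |
| `association` | 2 | i–j forms |
| `diatomic_dissociation` | 3 | i–j and i–k break, j–k forms |
| `diatomic_association` | 3 | j–k breaks, i–j and i–k form |
| `atom_transfer` | 3 | i–j breaks, i–k forms |

This is the smallest set under which hydrogen-transfer chemistry is
expressible; every class is invertible, and users can extend the
library from a YAML/JSON config (`reaction_classes_from_config()`),
including per-slot element filters. Tuples equivalent under a symmetry
of the pattern (the two orders of an association pair, the mirror of a
diatomic dissociation) are deduplicated so that one physical event is
counted once.

Products whose coordination numbers leave the allowed per-element range
are *rejected*: `apply_event()` returns a rejection value rather than
raising an error, because rejection is an ordinary, frequent outcome of
a search step. This filter removes nonphysical products at graph level,
with no energy evaluation of any kind.

## Single-ended exploration (SEGDS)

`explore_single_ended()` grows a chemical reaction network from
reactants alone. Each iteration picks a known system state uniformly at
random, then applies one valence-valid event chosen uniformly among all
applicable events (pattern matches are tried in random order and
rejected ones skipped — the first accepted event is uniform among the
valid ones). Nodes are unique canonical keys of whole-system graphs;
edges are deduplicated by (reactant key, product key, class), so
breaking either of two equivalent C–H bonds registers as one reaction.

The stopping rule is a fixed iteration budget. No kinetic or
flux-based convergence criterion is applied: the walk policy is the
simplest unbiased, seedable baseline, and for the small systems used in
the tests (three to twenty atoms) the explored node set converges to
the full valence-valid state space well within a hundred iterations —
for the three-hydrogen system the test suite checks this against exact
enumeration of all $2^{3}$ adjacency matrices.

## Double-ended mechanism search (DEGDS)

A *mechanism* is an ordered sequence of at most $N_r$ reaction events.
A distinguished identity step fills unused slots, which keeps the
search space fixed-dimensional while letting shorter mechanisms be
represented. Two cost functions score a propagated graph against a
target:

* **Element-wise** (`cost_elementwise`): the number of differing
  bonds between the propagated system graph and a full target graph,
  each unordered pair counted once. Zero exactly at matrix equality.
  Cheap, but it requires the target's atom indexing to be fixed in
  advance, and a permuted copy of the product scores positive.
* **Spectral product** (`cost_product`): scans the molecules of the
  propagated graph for one matching a *single* target molecule by the
  eigenvalue spectrum of the mass-weighted bonding graph
  $M = A + \mathrm{diag}(m)$; molecules with the wrong atom count
  contribute a large penalty $\Delta$, and the cost is the minimum over
  molecules. This cost is invariant under any atom permutation, so the
  target may be formed from *any* subset of atoms with the right
  masses.

The mass-weighting convention $M = A + \mathrm{diag}(m)$ was an open
choice; placing the masses on the diagonal makes the spectrum
element-sensitive while preserving permutation invariance, and the
convention is isolated behind `mass_weighted_spectrum()` so
alternatives (e.g. $\sqrt{m_i m_j}$-scaled entries) can be swapped
without touching the searches. Eigenvalues are compared after ascending
sort; degeneracies are handled by sorted order alone.

Three numerical choices matter here:

* $\Delta$ defaults to $10^6\ \mathrm{amu}^2$, far above any spectral
  distance achievable on the bundled systems, and is configurable.
* Spectral distances below `zero_tol` ($10^{-9}\ \mathrm{amu}^2$ by
  default) are snapped to exactly zero: distances between spectra of
  isomorphic graphs are pure eigensolver roundoff (order $10^{-25}$),
  while genuinely different small graphs sit many orders of magnitude
  above the threshold.
* Cospectral non-isomorphic impostors would also score zero under any
  purely spectral cost. Whenever the search reaches zero cost, the
  candidate molecule is therefore confirmed by an explicit
  element-labeled VF2 isomorphism check against the target; impostors
  are re-penalized and the search continues.

### Simulated annealing

`anneal_search()` optimizes the event sequence by Metropolis-accepted
random edits under geometric cooling. Four move types are proposed
with weights 0.3/0.4/0.15/0.15: resample a step's class, resample a
step's atom tuple, swap two steps, and set/unset an identity step.
Proposals are *constraint-guided*: a new event for a step is drawn by
placing the tuple's slots one at a time among atoms consistent with the
class pattern on the graph propagated up to that step. This proposal
distribution is not uniform over matches — for an optimization (rather
than a sampling) problem only reachability matters, and guided
proposals keep the acceptance rate of pattern-valid moves high enough
that systems of twenty atoms anneal in minutes on one core. Sequences
that fail to propagate (a later step's pattern no longer matches, or a
valence violation) cost twice the penalty $\Delta$, so they are never
preferred over any valid sequence.

Defaults — initial temperature 20 (cost units), final 0.02, cooling
factor 0.95, 40 proposals per temperature, up to 10 restarts — were
chosen once against the bundled endpoint systems (water formation,
formaldehyde decomposition, propanal formation from the
hydroformylation reactant set, benzene formation from
1,3-butadiene + C2H) and are exposed through `anneal_config()`.
Independent restarts draw fresh sub-seeds from the parent stream until
the requested number of distinct mechanisms (deduplicated by canonical
event sequence) is collected. Every returned mechanism is re-verified
by propagation, cost evaluation and the isomorphism guard.

### Ranking by landscape roughness

Given per-intermediate energies from any external evaluator,
`rank_mechanisms()` computes two roughness descriptors per mechanism:
`A`, the largest step-to-step energy increase, and `B`, the
root-mean-square step energy change, plus a barrierless flag (no
intermediate above the reactant energy beyond a tolerance). Mechanisms
are ranked ascending by `(A, B)` with ties broken by length. These
functional forms are this package's own declared choices — simple,
unit-preserving summaries of profile roughness — not reconstructions of
any particular published descriptor; both are trivially replaceable by
post-processing the same energy vectors.

## Back-transformation: the graph-restraining potential

To turn graphs back into coordinates, `embed_graph()` minimizes a
*graph-restraining potential* $W(\mathbf{r}; \mathbf{G})$: flat-bottom
quadratic wells over all atom pairs. A bonded pair is penalized only
beyond $(1-\delta)$ of its bonding cutoff; a nonbonded pair only below
$(1+\delta)$ of it; inside the allowed region the energy is exactly
zero. With the default margin $\delta = 0.1$, any zero-energy geometry
classifies strictly — never marginally — under the cutoff rule, which
gives the round-trip guarantee: whenever embedding reports success, the
recomputed adjacency of the returned geometry equals the target graph
exactly (and the gradient max-norm is below `grad_tol`). The potential
acts on *all* pairs, not only pairs whose bonding changed, precisely
so that this guarantee is global.

Minimization uses L-BFGS-B with the analytic gradient (validated
against central finite differences in the tests). Initialization
places atoms uniformly at random in a cube of 1.5 Å per atom per axis;
failed attempts restart from fresh random placements up to
`max_restarts`. Failure after all restarts returns an explicit failure
value carrying the best-effort geometry — never a silently wrong
geometry. `mechanism_geometries()` embeds every intermediate of a
mechanism, warm-starting each embedding from the previous step's
coordinates so consecutive structures stay spatially continuous and
converge in fewer optimizer evaluations than cold starts.

The GRP is a surrogate, not a physical surface: its minima are
*graph-consistent* geometries, not equilibrium structures. Bond
lengths inside the flat bottom are arbitrary within the buffer, and no
refinement on a real potential-energy surface is attempted here.

## Kinetics

The rate utilities use the Eyring form with the first-order prefactor
convention, $k = (k_B T / h)\, e^{-\Delta G^\ddagger / RT}$, with
CODATA 2018 constants hard-coded ($R$ in kJ/(mol·K)). The relative
rate between two activation energies differing by
$\Delta\Delta G^\ddagger$ is $e^{-\Delta\Delta G^\ddagger / RT}$; at
300 K a 5 kJ/mol error gives 0.135 (underestimate) or 7.42
(overestimate) — the package reports directly evaluated values, so the
two are exact reciprocals. A transmission coefficient
$\alpha(T) \in (0, 1]$ scales the TST rate down for recrossing
(`corrected_rate()`); computing $\alpha(T)$ itself is out of scope
and it enters as an input.

`ssa_simulate()` implements the exact Gillespie direct method (not the
next-reaction variant: simplicity, exactness and easy seeding).
Propensities are stochastic mass-action,
$a_j = c_j \prod_s \binom{x_s}{\nu_{js}}$; rate constants are
*stochastic* constants, so bimolecular macroscopic rates must be
converted by the reaction volume before use. Per-replica seeds are
drawn from a parent stream seeded by `rng_seed` — consecutive integer
seeds would yield correlated Mersenne-Twister streams, a bias that is
detectable at 200 replicas and that the test suite's 3-standard-error
decay check would catch. `reactive_flux()` aggregates per-reaction
firing counts, nets forward/backward firings of reversible pairs, and
extracts the sub-network above a flux fraction of the dominant channel.
Rate-law extraction (e.g. scanning a species' initial concentration
and regressing log-rate on log-concentration) is a documented recipe
over `ssa_simulate()` outputs rather than a bespoke fitter.

## What the fixtures do and do not show

The bundled systems (`fixture_systems()`) are idealized: graphs are
exact literature connectivities, and geometries are equilibrium
structures built from standard bond lengths and angles. They exercise
every code path — cutoff classification, valence rejection, search,
embedding, kinetics — at sizes from 3 to 20 atoms. Passing tests on
them demonstrates correctness of the discrete machinery, not chemical
realism: no energetics enter the searches, so the mechanism sets are
*hypotheses* ordered only by graph-space reachability, and
distinguishing plausible from implausible mechanisms requires external
energies (via `rank_mechanisms()`) that this package deliberately does
not compute. Problem sizes in the tests and the acceptance script
(two-step oracle systems of up to six atoms, twenty-atom annealing
endpoints, 200-replica kinetics with 500 molecules) were chosen as the
smallest sizes at which each property is non-trivially exercised.

## Known limitations

* Binary adjacency: no bond orders, formal charges or stereochemistry;
  charged-species bookkeeping is not modeled.
* Conformers collapse onto one node; no conformer enumeration.
* The element-wise cost is intentionally index-bound (kept as the
  cheap option and as a contrast to the spectral cost).
* The spectral cost relies on the isomorphism guard for exactness;
  without it, cospectral impostors would terminate searches early.
* The annealing schedule is tuned for tens of atoms; much larger
  systems will need longer schedules, more restarts, or active-atom
  restriction (`active_atoms`) to keep proposals focused.
* The GRP yields graph-consistent, not physically optimized,
  geometries.
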
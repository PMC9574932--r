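# grds — graph-driven reaction discovery

`grds` is an R toolkit for *automatic reaction discovery* (ARD): given
molecular reactants, find the elementary reactions and multi-step
mechanisms that connect them to products, and characterize the
resulting chemical reaction network (CRN) kinetically. It is aimed at
computational chemists who want mechanism hypotheses for catalytic or
astrochemical systems before committing to expensive electronic-structure
calculations.

## The method

Chemical space is discretized by **bonding graphs**: an N-atom system
is a symmetric binary adjacency matrix **G** with

```
G_ij = 1  iff  r_ij < α (R_i + R_j)
```

where `r_ij` is the interatomic distance, `R_i` are covalent radii and
`α ≈ 1.15`. Chemistry happens through **reaction classes** — before/after
bond patterns on 2–3 atom tuples (association, dissociation, diatomic
dissociation/association, atom transfer) — applied under per-element
**valence constraints** that reject nonphysical products with no energy
evaluation.

On top of this discrete space the package provides:

* **SEGDS** (single-ended graph-driven search): stochastic repeated
  application of reaction classes grows a CRN from reactants only.
* **DEGDS** (double-ended search): a mechanism is a sequence of at
  most `N_r` reaction events; simulated annealing minimizes a cost
  `F` that is zero exactly when the propagated graph reaches the
  target — either element-wise on the full adjacency matrix, or a
  permutation-invariant spectral cost `F_p` comparing eigenvalues of
  mass-weighted bonding graphs `A + diag(m)` molecule by molecule,
  with a penalty `Δ` for wrong-size molecules and an isomorphism
  guard against cospectral impostors.
* **GRP embedding**: a graph-restraining potential (flat-bottom pair
  wells) whose minima are exactly the geometries consistent with a
  target graph, used to back-transform graphs and whole mechanisms
  into 3D coordinates with a strict round-trip guarantee.
* **Kinetics**: Eyring rates `k = (k_B T/h) exp(−ΔG‡/RT)` with
  optional transmission coefficients, exact Gillespie stochastic
  simulation, and reactive-flux extraction of the minimal sub-network.

## Worked example

```r
library(grds)

# 1. explore formaldehyde's reaction space from its geometry
h2co <- fixture_systems("h2co")
net <- explore_single_ended(h2co$graph, builtin_library(),
                            explore_config(150, rng_seed = 2))
s <- crn_summary(net)
cat("states:", s$n_nodes, " reactions:", s$n_edges, "\n")
#> states: 13  reactions: 69
head(s$species$molecules)
#> [1] "C + H + H + O" "CO + H + H"    "C + H + HO"    "CHO + H"
#> [5] "C + H2O"       "CH + H + O"

# 2. find a mechanism forming water from H2 + O by double-ended search
target <- fixture_systems("h2o")$graph
found <- anneal_search(fixture_systems("h2_plus_o")$graph,
                       cost_spec("product_spectral", target),
                       builtin_library(), n_r = 3,
                       anneal_config(rng_seed = 2, max_restarts = 5))
found[[1]]
#> <mechanism> 2 step(s) (N_r = 3)
#>   atom_transfer(2, 3, 1)
#>   association(1, 3)

# 3. back-transform the water graph into coordinates (Angstrom)
emb <- embed_graph(target, params = grp_params(rng_seed = 1))
round(emb$coords, 3)
#>       [,1]  [,2]  [,3]
#> [1,] 1.662 3.089 3.528
#> [2,] 1.582 2.126 3.370
#> [3,] 2.203 3.822 3.158

# 4. an Eyring rate for an 80 kJ/mol barrier at 300 K
tst_rate(rate_params(300, 80))
#> k = 0.0736 /s
```

The 13 explored states are all valence-valid bonding arrangements of
{C, O, H, H} reachable from formaldehyde; the two-step water mechanism
first transfers one H from H2 to the O atom and then closes the second
O–H bond; the embedded coordinates reproduce the water graph exactly
when fed back through the cutoff rule.

A command-line front end wrapping the same functions ships at
`inst/cli/grds.R` (subcommands `explore`, `search`, `embed`,
`simulate`, `summarize`).

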
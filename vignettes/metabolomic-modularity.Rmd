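---
title: "Metabolomic Modularity Analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolomic Modularity Analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mma)
```

## The problem this package addresses

Pathway enrichment analysis interprets a metabolomics experiment through
pre-drawn pathway maps, which biases discovery toward interactions someone
already catalogued. Metabolomic Modularity Analysis (MMA) instead asks the
metabolic network itself where the significant metabolites cluster: it
partitions a genome-scale reaction network into a hierarchy of reaction
modules whose edges have been shortened wherever statistically significant
metabolites (SSMs) are dense, so modules enriched in SSMs fall out of an
unbiased graph partition. The defining payoff is modules coupled through the
shared production and consumption of energy cofactors (ATP, NADH, NADPH,
FADH2) — couplings that span several canonical pathways and are invisible to
pathway-map enrichment.

## The model, stage by stage

**SSM calling.** For each measured metabolite, replicate peak areas at two
timepoints are compared with a two-sided Mann–Whitney U test; a metabolite is
an SSM when `p < alpha` (default 0.05) *and* has a direction (the median
shift is nonzero; `accumulated` or `depleted`). Raw p-values are thresholded
by default — Benjamini–Hochberg is available behind `p_adjust = "BH"` but is
off to keep the default convention of the upstream analysis style this
implements. Because tissue extraction pools compartments, an SSM base name is
expanded to *every* compartmental node of that metabolite in the model.

The exact test enumerates the rank-sum null (closed form when tie-free, full
enumeration over the `choose(n+m, n)` group assignments with midranks
otherwise); the normal approximation applies the tie-corrected variance with
a 0.5 continuity correction. The default (`method = "auto"`) uses the exact
test up to 8 replicates per group. A consequence worth knowing: with three
replicates per group the exact two-sided test cannot go below p = 2/20 = 0.1,
so a three-replicate design with `alpha = 0.05` calls nothing under the exact
convention and only the normal approximation can produce calls. Both paths
are provided precisely because the conventions disagree at such small n.

**Graph construction.** The model becomes a directed bipartite graph
(reaction→product, reactant→reaction, both orientations for reversible
reactions). Currency metabolites from the exclusion list (protons, water,
phosphate, CO2, O2 and similar inorganics — *not* energy cofactors, which are
deliberately retained) contribute no edges. The reaction-centric graph
connects reactions i and j when a metabolite produced by one is consumed by
the other. Each reaction gets a reaction score `RS(i)` — the number of
*distinct* SSM nodes it produces or consumes (set semantics: stoichiometric
multiplicity is chemistry, not evidence) — and the weighted edge distance is

    RG(i, j) = 1 / (RS(i) + RS(j))

so an SSM-dense pair sits close (scores 3 and 2 give distance 0.2). Pairs
with `RS(i) + RS(j) = 0` get distance 1.0: that is the supremum of the
formula over scored pairs (attained at score sum 1), so unscored pairs are
"at least as far" as any scored pair without becoming unreachable. The
edge *set* never depends on the weights; `weighted = FALSE` assigns every
edge distance 1.0.

**B-matrix.** Within one connected component, `D` is the all-pairs
shortest-path matrix (Dijkstra under the edge distances). For each pair
(i, j), the comparison vector `V` collects `D(i, x)` and `D(j, x)` for every
other node `x`, plus `D(i, j)` itself (`L = 2(n-2) + 1` entries), and

    B(i, j) = 1 - 2 (r - 1) / (L - 1)

where `r` is the midrank of `D(i, j)` in ascending-sorted `V`. Relatively
close pairs get `B` near +1, relatively distant ones near −1.

**Partition.** The modularity of a ±1 assignment `s` is `Q = Σᵢⱼ Bᵢⱼ sᵢ sⱼ`
(unnormalized — only the sign matters for termination). The split is read
off the leading eigenvector of `B`: positive entries +1, negative −1. A
module is split only when both signs occur and `Q > 0`; after each split the
two sides are further divided into their connected components, and the
recursion repeats with `D` and `B` recomputed on each sub-module. Every
module ever instantiated stays in the tree.

**Annotation.** Per module: SSM density (distinct SSM nodes touched by the
module's reactions divided by module size — it may exceed 1), height
(longest downward path to a terminal module), and the baseline criteria
(size ≥ 2 and density > 0.5, i.e. at least one SSM per two reactions).

**Null model.** Random connected subgraphs are grown by the stochastic
procedure implemented verbatim in `random_connected_subgraph()`: seed, grow
by random incident edges, delete edges that close cycles — on a private
working copy per draw, so the source graph is never mutated and draws stay
identically distributed. The sampler is *not* uniform over connected
subgraphs and makes no such claim; it is the stated procedure. From the
sampled SSM counts come the per-size baseline-criterion background fraction
and the empirical module probability `(r + 1) / (n + 1)` (pseudocounted so
finite sampling never yields an impossible zero).

**Enrichment and conservation.** Pathway enrichment collapses a module's SSM
nodes to unique base names (compartments pooled — unlike SSM density, which
counts nodes; both conventions coexist deliberately) and asks whether any
single annotated pathway covers them all; if not, the module is
*counter-intuitive* — its interaction spans canonical pathways. Conservation
matches each baseline module of a reference partition to the deepest module
of another partition containing all its reactions (ties: highest density,
then smallest size); the raw matched density is reported for every entry and
the conserved flag applies the > 0.5 threshold on top.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `alpha` | 0.05 | probability | conventional two-sided significance level |
| `method` | auto (exact ≤ 8/group) | — | exact null is feasible and preferable at targeted-metabolomics replicate counts |
| exclusion list | shipped inorganics file | base names | removes currency coupling; cofactors retained by design |
| `weighted` | TRUE | — | the SSM-distance weighting is the method's point; FALSE gives the comparison baseline |
| `b_convention` | rank | — | the rank-linear map is the primary reading; `value` interpolates by distance instead |
| baseline criteria | size ≥ 2, density > 0.5 | — | at least one SSM per two reactions on average |
| `n_samples`, `repeats` | 1000, 10 | draws | null-distribution resolution vs. runtime |

## What the synthetic generator emulates — and what it does not

`plant_and_measure()` emulates the *statistical shape* of a two-timepoint
perfusion-style experiment: positive peak areas with multiplicative
(log-normal) replicate noise, a subset of metabolites shifted several-fold
between timepoints, a connected background reaction web with high-degree
currency hubs, compartmental duplication of part of the metabolite pool, and
two kinds of planted signal — SSM-dense reaction modules (chains of
reactions sharing designated SSMs) and a two-reaction pair coupled *only*
through NADPH plus one SSM product each, tethered by unit-distance edges
into different background regions. That pair is the minimal construction in
which edge-weighting should, and unit distances should not, bind the
coupled reactions into one terminal module.

Defaults: 50 reactions, 40 pool metabolites, 2 compartments, 10% currency,
noise sigma 0.2, effect size 8, five replicates per timepoint. Five
replicates (rather than the three typical of technical-replicate designs) is
a deliberate choice: it is the smallest balanced design at which the exact
two-sided rank-sum test can reach p < 0.05 at all (floor 2/252 ≈ 0.008
versus 0.1 at n = 3), so the exact-test pipeline has nonzero power under
realistic noise. Effect size 8 with sigma 0.2 makes planted metabolites
separate essentially always, which is what a "clearly significant"
metabolite looks like in targeted data.

What it does **not** emulate: perfusion biochemistry (no kinetics, no flux),
instrument artifacts (drift, censoring at the detection limit, missingness),
correlated replicate structure, and the topology idiosyncrasies of curated
genome-scale models (e.g. giant biomass reactions that make null SSM-count
distributions bimodal). Passing tests therefore certify the algorithmic
contracts and the recoverability of planted structure — not performance on
any particular curated model.

## Numerical and design choices

- **Rank vs. value B-matrix.** The rank-linear map is primary because the
  construction is explicitly rank-based; the value-linear alternative is
  kept behind `convention = "value"` since the defining description admits
  both readings. `D(i, j)` itself is included in the comparison vector; with
  it, a pair strictly closer than all its other distances maps exactly
  to +1.
- **Ties** in the rank map use midranks; a fully tied vector maps to 0.
- **Two-node components** get `B = 1`, which can never produce an accepted
  split — the intended terminal behavior.
- **Eigenvector determinism.** The dense symmetric eigensolver is used at
  every size; the ±v ambiguity is removed by orienting the first entry with
  |v| ≥ 1e−12 positive, and entries with |v| < 1e−12 are assigned +1.
  Identical inputs give identical trees.
- **Q acceptance** requires `Q > 1e-12` — a strict-positivity guard against
  floating-point zeros.
- **Degenerate inputs.** Metabolites observed at one timepoint get p = 1; a
  significant p with exactly tied medians is not called an SSM (no
  direction); empty SSM sets make the weighted graph identical to the
  unweighted one.
- **Chunk decomposability.** The O(N²) pair scan and the per-pair B
  computation are independent across index ranges; chunked evaluation is
  asserted bit-identical to the serial scan, so users can parallelize
  externally without changing results.

## Problem sizes used by the test suite

The suite exercises synthetic models of 25–200 reactions, twenty seeded
pipeline replicates for the recovery property, 10,000 sampler draws on a
200-node graph, 10,000 null simulations for test calibration, and exhaustive
bipartition enumeration (≤ 2⁹ sign vectors) as the independent oracle for
the eigenvector split on graphs of up to 10 nodes. These sizes were chosen
so every contract is checked at a scale where exhaustive or closed-form
oracles exist; the algorithms themselves contain nothing scale-specific
beyond the documented O(N²)–O(N³) costs.

## Known limitations

- The leading-eigenvector split is a heuristic for maximizing `Q`; it is
  verified never to beat the exhaustive optimum and to match it on clearly
  two-block structure, but on ambiguous structure it may return a
  sub-optimal split (as the underlying spectral method does).
- The subgraph sampler's distribution is procedure-defined, not uniform;
  empirical module probabilities are calibrated against that procedure, not
  against a uniform null.
- Allosteric regulation is absent from the graph: edges encode stoichiometry
  only.
- Accumulation or depletion of a metabolite must not be read as flux
  direction; concentration changes cannot resolve production from reduced
  consumption.
- The B-matrix costs O(n³) time per component at module size n; components
  of many thousands of reactions call for the chunked evaluation and
  patience, or external parallelism.
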
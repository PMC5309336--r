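---
title: "Methods: carbon-nitrogen flux analysis in cnflux"
author: "cnflux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon-nitrogen flux analysis in cnflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnflux)
```

# The modelling problem

cnflux studies how a phototrophic cell's metabolism re-routes flux when
inorganic carbon becomes more available while nitrogen does not. The cell
is represented as a genome-scale stoichiometric model: metabolites by the
rows and reactions by the columns of a sparse matrix $S$, growth by a
biomass objective reaction (BOF) that consumes precursors in fixed
proportions, and the environment by bounds on exchange reactions. At steady
state, flux vectors $v$ satisfy

$$ S v = 0, \qquad lb \le v \le ub, $$

with uptake encoded as negative exchange flux. A measured uptake of $u$ mM
is imposed as the equality bound $[-u, -u]$ — the cell is *forced* to take
the nutrient up, which is what makes over-supplied carbon interesting: it
has to go somewhere.

# Linear programming core

Flux balance analysis maximises $v_{\mathrm{BOF}}$ over the polytope above.
The package carries its own two-phase revised simplex for bounded
variables (`simplexSolver`): Bland's rule guarantees termination on the
degenerate vertices that flux variability analysis visits constantly, and
basic variable values are re-solved from the basis factorisation at every
iteration rather than updated incrementally, trading a little speed for
drift-free arithmetic on the small models this package targets. The solver
is a plug point: `optimizeModel()` and everything downstream accept any
function with the same contract.

Alternate optima are the rule in FBA, so whenever one representative flux
vector is reported the package uses parsimonious FBA: biomass is pinned at
its optimum and the total absolute flux $\sum_i |v_i|$ is minimised via the
standard split $v = p - m$, $p, m \ge 0$. This tie-break is what makes the
storage-routing predictions deterministic (see the toy model below).

Flux variability analysis minimises and maximises each reaction's flux,
optionally with biomass pinned at a fraction of its optimum; fraction 0 is
pure feasibility FVA. Blocked-reaction pruning removes every reaction whose
feasibility-FVA range lies within $[-10^{-9}, 10^{-9}]$ (the solver-noise
floor) and then drops metabolites that no remaining reaction touches.
Pruning under the *applied* constraints, rather than at the growth optimum,
mirrors how sampling inputs are usually prepared and preserves both
feasibility and the optimal objective value, which the test suite asserts.

# Limitation scenarios and the C/N breakpoint

`runScenario()` sweeps forced carbon uptake over a grid while nitrate
follows one of two rules: constant, or ramping by a fixed step once carbon
passes a threshold. Demand reactions — irreversible single-metabolite sinks
modelling storage (TAG, chrysolaminarin, nitrate) or release (DMSP) — are
opened or closed per scenario. Each step is solved parsimoniously and the
breakpoint is reported as the last grid point at which biomass still
increased (first forward difference below `tolFlat = 1e-8`); its resolution
is therefore one grid step, and the default grid step is documented
alongside every result. The C/N breakpoint ratio is that carbon uptake
divided by the nitrogen uptake at the same step.

# Sampling the flux polytope

`sampleFluxes()` implements artificially-centered hit-and-run. Warmup
points are the $2n$ full FVA-extreme solutions; their centroid is strictly
interior in every non-fixed coordinate. Each step draws the direction from
the current point toward a random warmup point re-centered on the running
centroid — the "centered" direction set mixes far better than isotropic
directions on the elongated cones flux polytopes form — finds the feasible
chord from the bounds alone (directions are differences of feasible points,
so they stay in the null space of $S$ automatically), and jumps to a
uniform point on the chord.

Numerical choices: every 50 steps the point is re-projected onto an
orthonormal null-space basis of $S$ (computed once by SVD) to stop floating
drift in $S v$; bound violations below $10^{-9}$ are clipped, larger ones
re-projected onto the box. A published "step count" mixing parameter maps
onto the chain as `thinning = ceiling(stepCount / nPoints)`, so the default
`stepCount = 2 * nReactions` retains every point on small models while a
large published step count thins the chain correspondingly. All randomness
flows from the `seed` argument; identical inputs give bit-identical sample
matrices.

The uniformity checks compare hit-and-run marginals with an independent
rejection sampler on polytopes of one and two free dimensions (a segment
and a hexagon), by two-sample Kolmogorov–Smirnov at 2000 points per side.
On those fixtures we run the chain with `stepCount` 10–20k (thinning 5–10)
because KS against an i.i.d. oracle is sensitive to the chain's residual
autocorrelation, not to any bias in its stationary distribution.

# The flux-shift permutation test

For each reaction the low- and high-carbon sample vectors (equal length
$n$) are compared as distributions. Per repeat, both vectors are
independently permuted and subtracted elementwise; the minority sign count
$m_k = \min(\#\{d>0\}, \#\{d<0\})$ of the difference vector measures
histogram overlap. With 100 repeats (the default),

$$ \text{stat} = \tfrac{1}{100}\sum_k m_k / n, \qquad
   p = \min(1,\, 2\,\text{stat}). $$

Zeros count toward neither sign, and two elementwise-identical vectors are
assigned $p = 1$ (no evidence of a difference) with the stat recorded as
0.5 so the $p = 2\cdot\text{stat}$ identity holds everywhere. Direction is
the sign of the median difference, chosen for robustness on the skewed
marginals sampling produces, and Benjamini–Hochberg control runs across all
tested reactions at threshold 0.05.

One property of this statistic deserves emphasis: the minority-sign
fraction estimates $\min(P(L > H), P(L < H))$, which for two normal
distributions shifted by $\delta$ equals $\Phi(-\delta/(\sigma\sqrt2))$.
Significance at $\alpha = 0.05$ therefore requires
$\delta \gtrsim 2.8\,\sigma$ — the test detects *near-separation* of the
two flux distributions, not mere mean shifts. Monte-Carlo checks in the
test suite confirm the implied operating curve: type-I error well below
$\alpha$ under the null, power essentially zero at a $2\sigma$ shift, and
power ~1 from $3\sigma$ upward. This conservatism is intrinsic to the
overlap statistic, and it matches the intuition that doubling a forced
uptake separates the distributions of tightly coupled reactions completely
while leaving loosely coupled ones untouched.

# Cluster-level analyses

**Enrichment.** Each (cluster, term) pair gets both exact hypergeometric
tails — over- and under-representation of the term among the cluster's
genes relative to the gene universe (default: the union of all cluster
genes). The reported direction, "enriched" or "purified", is the smaller
tail and its probability the p-value; no doubling is applied, and terms are
opaque strings with no hierarchy propagation. BH-FDR runs across all pairs.

**Carbon/nitrogen categorisation.** A fixed, case-insensitive subsystem map
assigns macro-categories: amino acid metabolism, nitrogen metabolism,
nucleotide metabolism and the urea cycle to nitrogen; aldehyde degradation,
ascorbate metabolism, butanoate metabolism, the Calvin–Benson cycle, carbon
fixation, galactose metabolism, nucleotide sugar metabolism, oxidative
phosphorylation, photosynthesis, pentose interconversions, the pentose
phosphate pathway and pyruvate metabolism to carbon; the TCA cycle to both.
A cluster is flagged carbon (or nitrogen) when any significant — enriched
*or* purified — term maps there.

**Connectivity.** Cluster genes map to reactions by GPR mention (a gene
participates in a reaction if it appears anywhere in the boolean GPR;
the and/or structure is irrelevant for association counting), reactions
contribute their substrate or product metabolites (both sides for
reversible reactions), and currency metabolites — water, ATP, ADP, AMP,
NAD(P)(H), protons, oxygen, phosphate, pyrophosphate, CO2, matched
compartment-agnostically on the base id — are removed so cofactors do not
connect everything. The connectivity of two clusters is the number of
shared metabolites divided by the *total* metabolites of both clusters.
We read "total" as the union (Jaccard similarity): with the sum of the two
set sizes as denominator, scores cannot exceed 0.5 and a 0.9 threshold
would disconnect every pair, so the union is the only reading under which
a strict `score > 0.9` rule can fire. The sum denominator remains available
as an option. Edges require strictly more than the threshold — a pair
sharing 9 of 10 metabolites scores exactly 0.9 and is *not* connected.
Components and normalised betweenness are computed on the unweighted
topology via igraph.

# The synthetic toy model and planted fixtures

`makeToyModel()` builds a two-compartment network small enough to solve by
hand: bicarbonate/nitrate exchanges and transporters, carbon fixation,
nitrate assimilation, a biomass reaction consuming 6 fixed carbons and 1
organic nitrogen per unit growth, and four sinks (DMSP release at 5 C each;
nitrate storage; TAG at 50 C; chrysolaminarin at 6 + 1 C). Design choices:

* Integer carbon bookkeeping (one `cfix_c` = one carbon) makes conservation
  identities exact at every LP solution — the tests assert
  $6\,b + 5\,d_{\mathrm{DMSP}} = u_C$ and $b + s_{\mathrm{NO3}} = u_N$ with
  zero tolerance.
* The bicarbonate transporter exports a proton that fixation re-consumes,
  locking transport and fixation fluxes together and giving the model a
  currency metabolite for the connectivity filter to act on.
* The chrysolaminarin route carries one wasted carbon per unit
  (`chrysoPenalty`), so parsimonious FBA routes excess carbon through TAG
  deterministically. This is a modelling device to make the storage
  preference reproducible, not a biological claim about diatom storage
  economics; with the penalty at zero the two routes would tie and the
  reported split would depend on the tie-break.
* Closing every carbon sink makes over-breakpoint forced uptake infeasible,
  which the tests use as a mass-balance sanity check.

`makePlantedSamples()` draws null reactions i.i.d. from a shared normal (or
lognormal) and shifts the high condition of planted reactions by a stated
number of standard deviations. These matrices deliberately skip mass
balance: they are distribution-level fixtures for the statistic, while
feasibility of real sample sets is validated separately by the sampler
module. `makePlantedClusters()` realises requested pairwise Jaccard
overlaps through blocks of metabolites shared by exactly one cluster pair
(set size 100 gives ~0.01 overlap precision; jointly unachievable targets
raise an error naming the limit) and plants one enriched term per cluster.

What passing on these fixtures does and does not show: the generators
emulate distribution shifts, overlap structure and enrichment signal, but
not the autocorrelation of real sampling chains, the heavy right tails of
genome-scale flux marginals, or annotation noise in real GPRs. Results on
real models inherit the method's guarantees (exact LP, validated samples,
exact tails) but not the fixtures' effect sizes.

# Problem sizes and reproducibility

The packaged analyses run at desk scale: 20×20 FBA grids, 2000-point
sample sets, 200-reaction Monte-Carlo calibrations, 8-cluster connectivity
fixtures — the full test suite completes in well under a minute, and
`scripts/acceptance.R` re-derives every headline quantity from scratch in
a few seconds from a single `--seed`. Genome-scale runs (tens of thousands
of sample points over thousands of reactions) use the same code paths with
larger `nPoints`/`stepCount` and the seeded `subsample` option of
`testFluxShifts()`.

# Known limitations

* The simplex is dense and single-threaded; it is built for models up to a
  few hundred reactions. For genome-scale work, plug a sparse LP backend
  into the `solver` argument.
* No thermodynamic or enzyme-capacity constraints, no MILP designs, no
  quadratic objectives.
* The shift test's detectability threshold (~2.8 sd) makes it conservative
  by construction; shifts smaller than that are invisible regardless of
  sample size.
* Differential expression and biclustering are consumed as inputs, never
  computed.
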
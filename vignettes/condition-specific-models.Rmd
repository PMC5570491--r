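---
title: "Building condition-specific metabolic models from exometabolomic profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building condition-specific metabolic models from exometabolomic profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exoflux)
```

## The modeling problem

Quantitative extracellular metabolomics measures the rates at which cultured
cells consume and release metabolites — fluxes across the cell boundary, here
always in U = fmol/cell/hr, negative for uptake and positive for secretion.
Such profiles constrain a constraint-based metabolic model: each measured
rate pins the corresponding exchange reaction's flux window, shrinking the
steady-state solution space

$$\min\ \theta(v)\quad \text{s.t.}\quad S\,v = 0,\ \; lb \le v \le ub,$$

where $S$ is the stoichiometric matrix and $\theta$ a linear flux objective
(flux balance analysis, FBA).

Two obstacles make the integration non-trivial. First, targeted platforms
quantify only part of the exchanged metabolome, and serum-containing medium
has unknown composition, so the measured exchange set is incomplete: closing
every unmeasured exchange leaves no feasible steady state. Second, a measured
quantity can conflict with mass balance once earlier measurements are in
place. This package implements a complete pipeline that addresses both and
then phenotypes the resulting models.

## Pipeline

1. **Medium preparation** (`medium_config()`, `set_medium_constraints()`).
   Exchanges open at ±2000 U; class-specific uptake limits (ions −100 U,
   vitamins −1 U, essential amino acids −10 U, bulk compounds such as water
   and protons −100 U); oxygen restricted to `[-1000, 0]` U; uptake of
   reactive oxygen species closed so models cannot dodge oxygen metabolism.
   The biomass reaction's lower bound is fixed at 0.008 U — the growth rate
   of an 88-hour doubling time under $\mu = \ln 2 / T$ — and stays in place
   throughout model building. With a unitary cell weight of $10^{-12}$ g,
   fmol/cell/hr coincides numerically with mmol/gDW/hr, so models
   parameterized in the conventional unit need no rescaling.
2. **Qualitative screening** (`screen_qualitative_exchanges()`). Before any
   quantitative bound is trusted, each profiled metabolite is tested for
   whether the network can consume (forced `ub = -1e-4` U) and produce
   (forced `lb = +1e-4` U) it at all. Directions without a route are
   discarded per direction: a metabolite that can be taken up but not
   secreted keeps its uptake.
3. **Quantitative integration** (`integrate_quantitative()`). Each measured
   flux $x$ becomes the window spanned by $0.8x$ and $1.2x$ (20% allowance;
   the ends are ordered by value, so for an uptake of −860 U the 1.2-fold
   multiple −1032 is the *lower* bound). Pairs are applied one at a time in
   profile order with a feasibility check after each; on infeasibility the
   pair's previous bounds are restored and the rollback is logged. The
   outcome is order-dependent, which is why the ledger records the
   application order; profile row order is the deterministic choice.
   Zero-valued entries are flagged and skipped rather than applied as
   `(0, 0)` — they mean "below calibration", and closing the exchange would
   assert more than was measured.
4. **Exchange-cardinality minimization** (`min_exchange_cardinality()`).
   The smallest set of unmeasured exchanges that restores feasibility is
   found through the one-norm relaxation

   $$\min \mathbf{1}^T v_e \quad \text{s.t.} \quad [S\ S_e]
   \begin{bmatrix} v \\ v_e \end{bmatrix} = 0,\quad lb \le v \le ub,
   \quad 0 \le v_e,$$

   with every candidate exchange split into nonnegative uptake and
   secretion components (capped at the 2000 U medium magnitude so the LP is
   bounded). Only the candidate components need the unidirectional split —
   the relaxation's objective touches nothing else — so interior reversible
   reactions keep their native bounds. Minimizing flux is not the same as
   minimizing count, so `verify_minimality_fva()` closes each active
   exchange in turn; any exchange whose closure leaves the system feasible
   is eliminated and the minimization re-runs (capped at 10 rounds). On
   every shipped fixture the verified cardinality equals
   `brute_force_min_card()`, the exhaustive oracle.
5. **Pruning** (`prune_model()`). Unused candidate exchanges are removed,
   then every net, non-exchange reaction unable to carry $|v| \ge 10^{-4}$ U
   in any feasible steady state (blocked reactions) is removed. Pruning must
   preserve the optimal biomass to a relative $10^{-6}$; a violation is an
   error, indicating the threshold is too coarse for the model at hand.

`build_condition_model()` chains steps 1–5 and attaches the constraint
ledger and verification report as attributes.

## Phenotyping the models

* **Flux splits** (`flux_splits()`): with a parsimonious-FBA solution
  maximizing ATP production, every reaction producing a target metabolite
  contributes $P_{ij} = S_{ij} v_j > 0$; shares are $P_{ij}/\Phi_i$ with
  $\Phi_i = \sum_j P_{ij}$. Transport reactions (target metabolite on both
  sides, possibly across compartments) and exchanges are excluded before
  summation, and an extra exclusion list mirrors curated discard tables.
* **ATP yield** (`atp_yield()`): $\Phi_{ATP}$ over the absolute glucose
  uptake. Note the semantics: this is a *production sum*. On the glycolytic
  toy network the two kinases produce 4 ATP per glucose while 2 are
  invested upstream, so `atp_yield()` reports 4 — whereas the *net*
  textbook figures (2 anaerobic, 32 aerobic) are what
  `max_atp_from_glucose()` reports, which closes all carbon uptakes except
  glucose, opens secretion bounds and maximizes ATP hydrolysis. Both
  numbers are meaningful; they answer different questions.
* **Energy classification** (`classify_energy_phenotype()`): the major ATP
  producer decides the class — phosphoglycerate kinase marks glycolytic
  models, ATP synthase OxPhos models — and the (ATP, NADH, NADPH, FADH2)
  major-producer tuple is looked up in a subtype table. The shipped
  `default_subtype_table()` reconstructs the eight published tuples from
  their described structure (the glycolytic pair differs only in the FADH2
  producer; NADPH splits the OxPhos models among dihydroceramide
  desaturase, cytosolic malic enzyme and isocitrate dehydrogenase; the
  NADH producer separates more-glycolytic from more-oxidative members),
  but reaction identifiers are reconstruction-specific, so the table is
  ordinary data the user can replace. Observed ATP-yield boundaries
  between classes are descriptive statistics, not the classifier.
* **Perturbation scans**: `phpp_scan()` fixes two exchange fluxes on a grid
  (defaults follow the spread of measured constraints: oxygen 0→−1000 U,
  glucose 0→−1080 U, glutamine 0→−400 U, lactate 1620→0 U, step 20 U) and
  maximizes biomass, flagging infeasible points rather than reporting zero.
  `classify_oxotype()` reduces the oxygen axis to a class: feasible only at
  low uptake magnitudes, only at high, or indifferent. The low/high
  boundary is never quantified in the source material — classification
  there was visual — so the split point is a configurable parameter
  defaulting to the midpoint of the scanned range, and the interval rule is
  documented as an interpretation.
* **Essentiality** (`single_gene_deletion()`, `reaction_essentiality()`):
  GPR rules are evaluated with all transcript variants of a gene off at
  once (a trailing `.N` suffix is the overridable transcript convention);
  reactions whose rule fails are closed and biomass re-maximized with the
  minimal-growth bound relaxed, so sub-threshold growth is measurable.
  Classes relative to the model's own wild-type maximum: terminated below
  5%, reduced between 5% and 95%, unchanged at or above 95%.
* **Reductive carboxylation** (`detect_reductive_carboxylation()`): flux
  variability of the isocitrate dehydrogenase and aconitase reactions
  (oxidative direction positive) at the minimal-growth bound, optionally
  after clamping oxygen (e.g. `lb = ub = -100` U). An entirely negative
  range is obligate reverse flux; a range spanning zero leaves the pathway
  optional.

## The optimization kernel

No linear-programming library is available to this package's dependency
set, so the kernel is a self-contained bounded-variable two-phase primal
simplex (`solve_lp()`): box bounds are handled natively (no constraint-row
doubling), the basis system is refactorized from scratch at every pivot so
no factorization error accumulates, and pivoting switches from the Dantzig
rule to Bland's rule after 500 iterations, which rules out cycling. This is
a deliberate design for the package's regime — dense problems with tens of
reactions — where refactorization costs microseconds and robustness matters
more than speed. The kernel is validated in the test suite against an
independent implementation (scipy's HiGHS-based `linprog`) on randomized
box-bounded equality LPs and against COBRApy on the aerobic toy network.

Determinism: candidate exchanges enter the LP in lexicographic order and
the pivoting rules are deterministic, so repeated runs return identical
active sets. Among alternate one-norm optima the tie-break is therefore
lexicographic by exchange id; the minimality verification makes the final
set independent of which optimum was hit whenever the true minimum is
unique.

Parsimonious FBA fixes the stage-1 optimum to a relative tolerance of
$10^{-7}$ (numerical headroom for the quadratic program; the realized
objective deviation stays well within the documented $10^{-6}$) and
minimizes the squared Euclidean norm of internal fluxes via `quadprog`,
with a vanishing $10^{-6}$ weight on exchange fluxes that makes the
quadratic form strictly convex and the solution unique. The norm domain is
internal reactions: flux-split analysis is the operative consumer of the
unique vector, and penalizing exchanges would distort measured uptakes.

Flux sampling (`sample_fluxes()`) is an artificial-centering hit-and-run:
warmup points come from the per-reaction variability LPs, directions mix
null-space Gaussians with directions through random warmup points, and the
chain recenters on a running mean. Every step stays exactly on
$S v = 0$ because directions live in the null space of $S$; only the box
bounds clip the step interval. A seed is a required argument.

## What the toy generators emulate — and what they do not

The fixture module stands in for a genome-scale human reconstruction plus
a measured exometabolome. Yields are exact by construction: textbook P/O
ratios of 2.5 (NADH) and 1.5 (FADH2) realize 32 ATP per fully oxidized
glucose ($2 + 2 + 10 \times 2.5 + 2 \times 1.5$) and 2 per anaerobically
fermented glucose; the 36/38 ATP conventions are deliberately not used.
Lumped reactions (one TCA turn as a single column) target stoichiometric
yield fidelity, not pathway enumeration. The exchange-completion fixtures
build growth requirements whose unique minimal completion is known by
construction and re-derived by exhaustive LP at test time; identifier
shuffling by seed prevents the minimizer's tie-breaking from accidentally
aligning with construction order. Synthetic profiles draw from a
parsimonious-FBA reference flux with multiplicative noise
$x = v(1+\delta)$, $\delta \sim U(-\eta, \eta)$: for $\eta \lesssim 1/6$
the true flux provably stays inside the 20% allowance window of the
reported value, so integration applies every pair.

Passing tests on these fixtures demonstrate the correctness of the
algorithms — oracle equality of the cardinality minimization, bound
handling, rollback logic, classification rules — not the biological
fidelity of any genome-scale result. Real reconstructions bring degenerate
alternate optima at much larger scale, metabolite-identifier mismatches,
and measured profiles whose replicate variability the generator does not
emulate.

## Numerical choices and degenerate inputs

* LP feasibility/optimality tolerances: $10^{-9}$ pivot tolerance; phase-1
  infeasibility declared above $10^{-6} (1 + \max|b|)$.
* A candidate counts as active above $10^{-6}$ U (`active_tol`), two
  orders below the minimal-growth bound that drives typical additions and
  two above solver noise.
* Blocked-reaction threshold $\varepsilon = 10^{-4}$ U; the screening flux
  magnitude equals it.
* Missing bounds in an input file are an error, never a default; all
  bounds must be finite, which keeps every LP bounded by construction.
* Zero production in a flux split yields an explicitly flagged empty
  report; zero glucose uptake makes the ATP yield an error, not a zero.
* Knockout growth is clamped at wild type (`min(ko, wt)`) so solver noise
  cannot produce a knockout that "out-grows" the wild type.
* Infeasible knockouts (fixed secretion windows can make a deletion model
  entirely infeasible) report zero growth and class "terminated".

## Problem sizes

The shipped analyses run on networks of 5–40 reactions; the
exchange-completion oracle suite enumerates subsets for up to 12 candidate
exchanges over 30 seeded instances, and the sampling demonstrations use a
few hundred points of a few dozen steps. These sizes keep every documented
property exactly checkable (closed forms, exhaustive enumeration) while
exercising the same code paths a genome-scale model would take.

## Known limitations

* The simplex kernel is dense; genome-scale models (thousands of
  reactions) need a sparse industrial LP solver behind the same
  `solve_lp()` surface.
* The rollback outcome of quantitative integration depends on profile
  order (inherent to the sequential scheme); the ledger records the order.
* The subtype table ships as a reconstruction-agnostic template; applying
  it to a specific reconstruction requires mapping its reaction ids.
* The oxotype split is an interpretation with a configurable default, not
  a measured constant.
* SBML support covers Level 3 + FBC v2 as produced by this package and by
  COBRA-style exporters; exotic SBML constructs (rules, events,
  `speciesReference` ids) are out of scope.
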
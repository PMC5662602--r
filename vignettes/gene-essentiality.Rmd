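---
title: "Gene essentiality analysis of polyamine biosynthesis with fbagea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene essentiality analysis of polyamine biosynthesis with fbagea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbagea)
```

## The model and its assumptions

`fbagea` implements flux balance analysis (FBA) and the gene essentiality
analysis built on it. A constraint-based model consists of a stoichiometric
matrix $S$ (metabolites $\times$ reactions), flux bounds $l_r \le v_r \le u_r$
(mmol gDW$^{-1}$ h$^{-1}$), and boolean gene-protein-reaction (GPR) rules. The
steady-state assumption — internal metabolite concentrations constant, so
production balances consumption — gives the mass-balance constraint

$$\sum_r S_{cr}\, v_r = 0 \quad \text{for every metabolite } c,$$

and growth is predicted by maximizing the flux $v_{bio}$ of an artificial
biomass reaction that consumes the building blocks of new cells:

$$\max v_{bio} \quad \text{s.t.} \quad S v = 0,\; l \le v \le u.$$

Metabolite concentrations are deliberately not represented: only the
steady-state flux space is. Exchange reactions are written
`met <-> (nothing)`; negative flux is uptake and the growth medium is the set
of exchange lower bounds (`apply_medium()` closes uptake for every substrate
it does not list, matching the convention of fixing intake fluxes of
non-available substrates to zero).

A gene deletion is translated through the GPR rules: the deletion of $g$
disables the reaction set $N(g)$ of reactions whose rule evaluates FALSE with
$g$ removed (AND = complex subunits, OR = isozymes; the grammar has no NOT,
which is why deletions are monotone — removing more genes can only disable
more reactions). Those reactions' bounds are clamped to $[0,0]$ and the LP is
re-solved. A gene is **essential** when the re-optimized $v_{bio}$ falls
strictly below the lethality threshold; a **synthetic lethal pair** is a pair
of individually non-essential genes whose joint deletion is lethal.

## Parameters that matter

* `threshold` (default $10^{-4}$ gDW/h): the minimum biomass production rate
  regarded as compatible with proliferation. The classification uses strict
  inequality, so a knockout growing at exactly the threshold is
  non-essential; `threshold_sweep()` re-classifies one screen's growth values
  over a ladder of thresholds (one LP per gene in total), and the resulting
  essential sets are nested by construction.
* `solver_config(big_M = 1000)`: cap for unbounded flux directions, the
  community convention for "a large positive scalar". Any value well above
  realistic pathway fluxes gives identical results.
* `feas_tol = opt_tol = 1e-9`: solver tolerances, kept five orders of
  magnitude below the lethality threshold so no essentiality call can hinge
  on solver noise; objectives within `opt_tol` of zero are reported as
  exactly 0.
* `polyamine_biomass_spec(coefficient = 0.01)`: biomass demand per polyamine
  (mmol/gDW), of the order used for minor biomass species in published
  reconstructions. It is a documented stand-in — the exact demands are not
  fixed by the analysis this package reproduces — and the lethality verdicts
  are invariant to it over $[10^{-4}, 1]$ (the demand only needs to be
  nonzero), which a test enforces.

## The LP layer

No dedicated LP interface is assumed: the default backend is a dense
two-phase bounded-variable simplex written for this package, with fully
deterministic pivoting (Dantzig pricing, lowest-index tie-breaks, Bland's
rule as an anti-cycling fallback), so a given model yields bit-identical
solutions across runs. `pracma::linprog` is wired as a second, pluggable
backend; because its pivot tie-breaks are randomized, the adapter runs it
under a fixed local seed and retries a handful of seeds when a tie-break path
stalls. Both backends must agree within `opt_tol`; a property test and the
robustness checks hold them to that. Every optimal solution is re-verified
against the mass-balance residuals and bounds (the feasibility certificate)
before it is accepted.

Knockouts are implemented by clamping bounds rather than deleting matrix
columns; a test confirms the two are equivalent. Double-deletion screens
memoize growth by the *disabled-reaction set*, not by gene pair, so pairs
that collapse to the same reaction knockout are solved once — with OR-heavy
GPRs this removes most of the $G^2$ LPs without changing any result, because
the memo key is the exact LP being solved.

## The curated polyamine mini-model

`build_polyamine_minimodel()` encodes the polyamine biosynthesis pathway at
desk scale: methionine adenosyltransferase (GPR
`MAT1A or (MAT2A and MAT2B)`) supplies SAM; AMD1 decarboxylates it to dcSAM,
the aminopropyl donor; ARG1 and the reversible OAT are the only two ornithine
producers; ODC1, SRM and SMS build putrescine, spermidine and spermine; MTAP
is the only consumer of the MTA byproduct, yielding adenine; APRT and (until
corrected) the mis-annotated PNP reaction are the only adenine consumers.
Biomass consumes a generic imported precursor plus, optionally, the three
polyamines. Uptakes are capped at 10 mmol/gDW/h, so wild-type growth is
exactly 10 gDW/h and every lethal knockout drops it to exactly 0 — the
screen's verdicts sit far from the threshold on both sides.

Two structural facts carry the interesting biology. First, MTA has no sink:
at steady state spermidine/spermine synthesis is impossible unless MTA is
drained through MTAP, which is what makes MTAP essential. Second, adenine has
no sink either, so once the spurious PNP adenine reaction is removed
(`correct_pnp_annotation()`, which deletes PNP-gated adenine-consuming
reactions direction-agnostically and retains PNP's genuine guanine/
hypoxanthine/uracil activities), APRT becomes the sole adenine outlet and
turns essential, while the APRT/PNP synthetic-lethal pair dissolves.

SMS is included because the pathway chemistry requires it for spermine, and
it is flagged essential whenever spermine is in biomass even though the
reference analysis does not list it — most plausibly a GPR gap in the source
genome-scale model. Table-reproduction tests therefore assert containment of
the listed genes rather than exact set equality.

The optional `add_xdh_branch()` adds the adenine → 2,8-dihydroxyadenine (DHA)
reaction (GPR: XDH) with a *closed* DHA sink. DHA is a poorly soluble,
growth-suppressive end product, so treating it as a free drain would let the
LP launder excess adenine through XDH and spuriously rescue the APRT
knockout; with the sink closed the branch carries no steady-state flux and
APRT keeps its essentiality. Setting `dha_sink_ub > 0` reproduces the rescue
explicitly if the user wants to see it.

## The synthetic generator and the reachability oracle

`generate_model()` assembles models from motifs whose verdicts are known by
construction: gene-gated linear chains (each chain gene essential), redundant
branches encoded either as two parallel reactions or as one OR-rule reaction
(each branch pair synthetic lethal, neither member essential), AND-gated
complexes (both subunit genes essential), and a gene-gated decoy into a
sinked dead end (non-essential). All coefficients are $\pm 1$, every
byproduct has a sink, and all randomness — identifier tags, motif encodings,
reaction order — flows from a single seed, so one seed gives byte-identical
model JSON. These models emulate the *logic* of a genome-scale screen
(redundancy, complexes, dead ends) but none of its scale, loops, cofactor
coupling or non-unit stoichiometry; passing them shows the screen machinery
is correct, not that any particular genome-scale reconstruction is.

`reachability_oracle()` answers the lethality question for this restricted
class without an LP. It computes two least fixpoints: *producible*
metabolites (a reaction fires once its substrates are reachable from the
medium and its GPR is TRUE) and *drainable* metabolites (consumed by some
active reaction whose co-substrates are producible and whose products are all
drainable, grounded in sinks and secretion). The least-fixpoint formulation
is essential: two reactions shuttling a metabolite back and forth justify
each other under a greatest fixpoint but drain nothing. Reactions failing
either test are pruned and the fixpoints re-run until stable; biomass is
producible iff its reaction survives. The drainability check is the
steady-state byproduct-clearance requirement — the MTA example above is
exactly the case it exists for. The oracle refuses models outside its safe
class (any non-unit coefficient outside the biomass reaction) rather than
guessing; biomass coefficients are exempt because producibility of a demand
metabolite does not depend on its demand magnitude. The central property
test compares the oracle with the LP screen on every single and double
deletion of 100 seeded models and of the mini-model variants.

## Numerical and design choices

* Stoichiometric coefficients are stored as exact integer rationals and
  converted to doubles only when the LP matrix is assembled; the JSON
  serializer writes `"p/q"` strings for non-integral values, so write–read
  round-trips are bit-exact (including thirds) and structural sign tests
  never see float noise. Decimal inputs expand exactly (0.01 → 1/100);
  irrational-looking doubles should be passed as fraction strings.
* Ordering is part of every contract: metabolites and reactions keep
  insertion order (fixing the LP column layout), genes and reported pairs are
  lexicographic, and report floats are written with 12 significant digits —
  two runs of the same configuration produce byte-identical TSV/JSON output.
* Degenerate inputs: models that cannot grow at the threshold are rejected
  before a screen starts; genes absent from every GPR are recorded at
  wild-type growth without an LP solve; re-correcting an already corrected
  model warns explicitly instead of silently doing nothing; infeasible LPs
  report `status = "infeasible"` rather than a zero objective.

## Problem sizes used in the shipped checks

The test suite and the acceptance script work at desk scale by design: the
mini-model (21 metabolites, 24 reactions, 12 genes) is screened exhaustively,
and the generator sweep uses 100 seeded models of at most 15 genes each,
giving several thousand LP/oracle comparisons in a few seconds. The same
machinery accepts any model in the supported JSON dialect, including trimmed
exports of genome-scale reconstructions, at correspondingly larger cost
($G$ LPs for a single screen, up to $G^2/2$ minus memoization hits for a
double screen).

## Known limitations

Plain FBA only — no flux variability analysis, no MOMA/ROOM-style knockout
models, no thermodynamic or kinetic constraints, and no representation of
metabolite pools (polyamine pool sizes and catabolism rates are exactly the
kind of refinement this framework cannot see). The oracle is exact only on
its safe class; outside it, the LP is the sole authority. SBML is not read
or written; the JSON dialect is the interchange format.
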
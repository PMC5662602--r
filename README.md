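# fbagea

Flux-balance-analysis gene essentiality screening for constraint-based
metabolic models, built around the polyamine biosynthesis pathway in cancer
metabolism.

## The problem

Constraint-based models predict metabolic phenotypes from a stoichiometric
matrix $S$, flux bounds $l \le v \le u$ and the steady-state assumption
$Sv = 0$. Growth is the flux $v_{bio}$ of a biomass reaction that consumes
the building blocks of new cells, and gene essentiality analysis (GEA) asks
which gene deletions make growth impossible: a gene $g$ is **essential** when

$$\max\; v_{bio} \;\;\text{s.t.}\;\; Sv = 0,\; l \le v \le u,\; v_r = 0 \;\forall r \in N(g)$$

falls strictly below a lethality threshold ($10^{-4}$ gDW/h by default),
where $N(g)$ is the set of reactions whose boolean gene–protein–reaction
(GPR) rule evaluates FALSE once $g$ is deleted. A **synthetic lethal pair**
is a pair of individually non-essential genes whose joint deletion is lethal.

Polyamines (putrescine, spermidine, spermine) are required for tumor cell
proliferation but are typically absent from the biomass equations of cancer
metabolic models, so GEA is blind to the pathway that makes them. This
package provides the two curation edits that change that — augmenting the
biomass reaction with polyamine demands, and removing the adenine-degrading
activity mis-annotated to PNP (human PNP does not act on adenine) — together
with the screening machinery, a curated mini-model of the pathway, a seeded
random-model generator with planted ground truth, and an LP-free
reachability oracle that independently verifies every verdict on small
models. It is aimed at people who work with metabolic reconstructions and
want an auditable, deterministic knockout screen at desk scale.

## Worked example

```r
library(fbagea)

mod <- build_polyamine_minimodel()     # polyamines in biomass, PNP uncorrected
scr <- double_deletion_screen(mod)
scr
#> <gea_screen>  threshold: 1e-04 gDW/h   wild-type growth: 10
#>   genes screened: 12   essential: 5
#>   essential genes: AMD1, MTAP, ODC1, SMS, SRM
#>   pairs screened: 21   synthetic lethal: 4
#>   synthetic lethal pairs: APRT&PNP, ARG1&OAT, MAT1A&MAT2A, MAT1A&MAT2B

fixed <- correct_pnp_annotation(mod)   # drop the spurious adenine-PNP reaction
double_deletion_screen(fixed)
#> <gea_screen>  threshold: 1e-04 gDW/h   wild-type growth: 10
#>   genes screened: 12   essential: 6
#>   essential genes: AMD1, APRT, MTAP, ODC1, SMS, SRM
#>   pairs screened: 10   synthetic lethal: 3
#>   synthetic lethal pairs: ARG1&OAT, MAT1A&MAT2A, MAT1A&MAT2B
```

Reading the output: wild-type growth is 10 gDW/h (capped by precursor
uptake). With polyamines in biomass, the single-deletion screen finds the
pathway's bottleneck enzymes essential — AMD1 (dcSAM supply), ODC1
(putrescine), SRM/SMS (spermidine/spermine) and MTAP, which is essential
because it is the only drain for the obligatory MTA byproduct of polyamine
synthesis. The four synthetic-lethal pairs are the pathway's redundancies:
the MAT isozymes, the two ornithine producers ARG1/OAT, and the two adenine
consumers APRT/PNP. After the PNP correction, APRT is the sole adenine
outlet: it becomes essential and the APRT&PNP pair disappears. (SMS is
essential here because the mini-model gives spermine synthase its own gene;
see the vignette for why reference gene lists may omit it.)

Other entry points: `single_deletion_screen()`, `threshold_sweep()`,
`differential_essentials()` (hits specific to a biomass variant),
`augment_biomass()` / `polyamine_biomass_spec()`, `add_xdh_branch()`,
`generate_model()` + `reachability_oracle()`, `read_model()` /
`write_model()` for the documented COBRA-JSON subset
(`inst/extdata/model.schema.json`), and `run_pipeline()` behind the
`inst/scripts/gea.R` command line (subcommands `screen`, `simulate`,
`curate`, `sweep`, `convert`).

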
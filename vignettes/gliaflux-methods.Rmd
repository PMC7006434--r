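---
title: "gliaflux methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gliaflux methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaflux)
```

## The modeling problem

Astrocytes protect neurons by clearing extracellular glutamate (recycled to
glutamine), exporting lactate, D-serine and reduced glutathione, and
buffering ATP demand. Chronic exposure to saturated free fatty acids such
as palmitate pushes these cells into an inflammatory state in which those
supportive functions degrade; tibolone, a synthetic steroid whose tissue
metabolites act on estrogen, progesterone and androgen receptors, is a
candidate counter-treatment. `gliaflux` frames this biology as
constraint-based modeling: a compartmentalized metabolic network is reduced
to its stoichiometric matrix $S$ ($m$ metabolites $\times$ $n$ reactions),
and the cell state is a steady-state flux vector $v$ solving

$$\max_v\; c^\top v \quad \text{s.t.}\quad S v = 0,\;\; lb \le v \le ub,$$

with $c$ selecting either the biomass pseudo-reaction or one of five
astrocyte objective functions (glutamate to glutamine, glycine to D-serine,
glucose to 2 lactate, glucose to 36 ATP, cysteine to reduced glutathione).
Fluxes are in mmol/gDW/h throughout; uptake through an exchange reaction is
negative flux by the usual convention, so medium composition is expressed
entirely through exchange lower bounds.

The three scenarios are: **healthy** (medium-constrained network, palmitate
uptake left to the optimizer), **inflammatory** (palmitate exchange fixed
at the mean half-maximal-inhibitory uptake, IC50, over the five
objectives), and **treatment** (inflammatory network plus a ten-reaction
tibolone set and a configurable estradiol-effect stub).

## The linear-programming layer

No LP backend is assumed: the target networks are small (tens of
reactions), so the package implements a dense bounded-variable two-phase
simplex. Three design choices matter to users:

* **Determinism.** Entering and leaving variables follow Bland's
  smallest-index rule with a fixed variable order. This forgoes speed
  (irrelevant at this scale) for two properties the pipeline depends on:
  termination is guaranteed without cycling, and repeated runs return
  byte-identical flux vectors.
* **Tolerances.** Reduced-cost and pivot tolerance is $10^{-9}$ (scaled by
  the objective magnitude); phase-1 feasibility is accepted below $10^{-7}$
  scaled by $\lVert b\rVert_\infty$. Every optimal solution is guaranteed
  to satisfy $\lVert S v\rVert_\infty \le 10^{-9}\max(1,\lVert
  v\rVert_\infty)$ — the test suite asserts this on every fixture. Reported
  fluxes below $10^{-9}$ are printed as 0 in TSV reports; solver state is
  never clamped.
* **Degenerate optima.** FBA optima are routinely non-unique. All
  cross-scenario comparisons therefore use `canonical_fluxes()`, the
  parsimonious solution: among optima of the objective (held within a
  relative $10^{-9}$), total absolute flux $\sum_j |v_j|$ is minimized over
  a split $v = v^+ - v^-$. This also zeroes internal cycles that carry no
  net function.

The solver is validated against two independent oracles: exhaustive vertex
enumeration of $\{Sv = 0,\; lb \le v \le ub\}$ for $n \le 6$ (agreement to
$10^{-8}$), and `scipy.optimize.linprog`/HiGHS on the toy network.

## Expression constraining and gap filling

Reaction capacity is tied to transcript abundance through
gene-protein-reaction (GPR) boolean rules. The combination rule is a design
decision the underlying data do not dictate; the package uses **AND = min**
(an enzyme complex is limited by its scarcest subunit) and **OR = sum**
(isoenzymes add capacity), with missing genes scoring 0 (no transcript, no
capacity — note the consequence that one missing gene zeroes an AND node).
Scores scale bounds proportionally: the highest-scoring reaction receives
`bound_cap` (default 1000 mmol/gDW/h, the conventional "unbounded" flux
cap), every other reaction $\mathrm{bound\_cap}\cdot s/s_{\max}$, negated
for the lower bound of reversible reactions. The scaling is invariant to
uniform rescaling of the profile, so expression units are irrelevant;
exchange reactions are never expression-limited.

Reactions whose GPR genes are entirely absent from the profile have no
correlated expression; the pipeline removes them and lets `gap_fill()` add
them back on demand: each round, every candidate whose *addition cost* —
the fraction of its metabolites absent from the model, in $[0,1]$ — is at
or below the threshold (default 0.25) is added, until the objective
optimum exceeds $10^{-9}$, the pool empties, or `max_rounds` (100) is hit.
Costs are re-evaluated every round because added reactions contribute
metabolites. The default threshold admits reactions anchored at least 75%
in the existing metabolite pool, which keeps gap filling from importing
disconnected subnetworks.

## Robustness, IC50 and the inflammatory forcing

`robustness_curve()` fixes the control exchange at uptake $u$
($lb = ub = -u$) for each of $n$ grid points (default 1000 on $[0, 1]$
mmol/gDW/h) and maximizes the objective. Grid points where the forced
uptake is infeasible are scored 0 and flagged — biologically, shutdown; the
flag keeps them distinguishable from a true zero optimum. The value
function of a maximization LP is concave in a bound parameter, so curves
are concave on their feasible prefix (asserted in the tests); the flagged
tail can break concavity at the crossover and is excluded from that check.

Two conventions were open and are fixed as follows: the IC50 **reference**
is the maximum objective value on the grid (not the value at zero uptake —
identical for monotone curves, more robust otherwise), and the IC50 is the
smallest uptake where the objective first reaches half that reference,
linearly interpolated between bracketing grid points. `mean_ic50()`
averages per-objective IC50s; objectives whose curve never falls to
half-maximum have no IC50 and are **excluded and reported** rather than
imputed. The inflammatory scenario then fixes the palmitate exchange to the
mean (lb = ub = $-\mathrm{IC50}_{\text{mean}}$).

## Fold changes and knockout classification

Flux differences between scenarios use

$$\mathrm{fc}(v_{\text{ref}}, v_{\text{alt}}) =
  \begin{cases} v_{\text{alt}}, & v_{\text{ref}} = 0\\[2pt]
  (v_{\text{alt}} - v_{\text{ref}})/|v_{\text{ref}}|, &
  \text{otherwise,}\end{cases}$$

with zero tested at $10^{-9}$. Of the two sign conventions in circulation
for the numerator, the package uses (alt $-$ ref): it is the one consistent
with the worked example frozen in the acceptance suite
(`fold_change_value(0.39, 1.28)` = 2.28 for a reaction whose flux rises
under inflammation). Records are filtered at $|\mathrm{fc}| \ge 2$ (the
conventional reporting threshold) and computed on the intersection of the
two reaction universes, so scenario-specific additions (the tibolone set)
are compared through their effect on shared fluxes, not through their own.

Knockout screening evaluates a **lexicographic objective**: biomass is
maximized first, then the chosen objective function subject to biomass
staying within a relative $10^{-6}$ of its optimum. The two-stage scheme is
deliberate: in a single LP a knockout shrinks the feasible set and can
never raise the optimum, so "knockout increases the objective" is only
meaningful when a prior stage absorbs shared resources — removing a
reaction the biomass stage depends on releases those resources to stage 2.
Labels, in precedence order:

1. **pro_inflammatory** — the stage-2 objective rises by more than `eps`
   (default $10^{-6}$, relative);
2. **anti_inflammatory** — the reaction changed $\ge 2$-fold between
   healthy and inflamed scenarios *and* its knockout lowers the
   lexicographic objective (stage 1 down, or stage 1 equal and stage 2
   down); an infeasible knockout scores (0, 0);
3. **treatment_essential** — for candidates from the tibolone/estradiol
   set only: knocking the reaction out in the treated model returns the
   *pair* (biomass, stage-2 objective) to the inflamed pair within `eps`.
   The pair, not the stage-2 value alone, defines "the treatment effect":
   in the toy network both scenarios drive the stage-2 value to zero
   (biomass consumes the whole capacity pool first), so a stage-2-only
   criterion would degenerately mark every candidate essential. A stricter
   whole-vector criterion (small $\lVert v_{\text{treated,ko}} -
   v_{\text{inflamed}}\rVert$) was considered and rejected as the default:
   parsimonious vectors can differ on zero-effect cycles of the added
   reactions themselves.
4. **neutral** — everything else.

The two objective constructs themselves (biomass and the stage-2 objective
reaction) are excluded from the candidate list: knocking out the measuring
stick is not an intervention.

## The synthetic toy astrocyte: what it emulates

`generate_toy_astrocyte()` builds a 30-metabolite, 35-reaction network over
compartments e/c/m covering glucose uptake, lumped fermentation (1 glucose
$\to$ 2 lactate), lumped oxidation (1 glucose + 6 O$_2$ $\to$ 36 ATP),
glutamine synthetase, a lumped glycine-to-D-serine conversion (2 glycine
$\to$ D-serine + CO$_2$ + NH$_3$), glutathione synthesis, palmitate
beta-oxidation, and a biomass pseudo-reaction. All chemical species carry
elemental formulas and every non-exchange, non-pseudo reaction is
elementally balanced; ATP/ADP/phosphate use bookkeeping elements (Q, P) so
that energy accounting is balance-checkable without modeling full adenine
chemistry. `validate_model()` returns zero findings on the default model.

The engineered ground truths, and the parameters that set them:

| parameter | default | meaning |
|---|---|---|
| `glucose_cap`, `glutamate_cap`, `glycine_cap`, `cysteine_cap` | 1, 1, 2, 1 | uptake caps (mmol/gDW/h) sizing each objective's optimum |
| `palmitate_cap` | 1 | healthy-scenario palmitate availability |
| `o2_cap` | 25 | sized so beta-oxidation is never oxygen-limited on the robustness grid |
| `atp_yield_ox` | 36 | ATP per glucose, the classical textbook yield matching the objective-table stoichiometry (not modern 30–32 estimates) |
| `lactate_yield` | 2 | lactate per glucose |
| `capacity_pool` | 1 | supply rate of the shared mitochondrial capacity token |
| `inhibition_u0` | 0.5 | forced palmitate uptake at which every objective hits 0 |
| `tibolone_cap`, `relief_per_estradiol` | 2.5, 0.5 | treatment-scenario tibolone uptake and capacity regenerated per estradiol |

The inhibition mechanism is a deliberately simple linear coupling: every
objective's terminal reaction consumes a shared finite capacity token
(`ctrf`, supply $C$ per hour) at rate $C/z_0$ per unit flux, and
beta-oxidation consumes it at $C/u_0$ per unit palmitate. Forcing uptake
$u$ leaves $C(1 - u/u_0)$ of the pool, so each objective declines exactly
linearly, $z(u) = z_0 (1 - u/u_0)$, and every IC50 is $u_0/2$ in closed
form — a parameter-recovery target the test suite checks at
$u_0 \in \{0.2, 0.5, 0.8\}$ to two grid spacings. The capacity token is
the one metabolite without a formula: it is a capacity, not a chemical,
and attaching a formula would force fake balancing species through every
consumer. In a genome-scale network the same inhibition is an emergent
property of redox and CoA sequestration; nothing that linear should be
expected there, which is exactly why the toy states it explicitly.

The treatment add-on follows the same philosophy. The ten tibolone
reactions are the printed set (exchange; 3α/3β-hydroxy interconversions;
Δ4-isomer formation; estradiol-receptor conversions; progesterone/androgen
receptor activation; sulfation and sink). Steroid metabolites carry no
formulas — the conversions are receptor-level events, not balanced
chemistry (a C21 steroid "becoming" C18 estradiol), mirroring annotation
gaps in real reconstructions — so mass-balance checking skips rather than
fails them. The five-reaction estradiol stub (relief reaction regenerating
`relief_per_estradiol` capacity units per estradiol, deactivated-steroid
export, two receptor-token sinks) stands in for a catalog of hundreds of
estradiol-derived database reactions that is explicitly out of scope; it
is fictional and documented as such. Defaults are sized so the treated
biomass optimum is 3.5 versus 1.0 inflamed: the treatment effect then
crosses the 2-fold reporting threshold on shared growth-linked fluxes,
and knocking out the tibolone exchange `T1` (or any single-point link of
the relief path) collapses the model exactly back to the inflamed state —
the toy's treatment-essential ground truth.

Synthetic expression profiles are log-normal (meanlog 2, sdlog 0.5) over
the model's genes — heavy right tail, everything positive, the shape
expected of mean expression values; with ~25 genes the induced bound
ratios stay far above any achievable flux, so default profiles constrain
shape, not feasibility.

**What a green test does not establish.** The toy network demonstrates
that the machinery is correct (yields, IC50 recovery, classification
ground truth, determinism); it does not validate any genome-scale claim.
Emergent inhibition curves, realistic growth rates (the toy's 2.0
mmol/gDW/h biomass is a design constant, not a prediction), degenerate
alternate optima at scale, and the behavior of gap filling on
thousand-reaction candidate pools are all outside what the fixtures can
show.

## Numerical and interface conventions

* Default bounds are $\pm 1000$ (0 to 1000 for irreversible reactions);
  reversibility and `lb < 0` are kept consistent at construction.
* Metabolite ids accept both `glu_L[e]` and `glu_L_e` dialects and are
  normalized to bracket form; exchange ids accept legacy spellings
  (`EXhdca(e)` resolves to `EX_hdca_e`).
* Reaction formulas accept Unicode and ASCII arrows; output is ASCII.
* SBML IO covers Level 3 core plus fbc-style bounds/GPR/objective —
  exactly what FBA consumes; kinetic laws are skipped with a warning.
  Subsystem tags and the pseudo-reaction kind travel in a private
  namespace so a write/read round trip is exact; files are readable by
  cobrapy.
* Orphan-metabolite validation treats a reversible reaction as both
  producer and consumer of all its participants, and excludes exchanges;
  blocked-reaction analysis is a separate, flux-based report (FVA with all
  exchanges opened, threshold $10^{-9}$), and the two are deliberately
  independent findings.
* All report writers sort by reaction id and print 6 significant digits;
  the pipeline writes no timestamps, so a fixed config and seed give
  byte-identical outputs.

## Known limitations

* The simplex is dense and unfactorized; it is sized for networks of tens
  to a few hundred reactions, not genome scale.
* Thermodynamic/loopless constraints, MILP gap filling, quadratic MOMA and
  dynamic FBA are out of scope.
* `flux_variability(fraction = 0)` drops the objective constraint
  entirely (the raw polytope), rather than constraining the objective to
  be nonnegative.
* Charge balance is only checked when every participant carries a charge;
  the toy model annotates formulas but not charges.
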
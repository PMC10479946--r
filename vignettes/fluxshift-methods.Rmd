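---
title: "Methods: from transcriptomes to flux shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from transcriptomes to flux shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxshift)
```

`fluxshift` chains four stages: condition-specific model construction,
reference flux estimation, quadratic fitting of the treated flux state
(qMTA), and transcriptome-overlap summaries. This vignette documents the
model behind each stage, the tunable parameters and their defaults, the
numerical choices, and what the synthetic test bed does and does not
establish about real data.

## The underlying model and its assumptions

Everything operates on a constraint-based metabolic model: a stoichiometric
matrix $S$ (metabolites × reactions), flux bounds $lb \le v \le ub$, and
boolean gene–protein–reaction (GPR) rules. The core assumption is
steady state, $S v = 0$: internal metabolite pools neither accumulate nor
drain. Fluxes are in arbitrary "model units" (for genome-scale human
models, conventionally mmol/gDW/h); all thresholds below that refer to
fluxes inherit those units. No thermodynamic or loopless constraints are
imposed, metabolite concentrations are not modeled, and the objective is a
single linear reaction (a biomass or energy demand).

**GPR score aggregation.** Mapping per-gene expression to reactions needs
rules for AND (enzyme complex) and OR (isozymes). The package defaults to
AND → `min` (a complex is limited by its scarcest subunit) and OR → `max`
(the best isozyme carries the activity), which is the standard choice in
context-specific model extraction; OR → `sum` (additive isozyme capacity)
is available via `or_rule = "sum"`. The choice is a genuine free parameter
of this class of methods, which is why both are exposed; all results in
the test suite use min/max.

**Missing scores.** Genes absent from the expression table make a
reaction's score "absent" (`NA`): an AND with an unscored subunit is
absent (unless `absent_and = "ignore"`), an OR ignores unscored
alternatives. Absent-scored reactions — notably exchanges and other
non-enzymatic pseudo-reactions — are exempt from every expression-based
decision, so unannotated chemistry is never silently penalized.

## Condition-specific model construction

`build_context_model()` applies, in order: medium constraints, measured
rates, removal of globally silent enzymes, then per-treatment removal of
drug-silenced enzymes. Whether pruning should precede or follow the
respiration bounds is not dictated by the construction rules themselves;
the package constrains first, on the grounds that the feasibility guard
("can the model still achieve the measured rates?") is only meaningful if
the measured-rate bounds are present while pruning. The order is fixed and
recorded in the provenance log.

* **Medium** (`apply_medium`): exchanges absent from the medium are closed
  for uptake; listed exchanges get `min(template capacity, medium value)` —
  a medium cannot open what the template forbids, and clips are logged.
  Uptake direction is detected from the exchange's stoichiometric sign.
* **Measured rates** (`apply_measurements`): each mapped reaction's bounds
  are intersected with mean ± `k_sd`·SD, default `k_sd = 2`. "Achieving a
  measured rate" is thus read as "carrying a flux within two standard
  deviations of the measured mean", a deliberate interpretation of an
  otherwise tolerance-free requirement; `k_sd = 0` pins the flux exactly.
  Oxygen-consumption-type parameters map to the oxygen exchange, ATP
  production to the ATP demand; unit conversion factors are explicit
  configuration, never guessed.
* **Global pruning** (`prune_globally_silent`): candidates are reactions
  scoring strictly below `fpkm_threshold` (default 1 FPKM — a score of
  exactly 1 is kept) in every condition. Candidates are removed greedily in
  ascending order of their maximum across-condition score, ties broken by
  reaction id, and each removal is re-validated: the pruned model must
  still attain `biomass_fraction` (default 0.2) of the template's biomass
  optimum under all applied bounds. Batch removal would let early removals
  hide the infeasibility caused by later ones; the one-at-a-time rule makes
  the guard exact and the outcome deterministic.
* **Condition-specific pruning** (`prune_condition_specific`): reactions
  whose GPR cites a differentially expressed gene (FDR < 0.05), scoring
  below the threshold under the drug but at/above it untreated, are removed
  from that condition's model only — same guard, same ordering rule.

Two invariants hold by construction and are enforced by tests: the biomass
floor is never violated, and no medium-listed exchange is ever pruned
(exchanges carry no GPR, hence no score).

## Reference flux estimation

The control flux state is not a single FBA vertex — degenerate optima make
that arbitrary — but the mean of a sample of the near-optimal space:

1. **Expression-weighted minimization** (`gim3e_minimize`): minimize
   $\sum_i w_i |v_i|$ subject to the biomass floor, with
   $w_i = \max(0, s_{\max} - s_i)$ on the $\log_2(\mathrm{FPKM}+1)$ scale
   (linear-scale penalties behind `form = "linear"`), plus a uniform
   fallback (default $10^{-3}$) added to every weight so the LP stays
   bounded even where penalties vanish. With uniform expression the stage
   degenerates, by design, to parsimonious minimal-total-flux FBA.
   Absolute values are linearized by splitting reversible reactions.
2. **Solution space** (`solution_space`): the constraint
   $\sum_i w_i |v_i| \le (1+\mathrm{slack}) P^\*$, slack default 0.01,
   captures "within 99 % of the optimum". For a minimization that phrase is
   ambiguous ($P^\*/0.99$ vs $1.01 P^\*$); the package uses the symmetric
   fraction-of-optimum convention $1.01 P^\*$, matching standard FVA
   semantics, and records the slack used. FVA under this budget gives
   per-reaction ranges.
3. **Sampling** (`achr_sample`): artificially-centered hit-and-run over the
   budgeted polytope. The budget row is encoded as an equality plus a
   bounded slack variable, so the walk sees only box constraints within an
   affine subspace and every chord is a simple ratio test. Warmup points
   are FVA vertex solutions (two per dimension, capped at `n_warmup`,
   default 100); directions are drawn through the running center; samples
   are emitted every `thinning` iterations (default 100) up to `n_samples`
   (default 5000). None of these counts is prescribed by the method
   definition; the defaults are engineering choices recorded per run, and
   the test suite uses smaller runs (200–2000 samples, thinning 2–20)
   sized so the whole suite stays interactive while the properties under
   test (feasibility of every sample, seed determinism, 1-D uniform mean)
   are scale-independent.
4. **Reference** (`reference_distribution`): the componentwise sample mean;
   convexity keeps it feasible, which is re-checked. Fluxes below $10^{-9}$
   are clamped to exactly zero so the reference-scaled divisions of the
   next stage never see denormal noise.

## qMTA: fitting the treated state

Given $v^{ref}$, a DE table and optional measured fluxes, `qmta()` solves

$$\min_{v}\;
\sum_{m \in DExp} W_m \sum_{i \in R_m}
  \left(\frac{v_i^{ref} FC_m - v_i}{v_i^{ref}(FC_m - 1)}\right)^2
+ \sum_{i \in Ru} \frac{(v_i^{ref} - v_i)^2}{v_i^{ref}}
+ \sum_{j \in Rexp} \frac{(E_j - v_j)^2}{\sigma_j}
\quad \text{s.t. } S v = 0,\; lb \le v \le ub .$$

Each significant gene ($p_m < p_{th}$, default 0.25, on FDR-adjusted
p-values) pulls its reactions toward the target $v^{ref} FC_m$ with weight
$W_m = \log_{10}(p_{th}) - \log_{10}(p_m)$ — one weight unit per decade of
significance. Reactions of no significant gene (`Ru`) are anchored to the
reference; measured reactions (`Rexp`) are pulled to their measured value,
weighted by the reported SD. Membership is exclusive: measured beats
DE-targeted beats unchanged, and a DE-over-measured conflict is resolved in
favor of the measurement (experimental data outrank inference; the
override is logged).

Decisions where the formulation is genuinely open:

* **Denominator exponents.** As typeset, the DE term's divisor
  $v^{ref}(FC-1)$ is squared with the residual while the `Ru` divisor
  $v^{ref}$ is not. The package implements this literal reading (DE ÷
  $(v^{ref}(FC-1))^2$, `Ru` ÷ $|v^{ref}|$) as the default and exposes the
  alternative reading via `de_denom_squared` / `ru_denom_squared`; both are
  convex, both are tested, neither is asserted to be "the" original.
* **Floors.** Denominators are floored at `epsilon_ref` ($10^{-6}$); genes
  with $|FC-1| <$ `epsilon_fc` contribute nothing (their target equals the
  reference); a DE-targeted reaction with zero reference flux falls back to
  an unscaled $W_m(v_{target}-v)^2$ term, since reference scaling is
  undefined there. Each fallback is recorded in the fit's notes.
* **Bounds.** The strict inequalities of the constraint set are implemented
  as closed bounds — QP solvers work on closed sets, and the distinction is
  immaterial at optimality.
* **Multiple genes per reaction** each contribute their own quadratic term
  (the double sum is taken literally; no pre-aggregation of fold changes).
* **Reversible reactions**: the target $v^{ref} FC$ scales the signed
  reference, so a fold change amplifies flux along the reference direction
  rather than its magnitude in the abstract.

The Hessian is diagonal and strictly positive (every reaction carries at
least one term — a term-less DE-targeted reaction is reassigned to `Ru`),
so the QP is strictly convex; it is solved with `quadprog`'s dual
active-set method after rescaling the objective by its largest coefficient
(the argmin is unchanged, the conditioning much improved). Results report
per-reaction $\log_2((|v^{MTA}|+\varepsilon)/(|v^{ref}|+\varepsilon))$ with
an explicit flag for direction reversals, which magnitude ratios would
otherwise hide.

## DEG filtering and overlap summaries

A gene is a DEG when $|\log_2 FC| \ge 1$ and $p < 0.05$; the gate uses raw
p-values by default with the FDR column as an option, since published
gene-set figures are not always explicit about which was used. Overlap
(Venn) summaries store counts and recompute percentages from them
(half-up, one decimal) — percentages are never stored free-floating,
because published percentage annotations are occasionally inconsistent
with their own counts, and counts are the ground truth. Undefined
percentages (empty set) are `NA`, never 0.

## The synthetic test bed

`ground_truth_scenario()` generates everything a pipeline run consumes,
with a known answer:

* The canonical 8-reaction toy ("glyc-ox-8") caricatures the real
  decision the method faces — an oxidative route (O2-limited, high ATP
  yield, complex-encoded) versus a fermentative route (isozyme-encoded) —
  with a hand-checkable optimum of 20 ATP flux units.
* The **control state** is the minimal-total-flux vertex at the *full*
  demand optimum. At the 20 % floor used by the analysis defaults,
  parsimonious FBA routes everything oxidatively and the fermentation
  branch carries zero flux, which would make perturbing it unobservable;
  at the full optimum both branches are active. This is a generator
  choice only — the analysis stages keep their 20 % default.
* The **default perturbation** (fermentation ×1.6, oxidation ×0.4) is the
  classic drug-induced glycolytic shift, sized so the requested state is
  exactly feasible (branch fluxes re-balance the fixed substrate supply:
  $5 \times 1.6 + 5 \times 0.4 = 10$). Requested plans are in general
  projected onto the feasible set (a small QP, with planned reactions
  weighted 100:1 over a ridge on the rest), and the *achieved* fold
  changes are the reported truth.
* **Expression** is coupled to flux deliberately directly: each gene
  inherits the achieved fold change of its (largest-flux) reaction, so at
  zero noise the DE table is exact and any recovery failure implicates the
  pipeline, not the generator. Noise is multiplicative log-normal with the
  stated CV over 4 samples per condition (a typical donor count).
* The generator's **FDR is a labeling convention** (t statistic on logs at
  noise > 0; `1e-9` vs 1 at noise 0) for exercising the significance
  weighting — it is not a claim about RNA-seq statistics, and the
  generator makes no attempt at negative-binomial count realism.

Consequently, passing tests demonstrate that the algorithms are implemented
correctly and are mutually consistent (oracle equivalence, identity fixed
points, parameter recovery on scenarios the model class can represent).
They do not demonstrate that a real transcriptome predicts real fluxes —
on real data the gene–flux coupling is far weaker than the generator's,
and model error dominates solver error.

## Numerical choices

* **LP solving** is a package-own dense two-phase tableau simplex with
  Bland's anti-cycling rule. Flux LPs here are small but massively
  degenerate, which is exactly the regime where anti-cycling matters more
  than speed; the explicit tableau avoids basis factorizations entirely.
  Infinite bounds are capped at $10^6$ model units (model caps are ~$10^3$).
  Feasibility tolerance is $10^{-6}$ (recorded in every
  `flux_distribution`), pivot tolerance $10^{-9}$.
* **QP solving** uses `quadprog` (dual active set) throughout; the test
  suite cross-checks it against an exhaustive active-set enumeration
  oracle (every box-constraint assignment solved by its KKT system) on
  small instances, and the LP path against a proximal-point sequence of
  strictly convex QPs.
* **Sampling determinism**: all randomness flows through a seed stored in
  the `sampling_config`; the RNG state of the caller is saved and restored
  around every seeded stage, so library use never perturbs a user's stream.
* **Degenerate inputs**: a zero-volume solution space yields its single
  point (with a warning), empty media close all uptakes, an FDR of exactly
  0 is rejected (the weight would be infinite) rather than floored
  silently.

## Known limitations

* No thermodynamic/loopless constraints; penalty budgets discourage but do
  not forbid futile cycles.
* The tableau simplex and the brute-force test oracle target small
  networks; genome-scale models load and validate, but the LP layer is not
  tuned for 10^4-reaction problems.
* Respiration-measurement mapping assumes one reaction per parameter;
  distributing one measurement over several reactions is out of scope.
* The biomass reaction is a configurable slot; no curated biomass
  composition ships with the package.
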
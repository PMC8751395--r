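---
title: "Constraint-based modelling and transcriptome-guided contextualization with rhizoflux"
author: "rhizoflux maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modelling and transcriptome-guided contextualization with rhizoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizoflux)
```

# Scope and model

`rhizoflux` implements the constraint-based workflow used to characterize
the metabolic lifestyles of root-associated bacteria such as *Rhizobium
leguminosarum*: validating a genome-scale metabolic model (growth rates,
carbon-source screens, gene essentiality, flux variability against
measured fluxes), extracting condition-specific models guided by
transcriptome data, scoring them by the rank correlation between sampled
fluxes and transcript abundance, and locating metabolites around which
coordinated expression changes occur (reporter metabolites).

The central object is a stoichiometric model: metabolites $m$, reactions
$r$, the stoichiometric matrix $S \in \mathbb{R}^{m \times r}$, flux
bounds $lb \le v \le ub$ and a linear objective $c$. At steady state the
flux vector satisfies $S v = 0$. Flux balance analysis (FBA) solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0,\; lb \le v \le ub.$$

Boundary reactions follow the standard convention: negative exchange or
sink flux is uptake/supply, positive flux is secretion/consumption.
Gene-protein-reaction (GPR) rules are boolean expressions over gene ids
(case-insensitive AND/OR with parentheses, no negation); an empty rule
marks a spontaneous or unannotated reaction that no deletion can disable.

## The linear-programming core

All optimizations are phrased as equality-form LPs over box-bounded
variables and solved by a dense bounded-variable primal simplex
implemented in the package (two-phase, Dantzig pricing with Bland's rule
engaged after degenerate streaks, basis inverse refreshed every 80 pivots;
pivot and feasibility tolerances $10^{-9}$). A dense method is
appropriate because every problem the package solves is small: toy
networks stay below roughly 40 reactions so that brute-force oracles
(exhaustive deletions, per-reaction LP enumeration) run in seconds, and a
flux-split system at that scale has on the order of a hundred columns.
Additional linear rows — the objective-fraction constraint
$c^\top v \ge f \cdot z^\*$ and the parsimony budget used during pruning
— are appended with slack/surplus columns rather than special-cased.
"Unbounded" slack variables are capped at $10^7$, far above the $\pm 1000$
flux-unit scale of model bounds.

## Parsimonious FBA (taxicab norm)

After FBA, the secondary LP fixes $c^\top v \ge f\, z^\*$ (default
$f = 1$) and minimizes $\sum_r |v_r|$ via the standard non-negative
splitting $v = v^+ - v^-$, $v^\pm \ge 0$. Minimizing the taxicab norm
removes thermodynamically infeasible internal cycles from the reported
distribution, because a cycle adds magnitude without changing any mass
balance.

## Flux variability analysis and cycle removal

FVA solves, per reaction, $\min / \max \; v_r$ subject to the steady
state, the bounds and $c^\top v \ge f z^\*$. The "loopless" mode
post-processes each extreme solution with a cycle-removal LP: boundary
(exchange/sink/demand) and objective-support fluxes are fixed at their
extreme-solution values, every internal flux is restricted to the closed
interval between 0 and its current value, and total internal $|v|$ is
minimized. Fluxes sustained only by internal cycles collapse to zero;
fluxes pinned by the fixed boundary pattern are untouched. We chose this
post-hoc scheme over the loop-law mixed-integer formulation deliberately:
it needs no integer programming, scales linearly in the number of FVA
subproblems, and on the package's model class (no large nested cycle
structures) produces the same zero envelopes for futile cycles. The
output records which mode produced it (`attr(x, "method")`).

## MOMA

Gene-deletion growth defects are also assessed by minimization of
metabolic adjustment: the mutant flux distribution closest (Euclidean) to
a wild-type reference,

$$\min_v \; \lVert v - v^{wt} \rVert_2^2 \quad \text{s.t.} \quad S v = 0,\;
lb \le v \le ub,\; v_i = 0 \; (i \in \text{disabled}),$$

solved with the dual-active-set QP solver in `quadprog`. The equality
rows (steady state plus knockouts) are first reduced to a linearly
independent subset by QR factorization, since redundant equalities are
rejected by the solver. The wild-type reference is the parsimonious FBA
solution, which is unique far more often than an arbitrary FBA vertex. A
taxicab variant (`method = "linear"`) is available for completeness. An
infeasible knockout reports status `"infeasible"` with growth 0.

## Gene essentiality

For each gene, the reactions whose GPR evaluates false under the deletion
are closed and growth recomputed by FBA or MOMA. A gene is essential when
mutant growth falls below 50% of wild type (configurable). The 50%
default reflects how pooled insertion-sequencing screens behave: all
mutants grow in one culture, so a half-speed mutant is depleted from the
pool even though its gene is not strictly essential.

## Flux sampling

The solution space $\{v: Sv = 0, lb \le v \le ub\}$ is sampled by
hit-and-run: directions are drawn in the null space of $S$ (augmented
with unit rows for fixed reactions so the walk never leaves them), the
feasible chord is computed from the bounds, and a uniform step is taken;
a fixed burn-in (100 steps) and thinning (5) precede emission. The start
point is the taxicab-minimal feasible point, which is deterministic.
With expression weights $w_r \in [0,1]$, each emitted sample is the convex
combination $\lambda \, a + (1-\lambda)\, x$ (default $\lambda = 0.5$) of
the walk state $x$ and an anchor $a$ that maximizes $\sum_r w_r s_r v_r$,
where $s_r$ is the sign of the taxicab-minimal flux ($+1$ for unused
reactions). The anchor pulls expected flux magnitude up in proportion to
weight; this is a monotone-bias contract, not a distributional guarantee,
which is all the downstream correlation analysis relies on. Identical
seeds give bit-identical sample matrices; the sampler runs on a private
RNG stream and leaves the caller's RNG state untouched.

# Nutrient environments

An environment is a list of available metabolite ids plus optional
exclusions and fixed uptake rates. Application to a model follows the
exchange/sink rules used when building in-silico rhizosphere and nodule
environments: available metabolites with an extracellular exchange have
that exchange opened to uptake (lower bound $-1000$, or $-$rate when a
measured uptake is supplied); available metabolites present only
intracellularly receive a supply sink with bounds $(-1000, 0)$, so a
nutrient is not lost merely because its transporter is unannotated; all
other exchanges are closed to uptake but left open to secretion; excluded
metabolites (central intermediates like glyceraldehyde 3-phosphate, whose
uptake would blur pathway predictions) never gain an uptake route.
Name matching is exact; cross-naming between data sets and model ids goes
through an explicit user-supplied mapping table, never fuzzy matching,
because silent approximate matches are untestable. Growth calls in
carbon-source screens use a strict-positive tolerance
($> 10^{-6}\,h^{-1}$) to absorb solver noise. Secretion bounds during
screens stay at the model's upper bounds (recorded in output metadata).

# Transcriptome-guided contextualization

The contextualization follows the parsimony-with-expression paradigm:
transcript abundance makes a reaction more likely to be used, the overall
flux is minimized, inactive reactions are removed, and the pruned
solution space is sampled with expression bias.

1. **Weights.** Gene abundance is aggregated over each GPR with
   OR $=$ max (isoenzymes add capacity) and AND $=$ min (a complex is
   limited by its scarcest subunit), then divided by the maximum over
   gene-associated reactions, giving $w_r \in [0,1]$. Non-gene-associated
   reactions get the median gene-associated weight; genes missing from
   the profile contribute the median observed abundance. The aggregation
   mode is recorded in run metadata.
2. **Pruning.** The LP $\min \sum_r (1 - w_r)\,|v_r|$ is solved subject
   to the steady state, bounds, $c^\top v \ge f z^\*$ and any forced task
   minima. A reaction is removed only if its flux magnitude is below
   $10^{-6}$ in that solution *and* an FVA check under the same
   constraints plus the (essentially tight, $+10^{-9}$ relative slack)
   weighted-flux budget shows it cannot carry flux at all. The second
   condition protects alternates the sampler would use and keeps the
   pruned model feasible; both conditions together remove decoy pathways
   whose use would cost more weighted flux than the optimum. Reactions of
   protected (task) genes, forced reactions and objective reactions are
   never removed. Forced minima (e.g. demand reactions for
   exopolysaccharide, lipopolysaccharide or Nod factor synthesis, one
   flux unit each) are applied as lower bounds before optimization.
3. **Fraction sweep ("max fit").** Candidate objective fractions span
   0.50–0.95 in steps of 0.05 by default. Each candidate is pruned,
   sampled (500 samples by default, matching the scale used for
   contextualized models in this line of work), and scored by the
   tie-corrected Spearman correlation between per-reaction median
   $|v|$ and aggregated abundance; medians are used because they are
   robust to sampler burn-in. After the coarse grid, one bisection pass
   evaluates the two midpoints flanking the best fraction (half the grid
   step) — this is how a best fraction off the coarse grid (77.5% from a
   5% grid) can arise, and we deliberately stop at one refinement level
   rather than inventing a deeper search. The correlation is computed
   over gene-associated reactions by default (`correlateOn = "all"` is
   available), since non-gene reactions carry no transcriptional signal
   of their own.
4. **Uptake summaries.** Exchange fluxes are normalized per sample by
   the objective flux; the median and interquartile range of uptake
   (negative exchange flux, zero when secreting) are reported and rows
   with zero median are dropped. Zero objective flux in any sample is an
   error rather than a silent division.

# Reporter metabolites

Gene p-values are transformed to z-scores $z_g = \Phi^{-1}(1-p)$ (p
clamped to $[10^{-16}, 1-10^{-16}]$ to keep z finite). A metabolite's
neighbour genes are the distinct genes in the GPRs of reactions that
contain it — defined through genes, not reactions, so duplicate reactions
cannot inflate a neighbourhood. The aggregate
$z_{raw} = \sum_g z_g / \sqrt{k}$ is corrected against the empirical
moments of `nBackground` random same-size gene sets drawn from the scored
pool, $z_{corr} = (z_{raw} - \mu_k)/\sigma_k$, and
$p = 1 - \Phi(z_{corr})$. Currency metabolites (protons, water, ATP/ADP,
NAD(P)(H), phosphate, CO2, …) neighbour most genes and are excluded by
default through a user-visible, compartment-independent list. Analyses
are run on the up-regulated gene set by default (mirroring how such
heatmaps are usually presented); down-set and all-gene modes are
available.

# Validation statistics

Confusion metrics use accuracy $=(TP+TN)/(TP+TN+FP+FN)$, precision
$=TP/(TP+FP)$ and recall $=TP/(TP+FN)$; zero-denominator metrics are
reported as `NA`, never 0. We use the standard recall denominator
$TP+FN$: a published variant printing $FP+FN$ there contradicts the
values reported alongside it and is treated as a typographical error
(noted in the function documentation). Measured-flux validation flags
whether each measured mean lies within the FVA envelope computed at the
same objective fraction. Amino-acid enrichment compares residue counts of
a protein subset against a background proteome with an upper-tail
hypergeometric test per standard amino acid (draws $=$ subset residues),
followed by Benjamini–Hochberg correction over the 20 tests; the test is
at residue level because that is what "comparing amino-acid compositions"
means operationally, and per-protein alternatives have no support in that
framing.

# Synthetic data: what it emulates and what it does not

The generators define the package's study conditions:

* `makeToyModel()` builds mass-balanced networks with exchange,
  transport, sink, demand and objective reactions, AND/OR GPR structure,
  optional decoy detours and an optional futile two-cycle. The FBA
  optimum is analytic (uptake bound × biomass yield × carbon sources), so
  solver correctness is checked against closed forms. Default sizes stay
  below 40 reactions so every oracle (vertex enumeration, exhaustive
  deletion, per-reaction LP) runs in seconds.
* `simulateExpression()` plants an active subnetwork: genes of active
  reactions draw lognormal abundance around a high median (100), decoy
  genes around a low median (10; a tenfold separation), everything else
  at the geometric midpoint, with `noiseSd = 0.2` by default — lognormal
  because RPKM distributions are heavy-tailed and right-skewed.
* `makeTradeoffToy()` + `simulateContextExpression()` form the
  objective-fraction recovery fixture. The toy has exactly one free
  degree of freedom (the biomass pathway) plus forced constant-flux
  modules whose levels tile, in log space, the window the biomass-pathway
  median sweeps as the fraction constraint moves; rank order between
  pathway and constant fluxes therefore changes monotonically with the
  fraction. The expression generator runs the same constrained sampling
  the sweep uses (a two-pass scheme: provisional weights from an
  unweighted pass, profile from the weighted pass) so the round trip is
  self-consistent, and uses small lognormal noise (`noiseSd = 0.003`)
  because fraction identifiability from rank correlations requires
  expression noise below the spacing of the fixture's flux ladder. This
  fixture is an identifiability probe, not a realism claim.
* `bruteForceEssentiality()` is the deletion oracle: per gene, disable
  GPR-false reactions and re-solve the FBA LP built directly from the
  stoichiometric matrix.
* `simulateDeScores()` draws neighbour-gene p-values from the shifted
  null $p = u^{1+e}$ and uniform p-values elsewhere; $e=0$ is exactly
  uniform, which drives the type-I-control simulations.

Passing tests on these fixtures demonstrate algorithmic correctness —
oracle agreement, parameter recovery, error control — on networks with
clean planted structure. They do not demonstrate biological fidelity on
genome-scale reconstructions: real models bring degenerate alternate
optima at much larger scale, noisy many-to-many GPRs, and expression
data whose correlation with flux is weak (rank correlations around
0.2–0.35 rather than near 1). The contracts that carry over are the ones
the tests assert: feasibility of everything returned, task protection,
monotone filtering of nutrient uptake, determinism under a fixed seed.

# Numerical choices and degenerate inputs

* Simplex: feasibility/pivot tolerance $10^{-9}$; phase-1 infeasibility
  declared above $10^{-7}$ total artificial flux; Bland's rule after a
  degeneracy streak of $2(m+n)$ pivots.
* Reported-flux zero threshold $10^{-6}$ throughout (pruning, loop
  checks, growth calls): comfortably above solver noise, far below any
  meaningful flux on the $\pm1000$ bound scale.
* Bounds default to $\pm 1000$ flux units when a file omits them;
  irreversible reactions are expected to carry an explicit 0 lower bound
  in the input.
* QP equality constraints are rank-reduced by QR before `quadprog`;
  box constraints enter as inequalities.
* Sampling of a singleton polytope (all bounds fixed) returns the forced
  point for every sample; an infeasible model errors before sampling.
* p-values are clamped to $[10^{-16}, 1-10^{-16}]$ before
  $\Phi^{-1}$; background standard deviations are floored at $10^{-12}$.
* Empty models (0 metabolites, 0 reactions) are valid, round-trip through
  both file formats, and yield a $0 \times 0$ stoichiometric matrix.

# File formats

SBML is written as Level 3 Version 1 with the FBC v2 package (shared
bound parameters, gene-product associations, an active maximization
objective, `M_`/`R_`/`G_` id prefixes). The reader accepts Level 3 FBC
and, as a fallback, Level 2 files with kineticLaw `LOWER_BOUND` /
`UPPER_BOUND` / `OBJECTIVE_COEFFICIENT` parameters and
`GENE_ASSOCIATION` notes; the level actually parsed is flagged on the
returned object, since released models in this field come in both
flavours. The JSON dialect mirrors the SBML content one-to-one (schema
documented in `R/io-json.R`) and additionally stores the reaction kind
explicitly; on SBML round trips the kind is re-inferred from structure
(boundary pattern, compartment span, objective membership), which is
deterministic. Result tables are TSV with numbers at six significant
digits so repeated runs are byte-identical; environments, expression,
task genes, forced reactions, gene scores and measured fluxes all use
small documented TSV/plain-text formats.

# Problem sizes used by the shipped tests

The test-suite and the acceptance script run entirely on generated
fixtures: 100 random toys for the LP-oracle comparison (an independent
scipy/HiGGS formulation solved per reaction), 20 toys for the
essentiality oracle, 20 planted contexts for retention and 20 generative
round trips for fraction recovery (400 samples each), 50 null score sets
for reporter type-I control, and 1000 random confusion matrices. These
sizes keep each property statistically meaningful while the whole suite
completes in a few minutes on one CPU.

# Known limitations

* The loop-law MILP variant of loopless FVA is not implemented; the
  cycle-removal scheme can, in principle, understate flux ranges for
  reactions that participate in both a cycle and a boundary-driven path
  when the two interact, which does not occur in the shipped fixtures.
* The sampler is a plain hit-and-run walk, adequate for the
  low-dimensional polytopes of this package's fixtures; genome-scale
  models would warrant an artificial-centering variant with much longer
  thinning.
* Weighted-sampling bias is a qualitative contract (monotone in the
  weights); no stationary distribution is claimed.
* MOMA requires the QP to be strictly convex in the flux variables,
  which identity-matrix distance guarantees; linear MOMA can return any
  minimizer when ties occur.
* The recall-denominator correction and the residue-level enrichment
  design are documented interpretations of ambiguous published formulas;
  both are flagged where implemented.
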
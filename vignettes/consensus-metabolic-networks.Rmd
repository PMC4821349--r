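---
title: "Consensus metabolic networks from expression evidence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus metabolic networks from expression evidence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metnet)
```

# The workflow

`metnet` analyses how a curated genome-scale metabolic model restricts to the
gene set that several related species demonstrably express. The workflow has
four stages:

1. **Evidence.** Homology hits of the model's genes against each species'
   transcriptome (from genome-guided and de-novo assemblies) become
   per-species presence calls at an e-value threshold (default `1e-4`).
2. **Consensus.** Genes present in *every* species form the consensus
   metabolic gene set.
3. **Extraction.** Expression scores are mapped onto reactions through their
   gene-protein-reaction (GPR) rules and a consistent sub-model is extracted
   with two independent algorithms (GIMME-style LP and iMAT-style MILP); the
   structural agreement of the two extractions is itself a robustness check.
4. **Simulation.** The extracted model is interrogated by flux balance
   analysis (FBA), linearized minimization of metabolic adjustment (lMOMA),
   single-gene deletion screening, robustness scans and local-search knockout
   design.

`run_pipeline()` executes the stages from one declarative configuration and
writes a manifest with parameters, outputs and checksums, so a rerun with the
same inputs and seed is reproducible byte for byte.

# Models and their invariants

A `metabolic_model` holds metabolites (with compartment and a boundary flag),
reactions (bounds in mmol/gDW/h, subsystem, objective coefficient), a signed
stoichiometry per reaction, and one GPR tree per reaction. The gene set is
*derived* — always the union of GPR leaves — so genes disappear exactly when
their last reaction does. The stoichiometric matrix `S` has one row per
non-boundary metabolite; boundary species (`boundaryCondition="true"` or an
`_b` suffix) are excluded from mass balance, which is the standard treatment
of exchange sinks.

File formats: an SBML subset (Level 2 with COBRA-style kinetic-law bound
parameters and `GENE_ASSOCIATION` notes, and Level 3 core with the `fbc`
extension) plus a flat TSV dialect (`reactions.tsv` with equation strings,
`metabolites.tsv`). Bounds missing from a file default to (-1000, 1000) for
reversible and (0, 1000) for irreversible reactions. If no objective is
flagged, the unique reaction whose id contains "biomass" is used; ambiguity
is an error rather than a guess. Reading back a written model reproduces the
original structurally (ids, bounds, stoichiometry, GPR boolean functions) —
the test suite enforces this round trip for both formats.

# The optimization engine

All analyses reduce to linear programs over
`{S v = 0, lb <= v <= ub}`. The package ships its own dense two-phase
primal simplex with explicit variable bounds (`R/lp.R`). Design points:

* Equality systems built from stoichiometric matrices are rank-deficient by
  construction (conserved moieties). Phase 1 handles this without
  preprocessing: artificial variables that cannot be driven out of the basis
  mark dependent rows, which are dropped.
* Pricing is Dantzig's rule with an automatic switch to Bland's rule after a
  fixed iteration count, which guarantees termination on degenerate models.
* Tolerances: pivot/feasibility `1e-9`; a phase-1 residual above `1e-6`
  (relative to the right-hand side) reports infeasibility. Growth comparisons
  elsewhere use `1e-6` relative.
* Solutions are deterministic: identical inputs take identical pivot
  sequences. Optimal *objective values* are also invariant to reaction
  permutation (tested); optimal flux *vectors* are one vertex of the optimal
  face and are not unique in general.

The iMAT extraction needs binary indicators, solved by depth-first branch
and bound over the LP relaxation with most-fractional branching and
incumbent pruning, with a hard time limit (default 300 s) that aborts rather
than silently returning a partial answer.

Correctness of this core is established in the test suite against
*independent oracles*: enumeration of all basic solutions of the constraint
polytope for LPs, brute force over all binary assignments for MILPs, and a
cross-check of every toy-model optimum against closed forms.

# Phenotype simulation

**FBA** maximizes the objective flux (a biomass pseudo-reaction whose flux
proxies growth). **Lexicographic product optimization** used for strain
designs fixes biomass at its optimum (exactly, tolerance `1e-9`), then
maximizes the product flux; reported product/biomass pairs therefore refer
to the inner biomass optimum. When a growth floor is given instead, biomass
is constrained to a fraction of the optimum.

**lMOMA** minimizes the L1 distance between mutant and wild-type flux
distributions subject to the knockout. Because FBA optima are degenerate,
the wild-type reference is pinned down by a parsimonious tie-break: after
maximizing biomass, total absolute flux is minimized at fixed optimal growth
(`wildtype_reference()`). This makes mutant adjustments reproducible without
changing the attainable growth.

**Deletions.** A gene deletion disables every reaction whose GPR evaluates
false with the deleted genes false and all others true; disabled reactions
have both bounds set to zero. Phenotypes use three classes: `no_growth`
(growth at or below `1e-6`, the LP noise floor), `unchanged` (mutant above
99.9% of the wild-type rate) and `reduced` in between. Where a two-class
summary is needed, "lethal" means `no_growth` and both `reduced` and
`unchanged` count as non-lethal; this convention is applied consistently in
summaries and the confusion statistics. Confusion counts against an
experimental essential-gene list follow the screening convention: a true
positive is predicted growth for an inessential gene, sensitivity is
`TP/(TP+FN)`, positive predictive value `TP/(TP+FP)`; genes absent from the
reference list are treated as inessential.

**Robustness scans** fix a reaction's flux on an even grid (default 20
points) spanning its flux-variability range — the interval the reaction can
actually reach under mass balance — and re-maximize biomass at each point,
reporting `NA` where a forced value is infeasible.

# Expression-guided extraction

Gene scores map to reactions through GPRs with min over "and" (a complex is
as available as its scarcest subunit) and max over "or" (isoenzymes
substitute). Reactions with no gene association, and genes with no
measurement, score `Inf` ("unevidenced"): lacking evidence *against* them,
they are never penalized. This retention rule is why an extracted model can
keep slightly more genes than the evidence set alone would suggest —
functionally required reactions keep their genes.

*GIMME-style LP.* Reactions scoring below a threshold `T` (default: the
median finite reaction score) are penalized by `(T - x_i)` per unit of
absolute flux, subject to mass balance, bounds, and biomass at least a
fraction `f` (default 0.9) of the full-model optimum. Penalized reactions
with zero flux in the minimizing solution are removed, then orphan
metabolites pruned.

*iMAT-style MILP.* Reactions are classed high/low by the 0.75/0.25 quantiles
of the finite scores (classes stay disjoint under ties); the MILP maximizes
the count of high reactions carrying at least `epsilon = 1` flux in either
direction (two indicators for reversible reactions) plus low reactions
carrying none. Low reactions inactive in the optimum are removed.

The defaults (`f = 0.9`, median threshold, quartile classes, `epsilon = 1`)
are conventional values for these algorithm families; all are explicit
`extraction_config()` fields and are echoed into the pipeline manifest.
On networks with a clearly unexpressed redundant route the two extractions
agree exactly (tested as a structural model diff), which is the behaviour
that motivates running both.

# Expression statistics

**RPKM** is `1e9 * C / (N * L)`.

**Differential expression** is a deliberately simple negative-binomial test,
documented as such: median-of-ratios size factors; per-gene dispersion by
method of moments pooled across the two groups (`Var = mu + alpha mu^2` on
normalized counts); an exact-style conditional test comparing the group
totals, summing the probabilities of all splits at most as likely as the
observed one. With few replicates the per-gene moment estimate is noisy and
its truncation at zero is biased low, which would inflate false positives;
the estimate is therefore floored at the experiment-wide median dispersion
(a conservative information-sharing rule in the spirit of classical NB DE
tools). The suite verifies calibration: under an NB null (3+3 replicates,
dispersion 0.1, 2000 genes) the empirical type-I error at nominal 0.05 must
fall in [0.03, 0.07], and planted four-fold changes must be recovered at
90%+ power. No dispersion-trend shrinkage is attempted, so significant-gene
counts are not comparable with a full DESeq-style analysis — which is why
genome-scale DEG tallies are not validation targets here.

A gene is a DEG at `p < 0.05` with fold change strictly below 0.5 or
strictly above 2 (boundary values do not qualify). **Divergence calls**
against a designated outgroup require the gene to be a DEG in the
outgroup-versus-species comparison for *every* other species with a
consistent direction (all fold changes above 2, or all below 0.5). The
p-value cutoff is configurable; 0.05 is the default, with 0.01 available for
stricter calls.

**Coexpression** uses Pearson correlation of `log2(RPKM + 1)` profiles
across all samples. The log scale keeps high-expression genes from
dominating and makes the planted log-scale module structure linear; raw-count
and plain-RPKM correlations are dominated by a handful of extreme samples.
The lowest-variance 25% of genes are removed first (exactly
`floor(0.25 n)` genes by variance rank, a deterministic reading of a
"bottom quartile" filter), and edges need `|r| >= 0.90` — the absolute value
keeps anti-correlated pairs, which are biologically informative.

**Assembly summaries** report n, mean and N50 (largest length whose
at-least-as-long contigs cover half the assembly).

# Knockout design

`gdls_search()` is a bounded local search: from the empty knockout set, each
round scores every candidate set within `k` changes of the incumbent
(default `k = 2`), subject to the knockout budget (default 5) and a growth
floor (default 0.05 mmol/gDW/h), and moves to the best product improvement;
it stops at a local optimum. Scoring is the lexicographic FBA above — exact
for a candidate set, and the reported biomass/product pairs are
well-defined. Ties break deterministically (fewer knockouts, then
lexicographic reaction order), and one search path is followed. Exchange
reactions are legitimate candidates when supplied explicitly (nutrient
exchanges can be profitable knockouts); by default candidates are all
non-exchange, non-objective reactions. Printed knockout lists from the
literature typeset ids loosely ("GLYt2 m"), so `normalize_reaction_ids()`
matches case-insensitively after stripping spaces.

The search is not global: on the small test networks it provably reaches the
exhaustive-enumeration optimum (tested), but at genome scale a local optimum
is all that bounded neighborhood search promises. A duality-embedded bilevel
MILP would be the natural extension.

# The synthetic data generators

The generators produce every input the pipeline consumes, so the whole
workflow is testable without downloads; they are first-class, tested code.

* `make_toy_model()` builds branched uptake-conversion-biomass networks with
  known closed-form optima (`uptake * max(yield)`), optional byproduct
  excretion (a natural design target), and three GPR schemes (none, one
  gene per reaction, nested complex/isoenzyme rules). Ground-truth
  essentiality is recomputed by exhaustive deletion at generation time.
* `simulate_expression()` draws NB counts (`Var = mu + alpha mu^2`) with a
  species-by-replicate layout, per-sample library-size factors
  (uniform 0.7-1.3), planted fold changes in designated species, and planted
  coexpression modules: a shared per-sample latent factor on the log2 scale
  (default spread 1.5, i.e. typical 3-fold swings) times a loading, plus
  per-gene log-normal noise.
* `simulate_homology()` emits BLAST-style tabular hits with planted
  presence/absence: present pairs get a strong hit (e-value at most `1e-6`),
  absent pairs either nothing or a decoy (at least `1e-2`), so presence
  calling at `1e-4` recovers the pattern exactly — the separation makes the
  threshold test sharp rather than flaky.

Simulation sizes used by the suite are deliberate choices: deletion and
design checks run on 7-10 reaction toys where enumeration oracles are exact;
differential-expression calibration uses 2000 genes at 3+3 replicates;
module recovery uses a 10-gene module among 1000 genes, 20 samples,
baseline mean 1000 and dispersion 0.02. The latter reflects the intended
biology — tightly co-regulated, highly expressed metabolic genes — and a
power consideration one can do on a napkin: the correlation between two
module genes is roughly `s / (s + v)` with `s` the shared log-scale variance
(`loading^2 * spread^2`) and `v` the sum of planted noise (`0.1^2`) and
counting noise (about `dispersion / ln(2)^2` at high means). Recovering 95%
of edges at `|r| >= 0.9` with 20 samples needs expected correlations around
0.97, i.e. shared variance well above counting noise; weak modules planted
in low-expression genes would *not* be recovered, and that regime is
documented rather than asserted.

What the generators do **not** emulate: read-level alignment and assembly
(only their summary statistics are in scope), mean-dependent dispersion
trends, compositional library effects of a few dominating transcripts,
correlated gene lengths, or genome-scale GPR complexity. Passing the
synthetic suite therefore demonstrates algorithmic correctness under the
stated generative model, not performance on any particular published
dataset.

# Numerical and degenerate-input conventions

* Finite lower bounds are required for all fluxes (curated models provide
  them; the conventional ±1000 defaults apply where files omit bounds).
* `growth_zero_tol = 1e-6` (absolute) separates "no growth" from LP noise.
* A robustness scan of a blocked reaction (degenerate flux range) returns a
  single point rather than an artificial grid.
* All-zero genes get `p = 1` and an undefined fold change; constant-
  expression genes are excluded from correlation with a message.
* Infeasible deletion mutants score growth 0; an infeasible design is
  flagged rather than silently dropped.
* MILP timeouts are errors, never partial results.

# Worked example

```{r example}
toy <- make_toy_model(n_branches = 2, branch_yields = c(0.5, 0.3),
                      gpr_scheme = "nested")
solve_fba(toy$model)$objective_value

screen <- single_gene_deletion_screen(toy$model)
table(screen$phenotype)

cfg <- design_config("EX_byp(e)", neighborhood_size = 2, max_knockouts = 2,
                     min_growth = 0.05)
gdls_search(toy$model, cfg)
```

# Known limitations

* The desk-scale suite validates algorithms on synthetic and toy inputs; the
  published four-species consensus SBML and genome-scale expression data are
  not bundled, so genome-scale benchmark values are reproduced only when a
  user supplies that model file (see `tests/testthat/test-acceptance.R`).
* The NB test is a documented simplification, not a DESeq replacement.
* No thermodynamic/loopless constraints, flux sampling, or quadratic MOMA.
* Knockout design is reaction-level; gene-level designs (through GPRs) and
  multi-path searches are future work.
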
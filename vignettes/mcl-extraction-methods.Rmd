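---
title: "Methods: multi-confidence-level model extraction and flux-based perturbation calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-confidence-level model extraction and flux-based perturbation calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcltissue)
library(dplyr)
```

## The problem

Genome-scale metabolic reconstructions describe everything a cell *could* do;
a tissue does much less.  `mcltissue` extracts a context-specific sub-model
from a general reconstruction using three tiers of evidence — a
high-confidence reaction set `C_h` (e.g. direct protein-expression evidence)
that must be fully retained, a medium-confidence set `C_m` (database-level
evidence) to be kept where possible, and a low-confidence remainder `C_x`
penalized for parsimony — and then uses the extracted model for two
flux-based perturbation analyses: gene-deletion biomarker prediction and
expression-fold-change flux-direction calling, each evaluated by
confusion-matrix/ROC machinery.

All computations sit on flux balance analysis: a steady-state flux vector
satisfies \(S v = 0\) with \(lb \le v \le ub\), where \(S\) is the
stoichiometric matrix.  Flux variability analysis (FVA) reports, per
reaction, the minimum and maximum flux attainable over that polytope; we
never constrain FVA to an optimal biomass objective, because a credible
single objective for differentiated mammalian tissue is hard to defend, and
the validation analyses need the plain attainable range.

## The extraction algorithm

Enumerating elementary flux modes is combinatorially infeasible at genome
scale, so the algorithm samples the mode space with randomized LPs:

1. **fdMatrix.** Draw `n_columns` random objectives, each maximizing `k`
   reactions sampled uniformly from \(C_h \cup C_m\) (never from \(C_x\)),
   solve each LP, and store the Boolean activity pattern
   (\(|v_i| >\) `activity_tol`) as one matrix column.
2. **Scoring.** A column's score is
   \(|active \cap C_m^{rem}| - w\,|active \cap C_x^{rem}|\) over the
   not-yet-included reactions.  The default weight \(w = 0.5\) balances one
   gained medium-confidence reaction against dropping two low-confidence
   ones — equal preference for coverage and parsimony.  `w` is exposed as
   `low_weight` for sensitivity analysis.
3. **High-tier coverage.** Repeatedly take the best-scoring column with at
   least one uncovered \(C_h\) reaction active, add *all* its active
   reactions, zero the added rows, rescore.  Ties between equal-scoring
   columns go to the lowest column index, which keeps runs deterministic
   under a fixed seed.  If some \(C_h\) reaction is active in no sampled
   column, a targeted LP maximizing (and, for reversible reactions,
   minimizing) its flux contributes a rescue column; if it cannot carry flux
   at all, extraction fails loudly with the uncovered ids — a silent drop
   would violate the tier contract.
4. **Positive-score growth.** While the best remaining column score is
   strictly positive, add it and rescore.  Stopping at zero (not merely
   negative) means a zero-gain pathway is left out: the objective is already
   at its maximum for this set of distributions.
5. **Outer loop.** Rebuild the matrix *on the partial model* and repeat; stop
   when the model size is unchanged between iterations (or immediately if
   the extraction is empty).  Within an iteration the reaction set only
   grows; across iterations it only shrinks, so the loop converges.

On toy networks (a dozen reactions) a few hundred columns already explore
every elementary mode many times over, and the greedy result matches
exhaustive search over all flux-consistent supersets of \(C_h\) (this is an
acceptance test); at genome scale the matrix is meant to hold 10,000–20,000
columns, which is the package default.

## The LP engine

The solver is a dense two-phase primal simplex with explicit variable bounds
(`lp_bounded()`): nonbasic variables rest at either bound, bound flips avoid
pivots, phase 1 drives artificials to zero, and Bland's rule engages after a
run of degenerate steps.  Infeasibility and unboundedness are *statuses*,
not exceptions, because both the extraction loop and the deletion protocol
routinely probe infeasible configurations.  The suite validates the solver
against an independent vertex-enumeration oracle on random bounded networks
(agreement within 1e-6) rather than trusting it axiomatically.  Internal
thermodynamically infeasible loops (type III cycles) are tolerated by
design: FVA on an exchange-free reversible loop correctly reports the full
\(\pm\)bound range, and no loop-law correction is attempted.

Numerical choices: solver pivot tolerance 1e-9; flux-activity threshold
1e-6 (a conventional LP tolerance — the source protocol never defines
"active"); all variable bounds must be finite (genome-scale conventions use
\(\pm 1000\)).

## Multi-tissue expansion

`expand_to_tissues()` replicates every reaction touching a non-extracellular
metabolite once per tissue (default adipocyte/hepatocyte/skeletal-muscle,
prefixes `A:/H:/M:`, metabolite suffixes `[Adp]/[Hep]/[Msc]`), while
reactions made only of extracellular metabolites — all exchanges — are kept
exactly once, so the extracellular (blood) compartment is genuinely shared.
Tissue identity is carried in `tissue_tag` metadata columns; downstream code
never parses ids.  Exchange sign convention: a positive flux on an exchange
written `met[e] ->` removes the metabolite across the system boundary, so an
increased positive exchange flux reads as an increased blood concentration.

## Gene deletion protocol

For a disorder's gene set, affected reactions are those whose GPR evaluates
to *inactive* under full Boolean evaluation with the genes absent (an `OR`
isozyme rescues; an `AND` complex does not).  The reference model forces the
affected reactions on (`lower_bound = 1`, overriding a negative bound):
allowing zero flux would compare "maybe unused" against "removed" and dilute
the contrast.  The disease model removes them.  FVA runs over exchange
reactions in both models and the normalized bound change
\[
\delta_i = \frac{(dMin_i + dMax_i) - (rMin_i + rMax_i)}
                {\max(|mean(rMin_i, rMax_i, dMin_i, dMax_i)|,\ tol)}
\]
is thresholded at \(\pm\varepsilon\) into increased/decreased/unchanged
calls per boundary metabolite.  The denominator is the absolute mean of all
four bounds, guarded against division by near-zero.  Disorders whose forced
reference is infeasible are reported as not simulable and excluded from
scoring rather than silently zeroed.  The ROC threshold grid is 201 values:
zero plus 200 log-spaced points from 0.001 to 1000, covering the
"0 to 1000" sweep with resolution where calls actually change.

## Fold-change protocol

Differential genes (filtered at `p < 0.05`, fold change > 1.5) collapse to
per-gene codes by majority vote over probe records (ties are unchanged);
distinct genes propagate through GPR logic with down = −1 < unchanged = 0 <
up = +1, `AND = min`, `OR = max` — the most restricted complex subunit
limits the enzyme, the least restricted isozyme rescues it.  Affected
reactions start at bound magnitude 100 (a tenth of normal) so that doubling
an upregulated reaction's bounds can actually widen attainable fluxes in a
steady-state model; unaffected reactions keep magnitude 1000; exchange
reactions are pinned to `[1, 1000]`, which deliberately forces every
boundary metabolite to be secreted.  On networks where that forced secretion
is infeasible the failure names the binding exchanges, and `exchange_lb = 0`
gives an exploratory escape hatch.  Up-status bounds are then doubled and
down-status bounds halved, FVA is compared control vs disease with the same
normalized delta, and transport-scope calls can be aggregated per metabolite
by summing signed deltas over all of its cytosol/extracellular transporters
across tissues — a single exchange can hide an effect that an unaffected
parallel pathway absorbs, while the transporter sum cannot.

Down-calls outnumber up-calls under balanced regulation statuses: halving
any one reaction in a chain caps the whole chain, while doubling one
reaction raises nothing unless every other bottleneck rises with it.  The
test suite asserts this asymmetry across 50 seeded random networks.

Subsystem-level significance uses a Welch two-sample t-test of the coded
calls against an equal-size random selector drawing each category with
probability 1/3 (drawn once per subsystem from one seeded stream).  Tiny
subsystems cannot reach large |t| — a two-reaction all-down subsystem is
matched by chance 1/9 of the time — which is precisely the filtering the
ranking is for.

## Evaluation machinery

Direction calls are scored with a fixed confusion convention: a predicted
change equal to the measured change is a true positive; predicted unchanged
against a measured change is a false negative; both unchanged is a true
negative; and any predicted change that is wrong — including the *opposite*
direction — is a false positive only.  This convention is not a free choice:
applied to the packaged 20-amino-acid validation panel it reproduces all
sixteen published confusion counts and every derived metric at 2-decimal
presentation rounding (half away from zero), and no alternative treatment of
direction mismatches does.

A consequence worth stating explicitly: under this convention a classifier
with deltas *independent* of the truth is not a 0.5-AUC coin.  Wrong-signed
deltas on truly-changed items inflate FP while deflating TP, so the chance
ROC lies below the diagonal; in the limit of mostly-unchanged truth the
chance AUC tends to \(2\ln 2 - 1 \approx 0.386\), and for a uniform
three-class truth it sits near 0.28–0.31.  The package's ROC reports
(trapezoid rule over FPR-sorted points with anchors (0,0) and (1,1) always
appended) therefore should be compared against this convention-specific
chance level, not against 0.5.  AUC is invariant to strictly monotone
transforms of the deltas when the exact sweep (`epsilons = NULL`) is used.

## Synthetic fixtures: what they do and do not show

`make_toy_network()` builds parallel linear pathways through a shared
extracellular compartment — uptake exchange, uptake transport, a cytosolic
chain, secretion transport, secretion exchange — with one gene per reaction
(optionally AND/OR motifs).  Tier plans (`high`, `medium`, `low`, `mixed`)
give exactly computable extraction optima; planted up/down perturbations
give known accumulation phenotypes; `synthetic_expression()` emulates the
*structure* of a filtered differential-expression table (significant planted
records, sub-threshold noise), not microarray intensity distributions.

Passing tests on these fixtures show the algorithmic machinery is correct:
the greedy extraction attains provable optima, FVA matches vertex
enumeration, planted signals are recovered end to end.  They do not show
that a genome-scale reconstruction with curated tier lists will reproduce
published tissue-model sizes or validation AUCs — those depend on the
reconstruction, the evidence curation and real expression data, none of
which ship with the package.  Problem sizes in the default suite (networks
of 8–20 reactions, 150–300 fdMatrix columns, 20-instance oracle sweeps) were
chosen so that exhaustive oracles stay exact and the whole suite runs in
well under a minute per module.

## Known limitations

* The simplex engine is dense; genome-scale models (thousands of reactions)
  need a sparse/revised implementation or an external solver behind the same
  `solve_lp()`/`fva()` contract.
* Forced exchange secretion (`exchange_lb = 1`) is applied verbatim from the
  study protocol and can be infeasible on real networks; the switch to 0
  changes the biology of the comparison and should be reported alongside any
  result that uses it.
* SBML support covers the two dialects genome-scale reconstructions actually
  use (kinetic-law bound parameters; fbc v2 bounds and gene associations);
  exotic SBML constructs (rules, events) are out of scope.
* Tissue tags survive native-table round trips only as id prefixes/suffixes;
  re-reading an expanded model recovers tags for metabolites (bracket
  suffix) but reaction tags only when the caller re-applies them.
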
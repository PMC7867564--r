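---
title: "Depletion-curve discrepancy analysis on genome-scale metabolic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depletion-curve discrepancy analysis on genome-scale metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depcurve)
```

## The model

A genome-scale metabolic network (GSMN) couples a stoichiometric model —
metabolites, reactions with flux bounds, exchange reactions at the system
boundary — to gene content through gene–protein–reaction (GPR) boolean rules:
`and` for enzyme complexes, `or` for isozymes, an empty rule for spontaneous
reactions. Removing a gene set switches off every reaction whose GPR can no
longer be satisfied; blocked reactions (those that cannot carry flux in any
feasible steady state of what remains) are then pruned, so a removal can
silence reactions whose own genes were never touched. This propagation is the
mechanistic core of everything below.

**Fitness.** Each sub-model is scored by the fraction of the network's
biomass components that remain producible: a metabolite is producible when a
steady-state flux vector within bounds can deliver it to a demand sink at
flux at least $\varepsilon$ (default $10^{-6}$). Fitness is 1 for the
comprehensive network and 0 for a totally degraded one. The upstream
literature this design follows does not pin down a unique fitness formula;
the producible-fraction definition satisfies the boundary contracts above and
is exposed as a pluggable scorer (`scorer` argument of `extract_submodel()`
and `build_series()`) so alternatives can be swapped in.

**Depletion curves.** For each expression sample, genes are ranked by
expression (lowest first, ties broken lexicographically) and removed
cumulatively; sub-models are extracted at each step. With
$i$ genes removed out of $k$,

$$x = \text{fitness}^* = (1 - i/k)\cdot \text{fitness},$$

and the depletion curve of a gene set $g$ is the fraction of $g$'s members
still present in the sub-model, as a step function of $x$. Ascending-order
removal (lowest expression first) is adopted: weakly expressed genes are the
least supported by the sample and are degraded first.

**Discrepancy statistics.** Condition curves are the pointwise means of
replicate curves. For two conditions $U, V$:

$$\bar A_{U,V} = \int_0^1 \lvert \bar D_U(x) - \bar D_V(x)\rvert\,dx,
\qquad
\Delta_{U,V} = \mathrm{AUC}_U - \mathrm{AUC}_V,$$

and across all conditions the test statistic is
$A^* = \max_{U,V} \bar A_{U,V}$. Significance comes from permuting replicate
labels between conditions (group sizes preserved), with the add-one estimator
$p = (\#\{E \ge E_\mathrm{obs}\} + 1)/(N + 1)$; ties count as exceedances
(conservative). Post-hoc pairwise tests use the pair's $\bar A$ with the same
scheme, and the signed matrix $\mathrm{sign}(\Delta)\cdot\bar A$ over gene
sets × contrasts feeds a clustered heatmap (Euclidean distance, average
linkage).

**Causal genes.** At unit removal step, every drop of a gene set's curve is
attributable to exactly one removed gene — possibly a non-member acting
through propagation. Each descent has a height $\Delta y$, a fitness*
decrement $\Delta x$, an angle $\arctan(\Delta y/\Delta x)$ measured in the
unit square (so the 45° threshold is scale-free; $\Delta x = 0$ gives 90°),
and a position (the fitness* of the sub-model after the removal; the choice
of the post-removal knot rather than the pre-removal one is a convention,
fixed and documented here). A gene passes the filters when (a) in at least
one condition strictly more than half of the replicates show a descent with
position > 0.1 and angle > 45°, and (b) both dispersion ratios across
per-condition means exceed 0.2. The dispersion ratio is
$\mathrm{RSD}(x) = \mathrm{mean}(x)/\mathrm{sd}(x)$ — the reciprocal of the
conventional relative standard deviation, kept as the method's printed
definition; `rsd_mode = "sd_over_mean"` switches to the conventional form.
With this default, RSD > 0.2 excludes genes whose per-condition means are
wildly dispersed (sd > 5× mean); identical condition means give RSD = ∞ and
pass. A gene with descents in fewer than two conditions has no defined
dispersion and fails criterion (b).

## Numerical choices

* **Feasibility engine.** Producibility and blocked-reaction detection are
  pure feasibility questions over convex polytopes. They are solved with
  `quadprog` (dual active-set, compiled): minimise $\tfrac12\lVert v\rVert^2$
  subject to the steady-state equalities and bounds; an inconsistent system
  raises, which is the "infeasible" verdict. Each reaction is probed in both
  directions ($v_j \ge \varepsilon$, then $v_j \le -\varepsilon$ if the lower
  bound allows). Flux threshold $\varepsilon = 10^{-6}$, configurable.
* **Pruning fixed point.** A blocked reaction carries zero flux in every
  feasible state, so removing it leaves the flux space unchanged; the blocked
  set is therefore determined by the GPR-active network alone, one pruning
  pass reaches the fixed point, and the result cannot depend on reaction
  visit order. The loop still re-verifies until no reaction is removed.
* **Exact step-function integration.** Depletion curves are step functions
  with known breakpoints, so $\bar A$, AUC and $\Delta$ are integrated
  exactly on the union of breakpoints (value × interval width). This makes
  the statistics invariant under any grid refinement — a fixed-grid trapezoid
  would instead carry $O(h)$ error at each jump. The uniform 1001-point grid
  (`curve_grid()`) exists only for export and plotting.
* **Curve convention.** At a knot the curve takes the post-drop value; below
  the last knot the final value is held. Replicate averaging happens on the
  union of replicate breakpoints.
* **Permutation ties.** Null statistics within $10^{-12}$ of the observed one
  count as exceedances, so floating-point noise in re-averaged means cannot
  turn a tie into a rejection.
* **Exhaustive mode.** When the number of distinct relabelings is at most
  `exhaustive_cap`, the test enumerates all of them and reports
  $p = \#\{E \ge E_\mathrm{obs}\}/\#\text{relabelings}$ (identity included).

## The ChIP-seq bin module

Single-end 5′ tags are shifted toward the fragment centre by half the
fragment length, where the fragment length is estimated per sample as the
argmax of the plus/minus strand cross-correlation over shifts 0–400 bp in
5 bp steps (ties to the smallest shift). A smoothed-prominence diagnostic
warns when the correlation curve has no usable apex (e.g. structure-free
tracks), in which case the estimate is unreliable. Shifted tags are counted
in consecutive non-overlapping 500-nt bins, scaled to counts per $10^7$
total tags, stabilised with 30 pseudo-counts and log2-transformed (the
scaling target and pseudo-count are explicit configuration; the log2 values
feed the M and A diagnostics). Enrichment of each ChIP bin over its matched
INPUT is tested with a one-sided binomial test of the ChIP count among the
pooled count, with expected proportion equal to the ChIP share of the
combined library — a standard count-enrichment test consistent with the
MA-plot view, used here as a documented stand-in since the original
procedure names no per-bin test. P-values are Benjamini–Hochberg adjusted
across all bins of a phase; bins with adjusted p < 0.05 are significant. The
whole procedure is repeated with bins shifted by half a bin (250 nt) to
suppress border effects; a sample's significant set is the union over the
two phases, a condition keeps only stretches significant in *all* of its
replicates, conditions are unioned, and gaps under 500 nt are merged.
Region densities are tags per bp per million total tags (scale constant
configurable). Coordinates are 0-based half-open externally (BED); matched
INPUT tracks are shifted by their ChIP sample's estimated fragment length,
since INPUT chromatin has no peak structure of its own to estimate from.

## What the synthetic generators emulate

`make_network()` builds a viable toy GSMN: a nutrient import, an
isozyme-gated hub, one linear chain per biomass component, spontaneous
exports, and dead-end filler branches. Chain steps are redundancy-dominated
— isozyme pairs, or enzyme complexes backed by a parallel isozyme — with
roughly one fragile single-gene step in ten. This mirrors the redundancy of
real genome-scale models, whose sub-models stay viable until deep into an
expression ranking; it is what spreads fitness* over (0, 1) instead of
collapsing it after a handful of removals. Fragile steps are kept because
they are what makes removals propagate (and the causal-gene machinery
meaningful). The comprehensive model is asserted viable at construction.

`make_expression()` draws log-normal baselines (meanlog log 100, sdlog 1),
multiplies the planted set by $2^{-\text{effect}}$ (default effect 6) in the
target condition only, and adds log-normal replicate noise (sd 0.2). The
default design is 4 conditions × 6 replicates: six is the replication of the
RNA profiling this emulates, and it matters statistically — with triplicates,
about 2% of random relabelings regroup one whole condition and tie the
observed statistic, a small-design artefact rather than a property of the
method. `effect = 0` gives an exchangeable null.

`make_chip()` plants mostly broad (4.5 kb) enriched domains — the scale of
the broad chromatin marks this emulates — plus one deliberately narrow
1.4 kb region centred on a phase-0 bin boundary, on a 1 Mb genome at depth
2×10⁵ with 10-fold enrichment, 2 conditions × 2 replicates. Bin-level
recovery expands every region by up to ~500 bp per side across the two
phases, which is why multi-kb truth regions are the right scale for judging
recovery by Jaccard overlap. Fragment centres pile on nucleosome-spaced
sites (200 bp apart, 20 bp jitter) inside regions: uniform centres would
leave the strand cross-correlation without an apex, whereas real
chromatin-mark fragments cluster on nucleosome positions. INPUT is uniform
Poisson background.

What the generators do **not** emulate: real transcriptome covariance
structure and tissue contamination, realistic ChIP noise beyond Poisson
background, genome mappability, reversible/looped metabolism with cofactor
coupling, or anything at the scale of a real mammalian GSMN. Tests passing
on these fixtures validate the machinery and its contracts, not biological
conclusions on real data.

## Problem sizes and the standard fixtures

Analyses in the tests and the acceptance script run at desk scale, chosen so
the full pipeline re-runs in minutes on one CPU: networks of ~20–30 genes and
~30–40 reactions, 12–24 expression samples, 20–200 gene sets with N = 99
resamples, and a 1 Mb ChIP genome. One calibration quantity deserves a note:
the null rejection rate over 200 gene sets is an average of strongly
*correlated* tests — every set shares the same 12-sample fixture — so it
varies widely from one random fixture to another even though each individual
test is valid. The calibration therefore runs on a fixed standard null
fixture (a frozen generator seed), with the resampling stream still seeded
externally; this is the usual fixed-seed calibration convention and the
variability is a property of averaging correlated tests, not of the test.

## Known limitations

* Fitness is the producible fraction of biomass components; it is a
  contract-compatible choice, not a claim of numerical equivalence with any
  other published scorer.
* The hypergeometric gene-set pre-filter is a plain over-representation
  test, a stand-in for topology-aware GO enrichment.
* The per-bin binomial enrichment test assumes independent counts given
  library sizes; overdispersion beyond Poisson would need a count model with
  a dispersion parameter.
* Descent attribution requires a unit removal step; coarser series raise an
  error rather than guessing which gene caused a drop.
* The exhaustive permutation mode enumerates multiset relabelings and is
  meant for tiny designs (its count grows multinomially).
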
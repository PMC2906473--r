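---
title: "Single-threshold GMYC delimitation and character-based barcode assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-threshold GMYC delimitation and character-based barcode assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmycbar)
```

## The problem

Given a clock-like (ultrametric) gene tree over many individuals sampled
across an unknown number of species, where does between-species
diversification stop and within-species coalescence begin? The general
mixed Yule coalescent (GMYC) answers this with a branching-process
likelihood that switches regime at a threshold age `T`: nodes older than
`|T|` are speciation events, branches crossing `|T|` define putative
species ("entities"), and nodes younger than `|T|` are coalescences inside
those entities. The package fits this model, tests it against a
single-population null, extracts the entity partition with confidence
sets, and then uses the partition to build character-based barcode rules
that can place degraded query sequences (for example a museum holotype)
into a delimited entity.

## The branching likelihood

Both models operate on the *branching schedule* of the tree: the internal
node ages `a_1 >= a_2 >= ...` (oldest first), the waiting times
`x_i = a_i - a_{i+1}` between consecutive events, and the lineage count
`n_i` during each interval (`branching_schedule()`). Each internode
interval contributes `log b_i - b_i x_i`, where `b_i` is the branching
rate of the interval and the event ending it.

Under the **null model** the whole sample is one coalescing population:

    b_i = lambda * [n_i (n_i - 1)]^p

The exponent `p` (boxed to [-5, 5]) absorbs departures from the strict
coalescent (`p = 1` gives the classical proportionality to lineage
pairs). For fixed `p` the maximizing `lambda` has the closed form
`(number of intervals) / sum_i [n_i(n_i-1)]^p x_i`, so the fit reduces to
a one-dimensional search (`fit_null()`).

Under the **GMYC model** each interval mixes a diversification and a
coalescent component:

    B_i = lambda1 * (n^s_i)^p1  +  lambda2 * sum_j [n_{j,i}(n_{j,i}-1)]^p2

where `n^s_i` counts species-level lineages and `n_{j,i}` counts the
lineages of entity `j` in interval `i`. A lineage is species-level unless
it descends from a threshold-crossing branch; a cluster's crossing branch
(its stem) therefore counts as a species lineage until the cluster's most
recent common ancestor. This per-branch bookkeeping is what makes the
likelihood piecewise constant in `T` between node ages, so profiling `T`
over midpoints between consecutive distinct node ages (plus a candidate
between the youngest node and the present) loses nothing. The
diversification component is pure birth — no extinction parameter — with
`p1` absorbing deviations; together with `lambda1, lambda2, p2, T` this
gives five free parameters against the null's two, hence the likelihood
ratio test uses 3 degrees of freedom.

Each interval contributes `log B_i - B_i x_i`: the *total* rate appears
in the event factor, exactly mirroring the null model's form. We
considered attributing each event to its own component's rate
(a competing-exponentials factorization), but under the schedule
bookkeeping above the first coalescence of every cluster ends an interval
in which that cluster still has a single lineage, so its component rate
is identically zero and every threshold producing a cluster would score
`-Inf`. The total-rate form has no such defect and makes the null model
the exact limit of the GMYC as the threshold reaches the root: with `T`
at the root age the whole sample is one cluster, the diversification
term vanishes, and `B_i` collapses to the null rate. The threshold
profile therefore includes this root-age row (entity count 1, its
log-likelihood computed by the null fit), which guarantees
`logL_GMYC >= logL_null` structurally and lets the confidence set
legitimately include the "no threshold" solution when the data cannot
exclude it.

Two further conventions: a node exactly at `|T|` is classed coalescent
(determinism at ties), and the terminal interval from the youngest node
to the present carries no event and is excluded by default; setting
`include_terminal = TRUE` adds it as a censored survival factor to both
models. The coalescent exponent is applied inside the per-cluster sum by
default (`coalescent_form = "per_cluster"`); the pooled alternative
`lambda2 * [sum_j n_j(n_j-1)]^p2` is available and the two provably
coincide at `p2 = 1`, which the test suite asserts.

Thresholds are *reported* negatively (present = 0, root = -root age), the
convention under which a tree rescaled to unit root depth
(`rescale_root()`) yields directly comparable values like `-0.07`.

## Optimization and numerical choices

Per candidate threshold, the likelihood is maximized over
`(lambda1, p1, lambda2, p2)` by Nelder-Mead over the two exponents with
the two rate scales profiled out at every step: for fixed exponents the
log-likelihood is concave in `(lambda1, lambda2)` and is maximized by a
safeguarded 2-by-2 Newton iteration. The sweep over thresholds is
warm-started from the previous candidate's exponents plus a null-fit
based start (`n_starts` adds more). On all fixtures with up to 8 tips the
resulting maxima agree with an exhaustive hierarchical grid search to
better than 1e-3 log-likelihood units.

Degenerate situations are handled explicitly: a component absent from
every event interval (for instance the coalescent term when every entity
is a singleton) has its rate fixed at the boundary 0; zero-length
internals (from resolved polytomies or simultaneous ages) contribute
their event factor but no survival term; trees with fewer than 4 tips
are rejected ("too few candidate thresholds"). Input trees must pass
`check_ultrametric()` at `rel_tol` (default 1e-6 of the root age);
`force_ultrametric()` will absorb terminal-branch round-off up to 1e-3
but refuses genuinely additive trees.

Confidence sets retain every profile row within `delta = 2`
log-likelihood units of the maximum and report the ranges of entity
count and threshold — the conventional 2-unit support interval.

## What the simulators emulate

`sim_gmyc_tree()` draws a pure-birth species tree
(waiting time `Exp(k * lambda_spec)` while `k` lineages exist), then for
each species an independent Kingman genealogy over its `m` samples
(coalescence rate `k(k-1)/(2 nu)`, so `nu` is exactly the expected
pairwise coalescence time), *redrawn* until the genealogy is at least a
factor `s` shallower than the species' stem age. Rejection rather than
rescaling keeps each genealogy exactly Kingman conditioned on the bound,
so the fitted coalescent family remains correctly specified in recovery
experiments. The truth ledger (partition, per-species depths, rejection
counts) rides along with every simulation.

Defaults are the validation conditions used throughout: 15 species,
`lambda_spec = 1`, 4 samples per species, separation `s = 10`, and
`nu = 0.005`. The value of `nu` is a deliberate choice: about half a
percent of the speciation timescale, the shallow intraspecific variation
typical of single-locus barcode data, and small enough that the
rejection sampler is well defined for every species even when the Yule
tree contains very young stems. Extinction is omitted from the species
tree, mirroring the pure-birth diversification term of the fitted model.

`sim_sequences()` evolves JC or HKY alignments along any tree (via
phangorn's simulator; branch lengths are expected substitutions per site
after the `rate` multiplier), and `sim_clones()` produces
deamination-damaged clone sets: per clone and site, a C becomes T (and a
G becomes A — the opposite strand's view of the same chemistry) with
probability `delta`, then any site is replaced by a uniformly random
different base with probability `epsilon`.

What these simulations do *not* emulate — and what passing recovery
tests therefore cannot certify on real data: gene flow and incomplete
lineage sorting across species boundaries, rate variation among lineages
(the clock is exact by construction), alignment error, recombination,
indels, and position-dependent damage gradients along ancient-DNA
fragments. A real Bayesian consensus chronogram also carries node-age
uncertainty that the single input tree ignores.

Two geometric caveats discovered by the recovery experiments are worth
stating. First, the separation bound is *per species*: two species that
split more recently than some third species' genealogy depth can make
every single threshold misclassify one of them, so perfect recovery of
the entity count is not guaranteed even at large `s` — the validation
criteria (median error at most 1, 90% within 2 at 15 species) reflect
that. Second, the GMYC likelihood-ratio test is known to be liberal;
on single-population coalescent trees of 40 tips we observe roughly 13%
rejections at the nominal 5% level, within the commonly cited range.

## Barcode and ancient-DNA layers

`extract_fragment()` cuts an alignment window by 1-based inclusive
coordinates on the *ungapped* reference (so the classic 85 bp window at
reference positions 666-750 is exactly 85 columns when the reference is
gapless; internal reference gaps are retained and flagged).
`find_diagnostics()` emits *pure* diagnostic characters — a state shared
by every member of one entity and absent from every other record —
skipping, for the candidate entity only, columns where any member
carries N or a gap. `classify_query()` scores a query by matched rules
per entity and assigns the unique top scorer; ties and zero scores
return "ambiguous" (the margin threshold of 1 is the simplest rule
consistent with unambiguous assignment; how the original character-based
tools break ties is not documented, so this is a choice, not a
reconstruction). `discriminability_matrix()` reports which entity pairs
the window can separate at all — the analogue of two recently diverged
entities sharing an identical fragment.

`clone_consensus()` uses a PCR-stratified majority rule: a base is
called only when the same within-batch majority appears in at least two
independent PCR batches, otherwise N; within-batch ties abstain. The
published studies do not state their exact consensus rule across clones,
so this conservative reconstruction is flagged as such.
`damage_report()` tallies clone-versus-consensus mismatches into the 12
directed classes; the type-2 fraction (C→T plus G→A over all
mismatches) is the deamination signature, and
`authenticity_summary()` operationalizes "strong bias" as a fraction of
at least 0.5 when at least 4 mismatches are available (with fewer the
criterion cannot be refuted and passes).

## Validation problem sizes

The test suite validates the pipeline at these scales, chosen as the
package's standing validation conditions: entity-count recovery over 50
simulated radiations (15 species x 4 samples, s = 10); type-I behaviour
over 100 single-population coalescent trees of 40 tips; grid-search
oracle agreement on all fixtures up to 8 tips; classifier accuracy over
100 degraded 85 bp queries against 5-entity references; and exact
boundary cases for the damage statistics. `scripts/acceptance.R` re-runs
the same computations end to end from a seed and writes the resulting
numbers as JSON.

## Known limitations

Only the single-threshold GMYC is implemented (no multiple-threshold
variant, no Bayesian version, no model averaging over trees); tree
inference and dating are out of scope — trees arrive ultrametric.
Node-age uncertainty does not propagate into the delimitation.
Compound (multi-column) diagnostic characters are not generated; the
discriminability argument rests on pure characters only. The
base-composition screen uses all countable sites; programs that drop
constant sites first will report different statistics on the same data.
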
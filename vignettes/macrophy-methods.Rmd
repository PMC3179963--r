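---
title: "Supertrees, ghost ranges and clade growth: methods and design"
author: "macrophy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supertrees, ghost ranges and clade growth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macrophy)
library(ape)
```

# What the package does

`macrophy` is a pipeline for family-level macroevolutionary analysis that
combines published phylogenies with the fossil record. It was built around
the kind of study done on ancient insect clades such as the Odonatoidea
(dragonflies, damselflies and their extinct relatives): a few dozen extant
families, a fossil record reaching back to the Carboniferous, and some
thirty partially overlapping source trees in the literature. The stages
are:

1. **Standardisation** (`parse_trees()`, `apply_taxonomy()`,
   `collapse_to_families()`): source trees are renamed to valid families,
   species- and genus-level tips are reduced to one leaf per family, and
   ambiguous families are removed.
2. **Supertree construction** (`mrp_encode()`, `supertree_search()`,
   `majority_rule_plus()`): matrix representation with parsimony (MRP) or
   compatibility (MRC), followed by a fully resolved majority-rule
   consensus with minority components.
3. **Nodal support** (`v_scores()`): the V and V+ indices over the input
   tree set.
4. **Diversification shifts** (`detect_shifts()`): the Slowinski–Guyer
   sister-clade imbalance test over all extant sister pairs, with a
   trickle-down correction.
5. **Ghost ranges** (`adjust_originations()`): family origination dates
   pulled back to the divergence implied by the older sister clade's first
   fossil appearance.
6. **Lineage-through-time series and growth tests** (`lineage_series()`,
   `akima_resample()`, `fit_gls_ar1()`, `classify_growth()`): stage-binned
   richness, Akima interpolation to equal spacing, and AR(1) generalized
   least squares comparing linear and quadratic models of log richness.

A synthetic-data module (`scenario()` and the `gen_*()` generators)
produces every input with known ground truth, so each stage is testable
without any download.

# Standardising input trees

Input trees are read as rooted newick/NEXUS topologies; unrooted trees are
rejected because the matrix encoding reads every internal node as a rooted
clade. After renaming to valid families a tree may carry several leaves of
the same family. The collapsing rule is operational: a family is reduced
to a single leaf if and only if reducing it to *any* single representative
yields the same family-level topology. This covers monophyletic and
paraphyletic families — a paraphyletic grade collapses to one branch
without affecting relationships among other families — while a family
whose representatives imply different topologies has genuinely uncertain
placement (polyphyly) and is removed entirely. The test is exact, by
enumeration over representatives, and is idempotent. Trees left with
fewer than three family leaves carry no grouping information and are
dropped with a logged message rather than an error.

# MRP, MRC and the search

Baum–Ragan coding turns every non-root internal node of every source tree
into a binary column: descendants 1, other taxa of that tree 0, absent
taxa missing. A hypothetical all-zero outgroup row is appended to columns
from trees lacking the outgroup; trees containing it score it like any
other taxon. Parsimony length is the two-state Fitch count with missing
entries carrying the full state set (this equals the length on the tree
restricted to the scored taxa). The compatibility score counts columns
whose 1-taxa form a clade of the tree restricted to the column's
non-missing taxa.

The original studies ran external parsimony software; search internals are
irrelevant downstream as long as the set of equally optimal trees is
well-defined. The package uses random-addition starting trees followed by
hill-climbing over NNI and then SPR neighbourhoods, restarted `restarts`
times, with the outgroup constrained as sister to everything else. All
distinct best-scoring topologies encountered anywhere in the search are
retained, capped at `max_optimal` (default 1000, logged when hit). The
search is deterministic given its seed. On six or fewer taxa it matches
exhaustive enumeration in the package's tests; at the study's scale
(dozens of taxa) it is a heuristic, as all parsimony searches are.

The consensus includes every clade above 50% of the optimal trees, then
adds minority clades greedily in decreasing frequency order, skipping
incompatibilities, so below 50% the relationship appearing more often than
any other is taken. Frequency ties break lexicographically on sorted
clade labels, making the output reproducible. Because the greedy pass
already admits every frequency-positive compatible clade, any residual
polytomy means no observed clade resolves it; it is resolved by a seeded
random resolution (frequency reported as 0) because the diversification
stage requires a fully bifurcating tree.

# V and V+ support

For a supertree clade restricted to an input tree's leaves, the input tree
*supports* the clade if it displays exactly the restricted clade,
*conflicts* if no refinement of the input tree could display it, *permits*
it if it is compatible but not displayed (e.g. across a polytomy), and is
*irrelevant* if the restriction keeps fewer than two members or an empty
complement. Then V = (s − q)/(s + q), from −1 (all relevant trees
conflict) to +1 (all support), undefined when no relevant tree takes a
side; V+ = (s + p − q)/(s + p + q) additionally credits permitting trees.
Tree-level scores are unweighted node means. Support here requires exact
display of the restricted clade — the strictest reading; softer variants
exist in the support-index literature and would score no lower.

# Sister-clade imbalance and the trickle-down correction

Under the equal-rates null, every split of a sister pair's combined
richness is equally likely, so the probability of a split at least as
extreme as observed is 2·N_small/(N_large + N_small − 1), capped at 1
(the raw expression exceeds 1 for near-balanced pairs). The test runs at
every internal node of the extant-family tree, tips to root, with no
multiple-testing adjustment (matching the practice of the studies this
pipeline follows); `alpha` defaults to 0.05. Polytomies are rejected:
the test is defined for sister pairs.

A genuine shift at one node inflates every ancestral comparison (the
trickle-down effect). The correction substitutes, at each significant
node, twice the poorer daughter's sum for the pair's contribution to all
deeper comparisons — as if the detected shift had not happened. The rule
is isolated behind `correct_trickle_down` so alternatives can be compared.
Two measured properties are worth knowing (both are exercised in the
package's tests): the *uncorrected* per-node test is calibrated
(rejection rate ≤ 0.05 under the equal-rates null, by construction of the
probability), while the corrected cascade can slightly exceed nominal at
deep nodes under the null (a corrected clade's substituted sum is small,
which can make its next comparison look imbalanced). The correction is
kept as the default because its purpose — preventing a real shift from
flagging every ancestor — is a power property, demonstrated in the
constructed-case test.

The test itself is symmetric between daughters; calling a significant
node an "upshift" or "downshift" is interpretation. The report labels
the daughter whose per-lineage richness deviates further (in log ratio)
from the node-wide mean: an upshift in the richer clade or a downshift in
the poorer one. This matches the intuitive reading of depauperate relict
families versus radiating clades, but users should read `n_A`/`n_B`
directly for nested patterns.

# Ghost ranges

If the tree is right and the record incomplete, both daughters of a node
were present when they diverged. Each family's origination is therefore
pulled back to `clade_fad(parent)`: the older of its own first appearance
and its sister clade's oldest first appearance. Only the divergence from
the *immediate* sister is used — older stem segments belong to ancestral
lineages, not to the family. The adjustment never moves an origination
younger (`adjusted_fad >= fad`), never alters extinctions, is idempotent,
and gives both daughters of every node the same implied stem origination.
Consequently the adjusted lineage-through-time curve dominates the
fossil-only curve pointwise.

The adjustment is conservative: `adjusted_fad` can never exceed the age
of the divergence it dates, so when the family's true immediate sister is
in the tree the adjusted value lies between the observed first appearance
and the true origination. When unsampled lineages have been pruned from
the tree, the "sister" is a more distant relative and the adjustment
dates an older (ancestral) divergence; this is the lineage-bookkeeping
caveat inherent to the method, and the synthetic recovery tests
distinguish the two situations.

Stage-named dates resolve conservatively — first appearances to the stage
base, last appearances to the stage top — and the choice is configurable.
The packaged timescale is a stage-level table from the base of the
Carboniferous (358.9 Ma) to the present with ICS/Gradstein-derived ages.

# Lineage series and growth tests

Per stage, richness counts families whose (adjusted) range overlaps the
stage interval, range-through and boundary-inclusive; originations fall in
the stage containing the first appearance and extinctions (extinct
families only) in the stage containing the last, so that total
originations minus extinctions equals the extant count. Series use stage
midpoints as time coordinates (configurable in principle to base or top;
midpoints are the plotted convention).

Time-series analysis wants equal spacing, so the stage-midpoint series is
interpolated with Akima's (1970) piecewise cubic onto the same number of
equally spaced points (via `pracma::akimaInterp`; the implementation
leaves the final interval unevaluated, which the package fills using the
method's exact symmetry under time reversal). Akima interpolation
reproduces its knots, is exact on linear data, and on equally spaced
samples of a quadratic; it is not exact for polynomials sampled at
unequal spacing, which is one reason the calibration simulations below
matter.

Exponential growth makes log richness linear in time; logistic growth
decelerates towards the present. The package fits
log(richness + 1) = b0 + b1·t (+ b2·t²), t = −Ma (so the present is
increasing t and deceleration is b2 < 0), with AR(1) errors estimated by
maximum likelihood through `nlme::gls` and `corAR1` — the positive lag-1
autocorrelation that motivates this is diagnosed by the Durbin–Watson
statistic of the ordinary-least-squares linear fit, which the fit object
carries. A series is *logistic-consistent* iff the quadratic term is
significant at `alpha` and negative; an accelerating quadratic is not
evidence of saturation. A "drop the extant point" variant
(`drop_extant = TRUE`) reruns the test without the youngest value.
Degenerate inputs are handled explicitly: an exactly noiseless series
makes the GLS likelihood singular, so the fit falls back to least squares
with phi = 0, and a quadratic coefficient at roundoff scale is reported
as exactly zero rather than as a spurious t statistic. Fixing `phi = 0`
reproduces ordinary least squares to numerical precision.

# The synthetic scenario and what it does (not) emulate

`scenario()` fixes the study conditions; all generators derive their
random streams deterministically from its seed. The defaults emulate the
empirical setting: a model birth–death tree conditioned on 24 extant
families (birth 0.03/My, death 0.015/My, giving a root age of the order
of 300 My, with extinct lineages retained via `ape::rphylo(fossils =
TRUE)`); 30 input trees, each a 50% leaf subsample given 2 random NNI
perturbations; about 5000 species allocated over extant families; a
Poisson fossilisation rate of 0.02 finds per lineage-My; and richness
trajectories spanning 320 My on stage-like sampling times drawn from the
packaged stage-duration distribution, with AR(1) noise (sd 0.2,
phi 0.6) on log richness.

Richness is allocated by a linear-rate urn — each new species joins
family *i* with probability proportional to rate_i·n_i — which with equal
rates is exactly the equal-rates Markov model underlying the
Slowinski–Guyer null, so type-I-error simulations are honest; an
implanted shift multiplies the rates in one clade. The exponential
trajectory mode is parameterised so that mean log(richness + 1) is
exactly linear, giving the quadratic-term calibration an exact null; the
logistic mode uses the natural K/(1 + c·e^(−rx)) curve.

What the generators do *not* emulate: non-independence among source trees
(shared data between published studies is an upstream curation problem),
heterogeneous or time-varying preservation, correlated richness and
preservation, and taxonomic error in the richness table. Passing the
synthetic tests therefore validates the machinery and its statistical
calibration, not the robustness of any empirical conclusion to those
real-data complications.

# Problem sizes used in the packaged checks

The test-suite simulations use 12–16-family trees, 500 null replicates
and 200 power replicates for shift detection, 30 replicates for
ghost-range recovery, and 200 replicates at 200 interpolated points for
growth-test calibration; the supertree search is validated exhaustively
at up to 6 taxa (105–945 rooted topologies) and by self-consistency and
score comparison at 12. These sizes make every distributional claim
measurable to within Monte-Carlo error of a few percent while keeping the
whole suite fast.

# A worked miniature

```{r example}
sc <- scenario(seed = 42, n_families = 10, death = 0.01,
               n_input_trees = 8, taxon_subsample_fraction = 0.8,
               nni_perturbations = 1, preservation_rate = 0.05)
model <- gen_model_tree(sc)
trees <- gen_input_trees(model, sc)
mat <- mrp_encode(trees, sc$outgroup)
mat
res <- supertree_search(mat, "mrp", restarts = 10, seed = 42)
res
cons <- majority_rule_plus(res)
v_scores(cons, trees)

record <- gen_fossil_record(model, sc)
tr <- ape::keep.tip(model, intersect(model$tip.label, record$family))
adj <- adjust_originations(tr, record)
extension_summary(record, adj)[c("n_extended", "max_extension")]

s_fossil <- lineage_series(record, geo_timescale(), "fad",
                           source = "fossil_only")
s_adj <- lineage_series(adj, geo_timescale(), "adjusted_fad",
                        source = "mrp_adjusted")
all(s_adj$richness >= s_fossil$richness)
```

# Known limitations

* The supertree search is heuristic beyond ~6 taxa; equally optimal sets
  found by different software on the same matrix can differ, and so can
  the minority components of the consensus.
* The trickle-down correction's null behaviour at deep nodes is slightly
  anticonservative (see above); the raw test is available alongside.
* Ghost ranges adjust against the immediate sister only; missing
  (unsampled) lineages make the adjustment date older, ancestral
  divergences.
* The growth test contrasts linear and quadratic curvature in log
  richness; it does not fit a logistic (Verhulst) model or locate
  breakpoints.
* Stage binning, midpoint time coordinates, and base/top resolution of
  stage-named dates are conventions; all are exposed as data so users can
  substitute their own timescale.
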
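---
title: "Models and methods behind phyloturn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phyloturn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

phyloturn asks how much of the spatial turnover of a clade's lineages is
explained by climate (phylogenetic niche conservatism, PNC) versus geographic
distance (dispersal limitation, DL), and how the underlying niches and ranges
evolved on the tree. This vignette is the package's own account of the models
it implements, the defaults it chooses where a choice was genuinely open, and
what its synthetic benchmarks do and do not establish.

## Time-calibrated trees

All evolutionary computations run on rooted ultrametric trees with branch
lengths in Ma; node ages are times before present (tips at 0) and
ultrametricity is enforced to 1e-6 Ma. Composite trees are assembled by
`graft_subtree()`: a densely sampled dated subtree replaces a set of backbone
tips, rescaled by a single multiplicative factor so its crown age equals the
attachment age. Uniform rescaling is the simplest order-preserving choice and
matches meta-tree practice; nothing finer (per-branch rate matching) is
attempted. Multi-tip replacements attach at the tips' MRCA (also when the
tips are paraphyletic, in which case all of them are removed — deterministic
and conservative); a single replaced tip attaches halfway along its terminal
branch. Single-tip subtrees keep a degree-2 attachment node so the pendant
branch records the attachment age. `expand_genus_polytomies()` applies the
same machinery to attach species-level polytomies at a genus' crown node, or
at the terminal-branch midpoint for genera represented by one tip.
`slice_tree_at()` collapses every branch crossing a cutoff into one lineage
tip, re-zeroed at the cutoff; this is the substrate for "ancient turnover".

## Gridding and predictors

Occurrences map to a half-degree plate-carrée lattice anchored at
(−180, −90); cells are half-open with the west/south edge inclusive — an
explicit convention so edge points have one unambiguous home. Retained cells
need a minimum richness (3 by default) and a cell-center latitude within 33°,
with an optional exempt region that bypasses only the latitude rule (the
Australia case). Dry season length is the longest run of months below
100 mm, evaluated circularly across the December–January boundary because a
dry season is an ecological, not calendrical, interval. Climate values are
aggregated to cells by the mean; synthetic layers are generated at cell
resolution so aggregation is the identity in tests. Biome distance is 0 for
same, 1 for different, and 0.5 when one cell carries the savanna/succulent
overlap class and the other one of its members.

## Beta diversity

Pairwise turnover uses the Simpson index `min(b,c)/(a+min(b,c))`, which is
insensitive to richness differences; the Sørensen form is kept for the PBD
deviation bookkeeping. In the phylogenetic version, a/b/c are branch lengths
of the spanning subtree of the two cells' pooled tips, classified as shared
or unique; the branch subtending the MRCA of the union is excluded, so the
index depends only on the spanning subtree and collapses to the taxonomic
index on a star tree — the property the test suite checks. Pairs with no
shared or unique structure (`a = 0` and `min(b,c) = 0`) are undefined and
flagged. Great-circle distances use the haversine on a 6371.0-km sphere.

## Generalized dissimilarity modelling

The GDM engine is written from scratch. Each predictor is transformed by
three quadratic I-splines with knots at its observed minimum, median and
maximum (trailing partial sums of an order-3 B-spline basis, so each basis
function rises monotonically from 0 to 1); pre-paired distances such as
geographic or biome distance enter their own basis directly. The model is
`d = 1 − exp(−η)` with `η` a non-negative combination of absolute
between-site basis differences, fitted by iteratively reweighted least
squares with a non-negativity constraint (Lawson–Hanson NNLS inside each
IRLS step), minimizing the binomial deviance. Convergence is a relative
deviance change below 1e-8 or 200 iterations. Percent deviance explained is
measured against the saturated model, so a perfect noiseless fit reports
100 %. Variation partitioning fits A+B, A and B and reports unique and
shared components, clamping small negative differences (numerical noise) to
zero; the rescaled fractions sum to one. Geographic residuals come from an
OLS regression of turnover on distance; because the negative-exponential
link needs an open unit interval, the residuals are min–max rescaled to
[0.001, 0.999] before being refit as a GDM response — the raw residuals are
returned too, and both conventions are usable since the original practice is
not fully specified.

## Phyloregionalization

Cells are clustered by `stats::hclust` behind the package's surface. Ward
clustering applies the Lance–Williams recursion to squared dissimilarities
(the common "ward.D2" contract; an unsquared variant is available behind a
flag), UPGMA is the average-linkage alternative, and algorithm choice is
informed by the cophenetic correlation together with the size of the largest
k = 2 cluster — UPGMA maximizes cophenetic fit by construction but tends to
accrete near-uniform dissimilarities onto one dominant blob, which is why a
balance diagnostic is reported alongside. Undefined pairs are imputed with
the matrix maximum (keeping cells, biased toward separation) with a logged
count. Climatic distinctness uses a two-sided Wilcoxon rank-sum test for two
clusters (exact for small tie-free samples) and Kruskal–Wallis plus Dunn's
z-tests with Bonferroni adjustment for more; a cluster counts as distinct
when it differs from every other cluster at 0.05.

## Niche evolution

Ancestral states under Brownian motion use the re-rooting ML estimator
(each internal estimate is the GLS mean of the tree re-rooted there); the
test suite verifies it against dense-matrix GLS solves to 1e-8. Pagel's λ is
estimated by ML with a likelihood-ratio test against λ = 0. Precipitation
regimes follow the dry < 1200 mm / wet > 1800 mm categories (DSL: wet < 4,
dry > 8 months); a branch carries a shift iff the endpoint categories differ
*and* the reconstructed change is at least 250 mm (1 month for DSL), dated
at the midpoint of the two node ages. Terminal branches use the observed tip
value as the child state. DSL, an integer, is reconstructed as continuous
and categorized afterwards, mirroring the use of one continuous machinery
for both variables. Per-5-Ma bins count internal nodes as the split
denominator (branch midpoints behind a flag, since the denominator
convention is ambiguous).

A structural limitation the benchmarks expose: ML reconstruction smooths,
so the estimated change across one short branch is a strongly shrunken
version of any true jump there, and the parent estimate is pulled toward the
shifted clade (halfway, for a cherry). Imposed-jump experiments at 100 tips
therefore recover only ~30–40 % of shifts on exactly the right branch and
~65–70 % within one branch of it, with a false-positive rate well under 5 %,
even for jumps of three times the minimum change and regardless of noise
level. Counts of shifts from real reconstructions should be read as
conservative event inventories, not branch-exact localizations.

## Discrete states and ranges

The Mk machinery (pruning likelihood, ARD ML fit with box-constrained
optimization on log rates, stationary-frequency root weighting) and
stochastic mapping (node states from conditional distributions, then
endpoint-conditioned paths by modified rejection sampling with a
uniformization fallback) are implemented from scratch and validated against
exhaustive enumeration and exact two-pass marginals. Transition branches are
those whose endpoint states conflict in at least half the maps, with the
majority direction reported.

DEC follows the classical parameterization: dispersal adds one area at rate
`d` per occupied source area, extinction removes one at rate `e`, the empty
range is absorbing; cladogenesis allows sympatry for single-area parents,
vicariance and subset sympatry for wider ones, and founder events with
weight `j` ∈ [0, 3] in DEC+J (j = 0 reduces exactly to DEC). The root prior
is uniform over allowed non-empty ranges, and the maximum range size
defaults to the number of areas. Matrix exponentials reuse one
eigendecomposition per rate matrix with a Padé fallback. Ancestral-range
marginals come from two-pass belief propagation, AIC weights
(`w ∝ exp(−ΔAIC/2)`) average them across models, and the decided range is
the smallest set of areas, taken in decreasing per-area marginal
probability, whose cumulative normalized probability exceeds 50 % (a
most-probable-composite mode exists, since the >50 % phrasing is ambiguous
between per-area and per-range probabilities). Dispersal events are branches
whose child's decided range includes a group absent from the parent's, dated
at the branch midpoint, under a seven-region grouping (the Americas merged)
and a stricter three-region grouping (Americas / Old World / Oceania).

An important estimation subtlety: the unconditioned DEC likelihood charges
every lineage for its probability of never going extinct, but simulated
range histories are conditioned on survival, so fitting them with the
default likelihood drives `ê` to zero structurally. `fit_dec()` therefore
offers a survival-conditioned likelihood (dividing by the probability that
no lineage hits the empty range), which the recovery benchmark uses; the
default stays unconditioned to match standard practice on empirical trees.

## The synthetic generator and what passing tests show

`sim_config()` fixes the study conditions: birth 0.3 and death 0.1 per
lineage per Ma, Brownian MAP niches (root 1500–1800 mm, σ² of a few thousand
mm²/Ma, λ = 1), a slow two-state Mk process, a linear west–east MAP gradient
(200–3800 mm across a 10° × 5° extent at 0.5°) whose twelve monthly layers
follow a fixed seasonal profile (wet months share the surplus, dry months
get 50 mm) so DSL has exact ground truth, and 20 occurrences per species
jittered around the cells nearest each species' optimum. One RNG stream per
generator, offset from the config seed, gives stage-level reproducibility.
The generator emulates the *structure* of real data — gradients, niche
tracking, range histories — but not their messiness: no sampling bias, no
spatial autocorrelation beyond the gradient, no coordinate error, no
mismatched taxonomies. Passing recovery tests therefore demonstrates
correctness of the estimators under the stated models, not robustness to
real-data pathologies.

Benchmark problem sizes, chosen once: λ recovery uses 200-tip trees
(~67 replicates per λ in the test suite, 40 in the acceptance script); the
DEC benchmark uses 100-tip trees rescaled to a 60-Ma crown — the age scale
of a mid-Cenozoic pantropical radiation, deep enough that extinction leaves
an identifiable signature — with a widespread ancestor and d = 0.02,
e = 0.01; shift recovery uses 10 imposed regime jumps per 100-tip tree,
each moving a subtree into the core of the opposite regime; the two-band
regionalization check requires both root clades to hold at least a quarter
of the tips, so that both climate bands survive the richness filter and the
k = 2 ground truth is well posed. The end-to-end pipeline demonstration runs
80 species over a 200-cell landscape and completes in a few seconds.

## Known limitations

Branch-exact niche-shift attribution is weakly identifiable (above); DEC's
extinction rate is near-unidentifiable without survival conditioning on
conditioned data; Ward on non-Euclidean dissimilarities is a heuristic
(the squared-input contract is stated, not derived); the biome scheme
implements only the three-biome-plus-overlap coding; and no attempt is made
to clean real occurrence records — gazetteer and cultivation filtering are
out of scope.
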
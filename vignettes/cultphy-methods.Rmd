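---
title: "Methods: discrete-trait cultural phylogenetics with cultphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discrete-trait cultural phylogenetics with cultphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cultphy implements a complete comparative-methods workflow for binary
cultural traits on population histories: building a supertree from
heterogeneous source trees by matrix representation with parsimony (MRP),
calibrating it in time from minimum node-age constraints, reconstructing
ancestral character states by parsimony and by maximum likelihood under Mk
models, quantifying homoplasy, and testing pairs of traits for correlated
evolution with Pagel's (1994) method under a Monte Carlo likelihood-ratio
null. The motivating application is the evolution of religiosity traits
(animism, belief in an afterlife, shamanism, ancestor worship and its
active form, high gods and their active form) across a worldwide sample of
33 hunter-gatherer societies, and the package ships a synthetic fixture
with that structure; every component is generic and works on any rooted
tree plus 0/1 character tibble.

## Supertree construction (MRP)

Each non-root internal node of each source tree is encoded as one binary
character: descendants 1, remaining taxa of that source 0, all other taxa
missing (`?`). Semi-rooted coding adds a hypothetical all-zero outgroup
that is scored 0 for characters from rooted sources (preserving their
rooting information) and `?` for characters from unrooted ones. Characters
derived from a linguistic-classification scaffold are up-weighted — the
reference weight is 100 — so that, whenever scaffold groupings conflict
with individual source trees, the scaffold wins; with a weight exceeding
the summed weight of conflicting characters the scaffold clades are
guaranteed in every optimal tree, which is exercised in the test suite.

The search is heuristic and deterministic given a seed: random-addition
starting trees (greedy stepwise insertion), first-improvement NNI
hill-climbing with a seeded visit order (ties collected as equally
parsimonious topologies), and a parsimony ratchet that doubles the weight
of a random quarter of the characters, re-climbs, and restores the original
weights. This is a documented, reproducible stand-in for the proprietary
"new technology" searches of TNT-class software; full-scale (hundreds of
taxa) searches are out of scope, and correctness is instead verified by
exhaustive enumeration: at 8 taxa the heuristic attains the global optimum
over all 10,395 unrooted topologies in the tests. Equally parsimonious
trees are summarised by the semi-strict (combinable-component) consensus:
every clade present in at least one optimum and contradicted by none.

## Time calibration

Published divergence-date estimates enter as *minimum* node ages attached
to clades (tab-separated tables with one row per constraint and a
`date_set` column, since analyses are run under both a "deep", mostly
molecular, and a "shallow", minimum-estimate, calibration). Enforcement
pins each constrained node at (at least) its minimum and propagates ages
rootwards so no parent is younger than a child. The remaining internal
nodes have no data to place them, so their ages are interpolated. The
historical tool chain left this interpolation unspecified ("arbitrarily
ultrametricize"); we define it deterministically: each chain of
unconstrained nodes between a fixed ancestor and its oldest fixed (or
leaf) descendant is spaced evenly, so a caterpillar below a root fixed at
12 kya places successive nodes at 8 and 4 kya. An alternative rule that
preserves the proportions of the original branch lengths is available via
`method = "proportional"`; even spacing is the default because input
supertrees typically carry no meaningful branch lengths. All leaves sit at
age 0 (all societies are extant) and ages are in kya throughout.

## Ancestral state reconstruction

**Parsimony.** `fitch_asr()` computes minimum change counts and *exact*
most-parsimonious state sets per node via a unit-cost dynamic program
(down-pass conditioning each node on each state, up-pass adding the cost
of the rest of the tree); a state is reported at a node iff some globally
optimal labelling uses it, and nodes with both states are flagged
equivocal. Homoplasy is summarised by the Kluge–Farris indices CI = m/s
and RI = (g − s)/(g − m), with m the minimum conceivable steps (1 for a
variable binary character), s the observed minimum on the tree, and g the
maximum needed on any tree (the minority-state count). Ensemble values sum
m, s, g over characters. Constant characters carry no signal and are
excluded from the ensemble sums (their CI/RI are `NA`); the all-zero
outgroup row is included by default, matching the reconstruction
convention, with `include_outgroup = FALSE` available for sensitivity
analysis, since published index values do not always state this
convention.

**Likelihood.** The two-state Mk1 model has a single rate q and closed-form
transition probabilities P(same) = 1/2 + e^(−2qt)/2; the asymmetric
variant has separate gain and loss rates. Likelihoods use Felsenstein
pruning (C++ core, with per-node rescaling against underflow); rates are
optimised on the log scale, bounded below at 1e−8 — a constant character
legitimately drives the rate to this floor — with golden-section search in
one dimension and bounded quasi-Newton with three seeded starts in two,
guarding against boundary traps. The root prior is uniform for Mk1 (its
stationary distribution); for the asymmetric model the default remains
uniform with `"stationary"` available, as the reference analyses do not
state their convention. Marginal ("proportional") node probabilities come
from the up-down algorithm and are validated in the tests against explicit
summation over all ancestral labelings. A node's reconstruction is deemed
significant when the log-likelihoods of the two states differ by at least
T = 2 — support e² ≈ 7.389 ≈ 7.4 times greater for one state — and
equivocal otherwise; the per-node stars in published tables are treated as
an alias of this rule, with no additional test. The reported "root" of
interest is the last common ancestor of the study societies, i.e. the
child of the global (outgroup-anchored) root (`ingroup_root()`). An
asymmetric likelihood-ratio test (`asymmetry_test()`, 2ΔlogL against
χ²(1)) checks per character whether the extra rate is warranted.

## Correlated evolution (Pagel 1994)

Two binary traits define a joint chain on four states (0,0), (0,1), (1,0),
(1,1), ordered A-major. The independent model has four rates (gain/loss of
each trait, unaffected by the other); the dependent model has eight (each
trait's gain/loss in each state of the other); simultaneous double
transitions have rate zero. Under a product root prior the independent
likelihood factorises into the two marginal chains, so the independent fit
uses the fast closed-form two-state machinery, and its embedding provides
the starting point for the dependent fit — which also guarantees, in
practice, the nesting inequality logL_d ≥ logL_i that the tests assert.
Dependent-model transition matrices come from an eigendecomposition of the
generator (with a scaling-and-squaring fallback for defective matrices) in
the C++ core. Optimisation is bounded quasi-Newton on log rates with an
iteration cap of 500 and three seeded starts for observed fits.

The reported likelihood ratio follows the raw-difference convention
LR = logL_d − logL_i (the arithmetic used in the reference results; the
conventional χ² statistic 2·LR is also reported by `glance()`).
Significance comes from a Monte Carlo null: simulate `n_sim` datasets
under the *fitted independent* model (exponential waiting times along each
branch), refit both models to each, and take
p = (1 + #\{LR_sim ≥ LR_obs\}) / (n_sim + 1). The add-one correction keeps
p away from an impossible zero; because the null distribution is the same
whether LR or 2·LR is compared, the convention choice cannot affect p.
Monte Carlo refits default to a single start seeded at the replicate's own
independent-model estimates, which keeps observed and null fits on the
same footing; they also use a looser convergence tolerance (L-BFGS-B
`factr` 1e9 with a projected-gradient cutoff of 1e-4 and a 250-iteration
cap, versus `factr` 1e7 and 500 iterations for observed fits), chosen so
the induced log-likelihood error is orders of magnitude below the
resolution of the LR statistic. The reference analyses used 1000 simulations and that is the
default of `pagel_mc_test()`; the packaged pipeline and acceptance script
use 99–199 simulations per test, which resolves p to 0.01–0.005 and keeps
a 21-pair run in minutes on one CPU.

## Synthetic data generation

`simulate_tree()` draws a pure-birth tree and rescales it to a stated root
depth (default 70 kya, the shallow-calibration depth of the study system).
`simulate_traits()` evolves each character by a continuous-time two-state
chain whose stationary frequency is calibrated to a target prevalence
(q01 = r·p, q10 = r·(1 − p)) with the root drawn from the same stationary
distribution, so the expected tip prevalence equals the target exactly;
the default total rate r gives about 1.5 expected changes per root-to-tip
lineage, a moderately labile cultural trait. Correlated pairs are
simulated under an explicit 8-rate dependent model. All generators require
a seed and are exactly reproducible. Branches are simulated event by event;
on saturated branches (more than a thousand expected transitions, where
only the end state is identifiable anyway) the end state is drawn directly
from the transition matrix — the same distribution, without the
astronomical event count that saturated fitted rates would otherwise
trigger inside Monte Carlo refits.

The packaged fixture (`load_study_fixture()`) is a *synthetic* stand-in
for the study dataset, whose per-society matrix and calibrated tree are
only distributed in supplementary material not included here. It
reproduces everything the published text pins down — the 33 society names
mentioned, the exact prevalence percentages (100/79/79/45/24/39/15), the
per-society presence/absence facts stated in prose (e.g. the Slave have
shamanism without afterlife belief; the Hadza, Mbuti and Aka lack both),
the 4-state codings behind the two "active" traits, the continental
topology (deep African/non-African split, Khoisan–Pygmy grouping, Vedda as
deepest non-African lineage, Paleo-Asiatic and Beringian-American clades)
and an out-of-Africa age above 60 kya — and it is integrity-checked by
md5 at load time. It does **not** reproduce the unpublished branch
lengths, the undocumented per-society codings, or any within-region
topology details, so fixture-derived numbers (CI/RI, log-likelihoods,
root proportional likelihoods) are expected to resemble, not equal, the
published ones. Consequently the test suite asserts published values only
where the fixture pins them exactly (prevalences, nesting of active
traits, topology statements) and otherwise verifies the *methods* against
independent oracles: exhaustive enumeration for Fitch counts, MPR sets and
pruning likelihoods; closed forms against the matrix exponential;
exhaustive topology search; and calibration/power simulations for the
Monte Carlo test. Passing tests therefore demonstrate correctness of the
machinery and faithfulness of the fixture's documented structure, not
agreement with unpublished data.

## Problem sizes and numerical choices

Simulation-backed checks use sizes chosen to make their statistical
targets sharp at desk scale: the Monte Carlo type-I calibration runs 200
outer replicates of a 99-simulation test on a 20-tip tree (rejection rate
required inside [0.01, 0.10] at α = 0.05); the power check uses 15
replicates at 100 tips under a 20-fold gain-rate asymmetry (required ≥
0.8); rate recovery uses 100 datasets at 100 tips (median relative error ≤
30%). Tolerances: pruning vs enumeration 1e−10; closed form vs matrix
exponential 1e−12 (absolute); ultrametricity 1e−9. Ties in the parsimony
search are broken by a seeded random visit order; equally old anchors in
the ultrametricizer prefer the longer original path. Degenerate inputs —
constant characters, zero-length branches, all-missing columns — are
exercised in the tests: constant characters pin rates to the lower bound
and are excluded from ensemble homoplasy; zero-length branches yield
identity transition matrices; all-missing columns give NaN prevalence with
a warning.

## Known limitations

MRP search is validated only at small taxon counts; no bootstrap or
jackknife supports are provided. The Mk machinery is strictly two-state
(multistate inputs must be recoded, as the 4-state worship/high-gods
scales are); there is no rate heterogeneity across branches and no
stochastic character mapping. The Pagel test covers pairs only, without
covarion or reversible-jump extensions, and p-values for the 21 pairs are
deliberately uncorrected for multiple testing, mirroring the reporting
style of the motivating analysis. Horizontal transmission (borrowing) and
geographic autocorrelation — real forces in cultural evolution — are
outside the model family; the synthetic generator correspondingly cannot
emulate them, so tests say nothing about robustness to reticulate
history.
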
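---
title: "Methods: models, estimators and simulations in divlimit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and simulations in divlimit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divlimit)
```

divlimit asks a simple question with a long time horizon: when two
orthologous proteins keep the same molecular function for billions of
years, does their pairwise sequence identity decay to the random-alignment
background, or does it level off at a finite floor? This vignette documents
the models, the estimators, the numerical choices, and the judgment calls
behind the package, together with their limitations.

## The three divergence models

Let `y(t)` be the expected percent identity between two orthologs whose
lineages split `t` billion years (Gy) ago. The package fits three nested
or alternative forms:

* **M1 (single exponential).** All sites substitute independently at the
  same rate and never revert: `y = 100 exp(-R0 t)`. Identity decays to
  zero; any long-term plateau falsifies this model.
* **M2 (divergence floor).** A fraction `Y0` of identity persists
  indefinitely: `y = Y0 + (100 - Y0) exp(-R0 t)`. M1 is the `Y0 = 0`
  special case, which is what makes the nested F-test meaningful.
* **M3 (gamma rates).** Substitution rates vary across sites following a
  gamma distribution with shape `alpha`; integrating the exponential decay
  over that distribution gives `y = 100 (R0 t / alpha + 1)^(-alpha)`.
  Identity still reaches zero eventually, but arbitrarily slowly for small
  `alpha` — the serious null hypothesis against a true floor.

Two derived quantities are used throughout: the instantaneous divergence
rate `-dy/dt` (`divergence_rate()`; for M3,
`100 R0 (R0 t / alpha + 1)^(-alpha - 1)`) and the same rate expressed as a
function of fractional distance `D = 1 - y/100` rather than time
(`expansion_rate()`; `dD/dt = R0 (1 - D)^((alpha + 1)/alpha)`), which
describes how fast the explored protein space expands as divergence
proceeds. `rate_decline_factor()` reports how many times slower divergence
has become by time `t`.

### The finite-alphabet interpretation of the floor

A mechanistic reading of M2: each site accepts an effective alphabet of
`a` residue types, exchanged uniformly at per-site rate `lambda`, with
back substitutions allowed. The expected pairwise identity is then

```
y/100 = 1/a + (1 - 1/a) exp(-2 lambda t a/(a - 1))
```

which is exactly M2 with `Y0 = 100/a` and `R0 = 2 lambda a/(a - 1)`
(`alphabet_to_limit()`, `limit_to_alphabet()`; the equivalence is tested
to 1e-12). A 40% floor corresponds to `a = 2.5` accepted residue types per
site. Inverting the curve gives the back-substitution-corrected distance
`expected_substitutions()`, which diverges as identity approaches the
`100/a` saturation level — the reason uncorrected identity is used for
fitting and the correction only for interpretation.

## Fitting and inference

`fit_divergence_model()` minimizes the unweighted residual sum of squares
over all pairwise observations. That choice is deliberate: each ortholog
pair contributes one point even when pairs share species, and duplicated
observations count with their multiplicity. Phylogenetic non-independence
is handled upstream (by edge-disjoint pair selection, below), not by the
loss function.

Numerics: bounded L-BFGS-B from a multi-start grid (`R0` log-spaced in
[0.05, 20] with 10 starts; `Y0` additionally from {0, 20, 40}; `alpha`
log-spaced in [0.1, 50] paired with the `R0` grid), with box constraints
`R0 <= 50`, `Y0` in [0, 100], `alpha <= 100`. Multi-start matters: the M3
objective in particular has long curved valleys in `(R0, alpha)` and a
single start frequently stalls. Standard errors come from the asymptotic
OLS covariance `sigma^2 (J'J)^{-1}` with a forward-difference Jacobian;
this is the same approximation standard nonlinear least-squares summaries
report and it is what the acceptance property on coverage tests.

Model comparison:

* `f_test_nested()` — M1 vs M2, `F = (rss1 - rss2)/(rss2/(n - 2))` on
  `(1, n - 2)` degrees of freedom, clamped at zero if the optimizer leaves
  `rss2` marginally above `rss1`. One caveat worth knowing: when the true
  floor is exactly zero, the `Y0 >= 0` constraint pins nearly half of the
  null F mass at zero, so the realized type-I error is roughly half the
  nominal level (about 0.028 at nominal 0.05 in simulation) — the test is
  conservative at the boundary, which only strengthens any rejection it
  does report.
* `wald_test_floor()` — one-sided `z = (Y0 - baseline)/SE(Y0)` against the
  random-alignment baseline (default 13.5%, see below). One-sided because
  the scientific claim is directional: the floor exceeds the background.
* `project_identity()` — model evaluation at a horizon, default 7.8 Gy
  (the deepest divergences in typical data plus the remaining habitable
  lifetime of Earth), used to ask whether even the gamma-rates model
  predicts identity above background within a biologically meaningful
  window.
* `resample_divergence_times()` — divergence-time estimates for deep
  splits carry huge systematic uncertainty. Rather than pretending to a
  distribution, every species pair's time is set to its literature minimum
  or maximum by a fair coin, models are refitted per family, and the
  fraction of families keeping a floor above 25% is recorded across runs.
  Rows sharing a `(time, time_min, time_max)` triple flip together by
  default (they usually come from one species pair), overridable via a
  `species_pair` column.

## The random-alignment baseline

The floor is only meaningful relative to the identity that *unrelated*
proteins achieve under the same alignment procedure. `global_align()`
implements textbook global alignment with affine gaps (Gotoh three-state
dynamic programming, end gaps penalized, deterministic tie-breaking), in
C++ for speed; `random_identity_baseline()` aligns i.i.d. random sequences
drawn from the Robinson–Robinson background composition
(`aa_background()`) and reports mean percent identity over non-gap
columns.

Default scoring is BLOSUM62 with gap open 12 and gap extend 3. The gap
defaults were chosen by calibrating the random baseline: with this scoring
the mean identity of 500 random length-300 pairs sits at ~13.5%, the
background level long-diverged orthologs should be compared against.
Notably permissive gap costs (e.g. extend penalties below 1) inflate
random-pair identity above 25% by letting the aligner stitch together
look-alike fragments, which would make even a true floor invisible; the
chosen defaults keep the baseline at the level that obtains across
reasonable, commonly used affine scoring schemes. `percent_identity()`
excludes gap columns from numerator and denominator, so identity is a
property of the aligned residues.

## Phylogenetically independent pairs

Identity observations from a tree of species are not independent: two
pairs whose connecting paths share a branch share evolutionary history.
`select_independent_pairs()` selects a maximum set of leaf pairs with
edge-disjoint connecting paths whose divergence times fall in a window.
For trees with at most 12 leaves the maximum is found exactly (branch and
bound over the pair-conflict graph); larger trees use a greedy heuristic
preferring short paths (cherries first). The exact/greedy threshold of 12
keeps worst-case exact search well under a second while covering the tree
sizes where optimality is actually checkable; the result is always
re-verified with `pairs_edge_disjoint()` regardless of path taken.

Supporting curation tools mirror the manual steps such analyses need:
`assign_divergence_time()` (literature lookup with deep-time overrides:
4 Gy for any cross-domain pair, 2.7 Gy for TACK-archaea–eukaryote pairs),
`calibrate_distance_time()` (linear 16S-distance calibration, clamped at
zero), `flag_hgt()` (normalized Robinson–Foulds conflict between gene and
species tree, flagging above 0.2), and `flag_ancient_duplication()` (an
internal node whose child subtrees share a species, ancestral to 3 or more
species, marks divergences that predate speciations).

## Which sites carry the floor

`site_identity_profile()` computes, per reference site, the fraction of
independent ortholog pairs with identical residues; sites conserved in at
least 90% of pairs are called *universal* (`universal_site_fraction()`).
`conserved_identity_share()` makes the key bookkeeping point: if 14% of
sites are universal but 40% identity persists, universal sites explain
only ~35% of the conserved residues — the floor is mostly carried by
different sites in different pair comparisons, as expected when each site
wanders within a small accepted alphabet rather than freezing.

`fitness_binned_divergence()` and `shell_divergence()` stratify the
identity-versus-time curve by experimentally measured per-site fitness
effects or by distance shells around the active site
(`assign_distance_shells()`, default shell width 5 Å — fine enough to
resolve a gradient over a typical enzyme radius, coarse enough to keep
tens of sites per shell). Aggregation order is: identity per pair over the
group's sites first, then mean/SD/SEM per time bin; this weights each
independent pair equally instead of letting long proteins dominate. Time
bins are left-closed, right-open; empty bins are reported as `NA`, never
an error.

## Growth-rate estimation from pooled competitions

The fitness inputs above come from MAGE-style saturation mutagenesis
followed by pooled turbidostat competition. In exponential growth, the log
ratio of mutant to wild-type read counts is linear in time with slope
equal to the growth-rate difference (per hour); dividing by the dilution
rate (default 1.37 e-folds/h) expresses it as a relative growth-rate
difference — a slope of −0.137/h is 10% slower growth.

`relative_growth_rates()` fits that slope by OLS per mutant over time
points with at least 20 mutant reads (and non-zero WT reads); mutants with
fewer than 5 qualifying points are flagged as filtered rather than
estimated, because a low-count tail is exactly where ratio noise explodes.
The 20-read and 5-point thresholds trade bias (dropouts are informatively
missing) against variance; the filter boundary is tested exactly.
`median_normalize()` removes batch-level abundance artifacts from 10-codon
mutagenesis batches (per time point: divide each batch by its median, then
rescale to preserve the non-WT total; zero-median batches are flagged and
left alone). `site_fitness_profile()` collapses codon-level estimates in
two stages — codon → amino acid, then amino acid → site — so that
amino-acid changes sampled by many codons do not dominate the site mean;
synonymous changes are excluded from site means by default (they measure
codon-level, not protein-level, effects) and nonsense changes are kept.
`split_half_consistency()` (random 32/64-codon split, Pearson across
sites) quantifies robustness to sampling noise.

## Structural divergence

`kabsch_rmsd()` is the standard SVD superposition with the reflection
guard on the determinant, so mirror images are never superposed by an
improper rotation. `rmsd_time_trend()` summarizes RMSD versus divergence
time (Spearman rank correlation, 0.5-Gy percentile bins, moving average);
`coverage_filter()` drops structure pairs with more than 70% of the
shorter chain unaligned, plus pairs flagged as needing flexible alignment.
`functional_group_comparison()` and `identity_by_structure_bins()` compare
identity or RMSD across functional-conservation groups with two-sided
Mann–Whitney tests (exact enumeration is an oracle in the test suite),
the latter within RMSD bins to ask whether functional conservation
constrains sequence beyond what structure maintenance requires.

## The simulator

`make_site_profile()` + `evolve_pair()` implement the generative model the
finite-alphabet math describes: per site, an allowed set of `a` residues
containing the ancestor, uniform exchange at rate `lambda_i` (optionally
gamma-distributed across sites), two lineages evolving independently from
the common ancestor. Site endpoints are sampled from the exact
continuous-time Markov transition probabilities
(`P(stay) = 1/a + (1 - 1/a) exp(-a lambda t/(a - 1))`) rather than by
event-by-event Gillespie simulation — the closed form is then the exact
expectation of simulated identity, which is what makes the
simulator-versus-theory acceptance property sharp, and endpoint sampling
is orders of magnitude faster at deep times.

What the simulator deliberately does *not* emulate: allowed sets are fixed
over time (no covarion behavior, no epistatic drift of the acceptable
alphabet), sites are independent, there are no insertions or deletions
(simulated pairs are gap-free and aligned by construction), and the
amino-acid identity of the allowed residues is uniform-random rather than
biochemically structured. These are the assumptions of the analytical
model, adopted so that theory is an oracle; they are not claims about
proteins.

`simulate_observations()` (model curve plus truncated Gaussian noise),
`simulate_mage()` (exponential trajectories observed through multinomial
read sampling, with an infinite-depth `"expected"` mode whose estimates
are exact), `simulate_tree()` (coalescent ultrametric trees) and
`simulate_ortholog_msa()` provide matched synthetic inputs for every
estimator in the package.

## Problem sizes and runtime

The package is desk-scale by design: alignments of a few hundred residues
(the C++ aligner does ~500 length-300 alignments in seconds), hundreds of
ortholog pairs, trees up to a few dozen leaves (exact pairing up to 12),
simulations of 10^3–10^4 replicates at 500 sites in under two minutes on
one core. Nothing in the package requires more than a single CPU and a
few hundred MB of memory.

## Limitations

* OLS on pairwise identities understates uncertainty when pairs share
  history; the package mitigates by pair selection, not by a phylogenetic
  covariance model.
* The floor/gamma dichotomy is a model comparison, not proof: data
  confined to `t <= 4` Gy cannot distinguish a true floor from decay slow
  enough to look flat, which is why projections and the Wald test against
  the random baseline are reported alongside the F-test.
* Divergence-time estimates for deep splits are systematically uncertain;
  the min/max resampling brackets rather than integrates that uncertainty.
* Growth-rate estimates assume exponential competition and independent
  reads; bottlenecks, lag phases and PCR duplicates are not modeled.
* The aligner's random-identity baseline depends on the scoring defaults;
  users comparing floors against it should keep scoring consistent between
  their ortholog alignments and `random_identity_baseline()`.
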
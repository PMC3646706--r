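---
title: "Methods: simulating gene trees under the multispecies coalescent with time-dependent migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coalmig models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, numerical
choices, and limitations. It states no empirical result beyond what the
test suite and `scripts/acceptance.R` themselves compute.

## The model

`coalmig` simulates genealogies backward in time inside a rooted
ultrametric species tree. Each species-tree branch is a Wright–Fisher
population with a *scaled* effective size ν(t) = N·τ, where τ is the
generation time expressed in the model's time unit; a pair of lineages
in the branch coalesces at rate 1/ν(t). Migration between two
populations is specified forward in time as the emigrating *fraction*
m(t) per time unit, giving an emigrant flow m(t)·ν(t); the
corresponding backward rate at which a lineage in *a* traces its
ancestry to *b* is m(t, b→a)·ν_b(t)/ν_a(t). We chose the fraction
parametrization (rather than a fixed per-lineage rate) because it keeps
its meaning — migrants per population unit per time unit — when
population sizes change over time.

When a population that exchanges migrants with another clade itself
splits, the split is treated as the clade's internal affair: the total
emigrant flow between the two sides is unchanged, and arrivals are
shared among the extant branches of the destination side in proportion
to their ν values. This is the only split semantics the package
implements; alternatives (a split cutting one daughter off from the
flow entirely, or intermediate cases) are conceivable but out of scope.

### Piecewise-linear rate functions

All of ν(t) and m(t) are nonnegative piecewise-linear functions
(`piecewise_linear()`), linearly interpolated between breakpoints and
constant beyond them. On any sub-interval where the migration fraction
and the two population sizes involved are simultaneously linear, the
hazard is of the form (a₁+b₁t)(a₂+b₂t)/(a₃+b₃t), which decomposes as
c₀ + c₁t + c₂/(a₃+b₃t) and integrates to a polynomial plus a
logarithm (`rational_decompose()`, `integrate_hazard()`). When the
denominator is constant the integrand is a pure quadratic and is
integrated directly — forcing the c₂ term would divide by zero.
The partition into simultaneously-linear sub-intervals is the union of
the component breakpoints; it is precomputed per hazard, together with
cumulative integrals at the partition boundaries, and cached per
species-tree epoch (see below).

Families such as exponential growth are not representable exactly, by
design; they can be approximated to any desired accuracy by refining
breakpoints. Recombination is out of scope, as are serially sampled
tips (all samples are contemporaneous).

### Waiting times

Event times are drawn by the inverse transform: solve
∫ₜ₀ᵗ f(s) ds = −log(1−U) with U uniform on [0, 1)
(`solve_waiting_time()`). We read the logarithm in the inverse
transform as the natural logarithm, the standard convention. The
mixed polynomial-plus-log cumulative has no closed-form inverse, so the
solver first locates the sub-interval whose cumulative straddles the
target and then inverts within it by Newton iteration with a bisection
safeguard, to ~1e−14 absolute in the cumulative (the package asserts
the round-trip identity at 1e−9 relative in time). If the total hazard
available before the horizon is below the target the event does not
happen (`Inf`) — this also covers impossible events (fewer than two
lineages for a coalescence, zero lineages for a migration), which get
an infinite waiting time via a zero hazard scale.

Two measure-zero conventions are fixed for determinism: u = 0 maps to
the infimum time with positive hazard, and ties among equal minimal
candidate times are broken by a fixed enumeration (coalescences in
species order, then migrations in ordered-pair order). ν = 0 is an
error whenever a lineage could occupy the interval, since the
coalescent hazard diverges; it is tolerated on stretches where the
hazard numerator is identically zero.

## The simulator

`simulate_gene_tree()` follows the event loop: draw one candidate
waiting time per possible event (one coalescence per species with ≥ 2
resident lineages, two migrations per ordered pair of co-extant
species), apply the earliest, and redraw everything from the new state.
Candidate times are *not* reused across steps — with time-varying rates
the classic draw-once-per-epoch speedup is unavailable. A candidate
beyond the next species divergence is rejected: time advances to the
*nearest* divergence only, the two daughter species' lineage sets merge
and the number of species drops by one. Above the root the process is a
single-population coalescent under the root branch's
constant-extended ν. Species with zero requested samples still exist as
migration destinations: a lineage may detour through an unsampled
branch.

Between two divergences the extant branch set is fixed, so all hazards
of that *epoch* (including the summed ν of each decorated side, itself
piecewise linear) are built once and reused for every redraw. This
makes the per-event cost a small segment walk plus, for the applied
event, one Newton inversion.

### Inconsistent coalescences

The package defines an *inconsistent coalescence* as a containment
violation against the weak species tree: a gene-tree node whose time is
more recent than the species-tree MRCA height of the species sampled
beneath it. This is impossible under strict divergence and is exactly
what migrating lineages enable. Since a published count could be per
node or per species pair, `count_inconsistent_coalescences()` provides
both (`per = "node"`, `per = "pair"`).

## The gradual-separation scenario

`gradual_separation_scenario()` generates the study condition used
throughout the tests: a Yule tree with birth rate λ (default 0.8,
n = 5 species), population histories (below), and reciprocal migration
at every divergence declining linearly from M at the divergence height
t_d to zero at the separation height t_s. The interval length
t_d − t_s is log-normal with *real-space* mean S/(2λ) — half the
expected Yule branch length, scaled by S — and log-space standard
deviation 0.25; we read "mean" as the real-space mean and set
μ = log(S/(2λ)) − σ²/2 accordingly, which is the literal reading of
the stated parameters. Intervals are truncated at the present
(t_s ≥ 0).

Separation must nest: a clade may not keep exchanging migrants with an
outside partner after its own internal separation has completed.
Divergences are processed from the root down and a child's interval is
redrawn (up to 100 times) until its t_s does not exceed its parent's;
as a deterministic fallback the interval is then truncated to equality.
Redrawing preserves the drawn distribution where possible. Because
intervals are floored at the present and may be clamped to the
parent's separation time, the strong tree can contain zero-length
branches (two divergences completing separation at the same instant,
or a separation still incomplete today); the tests assert that its
branch lengths never go negative, and the pair-location statistic
skips pairs whose weak and strong times coincide.

### Population assignment

The log-normal population procedure is the one genuinely
reverse-engineered component, and the main caveat for interpreting
sequence-level numbers. Each tip's present-day ν is log-normal with
real-space mean `tip_mean` and log-sd 0.4; each branch declines
linearly backward so its older end is 0.7 of its younger end (the
expansion factor: populations grow toward the present); an ancestral
branch starts from the mean of its children's older ends; the root
population is constant. The default `tip_mean = 0.85` is the value
implied by equating the expected within-species pairwise diversity
2 × 0.005 × ν to a reference value of 0.0085 at the default mutation
rate.

Under this reconstruction the *migration-level* behaviour of the
scenario is insensitive to the overall ν scale (backward rates depend
only on ν ratios), and the package's migration-incidence checks
reproduce their reference values closely. Sequence-level diversity is
more sensitive: the realized within-species diversity under the full
genealogy (whose pair TMRCAs are shortened by the backward population
decline) comes out below the 2·rate·ν̄ heuristic. The acceptance
quantities in `scripts/acceptance.R` use a *different*, fully specified
constant-population scenario and do not depend on this reconstruction.

## Validation oracles

Two independent oracles guard the exact simulator.

* `euler_simulate()` discretizes time into steps dt, multiplies every
  event rate by dt to get per-step probabilities, and allows at most
  one event per step. It shares no waiting-time code with the exact
  simulator. Steps with total probability above 0.1 are refused rather
  than silently biasing the discretization. For the constant-rate
  two-population case, `euler_root_heights()` runs the same discretized
  process vectorized over replicates so that large validation samples
  are cheap.

* `ctmc_model()` builds the generator Q of the lineage-configuration
  chain (i, j lineages in the two populations, down to the absorbing
  single lineage) for the constant-rate two-population case. The
  unordered-count state space is sufficient because lineages are
  exchangeable for root-height questions, and it is the smallest space
  that answers them. exp(QT) gives the configuration distribution at
  the divergence; lineages remaining there coalesce in the ancestral
  population, whose time to a single ancestor is hypoexponential with
  rates C(k,2)/ν. `root_height_density()`/`root_height_cdf()` combine
  the two regimes. The closed form requires constant rates on [0, T];
  time-varying regimes are covered by the Euler oracle instead, since
  no general closed form exists there.

The test suite compares all three routes pairwise by Kolmogorov–Smirnov
tests at α = 0.01 on two configurations of the constant-rate
two-population model (1+1 and 2+1 sampled lineages; n = 20,000 in the
acceptance checks), and additionally compares the exact and Euler
simulators under genuinely time-varying rates, where no closed form is
available.

## Experiment harness and statistics

`run_grid()` averages migration counts and inconsistent-coalescence
counts over replicated scenario draws on an (M, S) grid; one fresh
species tree and one gene tree per replicate (defaults: 5 species, 10
individuals each). `fit_hazard_curve()` fits the saturating form
a·hᶜ/(hᶜ + b) of the hazard h = M·S by Levenberg–Marquardt, with a
nested c = 1 fit for comparison.

`rooted_branch_score()` is the clade-matched branch-length distance for
rooted trees: over the union of clades of both trees, the squared
differences of subtending branch lengths (zero where a clade is
absent), square-rooted. The normalization constant of the published
"normalized" variant is not uniquely pinned down, so the package
reports the raw score by default and offers division by the number of
clade terms (`normalized = TRUE`); tests use the raw score, whose
properties (zero iff equal, symmetry, single-branch perturbation
equals the perturbation) are asserted directly.

`weak_strong_classification()` compares a sample of species-tree
estimates to the weak and strong references by mean branch score, and
places each species pair's estimated divergence at
(t̂ − t_s)/(t_w − t_s) between the strong and weak times.
Posterior samples from full Bayesian inference are out of scope; as a
perfect-data analogue, `pair_divergence_bounds()` extracts, per species
pair, the most recent cross-species coalescence over a set of true
simulated gene trees, playing the role of an infinite-sequence-length
divergence estimate.

## Sequences

`simulate_jc()` evolves iid sites under Jukes–Cantor with a strict
clock (uniform root states, branch mismatch probability
(3/4)(1 − e^(−4d/3)) at expected substitutions d); simulation is
delegated to `phangorn::simSeq()` and validated against the closed form
in the tests. No rate heterogeneity, indels, or richer substitution
models — the summaries of interest (identity, segregating sites,
diversity, haplotype counts) only require the plain clock model. In
the identity summaries, "two random individuals" are read as
same-species pairs, in contrast to the explicitly cross-species
figure; the two references are only mutually consistent under this
reading.

## Problem sizes in the test suite

The suite favours a few deep, parameterised checks over many shallow
ones. Monte-Carlo sizes were chosen once, as a balance between
statistical resolution and a test suite that runs in minutes on a
single core: 10,000 replicates for Yule height and KS calibration
checks, 2,000 scenario replicates per migration-incidence point,
20,000 root heights per oracle-agreement configuration, 100 species
trees × 4 loci for the sequence-identity experiment, and a few hundred
replicates for directional/monotonicity checks. All statistical
assertions are made at 3 Monte-Carlo standard errors or at KS
α = 0.01 under fixed seeds.

## Known limitations

* Population histories and migration fractions must be piecewise
  linear; other families are approximated by refinement.
* The closed-form oracle covers only the constant-rate two-population
  case (by construction); elsewhere validation is purely stochastic.
* The gradual-separation generator decorates sister pairs only;
  arbitrary pairs can be decorated manually via `set_migration()`, but
  no stochastic scenario is provided for them.
* The population-assignment procedure is a reconstruction (above);
  absolute sequence-diversity levels under the Yule-scenario defaults
  inherit its uncertainty.
* No recombination, no serial sampling, one gene tree per call
  (looping is the caller's or the CLI's job).
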
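---
title: "Niche-based breeding-goal optimization: models, estimation and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Niche-based breeding-goal optimization: models, estimation and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichegoal)
```

## The problem

Classical breeding-goal derivation maximizes expected profit: economic
values per trait feed a Smith–Hazel index b = P⁻¹Ga. This fails for breeds
whose owners do not breed for income — companion dogs most prominently, but
also livestock whose owners weight easygoingness or appearance beyond their
economic value. `nichegoal` implements an alternative: model the *niche* of
a breed as a distribution over owner environments, replace the profit
function with an *adaptedness* function (expected satisfaction of owners,
producers and consumers), and maximize it over the set of breeding goals
that are actually reachable within a planning horizon and compatible with
animal welfare. The optimized goal then yields a desired-gain selection
index, and a deterministic breeding simulation checks that the program
reaches the goal and that the niche can sustain a viable population.

## The model

**Environments and niches.** An environment e = (d, v) combines an owner's
desire profile d (nonnegative importance scores in five categories: profit,
performance, emotional, easygoing, altruistic) with influencing variables v
(owner traits, physical environment, market prices, legislative
conditions). A niche is a size-weighted mixture of subniches; each subniche
is either a finite set of environment atoms with probabilities or a
Gaussian over a declared subset of influencing variables (desire scores are
nonnegative, so continuous perturbation is supported only on the
influencing-variable side; questionnaire-style discrete profiles are
expressed as atoms). Subniche sizes grow or decay exponentially at constant
annual rates, giving the projected niche size
m_t = Σ_u m_0,u exp(g_u t); subniches whose projection falls below a
threshold at the horizon are *endangered* and can be dropped.

**Merit of an animal.** The total merit of an animal with phenotype y for
an owner in environment e is

TM_e(y) = φ_v(y) + λ_e (R_e(y) − C_e(y)),

with a linear profit equation φ_v (coefficients may depend on influencing
variables, e.g. the milk price multiplies milk yield), the non-monetary
reward R_e = w_1 R^Perf + w_2 R^Emot + w_3 R^Altr where each reward merit is
τ_max − Σ_k ω_k |y_k − Opt_k| over its own trait subset, and the perceived
easygoingness cost C_e = Σ_k (ω_k − ω_k^mon) y_k over traits whose perceived
cost exceeds the monetary cost (others are excluded from the sum). λ_e
weights the non-monetary side: 0 for a pure producer, near 1 for owners who
keep animals for their own sake. Product quality PQ(y) is a linear consumer
score. φ and PQ are not given a functional form by the theory; the linear
choice matches classical profit-equation practice and keeps the
traditional-approach equivalence exact.

**Adaptedness.** The adaptedness of a breed with mean vector μ to
environment e is

a(μ, e) = α_p E TM_ep(y′) + α_n E TM_e(y) + α_c E PQ(y),

with y ~ N(μ(e), P) for an animal kept in e and y′ ~ N(μ(e_p), P) for one in
the producer's environment; α_p + α_n + α_c = 1. Phenotypes are multivariate
Gaussian with constant phenotypic covariance P — a deliberate restriction
that buys a closed form: every E|y_k − Opt_k| is a folded-normal expectation

E|Y − c| = s√(2/π) e^{−δ²/(2s²)} + δ(2Φ(δ/s) − 1), δ = m − c,

implemented in `expected_abs_dev()`, so `adaptedness_env()` is exact and
cheap, with a Monte-Carlo mode as an independent cross-check (the two agree
within 4 Monte-Carlo standard errors in the test suite). Niche adaptedness
averages a(μ, e) over the niche mixture: exactly over atoms, by seeded
Monte Carlo over Gaussian subniches. Environment dependence of the means is
restricted to a linear reaction norm on declared physical variables
(constant means are the default); how goals should specify trait expression
across environments in general is left open by the theory, and only this
affine special case is implemented.

The special owner roles are weight configurations, not separate code paths:
owner = breeder is α = (0, α_n, α_c); owner = consumer (companion breeds,
no product beyond the animal) puts the owner's own total merit in the
middle slot, e.g. α = (0.1, 0.9, 0) with λ = 1 in the packaged dog
scenario. With α_n = 1 and λ = 0 the adaptedness collapses to expected
profit — the traditional criterion.

## Optimization

The search area is a per-trait box around the current means (half-width two
phenotypic standard deviations by default — wide enough to contain the
reachable set in practice, configurable) minus labelled ethical exclusions
(half-spaces or boxes, e.g. a health-score floor). With constant G and P and
selection intensity i per generation over T generations, the reachable set
is the response ellipsoid

{μ : (μ − μ_c)ᵀ (G P⁻¹ G)⁻¹ (μ − μ_c) ≤ (T i)²},

whose matrix follows from the per-generation index response
Δ = i G b/√(bᵀPb): every such response has quadratic form exactly i²
(asserted to 1e-9 for random indices in the tests). T =
floor(horizon_years / generation_interval); both are scenario inputs, and
the horizon should stay modest (the packaged scenarios use 8–20 years).
The permissible set is box ∩ ellipsoid minus exclusions; membership is
exact, with 1e-12 slack on the ellipsoid quadratic form only (the boundary
belongs to the set).

`optimize_goal()` maximizes an objective over this set by multi-start
compass (pattern) search in coordinates whitened by the ellipsoid, with
candidate projection (box clip, then radial shrink onto the ellipsoid — both
preserve feasibility because the center lies in the box) and rejection of
excluded points. Pattern search is used deliberately: the closed-form
adaptedness has kinks wherever a trait mean crosses a merit optimum, so
gradient ascent is unreliable there, while the objective is concave in μ
(linear terms plus negated convex folded-normal terms), so local ascent has
no spurious strict optima; multi-start and single-start agree in the tests.
The step size halves from 0.5 to 1e-6 (whitened scale); ties are broken by
the first start reaching the optimum, and the current means are always
included as a start, so the result never falls below the status quo. On
linear objectives the search recovers the analytic ellipsoid argmax
μ_c + r M⁻¹a/√(aᵀM⁻¹a) to the requested tolerance, and on 2-trait problems
it attains the 201×201 grid optimum within one grid-cell Lipschitz bound.

The desired gains Δμ = μ̇ − μ_c then give index weights
b = P⁻¹G(GP⁻¹G)⁻¹Δμ (normalized to bᵀPb = 1, so the index has unit
phenotypic variance; any positive rescaling is equivalent for ranking). The
expected response is collinear with Δμ by construction, and when producers
solely maximize income the chain Δμ* ∝ GP⁻¹Ga ⇒ b ∝ P⁻¹Ga reproduces the
Smith–Hazel index — the package's central consistency property, checked
over 25 random configurations with |cosine| ≥ 0.999.

## Estimating merit parameters from stated preferences

Merit parameters are identified from binary forced-choice data: two trait
profiles drawn uniformly in a design box, P(choose A) =
logistic((U(A) − U(B))/scale). This is the simplest identifiable
stated-preference model matching the merit structure; multinomial designs,
D-optimal designs and random coefficients are out of scope. Three numerical
points matter:

* **One experiment per merit function.** Choice experiments handle few
  attributes at a time, so each merit function is estimated in its own
  experiment: the `vary` argument keeps all other attributes identical
  between the two options of a task, so they cancel from the utility
  difference. Without this, omitted components act as extra logit noise and
  attenuate every coefficient. A trait that carries both a reward term
  |y − Opt| and a linear term (perceived cost, profit) gets an explicit
  linear feature in the fit.
* **Profile likelihood over the optima.** For fixed Opt the weights ω enter
  the utility linearly through |y − Opt| features, so the inner problem is a
  plain logistic regression (`glm.fit`); the outer search over Opt is
  derivative-free (Brent in one dimension, Nelder–Mead with a 5-points-per-
  dimension grid initialization otherwise) because the likelihood has kinks
  in Opt at every observed profile value. Standard errors come from the
  observed information at the joint MLE; when that matrix is singular —
  which happens exactly when some ω̂ ≈ 0 leaves its optimum unidentified —
  the fit falls back to conditional (fixed-Opt) standard errors for the
  linear coefficients and reports NA for the unidentified optima.
* **What is not identifiable.** Additive constants cancel from choice
  differences, so τ_max is never estimated (two scenarios differing only in
  τ_max generate byte-identical data under the same seed — asserted in the
  tests); only ω/scale is identified, so recovered ω are rescaled by the
  known scale and the λ·w weight of the component in the generating
  utility. Separation (perfect prediction) is flagged, with standard errors
  reported as unavailable rather than fabricated.

The producer/owner/consumer weights α are estimated in a final experiment
whose utility features are the three component merits of each profile;
coefficients are clamped to be nonnegative and normalized to the simplex,
and collinear features are flagged as "weights not identifiable". Parameter
recovery is verified by simulation: over 20 replicates of 5000 choices the
true (ω, Opt) fall within 3 reported standard errors in ≥ 90% of cells, and
α = (0, 1, 0) is recovered with α̂_n ≥ 0.9.

## Breeding simulation and validity

`simulate_breeding_program()` iterates the expectation-level recursion
μ_{t+1} = μ_t + i G b/√(bᵀPb) with constant G and P — the simplest-case
treatment; changing covariances (Bulmer effect), discounting, inbreeding
management and stochastic gene flow are out of scope. When Δμ sits exactly
at ellipsoid radius T·i, generation T lands on the goal to 1e-6
(telescoping of the linear recursion; √(bᵀPb) = T·i for the unnormalized
desired-gain solution, so each step is Δμ/T). The theory ties adaptedness
to the population growth rate but fixes no functional link; the package
uses the declared modelling choice n_{t+1} = n_t exp(κ(a_t − a_ref)), capped
by the breed's share of the projected niche c_b·m_t, isolated in one
operation so it can be replaced. The per-generation validity flag is
c_b·m_t ≥ N_min and n_t ≥ N_min; N_min is a census-size input informed by
the requirement to sustain an effective population size of about 100. The
genetic variance of the index bᵀGb is reported each generation and flagged
near zero (a goal that exhausts index variance before it is reached is
inadmissible).

## Packaged scenarios: what they emulate, and what they do not

`make_companion_dog_scenario()` — six traits, two atom subniches (apartment
owners with noise-sensitive neighbours: low barking optimum and a strong
perceived barking cost; garden owners: tolerant), zero profit, λ = 1,
α = (0.1, 0.9, 0), a health-score floor exclusion, generation interval 4
years over a 20-year horizon. `make_dairy_scenario()` — five traits, one
Gaussian subniche over milk price and feed quality, profit-dominated
(λ = 0.05), milk-price-dependent profit coefficient, reaction norm of milk
yield on feed quality, α = (0, 0.9, 0.1). `make_two_env_bodyweight_scenario()`
— one trait, two environments preferring opposite body weights (24 vs 36 kg)
with a reaction norm of 2 kg per feed-quality unit; the current mean (27 kg)
is deliberately off the niche-averaged optimum (30 kg) so the pipeline has
actual selection to do, and single-environment variants show the goal
clipping at the response-ellipsoid boundary. All parameter magnitudes are
fixture choices on plausible scales, not estimates for any real breed.

What passing tests on these scenarios show is internal consistency of the
machinery — closed forms against simulation oracles, recovery of known
parameters, determinism — under Gaussian phenotypes, linear profit, fixed
preferences and exponential niche dynamics. They do not show that real
owner preferences follow a conditional logit on these merit forms, that
real niches decompose into the assumed subniche structure, or that G and P
stay constant over a 20-year program.

## Numerical conventions

All randomness derives from one user seed through labelled substreams
(`derive_seed`), so environment draws, phenotype draws, choice simulation
and optimizer starts are independently reproducible; repeated CLI runs are
byte-identical. Scenario configs serialize doubles with 17 significant
digits so save/load round-trips are exact. Reward-merit defaults set
τ_max = Σ_k ω_k · 2 SD_k, keeping merits positive across the default search
box. Ellipsoid membership uses a closed boundary with 1e-12 slack;
optimizer step tolerance is 1e-6; Monte-Carlo standard errors are plug-in
estimates of the mean's SE. Degenerate inputs fail loudly: empty niches,
all-endangered niches, singular G (with advice to reduce the trait set),
non-positive-definite P, zero desired gains, null indices, empty
permissible sets (with advice to extend the planning horizon).

Default problem sizes (full test suite ≈ 2 minutes, acceptance script ≈ 1
minute on one CPU): Monte-Carlo cross-checks at n = 1e5 phenotypes,
Gaussian-subniche averages over a few thousand environments against 1-D
quadrature, 20 × 5000-choice recovery replicates, 201×201 grid oracles on
2-trait problems.
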
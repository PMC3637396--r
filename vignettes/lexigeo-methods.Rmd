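---
title: "Spatiotemporal inference for lexical cognate data: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal inference for lexical cognate data: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

lexigeo jointly infers *when* and *where* a family of closely related
language varieties diversified, from two kinds of data: a binary matrix of
cognate-set presence/absence across a basic-vocabulary meaning list, and the
geographic coordinates of the sampled varieties. This vignette is the
package's own account of the models it implements, the free choices made
where the underlying methods leave room, and what the bundled synthetic data
do and do not establish.

## The probabilistic model

The posterior is over a rooted, time-calibrated binary tree (node heights in
years BP), the cognate death rate, clock-rate multipliers, coalescent
population sizes, a 2x2 diffusion covariance, per-branch diffusion scalars,
and the latent geographic locations of ancestral nodes:

\[
p(\tau, \theta \mid X, Y) \;\propto\;
P_\mathrm{Dollo}(X \mid \tau, \mu)\;
P_\mathrm{RRW}(Y \mid \tau, \Sigma, \phi)\;
P_\mathrm{skyline}(\tau \mid N)\;
P_\mathrm{cal}(\tau)\;\pi(\theta).
\]

### Stochastic Dollo cognate evolution

Each cognate set arises exactly once (a single *birth*, uniformly
distributed over the tree plus a stem window above the root, with intensity
$\lambda$ per lineage-year), is inherited by both daughters at every split,
and is irreversibly lost at rate $\mu$ per lineage-year. A column's
probability integrates the birth placement analytically: for a birth on the
branch above node $c$ with duration $T$ and clock multiplier $c_b$,

\[
I_b \;=\; \mathbb{1}[\text{tips outside } c \text{ absent}]\;
\Bigl( D_c\,T + (A_c - D_c)\,\tfrac{1 - e^{-\mu c_b T}}{\mu c_b} \Bigr),
\]

where $A_c$ and $D_c$ are the alive/dead partial likelihoods at $c$ from the
two-state pruning recursion. Because data collection can only ever reveal
cognate sets present in at least one sampled variety, the likelihood
conditions on observability (ascertainment-bias correction): each column's
integrated weight is normalized by the total birth weight of observable
patterns. Under this conditioning the birth intensity contributes only a
constant given the observed number of columns, so it is profiled out and
$\mu$ is the only free Dollo parameter — the standard parameterization for
stochastic-Dollo inference, and the reason the sampler has no $\lambda$
move.

Free choices made here:

* **Stem window.** A single-origin process needs an origin window older
  than the root; its length is `stem_factor * root height` with default
  `stem_factor = 1`. The likelihood is insensitive to this choice in the
  regimes we simulate (the stem term only reweights patterns shared by both
  root children), but it is exposed as a parameter.
* **Missing data.** `?` entries are marginalized over both tip states, so
  column observability stays well defined; they are never dropped.
* **Clock coupling.** The relaxed clock's branch multipliers scale the
  death process (effective duration $c_b T_b$). Whether loss rates should
  be linked to the clock at all is genuinely open; the strict clock
  (`clock = "strict"`) sidesteps the question and is the default.

### Relaxed random walk geography

Branch displacements in (lat, lon) degrees are bivariate normal with
covariance $\Sigma\, t_b\, \phi_b$: a base covariance (degrees$^2$/year), the
branch duration, and an i.i.d. branch scalar. Three scalar laws are
implemented, plus the homogeneous (strict Brownian) special case:

| law | construction | character |
|---|---|---|
| gamma | $\phi \sim \Gamma(k, k)$, mean 1 | overdispersed, much mass near 0 for $k < 1$ |
| lognormal | mean-1 lognormal, log-sd free | overdispersed, no mass at 0 |
| cauchy | $\phi = 1/\gamma$, $\gamma \sim \Gamma(\tfrac12, \tfrac12)$ | marginally bivariate-Cauchy displacements, extreme tails |
| homogeneous | $\phi \equiv 1$ | plain Brownian diffusion |

The Cauchy case is realized as an inverse-gamma scale mixture so that all
laws share one Gibbs structure; its scalars then admit an exact conditional
draw, $\gamma_b \mid d_b \sim \Gamma(w + \tfrac12, \tfrac{1 + w\,q_b}{2})$
with $q_b$ the Mahalanobis norm of the displacement and $w$ the likelihood
power (see *Power posteriors* below).

Coordinates are treated as planar degrees. At the sub-10-degree spatial
scale of an island chain the great-circle correction is far below the
posterior uncertainty; this matches the usual continuous-phylogeography
practice.

**Land-only prior.** Ancestral locations (root and all internal nodes)
carry a flat prior on land and zero prior on water. In the sampler this is
simply auto-rejection of any location proposal into water; the
synthetic-data generator uses the matching construction, resampling each
simulated displacement until the child lands on land (truncated diffusion).
The two are an approximation pair, not exact duals: truncation renormalizes
per branch while the prior renormalizes globally. The difference is
invisible at our simulation settings but is the first suspect if coastline
effects ever look odd.

### Tree priors and calibration

The coalescent skyline prior uses piecewise-constant effective sizes over
groups of consecutive coalescent intervals (default 5 groups, scale-
invariant $1/N$ size priors bounded to $[10, 10^6]$ years). Absolute time
enters through a normal calibration on the age of a named clade: by default
`sd = 102.04` years, the unique spread that puts 95% of the mass within
±200 years of the mean — the reading of "95% of the distribution
incorporating 200 years of uncertainty" that yields a proper normal. The
calibration evaluates the MRCA of the named taxa on the current topology;
monophyly is not enforced. Calibrating a subclade (the northern-island
varieties in the bundled design) rather than the root is deliberate: a root
calibration at 500 BP would contradict root estimates older than that.

### Remaining parameter priors

The underlying methods papers leave most scalar priors unstated; the
package's defaults are diffuse and overridable, and are artifact choices,
not reconstructions: $\mu \sim$ lognormal(log 2e-4, sd 2);
relaxed-clock log-sd $\sim$ Exp(1); diffusion log-variances $\sim$
N(0, 5$^2$) with atanh-correlation $\sim$ N(0, 1.5$^2$) (chosen over a
Wishart on the precision because it shares one code path with the other
scale moves and is friendlier to the strongly non-spherical degree scale);
scalar-law shape $\sim$ lognormal(0, 1).

## Sampling machinery

`mcmc_run()` is a random-scan Metropolis-within-Gibbs sampler. Topology
moves are the classic narrow exchange (nephew-uncle swap) and a wide
subtree exchange, both symmetric by uniform selection with auto-rejection
of height-incompatible picks; heights move by uniform slides within their
bracket, a root scale, and a whole-tree scale; scalar parameters use
multiplicative proposals; locations use a bivariate random walk plus an
independence proposal uniform over the mask's bounding box (the latter is
what keeps latent locations mobile when the likelihood is powered down).
Proposal scales adapt toward ~30% acceptance only during a warm-up window
(default the first 10% of the chain, inside the discarded burn-in), so the
retained chain is Markovian.

**Power posteriors.** For stepping-stone estimation and prior-only runs the
*data* terms — the Dollo likelihood and the *tip-branch* displacement
densities — are raised to $\beta$. Internal-branch displacement densities
are the latent-variable structure of the model and stay at full weight,
exactly like any other prior term. This decomposition matters: treating the
internal-node density as "likelihood" makes the $\beta \to 0$ reference
distribution a flat cloud over the whole map and the stepping-stone
estimator essentially unusable (enormous variance, differential bias across
scalar laws — we measured double-digit log-unit distortions before adopting
the split). All per-branch conditional kernels (the scalar sweeps) use the
same per-branch power $w_b$ ($\beta$ on tip branches, 1 on internal ones).

**Stepping stone.** $\beta_k = (k/K)^{1/0.3}$, importance ratios estimated
per stone from the retained samples, Monte-Carlo standard errors by the
delta method treating retained draws as independent (an underestimate when
chains are short; the toy-model tests calibrate against closed forms at 3
s.e.). Chains are warm-started from the neighboring stone, posterior to
prior.

## Synthetic data: what it emulates, what it does not

`make_fixture()` freezes three designs:

* **tiny4** — 4 varieties, ≤15 columns, for brute-force oracle comparison.
* **island19** — the study scale: 19 varieties in two geographic subclades
  (14 on a schematic southern island, 5 on an elongated northern island,
  joined at a 1300 BP root), 200 meanings, birth rate calibrated once by
  pilot simulation to yield roughly 350 observable columns, death rate
  2e-4/yr (about 82% basic-vocabulary retention per millennium), gamma
  scalar diffusion with base covariance diag(2.5e-3) deg$^2$/yr from a
  homeland on the northern part of the southern island.
* **borrowed19** — island19 plus horizontal transfer at 20% of the
  vocabulary per lineage per 1000 years, the noise ceiling the method is
  expected to tolerate; borrowing copies a donor's cognates for a meaning
  over the recipient's (lexical replacement), donor uniform among
  contemporaneous lineages, event times exact (Gillespie).

The generator reproduces the statistical *structure* the analysis assumes —
single-origin cognates, land-truncated diffusion, two-island geography. It
does **not** emulate real coastline geometry, meaning-specific loss rates,
dialect-chain spatial autocorrelation, or judgment error in cognate coding.
Passing recovery tests therefore demonstrates internal consistency of
model and inference at realistic size and signal, not robustness to those
real-data complications.

## Test and verification design

Every likelihood has an independent oracle: the Dollo pruning integral is
checked against Simpson quadrature over birth placements with an
enumeration recursion, plus an exact normalization identity over all
observable patterns; the RRW density against a dense multivariate normal
assembled from shared root-path variances; the skyline against the Kingman
closed form; stepping stone against conjugate normal-normal and
beta-binomial marginals; the prior-only sampler against the calibration
normal (2 tips, where the root height is the only height) and against
direct coalescent simulation (4 tips), both by Kolmogorov-Smirnov after
thinning.

Problem sizes in the routine test suite are set for a laptop-scale run:
recovery uses 10 seeds of 15,000-state chains on island19 (posterior median
root age within 20% of truth and the true homeland inside the 80% HPD
polygon in at least 8 of 10).

Scalar-law model selection deserves its own note. The honest effect size is
small: on data simulated under the gamma law at the island19 settings, the
*exact* log-Bayes-factor against the best-fitting mean-1 lognormal is
typically only 1–4 nats even when every node location is observed, because
the two laws are genuinely close. A sampling-based marginal-likelihood
estimate over dozens of latent branch scalars carries Monte-Carlo error far
exceeding that separation at any feasible chain length (we measured
double-digit nat distortions in both directions while developing the
sampler), so ranking the laws that way is reading noise.
`scalar_law_evidence()` therefore integrates the scalars out *exactly*: they
are i.i.d. across branches, so the evidence factorizes into per-branch
one-dimensional integrals (quadrature), with an outer quadrature over the
shape hyperparameter. The model-selection check runs this on 40-tip
gamma-generated diffusion histories (40 rather than 19 tips for power) and
is cross-validated in the unit tests against brute-force Monte-Carlo
integration. `stepping_stone_marginal_lik()` remains the general tool for
the full joint model — where no factorization exists — and is validated
against conjugate closed forms; its per-comparison error there should be
respected when interpreting small differences.

## Known limitations

* Stepping-stone marginal likelihoods over models with many latent
  locations carry Monte-Carlo bias that shrinks only with more stones and
  longer chains; comparisons separated by less than a few log units should
  not be over-read at test-scale settings.
* The MCC tree clamps per-clade median heights to keep parents older than
  children; clades with support near 0.5 can have visibly clamped heights.
* The quartet statistics subsample beyond 25 taxa (seeded); exact up to 25.
* Mutual-intelligibility percentages depend on the per-meaning sharing
  convention; a per-column variant is available via `per = "column"` in
  `cognate_similarity()` for cross-checking against sources that count raw
  characters.
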
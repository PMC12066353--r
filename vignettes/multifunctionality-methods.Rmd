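---
title: "Models and methods behind mufunlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mufunlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mufunlab analyses split-plot suppression experiments on ground-foraging ant
communities: dominant species are removed from suppression zones, paired
with control zones inside spatial blocks, and the response of the remaining
community and of four ecosystem functions — scavenging, myrmecochory
(elaiosome-bearing seed dispersal), granivory and plant protection — is
followed over repeated sampling events. This vignette records the models the
package fits, the conventions it adopts where a published description leaves
the choice open, what the synthetic-data generator does and does not
emulate, and the numerical decisions a user may want to revisit.

## Trait space

`gower_matrix()` averages per-trait dissimilarities: `|x_i − x_j| / range`
for continuous and ordinal traits, 0/1 mismatch for binary and categorical
ones, over all traits observed in both species. A continuous trait with zero
range has no defined contribution and is dropped with a warning; a constant
binary or categorical trait has a perfectly well-defined contribution of
zero and is kept (this distinction matters: two species differing in one of
ten binary traits must be at distance 0.1, not 1).

`trait_pcoa()` performs classical scaling with species weighted by
site-wide incidence (the fraction of traps a species occupied), so the trait
space reflects how commonly trait combinations actually occur, via
`vegan::wcmdscale`. Gower matrices are generally non-Euclidean; when any
eigenvalue drops below −1e−8 a Cailliez correction is applied and variance
explained is reported over the corrected positive spectrum. An unweighted
analysis is available (`weights = NULL`) for cross-checks.

Trait groups come from partitioning-around-medoids on the Gower matrix
(`cluster_trait_groups()`): deterministic for a given matrix, robust to the
non-Euclidean geometry, with the number of groups `k` an explicit argument
(default 5) because no selection criterion for `k` is assumed. Each group's
dominant is the member with the highest incidence, ties broken by
lexicographically smallest species id and flagged.

`fric()` is the convex-hull area of the community's species in the first
two ordination axes — two because the ordination retains two interpretable
axes and because higher-dimensional hull volumes would add a heavy
computational dependency for little inferential gain; samples with fewer
than three distinct points (or collinear ones) have FRic 0. `fdis()` is the
abundance-weighted mean distance to the abundance-weighted centroid and uses
all supplied axes.

## Diversity and community tests

`hill_ens()` uses the Hill family, `exp(−Σ p ln p)` at `q = 1` and
`(Σ p^q)^{1/(1−q)}` elsewhere; richness is computed after removing the
suppressed targets, since their near-absence is imposed by the treatment,
not a community response.

The Raup–Crick uniqueness score draws, for every pair of samples, null
communities that preserve each sample's richness with species sampled
without replacement proportionally to their occurrence frequency, and scores
`RC = 2·(P(null shared ≥ observed shared), ties counted half) − 1`; a
sample's uniqueness is its mean RC over partners. The sign convention puts
+1 at "shares fewer species than chance" (compositionally unusual). Ties
counted half and 999 null draws are the package defaults; both the tail
convention and the null pool (`freq`) are arguments, because published
variants differ and the convention is documented rather than asserted to be
any particular study's. For enumerable micro-instances `method = "exact"`
computes the full null distribution, which the test suite checks against an
independent recursive enumeration.

`treatment_effect()` fits `response ~ zone + (1 | block) + (1 | block:plot)`
— the split-plot structure — with Poisson errors for counts and Gaussian
otherwise, reporting Wald *Z*. When the Pearson χ²/df ratio of a Poisson fit
exceeds 1.5 an observation-level random intercept is added (the standard
GLMM overdispersion device); if the mixed fit fails entirely the fallback is
a fixed-block GLM, always flagged in the result.

## SR–FR shape

`fit_srfr()` smooths FRic on S with a penalized cubic regression spline
(basis dimension k′ = 9), block and plot random-intercept smooths, and REML
smoothness selection. The effective degrees of freedom of the smooth is the
shape statistic: ≈1 linear, >2 clearly saturating. Smoothness selection uses
a penalty inflation of `gamma = 1.4`: plain REML occasionally undersmooths
truly linear data into spurious wiggles, and the inflation restores edf ≈ 1
under linear truth without affecting detection of real curvature (both
behaviours are exercised in the test suite). `compare_srfr_candidates()`
fits the five-candidate ladder (null; treatment; richness smooth; additive;
treatment-specific smooths) by ML so AICs are comparable; exact AIC ties go
to the simpler candidate and are flagged. The response is modelled as
Gaussian; FRic areas are bounded below by zero but far from the boundary at
the observed richness levels.

## Multifunctionality

`standardize_functions()` divides each observed rate by `F_max`, the mean of
the top 5% (`ceiling(0.05 n)` values) of that function's rates across all
observations, clipping at 1. With fewer than 20 observations the top-5% set
degenerates to the single maximum and is flagged. Rates travel through the
pipeline as `(n_success, n_offered)` pairs until this point, preserving the
binomial information.

Effective multifunctionality is `M_q = A · qN / N_f`, with `A` the
arithmetic mean of standardized values and `qN` the Hill number (order
`q = 1`) of the performance proportions: the mean discounted by how unevenly
performance is spread. The formula is isolated in `effective_mf()`, so an
alternative convention (plain `A`, or `qN` alone) is a one-line change;
identities (`M_q = A` for even performance, `M_q ≤ A` always) are tested.

`threshold_sweep()` counts, per sample, functions with standardized
performance at or above every threshold from 5–95% and fits Poisson mixed
models of that count on diversity per treatment arm. Slopes are reported on
the response scale as average marginal effects (`β · mean(μ̂)`), because the
quantity of interest — species needed per additional function — is the
reciprocal of a *functions per species* slope, which lives on the response
scale, not the log-link scale; the link-scale `β` and its CI are retained in
the curve table. Significance is a 95% Wald CI excluding zero. `R_mde` is
the largest significant slope, `T_mde` its threshold, and `mde_test()` runs
the single treatment test at the mean of the two arms' `T_mde`. Degenerate
thresholds (constant count) report slope 0 with a flag.

`function_covariance()` correlates plot-level mean standardized performance
between function pairs with permutation p-values; a `plot_event` unit is
available because six plots per arm estimate a correlation with a standard
error near 0.4, far too coarse for sign-recovery checks.

## Path analysis

`fit_paths()` follows the piecewise approach: one mixed model for
`mediator ~ treatment`, one for `response ~ treatment + mediator` (the
mediator centred, so the treatment coefficient is the direct effect at the
mean mediator level), both with the block/plot-in-block intercepts. Binomial
responses use the success/failure count pair; when overdispersed (χ²/df >
1.5) a sampling-round (plot-by-event) random intercept is added, since
repeated bait transects within one plot and round share conditions.
Standardized coefficients are `b · sd(x)/sd(y)` with `sd(y)` taken on the
latent scale for non-Gaussian links (linear-predictor variance plus π²/3 for
logit, `log(1 + 1/λ̄)` for log) — a documented convention, not asserted to
match any particular implementation. The indirect effect is the product of
the standardized treatment→mediator and mediator→response coefficients; the
treatment×mediator interaction is available by flag and off by default.

## Species–function association

`ses_null()` aggregates abundances and standardized rates to plot-by-event
units (plot totals per sampling round; a plot-level option exists), fits the
least-squares slope of rate on abundance per species×function, and compares
it with 999 permutations of the rate vector across units — rates are
permuted, not abundances, on the assumption that abundance drives function.
`SES = (observed − null mean)/null sd`, significant beyond |1.96|. The
plot-by-event default exists because with only six plot-level units the
permutation distribution cannot produce |SES| values much beyond 2, leaving
the test nearly powerless. Permutations are shared across species within a
function and replication seed, making tables seed-reproducible.
`delta_and_rank()` and `importance_response_correlation()` then quantify
compensation: negative Spearman rho means the species most associated with
function under dominants gain least from their removal.

## The synthetic generator

`scenario_config()` fixes the study conditions: 3 blocks × 2 zones × 2
plots × 4 quarters × 4 events (192 community samples); 34 species in 5
trait groups; 3 targets suppressed to 6%, 4% and 1% of their abundance
(94/96/99% reductions); ground functions assayed with 40 baits per sampled
quarter in 2 quarters per plot (80 per plot), plant protection with 16 (32
per plot). Abundances are negative-binomial (size 1.2; `Inf` recovers
Poisson) around log-normal species means with log-scale block, plot and
event effects; non-targets increase 1.4-fold under suppression and the five
rarest species act as colonists with a further 6-fold boost, emulating
immigration from the surrounding matrix. Function success is binomial with a
logit-linear model in non-target richness, treatment, the planted performer
species' plot-round abundance, and plot-by-event noise correlated across
functions (positive among scavenging/myrmecochory/protection, negative for
granivory–protection and granivory–myrmecochory).

Effect sizes on the probability scale are not published anywhere, so the
planted slopes (richness effects 0.15–0.22 in magnitude on the logit scale,
granivory negative; direct effects +0.5 granivory, −0.9 protection;
performer coefficient 1.0) were chosen once so that each recovery test is
well powered at the study's own design size, and are not tuned further. The
generator does **not** emulate: spatial foraging structure or colony
dynamics, temporal autocorrelation across events, trait–function mechanistic
links (function–trait group coupling is through the planted performers
only), detection error in pitfall trapping, or rate covariance induced by
shared resource depletion. Passing recovery tests therefore demonstrate that
the estimators recover the statistical structure they target at this design
size — not that field data satisfy that structure.

## Numerical choices and problem sizes

Sub-seeds per table are derived arithmetically from the scenario seed (kept
below 2³¹), so regenerating one table never perturbs another. Mixed models
are fitted with lme4; singular-fit messages on variance components estimated
at zero are expected with 3 blocks and are harmless for the Wald tests used.
The threshold sweep accepts `nAGQ = 0` for the cheaper Laplace-free
approximation, used in the simulation studies. The test suite sizes its
simulation studies at 100 replicates for path-coverage, 40 for the
threshold-band and SR–FR shape checks, 25 scenarios (100 performer cells)
for SES power and 12 null scenarios (~1,500 cells) for the SES
false-positive rate — sizes at which the binomial Monte-Carlo error is well
inside the asserted bounds.

## Limitations

Convex-hull FRic is restricted to two axes. The Raup–Crick variant and the
effective-multifunctionality formula follow documented conventions that may
differ from other implementations in tail handling or evenness discounting.
Standardized coefficients for non-Gaussian path components have no unique
definition; comparisons across link functions should use the unstandardized
coefficients. The mixed models assume independence across sampling events
within a plot beyond the shared random intercepts.
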
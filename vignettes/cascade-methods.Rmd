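---
title: "Models and methods behind molarcascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind molarcascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The inhibitory cascade and its testable geometry

The dental inhibitory cascade (DIC) model holds that the sizes of the three
lower molars are set by a balance between activators and inhibitors carried
along the developing tooth row: relative to the first molar, areas follow
$M_1 = 1$, $M_2 = a/i$, $M_3 = 2(a/i) - 1$, where $a/i$ is the
activator/inhibitor ratio. Everything this package tests follows from that
one-parameter family:

* Species proportions $(M_2/M_1,\,M_3/M_1)$ fall on the line
  $M_3/M_1 = 2(M_2/M_1) - 1$, with slope 2 and intercept $-1$.
* Besides the line itself, only the two orderings $M_1<M_2<M_3$ and
  $M_1>M_2>M_3$ are reachable by varying $a/i$; a dominant second molar
  ($M_1<M_2>M_3$) or a trough ($M_1>M_2<M_3$) cannot be produced.
* $M_2$ is exactly one third of total molar area for every $a/i$ above the
  agenesis boundary (total area is $3(a/i) M_1$).
* The third molar vanishes when $M_2$ falls below half of $M_1$
  ($a/i = 0.5$), predicting when agenesis should occur.
* Under a strict reading, $M_1$ influences $M_3$ only through $M_2$, so in
  a mediation decomposition the proportion mediated should be 1.

`dic_core` implements this geometry as pure functions. Numerical choices:
ties in the orderings are resolved with a tolerance of $10^{-9}$ on the
ratio comparisons and labelled `EQUAL` (equal molars satisfy the line, so
they count as consistent); membership of the line itself uses a
perpendicular-distance tolerance `line_tol` that defaults to 0, i.e. only
exact line membership counts, with the two open regions carrying the
consistency verdict. Predicted $M_3$ areas are clamped to zero only at the
exact boundary $a/i = 0.5$; below it the functions refuse rather than
silently clamp, so agenesis regimes surface explicitly.

# Morphometric preparation

Crown areas are rectangular products of mesio-distal length and the mean of
trigonid and talonid bucco-lingual breadths. Because rectangles
overestimate occlusal outlines, a calibration subset with traced outline
areas is used to solve, per tooth, a shape coefficient
$x = (oa - ea)/(ra - ea)$ placing the outline between the inscribed
ellipse ($ea = \pi\,ra/4$) and the rectangle; corrected areas are
$ca = ra\,x + ea\,(1-x)$. Coefficients are averaged within species and
then per molar position, and applied dataset-wide (per-species application
is available). The reconstruction identity
$ca(ra, ea, x(oa)) \equiv oa$ is exact and is enforced by tests.

Specimen filters mirror standard museum-sample hygiene and are applied in
a fixed order — worn or wear-unreported, indeterminate sex, zoo
provenance, incomplete lower dentition (a missing third molar is not
"incomplete" when agenesis is recorded) — followed by dropping species
with fewer than four specimens or a single sex. The order only affects the
per-rule exclusion counts, not the retained set. Species means use
two-stage sex pooling (mean within each sex, then the unweighted mean of
the two sex means), so unbalanced sex sampling does not tilt the species
value. Variability uses the small-sample coefficient of variation
$(1 + 1/(4n))\,s/\bar x$ with the $n-1$ standard deviation.

Whether species morphospace centroids should be ratios of mean areas or
means of specimen ratios is genuinely open; the package uses ratio of
means (consistent with the weighted-mean aggregation) and computes
specimen-level ratios only where the regressions require them.

# The Bayesian phylogenetic mixed model

All analyses run through one engine: a generalized linear mixed model
$\mathbf{y} \sim \mathcal{D}(g^{-1}(\boldsymbol\eta + \mathbf{e}), \phi)$,
with identity link for Gaussian responses and logit link for Bernoulli
ones, and location effects
$\boldsymbol\eta = X\boldsymbol\beta + Z\mathbf{p} + Z\mathbf{s}$.
The two random intercepts distinguish *why* species differ:
$\mathbf{p} \sim \mathcal{N}(0, \sigma_p^2 \Sigma)$ is structured by the
phylogeny, while $\mathbf{s} \sim \mathcal{N}(0, \sigma_s^2 I)$ is
species-specific noise. $\Sigma$ is the Brownian-motion covariance of an
ultrametric tree — entry $(i,j)$ the shared root-to-ancestor path length —
scaled by tree height to a unit diagonal. Scaling to unit height (rather
than, say, unit mean diagonal) is our choice: it puts $\sigma_p^2$ on the
same scale as $\sigma_s^2$ and $\sigma_e^2$, so phylogenetic signal

$$\lambda = \frac{\sigma_p^2}{\sigma_p^2 + \sigma_s^2 + \sigma_e^2}$$

is a clean variance share in $[0,1]$. $\lambda$ is computed per posterior
draw and summarized by its posterior mean and HDI (not as a ratio of
posterior means). For Bernoulli models the residual variance is the fixed
logistic variance $\pi^2/3$.

Because specimens are nested in species, every specimen-level predictor is
split by within-group centering into a between-species component (the
species mean, broadcast to its specimens) and a within-species component
(the specimen deviation). The between slope is the macroevolutionary
quantity the cascade constrains; the within slope absorbs intraspecific
variation and measurement error that would otherwise bias it. For the
proportion regression the within term is the deviation of the specimen's
ratio from its species mean ratio — a ratio of deviations would be
undefined whenever a specimen sits at its species mean.

## Priors and sampling

Fixed effects get diffuse priors: normal with variance $10^8$ for Gaussian
responses; for Bernoulli responses a Cauchy prior whose scale is
$\pi^2/3$ plus the current draw's random-effect variance, re-evaluated
each iteration (a pilot-fixed variant would also be defensible; the
re-evaluated form keeps the prior approximately flat on the probability
scale as the latent scale moves). Random-effect variances use
parameter-expanded priors — base variance inverse-gamma with scale 1 and
one degree of belief, times the square of a working parameter with mean 0
and variance $10^3$ — which behave like a heavy-tailed half-Cauchy on the
standard deviation and mix well near zero. The Gaussian residual variance,
nowhere pinned down by the model statement, gets the conventional weakly
informative inverse-gamma (V = 1, nu = 0.002).

Sampling is blocked Gibbs in compiled code: all location effects are drawn
jointly from their multivariate-normal full conditional (a
$\sim\!200$-dimensional Cholesky per iteration at study scale), variances
from inverse-gamma full conditionals, the working parameters from scalar
normal conditionals. Bernoulli responses add a latent logistic variable
per observation, updated by slice sampling, after which the Gaussian
machinery applies with $\sigma_e^2 = \pi^2/3$; the Cauchy prior enters as
a normal-inverse-gamma scale mixture, so it too is conjugate. The sampler
was validated against conjugate closed forms (known-variance mean;
one-way random effects with known variances) and by parameter recovery on
simulated data; it targets the same posterior as the reference MCMC
implementations of this model class but is not a line-for-line port, so
agreement is within Monte Carlo error, not bit-for-bit.

Two schedules are built in: `"paper"` (1.1e7 iterations, 1e6 burn-in,
thinning 1000 for Gaussian; 1.5e7/3e6/1200 for Bernoulli) and `"fast"`
(1.1e5/1e4/10 and 1.5e5/3e4/12), both retaining exactly 10,000 draws. The
fast schedule is the package default for desk-scale work; the analysis
scripts use 1,000-draw variants of the same shape for quick narrative
runs. Seeds are mandatory arguments everywhere, and identical seeds give
identical chains.

## Decision summaries and diagnostics

The cascade makes point predictions, so point nulls are replaced by
regions of practical equivalence: slope $[1.90, 2.10]$, intercept
$[-1.10, -0.90]$, $M_2$ share $[0.323, 0.343]$, proportion mediated
$[0.9, 1]$ (all overridable; lists of ROPEs are supported). Reported per
parameter: posterior mean, 95% highest-density interval (shortest
interval over the sorted draws; exact for unimodal posteriors), and the
posterior mass inside the ROPE.

Convergence is declared when Heidelberger and Welch's stationarity test
passes and lag-1 autocorrelation of the thinned chain is below 0.1. The
stationarity test is the Cramér–von Mises functional of the standardized
cumulative sums, with the spectral density at zero estimated by an
AIC-selected AR fit to the chain's second half, iteratively discarding
initial 10% segments; it reproduces the reference implementation's
p-values. A caveat worth knowing: when a deterministic trend dominates the
noise, the AR estimate absorbs the trend and the test loses power — a
property of the published diagnostic, not of this implementation; the test
is sharpest against drifts of a few noise standard deviations across the
chain.

## Mediation

The mediation analysis fits two models — $M_3$ on both $M_1$ and $M_2$
(between/within split), and $M_2$ on $M_1$ — and combines them per
retained draw $t$: indirect effect
$ab^{(t)} = \beta_{2B}^{(t)} \beta_{1B}'^{(t)}$, direct magnitude
$|c'|^{(t)} = |\beta_{1B}^{(t)}|$, proportion mediated
$pr_m^{(t)} = ab^{(t)} / (ab^{(t)} + |c'|^{(t)})$. Point estimates are
means over draws; because the slopes are areas-on-areas, $pr_m$ is
invariant to rescaling every molar area. The two component fits must
retain the same number of draws; they use consecutive seeds from one base
seed.

# What the synthetic generator does and does not emulate

The generator is the package's ground-truth instrument, not a fixture: a
pure-birth tree scaled to unit height; species $\log(a/i)$ and $\log M_1$
drawn from a multivariate normal whose covariance blends $\Sigma$ with the
identity by `lambda_true` (the Pagel transform, so `lambda_true` is the
estimand of the $\lambda$ formula above); molar areas from the cascade
geometry; an optional multiplicative $M_2$ inflation on named clades as a
controlled cascade violation; diet labels whose frugivory odds shift by a
configurable odds ratio when $M_2$ is the dominant molar; agenesis either
at the model threshold or at an independent rate; lognormal specimen noise
(areas are positive and CV-parameterized) with a symmetric multiplicative
sex offset; and a deterministic decomposition of each area into length and
trigonid/talonid breadths (aspect and taper drawn once per species) so the
morphometric reconstruction round-trips exactly.

Defaults are the study conditions: 100 species, 29 specimens per species
(a ~2,900-specimen sample), specimen CV 0.05, $\log(a/i)$ spread 0.25,
full phylogenetic signal, sex dimorphism 1.05, frugivory odds ratio 9.5.
Body mass follows a simple allometry on total molar area
($\log \mathrm{mass} = -9 + 1.8 \log M_T$ plus noise), which yields
anthropoid-like masses but deliberately contains no link to cascade
deviation — the mass–deviation regression on generated data is a null
check.

The strict-mediation generator draws $M_2 = 1.1 M_1 + \varepsilon_2$ and
$M_3 = 1.2 M_2 + \varepsilon_3$ with a zero direct coefficient, so the
true proportion mediated is 1. The two noise scales default to 8 and
1.5 mm² and are deliberately unequal: the mediator must carry variation
independent of $M_1$, or the between-species predictors are nearly
collinear and no estimator — Bayesian or least squares — can separate the
direct from the indirect path (specimen measurement error then leaks
indirect effect into the direct slope). The identifiability scaling is
roughly $\mathrm{se}(\text{direct}) \approx a\,\sigma_3 / (\sqrt{n}\,
\sigma_2)$.

What passing these tests shows is that the machinery recovers known
structure under the model's own assumptions. What it cannot show: the
generator has no wear gradients, no correlated measurement error between
molars of one specimen, no intraspecific geographic structure, no
diet-by-clade confounding, and its agenesis (under the independent rule)
carries no signal about $M_2/M_1$. Conclusions about real anthropoid data
depend on those aspects and are not certified by green tests here.

# Known limitations and numerical notes

* One binary observation per species with a fixed logistic residual
  leaves the species variance of the diet model unidentified; the latent
  scale can inflate and raw $e^{\beta_1}$ draws become extreme. The
  reported `odds_ratio_marginal` rescales each draw by
  $\sqrt{1 + c^2(\sigma_p^2 + \sigma_s^2)}$, $c = 16\sqrt{3}/(15\pi)$,
  giving the stable population-averaged odds ratio; the conditional
  `odds_ratio` is also reported for completeness.
* For the same reason, `logistic(beta0)` in an intercept-only Bernoulli
  model is the probability at zero latent residual; it is the *marginal*
  probability (integrating the $\pi^2/3$ residual) that matches a sample
  proportion.
* The agenesis probability $P(M_2/M_1 < 0.5 \mid \text{agenesis})$ is
  computed on the posterior of the group mean, not the posterior
  predictive of a new species.
* Random slopes are not fitted, matching the model family implemented;
  phylogenetic uncertainty (multiple trees) is out of scope; a single
  fixed ultrametric tree is assumed, checked at a relative tolerance of
  $10^{-6}$.
* Test and acceptance problem sizes: the end-to-end recovery runs use 100
  species with 10 specimens each and the fast schedule (10,000 retained
  draws), averaged over five seeds for the proportion line; unit tests
  use 30–50 species with 1,000–4,000 retained draws, sizes at which the
  checked contrasts are already decisive.
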
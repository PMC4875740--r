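# molarcascade

Tools for testing the **dental inhibitory cascade (DIC)** model of lower
molar proportions with Bayesian phylogenetic comparative methods. The
package is written for evolutionary morphologists who have specimen-level
molar measurements across a clade and an ultrametric phylogeny, and who
want to ask — with honest uncertainty — whether a one-parameter
developmental model explains their molar size patterns.

## The model being tested

Under the cascade, activator/inhibitor balance ($a/i$) set by earlier
molars determines later ones, giving relative areas

$$M_1 = 1, \qquad M_2 = a/i, \qquad M_3 = 2(a/i) - 1 .$$

This implies a bundle of sharp predictions: species proportions fall on
the line $M_3/M_1 = 2(M_2/M_1) - 1$; only the orderings
$M_1<M_2<M_3$ and $M_1>M_2>M_3$ (plus the line itself) are reachable in
morphospace; $M_2$ is exactly one third of total molar area; the third
molar is lost when $M_2 < M_1/2$; and $M_1$ influences $M_3$ only through
$M_2$ (full mediation). Each prediction is evaluated with a Bayesian
phylogenetic generalized linear mixed model (PGLMM) — Gaussian or
logit-link Bernoulli, with a phylogenetically correlated species intercept
(covariance from the tree, Pagel's $\lambda$ reported per draw) and an
i.i.d. species intercept, specimen-level predictors split by within-group
centering — and summarized as posterior means, 95% highest-density
intervals, and posterior mass inside a *region of practical equivalence*
(ROPE) around the model's point prediction (slope $[1.90, 2.10]$,
intercept $[-1.10, -0.90]$, $M_2$ share $[0.323, 0.343]$, proportion
mediated $[0.9, 1]$).

The MCMC engine (blocked Gibbs with parameter-expanded variance priors;
latent-variable slice sampling for binary responses) is implemented in
compiled code and validated against conjugate closed forms. A
synthetic-data generator with known ground truth — cascade-faithful
species on a simulated phylogeny, optional clade-specific M2 inflation as
a controlled violation, diet labels, agenesis, sex dimorphism, lognormal
specimen noise — drives all end-to-end tests.

## Worked example

```r
library(molarcascade)

cfg <- simulation_config(n_species = 60, n_specimens = 10, seed = 7)
sim <- simulate_dic_dataset(cfg)
areas <- specimen_areas(filter_specimens(sim$specimens)$retained)
summ  <- species_summaries(areas)

ms <- summarize_morphospace(summ)
cat(sprintf("%.1f%% of %d species centroids are cascade-consistent\n",
            ms$percent_consistent, ms$n))

res <- run_proportion_regression(areas, sim$tree,
                                 schedule = mcmc_schedule(21000, 1000, 20),
                                 seed = 7)
cat(sprintf("between-species slope %.2f (95%% HDI %.2f, %.2f), P(slope in [1.90, 2.10]) = %.2f\n",
            res$slope_between$mean, res$slope_between$hdi[1],
            res$slope_between$hdi[2], res$slope_between$rope_prob))
cat(sprintf("intercept %.2f, lambda %.2f\n", res$intercept$mean, res$lambda$mean))
```

prints

```
95.0% of 60 species centroids are cascade-consistent
between-species slope 1.95 (95% HDI 1.90, 2.01), P(slope in [1.90, 2.10]) = 0.97
intercept -0.96, lambda 0.03
```

Data here were generated exactly under the cascade, so most species sit in
consistent morphospace regions, the between-species slope recovers the
predicted 2 (ROPE probability 0.97), and the intercept recovers $-1$.
The few inconsistent centroids are specimen-noise scatter around the
equal-molar point. $\lambda$ is near zero because, conditional on the
regression, almost no species-level residual variation remains for the
phylogenetic term to absorb.

The `analysis/` directory holds the full numbered workflow —
`01_simulate.R` through `07_report.R` — which builds a 100-species study
with an M2-inflated clade, runs every analysis (morphospace, proportion
regression with clade subsets, M2 relative area, mediation,
mass–deviation, cv comparison, anthropoid and human agenesis, diet
logistic, area-correction validation), and collates `results/report.md`.

## Package layout

* `R/dic-core.R` — cascade geometry, morphospace classification.
* `R/morphometrics.R` — areas, shape-coefficient correction, filters,
  species summaries, CSV I/O.
* `R/phylo.R` — tree I/O, scaled phylogenetic covariance, Pagel's lambda.
* `R/pglmm.R` + `src/pglmm_gibbs.cpp` — the PGLMM engine, schedules,
  HDI/ROPE, convergence diagnostics.
* `R/analyses.R` — the study analyses as pipeline stages.
* `R/synthetic-data.R` — generators with ground truth.
* `vignettes/cascade-methods.Rmd` — models, priors, design decisions,
  generator scope, limitations.
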
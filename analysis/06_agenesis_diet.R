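#!/usr/bin/env Rscript
# Third-molar agenesis (across species, and within the polymorphic
# human-like sample) and the diet association with the M2-dominant
# morphospace region.

library(molarcascade)

summ <- read.csv("results/species_summaries.csv")
humans <- read.csv("results/data/humans.csv")
tree <- read_phylogeny("results/data/tree.nwk")
sched <- mcmc_schedule(31000, 1000, 30)

out <- list()

ag <- run_agenesis_anthropoid(summ, tree, schedule = sched, seed = 51)
cat(sprintf(
  "species-level M2/M1 | agenesis: %.3f (HDI %.3f, %.3f); retained: %.3f
P(M2/M1 < 0.5 | agenesis) = %.4f, lambda %.2f\n",
  ag$m2m1_agenesis$mean, ag$m2m1_agenesis$hdi[1], ag$m2m1_agenesis$hdi[2],
  ag$m2m1_retained$mean, ag$prob_below_half, ag$lambda$mean))
out$anthropoid <- list(m2m1_agenesis = ag$m2m1_agenesis,
                       m2m1_retained = ag$m2m1_retained,
                       difference = ag$difference,
                       prob_below_half = ag$prob_below_half)

hu <- run_agenesis_human(humans, schedule = sched, seed = 52)
cat(sprintf(
  "human M2/M1 | agenesis: %.3f (HDI %.3f, %.3f); retained: %.3f; diff %.3f
P(M2/M1 < 0.5 | agenesis) = %.4f\n",
  hu$m2m1_agenesis$mean, hu$m2m1_agenesis$hdi[1], hu$m2m1_agenesis$hdi[2],
  hu$m2m1_retained$mean, hu$difference$mean, hu$prob_below_half))
out$human <- list(m2m1_agenesis = hu$m2m1_agenesis,
                  m2m1_retained = hu$m2m1_retained,
                  difference = hu$difference,
                  prob_below_half = hu$prob_below_half)

diet <- run_diet_logistic(summ, tree,
                          schedule = mcmc_schedule(36000, 6000, 30,
                                                   family = "bernoulli"),
                          seed = 53)
cat(sprintf(
  "frugivory odds ratio (population-averaged): %.2f (HDI %.2f, %.2f), lambda %.2f\n",
  diet$odds_ratio_marginal$mean, diet$odds_ratio_marginal$hdi[1],
  diet$odds_ratio_marginal$hdi[2], diet$lambda$mean))
out$diet <- list(odds_ratio_marginal = diet$odds_ratio_marginal,
                 odds_ratio = diet$odds_ratio,
                 percent_increase = diet$percent_increase,
                 lambda = diet$lambda)

cat("\nAgenesis in the generator is independent of M2/M1, so the agenesis
group mean sits far above the 0.5 cascade threshold - the same
qualitative refutation pattern the analyses are designed to expose.\n")
jsonlite::write_json(out, "results/agenesis_diet.json", auto_unbox = TRUE,
                     digits = NA)
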
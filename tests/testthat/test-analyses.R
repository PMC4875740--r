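# species-summary table built by hand around chosen centroids
summary_fixture <- function(m2m1, m3m1, species = NULL) {
  n <- length(m2m1)
  if (is.null(species)) species <- sprintf("sp%03d", seq_len(n))
  data.frame(species = species, n_specimens = 5,
             mean_area_1 = 10, mean_area_2 = 10 * m2m1,
             mean_area_3 = 10 * m3m1,
             cv_1 = 0.05, cv_2 = 0.05, cv_3 = 0.07,
             m2m1 = m2m1, m3m1 = m3m1,
             total_area = 10 * (1 + m2m1 + m3m1),
             body_mass_kg = 5, diet = "fruit", m3_agenesis = FALSE)
}

test_that("morphospace summary counts regions and the consistent fraction", {
  # on the line: 100 %
  x <- c(0.8, 1, 1.3)
  s <- summary_fixture(x, predicted_m3m1(x))
  expect_equal(summarize_morphospace(s)$percent_consistent, 100)
  # 3 increasing + 1 M2 peak: 75 %
  s <- summary_fixture(c(1.2, 1.3, 1.4, 1.2), c(1.5, 1.7, 1.9, 1.0))
  out <- summarize_morphospace(s)
  expect_equal(out$percent_consistent, 75)
  expect_equal(unname(out$region_counts["INCREASING"]), 3L)
  expect_equal(unname(out$region_counts["M2_PEAK"]), 1L)
  # all M2 peak: 0 %
  s <- summary_fixture(c(1.2, 1.3), c(1.0, 1.1))
  expect_equal(summarize_morphospace(s)$percent_consistent, 0)
  # agenesis species drop out of the denominator
  s <- summary_fixture(c(1.2, 1.3, 0.9), c(1.5, 1.7, NA))
  s$m3_agenesis[3] <- TRUE
  out <- summarize_morphospace(s)
  expect_equal(out$n, 2)
  expect_equal(out$n_agenesis_excluded, 1)
})

test_that("proportion regression recovers the line from on-line data", {
  sim <- clean_sim(seed = 30, n_species = 40, n_specimens = 6,
                   specimen_cv = 0.01)
  areas <- specimen_areas(sim$specimens)
  res <- run_proportion_regression(areas, sim$tree,
                                   schedule = short_schedule(), seed = 1)
  expect_equal(res$slope_between$mean, 2, tolerance = 0.05)
  expect_equal(res$intercept$mean, -1, tolerance = 0.05)
})

test_that("proportion regression rejects the line for slope-1 data", {
  # species on y = x through (1,1): M3 = M2 everywhere
  tree <- simulate_tree(40, seed = 31)
  set.seed(31)
  r <- exp(rnorm(40, 0, 0.25))
  idx <- rep(1:40, each = 5)
  noise <- function() exp(rnorm(200, 0, 0.03))
  areas <- data.frame(species = tree$tip.label[idx],
                      m1_area = 10 * noise(),
                      m2_area = 10 * r[idx] * noise(),
                      m3_area = 10 * r[idx] * noise())
  res <- run_proportion_regression(areas, tree,
                                   schedule = short_schedule(), seed = 2)
  expect_equal(res$slope_between$mean, 1, tolerance = 0.1)
  expect_lt(res$slope_between$rope_prob, 0.01)
})

test_that("clade subsetting is honoured and refuses tiny clades", {
  sim <- clean_sim(seed = 32, n_species = 30, n_specimens = 5)
  areas <- specimen_areas(sim$specimens)
  clade <- sort(unique(areas$species))[1:10]
  res <- run_proportion_regression(areas, sim$tree, clade = clade,
                                   schedule = short_schedule(), seed = 3)
  expect_equal(sort(res$fit$species_levels),
               sort(intersect(clade, areas$species[is.finite(areas$m3_area)])))
  expect_error(run_proportion_regression(areas, sim$tree, clade = clade[1:3],
                                         schedule = short_schedule(),
                                         seed = 3),
               "fewer than")
})

test_that("M2 share slope sits at one-third for cascade data and above it when inflated", {
  sim <- clean_sim(seed = 33, n_species = 40, n_specimens = 6)
  areas <- specimen_areas(sim$specimens)
  res <- run_m2_relative(areas, sim$tree, schedule = short_schedule(),
                         seed = 4)
  expect_lt(abs(res$slope_between$mean - 1 / 3), 0.02)
  # uniform 1.2x M2 inflation: share becomes 1.2r/(3.2r) = 0.375
  inflated <- areas
  inflated$m2_area <- inflated$m2_area * 1.2
  res2 <- run_m2_relative(inflated, sim$tree, schedule = short_schedule(),
                          seed = 4)
  expect_gt(res2$slope_between$mean, 0.343)
  expect_lt(res2$slope_between$rope_prob, 0.01)
})

test_that("mediation algebra follows the draw-wise definitions", {
  eff <- mediation_effects(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))
  expect_equal(eff$ab, c(1, 1, 1))
  expect_equal(eff$c_prime_abs, c(1, 1, 1))
  expect_equal(eff$pr_m, c(0.5, 0.5, 0.5))
  # no direct path: fully mediated
  eff <- mediation_effects(rnorm(10, 2), rnorm(10, 2), rep(0, 10))
  expect_equal(eff$pr_m, rep(1, 10))
  # no indirect path: nothing mediated
  eff <- mediation_effects(rep(0, 10), rnorm(10), rnorm(10, 3))
  expect_equal(eff$pr_m, rep(0, 10))
})

test_that("mediation separates direct from indirect paths on constructed data", {
  tree <- simulate_tree(50, seed = 34)
  sched <- short_schedule()
  strict <- simulate_strict_mediation(50, seed = 10, n_specimens = 6)
  m <- run_mediation(strict$areas, tree, schedule = sched, seed = 5)
  expect_gt(m$pr_m$mean, 0.85)
  direct <- simulate_strict_mediation(50, seed = 10, b_coef = 0,
                                      direct_coef = 1.2, n_specimens = 6)
  m0 <- run_mediation(direct$areas, tree, schedule = sched, seed = 5)
  expect_lt(m0$pr_m$mean, 0.2)
})

test_that("mediation pr_m is invariant to rescaling every molar area", {
  tree <- simulate_tree(30, seed = 35)
  strict <- simulate_strict_mediation(30, seed = 11, n_specimens = 5)
  sched <- mcmc_schedule(4000, 1000, 5)
  m1 <- run_mediation(strict$areas, tree, schedule = sched, seed = 6)
  scaled <- strict$areas
  for (col in c("m1_area", "m2_area", "m3_area"))
    scaled[[col]] <- scaled[[col]] * 4
  m2 <- run_mediation(scaled, tree, schedule = sched, seed = 6)
  expect_equal(m2$pr_m$mean, m1$pr_m$mean, tolerance = 0.05)
})

test_that("mass-deviation regression finds nulls and planted slopes", {
  sim <- clean_sim(seed = 36, n_species = 40, n_specimens = 6,
                   m2_inflation = 1.2,
                   m2_inflated_taxa = sprintf("sp%03d", 1:20))
  areas <- specimen_areas(sim$specimens)
  areas <- areas[is.finite(areas$m3_area), ]
  # null: mass unrelated to deviation
  set.seed(36)
  sp_mass <- exp(rnorm(40, 1, 0.5))
  names(sp_mass) <- sprintf("sp%03d", 1:40)
  areas$body_mass_kg <- sp_mass[areas$species]
  res <- run_mass_deviation(areas, sim$tree, schedule = short_schedule(),
                            seed = 7)
  expect_true(res$slope_between$hdi[1] < 0 && res$slope_between$hdi[2] > 0)
  # planted: log mass = -3 * species mean deviation + noise
  dist <- perpendicular_distance(areas$m2_area / areas$m1_area,
                                 areas$m3_area / areas$m1_area)
  dbar <- tapply(dist, areas$species, mean)
  set.seed(37)
  lm_sp <- -3 * dbar + rnorm(length(dbar), 0, 0.01)
  areas$body_mass_kg <- exp(lm_sp[areas$species])
  res2 <- run_mass_deviation(areas, sim$tree, schedule = short_schedule(),
                             seed = 8)
  expect_lt(res2$slope_between$hdi[2], 0)
  expect_equal(res2$slope_between$mean, -3, tolerance = 0.5)
})

test_that("cv comparison recovers planted extra M3 variability", {
  sim <- clean_sim(seed = 38, n_species = 40, n_specimens = 10)
  summ <- species_summaries(specimen_areas(sim$specimens))
  summ <- summ[!summ$m3_agenesis, ]
  # equalize, then inflate M3 cv by a known amount
  summ$cv_1 <- summ$cv_2 <- summ$cv_3
  same <- run_cv_comparison(summ, sim$tree, schedule = short_schedule(),
                            seed = 9)
  expect_true(same$diff_m3_m1$hdi[1] < 0 && same$diff_m3_m1$hdi[2] > 0)
  summ$cv_3 <- summ$cv_3 + 0.02
  up <- run_cv_comparison(summ, sim$tree, schedule = short_schedule(),
                          seed = 10)
  expect_lt(abs(up$diff_m3_m1$mean - 0.02), 0.005)
  expect_lt(abs(up$diff_m3_m2$mean - 0.02), 0.005)
  expect_gt(up$diff_m3_m1$hdi[1], 0)
  # invariance to species order
  perm <- sample(nrow(summ))
  up2 <- run_cv_comparison(summ[perm, ], sim$tree,
                           schedule = short_schedule(), seed = 10)
  expect_lt(abs(up2$diff_m3_m1$mean - up$diff_m3_m1$mean), 1e-4)
})

test_that("anthropoid agenesis model locates the group means", {
  tree <- simulate_tree(40, seed = 39)
  set.seed(39)
  agen <- c(rep(TRUE, 6), rep(FALSE, 34))
  m2m1 <- ifelse(agen, 0.9, 1.1) + rnorm(40, 0, 0.03)
  summ <- summary_fixture(m2m1, predicted_m3m1(pmax(m2m1, 0.55)),
                          species = tree$tip.label)
  summ$m3_agenesis <- agen
  res <- run_agenesis_anthropoid(summ, tree, schedule = short_schedule(),
                                 seed = 11)
  expect_equal(res$m2m1_agenesis$mean, 0.9, tolerance = 0.1)
  expect_equal(res$m2m1_retained$mean, 1.1, tolerance = 0.1)
  expect_lt(res$prob_below_half, 0.01)
  # group centred below the threshold flips the probability
  m2m1_low <- ifelse(agen, 0.3, 1.1) + rnorm(40, 0, 0.03)
  summ$m2m1 <- m2m1_low
  res2 <- run_agenesis_anthropoid(summ, tree, schedule = short_schedule(),
                                  seed = 12)
  expect_gt(res2$prob_below_half, 0.99)
  summ$m3_agenesis <- FALSE
  expect_error(run_agenesis_anthropoid(summ, tree, seed = 1), "no agenesis")
})

test_that("human agenesis model recovers paper-like group means", {
  d <- simulate_human_agenesis(seed = 13)
  res <- run_agenesis_human(d, schedule = short_schedule(), seed = 13)
  expect_equal(res$m2m1_agenesis$mean, 0.92, tolerance = 0.05)
  expect_equal(res$m2m1_retained$mean, 0.95, tolerance = 0.05)
  expect_lt(res$prob_below_half, 0.01)
  # identical groups: difference HDI straddles zero
  d2 <- simulate_human_agenesis(group_means = c(agenesis = 0.95,
                                                retained = 0.95), seed = 14)
  res2 <- run_agenesis_human(d2, schedule = short_schedule(), seed = 14)
  expect_true(res2$difference$hdi[1] < 0 && res2$difference$hdi[2] > 0)
})

test_that("diet model is null when frugivory is independent of morphospace", {
  sim <- clean_sim(seed = 40, n_species = 50, n_specimens = 5,
                   m2_inflation = 1.25,
                   m2_inflated_taxa = sprintf("sp%03d", 1:20),
                   diet_or_true = 1)
  summ <- species_summaries(specimen_areas(sim$specimens))
  res <- run_diet_logistic(summ, sim$tree,
                           schedule = mcmc_schedule(12000, 2000, 10,
                                                    family = "bernoulli"),
                           seed = 15)
  expect_true(res$odds_ratio_marginal$hdi[1] < 1 &&
                res$odds_ratio_marginal$hdi[2] > 1)
  # percentage change is the per-draw transform of the odds ratio
  or_draws <- exp(res$fit$draws[, "fruit"])
  expect_equal(res$percent_increase$mean, mean((or_draws - 1) * 100))
  expect_equal(unname(res$percent_increase$hdi),
               unname((hdi(or_draws) - 1) * 100))
})

test_that("diet model recovers a planted frugivory odds ratio", {
  sim <- clean_sim(seed = 41, n_species = 100, n_specimens = 5,
                   ai_log_sd = 0.1, m2_inflation = 1.3,
                   m2_inflated_taxa = sprintf("sp%03d", 1:45),
                   diet_or_true = 9.5)
  summ <- species_summaries(specimen_areas(sim$specimens))
  res <- run_diet_logistic(summ, sim$tree,
                           schedule = mcmc_schedule(18000, 3000, 15,
                                                    family = "bernoulli"),
                           seed = 16)
  # the population-averaged odds ratio is the recoverable estimand
  expect_gt(res$odds_ratio_marginal$mean, 1)
  expect_true(res$odds_ratio_marginal$hdi[1] <= 9.5 &&
                res$odds_ratio_marginal$hdi[2] >= 2)
})

test_that("area-correction validation prefers corrected over rectangular areas", {
  sim <- clean_sim(seed = 42, n_species = 3, n_specimens = 10)
  rec <- sim$specimens
  set.seed(42)
  for (k in 1:3) {
    ra <- rec[[paste0("m", k, "_length")]] *
      (rec[[paste0("m", k, "_breadth_trigonid")]] +
         rec[[paste0("m", k, "_breadth_talonid")]]) / 2
    ea <- elliptical_area(ra)
    x_eff <- 0.7 + rnorm(nrow(rec), 0, 0.03)
    rec[[paste0("m", k, "_outline_area")]] <- corrected_area(ra, ea, x_eff)
  }
  res <- run_area_correction_check(rec, schedule = short_schedule(), seed = 17)
  expect_lt(abs(res$oa_minus_ca$mean), abs(res$oa_minus_ra$mean))
  expect_lt(res$oa_minus_ra$mean, 0)  # outlines sit below the rectangle
  expect_true(res$oa_minus_ca$hdi[1] < 0 && res$oa_minus_ca$hdi[2] > 0)
  expect_equal(unname(res$shape_coefficients), rep(0.7, 3), tolerance = 0.05)
})
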
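#' Default ROPE intervals for the cascade's point predictions
#'
#' Regions of practical equivalence around the DIC model's predicted
#' parameter values: proportion-line slope 2 and intercept -1, M2 share of
#' total molar area 1/3, and full mediation (pr_m = 1).
#'
#' @return named list of length-2 intervals.
#' @export
dic_ropes <- function() {
  list(slope = c(1.90, 2.10), intercept = c(-1.10, -0.90),
       m2_share = c(0.323, 0.343), pr_m = c(0.9, 1))
}

subset_check <- function(data, clade, min_species = 5) {
  if (!is.null(clade)) {
    data <- data[data$species %in% clade, , drop = FALSE]
    if (length(unique(data$species)) < min_species)
      stop("clade filter leaves fewer than ", min_species,
           " species; refusing to fit")
  }
  data
}

#' Morphospace summary of species centroids
#'
#' Classifies every species centroid into a morphospace region and reports
#' the percentage falling in regions consistent with the inhibitory
#' cascade. Species with third-molar agenesis have no centroid and are
#' excluded from the denominator (which is reported).
#'
#' @param summaries output of [species_summaries()].
#' @param line_tol perpendicular-distance tolerance for on-line
#'   membership (default 0: only exact line membership counts).
#' @param tol tie tolerance for region classification.
#' @return list: `percent_consistent`, `n` (denominator),
#'   `n_agenesis_excluded`, `region_counts` (named integer vector).
#' @export
summarize_morphospace <- function(summaries, line_tol = 0, tol = 1e-9) {
  has_centroid <- !summaries$m3_agenesis & is.finite(summaries$m3m1)
  s <- summaries[has_centroid, , drop = FALSE]
  if (nrow(s) == 0) stop("no species with all three molars")
  region <- classify_region(s$m2m1, s$m3m1, tol = tol)
  consistent <- dic_consistent(s$m2m1, s$m3m1, line_tol = line_tol, tol = tol)
  counts <- table(factor(region, levels = c("INCREASING", "DECREASING",
                                            "M2_PEAK", "M2_TROUGH", "EQUAL")))
  list(percent_consistent = 100 * mean(consistent), n = nrow(s),
       n_agenesis_excluded = sum(!has_centroid),
       region_counts = c(counts))
}

# shared scaffolding: prune the tree to the data's species, build the
# scaled covariance, and fit a Gaussian PGLMM with p and s intercepts
fit_gaussian_pglmm <- function(y, X, species, tree, schedule, seed) {
  sub <- prune_to_species(tree, species)
  Sigma <- phylo_covariance(sub)
  tips <- match_taxa(species, sub)
  pglmm_fit(y, X, tips, Sigma, family = "gaussian",
            random = c("phylo", "species"), schedule = schedule, seed = seed)
}

#' Molar-proportion regression against the DIC line
#'
#' Fits the specimen-level PGLMM of M3/M1 on within-group-centred M2/M1
#' (between- and within-species slopes; phylogenetic and species random
#' intercepts) and reports the posterior of the between-species slope and
#' intercept against the cascade's ROPEs ([1.90, 2.10] and
#' [-1.10, -0.90]), plus the within slope and Pagel's lambda. The within
#' component is the deviation of each specimen's ratio from its species
#' mean ratio.
#'
#' @param areas specimen-level data.frame with `species`, `m1_area`,
#'   `m2_area`, `m3_area` (see [specimen_areas()]); agenesis specimens
#'   (NA `m3_area`) are dropped.
#' @param tree ultrametric `phylo` covering the species.
#' @param clade optional character vector of species to keep (a named
#'   taxon set); fewer than 5 species is refused.
#' @param schedule an [mcmc_schedule()] or preset name.
#' @param seed integer seed.
#' @param ropes ROPE list as from [dic_ropes()].
#' @return list of posterior summaries: `slope_between`, `intercept`,
#'   `slope_within`, `lambda`, plus the `fit`.
#' @export
run_proportion_regression <- function(areas, tree, clade = NULL,
                                      schedule = "fast", seed = 1,
                                      ropes = dic_ropes()) {
  areas <- subset_check(areas, clade)
  keep <- is.finite(areas$m3_area) & is.finite(areas$m1_area) &
    is.finite(areas$m2_area)
  areas <- areas[keep, , drop = FALSE]
  y <- areas$m3_area / areas$m1_area
  x <- areas$m2_area / areas$m1_area
  cw <- center_within_groups(x, areas$species)
  X <- cbind(intercept = 1, between = cw$between, within = cw$within)
  fit <- fit_gaussian_pglmm(y, X, areas$species, tree, schedule, seed)
  list(slope_between = posterior_summary(fit$draws[, "between"], ropes$slope),
       intercept = posterior_summary(fit$draws[, "intercept"], ropes$intercept),
       slope_within = posterior_summary(fit$draws[, "within"]),
       lambda = posterior_summary(fit$draws[, "lambda"]),
       fit = fit)
}

#' Relative second-molar area regression
#'
#' Fits M2 area on within-group-centred total molar area; under the
#' cascade, M2 accounts for exactly one-third of the total, so the
#' between-species slope is tested against the ROPE [0.323, 0.343].
#'
#' @inheritParams run_proportion_regression
#' @return list: `slope_between` (with ROPE probability), `intercept`,
#'   `slope_within`, `lambda`, `fit`.
#' @export
run_m2_relative <- function(areas, tree, clade = NULL, schedule = "fast",
                            seed = 1, ropes = dic_ropes()) {
  areas <- subset_check(areas, clade)
  keep <- stats::complete.cases(areas[c("m1_area", "m2_area", "m3_area")])
  areas <- areas[keep, , drop = FALSE]
  y <- areas$m2_area
  total <- areas$m1_area + areas$m2_area + areas$m3_area
  cw <- center_within_groups(total, areas$species)
  X <- cbind(intercept = 1, between = cw$between, within = cw$within)
  fit <- fit_gaussian_pglmm(y, X, areas$species, tree, schedule, seed)
  list(slope_between = posterior_summary(fit$draws[, "between"], ropes$m2_share),
       intercept = posterior_summary(fit$draws[, "intercept"]),
       slope_within = posterior_summary(fit$draws[, "within"]),
       lambda = posterior_summary(fit$draws[, "lambda"]),
       fit = fit)
}

#' Per-draw mediation effects
#'
#' The mediation algebra applied draw-wise: indirect effect
#' ab = beta_2B * beta'_1B, direct magnitude |c'| = |beta_1B|, and
#' proportion mediated pr_m = ab / (ab + |c'|). Because the inputs are
#' regression slopes of areas on areas, pr_m is invariant to any positive
#' rescaling of all molar areas.
#'
#' @param beta2B draws of the M2 between-species slope in the full model.
#' @param beta1B_prime draws of the M1 between-species slope in the
#'   mediator model.
#' @param beta1B draws of the M1 between-species slope (direct path) in
#'   the full model.
#' @return list of draw vectors `ab`, `c_prime_abs`, `pr_m`.
#' @export
mediation_effects <- function(beta2B, beta1B_prime, beta1B) {
  ab <- beta2B * beta1B_prime
  c_prime_abs <- abs(beta1B)
  list(ab = ab, c_prime_abs = c_prime_abs, pr_m = ab / (ab + c_prime_abs))
}

#' Posterior mediation analysis of molar-area relationships
#'
#' How much of the M1-to-M3 relationship runs through M2: fits the full
#' model (M3 on M1 and M2, both within-group centred) and the mediator
#' model (M2 on M1), then per retained draw t computes the indirect effect
#' ab = beta_2B * beta'_1B, the direct magnitude |c'| = |beta_1B|, and the
#' proportion mediated pr_m = ab / (ab + |c'|). Under a strict cascade
#' pr_m = 1; the ROPE is [0.9, 1].
#'
#' @inheritParams run_proportion_regression
#' @return list: `ab`, `c_prime_abs`, `pr_m` posterior summaries (pr_m
#'   with ROPE probability), `pr_m_point` (ratio of the two point
#'   estimates), per-draw vectors in `draws`, and both fits.
#' @export
run_mediation <- function(areas, tree, clade = NULL, schedule = "fast",
                          seed = 1, ropes = dic_ropes()) {
  areas <- subset_check(areas, clade)
  keep <- stats::complete.cases(areas[c("m1_area", "m2_area", "m3_area")])
  areas <- areas[keep, , drop = FALSE]
  cw1 <- center_within_groups(areas$m1_area, areas$species)
  cw2 <- center_within_groups(areas$m2_area, areas$species)
  X_full <- cbind(intercept = 1, m1_between = cw1$between,
                  m1_within = cw1$within, m2_between = cw2$between,
                  m2_within = cw2$within)
  X_med <- cbind(intercept = 1, m1_between = cw1$between,
                 m1_within = cw1$within)
  fit_full <- fit_gaussian_pglmm(areas$m3_area, X_full, areas$species, tree,
                                 schedule, seed)
  fit_med <- fit_gaussian_pglmm(areas$m2_area, X_med, areas$species, tree,
                                schedule, seed + 1L)
  if (nrow(fit_full$draws) != nrow(fit_med$draws))
    stop("component fits retain different draw counts")
  eff <- mediation_effects(fit_full$draws[, "m2_between"],
                           fit_med$draws[, "m1_between"],
                           fit_full$draws[, "m1_between"])
  list(ab = posterior_summary(eff$ab),
       c_prime_abs = posterior_summary(eff$c_prime_abs),
       pr_m = posterior_summary(eff$pr_m, ropes$pr_m),
       pr_m_point = mean(eff$ab) / (mean(eff$ab) + mean(eff$c_prime_abs)),
       draws = eff,
       fit_full = fit_full, fit_mediator = fit_med)
}

#' Body mass against deviation from the DIC line
#'
#' Regresses log species mean body mass (replicated across a species'
#' specimens) on the within-group-centred absolute perpendicular distance
#' of each specimen from the molar-proportion line. Clade exclusions
#' (e.g. dropping callitrichins) are expressed through `clade`.
#'
#' @inheritParams run_proportion_regression
#' @return list: `slope_between`, `slope_within`, `lambda` summaries and
#'   the `fit`.
#' @export
run_mass_deviation <- function(areas, tree, clade = NULL, schedule = "fast",
                               seed = 1) {
  areas <- subset_check(areas, clade)
  keep <- stats::complete.cases(areas[c("m1_area", "m2_area", "m3_area")])
  areas <- areas[keep, , drop = FALSE]
  if (is.null(areas$body_mass_kg) || anyNA(areas$body_mass_kg))
    stop("body mass missing for some retained species")
  dist <- perpendicular_distance(areas$m2_area / areas$m1_area,
                                 areas$m3_area / areas$m1_area)
  sp_mass <- tapply(areas$body_mass_kg, areas$species, mean)
  y <- log(as.numeric(sp_mass[areas$species]))
  cw <- center_within_groups(dist, areas$species)
  X <- cbind(intercept = 1, between = cw$between, within = cw$within)
  fit <- fit_gaussian_pglmm(y, X, areas$species, tree, schedule, seed)
  list(slope_between = posterior_summary(fit$draws[, "between"]),
       slope_within = posterior_summary(fit$draws[, "within"]),
       lambda = posterior_summary(fit$draws[, "lambda"]),
       fit = fit)
}

#' Molar-area variability comparison
#'
#' Stacks the per-species small-sample coefficients of variation of the
#' three molars and fits them on indicator variables for M1 and M2 with
#' M3 as the reference level, so the negated coefficients are the average
#' M3 - M1 and M3 - M2 variability differences. The cascade predicts both
#' are positive (M3 most variable).
#'
#' @param summaries output of [species_summaries()]; species missing any
#'   cv (e.g. agenesis species) are dropped.
#' @inheritParams run_proportion_regression
#' @return list: `diff_m3_m1`, `diff_m3_m2`, `lambda` summaries, `fit`.
#' @export
run_cv_comparison <- function(summaries, tree, schedule = "fast", seed = 1) {
  keep <- stats::complete.cases(summaries[c("cv_1", "cv_2", "cv_3")])
  s <- summaries[keep, , drop = FALSE]
  long <- data.frame(
    species = rep(s$species, 3),
    cv = c(s$cv_1, s$cv_2, s$cv_3),
    molar = rep(1:3, each = nrow(s)))
  X <- cbind(intercept = 1, is_m1 = as.numeric(long$molar == 1),
             is_m2 = as.numeric(long$molar == 2))
  fit <- fit_gaussian_pglmm(long$cv, X, long$species, tree, schedule, seed)
  list(diff_m3_m1 = posterior_summary(-fit$draws[, "is_m1"]),
       diff_m3_m2 = posterior_summary(-fit$draws[, "is_m2"]),
       lambda = posterior_summary(fit$draws[, "lambda"]),
       fit = fit)
}

#' Third-molar agenesis and relative M2 size across species
#'
#' Cell-means PGLMM (no intercept) of species M2/M1 on agenesis and
#' retention indicators, with phylogenetic and species random intercepts.
#' The cascade predicts agenesis only when M2/M1 < 0.5; the reported
#' `prob_below_half` is the posterior probability that the agenesis-group
#' mean lies below that threshold.
#'
#' @param summaries output of [species_summaries()] containing at least
#'   one agenesis and one retained species.
#' @inheritParams run_proportion_regression
#' @return list: `m2m1_agenesis`, `m2m1_retained`, `difference`
#'   summaries, `prob_below_half`, `lambda`, `fit`.
#' @export
run_agenesis_anthropoid <- function(summaries, tree, schedule = "fast",
                                    seed = 1) {
  if (!any(summaries$m3_agenesis)) stop("no agenesis species in the sample")
  if (all(summaries$m3_agenesis)) stop("no retained species in the sample")
  y <- summaries$m2m1
  ag <- as.numeric(summaries$m3_agenesis)
  X <- cbind(agenesis = ag, retained = 1 - ag)
  fit <- fit_gaussian_pglmm(y, X, summaries$species, tree, schedule, seed)
  diff <- fit$draws[, "agenesis"] - fit$draws[, "retained"]
  list(m2m1_agenesis = posterior_summary(fit$draws[, "agenesis"]),
       m2m1_retained = posterior_summary(fit$draws[, "retained"]),
       difference = posterior_summary(diff),
       prob_below_half =
         mean(fit$draws[, "agenesis"] < agenesis_threshold_ratio()),
       lambda = posterior_summary(fit$draws[, "lambda"]),
       fit = fit)
}

#' Third-molar agenesis within a polymorphic human sample
#'
#' Same cell-means model as [run_agenesis_anthropoid()] but fitted to
#' individuals, with an i.i.d. population random intercept replacing the
#' phylogenetic terms.
#'
#' @param data data.frame with `m2m1`, `m3_agenesis`, `population` (see
#'   [simulate_human_agenesis()]).
#' @inheritParams run_proportion_regression
#' @return list: `m2m1_agenesis`, `m2m1_retained`, `difference`
#'   summaries, `prob_below_half`, `fit`.
#' @export
run_agenesis_human <- function(data, schedule = "fast", seed = 1) {
  if (length(unique(data$population)) < 2)
    warning("single population: its variance component is unidentifiable; ",
            "fit proceeds")
  ag <- as.numeric(data$m3_agenesis)
  X <- cbind(agenesis = ag, retained = 1 - ag)
  fit <- pglmm_fit(data$m2m1, X, data$population, family = "gaussian",
                   random = "species", schedule = schedule, seed = seed)
  diff <- fit$draws[, "agenesis"] - fit$draws[, "retained"]
  list(m2m1_agenesis = posterior_summary(fit$draws[, "agenesis"]),
       m2m1_retained = posterior_summary(fit$draws[, "retained"]),
       difference = posterior_summary(diff),
       prob_below_half =
         mean(fit$draws[, "agenesis"] < agenesis_threshold_ratio()),
       fit = fit)
}

#' Diet and the M2-dominant morphospace region
#'
#' Bernoulli (logit link) PGLMM of whether a species' centroid falls in
#' the M1 < M2 > M3 region on a frugivory indicator. Reports the
#' frugivore odds ratio exp(beta_1) and the equivalent percentage change
#' in odds, both computed per draw, plus Pagel's lambda (residual variance
#' fixed at pi^2/3).
#'
#' With a single binary observation per species the conditional latent
#' scale is only weakly identified (the species effect can absorb any
#' fit), so exp(beta_1) draws can be extreme. The population-averaged
#' odds ratio, `odds_ratio_marginal`, rescales each draw to the
#' observation scale, exp(beta_1 / sqrt(1 + c^2 (sigma_p^2 + sigma_s^2)))
#' with c = 16 sqrt(3) / (15 pi), and is the stable, comparable estimand.
#'
#' @param summaries output of [species_summaries()] with a `diet` column;
#'   agenesis species (no centroid) are dropped.
#' @inheritParams run_proportion_regression
#' @return list: `odds_ratio`, `odds_ratio_marginal`, `percent_increase`,
#'   `lambda` summaries, `fit`.
#' @export
run_diet_logistic <- function(summaries, tree, schedule = "fast", seed = 1) {
  keep <- !summaries$m3_agenesis & is.finite(summaries$m3m1) &
    !is.na(summaries$diet)
  s <- summaries[keep, , drop = FALSE]
  y <- as.numeric(classify_region(s$m2m1, s$m3m1) == "M2_PEAK")
  X <- cbind(intercept = 1, fruit = as.numeric(s$diet == "fruit"))
  sub <- prune_to_species(tree, s$species)
  fit <- pglmm_fit(y, X, match_taxa(s$species, sub), phylo_covariance(sub),
                   family = "bernoulli", random = c("phylo", "species"),
                   schedule = schedule, seed = seed)
  or <- exp(fit$draws[, "fruit"])
  c2 <- (16 * sqrt(3) / (15 * pi))^2
  shrink <- sqrt(1 + c2 * (fit$draws[, "sigma2_p"] + fit$draws[, "sigma2_s"]))
  or_marg <- exp(fit$draws[, "fruit"] / shrink)
  list(odds_ratio = posterior_summary(or),
       odds_ratio_marginal = posterior_summary(or_marg),
       percent_increase = posterior_summary((or - 1) * 100),
       lambda = posterior_summary(fit$draws[, "lambda"]),
       fit = fit)
}

#' Validation of the molar area correction
#'
#' On the calibration records carrying traced outline areas, compares the
#' per-tooth difference between outline and corrected areas with the
#' difference between outline and rectangular areas, each through a
#' Gaussian mixed model with a species random intercept. A much smaller
#' outline-minus-corrected mean indicates the correction works.
#'
#' @param records specimen data.frame with `m{k}_outline_area` columns on
#'   a calibration subset.
#' @inheritParams run_proportion_regression
#' @return list: `oa_minus_ca` and `oa_minus_ra` posterior summaries (of
#'   the mean difference, mm^2), and the shape coefficients used.
#' @export
run_area_correction_check <- function(records, schedule = "fast", seed = 1) {
  coefs <- estimate_shape_coefficients(records, level = "position")
  species <- d_ca <- d_ra <- numeric(0)
  for (k in 1:3) {
    oa_col <- paste0("m", k, "_outline_area")
    has <- is.finite(records[[oa_col]]) & molar_present(records, k)
    sub <- records[has, , drop = FALSE]
    if (nrow(sub) == 0) next
    ra <- crown_area_vec(sub, k)
    ca <- corrected_area(ra, elliptical_area(ra), coefs[[paste0("x_", k)]])
    species <- c(species, sub$species)
    d_ca <- c(d_ca, sub[[oa_col]] - ca)
    d_ra <- c(d_ra, sub[[oa_col]] - ra)
  }
  if (length(d_ca) == 0) stop("no records with outline areas")
  X <- matrix(1, length(d_ca), 1, dimnames = list(NULL, "intercept"))
  fit_ca <- pglmm_fit(d_ca, X, species, family = "gaussian",
                      random = "species", schedule = schedule, seed = seed)
  fit_ra <- pglmm_fit(d_ra, X, species, family = "gaussian",
                      random = "species", schedule = schedule, seed = seed + 1L)
  list(oa_minus_ca = posterior_summary(fit_ca$draws[, "intercept"]),
       oa_minus_ra = posterior_summary(fit_ra$draws[, "intercept"]),
       shape_coefficients = coefs)
}
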
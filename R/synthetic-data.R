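#' Configuration for a synthetic comparative dataset
#'
#' Defines the generative conditions the analyses assume: a pure-birth
#' phylogeny; species log activator/inhibitor ratios evolving with
#' tunable phylogenetic signal (a Pagel blend of the Brownian covariance
#' with the identity); molar areas from the cascade geometry with optional
#' clade-specific M2 inflation (a controlled violation of the cascade);
#' lognormal specimen-level noise and multiplicative sex dimorphism; diet
#' labels whose odds of frugivory shift when M2 is the dominant molar; and
#' third-molar agenesis either at the model threshold (a/i < 0.5) or at an
#' independent rate.
#'
#' @param n_species number of species (default 100, the study's breadth).
#' @param n_specimens specimens per species; scalar or length-2 range
#'   (default 29, matching a ~2900-specimen sample over 100 taxa).
#' @param lambda_true phylogenetic signal in [0, 1] used to blend the tree
#'   covariance with the identity when drawing species traits.
#' @param ai_log_mean,ai_log_sd mean and Brownian scale of log(a/i).
#' @param m1_log_mean,m1_log_sd mean and Brownian scale of log M1 area
#'   (mm^2).
#' @param m2_inflation multiplicative inflation of M2 areas for
#'   `m2_inflated_taxa` (1 = faithful cascade everywhere).
#' @param m2_inflated_taxa tip labels receiving the M2 inflation.
#' @param specimen_cv intra-species coefficient of variation of areas.
#' @param sex_dimorphism male/female ratio of areas (applied
#'   symmetrically, so the sex-pooled mean stays at the species value).
#' @param diet_or_true odds ratio linking M2 dominance to frugivory.
#' @param diet_base_rate frugivory probability when M2 is not dominant.
#' @param agenesis_rule `"dic_threshold"` (M3 lost when a/i < 0.5) or
#'   `"independent"` with `agenesis_rate`.
#' @param agenesis_rate agenesis probability under the independent rule.
#' @param wear_rate,zoo_rate,indeterminate_rate rates of high-wear, zoo,
#'   and indeterminate-sex specimens injected to exercise the filters.
#' @param mass_log_a,mass_log_b,mass_log_sd allometric body-mass model:
#'   log(mass kg) = a + b log(total molar area) + noise.
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_species = 100, n_specimens = 29,
                              lambda_true = 1,
                              ai_log_mean = 0, ai_log_sd = 0.25,
                              m1_log_mean = log(30), m1_log_sd = 0.4,
                              m2_inflation = 1, m2_inflated_taxa = character(),
                              specimen_cv = 0.05, sex_dimorphism = 1.05,
                              diet_or_true = 9.5, diet_base_rate = 0.3,
                              agenesis_rule = c("dic_threshold", "independent"),
                              agenesis_rate = 0.03,
                              wear_rate = 0.04, zoo_rate = 0.01,
                              indeterminate_rate = 0.01,
                              mass_log_a = -9, mass_log_b = 1.8,
                              mass_log_sd = 0.3,
                              seed = 1) {
  agenesis_rule <- match.arg(agenesis_rule)
  stopifnot(n_species >= 3, lambda_true >= 0, lambda_true <= 1,
            ai_log_sd >= 0, m1_log_sd >= 0, specimen_cv >= 0,
            sex_dimorphism > 0, diet_or_true > 0,
            diet_base_rate > 0, diet_base_rate < 1)
  structure(as.list(environment()), class = "simulation_config")
}

#' Simulate a pure-birth ultrametric phylogeny
#'
#' @param n_species number of tips (>= 3).
#' @param seed integer seed.
#' @return an ultrametric `phylo` tree scaled to unit height, tips
#'   labelled `sp001`, `sp002`, ...
#' @export
simulate_tree <- function(n_species, seed) {
  stopifnot(n_species >= 3)
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  tree$edge.length <- tree$edge.length / tree_height(tree)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

# draw one MVN trait vector on the Pagel-blended tree covariance
rmvn_pagel <- function(tree, mean, sd, lambda) {
  n <- length(tree$tip.label)
  if (sd == 0) return(stats::setNames(rep(mean, n), tree$tip.label))
  V <- sd^2 * (lambda * phylo_covariance(tree) + (1 - lambda) * diag(n))
  drop(mean + t(chol(V)) %*% stats::rnorm(n)) |>
    stats::setNames(tree$tip.label)
}

#' Simulate species-level traits on a phylogeny
#'
#' Draws log(a/i) and log M1 area from multivariate normals with
#' covariance `lambda_true * sd^2 * Sigma + (1 - lambda_true) * sd^2 * I`,
#' derives species mean molar areas from the cascade geometry, applies any
#' configured M2 inflation, assigns diet and agenesis, and an allometric
#' body mass.
#'
#' @param tree ultrametric `phylo` tree whose tips are the species.
#' @param config a [simulation_config()]; its `seed` drives all draws.
#' @return data.frame, one row per species: `species`, `ai_ratio`,
#'   `mean_m1`, `mean_m2`, `mean_m3` (NA under agenesis), `m3_agenesis`,
#'   `diet`, `body_mass_kg`.
#' @export
simulate_species_traits <- function(tree, config) {
  set.seed(config$seed + 1L)
  sp <- tree$tip.label
  ai <- exp(rmvn_pagel(tree, config$ai_log_mean, config$ai_log_sd,
                       config$lambda_true))
  m1 <- exp(rmvn_pagel(tree, config$m1_log_mean, config$m1_log_sd,
                       config$lambda_true))

  agenesis <- if (config$agenesis_rule == "dic_threshold") {
    ai < agenesis_threshold_ratio()
  } else {
    stats::runif(length(sp)) < config$agenesis_rate
  }
  m2 <- m1 * ai
  m3 <- ifelse(agenesis | ai < agenesis_threshold_ratio(),
               NA_real_, m1 * (2 * ai - 1))
  inflate <- sp %in% config$m2_inflated_taxa
  m2[inflate] <- m2[inflate] * config$m2_inflation

  m2_dominant <- m2 > m1 & (is.na(m3) | m2 > m3)
  logit_p <- stats::qlogis(config$diet_base_rate) +
    log(config$diet_or_true) * m2_dominant
  diet <- ifelse(stats::runif(length(sp)) < stats::plogis(logit_p),
                 "fruit", "leaves")

  total <- ifelse(is.na(m3), m1 + m2, m1 + m2 + m3)
  mass <- exp(config$mass_log_a + config$mass_log_b * log(total) +
                stats::rnorm(length(sp), 0, config$mass_log_sd))

  data.frame(species = sp, ai_ratio = ai, mean_m1 = m1, mean_m2 = m2,
             mean_m3 = m3, m3_agenesis = agenesis, diet = diet,
             body_mass_kg = mass, row.names = NULL)
}

# decompose an occlusal area into length and trigonid/talonid breadths so
# that crown_area() round-trips exactly: length * mean(breadths) == area
decompose_area <- function(area, aspect, taper) {
  len <- sqrt(area * aspect)
  b <- sqrt(area / aspect)
  list(length = len, breadth_trigonid = b * (1 + taper),
       breadth_talonid = b * (1 - taper))
}

#' Simulate specimen-level records from species traits
#'
#' Per specimen and molar, areas are the species mean times a lognormal
#' deviate with the configured coefficient of variation and a symmetric
#' multiplicative sex offset. Areas are decomposed into mesio-distal
#' length and trigonid/talonid breadths (aspect ratio and taper drawn once
#' per species) so that the morphometric reconstruction recovers them
#' exactly. Wear, provenance, and indeterminate-sex labels are injected at
#' the configured rates.
#'
#' @param traits output of [simulate_species_traits()].
#' @param config a [simulation_config()].
#' @return specimen data.frame in the [read_specimens()] schema.
#' @export
simulate_specimens <- function(traits, config) {
  set.seed(config$seed + 2L)
  sdlog <- sqrt(log(1 + config$specimen_cv^2))
  sex_f <- sqrt(config$sex_dimorphism)
  rows <- vector("list", nrow(traits))
  for (i in seq_len(nrow(traits))) {
    tr <- traits[i, ]
    n <- if (length(config$n_specimens) == 2)
      sample(config$n_specimens[1]:config$n_specimens[2], 1)
    else config$n_specimens
    sex <- rep(c("male", "female"), length.out = n)
    aspect <- stats::runif(3, 1.05, 1.35)
    taper <- stats::runif(3, 0, 0.1)
    rec <- data.frame(species = rep(tr$species, n), sex = sex,
                      wear = "acceptable", provenance = "wild")
    for (k in 1:3) {
      mean_k <- tr[[paste0("mean_m", k)]]
      if (k == 3 && tr$m3_agenesis) {
        rec$m3_length <- rec$m3_breadth_trigonid <- rec$m3_breadth_talonid <-
          NA_real_
        next
      }
      area <- mean_k * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog)) *
        ifelse(sex == "male", sex_f, 1 / sex_f)
      parts <- decompose_area(area, aspect[k], taper[k])
      rec[[paste0("m", k, "_length")]] <- parts$length
      rec[[paste0("m", k, "_breadth_trigonid")]] <- parts$breadth_trigonid
      rec[[paste0("m", k, "_breadth_talonid")]] <- parts$breadth_talonid
    }
    rec$body_mass_kg <- tr$body_mass_kg
    rec$diet <- tr$diet
    rec$m3_agenesis <- tr$m3_agenesis
    rows[[i]] <- rec
  }
  out <- do.call(rbind, rows)
  n_tot <- nrow(out)
  out$wear[stats::runif(n_tot) < config$wear_rate] <- "high"
  out$provenance[stats::runif(n_tot) < config$zoo_rate] <- "zoo"
  out$sex[stats::runif(n_tot) < config$indeterminate_rate] <- "indeterminate"
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic study dataset
#'
#' Tree, species traits, and specimen records in one call, with the
#' ground truth needed for parameter-recovery checks.
#'
#' @param config a [simulation_config()].
#' @return list: `tree` (`phylo`), `traits` (species-level ground truth),
#'   `specimens` (records in the [read_specimens()] schema), `config`.
#' @export
simulate_dic_dataset <- function(config = simulation_config()) {
  tree <- simulate_tree(config$n_species, config$seed)
  traits <- simulate_species_traits(tree, config)
  specimens <- simulate_specimens(traits, config)
  list(tree = tree, traits = traits, specimens = specimens, config = config)
}

#' Write a simulated dataset to disk
#'
#' Specimen CSV (the schema [read_specimens()] reads), Newick tree, and a
#' ground-truth JSON holding the configuration and per-species latents.
#'
#' @param sim output of [simulate_dic_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("specimens.csv", "tree.nwk", "ground_truth.json"))
  utils::write.csv(sim$specimens, paths[1], row.names = FALSE)
  ape::write.tree(sim$tree, paths[2])
  jsonlite::write_json(list(config = unclass(sim$config), traits = sim$traits),
                       paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Simulate data with M3 depending on M1 only through M2
#'
#' A strict reading of the cascade: first-molar size influences third-molar
#' size only through the second molar. Species M1 areas are lognormal (on
#' the tree when one is given), M2 = `a_coef` * M1 + species noise,
#' M3 = `b_coef` * M2 + `direct_coef` * M1 + species noise. With
#' `direct_coef = 0` the ground-truth proportion mediated is 1.
#'
#' @param n_species number of species.
#' @param tree optional `phylo` tree for phylogenetic structure in M1;
#'   when NULL, species are independent.
#' @param seed integer seed.
#' @param a_coef,b_coef,direct_coef path coefficients (defaults 1.1, 1.2,
#'   0).
#' @param m2_sd species-level noise sd (mm^2) on the M1-to-M2 path. This
#'   is the mediator's variation independent of M1; it must be
#'   substantial, or the between-species predictors M1 and M2 are nearly
#'   collinear and the direct and indirect paths cannot be separated by
#'   any estimator.
#' @param m3_sd species-level noise sd (mm^2) on the M2-to-M3 path.
#' @param n_specimens,specimen_cv specimen sampling as in the main
#'   generator.
#' @return list: `areas` (specimen data.frame: species, sex, m1_area,
#'   m2_area, m3_area), `truth` (the coefficients and implied pr_m).
#' @export
simulate_strict_mediation <- function(n_species = 100, tree = NULL, seed = 1,
                                      a_coef = 1.1, b_coef = 1.2,
                                      direct_coef = 0, m2_sd = 8, m3_sd = 1.5,
                                      n_specimens = 10, specimen_cv = 0.05) {
  set.seed(seed + 3L)
  if (is.null(tree)) {
    m1 <- exp(stats::rnorm(n_species, log(30), 0.4))
    species <- sprintf("sp%03d", seq_len(n_species))
  } else {
    n_species <- length(tree$tip.label)
    m1 <- exp(rmvn_pagel(tree, log(30), 0.4, 1))
    species <- tree$tip.label
  }
  m2 <- a_coef * m1 + stats::rnorm(n_species, 0, m2_sd)
  m3 <- b_coef * m2 + direct_coef * m1 + stats::rnorm(n_species, 0, m3_sd)
  m2 <- pmax(m2, 1e-3); m3 <- pmax(m3, 1e-3)
  sdlog <- sqrt(log(1 + specimen_cv^2))
  idx <- rep(seq_len(n_species), each = n_specimens)
  noise <- function() exp(stats::rnorm(length(idx), -sdlog^2 / 2, sdlog))
  areas <- data.frame(
    species = species[idx],
    sex = rep(c("male", "female"), length.out = length(idx)),
    m1_area = m1[idx] * noise(), m2_area = m2[idx] * noise(),
    m3_area = m3[idx] * noise())
  indirect <- b_coef * a_coef
  truth <- list(a_coef = a_coef, b_coef = b_coef, direct_coef = direct_coef,
                pr_m = indirect / (indirect + abs(direct_coef)))
  list(areas = areas, truth = truth)
}

#' Simulate a polymorphic human third-molar agenesis sample
#'
#' Individuals across several populations, a fraction with congenitally
#' missing third molars, with M2/M1 proportions drawn around group means
#' plus i.i.d. population offsets. Defaults mirror a 66-individual,
#' 6-population sample.
#'
#' @param n_individuals,n_populations sample shape.
#' @param group_means named numeric: `agenesis` and `retained` mean M2/M1.
#' @param agenesis_rate fraction of individuals with agenesis.
#' @param population_sd,individual_sd standard deviations of population
#'   offsets and individual deviates.
#' @param seed integer seed.
#' @return data.frame: `individual`, `population`, `m3_agenesis`, `m2m1`.
#' @export
simulate_human_agenesis <- function(n_individuals = 66, n_populations = 6,
                                    group_means = c(agenesis = 0.92,
                                                    retained = 0.95),
                                    agenesis_rate = 0.3,
                                    population_sd = 0.02, individual_sd = 0.05,
                                    seed = 1) {
  stopifnot(all(group_means > 0))
  set.seed(seed + 4L)
  pop <- rep(sprintf("pop%d", seq_len(n_populations)),
             length.out = n_individuals)
  offsets <- stats::rnorm(n_populations, 0, population_sd)
  agen <- stats::runif(n_individuals) < agenesis_rate
  mu <- ifelse(agen, group_means[["agenesis"]], group_means[["retained"]])
  m2m1 <- mu + offsets[as.integer(factor(pop, levels = unique(pop)))] +
    stats::rnorm(n_individuals, 0, individual_sd)
  data.frame(individual = sprintf("ind%03d", seq_len(n_individuals)),
             population = pop, m3_agenesis = agen, m2m1 = m2m1)
}
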
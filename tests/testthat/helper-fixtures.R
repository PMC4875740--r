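# shared fixtures, all generated in code

short_schedule <- function(iterations = 6000, burn_in = 1000, thin = 5,
                           family = "gaussian") {
  mcmc_schedule(iterations, burn_in, thin, family = family)
}

# a small clean simulated study (no filter-exercising contamination)
clean_sim <- function(seed = 42, n_species = 40, n_specimens = 8, ...) {
  cfg <- simulation_config(n_species = n_species, n_specimens = n_specimens,
                           wear_rate = 0, zoo_rate = 0,
                           indeterminate_rate = 0, seed = seed, ...)
  simulate_dic_dataset(cfg)
}

# hand-built specimen records with known filter outcomes
specimen_fixture <- function() {
  base <- function(species, sex, wear = "acceptable", provenance = "wild",
                   drop_m3 = FALSE) {
    r <- data.frame(species = species, sex = sex, wear = wear,
                    provenance = provenance)
    for (k in 1:3) {
      r[[paste0("m", k, "_length")]] <- 10 + k
      r[[paste0("m", k, "_breadth_trigonid")]] <- 8
      r[[paste0("m", k, "_breadth_talonid")]] <- 7
    }
    if (drop_m3)
      r$m3_length <- r$m3_breadth_trigonid <- r$m3_breadth_talonid <- NA_real_
    r
  }
  rbind(
    base("A", "male"), base("A", "female"), base("A", "male"),
    base("A", "female"),
    base("A", "male", wear = "high"), base("A", "female", wear = "high"),
    base("A", "male", provenance = "zoo"),
    base("B", "male"), base("B", "female"), base("B", "male"),
    base("B", "female"), base("B", "male", drop_m3 = TRUE),
    base("C", "male"), base("C", "female"), base("C", "indeterminate"))
}
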
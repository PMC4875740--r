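#' MCMC schedule
#'
#' Named presets: `"fast"` (desk-scale) retains 10,000 draws from
#' 1.1e5 iterations (Gaussian; 1.5e5 for Bernoulli), while `"paper"` uses
#' the long schedules (1.1e7 iterations, 1e6 burn-in, thin 1000 for
#' Gaussian; 1.5e7, 3e6, 1200 for Bernoulli), which also retain exactly
#' 10,000 draws.
#'
#' @param iterations,burn_in,thin integers; `burn_in < iterations`,
#'   `thin >= 1`, and `iterations - burn_in` divisible by `thin`. Or pass
#'   a preset name as `iterations`.
#' @param family model family the preset applies to.
#' @return an `mcmc_schedule` list.
#' @export
mcmc_schedule <- function(iterations, burn_in = NULL, thin = NULL,
                          family = c("gaussian", "bernoulli")) {
  family <- match.arg(family)
  if (is.character(iterations)) {
    preset <- match.arg(iterations, c("fast", "paper"))
    vals <- switch(paste(preset, family),
      "fast gaussian"   = c(1.1e5, 1e4, 10),
      "fast bernoulli"  = c(1.5e5, 3e4, 12),
      "paper gaussian"  = c(1.1e7, 1e6, 1000),
      "paper bernoulli" = c(1.5e7, 3e6, 1200))
    iterations <- vals[1]; burn_in <- vals[2]; thin <- vals[3]
  }
  stopifnot(burn_in >= 0, burn_in < iterations, thin >= 1,
            (iterations - burn_in) %% thin == 0)
  structure(list(iterations = as.double(iterations),
                 burn_in = as.double(burn_in), thin = as.double(thin)),
            class = "mcmc_schedule")
}

#' Retained posterior draws implied by a schedule
#'
#' @param schedule an [mcmc_schedule()].
#' @return `(iterations - burn_in) / thin`.
#' @export
retained_draw_count <- function(schedule) {
  (schedule$iterations - schedule$burn_in) / schedule$thin
}

#' Prior specification for a PGLMM
#'
#' Defaults follow the model's stated priors: Gaussian fixed effects get
#' independent normal(0, 1e8) priors; Bernoulli fixed effects get a
#' Cauchy(0, scale) prior with scale pi^2/3 plus the current random-effect
#' variance (re-evaluated each MCMC iteration). Random effects use
#' parameter-expanded priors with scale 1, degree of belief 1, and a
#' working parameter with mean 0 and variance 1e3. The Gaussian residual
#' variance gets a weakly informative inverse-gamma (V = 1, nu = 0.002);
#' the Bernoulli residual variance is fixed at pi^2/3.
#'
#' @param family model family.
#' @param beta_prior_var normal prior variance for Gaussian fixed effects.
#' @param px_alpha_var working-parameter prior variance.
#' @param px_nu,px_V degree of belief and scale of the base variance prior.
#' @param resid_nu,resid_V residual variance prior (Gaussian family).
#' @return a `pglmm_priors` list.
#' @export
pglmm_priors <- function(family = c("gaussian", "bernoulli"),
                         beta_prior_var = 1e8, px_alpha_var = 1e3,
                         px_nu = 1, px_V = 1,
                         resid_nu = 0.002, resid_V = 1) {
  family <- match.arg(family)
  structure(list(family = family, beta_prior_var = beta_prior_var,
                 px_alpha_var = px_alpha_var, px_nu = px_nu, px_V = px_V,
                 resid_nu = resid_nu, resid_V = resid_V),
            class = "pglmm_priors")
}

#' Split a specimen-level predictor into between and within components
#'
#' Within-group centering: each predictor is decomposed into the species
#' mean (broadcast to its specimens; the between-species component) and
#' the deviation of each specimen from that mean (the within-species
#' component). The within component sums to zero inside every group, so
#' the two slopes separate inter- from intra-specific effects.
#'
#' @param values numeric specimen-level predictor.
#' @param groups species label per specimen.
#' @return list with `between` and `within` numeric vectors, same length
#'   as `values`.
#' @export
center_within_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups), !anyNA(groups))
  groups <- as.character(groups)
  means <- tapply(values, groups, mean)
  between <- as.numeric(means[groups])
  list(between = between, within = values - between)
}

#' Fit a Bayesian phylogenetic generalized linear mixed model
#'
#' Gaussian (identity link) or Bernoulli (logit link) mixed model with
#' optional phylogenetically correlated (`p`) and i.i.d. (`s`) species
#' random intercepts, sampled by MCMC. The Gaussian family uses blocked
#' Gibbs updates (all location effects jointly from their multivariate
#' normal full conditional; variance components from inverse-gamma full
#' conditionals under parameter-expanded priors). The Bernoulli family
#' augments with a latent logistic variable (residual variance fixed at
#' pi^2/3) updated by slice sampling.
#'
#' @param y numeric response (0/1 for Bernoulli).
#' @param X fixed-effect design matrix (include the intercept column
#'   explicitly if wanted).
#' @param species species (or other grouping) label per observation.
#' @param Sigma scaled phylogenetic covariance matrix with dimnames
#'   covering all species; required when `"phylo" %in% random`.
#' @param family `"gaussian"` or `"bernoulli"`.
#' @param random random-intercept terms: any of `"phylo"`, `"species"`.
#'   `"species"` with a non-phylogenetic grouping factor gives the plain
#'   i.i.d. group intercept (e.g. human populations).
#' @param schedule an [mcmc_schedule()] or preset name.
#' @param priors a [pglmm_priors()].
#' @param seed integer seed (mandatory; all stochastic outputs record it).
#' @param sigma_e_fixed optionally fix the Gaussian residual variance
#'   (used by conjugate-oracle checks).
#' @param fixed_sigma2_p,fixed_sigma2_s optionally fix a random-effect
#'   variance instead of sampling it.
#' @return an object of class `pglmm`: list with `draws` (matrix, one
#'   column per parameter plus `sigma2_p`, `sigma2_s`, `sigma2_e`,
#'   `lambda`), `family`, `schedule`, `seed`, `species_levels`.
#' @export
pglmm_fit <- function(y, X, species, Sigma = NULL,
                      family = c("gaussian", "bernoulli"),
                      random = c("phylo", "species"),
                      schedule = "fast", priors = NULL, seed,
                      sigma_e_fixed = NULL,
                      fixed_sigma2_p = NULL, fixed_sigma2_s = NULL) {
  family <- match.arg(family)
  if (missing(seed)) stop("a seed is required for every fit")
  if (is.character(schedule) || !inherits(schedule, "mcmc_schedule"))
    schedule <- mcmc_schedule(schedule, family = family)
  if (is.null(priors)) priors <- pglmm_priors(family)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("beta", seq_len(ncol(X)) - 1)
  stopifnot(length(y) == nrow(X), length(species) == nrow(X))
  has_phylo <- "phylo" %in% random
  has_species <- "species" %in% random
  species <- as.character(species)
  levels <- sort(unique(species))
  sp_idx <- match(species, levels) - 1L

  Sigma_inv <- matrix(0, 0, 0)
  if (has_phylo) {
    if (is.null(Sigma)) stop("phylo random term requires a covariance matrix")
    if (!all(levels %in% rownames(Sigma)))
      stop("covariance matrix does not cover species: ",
           paste(setdiff(levels, rownames(Sigma)), collapse = ", "))
    S <- Sigma[levels, levels, drop = FALSE]
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("phylogenetic covariance is not positive semi-definite")
    if (min(ev) < 1e-10) S <- S + diag(1e-8, nrow(S))
    Sigma_inv <- chol2inv(chol(S))
  }
  if (family == "bernoulli") {
    stopifnot(all(y %in% c(0, 1)))
    if (all(y == y[1]))
      warning("response is all-", y[1], ": complete separation; the Cauchy ",
              "prior regularizes the fit")
  }

  set.seed(seed)
  res <- .pglmm_gibbs_cpp(
    as.double(y), X, sp_idx, length(levels), Sigma_inv,
    has_phylo, has_species, if (family == "gaussian") 0L else 1L,
    if (is.null(sigma_e_fixed)) -1 else sigma_e_fixed,
    if (is.null(fixed_sigma2_p)) -1 else fixed_sigma2_p,
    if (is.null(fixed_sigma2_s)) -1 else fixed_sigma2_s,
    priors$beta_prior_var, priors$px_alpha_var, priors$px_nu, priors$px_V,
    priors$resid_nu, priors$resid_V,
    as.integer(schedule$iterations), as.integer(schedule$burn_in),
    as.integer(schedule$thin))

  draws <- res$draws
  colnames(draws) <- c(colnames(X), "sigma2_p", "sigma2_s", "sigma2_e")
  if (has_phylo) {
    lambda <- pagels_lambda(draws[, "sigma2_p"],
                            draws[, "sigma2_s"], draws[, "sigma2_e"])
    draws <- cbind(draws, lambda = lambda)
  }
  structure(list(draws = draws, family = family, schedule = schedule,
                 seed = seed, random = random, species_levels = levels),
            class = "pglmm")
}

#' @export
print.pglmm <- function(x, ...) {
  cat("Bayesian PGLMM (", x$family, "), ", nrow(x$draws),
      " retained draws, seed ", x$seed, "\n", sep = "")
  print(round(t(apply(x$draws, 2, function(d)
    c(mean = mean(d), hdi(d)))), 4))
  invisible(x)
}

#' Highest density interval of posterior draws
#'
#' Shortest contiguous interval over the sorted draws containing
#' `ceiling(mass * n)` of them (assumes unimodality; a multimodal set of
#' draws triggers a warning-free but potentially misleading interval).
#'
#' @param draws numeric vector of at least 100 posterior draws.
#' @param mass interval probability mass in (0, 1).
#' @return named numeric vector `c(lower = , upper = )`.
#' @export
hdi <- function(draws, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  n <- length(draws)
  if (n < 100) stop("hdi needs at least 100 draws")
  sorted <- sort(draws)
  k <- ceiling(mass * n)
  widths <- sorted[k:n] - sorted[1:(n - k + 1)]
  i <- which.min(widths)
  c(lower = sorted[i], upper = sorted[i + k - 1])
}

#' Posterior probability inside a region of practical equivalence
#'
#' Fraction of posterior draws inside the closed interval `rope`. A ROPE
#' encloses parameter values negligibly different, for practical purposes,
#' from a theoretical point prediction; the probability mass inside it is
#' the decision statistic for whether that prediction is credible.
#'
#' @param draws numeric vector of posterior draws.
#' @param rope length-2 numeric, `rope[1] < rope[2]`.
#' @return probability in [0, 1].
#' @export
rope_probability <- function(draws, rope) {
  stopifnot(length(rope) == 2, rope[1] < rope[2])
  mean(draws >= rope[1] & draws <= rope[2])
}

#' Posterior summary of a draw vector
#'
#' Mean, 95% HDI, and optionally the posterior probability inside a ROPE.
#'
#' @param draws numeric posterior draws.
#' @param rope optional length-2 interval.
#' @param mass HDI mass.
#' @return named list `mean`, `hdi` (length 2), `rope_prob` (or NA).
#' @export
posterior_summary <- function(draws, rope = NULL, mass = 0.95) {
  list(mean = mean(draws), hdi = hdi(draws, mass),
       rope_prob = if (is.null(rope)) NA_real_ else rope_probability(draws, rope))
}

# limiting distribution function of the Cramer-von Mises statistic
# (series expansion with Bessel K terms)
pcvm <- function(q) {
  if (q <= 0) return(0)
  k <- 0:3
  u <- (4 * k + 1)^2 / (16 * q)
  terms <- ifelse(u > 700, 0,
                  exp(lgamma(k + 0.5) - lgamma(k + 1)) *
                    sqrt(4 * k + 1) * exp(-u) * besselK(u, 0.25))
  min(1, max(0, sum(terms) / (pi^1.5 * sqrt(q))))
}

spectrum0_ar <- function(x) {
  # spectral density at frequency zero via an AIC-selected AR fit
  fit <- stats::ar(x, aic = TRUE, order.max = min(30, length(x) %/% 4))
  if (length(fit$ar) == 0) return(stats::var(x))
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Heidelberger and Welch stationarity diagnostic
#'
#' Tests whether an MCMC chain has reached a stationary distribution:
#' a Cramer-von Mises statistic is computed on the standardized cumulative
#' sums (Brownian-bridge functional) of the chain, using an AR-based
#' estimate of the spectral density at zero; if the test rejects, the
#' initial 10% of the chain is discarded and the test repeated, up to half
#' the chain.
#'
#' @param draws numeric chain of at least 200 values.
#' @param pvalue rejection level.
#' @return list: `passed` (logical), `p_value` (of the final kept
#'   segment), `start` (first retained index).
#' @export
heidelberger_welch <- function(draws, pvalue = 0.05) {
  n0 <- length(draws)
  if (n0 < 200) stop("heidelberger_welch needs at least 200 draws")
  if (stats::var(draws) == 0)
    return(list(passed = TRUE, p_value = 1, start = 1L))
  s0 <- spectrum0_ar(draws[(n0 %/% 2):n0])
  for (frac in seq(0, 0.5, by = 0.1)) {
    start <- 1L + as.integer(frac * n0)
    x <- draws[start:n0]
    n <- length(x)
    S <- cumsum(x)
    t_idx <- seq_len(n)
    B <- (S - t_idx * mean(x)) / sqrt(n * s0)
    cvm <- sum(B^2) / n
    p <- 1 - pcvm(cvm)
    if (p > pvalue) return(list(passed = TRUE, p_value = p, start = start))
  }
  list(passed = FALSE, p_value = p, start = start)
}

#' Sample autocorrelation of a chain at a given lag
#'
#' @param draws numeric chain.
#' @param lag positive integer, less than half the chain length.
#' @return autocorrelation in [-1, 1].
#' @export
lag_autocorrelation <- function(draws, lag = 1) {
  n <- length(draws)
  stopifnot(lag >= 1, lag < n / 2)
  if (stats::var(draws) == 0) return(0)
  m <- mean(draws)
  sum((draws[1:(n - lag)] - m) * (draws[(1 + lag):n] - m)) /
    sum((draws - m)^2)
}

#' Convergence report for a fitted PGLMM
#'
#' Heidelberger-Welch stationarity and lag-1 autocorrelation per recorded
#' parameter. Chains were considered converged when the diagnostic passes
#' and autocorrelation is below 0.1.
#'
#' @param fit a `pglmm` object.
#' @return data.frame: parameter, hw_passed, hw_p_value, lag1_autocorr.
#' @export
convergence_report <- function(fit) {
  pars <- colnames(fit$draws)
  rows <- lapply(pars, function(p) {
    d <- fit$draws[, p]
    hw <- heidelberger_welch(d)
    data.frame(parameter = p, hw_passed = hw$passed,
               hw_p_value = hw$p_value,
               lag1_autocorr = lag_autocorrelation(d, 1))
  })
  do.call(rbind, rows)
}

#' Write posterior draws and fit metadata to disk
#'
#' Draws go to a plain CSV (one column per parameter); schedule, seed,
#' family and the convergence report go to a JSON sidecar.
#'
#' @param fit a `pglmm` object.
#' @param path output CSV path; the sidecar gets extension `.json`.
#' @return invisibly, the two paths written.
#' @export
write_pglmm <- function(fit, path) {
  utils::write.csv(as.data.frame(fit$draws), path, row.names = FALSE)
  side <- sub("\\.csv$", "", path)
  side <- paste0(side, ".json")
  meta <- list(family = fit$family, seed = fit$seed,
               schedule = unclass(fit$schedule), random = fit$random,
               convergence = convergence_report(fit))
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}
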
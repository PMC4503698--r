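# Shared fixtures: everything is generated in code, no files shipped.

# Parameter list without the constructor's probability checks, for
# boundary cases (d = 1, p = 0) used by oracle tests.
raw_params <- function(...) {
  p <- unclass(true_parameters())
  override <- list(...)
  p[names(override)] <- override
  p
}

# A small but complete study design that keeps fits to a couple of
# seconds: 16 SET1, 10 SET2, 4 + 4 SET3, 10 x 4 detection panel.
tiny_config <- function(seed = NULL) {
  generator_config(n_set1 = 16, n_set2 = 10, n_set3_restored = 4,
                   n_set3_unrestored = 4, n_detection_sites = 10,
                   seed = seed)
}

tiny_dataset <- function(seed = 11, params = true_parameters()) {
  sim <- simulate_dataset(params, tiny_config(seed = seed))
  det <- simulate_detection_study(params, tiny_config(seed = seed + 1))
  ds <- sim$dataset
  ds$detection <- det$detection
  ds
}

fast_mcmc <- function(seed = 1, n_chains = 2, n_burnin = 400,
                      n_samples = 800) {
  mcmc_config(n_chains = n_chains, n_burnin = n_burnin,
              n_samples = n_samples, seed = seed)
}

# A synthetic SET1 site at average covariates whose only observation is
# the 2008 count: its marginal is the single-site-year mixture
# (1-psi) 1[y=0] + psi [(1-p) 1[y=0] + p sum_N ZTP Binom].
site_2008_only <- function(y) {
  list(set = "SET1", work = 0, dist_s = 0, tree_s_1995 = 0, tree_s_2008 = 0,
       y_1995 = NA, y_2008 = y, y_2009 = NA)
}

# Parameters with a prescribed (psi, p, d, lambda) for that site.
params_for_site_year <- function(psi, p, d, lambda) {
  raw_params(c = qlogis(psi), gamma1 = 0, gamma2 = 0, gamma3 = 0,
             alpha = log(lambda), beta1 = 0, beta2 = 0, beta3 = 0,
             beta4 = 0, p = p, d = d, sigma_eps = 0)
}

# Degenerate posterior_samples carrying prescribed constant draws, for
# reporting-layer arithmetic tests.
constant_samples <- function(values, n = 50, n_chains = 2) {
  pars <- names(values)
  draws <- array(rep(unlist(values), each = n * n_chains),
                 c(n, n_chains, length(pars)),
                 dimnames = list(NULL, NULL, pars))
  structure(list(draws = draws, parameters = setdiff(pars, "deviance"),
                 variant = model_variant("M2"), config = NULL),
            class = "posterior_samples")
}
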
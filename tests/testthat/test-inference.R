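test_that("rhat implements the split-chain PSRF", {
  set.seed(3)
  one <- rnorm(1000)
  ident <- cbind(one, one)
  n <- nrow(ident)  # identical chains: B = 0, PSRF = sqrt((n-1)/n)
  expect_equal(rhat(ident, split = FALSE), sqrt((n - 1) / n),
               tolerance = 1e-10)
  expect_lt(abs(rhat(ident) - 1), 0.01)  # split variant stays ~1

  same <- cbind(rnorm(10000), rnorm(10000), rnorm(10000))
  expect_lt(rhat(same), 1.01)

  disjoint <- cbind(rnorm(2000, 0, 1), rnorm(2000, 10, 1))
  expect_gt(rhat(disjoint), 2)

  samp <- constant_samples(list(alpha = 1, deviance = 0), n = 100,
                           n_chains = 1)
  expect_error(rhat(samp), "2 chains")
})

test_that("summarize returns the posterior median and central 95% interval", {
  samp <- constant_samples(list(alpha = 3.2, deviance = 0))
  expect_equal(unname(summarize(samp, "alpha")), c(3.2, 3.2, 3.2))
  expect_error(summarize(samp, "nope"), "unknown parameter")

  set.seed(5)
  x <- rnorm(1e6)
  samp$draws <- array(x, c(5e5, 2, 1), dimnames = list(NULL, NULL, "alpha"))
  s <- summarize(samp, "alpha")
  expect_lt(abs(s["median"]), 0.01)
  expect_lt(abs(s["lower95"] + 1.96), 0.01)
  expect_lt(abs(s["upper95"] - 1.96), 0.01)

  # invariant to chain order
  samp2 <- samp
  samp2$draws <- samp$draws[, 2:1, , drop = FALSE]
  dimnames(samp2$draws)[[3]] <- "alpha"
  expect_equal(summarize(samp2, "alpha"), s)
})

test_that("fit is reproducible and enforces its contracts", {
  ds <- tiny_dataset(seed = 101)
  cfg <- fast_mcmc(seed = 5, n_burnin = 100, n_samples = 150)
  f1 <- fit(ds, "M2", cfg)
  f2 <- fit(ds, "M2", cfg)
  expect_identical(f1$draws, f2$draws)
  expect_setequal(
    f1$parameters,
    c("c", "c_set2", "gamma1", "gamma2", "gamma3", "alpha",
      paste0("beta", c(1:4, 6:7)), "sigma_eps", "p", "d"))

  # empty dataset is a configuration error unless sampling the prior
  empty <- study_dataset(restocc:::empty_sites())
  expect_error(fit(empty, "M2", cfg), "configuration error")

  # p and d are only identified via repeated counts
  no_det <- ds
  no_det$detection <- NULL
  expect_error(fit(no_det, "M2", cfg), "repeated-count")
  f3 <- fit(no_det, "M2", cfg, fixed = list(p = 0.8, d = 0.9))
  expect_false("p" %in% f3$parameters)
  expect_true(all(is.finite(f3$draws[, , "deviance"])))
})

test_that("M1 drops the random effect and M4 adds beta5", {
  ds <- tiny_dataset(seed = 102)
  cfg <- fast_mcmc(seed = 6, n_burnin = 100, n_samples = 100)
  f1 <- fit(ds, "M1", cfg)
  expect_false("sigma_eps" %in% f1$parameters)
  f4 <- fit(ds, "M4", cfg)
  expect_true("beta5" %in% f4$parameters)
})

test_that("posterior equals prior when the likelihood is switched off", {
  # quick version of the prior-recovery acceptance criterion
  cfg <- mcmc_config(n_chains = 2, n_burnin = 500, n_samples = 4000,
                     seed = 9)
  f <- fit(NULL, "M2", cfg, prior_only = TRUE)
  a <- draws_of(f, "alpha")
  expect_lt(abs(median(a)), 25)            # Normal(0, 100) median 0
  s <- draws_of(f, "sigma_eps")
  expect_true(all(s >= 0 & s <= 10))       # Uniform(0, 10) support
  p <- draws_of(f, "p")
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(abs(median(p) - 0.5), 0.1)
})

test_that("the transition kernel leaves the model joint invariant", {
  # Geweke-style successive-conditional check: alternate a few MCMC
  # updates with re-simulation of the data given the current parameters.
  # If the kernel targets the right posterior, the marginal over cycles
  # equals the prior.  Run with narrowed priors so re-simulated data
  # stay in a sane regime, and only alpha, sigma_eps, p, d free.
  priors <- default_priors()
  priors$alpha <- list(type = "normal", a = 1.3, b = 0.25)
  priors$sigma_eps <- list(type = "uniform", a = 0, b = 0.6)
  priors$p <- list(type = "uniform", a = 0.5, b = 0.95)
  priors$d <- list(type = "uniform", a = 0.6, b = 0.95)
  pm <- restocc:::priors_to_matrix(priors)
  truth <- true_parameters()
  fixed <- setdiff(restocc:::PARAM_NAMES,
                   c("alpha", "sigma_eps", "p", "d"))
  upd <- setNames(restocc:::PARAM_NAMES %in% c("alpha", "sigma_eps", "p", "d"),
                  restocc:::PARAM_NAMES)
  cfg <- generator_config(n_set1 = 10, n_set2 = 5, n_set3_restored = 3,
                          n_set3_unrestored = 3, n_detection_sites = 6)
  n_sites <- cfg$n_set1 + cfg$n_set2 + cfg$n_set3

  set.seed(1234)
  n_cycles <- 500
  state <- unlist(truth[restocc:::PARAM_NAMES])
  state["alpha"] <- 1.3; state["sigma_eps"] <- 0.3
  state["p"] <- 0.7; state["d"] <- 0.8
  eps_state <- rnorm(n_sites, 0, state["sigma_eps"])
  out <- matrix(NA_real_, n_cycles, 4,
                dimnames = list(NULL, c("alpha", "sigma_eps", "p", "d")))
  for (cy in seq_len(n_cycles)) {
    pars <- as.list(state)
    sim <- simulate_dataset(pars, cfg)  # config seed NULL: continue stream
    det <- simulate_detection_study(pars, cfg)
    ds <- sim$dataset
    ds$detection <- det$detection
    # the data step re-draws (eps, y) jointly given the globals, so the
    # sampler state must pick up the freshly drawn random effects
    eps_state <- sim$latent$eps[match(ds$sites$site_id,
                                      sim$latent$site_id)]
    md <- restocc:::prepare_model_data(ds, model_variant("M2"), 50)
    res <- restocc:::cpp_fit_chain(md, pm, state, upd, 4L, 1L, 1L,
                                   FALSE, TRUE, 0, eps_state)
    state[] <- res$draws[1, 1:16]
    out[cy, ] <- state[c("alpha", "sigma_eps", "p", "d")]
  }

  # cycles are autocorrelated; assume conservatively ~n/10 effective draws
  n_eff <- n_cycles / 10
  expect_lt(abs(mean(out[, "alpha"]) - 1.3), 5 * 0.25 / sqrt(n_eff))
  expect_lt(abs(mean(out[, "sigma_eps"]) - 0.3),
            5 * (0.6 / sqrt(12)) / sqrt(n_eff))
  expect_lt(abs(mean(out[, "p"]) - 0.725), 5 * (0.45 / sqrt(12)) / sqrt(n_eff))
  expect_lt(abs(mean(out[, "d"]) - 0.775), 5 * (0.35 / sqrt(12)) / sqrt(n_eff))
  # quartiles of the uniform-prior parameters
  expect_lt(abs(quantile(out[, "p"], 0.5) - 0.725), 0.08)
  expect_lt(abs(quantile(out[, "sigma_eps"], 0.5) - 0.3), 0.1)
})

test_that("compare_models ranks variants by posterior mean deviance", {
  ds <- tiny_dataset(seed = 103)
  cfg <- fast_mcmc(n_chains = 1, seed = 10, n_burnin = 300, n_samples = 600)
  tab <- compare_models(ds, c("M2", "M4"), cfg)
  expect_equal(sort(tab$variant), c("M2", "M4"))
  expect_true(all(diff(tab$mean_deviance) >= 0))
  # data simulated with beta5 = 0: the nested variants agree within noise
  expect_lt(abs(diff(tab$mean_deviance)), 2 * max(tab$sd_deviance))
  expect_error(compare_models(ds, "M2", cfg), "two variants")
})
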
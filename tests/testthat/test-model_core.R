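test_that("zero-truncated Poisson pmf and mean match closed forms", {
  expect_equal(ztpois_logpmf(1, 1), log(exp(-1) / (1 - exp(-1))),
               tolerance = 1e-12)
  for (lam in c(0.1, 1, 5, 20)) {
    expect_lt(abs(sum(exp(ztpois_logpmf(1:500, lam))) - 1), 1e-8)
  }
  # numerical stability at the extremes (absolute error; value is ~0)
  expect_lt(abs(ztpois_logpmf(1, 1e-10) -
                  (log(1e-10) - 1e-10 - log(-expm1(-1e-10)))), 1e-10)
  expect_true(is.finite(ztpois_logpmf(750, 750)))

  expect_equal(ztpois_mean(1), 1.58198, tolerance = 1e-5)
  expect_lt(abs(ztpois_mean(20) - 20) / 20, 1e-8)
  expect_equal(ztpois_mean(1e-12), 1, tolerance = 1e-6)

  expect_error(ztpois_logpmf(0, 2), "n >= 1")
  expect_error(ztpois_mean(0), "positive")
  expect_error(ztpois_logpmf(1, -1), "positive")
})

test_that("rztpois is supported on n >= 1 with the truncated mean", {
  set.seed(2)
  x <- rztpois(2e4, 0.5)
  expect_true(all(x >= 1))
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - ztpois_mean(0.5)), 4 * se)
})

test_that("occupancy_probability is the stated logit-linear model", {
  p0 <- raw_params(c = 0, c_set2 = 0, gamma1 = 0, gamma2 = 0, gamma3 = 0)
  expect_equal(occupancy_probability(p0, 1.2, -0.4, 1, "SET1"), 0.5)

  p1 <- raw_params(c = 0.4263)
  expect_equal(occupancy_probability(p1, 0, 0, 0, "SET1"), 0.605,
               tolerance = 1e-3)

  # monotone decreasing in distance when gamma1 < 0
  p2 <- raw_params(gamma1 = -0.7)
  d <- seq(-1, 1, length.out = 9)
  psi <- occupancy_probability(p2, d, 0, 0, "SET1")
  expect_true(all(diff(psi) < 0))

  # SET2 intercept-only variant ignores covariates
  p3 <- raw_params(c_set2 = 1, gamma1 = -5)
  expect_equal(occupancy_probability(p3, 0.9, 0, 0, "SET2", set2_linear = FALSE),
               plogis(1))
  expect_lt(occupancy_probability(p3, 0.9, 0, 0, "SET2", set2_linear = TRUE),
            plogis(1))
})

test_that("group_size_mean implements the per-stratum log-linear submodels", {
  zero <- raw_params(alpha = 0, beta1 = 0, beta2 = 0, beta3 = 0, beta4 = 0,
                     beta5 = 0, beta6 = 0, beta7 = 0)
  for (yr in c(1995, 2008, 2009)) {
    expect_equal(group_size_mean(zero, "M2", "SET1", yr, 0.3, -0.2, 1, 0), 1)
  }
  expect_equal(group_size_mean(zero, "M2", "SET3", 2008, work = 1), 1)

  p <- raw_params(alpha = log(4.5))
  expect_equal(group_size_mean(p, "M2", "SET1", 1995, 0, 0, 0, 0), 4.5)

  p <- raw_params(beta4 = log(1.22))
  r <- group_size_mean(p, "M2", "SET1", 2008, 0, 0, work = 1) /
    group_size_mean(p, "M2", "SET1", 2008, 0, 0, work = 0)
  expect_equal(r, 1.22)

  # exact log-linearity: a covariate shift multiplies the rate
  p <- true_parameters()
  l1 <- group_size_mean(p, "M2", "SET1", 2008, 0.4, 0.1, 1, 0.2)
  l2 <- group_size_mean(p, "M2", "SET1", 2008, 0.4 + 1, 0.1, 1, 0.2)
  expect_equal(l2 / l1, exp(p$beta1))

  # SET3 2009 chains off the 2008 rate
  l2008 <- group_size_mean(p, "M2", "SET3", 2008, work = 1, eps = 0.3)
  l2009 <- group_size_mean(p, "M2", "SET3", 2009, work = 1, eps = 0.3)
  expect_equal(l2009, l2008 * exp(p$beta6 + p$beta7))

  # beta5 enters every year under M4 only
  p <- raw_params(beta5 = 0.5)
  expect_equal(group_size_mean(p, "M4", "SET1", 1995, 0, 0, 1) /
                 group_size_mean(p, "M2", "SET1", 1995, 0, 0, 1), exp(0.5))

  expect_error(group_size_mean(p, "M2", "SET3", 1995, work = 1), "1995")
  expect_error(group_size_mean(p, "M2", "SET2", 1995, 0, 0, 0), "SET2")
  expect_error(group_size_mean(p, "M2", "SET1", 2008, NULL, NULL, 1),
               "required")
})

test_that("observation_logprob is Binomial(N, d A)", {
  expect_equal(observation_logprob(3, 3, 1, 1), 0)
  expect_equal(observation_logprob(2, 5, 0, 0.9), -Inf)
  expect_equal(observation_logprob(2, 4, 1, 0.5), log(6 * 0.0625),
               tolerance = 1e-10)
  expect_error(observation_logprob(5, 4, 1, 0.5), "\\[0, N\\]")
  expect_error(observation_logprob(0, 0, 1, 0.5), "N must be")
})

test_that("site_marginal_loglik matches hand marginalizations", {
  # SET1 2008 zero count with perfect individual detection:
  # P = (1-psi) + psi (1-p); psi = 0.5, p = 0.8 -> 0.6
  pr <- params_for_site_year(psi = 0.5, p = 0.8, d = 1, lambda = 4)
  expect_equal(site_marginal_loglik(site_2008_only(0), pr), log(0.6),
               tolerance = 1e-10)

  # p = d = 1: mixture of a point mass at 0 and the ZTPois pmf
  pr <- params_for_site_year(psi = 0.35, p = 1, d = 1, lambda = 2.5)
  for (y in 0:6) {
    expected <- if (y == 0) 1 - 0.35 else
      0.35 * exp(ztpois_logpmf(y, 2.5))
    expect_equal(exp(site_marginal_loglik(site_2008_only(y), pr)),
                 expected, tolerance = 1e-10)
  }

  expect_error(site_marginal_loglik(site_2008_only(8), pr, n_max = 5),
               "n_max")
})

test_that("site marginals normalize over the count support", {
  set.seed(9)
  for (i in 1:6) {
    psi <- runif(1, 0.1, 0.95)
    p <- runif(1, 0.3, 1)
    d <- runif(1, 0.3, 1)
    lam <- runif(1, 0.5, 8)
    pr <- params_for_site_year(psi, p, d, lam)
    tot <- sum(vapply(0:50, function(y) {
      exp(site_marginal_loglik(site_2008_only(y), pr))
    }, numeric(1)))
    expect_lt(abs(tot - 1), 1e-8)

    # SET3 (available by design) normalizes over y >= 0 too
    site3 <- list(set = "SET3", work = 1, y_1995 = NA, y_2008 = 1,
                  y_2009 = NA)
    tot3 <- sum(vapply(0:50, function(y) {
      s <- site3; s$y_2008 <- y
      exp(site_marginal_loglik(s, pr))
    }, numeric(1)))
    expect_lt(abs(tot3 - 1), 1e-8)
  }
})

test_that("the C++ likelihood agrees with the R enumeration oracle", {
  params <- true_parameters()
  sim <- simulate_dataset(params, tiny_config(seed = 51))
  det <- simulate_detection_study(params, tiny_config(seed = 52))
  ds <- sim$dataset
  ds$detection <- det$detection
  md <- restocc:::prepare_model_data(ds, model_variant("M2"), 50)
  set.seed(53)
  eps <- rnorm(nrow(ds$sites), 0, 0.3)

  r_ll <- 0
  for (i in seq_len(nrow(ds$sites))) {
    s <- ds$sites[i, ]
    site <- list(set = s$set, work = s$work, dist_s = md$dist_s[i],
                 tree_s_1995 = md$tree1_s[i], tree_s_2008 = md$tree2_s[i],
                 y_1995 = s$y_1995, y_2008 = s$y_2008, y_2009 = s$y_2009)
    r_ll <- r_ll + site_marginal_loglik(site, params, "M2", eps = eps[i])
  }
  # independent R-side detection-panel marginal: shared N within a site,
  # availability independent per visit
  lam <- exp(params$alpha + params$beta3)
  for (s in seq_len(nrow(ds$detection))) {
    y <- as.numeric(ds$detection[s, -1])
    lik_n <- exp(ztpois_logpmf(1:50, lam))
    per_visit <- vapply(1:50, function(N) {
      prod((1 - params$p) * (y == 0) + params$p * dbinom(y, N, params$d))
    }, numeric(1))
    r_ll <- r_ll + log(sum(lik_n * per_visit))
  }

  th <- unlist(params[restocc:::PARAM_NAMES])
  expect_equal(restocc:::cpp_total_loglik(md, th, eps), r_ll,
               tolerance = 1e-8)
})

test_that("log_prior applies the stated prior families", {
  p <- raw_params(c = 0, c_set2 = 0, gamma1 = 0, gamma2 = 0, gamma3 = 0,
                  alpha = 0, beta1 = 0, beta2 = 0, beta3 = 0, beta4 = 0,
                  beta5 = 0, beta6 = 0, beta7 = 0, sigma_eps = 1,
                  p = 0.5, d = 0.5)
  # Cauchy(0,10) intercept + 3 x Cauchy(0,2.5) + 9 x Normal(0,100)
  # + Uniform(0,10) + 2 x Uniform(0,1); M2 drops beta5
  expected <- dcauchy(0, 0, 10, log = TRUE) +
    3 * dcauchy(0, 0, 2.5, log = TRUE) +
    8 * dnorm(0, 0, 100, log = TRUE) +
    -log(10) + 0 + 0
  expect_equal(log_prior(p, "M2"), expected, tolerance = 1e-12)

  # component closed forms: Cauchy and Normal log densities at the mode
  expect_equal(dcauchy(0, 0, 2.5, log = TRUE), -log(pi * 2.5),
               tolerance = 1e-12)
  expect_equal(dnorm(0, 0, 100, log = TRUE), -log(100 * sqrt(2 * pi)),
               tolerance = 1e-12)
  expect_equal(dnorm(0, 0, 100, log = TRUE), -5.5241, tolerance = 1e-4)

  # beta5 enters under M4 only
  p4 <- p; p4$beta5 <- 3
  expect_equal(log_prior(p4, "M4") - log_prior(p, "M4"),
               dnorm(3, 0, 100, log = TRUE) - dnorm(0, 0, 100, log = TRUE))
  expect_equal(log_prior(p4, "M2"), log_prior(p, "M2"))

  p_bad <- p; p_bad$sigma_eps <- 11
  expect_equal(log_prior(p_bad, "M2"), -Inf)
})

test_that("conditional_deviance scores counts against latent states", {
  params <- true_parameters()
  sim <- simulate_dataset(raw_params(d = 1, p = 1, sigma_eps = 0.2),
                          tiny_config(seed = 61))
  # with d = 1 every available count equals N, so deviance is exactly 0
  expect_equal(conditional_deviance(sim$dataset, raw_params(d = 1),
                                    sim$latent), 0)

  ds <- study_dataset(data.frame(
    site_id = "s1", set = "SET3", work = 1, dist = NA, tree_1995 = NA,
    tree_2008 = NA, y_1995 = NA, y_2008 = 2, y_2009 = 2), validate = FALSE)
  lat <- data.frame(site_id = "s1", year = c(2008L, 2009L), Z = 1L, A = 1L,
                    N = c(4L, 2L))
  # y=2, N=4, d=0.5 -> -2 log(0.375); y=2, N=2, d=0.5 -> -2 log(0.25)
  expect_equal(conditional_deviance(ds, raw_params(d = 0.5), lat),
               -2 * log(6 * 0.0625) - 2 * log(0.25), tolerance = 1e-10)

  # deviance for one observation is minimized near d = y/N
  devs <- vapply(c(0.3, 0.5, 0.7), function(dd) {
    conditional_deviance(ds, raw_params(d = dd),
                         data.frame(site_id = "s1", year = c(2008L, 2009L),
                                    Z = 1L, A = 1L, N = c(4L, 4L)))
  }, numeric(1))
  expect_true(devs[2] < devs[1] && devs[2] < devs[3])

  bad <- data.frame(site_id = "s1", year = c(2008L, 2009L), Z = 0L, A = 0L,
                    N = NA_integer_)
  expect_error(conditional_deviance(ds, params, bad), "unavailable")
})
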
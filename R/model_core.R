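## The mathematical heart of the model: zero-truncated Poisson group
## sizes, logit-linear occupancy, a two-stage observation process
## (availability then per-bird detection), priors, and an exact
## marginalization over the latent states used as an oracle for the
## sampler and the generator.
##
## State process, site i, year k:
##   Z_ik ~ Bernoulli(psi_ik)                 occupancy
##   N_ik ~ ZTPois(lambda_ik)   given Z = 1   group size
## Observation process:
##   A_ik ~ Bernoulli(p * Z_ik)               group availability
##   Y_ik ~ Binomial(N_ik, d * A_ik)          counted birds

#' Model variants
#'
#' * `M1` — no site random effect, no baseline restoration term.
#' * `M2` — site random effect; no baseline difference between restored
#'   and unrestored sites (the headline model).
#' * `M4` — `M2` plus `beta5`, a baseline (1995) restoration difference.
#' * `M6` — `M2` plus the full linear occupancy model for SET2 sites
#'   (otherwise SET2 occupancy is intercept-only).
#'
#' @param name one of `"M1"`, `"M2"`, `"M4"`, `"M6"`, or a
#'   `model_variant` object (returned unchanged).
#' @return a `model_variant`: list with `name`, `include_beta5`,
#'   `set2_occupancy_linear`, `site_random_effect`.
#' @export
model_variant <- function(name = c("M2", "M1", "M4", "M6")) {
  if (inherits(name, "model_variant")) return(name)
  name <- match.arg(name)
  structure(
    list(name = name,
         include_beta5 = name == "M4",
         set2_occupancy_linear = name == "M6",
         site_random_effect = name != "M1"),
    class = "model_variant"
  )
}

as_model_variant <- model_variant

#' Zero-truncated Poisson log probability mass
#'
#' `log[ lambda^n e^{-lambda} / (n! (1 - e^{-lambda})) ]`, stable for
#' very small and very large rates.
#'
#' @param n integer counts >= 1.
#' @param lambda positive rate(s).
#' @return log pmf, vectorized over `n` and `lambda`.
#' @export
ztpois_logpmf <- function(n, lambda) {
  if (any(!is.finite(lambda) | lambda <= 0)) {
    stop("lambda must be positive", call. = FALSE)
  }
  if (any(!is.finite(n) | n < 1 | n != floor(n))) {
    stop("zero-truncated support is n >= 1", call. = FALSE)
  }
  dpois(n, lambda, log = TRUE) - log(-expm1(-lambda))
}

#' Mean of the zero-truncated Poisson
#'
#' `lambda / (1 - e^{-lambda})`; tends to 1 as `lambda -> 0` and to
#' `lambda` as `lambda` grows.
#'
#' @param lambda positive rate(s).
#' @export
ztpois_mean <- function(lambda) {
  if (any(!is.finite(lambda) | lambda <= 0)) {
    stop("lambda must be positive", call. = FALSE)
  }
  lambda / (-expm1(-lambda))
}

#' Draw zero-truncated Poisson deviates by inversion
#'
#' @param n number of draws.
#' @param lambda positive rate, scalar or length `n`.
#' @export
rztpois <- function(n, lambda) {
  if (any(!is.finite(lambda) | lambda <= 0)) {
    stop("lambda must be positive", call. = FALSE)
  }
  u <- runif(n, dpois(0, lambda), 1)
  qpois(u, lambda)
}

#' Probability that a site is occupied
#'
#' Logit-linear in scaled distance-to-nearest-group, scaled large-tree
#' density and the restoration-works flag. SET1 and SET2 sites share the
#' covariate effects and differ only in the intercept; under variants
#' without the SET2 linear model (`set2_linear = FALSE`) SET2 occupancy
#' is intercept-only.
#'
#' @param params parameter list (see [true_parameters()]).
#' @param dist_s,tree_s covariates, already centered and 2-SD scaled.
#' @param work restoration-works indicator (0/1).
#' @param set `"SET1"` or `"SET2"`.
#' @param set2_linear include covariate terms for SET2 sites.
#' @export
occupancy_probability <- function(params, dist_s, tree_s, work,
                                  set = c("SET1", "SET2"),
                                  set2_linear = TRUE) {
  set <- match.arg(set)
  if (set == "SET1") {
    eta <- params$c + params$gamma1 * dist_s + params$gamma2 * tree_s +
      params$gamma3 * work
  } else if (set2_linear) {
    eta <- params$c_set2 + params$gamma1 * dist_s + params$gamma2 * tree_s +
      params$gamma3 * work
  } else {
    eta <- params$c_set2 + 0 * dist_s
  }
  plogis(eta)
}

#' Expected group size (zero-truncated Poisson rate) for a site-year
#'
#' Log-linear submodels, per stratum and year:
#' \preformatted{
#' SET1 1995:  exp(alpha + b1 dist + b2 tree95 [+ b5 work] + eps)
#' SET1/2 2008: exp(alpha + b1 dist + b2 tree08 + b3 + (b4 [+ b5]) work + eps)
#' SET1/2 2009: exp(alpha + b1 dist + b2 tree08 + b3 + (b4 [+ b5] + b6) work
#'                  + b7 + eps)
#' SET3 2008:  exp(alpha + b3 + (b4 [+ b5]) work + eps)
#' SET3 2009:  lambda_2008 * exp(b6 work + b7)
#' }
#' `b5` enters only under variant M4. `alpha` is the log mean group size
#' in 1995 at an average site; `b3` the 1995-2008 time effect; `b4` its
#' interaction with restoration; `b6`/`b7` the 2008-2009 analogues.
#'
#' @param params parameter list.
#' @param variant a [model_variant()] (controls `beta5`).
#' @param set stratum, `"SET1"`, `"SET2"` or `"SET3"`.
#' @param year 1995, 2008 or 2009.
#' @param dist_s,tree_s scaled covariates (not needed for SET3).
#' @param work restoration flag.
#' @param eps site random effect on the log scale.
#' @return positive rate `lambda`.
#' @export
group_size_mean <- function(params, variant = model_variant("M2"),
                            set = c("SET1", "SET2", "SET3"),
                            year, dist_s = NULL, tree_s = NULL,
                            work = 0, eps = 0) {
  variant <- as_model_variant(variant)
  set <- match.arg(set)
  year <- as.integer(year)
  if (!year %in% c(1995L, 2008L, 2009L)) {
    stop("year must be 1995, 2008 or 2009", call. = FALSE)
  }
  b5 <- if (variant$include_beta5) params$beta5 else 0
  if (set == "SET3") {
    if (year == 1995L) {
      stop("SET3 sites were not surveyed in 1995", call. = FALSE)
    }
    lam2 <- exp(params$alpha + params$beta3 +
                  (params$beta4 + b5) * work + eps)
    if (year == 2008L) return(lam2)
    return(lam2 * exp(params$beta6 * work + params$beta7))
  }
  if (is.null(dist_s) || is.null(tree_s) || anyNA(dist_s) || anyNA(tree_s)) {
    stop("dist_s and tree_s are required for SET1/SET2 sites", call. = FALSE)
  }
  base <- params$alpha + params$beta1 * dist_s + params$beta2 * tree_s + eps
  if (year == 1995L) {
    if (set == "SET2") stop("SET2 sites have no 1995 group-size model",
                            call. = FALSE)
    return(exp(base + b5 * work))
  }
  lam2 <- exp(base + params$beta3 + (params$beta4 + b5) * work)
  if (year == 2008L) return(lam2)
  lam2 * exp(params$beta6 * work + params$beta7)
}

#' Log-probability of an observed count given the latent state
#'
#' `Y ~ Binomial(N, d * A)`: an unavailable group (`A = 0`) yields a
#' point mass at zero.
#'
#' @param y observed count, `0 <= y <= N`.
#' @param N latent group size (>= 1).
#' @param A availability indicator (0/1).
#' @param d per-bird detection probability.
#' @export
observation_logprob <- function(y, N, A, d) {
  if (any(N < 1 | N != floor(N))) stop("N must be an integer >= 1",
                                       call. = FALSE)
  if (any(y < 0 | y > N)) stop("y must lie in [0, N]", call. = FALSE)
  dbinom(y, N, d * A, log = TRUE)
}

## Marginal P(Y = y | Z = A = 1): sum_N ZTPois(N; lambda) Binom(y; N, d).
count_marginal_given_available <- function(y, lambda, d, n_max) {
  vapply(seq_along(y), function(i) {
    lo <- max(1, y[i])
    if (lo > n_max) return(0)
    nn <- lo:n_max
    sum(exp(ztpois_logpmf(nn, lambda[min(i, length(lambda))])) *
          dbinom(y[i], nn, d))
  }, numeric(1))
}

## Marginal P(Y = y) for an unconstrained site-year:
## (1-psi) 1[y=0] + psi [ (1-p) 1[y=0] + p * P(y | available) ].
count_marginal <- function(y, psi, p, d, lambda, n_max) {
  qa <- count_marginal_given_available(y, lambda, d, n_max)
  psi * ((1 - p) * (y == 0) + p * qa) + (1 - psi) * (y == 0)
}

#' Exact marginal log-likelihood of one site's counts
#'
#' Sums the latent occupancy, availability and group-size states out of
#' the likelihood, honoring the design constraints: SET1 sites are
#' occupied and available in 1995; SET3 sites are occupied and available
#' in both 2008 and 2009. Group sizes are drawn independently across
#' years given the site random effect. This enumeration is the oracle
#' against which both the generator and the MCMC likelihood are checked.
#'
#' @param site one-row data.frame/list with `set`, `work`, scaled
#'   covariates `dist_s`, `tree_s_1995`, `tree_s_2008` (SET1/2 only) and
#'   counts `y_1995`, `y_2008`, `y_2009` (NA = not surveyed).
#' @param params parameter list.
#' @param variant a [model_variant()].
#' @param eps site random effect (conditioned on, not integrated).
#' @param n_max truncation point of the group-size sum; must be at least
#'   the largest observed count. The zero-truncated tail beyond 50 is
#'   negligible for the rates relevant here.
#' @return log probability of the site's observed counts.
#' @export
site_marginal_loglik <- function(site, params, variant = model_variant("M2"),
                                 eps = 0, n_max = 50) {
  variant <- as_model_variant(variant)
  ys <- c(site$y_1995, site$y_2008, site$y_2009)
  if (any(ys > n_max, na.rm = TRUE)) {
    stop("n_max is smaller than an observed count", call. = FALSE)
  }
  ll <- 0
  if (site$set == "SET3") {
    lam2 <- group_size_mean(params, variant, "SET3", 2008,
                            work = site$work, eps = eps)
    lam3 <- group_size_mean(params, variant, "SET3", 2009,
                            work = site$work, eps = eps)
    if (!is.na(site$y_2008)) {
      ll <- ll + log(count_marginal_given_available(site$y_2008, lam2,
                                                    params$d, n_max))
    }
    if (!is.na(site$y_2009)) {
      ll <- ll + log(count_marginal_given_available(site$y_2009, lam3,
                                                    params$d, n_max))
    }
    return(ll)
  }
  if (site$set == "SET1" && !is.na(site$y_1995)) {
    lam1 <- group_size_mean(params, variant, "SET1", 1995,
                            dist_s = site$dist_s, tree_s = site$tree_s_1995,
                            work = site$work, eps = eps)
    ll <- ll + log(count_marginal_given_available(site$y_1995, lam1,
                                                  params$d, n_max))
  }
  if (!is.na(site$y_2008)) {
    psi <- occupancy_probability(params, site$dist_s, site$tree_s_2008,
                                 site$work, set = site$set,
                                 set2_linear = variant$set2_occupancy_linear)
    lam2 <- group_size_mean(params, variant, site$set, 2008,
                            dist_s = site$dist_s, tree_s = site$tree_s_2008,
                            work = site$work, eps = eps)
    ll <- ll + log(count_marginal(site$y_2008, psi, params$p, params$d,
                                  lam2, n_max))
  }
  ll
}

#' Prior specification
#'
#' Vague Normal(0, sd 100) priors on all regression coefficients except
#' the SET1 occupancy submodel, which gets weakly informative Cauchy
#' priors to aid convergence: scale 10 for the intercept `c`, scale 2.5
#' for `gamma1..gamma3`. The random-effect sd is Uniform(0, 10);
#' availability `p` and detection `d` are Uniform(0, 1).
#'
#' @return named list; each element is `list(type, location/min,
#'   scale/max)` with `type` one of `"normal"`, `"cauchy"`, `"uniform"`.
#' @export
default_priors <- function() {
  normal <- list(type = "normal", a = 0, b = 100)
  list(
    c = list(type = "cauchy", a = 0, b = 10),
    c_set2 = normal,
    gamma1 = list(type = "cauchy", a = 0, b = 2.5),
    gamma2 = list(type = "cauchy", a = 0, b = 2.5),
    gamma3 = list(type = "cauchy", a = 0, b = 2.5),
    alpha = normal, beta1 = normal, beta2 = normal, beta3 = normal,
    beta4 = normal, beta5 = normal, beta6 = normal, beta7 = normal,
    sigma_eps = list(type = "uniform", a = 0, b = 10),
    p = list(type = "uniform", a = 0, b = 1),
    d = list(type = "uniform", a = 0, b = 1)
  )
}

prior_logdens_1 <- function(x, spec) {
  switch(spec$type,
         normal = dnorm(x, spec$a, spec$b, log = TRUE),
         cauchy = dcauchy(x, spec$a, spec$b, log = TRUE),
         uniform = ifelse(x >= spec$a & x <= spec$b,
                          -log(spec$b - spec$a), -Inf),
         stop("unknown prior type ", spec$type, call. = FALSE))
}

#' Joint log prior density of the model parameters
#'
#' Sums the log prior over the parameters that are free under `variant`
#' (`beta5` only under M4; `sigma_eps` only with a site random effect).
#' Site random effects themselves contribute through their Normal(0,
#' `sigma_eps`) density and are handled by the sampler, not here.
#'
#' @param params parameter list.
#' @param variant a [model_variant()].
#' @param priors prior specification, see [default_priors()].
#' @export
log_prior <- function(params, variant = model_variant("M2"),
                      priors = default_priors()) {
  variant <- as_model_variant(variant)
  keep <- names(priors)
  if (!variant$include_beta5) keep <- setdiff(keep, "beta5")
  if (!variant$site_random_effect) keep <- setdiff(keep, "sigma_eps")
  sum(vapply(keep, function(nm) prior_logdens_1(params[[nm]], priors[[nm]]),
             numeric(1)))
}

#' Conditional deviance of the observed counts
#'
#' `-2` times the sum of observation log-probabilities given the current
#' latent availability and group sizes: the quantity whose posterior mean
#' is compared across model variants. Counts at unavailable site-years
#' contribute zero (the point mass at `y = 0`).
#'
#' @param dataset a `study_dataset` (only the counts are used).
#' @param params parameter list (`d` is used).
#' @param latents data.frame with columns `site_id`, `year`, `Z`, `A`,
#'   `N` covering every observed count.
#' @export
conditional_deviance <- function(dataset, params, latents) {
  sites <- dataset$sites
  dev <- 0
  for (r in seq_len(nrow(sites))) {
    s <- sites[r, ]
    for (yr in c(1995L, 2008L, 2009L)) {
      y <- s[[sprintf("y_%d", yr)]]
      if (is.na(y)) next
      lat <- latents[latents$site_id == s$site_id & latents$year == yr, ]
      if (nrow(lat) != 1L) {
        stop(sprintf("latent state missing for site '%s' year %d",
                     s$site_id, yr), call. = FALSE)
      }
      if (lat$Z == 0 || lat$A == 0) {
        if (y > 0) stop(sprintf(
          "site '%s' year %d: positive count at an unavailable site-year",
          s$site_id, yr), call. = FALSE)
        next  # log 1
      }
      if (is.na(lat$N)) stop(sprintf(
        "site '%s' year %d: occupied site-year lacks N", s$site_id, yr),
        call. = FALSE)
      dev <- dev - 2 * observation_logprob(y, lat$N, lat$A, params$d)
    }
  }
  dev
}
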
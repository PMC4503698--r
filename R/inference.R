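## Posterior sampling, convergence diagnostics and model comparison.

PARAM_NAMES <- c("c", "c_set2", "gamma1", "gamma2", "gamma3", "alpha",
                 "beta1", "beta2", "beta3", "beta4", "beta5", "beta6",
                 "beta7", "sigma_eps", "p", "d")

#' MCMC configuration
#'
#' Defaults mirror the original protocol (3 chains, 2,000 burn-in,
#' 100,000 retained samples); tests and examples run scaled-down chains
#' since the chain length is a budget, not part of the estimand.
#'
#' @param n_chains number of chains (>= 2 for the PSRF diagnostic).
#' @param n_burnin burn-in iterations, discarded; step sizes adapt only
#'   during this phase so the retained chain is a fixed Markov kernel.
#' @param n_samples retained post-burn-in samples per chain.
#' @param thin thinning interval.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param rhat_threshold convergence is flagged (not an error) when any
#'   parameter exceeds this potential scale reduction factor.
#' @export
mcmc_config <- function(n_chains = 3, n_burnin = 2000, n_samples = 100000,
                        thin = 1, seed = NULL, rhat_threshold = 1.1) {
  stopifnot(n_chains >= 1, n_burnin >= 0, n_samples >= 1, thin >= 1)
  structure(list(n_chains = n_chains, n_burnin = n_burnin,
                 n_samples = n_samples, thin = thin, seed = seed,
                 rhat_threshold = rhat_threshold),
            class = c("mcmc_config", "list"))
}

## Flatten a study_dataset into the arrays the C++ code consumes.
prepare_model_data <- function(dataset, variant, n_max) {
  sites <- dataset$sites
  n <- nrow(sites)
  set_int <- match(sites$set, c("SET1", "SET2", "SET3"))
  sc <- dataset$scaling
  zero_if_na <- function(x) ifelse(is.na(x), 0, x)
  dist_s <- tree1_s <- tree2_s <- numeric(n)
  if (!is.null(sc)) {
    dist_s <- zero_if_na(scale_with(sites$dist, sc$dist))
    tree1_s <- zero_if_na(scale_with(sites$tree_1995, sc$tree))
    tree2_s <- zero_if_na(scale_with(sites$tree_2008, sc$tree))
  }
  as_y <- function(x) {
    out <- as.integer(ifelse(is.na(x), -1L, x))
    out
  }
  ydet <- if (!is.null(dataset$detection)) {
    as.matrix(dataset$detection[, -1, drop = FALSE])
  } else {
    matrix(0L, 0, 0)
  }
  storage.mode(ydet) <- "integer"
  max_y <- suppressWarnings(max(c(0, sites$y_1995, sites$y_2008,
                                  sites$y_2009, ydet), na.rm = TRUE))
  if (n_max < max_y) {
    stop("n_max must be at least the largest observed count (", max_y, ")",
         call. = FALSE)
  }
  list(set = set_int, work = as.integer(sites$work),
       dist_s = dist_s, tree1_s = tree1_s, tree2_s = tree2_s,
       y1 = as_y(sites$y_1995), y2 = as_y(sites$y_2008),
       y3 = as_y(sites$y_2009), ydet = ydet, n_max = as.integer(n_max),
       include_b5 = variant$include_beta5,
       set2_linear = variant$set2_occupancy_linear,
       random_effect = variant$site_random_effect)
}

priors_to_matrix <- function(priors) {
  type_code <- c(normal = 0, cauchy = 1, uniform = 2)
  m <- matrix(0, length(PARAM_NAMES), 3,
              dimnames = list(PARAM_NAMES, c("type", "a", "b")))
  for (k in seq_along(PARAM_NAMES)) {
    spec <- priors[[PARAM_NAMES[k]]]
    if (is.null(spec)) stop("prior missing for ", PARAM_NAMES[k],
                            call. = FALSE)
    m[k, ] <- c(type_code[[spec$type]], spec$a, spec$b)
  }
  m
}

default_inits <- function() {
  c(c = 0.5, c_set2 = 1, gamma1 = 0, gamma2 = 0, gamma3 = 0,
    alpha = 1.4, beta1 = 0, beta2 = 0, beta3 = 0, beta4 = 0, beta5 = 0,
    beta6 = 0, beta7 = 0, sigma_eps = 0.5, p = 0.7, d = 0.8)
}

#' Fit the occupancy / group-size model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs over the marginalized likelihood:
#' latent occupancy, availability and group-size states are summed out
#' per site-year, and the sampler moves over the global parameters and
#' the site random effects. The availability and detection probabilities
#' are jointly identified only through the repeated-count calibration
#' panel, so fitting with both free requires detection data; without it,
#' fix both via `fixed = list(p = ..., d = ...)`.
#'
#' @param dataset a `study_dataset`; may be empty only with
#'   `prior_only = TRUE`.
#' @param variant a [model_variant()] or its name.
#' @param config an [mcmc_config()].
#' @param fixed named list of parameters to hold fixed (e.g. `p`, `d`).
#' @param priors prior specification, see [default_priors()].
#' @param prior_only sample from the prior (likelihood switched off);
#'   used for prior-recovery checks.
#' @param n_max truncation of the group-size marginalization.
#' @param save_random_effects retain per-site random-effect draws.
#' @return a `posterior_samples` object: `draws` is an array
#'   `[iteration, chain, parameter]` including a `deviance` column;
#'   `rhat` holds split-chain PSRFs and `converged` the threshold check
#'   (NA with a single chain).
#' @export
fit <- function(dataset, variant = "M2", config = mcmc_config(),
                fixed = list(), priors = default_priors(),
                prior_only = FALSE, n_max = 50,
                save_random_effects = FALSE) {
  variant <- as_model_variant(variant)
  if (!prior_only) {
    if (!inherits(dataset, "study_dataset")) {
      stop("dataset must be a study_dataset", call. = FALSE)
    }
    n_det <- if (is.null(dataset$detection)) 0L else nrow(dataset$detection)
    if (nrow(dataset$sites) == 0 && n_det == 0) {
      stop("configuration error: dataset has no sites and no detection data; ",
           "use prior_only = TRUE to sample the prior", call. = FALSE)
    }
    if (n_det == 0 && !("p" %in% names(fixed) && "d" %in% names(fixed))) {
      stop("availability (p) and detection (d) are jointly identified only ",
           "by repeated-count data; supply a detection study or fix both ",
           "via fixed = list(p = , d = )", call. = FALSE)
    }
  } else if (missing(dataset) || is.null(dataset)) {
    dataset <- study_dataset(empty_sites(), validate = FALSE)
  }

  md <- prepare_model_data(dataset, variant, n_max)
  pm <- priors_to_matrix(priors)

  update <- setNames(rep(TRUE, length(PARAM_NAMES)), PARAM_NAMES)
  if (!variant$include_beta5) update["beta5"] <- FALSE
  if (!variant$site_random_effect) update["sigma_eps"] <- FALSE
  init <- default_inits()
  if (!variant$include_beta5) init["beta5"] <- 0
  if (!variant$site_random_effect) init["sigma_eps"] <- 0
  for (nm in names(fixed)) {
    if (!nm %in% PARAM_NAMES) stop("unknown parameter in fixed: ", nm,
                                   call. = FALSE)
    update[nm] <- FALSE
    init[nm] <- fixed[[nm]]
  }

  if (!is.null(config$seed)) set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)

  free <- PARAM_NAMES[update]
  out_names <- c(PARAM_NAMES, "deviance",
                 if (save_random_effects) sprintf("eps[%d]", seq_len(nrow(dataset$sites))))
  chains <- vector("list", config$n_chains)
  accept <- matrix(NA_real_, config$n_chains, length(PARAM_NAMES),
                   dimnames = list(NULL, PARAM_NAMES))
  for (ch in seq_len(config$n_chains)) {
    set.seed(chain_seeds[ch])
    init_ch <- init
    jitter <- rnorm(length(free), 0, 0.1)
    init_ch[free] <- init_ch[free] + jitter
    for (nm in intersect(c("sigma_eps", "p", "d"), free)) {
      hi <- if (nm == "sigma_eps") 9.9 else 0.95
      init_ch[nm] <- min(max(init_ch[nm], 0.05), hi)
    }
    res <- cpp_fit_chain(md, pm, init_ch, update,
                         as.integer(config$n_burnin),
                         as.integer(config$n_samples),
                         as.integer(config$thin),
                         prior_only, save_random_effects,
                         if (variant$site_random_effect) 0.1 else 0,
                         NULL)
    colnames(res$draws) <- out_names
    chains[[ch]] <- res$draws
    accept[ch, ] <- res$accept
  }

  keep <- c(free, "deviance",
            if (save_random_effects) grep("^eps\\[", out_names, value = TRUE))
  draws <- array(
    NA_real_, c(config$n_samples, config$n_chains, length(keep)),
    dimnames = list(NULL, NULL, keep))
  for (ch in seq_len(config$n_chains)) {
    draws[, ch, ] <- chains[[ch]][, keep]
  }

  samples <- structure(
    list(draws = draws, parameters = free, variant = variant,
         config = config, fixed = fixed, prior_only = prior_only,
         fingerprint = dataset_fingerprint(dataset),
         accept = accept),
    class = "posterior_samples")
  if (config$n_chains >= 2) {
    rh <- rhat(samples)
    samples$rhat <- rh
    samples$converged <- all(rh[samples$parameters] <= config$rhat_threshold,
                             na.rm = TRUE)
  } else {
    samples$rhat <- NULL
    samples$converged <- NA
  }
  samples
}

empty_sites <- function() {
  data.frame(site_id = character(0), set = character(0), work = numeric(0),
             dist = numeric(0), tree_1995 = numeric(0),
             tree_2008 = numeric(0), y_1995 = numeric(0),
             y_2008 = numeric(0), y_2009 = numeric(0),
             stringsAsFactors = FALSE)
}

#' @export
print.posterior_samples <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("posterior_samples: variant %s, %d chains x %d draws\n",
              x$variant$name, d[2], d[1]))
  if (!is.null(x$rhat)) {
    cat(sprintf("  max PSRF %.3f (converged: %s)\n",
                max(x$rhat[x$parameters], na.rm = TRUE), x$converged))
  }
  print(summarize(x))
  invisible(x)
}

#' Extract pooled draws of one parameter
#'
#' @param samples a `posterior_samples`.
#' @param parameter parameter name.
#' @return numeric vector pooling all chains.
#' @export
draws_of <- function(samples, parameter) {
  if (!parameter %in% dimnames(samples$draws)[[3]]) {
    stop("unknown parameter '", parameter, "'", call. = FALSE)
  }
  as.vector(samples$draws[, , parameter])
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Split-chain PSRF: each chain is halved, and the factor compares the
#' between- and within-half variances,
#' `sqrt(((n-1)/n W + B/n) / W)`. Values near 1 indicate convergence.
#'
#' @param samples a `posterior_samples` with at least 2 chains, or a
#'   matrix with one column per chain.
#' @param split halve each chain first (detects within-chain trends).
#' @return named vector of PSRFs (per parameter), or a single value for
#'   a matrix input.
#' @export
rhat <- function(samples, split = TRUE) {
  if (is.matrix(samples)) return(rhat_matrix(samples, split))
  if (dim(samples$draws)[2] < 2) {
    stop("PSRF requires at least 2 chains", call. = FALSE)
  }
  pars <- dimnames(samples$draws)[[3]]
  vapply(pars, function(pn) rhat_matrix(samples$draws[, , pn], split),
         numeric(1))
}

rhat_matrix <- function(m, split = TRUE) {
  if (split) {
    n <- nrow(m)
    half <- floor(n / 2)
    m <- cbind(m[seq_len(half), , drop = FALSE],
               m[(n - half + 1):n, , drop = FALSE])
  }
  n <- nrow(m)
  W <- mean(apply(m, 2, var))
  B <- n * var(colMeans(m))
  if (!is.finite(W) || W == 0) {
    # all chains constant: identical chains converge trivially
    return(if (is.finite(B) && B > 0) Inf else 1)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior median and 95% credible interval
#'
#' @param samples a `posterior_samples`.
#' @param parameter single parameter name; if omitted, all parameters.
#' @return for one parameter, a named vector `(median, lower95,
#'   upper95)`; otherwise a data.frame with one row per parameter.
#' @export
summarize <- function(samples, parameter = NULL) {
  if (!is.null(parameter)) {
    x <- draws_of(samples, parameter)
    q <- quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
    return(c(median = q[1], lower95 = q[2], upper95 = q[3]))
  }
  pars <- dimnames(samples$draws)[[3]]
  pars <- pars[!grepl("^eps\\[", pars)]
  out <- t(vapply(pars, function(pn) summarize(samples, pn), numeric(3)))
  data.frame(parameter = pars, median = out[, 1], lower95 = out[, 2],
             upper95 = out[, 3], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Compare model variants by posterior deviance
#'
#' Fits each variant and reports the posterior mean and sd of the
#' conditional deviance (-2 log-likelihood of the counts given imputed
#' latent states), sorted ascending by mean.
#'
#' @param dataset a `study_dataset`.
#' @param variants character vector or list of variants (>= 2).
#' @param config an [mcmc_config()].
#' @param ... passed on to [fit()].
#' @return data.frame `variant`, `mean_deviance`, `sd_deviance`, sorted;
#'   fitted objects in `attr(, "fits")`.
#' @export
compare_models <- function(dataset, variants, config = mcmc_config(), ...) {
  if (length(variants) < 2) stop("supply at least two variants",
                                 call. = FALSE)
  fits <- lapply(variants, function(v) fit(dataset, v, config, ...))
  names(fits) <- vapply(fits, function(f) f$variant$name, character(1))
  dev <- vapply(fits, function(f) {
    x <- draws_of(f, "deviance")
    c(mean(x), sd(x))
  }, numeric(2))
  out <- data.frame(variant = names(fits), mean_deviance = dev[1, ],
                    sd_deviance = dev[2, ], row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean_deviance), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}
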
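## Simulation of study datasets from the generative model under the
## stratified before/after-control-impact survey design:
##   SET1: detected 1995 (occupied and available in 1995 by design),
##   SET2: detected only later (modelled from 2008 on),
##   SET3: surveyed 2008 + 2009 only, known occupied in 2008,
## plus a repeated-count detection-calibration panel (within one closed
## month, so the latent group size is constant across visits).

#' Generating parameter values
#'
#' Defaults describe a population in decline at unrestored sites
#' (log mean group size `alpha = 1.5`, i.e. about 4.5 birds in 1995; a
#' 1995-2008 time effect of -0.15, offset by +0.20 where restoration
#' works are present), moderately high occupancy persistence (intercept
#' `c = 0.4263`, probability 0.605), distance-dependent occupancy, and
#' an observation process with availability `p = 0.8` and per-bird
#' detection `d = 0.9`.
#'
#' @param c SET1 occupancy intercept, logit scale.
#' @param c_set2 SET2 occupancy intercept, logit scale.
#' @param gamma1,gamma2,gamma3 occupancy effects of scaled distance,
#'   scaled large-tree density and restoration works.
#' @param alpha log mean group size in 1995 at an average site.
#' @param beta1,beta2 group-size effects of scaled distance and trees.
#' @param beta3 time effect, 1995 to 2008.
#' @param beta4 restoration-by-time interaction, 1995 to 2008.
#' @param beta5 baseline restoration difference (variant M4 only).
#' @param beta6 restoration-by-time interaction, 2008 to 2009.
#' @param beta7 time effect, 2008 to 2009.
#' @param sigma_eps sd of the site random effect (log scale).
#' @param p probability the group is available during a survey.
#' @param d probability each bird of an available group is counted.
#' @return named list of class `true_parameters`.
#' @export
true_parameters <- function(c = 0.4263, c_set2 = 2.197,
                            gamma1 = -0.693, gamma2 = 0.3, gamma3 = 0.3,
                            alpha = 1.5, beta1 = -0.1, beta2 = 0.4,
                            beta3 = -0.15, beta4 = 0.20, beta5 = 0,
                            beta6 = 0, beta7 = 0,
                            sigma_eps = 0.3, p = 0.8, d = 0.9) {
  params <- list(c = c, c_set2 = c_set2, gamma1 = gamma1, gamma2 = gamma2,
                 gamma3 = gamma3, alpha = alpha, beta1 = beta1,
                 beta2 = beta2, beta3 = beta3, beta4 = beta4, beta5 = beta5,
                 beta6 = beta6, beta7 = beta7, sigma_eps = sigma_eps,
                 p = p, d = d)
  if (!(p >= 0 && p <= 1) || !(d >= 0 && d <= 1)) {
    stop("p and d must be probabilities in [0, 1]", call. = FALSE)
  }
  if (sigma_eps < 0) stop("sigma_eps must be >= 0", call. = FALSE)
  structure(params, class = c("true_parameters", "list"))
}

#' Generator configuration
#'
#' Sample sizes, covariate distributions and assignment rules for the
#' synthetic study. Covariate distributions are simulation scaffolding:
#' tree densities and distances are log-normal (trees rounded to
#' integers), with defaults chosen so the 2-SD-scaled covariates span
#' roughly \[-1, 1\].
#'
#' @param n_set1,n_set2 numbers of SET1 / SET2 sites.
#' @param n_set3_restored,n_set3_unrestored SET3 split by restoration.
#' @param n_detection_sites,n_visits calibration panel dimensions.
#' @param tree_meanlog,tree_sdlog log-normal parameters for large-tree
#'   density (trees per 0.25 ha site).
#' @param dist_meanlog,dist_sdlog log-normal parameters for distance to
#'   the nearest known group (metres).
#' @param work_prob probability a SET1/SET2 site has restoration works
#'   (unbiased assignment).
#' @param biased_assignment if `TRUE`, restoration is preferentially
#'   assigned to sites with below-median tree density, reproducing the
#'   lower-density-at-restored-sites pattern for balance checks.
#' @param condition_on_1995_detection rejection-sample SET1 sites until
#'   the 1995 count is >= 1. Off by default: the model as fitted sets
#'   `A = 1` in 1995 but does not condition the likelihood on detection,
#'   so recovery tests must simulate from the model as fitted.
#' @param seed integer seed or `NULL` (use the current RNG state).
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_set1 = 67, n_set2 = 50,
                             n_set3_restored = 21, n_set3_unrestored = 20,
                             n_detection_sites = 29, n_visits = 4,
                             tree_meanlog = log(30), tree_sdlog = 0.5,
                             dist_meanlog = log(1000), dist_sdlog = 0.7,
                             work_prob = 0.5,
                             biased_assignment = FALSE,
                             condition_on_1995_detection = FALSE,
                             seed = NULL) {
  cfg <- list(n_set1 = n_set1, n_set2 = n_set2,
              n_set3_restored = n_set3_restored,
              n_set3_unrestored = n_set3_unrestored,
              n_detection_sites = n_detection_sites, n_visits = n_visits,
              tree_meanlog = tree_meanlog, tree_sdlog = tree_sdlog,
              dist_meanlog = dist_meanlog, dist_sdlog = dist_sdlog,
              work_prob = work_prob,
              biased_assignment = biased_assignment,
              condition_on_1995_detection = condition_on_1995_detection,
              seed = seed)
  ns <- unlist(cfg[1:6])
  if (any(ns < 0 | ns != floor(ns))) {
    stop("all sample sizes must be non-negative integers", call. = FALSE)
  }
  cfg$n_set3 <- n_set3_restored + n_set3_unrestored
  structure(cfg, class = c("generator_config", "list"))
}

#' The study-design preset
#'
#' 67 SET1 sites, 50 SET2 sites, 41 SET3 sites (21 restored, 20 not) and
#' a 29-site by 4-visit detection-calibration panel.
#'
#' @param seed integer seed stored in the config.
#' @export
paper_like_config <- function(seed = NULL) {
  generator_config(seed = seed)
}

MAX_REJECTION_TRIES <- 1e6

## Vectorized single site-year draw of the full latent chain; the
## primitive every simulation above is built on, and the code path the
## enumeration-oracle acceptance check exercises.

#' Simulate independent site-year observations
#'
#' Draws `Z ~ Bern(psi)`, `A ~ Bern(p Z)`, `N ~ ZTPois(lambda)` where
#' occupied, `Y ~ Binomial(N, d A)` for `n` independent site-years with
#' common parameters.
#'
#' @param n number of replicate site-years.
#' @param psi occupancy probability.
#' @param p availability probability.
#' @param d per-bird detection probability.
#' @param lambda zero-truncated Poisson rate.
#' @return data.frame with columns `Z`, `A`, `N` (NA where unoccupied),
#'   `y`.
#' @export
simulate_site_year <- function(n, psi, p, d, lambda) {
  Z <- rbinom(n, 1, psi)
  A <- rbinom(n, 1, p * Z)
  N <- rep(NA_integer_, n)
  occ <- Z == 1
  N[occ] <- rztpois(sum(occ), lambda)
  y <- integer(n)
  av <- A == 1
  y[av] <- rbinom(sum(av), N[av], d)
  data.frame(Z = Z, A = A, N = N, y = y)
}

## Draw (N, y) for available site-years, optionally rejecting y == 0.
draw_available_counts <- function(lambda, d, require_detection) {
  n <- length(lambda)
  N <- rztpois(n, lambda)
  y <- rbinom(n, N, d)
  if (require_detection) {
    tries <- 0L
    while (any(y == 0)) {
      tries <- tries + 1L
      if (tries > MAX_REJECTION_TRIES) {
        stop("rejection sampling for a detected count exceeded ",
             MAX_REJECTION_TRIES, " tries; parameters are pathological",
             call. = FALSE)
      }
      redo <- y == 0
      N[redo] <- rztpois(sum(redo), lambda[redo])
      y[redo] <- rbinom(sum(redo), N[redo], d)
    }
  }
  list(N = N, y = y)
}

assign_work <- function(tree, config) {
  if (config$biased_assignment) {
    ## restoration targeted at poorer sites: 70% below the median tree
    ## density, 30% above
    pr <- ifelse(tree <= median(tree), 0.7, 0.3)
    rbinom(length(tree), 1, pr)
  } else {
    rbinom(length(tree), 1, config$work_prob)
  }
}

#' Simulate a study dataset from the generative model
#'
#' Draws covariates, latent occupancy/availability/group-size states and
#' observed counts for every site under the stratified design, honoring
#' the design constraints (SET1 occupied and available in 1995; SET3
#' occupied, available and detected in 2008, available in 2009). The
#' covariate scaling entering the linear predictors is computed from the
#' realized covariates with the same pooled rule the fitting code uses.
#'
#' @param params [true_parameters()].
#' @param config [generator_config()]; `config$seed` (if non-NULL) seeds
#'   the RNG.
#' @param variant [model_variant()] to simulate from (controls `beta5`
#'   and the SET2 occupancy structure).
#' @return list of class `restocc_simulation` with elements `dataset` (a
#'   `study_dataset`, without detection panel — see
#'   [simulate_detection_study()]), `latent` (per site-year `Z`, `A`,
#'   `N`, `psi`, `lambda`, `eps`), `params`, `config`.
#' @export
simulate_dataset <- function(params, config = paper_like_config(),
                             variant = model_variant("M2")) {
  variant <- as_model_variant(variant)
  if (!is.null(config$seed)) set.seed(config$seed)
  n1 <- config$n_set1; n2 <- config$n_set2; n3 <- config$n_set3
  if (n1 + n2 + n3 == 0) {
    stop("configuration error: no sites to simulate", call. = FALSE)
  }
  n12 <- n1 + n2
  b5 <- if (variant$include_beta5) params$beta5 else 0

  ## --- covariates (SET1 + SET2) -------------------------------------
  tree1 <- pmax(1, round(rlnorm(n12, config$tree_meanlog, config$tree_sdlog)))
  ## large trees cannot be created on a 13-year horizon; densities drift
  ## slightly (mostly down) between eras
  tree2 <- pmax(1, round(tree1 * exp(rnorm(n12, -0.05, 0.15))))
  dist <- round(rlnorm(n12, config$dist_meanlog, config$dist_sdlog), 1)
  work12 <- assign_work(tree1, config)
  work3 <- c(rep(1L, config$n_set3_restored), rep(0L, config$n_set3_unrestored))

  ## scaled covariates, same pooled rule as compute_scaling()
  scaling <- if (n12 >= 2) {
    list(dist = standardize(dist), tree = standardize(c(tree1, tree2)))
  }
  dist_s <- if (n12) scaling$dist$values else numeric(0)
  tree1_s <- if (n12) scaling$tree$values[seq_len(n12)] else numeric(0)
  tree2_s <- if (n12) scaling$tree$values[n12 + seq_len(n12)] else numeric(0)

  eps12 <- rnorm(n12, 0, params$sigma_eps)
  eps3 <- rnorm(n3, 0, params$sigma_eps)

  set <- c(rep("SET1", n1), rep("SET2", n2), rep("SET3", n3))
  site_id <- sprintf("S%03d", seq_len(n1 + n2 + n3))
  work <- c(work12, work3)

  y1 <- rep(NA_integer_, n1 + n2 + n3)
  y2 <- rep(NA_integer_, n1 + n2 + n3)
  y3 <- rep(NA_integer_, n1 + n2 + n3)
  latent <- list()

  ## --- SET1: 1995 (occupied, available by design) --------------------
  if (n1 > 0) {
    i1 <- seq_len(n1)
    lam1 <- exp(params$alpha + params$beta1 * dist_s[i1] +
                  params$beta2 * tree1_s[i1] + b5 * work[i1] + eps12[i1])
    dr <- draw_available_counts(lam1, params$d,
                                config$condition_on_1995_detection)
    y1[i1] <- dr$y
    latent[["set1_1995"]] <- data.frame(
      site_id = site_id[i1], year = 1995L, Z = 1L, A = 1L, N = dr$N,
      psi = 1, lambda = lam1, eps = eps12[i1])
  }

  ## --- SET1 + SET2: 2008 ---------------------------------------------
  if (n12 > 0) {
    i12 <- seq_len(n12)
    eta <- ifelse(set[i12] == "SET1",
                  params$c + params$gamma1 * dist_s +
                    params$gamma2 * tree2_s + params$gamma3 * work[i12],
                  params$c_set2 +
                    if (variant$set2_occupancy_linear) {
                      params$gamma1 * dist_s + params$gamma2 * tree2_s +
                        params$gamma3 * work[i12]
                    } else 0)
    psi2 <- plogis(eta)
    lam2 <- exp(params$alpha + params$beta1 * dist_s +
                  params$beta2 * tree2_s + params$beta3 +
                  (params$beta4 + b5) * work[i12] + eps12)
    Z2 <- rbinom(n12, 1, psi2)
    A2 <- rbinom(n12, 1, params$p * Z2)
    N2 <- rep(NA_integer_, n12)
    occ <- Z2 == 1
    N2[occ] <- rztpois(sum(occ), lam2[occ])
    yy <- integer(n12)
    av <- A2 == 1
    yy[av] <- rbinom(sum(av), N2[av], params$d)
    y2[i12] <- yy
    latent[["set12_2008"]] <- data.frame(
      site_id = site_id[i12], year = 2008L, Z = Z2, A = A2, N = N2,
      psi = psi2, lambda = lam2, eps = eps12)
  }

  ## --- SET3: 2008 (occupied, available, detected) and 2009 -----------
  if (n3 > 0) {
    i3 <- n12 + seq_len(n3)
    lam2 <- exp(params$alpha + params$beta3 +
                  (params$beta4 + b5) * work3 + eps3)
    dr2 <- draw_available_counts(lam2, params$d, require_detection = TRUE)
    y2[i3] <- dr2$y
    lam3 <- lam2 * exp(params$beta6 * work3 + params$beta7)
    N3 <- rztpois(n3, lam3)
    y3[i3] <- rbinom(n3, N3, params$d)
    latent[["set3_2008"]] <- data.frame(
      site_id = site_id[i3], year = 2008L, Z = 1L, A = 1L, N = dr2$N,
      psi = 1, lambda = lam2, eps = eps3)
    latent[["set3_2009"]] <- data.frame(
      site_id = site_id[i3], year = 2009L, Z = 1L, A = 1L, N = N3,
      psi = 1, lambda = lam3, eps = eps3)
  }

  sites <- data.frame(
    site_id = site_id, set = set, work = work,
    dist = c(dist, rep(NA_real_, n3)),
    tree_1995 = c(tree1, rep(NA_real_, n3)),
    tree_2008 = c(tree2, rep(NA_real_, n3)),
    y_1995 = y1, y_2008 = y2, y_2009 = y3,
    stringsAsFactors = FALSE)

  dataset <- study_dataset(
    sites, validate = TRUE,
    require_set1_detection = config$condition_on_1995_detection,
    max_count = .Machine$integer.max)  # generator does not clip counts
  attr(dataset, "seed") <- config$seed

  structure(
    list(dataset = dataset,
         latent = do.call(rbind, c(latent, list(make.row.names = FALSE))),
         params = params, config = config),
    class = "restocc_simulation")
}

#' Simulate the repeated-count detection-calibration study
#'
#' One latent group size per site (the panel is closed within a month),
#' availability drawn independently per visit, counts binomial given
#' availability. The group-size rate is `exp(alpha + beta3)`, the
#' average-site rate for the later survey era.
#'
#' @param params [true_parameters()].
#' @param config [generator_config()]; uses `n_detection_sites`,
#'   `n_visits`, and `seed` if non-NULL.
#' @return list with `detection` (data.frame `site_id`, `count_1..4`)
#'   and `latent` (per-site `N`).
#' @export
simulate_detection_study <- function(params, config = paper_like_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  S <- config$n_detection_sites
  J <- config$n_visits
  lam <- exp(params$alpha + params$beta3)
  N <- rztpois(S, lam)
  counts <- matrix(0L, S, J)
  for (j in seq_len(J)) {
    A <- rbinom(S, 1, params$p)
    counts[, j] <- rbinom(S, N, params$d * A)
  }
  det <- data.frame(site_id = sprintf("D%03d", seq_len(S)),
                    stringsAsFactors = FALSE)
  for (j in seq_len(J)) det[[sprintf("count_%d", j)]] <- counts[, j]
  list(detection = det, latent = data.frame(site_id = det$site_id, N = N))
}
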
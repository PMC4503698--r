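## Derived quantities: expected group sizes at average sites, effect
## tables on the odds-ratio and multiplicative scales, and the
## covariate-balance regression used to check for pre-existing
## differences between restored and unrestored sites.

ci_row <- function(x) {
  q <- quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
  c(median = q[1], lower95 = q[2], upper95 = q[3])
}

#' Expected group size at average sites, and the restoration effect
#'
#' Per posterior draw, the group-size rate is evaluated at a site with
#' all scaled covariates at 0 and (by default) random effect 0:
#' 1995 `exp(alpha)`, 2008 unrestored `exp(alpha + beta3)`, 2008
#' restored `exp(alpha + beta3 + beta4)`; the change without restoration
#' and the difference restoration made follow by subtraction, and each
#' is summarized by its posterior median and central 95% interval.
#'
#' @param samples fitted `posterior_samples` (variant M2 or M4).
#' @param truncation_adjusted report the zero-truncated mean
#'   `lambda / (1 - e^-lambda)` instead of the rate `lambda`. At rates
#'   around 4-5 the two differ by well under 0.1 birds.
#' @param marginalize_random_effect multiply rates by
#'   `exp(sigma_eps^2 / 2)`, the population-average rate rather than the
#'   rate of a typical (random effect 0) site.
#' @return data.frame, one row per scenario (`Y1995`,
#'   `Y2008_unrestored`, `Y2008_restored`, `change_unrestored`,
#'   `restoration_effect`) with `median`, `lower95`, `upper95`.
#' @export
scenario_predictions <- function(samples, truncation_adjusted = FALSE,
                                 marginalize_random_effect = FALSE) {
  need <- c("alpha", "beta3", "beta4")
  missing_par <- setdiff(need, dimnames(samples$draws)[[3]])
  if (length(missing_par)) {
    stop("samples lack parameters: ", paste(missing_par, collapse = ", "),
         call. = FALSE)
  }
  alpha <- draws_of(samples, "alpha")
  beta3 <- draws_of(samples, "beta3")
  beta4 <- draws_of(samples, "beta4")
  infl <- if (marginalize_random_effect) {
    exp(draws_of(samples, "sigma_eps")^2 / 2)
  } else 1
  f <- if (truncation_adjusted) ztpois_mean else identity
  g1995 <- f(exp(alpha) * infl)
  g2008u <- f(exp(alpha + beta3) * infl)
  g2008r <- f(exp(alpha + beta3 + beta4) * infl)
  scen <- list(Y1995 = g1995, Y2008_unrestored = g2008u,
               Y2008_restored = g2008r,
               change_unrestored = g2008u - g1995,
               restoration_effect = g2008r - g2008u)
  out <- t(vapply(scen, ci_row, numeric(3)))
  data.frame(scenario = rownames(out), out, row.names = NULL,
             truncation_adjusted = truncation_adjusted,
             stringsAsFactors = FALSE)
}

#' Occupancy effects on the logit and odds-ratio scales
#'
#' The intercept is reported as odds (and implied probability); the
#' covariate coefficients as odds ratios per 2-SD covariate change (per
#' presence, for the restoration flag).
#'
#' @param samples fitted `posterior_samples`.
#' @return data.frame with logit-scale median and 95% interval plus the
#'   exponentiated (odds / odds-ratio) scale.
#' @export
occupancy_effect_table <- function(samples) {
  pars <- intersect(c("c", "c_set2", "gamma1", "gamma2", "gamma3"),
                    dimnames(samples$draws)[[3]])
  rows <- lapply(pars, function(pn) {
    x <- draws_of(samples, pn)
    lg <- ci_row(x)
    or <- ci_row(exp(x))
    data.frame(name = pn, median = lg[1], lower95 = lg[2], upper95 = lg[3],
               odds_median = or[1], odds_lower95 = or[2],
               odds_upper95 = or[3],
               probability = if (pn %in% c("c", "c_set2")) {
                 median(plogis(x))
               } else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-size effects on the log and multiplicative scales
#'
#' The intercept exponentiates to the mean group size in 1995 at an
#' average site; coefficients exponentiate to multiplicative changes in
#' group size, also expressed as percent change `100 (e^b - 1)`.
#'
#' @param samples fitted `posterior_samples`.
#' @return data.frame with log-scale median and 95% interval, the
#'   multiplicative scale and percent change.
#' @export
groupsize_effect_table <- function(samples) {
  pars <- intersect(c("alpha", paste0("beta", 1:7)),
                    dimnames(samples$draws)[[3]])
  rows <- lapply(pars, function(pn) {
    x <- draws_of(samples, pn)
    lg <- ci_row(x)
    mult <- ci_row(exp(x))
    data.frame(name = pn, median = lg[1], lower95 = lg[2], upper95 = lg[3],
               mult_median = mult[1], mult_lower95 = mult[2],
               mult_upper95 = mult[3],
               percent_change = if (pn == "alpha") NA_real_ else
                 100 * (mult[1] - 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Balance of tree density across restored and unrestored sites
#'
#' Ordinary least squares of log tree density on the restoration flag —
#' the check that restoration was not assigned to sites that were better
#' to begin with. Restoration targeted at poorer sites shows up as a
#' negative slope.
#'
#' @param dataset a `study_dataset`.
#' @param covariate `"tree_large"` (the stored covariate) or
#'   `"tree_small"` (only if the site table carries optional
#'   `tree_small_<year>` columns).
#' @param year 1995 or 2008, selecting the assessment era.
#' @return list with `intercept`, `slope`, `slope_se`, `p_value`, `df`.
#' @export
covariate_balance <- function(dataset,
                              covariate = c("tree_large", "tree_small"),
                              year = 1995) {
  covariate <- match.arg(covariate)
  year <- as.integer(year)
  if (!year %in% c(1995L, 2008L)) stop("year must be 1995 or 2008",
                                       call. = FALSE)
  sites <- dataset$sites[dataset$sites$set != "SET3", ]
  col <- if (covariate == "tree_large") {
    sprintf("tree_%d", year)
  } else {
    sprintf("tree_small_%d", year)
  }
  if (!col %in% names(sites)) {
    stop("dataset has no column '", col, "'", call. = FALSE)
  }
  dens <- sites[[col]]
  work <- sites$work
  if (any(dens <= 0, na.rm = TRUE)) {
    stop("tree densities must be positive for the log transform",
         call. = FALSE)
  }
  if (length(unique(work)) < 2) {
    stop("both restored and unrestored sites are needed for the balance check",
         call. = FALSE)
  }
  m <- lm(log(dens) ~ work)
  sm <- summary(m)$coefficients
  list(intercept = unname(coef(m)[1]), slope = unname(coef(m)[2]),
       slope_se = sm["work", "Std. Error"],
       p_value = sm["work", "Pr(>|t|)"],
       df = m$df.residual)
}
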
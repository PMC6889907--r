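#' Generate a synthetic cohort
#'
#' Draws a complete cohort of children from the data-generating process in
#' \code{config}: income quintile, income-patterned confounders, MVPA
#' (inverse Box-Cox of a Gaussian on the transformed scale, truncated at 0),
#' scenario eligibility fields, the internalizing case indicator from the
#' logistic outcome model, an integer 0-20 internalizing score consistent
#' with the top-decile cut-off, and an i.i.d. lognormal design weight with
#' mean 1. Identical \code{(config, seed)} yields a byte-identical cohort.
#'
#' @param config A \code{cohort_config}, e.g. \code{\link{default_config}()}.
#' @param seed Integer seed.
#' @return A data.frame with one row per child and columns
#'   \code{child_id, income_q, maternal_age_first_birth, ethnicity,
#'   nbhd_safety, maternal_distress, overweight, longstanding_illness,
#'   conduct_hyperactivity, mvpa_min, commute_active_legs, deprived_area,
#'   prior_internalizing, internalizing_score, design_weight}. The seed is
#'   recorded in \code{attr(, "seed")}.
#' @export
generate_cohort <- function(config = default_config(), seed = 1L) {
  validate_config(config)
  set.seed(as.integer(seed))
  n <- as.integer(config$n)
  cf <- config$confounders
  el <- config$eligibility

  q <- sample.int(5L, n, replace = TRUE, prob = config$quintile_probs)

  maternal_age <- stats::rnorm(n, cf$maternal_age_mean[q], cf$maternal_age_sd)
  maternal_age <- pmax(maternal_age, 14)
  eth_u <- stats::runif(n)
  eth_cum <- t(apply(cf$ethnicity_probs, 1, cumsum))
  ethnicity <- 1L + (eth_u > eth_cum[q, 1]) + (eth_u > eth_cum[q, 2])
  nbhd_safety <- stats::rbinom(n, 1L, cf$nbhd_safety_p[q])
  distress <- stats::rbinom(n, 24L, cf$distress_p[q])
  overweight <- stats::rbinom(n, 1L, cf$overweight_p[q])
  illness <- stats::rbinom(n, 1L, cf$illness_p[q])
  conduct <- stats::rbinom(n, 20L, cf$conduct_p[q])

  com_u <- stats::runif(n)
  com_cum <- t(apply(el$commute_probs, 1, cumsum))
  commute <- 0L + (com_u > com_cum[q, 1]) + (com_u > com_cum[q, 2])
  deprived <- stats::rbinom(n, 1L, el$deprived_p[q])
  prior_int <- stats::rbinom(n, 1L, el$prior_int_p[q])

  cohort <- data.frame(
    child_id = seq_len(n),
    income_q = q,
    maternal_age_first_birth = maternal_age,
    ethnicity = ethnicity,
    nbhd_safety = nbhd_safety,
    maternal_distress = distress,
    overweight = overweight,
    longstanding_illness = illness,
    conduct_hyperactivity = conduct,
    commute_active_legs = commute,
    deprived_area = deprived,
    prior_internalizing = prior_int
  )

  X <- confounder_matrix(cohort, config)
  mm <- config$mvpa_model
  mu_bc <- mm$loc[q] + drop(X %*% mm$conf_coef[colnames(X)])
  bc_mvpa <- stats::rnorm(n, mu_bc, mm$sd)
  cohort$mvpa_min <- inv_boxcox(bc_mvpa, mm$lambda)

  p_case <- outcome_probability(cohort, config)
  case <- stats::rbinom(n, 1L, p_case)
  cohort$internalizing_score <- draw_score(case, p_case, config$score_model$dispersion)

  sdlog <- config$design_weight_sdlog
  cohort$design_weight <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)

  if (config$missing_mcar > 0) {
    miss <- stats::runif(n) < config$missing_mcar
    cohort$mvpa_min[miss] <- NA_real_
  }

  attr(cohort, "seed") <- as.integer(seed)
  cohort
}

# Centred confounder design matrix shared by the mediator model, the outcome
# model and (uncentred semantics aside) the weight models.
confounder_matrix <- function(cohort, config) {
  X <- cbind(
    maternal_age = cohort$maternal_age_first_birth,
    ethnicity2 = as.numeric(cohort$ethnicity == 2L),
    ethnicity3 = as.numeric(cohort$ethnicity == 3L),
    nbhd_safety = cohort$nbhd_safety,
    distress = cohort$maternal_distress,
    overweight = cohort$overweight,
    illness = cohort$longstanding_illness,
    conduct = cohort$conduct_hyperactivity
  )
  sweep(X, 2, config$centers[colnames(X)])
}

# True conditional case probability under the configured outcome model,
# optionally at a counterfactual quintile and/or mediator value.
outcome_probability <- function(cohort, config, quintile = cohort$income_q,
                                mvpa = cohort$mvpa_min) {
  om <- config$outcome_model
  X <- confounder_matrix(cohort, config)
  bc <- boxcox_transform(mvpa, config$mvpa_model$lambda)
  eta <- om$intercept + om$quintile_coef[quintile] +
    drop(X %*% om$conf_coef[colnames(X)]) +
    om$mediator_coef * (bc - om$mediator_center)
  stats::plogis(eta)
}

# Integer 0-20 score: cases land in 8..19, non-cases in 0..7, with the
# within-range placement a monotone (in expectation) map of case probability.
draw_score <- function(case, p_case, dispersion = 1) {
  n <- length(case)
  p_hi <- pmin(0.9, 0.20 + 0.8 * dispersion * p_case)
  p_lo <- pmin(0.9, 0.08 + 0.8 * dispersion * p_case)
  score <- stats::rbinom(n, 7L, p_lo)                 # non-cases: 0..7
  score[case == 1L] <- 8L + stats::rbinom(sum(case == 1L), 11L, p_hi[case == 1L])
  as.integer(score)
}

#' Monte-Carlo oracle for true counterfactual effects
#'
#' Computes the ground-truth controlled direct effect implied by
#' \code{config}, against which the weighted estimators can be checked.
#' A cohort of \code{n_mc} children is drawn; for each counterfactual income
#' quintile the case probability of every child is evaluated directly from
#' the outcome model, holding each child's confounders and mediator at their
#' simulated (quintile-free, i.e. marginal-distribution) values. The true
#' CDE risk ratio and risk difference contrast the mean counterfactual
#' probabilities of quintile 1 vs quintile 5.
#'
#' @param config A \code{cohort_config}.
#' @param n_mc Monte-Carlo sample size.
#' @param seed Integer seed.
#' @return A list with \code{true_cde_rr}, \code{true_cde_rd},
#'   \code{true_prevalence}, per-quintile counterfactual means
#'   \code{p_counterfactual}, and \code{mc_error} (delta-method standard
#'   errors of the three headline quantities).
#' @export
true_effects <- function(config = default_config(), n_mc = 200000L, seed = 1L) {
  stopifnot(n_mc >= 1)
  cfg <- config
  cfg$n <- as.integer(n_mc)
  cfg$missing_mcar <- 0
  cohort <- generate_cohort(cfg, seed)
  p_cf <- vapply(1:5, function(qq) {
    outcome_probability(cohort, cfg, quintile = rep(qq, nrow(cohort)))
  }, numeric(nrow(cohort)))
  m <- colMeans(p_cf)
  p1 <- p_cf[, 1]; p5 <- p_cf[, 5]
  n <- nrow(cohort)
  v1 <- stats::var(p1) / n; v5 <- stats::var(p5) / n
  cv <- stats::cov(p1, p5) / n
  rr <- m[1] / m[5]
  se_rr <- sqrt(v1 / m[5]^2 + m[1]^2 * v5 / m[5]^4 - 2 * m[1] * cv / m[5]^3)
  se_rd <- stats::sd(p1 - p5) / sqrt(n)
  p_fact <- outcome_probability(cohort, cfg)
  list(
    true_cde_rr = unname(rr),
    true_cde_rd = unname(m[1] - m[5]),
    true_prevalence = mean(p_fact),
    p_counterfactual = unname(m),
    mc_error = c(rr = se_rr, rd = se_rd,
                 prevalence = stats::sd(p_fact) / sqrt(n))
  )
}

#' Write / read a cohort as CSV
#'
#' The cohort is stored as plain delimited text with a fixed header (the
#' column set documented in \code{\link{generate_cohort}}); the generating
#' seed, when known, travels in a \code{# seed:} comment line.
#'
#' @param cohort A cohort data.frame.
#' @param path File path.
#' @return \code{write_cohort} returns the path invisibly;
#'   \code{read_cohort} the cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(cohort, "seed")
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  utils::write.csv(cohort, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 1)
  skip <- if (startsWith(first, "#")) 1L else 0L
  cohort <- utils::read.csv(path, skip = skip)
  required <- c("child_id", "income_q", "mvpa_min", "internalizing_score",
                "design_weight")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols)) {
    stop("cohort file lacks required columns: ", paste(missing_cols, collapse = ", "))
  }
  if (skip == 1L) {
    attr(cohort, "seed") <- as.integer(sub("# seed: *", "", first))
  }
  cohort
}
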
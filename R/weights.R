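#' Confounder sets
#'
#' Column names of the baseline confounders (fixed before the exposure:
#' maternal age at first live birth, ethnicity) and of the full confounder
#' set, which adds the intermediate covariates measured at the mediator
#' sweep (perceived neighbourhood safety, maternal psychological distress,
#' child overweight, longstanding illness, conduct/hyperactivity problems).
#' The total-direct-effect path weights on the baseline set only; the
#' controlled-direct-effect path accounts for the full set.
#'
#' @return Character vector of cohort column names.
#' @export
baseline_confounders <- function() {
  c("maternal_age_first_birth", "ethnicity")
}

#' @rdname baseline_confounders
#' @export
all_confounders <- function() {
  c(baseline_confounders(), "nbhd_safety", "maternal_distress", "overweight",
    "longstanding_illness", "conduct_hyperactivity")
}

# Model-matrix builder used by the weight models: ethnicity enters as
# dummies, everything else as given. Errors on unknown columns.
weight_design <- function(cohort, confounders) {
  missing_cols <- setdiff(confounders, names(cohort))
  if (length(missing_cols)) {
    stop("unknown confounder column(s): ", paste(missing_cols, collapse = ", "))
  }
  blocks <- lapply(confounders, function(v) {
    if (v == "ethnicity") {
      cbind(ethnicity2 = as.numeric(cohort$ethnicity == 2L),
            ethnicity3 = as.numeric(cohort$ethnicity == 3L))
    } else {
      m <- cbind(as.numeric(cohort[[v]])); colnames(m) <- v; m
    }
  })
  do.call(cbind, blocks)
}

#' Fit the multinomial exposure model
#'
#' Models the probability of each income quintile given confounders with a
#' multinomial logistic regression (no proportional-odds restriction),
#' weighted by the design weight. These conditional probabilities form the
#' denominator of the stabilized exposure weights.
#'
#' @param cohort Cohort data.frame.
#' @param confounders Character vector of confounder columns
#'   (default \code{\link{all_confounders}()}).
#' @return A list with the fitted \code{nnet::multinom} object, the n x 5
#'   matrix \code{probs} of per-child quintile probabilities (rows sum to 1),
#'   and the confounder set used.
#' @export
fit_exposure_model <- function(cohort, confounders = all_confounders()) {
  counts <- table(factor(cohort$income_q, levels = 1:5))
  if (any(counts == 0)) {
    stop("exposure model needs at least one child per quintile; empty: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  }
  X <- weight_design(cohort, confounders)
  dat <- data.frame(.q = factor(cohort$income_q, levels = 1:5), X,
                    check.names = FALSE)
  fml <- stats::as.formula(paste(".q ~", paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- nnet::multinom(fml, data = dat, weights = cohort$design_weight,
                        trace = FALSE, maxit = 400, MaxNWts = 5000)
  if (fit$convergence != 0) {
    stop("multinomial exposure model failed to converge after ", fit$maxit %||% 400,
         " iterations (final deviance ", signif(fit$deviance, 6), ")")
  }
  probs <- stats::fitted(fit)
  if (nrow(probs) != nrow(cohort)) probs <- probs[rep(1, nrow(cohort)), , drop = FALSE]
  if (any(abs(rowSums(probs) - 1) > 1e-8)) {
    stop("fitted quintile probabilities do not sum to 1")
  }
  list(model = fit, probs = probs, confounders = confounders)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stabilized exposure weights
#'
#' Computes the stabilized inverse probability of treatment weight
#' \code{w_i = P(Q = q_i) / P(Q = q_i | X_i)}, with the marginal quintile
#' shares (design-weighted) in the numerator. With stabilization the
#' design-weighted mean of the weights is close to 1.
#'
#' @param exposure_fit Result of \code{\link{fit_exposure_model}}, or an
#'   n x 5 probability matrix.
#' @param cohort Cohort data.frame.
#' @return Positive numeric weight per child.
#' @export
stabilized_exposure_weights <- function(exposure_fit, cohort) {
  probs <- if (is.list(exposure_fit)) exposure_fit$probs else exposure_fit
  stopifnot(nrow(probs) == nrow(cohort), ncol(probs) == 5)
  q <- cohort$income_q
  marg <- vapply(1:5, function(k) {
    stats::weighted.mean(q == k, cohort$design_weight)
  }, numeric(1))
  denom <- probs[cbind(seq_len(nrow(cohort)), q)]
  bad <- which(denom <= .Machine$double.eps)
  if (length(bad)) {
    stop("zero fitted exposure probability for child_id ",
         paste(utils::head(cohort$child_id[bad], 5), collapse = ", "))
  }
  marg[q] / denom
}

#' Stabilized mediator weights for a continuous mediator
#'
#' Density-ratio weights for Box-Cox-transformed MVPA: the numerator is the
#' Gaussian density of the transformed mediator given exposure (income
#' quintile) alone, the denominator the Gaussian density given exposure plus
#' confounders. Both conditional means are fitted by weighted least squares
#' (design weights); each model uses a single homoscedastic residual-scale
#' estimate from its weighted residuals.
#'
#' @param cohort Cohort data.frame.
#' @param confounders Confounder columns for the denominator model.
#' @param lambda Box-Cox exponent for the mediator transform.
#' @return Positive numeric weight per child.
#' @export
mediator_weights <- function(cohort, confounders = all_confounders(),
                             lambda = 0.34) {
  bc <- boxcox_transform(cohort$mvpa_min, lambda)
  w <- cohort$design_weight
  Q <- stats::model.matrix(~ factor(income_q, levels = 1:5), data = cohort)
  X <- weight_design(cohort, confounders)
  XD <- cbind(Q, X)
  if (qr(XD)$rank < ncol(XD)) {
    stop("mediator denominator model is rank deficient (collinear confounders)")
  }
  fit_wls <- function(M) {
    f <- stats::lm.wfit(M, bc, w)
    dfres <- length(bc) - f$rank
    sigma <- sqrt(sum(w * f$residuals^2) / (sum(w) * dfres / length(bc)))
    if (sigma <= 1e-8 * (1 + abs(mean(bc)))) {
      stop("zero residual variance in mediator model")
    }
    list(mu = bc - f$residuals, sigma = sigma)
  }
  num <- fit_wls(Q)
  den <- fit_wls(XD)
  out <- stats::dnorm(bc, num$mu, num$sigma) / stats::dnorm(bc, den$mu, den$sigma)
  if (any(!is.finite(out)) || any(out <= 0)) {
    stop("non-finite mediator weights produced")
  }
  out
}

#' Winsorize weights at percentile bounds
#'
#' Clamps weights below the lower percentile to the lower-percentile value
#' and above the upper percentile to the upper-percentile value (default 1st
#' and 99th). Percentiles use linear interpolation between closest ranks
#' (\code{stats::quantile} type 7). Clamping rather than dropping keeps the
#' full sample size. Idempotent and order-preserving for interior values.
#'
#' @param weights Positive numeric vector.
#' @param lower_pct,upper_pct Percentile bounds (defaults 1 and 99).
#' @return Winsorized weights.
#' @export
trim_weights <- function(weights, lower_pct = 1, upper_pct = 99) {
  stopifnot(length(weights) > 0, lower_pct < upper_pct)
  bounds <- stats::quantile(weights, c(lower_pct, upper_pct) / 100,
                            type = 7, names = FALSE)
  pmin(pmax(weights, bounds[1]), bounds[2])
}

#' Combine weight components into the analysis weight
#'
#' Elementwise product of the (trimmed) exposure weight, optionally the
#' (trimmed) mediator weight, and the design weight. The mediator factor is
#' omitted on the total-direct-effect path.
#'
#' @param iptw_exposure Trimmed stabilized exposure weights.
#' @param ipw_mediator Trimmed mediator weights, or NULL for the TDE path.
#' @param design_weight Per-child design weight.
#' @return Positive analysis weight per child.
#' @export
combine_weights <- function(iptw_exposure, ipw_mediator = NULL, design_weight) {
  n <- length(iptw_exposure)
  if (length(design_weight) != n ||
      (!is.null(ipw_mediator) && length(ipw_mediator) != n)) {
    stop("weight vectors have mismatched lengths")
  }
  out <- iptw_exposure * design_weight
  if (!is.null(ipw_mediator)) out <- out * ipw_mediator
  if (any(out <= 0)) stop("analysis weights must be positive")
  out
}

#' Build the full weight set for an analysis path
#'
#' Convenience wrapper producing a \code{weight_set}: stabilized exposure
#' weights (and mediator weights on the CDE path), each winsorized at the
#' 1st/99th percentiles, combined with the design weight.
#'
#' @param cohort Cohort data.frame.
#' @param path \code{"tde"} (baseline confounders, no mediator factor) or
#'   \code{"cde"} (all confounders plus mediator weights).
#' @param lambda Box-Cox exponent for the mediator transform.
#' @param trim Winsorize each weight component at the 1st/99th percentiles
#'   (default TRUE, the production analysis; FALSE gives the raw stabilized
#'   weights, useful for checking identification against the
#'   \code{\link{true_effects}} oracle since winsorizing trades a small
#'   systematic attenuation-of-adjustment bias for variance).
#' @return A list of class \code{weight_set} with components
#'   \code{iptw_exposure}, \code{ipw_mediator} (NULL on the TDE path),
#'   \code{analysis_weight} and \code{diagnostics}.
#' @export
build_weights <- function(cohort, path = c("cde", "tde"), lambda = 0.34,
                          trim = TRUE) {
  path <- match.arg(path)
  confs <- if (path == "tde") baseline_confounders() else all_confounders()
  ex <- fit_exposure_model(cohort, confs)
  maybe_trim <- if (trim) trim_weights else identity
  iptw <- maybe_trim(stabilized_exposure_weights(ex, cohort))
  ipw_m <- if (path == "cde") maybe_trim(mediator_weights(cohort, confs, lambda)) else NULL
  aw <- combine_weights(iptw, ipw_m, cohort$design_weight)
  ws <- list(path = path, iptw_exposure = iptw, ipw_mediator = ipw_m,
             analysis_weight = aw,
             diagnostics = weight_diagnostics(aw))
  class(ws) <- "weight_set"
  ws
}

#' Weight diagnostics
#'
#' Mean, range and Kish effective sample size of a weight vector.
#'
#' @param weights Positive numeric vector.
#' @return Named numeric vector: mean, min, max, effective sample size.
#' @export
weight_diagnostics <- function(weights) {
  c(mean = mean(weights), min = min(weights), max = max(weights),
    n_effective = sum(weights)^2 / sum(weights^2))
}
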
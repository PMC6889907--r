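#' Weighted logistic regression by IRLS
#'
#' Maximizes the weighted binomial log-likelihood
#' \code{sum_i w_i [y_i log p_i + (1-y_i) log(1-p_i)]} by iteratively
#' reweighted least squares. Convergence is declared when the maximum
#' absolute score falls below 1e-8 or the relative change in log-likelihood
#' falls below 1e-10. The returned covariance is the inverse Fisher
#' information of the weighted likelihood (weights treated as fixed).
#'
#' @param y 0/1 outcome vector.
#' @param X Design matrix (include an intercept column explicitly).
#' @param weights Positive weights.
#' @param max_iter Iteration cap (default 50).
#' @return A list of class \code{wlogit}: \code{coef}, \code{vcov},
#'   \code{fitted}, \code{loglik}, \code{iter}, \code{converged},
#'   \code{separation} (TRUE when fitted probabilities collapse to 0/1).
#' @export
fit_weighted_logistic <- function(y, X, weights = rep(1, length(y)),
                                  max_iter = 50L) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X), length(weights) == nrow(X),
            all(weights > 0), all(y %in% c(0, 1)))
  if (qr(X)$rank < ncol(X)) {
    stop("design matrix is rank deficient")
  }
  beta <- numeric(ncol(X))
  ll_old <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, weights * (y - mu)))
    wq <- weights * mu * (1 - mu)
    info <- crossprod(X, X * wq)
    beta <- beta + solve(info, score)
    mu_new <- stats::plogis(drop(X %*% beta))
    eps <- .Machine$double.eps
    ll <- sum(weights * (y * log(pmax(mu_new, eps)) +
                         (1 - y) * log(pmax(1 - mu_new, eps))))
    score_new <- drop(crossprod(X, weights * (y - mu_new)))
    if (max(abs(score_new)) < 1e-8 ||
        abs(ll - ll_old) < 1e-10 * (abs(ll_old) + 1e-10)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (!converged) {
    stop("IRLS did not converge in ", max_iter, " iterations",
         if (any(mu_new > 1 - 1e-8 | mu_new < 1e-8)) " (possible separation)")
  }
  mu <- stats::plogis(drop(X %*% beta))
  info <- crossprod(X, X * (weights * mu * (1 - mu)))
  structure(list(coef = stats::setNames(beta, colnames(X)),
                 vcov = solve(info), fitted = mu, loglik = ll_old,
                 iter = iter, converged = converged,
                 separation = any(mu > 1 - 1e-8) || any(mu < 1e-8),
                 X = X, weights = weights),
            class = "wlogit")
}

# Linear predictor on a (possibly modified) design matrix.
predict_wlogit <- function(fit, X = fit$X) {
  stats::plogis(drop(as.matrix(X) %*% fit$coef))
}

#' Weighted predicted prevalence
#'
#' Weighted mean of per-child fitted probabilities, overall and within each
#' income quintile.
#'
#' @param fit A \code{wlogit} fit.
#' @param quintile Integer quintile per child.
#' @param weights Analysis weights used for averaging.
#' @param X Optional design matrix replacing the one the model was fit on
#'   (e.g. with a modified mediator column).
#' @return List with \code{overall} and 5-vector \code{by_quintile}.
#' @export
predicted_prevalence <- function(fit, quintile, weights = fit$weights, X = fit$X) {
  p <- predict_wlogit(fit, X)
  by_q <- vapply(1:5, function(k) {
    idx <- quintile == k
    if (!any(idx)) return(NA_real_)
    stats::weighted.mean(p[idx], weights[idx])
  }, numeric(1))
  list(overall = stats::weighted.mean(p, weights), by_quintile = by_q)
}

#' Extreme-quintile inequality summary
#'
#' For a model with income quintile entered as a single linear term (codes
#' 1..5), computes the fitted probability of the outcome with every child's
#' quintile set to 1 and to 5 (other columns, including any mediator term,
#' held at their per-child values and marginalized by weighted averaging),
#' and returns the risk ratio p(1)/p(5) and risk difference p(1) - p(5).
#' A delta-method standard error of log RR and of RD (model-based, weights
#' fixed) accompanies the point estimates.
#'
#' @param fit A \code{wlogit} fit whose design has a column named
#'   \code{income_q}.
#' @param weights Averaging weights (default: the fit's weights).
#' @param X Optional modified design matrix.
#' @return List: \code{p_low}, \code{p_high}, \code{rr}, \code{rd},
#'   \code{se_log_rr}, \code{se_rd}.
#' @export
inequality_summary <- function(fit, weights = fit$weights, X = fit$X) {
  X <- as.matrix(X)
  if (!"income_q" %in% colnames(X)) {
    stop("design matrix needs a linear 'income_q' column")
  }
  X1 <- X; X1[, "income_q"] <- 1
  X5 <- X; X5[, "income_q"] <- 5
  p1 <- predict_wlogit(fit, X1)
  p5 <- predict_wlogit(fit, X5)
  w <- weights / sum(weights)
  m1 <- sum(w * p1); m5 <- sum(w * p5)
  # delta method: d m_k / d beta = X_k' (w * p_k (1 - p_k))
  g1 <- drop(crossprod(X1, w * p1 * (1 - p1)))
  g5 <- drop(crossprod(X5, w * p5 * (1 - p5)))
  g_lrr <- g1 / m1 - g5 / m5
  g_rd <- g1 - g5
  se_lrr <- sqrt(drop(t(g_lrr) %*% fit$vcov %*% g_lrr))
  se_rd <- sqrt(drop(t(g_rd) %*% fit$vcov %*% g_rd))
  list(p_low = m1, p_high = m5, rr = m1 / m5, rd = m1 - m5,
       se_log_rr = se_lrr, se_rd = se_rd)
}

# Shared worker: fit the linear-quintile weighted logistic (optionally with
# the transformed mediator), then summarize prevalence and inequality,
# possibly under modified mediator values.
effect_results <- function(cohort, analysis_weight, label,
                           include_mediator = FALSE, lambda = 0.34,
                           mediator_minutes = NULL) {
  y <- as.numeric(internalizing_case(cohort$internalizing_score))
  X <- cbind(intercept = 1, income_q = cohort$income_q)
  if (include_mediator) {
    X <- cbind(X, bc_mvpa = boxcox_transform(cohort$mvpa_min, lambda))
  }
  fit <- fit_weighted_logistic(y, X, analysis_weight)
  Xp <- X
  mvpa_final <- cohort$mvpa_min
  if (!is.null(mediator_minutes)) {
    if (!include_mediator) stop("mediator policy requires the mediator term")
    mvpa_final <- mediator_minutes
    Xp[, "bc_mvpa"] <- boxcox_transform(mvpa_final, lambda)
  }
  prev <- predicted_prevalence(fit, cohort$income_q, analysis_weight, Xp)
  ineq <- inequality_summary(fit, analysis_weight, Xp)
  out <- list(
    label = label,
    overall_prevalence = prev$overall,
    fitted_prob_by_quintile = prev$by_quintile,
    rr = ineq$rr, rd = ineq$rd,
    se_log_rr = ineq$se_log_rr, se_rd = ineq$se_rd,
    attainment_who = stats::weighted.mean(who_target_flag(mvpa_final),
                                          cohort$design_weight),
    n_effective = unname(weight_diagnostics(analysis_weight)["n_effective"]),
    fit = fit, ci = NULL
  )
  class(out) <- "effect_results"
  out
}

#' Crude, total-direct-effect and controlled-direct-effect estimates
#'
#' \code{estimate_crude} fits the design-weighted linear-quintile logistic
#' model with no confounding adjustment. \code{estimate_tde} weights it by
#' trimmed stabilized exposure weights built on the baseline confounders
#' (times the design weight): the total direct effect of income.
#' \code{estimate_cde} adds the Box-Cox-transformed mediator to the model
#' and weights by trimmed exposure weights on the full confounder set times
#' trimmed mediator weights times the design weight: the controlled direct
#' effect. \code{mediator_policy} controls the mediator values used at
#' prediction time (coefficients are always fitted on observed data):
#' \code{"observed"}, a single fixed number of minutes, or a vector of
#' per-child non-negative increments.
#'
#' @param cohort Cohort data.frame.
#' @param lambda Box-Cox exponent for the mediator.
#' @param mediator_policy \code{"observed"}, a scalar (fixed minutes), or a
#'   per-child increment vector (minutes, all >= 0).
#' @param weight_set Optional precomputed \code{\link{build_weights}} result
#'   (reused across scenarios to avoid refitting weight models).
#' @return An \code{effect_results} list: overall prevalence, per-quintile
#'   fitted probabilities, RR, RD, WHO-target attainment of the (possibly
#'   modified) mediator, effective sample size, and the underlying fit.
#' @export
estimate_crude <- function(cohort) {
  effect_results(cohort, cohort$design_weight, "crude")
}

#' @rdname estimate_crude
#' @export
estimate_tde <- function(cohort, weight_set = NULL) {
  ws <- weight_set %||% build_weights(cohort, "tde")
  effect_results(cohort, ws$analysis_weight, "tde")
}

#' @rdname estimate_crude
#' @export
estimate_cde <- function(cohort, mediator_policy = "observed", lambda = 0.34,
                         weight_set = NULL) {
  ws <- weight_set %||% build_weights(cohort, "cde", lambda)
  minutes <- NULL
  label <- "cde"
  if (is.numeric(mediator_policy)) {
    if (length(mediator_policy) == 1) {
      minutes <- rep(mediator_policy, nrow(cohort))
      label <- sprintf("cde_fixed_%g", mediator_policy)
    } else {
      if (length(mediator_policy) != nrow(cohort) || any(mediator_policy < 0)) {
        stop("per-child increments must be non-negative and one per child")
      }
      minutes <- cohort$mvpa_min + mediator_policy
      label <- "cde_incremented"
    }
  } else if (!identical(mediator_policy, "observed")) {
    stop("mediator_policy must be \"observed\", a fixed value, or increments")
  }
  effect_results(cohort, ws$analysis_weight, label,
                 include_mediator = TRUE, lambda = lambda,
                 mediator_minutes = minutes)
}

#' Percentile bootstrap confidence intervals
#'
#' Resamples children with replacement (design weights travel with the
#' child), recomputes a statistic vector on each replicate, and returns
#' percentile confidence intervals. Replicates where the statistic fails
#' (e.g. an empty quintile after resampling) are dropped and counted.
#'
#' @param statistic Function taking a cohort data.frame and returning a
#'   named numeric vector.
#' @param cohort Cohort data.frame.
#' @param reps Number of bootstrap replicates (>= 2).
#' @param seed Integer seed (results are deterministic given the seed).
#' @param level Confidence level (default 0.95).
#' @return List with matrices-free vectors \code{ci_low}, \code{ci_high}
#'   (named as the statistic), \code{reps_used}, \code{failures}.
#' @export
bootstrap_ci <- function(statistic, cohort, reps = 500L, seed = 1L,
                         level = 0.95) {
  stopifnot(reps >= 2)
  set.seed(as.integer(seed))
  n <- nrow(cohort)
  draws <- list()
  failures <- 0L
  for (b in seq_len(reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    val <- tryCatch(statistic(cohort[idx, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(val)) failures <- failures + 1L else draws[[length(draws) + 1L]] <- val
  }
  if (!length(draws)) stop("all bootstrap replicates failed")
  mat <- do.call(rbind, draws)
  alpha <- (1 - level) / 2
  list(ci_low = apply(mat, 2, stats::quantile, probs = alpha, type = 7),
       ci_high = apply(mat, 2, stats::quantile, probs = 1 - alpha, type = 7),
       reps_used = nrow(mat), failures = failures)
}
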
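#' Measurement parameters
#'
#' Bundles the constants used to construct analysis variables: the Box-Cox
#' exponent applied to moderate-to-vigorous physical activity (MVPA) before
#' regression, the WHO daily activity target, and the internalizing-score
#' cut-off that defines a "case" (the top decile of the 0-20 score).
#'
#' @param boxcox_lambda Box-Cox exponent for the MVPA transform (default 0.34).
#' @param who_target_min WHO daily MVPA target in minutes (default 60).
#' @param internalizing_cutoff Integer score at or above which a child is
#'   classified as having internalizing problems (default 8, the observed
#'   lower bound of the top decile on the 0-20 scale).
#' @param top_decile_fraction Nominal case fraction implied by the cut-off
#'   (default 0.10).
#' @return A list of class \code{measure_params}.
#' @export
measure_params <- function(boxcox_lambda = 0.34, who_target_min = 60,
                           internalizing_cutoff = 8, top_decile_fraction = 0.10) {
  stopifnot(who_target_min > 0,
            internalizing_cutoff >= 0, internalizing_cutoff <= 20,
            top_decile_fraction > 0, top_decile_fraction < 1)
  structure(list(boxcox_lambda = boxcox_lambda,
                 who_target_min = who_target_min,
                 internalizing_cutoff = internalizing_cutoff,
                 top_decile_fraction = top_decile_fraction),
            class = "measure_params")
}

#' Box-Cox transform
#'
#' Computes \code{(x^lambda - 1)/lambda}, with the log limit at
#' \code{lambda = 0}. Exact zeros are replaced by 0.5 minute before
#' transforming, so that zero activity has a finite transformed value for any
#' lambda (the power form tends to -1/lambda as x -> 0 but the log limit
#' diverges); half a minute is below the measurement resolution of a daily
#' accelerometer summary.
#'
#' @param x Non-negative numeric vector (minutes of MVPA per day).
#' @param lambda Box-Cox exponent.
#' @return Transformed values, strictly increasing in \code{x}.
#' @export
boxcox_transform <- function(x, lambda = 0.34) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("boxcox_transform: x must be finite and non-negative")
  }
  x <- ifelse(x == 0, 0.5, x)
  if (lambda == 0) log(x) else (x^lambda - 1) / lambda
}

#' Inverse Box-Cox transform
#'
#' Inverts \code{\link{boxcox_transform}} on its range; values whose inverse
#' would fall below zero (possible when a Gaussian is sampled on the
#' transformed scale) are truncated at zero.
#'
#' @param y Numeric vector on the transformed scale.
#' @param lambda Box-Cox exponent.
#' @return Non-negative minutes.
#' @export
inv_boxcox <- function(y, lambda = 0.34) {
  if (lambda == 0) return(exp(y))
  base <- lambda * y + 1
  ifelse(base <= 0, 0, base^(1 / lambda))
}

#' WHO activity-target flag
#'
#' TRUE when a child records at least the WHO daily MVPA target
#' (default 60 minutes).
#'
#' @param mvpa Minutes of MVPA per day (non-negative).
#' @param params A \code{\link{measure_params}} object.
#' @return Logical vector.
#' @export
who_target_flag <- function(mvpa, params = measure_params()) {
  stopifnot(all(mvpa >= 0))
  mvpa >= params$who_target_min
}

#' Internalizing-problems case indicator
#'
#' Dichotomizes the 0-20 internalizing score at the top-decile cut-off:
#' scores at or above the cut-off are cases.
#'
#' @param score Integer scores in 0..20.
#' @param cutoff Case cut-off (default from \code{\link{measure_params}}).
#' @return Logical vector.
#' @export
internalizing_case <- function(score, cutoff = measure_params()$internalizing_cutoff) {
  if (any(score < 0 | score > 20 | score != round(score))) {
    stop("internalizing_case: scores must be integers in [0, 20]")
  }
  score >= cutoff
}

#' Weighted quintile assignment
#'
#' Assigns ordinal labels 1..5 (1 = lowest) so that each stratum holds
#' approximately 20% of the total weight. Cut-points are the weighted
#' quantiles of the cumulative-weight distribution; all observations sharing
#' a tied value receive the label of the lower quintile the value first
#' enters, so the mapping is a deterministic monotone function of the value.
#'
#' @param values Numeric vector (e.g. equivalized household income).
#' @param weights Positive weights, default all 1.
#' @return Integer vector of labels in 1..5.
#' @export
assign_quintiles <- function(values, weights = rep(1, length(values))) {
  stopifnot(length(values) == length(weights), all(weights > 0))
  if (length(unique(values)) < 5) {
    stop("assign_quintiles: need at least 5 distinct values")
  }
  ord <- order(values)
  cw <- cumsum(weights[ord]) / sum(weights)
  # cumulative weight at the *start* of each value block decides its quintile;
  # ties therefore collapse to the lower stratum
  v_sorted <- values[ord]
  block_start <- c(0, cw[-length(cw)])
  first_of_block <- !duplicated(v_sorted)
  start_by_value <- block_start[first_of_block]
  names(start_by_value) <- as.character(v_sorted[first_of_block])
  q_sorted <- pmin(5L, as.integer(floor(start_by_value[as.character(v_sorted)] * 5)) + 1L)
  out <- integer(length(values))
  out[ord] <- q_sorted
  out
}
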
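# Shared test configurations.

# Default configuration scaled down to n children.
small_config <- function(n) {
  cfg <- default_config()
  cfg$n <- as.integer(n)
  cfg
}

# Configuration with every income effect removed: identical confounder
# distributions, mediator locations and eligibility probabilities across
# quintiles, and zero direct quintile effect on the outcome. Downstream
# estimates should all be null.
null_config <- function(n, keep_confounder_effects = TRUE) {
  cfg <- small_config(n)
  cf <- cfg$confounders
  cf$maternal_age_mean <- rep(25.5, 5)
  cf$ethnicity_probs <- matrix(rep(c(0.824, 0.108, 0.068), each = 5), 5, 3)
  cf$nbhd_safety_p <- rep(0.72, 5)
  cf$distress_p <- rep(0.12, 5)
  cf$overweight_p <- rep(0.24, 5)
  cf$illness_p <- rep(0.18, 5)
  cf$conduct_p <- rep(0.16, 5)
  cfg$confounders <- cf
  cfg$mvpa_model$loc <- rep(cfg$mvpa_model$loc[3], 5)
  cfg$eligibility$commute_probs <- matrix(rep(c(0.47, 0.15, 0.38), each = 5), 5, 3)
  cfg$eligibility$deprived_p <- rep(0.23, 5)
  cfg$eligibility$prior_int_p <- rep(0.12, 5)
  cfg$outcome_model$quintile_coef <- rep(0, 5)
  if (!keep_confounder_effects) {
    cfg$outcome_model$conf_coef[] <- 0
    cfg$mvpa_model$conf_coef[] <- 0
  }
  cfg
}
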
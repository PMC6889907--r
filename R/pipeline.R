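#' Derive a named seed substream
#'
#' Maps a global seed and a stream name to a reproducible 31-bit seed, so
#' each pipeline stage (cohort, uptake, increments, bootstrap) draws from
#' its own stream and can be rerun in isolation.
#'
#' @param seed Global integer seed.
#' @param name Stream name.
#' @return Integer seed in [0, 2^31 - 1).
#' @export
derive_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

#' Run the full estimation and simulation pipeline
#'
#' Generates (or loads) a cohort, builds the weight sets, estimates the
#' crude, total-direct-effect and controlled-direct-effect models, applies
#' every scenario plus the combined package, optionally bootstraps
#' confidence intervals, and writes all outputs to \code{outdir}:
#' \code{cohort.csv} (when generated), \code{weight_diagnostics.csv},
#' \code{effects_table.csv} (the side-by-side comparison table),
#' \code{estimates.json} (machine-readable results), and \code{run_log.txt}
#' (seeds and versions).
#'
#' @param config A \code{cohort_config} (to generate a cohort), or NULL if
#'   \code{cohort_path} is given.
#' @param cohort_path Path to an existing cohort CSV (exclusive with
#'   \code{config}).
#' @param scenarios Named list of \code{scenario_spec} objects (default
#'   \code{\link{default_scenarios}()}).
#' @param combine Names of the scenarios pooled into the combined
#'   intervention package; by default all except \code{scenario1} (the
#'   hypothetical universal WHO-target scenario is not part of the
#'   realistic proportionate-universal package).
#' @param reps Bootstrap replicates for confidence intervals (0 = point
#'   estimates only).
#' @param outdir Output directory (created if absent).
#' @param seed Global seed; all stage seeds derive from it via
#'   \code{\link{derive_seed}}.
#' @param write_cohort_file Whether to write the generated cohort CSV
#'   (default TRUE; skip for large runs).
#' @return Invisibly, a list with the cohort, the estimates (named list of
#'   \code{effect_results}) and the rendered table.
#' @export
run_pipeline <- function(config = default_config(), cohort_path = NULL,
                         scenarios = default_scenarios(), reps = 0L,
                         outdir = "results", seed = 1L,
                         write_cohort_file = TRUE,
                         combine = setdiff(names(scenarios), "scenario1")) {
  if (!is.null(config) && !is.null(cohort_path)) {
    stop("give exactly one cohort source: config or cohort_path")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste0("pamsim ", as.character(utils::packageVersion("pamsim"))),
                 paste0("R ", R.version.string),
                 paste0("global seed: ", seed))
  if (is.null(cohort_path)) {
    cohort_seed <- derive_seed(seed, "cohort")
    cohort <- generate_cohort(config, cohort_seed)
    log_lines <- c(log_lines, paste0("cohort: generated, n = ", nrow(cohort),
                                     ", seed = ", cohort_seed))
    if (write_cohort_file) write_cohort(cohort, file.path(outdir, "cohort.csv"))
  } else {
    cohort <- read_cohort(cohort_path)
    log_lines <- c(log_lines, paste0("cohort: loaded from ", cohort_path,
                                     ", n = ", nrow(cohort)))
  }

  ws_tde <- build_weights(cohort, "tde")
  ws_cde <- build_weights(cohort, "cde")
  diag_df <- rbind(tde = ws_tde$diagnostics, cde = ws_cde$diagnostics)
  utils::write.csv(data.frame(path = rownames(diag_df), diag_df,
                              row.names = NULL),
                   file.path(outdir, "weight_diagnostics.csv"),
                   row.names = FALSE)

  results <- list(
    crude = estimate_crude(cohort),
    tde = estimate_tde(cohort, weight_set = ws_tde),
    cde = estimate_cde(cohort, weight_set = ws_cde)
  )
  for (nm in names(scenarios)) {
    sc <- apply_scenario(cohort, scenarios[[nm]], seed = seed,
                         weight_set = ws_cde)
    results[[nm]] <- sc$effects
  }
  if (length(combine) > 1) {
    comb <- combine_scenarios(cohort, scenarios[combine], seed = seed,
                              weight_set = ws_cde)
    results$combined <- comb$effects
  }

  if (reps > 0) {
    boot_seed <- derive_seed(seed, "bootstrap")
    log_lines <- c(log_lines, paste0("bootstrap: ", reps,
                                     " reps, seed = ", boot_seed))
    stat_fn <- function(dat) {
      crude <- estimate_crude(dat)
      c(crude_prevalence = crude$overall_prevalence,
        crude_rr = crude$rr, crude_rd = crude$rd)
    }
    ci <- bootstrap_ci(stat_fn, cohort, reps = reps, seed = boot_seed)
    results$crude$ci <- list(low = ci$ci_low, high = ci$ci_high)
  }

  tab <- render_table(results)
  utils::write.table(tab, file.path(outdir, "effects_table.csv"),
                     sep = ",", row.names = FALSE, qmethod = "double")
  json <- lapply(results, function(r) {
    r[c("label", "overall_prevalence", "fitted_prob_by_quintile",
        "rr", "rd", "attainment_who", "n_effective")]
  })
  jsonlite::write_json(list(seed = seed, estimates = json),
                       file.path(outdir, "estimates.json"),
                       auto_unbox = TRUE, digits = 10)
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(list(cohort = cohort, results = results, table = tab))
}

#' Render a comparison table of effect results
#'
#' One row per model/scenario: prevalence, extreme-quintile risk ratio and
#' risk difference (with bootstrap CIs where available), and WHO-target
#' attainment. Percentages are printed to one decimal.
#'
#' @param results Named list of \code{effect_results}.
#' @return A data.frame of formatted character columns.
#' @export
render_table <- function(results) {
  stopifnot(length(results) >= 1)
  fmt_pct <- function(x) sprintf("%.1f", 100 * x)
  rows <- lapply(results, function(r) {
    ci <- r$ci
    with_ci <- function(val, key, f) {
      if (is.null(ci) || !key %in% names(ci$low)) return(f(val))
      sprintf("%s (%s, %s)", f(val), f(ci$low[[key]]), f(ci$high[[key]]))
    }
    data.frame(
      model = r$label,
      prevalence_pct = with_ci(r$overall_prevalence, "crude_prevalence", fmt_pct),
      rr = with_ci(r$rr, "crude_rr", function(x) sprintf("%.2f", x)),
      rd_pct = with_ci(r$rd, "crude_rd", fmt_pct),
      who_attainment_pct = fmt_pct(r$attainment_who),
      n_effective = sprintf("%.0f", r$n_effective),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
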
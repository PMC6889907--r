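test_that("eligibility masks follow their predicates", {
  cfg <- small_config(5000)
  co <- generate_cohort(cfg, 71)
  specs <- default_scenarios()
  expect_true(all(eligibility_mask(co, specs$scenario1)))
  expect_equal(eligibility_mask(co, specs$scenario4), co$deprived_area == 1)
  expect_equal(eligibility_mask(co, specs$scenario5), co$prior_internalizing == 1)
  expect_equal(eligibility_mask(co, specs$scenario3), co$commute_active_legs < 2)
  bad <- scenario_spec("bad", eligibility = "no_such_field > 1")
  expect_error(eligibility_mask(co, bad), "no_such_field")
})

test_that("uptake sampling hits its nominal rate and its edge cases", {
  cfg <- small_config(50000)
  co <- generate_cohort(cfg, 72)
  mask <- rep(TRUE, nrow(co))
  expect_equal(sample_uptake(mask, 1, co, 1), mask)
  expect_equal(sum(sample_uptake(mask, 0, co, 1)), 0)
  part <- sample_uptake(mask, 0.77, co, 2)
  expect_lt(abs(mean(part) - 0.77), 3 * sqrt(0.77 * 0.23 / nrow(co)))
  # differential uptake by quintile
  part_q <- sample_uptake(mask, c(0.9, 0.7, 0.5, 0.3, 0.1), co, 3)
  rate_q <- tapply(part_q, co$income_q, mean)
  expect_true(all(abs(rate_q - c(0.9, 0.7, 0.5, 0.3, 0.1)) < 0.05))
  expect_error(scenario_spec("x", uptake = 1.2), "probability")
})

test_that("increments are truncated-normal draws with stratum-specific parameters", {
  cfg <- small_config(60000)
  co <- generate_cohort(cfg, 73)
  specs <- default_scenarios()

  # degenerate SD: every participant gets exactly the mean
  part <- rep(TRUE, nrow(co))
  inc1 <- sample_increments(part, specs$scenario1, co, 1)
  expect_true(all(inc1 == 30))

  # non-participants always get zero and increments are never negative
  part2 <- sample_uptake(eligibility_mask(co, specs$scenario3),
                         specs$scenario3$uptake, co, 4)
  inc3 <- sample_increments(part2, specs$scenario3, co, 5)
  expect_true(all(inc3[!part2] == 0))
  expect_true(all(inc3 >= 0))

  # stratum means match the truncated-normal closed form
  zero_legs <- part2 & co$commute_active_legs == 0
  one_leg <- part2 & co$commute_active_legs == 1
  expect_lt(abs(mean(inc3[zero_legs]) - truncnorm0_mean(4, 2)),
            3 * stats::sd(inc3[zero_legs]) / sqrt(sum(zero_legs)))
  expect_lt(abs(mean(inc3[one_leg]) - truncnorm0_mean(2, 1)),
            3 * stats::sd(inc3[one_leg]) / sqrt(sum(one_leg)))

  # the closed form itself agrees with direct numerical integration
  for (p in list(c(4, 2), c(2.3, 1), c(1, 3))) {
    num <- stats::integrate(function(x) x * stats::dnorm(x, p[1], p[2]),
                            0, Inf)$value / (1 - stats::pnorm(0, p[1], p[2]))
    expect_equal(truncnorm0_mean(p[1], p[2]), num, tolerance = 1e-6)
  }

  # cap_at limits post-increment minutes
  capped <- scenario_spec("cap", "all", 1, increment_mean = 100,
                          increment_sd = 0, cap_at = 90)
  incc <- sample_increments(rep(TRUE, nrow(co)), capped, co, 6)
  expect_true(all(co$mvpa_min + incc <= pmax(90, co$mvpa_min) + 1e-9))
  expect_true(all(incc >= 0))
})

test_that("scenario application is deterministic and reduces to the observed CDE when inert", {
  cfg <- small_config(12000)
  co <- generate_cohort(cfg, 74)
  ws <- build_weights(co, "cde")
  base <- estimate_cde(co, weight_set = ws)

  null_spec <- scenario_spec("nothing", "all", uptake = 0, increment_mean = 10,
                             increment_sd = 2)
  out <- apply_scenario(co, null_spec, seed = 1, weight_set = ws)
  expect_equal(out$effects$overall_prevalence, base$overall_prevalence,
               tolerance = 1e-12)
  expect_equal(out$effects$rr, base$rr, tolerance = 1e-12)

  s3 <- default_scenarios()$scenario3
  a <- apply_scenario(co, s3, seed = 5, weight_set = ws)
  b <- apply_scenario(co, s3, seed = 5, weight_set = ws)
  expect_identical(a$increment, b$increment)
  expect_false(identical(a$increment,
                         apply_scenario(co, s3, seed = 6, weight_set = ws)$increment))
  # uptake and increment draws come from distinct substreams
  expect_false(identical(derive_seed(5, "uptake:scenario3_active_transport"),
                         derive_seed(5, "increment:scenario3_active_transport")))
})

test_that("combining scenarios adds increments and cannot do worse than its parts", {
  cfg <- small_config(12000)
  co <- generate_cohort(cfg, 75)
  ws <- build_weights(co, "cde")

  fixed <- scenario_spec("fixed", "all", uptake = 1, increment_mean = 7,
                         increment_sd = 0)
  both <- combine_scenarios(co, list(fixed, fixed), seed = 1, weight_set = ws)
  expect_true(all(both$increment == 14))

  specs <- default_scenarios()[c("scenario2", "scenario3", "scenario4", "scenario5")]
  singles <- vapply(specs, function(s)
    apply_scenario(co, s, seed = 2, weight_set = ws)$effects$overall_prevalence,
    numeric(1))
  pack <- combine_scenarios(co, specs, seed = 2, weight_set = ws)
  expect_lte(pack$effects$overall_prevalence, min(singles) + 1e-12)

  base <- estimate_cde(co, weight_set = ws)
  none <- combine_scenarios(co, list(scenario_spec("off", "all", uptake = 0)),
                            seed = 3, weight_set = ws)
  expect_equal(none$effects$overall_prevalence, base$overall_prevalence,
               tolerance = 1e-12)
})

test_that("scenario files load with validation", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "walk:",
    "  eligibility: commute_active_legs < 2",
    "  uptake: 0.77",
    "  strata:",
    "  - when: commute_active_legs == 0",
    "    mean: 4",
    "    sd: 2",
    "  - when: commute_active_legs == 1",
    "    mean: 2",
    "    sd: 1",
    "club:",
    "  eligibility: deprived_area == 1",
    "  uptake: 0.6",
    "  increment_mean: 10",
    "  increment_sd: 5",
    "  unverified: true"), path)
  sc <- read_scenarios(path)
  expect_named(sc, c("walk", "club"))
  expect_equal(sc$walk$strata[[1]]$mean, 4)
  expect_true(sc$club$unverified)

  bad <- withr::local_tempfile(lines = c("oops:", "  uptake: 1.4"))
  expect_error(read_scenarios(bad), "oops")
})
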
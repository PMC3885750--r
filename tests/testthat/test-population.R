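test_that("zero-SD configuration collapses every individual to central values", {
  cfg <- zero_sd_config()
  pop <- sample_population(50, "rural", cfg, seed = 1)
  expect_true(all(pop$ach == 0.59))
  expect_true(all(pop$floor_area == 128.9))
  expect_true(all(pop$volume == 128.9 * 2.7))
  expect_true(all(pop$penetration == 0.90))
  expect_true(all(pop$biomass_kg == 4.00))
  # time budget at central values: home 16, work 5.45, outdoor 2.55
  emp <- pop$employed
  expect_true(all(pop$hours_home[emp] == 16))
  expect_true(all(pop$hours_work[emp] == 5.45))
  expect_equal(pop$hours_outdoor[emp], rep(24 - 16 - 5.45, sum(emp)))
  # non-employed get work hours reallocated to home
  expect_true(all(pop$hours_work[!emp] == 0))
  expect_true(all(pop$hours_home[!emp] == 16 + 5.45))
})

test_that("time budgets always close to exactly 24 hours", {
  pop <- sample_population(5000, "mixed", default_config(), seed = 11)
  expect_equal(pop$hours_home + pop$hours_work + pop$hours_outdoor,
               rep(24, 5000), tolerance = 1e-12)
  expect_true(all(pop$hours_home >= 0 & pop$hours_work >= 0 &
                  pop$hours_outdoor >= 0))
})

test_that("smoker assignment matches the configured prevalence", {
  n <- 10000
  pop <- sample_population(n, "urban", default_config(), seed = 5)
  p <- 0.311
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(pop$is_smoker) - p), 3 * se)
})

test_that("sample means recover the configured (truncated) distributions", {
  n <- 10000
  cfg <- default_config()
  sh <- cfg$population$shared
  pop <- sample_population(n, "rural", cfg, seed = 21)
  rc <- cfg$population$rural
  checks <- list(
    list(pop$ach, rc$ach, sh$ach_min, Inf),
    list(pop$floor_area, rc$area, sh$area_min, Inf),
    list(pop$penetration, sh$penetration, 0, 1),
    list(pop$hours_work[pop$employed], sh$t_work, 0, 24 - sh$t_home)
  )
  for (chk in checks) {
    m <- chk[[2]][["mean"]]; s <- chk[[2]][["sd"]]
    expected <- tnorm_mean(m, s, chk[[3]], chk[[4]])
    expect_lt(abs(mean(chk[[1]]) - expected), 4 * s / sqrt(length(chk[[1]])))
  }
  # lognormal fuel quantity: arithmetic mean is the configured central value
  expect_lt(abs(mean(pop$biomass_kg) - 4.00), 4 * 2.61 / sqrt(n))
  # smoking quantity with prohibitions disabled
  cfg$population$rural$home_smoking_ban <- 0
  pop2 <- sample_population(n, "rural", cfg, seed = 21)
  expect_lt(abs(mean(pop2$smoking_home) - 9), 4 * 19 / sqrt(n))
})

test_that("raising coal prevalence never removes a coal-using household", {
  cfg1 <- default_config()
  cfg1$population$rural$coal_prevalence <- 0.3
  cfg2 <- default_config()
  cfg2$population$rural$coal_prevalence <- 0.8
  p1 <- sample_population(2000, "rural", cfg1, seed = 9)
  p2 <- sample_population(2000, "rural", cfg2, seed = 9)
  expect_true(all(p2$coal_user[p1$coal_user]))
  expect_gte(sum(p2$coal_user), sum(p1$coal_user))
})

test_that("sampling is deterministic under a fixed seed", {
  a <- sample_population(500, "mixed", default_config(), seed = 42)
  b <- sample_population(500, "mixed", default_config(), seed = 42)
  expect_identical(a, b)
})

test_that("individuals carry a consistent household and budget structure", {
  ind <- sample_individual("rural", default_config(), seed = 2)
  expect_s3_class(ind, "pah_individual")
  expect_equal(ind$region, "rural")
  expect_equal(ind$household$volume,
               ind$household$floor_area * 2.7)
  tb <- ind$time_budget
  expect_equal(tb$hours_home_indoor + tb$hours_work_school_indoor +
                 tb$hours_outdoor, 24, tolerance = 1e-12)
  expect_error(sample_population(10, "suburban"), "suburban|arg")
  expect_error(sample_population(0, "urban"), "n")
})

test_that("configuration validation names the offending key", {
  pc <- default_population_config()
  pc$smoker_fraction <- 1.2
  expect_error(validate_population_config(pc), "smoker_fraction")
  pc <- default_population_config()
  pc$rural$ach[["sd"]] <- -1
  expect_error(validate_population_config(pc), "rural\\$ach")
  pc <- default_population_config()
  pc$urban$hood_fraction <- -0.1
  expect_error(validate_population_config(pc), "hood_fraction")
})
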
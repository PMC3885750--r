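test_that("runs are reproducible and summaries internally consistent", {
  a <- run_scenario("B-u", n_reps = 800, seed = 3)
  b <- run_scenario("B-u", n_reps = 800, seed = 3)
  expect_identical(a$individuals, b$individuals)
  expect_identical(a$summary, b$summary)
  for (m in names(a$summary)) {
    s <- a$summary[[m]]
    expect_lte(s[["p25"]], s[["p75"]])
    expect_lte(s[["p75"]], s[["p95"]])
    iqr <- s[["p75"]] - s[["p25"]]
    expect_gte(s[["mean"]], s[["p25"]] - 3 * iqr)
    expect_lte(s[["mean"]], s[["p75"]] + 3 * iqr)
  }
  expect_error(run_scenario("B-u", n_reps = 0), "n_reps")
})

test_that("standard error of the mean dose scales as 1/sqrt(n)", {
  mean_dose <- function(n, seed)
    run_scenario("B-u", n_reps = n, seed = seed)$summary$annual_dose_ug[["mean"]]
  seeds <- 1:12
  small <- vapply(seeds, function(s) mean_dose(300, s), 0)
  large <- vapply(seeds, function(s) mean_dose(1200, s * 101), 0)
  ratio <- sd(small) / sd(large)   # expect about sqrt(4) = 2
  expect_gt(ratio, 1.2)
  expect_lt(ratio, 3.3)
})

test_that("scenario comparison ranks interventions by PIF against baselines", {
  cmp <- compare_scenarios(c("B-r", "SF-r", "Atm-WHO-r"), n_reps = 1500,
                           seed = 19)
  tab <- cmp$table
  expect_setequal(tab$scenario, c("B-r", "SF-r", "Atm-WHO-r"))
  expect_true(is.na(tab$pif[tab$scenario == "B-r"]))
  iv <- tab[!is.na(tab$pif), ]
  expect_equal(iv$rank, seq_len(nrow(iv)))
  expect_true(all(diff(iv$pif) <= 0))
  # baseline compared with itself has PIF zero
  b <- cmp$runs[["B-r"]]
  expect_equal(potential_impact_fraction(b$mean_rr, b$mean_rr), 0)
  expect_error(compare_scenarios("nope"), "valid ids")
})

test_that("sensitivity sweep responds to SDs and is symmetric for penetration", {
  cfg <- default_config()
  # parameter with SD forced to zero: exactly 0% change both directions
  cfg$population$shared$smoking[["sd"]] <- 0
  sw <- sensitivity_sweep(cfg, scenarios = "B-u", parameters = "smoking",
                          n_reps = 800, seed = 7)
  expect_equal(sw$pct_change_dose, c(0, 0), tolerance = 1e-12)

  sw2 <- sensitivity_sweep(default_config(), scenarios = c("B-u", "B-r"),
                           parameters = c("penetration", "smoking"),
                           n_reps = 4000, seed = 7)
  pen_u <- sw2[sw2$parameter == "penetration" & sw2$scenario == "B-u", ]
  expect_gt(pen_u$pct_change_dose[pen_u$direction == "+SD"], 0)
  expect_lt(pen_u$pct_change_dose[pen_u$direction == "-SD"], 0)
  # penetration enters the outdoor-origin term linearly, so +/-SD shifts are
  # symmetric when the central value sits away from the [0, 1] truncation
  cfg_mid <- default_config()
  cfg_mid$population$shared$penetration <- c(mean = 0.5, sd = 0.06)
  swp <- sensitivity_sweep(cfg_mid, scenarios = "B-u",
                           parameters = "penetration", n_reps = 4000, seed = 7)
  up <- swp$pct_change_dose[swp$direction == "+SD"]
  dn <- swp$pct_change_dose[swp$direction == "-SD"]
  expect_equal(up, -dn, tolerance = 0.05)
  # smoking shift matters more (in % of dose) for urban than rural
  smoke <- sw2[sw2$parameter == "smoking" & sw2$direction == "+SD", ]
  expect_gt(smoke$pct_change_dose[smoke$scenario == "B-u"],
            smoke$pct_change_dose[smoke$scenario == "B-r"])
  expect_error(sensitivity_sweep(parameters = "humidity"), "humidity")
})

test_that("reports are written deterministically with a usable manifest", {
  cmp <- compare_scenarios(c("B-u", "SF-u", "IC-u"), n_reps = 400, seed = 2)
  out1 <- file.path(tempdir(), "rep1"); out2 <- file.path(tempdir(), "rep2")
  p1 <- write_reports(cmp, out1)
  expect_true(all(file.exists(unlist(p1))))
  expect_setequal(basename(unlist(p1)),
                  c("scenario_summaries.csv", "ranking.csv", "risk_table.csv",
                    "manifest.json"))
  rk <- read.csv(file.path(out1, "risk_table.csv"))
  expect_equal(nrow(rk), 3 * 4)   # scenarios x URR variants
  man <- jsonlite::read_json(file.path(out1, "manifest.json"))
  expect_equal(man$seed, 2); expect_equal(man$n_reps, 400)
  # byte-identical re-run from the same inputs
  cmp2 <- compare_scenarios(c("B-u", "SF-u", "IC-u"), n_reps = 400, seed = 2)
  write_reports(cmp2, out2)
  for (f in basename(unlist(p1)))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("run configs load from YAML with defaults and validation", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "population:",
    "  smoker_fraction: 0.25",
    "  rural:",
    "    coal_prevalence: 0.5",
    "risk:",
    "  urr: 3.0"
  ), path)
  cfg <- load_run_config(path)
  expect_equal(cfg$population$smoker_fraction, 0.25)
  expect_equal(cfg$population$rural$coal_prevalence, 0.5)
  expect_equal(cfg$risk$urr, 3.0)
  # untouched keys keep their defaults
  expect_equal(cfg$population$urban_fraction, 0.84)
  expect_equal(cfg$population$rural$ach[["mean"]], 0.59)

  writeLines(c("population:", "  smoker_fraction: 1.2"), path)
  expect_error(load_run_config(path), "smoker_fraction")
  expect_error(load_run_config(tempfile()), "not found")

  # the packaged example config validates and keeps the documented constants
  example <- system.file("extdata", "run_config_example.yaml",
                         package = "pahpopex")
  cfg_ex <- load_run_config(example)
  expect_equal(cfg_ex$population$smoker_fraction, 0.311)
  expect_equal(cfg_ex$risk$urr, 4.49)
  expect_equal(cfg_ex$intervention$cleaner_cadr, 134)
})
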
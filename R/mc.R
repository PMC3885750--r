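# Core vectorized exposure computation: from an (edited) population frame and
# outdoor field to per-individual exposure and risk metrics.
compute_population_exposure <- function(population, field, config) {
  pop <- population
  n <- nrow(pop)
  tefs <- config$tefs
  pfrac <- config$particle_fractions[names(tefs)]
  sh <- config$population$shared

  bp <- field_baep_by_phase(field, tefs, pfrac)       # [n x season] per phase
  efb <- ef_baep_by_phase(config$emission_factors, tefs)  # [source x phase]

  # 24-h averaged household B[a]Peq emission rates (ng/h)
  cook_part <- pop$coal_kg * efb["cooking_coal", "particle"] +
    pop$biomass_kg * efb["cooking_biomass", "particle"] +
    pop$lpg_kg * efb["cooking_lpg", "particle"]
  cook_gas <- pop$coal_kg * efb["cooking_coal", "gas"] +
    pop$biomass_kg * efb["cooking_biomass", "gas"] +
    pop$lpg_kg * efb["cooking_lpg", "gas"]
  e_part <- (pop$smoking_home * efb["smoking", "particle"] +
               pop$erf_cook * cook_part) / 24
  e_gas <- (pop$smoking_home * efb["smoking", "gas"] +
              pop$erf_cook * cook_gas) / 24

  # home: gas phase has P = 1, k = 0, no CADR effect
  loss_part <- pop$ach + pop$k_dep + pop$cadr / pop$volume
  home_out <- bp$particle * (pop$penetration * pop$ach / loss_part) + bp$gas
  home_in <- matrix((e_part / pop$volume) / loss_part +
                      (e_gas / pop$volume) / pop$ach, n, dim(field)[2])

  # workplace: simpler per-occupant zone, smoking the only indoor source
  wk <- sh$workplace
  loss_w <- wk$ach + sh$deposition_rate
  work_out <- (bp$particle * (pop$penetration * wk$ach / loss_w) + bp$gas) *
    pop$employed
  ew_part <- pop$smoking_work * efb["smoking", "particle"] / 24
  ew_gas <- pop$smoking_work * efb["smoking", "gas"] / 24
  work_in <- matrix(((ew_part / wk$volume) / loss_w +
                       (ew_gas / wk$volume) / wk$ach) * pop$employed,
                    n, dim(field)[2])

  outdoor <- bp$particle + bp$gas

  br <- sh$breathing
  vent <- br$daily_m3 / 24 * br$multipliers

  met <- annual_metrics(
    time_budget = pop,
    breathing = c(home = vent[["home"]], work = vent[["work"]],
                  outdoor = vent[["outdoor"]]),
    home_indoor_origin = home_in, home_outdoor_origin = home_out,
    work_indoor_origin = work_in, work_outdoor_origin = work_out,
    outdoor = outdoor, lifetime_years = config$risk$lifetime_years)

  home_mean <- rowMeans(home_in + home_out)
  out_mean <- rowMeans(outdoor)
  cbind(
    data.frame(region = pop$region, stringsAsFactors = FALSE),
    met,
    data.frame(
      home_conc_ng_m3 = home_mean,
      outdoor_conc_ng_m3 = out_mean,
      io_ratio = io_ratio(home_mean, out_mean),
      rr = relative_risk(met$c_life, config$risk$urr,
                         config$risk$reference_exposure)
    )
  )
}

summary_stats <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75, 0.95), type = 7, names = FALSE,
                       na.rm = TRUE)
  c(mean = mean(x, na.rm = TRUE), p25 = q[1], p75 = q[2], p95 = q[3])
}

#' Run one Monte Carlo scenario
#'
#' Samples `n_reps` individuals of the scenario's sub-population and one
#' outdoor concentration field per individual, applies the scenario's edits
#' under common random numbers, computes each individual's exposure and
#' relative risk, and aggregates distributional summaries. Fully reproducible
#' under a fixed seed.
#'
#' @param scenario Scenario id (see [scenario_registry()]) or definition.
#' @param config Full model configuration ([default_config()]).
#' @param n_reps Number of simulated individuals (default 10,000).
#' @param seed Integer seed.
#' @return Object of class `pah_run`: a list with `id`, `sub_population`,
#'   `n_reps`, `seed`, `individuals` (per-individual data frame), `summary`
#'   (mean/P25/P75/P95 of home indoor B\[a\]Peq, I/O ratio and annual dose),
#'   `pattern` ([pattern_statistics()] output), `mean_rr` and `paf`.
#' @export
run_scenario <- function(scenario, config = default_config(),
                         n_reps = 10000, seed = 1) {
  def <- get_scenario(scenario)
  if (n_reps < 1) stop("n_reps must be >= 1 (scenario ", def$id, ")")
  set.seed(seed)
  pop <- sample_population(n_reps, def$sub_population, config)
  field <- sample_outdoor_field(config$outdoor, n_reps,
                                config$correlated_congeners)
  ed <- apply_scenario(pop, field, def, config)
  ind <- compute_population_exposure(ed$population, ed$field, config)
  mean_rr <- mean(ind$rr)
  res <- list(
    id = def$id,
    label = def$label,
    sub_population = def$sub_population,
    n_reps = as.integer(n_reps),
    seed = seed,
    individuals = ind,
    summary = list(home_conc_ng_m3 = summary_stats(ind$home_conc_ng_m3),
                   io_ratio = summary_stats(ind$io_ratio),
                   annual_dose_ug = summary_stats(ind$annual_dose_ug)),
    pattern = pattern_statistics(ind),
    mean_rr = mean_rr,
    paf = population_attributable_fraction(mean_rr)
  )
  class(res) <- "pah_run"
  res
}

#' @export
print.pah_run <- function(x, ...) {
  cat("Monte Carlo exposure run:", x$id, "(", x$label, ")\n")
  cat(sprintf("  %d individuals, %s sub-population, seed %s\n",
              x$n_reps, x$sub_population, format(x$seed)))
  s <- x$summary
  for (m in names(s))
    cat(sprintf("  %-16s mean %8.3f  IQR [%.3f, %.3f]  P95 %8.3f\n",
                m, s[[m]]["mean"], s[[m]]["p25"], s[[m]]["p75"], s[[m]]["p95"]))
  cat(sprintf("  mean RR %.5f   PAF %.2f%%\n", x$mean_rr, 100 * x$paf))
  cat(sprintf("  mean exposure shares: IN-in %.3f, OUT-in %.3f, OUT-out %.3f\n",
              x$pattern$mean_share[["in_in"]],
              x$pattern$mean_share[["out_in"]],
              x$pattern$mean_share[["out_out"]]))
  invisible(x)
}

#' @export
summary.pah_run <- function(object, ...) {
  print(object)
  invisible(object$summary)
}

#' Compare intervention scenarios against their baselines
#'
#' Runs each requested scenario (baselines are added automatically) with the
#' same seed, computes each intervention's PIF against the baseline of its
#' sub-population, and ranks interventions by PIF (descending; ties broken by
#' scenario id).
#'
#' @param scenarios Character vector of scenario ids; defaults to all 15.
#' @param config Full model configuration.
#' @param n_reps Individuals per scenario.
#' @param seed Integer seed shared by all runs (common random numbers).
#' @return Object of class `pah_comparison`: list with `runs` (named list of
#'   `pah_run`), `table` (ranking data frame with mean_rr, paf, pif,
#'   paf_reduction_pct), `n_reps`, `seed`.
#' @export
compare_scenarios <- function(scenarios = names(scenario_registry()),
                              config = default_config(),
                              n_reps = 10000, seed = 1) {
  reg <- scenario_registry()
  bad <- setdiff(scenarios, names(reg))
  if (length(bad))
    stop("unknown scenario id(s): ", paste(bad, collapse = ", "),
         "; valid ids: ", paste(names(reg), collapse = ", "))
  baselines <- unique(vapply(reg[scenarios], `[[`, "", "baseline"))
  ids <- union(baselines, scenarios)
  ids <- names(reg)[names(reg) %in% ids]   # registry order
  runs <- lapply(ids, run_scenario, config = config, n_reps = n_reps,
                 seed = seed)
  names(runs) <- ids
  tab <- do.call(rbind, lapply(ids, function(id) {
    r <- runs[[id]]
    b <- runs[[reg[[id]]$baseline]]
    is_base <- id == b$id
    data.frame(
      scenario = id,
      sub_population = r$sub_population,
      baseline = b$id,
      mean_rr = r$mean_rr,
      paf = r$paf,
      pif = if (is_base) NA_real_ else
        potential_impact_fraction(b$mean_rr, r$mean_rr),
      paf_reduction_pct = if (is_base) NA_real_ else
        100 * (b$paf - r$paf) / b$paf,
      stringsAsFactors = FALSE
    )
  }))
  iv <- !is.na(tab$pif)
  ord <- c(which(iv)[order(-tab$pif[iv], tab$scenario[iv])], which(!iv))
  tab <- tab[ord, ]
  tab$rank <- c(seq_len(sum(iv)), rep(NA_integer_, sum(!iv)))
  rownames(tab) <- NULL
  res <- list(runs = runs, table = tab, n_reps = as.integer(n_reps),
              seed = seed)
  class(res) <- "pah_comparison"
  res
}

#' @export
print.pah_comparison <- function(x, ...) {
  cat(sprintf("Scenario comparison: %d runs, %d individuals each, seed %s\n",
              length(x$runs), x$n_reps, format(x$seed)))
  tab <- x$table
  tab$mean_rr <- sprintf("%.5f", tab$mean_rr)
  tab$paf <- sprintf("%.2f%%", 100 * tab$paf)
  tab$pif <- ifelse(is.na(x$table$pif), "-",
                    sprintf("%.2f%%", 100 * x$table$pif))
  tab$paf_reduction_pct <- ifelse(is.na(x$table$paf_reduction_pct), "-",
                                  sprintf("%.1f%%", x$table$paf_reduction_pct))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.pah_comparison <- function(x, ...) {
  tab <- x$table[!is.na(x$table$pif), ]
  graphics::barplot(100 * tab$pif, names.arg = tab$scenario, las = 2,
                    ylab = "PIF (%)",
                    col = ifelse(tab$sub_population == "urban",
                                 "grey40", "grey75"), ...)
  invisible(x)
}

# Shift one sensitivity parameter's central value by delta standard
# deviations, leaving the SD itself intact.
shift_config <- function(config, parameter, delta) {
  cfg <- config
  shift_meansd <- function(x, lower = 0, upper = Inf) {
    x[["mean"]] <- min(max(x[["mean"]] + delta * x[["sd"]], lower), upper)
    x
  }
  switch(parameter,
    ach = {
      for (reg in c("urban", "rural"))
        cfg$population[[reg]]$ach <- shift_meansd(cfg$population[[reg]]$ach)
    },
    winter_bap = {
      i <- cfg$outdoor$congener == "BaP" & cfg$outdoor$season == "winter"
      cfg$outdoor$median_ng_m3[i] <-
        max(cfg$outdoor$median_ng_m3[i] + delta * cfg$outdoor$sd_ng_m3[i], 0)
    },
    area = {
      for (reg in c("urban", "rural"))
        cfg$population[[reg]]$area <- shift_meansd(cfg$population[[reg]]$area)
    },
    biomass = {
      for (reg in c("urban", "rural"))
        cfg$population[[reg]]$biomass_kg <-
          shift_meansd(cfg$population[[reg]]$biomass_kg)
    },
    t_work = {
      cfg$population$shared$t_work <-
        shift_meansd(cfg$population$shared$t_work, upper = 24)
    },
    penetration = {
      cfg$population$shared$penetration <-
        shift_meansd(cfg$population$shared$penetration, upper = 1)
    },
    smoking = {
      cfg$population$shared$smoking <-
        shift_meansd(cfg$population$shared$smoking)
    },
    stop("unknown sensitivity parameter '", parameter, "'; valid: ",
         paste(sensitivity_parameters(), collapse = ", "))
  )
  cfg
}

#' Names of the one-at-a-time sensitivity parameters
#'
#' The seven inputs swept by [sensitivity_sweep()]: infiltration air-exchange
#' rate, winter outdoor BaP concentration, residential floor area, wood/crop
#' fuel quantity, time at work/school, penetration coefficient, and household
#' smoking quantity.
#'
#' @return Character vector of parameter names.
#' @export
sensitivity_parameters <- function() {
  c("ach", "winter_bap", "area", "biomass", "t_work", "penetration", "smoking")
}

#' One-at-a-time sensitivity sweep
#'
#' Shifts each parameter's central value by + and - one standard deviation
#' (the SD stays fixed), re-runs the requested scenarios under common random
#' numbers, and reports the percentage change in the mean annual inhalation
#' dose plus the PIF-based rank of each intervention under the shift.
#'
#' @param config Full model configuration.
#' @param scenarios Scenario ids to re-run (include baselines to obtain PIF
#'   ranks).
#' @param parameters Parameter names (see [sensitivity_parameters()]).
#' @param n_reps Individuals per run.
#' @param seed Integer seed shared by all runs.
#' @return Object of class `pah_sensitivity`: a data frame with one row per
#'   parameter x direction x scenario (`pct_change_dose`, `pif`, `rank`).
#' @export
sensitivity_sweep <- function(config = default_config(),
                              scenarios = c("B-u", "B-r"),
                              parameters = sensitivity_parameters(),
                              n_reps = 10000, seed = 1) {
  bad <- setdiff(parameters, sensitivity_parameters())
  if (length(bad))
    stop("unknown sensitivity parameter(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(sensitivity_parameters(), collapse = ", "))
  base <- compare_scenarios(scenarios, config, n_reps, seed)
  base_dose <- vapply(base$runs, function(r)
    r$summary$annual_dose_ug[["mean"]], 0)
  rows <- list()
  for (param in parameters) {
    for (delta in c(1, -1)) {
      cmp <- compare_scenarios(scenarios, shift_config(config, param, delta),
                               n_reps, seed)
      tab <- cmp$table
      dose <- vapply(cmp$runs[tab$scenario], function(r)
        r$summary$annual_dose_ug[["mean"]], 0)
      rows[[length(rows) + 1]] <- data.frame(
        parameter = param,
        direction = if (delta > 0) "+SD" else "-SD",
        scenario = tab$scenario,
        mean_dose_ug = unname(dose),
        pct_change_dose = 100 * (unname(dose) / base_dose[tab$scenario] - 1),
        pif = tab$pif,
        rank = tab$rank,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pah_sensitivity", "data.frame")
  out
}
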
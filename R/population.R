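#' Default population and housing configuration
#'
#' Parameters describing the simulated urban/rural population: demographic
#' fractions, per-region housing and fuel-use distributions (each a central
#' value and SD, sampled from truncated normal or lognormal laws), baseline
#' behaviour prevalences (exhaust-hood use, smoking prohibitions, chimneys for
#' coal users) and the shared time-activity / breathing-rate parameters.
#'
#' Central values and SDs reproduce the Beijing 2006 baseline the model was
#' built for: 84% urban residents, 31.1% smokers, 81% employed or in school,
#' infiltration air-exchange rate 0.31 (0.23) /h urban and 0.59 (0.47) /h
#' rural, residential floor area 53.4 (24.6) m2 urban and 128.9 (59.3) m2
#' rural, time at work/school 5.45 (3.01) h/day, penetration coefficient
#' 0.90 (0.06), household smoking quantity 9 (19) cigarettes/day, and
#' wood/crop-residue use 4.00 (2.61) kg/day in rural households.
#'
#' @return A nested list of class `population_config`.
#' @export
default_population_config <- function() {
  cfg <- list(
    urban_fraction = 0.84,
    male_fraction = 0.511,
    smoker_fraction = 0.311,
    employed_fraction = 0.72,
    school_age_fraction = 0.09,
    shared = list(
      t_work = c(mean = 5.45, sd = 3.01),          # h/day at work or school
      penetration = c(mean = 0.90, sd = 0.06),     # particle penetration, [0, 1]
      smoking = c(mean = 9, sd = 19),              # household cigarettes/day
      t_home = 16,                                 # h/day at home (central)
      ceiling_height = 2.7,                        # m
      deposition_rate = 0.2,                       # particle deposition, 1/h
      ach_min = 0.05,                              # lower truncation for ACH, 1/h
      area_min = 5,                                # lower truncation for area, m2
      chimney_erf = 0.10,   # emission fraction remaining indoors, coal + chimney
      hood_erf = 0.50,      # emission fraction remaining indoors, exhaust hood
      workplace = list(ach = 1.0, volume = 30),    # per-occupant workplace zone
      breathing = list(daily_m3 = 16,
                       multipliers = c(home = 0.8, work = 1.0, outdoor = 1.5))
    ),
    urban = list(
      ach = c(mean = 0.31, sd = 0.23),
      area = c(mean = 53.4, sd = 24.6),
      biomass_kg = c(mean = 0, sd = 0),
      coal_kg = c(mean = 0, sd = 0),
      coal_prevalence = 0,
      lpg_kg = c(mean = 0.4, sd = 0.2),
      hood_fraction = 0.30,
      home_smoking_ban = 0.20,
      work_smoking_ban = 0.30
    ),
    rural = list(
      ach = c(mean = 0.59, sd = 0.47),
      area = c(mean = 128.9, sd = 59.3),
      biomass_kg = c(mean = 4.00, sd = 2.61),
      coal_kg = c(mean = 2.0, sd = 1.5),
      coal_prevalence = 0.11 / 0.16,   # coal users are 11% of the whole population
      lpg_kg = c(mean = 0, sd = 0),
      hood_fraction = 0,
      home_smoking_ban = 0.10,
      work_smoking_ban = 0.10
    )
  )
  class(cfg) <- c("population_config", "list")
  cfg
}

# Truncated-normal sampler via inverse CDF. Always consumes exactly n
# uniforms so the random stream is identical across parameter settings
# (common random numbers across scenarios and sensitivity shifts).
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  u <- stats::runif(n)
  if (all(sd == 0)) return(pmin(pmax(rep(mean, length.out = n), lower), upper))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  x <- stats::qnorm(plo + u * (phi - plo), mean, sd)
  pmin(pmax(x, lower), upper)
}

# Lognormal matched to an arithmetic mean and SD; mean 0 gives a point mass
# at 0, sd 0 a point mass at the mean. Consumes exactly n uniforms.
rlnorm_meansd <- function(n, mean, sd) {
  u <- stats::runif(n)
  if (mean <= 0) return(rep(0, n))
  if (sd == 0) return(rep(mean, n))
  sigma2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - sigma2 / 2
  exp(mu + sqrt(sigma2) * stats::qnorm(u))
}

region_param <- function(regions, config, key, component = NULL) {
  u <- config$urban[[key]]; r <- config$rural[[key]]
  if (!is.null(component)) { u <- u[[component]]; r <- r[[component]] }
  ifelse(regions == "urban", u, r)
}

#' Sample a synthetic population
#'
#' Draws `n` individuals with region, demographics, household environment,
#' fuel use, smoking, and a 24-h time budget over the three microenvironments
#' (home indoor, work/school indoor, outdoor). Urban and rural scenario runs
#' fix the region; `region = "mixed"` assigns it with the configured urban
#' fraction.
#'
#' The sampling stream consumes the same number of random draws regardless of
#' parameter values, so runs that differ only in central values or scenario
#' edits are paired draw-for-draw (common random numbers).
#'
#' @param n Number of individuals (>= 1).
#' @param region `"urban"`, `"rural"` or `"mixed"`.
#' @param config A full model config (see [default_config()]) or a bare
#'   population config (see [default_population_config()]).
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @return A data frame of class `pah_population`, one row per individual.
#' @export
sample_population <- function(n, region = c("urban", "rural", "mixed"),
                              config = default_config(), seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  region <- match.arg(region)
  if (!is.null(seed)) set.seed(seed)
  pc <- if (!is.null(config$population)) config$population else config
  validate_population_config(pc)
  sh <- pc$shared

  regions <- if (region == "mixed") {
    ifelse(stats::runif(n) < pc$urban_fraction, "urban", "rural")
  } else {
    stats::runif(n)  # keep the stream aligned across region modes
    rep(region, n)
  }

  is_smoker <- stats::runif(n) < pc$smoker_fraction
  employed <- stats::runif(n) <
    (pc$employed_fraction + pc$school_age_fraction)

  ach <- rtnorm(n, region_param(regions, pc, "ach", "mean"),
                region_param(regions, pc, "ach", "sd"), lower = sh$ach_min)
  area <- rtnorm(n, region_param(regions, pc, "area", "mean"),
                 region_param(regions, pc, "area", "sd"), lower = sh$area_min)
  penetration <- rtnorm(n, sh$penetration[["mean"]], sh$penetration[["sd"]],
                        lower = 0, upper = 1)
  t_work_draw <- rtnorm(n, sh$t_work[["mean"]], sh$t_work[["sd"]],
                        lower = 0, upper = 24 - sh$t_home)

  smoking_home <- rlnorm_meansd(n, sh$smoking[["mean"]], sh$smoking[["sd"]])
  smoking_home[stats::runif(n) <
                 region_param(regions, pc, "home_smoking_ban")] <- 0
  smoking_work <- rlnorm_meansd(n, sh$smoking[["mean"]], sh$smoking[["sd"]])
  smoking_work[stats::runif(n) <
                 region_param(regions, pc, "work_smoking_ban")] <- 0
  smoking_work[!employed] <- 0

  hood_user <- stats::runif(n) < region_param(regions, pc, "hood_fraction")
  coal_user <- stats::runif(n) < region_param(regions, pc, "coal_prevalence")

  coal_kg <- numeric(n); biomass_kg <- numeric(n); lpg_kg <- numeric(n)
  for (reg in c("urban", "rural")) {
    idx <- regions == reg
    coal_kg[idx] <- rlnorm_meansd(n, pc[[reg]]$coal_kg[["mean"]],
                                  pc[[reg]]$coal_kg[["sd"]])[idx]
    biomass_kg[idx] <- rlnorm_meansd(n, pc[[reg]]$biomass_kg[["mean"]],
                                     pc[[reg]]$biomass_kg[["sd"]])[idx]
    lpg_kg[idx] <- rlnorm_meansd(n, pc[[reg]]$lpg_kg[["mean"]],
                                 pc[[reg]]$lpg_kg[["sd"]])[idx]
  }
  coal_kg[!coal_user] <- 0
  u_select <- stats::runif(n)   # reserved for scenario household selection

  budget <- build_time_budget(employed, t_work_draw, sh)

  erf_cook <- ifelse(coal_user, sh$chimney_erf,
                     ifelse(hood_user, sh$hood_erf, 1))

  pop <- data.frame(
    region = regions,
    is_smoker = is_smoker,
    employed = employed,
    floor_area = area,
    volume = area * sh$ceiling_height,
    ach = ach,
    penetration = penetration,
    k_dep = sh$deposition_rate,
    cadr = 0,
    hours_home = budget$hours_home,
    hours_work = budget$hours_work,
    hours_outdoor = budget$hours_outdoor,
    smoking_home = smoking_home,
    smoking_work = smoking_work,
    hood_user = hood_user,
    coal_user = coal_user,
    coal_kg = coal_kg,
    biomass_kg = biomass_kg,
    lpg_kg = lpg_kg,
    erf_cook = erf_cook,
    u_select = u_select,
    stringsAsFactors = FALSE
  )
  class(pop) <- c("pah_population", "data.frame")
  pop
}

#' Sample a single synthetic individual
#'
#' Convenience wrapper around [sample_population()] returning one individual
#' as a list with the household environment and time budget broken out.
#'
#' @inheritParams sample_population
#' @return A list of class `pah_individual`.
#' @export
sample_individual <- function(region = c("urban", "rural"),
                              config = default_config(), seed = NULL) {
  region <- match.arg(region)
  row <- as.list(sample_population(1L, region, config, seed))
  ind <- list(
    region = row$region,
    is_smoker = row$is_smoker,
    is_employed_or_student = row$employed,
    time_budget = list(hours_home_indoor = row$hours_home,
                       hours_work_school_indoor = row$hours_work,
                       hours_outdoor = row$hours_outdoor),
    household = list(floor_area = row$floor_area,
                     volume = row$volume,
                     ach = row$ach,
                     penetration = row$penetration,
                     deposition_rate_particle = row$k_dep,
                     cadr = row$cadr,
                     fuel_use = c(coal = row$coal_kg, biomass = row$biomass_kg,
                                  lpg = row$lpg_kg),
                     cooking_erf = row$erf_cook,
                     smoking_cigarettes_per_day = row$smoking_home)
  )
  class(ind) <- "pah_individual"
  ind
}

#' Build a 24-hour time budget
#'
#' Hours at work/school are drawn from the configured distribution truncated
#' to `[0, 24 - t_home]`; home hours are centred on 16 h/day; outdoor time is
#' the remainder, so the three components always sum to 24. Individuals who
#' are neither employed nor in school have their work hours reallocated to
#' home.
#'
#' @param employed Logical vector.
#' @param t_work_draw Sampled work/school hours (already truncated).
#' @param shared The `shared` block of a population config.
#' @return A list of three numeric vectors: `hours_home`, `hours_work`,
#'   `hours_outdoor`.
#' @export
build_time_budget <- function(employed, t_work_draw, shared) {
  t_home <- shared$t_home
  hours_home <- ifelse(employed, t_home, t_home + t_work_draw)
  hours_work <- ifelse(employed, t_work_draw, 0)
  hours_outdoor <- 24 - hours_home - hours_work
  list(hours_home = hours_home, hours_work = hours_work,
       hours_outdoor = pmax(hours_outdoor, 0))
}

check_prop <- function(x, key) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop("configuration key '", key, "' must be a proportion in [0, 1]")
}

check_meansd <- function(x, key) {
  if (!is.numeric(x) || length(x) != 2 || anyNA(x))
    stop("configuration key '", key, "' must be c(mean, sd)")
  if (x[["sd"]] < 0) stop("configuration key '", key, "' has negative SD")
}

#' Validate a population configuration
#'
#' Checks that all proportions lie in \[0, 1\], all SDs are non-negative and
#' the physical parameters are usable. Errors name the offending key.
#'
#' @param config A population config.
#' @return The config, invisibly.
#' @export
validate_population_config <- function(config) {
  for (key in c("urban_fraction", "male_fraction", "smoker_fraction",
                "employed_fraction", "school_age_fraction"))
    check_prop(config[[key]], key)
  if (config$employed_fraction + config$school_age_fraction > 1)
    stop("employed_fraction + school_age_fraction must not exceed 1")
  sh <- config$shared
  for (key in c("t_work", "penetration", "smoking"))
    check_meansd(sh[[key]], paste0("shared$", key))
  if (sh$t_home < 0 || sh$t_home > 24) stop("shared$t_home must lie in [0, 24]")
  if (sh$ceiling_height <= 0) stop("shared$ceiling_height must be > 0")
  if (sh$deposition_rate < 0) stop("shared$deposition_rate must be >= 0")
  if (sh$ach_min <= 0) stop("shared$ach_min must be > 0")
  check_prop(sh$chimney_erf, "shared$chimney_erf")
  check_prop(sh$hood_erf, "shared$hood_erf")
  for (reg in c("urban", "rural")) {
    rc <- config[[reg]]
    for (key in c("ach", "area", "biomass_kg", "coal_kg", "lpg_kg"))
      check_meansd(rc[[key]], paste0(reg, "$", key))
    for (key in c("coal_prevalence", "hood_fraction", "home_smoking_ban",
                  "work_smoking_ban"))
      check_prop(rc[[key]], paste0(reg, "$", key))
  }
  invisible(config)
}
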
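#' Default model configuration
#'
#' Assembles the full configuration: population/housing parameters, the
#' packaged seasonal outdoor concentration table, TEFs, particle-bound
#' fractions, emission factors, the risk model (URR 4.49, reference exposure
#' 100 ug/m3.year, 70-year lifetime, alternative URR 1.30), and the
#' intervention constants (WHO BaP guideline 1.2 ng/m3, BaP share of
#' B\[a\]Peq 0.381, cleaner CADR 134 m3/h operated 16 h/day, fuel energy
#' densities for the clean-fuel shift).
#'
#' @return A nested list of class `pah_config`.
#' @export
default_config <- function() {
  cfg <- list(
    population = default_population_config(),
    outdoor = read_congener_table(),
    tefs = read_tefs(),
    particle_fractions = read_particle_fractions(),
    correlated_congeners = TRUE,
    emission_factors = read_emission_factors(),
    risk = list(urr = 4.49, reference_exposure = 100, lifetime_years = 70,
                urr_alternative = 1.30),
    intervention = list(
      who_bap_guideline = 1.2,   # ng/m3 BaP
      bap_fraction = 0.381,      # average BaP share of total B[a]Peq
      cleaner_cadr = 134,        # m3/h
      cleaner_hours = 16,        # h/day of cleaner operation
      energy_density = c(coal = 23, biomass = 15.5, lpg = 46.1)  # MJ/kg
    )
  )
  class(cfg) <- c("pah_config", "list")
  cfg
}

#' Validate a full model configuration
#'
#' Schema checks for every block; errors name the offending key and the
#' violated constraint.
#'
#' @param config A full model configuration.
#' @return The config, invisibly.
#' @export
validate_config <- function(config) {
  need <- c("population", "outdoor", "tefs", "particle_fractions",
            "emission_factors", "risk", "intervention")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("configuration is missing block(s): ", paste(missing, collapse = ", "))
  validate_population_config(config$population)
  if (!inherits(config$outdoor, "congener_table"))
    stop("outdoor must be a congener_table (see read_congener_table)")
  if (abs(config$tefs[["BaP"]] - 1) > 1e-12) stop("tefs: TEF(BaP) must be 1")
  if (any(config$particle_fractions < 0 | config$particle_fractions > 1))
    stop("particle_fractions must lie in [0, 1]")
  rk <- config$risk
  if (rk$urr <= 1) stop("risk$urr must be > 1")
  if (rk$reference_exposure <= 0) stop("risk$reference_exposure must be > 0")
  if (rk$lifetime_years < 0) stop("risk$lifetime_years must be >= 0")
  iv <- config$intervention
  if (iv$bap_fraction <= 0 || iv$bap_fraction > 1)
    stop("intervention$bap_fraction must lie in (0, 1]")
  if (iv$cleaner_cadr < 0) stop("intervention$cleaner_cadr must be >= 0")
  if (iv$cleaner_hours < 0 || iv$cleaner_hours > 24)
    stop("intervention$cleaner_hours must lie in [0, 24]")
  if (any(iv$energy_density <= 0))
    stop("intervention$energy_density must be > 0")
  invisible(config)
}

merge_lists <- function(base, override) {
  for (key in names(override)) {
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_lists(base[[key]], override[[key]])
    } else if (is.numeric(base[[key]]) && !is.null(names(base[[key]])) &&
               is.list(override[[key]])) {
      v <- unlist(override[[key]])
      base[[key]][names(v)] <- v
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Load a run configuration from a structured text file
#'
#' Reads a YAML file of overrides, merges it over the packaged defaults,
#' resolves any referenced data files (`outdoor_csv`, `tef_csv`,
#' `particle_fraction_csv`, `emission_factor_csv`) and validates the result.
#' Absent keys keep their documented defaults.
#'
#' @param path YAML file path.
#' @return A validated configuration of class `pah_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  override <- yaml::read_yaml(path)
  cfg <- default_config()
  if (!is.null(override$outdoor_csv)) cfg$outdoor <- read_congener_table(override$outdoor_csv)
  if (!is.null(override$tef_csv)) cfg$tefs <- read_tefs(override$tef_csv)
  if (!is.null(override$particle_fraction_csv))
    cfg$particle_fractions <- read_particle_fractions(override$particle_fraction_csv)
  if (!is.null(override$emission_factor_csv))
    cfg$emission_factors <- read_emission_factors(override$emission_factor_csv)
  override[c("outdoor_csv", "tef_csv", "particle_fraction_csv",
         "emission_factor_csv")] <- NULL
  pop_class <- class(cfg$population)
  cfg <- merge_lists(cfg, override)
  class(cfg$population) <- pop_class
  class(cfg) <- c("pah_config", "list")
  validate_config(cfg)
  cfg
}
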
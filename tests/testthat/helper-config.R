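# Shared fixtures: degenerate (zero-SD) configurations and analytic moments
# of the truncated sampling distributions, used as oracles.

zero_sd_population_config <- function() {
  pc <- default_population_config()
  for (reg in c("urban", "rural"))
    for (key in c("ach", "area", "biomass_kg", "coal_kg", "lpg_kg"))
      pc[[reg]][[key]][["sd"]] <- 0
  for (key in c("t_work", "penetration", "smoking"))
    pc$shared[[key]][["sd"]] <- 0
  pc
}

zero_sd_config <- function() {
  cfg <- default_config()
  cfg$population <- zero_sd_population_config()
  cfg$outdoor$sd_ng_m3 <- 0
  cfg
}

# config with all indoor emissions and outdoor concentrations removed
zero_exposure_config <- function() {
  cfg <- default_config()
  cfg$outdoor$median_ng_m3 <- 0
  cfg$outdoor$sd_ng_m3 <- 0
  cfg$emission_factors$ng_per_unit <- 0
  cfg
}

# mean of a normal truncated to [lo, hi]
tnorm_mean <- function(m, s, lo = -Inf, hi = Inf) {
  if (s == 0) return(min(max(m, lo), hi))
  a <- (lo - m) / s; b <- (hi - m) / s
  m + s * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# toy emission-factor table: a single congener emitted, for hand arithmetic
toy_ef_table <- function(congener = "BaP", source = "cooking_coal",
                         ng = 1000, phase = "particle") {
  tab <- data.frame(source = source, congener = congener, phase = phase,
                    ng_per_unit = ng, stringsAsFactors = FALSE)
  class(tab) <- c("emission_factor_table", "data.frame")
  tab
}
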
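#' Read an indoor emission-factor table
#'
#' CSV with columns `source`, `congener`, `phase`, `ng_per_unit`: nanograms of
#' each congener emitted per unit of source activity (one cigarette, or one kg
#' of fuel burned), split into gas and particle phase. The packaged defaults
#' are editable placeholder values: per-source emission inventories for the
#' study region are not public, so the shipped table carries a
#' literature-plausible congener profile scaled per source; all deterministic
#' identities in the package are independent of these absolute values.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return A validated data frame of class `emission_factor_table`.
#' @export
read_emission_factors <- function(path = ext_file("emission_factors.csv")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("source", "congener", "phase", "ng_per_unit")
  if (!all(need %in% names(tab)))
    stop("emission-factor table must have columns: ", paste(need, collapse = ", "))
  known <- c("smoking", "cooking_coal", "cooking_biomass", "cooking_lpg")
  if (!all(tab$source %in% known))
    stop("unknown emission source(s): ",
         paste(setdiff(tab$source, known), collapse = ", "))
  if (!all(tab$phase %in% c("gas", "particle")))
    stop("phase must be 'gas' or 'particle'")
  if (any(tab$ng_per_unit < 0)) stop("emission factors must be >= 0")
  class(tab) <- c("emission_factor_table", "data.frame")
  tab
}

# Collapse an emission-factor table to B[a]Peq per unit activity:
# matrix [source x phase] of sum_i TEF_i * EF_i (ng B[a]Peq per unit).
ef_baep_by_phase <- function(ef_table, tefs) {
  sources <- c("smoking", "cooking_coal", "cooking_biomass", "cooking_lpg")
  out <- matrix(0, length(sources), 2,
                dimnames = list(sources, c("gas", "particle")))
  for (i in seq_len(nrow(ef_table))) {
    cg <- ef_table$congener[i]
    if (!cg %in% names(tefs)) next
    out[ef_table$source[i], ef_table$phase[i]] <-
      out[ef_table$source[i], ef_table$phase[i]] +
      tefs[[cg]] * ef_table$ng_per_unit[i]
  }
  out
}

fuel_source_map <- c(coal = "cooking_coal", biomass = "cooking_biomass",
                     lpg = "cooking_lpg")

#' Build a household indoor emission inventory
#'
#' Converts household activity (smoking cigarettes/day, cooking fuel kg/day)
#' into 24-h-averaged per-congener, per-phase emission rates (ng/h):
#' `E = (cigarettes * EF_cig + sum_fuel kg * EF_fuel * ERF) / 24`, where the
#' emission-remaining factor ERF is the fraction of cooking emissions staying
#' indoors (0.10 for coal users with chimneys, 0.50 for exhaust-hood users,
#' 1 otherwise; smoking is never exhausted).
#'
#' @param household List with `smoking_cigarettes_per_day`, `fuel_use` (named
#'   kg/day vector over `coal`, `biomass`, `lpg`) and `cooking_erf`.
#' @param ef_table An emission-factor table ([read_emission_factors()]).
#' @param remove_smoking Zero the smoking component (smoking-free scenario)?
#' @param erf_multiplier Extra multiplicative factor on current cooking
#'   emissions (exhaust intervention scenarios).
#' @return List with `total` (congener x phase matrix, ng/h) and `by_source`
#'   (congener x phase x source array).
#' @export
build_emission_inventory <- function(household, ef_table,
                                     remove_smoking = FALSE,
                                     erf_multiplier = 1) {
  fuels <- household$fuel_use
  unknown <- setdiff(names(fuels), names(fuel_source_map))
  if (length(unknown))
    stop("unknown fuel(s) in household: ", paste(unknown, collapse = ", "))
  sources <- c("smoking", unname(fuel_source_map))
  congeners <- pah_congeners
  by_source <- array(0, dim = c(length(congeners), 2, length(sources)),
                     dimnames = list(congeners, c("gas", "particle"), sources))
  for (i in seq_len(nrow(ef_table))) {
    by_source[ef_table$congener[i], ef_table$phase[i], ef_table$source[i]] <-
      ef_table$ng_per_unit[i]
  }
  cig <- if (remove_smoking) 0 else household$smoking_cigarettes_per_day
  by_source[, , "smoking"] <- by_source[, , "smoking"] * cig / 24
  erf <- household$cooking_erf * erf_multiplier
  for (src in unname(fuel_source_map)) {
    fuel <- names(fuel_source_map)[fuel_source_map == src]
    qty <- if (fuel %in% names(fuels)) fuels[[fuel]] else 0
    by_source[, , src] <- by_source[, , src] * qty * erf / 24
  }
  list(total = apply(by_source, c(1, 2), sum), by_source = by_source)
}

#' Steady-state indoor concentration (single-zone mass balance)
#'
#' Well-mixed single-zone balance at steady state for one phase:
#' `loss = a + k + CADR/V`; the outdoor-origin component is
#' `P * a * C_out / loss` and the indoor-origin component `(E/V) / loss`.
#' The gas phase takes `P = 1`, `k = 0` and no CADR effect; the particle
#' phase uses the household's penetration, deposition and cleaner rates.
#'
#' @param c_out Outdoor concentration of the phase (ng/m3).
#' @param emission Indoor emission rate of the phase (ng/h).
#' @param volume Zone volume (m3).
#' @param ach Air exchange rate `a` (1/h), > 0.
#' @param penetration Penetration coefficient `P` in \[0, 1\] (1 for gas).
#' @param deposition Deposition rate `k` (1/h; 0 for gas).
#' @param cadr Time-averaged clean-air delivery rate (m3/h; 0 for gas).
#' @return List with `total`, `outdoor_origin`, `indoor_origin` (ng/m3);
#'   `total` is exactly their sum.
#' @export
steady_state_concentration <- function(c_out, emission, volume, ach,
                                       penetration = 1, deposition = 0,
                                       cadr = 0) {
  loss <- ach + deposition + cadr / volume
  if (any(loss <= 0)) stop("total loss rate must be > 0 (unventilated zone)")
  outdoor_origin <- penetration * ach * c_out / loss
  indoor_origin <- (emission / volume) / loss
  list(total = outdoor_origin + indoor_origin,
       outdoor_origin = outdoor_origin,
       indoor_origin = indoor_origin)
}

#' Indoor/outdoor concentration ratio
#'
#' @param indoor Indoor B\[a\]Peq concentration (ng/m3).
#' @param outdoor Outdoor B\[a\]Peq concentration (ng/m3); ratios where the
#'   outdoor concentration is zero are returned as `NA` with a warning.
#' @return `indoor / outdoor`.
#' @export
io_ratio <- function(indoor, outdoor) {
  bad <- outdoor <= 0
  if (any(bad)) warning("I/O ratio undefined where outdoor concentration is 0")
  out <- indoor / outdoor
  out[bad] <- NA_real_
  out
}
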
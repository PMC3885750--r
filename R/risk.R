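#' Lifetime relative risk of lung cancer from PAH exposure
#'
#' The unit relative risk (URR) is the relative risk after a lifetime
#' exposure of 100 ug/m3.year of BaP; a lifetime B\[a\]Peq exposure
#' concentration `C` then carries `RR = URR^(C / 100)`. The packaged default
#' URR of 4.49 comes from a Chinese-population study; 1.30 is the alternative
#' for Asian populations used in the URR sensitivity table.
#'
#' @param c_life Lifetime exposure concentration (ug/m3.year), >= 0.
#' @param urr Unit relative risk, > 0.
#' @param reference_exposure Exposure defining the URR (ug/m3.year).
#' @return Relative risk (dimensionless).
#' @export
relative_risk <- function(c_life, urr = 4.49, reference_exposure = 100) {
  if (any(c_life < 0)) stop("lifetime exposure must be >= 0")
  if (any(urr <= 0)) stop("URR must be > 0")
  if (reference_exposure <= 0) stop("reference exposure must be > 0")
  urr^(c_life / reference_exposure)
}

#' Population attributable fraction
#'
#' The proportional reduction in disease that would occur if the exposure
#' were removed entirely: `PAF = (RRbar - 1) / RRbar`, with `RRbar` the mean
#' relative risk over all simulated individuals.
#'
#' @param mean_rr Mean relative risk, >= 1.
#' @return PAF as a fraction in \[0, 1).
#' @export
population_attributable_fraction <- function(mean_rr) {
  if (any(mean_rr < 1 - 1e-12))
    stop("mean relative risk must be >= 1")
  (mean_rr - 1) / mean_rr
}

#' Mean relative risk implied by a PAF
#'
#' Inverts `PAF = (RR - 1)/RR` to `RR = 1 / (1 - PAF)`; used to recover mean
#' relative risks from reported PAF values.
#'
#' @param paf PAF as a fraction in \[0, 1).
#' @return Mean relative risk.
#' @export
rr_from_paf <- function(paf) {
  if (any(paf < 0 | paf >= 1)) stop("PAF must lie in [0, 1)")
  1 / (1 - paf)
}

#' Potential impact fraction
#'
#' The proportional reduction in disease if the exposure were reduced to the
#' non-minimal counterfactual of an intervention:
#' `PIF = (RRbar_baseline - RRbar_intervention) / RRbar_baseline`,
#' equivalently `1 - (1 - PAF_b) / (1 - PAF_i)`. A negative PIF (an
#' intervention that worsens exposure) is allowed.
#'
#' @param mean_rr_baseline Mean relative risk in the baseline scenario.
#' @param mean_rr_intervention Mean relative risk under the intervention.
#' @return PIF as a fraction.
#' @export
potential_impact_fraction <- function(mean_rr_baseline, mean_rr_intervention) {
  if (any(mean_rr_baseline < 1 - 1e-12) || any(mean_rr_intervention < 1 - 1e-12))
    stop("mean relative risks must be >= 1")
  (mean_rr_baseline - mean_rr_intervention) / mean_rr_baseline
}

#' PAF/PIF table across URR variants
#'
#' Recomputes PAF (and PIF against the matching baseline) for each scenario
#' under four URR values: the default, +/-20%, and an alternative value, and
#' ranks interventions by PIF within each URR. The per-individual lifetime
#' exposures are fixed; only the dose-response changes.
#'
#' @param c_life_by_scenario Named list of per-individual lifetime exposure
#'   vectors (ug/m3.year), one element per scenario.
#' @param baseline_of Named character vector mapping each scenario id to the
#'   id of its baseline (baselines map to themselves).
#' @param urr Default URR.
#' @param urr_alternative Alternative URR.
#' @param reference_exposure Exposure defining the URR (ug/m3.year).
#' @return Data frame with one row per scenario x URR: `scenario`,
#'   `urr_label`, `urr`, `mean_rr`, `paf`, `pif` (NA for baselines), `rank`
#'   (by PIF, descending, within URR).
#' @export
urr_sensitivity_table <- function(c_life_by_scenario, baseline_of,
                                  urr = 4.49, urr_alternative = 1.30,
                                  reference_exposure = 100) {
  ids <- names(c_life_by_scenario)
  missing_base <- setdiff(unname(baseline_of[ids]), ids)
  if (length(missing_base))
    stop("baseline scenario(s) missing from inputs: ",
         paste(missing_base, collapse = ", "))
  urrs <- c(urr, urr * 1.2, urr * 0.8, urr_alternative)
  labels <- c(sprintf("URR=%.4g", urr), "URR+20%", "URR-20%",
              sprintf("URR=%.4g", urr_alternative))
  out <- list()
  for (k in seq_along(urrs)) {
    mean_rr <- vapply(c_life_by_scenario, function(cl)
      mean(relative_risk(cl, urrs[k], reference_exposure)), 0)
    paf <- population_attributable_fraction(mean_rr)
    pif <- potential_impact_fraction(mean_rr[baseline_of[ids]], mean_rr)
    pif[ids == baseline_of[ids]] <- NA_real_
    df <- data.frame(scenario = ids, urr_label = labels[k], urr = urrs[k],
                     mean_rr = unname(mean_rr), paf = unname(paf),
                     pif = unname(pif), stringsAsFactors = FALSE)
    # rank interventions by PIF (descending); ties broken by scenario id
    iv <- !is.na(df$pif)
    df$rank <- NA_integer_
    df$rank[iv] <- order(order(-df$pif[iv], df$scenario[iv]))
    out[[k]] <- df
  }
  do.call(rbind, out)
}
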
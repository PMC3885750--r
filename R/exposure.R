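#' Exposure in one microenvironment
#'
#' Inhalation exposure is the product of the concentration there, the time
#' spent there and the pulmonary ventilation rate while there.
#'
#' @param conc Concentration (ng/m3).
#' @param hours Time spent (h).
#' @param vent Pulmonary ventilation rate (m3/h).
#' @return Inhaled amount (ng).
#' @export
microenvironment_exposure <- function(conc, hours, vent) {
  if (any(conc < 0) || any(hours < 0) || any(vent < 0))
    stop("concentration, hours and ventilation rate must be >= 0")
  conc * hours * vent
}

as_season_matrix <- function(x, n, ns) {
  if (is.matrix(x)) {
    if (nrow(x) != n || ncol(x) != ns) stop("season matrix has wrong shape")
    return(x)
  }
  matrix(x, n, ns)
}

#' Annual exposure metrics per individual
#'
#' Integrates microenvironment B\[a\]Peq concentrations over each
#' individual's daily time budget and the seasons of the year into an annual
#' inhaled dose, a time-weighted exposure concentration, a lifetime exposure
#' concentration, and the decomposition of exposure into the IN-in (indoors,
#' indoor-origin), OUT-in (indoors, outdoor-origin) and OUT-out (outdoors)
#' patterns. IN-out exposure (a household's own emissions met outdoors) is
#' not modelled.
#'
#' Concentration arguments are `n x S` matrices (individual x season) or
#' vectors recycled across seasons; seasons get equal weight
#' (`365.25 / S` days each).
#'
#' @param time_budget Data frame or list with `hours_home`, `hours_work`,
#'   `hours_outdoor` (h/day, summing to 24).
#' @param breathing Named vector `c(home=, work=, outdoor=)` of ventilation
#'   rates (m3/h).
#' @param home_indoor_origin,home_outdoor_origin Home indoor B\[a\]Peq
#'   components (ng/m3).
#' @param work_indoor_origin,work_outdoor_origin Workplace components
#'   (ng/m3).
#' @param outdoor Outdoor B\[a\]Peq concentration (ng/m3).
#' @param lifetime_years Exposure duration used for the lifetime
#'   concentration (years).
#' @return Data frame with columns `annual_dose_ug`, `twa_conc_ng_m3`,
#'   `c_life` (ug/m3.year), `share_in_in`, `share_out_in`, `share_out_out`.
#' @export
annual_metrics <- function(time_budget, breathing,
                           home_indoor_origin, home_outdoor_origin,
                           work_indoor_origin, work_outdoor_origin,
                           outdoor, lifetime_years = 70) {
  th <- time_budget$hours_home
  tw <- time_budget$hours_work
  to <- time_budget$hours_outdoor
  n <- length(th)
  ns <- if (is.matrix(outdoor)) ncol(outdoor) else 1L
  season_days <- 365.25 / ns

  hi <- as_season_matrix(home_indoor_origin, n, ns)
  ho <- as_season_matrix(home_outdoor_origin, n, ns)
  wi <- as_season_matrix(work_indoor_origin, n, ns)
  wo <- as_season_matrix(work_outdoor_origin, n, ns)
  oc <- as_season_matrix(outdoor, n, ns)

  vh <- breathing[["home"]]; vw <- breathing[["work"]]; vo <- breathing[["outdoor"]]

  # daily inhaled amounts (ng/day) by pattern, per season, then annualized
  in_in <- (hi * th) * vh + (wi * tw) * vw
  out_in <- (ho * th) * vh + (wo * tw) * vw
  out_out <- (oc * to) * vo

  dose_in_in <- rowSums(in_in) * season_days
  dose_out_in <- rowSums(out_in) * season_days
  dose_out_out <- rowSums(out_out) * season_days
  total <- dose_in_in + dose_out_in + dose_out_out

  twa <- rowMeans(((hi + ho) * th + (wi + wo) * tw + oc * to) / 24)
  share <- function(x) ifelse(total > 0, x / total, 0)

  data.frame(
    annual_dose_ug = total / 1000,
    twa_conc_ng_m3 = twa,
    c_life = lifetime_concentration(twa, lifetime_years),
    share_in_in = share(dose_in_in),
    share_out_in = share(dose_out_in),
    share_out_out = share(dose_out_out)
  )
}

#' Lifetime exposure concentration
#'
#' Converts a time-weighted average B\[a\]Peq concentration (ng/m3) into the
#' lifetime exposure concentration in ug/m3.year used by the risk model.
#'
#' @param twa_conc_ng_m3 Time-weighted concentration (ng/m3).
#' @param lifetime_years Exposure duration (years).
#' @return Lifetime exposure concentration (ug/m3.year).
#' @export
lifetime_concentration <- function(twa_conc_ng_m3, lifetime_years = 70) {
  if (any(twa_conc_ng_m3 < 0) || any(lifetime_years < 0))
    stop("inputs must be >= 0")
  twa_conc_ng_m3 * lifetime_years / 1000
}

#' Summary statistics of exposure patterns
#'
#' For the IN-in / OUT-in / OUT-out shares of a set of individuals, reports
#' the mean share of each pattern, the fraction of individuals for which each
#' pattern is the dominating one (largest share; ties broken by the fixed
#' priority OUT-in > IN-in > OUT-out and counted once), and the fraction for
#' which the pattern composes over half of total exposure.
#'
#' @param shares Data frame or matrix with columns `share_in_in`,
#'   `share_out_in`, `share_out_out`.
#' @return List with `mean_share`, `dominance_rate`, `over_half_rate`, each a
#'   named vector over the three patterns.
#' @export
pattern_statistics <- function(shares) {
  shares <- as.data.frame(shares)
  cols <- c("share_in_in", "share_out_in", "share_out_out")
  if (!all(cols %in% names(shares)))
    stop("shares must have columns ", paste(cols, collapse = ", "))
  if (nrow(shares) == 0) stop("shares must be non-empty")
  m <- as.matrix(shares[cols])
  patterns <- c("in_in", "out_in", "out_out")
  colnames(m) <- patterns
  # tie-break priority: OUT-in, then IN-in, then OUT-out
  prio <- m[, c("out_in", "in_in", "out_out"), drop = FALSE]
  winner <- c("out_in", "in_in", "out_out")[max.col(prio, ties.method = "first")]
  list(
    mean_share = colMeans(m),
    dominance_rate = vapply(patterns, function(p) mean(winner == p), 0),
    over_half_rate = vapply(patterns, function(p) mean(m[, p] > 0.5), 0)
  )
}
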
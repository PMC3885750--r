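#' The 16 USEPA priority PAH congeners
#'
#' Congener short names in the conventional order, naphthalene (Nap) through
#' benzo[g,h,i]perylene (BghiP).
#'
#' @export
pah_congeners <- c("Nap", "Acy", "Ace", "Fluo", "Phe", "Ant", "Flu", "Pyr",
                   "Chry", "BaA", "BbF", "BkF", "BaP", "DBA", "IP", "BghiP")

#' Season labels used throughout the package
#' @export
pah_seasons <- c("spring", "summer", "autumn", "winter")

ext_file <- function(name) {
  path <- system.file("extdata", name, package = "pahpopex")
  if (!nzchar(path)) stop("packaged data file not found: ", name)
  path
}

#' Read a seasonal congener concentration table
#'
#' Reads a CSV with columns `congener`, `season`, `median_ng_m3`, `sd_ng_m3`
#' describing the seasonal-average outdoor concentration of each of the 16
#' priority congeners. The packaged default holds the Beijing 2005-2007
#' measurement summary the model is built on.
#'
#' @param path CSV path; defaults to the packaged table.
#' @return A validated data frame of class `congener_table` (64 rows).
#' @export
read_congener_table <- function(path = ext_file("outdoor_seasonal_medians.csv")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("congener", "season", "median_ng_m3", "sd_ng_m3")
  if (!all(need %in% names(tab)))
    stop("congener table must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(pah_congeners, tab$congener)
  if (length(missing))
    stop("congener table is missing congeners: ", paste(missing, collapse = ", "))
  if (!all(tab$season %in% pah_seasons))
    stop("unknown season labels: ",
         paste(setdiff(tab$season, pah_seasons), collapse = ", "))
  if (nrow(tab) != length(pah_congeners) * length(pah_seasons))
    stop("congener table must have one row per congener x season")
  if (any(tab$median_ng_m3 < 0) || any(tab$sd_ng_m3 < 0))
    stop("medians and SDs must be non-negative")
  class(tab) <- c("congener_table", "data.frame")
  tab
}

#' Toxic equivalency factors
#'
#' Named vector of TEFs scaling each congener's carcinogenic potency to that
#' of benzo[a]pyrene (TEF = 1). Editable via the CSV interface.
#'
#' @param path CSV path with columns `congener`, `tef`.
#' @return Named numeric vector over the 16 congeners.
#' @export
read_tefs <- function(path = ext_file("tef.csv")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tefs <- stats::setNames(tab$tef, tab$congener)[pah_congeners]
  if (anyNA(tefs)) stop("TEF table must cover all 16 congeners")
  if (abs(tefs[["BaP"]] - 1) > 1e-12) stop("TEF(BaP) must equal 1")
  tefs
}

#' Particle-bound fraction per congener
#'
#' Fraction of each congener's airborne mass attached to particles (the
#' remainder is gas phase). Season-independent by default; an explicit,
#' editable assumption needed only for the deposition / penetration / CADR
#' pathways.
#'
#' @param path CSV path with columns `congener`, `particle_fraction`.
#' @return Named numeric vector in \[0, 1\] over the 16 congeners.
#' @export
read_particle_fractions <- function(path = ext_file("particle_fraction.csv")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  pf <- stats::setNames(tab$particle_fraction, tab$congener)[pah_congeners]
  if (anyNA(pf)) stop("particle-fraction table must cover all 16 congeners")
  if (any(pf < 0 | pf > 1)) stop("particle fractions must lie in [0, 1]")
  pf
}

#' Fit a lognormal to a reported (median, SD) pair
#'
#' Concentration tables report the median and standard deviation of
#' seasonal-average concentrations. For a lognormal with log-mean `mu` and
#' log-sd `sigma`, the median is `exp(mu)` and the SD is
#' `median * exp(sigma^2/2) * sqrt(exp(sigma^2) - 1)`; writing `w =
#' exp(sigma^2)` the second relation is the quadratic `w^2 - w - (sd/median)^2
#' = 0`, solved in closed form.
#'
#' @param median Reported median, must be > 0 (cells with median 0 are point
#'   masses at zero and must be handled upstream).
#' @param sd Reported standard deviation, >= 0.
#' @return `c(mu, sigma)` of the fitted lognormal.
#' @export
lognormal_from_median_sd <- function(median, sd) {
  if (!is.finite(median) || median <= 0)
    stop("median must be > 0 (zero-median congeners are point masses at 0)")
  if (!is.finite(sd) || sd < 0) stop("sd must be >= 0")
  if (sd == 0) return(c(mu = log(median), sigma = 0))
  r2 <- (sd / median)^2
  w <- (1 + sqrt(1 + 4 * r2)) / 2
  c(mu = log(median), sigma = sqrt(log(w)))
}

# Fit all cells of a congener table; returns season x congener matrices of
# mu and sigma, with zero-median cells flagged (sampled as exactly 0).
fit_outdoor_lognormals <- function(table) {
  mu <- sigma <- zero <- matrix(
    0, length(pah_seasons), length(pah_congeners),
    dimnames = list(pah_seasons, pah_congeners))
  for (i in seq_len(nrow(table))) {
    s <- table$season[i]; cg <- table$congener[i]
    m <- table$median_ng_m3[i]
    if (m <= 0) {
      zero[s, cg] <- 1
    } else {
      p <- lognormal_from_median_sd(m, table$sd_ng_m3[i])
      mu[s, cg] <- p[["mu"]]; sigma[s, cg] <- p[["sigma"]]
    }
  }
  list(mu = mu, sigma = sigma, zero = zero == 1)
}

#' Sample seasonal outdoor concentration fields
#'
#' Draws `n` replicate outdoor fields: one seasonal-average concentration per
#' congener per season, each from the lognormal fitted to the table's
#' (median, SD) cell. By default all congeners within a replicate and season
#' share a single lognormal quantile (perfect rank correlation, emulating
#' co-variation with combustion activity); set `correlated = FALSE` for
#' independent congeners.
#'
#' @param table A `congener_table` (see [read_congener_table()]).
#' @param n Number of replicate fields.
#' @param correlated Share one standard-normal quantile across congeners
#'   within each season and replicate?
#' @return Numeric array `[n, season, congener]` in ng/m3.
#' @export
sample_outdoor_field <- function(table, n = 1, correlated = TRUE) {
  fit <- fit_outdoor_lognormals(table)
  ns <- length(pah_seasons); nc <- length(pah_congeners)
  field <- array(0, dim = c(n, ns, nc),
                 dimnames = list(NULL, pah_seasons, pah_congeners))
  for (s in seq_len(ns)) {
    z <- if (correlated) {
      matrix(stats::rnorm(n), n, nc)
    } else {
      matrix(stats::rnorm(n * nc), n, nc)
    }
    cmat <- exp(sweep(sweep(z, 2, fit$sigma[s, ], "*"), 2, fit$mu[s, ], "+"))
    cmat[, fit$zero[s, ]] <- 0
    field[, s, ] <- cmat
  }
  field
}

#' Benzo[a]pyrene-equivalent concentration
#'
#' TEF-weighted sum of congener concentrations, `sum_i TEF_i * C_i`.
#'
#' @param conc Named numeric vector of congener concentrations (ng/m3), or a
#'   matrix with congeners as columns.
#' @param tefs Named TEF vector (see [read_tefs()]).
#' @return B\[a\]Peq concentration(s) in ng/m3.
#' @export
baep_equivalent <- function(conc, tefs) {
  if (is.matrix(conc)) {
    missing <- setdiff(names(tefs), colnames(conc))
    if (length(missing))
      stop("missing congener(s): ", paste(missing, collapse = ", "))
    return(drop(conc[, names(tefs), drop = FALSE] %*% tefs))
  }
  missing <- setdiff(names(tefs), names(conc))
  if (length(missing))
    stop("missing congener(s): ", paste(missing, collapse = ", "))
  sum(conc[names(tefs)] * tefs)
}

# B[a]Peq of an [n, season, congener] field: returns [n, season] matrices for
# the particle-bound and gas-phase parts.
field_baep_by_phase <- function(field, tefs, pfrac) {
  n <- dim(field)[1]; ns <- dim(field)[2]
  m <- matrix(field, nrow = n * ns)          # (replicate, season) rows
  part <- matrix(m %*% (tefs * pfrac), n, ns, dimnames = list(NULL, pah_seasons))
  gas <- matrix(m %*% (tefs * (1 - pfrac)), n, ns, dimnames = list(NULL, pah_seasons))
  list(particle = part, gas = gas)
}
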
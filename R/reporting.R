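pct2 <- function(x) ifelse(is.na(x), NA, sprintf("%.2f", 100 * x))

#' Write report files for a scenario comparison
#'
#' Emits deterministic CSV reports and a JSON run manifest into `outdir`:
#' `scenario_summaries.csv` (distributional summaries, mean RR, PAF, PIF and
#' exposure-pattern statistics per scenario), `ranking.csv` (interventions
#' sorted by PIF), `risk_table.csv` (PAF and PIF per scenario under the four
#' URR variants, as percentages rounded to 2 decimals with full-precision
#' columns alongside), optionally `sensitivity.csv` and
#' `per_individual.csv`, and `manifest.json` (seed, sizes, scenario ids,
#' config checksum) from which a re-run reproduces every CSV byte for byte.
#'
#' @param comparison A `pah_comparison` from [compare_scenarios()].
#' @param outdir Output directory (created if needed).
#' @param config The configuration used for the runs (for the manifest
#'   checksum and the URR variants).
#' @param sensitivity Optional `pah_sensitivity` from [sensitivity_sweep()].
#' @param write_individuals Also write the per-individual results?
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(comparison, outdir, config = default_config(),
                          sensitivity = NULL, write_individuals = FALSE) {
  if (!length(comparison$runs)) stop("comparison holds no runs")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outdir, mode = 2) != 0)
    stop("output directory is not writable: ", outdir)
  paths <- character()
  put <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE, na = "")
    paths[[name]] <<- p
  }

  summaries <- do.call(rbind, lapply(comparison$runs, function(r) {
    s <- r$summary
    row <- data.frame(scenario = r$id, sub_population = r$sub_population,
                      n_reps = r$n_reps, stringsAsFactors = FALSE)
    for (m in names(s)) {
      v <- s[[m]]
      names(v) <- paste(m, names(v), sep = "_")
      row <- cbind(row, as.data.frame(as.list(v)))
    }
    pat <- r$pattern
    cbind(row, data.frame(
      mean_rr = r$mean_rr, paf_pct = 100 * r$paf,
      mean_share_in_in = pat$mean_share[["in_in"]],
      mean_share_out_in = pat$mean_share[["out_in"]],
      mean_share_out_out = pat$mean_share[["out_out"]],
      dominance_in_in = pat$dominance_rate[["in_in"]],
      dominance_out_in = pat$dominance_rate[["out_in"]],
      dominance_out_out = pat$dominance_rate[["out_out"]]
    ))
  }))
  rownames(summaries) <- NULL
  put(summaries, "scenario_summaries.csv")

  ranking <- comparison$table[!is.na(comparison$table$pif), ]
  if (nrow(ranking)) {
    ranking$pif_pct <- pct2(ranking$pif)
    ranking$paf_pct <- pct2(ranking$paf)
    put(ranking, "ranking.csv")
  }

  # URR-variant risk table from the stored per-individual lifetime exposures
  reg <- scenario_registry()
  ids <- names(comparison$runs)
  c_life <- lapply(comparison$runs, function(r) r$individuals$c_life)
  baseline_of <- vapply(reg[ids], `[[`, "", "baseline")
  risk_tab <- urr_sensitivity_table(
    c_life, baseline_of,
    urr = config$risk$urr, urr_alternative = config$risk$urr_alternative,
    reference_exposure = config$risk$reference_exposure)
  risk_tab$paf_pct <- pct2(risk_tab$paf)
  risk_tab$pif_pct <- pct2(risk_tab$pif)
  put(risk_tab, "risk_table.csv")

  if (!is.null(sensitivity)) put(as.data.frame(sensitivity), "sensitivity.csv")
  if (write_individuals) {
    per_ind <- do.call(rbind, lapply(ids, function(id)
      cbind(scenario = id, comparison$runs[[id]]$individuals)))
    put(per_ind, "per_individual.csv")
  }

  cfg_file <- tempfile()
  saveRDS(config, cfg_file, version = 2)
  manifest <- list(
    package = "pahpopex",
    version = as.character(utils::packageVersion("pahpopex")),
    seed = comparison$seed,
    n_reps = comparison$n_reps,
    scenarios = ids,
    config_md5 = unname(tools::md5sum(cfg_file)),
    files = names(paths)
  )
  unlink(cfg_file)
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  paths[["manifest.json"]] <- mp
  invisible(paths)
}
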
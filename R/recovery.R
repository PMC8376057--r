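# Ground-truth recovery experiment: run the full pipeline on one synthetic
# season and compare recovered electivities with the scenario's analytic truth.

#' Run the pipeline on synthetic data and compare against ground truth
#'
#' Generates the scenario's landscape for one year, places that season's
#' units, runs the electivity analysis (individual level, availability
#' averaged over squares, the scenario's plot radius) and joins the bootstrap
#' summary with the analytic ground truth.
#'
#' The first scenario year is the default because its coarser fragmentation
#' keeps patches large relative to the plot radius, where plot-composition
#' smoothing of point placements is smallest; winter is the default season
#' because multi-relocation units are needed to estimate per-unit use. The
#' per-square availability frame is used because the placement model defines
#' preference relative to each square's own composition: judged against an
#' averaged frame, between-square composition variance propagates through the
#' concave alpha-to-epsilon mapping into a downward bias of mean electivity.
#'
#' @param scenario a [partridge_scenario()].
#' @param year scenario year to simulate (default: first).
#' @param season season whose units are placed (default `"winter"`).
#' @param spec a [bootstrap_spec()]; defaults to 1500 resamples at 95% with
#'   the scenario's seed.
#' @return data.frame with one row per habitat: `habitat`, `true_epsilon`,
#'   `mean_epsilon`, `error`, `ci_low`, `ci_high`, `n_units`, `significance`,
#'   `sign_match` (`NA` where truth is 0 or the habitat was untested).
#' @export
recovery_experiment <- function(scenario, year = scenario$years[1], season = "winter",
                                spec = NULL) {
  stopifnot(inherits(scenario, "partridge_scenario"))
  if (is.null(spec)) spec <- bootstrap_spec(seed = substream_seed(scenario$seed, "recovery"))
  maps <- generate_landscape(scenario, year)
  obs <- place_units(scenario, maps, season = season, year = year)
  res <- electivity_analysis(maps, obs, level = "individual",
                             availability = "per_square",
                             radius = scenario$plot_radius, spec = spec,
                             availability_source = "square_maps")
  truth <- scenario_ground_truth(scenario)[[season]]
  out <- merge(truth, res$summary, by = "habitat", all.x = TRUE)
  out$error <- out$mean_epsilon - out$true_epsilon
  out$sign_match <- ifelse(
    out$significance == "not_tested" | out$true_epsilon == 0, NA,
    (out$significance == "preferred" & out$true_epsilon > 0) |
      (out$significance == "avoided" & out$true_epsilon < 0)
  )
  out[order(out$habitat),
      c("habitat", "true_epsilon", "mean_epsilon", "error", "ci_low", "ci_high",
        "n_units", "significance", "sign_match")]
}
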
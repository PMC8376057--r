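# End-to-end orchestration: input validation, the electivity analysis engine,
# and a file-based run producing the report bundle (CSV tables + metadata).

#' Validate an observation table against maps
#'
#' Report-only: returns a violation table rather than stopping, so a run can
#' surface all problems at once. Checked: required columns, unknown squares,
#' locations outside their square (with tolerance), coveys of 2 or fewer
#' birds, non-positive group sizes, unknown season labels.
#'
#' @param observations observation data.frame.
#' @param maps named list of `patch_map`s (names or `square_id`s identify
#'   squares).
#' @param tolerance allowed out-of-square overshoot in m.
#' @return data.frame with columns `rule`, `id`, `message` (0 rows when clean).
#' @export
validate_inputs <- function(observations, maps, tolerance = 0) {
  v <- list()
  add <- function(rule, id, msg) {
    v[[length(v) + 1L]] <<- data.frame(rule = rule, id = as.character(id),
                                       message = msg, stringsAsFactors = FALSE)
  }
  required <- c("obs_id", "square_id", "x", "y", "year", "season", "unit_kind", "group_size")
  missing <- setdiff(required, names(observations))
  if (length(missing)) {
    add("schema", "observations", sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
    out <- do.call(rbind, v)
    return(out)
  }
  sq_ids <- unique(vapply(maps, `[[`, character(1), "square_id"))
  for (i in seq_len(nrow(observations))) {
    o <- observations[i, ]
    if (!o$square_id %in% sq_ids) {
      add("unknown_square", o$obs_id, sprintf("square %s has no map", o$square_id))
      next
    }
    m <- maps[[match(o$square_id, vapply(maps, `[[`, character(1), "square_id"))]]
    x0 <- m$origin[1]; y0 <- m$origin[2]
    x1 <- x0 + ncol(m$grid) * m$cell_size; y1 <- y0 + nrow(m$grid) * m$cell_size
    if (o$x < x0 - tolerance || o$x > x1 + tolerance ||
        o$y < y0 - tolerance || o$y > y1 + tolerance) {
      add("out_of_square", o$obs_id,
          sprintf("location (%.1f, %.1f) outside square %s", o$x, o$y, o$square_id))
    }
    if (identical(o$unit_kind, "covey") && o$group_size <= 2) {
      add("covey_size", o$obs_id,
          sprintf("covey with group_size %d; coveys require > 2 birds", o$group_size))
    }
    if (o$group_size < 1) add("group_size", o$obs_id, "group_size must be >= 1")
    if (!o$season %in% c("winter", "spring")) {
      add("season", o$obs_id, sprintf("unknown season '%s'", o$season))
    }
  }
  if (!length(v)) {
    return(data.frame(rule = character(), id = character(), message = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

#' Electivity analysis of one year's observations against one year's maps
#'
#' The in-memory engine behind [run_analysis()]: builds availability from
#' reference plots at square centres, groups observations into analysis units
#' at the requested level, extracts use compositions from circular plots,
#' computes per-unit Manly alpha / Chesson electivity, and bootstraps
#' per-habitat means.
#'
#' Levels: `square` pools all locations within a square into one unit;
#' `individual` treats each `unit_id` (bird, covey) as a unit; `territory`
#' uses spring records only, one unit per `unit_id` (a pair counts once).
#'
#' @param maps named list of `patch_map`s, one per square, all of one year.
#' @param observations observation rows of the same year.
#' @param level `"square"`, `"individual"` or `"territory"`.
#' @param availability `"averaged_over_squares"` or `"per_square"`.
#' @param radius plot radius in m.
#' @param spec a [bootstrap_spec()].
#' @param availability_source `"reference_plots"` measures availability in a
#'   circular plot at each square centre (the field design); `"square_maps"`
#'   uses each square map's full composition (exact availability, preferable
#'   when complete maps exist, e.g. for synthetic data).
#' @return List with `long` (unit x habitat electivities), `summary`
#'   (per-habitat bootstrap + significance), `frame`, `avail_profiles`,
#'   `use_profiles`.
#' @export
electivity_analysis <- function(maps, observations, level = c("individual", "square", "territory"),
                                availability = c("averaged_over_squares", "per_square"),
                                radius = 100, spec = bootstrap_spec(),
                                availability_source = c("reference_plots", "square_maps")) {
  level <- match.arg(level)
  availability <- match.arg(availability)
  availability_source <- match.arg(availability_source)
  stopifnot(is.list(maps), length(maps) >= 1L)
  if (is.null(names(maps)) || any(!nzchar(names(maps)))) {
    names(maps) <- vapply(maps, `[[`, character(1), "square_id")
  }
  if (!nrow(observations)) stop("empty observation set", call. = FALSE)

  avail_profiles <- lapply(maps, function(m) {
    if (availability_source == "reference_plots") {
      plot <- circular_plot(map_centre(m), radius = radius, kind = "availability",
                            source = m$square_id)
      plot_composition(m, plot)
    } else {
      map_composition(m)
    }
  })
  frame <- availability_frame(avail_profiles, mode = availability)

  obs <- switch(level,
    territory = observations[observations$season == "spring", , drop = FALSE],
    observations
  )
  if (!nrow(obs)) stop(sprintf("no observations for level '%s'", level), call. = FALSE)
  unit_key <- switch(level, square = obs$square_id, obs$unit_id)
  units <- split(seq_len(nrow(obs)), unit_key)
  use_profiles <- lapply(units, function(idx) {
    lapply(idx, function(i) {
      m <- maps[[obs$square_id[i]]]
      if (is.null(m)) stop(sprintf("no map for square %s", obs$square_id[i]), call. = FALSE)
      plot_composition(m, circular_plot(c(obs$x[i], obs$y[i]), radius = radius,
                                        kind = "use", source = obs$obs_id[i]))
    })
  })
  square_ids <- vapply(units, function(idx) obs$square_id[idx[1]], character(1))
  long <- electivity_table(use_profiles, frame, level = level, square_ids = square_ids)
  summary <- bootstrap_all_habitats(long, spec)
  list(long = long, summary = summary, frame = frame,
       avail_profiles = avail_profiles, use_profiles = use_profiles)
}

#' Assemble an analysis configuration
#'
#' @param observations path to the observation CSV.
#' @param maps_dir directory of paired `<square>_<year>.asc` /
#'   `<square>_<year>_legend.csv` patch maps.
#' @param scale mapping scale.
#' @param availability availability-frame mode.
#' @param level analysis level.
#' @param radius plot radius in m.
#' @param n_resamples,ci_level,min_units bootstrap settings.
#' @param availability_source `"reference_plots"` or `"square_maps"` (see
#'   [electivity_analysis()]).
#' @param outdir output directory for the report bundle.
#' @param seed master seed.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(observations, maps_dir, scale = "rough",
                            availability = "averaged_over_squares",
                            level = "individual", radius = 100,
                            n_resamples = 1500, ci_level = 0.95, min_units = 7,
                            availability_source = "reference_plots",
                            outdir = "results", seed = 1L) {
  stop_if_not_scalar_number(radius, "radius", positive = TRUE)
  structure(list(
    observations = observations, maps_dir = maps_dir, scale = scale,
    availability = availability, level = level, radius = radius,
    availability_source = availability_source,
    n_resamples = n_resamples, ci_level = ci_level, min_units = min_units,
    outdir = outdir, seed = as.integer(seed)
  ), class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path file path ending in `.yml`/`.yaml` or `.json`.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file %s does not exist", path), call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(analysis_config, cfg)
}

# Read all asc/legend map pairs from a directory.
read_maps_dir <- function(maps_dir, vocab = NULL) {
  ascs <- sort(list.files(maps_dir, pattern = "\\.asc$", full.names = TRUE))
  if (!length(ascs)) stop(sprintf("no .asc maps in %s", maps_dir), call. = FALSE)
  maps <- lapply(ascs, function(a) {
    leg <- sub("\\.asc$", "_legend.csv", a)
    if (!file.exists(leg)) stop(sprintf("missing legend for %s", a), call. = FALSE)
    read_patch_asc(a, leg, vocab = vocab)
  })
  names(maps) <- vapply(maps, function(m) sprintf("%s_%d", m$square_id, m$year), character(1))
  maps
}

#' Run the full analysis and write the report bundle
#'
#' Stages: read + validate inputs, per-year electivity with bootstrap
#' summaries, multi-year change tables, diversity table, and (when both
#' seasons are present in the final year) the seasonal infrastructure-distance
#' summary. All outputs are deterministic under the config's seed. Every stage
#' logs row counts; validation violations abort the run.
#'
#' @param config an [analysis_config()] or a path readable by
#'   [read_analysis_config()].
#' @return Invisibly, the report bundle: a list of the output data.frames and
#'   file paths.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- read_analysis_config(config)
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$outdir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    cat(line, "\n", file = log_path, append = TRUE)
    message(line)
  }

  obs <- read_observations(config$observations)
  maps <- read_maps_dir(config$maps_dir)
  logf("read %d observations, %d maps", nrow(obs), length(maps))
  if (!nrow(obs)) stop("empty observation set", call. = FALSE)

  report <- validate_inputs(obs, maps)
  if (nrow(report)) {
    utils::write.csv(report, file.path(config$outdir, "validation.csv"), row.names = FALSE)
    stop(sprintf("input validation failed with %d violation(s); see %s",
                 nrow(report), file.path(config$outdir, "validation.csv")), call. = FALSE)
  }
  logf("validation clean")

  spec <- bootstrap_spec(n_resamples = config$n_resamples, level = config$ci_level,
                         seed = config$seed, min_units = config$min_units)
  years <- sort(unique(obs$year))
  long_all <- list(); summary_all <- list(); div_all <- list()
  for (yr in years) {
    yr_maps <- Filter(function(m) m$year == yr, maps)
    names(yr_maps) <- vapply(yr_maps, `[[`, character(1), "square_id")
    yr_obs <- obs[obs$year == yr, , drop = FALSE]
    res <- electivity_analysis(yr_maps, yr_obs, level = config$level,
                               availability = config$availability,
                               radius = config$radius, spec = spec,
                               availability_source = config$availability_source)
    res$long$year <- yr
    res$summary$year <- yr
    long_all[[as.character(yr)]] <- res$long
    summary_all[[as.character(yr)]] <- res$summary
    unit_means <- lapply(res$use_profiles, function(pl) {
      p <- colMeans(do.call(rbind, lapply(pl, as.numeric)))
      stats::setNames(p / sum(p), names(pl[[1]]))
    })
    dv <- diversity_table(unit_means, res$avail_profiles)
    dv$year <- yr
    # square as grouping factor for external mixed-model fitting
    unit_sq <- vapply(res$use_profiles, function(pl) attr(pl[[1]], "square_id"), character(1))
    dv$square_id <- ifelse(dv$type == "used", unit_sq[dv$unit], dv$unit)
    div_all[[as.character(yr)]] <- dv
    logf("year %d: %d units, %d habitats summarised", yr,
         length(res$use_profiles), nrow(res$summary))
  }
  long <- do.call(rbind, long_all)
  summary <- do.call(rbind, summary_all)
  diversity <- do.call(rbind, div_all)

  change <- change_summary(maps, obs, radius = config$radius)
  final_yr <- max(years)
  fin_obs <- obs[obs$year == final_yr, , drop = FALSE]
  distance <- if (all(c("winter", "spring") %in% fin_obs$season)) {
    seasonal_distance_summary(fin_obs, maps, year = final_yr,
                              seed = substream_seed(config$seed, "distance"))
  } else NULL

  paths <- c(
    electivity_long = file.path(config$outdir, "electivity_long.csv"),
    electivity_summary = file.path(config$outdir, "electivity_summary.csv"),
    change_tables = file.path(config$outdir, "change_tables.csv"),
    diversity = file.path(config$outdir, "diversity.csv")
  )
  utils::write.csv(long, paths[["electivity_long"]], row.names = FALSE)
  utils::write.csv(summary, paths[["electivity_summary"]], row.names = FALSE)
  utils::write.csv(change, paths[["change_tables"]], row.names = FALSE)
  utils::write.csv(diversity, paths[["diversity"]], row.names = FALSE)
  if (!is.null(distance)) {
    paths[["distance_summary"]] <- file.path(config$outdir, "distance_summary.csv")
    utils::write.csv(distance, paths[["distance_summary"]], row.names = FALSE)
  }
  meta <- list(
    package_version = as.character(utils::packageVersion("perdixsel")),
    r_version = R.version.string,
    seed = config$seed,
    n_resamples = config$n_resamples, ci_level = config$ci_level,
    min_units = config$min_units, level = config$level,
    availability = config$availability, radius = config$radius,
    config_hash = substream_seed(0L, paste(deparse(unclass(config)), collapse = ""))
  )
  jsonlite::write_json(meta, file.path(config$outdir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  logf("bundle written to %s", config$outdir)
  invisible(list(electivity_long = long, electivity_summary = summary,
                 change_tables = change, diversity = diversity,
                 distance_summary = distance, paths = paths,
                 metadata = meta))
}
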
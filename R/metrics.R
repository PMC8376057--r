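# Landscape change and diversity metrics: patch labelling, per-year change
# summaries, Shannon-Wiener diversity, infrastructure proximity by season,
# and trend correlation.

#' Decompose a patch map into patches
#'
#' A patch ("area" in the change tables) is a maximal connected region of one
#' habitat type. Grid cells are connected through edges (4-connectivity,
#' the default, giving conservative fragmentation counts) or edges plus
#' corners (8-connectivity). Component labelling is delegated to igraph on the
#' same-code adjacency graph.
#'
#' @param map a `patch_map`.
#' @param connectivity 4 or 8.
#' @return data.frame with columns `patch_id`, `habitat`, `n_cells`,
#'   `area_ha`, and an attribute `labels`: an integer matrix assigning every
#'   cell its `patch_id` (`NA` for unlabelled cells).
#' @export
patchify <- function(map, connectivity = 4) {
  stopifnot(inherits(map, "patch_map"), connectivity %in% c(4, 8))
  g <- map$grid
  nr <- nrow(g); nc <- ncol(g)
  idx <- matrix(seq_along(g), nr, nc)
  pair_edges <- function(a, b) {
    a <- as.vector(a); b <- as.vector(b)  # linear indices, never coordinate pairs
    same <- !is.na(g[a]) & !is.na(g[b]) & g[a] == g[b]
    rbind(a[same], b[same])
  }
  down  <- pair_edges(idx[-nr, , drop = FALSE], idx[-1, , drop = FALSE])
  right <- pair_edges(idx[, -nc, drop = FALSE], idx[, -1, drop = FALSE])
  edges <- cbind(down, right)
  if (connectivity == 8) {
    d1 <- pair_edges(idx[-nr, -nc, drop = FALSE], idx[-1, -1, drop = FALSE])
    d2 <- pair_edges(idx[-nr, -1, drop = FALSE], idx[-1, -nc, drop = FALSE])
    edges <- cbind(edges, d1, d2)
  }
  gr <- igraph::make_graph(as.vector(edges), n = length(g), directed = FALSE)
  membership <- igraph::components(gr)$membership
  membership[is.na(g)] <- NA
  ids <- unique(membership[!is.na(membership)])  # ordered by first occurrence
  lab_dense <- matrix(match(membership, ids), nr, nc)
  n_cells <- tabulate(lab_dense[!is.na(lab_dense)], nbins = length(ids))
  habitat <- map$levels[g[match(seq_along(ids), as.vector(lab_dense))]]
  out <- data.frame(
    patch_id = seq_along(ids), habitat = habitat, n_cells = n_cells,
    area_ha = n_cells * map$cell_size^2 / 1e4, stringsAsFactors = FALSE
  )
  attr(out, "labels") <- lab_dense
  out
}

# Square centre implied by a map's extent.
map_centre <- function(map) {
  c(map$origin[1] + ncol(map$grid) * map$cell_size / 2,
    map$origin[2] + nrow(map$grid) * map$cell_size / 2)
}

# Patch count and mean area for the patches intersecting a circular plot.
# Areas are the full (unclipped) patch areas by default: a plot samples the
# patches it touches, whose sizes extend beyond the plot.
plot_patch_stats <- function(patches, map, plot, clip = FALSE) {
  labels <- attr(patches, "labels")
  idx <- plot_cell_index(map, plot)
  ids <- unique(labels[idx])
  ids <- ids[!is.na(ids)]
  if (!length(ids)) return(c(n = 0, mean_area = NA_real_))
  if (clip) {
    inside <- labels[idx]
    areas <- as.numeric(table(inside)) * map$cell_size^2 / 1e4
  } else {
    areas <- patches$area_ha[ids]
  }
  c(n = length(ids), mean_area = mean(areas))
}

#' Per-year landscape change summary
#'
#' Reproduces the change-table layout: per year and scope, the average number
#' of patches ("areas") sampled by 3.14 ha circular plots and their average
#' size, plus whole-square infrastructure statistics (average number of
#' infrastructure patches per square, their mean size, and the total
#' infrastructure area across squares).
#'
#' Scopes: `availability` uses reference plots at all square centres;
#' `squares_with_presence` restricts to squares holding at least one
#' observation that year; `per_partridge` averages over plots around every
#' observed location; `per_territory` over one plot per territory unit
#' (spring records).
#'
#' @param maps list of `patch_map`s (all squares x years).
#' @param observations observation data.frame (required for presence-based
#'   scopes).
#' @param scopes subset of the four scopes.
#' @param radius plot radius in m (default 100).
#' @param connectivity passed to [patchify()].
#' @param clip report patch areas clipped to the plot instead of full patch
#'   areas.
#' @param season optional filter (`"winter"`/`"spring"`) applied to
#'   observation-based scopes.
#' @return data.frame with one row per year x scope; rows for scopes with no
#'   units that year carry `empty = TRUE` and `NA` statistics.
#' @export
change_summary <- function(maps, observations = NULL,
                           scopes = c("availability", "squares_with_presence",
                                      "per_partridge", "per_territory"),
                           radius = 100, connectivity = 4, clip = FALSE,
                           season = NULL) {
  scopes <- match.arg(scopes, several.ok = TRUE)
  stopifnot(is.list(maps), length(maps) >= 1L)
  years <- sort(unique(vapply(maps, `[[`, integer(1), "year")))
  obs <- observations
  if (!is.null(obs) && !is.null(season)) obs <- obs[obs$season %in% season, , drop = FALSE]
  rows <- list()
  for (yr in years) {
    yr_maps <- Filter(function(m) m$year == yr, maps)
    patched <- lapply(yr_maps, patchify, connectivity = connectivity)
    names(patched) <- vapply(yr_maps, `[[`, character(1), "square_id")
    names(yr_maps) <- names(patched)
    yr_obs <- if (!is.null(obs)) obs[obs$year == yr, , drop = FALSE] else NULL

    infra <- lapply(names(yr_maps), function(sq) {
      p <- patched[[sq]]
      pin <- p[p$habitat %in% infrastructure_codes(yr_maps[[sq]]$vocab), , drop = FALSE]
      c(n = nrow(pin), mean_area = if (nrow(pin)) mean(pin$area_ha) else NA_real_,
        total = sum(pin$area_ha))
    })
    infra_mat <- do.call(rbind, infra)
    infra_stats <- c(
      avg_infra_patches = mean(infra_mat[, "n"]),
      avg_infra_area_ha = mean(infra_mat[, "mean_area"], na.rm = TRUE),
      total_infra_ha = sum(infra_mat[, "total"])
    )

    square_stat <- function(square_ids) {
      st <- vapply(square_ids, function(sq) {
        plot <- circular_plot(map_centre(yr_maps[[sq]]), radius = radius,
                              kind = "availability", source = sq)
        plot_patch_stats(patched[[sq]], yr_maps[[sq]], plot, clip = clip)
      }, numeric(2))
      c(n_units = length(square_ids), avg_patches = mean(st["n", ]),
        avg_patch_area_ha = mean(st["mean_area", ], na.rm = TRUE))
    }
    obs_stat <- function(o) {
      st <- vapply(seq_len(nrow(o)), function(i) {
        sq <- o$square_id[i]
        plot <- circular_plot(c(o$x[i], o$y[i]), radius = radius,
                              kind = "use", source = o$obs_id[i])
        plot_patch_stats(patched[[sq]], yr_maps[[sq]], plot, clip = clip)
      }, numeric(2))
      c(n_units = nrow(o), avg_patches = mean(st["n", ]),
        avg_patch_area_ha = mean(st["mean_area", ], na.rm = TRUE))
    }

    for (scope in scopes) {
      stat <- switch(scope,
        availability = square_stat(names(yr_maps)),
        squares_with_presence = {
          sqs <- intersect(names(yr_maps), unique(yr_obs$square_id))
          if (length(sqs)) square_stat(sqs) else NULL
        },
        per_partridge = {
          if (!is.null(yr_obs) && nrow(yr_obs)) {
            obs_stat(yr_obs[yr_obs$square_id %in% names(yr_maps), , drop = FALSE])
          } else NULL
        },
        per_territory = {
          terr <- yr_obs[yr_obs$season == "spring" & yr_obs$square_id %in% names(yr_maps), , drop = FALSE]
          if (!is.null(terr) && nrow(terr)) {
            terr <- terr[!duplicated(terr$unit_id), , drop = FALSE]
            obs_stat(terr)
          } else NULL
        }
      )
      empty <- is.null(stat)
      if (empty) stat <- c(n_units = 0, avg_patches = NA_real_, avg_patch_area_ha = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        year = yr, scope = scope, n_units = stat[["n_units"]],
        avg_patches = stat[["avg_patches"]],
        avg_patch_area_ha = stat[["avg_patch_area_ha"]],
        avg_infra_patches = infra_stats[["avg_infra_patches"]],
        avg_infra_area_ha = infra_stats[["avg_infra_area_ha"]],
        total_infra_ha = infra_stats[["total_infra_ha"]],
        empty = empty, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Shannon-Wiener diversity of a composition
#'
#' `H = -sum(p_i * log(p_i))` in nats (natural log, the convention of the
#' vegan package, which performs the computation here).
#'
#' @param proportions non-negative proportions summing to 1 (zeros allowed).
#' @return H in nats.
#' @export
shannon_index <- function(proportions) {
  p <- as.numeric(proportions)
  if (any(!is.finite(p)) || any(p < 0)) stop("proportions must be non-negative", call. = FALSE)
  check_proportions(p, "proportions", tol = 1e-6)
  as.numeric(vegan::diversity(p, index = "shannon"))
}

#' Long diversity table for used and available compositions
#'
#' @param used named list of use compositions (one per unit).
#' @param available named list of availability compositions (one per square).
#' @return data.frame with columns `unit`, `type` (`used`/`available`), `H`.
#' @export
diversity_table <- function(used, available) {
  one <- function(lst, type) data.frame(
    unit = names(lst), type = type,
    H = vapply(lst, shannon_index, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  rbind(one(used, "used"), one(available, "available"))
}

#' Nearest-infrastructure distance summaries by season and point type
#'
#' Computes the distance from every observation to the nearest infrastructure
#' patch of its square's map, and from every square centre (availability
#' points), then summarises each group (winter used, spring used,
#' availability) by its median and a bootstrap standard error of the median
#' (percentile method). Points on squares without infrastructure have
#' undefined distance and are excluded with a count.
#'
#' @param observations observation data.frame.
#' @param maps list of `patch_map`s covering the observations' squares/years.
#' @param year year of the comparison (default: the single year present).
#' @param n_resamples,seed bootstrap-SE settings.
#' @return data.frame with one row per group: `group`, `n`, `n_undefined`,
#'   `median_m`, `se_median`.
#' @export
seasonal_distance_summary <- function(observations, maps, year = NULL,
                                      n_resamples = 1000, seed = 1L) {
  if (is.null(year)) {
    yrs <- unique(observations$year)
    stopifnot(length(yrs) == 1L)
    year <- yrs
  }
  yr_maps <- Filter(function(m) m$year == year, maps)
  names(yr_maps) <- vapply(yr_maps, `[[`, character(1), "square_id")
  obs <- observations[observations$year == year, , drop = FALSE]
  dist_one <- function(x, y, sq) {
    m <- yr_maps[[sq]]
    if (is.null(m)) return(NA_real_)
    distance_to_nearest_infrastructure(c(x, y), m)
  }
  groups <- list(
    winter_used = obs[obs$season == "winter", c("x", "y", "square_id")],
    spring_used = obs[obs$season == "spring", c("x", "y", "square_id")],
    availability = data.frame(
      x = vapply(yr_maps, function(m) map_centre(m)[1], numeric(1)),
      y = vapply(yr_maps, function(m) map_centre(m)[2], numeric(1)),
      square_id = names(yr_maps), stringsAsFactors = FALSE
    )
  )
  rows <- lapply(names(groups), function(gname) {
    g <- groups[[gname]]
    if (!nrow(g)) {
      return(data.frame(group = gname, n = 0L, n_undefined = 0L,
                        median_m = NA_real_, se_median = NA_real_,
                        stringsAsFactors = FALSE))
    }
    d <- mapply(dist_one, g$x, g$y, g$square_id)
    und <- sum(is.na(d))
    d <- d[!is.na(d)]
    data.frame(
      group = gname, n = length(d), n_undefined = und,
      median_m = if (length(d)) stats::median(d) else NA_real_,
      se_median = boot_median_se(d, n_resamples = n_resamples,
                                 seed = substream_seed(seed, paste0("medse/", gname))),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Pearson correlation of a totals trend against year
#'
#' @param x numeric vector (e.g. years), length >= 3.
#' @param y numeric vector of totals.
#' @return Pearson product-moment correlation coefficient.
#' @export
trend_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("zero variance in `x` or `y`", call. = FALSE)
  stats::cor(x, y, method = "pearson")
}
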
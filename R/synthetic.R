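# Synthetic multi-year landscapes and selection-driven observations with
# analytic ground truth, for desk-scale validation of the whole pipeline.
#
# Landscape synthesis is seeded multiplicative region-growing on a grid: each
# patch grows from a seed point at a rate given by a per-seed growth factor,
# so a cell belongs to the seed that reaches it first (argmin of
# distance / factor). Factors are set so that expected area shares match the
# per-year composition targets (share of a seed scales with factor^2), with
# lognormal jitter for irregular boundaries.
#
# Bird placement follows a weighted selection model: a location falls in
# habitat type i with probability proportional to w_i times the available
# area of type i, uniformly within the type. Under this model the analytic
# Manly alpha of type i is w_i / sum_j w_j regardless of availability, which
# gives closed-form ground-truth electivities for recovery tests.

#' Define a synthetic scenario
#'
#' Defaults emulate the study design the generator stands in for: 20 survey
#' squares of 618 m side, three survey years with progressive fragmentation
#' (patch counts doubling per step) and infrastructure growth (area share
#' 0.14 to 0.20), winter coveys (> 2 birds, sizes 3-15) with repeated
#' relocations and spring territories with a single location each.
#'
#' @param n_squares number of survey squares.
#' @param side square side length in m.
#' @param cell_size grid resolution in m.
#' @param years survey years.
#' @param habitats habitat codes (rough-scale subset by default).
#' @param scale mapping scale of the vocabulary.
#' @param composition matrix of target area shares, one row per year (rows sum
#'   to 1), columns = habitats.
#' @param patches_per_square integer vector per year: region seeds per square
#'   (the fragmentation trend).
#' @param weights named list `winter`/`spring` of positive selection weights
#'   over `habitats`.
#' @param units_per_season named vector: units placed per season.
#' @param covey_size_range inclusive range of winter covey sizes (all > 2).
#' @param locations_per_unit named vector: relocations per unit and season
#'   (spring territories have 1).
#' @param plot_radius analysis plot radius in m used with this scenario.
#' @param seed master seed governing landscape, placement and bootstrap
#'   substreams.
#' @return A list of class `partridge_scenario`.
#' @export
partridge_scenario <- function(
    n_squares = 20, side = 618, cell_size = 6,
    years = c(2001L, 2009L, 2017L),
    habitats = c("arable", "meadow", "vineyard", "hedgerow", "road", "field_path"),
    scale = "rough",
    composition = NULL,
    patches_per_square = c(12L, 24L, 48L),
    weights = list(
      winter = c(arable = 0.10, meadow = 0.34, vineyard = 0.12,
                 hedgerow = 0.06, road = 0.24, field_path = 0.14),
      spring = c(arable = 0.44, meadow = 0.16, vineyard = 0.14,
                 hedgerow = 0.06, road = 0.06, field_path = 0.14)
    ),
    units_per_season = c(winter = 40, spring = 40),
    covey_size_range = c(3L, 15L),
    locations_per_unit = c(winter = 280, spring = 1),
    plot_radius = 14,
    seed = 1L) {
  if (is.null(composition)) {
    composition <- rbind(
      c(arable = 0.40, meadow = 0.18, vineyard = 0.16, hedgerow = 0.12, road = 0.08, field_path = 0.06),
      c(arable = 0.38, meadow = 0.18, vineyard = 0.15, hedgerow = 0.12, road = 0.10, field_path = 0.07),
      c(arable = 0.34, meadow = 0.17, vineyard = 0.14, hedgerow = 0.15, road = 0.13, field_path = 0.07)
    )[seq_along(years), , drop = FALSE]
    composition <- composition[, habitats, drop = FALSE]
  }
  stopifnot(
    nrow(composition) == length(years), ncol(composition) == length(habitats),
    length(patches_per_square) == length(years)
  )
  for (r in seq_len(nrow(composition))) check_proportions(composition[r, ], "composition row")
  for (s in names(weights)) {
    w <- weights[[s]]
    if (any(w <= 0)) stop("selection weights must be > 0", call. = FALSE)
    if (!setequal(names(w), habitats)) stop("weights must cover all habitats", call. = FALSE)
  }
  if (covey_size_range[1] <= 2) stop("covey sizes must exceed 2 birds", call. = FALSE)
  vocab <- habitat_vocabulary(scale)
  assert_known_codes(habitats, vocab, "scenario habitats")
  structure(list(
    n_squares = as.integer(n_squares), side = side, cell_size = cell_size,
    years = as.integer(years), habitats = habitats, scale = scale,
    composition = composition, patches_per_square = as.integer(patches_per_square),
    weights = weights, units_per_season = units_per_season,
    covey_size_range = as.integer(covey_size_range),
    locations_per_unit = locations_per_unit, plot_radius = plot_radius,
    seed = as.integer(seed)
  ), class = "partridge_scenario")
}

#' Survey squares of a scenario
#'
#' Squares are laid out in a row with a 100 m gap; each square's map covers
#' exactly its extent.
#'
#' @param scenario a `partridge_scenario`.
#' @return A [survey_square()] data.frame.
#' @export
scenario_squares <- function(scenario) {
  q <- seq_len(scenario$n_squares)
  x0 <- (q - 1) * (scenario$side + 100)
  survey_square(
    sprintf("sq%02d", q),
    cx = x0 + scenario$side / 2, cy = rep(scenario$side / 2, length(q)),
    side = scenario$side
  )
}

# Deterministic seat allocation: >=1 seed per habitat (when k allows), then
# largest remainder on target shares.
allocate_seats <- function(shares, k) {
  t_n <- length(shares)
  if (k < t_n) {
    # too few seeds to host all types: largest-remainder only
    seats <- floor(shares * k)
    rem <- shares * k - seats
    seats[order(rem, decreasing = TRUE)[seq_len(k - sum(seats))]] <-
      seats[order(rem, decreasing = TRUE)[seq_len(k - sum(seats))]] + 1L
    return(seats)
  }
  seats <- pmax(1L, floor(shares * k))
  while (sum(seats) > k) {
    i <- which.max(seats - shares * k)
    seats[i] <- seats[i] - 1L
  }
  if (sum(seats) < k) {
    rem <- shares * k - seats
    add <- order(rem, decreasing = TRUE)
    i <- 0L
    while (sum(seats) < k) {
      i <- i %% t_n + 1L
      seats[add[i]] <- seats[add[i]] + 1L
    }
  }
  seats
}

#' Generate the synthetic landscape of one year
#'
#' @param scenario a `partridge_scenario`.
#' @param year one of the scenario's years.
#' @return Named list of `patch_map`s, one per square.
#' @export
generate_landscape <- function(scenario, year) {
  stopifnot(inherits(scenario, "partridge_scenario"))
  yi <- match(year, scenario$years)
  if (is.na(yi)) stop(sprintf("year %s is not part of the scenario", year), call. = FALSE)
  shares <- scenario$composition[yi, ]
  k <- scenario$patches_per_square[yi]
  seats <- allocate_seats(shares, k)
  # growth factor per type: multiplicative growth makes a seed's area scale
  # with factor^2, so factor = sqrt(share / seat fraction) targets the shares.
  f_type <- sqrt((shares / pmax(seats, 1)) * k)
  squares <- scenario_squares(scenario)
  vocab <- habitat_vocabulary(scenario$scale)
  n <- max(1L, round(scenario$side / scenario$cell_size))
  xs <- (seq_len(n) - 0.5) * scenario$cell_size
  grow_once <- function(k_try, rng_key) {
    seats_try <- allocate_seats(shares, k_try)
    ftype_try <- sqrt((shares / pmax(seats_try, 1)) * k_try)
    with_seed(rng_key, {
      seed_code <- rep.int(seq_along(shares), seats_try)
      sx <- stats::runif(k_try, 0, scenario$side)
      sy <- stats::runif(k_try, 0, scenario$side)
      f <- ftype_try[seed_code] * exp(stats::rnorm(k_try, 0, 0.15))
      best_cost <- matrix(Inf, n, n)
      best_seed <- matrix(NA_integer_, n, n)
      for (j in seq_len(k_try)) {
        cost <- outer((xs - sy[j])^2, (xs - sx[j])^2, "+") / f[j]^2
        take <- cost < best_cost
        best_cost[take] <- cost[take]
        best_seed[take] <- j
      }
      matrix(seed_code[best_seed], n, n)
    })
  }
  maps <- lapply(seq_len(nrow(squares)), function(q) {
    sq <- squares[q, ]
    # adjacent same-type regions merge into one patch, so the realised patch
    # count falls below the seed count, increasingly so at high seed density;
    # a correction loop re-grows with more seeds until counts match the trend
    k_try <- k
    grid <- NULL
    for (iter in 1:3) {
      grid <- grow_once(k_try, substream_seed(
        scenario$seed, sprintf("landscape/%d/%s/%d", year, sq$square_id, iter)))
      tmp <- patch_map(grid, levels = scenario$habitats, square_id = sq$square_id,
                       year = year, scale = scenario$scale,
                       cell_size = scenario$cell_size, origin = c(0, 0), vocab = vocab)
      realised <- nrow(patchify(tmp))
      if (abs(realised - k) <= 0.1 * k || k_try >= 8 * k) break
      k_try <- max(length(shares), ceiling(k_try * k / max(realised, 1)))
    }
    patch_map(grid, levels = scenario$habitats, square_id = sq$square_id,
              year = year, scale = scenario$scale, cell_size = scenario$cell_size,
              origin = c(sq$cx - sq$side / 2, sq$cy - sq$side / 2), vocab = vocab)
  })
  names(maps) <- squares$square_id
  maps
}

#' Place synthetic bird units on generated maps
#'
#' Each unit lives in one square (squares drawn uniformly); its locations fall
#' in habitat type i with probability proportional to `w_i` times the type's
#' area in that square, uniformly within the type. Winter units are coveys
#' (group sizes uniform on the configured range, with repeated relocations);
#' spring units are territories with a single location and a pair.
#'
#' @param scenario a `partridge_scenario`.
#' @param maps named list of `patch_map`s from [generate_landscape()].
#' @param season `"winter"` or `"spring"`.
#' @param year observation year recorded on the rows.
#' @return Observation data.frame (one row per location) with `unit_id`
#'   grouping relocations of a unit.
#' @export
place_units <- function(scenario, maps, season = c("winter", "spring"), year) {
  season <- match.arg(season)
  w <- scenario$weights[[season]]
  present <- unique(unlist(lapply(maps, function(m) m$levels[sort(unique(as.vector(m$grid)))])))
  missing <- setdiff(names(w)[w > 0], present)
  if (length(missing)) {
    warning(sprintf("weighted type(s) absent from all maps: %s; weights renormalised",
                    paste(missing, collapse = ", ")), call. = FALSE)
    w <- w[setdiff(names(w), missing)]
    w <- w / sum(w)
  }
  n_units <- scenario$units_per_season[[season]]
  n_loc <- scenario$locations_per_unit[[season]]
  cs <- scenario$cell_size
  with_seed(substream_seed(scenario$seed, sprintf("units/%s/%d", season, year)), {
    unit_sq <- sample(names(maps), n_units, replace = TRUE)
    rows <- lapply(seq_len(n_units), function(u) {
      m <- maps[[unit_sq[u]]]
      cell_w <- w[m$levels[m$grid]]
      cell_w[is.na(cell_w)] <- 0
      idx <- sample.int(length(m$grid), n_loc, replace = TRUE, prob = cell_w)
      cc <- cell_centres(m)
      ij <- arrayInd(idx, dim(m$grid))
      x <- cc$x[ij[, 2]] + stats::runif(n_loc, -cs / 2, cs / 2)
      y <- cc$y[ij[, 1]] + stats::runif(n_loc, -cs / 2, cs / 2)
      gsize <- if (season == "winter") {
        sample(seq(scenario$covey_size_range[1], scenario$covey_size_range[2]), 1L)
      } else 2L
      data.frame(
        obs_id = sprintf("%s%d_u%03d_l%02d", substr(season, 1, 1), year, u, seq_len(n_loc)),
        unit_id = sprintf("%s%d_u%03d", substr(season, 1, 1), year, u),
        square_id = unit_sq[u], x = x, y = y, year = as.integer(year), season = season,
        unit_kind = if (season == "winter") "covey" else "territory",
        group_size = gsize, stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Analytic ground truth of a scenario
#'
#' Under the placement model, the expected use share of type i is
#' `w_i * n_i / sum_j w_j * n_j`, so Manly's alpha is `w_i / sum_j w_j`
#' independent of availability, and the true electivity follows from the
#' alpha-to-epsilon mapping with `m` = number of scenario habitats.
#'
#' @param scenario a `partridge_scenario`.
#' @return List with `m` and one data.frame per season (`habitat`,
#'   `true_alpha`, `true_epsilon`).
#' @export
scenario_ground_truth <- function(scenario) {
  m <- length(scenario$habitats)
  seasons <- lapply(scenario$weights, function(w) {
    a <- w[scenario$habitats] / sum(w)
    data.frame(habitat = scenario$habitats, true_alpha = as.numeric(a),
               true_epsilon = as.numeric(chesson_epsilon(as.numeric(a), m = m)),
               stringsAsFactors = FALSE)
  })
  c(list(m = m), seasons)
}

#' Simulate a full multi-year study dataset
#'
#' Generates every year's landscape and places units: spring territories every
#' year, winter coveys in the final year (the within-year season comparison).
#'
#' @param scenario a `partridge_scenario`.
#' @return List with `squares`, `maps` (flat list across years) and
#'   `observations`.
#' @export
simulate_scenario <- function(scenario) {
  squares <- scenario_squares(scenario)
  maps <- list()
  obs <- list()
  for (yr in scenario$years) {
    yr_maps <- generate_landscape(scenario, yr)
    maps <- c(maps, yr_maps)
    obs[[length(obs) + 1L]] <- place_units(scenario, yr_maps, "spring", yr)
    if (yr == max(scenario$years)) {
      obs[[length(obs) + 1L]] <- place_units(scenario, yr_maps, "winter", yr)
    }
  }
  list(squares = squares, maps = maps, observations = do.call(rbind, obs))
}

#' Tiny fixture scenario for unit tests and examples
#'
#' @param seed master seed.
#' @return A 3-square, single-year `partridge_scenario` with 3 habitat types.
#' @export
scenario_fixture <- function(seed = 42L) {
  partridge_scenario(
    n_squares = 3, side = 240, cell_size = 4, years = 2017L,
    habitats = c("arable", "meadow", "road"),
    composition = matrix(c(0.55, 0.30, 0.15), nrow = 1,
                         dimnames = list(NULL, c("arable", "meadow", "road"))),
    patches_per_square = 6L,
    weights = list(
      winter = c(arable = 1, meadow = 2, road = 1),
      spring = c(arable = 2, meadow = 1, road = 1)
    ),
    units_per_season = c(winter = 6, spring = 6),
    locations_per_unit = c(winter = 12, spring = 1),
    plot_radius = 20, seed = seed
  )
}
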
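# Circular plots and the use/availability geometry: plot composition,
# reference plots, super-hedge classification, proximity to infrastructure.

#' Construct a circular plot
#'
#' Habitat use is measured in circular plots around bird locations (3.14 ha at
#' the default 100 m radius, covering a breeding home range); availability in
#' equal-sized reference plots at square centres.
#'
#' @param center numeric `c(x, y)` in m.
#' @param radius radius in m (default 100).
#' @param kind `"use"` or `"availability"`.
#' @param source id of the originating observation or square.
#' @return An object of class `circular_plot`.
#' @export
circular_plot <- function(center, radius = 100, kind = c("use", "availability"),
                          source = NA_character_) {
  kind <- match.arg(kind)
  stop_if_not_scalar_number(radius, "radius", positive = TRUE)
  stopifnot(is.numeric(center), length(center) == 2L)
  structure(
    list(center = as.numeric(center), radius = radius, kind = kind,
         source = as.character(source), area_ha = pi * radius^2 / 1e4),
    class = "circular_plot"
  )
}

#' Reference (availability) plot at a square centre
#'
#' @param square one-row [survey_square()].
#' @param radius radius in m (default 100).
#' @return A `circular_plot` of kind `"availability"`.
#' @export
reference_plot <- function(square, radius = 100) {
  stopifnot(inherits(square, "survey_square") || is.data.frame(square), nrow(square) == 1L)
  circular_plot(c(square$cx, square$cy), radius = radius, kind = "availability",
                source = square$square_id)
}

# Linear cell indices of map cells whose centre lies within the plot circle.
plot_cell_index <- function(map, plot) {
  cc <- cell_centres(map)
  jr <- which(abs(cc$x - plot$center[1]) <= plot$radius)
  ir <- which(abs(cc$y - plot$center[2]) <= plot$radius)
  if (!length(jr) || !length(ir)) return(integer(0))
  dx2 <- (cc$x[jr] - plot$center[1])^2
  dy2 <- (cc$y[ir] - plot$center[2])^2
  inside <- outer(dy2, dx2, "+") <= plot$radius^2
  n <- nrow(map$grid)
  idx <- outer(ir, (jr - 1L) * n, "+")  # linear indices of candidate block
  idx[inside]
}

#' Habitat composition of a circular plot
#'
#' Tabulates the habitat codes of map cells whose centre falls inside the plot
#' (cell-centre membership). Plots overlapping the square boundary are clipped
#' at it — the map only covers the square — and proportions are renormalised
#' over the clipped area.
#'
#' @param map a `patch_map`.
#' @param plot a `circular_plot`.
#' @param coverage_tol maximum tolerated fraction of unlabelled cells in the
#'   clipped plot.
#' @return A named numeric vector of class `composition_profile`: proportions
#'   over the map's full vocabulary (zeros for absent types), summing to 1.
#'   Attributes: `kind`, `source`, `n_cells`, `square_id`.
#' @export
plot_composition <- function(map, plot, coverage_tol = 0.05) {
  stopifnot(inherits(map, "patch_map"), inherits(plot, "circular_plot"))
  idx <- plot_cell_index(map, plot)
  if (!length(idx)) {
    stop(sprintf(
      "plot at (%.0f, %.0f) does not intersect the map of square %s",
      plot$center[1], plot$center[2], map$square_id
    ), call. = FALSE)
  }
  vals <- map$grid[idx]
  na_frac <- mean(is.na(vals))
  if (na_frac > coverage_tol) {
    stop(sprintf(
      "square %s: %.1f%% of the plot area is unlabelled (tolerance %.1f%%)",
      map$square_id, 100 * na_frac, 100 * coverage_tol
    ), call. = FALSE)
  }
  vals <- vals[!is.na(vals)]
  counts <- tabulate(vals, nbins = length(map$levels))
  p <- stats::setNames(numeric(nrow(map$vocab)), map$vocab$code)
  p[map$levels] <- counts / sum(counts)
  structure(p, class = "composition_profile", kind = plot$kind,
            source = plot$source, n_cells = length(vals), square_id = map$square_id)
}

#' Classify a hedge as a "super hedge"
#'
#' Super hedges are hedges of structural quality for sheltering partridges:
#' all three thresholds must be strictly exceeded (height > 4 m, width > 2 m,
#' understory herbal cover > 70% by default).
#'
#' @param height,width hedge dimensions in m.
#' @param understory_cover herbal cover fraction in `[0, 1]`.
#' @param thresholds named list with elements `height`, `width`, `cover`.
#' @return Logical vector.
#' @export
classify_super_hedge <- function(height, width, understory_cover,
                                 thresholds = list(height = 4, width = 2, cover = 0.7)) {
  if (any(height < 0, width < 0, understory_cover < 0)) {
    stop("hedge attributes must be non-negative", call. = FALSE)
  }
  if (any(understory_cover > 1)) stop("`understory_cover` must be <= 1", call. = FALSE)
  height > thresholds$height & width > thresholds$width & understory_cover > thresholds$cover
}

#' Distance from a point to the nearest infrastructure patch
#'
#' Euclidean distance (m) from the query point to the nearest cell of an
#' infrastructure habitat type, measured to the cell rectangle (0 inside).
#' With no infrastructure anywhere on the map the distance is undefined and
#' `NA_real_` is returned.
#'
#' @param point numeric `c(x, y)`.
#' @param map a `patch_map`.
#' @param infra_codes codes counted as infrastructure; defaults to the map
#'   vocabulary's infrastructure flags.
#' @return Distance in m, or `NA_real_` if the map has no infrastructure.
#' @export
distance_to_nearest_infrastructure <- function(point, map, infra_codes = NULL) {
  stopifnot(inherits(map, "patch_map"), is.numeric(point), length(point) == 2L)
  if (is.null(infra_codes)) infra_codes <- infrastructure_codes(map$vocab)
  lev_idx <- which(map$levels %in% infra_codes)
  if (!length(lev_idx)) return(NA_real_)
  hit <- which(matrix(map$grid %in% lev_idx, nrow = nrow(map$grid)), arr.ind = TRUE)
  if (!nrow(hit)) return(NA_real_)
  cc <- cell_centres(map)
  half <- map$cell_size / 2
  dx <- pmax(abs(cc$x[hit[, 2]] - point[1]) - half, 0)
  dy <- pmax(abs(cc$y[hit[, 1]] - point[2]) - half, 0)
  sqrt(min(dx^2 + dy^2))
}
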
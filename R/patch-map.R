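# Survey squares and categorical patch maps on a regular grid.
#
# Coordinates are planar metric (projected), y-up. A patch map stores one
# square's land cover in one year at one scale as an integer matrix over a
# closed habitat vocabulary; row 1 is the bottom row, so cell (i, j) has its
# centre at (x0 + (j - 0.5) * cell, y0 + (i - 0.5) * cell). Areas are in ha.

#' Define survey squares
#'
#' Survey squares are the study units: squares of 618 m side (one sixth of a
#' geographical minute) identified by `square_id` and located by their
#' centroid in a projected coordinate system.
#'
#' @param square_id character vector of identifiers.
#' @param cx,cy numeric centroid coordinates (m).
#' @param side side length in m (default 618).
#' @return A data.frame of class `survey_square` with columns `square_id`,
#'   `cx`, `cy`, `side`.
#' @export
survey_square <- function(square_id, cx, cy, side = 618) {
  stopifnot(length(square_id) == length(cx), length(cx) == length(cy))
  if (any(side <= 0)) stop("`side` must be > 0", call. = FALSE)
  if (anyDuplicated(square_id)) stop("`square_id` must be unique", call. = FALSE)
  out <- data.frame(
    square_id = as.character(square_id), cx = as.numeric(cx),
    cy = as.numeric(cy), side = rep_len(as.numeric(side), length(cx)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("survey_square", "data.frame")
  out
}

#' Construct a patch map from a code matrix
#'
#' @param grid integer matrix of habitat level indices (row 1 = bottom row),
#'   or a character matrix of habitat codes. `NA` marks unlabelled cells.
#' @param levels character vector of habitat codes indexed by the integers in
#'   `grid` (ignored when `grid` is character).
#' @param square_id,year,scale map identity.
#' @param cell_size cell edge length in m.
#' @param origin numeric `c(x0, y0)` of the lower-left corner.
#' @param vocab habitat vocabulary the codes must belong to; defaults to the
#'   built-in vocabulary for `scale`.
#' @return An object of class `patch_map`.
#' @export
patch_map <- function(grid, levels = NULL, square_id, year, scale = c("rough", "fine"),
                      cell_size, origin = c(0, 0), vocab = NULL) {
  scale <- match.arg(scale)
  stop_if_not_scalar_number(cell_size, "cell_size", positive = TRUE)
  if (is.character(grid)) {
    levels <- sort(unique(as.vector(grid[!is.na(grid)])))
    grid <- matrix(match(grid, levels), nrow = nrow(grid))
  }
  stopifnot(is.matrix(grid), is.character(levels))
  if (is.null(vocab)) vocab <- habitat_vocabulary(scale)
  assert_known_codes(levels, vocab, context = sprintf("patch map %s/%s", square_id, year))
  structure(
    list(
      square_id = as.character(square_id), year = as.integer(year), scale = scale,
      grid = grid, levels = levels, cell_size = cell_size,
      origin = as.numeric(origin), vocab = vocab
    ),
    class = "patch_map"
  )
}

#' @export
print.patch_map <- function(x, ...) {
  cat(sprintf(
    "<patch_map> square %s, year %d, %s scale: %d x %d cells of %g m (%.1f ha)\n",
    x$square_id, x$year, x$scale, nrow(x$grid), ncol(x$grid), x$cell_size,
    map_total_area(x)
  ))
  tab <- sort(table(x$levels[x$grid]), decreasing = TRUE)
  cat("  cover:", paste(sprintf("%s %.0f%%", names(tab), 100 * tab / sum(tab)), collapse = ", "), "\n")
  invisible(x)
}

#' Total labelled area of a patch map in ha
#' @param map a `patch_map`.
#' @export
map_total_area <- function(map) {
  sum(!is.na(map$grid)) * map$cell_size^2 / 1e4
}

# Cell-centre coordinates; returns list(x = by column, y = by row).
cell_centres <- function(map) {
  list(
    x = map$origin[1] + (seq_len(ncol(map$grid)) - 0.5) * map$cell_size,
    y = map$origin[2] + (seq_len(nrow(map$grid)) - 0.5) * map$cell_size
  )
}

# Habitat code of every cell as a character matrix (internal).
map_codes <- function(map) {
  matrix(map$levels[map$grid], nrow = nrow(map$grid))
}

#' Area share of each habitat type over a whole patch map
#'
#' @param map a `patch_map`.
#' @return Named numeric vector over the map's vocabulary codes, summing to 1.
#' @export
map_composition <- function(map) {
  counts <- tabulate(map$grid[!is.na(map$grid)], nbins = length(map$levels))
  p <- stats::setNames(numeric(nrow(map$vocab)), map$vocab$code)
  p[map$levels] <- counts / sum(counts)
  p
}

# ---- ASCII-grid + legend CSV round trip ------------------------------------

#' Write a patch map as an ESRI ASCII grid plus a CSV legend
#'
#' The grid file holds integer level indices (NODATA -9999); the legend CSV
#' maps them back to habitat codes and carries the map identity (`square_id`,
#' `year`, `scale`, `cell_size`, origin). [read_patch_asc()] inverts this
#' bit-identically.
#'
#' @param map a `patch_map`.
#' @param asc_path,legend_path output file paths.
#' @return Invisibly, `c(asc_path, legend_path)`.
#' @export
write_patch_asc <- function(map, asc_path, legend_path) {
  g <- map$grid
  g[is.na(g)] <- -9999L
  hdr <- c(
    sprintf("ncols %d", ncol(g)), sprintf("nrows %d", nrow(g)),
    sprintf("xllcorner %.10g", map$origin[1]), sprintf("yllcorner %.10g", map$origin[2]),
    sprintf("cellsize %.10g", map$cell_size), "NODATA_value -9999"
  )
  # ASCII grids store the top row first; our row 1 is the bottom row.
  body <- apply(g[rev(seq_len(nrow(g))), , drop = FALSE], 1L, paste, collapse = " ")
  writeLines(c(hdr, body), asc_path)
  legend <- data.frame(
    value = seq_along(map$levels), habitat = map$levels,
    square_id = map$square_id, year = map$year, scale = map$scale,
    stringsAsFactors = FALSE
  )
  utils::write.csv(legend, legend_path, row.names = FALSE)
  invisible(c(asc_path, legend_path))
}

#' Read a patch map written by [write_patch_asc()]
#'
#' @param asc_path,legend_path file paths.
#' @param vocab optional vocabulary override.
#' @return A `patch_map`.
#' @export
read_patch_asc <- function(asc_path, legend_path, vocab = NULL) {
  lines <- readLines(asc_path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  hv <- stats::setNames(
    vapply(hdr, function(p) as.numeric(p[2]), numeric(1)),
    tolower(vapply(hdr, `[[`, character(1), 1L))
  )
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), what = integer(), quiet = TRUE)
  ncols <- as.integer(hv[["ncols"]]); nrows <- as.integer(hv[["nrows"]])
  if (length(vals) != ncols * nrows) stop("ASCII grid body does not match header dimensions", call. = FALSE)
  g <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  g <- g[rev(seq_len(nrows)), , drop = FALSE]  # back to y-up
  g[g == -9999L] <- NA_integer_
  legend <- utils::read.csv(legend_path, stringsAsFactors = FALSE)
  stopifnot(all(c("value", "habitat", "square_id", "year", "scale") %in% names(legend)))
  levels <- character(max(legend$value))
  levels[legend$value] <- legend$habitat
  patch_map(
    g, levels = levels, square_id = legend$square_id[1], year = legend$year[1],
    scale = legend$scale[1], cell_size = hv[["cellsize"]],
    origin = c(hv[["xllcorner"]], hv[["yllcorner"]]), vocab = vocab
  )
}

# ---- GeoJSON polygon input --------------------------------------------------

# Even-odd (ray casting) point-in-polygon; pts is a 2-col matrix, ring a
# closed or open 2-col matrix of vertices. Vectorised over pts.
point_in_ring <- function(pts, ring) {
  n <- nrow(ring)
  if (all(ring[1, ] == ring[n, ])) { ring <- ring[-n, , drop = FALSE]; n <- n - 1L }
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]; xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterise a GeoJSON FeatureCollection of habitat polygons onto a square grid
#'
#' Polygon features must carry properties `square_id`, `year`, `scale` and
#' `habitat`. Features belonging to `square` are rasterised by cell-centre
#' membership (even-odd rule; interior rings are treated as holes). Later
#' features overwrite earlier ones where they overlap, but inputs are expected
#' to be non-overlapping.
#'
#' @param path GeoJSON file path.
#' @param square one-row [survey_square()] selecting the square to rasterise.
#' @param cell_size grid resolution in m (default 1).
#' @param vocab optional vocabulary override.
#' @param coverage_tol maximum tolerated unlabelled area fraction.
#' @return A `patch_map`.
#' @export
read_patch_geojson <- function(path, square, cell_size = 1, vocab = NULL,
                               coverage_tol = 0.01) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection")) stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  feats <- Filter(function(f) identical(f$properties$square_id, square$square_id[1]), gj$features)
  if (!length(feats)) stop(sprintf("no features for square %s in %s", square$square_id[1], path), call. = FALSE)
  scale <- feats[[1]]$properties$scale
  year <- as.integer(feats[[1]]$properties$year)
  x0 <- square$cx[1] - square$side[1] / 2
  y0 <- square$cy[1] - square$side[1] / 2
  n <- max(1L, round(square$side[1] / cell_size))
  xc <- x0 + (seq_len(n) - 0.5) * cell_size
  yc <- y0 + (seq_len(n) - 0.5) * cell_size
  pts <- cbind(rep(xc, each = n), rep.int(yc, n))  # grouped by column
  codes <- vapply(feats, function(f) as.character(f$properties$habitat), character(1))
  levels <- sort(unique(codes))
  g <- rep(NA_integer_, n * n)
  for (k in seq_along(feats)) {
    geom <- feats[[k]]$geometry
    polys <- switch(geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop(sprintf("unsupported geometry type '%s'", geom$type), call. = FALSE)
    )
    hit <- rep(FALSE, n * n)
    for (poly in polys) {
      inside <- point_in_ring(pts, do.call(rbind, lapply(poly[[1]], function(c2) unlist(c2)[1:2])))
      for (ring in poly[-1]) {  # holes
        inside <- inside & !point_in_ring(pts, do.call(rbind, lapply(ring, function(c2) unlist(c2)[1:2])))
      }
      hit <- hit | inside
    }
    g[hit] <- match(codes[k], levels)
  }
  uncovered <- mean(is.na(g))
  if (uncovered > coverage_tol) {
    stop(sprintf(
      "square %s: %.1f%% of the area is unlabelled (tolerance %.1f%%)",
      square$square_id[1], 100 * uncovered, 100 * coverage_tol
    ), call. = FALSE)
  }
  # g is ordered with y varying fastest within x-blocks, so column-wise fill
  # yields rows = y (bottom first), columns = x.
  grid <- matrix(g, nrow = n, ncol = n)
  patch_map(grid, levels = levels, square_id = square$square_id[1], year = year,
            scale = scale, cell_size = cell_size, origin = c(x0, y0), vocab = vocab)
}

# ---- Observations -----------------------------------------------------------

#' Read an observation table
#'
#' Observations are bird records: one row per mapped location with the square,
#' planar coordinates, year, season (`winter`/`spring`), unit kind
#' (`individual`, `pair`, `covey`, `territory`) and group size. An optional
#' `unit_id` column groups repeated locations of one analysis unit (e.g. covey
#' relocations); it defaults to `obs_id`.
#'
#' @param path CSV path with columns `obs_id`, `square_id`, `x`, `y`, `year`,
#'   `season`, `unit_kind`, `group_size` (optionally `unit_id`).
#' @return A data.frame.
#' @export
read_observations <- function(path) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("obs_id", "square_id", "x", "y", "year", "season", "unit_kind", "group_size")
  missing <- setdiff(required, names(obs))
  if (length(missing)) {
    stop(sprintf("observation file %s lacks column(s): %s", path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (is.null(obs$unit_id)) obs$unit_id <- obs$obs_id
  obs
}
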
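# Manly's alpha selection index and Chesson's electivity index.
#
# For habitat type i with use proportion r_i and availability proportion n_i
# over m available types:
#
#   alpha_i = (r_i / n_i) / sum_j (r_j / n_j)              (selection index)
#   eps_i   = (m * alpha_i - 1) / ((m - 2) * alpha_i + 1)  (electivity)
#
# eps is 0 at neutral use (alpha = 1/m), +1 at exclusive use, -1 at complete
# avoidance, and is comparable across units with differing numbers of
# available types.

#' Manly's alpha selection index
#'
#' @param use named numeric vector of use proportions `r_i` (sums to 1).
#' @param avail named numeric vector of availability proportions `n_i` over the
#'   same habitat codes (sums to 1). Types with zero availability and zero use
#'   are dropped; zero availability with positive use is an error (an
#'   availability-frame mismatch, never silently dropped).
#' @return Named numeric vector of `alpha_i` over the retained types (summing
#'   to 1), with attribute `m` = number of types with positive availability.
#' @examples
#' manly_alpha(c(a = 0.5, b = 0.3, c = 0.2), c(a = 0.2, b = 0.3, c = 0.5))
#' @export
manly_alpha <- function(use, avail) {
  stopifnot(is.numeric(use), is.numeric(avail))
  if (is.null(names(use)) || is.null(names(avail))) {
    stop("`use` and `avail` must be named by habitat code", call. = FALSE)
  }
  if (!setequal(names(use), names(avail))) {
    stop("`use` and `avail` must cover the same habitat vocabulary", call. = FALSE)
  }
  avail <- avail[names(use)]
  check_proportions(use, "use")
  check_proportions(avail, "avail")
  unsupported <- names(use)[use > 0 & avail == 0]
  if (length(unsupported)) {
    stop(sprintf(
      "unsupported use: type(s) %s used but unavailable in the active availability frame",
      paste(unsupported, collapse = ", ")
    ), call. = FALSE)
  }
  keep <- avail > 0  # jointly-zero types dropped; use>0&avail==0 already rejected
  use <- use[keep]; avail <- avail[keep]
  if (sum(use) <= 0) stop("all-zero use profile", call. = FALSE)
  m <- length(use)
  if (m < 2) stop("need at least 2 available habitat types (m >= 2)", call. = FALSE)
  w <- use / avail
  structure(w / sum(w), m = m)
}

#' Chesson's electivity index from Manly's alpha
#'
#' @param alpha numeric vector of selection indices in `[0, 1]`.
#' @param m number of potential habitat types (>= 2); defaults to the `m`
#'   attribute set by [manly_alpha()], else `length(alpha)`.
#' @return Numeric vector of electivities in `[-1, 1]`.
#' @examples
#' chesson_epsilon(c(1, 0, 0, 0))        # exclusive use -> (1, -1, -1, -1)
#' chesson_epsilon(0.5, m = 4)           # 0.5
#' @export
chesson_epsilon <- function(alpha, m = NULL) {
  if (is.null(m)) m <- attr(alpha, "m", exact = TRUE)
  if (is.null(m)) m <- length(alpha)
  if (m < 2) stop("`m` must be >= 2", call. = FALSE)
  if (any(alpha < -1e-12 | alpha > 1 + 1e-12)) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  eps <- (m * as.numeric(alpha) - 1) / ((m - 2) * as.numeric(alpha) + 1)
  eps <- pmin(pmax(eps, -1), 1)
  names(eps) <- names(alpha)
  eps
}

#' Invert Chesson's electivity back to Manly's alpha
#'
#' Testing inverse of [chesson_epsilon()]: `alpha = (1 + eps) / (m - (m - 2) * eps)`.
#'
#' @param eps electivities in `[-1, 1]`.
#' @param m number of potential habitat types (>= 2).
#' @return Numeric vector of alphas.
#' @export
alpha_from_epsilon <- function(eps, m) {
  if (m < 2) stop("`m` must be >= 2", call. = FALSE)
  (1 + eps) / (m - (m - 2) * eps)
}

#' Build an availability frame from reference-plot compositions
#'
#' At the rough scale availability was averaged over all squares' reference
#' plots; at the fine scale it was kept per square, because averaging includes
#' habitat types absent from individual squares and inflates avoidances.
#'
#' @param profiles named list of availability compositions (one per square,
#'   names = square ids), e.g. from [plot_composition()] on [reference_plot()]s,
#'   or from [map_composition()].
#' @param mode `"averaged_over_squares"` or `"per_square"`.
#' @return An object of class `availability_frame`: list with `mode` and
#'   `proportions` (a single named vector, or a named list per square).
#' @export
availability_frame <- function(profiles, mode = c("averaged_over_squares", "per_square")) {
  mode <- match.arg(mode)
  stopifnot(is.list(profiles), length(profiles) >= 1L, !is.null(names(profiles)))
  mat <- do.call(rbind, lapply(profiles, as.numeric))
  colnames(mat) <- names(profiles[[1]])
  if (mode == "averaged_over_squares") {
    p <- colMeans(mat)
    p <- p / sum(p)
    props <- p
  } else {
    props <- lapply(profiles, function(p) {
      p <- as.numeric(p) / sum(p)
      stats::setNames(p, names(profiles[[1]]))
    })
  }
  structure(list(mode = mode, proportions = props), class = "availability_frame")
}

# Availability vector applying to a given square under either mode.
frame_for_square <- function(frame, square_id) {
  stopifnot(inherits(frame, "availability_frame"))
  if (frame$mode == "averaged_over_squares") return(frame$proportions)
  p <- frame$proportions[[square_id]]
  if (is.null(p)) stop(sprintf("availability frame has no entry for square %s", square_id), call. = FALSE)
  p
}

#' Electivity of one analysis unit
#'
#' The unit's use profile is the unweighted mean of the compositions of its
#' plots (plots have equal area), compared against the availability frame
#' active for its square.
#'
#' @param profiles list of `composition_profile`s (>= 1) for the unit's
#'   locations.
#' @param frame an [availability_frame()].
#' @param square_id square the unit belongs to (used in `per_square` mode).
#' @return List with `alpha`, `epsilon` (named vectors over retained types),
#'   `m`, and `use` (the mean use profile).
#' @export
unit_electivity <- function(profiles, frame, square_id = NULL) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  if (is.null(square_id)) square_id <- attr(profiles[[1]], "square_id")
  use <- colMeans(do.call(rbind, lapply(profiles, as.numeric)))
  use <- stats::setNames(use / sum(use), names(profiles[[1]]))
  avail <- frame_for_square(frame, square_id)
  alpha <- manly_alpha(use, avail)
  list(alpha = alpha, epsilon = chesson_epsilon(alpha), m = attr(alpha, "m"), use = use)
}

#' Long electivity table across units
#'
#' One row per unit x retained habitat type, ready for per-habitat bootstrap
#' resampling. Types unavailable to a unit (dropped from its availability
#' frame) simply have no row for that unit, so `m` may differ across units in
#' `per_square` mode.
#'
#' @param units named list; each element is a list of `composition_profile`s
#'   for one unit (names = unit ids).
#' @param frame an [availability_frame()].
#' @param level analysis level label: `"square"`, `"individual"` or
#'   `"territory"`.
#' @param square_ids optional character vector mapping units to squares
#'   (defaults to each unit's first profile's `square_id` attribute).
#' @return data.frame with columns `level`, `unit_id`, `habitat`, `alpha`,
#'   `epsilon`, `m`.
#' @export
electivity_table <- function(units, frame, level = c("square", "individual", "territory"),
                             square_ids = NULL) {
  level <- match.arg(level)
  stopifnot(is.list(units), length(units) >= 1L, !is.null(names(units)))
  rows <- lapply(seq_along(units), function(k) {
    sq <- if (!is.null(square_ids)) square_ids[[k]] else attr(units[[k]][[1]], "square_id")
    res <- unit_electivity(units[[k]], frame, square_id = sq)
    data.frame(
      level = level, unit_id = names(units)[k], habitat = names(res$alpha),
      alpha = as.numeric(res$alpha), epsilon = as.numeric(res$epsilon),
      m = res$m, stringsAsFactors = FALSE, row.names = NULL
    )
  })
  do.call(rbind, rows)
}
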
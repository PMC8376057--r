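# Habitat vocabularies: closed sets of habitat codes per mapping scale.

# Codes flagged as infrastructure (human constructions) at either scale.
.infrastructure_codes <- c(
  "road", "field_path", "settlement", "park", "windmill", "power_pole",
  "under_construction", "gravel_walk", "tarred_road"
)

.rough_codes <- c(
  "arable", "meadow", "vineyard", "forest", "hedgerow", "water_body",
  "field_path", "road", "settlement", "park", "power_pole", "windmill",
  "under_construction"
)

.fine_codes <- c(
  "winter_grain", "harvested_field", "without_crop", "meadow",
  "fallow_green_manure", "field_path", "gravel_walk", "tarred_road",
  "hedgerow_small_trees", "super_hedge"
)

#' Habitat vocabulary for a mapping scale
#'
#' Land cover is mapped at two scales: a rough scale from annual land-cover maps
#' (arable land, meadow, vineyard, forest, hedgerow, water body, plus
#' infrastructure types) and a fine scale from field visits (crop states,
#' tracks, hedge classes). Codes form a closed vocabulary per scale; unknown
#' codes are an error everywhere in the package, never silently pooled.
#'
#' @param scale `"rough"` or `"fine"`.
#' @param codes optional character vector to restrict/customise the vocabulary;
#'   each entry's infrastructure flag is looked up from the built-in code list,
#'   unknown custom codes default to non-infrastructure.
#' @return A data.frame with columns `code`, `scale`, `is_infrastructure`,
#'   `display_name`.
#' @examples
#' habitat_vocabulary("rough")
#' @export
habitat_vocabulary <- function(scale = c("rough", "fine"), codes = NULL) {
  scale <- match.arg(scale)
  if (is.null(codes)) {
    codes <- if (scale == "rough") .rough_codes else .fine_codes
  } else {
    codes <- as.character(codes)
    if (anyDuplicated(codes)) stop("habitat codes must be unique within a scale", call. = FALSE)
  }
  data.frame(
    code = codes,
    scale = scale,
    is_infrastructure = codes %in% .infrastructure_codes,
    display_name = gsub("_", " ", codes),
    stringsAsFactors = FALSE
  )
}

#' Infrastructure codes within a vocabulary
#'
#' @param vocab a data.frame from [habitat_vocabulary()].
#' @return Character vector of codes with `is_infrastructure = TRUE`.
#' @export
infrastructure_codes <- function(vocab) {
  stopifnot(is.data.frame(vocab), all(c("code", "is_infrastructure") %in% names(vocab)))
  vocab$code[vocab$is_infrastructure]
}

# Error on codes outside the vocabulary; used by readers and the generator.
assert_known_codes <- function(codes, vocab, context = "input") {
  unknown <- setdiff(unique(codes), vocab$code)
  if (length(unknown)) {
    stop(sprintf(
      "unknown habitat code(s) in %s: %s (vocabulary scale '%s')",
      context, paste(unknown, collapse = ", "), vocab$scale[1]
    ), call. = FALSE)
  }
  invisible(codes)
}
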
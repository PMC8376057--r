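# Shared fixture builders: all fixtures are constructed in code.

# Grid map from a character matrix (row 1 = bottom row, y-up). `vocab_codes`
# can widen the vocabulary beyond the codes present in the matrix.
make_grid_map <- function(codes, cell_size = 10, square_id = "t1", year = 2017L,
                          scale = "rough", origin = c(0, 0), vocab_codes = NULL) {
  vocab <- habitat_vocabulary(
    scale, codes = sort(unique(c(as.vector(codes), vocab_codes))))
  patch_map(codes, square_id = square_id, year = year, scale = scale,
            cell_size = cell_size, origin = origin, vocab = vocab)
}

# Uniform one-type square map.
uniform_map <- function(code = "arable", n = 20, cell_size = 10, ...) {
  make_grid_map(matrix(code, n, n), cell_size = cell_size, ...)
}

# Left half code_a, right half code_b (split at the vertical midline).
halfplane_map <- function(code_a = "arable", code_b = "meadow", n = 200,
                          cell_size = 1, ...) {
  codes <- matrix(code_b, n, n)
  codes[, seq_len(n / 2)] <- code_a
  make_grid_map(codes, cell_size = cell_size, ...)
}

# Write a toy GeoJSON FeatureCollection of habitat polygons.
write_toy_geojson <- function(path, features) {
  fc <- list(
    type = "FeatureCollection",
    features = lapply(features, function(f) {
      list(
        type = "Feature",
        properties = list(square_id = f$square_id, year = f$year,
                          scale = f$scale, habitat = f$habitat),
        geometry = list(type = "Polygon",
                        coordinates = list(lapply(seq_len(nrow(f$ring)),
                                                  function(i) as.list(f$ring[i, ]))))
      )
    })
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  path
}
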
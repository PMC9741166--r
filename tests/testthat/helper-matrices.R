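# Shared generators for property-style tests. All randomness is seeded at
# the call site so failures reproduce.

# a batch of random tables of varying shape
random_matrices <- function(n, seed, n_cat = 2:8, n_attr = 1:5,
                            distribution = "uniform") {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    generate_matrix(sample(n_cat, 1L), sample(n_attr, 1L),
                    value_range = c(0, sample(c(1, 10, 100), 1L)),
                    distribution = distribution)
  })
}

# a table guaranteed to have no ties within any attribute column
tie_free_matrix <- function(n_cat, n_attr, seed) {
  set.seed(seed)
  vals <- matrix(0, n_cat, n_attr)
  for (j in seq_len(n_attr)) vals[, j] <- sample(seq_len(n_cat) * 7)
  data_matrix(vals, paste0("C", seq_len(n_cat)), paste0("A", seq_len(n_attr)))
}

# independent extreme-value scan: linear pass keeping the first strict best
brute_force_extremes <- function(m) {
  out <- NULL
  for (j in seq_along(m$attributes)) {
    best_max <- 1L; best_min <- 1L
    for (i in seq_along(m$categories)) {
      if (m$values[i, j] > m$values[best_max, j]) best_max <- i
      if (m$values[i, j] < m$values[best_min, j]) best_min <- i
    }
    rows <- data.frame(
      attribute = m$attributes[j],
      category = m$categories[c(best_max, best_min)],
      kind = c("max", "min"),
      value = m$values[c(best_max, best_min), j],
      stringsAsFactors = FALSE
    )
    if (rows$value[1L] == rows$value[2L]) rows <- rows[1L, , drop = FALSE]
    out <- rbind(out, rows)
  }
  rownames(out) <- NULL
  out
}

# hsl lightness (0-100) of a hex colour, for shade assertions
hex_lightness <- function(hex) {
  unname(farver::decode_colour(hex, to = "hsl")[, "l"])
}
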
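test_that("the circle divides equally among attributes and petals", {
  expect_equal(section_angle(4), 90)
  expect_equal(section_angle(1), 360)
  expect_equal(section_angle(6), 60)
  expect_equal(petal_angle(4, 6), 15)
  expect_equal(petal_angle(1, 1), 360)
  expect_equal(petal_angle(2, 5), 36)
  expect_error(section_angle(0), "positive")
  expect_error(petal_angle(4, 0), "positive")
})

test_that("value_to_radius hits its anchors in both modes", {
  lin <- chart_config(radius_mode = "linear", r_max = 2, r_inner = 0.3)
  area <- chart_config(radius_mode = "area", r_max = 2, r_inner = 0.3)
  area0 <- chart_config(radius_mode = "area", r_max = 2, r_inner = 0)
  expect_equal(value_to_radius(10, 10, lin), 2)
  expect_equal(value_to_radius(10, 10, area), 2)
  expect_equal(value_to_radius(0, 10, lin), 0.3)
  expect_equal(value_to_radius(0, 10, area), 0.3)
  # quarter of the reference at r_inner = 0 gives half the radius (area mode)
  expect_equal(value_to_radius(2.5, 10, area0), 1)
  # monotone non-decreasing in v
  v <- seq(0, 10, length.out = 101)
  for (cfg in list(lin, area)) {
    expect_true(all(diff(value_to_radius(v, 10, cfg)) >= 0))
  }
  expect_error(value_to_radius(1, 0, lin), "positive")
  expect_error(value_to_radius(-1, 10, lin), ">= 0")
  expect_warning(r <- value_to_radius(12, 10, lin), "clamped")
  expect_equal(r, 2)
})

test_that("the flat case-study layout yields 24 petals in four 90-degree sections", {
  model <- compute_flat_layout(covid_fixture(), chart_config())
  p <- model$petals
  expect_equal(nrow(p), 24L)
  expect_equal(unique(p$theta_end_deg - p$theta_start_deg), 15)
  # each attribute occupies one contiguous quarter
  for (ai in 1:4) {
    sec <- p[p$attribute_index == ai, ]
    expect_equal(min(sec$theta_start_deg), (ai - 1) * 90)
    expect_equal(max(sec$theta_end_deg), ai * 90)
  }
  # categories in row order within a section
  first <- p[p$attribute_index == 1, ]
  expect_identical(first$category[order(first$theta_start_deg)],
                   covid_fixture()$categories)
})

test_that("a 1x1 table yields one full-circle petal reaching r_max", {
  m <- data_matrix(matrix(5), "only", "A")
  model <- compute_flat_layout(m, chart_config(r_max = 3))
  expect_equal(nrow(model$petals), 1L)
  expect_equal(model$petals$theta_start_deg, 0)
  expect_equal(model$petals$theta_end_deg, 360)
  expect_equal(model$petals$r_outer, 3)
})

test_that("angular spans tile the circle without gaps or overlaps", {
  for (m in random_matrices(12, seed = 21)) {
    for (kind in c("flat", "stacked")) {
      cfg <- chart_config(kind = kind)
      model <- if (kind == "flat") compute_flat_layout(m, cfg) else
        compute_stacked_layout(m, cfg)
      p <- model$petals
      for (layer in unique(p$layer_index)) {
        lay <- p[p$layer_index == layer, ]
        lay <- lay[order(lay$theta_start_deg), ]
        expect_equal(sum(lay$theta_end_deg - lay$theta_start_deg), 360,
                     tolerance = 1e-9)
        # brute-force interval check: each petal starts where the previous ends
        expect_equal(lay$theta_start_deg[1L], 0)
        if (nrow(lay) > 1L) {
          expect_equal(lay$theta_start_deg[-1L],
                       lay$theta_end_deg[-nrow(lay)], tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("flat radii are monotone in value against the shared reference", {
  for (m in random_matrices(8, seed = 22)) {
    for (mode in c("linear", "area")) {
      model <- compute_flat_layout(m, chart_config(radius_mode = mode))
      p <- model$petals[order(model$petals$scaled_value), ]
      expect_true(all(diff(p$r_outer) >= -1e-12))
      expect_equal(max(p$r_outer), model$config$r_max)
    }
  }
})

test_that("the stacked case-study layout yields six 60-degree petals of four layers", {
  model <- compute_stacked_layout(covid_fixture(), chart_config(kind = "stacked"))
  p <- model$petals
  expect_equal(nrow(p), 24L)
  expect_equal(length(unique(p$category_index)), 6L)
  expect_equal(unique(p$theta_end_deg - p$theta_start_deg), 60)
  expect_identical(sort(unique(p$layer_index)), 0:3)
  # default layer order follows column order from the centre out
  usa <- p[p$category == "USA", ]
  expect_identical(usa$attribute[order(usa$layer_index)],
                   covid_fixture()$attributes)
})

test_that("stacked layers accumulate: top radius encodes the category total", {
  for (m in random_matrices(8, seed = 23)) {
    for (mode in c("linear", "area")) {
      cfg <- chart_config(kind = "stacked", radius_mode = mode)
      model <- compute_stacked_layout(m, cfg)
      p <- model$petals
      totals <- unname(rowSums(m$values))
      v_ref <- max(totals)
      for (ci in seq_along(m$categories)) {
        pet <- p[p$category_index == ci, ]
        pet <- pet[order(pet$layer_index), ]
        # layers chain without gaps and never invert
        expect_equal(pet$r_inner[1L], cfg$r_inner)
        if (nrow(pet) > 1L) {
          expect_equal(pet$r_inner[-1L], pet$r_outer[-nrow(pet)])
        }
        expect_true(all(pet$r_outer >= pet$r_inner))
        # positive thickness iff positive value
        expect_identical(pet$r_outer - pet$r_inner > 0, pet$scaled_value > 0)
        # cumulative-sum oracle for the top layer
        expect_equal(pet$r_outer[nrow(pet)],
                     value_to_radius(totals[ci], v_ref, cfg),
                     tolerance = 1e-12)
      }
      expect_equal(max(p$r_outer), cfg$r_max)
    }
  }
})

test_that("a single-attribute stack coincides with the flat rose of that attribute", {
  m <- generate_matrix(6, 1, seed = 9)
  flat <- compute_flat_layout(m, chart_config(kind = "flat"))
  stacked <- compute_stacked_layout(m, chart_config(kind = "stacked"))
  f <- flat$petals[order(flat$petals$theta_start_deg), ]
  s <- stacked$petals[order(stacked$petals$theta_start_deg), ]
  expect_equal(f$theta_start_deg, s$theta_start_deg)
  expect_equal(f$theta_end_deg, s$theta_end_deg)
  expect_equal(f$r_outer, s$r_outer)
  expect_identical(f$category, s$category)
})

test_that("layer_order permutes stacked layers and rejects non-permutations", {
  m <- covid_fixture()
  ord <- rev(m$attributes)
  model <- compute_stacked_layout(m, chart_config(kind = "stacked",
                                                  layer_order = ord))
  usa <- model$petals[model$petals$category == "USA", ]
  expect_identical(usa$attribute[order(usa$layer_index)], ord)
  expect_error(
    compute_stacked_layout(m, chart_config(kind = "stacked",
                                           layer_order = m$attributes[1:2])),
    "permutation")
})

test_that("clockwise sorting orders the death-rate section with a stable tie", {
  model <- compute_flat_layout(covid_fixture(), chart_config())
  sorted <- sort_petals(model, "clockwise")
  sec <- sorted$petals[sorted$petals$attribute == "Death Rate", ]
  sec <- sec[order(sec$theta_start_deg), ]
  # Russia 2.79, Brazil 2.48, then the USA/India tie at 1.18 kept in row
  # order, UK 0.91, France 0.69
  expect_identical(sec$category,
                   c("Russia", "Brazil", "USA", "India", "UK", "France"))
  expect_equal(sec$value, c(2.79, 2.48, 1.18, 1.18, 0.91, 0.69))
  # slot boundaries unchanged
  expect_equal(sort(sec$theta_start_deg), seq(0, 75, by = 15))
})

test_that("sorting permutes occupancy only, reverses cleanly, and is idempotent", {
  model <- compute_flat_layout(covid_fixture(), chart_config())
  cw <- sort_petals(model, "clockwise")
  # multiset of (category, value) per section preserved
  for (ai in 1:4) {
    before <- model$petals[model$petals$attribute_index == ai, ]
    after <- cw$petals[cw$petals$attribute_index == ai, ]
    expect_identical(sort(paste(before$category, before$value)),
                     sort(paste(after$category, after$value)))
  }
  expect_identical(sort_petals(cw, "clockwise")$petals, cw$petals)
  # tie-free tables: counterclockwise is the exact reverse of clockwise
  m <- tie_free_matrix(7, 3, seed = 5)
  model <- compute_flat_layout(m, chart_config())
  cw <- sort_petals(model, "clockwise")
  ccw <- sort_petals(model, "counterclockwise")
  for (ai in 1:3) {
    a <- cw$petals[cw$petals$attribute_index == ai, ]
    b <- ccw$petals[ccw$petals$attribute_index == ai, ]
    expect_identical(a$category[order(a$theta_start_deg)],
                     rev(b$category[order(b$theta_start_deg)]))
  }
})

test_that("stacked petals sort by total or by a key attribute", {
  m <- covid_fixture()
  model <- compute_stacked_layout(m, chart_config(kind = "stacked"))
  by_total <- sort_petals(model, "clockwise", "total")
  p <- by_total$petals[by_total$petals$layer_index == 0L, ]
  got <- p$category[order(p$theta_start_deg)]
  want <- m$categories[order(-rowSums(m$values))]
  expect_identical(got, want)
  by_death <- sort_petals(model, "clockwise", "Death Rate")
  p <- by_death$petals[by_death$petals$layer_index == 0L, ]
  expect_identical(p$category[order(p$theta_start_deg)],
                   c("Russia", "Brazil", "USA", "India", "UK", "France"))
  expect_error(sort_petals(model, "clockwise", "Nope"), "unknown sort key")
})

test_that("petal_area follows the annular-sector formula", {
  p <- data.frame(theta_start_deg = 0, theta_end_deg = 90,
                  r_inner = 0, r_outer = 2)
  expect_equal(petal_area(p), pi)
  p$r_inner <- 2
  expect_equal(petal_area(p), 0)
})

test_that("area mode makes petal areas proportional to values", {
  for (m in random_matrices(10, seed = 31)) {
    cfg <- chart_config(radius_mode = "area", r_inner = 0)
    model <- compute_flat_layout(m, cfg)
    p <- model$petals
    areas <- petal_area(p)
    pos <- p$scaled_value > 0
    if (sum(pos) > 1L) {
      ratio <- areas[pos] / p$scaled_value[pos]
      expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
    }
    expect_true(all(areas[!pos] == 0))
  }
})
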
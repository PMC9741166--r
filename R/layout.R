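#' Angular span of one attribute section
#'
#' A flat rose chart divides the circle equally among the attributes: four
#' attributes give four 90-degree sections, six give 60-degree sections.
#'
#' @param n_attr number of attributes (>= 1).
#' @return the section angle in degrees, `360 / n_attr`.
#' @export
section_angle <- function(n_attr) {
  if (!is.numeric(n_attr) || length(n_attr) != 1L || n_attr < 1) {
    stop("section_angle: n_attr must be a positive integer", call. = FALSE)
  }
  360 / n_attr
}

#' Angular span of one petal in the flat layout
#'
#' Each attribute section is subdivided equally among the categories, so a
#' petal spans `360 / (n_attr * n_cat)` degrees (15 degrees for a 4-attribute,
#' 6-category table).
#'
#' @param n_attr,n_cat numbers of attributes and categories (both >= 1).
#' @return the petal angle in degrees.
#' @export
petal_angle <- function(n_attr, n_cat) {
  if (!is.numeric(n_cat) || length(n_cat) != 1L || n_cat < 1) {
    stop("petal_angle: n_cat must be a positive integer", call. = FALSE)
  }
  section_angle(n_attr) / n_cat
}

#' Map a value to a radius
#'
#' In `"linear"` mode the radial extent above `r_inner` is proportional to
#' the value. In `"area"` mode (the polar-area convention) the annular-sector
#' area between `r_inner` and the returned radius is proportional to the
#' value, i.e. `r = sqrt(r_inner^2 + (r_max^2 - r_inner^2) * v / v_ref)`.
#' Both modes map 0 to `r_inner` and `v_ref` to `r_max` and are monotone
#' non-decreasing in `v`. Values above `v_ref` are clamped with a warning.
#'
#' @param v non-negative value(s), already on the geometry (scaled) scale.
#' @param v_ref positive reference maximum that maps to `r_max`.
#' @param cfg a [chart_config()] providing `radius_mode`, `r_inner`, `r_max`.
#' @return radius (vectorised over `v`) in `[r_inner, r_max]`.
#' @export
value_to_radius <- function(v, v_ref, cfg) {
  if (!is.numeric(v_ref) || length(v_ref) != 1L || v_ref <= 0) {
    stop("value_to_radius: v_ref must be a single positive number",
         call. = FALSE)
  }
  if (any(v < 0)) stop("value_to_radius: v must be >= 0", call. = FALSE)
  if (any(v > v_ref)) {
    warning("value_to_radius: value(s) above v_ref clamped to v_ref")
    v <- pmin(v, v_ref)
  }
  frac <- v / v_ref
  if (cfg$radius_mode == "linear") {
    cfg$r_inner + (cfg$r_max - cfg$r_inner) * frac
  } else {
    sqrt(cfg$r_inner^2 + (cfg$r_max^2 - cfg$r_inner^2) * frac)
  }
}

new_chart_model <- function(kind, petals, cfg, data, v_ref) {
  structure(
    list(kind = kind, petals = petals, labels = NULL, legend = NULL,
         center_text = "", config = cfg, data = data, v_ref = v_ref),
    class = "chart_model"
  )
}

#' @export
print.chart_model <- function(x, ...) {
  cat(sprintf("<chart_model: %s, %d petals, %d labels, v_ref = %g>\n",
              x$kind, nrow(x$petals),
              if (is.null(x$labels)) 0L else nrow(x$labels), x$v_ref))
  invisible(x)
}

#' Compute the flat multidimensional rose layout
#'
#' Attributes occupy contiguous sections of [section_angle()] degrees each,
#' in column order; within a section, categories occupy [petal_angle()]
#' slots in row order. Every petal's outer radius encodes its (scaled) value
#' against a single reference maximum -- the largest scaled value in the
#' whole table -- so petal sizes are comparable across sections. Angles in
#' the returned geometry are measured from the configured start angle,
#' increasing in the configured direction.
#'
#' @param m a [data_matrix()]; scale factors in `cfg` are applied internally
#'   and recorded per petal as `scaled_value` (the `value` column keeps the
#'   unscaled number).
#' @param cfg a [chart_config()] with `kind = "flat"`.
#' @return a `chart_model` with geometry only (fills unresolved); pass it to
#'   [resolve_colors()] and [place_labels()] or use [rose_chart()].
#' @export
compute_flat_layout <- function(m, cfg) {
  validate_data_matrix(m)
  stopifnot(inherits(cfg, "chart_config"))
  if (cfg$kind != "flat") {
    stop("compute_flat_layout: cfg$kind must be 'flat'", call. = FALSE)
  }
  scaled <- apply_scale_factors(m, cfg$scale_factors)
  n_cat <- length(m$categories); n_attr <- length(m$attributes)
  pa <- petal_angle(n_attr, n_cat)
  v_ref <- max(scaled$values)
  if (v_ref <= 0) v_ref <- 1  # all-zero table: every petal collapses to r_inner
  g2 <- min(cfg$gap_deg, pa) / 2
  idx <- expand.grid(category_index = seq_len(n_cat),
                     attribute_index = seq_len(n_attr))
  slot0 <- (idx$attribute_index - 1L) * n_cat + (idx$category_index - 1L)
  petals <- data.frame(
    attribute_index = idx$attribute_index,
    category_index = idx$category_index,
    layer_index = 0L,
    attribute = m$attributes[idx$attribute_index],
    category = m$categories[idx$category_index],
    theta_start_deg = slot0 * pa + g2,
    theta_end_deg = (slot0 + 1) * pa - g2,
    r_inner = cfg$r_inner,
    r_outer = value_to_radius(
      scaled$values[cbind(idx$category_index, idx$attribute_index)],
      v_ref, cfg),
    value = m$values[cbind(idx$category_index, idx$attribute_index)],
    scaled_value = scaled$values[cbind(idx$category_index, idx$attribute_index)],
    fill = NA_character_,
    stringsAsFactors = FALSE
  )
  model <- new_chart_model("flat", petals, cfg, m, v_ref)
  if (cfg$sort != "none") {
    model <- sort_petals(model, cfg$sort, cfg$sort_key)
  }
  model
}

#' Compute the stacked multidimensional rose layout
#'
#' One petal per category, spanning `360 / n_cat` degrees; within a petal the
#' attributes form radial layers from the centre outward in `layer_order`.
#' Layer radii are cumulative: layer k runs from the radius encoding the sum
#' of the first k-1 layer values to the radius encoding the sum of the first
#' k, so under `radius_mode = "linear"` each layer's thickness is
#' proportional to its value and under `"area"` each layer's annular area
#' is. The reference maximum is the largest per-category sum of scaled
#' values, so the tallest stacked petal reaches `r_max`.
#'
#' @inheritParams compute_flat_layout
#' @param cfg a [chart_config()] with `kind = "stacked"`.
#' @return a `chart_model` (geometry only).
#' @export
compute_stacked_layout <- function(m, cfg) {
  validate_data_matrix(m)
  stopifnot(inherits(cfg, "chart_config"))
  if (cfg$kind != "stacked") {
    stop("compute_stacked_layout: cfg$kind must be 'stacked'", call. = FALSE)
  }
  layer_order <- cfg$layer_order
  if (is.null(layer_order)) layer_order <- m$attributes
  if (!identical(sort(layer_order), sort(m$attributes)) ||
      length(layer_order) != length(m$attributes)) {
    stop("compute_stacked_layout: layer_order must be a permutation of the attributes",
         call. = FALSE)
  }
  scaled <- apply_scale_factors(m, cfg$scale_factors)
  n_cat <- length(m$categories); n_attr <- length(m$attributes)
  span <- 360 / n_cat
  totals <- rowSums(scaled$values[, layer_order, drop = FALSE])
  v_ref <- max(totals)
  if (v_ref <= 0) v_ref <- 1
  g2 <- min(cfg$gap_deg, span) / 2
  rows <- vector("list", n_cat)
  for (ci in seq_len(n_cat)) {
    vals_scaled <- scaled$values[ci, layer_order]
    vals_raw <- m$values[ci, layer_order]
    cum <- cumsum(vals_scaled)
    radii <- value_to_radius(c(0, cum), v_ref, cfg)
    rows[[ci]] <- data.frame(
      attribute_index = match(layer_order, m$attributes),
      category_index = ci,
      layer_index = seq_len(n_attr) - 1L,
      attribute = layer_order,
      category = m$categories[ci],
      theta_start_deg = (ci - 1) * span + g2,
      theta_end_deg = ci * span - g2,
      r_inner = radii[-length(radii)],
      r_outer = radii[-1L],
      value = unname(vals_raw),
      scaled_value = unname(vals_scaled),
      fill = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  petals <- do.call(rbind, rows)
  rownames(petals) <- NULL
  model <- new_chart_model("stacked", petals, cfg, m, v_ref)
  if (cfg$sort != "none") {
    model <- sort_petals(model, cfg$sort, cfg$sort_key)
  }
  model
}

#' Re-order petals by value
#'
#' Permutes which category occupies which angular slot; the slot boundaries
#' themselves never move. For a flat chart each attribute section is sorted
#' independently by its own values; for a stacked chart whole petals are
#' re-ordered by the key attribute's value (or the layer sum for
#' `key = "total"`). `"clockwise"` places the largest value first along the
#' rotation direction, `"counterclockwise"` the smallest. Ties keep the
#' original row order (stable sort), and sorting an already-sorted model is
#' a no-op.
#'
#' @param model a `chart_model`.
#' @param sort `"none"`, `"clockwise"` or `"counterclockwise"`.
#' @param key attribute name or `"total"`; only consulted for stacked
#'   models (default `"total"`).
#' @return the model with permuted petal angles.
#' @export
sort_petals <- function(model, sort = c("clockwise", "counterclockwise", "none"),
                        key = NULL) {
  stopifnot(inherits(model, "chart_model"))
  sort <- match.arg(sort)
  if (sort == "none") return(model)
  decreasing <- sort == "clockwise"
  p <- model$petals
  if (model$kind == "flat") {
    for (ai in unique(p$attribute_index)) {
      sel <- which(p$attribute_index == ai)
      sec <- p[sel, ]
      slots <- sec[order(sec$theta_start_deg), c("theta_start_deg", "theta_end_deg")]
      ord <- order(if (decreasing) -sec$value else sec$value,
                   sec$category_index)
      p[sel[ord], c("theta_start_deg", "theta_end_deg")] <- slots
    }
  } else {
    if (is.null(key)) key <- "total"
    keyvals <- stacked_key_values(model, key)
    cats <- sort(unique(p$category_index))
    slot_theta <- t(vapply(cats, function(ci) {
      r <- p[p$category_index == ci, ][1L, ]
      c(r$theta_start_deg, r$theta_end_deg)
    }, numeric(2)))
    slot_order <- order(slot_theta[, 1L])
    ord <- order(if (decreasing) -keyvals[cats] else keyvals[cats], cats)
    for (k in seq_along(cats)) {
      ci <- cats[ord[k]]
      slot <- slot_order[k]
      sel <- p$category_index == ci
      p$theta_start_deg[sel] <- slot_theta[slot, 1L]
      p$theta_end_deg[sel] <- slot_theta[slot, 2L]
    }
  }
  model$petals <- p[order(p$theta_start_deg, p$layer_index), ]
  rownames(model$petals) <- NULL
  model
}

stacked_key_values <- function(model, key) {
  p <- model$petals
  cats <- sort(unique(p$category_index))
  if (identical(key, "total")) {
    vapply(cats, function(ci) sum(p$value[p$category_index == ci]), 0)
  } else {
    if (!key %in% p$attribute) {
      stop("sort_petals: unknown sort key '", key, "'", call. = FALSE)
    }
    vapply(cats, function(ci) {
      p$value[p$category_index == ci & p$attribute == key]
    }, 0)
  }
}

#' Area of an annular-sector petal
#'
#' `(delta_theta_radians / 2) * (r_outer^2 - r_inner^2)`. Under area-true
#' encoding with `r_inner = 0`, petal areas of equal angular span are
#' proportional to their values.
#'
#' @param p one or more petal rows from a `chart_model`'s `petals` data
#'   frame (needs columns `theta_start_deg`, `theta_end_deg`, `r_inner`,
#'   `r_outer`).
#' @return numeric vector of areas in squared chart units.
#' @export
petal_area <- function(p) {
  dtheta <- (p$theta_end_deg - p$theta_start_deg) * pi / 180
  (dtheta / 2) * (p$r_outer^2 - p$r_inner^2)
}
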
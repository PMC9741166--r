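#' Built-in colour anchors
#'
#' The `"paper"` palette follows the conventional reading of the four case
#' hues -- red for death rates, yellow for infection rates, blue for
#' vaccination rates, green for complete vaccination rates -- with a
#' documented extension list for tables with more attributes. The exact hex
#' values are conventional anchors, not measured from any figure.
#'
#' @format named list of character vectors of hex colours.
#' @export
rose_palettes <- list(
  paper = c(red = "#D32F2F", yellow = "#F9A825", blue = "#1976D2",
            green = "#388E3C", purple = "#7B1FA2", orange = "#E64A19",
            cyan = "#0097A7", magenta = "#C2185B", brown = "#5D4037",
            grey = "#616161")
)

#' Assign a base hue to each attribute
#'
#' Deterministic positional assignment: the i-th attribute gets the i-th
#' palette entry. The default palette starts red, yellow, blue, green.
#'
#' @param attributes character vector of attribute names.
#' @param palette `NULL` (default palette), the name of a palette in
#'   [rose_palettes], or a character vector of hex anchors with at least as
#'   many entries as attributes.
#' @return named character vector, `attribute = hex anchor`.
#' @examples
#' assign_palette(c("Death Rate", "Infection Rate"))
#' @export
assign_palette <- function(attributes, palette = NULL) {
  stopifnot(is.character(attributes), length(attributes) >= 1L)
  if (is.null(palette)) {
    palette <- rose_palettes$paper
  } else if (length(palette) == 1L && palette %in% names(rose_palettes)) {
    palette <- rose_palettes[[palette]]
  }
  palette <- unname(unlist(palette))
  if (length(palette) < length(attributes)) {
    stop(sprintf("assign_palette: palette has %d colours but %d attributes need one each",
                 length(palette), length(attributes)), call. = FALSE)
  }
  if (any(!grepl("^#[0-9A-Fa-f]{6}$", palette[seq_along(attributes)]))) {
    stop("assign_palette: palette entries must be 6-digit hex colours",
         call. = FALSE)
  }
  stats::setNames(toupper(palette[seq_along(attributes)]), attributes)
}

#' Shade a hue by value
#'
#' Implements "the smaller the value, the lighter the colour": hue and
#' saturation are taken from the attribute's anchor colour, and lightness is
#' interpolated linearly (in HSL space) from `light` at the attribute
#' minimum down to `dark` at the attribute maximum. A constant column
#' (v_min = v_max) gets the midpoint lightness. Equal values always resolve
#' to identical hex strings.
#'
#' @param v value(s) to shade, on the unscaled data scale.
#' @param v_min,v_max the attribute column's minimum and maximum;
#'   normalisation is per attribute, so shades are invariant under positive
#'   per-attribute rescaling.
#' @param anchor 6-digit hex anchor colour.
#' @param range lightness pair `c(light, dark)` in (0, 1), light > dark.
#' @return character vector of 6-digit hex colours.
#' @examples
#' shade_for_value(c(0, 5, 10), 0, 10, "#1976D2")
#' @export
shade_for_value <- function(v, v_min, v_max, anchor, range = c(0.85, 0.35)) {
  stopifnot(length(v_min) == 1L, length(v_max) == 1L, v_min <= v_max)
  if (any(v < v_min) || any(v > v_max)) {
    stop("shade_for_value: v outside [v_min, v_max]", call. = FALSE)
  }
  light <- range[1L]; dark <- range[2L]
  frac <- if (v_max == v_min) rep(0.5, length(v)) else (v - v_min) / (v_max - v_min)
  lightness <- light - (light - dark) * frac
  hsl <- farver::decode_colour(anchor, to = "hsl")
  out <- farver::encode_colour(
    cbind(h = rep(hsl[1L, "h"], length(v)),
          s = rep(hsl[1L, "s"], length(v)),
          l = lightness * 100),
    from = "hsl")
  toupper(out)
}

#' Resolve petal fill colours of a chart model
#'
#' Assigns the palette to the attributes and fills every petal with its
#' value-shaded hue; also records the legend (attribute, base colour).
#' Shading is normalised per attribute column on the unscaled values, so the
#' darkest petal of a section is always that attribute's maximum regardless
#' of any geometry scale factors.
#'
#' @param model a `chart_model` from [compute_flat_layout()] or
#'   [compute_stacked_layout()].
#' @return the model with `petals$fill` and `legend` populated.
#' @export
resolve_colors <- function(model) {
  stopifnot(inherits(model, "chart_model"))
  m <- model$data
  anchors <- assign_palette(m$attributes, model$config$palette)
  range <- model$config$lightness_range
  p <- model$petals
  for (ai in seq_along(m$attributes)) {
    col <- m$values[, ai]
    sel <- p$attribute_index == ai
    p$fill[sel] <- shade_for_value(p$value[sel], min(col), max(col),
                                   anchors[ai], range)
  }
  model$petals <- p
  model$legend <- data.frame(attribute = m$attributes,
                             color = unname(anchors),
                             stringsAsFactors = FALSE)
  model
}
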
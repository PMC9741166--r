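#' Chart configuration
#'
#' Collects every layout and encoding choice for a rose chart. Defaults
#' follow the conventional polar-area reading: area-true radii (radius grows
#' with the square root of the value), angle zero at 12 o'clock, clockwise
#' rotation, and a small central hole (the "stamen") reserved for detail
#' text.
#'
#' @param kind `"flat"` (one petal per category-attribute pair, attributes in
#'   contiguous angular sections) or `"stacked"` (one petal per category,
#'   attributes as radial layers).
#' @param radius_mode `"area"` makes each petal's annular area proportional
#'   to its value; `"linear"` makes the radial extent proportional instead.
#' @param r_max outer radius in abstract chart units.
#' @param r_inner radius of the central hole; must be `< r_max`. The default
#'   `0.12 * r_max` leaves room for the centre text; 0 is allowed.
#' @param scale_factors named positive multipliers applied per attribute
#'   before layout (see [apply_scale_factors()]); labels always show
#'   unscaled values.
#' @param sort `"none"`, `"clockwise"` (descending along the rotation
#'   direction) or `"counterclockwise"` (ascending).
#' @param sort_key attribute name, or `"total"` for the per-category sum
#'   (stacked charts).
#' @param start_angle_deg angle of the first petal edge, degrees from
#'   12 o'clock.
#' @param direction `"cw"` or `"ccw"`; the sense in which petal angles grow.
#' @param layer_order for stacked charts, a permutation of the attribute
#'   names giving the order of layers from the centre outward; `NULL` keeps
#'   column order.
#' @param palette character vector of hex colour anchors, one per attribute
#'   (extra entries ignored), or a palette name understood by
#'   [assign_palette()]. `NULL` uses the default palette.
#' @param lightness_range numeric pair `c(light, dark)`, both in (0, 1) with
#'   `light > dark`: the lightness assigned to an attribute's smallest and
#'   largest value respectively.
#' @param gap_deg angular gap inserted between adjacent petals, purely
#'   cosmetic; the default 0 tiles the full circle.
#' @param label_decimals decimal places in printed labels.
#' @param label_suffix unit string appended to labels, default `"%"`.
#' @param center_detail optional `c(category, attribute)` pair; when given,
#'   the chart's centre shows that cell's value (see
#'   [format_center_detail()]).
#' @return an object of class `chart_config`.
#' @export
chart_config <- function(kind = c("flat", "stacked"),
                         radius_mode = c("area", "linear"),
                         r_max = 1,
                         r_inner = 0.12 * r_max,
                         scale_factors = NULL,
                         sort = c("none", "clockwise", "counterclockwise"),
                         sort_key = NULL,
                         start_angle_deg = 0,
                         direction = c("cw", "ccw"),
                         layer_order = NULL,
                         palette = NULL,
                         lightness_range = c(0.85, 0.35),
                         gap_deg = 0,
                         label_decimals = 2L,
                         label_suffix = "%",
                         center_detail = NULL) {
  kind <- match.arg(kind)
  radius_mode <- match.arg(radius_mode)
  sort <- match.arg(sort)
  direction <- match.arg(direction)
  stopifnot(is.numeric(r_max), length(r_max) == 1L, r_max > 0)
  stopifnot(is.numeric(r_inner), length(r_inner) == 1L, r_inner >= 0)
  if (r_inner >= r_max) {
    stop("chart_config: r_inner must be < r_max", call. = FALSE)
  }
  if (!is.null(scale_factors)) {
    scale_factors <- unlist(scale_factors)
    if (any(!is.finite(scale_factors) | scale_factors <= 0)) {
      stop("chart_config: scale_factors must be > 0", call. = FALSE)
    }
  }
  stopifnot(length(lightness_range) == 2L)
  light <- lightness_range[1L]; dark <- lightness_range[2L]
  if (!(dark > 0 && dark < light && light < 1)) {
    stop("chart_config: need 0 < dark < light < 1 in lightness_range",
         call. = FALSE)
  }
  stopifnot(is.numeric(gap_deg), gap_deg >= 0, gap_deg < 360)
  label_decimals <- as.integer(label_decimals)
  stopifnot(label_decimals >= 0L)
  if (!is.null(center_detail) && length(center_detail) != 2L) {
    stop("chart_config: center_detail must be c(category, attribute)",
         call. = FALSE)
  }
  structure(
    list(kind = kind, radius_mode = radius_mode, r_max = r_max,
         r_inner = r_inner, scale_factors = scale_factors, sort = sort,
         sort_key = sort_key, start_angle_deg = start_angle_deg,
         direction = direction, layer_order = layer_order,
         palette = palette, lightness_range = c(light, dark),
         gap_deg = gap_deg, label_decimals = label_decimals,
         label_suffix = label_suffix, center_detail = center_detail),
    class = "chart_config"
  )
}

#' @export
print.chart_config <- function(x, ...) {
  cat(sprintf("<chart_config: %s, %s radii, r %g..%g, sort %s, %s>\n",
              x$kind, x$radius_mode, x$r_inner, x$r_max, x$sort, x$direction))
  invisible(x)
}
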
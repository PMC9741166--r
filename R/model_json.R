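#' Serialise a chart model to JSON
#'
#' The renderer-independent export: petal geometry (angles in degrees from
#' the start angle, radii in chart units), resolved fills, labels with
#' anchors, legend and configuration. This is the integration point for
#' external (e.g. interactive) front ends.
#'
#' @param model a `chart_model`.
#' @return a JSON string.
#' @export
chart_model_json <- function(model) {
  stopifnot(inherits(model, "chart_model"))
  cfg <- model$config
  obj <- list(
    kind = model$kind,
    v_ref = model$v_ref,
    config = list(
      radius_mode = cfg$radius_mode, r_max = cfg$r_max,
      r_inner = cfg$r_inner, start_angle_deg = cfg$start_angle_deg,
      direction = cfg$direction, sort = cfg$sort, gap_deg = cfg$gap_deg,
      lightness_range = cfg$lightness_range
    ),
    petals = model$petals,
    labels = if (is.null(model$labels)) list() else model$labels,
    legend = if (is.null(model$legend)) list() else model$legend,
    center_text = model$center_text
  )
  as.character(jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                                digits = NA, null = "null"))
}

#' Write the chart model JSON to a file
#'
#' @param model a `chart_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chart_model <- function(model, path) {
  writeLines(chart_model_json(model), path, useBytes = TRUE)
  invisible(path)
}

#' Build a complete rose chart model
#'
#' The one-call pipeline: layout (flat or stacked per the config), colour
#' resolution, extreme-value label selection and placement, and the centre
#' detail text. Returns a fully resolved `chart_model` ready for
#' [render_svg()] or [chart_model_json()].
#'
#' @param m a [data_matrix()].
#' @param cfg a [chart_config()].
#' @param labels `"extremes"` (annotate each attribute's maximum and
#'   minimum) or `"none"`.
#' @return a resolved `chart_model`.
#' @examples
#' model <- rose_chart(covid_fixture(), chart_config(kind = "stacked"))
#' nrow(model$petals)  # 24 layers in 6 petals
#' @export
rose_chart <- function(m, cfg = chart_config(), labels = c("extremes", "none")) {
  labels <- match.arg(labels)
  model <- if (cfg$kind == "flat") {
    compute_flat_layout(m, cfg)
  } else {
    compute_stacked_layout(m, cfg)
  }
  model <- resolve_colors(model)
  if (labels == "extremes") {
    sel <- select_extreme_labels(m, cfg$label_decimals, cfg$label_suffix)
    model$labels <- place_labels(sel, model)
  }
  if (!is.null(cfg$center_detail)) {
    model$center_text <- format_center_detail(cfg$center_detail[1L],
                                              cfg$center_detail[2L], m, cfg)
  }
  model
}
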
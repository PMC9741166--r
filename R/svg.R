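#' Rendering options
#'
#' @param canvas_px square canvas side in pixels.
#' @param margin_px margin kept free around the chart.
#' @param font_family,font_size_px label typography.
#' @param background canvas background as hex colour, or `"none"`.
#' @return an object of class `render_options`.
#' @export
render_options <- function(canvas_px = 640L, margin_px = 40L,
                           font_family = "sans-serif", font_size_px = 12,
                           background = "none") {
  canvas_px <- as.numeric(canvas_px); margin_px <- as.numeric(margin_px)
  stopifnot(canvas_px > 0, margin_px >= 0)
  if (canvas_px <= 2 * margin_px) {
    stop("render_options: canvas_px must exceed 2 * margin_px", call. = FALSE)
  }
  structure(list(canvas_px = canvas_px, margin_px = margin_px,
                 font_family = font_family, font_size_px = font_size_px,
                 background = background),
            class = "render_options")
}

# fixed 4-decimal coordinate formatting => byte-stable output
fmt4 <- function(x) {
  x[abs(x) < 5e-5] <- 0  # avoid "-0.0000"
  sprintf("%.4f", x)
}

# screen position of polar point: angle measured from north, clockwise
# positive on a y-down canvas: x = cx + r sin(theta), y = cy - r cos(theta)
polar_xy <- function(theta_deg, r, cx, cy) {
  a <- theta_deg * pi / 180
  list(x = cx + r * sin(a), y = cy - r * cos(a))
}

# absolute screen angle of a model angle under the config's start/direction
screen_angle <- function(theta_deg, cfg) {
  sgn <- if (cfg$direction == "cw") 1 else -1
  cfg$start_angle_deg + sgn * theta_deg
}

#' SVG path for one petal
#'
#' Builds the closed annular-sector path: outer arc forward, radial line
#' inward, inner arc back, close. With `r_inner = 0` the inner arc
#' degenerates to the centre point. A full 360-degree petal is drawn as two
#' 180-degree arcs because a single SVG arc cannot span the full circle.
#' Angles here are absolute screen angles (degrees from north, clockwise
#' positive); the mapping to canvas coordinates is
#' `x = cx + r * sin(theta)`, `y = cy - r * cos(theta)`.
#'
#' @param theta_start_deg,theta_end_deg absolute screen angles,
#'   `theta_end_deg >= theta_start_deg`.
#' @param r_inner,r_outer radii in canvas pixels.
#' @param cx,cy canvas centre in pixels.
#' @return the `d` attribute string, or `""` (with a warning) for a
#'   zero-span petal.
#' @export
petal_path <- function(theta_start_deg, theta_end_deg, r_inner, r_outer,
                       cx, cy) {
  span <- theta_end_deg - theta_start_deg
  if (span <= 0) {
    warning("petal_path: degenerate petal with zero angular span")
    return("")
  }
  arc_points <- function(r) {
    # split spans > 180 into two arcs (SVG large-arc alone cannot do 360)
    if (span > 180) {
      mids <- theta_start_deg + span / 2
      thetas <- c(theta_start_deg, mids, theta_end_deg)
    } else {
      thetas <- c(theta_start_deg, theta_end_deg)
    }
    lapply(thetas, polar_xy, r = r, cx = cx, cy = cy)
  }
  arc_cmd <- function(pts, r, sweep) {
    # pts in draw order; one A command per segment
    paste(vapply(seq_len(length(pts) - 1L), function(i) {
      sprintf("A %s %s 0 0 %d %s %s", fmt4(r), fmt4(r), sweep,
              fmt4(pts[[i + 1L]]$x), fmt4(pts[[i + 1L]]$y))
    }, ""), collapse = " ")
  }
  outer <- arc_points(r_outer)
  d <- sprintf("M %s %s %s", fmt4(outer[[1L]]$x), fmt4(outer[[1L]]$y),
               arc_cmd(outer, r_outer, 1L))
  if (r_inner > 0) {
    inner <- rev(arc_points(r_inner))
    d <- sprintf("%s L %s %s %s Z", d,
                 fmt4(inner[[1L]]$x), fmt4(inner[[1L]]$y),
                 arc_cmd(inner, r_inner, 0L))
  } else {
    d <- sprintf("%s L %s %s Z", d, fmt4(cx), fmt4(cy))
  }
  d
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Render a chart model to a standalone SVG document
#'
#' Deterministic rendering: stable element ordering, coordinates formatted
#' at 4 decimals, no timestamps or generated ids, so identical models
#' produce byte-identical documents. The document contains one `<path>` per
#' petal (stacked petals grouped per category), one `<text>` per placed
#' label, one legend entry per attribute and a centre text group; the chart
#' model JSON is embedded in a `<metadata>` block for provenance.
#'
#' @param model a `chart_model` with resolved fills (see [resolve_colors()]
#'   or [rose_chart()]); unresolved fills are drawn grey.
#' @param opts a [render_options()].
#' @return the SVG document as a single character string.
#' @examples
#' svg <- render_svg(rose_chart(covid_fixture()))
#' substr(svg, 1, 60)
#' @export
render_svg <- function(model, opts = render_options()) {
  stopifnot(inherits(model, "chart_model"), inherits(opts, "render_options"))
  if (is.null(model$petals) || nrow(model$petals) == 0L) {
    stop("render_svg: model has no petals", call. = FALSE)
  }
  cfg <- model$config
  side <- opts$canvas_px
  cx <- side / 2; cy <- side / 2
  scale <- (side / 2 - opts$margin_px) / cfg$r_max
  px <- function(r) r * scale
  p <- model$petals
  p$fill[is.na(p$fill)] <- "#BDBDBD"

  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%s\" ",
                   "height=\"%s\" viewBox=\"0 0 %s %s\">"),
            fmt4(side), fmt4(side), fmt4(side), fmt4(side)),
    sprintf("<metadata id=\"chart-model\">%s</metadata>",
            xml_escape(chart_model_json(model)))
  )
  if (!identical(opts$background, "none")) {
    out <- c(out, sprintf("<rect width=\"%s\" height=\"%s\" fill=\"%s\"/>",
                          fmt4(side), fmt4(side), opts$background))
  }

  petal_elem <- function(row) {
    t0 <- screen_angle(row$theta_start_deg, cfg)
    t1 <- screen_angle(row$theta_end_deg, cfg)
    d <- petal_path(min(t0, t1), max(t0, t1), px(row$r_inner),
                    px(row$r_outer), cx, cy)
    sprintf(paste0("<path class=\"petal\" d=\"%s\" fill=\"%s\" ",
                   "stroke=\"#FFFFFF\" stroke-width=\"1\"/>"), d, row$fill)
  }
  out <- c(out, "<g class=\"petals\">")
  if (model$kind == "stacked") {
    for (ci in unique(p$category_index)) {
      sub <- p[p$category_index == ci, ]
      sub <- sub[order(sub$layer_index), ]
      out <- c(out,
               sprintf("<g class=\"petal-group\" data-category=\"%s\">",
                       xml_escape(sub$category[1L])),
               vapply(seq_len(nrow(sub)),
                      function(i) petal_elem(sub[i, ]), ""),
               "</g>")
    }
  } else {
    out <- c(out, vapply(seq_len(nrow(p)), function(i) petal_elem(p[i, ]), ""))
  }
  out <- c(out, "</g>")

  # labels
  out <- c(out, "<g class=\"labels\">")
  if (!is.null(model$labels) && nrow(model$labels) > 0L) {
    lab <- model$labels
    for (i in seq_len(nrow(lab))) {
      pos <- polar_xy(screen_angle(lab$anchor_theta_deg[i], cfg),
                      px(lab$anchor_r[i]), cx, cy)
      out <- c(out, sprintf(
        paste0("<text class=\"label label-%s\" x=\"%s\" y=\"%s\" ",
               "text-anchor=\"middle\" font-family=\"%s\" ",
               "font-size=\"%s\">%s</text>"),
        lab$kind[i], fmt4(pos$x), fmt4(pos$y), xml_escape(opts$font_family),
        fmt4(opts$font_size_px), xml_escape(lab$text[i])))
    }
  }
  out <- c(out, "</g>")

  # legend: one swatch + text per attribute, top-left column
  out <- c(out, "<g class=\"legend\">")
  if (!is.null(model$legend)) {
    for (i in seq_len(nrow(model$legend))) {
      y <- opts$margin_px / 2 + (i - 1) * (opts$font_size_px + 6)
      out <- c(out, sprintf(
        "<rect class=\"legend-swatch\" x=\"4\" y=\"%s\" width=\"%s\" height=\"%s\" fill=\"%s\"/>",
        fmt4(y), fmt4(opts$font_size_px), fmt4(opts$font_size_px),
        model$legend$color[i]))
      out <- c(out, sprintf(
        paste0("<text class=\"legend-label\" x=\"%s\" y=\"%s\" ",
               "font-family=\"%s\" font-size=\"%s\">%s</text>"),
        fmt4(8 + opts$font_size_px), fmt4(y + opts$font_size_px - 2),
        xml_escape(opts$font_family), fmt4(opts$font_size_px),
        xml_escape(model$legend$attribute[i])))
    }
  }
  out <- c(out, "</g>")

  # centre ("stamen") text, one <text> per line
  out <- c(out, "<g class=\"center\">")
  if (nzchar(model$center_text)) {
    lines <- strsplit(model$center_text, "\n", fixed = TRUE)[[1L]]
    for (i in seq_along(lines)) {
      y <- cy + (i - (length(lines) + 1) / 2) * (opts$font_size_px + 2)
      out <- c(out, sprintf(
        paste0("<text class=\"center-line\" x=\"%s\" y=\"%s\" ",
               "text-anchor=\"middle\" font-family=\"%s\" ",
               "font-size=\"%s\">%s</text>"),
        fmt4(cx), fmt4(y), xml_escape(opts$font_family),
        fmt4(opts$font_size_px), xml_escape(lines[i])))
    }
  }
  out <- c(out, "</g>", "</svg>")
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Write an SVG document to a file
#'
#' @param svg string from [render_svg()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_svg <- function(svg, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(svg), con)
  invisible(path)
}
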
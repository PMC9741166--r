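#' Format a value for display
#'
#' Rounds half-even at `decimals` (the IEEE default used by [round()]) and
#' appends the suffix.
#' @param v numeric value(s).
#' @param decimals non-negative integer.
#' @param suffix unit string, e.g. `"%"`.
#' @return character vector.
#' @keywords internal
format_value <- function(v, decimals = 2L, suffix = "%") {
  paste0(formatC(round(v, decimals), format = "f", digits = decimals),
         suffix)
}

#' Select the extreme-value labels
#'
#' The occlusion remedy of the multidimensional rose chart: instead of
#' labelling every petal, only each attribute's maximum and minimum are
#' annotated. Ties are broken by the first occurrence in category order; a
#' constant column yields a single label of kind `"max"`.
#'
#' @param m a [data_matrix()].
#' @param decimals,suffix label formatting, see [format_value()].
#' @return data frame with one row per label: `attribute`, `category`,
#'   `kind` (`"max"`/`"min"`), `value` (unscaled) and `text`.
#' @examples
#' labs <- select_extreme_labels(covid_fixture())
#' subset(labs, attribute == "Death Rate")
#' @export
select_extreme_labels <- function(m, decimals = 2L, suffix = "%") {
  validate_data_matrix(m)
  rows <- lapply(seq_along(m$attributes), function(ai) {
    col <- m$values[, ai]
    i_max <- which.max(col)  # first occurrence on ties
    i_min <- which.min(col)
    d <- data.frame(
      attribute = m$attributes[ai],
      category = m$categories[c(i_max, i_min)],
      kind = c("max", "min"),
      value = unname(col[c(i_max, i_min)]),
      stringsAsFactors = FALSE
    )
    if (col[i_max] == col[i_min]) d <- d[1L, , drop = FALSE]
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$text <- format_value(out$value, decimals, suffix)
  out
}

#' Centre ("stamen") detail text
#'
#' The chart centre shows one selected cell in full: the attribute with its
#' formatted unscaled value on the first line and the category on the
#' second. This is the static counterpart of the hover detail of an
#' interactive rose chart.
#'
#' @param category,attribute the cell to describe.
#' @param m a [data_matrix()].
#' @param cfg a [chart_config()] (supplies `label_decimals`,
#'   `label_suffix`).
#' @return a two-line string, lines separated by `"\n"`.
#' @examples
#' format_center_detail("USA", "Death Rate", covid_fixture(), chart_config())
#' @export
format_center_detail <- function(category, attribute, m, cfg = chart_config()) {
  v <- value_at(m, category, attribute)
  paste0(attribute, ": ",
         format_value(v, cfg$label_decimals, cfg$label_suffix),
         "\n", category)
}

#' Place labels around the chart
#'
#' Each label anchors at the mid-angle of its petal, just outside the
#' petal's outer radius. When two anchors fall closer than a minimum angular
#' separation, the later one (in attribute-then-kind order) is pushed
#' outward radially by one step per earlier neighbour -- a deterministic
#' rule; the chart's principal defence against occlusion is label
#' *reduction*, not a general overlap solver.
#'
#' @param labels data frame from [select_extreme_labels()].
#' @param model a `chart_model` whose petals the labels refer to.
#' @param offset radial gap between `r_outer` and the anchor, chart units.
#' @param min_sep_deg anchors closer than this (circular distance) collide.
#' @param step radial push-out per collision, chart units.
#' @return `labels` with `anchor_theta_deg` and `anchor_r` columns added.
#' @export
place_labels <- function(labels, model, offset = 0.05 * model$config$r_max,
                         min_sep_deg = 10, step = 0.07 * model$config$r_max) {
  stopifnot(inherits(model, "chart_model"))
  p <- model$petals
  n <- nrow(labels)
  labels <- labels[order(match(labels$attribute, model$data$attributes),
                         match(labels$kind, c("max", "min"))), ,
                   drop = FALSE]
  rownames(labels) <- NULL
  theta <- numeric(n); r <- numeric(n)
  for (i in seq_len(n)) {
    sel <- which(p$attribute == labels$attribute[i] &
                 p$category == labels$category[i])
    if (length(sel) != 1L) {
      stop(sprintf("place_labels: no petal for (%s, %s)",
                   labels$category[i], labels$attribute[i]), call. = FALSE)
    }
    theta[i] <- (p$theta_start_deg[sel] + p$theta_end_deg[sel]) / 2
    r[i] <- p$r_outer[sel] + offset
    if (i > 1L) {
      dtheta <- abs(theta[seq_len(i - 1L)] - theta[i]) %% 360
      dtheta <- pmin(dtheta, 360 - dtheta)
      n_close <- sum(dtheta < min_sep_deg)
      r[i] <- r[i] + n_close * step
    }
  }
  labels$anchor_theta_deg <- theta
  labels$anchor_r <- r
  labels
}
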
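# Case-study table: four COVID-19 rates of change for six countries
# (cumulative, January 2020 - January 2022, WHO-derived).
covid_values <- matrix(
  c(1.18,  9.37, 75.28, 63.54,
    1.18,  5.67, 67.68, 50.95,
    2.48, 37.86, 79.59, 70.06,
    0.91,  3.92, 76.77, 71.02,
    0.69,  7.90, 79.79, 76.39,
    2.79,  4.63, 52.49, 47.85),
  nrow = 6, byrow = TRUE
)
covid_countries <- c("USA", "India", "Brazil", "UK", "France", "Russia")
covid_rates <- c("Death Rate", "Infection Rate", "Vaccination Rate",
                 "Complete Vaccination Rate")

#' COVID-19 rates case-study table
#'
#' The 6-country by 4-attribute table behind the case-study charts: death,
#' infection, vaccination and complete-vaccination rates (all percentages,
#' cumulative over January 2020 - January 2022). Death rate is cumulative
#' deaths over cumulative infections; infection rate is cumulative
#' infections over cumulative tests; the two vaccination rates are people
#' with at least one dose, respectively all doses, over population. Also
#' installed as `extdata/covid_rates.csv`.
#'
#' @return a 6 x 4 [data_matrix()], categories USA, India, Brazil, UK,
#'   France, Russia.
#' @examples
#' value_at(covid_fixture(), "Russia", "Vaccination Rate")  # 52.49
#' @export
covid_fixture <- function() {
  data_matrix(covid_values, covid_countries, covid_rates,
              units = stats::setNames(rep("%", 4L), covid_rates))
}

#' Chart-method comparison counts
#'
#' Advantage and disadvantage counts for six chart types (line, bar, tree,
#' parallel coordinates, Nightingale rose, multidimensional rose), obtained
#' by counting the enumerated pro/con items for each method. Rendering this
#' table as a stacked rose chart reproduces the methods-comparison figure.
#' Also installed as `extdata/chart_comparison_counts.csv`.
#'
#' @return a 6 x 2 [data_matrix()].
#' @examples
#' value_at(comparison_fixture(), "Multidimensional Rose", "Advantages")  # 4
#' @export
comparison_fixture <- function() {
  vals <- matrix(c(1, 2,
                   1, 2,
                   1, 3,
                   3, 2,
                   3, 3,
                   4, 2), nrow = 6, byrow = TRUE)
  data_matrix(vals,
              c("Line", "Bar", "Tree", "ParallelCoordinate",
                "Nightingale Rose", "Multidimensional Rose"),
              c("Advantages", "Disadvantages"))
}

#' Generate a synthetic value table
#'
#' Emulates case-study-shaped inputs for property testing and demos:
#' `n_cat` categories named `C1..Cn` by `n_attr` attributes named `A1..Am`,
#' with strictly non-negative values drawn from `value_range`. `"uniform"`
#' draws flat over the range; `"lognormal"` draws a right-skewed standard
#' log-normal, truncated at its 0.1% and 99.9% quantiles and rescaled into
#' the range, mimicking rate tables where a few cells dominate. Fixed seed
#' gives bit-identical output.
#'
#' @param n_cat,n_attr table dimensions (>= 1).
#' @param value_range numeric pair `c(low, high)`, `0 <= low < high`.
#' @param distribution `"uniform"` or `"lognormal"`.
#' @param seed optional integer seed.
#' @return a validated [data_matrix()].
#' @examples
#' generate_matrix(6, 4, seed = 7)
#' @export
generate_matrix <- function(n_cat, n_attr, value_range = c(0, 100),
                            distribution = c("uniform", "lognormal"),
                            seed = NULL) {
  distribution <- match.arg(distribution)
  stopifnot(n_cat >= 1, n_attr >= 1, length(value_range) == 2L)
  low <- value_range[1L]; high <- value_range[2L]
  if (!(low >= 0 && high > low)) {
    stop("generate_matrix: need 0 <= low < high in value_range",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- n_cat * n_attr
  vals <- if (distribution == "uniform") {
    stats::runif(n, low, high)
  } else {
    q <- stats::qlnorm(c(0.001, 0.999))
    x <- pmin(pmax(stats::rlnorm(n), q[1L]), q[2L])
    low + (high - low) * (x - q[1L]) / (q[2L] - q[1L])
  }
  data_matrix(matrix(vals, n_cat, n_attr),
              paste0("C", seq_len(n_cat)), paste0("A", seq_len(n_attr)))
}
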